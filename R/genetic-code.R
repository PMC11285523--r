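# Standard nuclear genetic code, codon indexing, and Nei-Gojobori lookup
# tables.  Everything downstream (simulator, counting estimators, pairwise ML,
# ancestral reconstruction) shares the 61-state sense-codon alphabet built
# here.  Tables are computed once per session and cached.

NUCS <- c("T", "C", "A", "G")

# amino acids in TCAG order, first codon position slowest
.AA64 <- strsplit(paste0(
  "FFLLSSSSYY**CC*W",
  "LLLLPPPPHHQQRRRR",
  "IIIMTTTTNNKKSSRR",
  "VVVVAAAADDEEGGGG"), "")[[1]]

.codon_cache <- new.env(parent = emptyenv())

#' Codon alphabet and Nei-Gojobori lookup tables
#'
#' Builds (and caches) the shared tables for the 61 sense codons of the
#' standard nuclear genetic code: single-nucleotide neighbourhoods with
#' transition/transversion and synonymous/non-synonymous annotation,
#' per-codon NG86 site counts, and path-averaged pairwise difference counts
#' for every ordered codon pair.
#'
#' @return A list with elements:
#'   \item{codons}{character(61), sense codons}
#'   \item{aa}{character(61), encoded amino acids}
#'   \item{index}{named integer(64): codon string -> 1..61, NA for stops}
#'   \item{nb_target}{61 x 9 integer matrix; columns are the 9 single-nucleotide
#'     neighbours (position-major); NA where the neighbour is a stop codon}
#'   \item{nb_pos, nb_ts, nb_syn}{companion 61 x 9 matrices: mutated position,
#'     transition flag, synonymous flag}
#'   \item{n_sites, s_sites}{numeric(61): NG86 non-synonymous / synonymous
#'     site counts per codon (n + s = 3)}
#'   \item{Nd, Sd}{61 x 61 path-averaged non-synonymous / synonymous
#'     difference counts; NA where no stop-free mutational path exists}
#' @keywords internal
codon_tables <- function() {
  if (!is.null(.codon_cache$tab)) return(.codon_cache$tab)

  codons64 <- paste0(rep(NUCS, each = 16),
                     rep(rep(NUCS, each = 4), 4),
                     rep(NUCS, 16))
  sense <- .AA64 != "*"
  codons <- codons64[sense]
  aa <- .AA64[sense]
  ncod <- length(codons)   # 61
  index <- rep(NA_integer_, 64)
  names(index) <- codons64
  index[codons] <- seq_len(ncod)

  aa64 <- .AA64
  names(aa64) <- codons64

  is_transition <- function(a, b) {
    (a %in% c("A", "G") && b %in% c("A", "G")) ||
      (a %in% c("C", "T") && b %in% c("C", "T"))
  }

  nb_target <- matrix(NA_integer_, ncod, 9)
  nb_pos <- matrix(NA_integer_, ncod, 9)
  nb_ts <- matrix(NA, ncod, 9)
  nb_syn <- matrix(NA, ncod, 9)
  n_sites <- numeric(ncod)
  s_sites <- numeric(ncod)

  for (i in seq_len(ncod)) {
    cod <- strsplit(codons[i], "")[[1]]
    col <- 0L
    s_i <- 0
    for (pos in 1:3) {
      syn_cnt <- 0L
      valid_cnt <- 0L
      for (nuc in setdiff(NUCS, cod[pos])) {
        col <- col + 1L
        mut <- cod
        mut[pos] <- nuc
        mutstr <- paste(mut, collapse = "")
        nb_pos[i, col] <- pos
        nb_ts[i, col] <- is_transition(cod[pos], nuc)
        if (aa64[mutstr] == "*") {
          # stop neighbour: excluded from the site-count denominator at this
          # position and unreachable as a mutational target
          next
        }
        valid_cnt <- valid_cnt + 1L
        nb_target[i, col] <- index[mutstr]
        nb_syn[i, col] <- aa64[mutstr] == aa[i]
        if (nb_syn[i, col]) syn_cnt <- syn_cnt + 1L
      }
      if (valid_cnt > 0L) s_i <- s_i + syn_cnt / valid_cnt
    }
    s_sites[i] <- s_i
    n_sites[i] <- 3 - s_i
  }

  # path-averaged pairwise difference counts (NG86): for codons differing at
  # k positions, average synonymous/non-synonymous step counts over the k!
  # orderings whose intermediates are all sense codons
  Nd <- matrix(0, ncod, ncod)
  Sd <- matrix(0, ncod, ncod)
  perms <- list(matrix(1L, 1, 1),
                rbind(c(1L, 2L), c(2L, 1L)),
                rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                      c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  for (i in seq_len(ncod)) {
    ci <- strsplit(codons[i], "")[[1]]
    for (j in seq_len(ncod)) {
      if (i == j) next
      cj <- strsplit(codons[j], "")[[1]]
      dpos <- which(ci != cj)
      k <- length(dpos)
      ords <- perms[[k]]
      nd_tot <- 0; sd_tot <- 0; npaths <- 0L
      for (r in seq_len(nrow(ords))) {
        cur <- ci
        nd <- 0L; sd <- 0L
        ok <- TRUE
        for (step in dpos[ords[r, ]]) {
          nxt <- cur
          nxt[step] <- cj[step]
          nxtstr <- paste(nxt, collapse = "")
          if (aa64[nxtstr] == "*") { ok <- FALSE; break }
          if (aa64[nxtstr] == aa64[paste(cur, collapse = "")]) {
            sd <- sd + 1L
          } else {
            nd <- nd + 1L
          }
          cur <- nxt
        }
        if (ok) {
          nd_tot <- nd_tot + nd
          sd_tot <- sd_tot + sd
          npaths <- npaths + 1L
        }
      }
      if (npaths == 0L) {
        Nd[i, j] <- NA_real_
        Sd[i, j] <- NA_real_
      } else {
        Nd[i, j] <- nd_tot / npaths
        Sd[i, j] <- sd_tot / npaths
      }
    }
  }

  tab <- list(codons = codons, aa = aa, index = index,
              nb_target = nb_target, nb_pos = nb_pos,
              nb_ts = nb_ts, nb_syn = nb_syn,
              n_sites = n_sites, s_sites = s_sites,
              Nd = Nd, Sd = Sd)
  .codon_cache$tab <- tab
  tab
}

#' Split aligned sequences into codon index matrices
#'
#' @param seqs named character vector of equal-length, in-frame DNA strings.
#' @return integer matrix (n_codons x n_seqs) of sense-codon indices; NA for
#'   codons containing ambiguity characters (anything outside ACGT) or stops.
#' @keywords internal
codon_index_matrix <- function(seqs) {
  tab <- codon_tables()
  len <- unique(nchar(seqs))
  if (length(len) != 1L)
    stop("sequences are not aligned: unequal lengths")
  if (len %% 3L != 0L)
    stop("alignment length ", len, " is not divisible by 3")
  ncod <- len %/% 3L
  starts <- seq(1L, len, by = 3L)
  out <- vapply(seqs, function(s) {
    cods <- substring(toupper(s), starts, starts + 2L)
    idx <- tab$index[cods]
    unname(idx)
  }, integer(ncod))
  if (!is.matrix(out)) out <- matrix(out, nrow = ncod,
                                     dimnames = list(NULL, names(seqs)))
  out
}

#' Translate a vector of codon indices back to a DNA string
#' @keywords internal
codons_to_string <- function(idx) {
  tab <- codon_tables()
  paste(tab$codons[idx], collapse = "")
}
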