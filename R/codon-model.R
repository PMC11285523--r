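# Single-nucleotide-step codon substitution model (Goldman-Yang style):
# rate(i -> j) = pi_j * kappa^[transition] * omega^[non-synonymous] for codon
# pairs differing at one position; 0 otherwise; stop codons are excluded from
# the state space (rates into stops are structurally zero).  The generator
# matrix is scaled to one expected substitution per codon per unit time, so
# branch lengths are expected codon substitutions per codon site.

#' Construct a codon substitution model
#'
#' @param kappa transition/transversion rate ratio (>= 0).
#' @param omega non-synonymous/synonymous rate ratio dN/dS (>= 0).
#' @param pi codon frequencies over the 61 sense codons (default uniform);
#'   must be non-negative and sum to 1 within 1e-12.
#' @return An object of class `codon_model`: the scaled generator `Q`, its
#'   symmetric eigendecomposition for fast transition probabilities, and the
#'   flux decomposition used to convert divergence into per-site dN and dS.
#' @export
codon_model <- function(kappa = 2, omega = 0.2, pi = NULL) {
  tab <- codon_tables()
  ncod <- length(tab$codons)
  if (is.null(pi)) pi <- rep(1 / ncod, ncod)
  stopifnot(length(pi) == ncod)
  if (any(pi <= 0))
    stop("codon frequencies must be strictly positive over the sense codons")
  if (abs(sum(pi) - 1) > 1e-12)
    stop("codon frequencies pi must sum to 1 (within 1e-12)")
  if (kappa < 0 || omega < 0) stop("kappa and omega must be >= 0")

  Q <- matrix(0, ncod, ncod)
  for (col in 1:9) {
    tgt <- tab$nb_target[, col]
    ok <- !is.na(tgt)
    rate <- pi[tgt[ok]] *
      ifelse(tab$nb_ts[ok, col], kappa, 1) *
      ifelse(tab$nb_syn[ok, col], 1, omega)
    Q[cbind(which(ok), tgt[ok])] <- Q[cbind(which(ok), tgt[ok])] + rate
  }
  diag(Q) <- -rowSums(Q)
  mean_rate <- -sum(pi * diag(Q))
  if (mean_rate > 0) Q <- Q / mean_rate

  # flux shares: fraction of substitutions that are non-synonymous under the
  # fitted omega, and under omega = 1 (the mutational site proportions)
  syn_flux <- function(om) {
    fN <- 0; fS <- 0
    for (col in 1:9) {
      tgt <- tab$nb_target[, col]
      ok <- !is.na(tgt)
      r <- pi[ok] * pi[tgt[ok]] * ifelse(tab$nb_ts[ok, col], kappa, 1)
      nonsyn <- !tab$nb_syn[ok, col]
      fN <- fN + sum(r[nonsyn]) * om
      fS <- fS + sum(r[!nonsyn])
    }
    c(N = fN / (fN + fS), S = fS / (fN + fS))
  }
  flux <- syn_flux(omega)
  flux1 <- syn_flux(1)

  # reversible w.r.t. pi: symmetrize with D^{1/2} Q D^{-1/2} and eigendecompose
  sq <- sqrt(pi)
  S <- Q * (sq %o% (1 / sq))
  S <- (S + t(S)) / 2
  eig <- eigen(S, symmetric = TRUE)
  structure(list(kappa = kappa, omega = omega, pi = pi, Q = Q,
                 evec_left = eig$vectors / sq,       # D^{-1/2} U
                 evec_right = t(eig$vectors * sq),   # U' D^{1/2}
                 evalues = eig$values,
                 prop_nonsyn = unname(flux["N"]),
                 prop_nonsyn_neutral = unname(flux1["N"])),
            class = "codon_model")
}

#' Transition probability matrix P(t) of a codon model
#'
#' @param model a [codon_model()].
#' @param t branch length (expected codon substitutions per codon site, >= 0).
#' @return 61 x 61 row-stochastic matrix.
#' @export
codon_prob_matrix <- function(model, t) {
  stopifnot(inherits(model, "codon_model"), t >= 0)
  P <- model$evec_left %*% (exp(model$evalues * t) * model$evec_right)
  # clip tiny negative values from finite-precision eigendecomposition
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Convert divergence t into per-site dN and dS under a codon model
#'
#' Splits the expected `t` substitutions per codon into non-synonymous and
#' synonymous fluxes and divides each by the corresponding number of sites,
#' where sites are apportioned from the neutral (omega = 1) flux shares:
#' N = 3 * prop_nonsyn_neutral sites per codon, S = 3 - N.
#'
#' @param model a [codon_model()].
#' @param t divergence in expected codon substitutions per codon site.
#' @return named numeric: `dN`, `dS`, and the per-codon site counts `N`, `S`.
#' @export
codon_flux_rates <- function(model, t) {
  Nsites <- 3 * model$prop_nonsyn_neutral
  Ssites <- 3 - Nsites
  dN <- t * model$prop_nonsyn / Nsites
  dS <- t * (1 - model$prop_nonsyn) / Ssites
  c(dN = dN, dS = dS, N = Nsites, S = Ssites)
}

# Jump-chain representation used by the event-by-event simulator: per-codon
# total leave rates plus padded cumulative target distributions.
codon_jump_chain <- function(model) {
  tab <- codon_tables()
  ncod <- length(tab$codons)
  rate <- -diag(model$Q)
  tgt <- matrix(1L, ncod, 9)       # padding target (never selected)
  syn <- matrix(FALSE, ncod, 9)
  cum <- matrix(1, ncod, 9)        # padded with 1 so u < 1 never lands there
  for (i in seq_len(ncod)) {
    if (rate[i] <= 0) next        # absorbing under this model (e.g. omega = 0)
    ok <- which(!is.na(tab$nb_target[i, ]))
    p <- model$Q[i, tab$nb_target[i, ok]] / rate[i]
    o <- seq_along(ok)
    tgt[i, o] <- tab$nb_target[i, ok]
    syn[i, o] <- tab$nb_syn[i, ok]
    cum[i, o] <- cumsum(p)
    cum[i, length(ok)] <- 1        # guard against rounding
  }
  list(rate = rate, tgt = tgt, syn = syn, cum = cum)
}
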