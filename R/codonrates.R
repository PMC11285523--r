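# Per-gene substitution-rate estimation: Nei-Gojobori (1986) counting with
# Jukes-Cantor correction, pairwise codon maximum likelihood, and a
# free-ratios substitute built from marginal ancestral reconstruction plus
# per-terminal-branch counting.

#' NG86 site counts for one codon
#'
#' Over the nine single-nucleotide neighbours, the synonymous site count `s`
#' is the sum over the three positions of the fraction of non-stop
#' neighbours that are synonymous; `n = 3 - s`.
#'
#' @param codon a 3-letter sense codon (upper case).
#' @return named numeric `c(n, s)`.
#' @export
ng86_site_counts <- function(codon) {
  tab <- codon_tables()
  i <- tab$index[toupper(codon)]
  if (is.na(i))
    stop("'", codon, "' is not a sense codon of the standard code")
  c(n = tab$n_sites[[i]], s = tab$s_sites[[i]])
}

# core pairwise counting shared by ng86_pairwise and branch_counts:
# ia, ib are codon-index vectors (NA = ambiguous/stop, skipped
# pairwise-complete)
ng86_count_core <- function(ia, ib) {
  tab <- codon_tables()
  ok <- !is.na(ia) & !is.na(ib)
  n_skipped_ambiguous <- sum(!ok)
  ia <- ia[ok]; ib <- ib[ok]
  # drop codon pairs with no stop-free mutational path (does not occur under
  # the standard code, but guarded for)
  if (length(ia)) {
    nd <- tab$Nd[cbind(ia, ib)]
    pathless <- is.na(nd)
  } else pathless <- logical(0)
  n_skipped_pathless <- sum(pathless)
  ia <- ia[!pathless]; ib <- ib[!pathless]
  list(Nd = sum(tab$Nd[cbind(ia, ib)]),
       Sd = sum(tab$Sd[cbind(ia, ib)]),
       N_a = sum(tab$n_sites[ia]), S_a = sum(tab$s_sites[ia]),
       N_b = sum(tab$n_sites[ib]), S_b = sum(tab$s_sites[ib]),
       n_codons = length(ia),
       n_skipped = n_skipped_ambiguous + n_skipped_pathless)
}

jc_correct <- function(p) {
  ifelse(p >= 3 / 4, NA_real_, -3 / 4 * log(1 - 4 / 3 * p))
}

#' NG86 pairwise substitution rates between two aligned sequences
#'
#' Difference counts are path-averaged over the minimal mutational paths
#' (orderings of the differing positions) whose intermediates are sense
#' codons; site counts are averaged between the two sequences; proportions
#' are Jukes-Cantor corrected: `d = -3/4 log(1 - 4/3 p)`.
#'
#' @param seq_a,seq_b aligned, equal-length, in-frame DNA strings.  Codons
#'   containing ambiguity characters or stops in either sequence are skipped
#'   pairwise-complete.
#' @return list of class `gene_subst_record`: `Nd`, `Sd`, `N`, `S`, `dN`,
#'   `dS`, `dnds`, `flags` (character vector; `"saturated"` when a corrected
#'   proportion is undefined, `"dS_zero"` when the ratio is undefined).
#' @export
ng86_pairwise <- function(seq_a, seq_b) {
  m <- codon_index_matrix(c(a = seq_a, b = seq_b))
  cnt <- ng86_count_core(m[, 1], m[, 2])
  N <- (cnt$N_a + cnt$N_b) / 2
  S <- (cnt$S_a + cnt$S_b) / 2
  pN <- if (N > 0) cnt$Nd / N else 0
  pS <- if (S > 0) cnt$Sd / S else 0
  dN <- jc_correct(pN)
  dS <- jc_correct(pS)
  flags <- character(0)
  if (is.na(dN) || is.na(dS)) flags <- c(flags, "saturated")
  dnds <- if (!is.na(dN) && !is.na(dS) && dS > 0) dN / dS else NA_real_
  if (!is.na(dS) && dS == 0) flags <- c(flags, "dS_zero")
  if (cnt$n_skipped > 0) flags <- c(flags, "codons_skipped")
  structure(list(Nd = cnt$Nd, Sd = cnt$Sd, N = N, S = S,
                 dN = dN, dS = dS, dnds = dnds,
                 n_codons = cnt$n_codons, flags = flags),
            class = "gene_subst_record")
}

#' Pairwise codon maximum likelihood (divergence, kappa, omega)
#'
#' Maximizes the likelihood of the codon-pair pattern counts under the same
#' single-nucleotide-step codon model used by the simulator, over
#' `(log t, log kappa, log omega)` with bounded quasi-Newton restarts from
#' three fixed starting points.  Divergence is decomposed into per-site dN
#' and dS by expected flux (see [codon_flux_rates()]).
#'
#' @param seq_a,seq_b aligned in-frame DNA strings.
#' @param pi codon frequencies: `"uniform"` (default), `"empirical"` (average
#'   codon usage of the two sequences, with a small floor), or a 61-vector.
#' @param t_bounds,kappa_bounds,omega_bounds optimizer box constraints.
#' @return list: `t`, `kappa`, `omega`, `loglik`, `dN`, `dS`, `dnds`,
#'   `convergence` (0 = converged), `flags`.
#' @export
ml_pairwise <- function(seq_a, seq_b, pi = "uniform",
                        t_bounds = c(1e-6, 20),
                        kappa_bounds = c(0.05, 50),
                        omega_bounds = c(1e-6, 20)) {
  m <- codon_index_matrix(c(a = seq_a, b = seq_b))
  ok <- !is.na(m[, 1]) & !is.na(m[, 2])
  ia <- m[ok, 1]; ib <- m[ok, 2]
  if (!length(ia)) stop("no unambiguous codon pairs to fit")
  if (is.character(pi)) {
    pi <- match.arg(pi, c("uniform", "empirical"))
    pi <- if (pi == "uniform") rep(1 / 61, 61) else {
      u <- tabulate(c(ia, ib), 61) + 0.5
      u / sum(u)
    }
  }
  pat <- table(factor(ia, levels = 1:61), factor(ib, levels = 1:61))
  pat <- as.matrix(pat)
  nz <- which(pat > 0, arr.ind = TRUE)
  cnt <- pat[nz]

  negll <- function(par) {
    t <- exp(par[1]); kap <- exp(par[2]); om <- exp(par[3])
    mod <- codon_model(kap, om, pi)
    P <- codon_prob_matrix(mod, t)
    lik <- pi[nz[, 1]] * P[nz]
    if (any(lik <= 0)) return(1e10)
    -sum(cnt * log(lik))
  }

  flags <- character(0)
  if (all(ia == ib)) {
    # identical sequences: divergence sits at the lower bound
    mod <- codon_model(2, 1, pi)
    fl <- codon_flux_rates(mod, t_bounds[1])
    return(list(t = t_bounds[1], kappa = NA_real_, omega = NA_real_,
                loglik = -negll(log(c(t_bounds[1], 2, 1))),
                dN = fl[["dN"]], dS = fl[["dS"]], dnds = NA_real_,
                convergence = 0L, flags = "identical_sequences"))
  }

  starts <- list(c(0.1, 2, 0.2), c(0.5, 1, 1), c(0.05, 4, 0.05))
  lower <- log(c(t_bounds[1], kappa_bounds[1], omega_bounds[1]))
  upper <- log(c(t_bounds[2], kappa_bounds[2], omega_bounds[2]))
  best <- NULL
  for (s in starts) {
    fit <- try(stats::optim(log(s), negll, method = "L-BFGS-B",
                            lower = lower, upper = upper,
                            control = list(factr = 10)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    return(list(t = NA_real_, kappa = NA_real_, omega = NA_real_,
                loglik = NA_real_, dN = NA_real_, dS = NA_real_,
                dnds = NA_real_, convergence = 1L,
                flags = "non_convergence"))
  }
  t_hat <- exp(best$par[1]); k_hat <- exp(best$par[2]); w_hat <- exp(best$par[3])
  if (best$convergence != 0) flags <- c(flags, "optimizer_warning")
  if (w_hat <= omega_bounds[1] * (1 + 1e-6)) flags <- c(flags, "omega_at_bound")
  mod <- codon_model(k_hat, w_hat, pi)
  fl <- codon_flux_rates(mod, t_hat)
  list(t = t_hat, kappa = k_hat, omega = w_hat, loglik = -best$value,
       dN = fl[["dN"]], dS = fl[["dS"]],
       dnds = if (fl[["dS"]] > 0) fl[["dN"]] / fl[["dS"]] else NA_real_,
       convergence = as.integer(best$convergence), flags = flags)
}

#' Marginal ancestral codon reconstruction by the pruning algorithm
#'
#' Computes marginal posterior codon probabilities at every internal node for
#' every site under a global codon model (one kappa and one omega for the
#' whole gene), via Felsenstein's pruning algorithm with a root-to-tips
#' downward pass, and returns the maximum-posterior codon per node per site.
#'
#' @param tree a `phylo` object whose tips match the alignment taxa.
#' @param aln named character vector of aligned in-frame sequences.
#' @param model a [codon_model()]; if `NULL`, a global model is fitted with
#'   kappa 2 and omega from pooled NG86 counts of each tip against the first.
#' @return list: `states` (internal-nodes x sites matrix of codon indices,
#'   rows named by node number), `posterior` (matching matrix of posterior
#'   probabilities), `model`, `root_node`.
#' @export
reconstruct_ancestors <- function(tree, aln, model = NULL) {
  missing <- setdiff(tree$tip.label, names(aln))
  extra <- setdiff(names(aln), tree$tip.label)
  if (length(missing) || length(extra))
    stop("tree/alignment taxa mismatch; missing from alignment: ",
         paste(missing, collapse = ", "), "; not in tree: ",
         paste(extra, collapse = ", "))
  idx <- codon_index_matrix(aln[tree$tip.label])
  nsite <- nrow(idx)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- ntip + 1L

  if (is.null(model)) {
    cnt <- lapply(seq_len(ntip)[-1], function(j)
      ng86_count_core(idx[, 1], idx[, j]))
    Nd <- sum(vapply(cnt, `[[`, numeric(1), "Nd"))
    Sd <- sum(vapply(cnt, `[[`, numeric(1), "Sd"))
    Nn <- sum(vapply(cnt, function(x) (x$N_a + x$N_b) / 2, numeric(1)))
    Ss <- sum(vapply(cnt, function(x) (x$S_a + x$S_b) / 2, numeric(1)))
    om <- if (Sd > 0 && Nn > 0) (Nd / Nn) / (Sd / Ss) else 0.2
    om <- min(max(om, 1e-3), 5)
    model <- codon_model(kappa = 2, omega = om)
  }

  post <- ape::reorder.phylo(tree, "postorder")
  Pmats <- lapply(seq_len(nrow(post$edge)), function(e)
    codon_prob_matrix(model, post$edge.length[e]))

  # upward (pruning) pass: partial likelihoods L[[v]] (61 x nsite)
  L <- vector("list", ntip + nnode)
  for (v in seq_len(ntip)) {
    Lm <- matrix(0, 61, nsite)
    obs <- idx[, v]
    Lm[cbind(obs[!is.na(obs)], which(!is.na(obs)))] <- 1
    Lm[, is.na(obs)] <- 1          # ambiguous codon: uninformative
    L[[v]] <- Lm
  }
  msg <- vector("list", nrow(post$edge))   # P_e %*% L[child]
  for (e in seq_len(nrow(post$edge))) {
    par <- post$edge[e, 1]; chi <- post$edge[e, 2]
    msg[[e]] <- Pmats[[e]] %*% L[[chi]]
    if (is.null(L[[par]])) L[[par]] <- msg[[e]] else
      L[[par]] <- L[[par]] * msg[[e]]
  }

  # downward pass: D[[v]] carries the likelihood of everything outside the
  # clade of v, conditioned on the state at v
  D <- vector("list", ntip + nnode)
  D[[root]] <- matrix(model$pi, 61, nsite)
  children <- split(seq_len(nrow(post$edge)), post$edge[, 1])
  for (e in rev(seq_len(nrow(post$edge)))) {     # pre-order in reversed postorder
    par <- post$edge[e, 1]; chi <- post$edge[e, 2]
    if (chi <= ntip) next
    sib_prod <- D[[par]]
    for (e2 in children[[as.character(par)]]) {
      if (e2 != e) sib_prod <- sib_prod * msg[[e2]]
    }
    D[[chi]] <- crossprod(Pmats[[e]], sib_prod)
  }

  nodes <- root:(ntip + nnode)
  states <- matrix(NA_integer_, length(nodes), nsite,
                   dimnames = list(as.character(nodes), NULL))
  posterior <- matrix(NA_real_, length(nodes), nsite,
                      dimnames = list(as.character(nodes), NULL))
  for (k in seq_along(nodes)) {
    v <- nodes[k]
    marg <- L[[v]] * D[[v]]
    tot <- colSums(marg)
    marg <- sweep(marg, 2, tot, "/")
    states[k, ] <- max.col(t(marg), ties.method = "first")
    posterior[k, ] <- marg[cbind(states[k, ], seq_len(nsite))]
  }
  list(states = states, posterior = posterior, model = model,
       root_node = root)
}

#' Per-terminal-branch substitution counts from reconstructed ancestors
#'
#' The free-ratios substitute: for every terminal branch, NG86 difference
#' counts between the reconstructed parent sequence and the observed tip,
#' with site counts taken from the tip sequence, Jukes-Cantor corrected.
#'
#' @param tree a `phylo` object.
#' @param aln named character vector of aligned in-frame sequences.
#' @param model optional [codon_model()] passed to
#'   [reconstruct_ancestors()].
#' @return data.frame with one row per terminal branch: `unit` (tip label),
#'   `Nd`, `Sd`, `N`, `S`, `dN`, `dS`, `dnds`, `flags`.
#' @export
branch_counts <- function(tree, aln, model = NULL) {
  rec <- reconstruct_ancestors(tree, aln, model)
  idx <- codon_index_matrix(aln[tree$tip.label])
  ntip <- length(tree$tip.label)
  term <- which(tree$edge[, 2] <= ntip)
  rows <- lapply(term, function(e) {
    tip <- tree$edge[e, 2]
    par <- tree$edge[e, 1]
    anc <- rec$states[as.character(par), ]
    cnt <- ng86_count_core(anc, idx[, tip])
    N <- cnt$N_b; S <- cnt$S_b         # site counts from the tip sequence
    pN <- if (N > 0) cnt$Nd / N else 0
    pS <- if (S > 0) cnt$Sd / S else 0
    dN <- jc_correct(pN); dS <- jc_correct(pS)
    flags <- if (is.na(dN) || is.na(dS)) "saturated" else ""
    data.frame(unit = tree$tip.label[tip], Nd = cnt$Nd, Sd = cnt$Sd,
               N = N, S = S, dN = dN, dS = dS,
               dnds = if (!is.na(dS) && dS > 0 && !is.na(dN)) dN / dS
                      else NA_real_,
               flags = flags, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
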