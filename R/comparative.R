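# Mating-system classification and the downstream statistics: paired and
# Welch t-tests, phylogenetic generalized least squares with
# maximum-likelihood Pagel's lambda, and two-state Mk ancestral-state
# reconstruction.

#' Classify a mating system from polygamy rates and care
#'
#' Rules applied in order: role-reversed polyandry (>20% of breeding females
#' polygamous, <1% of males, male-majority care), lekking polygyny (>20% in
#' both sexes, with lekking), polygynandry (>20% in both sexes, no lekking),
#' weak polyandry (>5% female with >1% male polygamy), monogamy (<1% in both
#' sexes), otherwise unknown.  Missing percentages give `"unknown"`.
#'
#' @param female_polygamy_pct,male_polygamy_pct percentage of breeding
#'   females/males polygamous within a season, in `[0, 100]`.
#' @param care_sex sex providing the majority of parental care
#'   (`"male"`, `"female"`, `"both"`, or NA).
#' @param lekking logical, lekking behaviour.
#' @return character vector of categories.
#' @export
classify_mating_system <- function(female_polygamy_pct, male_polygamy_pct,
                                   care_sex = NA, lekking = FALSE) {
  n <- max(length(female_polygamy_pct), length(male_polygamy_pct))
  f <- rep_len(female_polygamy_pct, n)
  m <- rep_len(male_polygamy_pct, n)
  care <- rep_len(care_sex, n)
  lek <- rep_len(lekking, n)
  bad <- !is.na(f) & (f < 0 | f > 100) | !is.na(m) & (m < 0 | m > 100)
  if (any(bad)) stop("polygamy percentages must lie in [0, 100]")
  out <- rep("unknown", n)
  known <- !is.na(f) & !is.na(m)
  rule <- function(cond) known & cond & out == "unknown"
  out[rule(f > 20 & m < 1 & !is.na(care) & care == "male")] <-
    "role_reversed_polyandry"
  out[rule(f > 20 & m > 20 & lek)] <- "lekking_polygyny"
  out[rule(f > 20 & m > 20)] <- "polygynandry"
  out[rule(f > 5 & m > 1)] <- "weak_polyandry"
  out[rule(f < 1 & m < 1)] <- "monogamy"
  out
}

#' Paired t-test on species-matched measurements
#'
#' @param x,y equal-length numeric vectors, paired by position.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return list: `t`, `df`, `p`, `mean_diff`, `n`.
#' @export
paired_ttest <- function(x, y, alternative = "two.sided") {
  alternative <- match.arg(alternative, c("two.sided", "greater", "less"))
  if (length(x) != length(y)) stop("x and y must have equal length")
  d <- x - y
  n <- length(d)
  if (n < 2) stop("need at least 2 pairs")
  sd_d <- stats::sd(d)
  if (sd_d == 0) stop("zero variance of differences: t is undefined")
  t <- mean(d) / (sd_d / sqrt(n))
  df <- n - 1
  p <- switch(alternative,
              two.sided = 2 * stats::pt(-abs(t), df),
              greater = stats::pt(t, df, lower.tail = FALSE),
              less = stats::pt(t, df))
  list(t = t, df = df, p = p, mean_diff = mean(d), n = n)
}

#' Welch two-sample t-test with per-group summaries
#'
#' Welch statistic with Satterthwaite degrees of freedom; per-group means
#' and t-based 95% confidence intervals are reported alongside.
#'
#' @param group1,group2 numeric vectors (each length >= 2).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param conf_level level for the per-group confidence intervals.
#' @return list: `t`, `df`, `p`, `mean1`, `mean2`, `ci1`, `ci2`, `n1`, `n2`.
#' @export
welch_ttest <- function(group1, group2, alternative = "two.sided",
                        conf_level = 0.95) {
  alternative <- match.arg(alternative, c("two.sided", "greater", "less"))
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 observations")
  m1 <- mean(group1); m2 <- mean(group2)
  v1 <- stats::var(group1); v2 <- stats::var(group2)
  if (v1 == 0 && v2 == 0) stop("zero variance in both groups: t is undefined")
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- switch(alternative,
              two.sided = 2 * stats::pt(-abs(t), df),
              greater = stats::pt(t, df, lower.tail = FALSE),
              less = stats::pt(t, df))
  ci <- function(m, v, n) {
    half <- stats::qt(1 - (1 - conf_level) / 2, n - 1) * sqrt(v / n)
    c(m - half, m + half)
  }
  list(t = t, df = df, p = p, mean1 = m1, mean2 = m2,
       ci1 = ci(m1, v1, n1), ci2 = ci(m2, v2, n2), n1 = n1, n2 = n2)
}

# phylogenetic covariance under Pagel's lambda: off-diagonal shared branch
# lengths scaled by lambda, diagonal unchanged
lambda_vcv <- function(V, lambda) {
  W <- lambda * V
  diag(W) <- diag(V)
  W
}

#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' GLS regression whose residual covariance is `V(lambda)`: the shared
#' branch-length matrix of the tree with off-diagonals multiplied by lambda.
#' Lambda is either fixed or estimated by maximum likelihood over `[0, 1]`
#' (51-point grid followed by bounded refinement; ties broken toward the
#' smaller lambda).  Coefficient tests use the t distribution with `n - k`
#' degrees of freedom and the unbiased residual variance.
#'
#' @param formula model formula.
#' @param data data.frame whose rownames (or `species` column) match the
#'   tree's tip labels.
#' @param tree a `phylo` object with branch lengths.
#' @param lambda `"ML"` (default) or a fixed value in `[0, 1]`.
#' @return object of class `pgls_fit`: `coefficients` table (estimate, se,
#'   t, p), `lambda`, `lambda_ml` (logical), `loglik`, `n`, `k`, `sigma2`,
#'   `residuals`, `fitted`.
#' @export
pgls_fit <- function(formula, data, tree, lambda = "ML") {
  if (!is.null(data$species)) rownames(data) <- data$species
  taxa <- rownames(data)
  missing <- setdiff(tree$tip.label, taxa)
  extra <- setdiff(taxa, tree$tip.label)
  if (length(missing) || length(extra))
    stop("tree/data taxa mismatch; missing from data: ",
         paste(missing, collapse = ", "), "; not in tree: ",
         paste(extra, collapse = ", "))
  data <- data[tree$tip.label, , drop = FALSE]
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  n <- nrow(X); k <- ncol(X)
  if (qr(X)$rank < k) stop("rank-deficient design matrix")
  V <- ape::vcv(tree)[tree$tip.label, tree$tip.label]

  fit_at <- function(lam) {
    W <- lambda_vcv(V, lam)
    ch <- chol(W)
    Xs <- backsolve(ch, X, transpose = TRUE)
    ys <- backsolve(ch, y, transpose = TRUE)
    qrx <- qr(Xs)
    beta <- qr.coef(qrx, ys)
    resid_w <- ys - Xs %*% beta
    rss <- sum(resid_w^2)
    sigma2_ml <- rss / n
    ll <- -0.5 * (n * log(2 * pi * sigma2_ml) +
                    2 * sum(log(diag(ch))) + n)
    list(beta = beta, rss = rss, ll = ll, ch = ch, qrx = qrx)
  }

  lambda_ml <- identical(lambda, "ML")
  if (lambda_ml) {
    grid <- seq(0, 1, length.out = 51)
    lls <- vapply(grid, function(l) fit_at(l)$ll, numeric(1))
    i <- which(lls == max(lls))[1]     # ties toward smaller lambda
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    opt <- stats::optimize(function(l) fit_at(l)$ll, c(lo, hi),
                           maximum = TRUE, tol = 1e-8)
    lambda <- if (opt$objective > lls[i] + 1e-10) opt$maximum else grid[i]
  } else {
    stopifnot(is.numeric(lambda), lambda >= 0, lambda <= 1)
  }
  f <- fit_at(lambda)
  sigma2 <- f$rss / (n - k)
  XtX_inv <- chol2inv(qr.R(f$qrx))
  se <- sqrt(diag(XtX_inv) * sigma2)
  tval <- as.vector(f$beta) / se
  pval <- 2 * stats::pt(-abs(tval), n - k)
  coef_tab <- data.frame(term = colnames(X), estimate = as.vector(f$beta),
                         se = se, t = tval, p = pval,
                         stringsAsFactors = FALSE)
  rownames(coef_tab) <- NULL
  fitted <- as.vector(X %*% f$beta)
  structure(list(coefficients = coef_tab, lambda = lambda,
                 lambda_ml = lambda_ml, loglik = f$ll, n = n, k = k,
                 sigma2 = sigma2, residuals = as.vector(y) - fitted,
                 fitted = fitted, formula = formula),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS fit (Pagel's lambda =", format(x$lambda, digits = 4),
      if (x$lambda_ml) "[ML]" else "[fixed]", ")\n")
  cat("n =", x$n, " logLik =", format(x$loglik, digits = 6), "\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}

# analytic 2-state transition probabilities for rates q01, q10
mk2_prob <- function(q01, q10, t) {
  qs <- q01 + q10
  if (qs <= 0) return(diag(2))
  e <- exp(-qs * t)
  p0 <- q10 / qs   # stationary P(state 0)
  matrix(c(p0 + (1 - p0) * e, 1 - p0 - (1 - p0) * e,
           p0 - p0 * e, 1 - p0 + p0 * e),
         2, 2, byrow = TRUE)
}

mk2_loglik <- function(tree, states01, q01, q10) {
  ntip <- length(tree$tip.label)
  post <- ape::reorder.phylo(tree, "postorder")
  L <- matrix(NA_real_, ntip + tree$Nnode, 2)
  L[seq_len(ntip), ] <- cbind(states01 == 0, states01 == 1) * 1
  for (e in seq_len(nrow(post$edge))) {
    par <- post$edge[e, 1]; chi <- post$edge[e, 2]
    P <- mk2_prob(q01, q10, post$edge.length[e])
    m <- P %*% L[chi, ]
    if (is.na(L[par, 1])) L[par, ] <- m else L[par, ] <- L[par, ] * m
  }
  qs <- q01 + q10
  prior <- if (qs > 0) c(q10, q01) / qs else c(0.5, 0.5)
  sum(log(prior %*% L[ntip + 1L, ]))
}

#' Two-state Mk ancestral-state reconstruction
#'
#' Maximum-likelihood transition rates under the equal-rates (default) or
#' all-rates-different two-state Mk model, computed by Felsenstein pruning
#' with the stationary distribution of the fitted rate matrix as root prior,
#' followed by marginal state probabilities at every internal node via the
#' rerooting (outside-in) pass.
#'
#' @param tree a `phylo` object with branch lengths.
#' @param tip_states named vector of 0/1 states (names = tip labels).
#'   Tips with missing states are dropped with a warning.
#' @param model `"ER"` (equal rates, default) or `"ARD"`.
#' @return object of class `asr_fit`: `rates` (named: q01, q10), `loglik`,
#'   `node_probs` (internal-nodes x 2 matrix, columns `state0`, `state1`,
#'   rows named by node number), `tree`, `model`.
#' @export
mk_asr <- function(tree, tip_states, model = c("ER", "ARD")) {
  model <- match.arg(model)
  if (is.null(names(tip_states)))
    stop("tip_states must be named by tip label")
  drop <- tree$tip.label[is.na(tip_states[tree$tip.label])]
  if (length(drop)) {
    warning("dropping tips with missing states: ",
            paste(drop, collapse = ", "))
    tree <- ape::drop.tip(tree, drop)
  }
  s <- tip_states[tree$tip.label]
  if (!all(s %in% c(0, 1))) stop("tip states must be 0/1")
  ntip <- length(tree$tip.label)

  bounds <- log(c(1e-8, 1e3))
  if (model == "ER") {
    nll <- function(lq) -mk2_loglik(tree, s, exp(lq), exp(lq))
    opt <- stats::optimize(nll, bounds)
    q01 <- q10 <- exp(opt$minimum)
    ll <- -opt$objective
  } else {
    nll <- function(p) -mk2_loglik(tree, s, exp(p[1]), exp(p[2]))
    opt <- stats::optim(log(c(0.5, 0.5)), nll, method = "L-BFGS-B",
                        lower = bounds[1], upper = bounds[2])
    q01 <- exp(opt$par[1]); q10 <- exp(opt$par[2])
    ll <- -opt$value
  }

  # marginal node probabilities: pruning pass up, rerooting pass down
  post <- ape::reorder.phylo(tree, "postorder")
  nnode <- tree$Nnode
  root <- ntip + 1L
  L <- matrix(NA_real_, ntip + nnode, 2)
  L[seq_len(ntip), ] <- cbind(s == 0, s == 1) * 1
  msg <- vector("list", nrow(post$edge))
  Pm <- lapply(post$edge.length, function(t) mk2_prob(q01, q10, t))
  for (e in seq_len(nrow(post$edge))) {
    par <- post$edge[e, 1]; chi <- post$edge[e, 2]
    msg[[e]] <- as.vector(Pm[[e]] %*% L[chi, ])
    if (is.na(L[par, 1])) L[par, ] <- msg[[e]] else
      L[par, ] <- L[par, ] * msg[[e]]
  }
  qs <- q01 + q10
  prior <- if (qs > 0) c(q10, q01) / qs else c(0.5, 0.5)
  D <- matrix(NA_real_, ntip + nnode, 2)
  D[root, ] <- prior
  children <- split(seq_len(nrow(post$edge)), post$edge[, 1])
  for (e in rev(seq_len(nrow(post$edge)))) {
    par <- post$edge[e, 1]; chi <- post$edge[e, 2]
    if (chi <= ntip) next
    sib <- D[par, ]
    for (e2 in children[[as.character(par)]])
      if (e2 != e) sib <- sib * msg[[e2]]
    D[chi, ] <- as.vector(t(Pm[[e]]) %*% sib)
  }
  nodes <- root:(ntip + nnode)
  marg <- L[nodes, , drop = FALSE] * D[nodes, , drop = FALSE]
  marg <- marg / rowSums(marg)
  dimnames(marg) <- list(as.character(nodes), c("state0", "state1"))
  structure(list(rates = c(q01 = q01, q10 = q10), loglik = ll,
                 node_probs = marg, tree = tree, model = model),
            class = "asr_fit")
}

#' @export
print.asr_fit <- function(x, ...) {
  cat("2-state Mk ancestral-state reconstruction (", x$model, ")\n", sep = "")
  cat("rates: q01 =", format(x$rates[["q01"]], digits = 4),
      " q10 =", format(x$rates[["q10"]], digits = 4),
      " logLik =", format(x$loglik, digits = 6), "\n")
  cat("root P(state1) =", format(x$node_probs[1, "state1"], digits = 4), "\n")
  invisible(x)
}
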