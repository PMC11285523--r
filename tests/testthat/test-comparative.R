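# mating-system classifier, t-tests, PGLS with Pagel's lambda, Mk ASR

test_that("mating systems classify by the strict ordered rules", {
  expect_equal(classify_mating_system(60, 0, "male"),
               "role_reversed_polyandry")
  expect_equal(classify_mating_system(0.5, 0.5), "monogamy")
  expect_equal(classify_mating_system(10, 2), "weak_polyandry")
  expect_equal(classify_mating_system(30, 30, lekking = TRUE),
               "lekking_polygyny")
  expect_equal(classify_mating_system(30, 30), "polygynandry")
  # >20% female polygamy without male care is not role-reversed
  expect_equal(classify_mating_system(60, 0, "female"), "unknown")
  expect_equal(classify_mating_system(NA, 0), "unknown")
  expect_equal(classify_mating_system(c(60, 0.5), c(0, 0.5),
                                      c("male", NA)),
               c("role_reversed_polyandry", "monogamy"))
  expect_error(classify_mating_system(-5, 0), "\\[0, 100\\]")
})

test_that("paired t matches the textbook formula and stats::t.test", {
  p <- paired_ttest(c(2, 4, 6), c(1, 2, 3))
  expect_equal(p$t, sqrt(12), tolerance = 1e-12)
  expect_equal(p$df, 2)
  expect_equal(p$p, 0.0742, tolerance = 1e-3)
  swap <- paired_ttest(c(1, 2, 3), c(2, 4, 6))
  expect_equal(swap$t, -p$t)
  expect_error(paired_ttest(1:4, 1:4), "zero variance")
  expect_error(paired_ttest(1:3, 1:4), "equal length")

  set.seed(101)
  for (i in 1:250) {
    n <- sample(3:12, 1)
    x <- rnorm(n); y <- rnorm(n, sd = runif(1, 0.5, 2))
    mine <- paired_ttest(x, y)
    ref <- t.test(x, y, paired = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Welch t matches hand computation and stats::t.test", {
  w <- welch_ttest(c(1, 2, 3), c(2, 4, 6, 8))
  expect_equal(w$t, -2.1213, tolerance = 1e-4)
  expect_equal(w$df, 4.0755, tolerance = 1e-4)
  expect_equal(w$mean1, 2)
  expect_equal(w$ci1, 2 + c(-1, 1) * qt(0.975, 2) / sqrt(3))
  # identical groups: t = 0
  expect_equal(welch_ttest(c(1, 2, 3), c(1, 2, 3))$t, 0)
  # equal n, equal variance: Welch equals the pooled Student statistic
  x <- c(1.2, 0.8, 1.6, 0.4); y <- c(2.2, 1.8, 2.6, 1.4)
  expect_equal(welch_ttest(x, y)$t,
               unname(t.test(x, y, var.equal = TRUE)$statistic))
  expect_error(welch_ttest(c(1, 1), c(2, 2)), "zero variance")

  set.seed(202)
  for (i in 1:250) {
    x <- rnorm(sample(3:10, 1)); y <- rnorm(sample(3:10, 1), 1, 2)
    mine <- welch_ttest(x, y)
    ref <- t.test(x, y)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-8)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("PGLS reduces to OLS at lambda 0 and matches the GLS oracle", {
  set.seed(11)
  tr <- ape::rcoal(5)
  tr$tip.label <- paste0("s", 1:5)
  d <- data.frame(y = rnorm(5), x = rnorm(5), row.names = tr$tip.label)
  f0 <- pgls_fit(y ~ x, d, tr, lambda = 0)
  ols <- summary(lm(y ~ x, d))
  expect_equal(f0$coefficients$estimate, unname(coef(ols)[, 1]),
               tolerance = 1e-8)
  expect_equal(f0$coefficients$se, unname(coef(ols)[, 2]), tolerance = 1e-8)
  expect_equal(f0$coefficients$p, unname(coef(ols)[, 4]), tolerance = 1e-8)

  # explicit-matrix GLS oracle at fixed lambda
  for (lam in c(0.3, 0.7, 1)) {
    V <- ape::vcv(tr)
    W <- lam * V; diag(W) <- diag(V)
    X <- cbind(1, d$x)
    Wi <- solve(W)
    beta <- solve(t(X) %*% Wi %*% X, t(X) %*% Wi %*% d$y)
    f <- pgls_fit(y ~ x, d, tr, lambda = lam)
    expect_equal(f$coefficients$estimate, as.vector(beta), tolerance = 1e-8)
    s2 <- sum((Wi %*% (d$y - X %*% beta)) * (d$y - X %*% beta)) / (5 - 2)
    expect_equal(f$coefficients$se,
                 sqrt(diag(solve(t(X) %*% Wi %*% X)) * s2), tolerance = 1e-8)
  }

  # star tree: no shared history, ML fit equals OLS for any lambda
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1,e:1);")
  ds <- data.frame(y = rnorm(5), x = rnorm(5),
                   row.names = star$tip.label)
  fs <- pgls_fit(y ~ x, ds, star)
  expect_equal(fs$coefficients$estimate, unname(coef(lm(y ~ x, ds))),
               tolerance = 1e-8)

  expect_error(pgls_fit(y ~ x, d[1:4, ], tr), "mismatch")
  d2 <- d; d2$x2 <- d2$x * 2
  expect_error(pgls_fit(y ~ x + x2, d2, tr), "rank-deficient")
})

test_that("ML lambda stays in [0, 1] and beats every grid value", {
  set.seed(12)
  for (i in 1:8) {
    tr <- ape::rcoal(12)
    tr$tip.label <- paste0("s", 1:12)
    lamt <- runif(1)
    V <- fastz:::lambda_vcv(ape::vcv(tr), lamt)
    y <- drop(chol(V) %*% rnorm(12))   # correlated residuals
    d <- data.frame(y = y, x = rnorm(12), row.names = tr$tip.label)
    f <- pgls_fit(y ~ x, d, tr)
    expect_gte(f$lambda, 0)
    expect_lte(f$lambda, 1)
    grid_ll <- vapply(seq(0, 1, length.out = 21), function(l)
      pgls_fit(y ~ x, d, tr, lambda = l)$loglik, numeric(1))
    expect_gte(f$loglik, max(grid_ll) - 1e-6)
  }
})

test_that("Mk ASR matches brute force, sums to one, and is symmetric", {
  tr <- three_tip_tree(0.4, 0.7, 1.1, 0.5)
  s <- setNames(c(0, 1, 1), c("a", "b", "c"))
  fit <- mk_asr(tr, s)
  expect_equal(unname(rowSums(fit$node_probs)), c(1, 1), tolerance = 1e-9)

  # brute force over both internal states at the fitted rate
  q <- fit$rates[["q01"]]
  P <- function(t) fastz:::mk2_prob(q, q, t)
  lab <- tr$tip.label
  el <- tr$edge.length
  e_of <- function(node) which(tr$edge[, 2] == node)
  joint <- matrix(0, 2, 2)
  for (r in 0:1) for (i in 0:1) {
    joint[r + 1, i + 1] <- 0.5 *
      P(el[e_of(which(lab == "c"))])[r + 1, s[["c"]] + 1] *
      P(el[e_of(5)])[r + 1, i + 1] *
      P(el[e_of(which(lab == "a"))])[i + 1, s[["a"]] + 1] *
      P(el[e_of(which(lab == "b"))])[i + 1, s[["b"]] + 1]
  }
  expect_equal(unname(fit$node_probs["4", ]),
               rowSums(joint) / sum(joint), tolerance = 1e-10)
  expect_equal(unname(fit$node_probs["5", ]),
               colSums(joint) / sum(joint), tolerance = 1e-10)

  # relabelling the states mirrors the marginals under equal rates
  fit_swapped <- mk_asr(tr, setNames(1 - s, names(s)))
  expect_equal(unname(fit_swapped$node_probs[, c(2, 1)]),
               unname(fit$node_probs), tolerance = 1e-6)

  # all tips in one state: no evidence of change anywhere
  tr8 <- simulate_tree(8, 4, seed = 3)
  all0 <- mk_asr(tr8, setNames(rep(0, 8), tr8$tip.label))
  expect_true(all(all0$node_probs[, "state0"] >= 0.999))

  # symmetric cherry: root marginals are (1/2, 1/2)
  cherry <- ape::read.tree(text = "(a:1,b:1);")
  fc <- mk_asr(cherry, setNames(c(0, 1), c("a", "b")))
  expect_equal(unname(fc$node_probs[1, ]), c(0.5, 0.5), tolerance = 1e-9)

  expect_warning(mk_asr(tr8, setNames(c(rep(0, 7), NA), tr8$tip.label)),
                 "missing")
  expect_error(mk_asr(tr8, setNames(rep(2, 8), tr8$tip.label)), "0/1")
})

test_that("Mk rate recovery is adequate on larger trees", {
  hits <- 0
  for (i in 1:10) {
    tr <- simulate_tree(150, 1, seed = 400 + i)
    sim <- simulate_trait_mk(tr, 1.5, 1.5, root_state = 0, seed = 500 + i)
    fit <- mk_asr(tr, sim$tip_states)
    if (abs(fit$rates[["q01"]] - 1.5) / 1.5 <= 0.5) hits <- hits + 1
  }
  expect_gte(hits, 7)
})

test_that("ARD Mk nests ER and estimates asymmetric rates", {
  tr <- simulate_tree(60, 1, seed = 31)
  sim <- simulate_trait_mk(tr, 0.5, 2, root_state = 0, seed = 32)
  er <- mk_asr(tr, sim$tip_states, model = "ER")
  ard <- mk_asr(tr, sim$tip_states, model = "ARD")
  # ER is nested in ARD: the richer model cannot fit worse
  expect_gte(ard$loglik, er$loglik - 1e-6)
  expect_true(all(ard$rates > 0))
  expect_equal(unname(rowSums(ard$node_probs)), rep(1, tr$Nnode),
               tolerance = 1e-9)
})
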