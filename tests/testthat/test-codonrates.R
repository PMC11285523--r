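# NG86 counting, pairwise codon ML, ancestral reconstruction and the
# per-terminal-branch counting that substitutes for a free-ratios fit

rep_codon <- function(codon, n) paste(rep(codon, n), collapse = "")

test_that("NG86 site counts match hand enumeration", {
  expect_equal(ng86_site_counts("TTT"), c(n = 8 / 3, s = 1 / 3))
  expect_equal(ng86_site_counts("ATG"), c(n = 3, s = 0))
  expect_equal(ng86_site_counts("CTG"), c(n = 5 / 3, s = 4 / 3))
  expect_error(ng86_site_counts("TAA"), "sense codon")
  # site-count conservation: n + s = 3 for every sense codon
  tabs <- vapply(fastz:::codon_tables()$codons,
                 function(c) sum(ng86_site_counts(c)), numeric(1))
  expect_equal(unname(tabs), rep(3, 61))
})

test_that("pairwise NG86 reproduces the worked examples and is symmetric", {
  a <- paste0(rep_codon("CTG", 9), "TTT")
  b <- paste0(rep_codon("CTG", 9), "TTC")
  r <- ng86_pairwise(a, b)
  expect_equal(r$S, 37 / 3, tolerance = 1e-12)
  expect_equal(r$N, 53 / 3, tolerance = 1e-12)
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$dS, -3 / 4 * log(1 - 4 / 3 * (3 / 37)), tolerance = 1e-12)
  expect_equal(r$dN, 0)

  # TTT vs GTA: two orderings, one with a synonymous second step
  r2 <- ng86_pairwise("TTT", "GTA")
  expect_equal(r2$Nd, 1.5)
  expect_equal(r2$Sd, 0.5)

  r0 <- ng86_pairwise(a, a)
  expect_equal(c(r0$Nd, r0$Sd, r0$dN, r0$dS), c(0, 0, 0, 0))

  ab <- ng86_pairwise(a, b); ba <- ng86_pairwise(b, a)
  expect_equal(ab[c("Nd", "Sd", "N", "S", "dN", "dS")],
               ba[c("Nd", "Sd", "N", "S", "dN", "dS")])

  # ambiguity characters are skipped pairwise-complete
  rn <- ng86_pairwise(paste0("NNN", rep_codon("CTG", 3)),
                      paste0("ATG", rep_codon("CTG", 3)))
  expect_equal(rn$n_codons, 3)
  expect_true("codons_skipped" %in% rn$flags)

  # saturation flag (p_N beyond the Jukes-Cantor range)
  sat <- ng86_pairwise(rep_codon("ATG", 3), rep_codon("CCC", 3))
  expect_true("saturated" %in% sat$flags)
  expect_true(is.na(sat$dN))
})

test_that("pairwise ML recovers parameters and honours degenerate inputs", {
  a <- rep_codon("CTG", 40)
  fid <- ml_pairwise(a, a)
  expect_lt(fid$t, 1e-5)
  expect_true("identical_sequences" %in% fid$flags)

  # only synonymous differences: omega driven to its lower bound
  b <- paste0(rep_codon("CTA", 10), rep_codon("CTG", 30))
  fsyn <- ml_pairwise(a, b)
  expect_true("omega_at_bound" %in% fsyn$flags)

  g <- simulate_codon_gene(pair_tree(0.15, 0.15), 0.2, 2, NULL, 2000,
                           seed = 5)
  f <- ml_pairwise(g$aln[["a"]], g$aln[["b"]])
  expect_equal(f$convergence, 0L)
  expect_lt(abs(f$t - 0.3) / 0.3, 0.2)
  expect_lt(abs(f$omega - 0.2) / 0.2, 0.25)
  expect_lt(abs(f$kappa - 2) / 2, 0.35)
  # the optimum is at least as good as the truth
  expect_gte(f$loglik + 1e-6,
             local({
               m <- codon_model(2, 0.2)
               idx <- fastz:::codon_index_matrix(g$aln)
               P <- codon_prob_matrix(m, 0.3)
               sum(log(m$pi[idx[, 1]] * P[cbind(idx[, 1], idx[, 2])]))
             }))
})

test_that("marginal reconstruction matches brute-force enumeration", {
  tr <- three_tip_tree()
  g <- simulate_codon_gene(tr, 0.3, 2, NULL, 25, seed = 8)
  model <- codon_model(2, 0.3)
  rec <- reconstruct_ancestors(tr, g$aln, model)

  # brute force: enumerate both internal states for every site
  idx <- fastz:::codon_index_matrix(g$aln[tr$tip.label])
  P <- lapply(seq_len(nrow(tr$edge)),
              function(e) codon_prob_matrix(model, tr$edge.length[e]))
  root <- 4L; inner <- 5L
  e_in <- which(tr$edge[, 2] == inner)
  e_c <- which(tr$edge[, 2] == which(tr$tip.label == "c"))
  e_a <- which(tr$edge[, 2] == which(tr$tip.label == "a"))
  e_b <- which(tr$edge[, 2] == which(tr$tip.label == "b"))
  ia <- idx[, "a"]; ib <- idx[, "b"]; ic <- idx[, "c"]
  for (site in c(1, 7, 13, 25)) {
    joint <- matrix(0, 61, 61)   # root x inner
    for (r in 1:61) for (i in 1:61) {
      joint[r, i] <- model$pi[r] * P[[e_c]][r, ic[site]] *
        P[[e_in]][r, i] * P[[e_a]][i, ia[site]] * P[[e_b]][i, ib[site]]
    }
    pr <- rowSums(joint) / sum(joint)
    pi_in <- colSums(joint) / sum(joint)
    expect_equal(unname(rec$posterior["4", site]), max(pr), tolerance = 1e-10)
    expect_equal(unname(rec$posterior["5", site]), max(pi_in), tolerance = 1e-10)
    expect_equal(unname(rec$states["4", site]), which.max(pr))
    expect_equal(unname(rec$states["5", site]), which.max(pi_in))
  }

  # all tips identical at a site: the ancestor is that codon
  same <- rep(rep_codon("ATG", 10), 3)
  names(same) <- tr$tip.label
  rs <- reconstruct_ancestors(tr, same, model)
  expect_true(all(rs$states == fastz:::codon_tables()$index[["ATG"]]))
  expect_true(all(rs$posterior > 0.99))

  expect_error(reconstruct_ancestors(tr, g$aln[c("a", "b")], model),
               "mismatch")
})

test_that("branch counts reduce to pairwise on two tips and honour zeros", {
  tr <- pair_tree(0.05, 0.05)
  g <- simulate_codon_gene(tr, 0.25, 2, NULL, 500, seed = 9)
  bc <- branch_counts(tr, g$aln, codon_model(2, 0.25))
  pw <- ng86_pairwise(g$aln[["a"]], g$aln[["b"]])
  expect_lt(abs(sum(bc$Nd) - pw$Nd), 0.25 * max(4, pw$Nd))
  expect_lt(abs(sum(bc$Sd) - pw$Sd), 0.25 * max(4, pw$Sd))

  trz <- pair_tree(0, 0.2)
  gz <- simulate_codon_gene(trz, 0.25, 2, NULL, 300, seed = 10)
  bz <- branch_counts(trz, gz$aln, codon_model(2, 0.25))
  expect_equal(bz$Nd[bz$unit == "a"] + bz$Sd[bz$unit == "a"], 0)
})

test_that("summed branch counts track simulation truth on a small clade", {
  tr <- simulate_tree(8, 6, seed = 21)
  tot_true <- c(N = 0, S = 0); tot_est <- c(N = 0, S = 0)
  for (i in 1:25) {
    g <- simulate_codon_gene(tr, 0.2, 2, NULL, 300, seed = 300 + i)
    bc <- branch_counts(tr, g$aln, codon_model(2, 0.2))
    term <- g$truth$child_label %in% tr$tip.label
    tot_true <- tot_true + c(N = sum(g$truth$nnonsyn[term]),
                             S = sum(g$truth$nsyn[term]))
    tot_est <- tot_est + c(N = sum(bc$Nd), S = sum(bc$Sd))
  }
  expect_lt(abs(tot_est[["N"]] - tot_true[["N"]]) / tot_true[["N"]], 0.15)
  expect_lt(abs(tot_est[["S"]] - tot_true[["S"]]) / tot_true[["S"]], 0.15)
})
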