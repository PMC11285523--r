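# simulated trees, traits, codon alignments, coverage tables and the
# sex-linked effective-size theory

test_that("simulate_tree produces rooted binary trees deterministically", {
  expect_error(simulate_tree(1), "n_tips")
  t2 <- simulate_tree(2, 1, seed = 5)
  expect_equal(length(t2$tip.label), 2)
  expect_equal(nrow(t2$edge), 2)           # a single cherry
  t16 <- simulate_tree(16, 1, seed = 5)
  expect_equal(nrow(t16$edge), 30)         # 2n - 2 edges
  expect_true(ape::is.binary.phylo(t16))
  expect_true(ape::is.rooted(t16))
  expect_true(all(t16$edge.length >= 0))
  expect_identical(ape::write.tree(t16),
                   ape::write.tree(simulate_tree(16, 1, seed = 5)))
})

test_that("Mk trait simulation respects rates, seed, and stationarity", {
  tr <- simulate_tree(8, 4, seed = 2)
  expect_error(simulate_trait_mk(tr, -1, 1), "rates")
  frozen <- simulate_trait_mk(tr, 0, 0, root_state = 0, seed = 1)
  expect_true(all(frozen$tip_states == 0))
  expect_equal(frozen$n_changes, 0L)
  a <- simulate_trait_mk(tr, 1, 3, seed = 42)
  b <- simulate_trait_mk(tr, 1, 3, seed = 42)
  expect_identical(a, b)

  # long isolated branches reach the stationary distribution q01/(q01+q10)
  ntip <- 300
  star <- structure(list(
    edge = cbind(rep(ntip + 1L, ntip), seq_len(ntip)),
    edge.length = rep(100, ntip),
    tip.label = paste0("s", seq_len(ntip)), Nnode = 1L), class = "phylo")
  s <- simulate_trait_mk(star, 1, 3, root_state = 0, seed = 7)
  p1 <- mean(s$tip_states)
  expect_lt(abs(p1 - 0.25), 3 * sqrt(0.25 * 0.75 / ntip))
})

test_that("omega_profile maps categories to branch-level omega", {
  tr <- simulate_tree(6, 4, seed = 3)
  tips <- setNames(rep("monogamy", 6), tr$tip.label)
  tips[c("t1", "t2")] <- "role_reversed_polyandry"
  nodes <- setNames(rep("monogamy", tr$Nnode),
                    as.character(7:(6 + tr$Nnode)))
  fac <- c(role_reversed_polyandry = 1.27, monogamy = 1.09)
  prof <- omega_profile(tr, tips, nodes, 0.145, fac)
  expect_equal(nrow(prof), nrow(tr$edge))
  rr_edges <- prof$child_label %in% c("t1", "t2")
  expect_equal(unique(prof$omega_z[rr_edges]), 0.145 * 1.27)
  expect_equal(prof$omega_z[prof$child_label == "t3"], 0.145 * 1.09)
  expect_equal(unique(prof$omega_a), 0.145)

  ident <- omega_profile(tr, tips, nodes, 0.15,
                         c(role_reversed_polyandry = 1, monogamy = 1))
  expect_equal(ident$omega_z, ident$omega_a)
  zero <- omega_profile(tr, tips, nodes, 0.15,
                        c(role_reversed_polyandry = 0, monogamy = 0))
  expect_true(all(zero$omega_z == 0))
  expect_error(omega_profile(tr, tips, nodes, 0.15, c(monogamy = 1.09)),
               "category")
})

test_that("codon simulation honours omega, branch lengths, seed and truth", {
  tr <- simulate_tree(6, 6, seed = 4)
  g0 <- simulate_codon_gene(tr, 0, 2, NULL, 150, seed = 1)
  expect_equal(sum(g0$truth$nnonsyn), 0)    # omega 0: no non-synonymous events
  expect_gt(sum(g0$truth$nsyn), 0)

  tr0 <- tr; tr0$edge.length[] <- 0
  gz <- simulate_codon_gene(tr0, 0.2, 2, NULL, 60, seed = 2)
  expect_true(all(gz$aln == gz$root))
  expect_equal(sum(gz$truth$nsyn) + sum(gz$truth$nnonsyn), 0)

  ga <- simulate_codon_gene(tr, 0.3, 2, NULL, 120, seed = 3)
  gb <- simulate_codon_gene(tr, 0.3, 2, NULL, 120, seed = 3)
  expect_identical(ga, gb)
  expect_true(all(nchar(ga$aln) == 360))
  expect_false(any(grepl("TAA|TAG|TGA",
                         vapply(ga$aln, function(s)
                           paste(substring(s, seq(1, 358, 3),
                                           seq(3, 360, 3)),
                                 collapse = " "), "")[1])))
  # positive frequency on a stop codon (TAA) is rejected
  bad_pi <- rep(1 / 64, 64)
  bad_pi[11] <- bad_pi[11] + 3 / 64   # TAA in TCAG order
  bad_pi <- bad_pi / sum(bad_pi)
  expect_error(simulate_codon_gene(tr, 0.2, 2, pi = bad_pi, n_codons = 10),
               "stop codons")
})

test_that("NG86 on a long simulated pair recovers the generative omega", {
  tr <- pair_tree(0.15, 0.15)
  g <- simulate_codon_gene(tr, 0.2, 2, NULL, 5000, seed = 1)
  est <- ng86_pairwise(g$aln[["a"]], g$aln[["b"]])
  expect_lt(abs(est$dnds - 0.2) / 0.2, 0.15)
  # omega = 1: estimates centred on 1 within 10%
  g1 <- simulate_codon_gene(tr, 1, 2, NULL, 5000, seed = 1)
  est1 <- ng86_pairwise(g1$aln[["a"]], g1$aln[["b"]])
  expect_lt(abs(est1$dnds - 1), 0.1)
})

test_that("coverage simulation encodes the half-depth Z signal", {
  scafs <- data.frame(scaffold = c("z1", "a1"), length_bp = 5e4,
                      is_z = c(TRUE, FALSE))
  cov <- simulate_coverage(scafs, 5, 5, 45, 20, seed = 1)
  expect_identical(cov, simulate_coverage(scafs, 5, 5, 45, 20, seed = 1))
  expect_equal(nrow(cov), 20)
  # construction: expected female depth on Z is half the male depth
  fz <- mean(cov$mean_depth[cov$scaffold == "z1" & cov$sex == "female"])
  mz <- mean(cov$mean_depth[cov$scaffold == "z1" & cov$sex == "male"])
  expect_lt(abs(fz / mz - 0.5), 0.25)
  expect_warning(simulate_coverage(scafs, 0, 5, 45, 20, seed = 1),
                 "missing sex")
})

test_that("closed-form Ne ratios match theory in centre and limits", {
  expect_equal(ne_ratio(50, 50), 0.75)
  expect_equal(ne_ratio(50, 50, "variance"), 0.75)
  # extreme polygyny: copy-count limit 1/2; variance limit 9/16
  expect_lt(abs(ne_ratio(1, 1e6) - 0.5), 1e-3)
  expect_lt(abs(ne_ratio(1, 1e6, "variance") - 9 / 16), 1e-3)
  # extreme role-reversed polyandry: copy-count limit 1
  expect_lt(abs(ne_ratio(1e6, 1) - 1), 1e-3)
  expect_error(ne_ratio(0, 5), ">= 1")
  # monotone increasing in the male share, equal to 0.75 iff N_m = N_f
  share <- seq(0.05, 0.95, by = 0.05)
  vals <- vapply(share, function(s)
    ne_ratio(round(1000 * s), 1000 - round(1000 * s)), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_equal(vals[share == 0.5], 0.75)
  expect_true(all(vals[share != 0.5] != 0.75))
})

test_that("Wright-Fisher simulation tracks the closed forms", {
  w <- wf_simulate_ne(20, 20, n_loci = 200, generations = 120, seed = 11)
  expect_lt(abs(w$ratio - 0.75), 3 * w$se)
  # strong harem skew pushes the ratio below the monogamy value, toward
  # the variance closed form for the reduced number of breeding males
  wsk <- wf_simulate_ne(20, 20, skew = 0.8, n_loci = 200,
                        generations = 120, seed = 12)
  expect_lt(wsk$ratio, w$ratio)
  expect_lt(abs(wsk$ratio - ne_ratio(4, 20, "variance")), 3 * wsk$se)
  expect_error(wf_simulate_ne(1, 20), ">= 2")
})
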