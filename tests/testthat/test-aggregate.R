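# filtering, concatenation, fast-Z statistics and bootstrap

test_that("free-ratios filter drops genes by the strict > 1 rule", {
  # 5 genes; g2 has dS = 1.2 on one branch; g5 sits exactly at 1.0
  recs <- make_records(
    list("g1", "sp1", "A", 4, 2, 200, 100),
    list("g2", "sp1", "A", 4, 120, 200, 100),
    list("g3", "sp1", "A", 4, 5, 200, 100),
    list("g4", "sp2", "A", 4, 5, 200, 100),
    list("g5", "sp1", "A", 4, 100, 200, 100))
  f <- filter_free_ratios(recs)
  expect_setequal(unique(f$kept$gene), c("g1", "g3", "g4", "g5"))
  expect_equal(f$excluded$gene, "g2")
  expect_equal(f$excluded$reason, "rate_exceeds_1")
  # saturated records (NA rates) also drop the gene
  recs$dN[recs$gene == "g3"] <- NA
  f2 <- filter_free_ratios(recs)
  expect_setequal(unique(f2$kept$gene), c("g1", "g4", "g5"))
  # all clean is the identity
  clean <- make_records(list("g1", "sp1", "A", 4, 2, 200, 100))
  expect_equal(filter_free_ratios(clean)$kept, clean)
})

test_that("concatenation sums counts before dividing", {
  recs <- make_records(
    list("gene1", "sp1", "A", 4, 2, 200, 100),
    list("gene2", "sp1", "A", 0, 6, 100, 50))
  cc <- concat_partition_rates(recs)
  expect_equal(cc$DN, 4 / 300)
  expect_equal(cc$DS, 8 / 150)
  expect_equal(cc$ratio, 0.25)
  expect_equal(cc$n_subs, 12)
  # single gene: equals that gene's rates
  one <- concat_partition_rates(recs[1, ])
  expect_equal(one$ratio, (4 / 200) / (2 / 100))
  # duplicating every gene leaves the rates unchanged
  dup <- rbind(recs, transform(recs, gene = paste0(gene, "_copy")))
  expect_equal(concat_partition_rates(dup)[c("DN", "DS", "ratio")],
               cc[c("DN", "DS", "ratio")])
  # gene order is irrelevant
  expect_equal(concat_partition_rates(recs[2:1, ])[c("DN", "DS", "ratio")],
               cc[c("DN", "DS", "ratio")])
  # no synonymous substitutions: flagged undefined
  z <- concat_partition_rates(make_records(
    list("g", "sp1", "Z", 4, 0, 200, 100)))
  expect_true(is.na(z$ratio))
  expect_equal(z$flag, "DS_zero")
})

test_that("fast-Z ratio divides partition ratios per species", {
  recs <- rbind(make_records(list("gz", "sp1", "Z", 18.415, 100, 1000, 1000)),
                make_records(list("ga", "sp1", "A", 14.5, 100, 1000, 1000)))
  cc <- concat_partition_rates(recs)
  fz <- fastz_ratio(cc)
  # group-mean consistency: 0.184 over 0.145 prints as 1.27
  expect_equal(round(fz$fastz, 2), 1.27)
  expect_equal(fz$ratio_Z, 0.18415)
  equal <- rbind(make_records(list("gz", "s", "Z", 5, 10, 100, 100)),
                 make_records(list("ga", "s", "A", 5, 10, 100, 100)))
  expect_equal(fastz_ratio(concat_partition_rates(equal))$fastz, 1)
})

test_that("bootstrap is seed-stable with degenerate and regular inputs", {
  # identical genes: zero-width intervals
  same <- make_records(list("g1", "sp1", "A", 4, 2, 200, 100),
                       list("g2", "sp1", "A", 4, 2, 200, 100),
                       list("g3", "sp1", "A", 4, 2, 200, 100))
  b <- bootstrap_ci(same, B = 50, seed = 1)
  r <- b[b$quantity == "ratio", ]
  expect_equal(r$ci_lo, r$ci_hi)
  expect_equal(r$ci_lo, r$estimate)

  set.seed(33)
  recs <- do.call(rbind, lapply(1:12, function(i)
    make_records(list(paste0("g", i), "sp1",
                      if (i <= 6) "Z" else "A",
                      rpois(1, 8) + 1, rpois(1, 12) + 1, 500, 260))))
  b1 <- bootstrap_ci(recs, B = 200, seed = 7)
  b2 <- bootstrap_ci(recs, B = 200, seed = 7)
  expect_identical(b1, b2)
  fzrow <- b1[b1$quantity == "fastz", ]
  expect_true(fzrow$ci_lo <= fzrow$estimate & fzrow$estimate <= fzrow$ci_hi)
  # fewer than 2 genes: intervals undefined
  b3 <- bootstrap_ci(recs[recs$gene == "g1", ], B = 20, seed = 1)
  expect_true(all(is.na(b3$ci_lo)))
})

test_that("pairwise filter applies count thresholds per outgroup", {
  pr <- function(gene, focal, outgroup, Nd, Sd, dN = Nd / 300, dS = Sd / 150)
    data.frame(gene = gene, focal = focal, outgroup = outgroup,
               partition = "A", Nd = Nd, Sd = Sd, N = 300, S = 150,
               dN = dN, dS = dS, dnds = dN / dS, stringsAsFactors = FALSE)
  recs <- rbind(
    pr("g1", "f1", "o1", 6, 4),     # 4 synonymous: dropped for o1
    pr("g1", "f2", "o1", 8, 9),
    pr("g1", "f1", "o2", 5, 5),     # exactly 5/5 everywhere: kept
    pr("g1", "f2", "o2", 6, 7),
    pr("g2", "f1", "o1", 9, 9),
    pr("g2", "f2", "o1", 9, 9, dS = 1.3),  # rate > 1: dropped for o1 only
    pr("g2", "f1", "o2", 9, 9),
    pr("g2", "f2", "o2", 9, 9))
  f <- filter_pairwise(recs)
  kept_keys <- unique(paste(f$kept$gene, f$kept$outgroup))
  expect_setequal(kept_keys, c("g1 o2", "g2 o2"))
  expect_setequal(paste(f$excluded$gene, f$excluded$outgroup,
                        f$excluded$reason),
                  c("g1 o1 too_few_substitutions", "g2 o1 rate_exceeds_1"))
  # boundary: a rate of exactly 1.0 is kept
  ok1 <- filter_pairwise(rbind(pr("g3", "f1", "o1", 9, 9, dS = 1.0)))
  expect_equal(nrow(ok1$kept), 1)
  # the non-synonymous threshold can be switched off for the dS analysis
  fds <- filter_pairwise(rbind(pr("g4", "f1", "o1", 2, 9)), min_nonsyn = 0)
  expect_equal(nrow(fds$kept), 1)
})

test_that("pairwise aggregation is a geometric mean with outgroup averaging", {
  pr <- function(gene, focal, outgroup, partition, dnds)
    data.frame(gene = gene, focal = focal, outgroup = outgroup,
               partition = partition, Nd = 9, Sd = 9, N = 300, S = 150,
               dN = 0.03, dS = 0.06, dnds = dnds, stringsAsFactors = FALSE)
  recs <- rbind(pr("g1", "f1", "o1", "A", 0.1),
                pr("g2", "f1", "o1", "A", 0.4),
                pr("g3", "f1", "o1", "Z", 0.3),
                pr("g1", "f1", "o2", "A", 0.2),
                pr("g3", "f1", "o2", "Z", 0.3))
  agg <- aggregate_pairwise(recs)
  po <- agg$per_outgroup
  expect_equal(po$geomean[po$outgroup == "o1" & po$partition == "A"],
               sqrt(0.1 * 0.4))   # back-transform of mean log2 = geometric mean
  # single gene: back-transform inverts the transform
  expect_equal(po$geomean[po$outgroup == "o2" & po$partition == "A"], 0.2)
  # per-species average across outgroups is arithmetic
  expect_equal(agg$per_species$value_A, mean(c(0.2, 0.2)))
  expect_equal(agg$per_species$fastz, mean(c(0.3 / 0.2, 0.3 / 0.2)))
  # permuting gene order changes nothing
  agg2 <- aggregate_pairwise(recs[sample(nrow(recs)), ])
  expect_equal(agg2$per_species, agg$per_species)
  # scale consistency: multiplying every dN/dS by c scales the aggregate by c
  sc <- recs; sc$dnds <- sc$dnds * 3
  expect_equal(aggregate_pairwise(sc)$per_outgroup$geomean,
               agg$per_outgroup$geomean * 3)
  bad <- recs; bad$dnds[1] <- 0
  expect_error(aggregate_pairwise(bad), "non-positive")
})
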