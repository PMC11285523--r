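#!/usr/bin/env Rscript
# Stage 5: mating-system comparisons.
#
# Paired t-test for the presence of fast-Z (Z vs autosomal concatenated
# dN/dS, paired by species); Welch t-tests for the effect of role-reversed
# polyandry on the fast-Z ratio and on each partition's rate; PGLS (with
# maximum-likelihood Pagel's lambda) on the pairwise-route per-species
# values, including the dS models with a generation-time covariate.

suppressPackageStartupMessages(library(fastz))

out <- "results/stats"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

traits <- read_fastz_tsv("results/simdata/traits.tsv")
tree <- read_newick("results/simdata/tree.nwk")
fz <- read_fastz_tsv("results/fastz/fastz_per_species.tsv")
ps <- read_fastz_tsv("results/fastz/pairwise_per_species.tsv")
ds <- read_fastz_tsv("results/fastz/pairwise_ds_per_species.tsv")

rows <- list()
add <- function(test, term, estimate, t, df, p)
  rows[[length(rows) + 1]] <<- data.frame(test = test, term = term,
                                          estimate = estimate, t = t,
                                          df = df, p = p)

pt <- paired_ttest(fz$ratio_Z, fz$ratio_A)
add("paired_fastz_presence", "Z_minus_A", pt$mean_diff, pt$t, pt$df, pt$p)
message("fast-Z presence (paired, n=", pt$n, "): t = ", round(pt$t, 2),
        ", p = ", signif(pt$p, 3))

cat_sp <- traits$category[match(fz$unit, traits$species)]
rr <- cat_sp == "role_reversed_polyandry"
for (v in c("fastz", "ratio_Z", "ratio_A")) {
  w <- welch_ttest(fz[[v]][rr], fz[[v]][!rr])
  add(paste0("welch_", v), "role_reversed_vs_other", w$mean1 - w$mean2,
      w$t, w$df, w$p)
  message("Welch ", v, ": groups ", round(w$mean1, 3), " vs ",
          round(w$mean2, 3), ", t = ", round(w$t, 2), ", p = ",
          signif(w$p, 3))
}

pdat <- data.frame(
  species = ps$focal,
  fastz = ps$fastz,
  mating_system = as.integer(traits$category[match(ps$focal,
                                                   traits$species)] ==
                               "role_reversed_polyandry"),
  generation_time = traits$generation_time_yr[match(ps$focal,
                                                    traits$species)],
  log2_dsz = log2(ds$value_Z[match(ps$focal, ds$focal)]),
  log2_dsa = log2(ds$value_A[match(ps$focal, ds$focal)]))
ftree <- ape::keep.tip(tree, pdat$species)

models <- list(fastz = fastz ~ mating_system,
               log2_dsz = log2_dsz ~ mating_system + generation_time,
               log2_dsa = log2_dsa ~ mating_system + generation_time)
pg_rows <- list()
for (nm in names(models)) {
  fit <- pgls_fit(models[[nm]], pdat, ftree)
  co <- fit$coefficients
  co$model <- nm
  co$lambda <- fit$lambda
  pg_rows[[nm]] <- co
  ms <- co[co$term == "mating_system", ]
  message("PGLS ", nm, ": lambda = ", round(fit$lambda, 3),
          ", mating-system t = ", round(ms$t, 2), ", p = ",
          signif(ms$p, 3))
}
write_fastz_tsv(do.call(rbind, rows), file.path(out, "ttests.tsv"))
write_fastz_tsv(do.call(rbind, pg_rows), file.path(out, "pgls.tsv"))
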