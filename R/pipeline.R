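# Study-level synthetic data generation and the end-to-end pipeline:
# simulate -> Z assignment -> substitution rates -> filters/aggregation/
# bootstrap -> comparative statistics -> ancestral-state reconstruction.

#' Pipeline configuration with the analysis defaults
#'
#' Thresholds default to the printed values of the comparative fast-Z design
#' (coverage band 0.4-0.65, >20 kb scaffolds, autosome size window 20-200
#' Mb, substitution-rate cap 1, minimum 5 synonymous and 5 non-synonymous
#' substitutions per pairwise comparison, bootstrap B = 1000 at the 95%
#' level); generative defaults place autosomal dN/dS at 0.145 with a Z
#' amplification of 1.27 under role-reversed polyandry and 1.09 otherwise,
#' the group means of the free-ratios comparison the generator emulates.
#'
#' @param n_tips,tree_rate tips and Yule birth rate of the simulated tree.
#' @param q01,q10 Mk transition rates of the mating-system trait
#'   (0 = non-reversed, 1 = role-reversed polyandry).
#' @param omega_a autosomal dN/dS.
#' @param z_factor_role_reversed,z_factor_other Z amplification factors.
#' @param kappa transition/transversion rate ratio of the codon model.
#' @param n_genes_a,n_genes_z,n_genes_micro genes on macro-autosomes, on the
#'   Z, and on micro-chromosomes (the latter exercise the size filter).
#' @param n_codons codons per gene.
#' @param n_males,n_females,mean_depth,dispersion coverage-simulation
#'   parameters (5 + 5 sexed samples at 45X by default).
#' @param n_z_scaffolds,n_a_scaffolds,scaffold_bp coverage scaffold layout.
#' @param min_scaffold_bp,ratio_band Z-assignment thresholds.
#' @param size_window autosome size window name or c(lo, hi) in Mb.
#' @param rate_cap per-branch dN/dS exclusion threshold.
#' @param min_syn,min_nonsyn pairwise substitution-count thresholds.
#' @param bootstrap_B,ci_level bootstrap settings.
#' @param seed master seed; all stage seeds derive from it.
#' @param out_dir if non-NULL, all tables are written there as TSV.
#' @return named list of class `fastz_config`.
#' @export
run_config <- function(n_tips = 16, tree_rate = 8,
                       q01 = 2, q10 = 4,
                       omega_a = 0.145,
                       z_factor_role_reversed = 1.27,
                       z_factor_other = 1.09,
                       kappa = 2,
                       n_genes_a = 200, n_genes_z = 40, n_genes_micro = 10,
                       n_codons = 300,
                       n_males = 5, n_females = 5,
                       mean_depth = 45, dispersion = 20,
                       n_z_scaffolds = 10, n_a_scaffolds = 40,
                       scaffold_bp = 50000,
                       min_scaffold_bp = 20000,
                       ratio_band = c(0.4, 0.65),
                       size_window = "default",
                       rate_cap = 1,
                       min_syn = 5, min_nonsyn = 5,
                       bootstrap_B = 1000, ci_level = 0.95,
                       seed = 1, out_dir = NULL) {
  cfg <- as.list(environment())
  stopifnot(cfg$omega_a >= 0, cfg$kappa >= 0,
            cfg$z_factor_role_reversed >= 0, cfg$z_factor_other >= 0,
            cfg$q01 >= 0, cfg$q10 >= 0)
  class(cfg) <- "fastz_config"
  cfg
}

# chicken-like chromosome sizes (Mb): macro-autosomes 1-10, a few
# micro-chromosomes, and the Z
chromosome_map <- function() {
  data.frame(
    chromosome = c(as.character(1:10), "m1", "m2", "m3", "Z"),
    size_mb = c(197, 149, 111, 91, 60, 36, 39, 30, 26, 21, 12, 8, 5, 83),
    stringsAsFactors = FALSE)
}

#' Generate a full synthetic study data set
#'
#' One call produces every input of the comparative fast-Z analysis, plus
#' the exact truth needed to score estimators: a Yule tree, a binary
#' mating-system trait (with at least two tips per state overall and within
#' the focal clade, by deterministic redraw), per-species trait records,
#' gene locations on a chicken-like chromosome map, codon alignments evolved
#' with partition- and category-dependent omega, a sexed coverage table over
#' Z and autosomal scaffolds, and event-level substitution truth.
#'
#' @param config a [run_config()].
#' @return list with `tree`, `trait` (tip/node states), `traits`
#'   (per-species table), `genes` (gene metadata: gene, chromosome, size_mb,
#'   scaffold, partition_true), `alignments` (named list of named character
#'   vectors), `truth` (per gene x edge event counts), `scaffolds`,
#'   `coverage`, `outgroups`, `focal`, `config`.
#' @export
simulate_study <- function(config = run_config()) {
  cfg <- config
  tree <- simulate_tree(cfg$n_tips, cfg$tree_rate, seed = cfg$seed)

  # outgroup set = the smaller clade off the root (ties: the one holding t1)
  root <- length(tree$tip.label) + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  clade_tips <- lapply(kids, function(k) {
    if (k <= length(tree$tip.label)) tree$tip.label[k]
    else ape::extract.clade(tree, k)$tip.label
  })
  sizes <- lengths(clade_tips)
  og_i <- if (sizes[1] == sizes[2]) {
    if ("t1" %in% clade_tips[[1]]) 1L else 2L
  } else which.min(sizes)
  outgroups <- clade_tips[[og_i]]
  focal <- setdiff(tree$tip.label, outgroups)

  # trait: redraw deterministically until both states are represented twice
  # overall and twice among focal species (the comparative design needs
  # role-reversed and non-reversed focal species)
  attempt <- 0L
  repeat {
    trait <- simulate_trait_mk(tree, cfg$q01, cfg$q10, root_state = 0,
                               seed = cfg$seed + 13L + 101L * attempt)
    st <- trait$tip_states
    if (min(tabulate(st + 1L, 2L)) >= 2 &&
        min(tabulate(st[focal] + 1L, 2L)) >= 2) break
    attempt <- attempt + 1L
    if (attempt > 500L)
      stop("could not place both mating systems among the focal clade; ",
           "adjust q01/q10 or the tree")
  }
  categories <- ifelse(trait$tip_states == 1, "role_reversed_polyandry",
                       "monogamy")
  names(categories) <- names(trait$tip_states)
  node_categories <- ifelse(trait$node_states == 1,
                            "role_reversed_polyandry", "monogamy")
  names(node_categories) <- names(trait$node_states)

  traits <- with_seed(cfg$seed + 29L, {
    rr <- categories == "role_reversed_polyandry"
    data.frame(
      species = names(categories),
      female_polygamy_pct = ifelse(rr, stats::runif(sum(rr) + sum(!rr),
                                                    30, 80),
                                   stats::runif(length(rr), 0, 0.9)),
      male_polygamy_pct = stats::runif(length(rr), 0, 0.9),
      care_sex = ifelse(rr, "male", "both"),
      lekking = FALSE,
      generation_time_yr = stats::rlnorm(length(rr), log(6), 0.3),
      category = unname(categories),
      stringsAsFactors = FALSE)
  })

  chrom <- chromosome_map()
  macro <- chrom[chrom$chromosome %in% as.character(1:10), ]
  micro <- chrom[grepl("^m", chrom$chromosome), ]
  gene_chr <- with_seed(cfg$seed + 31L, c(
    sample(macro$chromosome, cfg$n_genes_a, replace = TRUE,
           prob = macro$size_mb),
    rep("Z", cfg$n_genes_z),
    sample(micro$chromosome, cfg$n_genes_micro, replace = TRUE)))
  n_genes <- length(gene_chr)
  genes <- data.frame(
    gene = sprintf("g%04d", seq_len(n_genes)),
    chromosome = gene_chr,
    size_mb = chrom$size_mb[match(gene_chr, chrom$chromosome)],
    partition_true = ifelse(gene_chr == "Z", "Z",
                            ifelse(grepl("^m", gene_chr), "micro", "A")),
    stringsAsFactors = FALSE)

  # coverage scaffolds; Z genes are spread over the Z scaffolds so
  # coverage-based calls propagate to genes.  A few sub-cutoff scaffolds
  # exercise the length filter.
  scaffolds <- data.frame(
    scaffold = c(sprintf("scafZ%02d", seq_len(cfg$n_z_scaffolds)),
                 sprintf("scafA%02d", seq_len(cfg$n_a_scaffolds)),
                 "scafZshort", "scafAshort"),
    length_bp = c(rep(cfg$scaffold_bp, cfg$n_z_scaffolds + cfg$n_a_scaffolds),
                  10000, 10000),
    is_z = c(rep(TRUE, cfg$n_z_scaffolds), rep(FALSE, cfg$n_a_scaffolds),
             TRUE, FALSE),
    stringsAsFactors = FALSE)
  genes$scaffold <- with_seed(cfg$seed + 37L, ifelse(
    genes$partition_true == "Z",
    sample(sprintf("scafZ%02d", seq_len(cfg$n_z_scaffolds)),
           n_genes, replace = TRUE),
    sample(sprintf("scafA%02d", seq_len(cfg$n_a_scaffolds)),
           n_genes, replace = TRUE)))

  coverage <- simulate_coverage(scaffolds, cfg$n_males, cfg$n_females,
                                cfg$mean_depth, cfg$dispersion,
                                seed = cfg$seed + 41L)

  factors <- c(role_reversed_polyandry = cfg$z_factor_role_reversed,
               monogamy = cfg$z_factor_other)
  prof <- omega_profile(tree, categories, node_categories, cfg$omega_a,
                        factors)
  alignments <- vector("list", n_genes)
  truth <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    om <- if (genes$partition_true[i] == "Z") prof$omega_z else prof$omega_a
    g <- simulate_codon_gene(tree, om, cfg$kappa, NULL, cfg$n_codons,
                             seed = cfg$seed + 1000L + i)
    alignments[[i]] <- g$aln
    tr_i <- g$truth
    tr_i$gene <- genes$gene[i]
    truth[[i]] <- tr_i
  }
  names(alignments) <- genes$gene
  truth <- do.call(rbind, truth)

  list(tree = tree, trait = trait, traits = traits, genes = genes,
       alignments = alignments, truth = truth, scaffolds = scaffolds,
       coverage = coverage, outgroups = outgroups, focal = focal,
       config = cfg)
}

#' Free-ratios-substitute records for a set of genes
#'
#' Runs [branch_counts()] on every alignment and stacks the per-terminal-
#' branch records, attaching each gene's partition label.
#'
#' @param tree a `phylo` object.
#' @param alignments named list of codon alignments (named character
#'   vectors keyed by tip label).
#' @param partition named character vector gene -> `"Z"`/`"A"`.
#' @return free-ratios gene record data.frame (see [filter_free_ratios()]).
#' @export
free_ratio_records <- function(tree, alignments, partition) {
  recs <- lapply(names(alignments), function(g) {
    bc <- branch_counts(tree, alignments[[g]])
    bc$gene <- g
    bc$partition <- partition[[g]]
    bc
  })
  out <- do.call(rbind, recs)
  out[c("gene", "unit", "partition", "Nd", "Sd", "N", "S",
        "dN", "dS", "dnds", "flags")]
}

#' Pairwise NG86 records for focal x outgroup species pairs
#'
#' NG86 counting between every focal and every outgroup sequence of each
#' gene, with Jukes-Cantor corrected rates.
#'
#' @param alignments named list of codon alignments.
#' @param focal,outgroups character vectors of tip labels.
#' @param partition named character vector gene -> `"Z"`/`"A"`.
#' @return pairwise gene record data.frame (see [filter_pairwise()]).
#' @export
pairwise_records <- function(alignments, focal, outgroups, partition) {
  recs <- list()
  for (g in names(alignments)) {
    idx <- codon_index_matrix(alignments[[g]])
    for (o in outgroups) {
      for (f in focal) {
        cnt <- ng86_count_core(idx[, o], idx[, f])
        N <- (cnt$N_a + cnt$N_b) / 2
        S <- (cnt$S_a + cnt$S_b) / 2
        dN <- jc_correct(if (N > 0) cnt$Nd / N else 0)
        dS <- jc_correct(if (S > 0) cnt$Sd / S else 0)
        recs[[length(recs) + 1L]] <- data.frame(
          gene = g, focal = f, outgroup = o, partition = partition[[g]],
          Nd = cnt$Nd, Sd = cnt$Sd, N = N, S = S, dN = dN, dS = dS,
          dnds = if (!is.na(dN) && !is.na(dS) && dS > 0) dN / dS
                 else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, recs)
}

#' Run the full fast-Z analysis pipeline on synthetic data
#'
#' Executes: study simulation; coverage-based Z assignment and consensus
#' with the annotated chromosome map; free-ratios-substitute per-branch
#' rates with the dN/dS > 1 filter, concatenation, fast-Z ratios and
#' gene-resampling bootstrap; the paired t-test (Z vs autosomal rates across
#' species) and Welch t-tests (role-reversed vs non-reversed); pairwise
#' NG86 rates with the count filters, log2 aggregation and PGLS (fast-Z,
#' and dS with a generation-time covariate); and the Mk ancestral-state
#' reconstruction of the mating system.  Fully deterministic given
#' `config$seed`; all tables are written to `config$out_dir` when set.
#'
#' @param config a [run_config()].
#' @return list of class `fastz_run` with elements `study`, `z_assignment`,
#'   `partition`, `free_ratios`, `pairwise`, `stats`, `asr`, `summary_lines`.
#' @export
run_pipeline <- function(config = run_config()) {
  cfg <- config
  study <- simulate_study(cfg)
  log_lines <- character(0)
  note <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }

  # --- Z assignment from sexed coverage --------------------------------
  norm <- normalize_depths(study$coverage, cfg$min_scaffold_bp)
  ratios <- female_male_ratio(norm)
  calls <- assign_z(ratios, cfg$min_scaffold_bp, cfg$ratio_band)
  scall <- calls$call[match(study$genes$scaffold, calls$scaffold)]
  gene_calls <- data.frame(
    gene = study$genes$gene,
    call_refA = ifelse(scall == "Z", "Z",
                       ifelse(scall == "non-Z", "non-Z", NA)),
    call_refB = ifelse(study$genes$chromosome == "Z", "Z", "non-Z"),
    stringsAsFactors = FALSE)
  cons <- consensus_z_genes(gene_calls)
  note("Z assignment: ", sum(calls$call == "Z"), "/",
       nrow(calls), " scaffolds called Z; gene-call concordance ",
       format(cons$concordance, digits = 3))

  gene_meta <- cbind(study$genes,
                     cons$genes[match(study$genes$gene, cons$genes$gene),
                                c("call_refA", "call_refB", "consensus")])
  aut <- size_filter_autosomes(gene_meta, cfg$size_window)
  z_genes <- gene_meta$gene[gene_meta$consensus == "Z"]
  a_genes <- aut$genes$gene
  partition <- setNames(rep(NA_character_, nrow(gene_meta)), gene_meta$gene)
  partition[z_genes] <- "Z"
  partition[a_genes] <- "A"
  note("partitions: ", length(z_genes), " Z genes, ", length(a_genes),
       " autosomal genes (", nrow(aut$excluded), " excluded by size/",
       "discordance)")
  if (!length(z_genes))
    note("NOTE: empty Z partition; fast-Z statistics unavailable")

  used <- names(partition)[!is.na(partition)]
  aln_used <- study$alignments[used]

  # --- free-ratios substitute path -------------------------------------
  fr_recs <- free_ratio_records(study$tree, aln_used, partition)
  fr_filt <- filter_free_ratios(fr_recs)
  note("free-ratios filter: ", length(unique(fr_filt$kept$gene)), "/",
       length(unique(fr_recs$gene)), " genes kept (",
       nrow(fr_filt$excluded), " excluded)")
  concat <- concat_partition_rates(fr_filt$kept)
  fz <- fastz_ratio(concat)
  boot <- bootstrap_ci(fr_filt$kept, B = cfg$bootstrap_B,
                       level = cfg$ci_level, seed = cfg$seed + 71L)

  # --- comparative statistics on the free-ratios path ------------------
  stats_out <- list()
  zr <- fz$ratio_Z[match(study$tree$tip.label, fz$unit)]
  ar <- fz$ratio_A[match(study$tree$tip.label, fz$unit)]
  okp <- !is.na(zr) & !is.na(ar)
  if (sum(okp) >= 2 && stats::sd(zr[okp] - ar[okp]) > 0) {
    stats_out$paired <- paired_ttest(zr[okp], ar[okp])
    note("paired t-test (Z vs A dN/dS, ", sum(okp), " species): t = ",
         format(stats_out$paired$t, digits = 3), ", p = ",
         format(stats_out$paired$p, digits = 3))
  }
  cat_by_unit <- study$traits$category[match(fz$unit, study$traits$species)]
  rr <- cat_by_unit == "role_reversed_polyandry" & !is.na(fz$fastz)
  nr <- cat_by_unit != "role_reversed_polyandry" & !is.na(fz$fastz)
  if (sum(rr) >= 2 && sum(nr) >= 2) {
    stats_out$welch_fastz <- welch_ttest(fz$fastz[rr], fz$fastz[nr])
    stats_out$welch_z <- welch_ttest(fz$ratio_Z[rr], fz$ratio_Z[nr])
    stats_out$welch_a <- welch_ttest(fz$ratio_A[rr], fz$ratio_A[nr])
    note("Welch t-test on fast-Z (role-reversed n=", sum(rr),
         " vs other n=", sum(nr), "): t = ",
         format(stats_out$welch_fastz$t, digits = 3), ", p = ",
         format(stats_out$welch_fastz$p, digits = 3),
         "; group means ", format(stats_out$welch_fastz$mean1, digits = 3),
         " vs ", format(stats_out$welch_fastz$mean2, digits = 3))
  }

  # --- pairwise path ----------------------------------------------------
  pw_recs <- pairwise_records(aln_used, study$focal, study$outgroups,
                              partition)
  pw_filt <- filter_pairwise(pw_recs, cfg$min_syn, cfg$min_nonsyn)
  note("pairwise filter: ", nrow(pw_filt$kept), "/", nrow(pw_recs),
       " records kept (", nrow(pw_filt$excluded),
       " gene x outgroup exclusions)")
  pw_agg <- aggregate_pairwise(pw_filt$kept)
  pw_ds_filt <- filter_pairwise(pw_recs, cfg$min_syn, 0)
  pw_ds <- aggregate_pairwise(pw_ds_filt$kept, value = "dS")

  ps <- pw_agg$per_species
  pdat <- data.frame(
    species = ps$focal,
    fastz = ps$fastz,
    value_z = ps$value_Z,
    value_a = ps$value_A,
    mating_system = as.integer(
      study$traits$category[match(ps$focal, study$traits$species)] ==
        "role_reversed_polyandry"),
    generation_time = study$traits$generation_time_yr[
      match(ps$focal, study$traits$species)],
    stringsAsFactors = FALSE)
  pdat <- pdat[is.finite(pdat$fastz), , drop = FALSE]
  focal_tree <- if (nrow(pdat) >= 2)
    ape::keep.tip(study$tree, pdat$species) else NULL
  if (nrow(pdat) >= 4 &&
      length(unique(pdat$mating_system)) == 2 &&
      min(table(pdat$mating_system)) >= 2) {
    stats_out$pgls_fastz <- pgls_fit(fastz ~ mating_system, pdat, focal_tree)
    note("PGLS fast-Z ~ mating system: lambda = ",
         format(stats_out$pgls_fastz$lambda, digits = 3), ", t = ",
         format(stats_out$pgls_fastz$coefficients$t[2], digits = 3),
         ", p = ",
         format(stats_out$pgls_fastz$coefficients$p[2], digits = 3))
    dsdat <- pdat
    dss <- pw_ds$per_species
    dsdat$log2_dsz <- log2(dss$value_Z[match(dsdat$species, dss$focal)])
    dsdat$log2_dsa <- log2(dss$value_A[match(dsdat$species, dss$focal)])
    dsdat$ds_ratio <- dss$value_Z[match(dsdat$species, dss$focal)] /
      dss$value_A[match(dsdat$species, dss$focal)]
    ok <- !is.na(dsdat$generation_time)
    if (any(!ok))
      note("dropping ", sum(!ok), " species without generation time ",
           "from the dS models")
    stats_out$pgls_dsz <- pgls_fit(log2_dsz ~ mating_system +
                                     generation_time,
                                   dsdat[ok, ], focal_tree)
    stats_out$pgls_dsa <- pgls_fit(log2_dsa ~ mating_system +
                                     generation_time,
                                   dsdat[ok, ], focal_tree)
    stats_out$pgls_ds_ratio <- pgls_fit(ds_ratio ~ mating_system +
                                          generation_time,
                                        dsdat[ok, ], focal_tree)
  } else {
    note("NOTE: focal species lack a two-group mating-system contrast; ",
         "PGLS skipped")
  }

  # --- ancestral state reconstruction ----------------------------------
  asr <- mk_asr(study$tree, study$trait$tip_states)
  note("Mk ASR (ER): rate = ", format(asr$rates[["q01"]], digits = 3),
       ", root P(role-reversed) = ",
       format(asr$node_probs[1, "state1"], digits = 3))

  out <- structure(list(study = study,
                        z_assignment = calls,
                        gene_partition = data.frame(
                          gene = names(partition),
                          partition = unname(partition),
                          stringsAsFactors = FALSE),
                        free_ratios = list(records = fr_recs,
                                           kept = fr_filt$kept,
                                           excluded = fr_filt$excluded,
                                           concat = concat,
                                           fastz = fz,
                                           bootstrap = boot),
                        pairwise = list(records = pw_recs,
                                        kept = pw_filt$kept,
                                        excluded = pw_filt$excluded,
                                        aggregate = pw_agg,
                                        ds_aggregate = pw_ds),
                        stats = stats_out,
                        asr = asr,
                        summary_lines = log_lines,
                        config = cfg),
                   class = "fastz_run")
  if (!is.null(cfg$out_dir)) write_run(out, cfg$out_dir)
  out
}

# write all pipeline tables, a plain-text summary and a run manifest
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) write_fastz_tsv(df, file.path(dir, name))
  write_newick(run$study$tree, file.path(dir, "tree.nwk"))
  w(run$study$traits, "traits.tsv")
  w(run$study$genes, "genes.tsv")
  w(run$study$coverage, "coverage.tsv")
  w(run$study$truth, "truth_events.tsv")
  w(run$z_assignment, "z_assignment.tsv")
  w(run$gene_partition, "gene_partition.tsv")
  w(run$free_ratios$kept, "free_ratios_records.tsv")
  w(run$free_ratios$excluded, "free_ratios_excluded.tsv")
  w(run$free_ratios$concat, "concat_rates.tsv")
  w(run$free_ratios$fastz, "fastz_per_species.tsv")
  w(run$free_ratios$bootstrap, "bootstrap_ci.tsv")
  w(run$pairwise$kept, "pairwise_records.tsv")
  w(run$pairwise$excluded, "pairwise_excluded.tsv")
  w(run$pairwise$aggregate$per_species, "pairwise_per_species.tsv")
  np <- run$asr$node_probs
  w(data.frame(node = rownames(np), p_state0 = np[, 1], p_state1 = np[, 2]),
    "asr_node_probs.tsv")
  writeLines(run$summary_lines, file.path(dir, "summary.txt"))
  cfg <- run$config
  keys <- setdiff(names(cfg)[!vapply(cfg, is.null, TRUE)], "out_dir")
  cfg_lines <- vapply(keys,
                      function(k) paste0(k, " = ",
                                         paste(cfg[[k]], collapse = ", ")),
                      character(1))
  ver <- tryCatch(as.character(utils::packageVersion("fastz")),
                  error = function(e) "dev")
  writeLines(c(paste0("fastz ", ver),
               paste0("R ", R.version.string),
               cfg_lines),
             file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' @export
print.fastz_run <- function(x, ...) {
  cat("fastz pipeline run (seed ", x$config$seed, ")\n", sep = "")
  writeLines(paste(" -", x$summary_lines))
  invisible(x)
}
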