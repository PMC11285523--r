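# Filtering, concatenation, fast-Z statistics and gene-resampling bootstrap.
#
# Gene records are plain data.frames.  The free-ratios path uses columns
#   gene, unit (terminal-branch species), partition ("Z"/"A"), Nd, Sd, N, S,
#   dN, dS, dnds, flags;
# the pairwise path uses focal and outgroup columns instead of unit.

#' Exclude genes with a substitution rate exceeding 1 on any branch
#'
#' A gene is dropped iff any terminal branch has `dN > 1` or `dS > 1`
#' (strictly greater: a rate of exactly 1.0 is kept).  Saturated records
#' (undefined corrected rate, i.e. beyond the correctable range) also drop
#' their gene.
#'
#' @param records free-ratios gene record data.frame.
#' @return list: `kept` (records of surviving genes), `excluded`
#'   (data.frame gene, reason; one row per removed gene).
#' @export
filter_free_ratios <- function(records) {
  stopifnot(all(c("gene", "dN", "dS") %in% names(records)))
  sat <- is.na(records$dN) | is.na(records$dS)
  over <- !sat & (records$dN > 1 | records$dS > 1)
  bad_genes_over <- unique(records$gene[over])
  bad_genes_sat <- setdiff(unique(records$gene[sat]), bad_genes_over)
  bad <- c(bad_genes_over, bad_genes_sat)
  excluded <- data.frame(
    gene = bad,
    reason = c(rep("rate_exceeds_1", length(bad_genes_over)),
               rep("saturated", length(bad_genes_sat))),
    stringsAsFactors = FALSE)
  list(kept = records[!records$gene %in% bad, , drop = FALSE],
       excluded = excluded)
}

#' Concatenated partition-level substitution rates
#'
#' Sums difference and site counts over the genes of each partition
#' (equivalent to concatenating the orthologues into a single sequence):
#' `D_N = sum(Nd) / sum(N)`, `D_S = sum(Sd) / sum(S)`, ratio `D_N / D_S`.
#'
#' @param records gene record data.frame with a `partition` column.
#' @param by grouping columns in addition to `partition`
#'   (default `"unit"`: one summary per terminal branch).
#' @return data.frame: grouping columns, `partition`, `DN`, `DS`, `ratio`
#'   (NA with flag `"DS_zero"` when no synonymous substitutions), `n_genes`,
#'   `n_subs` (total substitution count, diagnostic).
#' @export
concat_partition_rates <- function(records, by = "unit") {
  stopifnot(all(c("partition", "Nd", "Sd", "N", "S") %in% names(records)))
  key <- interaction(records[c(by, "partition")], drop = TRUE, sep = "\r")
  agg <- function(v) tapply(v, key, sum)
  Nd <- agg(records$Nd); Sd <- agg(records$Sd)
  N <- agg(records$N); S <- agg(records$S)
  ng <- tapply(records$gene, key, function(g) length(unique(g)))
  lab <- do.call(rbind, strsplit(names(Nd), "\r", fixed = TRUE))
  out <- data.frame(lab, stringsAsFactors = FALSE)
  names(out) <- c(by, "partition")
  out$DN <- as.vector(Nd / N)
  out$DS <- as.vector(Sd / S)
  out$ratio <- as.vector(ifelse(Sd > 0, out$DN / out$DS, NA_real_))
  out$flag <- as.vector(ifelse(Sd > 0, "", "DS_zero"))
  out$n_genes <- as.vector(ng)
  out$n_subs <- as.vector(Nd + Sd)
  rownames(out) <- NULL
  out
}

#' Fast-Z ratio from a branch partition summary
#'
#' `(D_NZ / D_SZ) / (D_NA / D_SA)` per grouping unit.
#'
#' @param branch_summary output of [concat_partition_rates()] containing
#'   partitions `"Z"` and `"A"`.
#' @param by the grouping column (default `"unit"`).
#' @return data.frame: `by` column, `ratio_Z`, `ratio_A`, `fastz` (NA with a
#'   flag when either partition ratio is undefined).
#' @export
fastz_ratio <- function(branch_summary, by = "unit") {
  z <- branch_summary[branch_summary$partition == "Z", , drop = FALSE]
  a <- branch_summary[branch_summary$partition == "A", , drop = FALSE]
  units <- union(z[[by]], a[[by]])
  rz <- z$ratio[match(units, z[[by]])]
  ra <- a$ratio[match(units, a[[by]])]
  out <- data.frame(units, ratio_Z = rz, ratio_A = ra,
                    fastz = ifelse(!is.na(rz) & !is.na(ra) & ra > 0,
                                   rz / ra, NA_real_),
                    stringsAsFactors = FALSE)
  names(out)[1] <- by
  out$flag <- ifelse(is.na(out$fastz), "undefined_partition_ratio", "")
  out
}

#' Gene-resampling bootstrap for concatenated statistics
#'
#' Resamples genes with replacement within each partition, recomputes the
#' concatenated `D_N`, `D_S`, `D_N/D_S` and the fast-Z ratio per unit, and
#' returns percentile intervals.
#'
#' @param records free-ratios gene record data.frame (post-filtering).
#' @param B number of bootstrap resamples (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @param by grouping column (default `"unit"`).
#' @return data.frame with one row per unit x quantity (`DN`, `DS`, `ratio`
#'   per partition, and `fastz`): point estimate, `ci_lo`, `ci_hi`, `level`,
#'   `B`.  Units/partitions with fewer than 2 genes get NA intervals.
#' @export
bootstrap_ci <- function(records, B = 1000, level = 0.95, seed = NULL,
                         by = "unit") {
  point <- concat_partition_rates(records, by = by)
  fz_point <- fastz_ratio(point, by = by)
  units <- unique(records[[by]])
  alpha <- (1 - level) / 2
  with_seed(seed, {
    rows <- list()
    for (u in units) {
      ru <- records[records[[by]] == u, , drop = FALSE]
      stat_boot <- list()
      for (p in intersect(c("Z", "A"), unique(ru$partition))) {
        rp <- ru[ru$partition == p, , drop = FALSE]
        genes <- unique(rp$gene)
        G <- length(genes)
        if (G < 2) {
          stat_boot[[p]] <- NULL
          rows[[length(rows) + 1]] <- data.frame(
            unit = u, partition = p, quantity = c("DN", "DS", "ratio"),
            estimate = unlist(point[point[[by]] == u & point$partition == p,
                                    c("DN", "DS", "ratio")]),
            ci_lo = NA_real_, ci_hi = NA_real_, level = level, B = B,
            stringsAsFactors = FALSE)
          next
        }
        # per-gene count matrix (genes may hold one row per unit already)
        cm <- rowsum(as.matrix(rp[c("Nd", "Sd", "N", "S")]),
                     group = match(rp$gene, genes))
        idx <- matrix(sample.int(G, G * B, replace = TRUE), G, B)
        bNd <- colSums(matrix(cm[idx, "Nd"], G, B))
        bSd <- colSums(matrix(cm[idx, "Sd"], G, B))
        bN <- colSums(matrix(cm[idx, "N"], G, B))
        bS <- colSums(matrix(cm[idx, "S"], G, B))
        DN <- bNd / bN; DS <- bSd / bS
        ratio <- ifelse(bSd > 0, DN / DS, NA)
        stat_boot[[p]] <- ratio
        est <- point[point[[by]] == u & point$partition == p, ]
        qs <- function(x) stats::quantile(x, c(alpha, 1 - alpha),
                                          na.rm = TRUE, names = FALSE)
        for (q in c("DN", "DS", "ratio")) {
          v <- switch(q, DN = DN, DS = DS, ratio = ratio)
          ci <- qs(v)
          rows[[length(rows) + 1]] <- data.frame(
            unit = u, partition = p, quantity = q, estimate = est[[q]],
            ci_lo = ci[1], ci_hi = ci[2], level = level, B = B,
            stringsAsFactors = FALSE)
        }
      }
      if (!is.null(stat_boot$Z) && !is.null(stat_boot$A)) {
        fz <- stat_boot$Z / stat_boot$A
        ci <- stats::quantile(fz, c(alpha, 1 - alpha), na.rm = TRUE,
                              names = FALSE)
        rows[[length(rows) + 1]] <- data.frame(
          unit = u, partition = "Z:A", quantity = "fastz",
          estimate = fz_point$fastz[fz_point[[by]] == u],
          ci_lo = ci[1], ci_hi = ci[2], level = level, B = B,
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    names(out)[1] <- by
    rownames(out) <- NULL
    out
  })
}

# round-half-up used for the substitution-count thresholds (path-averaged
# counts can be fractional; printed counts in the source analyses are
# integers)
round_half_up <- function(x) floor(x + 0.5)

#' Pairwise-path gene filters
#'
#' Within each outgroup, a gene is dropped if any focal comparison has
#' `dN > 1` or `dS > 1` (or is saturated), and dropped if any focal
#' comparison has fewer than `min_syn` synonymous or `min_nonsyn`
#' non-synonymous substitutions (counts rounded half-up; "at least five" is
#' inclusive).  Exclusions are per-outgroup: a gene may survive under one
#' outgroup and not another.
#'
#' @param records pairwise gene record data.frame with columns `gene`,
#'   `focal`, `outgroup`, `partition`, `Nd`, `Sd`, `dN`, `dS`, `dnds`.
#' @param min_syn,min_nonsyn minimum substitution counts (default 5 each);
#'   set `min_nonsyn = 0` for the synonymous-rate analysis.
#' @return list: `kept` records, `excluded` (gene, outgroup, reason).
#' @export
filter_pairwise <- function(records, min_syn = 5, min_nonsyn = 5) {
  req <- c("gene", "focal", "outgroup", "Nd", "Sd", "dN", "dS")
  stopifnot(all(req %in% names(records)))
  key <- paste(records$gene, records$outgroup, sep = "\r")
  sat <- is.na(records$dN) | is.na(records$dS)
  over <- sat | records$dN > 1 | records$dS > 1
  few <- round_half_up(records$Sd) < min_syn |
    round_half_up(records$Nd) < min_nonsyn
  drop_over <- unique(key[over])
  drop_few <- setdiff(unique(key[few]), drop_over)
  dropped <- c(drop_over, drop_few)
  reason <- c(rep("rate_exceeds_1", length(drop_over)),
              rep("too_few_substitutions", length(drop_few)))
  parts <- do.call(rbind, strsplit(dropped, "\r", fixed = TRUE))
  excluded <- if (length(dropped))
    data.frame(gene = parts[, 1], outgroup = parts[, 2], reason = reason,
               stringsAsFactors = FALSE)
  else data.frame(gene = character(0), outgroup = character(0),
                  reason = character(0), stringsAsFactors = FALSE)
  list(kept = records[!key %in% dropped, , drop = FALSE],
       excluded = excluded)
}

#' Aggregate pairwise records into per-species summaries
#'
#' Per (focal, outgroup, partition): back-transformed mean of
#' `log2(dN/dS)` over genes (the geometric mean).  Per (focal, outgroup):
#' fast-Z ratio of the Z and A aggregates.  Per focal species: arithmetic
#' mean across outgroups of the back-transformed values.  The same machinery
#' applied to `dS` alone supports the synonymous-rate analysis (`log2(dS)`
#' scale).
#'
#' @param records kept pairwise records (see [filter_pairwise()]).
#' @param value column to aggregate (default `"dnds"`; use `"dS"` for the
#'   synonymous-rate analysis).
#' @return list: `per_outgroup` (focal, outgroup, partition, geomean,
#'   n_genes), `per_pair` (focal, outgroup, value_Z, value_A, fastz),
#'   `per_species` (focal, value_Z, value_A, fastz, n_outgroups).
#' @export
aggregate_pairwise <- function(records, value = "dnds") {
  stopifnot(value %in% names(records))
  v <- records[[value]]
  if (any(is.na(v) | v <= 0))
    stop("non-positive or missing ", value,
         " reached aggregation; the count filters should prevent this")
  key <- interaction(records$focal, records$outgroup, records$partition,
                     drop = TRUE, sep = "\r")
  gm <- tapply(log2(v), key, mean)
  ng <- tapply(v, key, length)
  lab <- do.call(rbind, strsplit(names(gm), "\r", fixed = TRUE))
  per_outgroup <- data.frame(focal = lab[, 1], outgroup = lab[, 2],
                             partition = lab[, 3],
                             geomean = unname(2^gm),
                             n_genes = unname(ng),
                             stringsAsFactors = FALSE)
  zz <- per_outgroup[per_outgroup$partition == "Z", ]
  aa <- per_outgroup[per_outgroup$partition == "A", ]
  pk <- function(d) paste(d$focal, d$outgroup, sep = "\r")
  pairs <- union(pk(zz), pk(aa))
  vz <- zz$geomean[match(pairs, pk(zz))]
  va <- aa$geomean[match(pairs, pk(aa))]
  lab2 <- do.call(rbind, strsplit(pairs, "\r", fixed = TRUE))
  per_pair <- data.frame(focal = lab2[, 1], outgroup = lab2[, 2],
                         value_Z = vz, value_A = va,
                         fastz = vz / va, stringsAsFactors = FALSE)
  sp <- split(per_pair, per_pair$focal)
  per_species <- do.call(rbind, lapply(sp, function(d) {
    data.frame(focal = d$focal[1],
               value_Z = mean(d$value_Z, na.rm = TRUE),
               value_A = mean(d$value_A, na.rm = TRUE),
               fastz = mean(d$fastz, na.rm = TRUE),
               n_outgroups = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(per_species) <- NULL
  list(per_outgroup = per_outgroup, per_pair = per_pair,
       per_species = per_species)
}
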