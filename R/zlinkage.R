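# Z-chromosome assignment from sexed read-depth tables, plus the
# chromosome-size gene filters used to build the autosomal comparison set.

#' Normalize read depths within samples
#'
#' Each sample's depths are divided by that sample's median depth over
#' scaffolds of at least `min_length` bp, making samples with different
#' sequencing effort comparable.  The median is robust to a minority of
#' sex-linked scaffolds sitting at half depth in females.
#'
#' @param coverage data.frame with columns `scaffold`, `length_bp`, `sample`,
#'   `sex` (`"male"`/`"female"`), `mean_depth`.
#' @param min_length minimum scaffold length (bp) entering the scaling median.
#' @return the coverage data.frame with an added `norm_depth` column; samples
#'   whose depths are all zero are dropped with a warning.
#' @export
normalize_depths <- function(coverage, min_length = 20000) {
  req <- c("scaffold", "length_bp", "sample", "sex", "mean_depth")
  stopifnot(all(req %in% names(coverage)))
  if (any(coverage$mean_depth < 0)) stop("depths must be >= 0")
  tot <- tapply(coverage$mean_depth, coverage$sample, sum)
  dead <- names(tot)[tot == 0]
  if (length(dead)) {
    warning("excluding sample(s) with all-zero depth: ",
            paste(dead, collapse = ", "))
    coverage <- coverage[!coverage$sample %in% dead, , drop = FALSE]
  }
  med <- vapply(split(coverage, coverage$sample), function(d) {
    big <- d$mean_depth[d$length_bp >= min_length]
    if (!length(big)) big <- d$mean_depth
    stats::median(big)
  }, numeric(1))
  coverage$norm_depth <- coverage$mean_depth / med[coverage$sample]
  coverage
}

#' Per-scaffold female:male depth ratio
#'
#' Mean of the normalized female depths over the mean of the normalized male
#' depths, each sex contributing one equally weighted value per individual.
#'
#' @param normalized output of [normalize_depths()].
#' @return data.frame: `scaffold`, `length_bp`, `fm_ratio` (NA, with a flag
#'   column `flag = "male_depth_zero"`, where the male mean is zero).
#' @export
female_male_ratio <- function(normalized) {
  stopifnot("norm_depth" %in% names(normalized))
  if (!any(normalized$sex == "female") || !any(normalized$sex == "male"))
    stop("both sexes are required to form a female:male ratio")
  agg <- function(sex) {
    d <- normalized[normalized$sex == sex, , drop = FALSE]
    tapply(d$norm_depth, d$scaffold, mean)
  }
  f <- agg("female"); m <- agg("male")
  scaf <- sort(unique(normalized$scaffold))
  len <- normalized$length_bp[match(scaf, normalized$scaffold)]
  fm <- f[scaf] / m[scaf]
  flag <- ifelse(is.finite(fm), "", "male_depth_zero")
  fm[!is.finite(fm)] <- NA_real_
  data.frame(scaffold = scaf, length_bp = len, fm_ratio = unname(fm),
             flag = flag, row.names = NULL, stringsAsFactors = FALSE)
}

#' Call Z-linked scaffolds from female:male depth ratios
#'
#' A scaffold is called `Z` iff it is longer than `min_length` bp and its
#' female:male ratio lies inside the closed band; long scaffolds outside the
#' band are `non-Z`; short scaffolds (and undefined ratios) are `unassigned`.
#'
#' @param ratios output of [female_male_ratio()].
#' @param min_length length cutoff in bp (strict `>`, default 20 kb).
#' @param band inclusive female:male ratio band, default `c(0.4, 0.65)`.
#' @return the input with an added `call` column.
#' @export
assign_z <- function(ratios, min_length = 20000, band = c(0.4, 0.65)) {
  stopifnot(length(band) == 2, band[1] <= band[2])
  in_band <- !is.na(ratios$fm_ratio) &
    ratios$fm_ratio >= band[1] & ratios$fm_ratio <= band[2]
  long <- ratios$length_bp > min_length
  ratios$call <- ifelse(!long | is.na(ratios$fm_ratio), "unassigned",
                        ifelse(in_band, "Z", "non-Z"))
  ratios
}

#' Consensus Z calls across two reference assignments
#'
#' A gene is in the Z set iff called Z under both references; genes with
#' discordant calls are excluded from both partitions; genes called non-Z in
#' both are eligible for the autosomal partition.
#'
#' @param genes data.frame with columns `gene`, `call_refA`, `call_refB`
#'   (each `"Z"`/`"non-Z"`; anything else, or NA, counts as missing).
#' @return list with `genes` (input plus `consensus` column:
#'   `Z` / `non-Z` / `discordant` / `missing`), `concordance` (fraction of
#'   doubly-called genes with equal calls) and `n_missing`.
#' @export
consensus_z_genes <- function(genes) {
  stopifnot(all(c("gene", "call_refA", "call_refB") %in% names(genes)))
  valid <- c("Z", "non-Z")
  a <- ifelse(genes$call_refA %in% valid, genes$call_refA, NA)
  b <- ifelse(genes$call_refB %in% valid, genes$call_refB, NA)
  both <- !is.na(a) & !is.na(b)
  genes$consensus <- ifelse(!both, "missing",
                            ifelse(a == b,
                                   ifelse(a == "Z", "Z", "non-Z"),
                                   "discordant"))
  list(genes = genes,
       concordance = if (any(both)) mean(a[both] == b[both]) else NA_real_,
       n_missing = sum(!both))
}

#' Size windows for the autosomal comparison set
#'
#' The default window keeps chromosomes of 20-200 Mb (macro-chromosomes of
#' size comparable to the Z); the named robustness sub-windows split these
#' into chromosomes larger and smaller than the Z.
#' @export
autosome_size_windows <- function() {
  list(default = c(20, 200),
       larger_than_z = c(91, 200),
       smaller_than_z = c(21, 60))
}

#' Filter genes to autosomes inside a chromosome-size window
#'
#' @param gene_locations data.frame with columns `gene`, `chromosome`,
#'   `size_mb`, and optionally `consensus` (from [consensus_z_genes()]).
#' @param window numeric length-2 (Mb, inclusive) or the name of a window in
#'   [autosome_size_windows()].
#' @return list with `genes` (kept autosomal gene data.frame) and
#'   `excluded` (data.frame of gene, reason).  Genes on the Z (chromosome
#'   label `"Z"` or consensus `Z`/`discordant`) never enter the autosomal
#'   set; genes with missing size are excluded and counted.
#' @export
size_filter_autosomes <- function(gene_locations, window = "default") {
  if (is.character(window)) {
    window <- autosome_size_windows()[[match.arg(window,
      names(autosome_size_windows()))]]
  }
  stopifnot(length(window) == 2, window[1] <= window[2])
  g <- gene_locations
  reason <- rep(NA_character_, nrow(g))
  on_z <- g$chromosome == "Z"
  if ("consensus" %in% names(g))
    on_z <- on_z | g$consensus %in% c("Z", "discordant")
  reason[on_z] <- "z_or_discordant"
  nosize <- !on_z & (is.na(g$size_mb))
  reason[nosize] <- "missing_size"
  out <- !on_z & !nosize & (g$size_mb < window[1] | g$size_mb > window[2])
  reason[out] <- "outside_size_window"
  keep <- is.na(reason)
  list(genes = g[keep, , drop = FALSE],
       excluded = data.frame(gene = g$gene[!keep],
                             reason = reason[!keep],
                             stringsAsFactors = FALSE))
}
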