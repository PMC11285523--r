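# File formats: codon FASTA, Newick trees, and the versioned TSV tables the
# pipeline exchanges.

#' Read and validate a codon alignment from FASTA
#'
#' Enforces the codon-alignment contract: equal sequence lengths, length
#' divisible by 3, no gap characters, no internal stop codons under the
#' standard code.  Violations raise errors naming the sequence and position.
#'
#' @param path FASTA file.
#' @return named character vector of upper-case sequences with attribute
#'   `gene` (the file name sans extension).
#' @export
read_codon_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  head_i <- grep("^>", lines)
  if (!length(head_i)) stop("not a FASTA file: ", path)
  names_ <- sub("^>\\s*", "", lines[head_i])
  names_ <- sub("\\s.*$", "", names_)
  ends <- c(head_i[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(head_i), function(i) {
    body <- lines[seq(head_i[i] + 1L, ends[i])]
    toupper(paste(body[!grepl("^>", body)], collapse = ""))
  }, character(1))
  names(seqs) <- names_
  validate_codon_alignment(seqs, label = basename(path))
  attr(seqs, "gene") <- sub("\\.[^.]*$", "", basename(path))
  seqs
}

#' Validate the codon-alignment contract
#' @keywords internal
validate_codon_alignment <- function(seqs, label = "alignment") {
  if (anyDuplicated(names(seqs)))
    stop(label, ": duplicate sequence names")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop(label, ": unequal sequence lengths (",
         paste(unique(lens), collapse = ", "), ")")
  if (lens[1] %% 3L != 0L)
    stop(label, ": length ", lens[1], " is not divisible by 3 (frame error)")
  gap <- regexpr("-", seqs, fixed = TRUE)
  if (any(gap > 0)) {
    i <- which(gap > 0)[1]
    stop(label, ": gap character in sequence '", names(seqs)[i],
         "' at position ", gap[i])
  }
  tab <- codon_tables()
  starts <- seq(1L, lens[1], by = 3L)
  for (i in seq_along(seqs)) {
    cods <- substring(seqs[[i]], starts, starts + 2L)
    stop_at <- which(cods %in% c("TAA", "TAG", "TGA"))
    if (length(stop_at))
      stop(label, ": internal stop codon '", cods[stop_at[1]],
           "' in sequence '", names(seqs)[i], "' at codon ", stop_at[1],
           " (nucleotide ", (stop_at[1] - 1L) * 3L + 1L, ")")
  }
  invisible(seqs)
}

#' Write a codon alignment as FASTA
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @param width line width for wrapping (default 70).
#' @export
write_codon_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a rooted phylogeny from Newick
#'
#' @param path Newick file.
#' @return a `phylo` object; duplicate tip labels raise an error, polytomies
#'   are accepted with attribute `polytomies = TRUE` and a warning.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick in ", path)
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
               collapse = ", "))
  if (tr$Nnode < length(tr$tip.label) - 1L) {
    warning("tree contains polytomies")
    attr(tr, "polytomies") <- TRUE
  }
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    stop("negative branch lengths")
  tr
}

#' Write a phylogeny as Newick
#' @param tree a `phylo` object.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

# versioned TSV interchange (tab-separated, header row, '.' decimal)
TSV_SCHEMA <- "# fastz tsv v1"

#' Write a pipeline TSV table (versioned header)
#' @export
write_fastz_tsv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(TSV_SCHEMA, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline TSV table
#' @export
read_fastz_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
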