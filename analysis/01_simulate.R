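#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data set.
#
# Emulates the inputs of a comparative fast-Z analysis of shorebird-style
# genomes: a 16-species phylogeny, a binary mating-system trait (role-
# reversed polyandry vs monogamy) evolving under a 2-state Mk model, codon
# alignments for 200 macro-autosomal + 40 Z-linked + 10 micro-chromosome
# genes evolved with dN/dS = 0.145 on autosomes and a Z amplification of
# 1.27 (role-reversed lineages) or 1.09 (others), and a 45X sexed coverage
# table (5 males, 5 females) over Z and autosomal scaffolds.

suppressPackageStartupMessages(library(fastz))

out <- "results/simdata"
dir.create(file.path(out, "alignments"), recursive = TRUE,
           showWarnings = FALSE)

cfg <- run_config(seed = 1)
st <- simulate_study(cfg)

write_newick(st$tree, file.path(out, "tree.nwk"))
write_fastz_tsv(st$traits, file.path(out, "traits.tsv"))
write_fastz_tsv(st$genes, file.path(out, "genes.tsv"))
write_fastz_tsv(st$scaffolds, file.path(out, "scaffolds.tsv"))
write_fastz_tsv(st$coverage, file.path(out, "coverage.tsv"))
write_fastz_tsv(st$truth, file.path(out, "truth_events.tsv"))
for (g in names(st$alignments))
  write_codon_fasta(st$alignments[[g]],
                    file.path(out, "alignments", paste0(g, ".fa")))
writeLines(c(st$outgroups), file.path(out, "outgroups.txt"))

n_rr <- sum(st$traits$category == "role_reversed_polyandry")
message("simulated ", length(st$alignments), " genes on ",
        length(st$tree$tip.label), " species (", n_rr,
        " role-reversed, ", nrow(st$traits) - n_rr, " monogamous; ",
        length(st$outgroups), " outgroup species)")
message("total true substitution events: ",
        sum(st$truth$nsyn) + sum(st$truth$nnonsyn),
        " (", sum(st$truth$nnonsyn), " non-synonymous)")
message("inputs written under ", out)
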