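# shared fixtures built in code

# rooted two-tip tree with given branch lengths
pair_tree <- function(ta = 0.15, tb = 0.15) {
  structure(list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
                 edge.length = c(ta, tb),
                 tip.label = c("a", "b"), Nnode = 1L),
            class = "phylo")
}

# deterministic three-tip tree ((a,b),c)
three_tip_tree <- function(t1 = 0.1, t2 = 0.15, t3 = 0.2, t_in = 0.08) {
  ape::read.tree(text = sprintf("((a:%g,b:%g):%g,c:%g);", t1, t2, t_in, t3))
}

# free-ratios gene record rows from compact argument lists
make_records <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(gene = r[[1]], unit = r[[2]], partition = r[[3]],
               Nd = r[[4]], Sd = r[[5]], N = r[[6]], S = r[[7]],
               dN = r[[4]] / r[[6]], dS = r[[5]] / r[[7]],
               dnds = (r[[4]] / r[[6]]) / (r[[5]] / r[[7]]),
               flags = "", stringsAsFactors = FALSE)
  }))
}
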