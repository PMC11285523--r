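# Synthetic-data generation: phylogenies, discrete mating-system traits,
# codon alignments with exact event-level truth, sexed coverage tables, and
# the sex-linked effective-population-size theory they are built to probe.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's random-number state so seeded generator
#' calls do not perturb the surrounding session.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Simulate a rooted binary phylogeny
#'
#' Yule (pure-birth) tree via [ape::rphylo()]; branch lengths are in expected
#' codon substitutions per codon site, so `rate` (the birth rate) controls the
#' overall divergence: root-to-tip height is roughly `log(n_tips)/rate`.
#'
#' @param n_tips number of tips (>= 2).
#' @param rate birth rate of the Yule process (> 0).
#' @param seed integer seed; identical seeds give identical trees.
#' @return an [ape::rphylo()] `phylo` object, rooted and binary
#'   (`2 * n_tips - 2` edges), with tips labelled `t1..tn`.
#' @export
simulate_tree <- function(n_tips, rate = 1, seed = NULL) {
  if (n_tips < 2) stop("n_tips must be >= 2")
  if (rate <= 0) stop("rate must be > 0")
  with_seed(seed, {
    tr <- ape::rphylo(n_tips, birth = rate, death = 0)
    tr$tip.label <- paste0("t", seq_len(n_tips))
    tr
  })
}

#' Simulate a binary trait along a tree under a 2-state Mk model
#'
#' Event-by-event simulation: along each branch the current state waits an
#' exponential time with rate `q01` (from 0) or `q10` (from 1) before
#' flipping, so both tip states and true internal-node states are recorded.
#'
#' @param tree a `phylo` object.
#' @param q01,q10 transition rates 0->1 and 1->0 (>= 0).
#' @param root_state state at the root (0 or 1).
#' @param seed integer seed.
#' @param min_per_state if not `NULL`, redraw (with deterministic sub-seeds)
#'   until every state has at least this many tips; used when downstream
#'   group comparisons need both categories represented.
#' @return list with `tip_states` (named 0/1 integer vector), `node_states`
#'   (named by internal node number, root first), and `n_changes`.
#' @export
simulate_trait_mk <- function(tree, q01, q10, root_state = 0, seed = NULL,
                              min_per_state = NULL) {
  if (q01 < 0 || q10 < 0) stop("transition rates must be >= 0")
  stopifnot(root_state %in% c(0L, 1L))
  draw_once <- function() {
    ntip <- length(tree$tip.label)
    nnode <- tree$Nnode
    states <- rep(NA_integer_, ntip + nnode)
    root <- ntip + 1L
    states[root] <- as.integer(root_state)
    rates <- c(q01, q10)              # indexed by state + 1
    n_changes <- 0L
    pre <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(pre$edge))) {
      par <- pre$edge[e, 1]; chi <- pre$edge[e, 2]
      s <- states[par]
      t_rem <- pre$edge.length[e]
      repeat {
        r <- rates[s + 1L]
        if (r <= 0) break
        w <- stats::rexp(1, r)
        if (w >= t_rem) break
        t_rem <- t_rem - w
        s <- 1L - s
        n_changes <- n_changes + 1L
      }
      states[chi] <- s
    }
    tips <- states[seq_len(ntip)]
    names(tips) <- tree$tip.label
    nodes <- states[root:(ntip + nnode)]
    names(nodes) <- as.character(root:(ntip + nnode))
    list(tip_states = tips, node_states = nodes, n_changes = n_changes)
  }
  res <- with_seed(seed, draw_once())
  if (!is.null(min_per_state)) {
    attempt <- 1L
    while (min(tabulate(res$tip_states + 1L, 2L)) < min_per_state) {
      attempt <- attempt + 1L
      if (attempt > 1000L)
        stop("could not draw a trait with >= ", min_per_state,
             " tips per state in 1000 attempts; raise the rates")
      sub <- if (is.null(seed)) NULL else (seed + 7919L * attempt) %% .Machine$integer.max
      res <- with_seed(sub, draw_once())
    }
  }
  res
}

#' Per-branch, per-partition dN/dS profile
#'
#' Autosomal omega is constant; Z-chromosome omega on a branch is
#' `factor(category) * omega_a`, where terminal branches take the tip's
#' mating-system category and internal branches take the (simulated, hence
#' known) category of the child node.
#'
#' @param tree a `phylo` object.
#' @param tip_categories named character vector, one category per tip.
#' @param node_categories named character vector, one category per internal
#'   node (names = node numbers as in `tree$edge`).
#' @param omega_a autosomal dN/dS.
#' @param factors named numeric vector mapping category -> Z amplification
#'   factor (omega_Z = factor * omega_a).
#' @return data.frame with one row per edge: `edge`, `child`, `child_label`,
#'   `category`, `omega_a`, `omega_z`.
#' @export
omega_profile <- function(tree, tip_categories, node_categories,
                          omega_a, factors) {
  ntip <- length(tree$tip.label)
  child <- tree$edge[, 2]
  cat_of <- function(node) {
    if (node <= ntip) tip_categories[[tree$tip.label[node]]]
    else node_categories[[as.character(node)]]
  }
  category <- vapply(child, cat_of, character(1))
  unknown <- setdiff(unique(category), names(factors))
  if (length(unknown))
    stop("no Z factor configured for category: ",
         paste(unknown, collapse = ", "))
  data.frame(edge = seq_along(child),
             child = child,
             child_label = ifelse(child <= ntip, tree$tip.label[child],
                                  as.character(child)),
             category = category,
             omega_a = omega_a,
             omega_z = unname(factors[category]) * omega_a,
             stringsAsFactors = FALSE)
}

# exact jump-process simulation of one branch for all sites at once
evolve_branch <- function(states, tlen, jump) {
  nsyn <- 0L; nnonsyn <- 0L
  if (tlen <= 0) return(list(states = states, nsyn = 0L, nnonsyn = 0L))
  t_rem <- rep(tlen, length(states))
  active <- which(jump$rate[states] > 0)
  while (length(active)) {
    w <- stats::rexp(length(active), jump$rate[states[active]])
    hit <- w < t_rem[active]
    t_rem[active] <- t_rem[active] - w
    idx <- active[hit]
    if (length(idx)) {
      s <- states[idx]
      u <- stats::runif(length(idx))
      j <- rowSums(u > jump$cum[s, , drop = FALSE]) + 1L
      flip <- cbind(s, j)
      syn <- jump$syn[flip]
      nsyn <- nsyn + sum(syn)
      nnonsyn <- nnonsyn + sum(!syn)
      states[idx] <- jump$tgt[flip]
    }
    active <- idx[jump$rate[states[idx]] > 0]
  }
  list(states = states, nsyn = nsyn, nnonsyn = nnonsyn)
}

#' Simulate one codon alignment on a tree with exact substitution truth
#'
#' Event-by-event (Gillespie) simulation under the single-nucleotide-step
#' codon model: each site carries an exponential clock whose rate depends on
#' its current codon; kappa multiplies transitions, the branch's omega
#' multiplies non-synonymous changes, and target frequencies follow `pi`.
#' Because every substitution event is realised explicitly, the true
#' per-branch synonymous and non-synonymous event counts are returned.
#'
#' @param tree a `phylo` object (branch lengths in expected codon
#'   substitutions per codon site).
#' @param omega_edges numeric vector, omega for each row of `tree$edge`; a
#'   single value is recycled.
#' @param kappa transition/transversion rate ratio.
#' @param pi codon frequencies (61 sense codons, or 64 with zero mass on
#'   stops); default uniform.
#' @param n_codons number of codons (>= 1).
#' @param seed integer seed.
#' @return list with `aln` (named uppercase DNA strings, one per tip, no gaps
#'   or stops), `truth` (data.frame per edge: `edge`, `child_label`, `nsyn`,
#'   `nnonsyn`, `omega`), and `root` (root DNA string).
#' @export
simulate_codon_gene <- function(tree, omega_edges, kappa = 2, pi = NULL,
                                n_codons, seed = NULL) {
  if (n_codons < 1) stop("n_codons must be >= 1")
  pi <- check_pi(pi)
  nedge <- nrow(tree$edge)
  omega_edges <- rep_len(omega_edges, nedge)
  if (any(omega_edges < 0)) stop("omega must be >= 0")
  ntip <- length(tree$tip.label)

  # one jump chain per distinct omega on this gene
  chains <- new.env(parent = emptyenv())
  chain_for <- function(om) {
    key <- format(om, digits = 15)
    if (is.null(chains[[key]]))
      chains[[key]] <- codon_jump_chain(codon_model(kappa, om, pi))
    chains[[key]]
  }

  with_seed(seed, {
    pre <- ape::reorder.phylo(tree, "cladewise")
    # map reordered edges back to original edge indices
    edge_id <- match(paste(pre$edge[, 1], pre$edge[, 2]),
                     paste(tree$edge[, 1], tree$edge[, 2]))
    seqs <- vector("list", ntip + tree$Nnode)
    root <- ntip + 1L
    seqs[[root]] <- sample.int(61L, n_codons, replace = TRUE, prob = pi)
    nsyn <- integer(nedge); nnonsyn <- integer(nedge)
    for (e in seq_len(nrow(pre$edge))) {
      id <- edge_id[e]
      res <- evolve_branch(seqs[[pre$edge[e, 1]]], pre$edge.length[e],
                           chain_for(omega_edges[id]))
      seqs[[pre$edge[e, 2]]] <- res$states
      nsyn[id] <- res$nsyn
      nnonsyn[id] <- res$nnonsyn
    }
    aln <- vapply(seq_len(ntip), function(i) codons_to_string(seqs[[i]]),
                  character(1))
    names(aln) <- tree$tip.label
    child <- tree$edge[, 2]
    truth <- data.frame(edge = seq_len(nedge),
                        child_label = ifelse(child <= ntip,
                                             tree$tip.label[child],
                                             as.character(child)),
                        nsyn = nsyn, nnonsyn = nnonsyn,
                        omega = omega_edges, stringsAsFactors = FALSE)
    list(aln = aln, truth = truth, root = codons_to_string(seqs[[root]]))
  })
}

# accept 61- or 64-length codon frequency vectors
check_pi <- function(pi) {
  if (is.null(pi)) return(rep(1 / 61, 61))
  if (length(pi) == 64) {
    stops <- which(.AA64 == "*")
    if (any(pi[stops] > 0))
      stop("stop codons must have zero frequency")
    pi <- pi[-stops]
  }
  stopifnot(length(pi) == 61)
  pi
}

#' Simulate a sexed per-scaffold read-depth table
#'
#' Mean depth is `mean_depth` for autosomal scaffolds in both sexes and for Z
#' scaffolds in (homogametic ZZ) males, and `mean_depth / 2` for Z scaffolds
#' in (ZW) females.  Depths are negative-binomially overdispersed around
#' these means.
#'
#' @param scaffolds data.frame with columns `scaffold`, `length_bp`, `is_z`.
#' @param n_males,n_females numbers of sexed samples.
#' @param mean_depth mean read depth (reads/base).
#' @param dispersion negative-binomial size parameter (larger = closer to
#'   Poisson).
#' @param seed integer seed.
#' @return data.frame: `scaffold`, `length_bp`, `sample`, `sex`, `mean_depth`.
#' @export
simulate_coverage <- function(scaffolds, n_males = 5, n_females = 5,
                              mean_depth = 45, dispersion = 20, seed = NULL) {
  stopifnot(all(c("scaffold", "length_bp", "is_z") %in% names(scaffolds)))
  if (any(scaffolds$length_bp <= 0)) stop("scaffold lengths must be > 0")
  if (n_males == 0 || n_females == 0)
    warning("coverage table with a missing sex: female:male ratios will be undefined")
  samples <- c(if (n_males > 0) paste0("M", seq_len(n_males)),
               if (n_females > 0) paste0("F", seq_len(n_females)))
  sexes <- c(rep("male", n_males), rep("female", n_females))
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_along(samples), function(i) {
      mu <- ifelse(scaffolds$is_z & sexes[i] == "female",
                   mean_depth / 2, mean_depth)
      data.frame(scaffold = scaffolds$scaffold,
                 length_bp = scaffolds$length_bp,
                 sample = samples[i], sex = sexes[i],
                 mean_depth = stats::rnbinom(nrow(scaffolds),
                                             mu = mu, size = dispersion),
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}

#' Closed-form Z-to-autosome effective-size ratio
#'
#' Two classical formulas for `N_eZ / N_eA` given the numbers of breeding
#' males and females.  The chromosome-copy-count model counts Z copies
#' (two per male, one per female) against autosomal copies:
#' `(2 N_m + N_f) / (2 (N_m + N_f))`, giving 3/4 under equal sex numbers,
#' 1/2 in the extreme-polygyny limit (`N_m -> 0` relative to `N_f`) and 1 in
#' the extreme role-reversed-polyandry limit (`N_f -> 0` relative to `N_m`).
#' The variance (harmonic) effective-size model uses
#' `N_eZ = 9 N_m N_f / (2 N_m + 4 N_f)` over `N_eA = 4 N_m N_f / (N_m + N_f)`,
#' which also gives 3/4 at equality but tends to 9/16 under extreme polygyny.
#'
#' @param n_males,n_females breeding males and females (>= 1).
#' @param method `"copy_count"` (default) or `"variance"`.
#' @return the ratio `N_eZ / N_eA`.
#' @export
ne_ratio <- function(n_males, n_females,
                     method = c("copy_count", "variance")) {
  method <- match.arg(method)
  if (n_males < 1 || n_females < 1)
    stop("breeding numbers must be >= 1")
  if (method == "copy_count") {
    (2 * n_males + n_females) / (2 * (n_males + n_females))
  } else {
    ne_z <- 9 * n_males * n_females / (2 * n_males + 4 * n_females)
    ne_a <- 4 * n_males * n_females / (n_males + n_females)
    ne_z / ne_a
  }
}

#' Wright-Fisher simulation of the Z-to-autosome effective-size ratio
#'
#' Discrete-generation allele-sampling simulation of unlinked neutral loci:
#' autosomal loci live on `2(N_m + N_f)` gene copies, Z-linked loci on
#' `2 N_m + N_f` copies (two per male, one per female), and each offspring
#' draws parental copies at random (daughters inherit their single Z from the
#' father).  Effective sizes are estimated from the decay of heterozygosity,
#' `E[H_t] = H_0 (1 - 1/(2 N_e))^t`, by log-linear regression, and the ratio
#' is returned with a Monte-Carlo standard error from independent locus
#' blocks.
#'
#' @param n_males,n_females breeding males and females per generation (>= 2).
#' @param skew fraction of males excluded from breeding (harem skew in
#'   `[0, 1)`); `0` is random mating.
#' @param n_loci loci per genome class (>= 1).
#' @param generations generations to simulate.
#' @param seed integer seed.
#' @param n_blocks locus blocks for the Monte-Carlo standard error.
#' @return list: `ratio`, `se`, `ne_z`, `ne_a`, and `block_ratios`.
#' @export
wf_simulate_ne <- function(n_males, n_females, skew = 0, n_loci = 500,
                           generations = 200, seed = NULL, n_blocks = 10) {
  if (n_males < 2 || n_females < 2) stop("population sizes must be >= 2")
  if (n_loci < 1) stop("n_loci must be >= 1")
  if (skew < 0 || skew >= 1) stop("skew must be in [0, 1)")
  n_breed_m <- max(1L, as.integer(round((1 - skew) * n_males)))

  with_seed(seed, {
    ka <- 2L * (n_males + n_females)
    kz <- 2L * n_males + n_females
    A <- matrix(rep(seq_len(ka), each = n_loci), n_loci, ka)
    Z <- matrix(rep(seq_len(kz), each = n_loci), n_loci, kz)
    # Z layout: cols 1..n_females = female copies, then male pairs
    hetero <- function(M) {
      k <- ncol(M)
      apply(M, 1, function(x) 1 - sum(tabulate(x, max(ka, kz))^2) / k^2)
    }
    HA <- matrix(NA_real_, generations + 1L, n_loci)
    HZ <- matrix(NA_real_, generations + 1L, n_loci)
    HA[1L, ] <- hetero(A)
    HZ[1L, ] <- hetero(Z)
    gather <- function(M, src) {
      out <- matrix(M[cbind(rep(seq_len(n_loci), ncol(src)), as.vector(src))],
                    n_loci, ncol(src))
      out
    }
    for (g in seq_len(generations)) {
      n_off <- n_males + n_females
      # autosomes: maternal + paternal copy per offspring
      mom <- matrix(sample.int(n_females, n_loci * n_off, TRUE), n_loci)
      dad <- matrix(sample.int(n_breed_m, n_loci * n_off, TRUE), n_loci)
      momcol <- 2L * (mom - 1L) + sample(c(1L, 2L), length(mom), TRUE)
      dadcol <- 2L * n_females + 2L * (dad - 1L) +
        sample(c(1L, 2L), length(dad), TRUE)
      # interleave so offspring i's pair occupies columns 2i-1, 2i
      # (offspring 1..n_females are the next generation's females)
      A <- cbind(gather(A, momcol), gather(A, dadcol))[,
        c(rbind(seq_len(n_off), n_off + seq_len(n_off))), drop = FALSE]
      # Z: daughters (first n_females offspring) get one paternal Z;
      # sons get the maternal Z plus one paternal Z
      dadz <- matrix(sample.int(n_breed_m, n_loci * n_off, TRUE), n_loci)
      dadzcol <- n_females + 2L * (dadz - 1L) +
        sample(c(1L, 2L), length(dadz), TRUE)
      momz <- matrix(sample.int(n_females, n_loci * n_males, TRUE), n_loci)
      Z <- cbind(gather(Z, dadzcol[, seq_len(n_females), drop = FALSE]),
                 gather(Z, momz),
                 gather(Z, dadzcol[, n_females + seq_len(n_males),
                                   drop = FALSE]))
      # reorder male Z copies into pairs (mom copy, dad copy) per male
      ord <- c(seq_len(n_females),
               n_females + as.vector(rbind(seq_len(n_males),
                                           n_males + seq_len(n_males))))
      Z <- Z[, ord, drop = FALSE]
      HA[g + 1L, ] <- hetero(A)
      HZ[g + 1L, ] <- hetero(Z)
    }
    fit_ne <- function(H) {
      hbar <- rowMeans(H)
      # restrict to the window where heterozygosity is still substantial:
      # once most loci approach fixation the surviving-locus mean decays
      # slower than E[H] and would bias Ne upward
      keep <- hbar > 0.1 * hbar[1]
      slope <- stats::coef(stats::lm(log(hbar[keep]) ~ seq_along(hbar)[keep]))[2]
      1 / (2 * (1 - exp(slope)))
    }
    blocks <- split(seq_len(n_loci),
                    cut(seq_len(n_loci), n_blocks, labels = FALSE))
    block_ratios <- vapply(blocks, function(ix) {
      fit_ne(HZ[, ix, drop = FALSE]) / fit_ne(HA[, ix, drop = FALSE])
    }, numeric(1))
    decay <- 1 - rowMeans(HA)[generations + 1L] / rowMeans(HA)[1L]
    if (decay < 0.1)
      warning("heterozygosity decayed by only ",
              format(100 * decay, digits = 2),
              "%; the N_e estimate has a wide standard error")
    list(ratio = mean(block_ratios),
         se = stats::sd(block_ratios) / sqrt(length(block_ratios)),
         ne_z = fit_ne(HZ), ne_a = fit_ne(HA),
         block_ratios = unname(block_ratios))
  })
}
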