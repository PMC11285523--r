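---
title: "Methods: fast-Z evolution under role-reversed polyandry, on simulated data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fast-Z evolution under role-reversed polyandry, on simulated data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fastz)
```

## The scientific question

In birds the Z chromosome evolves faster than comparably sized autosomes:
the ratio of non-synonymous to synonymous substitution rates
($D_N/D_S$, also written $\omega$) is higher for Z-linked genes — the
*fast-Z* effect.  Two mechanisms can produce it.  Because females carry a
single Z, partially recessive beneficial alleles are exposed to selection
in females, strengthening positive selection; and because the Z spends two
thirds of its time in males, its effective population size $N_{eZ}$ is
below the autosomal $N_{eA}$, weakening purifying selection.  Mating
systems move these two forces in opposite directions.  Under random mating
$N_{eZ}/N_{eA} = 3/4$; extreme polygyny pushes the ratio towards $1/2$
(few breeding males hold most Z copies), while role-reversed polyandry —
polygamous females, essentially monogamous care-giving males — pushes it
towards $1$.  If drift drives fast-Z, role-reversed lineages should show a
*weaker* effect; if selection on hemizygous females drives it, a
*stronger* one.  The package implements the full comparative pipeline that
discriminates these predictions, with a synthetic-data generator standing
in for genome downloads so that every stage can be verified against exact
simulation truth.

## The generator and what it emulates

`simulate_study()` produces one self-consistent data set:

* **Tree** — a Yule tree (`simulate_tree()`, default 16 tips, birth rate 8,
  giving a root height of roughly 0.3).  Branch lengths are read everywhere
  as expected codon substitutions per codon site under the branch's own
  (mean-one-scaled) model, the unit in which divergences $t$ are also
  reported.
* **Mating system** — a binary trait (role-reversed polyandry vs monogamy)
  evolved along the tree under a 2-state Mk model with rates
  $q_{01} = 2$, $q_{10} = 4$ (stationary role-reversed frequency $1/3$,
  a handful of transitions per tree).  The generator redraws the trait with
  deterministic sub-seeds until each state has at least two species overall
  and two among the focal clade — the comparative design is meaningless
  without both role-reversed and control species represented.  Trait records (female and male
  polygamy percentages, caring sex, generation time) are drawn so that
  `classify_mating_system()` recovers the generating category exactly:
  role-reversed species get 30–80% female and <1% male polygamy with male
  care; monogamous species <1% in both sexes.
* **Codon alignments** — each gene evolves under a Goldman–Yang-style
  single-nucleotide-step codon model: rate $\propto \pi_j\,
  \kappa^{[\text{transition}]}\, \omega^{[\text{non-synonymous}]}$, stop
  codons excluded from the state space, $\pi$ uniform over the 61 sense
  codons by default, $\kappa = 2$.  Autosomal genes use
  $\omega_A = 0.145$; Z genes use $\omega_Z = f \cdot \omega_A$ with
  $f = 1.27$ on branches whose (simulated, hence known) category is
  role-reversed and $f = 1.09$ otherwise — the two group means of the
  free-ratios comparison the generator emulates.  Simulation is exact
  event-by-event (Gillespie) rather than by matrix exponentiation so the
  true per-branch synonymous and non-synonymous event counts exist and are
  returned; they are the oracle every estimator is scored against.
  Internal branches with mixed descendant categories take the child node's
  true state, which keeps the truth well defined.
* **Gene locations** — genes sit on a chicken-like chromosome map
  (macro-autosomes 1–10 of 21–197 Mb, three micro-chromosomes, an 83 Mb
  Z), so the 20–200 Mb size filter and its robustness sub-windows
  (91–200 Mb, 21–60 Mb) have something to act on.
* **Coverage** — per-sample per-scaffold mean depths for 5 males and 5
  females at 45X, negative-binomial with dispersion 20 (read depth is
  overdispersed relative to Poisson; the value is deliberately generous so
  that the 0.4–0.65 band loses some true Z scaffolds and the
  two-reference consensus machinery is actually exercised, leaving a
  realistic fraction of genes discordant between references).  Z scaffolds in females have
  half the mean depth.
* **Demography** — `ne_ratio()` exposes both classical closed forms for
  $N_{eZ}/N_{eA}$.  The chromosome-copy-count model
  $(2N_m + N_f)/(2(N_m+N_f))$ reproduces the $1/2$ – $3/4$ – $1$
  narrative for polygyny/monogamy/polyandry.  The variance-effective-size
  model ($N_{eZ} = 9N_mN_f/(2N_m+4N_f)$ over
  $N_{eA} = 4N_mN_f/(N_m+N_f)$) agrees at $N_m = N_f$ but tends to
  $9/16$, not $1/2$, in the extreme-polygyny limit.  The two formulas
  genuinely disagree there; we implement and report both rather than guess
  which is "intended", and the Wright–Fisher simulator
  (`wf_simulate_ne()`) — an explicit two-sex allele-sampling simulation
  whose $N_e$ estimates come from the log-linear decay of mean
  heterozygosity — tracks the variance form (its harem-skew runs match
  `ne_ratio(n_breeding_males, n_females, "variance")` within Monte-Carlo
  error).  The heterozygosity regression is restricted to the window where
  mean heterozygosity exceeds 10% of its initial value; beyond that the
  surviving-locus mean decays more slowly than its expectation and would
  bias $N_e$ upward.

What the generator does **not** emulate: indels and alignment error (all
alignments are ungapped by construction), selection on synonymous sites,
site-to-site rate heterogeneity, GC-biased gene conversion (beyond the
chromosome-size filter), gene-tree discordance, and mapping artefacts in
coverage.  Green tests therefore certify the statistical machinery and its
filters, not robustness to those real-data pathologies.

## Estimators

Analyses of this design traditionally call an external codon-model ML
engine; here the engines are in-repo and validated by simulation
recovery, not by bit-equivalence with any external tool.

* **NG86 counting** (`ng86_pairwise()`): per-codon site counts split each
  position by the fraction of its non-stop single-nucleotide neighbours
  that are synonymous; difference counts average over the minimal
  mutational paths whose intermediates are sense codons (paths through
  stops are excluded; codons with ambiguity characters are skipped
  pairwise-complete); proportions are Jukes–Cantor corrected,
  $d = -\tfrac34\log(1-\tfrac43 p)$, undefined (`saturated`) at
  $p \ge 3/4$.  NG86's site counting ignores the transition bias, which
  at $\kappa = 2$ depresses $\hat\omega$ by roughly 10% — the classical
  behaviour of this estimator, visible in our recovery tests and worth
  remembering when reading absolute $\omega$ values (the Z:A *ratio* is
  essentially immune, because the bias cancels between partitions).
* **Pairwise ML** (`ml_pairwise()`): maximizes the codon-pair likelihood
  under the same model family the simulator uses, over
  $(\log t, \log\kappa, \log\omega)$ with L-BFGS-B from three fixed
  starting points; $t$ is decomposed into per-site $d_N$ and $d_S$ by
  expected flux, with site totals defined from the neutral
  ($\omega = 1$) flux shares, the standard codon-model convention.
* **Free-ratios substitute** (`branch_counts()`): marginal ancestral
  codons at every internal node by Felsenstein pruning under one global
  per-gene model (per-gene $\omega$ from pooled NG86 counts against the
  first taxon, $\kappa$ fixed at 2 — reconstruction is insensitive to
  both), then NG86 counting between each reconstructed parent and its tip,
  with site counts from the tip sequence.  Per-branch rates come from
  counting, never from the reconstruction model, which avoids circularity.

## Filters, aggregation, bootstrap

Following the comparative design: on the free-ratios route a gene is
excluded when any terminal branch has $d_N > 1$ or $d_S > 1$ (strictly
greater — exactly 1.0 survives; a synonymous rate of 1 already means every
site substituted once on average, so anything beyond is unreliable);
surviving counts are summed over genes (concatenation) and divided by
summed site counts.  Fast-Z is $(D_{NZ}/D_{SZ})/(D_{NA}/D_{SA})$, with
percentile confidence intervals from resampling genes with replacement
within partitions (B = 1000 by default; the CI type is a free
choice of the design, percentile here).  On the pairwise route exclusions are
per-outgroup, and a gene additionally needs at least five synonymous and
five non-synonymous substitutions in every focal comparison — inclusive
thresholds, tested on half-up-rounded counts because path-averaged counts
can be fractional while count thresholds are naturally integer.  Gene-level
$d_N/d_S$ is log2-transformed, averaged, and back-transformed (a
geometric mean), then averaged arithmetically across outgroups — the
back-transform precedes the cross-outgroup average in this design;
arithmetic averaging across outgroups is the documented, configurable
choice.  The synonymous-rate
analysis reuses the machinery with the non-synonymous threshold switched
off and $\log_2 d_S$ as the response.

## Comparative statistics

`paired_ttest()` and `welch_ttest()` are the textbook statistics (two-sided
by default; the hypothesis is directional, but two-sided tests are the
conservative default and sidedness is configurable).  `pgls_fit()` is generalized
least squares with covariance $V(\lambda)$: the tree's shared
branch-length matrix with off-diagonals scaled by Pagel's $\lambda$,
estimated by maximum likelihood over $[0,1]$ on a 51-point grid with
bounded refinement (ties toward smaller $\lambda$; $\lambda$ can be fixed,
e.g. at 1, for sensitivity analyses).  Coefficient tests use
$t_{n-k}$ with the unbiased residual variance.  `mk_asr()` fits the
2-state Mk model (equal-rates default, all-rates-different available) by
pruning, with the stationary distribution of the fitted rate matrix as the
root prior, and computes marginal node probabilities by the rerooting
(outside-in) pass; on small trees the marginals are checked against exact
enumeration over all internal-state assignments to 1e-10.

## Numerical choices and degenerate inputs

Transition probabilities come from the symmetrized eigendecomposition of
the reversible generator (exact to machine precision; tiny negative
entries are clipped and rows renormalized).  Identical sequences put
$\hat t$ at its lower bound and are flagged; purely synonymous divergence
drives $\hat\omega$ to its bound, flagged `omega_at_bound`.  Zero
synonymous totals flag the concatenated ratio as undefined rather than
dividing by zero.  Samples with all-zero depth are dropped with a warning;
scaffolds with zero male depth are excluded from ratio calls.  All
randomness flows from one master seed; per-gene sub-seeds make gene
simulation order-independent, and rerunning any stage with the same
configuration reproduces byte-identical tables.

## Problem sizes used by the shipped runs

The default study is 16 species, 200 + 40 + 10 genes of 300 codons —
large enough for every filter and statistic to engage, small enough to run
in about a minute.  The test suite's heavier checks use: 50 replicates of
5000-codon pairs for estimator recovery; 20 replicate studies for
pipeline-level fast-Z recovery (bootstrap B = 300 there; B is a free
parameter of ours); 200 data sets of 50 genes for bootstrap coverage
against a 3000-gene estimand; and a 50 + 50 Wright–Fisher population of
500 loci over 200 generations.  These sizes are the package's own choices
balancing Monte-Carlo resolution against desk-scale runtimes.

## Known limitations

NG86's transition-blind site counting biases absolute $\omega$ downward at
realistic $\kappa$ (see above).  Ancestral-reconstruction counting
attributes some internal-branch events to terminal branches at high
divergence; at the default tree height the summed-count bias is within a
few percent (regression-tested) but grows with divergence.  The pairwise
route's cross-outgroup average treats outgroups as exchangeable replicates
though they share history — exactly why the downstream comparison is PGLS
rather than ordinary regression.  The Wright–Fisher $N_e$ estimator is a
decay-rate regression, not a coalescent likelihood; its Monte-Carlo
standard errors come from locus blocks and can be optimistic when few
blocks remain polymorphic.
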