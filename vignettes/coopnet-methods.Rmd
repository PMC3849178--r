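---
title: "Inferring cooperative TF partners and active targets: models and design choices"
author: "coopnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring cooperative TF partners and active targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

A ChIP-seq experiment tells you where a transcription factor (TF) binds,
but not which of those binding events are functional in a given cell state,
nor which other TFs the factor partners with.  `coopnet` combines three
independent lines of evidence around one primary TF — here modelled on the
AP-1 family, whose dimers read the TRE (`TGA[C/G]TCA`) and CRE
(`TGACGTCA`) elements:

1. **Sequence evidence**: if two TFs bind DNA as a physical complex, their
   motifs co-occur at a *fixed spacing and orientation* inside peaks far
   more often than chance allows (spaced-motif enrichment).
2. **Co-expression evidence**: genes bound by *both* TFs should be more
   tightly co-expressed than genes bound by either alone (a hypergeometric
   test on the top of the pair-correlation ranking).
3. **Dynamic evidence**: a genuine target's expression trajectory should
   be explainable as the output of a transcription ODE driven by the TF's
   own profile (a Gaussian-process latent-force model), and the target
   sets of genuine partners should be enriched at the top of that ranking
   (preranked GSEA with permutation FWER), with their members responding
   to stimulation (SAM differential expression plus direction-separated
   over-representation).

Partners supported by both (1) and (3) and the union of their target sets
form the exported dimer–partner–target network.

# Models and statistics

## Spaced-motif enrichment

Each peak sequence is centred and oriented on the best log-odds hit of the
primary motif.  Within the two `margin` = 50 bp flanks, the best hit of
each candidate secondary motif is recorded as a (gap, quadrant) bin, where
gap is the distance in bp between motif edges (1 bp bins) and quadrant is
left/right x same/opposite strand.  Under the null every surviving
sequence falls into one of the `4 * (margin - L2 + 1)` bins uniformly, so
a bin with `count` of `n` sequences is scored with the exact binomial
upper tail `P[Binom(n, 1/n_bins) >= count]`, Bonferroni-adjusted by
`n_bins x n_motifs`.  Sequences whose flanks truncate at the sequence edge
are dropped and reported.  Notes:

* Every surviving sequence contributes its best secondary hit regardless
  of score (a minimum-score option exists).  Ties are broken by smallest
  gap, then by quadrant order, which is only neutral when windows rarely
  tie — realistic position weight matrices (PWMs) have heterogeneous
  columns, and `consensus_pwm()` deliberately builds such matrices.
* A near-palindromic primary (TRE differs from its reverse complement
  only in the degenerate middle base) makes the orientation of each
  sequence ambiguous, so a planted spacing splits between a quadrant and
  its mirror image.  Both bins become significant; partner-level calls
  (`significant_partners()`) are unaffected.
* Redundant (near-duplicate) sequences are not collapsed before testing.

## Cooperativity from expression correlations

For TFs A and B, gene pairs are formed *within* the both-bound class and
within each single-bound class (cross-class pairs are excluded).  All `N`
pairs are ranked by Pearson correlation of log2 expression across the
samples of one condition and the top `k = ceiling(0.05 N)` taken.  Under
the null that class labels carry no information, the number `x` of
both-bound pairs in the top set follows the marginal of a multivariate
hypergeometric — i.e. `Hypergeom(N, |P_both|, k)` — giving the upper-tail
p-value.  Choices and caveats:

* `top_fraction` defaults to 0.05; the quantile cut (rather than a fixed
  correlation threshold) is robust to the overall correlation level.
  Spearman correlation is available by flag.
* The hypergeometric null assumes the pair correlations are exchangeable
  across classes.  Pairs sharing a gene are not independent: genes with
  extreme sample patterns drag all their pairs up the ranking, which
  slightly overdisperses `x`.  In simulations with iid correlation scores
  (`coop_test_cor()`) the p-values are uniform, while with iid *gene*
  profiles the Kolmogorov–Smirnov test detects a small deviation
  (D around 0.08) that does not shrink with class size.  Treat p-values
  near a decision boundary with care; the planted-structure detection
  rate (shared-target correlation 0.7 against 0.1 background) is >90% at
  p < 1e-3 either way.
* A pair class with fewer than two usable genes makes the test degenerate
  (p = 1, flagged), mirroring a partner whose motif never occurs under a
  peak ("no binding sites" in the screening table).

## Gaussian-process latent-force target ranking

Each candidate target is modelled as the output of the linear ODE

    dx/dt = B + S f(t) - D x,

with basal rate `B` (expression units/h), sensitivity `S` (units/h per
force unit), decay `D` (1/h), and latent force `f ~ GP(0, exp(-(t-t')^2/l^2))`
with length-scale `l` (hours).  The TF's own mRNA profile is taken as a
direct noisy observation of `f` (no protein-translation stage: the
simplest variant for a 4-point time course); it is mean-centred to match
the zero-mean prior, and the reported `B` is mapped back to the uncentred
scale.  The output covariances and the output–force cross-covariance have
closed error-function forms; they are evaluated with all exponentials
combined in log space (via the log complementary error function), so the
kernel stays finite for large decay rates.  A 1e-8 diagonal jitter is
added before Cholesky factorization.

The marginal likelihood of (TF block, gene block) is maximized over
`(B, S, D, x0, sigma2, l)` from a deterministic grid of starts
(`D in {0.1, 0.5, 1.5}/h`, `l in {1, 2, 4} h`, `S in {0.5, 2}`), refining
the two best grid points with bounded quasi-Newton iterations; the null
clamps `S = 0` (the model then factorizes into a GP fit of the TF and an
exponential-relaxation fit of the gene).  Genes are ranked by the
log-likelihood ratio `ll_alt - ll_null` — scale-free, and exactly zero in
expectation for force-free genes (the raw `ll_alt` is also reported).
Replicates enter as repeated observations of the same latent trajectory;
the TF's observation noise is estimated once from its replicate variance.
Box constraints (`D <= 6`, `l <= 8` etc.) keep the optimizer inside the
numerically comfortable region; with 4 time points, faster decay rates
are not identifiable anyway.

## Preranked GSEA and over-representation

The enrichment score is the standard weighted Kolmogorov–Smirnov running
sum; the null is built from random gene-label sets of matched size (the
only valid permutation scheme for a preranked metric), normalized scores
are sign-stratified, and the family-wise error rate of each set is the
fraction of permutations whose *maximum* |NES| over the whole collection
exceeds the observed one.

The pipeline calls GSEA with `weight_p = 0` (classic KS) rather than the
conventional 1.  The ranking metric here is a likelihood ratio: almost
all mass sits on a few strongly driven genes, and with metric-weighted
increments *any* set containing two or three of them reaches a
near-maximal ES — including the random sets of the null — which destroys
the contrast (observed in simulation: planted sets at FWER ~ 0.85 with
weight 1, ~ 0 with weight 0).  The rank-based statistic asks the right
question for this metric: are the set's members concentrated near the top
of the list?  `es_score()` keeps `weight_p = 1` as its own default so it
behaves like standard GSEA when handed a conventional signed metric.

Over-representation of a target set among up- or down-regulated genes is
the hypergeometric upper tail on the 2x2 table against the expression
universe, run separately per direction and time point; odds ratios use a
Haldane 0.5 correction only when a cell is empty.

## SAM differential expression

Each post-stimulation time point is compared with the basal state using
the SAM statistic `d = (mean2 - mean1)/(s + s0)` with the pooled standard
error `s` and the fudge factor `s0` chosen on the 0,5,...,100 percentile
grid of `s` to minimize the coefficient of variation of the median |d|
across ten `s`-quantile windows.  The null is group-label permutation —
exhaustive when there are at most `n_perm` distinct assignments, which is
always the case for the 4+4 replicate design (C(8,4) = 70, making q
values deterministic there).  The FDR at a gene's |d| is the median
permutation false-call count over the observed call count, made monotone
in |d|; calls at q <= 0.05 are split by the sign of the mean difference.
No prior-fraction (pi0) shrinkage is applied, which keeps the estimate
conservative.

# The synthetic scenario: what it emulates, and what it does not

The generator reproduces the statistical structure the method assumes:

* **Design**: 0/2/4/8 h, 4 biological replicates, two conditions; the
  second condition attenuates the TF induction 20-fold (a congenic-like
  contrast).  Gaussian noise, sd 0.25 on the log2 scale (typical
  microarray replicate noise).
* **TF profile**: a fixed smooth pulse `a (t/2) exp(1 - t/2)` — rising to
  its peak by 2 h and decayed by 8 h — on a basal level of 7 log2 units
  with amplitude 3.  The pulse is deterministic so that ranking results
  vary only through observation noise.
* **Targets** follow the ODE above with per-gene `B ~ U(0.5, 2)`,
  `S ~ U(1, 3)`, `D ~ U(0.4, 1.2)/h` (time-scales commensurate with an
  8 h response), integrated by trapezoid on a fine grid; non-targets sit
  at `B/D`.
* **Peaks**: 200 bp sequences, one primary-motif instance sampled from
  the PWM at a random offset (orientation randomized), partner motifs
  planted at fixed gap/quadrant in disjoint subsets of sequences —
  overlapping plantings would corrupt each other and fabricate
  cross-motif spacings.  Promoter peaks are placed for every target and a
  handful of bound non-targets; distal peaks exercise the +/-20 kb
  assignment window, its boundary, and the posterior > 0.9 filter.
* **Cooperative blocks** add a shared per-sample latent component scaled
  to a chosen within-block pairwise correlation.

The bundled end-to-end scenario (`demo_scenario()`) uses 400 genes with
120 targets, 300 peaks, five planted partners (16% of sequences each,
gaps 4–12 bp) and three decoy motifs.  The 30%-target base rate is
deliberate: with a much higher fraction, matched-size random gene sets
contain as many top-ranked genes as real partner sets and the GSEA
contrast vanishes; with real genome-scale data the base rate is far
lower and discrimination only gets easier.

What the generator does *not* emulate — so green tests here do not
certify behaviour on real data: read-level noise and peak-calling
artefacts, probe effects and normalization residue, correlated gene
modules unrelated to the TF, chromatin context (motif presence is not
binding), heteroscedastic noise, and TF profiles less identifiable than a
clean pulse.  One structural confound is worth knowing: when all of a
TF's targets are driven by the same induction pulse, within-condition
correlations among targets saturate, and the cooperativity test loses
contrast between both-bound and single-bound pairs (visible in the demo
screen).  In real data, heterogeneous target kinetics make that contrast
informative.

# Numerical and design choices

* **Coordinates** are 0-based half-open throughout (BED-native).
* **TRANSFAC counts** become probabilities by row normalization followed
  by a pseudocount of 0.01 and renormalization; a pseudocount also guards
  MEME probabilities, so no log-odds is ever -Inf.
* **Motif presence** ("the peak contains the partner's site") is best hit
  >= 60% of the PWM's maximum log-odds.  At 70%, one mismatch to an 8-mer
  consensus already fails, and a third of sites sampled from the PWM
  itself go undetected; 60% tolerates a single mismatch while keeping the
  false-hit rate per 200 bp sequence low.
* **Peak-to-gene distance** is measured from the peak midpoint,
  unstranded; equidistant TSS ties go to the lexicographically smallest
  gene id.  Midpoint-vs-overlap for the 20 kb rule is a genuine open
  choice; midpoint is the conventional summary.
* **Tie-breaks** are deterministic everywhere (offsets before strands,
  smallest gap before quadrant order, lexicographic pair and gene ids),
  so every stage is a pure function of inputs, configuration and seed —
  reruns are byte-identical.
* **Problem sizes** in the shipped tests and acceptance script (200–400
  genes, 300–500 peaks, 500 calibration replicates, 300–1000 GSEA
  permutations) were chosen as the smallest sizes at which the calibration
  and power properties stabilize.

# Known limitations

* The cooperativity p-value is exact under pair-level exchangeability but
  slightly anticonservative in the extreme tails for gene-level nulls
  (shared-gene dependence, above).
* The spacing test inherits SpaMo's one-best-hit-per-sequence convention;
  sequences containing two genuine spacings contribute only the stronger.
* The latent-force model assumes linear activation; saturating or
  repressive regulation shows up only through a reduced likelihood ratio,
  and strongly *repressed* targets rank by model misfit rather than by a
  signed effect.
* FWER from label permutation is conservative when sets overlap heavily
  (shared targets are common for dimer partners).
* With only four time points, `D` and `l` are weakly identified; the
  likelihood ratio is robust to this, the individual parameter estimates
  less so.
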