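---
title: "Stage-wise pathway activity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-wise pathway activity: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germclock)
```

`germclock` turns a staged, replicated FPKM matrix into an ordered pathway
activation timetable. This vignette explains the statistical model behind
each stage of the pipeline, the parameters that matter, what the synthetic
data generator does and does not emulate, and the design decisions that
were genuinely open.

## Differential expression: a nonparametric signal-vs-noise caller

The caller works on FPKM values and never sees read counts, so a
count-based model (negative binomial) is not applicable. Instead it follows
the signal-versus-noise idea of nonparametric callers: for a contrast
between a test and a reference stage it computes per gene

* `M = log2(mean_test / mean_ref)` — the log2 ratio of stage means, and
* `D = |mean_test − mean_ref|` — their absolute difference in FPKM,

both after adding a pseudo-count (default **0.5 FPKM**) to every value.
The pseudo-count keeps `M` finite for zero-expression genes; it cancels in
`D`. The null is an empirical cloud of the same two statistics computed
between every unordered pair of replicates *within* each of the contrast's
two stages, pooled over all genes (for 3 replicates per stage and `G`
genes that is `6G` noise points). The probability of differential
expression is the fraction of noise points strictly dominated by the
gene's signal:

```
P(g) = #{ (m*, d*) : m* < |M_g| and d* < D_g } / #noise
```

Strict dominance means ties count against the gene, so a gene with
`M = 0, D = 0` has probability exactly 0. No kernel smoothing is applied:
the downstream analysis only uses the threshold behaviour of the
probability, and the empirical cloud makes that behaviour exact and
deterministic. A gene is called up-regulated at fold change ≥ 2
(`M ≥ 1`) and probability ≥ 0.8, down-regulated symmetrically; both
thresholds are inclusive and configurable (`fc_threshold`,
`prob_threshold`).

This is deliberately a NOISeq-*like* caller, not a re-implementation of
any specific tool: replicate mode and normalisation options of existing
callers are not modelled. Users who prefer an external caller can supply
its calls as a TSV (`read_de_calls()`) and skip this module; the
enrichment and activity stages are agnostic to where calls come from.

The internal dominance count uses an offline sweep with a Fenwick tree
(O((G+P) log P) for P noise points) and is checked in the tests against a
direct per-gene brute-force count.

## Directional enrichment: hypergeometric p to signed Z

For each rolled-up Mapman BIN, each contrast and each direction, the
overlap `k` between the bin (`K` genes in the universe) and the DE set of
that direction (`n` genes) is tested against the hypergeometric law on a
universe of `N` genes. Two conventions had to be fixed:

* **Universe** — by default the universe is the annotated measured genes
  (`universe = "annotated"`); unannotated genes would otherwise dilute
  `N` without being able to appear in any `k`. `"all_measured"` is
  available for users who consider the unannotated fraction informative.
  Both directions share the same universe; `n` counts one direction only.
* **Two-sidedness** — the two-tailed p-value uses minimum-likelihood
  summation (sum of all point probabilities not exceeding the observed
  one, with a 1e-7 relative tolerance on the comparison), the same
  convention as `fisher.test()`. Doubling the smaller tail is offered as
  `method = "double"` but is not the default because it can exceed 1 and
  varies between implementations.

The p-value becomes a signed Z through the inverse-normal transform
`Z = sign(k − nK/N) · qnorm(1 − p/2)`, zero when the observed overlap
equals its expectation, and capped at |Z| = 8 (`z_cap`), where p-values
underflow double precision anyway. This conversion is what makes the
1.96 significance rule exact: |Z| ≥ qnorm(0.975) if and only if p ≤ 0.05.
The original GUI tooling for BIN enrichment does not publish its exact Z
transformation; the inverse-normal convention here is declared, not
claimed identical. Bins with fewer than `min_bin_size = 5` universe genes
are not tested — below that size the discrete p-values are too coarse to
ever reach significance and only add noise to the tables.

No multiple-testing correction is applied by default: the activity
classification thresholds raw Z at 1.96, and correcting would silently
redefine that scale. Benjamini–Hochberg across bins can be layered on by
the user from the returned p column.

## Pathway activity, concordance and the timetable

The activity statistic is the relative Z-value
`sigma_Z = Z_up − Z_down`: up-regulation enrichment pushes it positive,
down-regulation enrichment negative. Classification is `active` for
`sigma_Z > 0`, `significantly_active` for `sigma_Z ≥ 1.96`, and mirrored
for non-positive values. The boundary 1.96 itself counts as significant —
the inclusive reading is adopted uniformly everywhere a 1.96 threshold
appears (activity, concordance), and the tests pin this behaviour. When a
(bin, contrast) lacks one direction's cell (no DE genes of that direction
at all), that direction contributes `Z = 0`, which is the continuous
limit: `n = 0` forces `k = 0`, `p = 1`, `Z = 0`.

Both contrast systems are evaluated: **fixed** (each stage vs the
baseline) and **continuous** (each stage vs its predecessor). Their first
contrast is identical by construction, so the concordance analysis starts
at the third stage: each (bin, stage) pair maps to a point
`(x, y) = (sigma_Z_fixed, sigma_Z_continuous)` coloured green when neither
coordinate reaches 1.96 in magnitude, blue when at least one does and the
point sits strictly inside quadrant I or III (the systems agree in
direction), red otherwise. Points exactly on an axis with a significant
coordinate are red, not blue: sign agreement cannot be claimed at zero.

The timetable is defined on the fixed system, because onset is a
statement about change relative to the dry seed, not relative to the
previous stage. Per bin: **onset** is the first stage with
`sigma_Z ≥ 1.96`; **peak** is the global argmax of the trajectory (first
stage on ties); **offset** is the first stage after onset with
`sigma_Z ≤ 0`. Offset deliberately means loss of *activity*, not loss of
*significance* — a pathway drifting from 2.5 to 0.4 is still active; users
wanting the stricter reading can re-derive it from the activity table.
Bins are ranked by onset stage index, ties broken by peak stage index,
then by numeric bin code; never-significant bins have no onset and sort
last.

## The synthetic-data generator

`simulate_expression()` emulates the target study design: six stages
(0, 0.75, 6, 24, 48, 144 h), three replicates per stage, 2000 genes of
which 20 bins × 40 genes are annotated. Baseline means are log-normal
(meanlog 3, sdlog 1 on the natural scale, i.e. a median around 20 FPKM
with a realistically long right tail). Replicate noise is multiplicative
log-normal with sd 0.25 on the log2 scale — the pipeline consumes FPKM
and never sees counts, so a count-level noise model would add machinery
the downstream statistics cannot distinguish. A planted schedule assigns
each perturbed category a direction, active stages and a log2 effect
profile; a responding gene's stage mean is its baseline times
`2^(direction · effect)`. One global seed drives everything, split into
per-stage substreams (seed + stage index) so stages are independently
reproducible.

The canonical schedule (`germination_schedule()`) plants the biological
order the package is designed to detect: CHO up from 0.75 h with an
early-peaking profile, lipid up at 6–48 h peaking early, protein up at
6–48 h with a ramp (0.8, 1.6, 2.0 log2 units at peak effect 2) whose
first step is below the fold-change threshold — so protein's *detectable*
onset and peak both trail lipid's. Effect profiles (a vector per active
stage) are the one generalisation over a scalar effect size; without
them neither distinguishable peaks nor monotone trajectories can be
planted.

What the generator does **not** emulate: library-size or length biases
(inputs are already FPKM), count-level overdispersion, correlated genes
within a pathway, partially overlapping bin membership, or
presence/absence (on/off) expression patterns. The last point matters for
interpretation: with a 20 FPKM median baseline essentially every
simulated gene is "expressed" at every stage, so planted-schedule runs
yield empty stage-specific sets. The stage-specific module is therefore
validated against brute-force classification of constructed masks rather
than against the generator. Passing tests demonstrate correctness of the
machinery under this noise model, not robustness to every artefact of
real RNA-seq.

## Stage-specific genes

The presence call is FPKM ≥ 1 in at least 2 replicates, both
configurable — there is no single community criterion, so the parameters
are surfaced rather than hidden. A gene expressed at exactly one stage is
stage-specific; the partition is exact (checked against a per-gene
brute-force classifier) and monotone in the threshold: raising τ can only
shrink each gene's expressed-stage set.

## Validation problem sizes

The test suite validates the exact test against full enumeration for
every contingency configuration with N ≤ 40 (~136,000 cases), the
planted-order recovery over 20 simulation runs at 2000 genes each, null
calibration at the same size, and concordance on 1200-gene runs — sizes
at which the stochastic properties are stable across seeds while the
whole suite stays fast enough to run on every change.

## Known limitations

* The DE caller is an approximation of the nonparametric
  signal/noise idea, not a drop-in replacement for any published tool;
  with few replicates its probability is coarse (multiples of
  1/#noise-points).
* Enrichment Z-values saturate at ±8; trajectories of very strongly
  perturbed pathways flatten at the cap, and peak detection then falls
  back to the first capped stage.
* FPKM input means between-sample normalisation is assumed done;
  the package does not renormalise.
* The activation timetable orders pathways by detectable transcriptional
  onset; it is not a causal statement about metabolic flux.
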