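---
title: "Methods: expression-based CNV inference and clone-tree reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression-based CNV inference and clone-tree reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the model each
stage assumes, the tunable parameters and why their defaults are what they
are, what the synthetic-data generator emulates (and deliberately does not),
and the numerical choices made where the design was genuinely open. It
states no empirical result that the test suite does not itself compute.

## 1. The inference model

Expression-based CNV inference rests on a dosage argument: a segmental gain
or loss changes the DNA copy number of every gene in the segment, and
average expression over many consecutive genes tracks that dosage even
though any single gene's expression is dominated by biological and sampling
noise. The chain is:

**Reference centering** (`center_on_reference`). Log-normalised expression
(`normalize_log1p`, counts scaled to 10,000 per cell, then `log1p`) is
centred per gene on a copy-neutral reference population — immune and
endothelial cells, or normal epithelium; both work and both modes are
supported. Genes with mean expression below `cutoff = 0.1` are dropped:
below that level the log-residual carries almost no dosage information.
Each cell's residuals are additionally median-centred (`center_cells =
TRUE`): library-size normalisation forces counts to a fixed total, so an
aneuploid cell's *neutral* genes are depleted in proportion to its total
gain; without the per-cell recentering the whole genome of an amplified
cell drifts negative. Residuals are clipped at ±3 to bound outlier leverage.

**Genome smoothing** (`smooth_genome`). A `window = 101`-gene moving
average within each chromosome (shrinking at edges, never crossing a
chromosome boundary). The window is the reference tool's long-standing
default; smaller windows let single-gene noise through, larger ones erase
focal events.

**Dynamic denoising** (`denoise_dynamic`). Per gene, values within
`k_sd = 1.5` standard deviations of the reference-cell distribution are
treated as noise and set to exactly zero signal; values outside pass
through relative to the reference mean. The band is *closed* (a value at
exactly mean + 1.5·SD is suppressed) — the boundary convention is not
dictated by anything, so we chose the one that makes "suppress the
reference band" literally true and keeps monotonicity in `k_sd` exact.
The band is per-gene rather than global because reference variance differs
strongly across expression levels.

**Rescaling and scoring** (`rescale_unit`, `cnv_score`). The denoised
matrix is divided by its maximum absolute value, yielding values in
[−1, 1]; optional symmetric percentile clipping is available but off by
default. The per-cell CNV score is the mean absolute rescaled signal. A
plain sum grows with the gene panel, which would make scores from
different panels incomparable; dividing by gene count fixes that, and a
`sum_abs` mode preserves the raw-sum reading. Absolute score values are
therefore *not* comparable with any externally published score whose
normalisation constant is unknown.

## 2. Discrete events: HMM and boundary refinement

`call_states_hmm` decodes a 3-state HMM per chromosome: state means
(−δ, 0, +δ), shared Gaussian σ estimated from reference residuals,
symmetric transitions with self-transition `p_stay = 0.99`. δ defaults to
the median absolute signal over genes that survived denoising (fallback
0.2 when nothing survives). Viterbi ties break deterministically toward
the lower state index; a brute-force path enumeration over all 3^8 paths
on random 8-gene instances guards the implementation in the tests.

A 101-gene moving average blurs every event edge into a ±50-gene ramp, so
raw Viterbi boundaries sit wherever the ramp crosses δ/2 — up to tens of
genes away from the true edge, and dependent on δ. With `refine = TRUE`
each emitted boundary that is interior to its chromosome is re-estimated
by a least-squares single-changepoint fit on the *unsmoothed* residuals
(`refine_on`), searching ±60 genes around the Viterbi boundary but never
past a neighbouring called segment (whose residuals would distort the
fit). On unsmoothed residuals the step is sharp, and the changepoint
estimator localises it to a couple of genes. This refinement was designed
from the smoothing analysis, not fitted to any test outcome.

**Segmentation unit.** Clone-mean profiles are the default segmentation
unit (per-subcluster region files are the natural granularity of this
analysis): averaging ~200 cells shrinks residual noise by ~14× and makes
boundary estimates essentially deterministic. Per-cell calls are still
made — they provide the supporting fraction behind every consensus event.
When calling on clone profiles, δ should be taken from the per-cell
matrix (`delta = median(abs(cnv[cnv != 0]))`): averaging denoised cells
dilutes the nonzero-median the profile matrix itself would give.

`consensus_clone_events` accepts an event for a clone when ≥ 75 % of the
clone's cells carry an overlapping same-direction call (reciprocal overlap
≥ 50 %); clones with fewer than 5 cells are skipped with a warning. Events
are then harmonised across clones (same chromosome, same direction,
reciprocal overlap) into shared event ids, so clone event sets are
directly comparable — without harmonisation, ±1-gene boundary differences
between clones would break every subset relation the tree builder needs.

## 3. Malignancy calling

Epithelial cells are clustered on their scalar CNV score with k = 3 per
sample, and only the cluster with the highest mean score is labelled
tumor. This deliberately prioritises specificity: the middle cluster may
contain genuine tumor cells, but a high-confidence malignant population is
worth more downstream than a complete one. Two clusters tying on mean
score (within 1e−12) abort with a request for manual review rather than
silently picking one.

The k-means itself is *exact*: optimal 1-D clusters are contiguous in
sorted order, so the global within-cluster-sum-of-squares optimum is found
by dynamic programming over split points. The design brief suggested
quantile-initialised Lloyd iterations, but Lloyd demonstrably sticks in
local optima on heavy-tailed score distributions (roughly a third of
random instances in our checks), while the DP is deterministic, O(k·n²),
and optimal by construction — it satisfies the "assignment minimising
within-cluster sum of squares" contract exactly, so we ship the DP. An
independently written DP oracle still guards it in the tests.

Whether to cluster the scalar score or the full CNV profile was left open
by the source analysis; the scalar is implemented here (matching the
"classified by CNV score" description), and `cluster_clones` provides
profile-based Ward clustering for clone assignment, with k selected by
mean silhouette when not given.

## 4. Clone trees

Under irreversibility, a clone's event set contains its ancestor's. The
root P carries the intersection of all clone event sets; each clone
attaches to the node with the largest event set strictly contained in its
own, with ties preferring observed clones over synthesized ancestors.
Non-nested clones with partial overlap attach through a synthesized
ancestor carrying their intersection — internal nodes beyond the observed
clones are implied by any hierarchical reconstruction, and the inferred
common ancestor P is itself such a node. Synthesized single-child nodes
are spliced out. Opposite-direction events on the same region between two
clones violate irreversibility; real tumors do show CNV reversion, so the
conflict is reported explicitly and the tree is built on the
non-conflicting events rather than silently dropped.

Branch lengths are `bk = scale · log2(Δ)` with `scale = 10` px, where Δ is
the event-count difference along the edge. The formula is undefined at
Δ ≤ 1 (log2(0) = −∞, log2(1) = 0), so those branches get a `floor_px = 2`
pixel floor — the arbitrary-scaling-for-visibility convention made
explicit and configurable. Node diameters are `dl = sqrt(p)` with p the
percentage of the sample's assigned cells/spots in the clone. Whether the
parent's event count should count only events retained in the descendant
is moot under strict irreversibility (the two coincide), which is what the
builder enforces.

## 5. Statistics

- `wilcoxon_compare`: exact permutation enumeration of the Mann–Whitney U
  when n₁+n₂ ≤ 20 (two-sided p = probability of a U at least as far from
  its null mean; ties handled by midranks, identical samples give p = 1),
  tie-corrected normal approximation with continuity correction otherwise.
- `best_cutpoint`: scans every distinct expression value whose
  dichotomisation leaves ≥ 10 subjects per arm within the 10th–90th
  percentile band, using a vectorised log-rank score test (algebraically
  identical to `survival::survdiff`, which the tests verify split by
  split). The minimum p over a scan is selection-biased by construction,
  so the function also reports a permutation-adjusted p (min-p null over
  seeded permutations of the expression vector, default 1000). The naive
  minimum is what the "best p-value" convention reports; the adjusted
  value is what one should believe.
- `cox_univariate`: partial likelihood with Wald CI; monotone-likelihood /
  separation is flagged with `NA` estimates instead of a silently huge HR.
- `correlate_expr_score`: Spearman by default (CNV scores are heavy-tailed
  and bounded; rank correlation is the safer default), Pearson by flag.
- Burden comparisons treat cells/spots as independent units, as in the
  source analysis; this pseudoreplicates across patients, so for cohort
  inference aggregate per patient first and test the aggregates.

## 6. The synthetic world

`simulate_cohort` states one world and the tests live in it:

| parameter | default | rationale |
|---|---|---|
| genome | 6 autosomes × 300 genes + 13-gene chrM | small enough for fast tests, large enough for 101-gene smoothing; chrM exercises the mito QC filter and is excluded from CNV inference |
| counts | negative binomial, dispersion 0.1 | overdispersion is the dominant scRNA-seq noise feature the denoising must survive; Poisson would flatter the pipeline |
| dosage | multiplier = copy/2, floor 0.05 at copy 0 | linear dosage in expectation; homozygous deletions still show ambient counts |
| library sizes | lognormal(0, 0.3), per-sample lognormal(0, 0.1) scale | realistic cell-to-cell depth spread; a per-sample factor is the only batch effect simulated |
| clones | founder with 4 arm-scale events (120–150 genes, copies 1/3/4), three descendants (+1/+2 events, branching) | HER2+ tumors carry on the order of ten arm-level CNVs across chr1/6/11/12/17/20/21; a 4–6-event clone family is conservative |
| histology | DCIS-dominant founder → IDC-dominant derived clones | mirrors the DCIS→IDC burden gradient the statistics are meant to detect |
| survival | exponential times, hazard × HR above the cutpoint, uniform censoring | the simplest world in which log-rank/Cox calibration is checkable in closed form |

What the generator does **not** emulate: gene-length/GC bias, doublets,
ambient RNA, real batch structure, subclonal mosaicism within a clone, and
any real noise model (the source data are patient accessions; the NB and
dosage choices are declared stand-ins). A green test therefore establishes
that the algorithms are implemented correctly and recover planted structure
under realistic overdispersion — not that they would recover the published
patient-level numbers, which depend on external accessions and are out of
scope by design.

## 7. Numerical and degenerate-input choices

- Denoising band closed; suppressed values are exactly 0, so monotonicity
  in `k_sd` is exact rather than approximate.
- `rescale_unit` of an all-zero matrix is the identity (no 0/0).
- Viterbi and 1-D k-means tie-breaks are deterministic (lower state index /
  earliest split), making byte-identical reruns possible.
- Smoothing windows cap with a warning on chromosomes shorter than the
  window.
- Clone composition over zero labelled members is flagged undefined, never
  0/0; all-censored survival tables, constant covariates, single groups,
  and empty references all raise errors naming the problem.
- All randomness (simulation, control-gene sampling, community detection,
  permutation nulls) flows through explicit seeds; the CLI pipeline is
  byte-identical across runs with the same seed.

## 8. Known limitations

- Expression-inferred CNV cannot see copy-neutral LOH, and focal events
  shorter than ~half the smoothing window are attenuated toward the
  denoising band.
- The 3-state HMM reports direction, not integer copy number; the 6-state
  quantification of the reference tool is deliberately out of scope.
- The malignancy rule assigns exactly one tumor cluster per sample; samples
  with no malignant cells will still nominate their highest-burden cluster
  (inspect cluster means before trusting the label).
- Batch integration is a per-batch PC centering stand-in, adequate for the
  location shifts the simulator produces, not for real nonlinear batch
  effects.
- `best_cutpoint`'s naive p is anti-conservative by construction; report
  the permutation-adjusted value.
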