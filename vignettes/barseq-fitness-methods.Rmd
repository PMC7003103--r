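---
title: "Competitive fitness from pooled barcode sequencing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Competitive fitness from pooled barcode sequencing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barseqfit)
```

# The assay

A pool of strains, each carrying a unique chromosomal barcode pair (two 12-nt
codes separated by a fixed 92-nt loxP-scar spacer), is grown competitively
through serial batch passages: grow to stationary phase, sample, dilute into
fresh medium, repeat. Amplicon sequencing of the barcode element at each
sampling point (T1, T2, ...) yields a strain-by-sample count matrix; a
strain's change in relative barcode abundance over passages measures its
competitive fitness. Treatment flasks are inoculated from the same T1 culture
as the reference flasks, so differencing a strain's temporal change in a
treatment against its change in the reference medium isolates the
treatment-specific fitness effect.

`barseqfit` implements the full path — a generative simulator with known
ground truth, read demultiplexing, normalization, per-strain GLM contrasts,
and downstream reporting — so that every stage is testable without external
data.

# Fitness parameterization

The simulator's selection coefficient `s` is a *log2 per-generation
growth-rate advantage*: over `g` generations a strain's log2 abundance ratio
to a neutral competitor changes by `s * g`. Within each growth phase
abundance multiplies by `2^((1 + s) * g_p)` and fractions renormalize. This
convention makes recovery targets closed-form: with the default 8 generations
per passage and the T1-versus-T3 contrast (two re-inoculations, 16
generations), a strain with `s = 0.1` in a treatment and `s = 0` elsewhere
has expected treatment fitness `0.1 * 16 = 1.6` log2 units. Assays report
per-contrast log2 fold-changes; the per-generation decomposition exists only
in the simulator.

Two inoculation schemes are supported. Under the default
(`inoculation = "reference_first"`) the first growth phase takes place in the
reference medium in every flask — the serial scheme in which control and
treatment flasks are split from one reference-grown culture after T1. With
`"direct"`, each condition's selection acts from the first phase, as when
strains are inoculated straight into fresh juices. The choice matters for
ground-truth bookkeeping: under the default, treatment exposure between T1
and T3 is exactly `2 * g_p` generations.

# The measurement model

Observed counts are not proportional to cell numbers. DNA extraction yield is
strain-specific — equal-abundance pools show count spreads of more than
20-fold — so the simulator draws a fixed per-strain bias factor `b_i`
(log-normal, rescaled so the realized max/min ratio equals a target, default
22) and forms template proportions `p_i ∝ f_i * b_i`. Sequencing is a single
multinomial draw of `depth` reads (default 3e4 per sample). PCR bias is not
modeled separately: with one-step amplicon generation and few cycles it is
assumed negligible relative to extraction bias and counting noise. Read
errors are i.i.d. substitutions; indels are out of scope because barcodes are
matched positionally at fixed offsets.

Because `b_i` is constant across all samples of an experiment it cancels
exactly from any within-strain temporal contrast. This is a theorem about the
estimator, not an approximation, and the package is built so it holds to
machine precision (see below).

# Demultiplexing

Reads are assigned by extracting both 12-nt windows at the template offsets,
concatenating them, and computing Hamming distances to every library pair.
The unique pair at minimum distance at most `max_mismatch` wins; ties are
`ambiguous` (never fractionally assigned); everything else, including reads
too short to span the template, is `unassigned`. Per sample,
`assigned + ambiguous + unassigned` equals reads processed, always.

Default `max_mismatch = 1` over the 24-nt concatenated barcode: libraries
generated by `make_barcode_library()` keep distinct same-side codes at
Hamming distance at least 3, so single-error reads cannot cross strains. An
`offset_scan` fallback (try shifts of up to ±k nt, keep the best distance)
handles ragged 5' ends in real data; simulated reads do not need it.

# Filtering and normalization

Following standard count-pipeline practice, samples with fewer than 15 total
assigned reads are dropped, then strains with fewer than 3 reads across the
remaining samples ("total" is our reading of the thresholds; both are
arguments). Size factors are relative-log-expression (median-of-ratios)
values: each strain's reference is its geometric mean across samples, and a
sample's factor is the median over strains of count/reference. We keep the
raw convention — factors carry sequencing depth and are *not* rescaled to
geometric mean 1 — so `log(c_j)` is the complete GLM offset. Multiplying the
factors by library size as well would count depth twice; any global constant
in the offsets cancels from every contrast, so the convention is irrelevant
to the results and matters only when comparing factors across
implementations.

Two defaults in `barseq_fit()` deserve justification:

* **Timepoints.** The fit subsets samples to the contrasted time points
  (default T1/T3) before normalizing. Late passages accumulate extreme
  composition shifts — strongly selected-against strains approach zero counts
  — and a reference that averages over those samples drags each strain's
  ratio by its own selection history, biasing the per-sample medians. T4
  samples carry no information about a T1-vs-T3 contrast, so they are
  excluded by default (`timepoints = NULL` restores the full design).
* **Positive-counts reference.** The strict median-of-ratios estimator uses
  only strains with nonzero counts in *every* sample. In a competition assay
  that subset is systematically enriched for high-fitness strains, which
  shifts the median of the remaining ratios. `barseq_fit()` therefore uses
  the positive-counts variant (per-strain reference over positive counts,
  per-sample median over strains observed in that sample), which reduces to
  the strict estimator exactly when the matrix has no zeros.

Normalized log2 counts, `log2(count / c_j + 0.5)`, exist for descriptive
output only (clustering, CVs); inference always works on raw counts with
offsets. The pseudo-count is added after scaling so that jointly rescaling a
sample's counts and its factor leaves the values unchanged.

# The GLM and its contrasts

The design is the cell-means encoding of treatment-by-time,
`~ 0 + treatment + treatment:time` with time categorical (the contrasts
difference specific sampling points; no growth curve is fit). An
intercept-form variant, `~ treatment + treatment:time` with the reference
condition as baseline, spans the identical column space and is provided for
workflows that prefer a baseline parameterization; fitted cell means and all
contrasts are identical between the two, and the test suite asserts it.

Two contrasts define the assay:

* reference fitness: `(T3, ref) − (T1, ref)`;
* treatment fitness: `((T3, t) − (T1, t)) − ((T3, ref) − (T1, ref))`.

**Estimator.** Per strain, coefficients solve the quasi-Poisson score
equations `X'(y − mu) = 0` with log link and known offsets. Under any
saturated treatment-by-time encoding the fitted cell mean is then the
offset-adjusted arithmetic mean `sum(y) / sum(exp(o))` of the cell's counts.
This estimator was chosen deliberately over the dispersion-weighted
negative-binomial score: it is independent of the (estimated) dispersion,
identical across reparameterizations, and *exactly* equivariant under
per-strain scaling — multiply one strain's counts by any `b > 0` in every
sample and every cell mean shifts by `log b`, so every contrast is bit-level
unchanged, as are the size factors (each strain is compared only to its own
reference). That exactness is the computational content of the assay's
extraction-bias robustness. A dispersion-weighted estimator with an estimated
dispersion is only approximately equivariant. The two estimators coincide
whenever offsets are balanced within cells, and differ negligibly otherwise;
log fold-changes agree with an independent GLM engine's to four decimals in
the cross-check test.

**Dispersion.** The negative-binomial dispersion enters inference, not
estimation. Raw per-strain dispersions solve the method-of-moments equation
`Pearson X^2(phi) = residual df` on the fitted means; a common value solves
the pooled equation; per-strain values are shrunk toward the common one by an
empirical-Bayes weighted average with `prior_df = 10` prior degrees of
freedom (each shrunk value lies between its raw estimate and the common one —
a tested invariant). A quasi-likelihood layer absorbs what the shrunk
dispersions miss: the per-strain quasi-dispersion `X^2(phi_i)/df` is squeezed
across strains (`limma::squeezeVar`), and the contrast statistic
`est^2 / (var * s2_post)` is referred to `F(1, df_resid + df_prior)`,
two-sided. The contrast variance is the delta-method value at the NB variance
function, matching the quasi-score estimator. This is a documented
simplification of the quasi-likelihood machinery in dedicated
differential-abundance packages: numerical agreement on test statistics with
any particular package is not promised; agreement on log fold-changes is,
because cell means are estimator-independent.

**Degenerate strains.** A strain with zero counts in every sample of a
contrast cell is flagged: its fold-change is reported with a 0.5 pseudo-count
fallback, its p-value is `NA`, and it is excluded from the
Benjamini-Hochberg denominator. FDR is adjusted per contrast over the non-NA
p-values; the significance threshold used by downstream classification
defaults to 0.05 (a choice, since significance conventions vary).

# Downstream reporting

* **Tolerance calls.** A strain is tolerant in a condition group (e.g. three
  independent high-copper contrasts) when at least `min_support = 2`
  contrasts are significant with positive fold-change and none is significant
  negative; sensitive symmetrically; anything else — including mixed signs —
  is unclassified. The call is monotone: tightening `fdr` or raising
  `min_support` can only declassify. A mean-based variant (`rule = "mean"`)
  is exposed because prevalence-style summaries are sometimes computed from
  mean fitness; neither rule's prevalence is promised by the package.
* **Clustering.** Strains and treatments are clustered with Euclidean
  distance and Ward.D2 linkage (unsquared distances in, squared update inside
  the Lance-Williams recurrence — the `ward.D2` convention). Ties are broken
  by `stats::hclust`'s deterministic lowest-index rule. Missing fold-changes
  are imputed as 0 (neutral) with a flag; heat-map rendering is a thin layer
  over the orderings and linkage heights, which are the scientific surface.
* **Cross-batch agreement.** Reference-condition fitness vectors from
  different experimental batches are compared by Spearman rank correlation on
  shared strains (pairs sharing fewer than 3 strains give `NA`).
* **OD calibration.** Cell numbers are estimated from absorbance through the
  log-log line `log10(cells) = a * log10(abs) + b`, fit by ordinary least
  squares; the published coefficients (a = 1.011, b = 7.489) can be supplied
  directly via `calibration_model()`. The slope must be positive so the model
  is strictly increasing.

# What the simulator does and does not emulate

Emulated: pool sizes around 82–94 strains; triplicate cultures; four
passages of ~8 generations (16 generations between T1 and T3); strain-
specific selection; a >20-fold extraction-bias spread constant across
samples; multinomial sequencing noise at configurable depth; bottleneck drift
with multinomial variance `f(1-f)/N_b`; substitution errors in emitted
FASTQ, with sample identity in dual-index header fields.

Not emulated: medium chemistry (conditions are abstract labels with
per-strain `s`), growth-curve kinetics and OD/sugar time courses, PCR
amplification noise, indels and quality-score structure in reads, and
pool-construction optical densities. Passing tests therefore demonstrate the
statistical pipeline's correctness under the assay's assumed noise structure,
not robustness to artifacts the generator does not produce (chimeric reads,
index hopping, batch-varying extraction bias).

# Numerical choices and problem sizes

Degenerate inputs: negative generations per passage are rejected; extinct
lineages (fraction exactly 0) are legal and stay extinct; empty FASTQ files
produce zero columns with a warning; all-dropped filtering is an error with
diagnostics. Dispersion root-finding brackets `phi` in `[0, 1e6]` with
tolerance 1e-10; quasi-dispersions are floored at 1e-8. Seeded operations
save and restore the caller's RNG state, so seeded helpers compose without
side effects and identical seeds give byte-identical counts and FASTQ.

The test and acceptance workloads use pools of 20–87 strains at depths of
1e4–1e5 reads per sample — sizes at which every stage, including the
10,000-read brute-force demultiplexing cross-check and the 15-quantity
acceptance run, completes in seconds while leaving the statistical checks
(parameter recovery across the `s` grid, null calibration over five seeds,
drift variance over 200 replicates) well powered.

# Known limitations

Fold-change estimates at very low counts carry the usual log-of-small-counts
bias; strains flagged as non-testable are the extreme of this. The
quasi-likelihood F-test's prior df comes from a moment fit and can be
optimistic for very small strain panels (a two-strain toy will trip a
squeeze warning). RLE normalization assumes the median strain is stable
between the contrasted samples; designs in which most of the pool moves in
one direction violate it, which is why symmetric effect grids are used for
recovery checks and why heavily selected late passages are excluded by
default.
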