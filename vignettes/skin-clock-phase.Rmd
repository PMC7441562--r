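---
title: "Inferring circadian clock phase from skin expression: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring circadian clock phase from skin expression: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circaskin)
```

## The problem

Dosing time matters for many drugs, but a patient's internal circadian
phase can differ from wall time by hours. A practical biomarker of
molecular clock phase needs to be readable from a *single* tissue sample.
Skin is attractive: it is accessible, and its epidermal clock is strong.
`circaskin` implements a complete analysis chain for discovering and
evaluating such a biomarker from a hybrid study design that combines

* a small *longitudinal* cohort: participants biopsied at four known clock
  times (6 AM, 12 PM, 6 PM, 12 AM), anchoring absolute time; and
* a large *population* cohort: one biopsy per body site (arm, buttock,
  cheek) per participant, split into epidermis and dermis by laser-capture
  microdissection, with **no** recorded collection time.

The chain is: rhythm detection (cosinor), clock-strength scoring of sample
groups (Mantel statistics on clock-gene correlation matrices), circular
ordering of the unstamped samples (a circular-bottleneck autoencoder),
sparse training of a periodic phase predictor, and circular-error
evaluation. A synthetic-data generator with known hidden phases makes
every stage testable end to end.

## Rhythm detection: cosinor

For a series $y_i$ observed at times $t_i$ (hours) the cosinor model is

$$y_i = M + a\cos(2\pi t_i/24) + b\sin(2\pi t_i/24) + \varepsilon_i,$$

fit by least squares. The amplitude is $\sqrt{a^2+b^2}$, the peak phase
(acrophase) $\hat\phi = \frac{24}{2\pi}\,\mathrm{atan2}(b,a)$, the p-value
comes from the F test of $(a,b)=0$, and the relative amplitude
rAMP $=$ amplitude / mesor. The period is fixed at 24 h; no multi-period
scan is attempted. Per-participant series (4 points each) are combined
across participants by Fisher's method on the p-values, an
amplitude-weighted circular mean of the peak phases, and the median rAMP
(`meta_integrate()`). This is a deliberately exact, testable substitute
for autoregressive spectral detectors whose internals are heuristic; with
the period fixed and four samples per cycle, the cosinor is the natural
estimator.

Circadian calls are threshold conjunctions (`classify_circadian()`):
*longitudinal* p < 0.05 & rAMP > 0.1; *relaxed* p < 0.1 & rAMP > 0.1;
*population* (used on ordered data) FDR < 0.05 & fitmean > 16 &
rAMP > 0.1 & rsq > 0.1. The abundance cutoff of 16 is a platform-specific
log2 level kept as a configurable default.

## Clock strength: Mantel Z against a reference

A sample group's clock integrity is summarized by the pairwise Spearman
correlation matrix of a 17-gene clock panel. Intact clocks produce a
stereotyped structure (activators anticorrelated with repressors); damped
or desynchronized groups lose it. Similarity to a reference matrix is the
sum over the lower triangle of entrywise products; permutations relabel
the reference's rows and columns jointly, and the reported
$Z = (\text{obs} - \bar s_{\text{perm}})/\mathrm{sd}(s_{\text{perm}})$
with a two-tailed permutation p. When the permutation sd is zero
(structureless matrices) $Z$ is defined as 0 and p as 1. Absolute $Z$
magnitudes depend on the permutation scheme and panel; only *comparisons*
between groups scored identically are meaningful, and that is how the
package uses them (epidermis vs dermis, subset selection). The
multi-tissue reference shipped here is synthetic
(`reference_matrix_from_panel()`): virtual tissues sampled densely around
the cycle and pooled.

The down-sampling selector (`downsample_select()`) scores many random
subsets of a fixed fraction of samples and keeps the subset with the
highest Mantel Z, shedding samples that disrupt the correlation structure
before ordering. The default draw count (10,000) is a desk-scale stand-in
for an exhaustive search; the pipeline configuration uses 300 draws, which
already recovers most of the attainable gain on simulated contamination.

## Circular ordering

Unstamped samples are ordered on a circle from seed-gene expression.
Seed genes (default: the 17-gene clock panel) are standardized and reduced
to principal-component *eigengenes* retaining 85% of variance (cap 10).
The ordering model is an autoencoder with a circular bottleneck: encode a
sample's eigengene vector to an angle $\theta$, decode as
$\hat x(\theta) = m + a\cos\theta + b\sin\theta$ with gene-space vectors
$m, a, b$, and minimize total squared reconstruction error. We fit it by
alternating least squares rather than gradient descent: given the angles,
the decoder is a linear regression; given the decoder, each sample's
optimal angle is found exactly on a 720-point grid with parabolic
refinement. Both half-steps decrease the loss monotonically, convergence
is declared at a relative change below 1e-6 (cap 5,000 epochs), and the
best of 40 deterministic restarts is kept (restart 1 starts from the first
two eigengenes, the rest from seeded random angles). ALS needs no step
size, cannot diverge, and is reproducible to the last bit under a fixed
seed, which is why we prefer it over SGD for these very small models.

An ordering is identifiable only up to rotation and reflection.
`register_phase()` fixes the gauge: the ordering is reflected if its
circular correlation with a direction reference (the stamped samples'
collection times) is negative, then rotated so the anchor gene ARNTL peaks
at phase 0. All downstream phases use this convention ("0 = ARNTL peak").
Quality is scored by two Fisher-Lee circular correlations
(`score_ordering()`): ordered phase vs known time over the stamped
samples, and fitted clock-gene peak phases vs their reference phases,
where clock genes must pass p < 0.01, fitmean > 16, rAMP > 0.1,
rsq > 0.1, and fewer than 8 passing genes zeroes the clock criterion.

## Sparse periodic phase prediction

Training data are (normalized expression, ordering phase) pairs.
Normalization has three steps, with every constant stored so that a single
test sample can be normalized identically (`normalize_expression()`,
`apply_normalization()`):

1. subtract, per sample, the mean of three non-circadian reference genes
   (GPKOW, BMS1, ANKFY1) — removes per-sample level shifts;
2. winsorize each gene at its (0.5%, 99.5%) training quantiles — the
   package's concrete interpretation of "rounding expression outliers";
3. divide each gene by its maximum post-winsorization *magnitude*. After
   the centering in step 1 values are signed, and a plain maximum can sit
   arbitrarily close to zero for genes whose centered level straddles 0,
   exploding the scale; the max-magnitude form is the stable signed
   analogue and coincides with the plain maximum on all-positive data.

Re-applying the stored spec to already-normalized data is a no-op (the
matrix carries a spec hash), making normalization idempotent by
construction.

"Dynamic" genes (cosinor rsq > 0.1 against the ordering) are candidates.
Each candidate's normalized expression is smoothed against phase with a
periodic harmonic basis (4 harmonics) and evaluated on a 48-point grid;
the centered gene-by-time curve matrix is then decomposed into K = 2
sparse principal components by penalized matrix decomposition: loading
vectors with unit L2 norm and L1 norm at most `sumabsv`, alternating
soft-thresholding updates, deterministic initialization from the dense
SVD. Deflation projects out the fitted *time-course* direction
($R \leftarrow R(I - vv^\top)$) instead of subtracting the sparse rank-1
fit. This matters: with a sparse loading vector, subtractive deflation
leaves most of the dominant-axis variance (from unselected genes) in the
residual, so the second component re-describes the first axis. Because
circadian peak times are strongly bimodal (~8.5 h and ~20.5 h, antiphase),
that failure mode discards exactly the quadrature genes (CRY1-, NFIL3-like
phases) that disambiguate a phase from its reflection, and prediction
errors then include reflection flips. Time-course-orthogonal deflation
forces the second component onto the quadrature axis and eliminated those
flips in our simulations.

Genes with any |loading| > 0.05 on the two components form the biomarker
set; the stored model is restricted to them, so predictions provably
depend on nothing else. Per-component residual sds come from the training
projections around the component time-courses. Prediction for one sample
projects it onto the loadings and maximizes
$\sum_k \log \mathcal N(p_k;\, c_k(\theta),\, \sigma_k)$ over the phase
grid with quadratic refinement. A sample that is constant across the
model genes is flagged `mle_ok = FALSE` with a flat profile.

## The synthetic study design

`make_gene_panel()` + `simulate_longitudinal()` + `simulate_population()`
emulate the study conditions: 20 stamped participants x 4 timepoints
(per-participant chronotype = pure phase shift, sd 1 h), 154 unstamped
participants x 3 body sites x 2 layers with one hidden phase per
participant, a 17-gene clock panel with canonical relative phases anchored
at ARNTL (repressors/PAR-bZip factors ~10-13 h later), bimodal free-gene
peak times (wrapped-normal mixture at 8.5 h and 20.5 h, sd 1.5 h), and
melatonin/cortisol marker phases at +7 h and +10 h from each participant's
ARNTL peak. Expression is
$\text{mesor}\cdot(1 + \text{rAMP}\cos(\theta - \phi))$ plus additive
Gaussian noise on the log2 scale — the simplest model consistent with
microarray data. Three generator choices deserve comment:

* **Noise scale.** Per-gene noise sd defaults to 0.1 x mesor, calibrated
  so a 4-timepoint cosinor detects rAMP >= 0.2 at p < 0.05 — the stated
  operating point of the longitudinal design.
* **Inter-individual variability.** Each participant carries persistent
  per-gene expression offsets (sd 0.1 x mesor) shared across their sites,
  layers and timepoints. Population skin cohorts spanning ages 20-74 show
  substantial interpersonal variation; without this term the clock-gene
  correlation matrices of both layers are essentially perfect and the
  epidermis/dermis clock-strength contrast degenerates (the Mantel Z is
  invariant to uniformly scaling all amplitudes). The value was fixed at
  the same order as measurement noise before the acceptance suite was
  written.
* **Mesor ranges.** Genome-wide mesors are drawn from (12, 20) so the
  fitmean > 16 abundance filter is genuinely exercised; clock-panel
  mesors are drawn from (16.5, 20) because clock genes are robustly
  expressed in skin arrays and the 8-of-17 quality gate presupposes an
  abundant panel.

What the generator does **not** emulate: probe-level structure, batch
effects (available only as an optional additive offset, off by default),
platform differences, non-sinusoidal waveforms, and amplitude effects of
chronotype. Passing tests therefore demonstrate correctness of the
machinery and qualitative reproduction of the study's structure (layer
contrast, ordering quality, compact biomarker sets, few-hour errors), not
quantitative performance on real microarray data.

## Evaluation

Errors are shortest-arc circular distances in hours. Predicted phases are
registered to the ARNTL-peak convention while hidden truth phases are
absolute, so evaluation aligns the two by one global rotation (the
circular mean of the differences) before computing errors — the quantity
that matters is phase *differences*, which chronotype and registration do
not affect. Per-participant order recall asks whether the circular
sequence of predicted phases, read forward from the earliest sample,
visits the stamped samples in time order; a reading-direction
minimization is available and makes recall reflection-invariant, but the
forward default treats a backwards-running prediction as a failure, which
is the right call for registered predictions. Layer amplitude contrasts
use the two-tailed Wilcoxon signed-rank test (exact for <= 25 untied
pairs). The Fisher-Lee T-linear coefficient is the default circular
correlation (the Jammalamadaka-SenGupta variant is implemented for
comparison); it is rotation-invariant and sign-flips under reflection,
which the quality gates rely on.

## The pipeline

`run_pipeline(default_config(seed), outdir)` executes simulate ->
downsample -> order -> detect -> train -> predict -> evaluate with one
TSV/JSON artifact per stage and a manifest of configuration, derived
seeds and artifact checksums (no timestamps, so identical runs give
identical manifests). Every stage seed derives deterministically from the
master seed. The train/test split holds out 9 stamped participants *by
participant*, never by sample. No stage except simulation and evaluation
reads the hidden truth table; the test suite verifies this by corrupting
the truth file and re-running everything downstream of simulation,
requiring byte-identical predictions. Default problem sizes (400 genes,
526 hybrid samples, 300 down-sampling draws, 20 ordering restarts) run
the whole pipeline in a few seconds while preserving the study's sample
structure.

## Known limitations

* Absolute Mantel Z values are not comparable across permutation schemes
  or panels; only within-run comparisons are used.
* The circular autoencoder is linear; strongly non-elliptical expression
  manifolds would need the nonlinear encoder of the original method.
* A multimillion-draw subset search is impractical on a desktop; the
  selector is the same algorithm at a configurable, much smaller draw
  count.
* Cross-platform transfer of the stored normalization constants (training
  maxima) is undefined for platforms with different dynamic ranges; the
  model refuses to predict when reference or model genes are missing, but
  cannot detect a scale mismatch.
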