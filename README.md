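# circaskin

Circadian rhythm detection and single-sample clock phase prediction from
skin gene expression.

## What problem this solves

Circadian medicine needs to know a patient's *molecular clock phase* —
the angular position of their tissue's circadian oscillator — but wall
time is a poor proxy: chronotype, age and lifestyle shift internal phase
by hours. `circaskin` implements an analysis chain for discovering a
compact gene-expression biomarker that reports clock phase from a single
skin sample, built around a hybrid study design: a small longitudinal
cohort biopsied at known clock times (anchoring absolute time) combined
with a large population cohort whose collection times were never recorded
(powering the statistics). It is aimed at computational chronobiologists
working with bulk skin expression matrices.

The chain, stage by stage:

1. **Cosinor rhythm detection** — least-squares fit of
   `y = M + a cos(2πt/24) + b sin(2πt/24)` per gene; amplitude
   `√(a²+b²)`, acrophase `atan2(b,a)·24/2π`, F-test p-values, Fisher
   meta-integration across participants, BH correction, and the
   threshold rules (`p`/`FDR`, rAMP, fitmean, rsq) for calling circadian
   genes.
2. **Clock-strength scoring** — Spearman correlation matrices over a
   17-gene clock panel, compared to a multi-tissue reference by a
   permutation Mantel Z statistic, plus a down-sampling selector that
   keeps the sample subset maximizing the clock signal.
3. **Circular ordering** — a circular-bottleneck autoencoder (fit by
   alternating least squares over seed-gene eigengenes) assigns every
   unstamped sample a phase in `[0, 2π)`, registered so that the ARNTL
   peak defines phase 0, and scored by two Fisher–Lee circular
   correlations (match to sampling time; match to reference clock-gene
   phases).
4. **Sparse phase model** — periodic per-gene curves over the ordering,
   two sparse principal components under an L1 budget (`sumabsv`), genes
   with |loading| > 0.05 as the biomarker set, and maximum-likelihood
   phase prediction for single samples.
5. **Circular evaluation** — absolute circular errors in hours,
   per-participant order recall, Wilcoxon amplitude contrasts between
   skin layers, and correlations with melatonin/cortisol marker phases.

A synthetic-data generator reproduces the study structure (20 stamped
participants × 4 timepoints; 154 unstamped participants × 3 body sites ×
2 layers; clock-gene co-oscillation; dermal amplitude attenuation;
chronotype offsets; bimodal peak times) with known hidden phases, so the
whole pipeline is testable without any external data.

## Worked example

```r
library(circaskin)

## simulate the hybrid study design and run the full pipeline
st <- run_pipeline(default_config(seed = 11), outdir = "skin_run", quiet = TRUE)

print(st$quality)   # how good is the circular ordering?
print(st$model)     # the trained biomarker model
print(st$eval)      # held-out prediction accuracy
```

```
Ordering quality
  time correlation 0.922
  clock-phase correlation 0.996 (17 clock genes passing)
  reconstruction error 694.2
Sparse periodic phase model
  13 biomarker genes (|loading| > 0.05), 2 SPCs, sumabsv 2
  trained on 491 samples, 48-point time grid
  genes: ARNTL2, PER3, CRY1, TEF, G00021, G00032, G00106, G00211, G00231, G00297, G00362, G00374, G00378
Phase prediction evaluation (36 samples)
  mean |error| 0.67 h (sd 0.52)
  order recalled in 9/9 participants
  time correlation 0.927
  marker correlation: melatonin 0.511, cortisol 0.516
```

Reading the output: the circular ordering of 526 epidermis samples
correlates 0.92 with the known collection times of the stamped subset and
0.996 with the canonical clock-gene phase order. Training on the 491
ordered samples that remain after holding out 9 stamped participants
selects a 13-gene biomarker panel (clock genes plus synthetic rhythmic
genes). On the 36 held-out stamped samples, predicted phase is off by
0.67 h on average, the within-participant sampling order is recovered for
all 9 participants, and the implied per-participant ARNTL peaks correlate
with the simulated melatonin and cortisol phases. All artifacts (ordering
TSV, cosinor results, model JSON, predictions, evaluation report,
manifest with checksums) are written to `skin_run/`.

Individual stages are plain functions if you want them separately:
`fit_cosinor()`, `cosinor_scan()`, `meta_integrate()`, `clock_corr()`,
`mantel_z()`, `downsample_select()`, `prepare_eigengenes()`,
`fit_circular_ordering()`, `register_phase()`, `score_ordering()`,
`normalize_expression()`, `train_phase_model()`, `predict()`,
`evaluate_predictions()`.

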