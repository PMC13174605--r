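---
title: "Methods: cross-platform bridging, imputation and fidelity tiering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-platform bridging, imputation and fidelity tiering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(proteoBridge)
```

## The measurement model

proteoBridge treats a paired two-platform proteomic study as two noisy,
possibly distorted views of one latent concentration matrix. Platform A
is an aptamer panel reporting raw relative-fluorescence units (RFU,
strictly positive, roughly log-normal); platform B is a
proximity-extension panel reporting NPX, already log2-proportional to
concentration, with values below the assay's limit of detection recorded
as missing. All modeling happens after both matrices are brought to a
common standardized scale: log2 (for raw RFU) followed by per-assay
z-scoring.

Cross-platform concordance for a protein is summarized by two signed
Pearson correlations:

* **baseline r** — measured A vs measured B, on the training samples;
* **post-imputation r** — model-imputed destination values vs the
  *measured source counterpart*, on held-out samples only.

The post-imputation correlation deliberately compares against the source
platform, not the destination: the imputation is a denoising device, and
its success is judged by how consistently it reconstructs the signal that
the source platform carries. A third quantity, **model performance r**
(imputed vs measured destination, held-out samples), is defined for every
destination assay, including the platform-exclusive ones.

## Tier rules

With thresholds `t_high = 0.7`, `t_mid = 0.4`, `t_low = 0.1`:
tier 1 when baseline ≥ 0.7 and post ≥ 0.7; else tier 4 when baseline
≤ 0.1 and post ≤ 0.1; else tier 2 when post ≥ 0.4; else tier 3. The four
rules are evaluated in that order and partition the correlation plane
exhaustively and exclusively (a property asserted on a dense 401×401 grid
in the test suite).

Two conventions were genuinely open and are fixed as follows:

* **Signed correlations.** The rules compare signed r, not |r|. A protein
  whose two platforms anti-correlate (an epitope-distorted target) then
  falls in tier 4 even when the magnitude of its correlation is sizable —
  which is the scientifically intended reading: such a protein is not
  portable between platforms without sign-aware handling.
* **Tier-4 boundary.** Membership uses ≤ 0.1 (and ≥ for the upper
  thresholds). Boundary values are measure-zero in practice; the
  convention is recorded in the metadata block of every `tierReport`
  output.

Proteins with several aptamers get one record per (aptamer, PEA) pair; a
protein-level view keeps the pair with the highest post-imputation r
(`rollupBestAptamer`), a deliberate "best reagent" convention. Undefined
correlations (zero-variance columns) are flagged `NA` and excluded from
tier statistics rather than coerced to 0.

## Harmonization choices

* **Panel lifting** is a per-assay positive affine map applied on the raw
  scale. Pearson correlations are invariant under it, so tiering is
  unaffected; it matters only for absolute-scale interpretation.
* **z-scoring** uses the sample (n−1) SD and is estimated on the
  *training split only*, then re-applied to held-out samples via the
  returned `Scaler` — preventing information leakage through the
  standardization parameters. Already-standardized input is rejected
  (double-transform guard), as are non-positive values at the log step
  and zero-variance assays (named in the error).
* **Missingness QC** drops assays with strictly more than 10% missing
  entries, then samples by the same rule over the retained assays.
  Assays-first ordering reflects that assay failure drives apparent
  sample missingness on PEA panels.
* **KNN imputation** fills each below-LOD hole with the unweighted mean
  of the k = 10 nearest *assays* (feature-wise neighbors), with distance
  the Euclidean over shared observed samples scaled by the shared-sample
  count. Feature-wise orientation matches the semantics of the
  established expression-matrix KNN imputers. Ties break by assay id;
  k is clamped (with a warning) when fewer assays exist; an entry with no
  usable neighbor falls back to the assay mean; a fully missing assay is
  an error. The implementation is checked against an exhaustive
  brute-force oracle on small matrices.
* **Duplicate PEA assays** for one protein keep the assay with the lowest
  pre-imputation missing fraction (a detectability proxy), ties by assay
  id; aptamer duplicates are kept as distinct reagents.

## The imputation engine

One gradient-boosted tree regressor per destination assay, with the
entire source panel as features (never any destination-platform assay, so
the overlap cannot leak). Defaults: histogram binning with 255 bins,
learning rate 0.1, depth ≤ 6, at most 300 rounds with early stopping
monitored on a 10% slice carved from the *training* split. These
hyperparameters are package choices — tree ensembles of this shape are
robust to the noise and outliers typical of affinity measurements while
capturing the non-linear inter-platform relationships the tiering relies
on.

Determinism and independence: every target's RNG seed derives from a
stable hash of its assay id XOR the global seed, so adding or removing
targets never perturbs the other models; training runs single-threaded;
retraining after permuting only held-out rows of the target yields
bit-identical predictions (asserted in tests). Model bundles serialize to
a directory of per-target payloads plus a JSON manifest with a format
version; loading a bundle with a different format version is an explicit
error.

## Importance attribution

Permutation importance is computed on held-out data only: the drop in
squared Pearson r after shuffling one feature's column, repeated 5 times
(seeded), reported as mean ± SD and ranked by mean drop (ties: SD, then
feature id). r² is the *squared Pearson correlation* between prediction
and truth — not 1 − SSE/SST; the two differ for biased predictions, and
the convention is fixed package-wide. First-K curves retrain the model on
the top-K features with the original hyperparameters and per-target seed;
K values beyond the feature count are clamped with a warning. Note that
retraining on a reordered feature set can differ from the full model by
tree tie-breaking at the float level; exact reproduction of the full
model requires the original column order.

## Replication analyses

* **Continuous outcome.** Elastic net with covariates included at penalty
  factor 0 (they survive any penalty). The mixing parameter is tuned over
  α ∈ {0.1, …, 1.0} with 10-fold CV on the full analytic set, then the
  final model is refit on an 80% split and scored on the 20% hold-out by
  squared Pearson r; per-protein permutation importance is computed on
  that hold-out. Tuning on the full set implies a mild optimism; it is
  reproduced as the default because it mirrors common epidemiological
  practice, and a `leakage_mode = "strict"` variant tunes on the training
  split only. Samples with missing outcome are removed; zero-variance
  proteins are dropped with a warning; missing covariates are an error
  directing to `knnImputeCovariates` (sample-neighbor KNN, k = 10).
* **Survival scan.** One Cox proportional-hazards model per protein
  (protein standardized to unit SD inside its model, so the hazard ratio
  is per 1 SD of log2 level), Breslow tie handling, Wald CIs, Bonferroni
  adjustment with the denominator equal to the number of converged fits
  (recorded as an attribute; non-converged fits are flagged and
  excluded with a warning). Competing risks and time-varying effects are
  out of scope.

## What the simulator emulates — and what it does not

`SimConfig`/`simulateLatent`/`measurePlatform` generate a zero-mean,
unit-variance latent proteome with block-exchangeable correlation
(default: blocks of 4 at ρ = 0.5 — "biological neighbors"), then measure
it twice under per-protein fidelity classes:

* **faithful** (default 20%): positive affine + mild noise (SD 0.3) on
  both platforms. Designed to land in tier 1.
* **recoverable** (35%): a monotone cubic distortion g(x) = x + 0.4x³ on
  platform A only, plus SD-1.0 noise on both. The cubic is invertible and
  learnable by tree ensembles; with the default noise the baseline r sits
  in the 0.4–0.6 range while the model, leaning on the target's own
  counterpart assay and its block neighbors, recovers post-imputation r
  above 0.7 — the tier-2 "denoising" phenotype with the largest gains.
* **ambivalent** (25%): heavy noise (SD 2.5) on both platforms; baseline
  and post-imputation r both stay low — tier 3 with small gains.
* **irreconcilable** (20%), two alternating mechanisms: *off-target*
  (platform A measures an independent latent — both correlations ≈ 0,
  tier 4) and *epitope* (a carrier genotype with frequency 0.3 shifts the
  two platforms' signals in opposite directions with effect size 2.5,
  driving the baseline correlation to ≈ −0.45 — the sign-distortion
  phenotype, also tier 4 under signed rules).

Class proportions echo the tier shares reported for real paired panels
(roughly 20/35/25/20). Platform B left-censors the lowest 5% of each
assay to `NA` *before* any transformation, and censored values are stored
as missing, never as the LOD value. Phenotypes: a continuous outcome from
10 causal proteins (effect 0.5 per SD) plus independent covariates, and
exponential proportional-hazards event times (baseline hazard 0.1,
default log HR = log 1.5 for causal proteins) with independent
exponential censoring calibrated to a 30% censored fraction at a null
linear predictor.

The simulator does **not** emulate batch or plate effects, longitudinal
sampling, peptide-level mass-spectrometry structure, non-Gaussian noise
families, or confounding between covariates and proteins (a confounded
mode is deliberately absent by default: covariates are generated
independent of the proteome). Passing the recovery tests therefore shows
that the pipeline identifies the *mechanisms it models* — affine
fidelity, monotone distortion, heavy noise, off-target and epitope
artifacts under Gaussian noise — not that it is robust to every
real-data pathology.

## Problem sizes and numerical tolerances used in validation

The test bench runs the full pipeline at 2,000 samples × 120 proteins for
fidelity-class recovery (expecting ≥ 90% of faithful proteins in tier 1
and ≥ 90% of off-target proteins in tier 4); hazard-ratio recovery at
n = 5,000 with CI coverage over 200 replicates at n = 300; and the
cross-cohort replication property over 10 replicates of 1,000 samples ×
60 proteins split into two disjoint single-platform cohorts, where the
importance-ranking agreement restricted to simulated tier-1 (faithful)
proteins is compared against agreement over the full overlap. Numeric
kernels (KNN imputation, Pearson computations) are checked against
brute-force oracles at 1e-10 on ≤ 10×10 fixtures; hand-computable
transforms (log2 z-scoring of (8, 16, 32) → (−1, 0, 1) under the n−1 SD
convention) are frozen as golden values.

## Known limitations

Imputed values for platform-exclusive proteins remain model predictions
and inherit the biases of the training cohort; the gradient-boosted
models minimize prediction loss, not a biophysical binding model; the
tier thresholds are conventional cut points on correlation, and proteins
near a boundary can change tier under resampling. The bundled simulator
is a validation instrument, not a generative model of any particular
commercial panel.
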