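---
title: "Methods: white-matter low-frequency fluctuation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: white-matter low-frequency fluctuation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem this package addresses

Resting-state BOLD fluctuations in cerebral white matter (WM) carry
low-frequency signal that differs between clinical groups. The package
implements the full analysis chain for a two-group (patients vs. healthy
controls) WM amplitude study: preprocessing of 4D BOLD series, construction
of a group WM analysis mask, voxel-wise ALFF and fALFF maps, two-sample
inference with Gaussian random-field (GRF) cluster-level correction, cluster
reporting against an atlas, clinical covariate comparisons, and a Q-learning
classifier over cluster-mean features evaluated by leave-one-out
cross-validation (LOOCV). Because raw patient data of such studies are
typically not deposited, the package ships a first-class synthetic cohort
generator so that every stage is exercisable and testable against known
ground truth.

## Spectral amplitude metrics

For a series of length $N$ sampled at interval $TR$, the single-sided
amplitude spectrum is $a_k = (2/N)\,|X_k|$ for DFT bins
$k = 1,\dots,\lfloor N/2\rfloor$, with the Nyquist bin (even $N$) scaled by
$1/N$. This normalisation makes a unit-amplitude bin-aligned sinusoid have
unit spectral amplitude, which pins down every downstream constant; the
tests verify Parseval's identity under exactly this convention. The DC bin
is always excluded.

* **ALFF** is the mean of $a_k$ over bins whose frequencies lie in the
  analysis band, default 0.01–0.15 Hz (closed interval on bin frequencies;
  with $N = 230$, $TR = 2$ s these are bins 5–69, i.e. 65 bins — the
  closed-edge choice is documented because floor/ceiling conventions change
  bin counts). Alternate bands 0.01–0.08 and 0.01–0.10 Hz are plain
  configuration.
* **fALFF** is the amplitude sum over the analysis band divided by the sum
  over the full positive-frequency band (default 0–0.25 Hz, read as the
  positive axis, DC excluded from both sums), and is defined as 0 when the
  denominator vanishes.
* **mALFF** divides an ALFF map by its mean over the analysis mask (mask
  mean 1 afterwards); the **z transform** standardises a map over its mask
  using the population (divisor $n$) SD, a convention stated explicitly
  since $n$ vs. $n-1$ is often left ambiguous.

Group inference consumes the z-transformed mALFF map for ALFF and the
z-transformed fALFF map. No separate band-pass filtering step exists: band
selection happens inside the metric. Band edges are compared with a relative
tolerance of $10^{-9}$ of the maximum frequency so exact band limits like
0.15 Hz do not fall out of the band through floating-point representation.

## Preprocessing

The stage order is fixed: trim leading volumes (default 10, leaving 230 of
240) → per-voxel linear detrend → nuisance regression → tissue-restricted
smoothing. Choices that needed fixing:

* Detrending and nuisance regression restore the temporal mean, so
  downstream spectra keep a defined DC reference (DC is excluded from the
  metrics regardless).
* The nuisance design is the Friston-24 motion expansion (six rigid-body
  parameters, their one-volume lags, and both sets squared; lagged rows at
  the first volume zero-filled), the mean CSF signal, and one-hot spike
  regressors. Spike handling is regressor-based rather than deletion, so
  the time grid stays intact for the spectral metrics; the residual at a
  spiked volume equals the voxel mean exactly.
* Spike volumes are flagged by framewise displacement (FD): the sum of
  absolute backward differences of the six parameters with rotations
  converted to arc length on a 50 mm sphere. Motion tables store rotations
  in degrees. No FD threshold is canonical; the default is 0.5 mm, exposed
  as configuration.
* Smoothing uses a Gaussian kernel of fixed FWHM (default 4 mm, converted
  to per-axis voxel sigmas via the affine) applied as
  `smooth(data·mask)/smooth(mask)` inside the mask and zero outside, so no
  signal crosses the mask boundary and constants are preserved. `fwhm = 0`
  is the identity. The kernel is truncated at $4\sigma$ and normalised.

## Tissue masks

Voxels are labelled by maximum tissue probability with the fixed tie-break
priority WM > GM > CSF (favouring the tissue under study; the choice is
documented and tested, as segmentation outputs can produce exact ties).
The group WM mask keeps voxels labelled WM in *strictly more than* the
overlap threshold (default 0.6) of subjects, then removes a caller-supplied
subcortical mask; in synthetic runs the phantom's subcortical block plays
that role.

## GRF cluster-level correction

The t map (patients minus controls, pooled variance, so deficits are
negative; zero-variance voxels get $t = 0$ and are counted) is converted to
z scores preserving tail probability. Two-sided inference is implemented as
two one-tailed families, each thresholded at the one-tailed z quantile for
`voxel_p / 2`, with the cluster-level alpha applied per sign; a `tails =
"one"` option thresholds each sign at `voxel_p`. Clusters form under
18-connectivity by default (faces + edges; 6 and 26 available).

Corrected cluster p-values use the standard 3D Gaussian-field quantities at
threshold $u$: expected cluster count
$E[m] = R\,(4\ln 2)^{3/2}(2\pi)^{-2}(u^2-1)e^{-u^2/2}$ with $R$ the resel
count, expected supra-threshold volume $E[N] = S\,\Phi(-u)$, extent tail
$P(n \ge k) = \exp(-\beta k^{2/3})$ with
$\beta = (\Gamma(5/2)\,E[m]/E[N])^{2/3}$, and corrected
$p = 1 - \exp(-E[m]\,P(n \ge k))$.

**Smoothness estimation.** Residual maps (subject minus group mean) are
standardised per voxel; the variance $v_i$ of their first differences along
axis $i$, over in-mask neighbour pairs, gives the lag-one field correlation
$\rho_i = 1 - v_i/2$. We invert the Gaussian autocorrelation model exactly
on the lattice, $\mathrm{FWHM}_i = \sqrt{-2\ln 2/\ln\rho_i}$ voxels, rather
than using the continuum-derivative approximation
$\sqrt{4\ln 2/v_i}$: at the operating point of interest (4 mm kernels on
3 mm voxels) the continuum formula overestimates the FWHM by roughly 20 %
because the discrete first difference is not the field derivative, while
the exact inversion recovers the applied kernel width. Sub-voxel smoothness
is not identifiable from lattice differences, so estimates are floored at
one voxel; near-perfectly correlated residuals raise a degeneracy error.
Resels are the mask volume divided by the product of per-axis FWHMs in
voxel units.

A permutation oracle (max-cluster-extent null over relabelled groups, with
the $(b+1)/(m+1)$ p-value convention and exhaustive enumeration when fewer
distinct assignments exist than requested permutations) provides an
assumption-free cross-check; on planted effects both methods must agree on
every cluster either considers confident.

**Calibration design.** The null calibration simulates subject-level metric
maps directly — Gaussian noise smoothed with the pipeline's 4 mm kernel on a
$32^3$ phantom WM mask, two groups of 10 — and pushes them through the
inference stage, 100 replicates. This isolates the stage whose error rate
is being measured; the spectral stages have closed-form oracles of their
own. Measured per-sign family-wise error sits inside the 95 % binomial band
around the nominal 0.05.

**Cluster reporting.** The cluster peak is the voxel attaining the extremum
of the cluster's sign; world coordinates come from the affine (0-based
voxel convention); the atlas label is the atlas value at the peak (matching
single-label-per-cluster reporting). A peak outside the atlas keeps the
cluster but labels it `"unlabeled"` with an `off_atlas` flag.

## The Q-learning classifier

Features are cluster means of the z-scored metric maps, one feature per
(metric, cluster) — with three clusters per metric this gives six features —
min–max scaled to $[-1, 1]$ on the training set (test values clipped;
constant training columns map to 0 with a warning).

The literature this component follows specifies only the discount factor
$\gamma = 0.9$, the learning rate $\alpha = 0.001$, a linear action-value
model, and LOOCV; the decision process itself is underdetermined. The
package therefore documents its reconstruction prominently: an episode is
one seeded shuffle of the training set; the state is the current subject's
feature vector; the actions are predict-patient and predict-control; the
reward is $+1$ for a correct prediction, $-1$ otherwise; the next state is
the next subject in the stream, terminal after the last (bootstrap term
dropped). $Q(s,a) = w_a\cdot[s;1]$ is learned by the temporal-difference
update with $\varepsilon$-greedy behaviour, $\varepsilon$ decaying linearly
from 0.3 to 0 across epochs (default 1000). Weights start at zero, which
makes $\alpha = 0$ exactly inert and training deterministic under a seed.
Prediction uses the action-value difference with ties going to control.
This is the simplest faithful sequential construction in which $\gamma$ is
meaningful; published headline percentages obtained on unavailable cohort
data cannot be expected to reproduce under any reconstruction.

LOOCV scales and trains on the $n-1$ retained subjects only; per-fold
scaling is a deliberate strictness choice that avoids leaking the held-out
subject's range (a `scaling = "whole-sample"` toggle exists for fidelity
experiments). Note one circularity reproduced deliberately: clusters (and
hence features) come from the whole-sample group contrast before LOOCV, as
is common in this literature; the cross-validation therefore protects
against overfitting of the classifier, not of the feature definition.

Reported metrics treat patient as the positive class; a metric with a zero
denominator is `NA` and flagged, never forced to 0. The ROC is the
tie-grouped staircase over pooled held-out scores and the AUC its
trapezoidal integral (cross-checked against an independent implementation
in the tests).

## The synthetic cohort generator

The generator is the package's study-conditions module, not a test
convenience, and its defaults are the conditions the analysis targets:
48 patients and 41 controls, 240 volumes at $TR = 2$ s (230 analysed after
trimming), 3 mm voxels, 0.01–0.15 Hz signal band, 4 mm smoothing, >60 % WM
overlap.

* **Anatomy.** Concentric shells (CSF core, WM interior, GM shell, CSF rim)
  with soft, seeded-textured boundaries; probabilities sum to one
  everywhere (the exterior rides the CSF channel). The geometry is
  deliberately not brain-shaped: the pipeline is geometry-agnostic and
  shells make compartment membership exactly known. A small interior block
  stands in for subcortical exclusion, and an octant tiling of the WM
  provides at least four named tract-like atlas labels.
* **Signal.** Per voxel: baseline + oscillation + noise. The oscillation is
  a sum of sinusoids (default 4) at frequencies drawn within the band, unit
  amplitude, independent uniform phases per voxel. Inside designated WM
  spheres the patient group's oscillation amplitude is multiplied by
  `amplitude_ratio` (default 0.6); the mean and the noise are untouched, so
  the ALFF effect is analytically predictable, and with noise disabled the
  patient/control spectra differ exactly by the ratio. Random draws do not
  depend on the group label, so matched seeds give paired simulations.
* **Noise.** First-order autoregressive Gaussian noise (marginal SD 1,
  lag-one coefficient 0.3) plus white noise (SD 0.5): the simplest model
  with realistic temporal autocorrelation. Optional spike volumes add a
  global signal jump and a motion-trace jump. Motion is a Gaussian random
  walk (translations in mm, rotations in degrees).
* **Effect placement.** Spheres (default radius 2 voxels, extent 33) are
  placed by eroding the WM compartment by the radius and greedily choosing
  well-separated centers away from the subcortical block — fully
  deterministic given the anatomy.
* **Clinical table.** Continuous covariates are independent normals per
  group with the reference means/SDs of `table1_summaries()` (no covariance
  structure is published, so none is modelled); binary covariates follow
  the reference rates and are recorded for patients only. A fraction of
  controls (6/41 at reference size) has missing biochemical values and a
  fraction of patients (4/48) drops out of follow-up, so the missing-data
  structure of downstream comparisons arises naturally.

What the generator does **not** emulate: hemodynamic response shapes,
susceptibility or physiological artifacts, brain-shaped templates, spatial
noise correlations beyond the smoothing kernel, and between-subject
amplitude variability beyond the noise. Passing tests therefore demonstrate
the correctness and calibration of the *pipeline*, not that real WM data
would yield any particular result.

## Problem sizes used by the checks

The package's heavier validations use sizes chosen to make their arguments
at realistic operating points: null calibration at the $32^3$ grid with
100 replicates of 10 + 10 smoothed-noise maps; planted-effect recovery on a
$24^3$ phantom with the full BOLD route (240 volumes, TR 2 s, ratio 0.6,
20 + 20 subjects, 20 seeded replicates, detection required in ≥ 90 %);
classifier checks on a 6-feature, 48 + 41 separable fixture (class means
$\mp 0.6$, SD 0.1) plus 20 label permutations. Smoke and determinism checks
run on $18^3$ grids with reduced cohorts.

## Degenerate inputs and numerical conventions

* Zero pooled variance → $t = 0$, counted and surfaced as a warning count.
* Empty masks/ROIs, rank-deficient designs, invalid bands, non-finite
  volumes: immediate errors with specific messages.
* Constant training features scale to 0 with a warning; undefined
  classification metrics are `NA`, never 0.
* mALFF requires a positive mask mean; the z transform a positive mask SD.
* All stages are deterministic given seeds; the pipeline manifest records
  content hashes per stage, and re-running an identical configuration
  reproduces them bit for bit (hash-based caching makes reruns cheap on any
  filesystem).

## Known limitations

GRF extent p-values rely on asymptotic random-field theory; at
cluster-forming thresholds as low as $z \approx 1.96$ and smoothness close
to the voxel size their accuracy is empirical, which is why the calibration
and the permutation cross-check are part of the acceptance checks rather
than assumed. The relative (mALFF/z) normalisations mean a strong localised
deficit slightly elevates the rest of the map, which can surface as small
opposite-signed clusters; this is a property of relative normalisation, not
a bug. The Q-learning construction is a documented reconstruction, and the
phantom's simplicity means effect sizes there translate only qualitatively
to real data.
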