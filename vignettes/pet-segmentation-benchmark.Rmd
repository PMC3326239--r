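---
title: "Benchmarking PET tumour delineation on synthetic phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking PET tumour delineation on synthetic phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petseg)
```

## The problem

Delineating the biological tumour volume (BTV) on FDG-PET is hard because
PET images are blurry (scanner point-spread functions of several mm FWHM),
noisy, and tumours — head-and-neck carcinomas in particular — often show
heterogeneous uptake with low-avidity (necrotic-like) cores inside an avid
rim. Many automated delineation families coexist: adaptive SUV thresholds,
deformable contours, mixture classifiers and fuzzy clustering. `petseg`
implements nine representative methods behind one interface, the two-step
image-restoration chain usually applied before segmentation, overlap and
volume statistics for judging them against a known reference, and a
synthetic phantom generator that supplies that reference, so the whole
comparison is reproducible on a laptop.

Because no public clinical dataset with a histology-grade reference exists
for this task, the cohort here is synthetic by design. The phantoms emulate
the statistical structure of a clinical neck cohort — lesion volumes of
4–33 cm^3, heterogeneous rim/core uptake, ~6 mm FWHM system blur,
post-reconstruction noise — but they are not clinical data, and nothing in
this vignette is a claim about patient-level accuracy. What the benchmark
shows is how the methods rank under controlled, known-truth conditions.

## The phantom model

A case is a piecewise-constant uptake map on a 96^3 grid at 2 mm spacing:
a soft-tissue background (default 2 SUV) plus overlapping spherical or
ellipsoidal components. The default heterogeneous lesion is an ellipsoid
at 4x background containing a concentric core at 1.5x background
(half the lesion radius) — an avid rim around a hypometabolic centre. The
ground-truth mask is defined *before* degradation as every voxel centre
inside a component with uptake above background; the core therefore counts
as tumour. Degradation is a separable Gaussian blur (default 6 mm FWHM,
matching both the restoration kernels and typical scanner resolution) and
additive Gaussian noise after the blur (default sigma 0.3 SUV, i.e. 15% of
the background level — a realistic post-reconstruction noise figure for an
iteratively reconstructed static scan). Gaussian rather than Poisson noise
is the package's choice for reconstructed images; a scaled-Poisson option
exists in `phantom_spec()`. Voxel centres sit at `(index - 0.5) * spacing`
and masks are defined by centre inclusion, so truth volumes converge to
the analytic component volume as the grid is refined.

What the generator does *not* model: intra-lesion texture, anisotropic or
spatially varying point-spread functions, correlated reconstruction noise,
respiratory motion, and anatomical background structure. Passing results
here therefore demonstrate algorithmic correctness and controlled-contrast
behaviour, not clinical performance.

`make_cohort()` draws `n_cases` lesions with volumes uniform on 4–33 cm^3,
mild per-case shape anisotropy and centre jitter, with per-case seeds
derived from one master seed.

## Preprocessing

Segmentation runs on restored images: two passes of a 3-D bilateral filter
(spatial kernel 6 mm FWHM) followed by 30 Landweber iterations against a
6 mm FWHM Gaussian blur model. Choices the original description leaves
open are fixed as follows:

* **Radiometric sigma** of the bilateral filter: 10% of the robust
  (1st–99th percentile) intensity range — scale-free and insensitive to
  hot-spot outliers. As this sigma grows the filter converges to plain
  Gaussian smoothing; as it shrinks the filter stops averaging across
  edges.
* **Landweber relaxation**: 1.0 with the blur operator normalized to unit
  DC gain, so the operator norm is 1 and the residual
  `||y - Hx||` is provably nonincreasing; the iteration is stable for any
  relaxation in (0, 2).
* **Nonnegativity**: the iterate is clamped at zero after every step
  (projected Landweber). SUV images are nonnegative and the clamp
  suppresses Gibbs undershoot at sharp edges.
* **Boundaries**: all convolutions use half-sample mirror padding, which
  conserves total intensity and makes results bit-reproducible.

## The nine segmentation methods

All methods operate inside a lesion *analysis region* (in the benchmark:
the truth bounding box plus a 32 mm margin, emulating the clinician-placed
VOI that every semi-automatic PET tool assumes), take a seed voxel in the
lesion, and return the 26-connected component of their decision at that
seed. The maximum SUV is always taken over the analysis region, never the
whole volume, to avoid hot-spot leakage.

**Thresholding.** `segment_pct_max()` thresholds at 40% of the maximum.
`segment_biehl()` uses the volume-adaptive percentage
`%T = 59.1 - 18.5 log10(V cm^3)`; since the volume depends on the mask,
the circular dependence is resolved by damped Picard iteration from the
40% mask, stopping when the threshold moves by less than 0.1% of SUVmax,
with a period-2 oscillation guard that settles on the midpoint and reports
non-convergence. `segment_black()` iterates `T = 0.307 mean(SUV|mask) +
0.588` the same way. `segment_nestle()` is a single pass:
`T = 0.15 I_mean + I_bkg`, where `I_mean` averages the 70% isocontour and
`I_bkg` a user-supplied background region — the benchmark supplies a shell
15–25 mm outside the reference bounding box. `segment_schaefer()` computes
a fraction of SUVmax, `(a SUVmean70 + b BKG)/SUVmax`, with coefficients
switched on the equivalent-sphere diameter at 3 cm (first estimated from
the 40% mask, re-estimated once from the result).

**Level set.** `segment_levelset()` evolves a signed distance function
under `phi_t = g(|grad I|) (nu - eps kappa) |grad phi|` with the geodesic
edge-stopping function `g(s) = 1/(1 + (s/lambda)^2)`; `lambda` defaults to
the median nonzero gradient magnitude (contrast-adaptive), `nu = 0.3` mm
per unit time of balloon expansion, `eps = 1` of curvature regularization.
The balloon term is Godunov-upwinded, curvature is central-differenced and
clamped at the grid-resolvable 1/h, the default time step obeys both the
advective and parabolic CFL bounds, and the front is redistanced by an
exact Euclidean transform every 20 steps. The initial contour is the 40%
SUVmax mask, keeping the pipeline automatic; convergence is declared when
the flipped-voxel fraction stays below 0.2% for five consecutive steps.

**EM mixture.** `em_fit()` is classic univariate Gaussian-mixture EM with
deterministic initialization and two safeguards: means start spread evenly
over the intensity *range* rather than at quantiles (quantile starts
collapse onto the dominant background spike of a lesion-centred volume),
and standard deviations are floored at 0.5% of the range, which removes
the well-known likelihood degeneracy of components shrinking onto a
zero-variance spike — without it, two classes camp on the flat background
of a noiseless phantom and the third absorbs everything else. The floor is
the constrained M-step maximizer, so the likelihood trace remains
monotone. `em_segment()` labels each voxel by maximum responsibility and
keeps the highest-mean class at the seed.

**FCM family.** `fcm_fit()` alternates the inverse-squared-distance
membership update and the `u^b`-weighted centroid update (fuzzifier
`b = 2`), with quantile-ordered deterministic initialization, an exact-hit
rule (a voxel on a centroid gets membership 1) and a jitter guard for
duplicated centroids. Following the over-clustering strategy, the
segmenters fit `K_init = 9` clusters and merge nearest centroid pairs down
to `K_target = 3` (tumour / transition / background). Merged memberships
are summed — they stay on the simplex — and the merged centroid is
recomputed from the data.

`segment_fcm_sw()` adds spatial context through three per-voxel channels:
the intensity, an anisotropic-diffusion-filtered copy (Perona–Malik, 10
iterations, edge-preserving local averaging), and the coarse a-trous
wavelet approximation — the B3-spline undecimated transform with the two
finest detail scales removed, in which a heterogeneous lesion appears as a
single high-uptake blob. Channels are z-scored before clustering. The
wavelet channel enters the distance with per-class weights
`1 + beta_k`, `beta_k = beta0 ((c_k - c_min)/(c_max - c_min))^gamma`
(defaults `beta0 = 0.8`, `gamma = 2`), estimated once from a plain
multichannel fit and then frozen so the weighted objective stays monotone.
This realizes the intended behaviour — the coarse-scale context matters
most in high-uptake classes — while keeping the optimization a standard
weighted FCM. As the final spatial-regularization step, non-tumour
cavities fully enclosed by the delineated rim are filled: an enclosed
hypometabolic core shares the lesion's coarse-scale context and belongs to
the BTV. With `beta0 = 0` every spatial term (including the fill) is off
and the method reduces bit-exactly to plain FCM.

Two design points deserve emphasis because the obvious alternatives fail:

* **Tumour-class mapping.** Mapping only the single highest-centroid class
  to tumour is fragile: the nearest-pair merge sometimes leaves the lesion
  split across two classes (rim edge and rim interior) with all background
  collapsed into one, and the single-class rule then erodes the mask by
  the rim-edge class. Both FCM segmenters therefore map to tumour every
  class whose intensity centroid lies closer to the hottest class than to
  the background class; with a clean (background, transition, lesion)
  split this reduces to the hottest class alone.
* **Membership weighting cannot rescue the core by itself.** A core at
  1.5x background is closer to the background than to the rim in every
  intensity-derived channel, so no admissible `beta_k` reassigns it during
  defuzzification; the coarse channel's role is to keep the core's cluster
  attached to the lesion during merging, and the cavity fill makes the
  inclusion explicit.

## Evaluation statistics

`spatial_overlap_index()` is the Dice-type `2|A ∩ B|/(|A| + |B|)`; two
empty masks are defined to agree (SOI 1) — a degenerate convention the
package documents rather than errors on. `classification_error()` reports
`(PCE + NCE)/VoIL x 100%` with the reference voxel count as denominator,
so gross over-segmentation can exceed 100%. `relative_volume_error()` is
signed (underestimation negative). `paired_ttest()` is the two-tailed
paired t on measured vs reference volumes, with degenerate inputs (zero
variance of the differences) reported as exact ties (`t = 0, p = 1`) or
flagged infinite statistics rather than errors. `summarize_cohort()`
aggregates per-case records into the method-by-method table (mean, SD and
range of SOI; mean volumes; relative errors; CE; p values) and
`plot_benchmark()` draws the three companion bar charts.

## Numerical choices and degenerate inputs

* Convolution truncation: Gaussian kernels at 3.5 sigma, bilateral windows
  at 2 sigma per axis (normalized, so truncation costs no intensity).
* Fixed-point thresholds stop at 0.1% of SUVmax; on two-level images they
  land in at most two iterations.
* FCM convergence: maximum centroid shift below 1e-4 (1e-3 inside the
  segmenters, whose channels are standardized); EM stops at a
  log-likelihood gain below 1e-6.
* Flat images are rejected by `segment_pct_max()` (degenerate-input
  error); thresholds above the global maximum yield an empty-mask signal,
  not an error; a contrast-oriented fraction at or above 1 likewise.
* A level-set update moving any voxel by more than one voxel raises a CFL
  error instead of silently destabilizing.
* All randomness (noise draws, cohort draws) flows from explicit seeds
  through a local RNG stream that never disturbs the caller's RNG state.

## Problem sizes

The shipped tests and the cohort benchmark use 96^3-voxel cases analysed
inside ~46^3-voxel lesion regions, 7-case cohorts and 20 noise replicates
per case for the behavioural comparison — sizes chosen so a full
comparison (9 methods x 7 cases, plus the replicate sweep) completes in
minutes on one core while leaving every method's asymptotic behaviour
visible. Larger grids only sharpen the truth-volume convergence already
demonstrated at 2/1/0.5 mm spacings.

## Known limitations

* The synthetic cohort cannot validate clinical accuracy claims; it ranks
  methods under idealized, known-truth conditions.
* Published threshold coefficients are scanner-calibrated; applying them
  to phantoms (or any other scanner) without recalibration — as done here
  deliberately, to represent default use — biases the thresholding
  methods in ways the benchmark quantifies but does not correct.
* The level set implements the curvature/balloon geometric flow with an
  edge-stopping factor only; no advection (`grad g . grad phi`) term, no
  topology control.
* The exact objective of the original wavelet-regularized FCM is not
  recoverable from the published description; the regularization here is
  the package's own explicit, testable formulation of the stated
  behaviour, with its two tuning parameters exposed.
* EM runs on the same preprocessed images as every other method for
  parity, although the original processing order is unstated.

## A minimal run

```{r, eval = FALSE}
library(petseg)
cfg <- benchmark_config(n_cases = 7, master_seed = 1,
                        out_dir = "petseg-report")
bm <- run_benchmark(cfg)
bm$summary
plot_benchmark(bm$summary)
```
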