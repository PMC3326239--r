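# petseg

Comparative benchmarking of automated PET tumour delineation in R.

Delineating the biological tumour volume (BTV) on FDG-PET drives
radiotherapy planning, but PET's blur (~4–6 mm FWHM), noise and
heterogeneous uptake make the boundary genuinely ambiguous, and the many
published delineation rules disagree substantially. `petseg` implements
nine representative methods from the four major families behind one
interface, together with the restoration chain applied before
segmentation, the standard accuracy statistics, and a synthetic phantom
generator with known ground truth, so the whole method comparison is
reproducible end to end:

* **Thresholding** — 40% of SUVmax; the volume-adaptive rule
  `%T = 59.1 − 18.5·log10(V)`; the signal-adaptive rule
  `T = 0.307·SUVmean + 0.588` (both solved by fixed-point iteration); the
  background-corrected rule `T = 0.15·I_mean(70%) + I_bkg`; and the
  contrast-oriented rule `T = (a·SUVmean(70%) + b·BKG)/SUVmax` with
  size-dependent coefficients.
* **Variational** — a geometric level-set active contour,
  `φ_t = g(|∇I|)(ν − εκ)|∇φ|`, with geodesic edge stopping
  `g(s) = 1/(1+(s/λ)²)`.
* **Stochastic** — Gaussian-mixture EM classification with
  responsibilities `p_ik = π_k f_k(x_i) / Σ_m π_m f_m(x_i)`.
* **Learning** — fuzzy c-means (memberships
  `u_ik ∝ ‖x_i − c_k‖^{−2/(b−1)}`, centroids the `u^b`-weighted means)
  with over-clustering and merging, plus a spatially regularized variant
  adding anisotropic-diffusion and coarse à-trous-wavelet channels with
  per-class weights `β_k` — built for heterogeneous lesions with
  low-avidity cores.

Preprocessing is the two-step restoration used in clinical practice: a
3-D bilateral filter (6 mm FWHM, 2 iterations) followed by Landweber
deconvolution (6 mm FWHM Gaussian PSF, 30 iterations). Accuracy is scored
by the Dice-type spatial overlap index `SOI = 2|A∩B|/(|A|+|B|)`, the
voxel classification error `CE = (PCE+NCE)/VoIL × 100%` (which can exceed
100%), the signed relative volume error, and paired two-tailed t-tests of
measured vs reference volumes.

## Worked example

Seven synthetic neck-like cases (heterogeneous rim/core lesions of
4–33 cm³ at 2 mm voxels, 6 mm blur, σ = 0.3 SUV noise), all nine methods:

```r
library(petseg)
cfg <- benchmark_config(n_cases = 7, master_seed = 42)
bm  <- run_benchmark(cfg)
bm$summary[, c("method", "soi_mean", "rel_err_mean", "ce_mean", "p_value")]
```

```
           method soi_mean rel_err_mean ce_mean  p_value
biehl       biehl    0.902        11.35   20.69 7.24e-05
black       black    0.882        20.70   26.18 7.56e-08
em             em    0.903        10.70   20.48 1.20e-05
fcm           fcm    0.925         1.58   15.07 2.79e-01
fcm_sw     fcm_sw    0.953        -5.00    8.92 2.94e-01
levelset levelset    0.924         2.40   15.38 9.80e-02
nestle     nestle    0.903        10.70   20.54 1.37e-07
schaefer schaefer    0.918       -13.15   14.96 5.46e-05
suvmax40 suvmax40    0.924         2.40   15.38 9.80e-02
```

Reading the table: the plain thresholding rules and EM overestimate the
volume (positive mean relative error, small paired-t p values — the
volumes differ significantly from the reference), the contrast-oriented
rule underestimates, and the wavelet-regularized FCM gives the best
overlap (mean SOI 0.95), the smallest classification error (8.9%) and a
small negative volume bias — it is the only family that recovers the
low-avidity cores of heterogeneous lesions. `plot_benchmark(bm$summary)`
draws the companion volume / relative-error / CE bar charts, and
`out_dir =` writes `results.csv` (one row per case × replicate × method)
and `summary.csv`.

Individual pieces are exported too:

```r
ph  <- make_phantom(phantom_spec(components = heterogeneous_lesion(15, c(96, 96, 96))))
pre <- preprocess_volume(ph$image)
m   <- segment_fcm_sw(pre, seed_point = hottest_voxel(pre, ph$truth))
spatial_overlap_index(m, ph$truth)
```

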