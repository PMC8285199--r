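# speckleMAP

Speckle simulation and homomorphic Bayesian MAP denoising for grayscale
MRI, with the image-optimization and statistics layers needed to evaluate
it: a weighted low-resolution acquisition model with least-squares
reconstruction, residual-based enhancement, best-threshold segmentation
and edge detection, reference-based SNR/SSIM quality metrics, and the
two-group clinical statistics (summary *t*-tests, 2×2 χ²/Fisher tests,
UPDRS/MoCA/MMSE direction handling) used in deep-brain-stimulation
outcome studies of Parkinson's disease.

The package is for image-analysis practitioners who want a testable,
seeded implementation of this processing chain: every stage runs on
synthetic phantoms with known ground truth, so each claim the chain makes
is checkable.

## The model

A noisy image `y` is modelled as a noise-free image `l` under
multiplicative speckle `i` and a small additive term `a`:

    y = l · i + a,        amplitude of i ~ Rayleigh(d):
    r(t) = (t / d²) · exp(−t² / 2d²),   t ≥ 0

Dropping the small additive term and taking logs gives the additive
(homomorphic) form `f = m + n` with `f = log y`, `m = log l`,
`n = log i`. The denoiser recovers each noise-free log pixel as a
Bayesian maximum-a-posteriori estimate

    ẑ(y) = argmax_z  log h_t(y − z) + log h_z(z − c)

where both the noise density `h_t` and the signal prior `h_z` are
two-sided normalized Rayleigh densities `|t|/(2d²)·exp(−t²/2d²)` with
their own parameters, and `c` is the local low-pass log level.
Noise characterization runs first: with a known speckle parameter the
deterministic log-gain `E[log i] = log d + (log 2 − γ)/2` is removed and
the log-noise scale is closed-form; otherwise it is estimated from a
background region or a robust high-pass residual scale. The maximizer is
found numerically (coarse grid + golden-section refinement) and verified
against brute-force dense-grid searches. See the methods vignette
(`vignettes/speckle-map-denoising.Rmd`) for the design rationale and
limitations.

## Worked example

```r
library(speckleMAP)

clean <- make_phantom(c(64, 64), "blobs", seed = 2)
noisy <- apply_speckle(clean, speckle_params(d = 0.5, seed = 9))
rep   <- denoise_image(noisy, map_config(speckle_d = 0.5))
rep
#> <denoise_report> 64 x 64 image | noise_d 0.4534, prior_d 0.0001, log-gain removed -0.6352
#>   pixels floored: 0 | objective evaluations: 2359296 | prior centre: local

quality_report(clean, noisy)
#> <quality_report> SNR 5.97 dB | SSIM 0.5192 | window 11px (sigma 1.50)
quality_report(clean, rep$denoised)
#> <quality_report> SNR 13.03 dB | SSIM 0.7950 | window 11px (sigma 1.50)

best_threshold_segment(rep$denoised)
#> <segmentation_result> threshold 0.300981 | 811/4096 pixels above | between-class variance 0.0274137
```

Denoising lifts SNR from 5.97 to 13.03 dB and SSIM from 0.52 to 0.80 on
this phantom: the MAP shrinkage removes most of the multiplicative
fluctuation while the local prior centre preserves the blob structure;
segmentation then separates tissue from background at the automatically
chosen gray threshold.

The clinical layer reproduces printed two-arm tables directly from the
bundled CSVs (40 Parkinson's patients, STN-DBS + levodopa vs levodopa):

```r
ev  <- system.file("extdata", "stn_dbs_adverse_events.csv", package = "speckleMAP")
chi_square_2x2(read_contingency_2x2(ev, outcome = "dyskinesia"))
#> chi-square (2x2, correction: none): X2 = 5.6250, df = 1, p = 0.01771  [expected count < 5: consider Fisher]

bl  <- system.file("extdata", "stn_dbs_baseline_summaries.csv", package = "speckleMAP")
age <- read_group_summaries(bl, measure = "age_years")
t_test_from_summaries(age[[1]], age[[2]])
#> pooled two-sample t-test (control vs observation): t = -0.3125, df = 38.00, p = 0.7563
```

The dyskinesia incidences differ significantly between arms
(35% vs 5%, p < 0.05) while the baseline ages do not (p > 0.05), the
pattern expected of a randomized comparison.

A command-line front end is installed at
`system.file("exec", "mritool", package = "speckleMAP")` with
subcommands `simulate`, `denoise`, `evaluate`, `segment`, `reconstruct`,
`stats` and `pipeline`, each emitting machine-readable JSON.

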