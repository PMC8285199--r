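---
title: "Homomorphic Rayleigh MAP denoising: model, design choices, limitations"
author: "speckleMAP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homomorphic Rayleigh MAP denoising: model, design choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speckleMAP)
```

## The noise model

speckleMAP treats a grayscale MR image as a noise-free intensity field
$l$ corrupted by multiplicative speckle and a small additive term,

$$y = l \cdot i + a,$$

where the amplitude of the multiplicative field $i$ follows a one-sided
Rayleigh density with attenuation parameter $d$,

$$r(t) = \frac{t}{d^2}\, e^{-t^2/2d^2}, \qquad t \ge 0 ,$$

and $a$ is zero-mean Gaussian with standard deviation
`additive_sigma`.  The additive term is small relative to the
multiplicative one and is dropped in the analysis regime
(`additive_sigma = 0` makes the corruption exactly $y = l \cdot i$).
Speckle is physically a coherent-imaging (ultrasound) phenomenon; the
package implements the model as stated for MR intensities without
adjudicating the physics — see *Limitations*.

Taking logarithms turns the multiplicative problem into an additive one
(homomorphic separation):

$$f = m + n, \qquad f = \log y,\; m = \log l,\; n = \log i .$$

Since logs require positivity, pixels at or below
$10^{-6}\cdot\max(y)$ are floored to that epsilon first; the flooring
preserves ordering and the affected pixel count is reported.

A mirrored, two-sided form of the Rayleigh density is used for
log-domain residuals.  Mirroring the one-sided density with step
functions doubles its mass, so the implementation includes a factor
$\tfrac12$:

$$r_2(t) = \frac{|t|}{2d^2}\, e^{-t^2/2d^2},$$

a proper symmetric density on the whole line
(`rayleigh_density(d, "two_sided_normalized")`).  Both forms vanish at
$t = 0$.

## The MAP estimator

Per pixel, the denoiser maximizes the posterior log-density

$$\hat z(y) = \arg\max_z \; \log h_t(y - z) + \log h_z(z - c),$$

with the noise term $h_t = r_2(\cdot\,; d_\text{noise})$ and the signal
prior $h_z = r_2(\cdot\,; d_\text{prior})$ — the Rayleigh family is the
model's only density family, so it serves for both roles, each with its
own parameter.  Both densities are floored at `density_floor`
($10^{-300}$) before the log, which keeps the objective finite
everywhere including the singular points $z = y$ and $z = c$.

A closed-form shrinkage rule is sometimes quoted for this problem, but
its usual statement is self-referential (the sign of $z$ appears on its
own right-hand side) and merges the two $d$ parameters into one.  We
therefore take the numerical maximizer as normative — it can be checked
against a brute-force dense-grid search, which the garbled formula
cannot — and expose one literal fixed-point reading as
`map_shrinkage_literal()`, for reference only.

`map_estimate()` searches $[y - h, y + h]$ with
$h = 5\max(d_\text{noise}, d_\text{prior})$ by default: a coarse grid of
`grid_points` (512) candidates, augmented with a few offsets at the
$d_\text{noise}$ and $d_\text{prior}$ scales so that sharply peaked
densities are never stepped over, then golden-section refinement of the
winning bracket down to `refine_tol` ($10^{-6}$), clamped to the search
interval.  Candidates are scanned in order of increasing $|z - y|$ and
only a strictly better objective displaces the incumbent, so ties break
toward the minimal change.  Note the objective is multimodal (up to four
local maxima from the $\pm d$ modes of the two densities), so
$\hat z(y)$ is **not** monotone in $y$ and at $c = y$ the two global
maxima are mirror-symmetric; the tests compare against the dense-grid
argmax rather than asserting monotonicity.

## Noise characterization and prior centring

Two design questions are genuinely open once the per-pixel estimator is
fixed: where the noise parameters come from, and where the prior is
centred.  The choices below are the package's own; they were selected
because the alternatives measurably degrade the estimator.

**Log-domain gain.**  The two-sided Rayleigh noise density is centred at
zero, but the log of a Rayleigh amplitude is not: for
$i \sim \text{Rayleigh}(d)$,

$$\mathbb E[\log i] = \log d + \tfrac{\log 2 - \gamma}{2}, \qquad
  \text{sd}(\log i) = \sqrt{\pi^2/24} \approx 0.641,$$

with the spread independent of $d$ (`log_speckle_moments()`).  The mean
is a *deterministic gain*: it shifts every log pixel equally and no
zero-centred symmetric noise model can remove it.  Noise
characterization therefore runs first: when the speckle parameter is
known (`map_config(speckle_d = ...)` — always the case in simulation
studies, and obtainable by calibration otherwise), the gain is
subtracted and the log-noise scale is closed-form, giving
$d_\text{noise} = \text{sd}(\log i)/\sqrt2$ (the two-sided Rayleigh
with that parameter matches the noise second moment).  With a background
mask, $d_\text{noise}$ is the moment estimate from mean-centred
background residuals; otherwise a robust high-pass scale
($1.4826 \times \text{MAD}$ of the residual against a $3^k$ moving
median) is used and the gain, then unidentifiable, is left untouched.

**Prior centre.**  A prior centred at a fixed point of the log axis
cannot smooth: the MAP would merely transform each pixel pointwise, and
on the synthetic suite that *lowers* SNR.  By default the prior is
centred on the local low-pass log level (Gaussian, `center_sigma = 1.5`
pixels), so the MAP shrinks each log pixel toward its neighbourhood
level with a strength set by $d_\text{prior}$ — small
$d_\text{prior}$ (quiet neighbourhoods) gives strong smoothing, large
$d_\text{prior}$ (structured neighbourhoods) preserves detail.  When
`prior_d = "estimate"`, it is set from the spread of $f$ about the
centre with the noise second moment removed:
$d_\text{prior} = \sqrt{\max(\overline{(f-c)^2} - 2d_\text{noise}^2,\,
10^{-8})/2}$.  `"global"` and `"zero"` centres remain available for
experiments.

The denoised image is $\exp(\hat z)$ with no retransformation
correction by default; `bias_correct = TRUE` divides by
$e^{d_\text{noise}^2}$ (a Gaussian-approximation smearing factor),
documented as a heuristic and off by default.

```{r denoise-example}
clean <- make_phantom(c(64, 64), "blobs", seed = 2)
noisy <- apply_speckle(clean, speckle_params(d = 0.5, seed = 9))
rep <- denoise_image(noisy, map_config(speckle_d = 0.5))
c(snr_noisy = as.numeric(snr(clean, noisy)),
  snr_denoised = as.numeric(snr(clean, rep$denoised)))
```

## Reconstruction, enhancement, segmentation

The acquisition model ties a high-resolution image $X$ (flattened,
$P$ pixels) to low-resolution frames through dense weights:
$A_{m,n} = \sum_{s=1}^{P} Q_{m,n,s} X_s + l_{m,n}$.  Only the forward
map is part of the model; inversion is ordinary stacked least squares
(QR), with a warning and the minimum-norm pseudoinverse solution on
rank-deficient systems.  Indices are dense and 0-based internally; the
1-based $s = 1..P$ of the display convention is cosmetic.

Enhancement minimizes the restoration objective
$W(g) = \lVert b - j \circledast g \rVert^2$ (observed degraded image
$b$, point-spread function $j$) by projected gradient descent with
backtracking: a step is only accepted if the cost does not increase,
and exhausted backtracking terminates as converged.  The symbols of
this objective hint at a population-based search in its original
setting; no algorithm being specified, descent is our stand-in and is
flagged as such.  The convolution convention is fixed bit-exactly:
"same"-size output, kernel centred at its geometric middle
$\lceil (\text{dim}+1)/2 \rceil$, replicate padding.

Segmentation selects the threshold maximizing between-class variance
(Otsu's criterion) over a uniform 256-level quantization, lowest level
winning ties; the mask is exactly `image >= threshold`.  "Coding" of the
mask is interpreted as run-length encoding (`encode_mask_rle()`), an
interpretation rather than ground truth.  Edge detection flags pixels
whose central-difference gradient magnitude (unit pixel steps,
replicate borders) exceeds a threshold defaulting to the Otsu threshold
of the gradient image.

## Quality metrics

SNR is $10\log_{10}\!\big(\sum \text{ref}^2 / \sum(\text{ref} -
\text{test})^2\big)$ in dB (treated as dB throughout; the quantity is
sometimes printed unitless elsewhere), capped at 300 dB for identical
images.  The clean phantom is the reference both before (vs noisy) and
after (vs denoised) — the only convention computable with ground truth.
SSIM uses the standard $11\times11$ Gaussian window, $\sigma = 1.5$,
$K_1 = 0.01$, $K_2 = 0.03$, $L$ = reference range, replicate borders.
Absolute SNR/SSIM values reported for patient scans elsewhere are not
reproducible without those scans; what the synthetic suite establishes
is the *direction* — denoising must strictly increase both metrics on
every phantom/noise combination.

## The clinical layer

Group comparisons follow the conventions of two-arm clinical reporting:
measurement data as mean ± SD with a two-sample *t*-test
(pooled-variance by default, Welch selectable), count data as case (%)
with a Pearson $\chi^2$ test on the 2×2 table (no continuity correction
by default, Yates selectable), significance at two-sided
$P < 0.05$.  Because incidence tables from small trials often contain
arms with zero events, every $\chi^2$ result flags expected counts
below 5 and `fisher_exact_2x2()` provides the exact test.  Scale
direction is encoded once (`scale_spec()`): UPDRS higher = worse; MoCA
higher = better, 30 points, above 26 normal; MMSE higher = better.

```{r clinical-example}
events <- system.file("extdata", "stn_dbs_adverse_events.csv",
                      package = "speckleMAP")
dys <- read_contingency_2x2(events, outcome = "dyskinesia")
chi_square_2x2(dys)
```

## What the generator emulates — and what it does not

The phantom generator produces piecewise-smooth, multi-region 2-D/3-D
images in $[0,1]$: nested ellipses (`shepp_like`), seeded Gaussian
bumps (`blobs`), and a two-level wedge (`step_wedge`).  The corruption
is exactly the stated model: i.i.d. one-sided Rayleigh multiplicative
amplitudes plus optional Gaussian additive noise, clipped at zero.

Real MR data differ in ways the suite deliberately does not emulate:
MR magnitude noise is Rician (approximately Gaussian at high SNR), not
multiplicative Rayleigh; real speckle is spatially correlated, not
i.i.d.; scanners add bias fields, partial-volume effects and
acquisition blur.  Passing the synthetic suite therefore shows that the
estimator removes *the noise it models*, under the exact match between
generator and denoiser assumptions — it is evidence of correctness, not
of clinical performance.  Rician modelling is explicitly out of scope.

## Problem sizes and numerical tolerances

The test and acceptance workloads are sized for interactive runs:
the denoising suite uses six 64×64 phantom/noise combinations
($d \in \{0.3, 0.5\}$); sampler calibration uses $10^5$ draws (KS
distance against the analytic CDF at the 1% critical value,
$d$ recovery within 2% for $d \in \{0.3, 0.8, 1.5\}$); the MAP
estimator is checked against $10^6$-point dense-grid searches on 100
seeded scalar cases to $10^{-4}$; forward/inverse acquisition uses a
6×6 image with two 36×36 frames ($10^{-12}$ forward agreement,
$10^{-8}$ inversion); segmentation agreement is exact against an
exhaustive 256-cut scan on 50 seeded images.  All randomness flows from
explicit seeds, with pipeline stages drawing from named substreams
(`stage_seed()`).

## Known limitations

* The Rayleigh-speckle model is adopted as stated; it is not the
  physically standard model for MR magnitude data.
* The per-pixel MAP uses no spatial coupling beyond the prior centre;
  transform-domain (wavelet-subband) variants are out of scope.
* The robust (`"estimate"`, no background, no speckle model) path
  cannot identify the multiplicative gain; absolute intensities then
  carry the speckle-mean bias even though structure is denoised.
* PNG output is 8-bit (the 16-bit raster path is TIFF; the lossless
  float path is NIfTI).
* The enhancement PSF must be supplied; blind deconvolution and full
  super-resolution (motion estimation, registration) are out of scope.
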