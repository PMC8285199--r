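#' Synthetic anatomy-like phantoms
#'
#' Generates noise-free test images used throughout the toolkit in place of
#' patient scans.  Three families are available:
#' \describe{
#'   \item{`shepp_like`}{a deterministic nested-ellipse (2-D) / ellipsoid
#'     (3-D) head phantom with a bright shell, a darker inclusion and a
#'     brighter lesion-like inclusion;}
#'   \item{`blobs`}{a seeded superposition of Gaussian bumps on a faint
#'     background, normalised to peak 1;}
#'   \item{`step_wedge`}{a two-level image, the first half of the columns at
#'     0.2 and the second half at 0.8 (exactly two unique values).}
#' }
#' All phantoms have intensities in \[0, 1\], contain at least two distinct
#' intensity regions, and are bit-reproducible for a fixed
#' `(shape, kind, seed)`.
#'
#' @param shape integer vector of 2 or 3 axis sizes, each at least 8.
#' @param kind one of `"shepp_like"`, `"blobs"`, `"step_wedge"`.
#' @param seed integer RNG seed (only `blobs` consumes randomness).
#' @return An [image_grid] with `modality = "synthetic"`.
#' @examples
#' p <- make_phantom(c(64, 64), "blobs", seed = 1)
#' range(p$values)
#' @export
make_phantom <- function(shape, kind = c("shepp_like", "blobs", "step_wedge"),
                         seed = 0L) {
  kind <- tryCatch(match.arg(kind),
                   error = function(e) stop("unknown phantom kind", call. = FALSE))
  shape <- as.integer(shape)
  if (length(shape) < 2L || length(shape) > 3L || any(shape < 8L)) {
    stop("`shape` must give 2 or 3 axis sizes, each >= 8", call. = FALSE)
  }
  vals <- switch(kind,
    step_wedge = phantom_step_wedge(shape),
    shepp_like = phantom_shepp_like(shape),
    blobs      = phantom_blobs(shape, seed)
  )
  image_grid(vals, modality = "synthetic")
}

phantom_step_wedge <- function(shape) {
  vals <- array(0.2, dim = shape)
  nc <- shape[2]
  if (length(shape) == 2L) {
    vals[, (nc %/% 2 + 1):nc] <- 0.8
  } else {
    vals[, (nc %/% 2 + 1):nc, ] <- 0.8
  }
  vals
}

## normalised axis coordinates in [-1, 1] for each voxel, per dimension
axis_coords <- function(shape) {
  a <- array(0, dim = shape)
  lapply(seq_along(shape), function(k) {
    g <- seq(-1, 1, length.out = shape[k])
    g[slice.index(a, k)]
  })
}

phantom_shepp_like <- function(shape) {
  co <- axis_coords(shape)
  ## ellipse/ellipsoid membership: sum((x - c)^2 / ax^2) <= 1
  inside <- function(centre, axes) {
    q <- 0
    for (k in seq_along(co)) q <- q + (co[[k]] - centre[k])^2 / axes[k]^2
    q <= 1
  }
  nd <- length(shape)
  pad <- function(v2, v3) if (nd == 2L) v2 else c(v2, v3)
  vals <- array(0.05, dim = shape)
  vals[inside(pad(c(0, 0), 0), pad(c(0.9, 0.7), 0.9))] <- 0.8
  vals[inside(pad(c(0.2, 0), 0), pad(c(0.3, 0.2), 0.35))] <- 0.4
  vals[inside(pad(c(-0.3, 0.2), 0.1), pad(c(0.2, 0.25), 0.3))] <- 0.95
  vals
}

phantom_blobs <- function(shape, seed, k = 5L) {
  set.seed(seed)
  co <- axis_coords(shape)
  vals <- array(0, dim = shape)
  for (j in seq_len(k)) {
    centre <- stats::runif(length(shape), -0.6, 0.6)
    width  <- stats::runif(1, 0.1, 0.3)
    amp    <- stats::runif(1, 0.4, 1)
    q <- 0
    for (d in seq_along(co)) q <- q + (co[[d]] - centre[d])^2
    vals <- vals + amp * exp(-q / (2 * width^2))
  }
  vals <- vals / max(vals)
  ## faint constant background keeps the image strictly positive
  (vals + 0.05) / 1.05
}

#' Speckle-noise parameters
#'
#' Parameters of the multiplicative-plus-additive noise model
#' `y = l * i + a`, where the multiplicative field `i` has one-sided
#' Rayleigh-distributed amplitude with attenuation parameter `d` and the
#' additive term `a` is zero-mean Gaussian.
#'
#' @param d Rayleigh attenuation parameter of the speckle amplitude
#'   (strictly positive).
#' @param additive_sigma standard deviation of the additive term
#'   (non-negative; 0 gives the purely multiplicative regime).
#' @param seed integer RNG seed.
#' @return An object of class `speckle_params`.
#' @export
speckle_params <- function(d, additive_sigma = 0, seed = 0L) {
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d <= 0) {
    stop("`d` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(additive_sigma) || length(additive_sigma) != 1L ||
      !is.finite(additive_sigma) || additive_sigma < 0) {
    stop("`additive_sigma` must be a single non-negative number", call. = FALSE)
  }
  structure(list(d = d, additive_sigma = additive_sigma,
                 seed = as.integer(seed)),
            class = "speckle_params")
}

#' Sample a multiplicative speckle field
#'
#' Draws i.i.d. speckle amplitudes from the one-sided Rayleigh density with
#' parameter `d` by inverse-CDF sampling (`d * sqrt(-2 log U)`), seeded and
#' reproducible.
#'
#' @param shape integer vector of axis sizes.
#' @param params a [speckle_params] object.
#' @return Numeric array of non-negative multiplicative factors with
#'   dimensions `shape`.
#' @export
sample_speckle_field <- function(shape, params) {
  stopifnot(inherits(params, "speckle_params"))
  set.seed(params$seed)
  u <- pmax(stats::runif(prod(shape)), .Machine$double.xmin)
  array(params$d * sqrt(-2 * log(u)), dim = shape)
}

#' Corrupt a clean image with multiplicative speckle and additive noise
#'
#' Applies the noise model `y = l * i + a` elementwise.  With
#' `additive_sigma = 0` the output is exactly `l * i`.  Intensities driven
#' negative by the additive term are clipped at 0.  The multiplicative field
#' and (when needed) the additive draws come from a single RNG stream seeded
#' by `params$seed`, so repeated calls are bit-identical.
#'
#' @param clean an [image_grid] of noise-free intensities.
#' @param params a [speckle_params] object.
#' @param field optional pre-computed multiplicative field (same dimensions
#'   as `clean`); used mainly to force degenerate fields in tests.
#' @return An [image_grid] of noisy intensities `y`.
#' @examples
#' cl <- make_phantom(c(16, 16), "step_wedge")
#' ny <- apply_speckle(cl, speckle_params(d = 0.5, seed = 3))
#' @export
apply_speckle <- function(clean, params, field = NULL) {
  stopifnot(is_image_grid(clean), inherits(params, "speckle_params"))
  dm <- dim(clean$values)
  if (is.null(field)) {
    field <- sample_speckle_field(dm, params)   # seeds the stream
  } else {
    if (!identical(dim(field), dm)) stop("`field` dimensions must match `clean`",
                                         call. = FALSE)
    set.seed(params$seed)
  }
  y <- clean$values * field
  if (params$additive_sigma > 0) {
    y <- y + stats::rnorm(length(y), 0, params$additive_sigma)
  }
  image_grid(pmax(y, 0), spacing = clean$spacing, modality = clean$modality)
}

#' Homomorphic log-domain separation
#'
#' Takes logarithms to turn the multiplicative model `y = l * i` into the
#' additive model `f = m + n` with `f = log y`, `m = log l`, `n = log i`.
#' Pixels at or below `1e-6 * max(image)` are floored to that epsilon before
#' the log so the transform is defined everywhere; the number of floored
#' pixels is reported.
#'
#' @param noisy an [image_grid] (or numeric array) of noisy intensities.
#' @param clean optional matching clean image; when supplied, `m = log l`.
#' @param field optional matching multiplicative field; when supplied,
#'   `n = log i`.
#' @return An object of class `log_domain_pair`: a list with `f`, and `m`,
#'   `n` when available, plus `floored` counts per component.
#' @export
log_separate <- function(noisy, clean = NULL, field = NULL) {
  safe_log <- function(v, what) {
    mx <- max(v)
    if (mx <= 0) stop("degenerate input: `", what, "` is identically zero",
                      call. = FALSE)
    eps <- 1e-6 * mx
    list(lg = log(pmax(v, eps)), floored = sum(v < eps))
  }
  fy <- safe_log(grid_values(noisy, "noisy"), "noisy")
  out <- list(f = fy$lg, m = NULL, n = NULL,
              floored = c(f = fy$floored, m = NA_integer_, n = NA_integer_))
  if (!is.null(clean)) {
    fm <- safe_log(grid_values(clean, "clean"), "clean")
    out$m <- fm$lg
    out$floored["m"] <- fm$floored
  }
  if (!is.null(field)) {
    fn <- safe_log(field, "field")
    out$n <- fn$lg
    out$floored["n"] <- fn$floored
  }
  structure(out, class = "log_domain_pair")
}

#' Rayleigh density specification
#'
#' The speckle-amplitude density with attenuation parameter `d`.  Two forms
#' are supported: the `one_sided` density
#' \deqn{r(t) = (t/d^2)\,e^{-t^2/(2d^2)},\quad t \ge 0,}
#' which integrates to 1 on \[0, Inf), and the `two_sided_normalized` form
#' \deqn{r(t) = (|t|/(2d^2))\,e^{-t^2/(2d^2)},}
#' a symmetric density on the whole line.  The raw two-sided construction
#' obtained by mirroring the one-sided density with step functions
#' integrates to 2, so the normalized form carries an extra factor of 1/2 to
#' be a proper density.  Both forms vanish at `t = 0`.
#'
#' @param d attenuation parameter, strictly positive.
#' @param form `"one_sided"` or `"two_sided_normalized"`.
#' @return An object of class `rayleigh_density`.
#' @seealso [rayleigh_pdf()], [rayleigh_cdf()]
#' @export
rayleigh_density <- function(d, form = c("one_sided", "two_sided_normalized")) {
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d <= 0) {
    stop("`d` must be a single positive number", call. = FALSE)
  }
  structure(list(d = d, form = match.arg(form)), class = "rayleigh_density")
}

#' Rayleigh probability density
#'
#' @param t numeric vector of noise amplitudes.
#' @param density a [rayleigh_density] object.
#' @return Non-negative density values, vectorized over `t`.
#' @examples
#' rayleigh_pdf(1, rayleigh_density(1))          # the mode, exp(-1/2)
#' rayleigh_pdf(-1, rayleigh_density(1))         # 0 on the negative axis
#' @export
rayleigh_pdf <- function(t, density) {
  stopifnot(inherits(density, "rayleigh_density"))
  d <- density$d
  if (density$form == "one_sided") {
    unit_step(t) * (abs(t) / d^2) * exp(-t^2 / (2 * d^2))
  } else {
    (abs(t) / (2 * d^2)) * exp(-t^2 / (2 * d^2))
  }
}

#' One-sided Rayleigh cumulative distribution function
#'
#' `P(T <= t) = 1 - exp(-t^2 / (2 d^2))` for `t >= 0`, 0 below.
#'
#' @param t numeric vector of quantiles.
#' @param d attenuation parameter, strictly positive.
#' @return Probabilities in \[0, 1\].
#' @export
rayleigh_cdf <- function(t, d) {
  if (!is.numeric(d) || length(d) != 1L || d <= 0) {
    stop("`d` must be a single positive number", call. = FALSE)
  }
  ifelse(t < 0, 0, 1 - exp(-t^2 / (2 * d^2)))
}

#' Unit step function
#'
#' `1` for `t >= 0` and `0` for `t < 0`; used to restrict the Rayleigh
#' density to one side and to build its mirrored two-sided form.
#'
#' @param t finite numeric vector.
#' @return Numeric vector of 0s and 1s.
#' @export
unit_step <- function(t) {
  if (any(!is.finite(t))) stop("`t` must be finite", call. = FALSE)
  as.numeric(t >= 0)
}

#' Moment estimator of the Rayleigh attenuation parameter
#'
#' The maximum-likelihood / second-moment estimator
#' `d_hat = sqrt(mean(t^2) / 2)`, consistent for both the one-sided density
#' and its two-sided normalized form (whose second moments coincide).
#'
#' @param samples numeric vector with at least 2 finite entries.
#' @return The non-negative estimate `d_hat`.
#' @examples
#' estimate_d(c(1, 1, 1, 1))   # sqrt(1/2)
#' @export
estimate_d <- function(samples) {
  if (length(samples) == 0L) stop("`samples` is empty", call. = FALSE)
  s <- samples[is.finite(samples)]
  if (length(s) < 2L) stop("need at least 2 finite samples", call. = FALSE)
  sqrt(mean(s^2) / 2)
}

#' Log-domain moments of the multiplicative speckle field
#'
#' For a one-sided Rayleigh amplitude `i` with parameter `d`, the log-noise
#' `n = log i` has closed-form moments
#' `E[n] = log d + (log 2 - gamma)/2` (Euler-Mascheroni `gamma`) and
#' `sd(n) = sqrt(pi^2 / 24)`, independent of `d`.  The mean is the
#' deterministic log-domain gain of the speckle field; the standard
#' deviation fixes the scale of the additive log-domain noise.
#'
#' @param d attenuation parameter, strictly positive.
#' @return A list with elements `mean` and `sd`.
#' @export
log_speckle_moments <- function(d) {
  if (!is.numeric(d) || length(d) != 1L || d <= 0) {
    stop("`d` must be a single positive number", call. = FALSE)
  }
  ## i = d * sqrt(2 E), E ~ Exp(1):  log i = log d + log(2)/2 + log(E)/2,
  ## E[log E] = -gamma, Var(log E) = pi^2/6.
  list(mean = log(d) + (log(2) - (-digamma(1))) / 2,
       sd = sqrt(pi^2 / 24))
}
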