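#' Signal-to-noise ratio in decibels
#'
#' `SNR = 10 log10( sum(ref^2) / sum((ref - test)^2) )`.  The reference is
#' the ground-truth image; a common rescaling of both images leaves the
#' value unchanged.  Identical images would give an infinite ratio, so the
#' value is capped at 300 dB and flagged.
#'
#' @param reference reference (ground-truth) image, [image_grid] or array;
#'   must not be identically zero.
#' @param test test image of the same shape.
#' @return SNR in dB, with attribute `"identical"` set to `TRUE` when the
#'   images coincide exactly (capped value).
#' @examples
#' a <- matrix(1:16, 4)
#' snr(a, a + 0.1)
#' @export
snr <- function(reference, test) {
  r <- grid_values(reference, "reference")
  t <- grid_values(test, "test")
  if (!identical(dim(r), dim(t))) {
    stop("`reference` and `test` must have the same shape", call. = FALSE)
  }
  sig <- sum(r^2)
  if (sig == 0) stop("`reference` must not be identically zero", call. = FALSE)
  res <- sum((r - t)^2)
  if (res == 0) {
    out <- 300
    attr(out, "identical") <- TRUE
    return(out)
  }
  out <- 10 * log10(sig / res)
  attr(out, "identical") <- FALSE
  out
}

#' Structural similarity index (SSIM)
#'
#' The standard local-window SSIM: local means, variances and covariance
#' are computed under a Gaussian window (default 11 x 11, sigma 1.5,
#' replicate borders), combined per pixel as
#' \deqn{\frac{(2\mu_x\mu_y + C_1)(2\sigma_{xy} + C_2)}
#'            {(\mu_x^2 + \mu_y^2 + C_1)(\sigma_x^2 + \sigma_y^2 + C_2)}}
#' with `C1 = (K1 L)^2`, `C2 = (K2 L)^2`, and averaged over all pixels.
#' `L` is the dynamic range, defaulting to `max(reference) -
#' min(reference)` (1 when the reference is constant).
#'
#' @param reference reference image ([image_grid] or array).
#' @param test test image of the same shape.
#' @param window_size odd window width in pixels (default 11); every image
#'   axis must be at least this large.
#' @param window_sigma Gaussian window standard deviation (default 1.5).
#' @param dynamic_range `L`; `NULL` for the reference range.
#' @param K1,K2 stabilization constants (defaults 0.01 and 0.03).
#' @return Mean SSIM in \[-1, 1\], with attribute `"map"` holding the
#'   per-pixel SSIM array.
#' @examples
#' a <- matrix(runif(32 * 32), 32)
#' ssim(a, a)   # exactly 1
#' @export
ssim <- function(reference, test, window_size = 11L, window_sigma = 1.5,
                 dynamic_range = NULL, K1 = 0.01, K2 = 0.03) {
  r <- grid_values(reference, "reference")
  t <- grid_values(test, "test")
  if (!identical(dim(r), dim(t))) {
    stop("`reference` and `test` must have the same shape", call. = FALSE)
  }
  if (any(dim(r) < window_size)) {
    stop("image smaller than the SSIM window (", window_size, ")", call. = FALSE)
  }
  if (is.null(dynamic_range)) {
    dynamic_range <- diff(range(r))
    if (dynamic_range <= 0) dynamic_range <- 1
  }
  if (dynamic_range <= 0) stop("`dynamic_range` must be positive", call. = FALSE)
  C1 <- (K1 * dynamic_range)^2
  C2 <- (K2 * dynamic_range)^2
  g <- function(x) gaussian_filter(x, window_sigma, window_size)
  mx <- g(r); my <- g(t)
  sxx <- g(r * r) - mx^2
  syy <- g(t * t) - my^2
  sxy <- g(r * t) - mx * my
  map <- ((2 * mx * my + C1) * (2 * sxy + C2)) /
    ((mx^2 + my^2 + C1) * (sxx + syy + C2))
  out <- mean(map)
  attr(out, "map") <- map
  out
}

#' Image quality report
#'
#' Convenience wrapper computing both [snr()] and [ssim()] for a
#' reference/test pair.
#'
#' @inheritParams ssim
#' @return An object of class `quality_report`: a list with `snr_db`,
#'   `ssim`, `window` (size and sigma) and `dynamic_range`.
#' @export
quality_report <- function(reference, test, window_size = 11L,
                           window_sigma = 1.5, dynamic_range = NULL) {
  s <- snr(reference, test)
  ss <- ssim(reference, test, window_size, window_sigma, dynamic_range)
  structure(list(
    snr_db = as.numeric(s),
    ssim = as.numeric(ss),
    snr_capped = isTRUE(attr(s, "identical")),
    window = list(size = window_size, sigma = window_sigma),
    dynamic_range = if (is.null(dynamic_range)) diff(range(grid_values(reference)))
                    else dynamic_range
  ), class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> SNR %.2f dB%s | SSIM %.4f | window %dpx (sigma %.2f)\n",
              x$snr_db, if (x$snr_capped) " (identical, capped)" else "",
              x$ssim, x$window$size, x$window$sigma))
  invisible(x)
}
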