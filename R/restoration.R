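#' Weighted low-resolution acquisition model
#'
#' The forward observation model that ties a high-resolution image `X`
#' (flattened to `P` pixels) to several observed low-resolution frames:
#' each low-res pixel `n` of frame `m` is the weighted sum
#' `A[m, n] = sum_s Q[m, n, s] X[s] + l[m, n]`, where the weight row
#' `Q[m, n, ]` gives the contribution of every high-res pixel and
#' `l[m, n]` is an additive offset (additional noise term).
#'
#' @param weights list with one numeric matrix per frame; each matrix has
#'   one row per low-res pixel and `high_res_size` columns.
#' @param offsets list with one numeric vector per frame (one offset per
#'   low-res pixel), or `NULL` for all-zero offsets.
#' @param high_res_size `P`, the number of high-resolution pixels.
#' @return An object of class `acquisition_model`.
#' @export
acquisition_model <- function(weights, offsets = NULL, high_res_size) {
  if (!is.list(weights) || length(weights) == 0L) {
    stop("`weights` must be a non-empty list of matrices", call. = FALSE)
  }
  P <- as.integer(high_res_size)
  weights <- lapply(weights, as.matrix)
  for (m in seq_along(weights)) {
    if (ncol(weights[[m]]) != P) {
      stop("frame ", m, ": weight matrix must have ", P, " columns", call. = FALSE)
    }
    if (any(!is.finite(weights[[m]]))) {
      stop("frame ", m, ": weights must be finite", call. = FALSE)
    }
  }
  if (is.null(offsets)) {
    offsets <- lapply(weights, function(w) numeric(nrow(w)))
  }
  if (length(offsets) != length(weights)) {
    stop("`offsets` must have one vector per frame", call. = FALSE)
  }
  for (m in seq_along(offsets)) {
    if (length(offsets[[m]]) != nrow(weights[[m]])) {
      stop("frame ", m, ": offsets length must match weight rows", call. = FALSE)
    }
  }
  structure(list(weights = weights, offsets = offsets, P = P),
            class = "acquisition_model")
}

#' Forward low-resolution observation
#'
#' Applies the [acquisition_model()] to a high-resolution image:
#' `A[m, n] = sum_s Q[m, n, s] X[s] + l[m, n]`, computed exactly as a
#' weighted sum (a matrix product per frame).  The image is flattened in
#' column-major order.
#'
#' @param high_res an [image_grid] (or numeric array) with `model$P`
#'   pixels in total.
#' @param model an [acquisition_model].
#' @return A list of numeric vectors, one observed frame per entry.
#' @export
forward_observe <- function(high_res, model) {
  stopifnot(inherits(model, "acquisition_model"))
  x <- as.vector(grid_values(high_res, "high_res"))
  if (length(x) != model$P) {
    stop("high-res image has ", length(x), " pixels but model expects ",
         model$P, call. = FALSE)
  }
  lapply(seq_along(model$weights), function(m) {
    as.vector(model$weights[[m]] %*% x) + model$offsets[[m]]
  })
}

#' Least-squares inversion of the acquisition model
#'
#' Recovers a high-resolution estimate from observed frames by minimizing
#' the stacked sum of squares
#' `sum_(m,n) (A[m,n] - sum_s Q[m,n,s] X[s] - l[m,n])^2`.  Full-rank
#' systems are solved by QR; rank-deficient systems produce a warning and
#' the minimum-norm solution via the Moore-Penrose pseudoinverse.
#'
#' @param frames list of observed frames, as returned by
#'   [forward_observe()].
#' @param model the [acquisition_model] that produced them.
#' @return An object of class `reconstruction`: a list with `estimate`
#'   (length-`P` vector), `residual_norm`, and `rank_deficient`.
#' @export
reconstruct <- function(frames, model) {
  stopifnot(inherits(model, "acquisition_model"))
  if (length(frames) != length(model$weights)) {
    stop("`frames` must have one entry per model frame", call. = FALSE)
  }
  Q <- do.call(rbind, model$weights)
  b <- unlist(frames) - unlist(model$offsets)
  if (nrow(Q) < model$P) {
    stop("stacked system has ", nrow(Q), " equations for ", model$P,
         " unknowns; need at least P equations", call. = FALSE)
  }
  qrQ <- qr(Q)
  rank_deficient <- qrQ$rank < model$P
  if (rank_deficient) {
    warning("acquisition model is rank-deficient; returning the ",
            "minimum-norm least-squares solution", call. = FALSE)
    x <- as.vector(MASS::ginv(Q) %*% b)
  } else {
    x <- as.vector(qr.coef(qrQ, b))
  }
  structure(list(estimate = x,
                 residual_norm = sqrt(sum((b - as.vector(Q %*% x))^2)),
                 rank_deficient = rank_deficient),
            class = "reconstruction")
}

## 2-D convolution, "same"-size output, kernel centred at its geometric
## middle ceil((dim+1)/2), replicate padding.  True convolution: the
## kernel is flipped in both axes relative to sliding correlation.
conv2_same_replicate <- function(x, k) {
  if (length(k) == 0L || is.null(dim(k))) k <- as.matrix(k)
  kr <- nrow(k); kc <- ncol(k)
  cr <- (kr + 1L) %/% 2L; cc <- (kc + 1L) %/% 2L
  out <- array(0, dim = dim(x))
  for (i in seq_len(kr)) {
    for (j in seq_len(kc)) {
      if (k[i, j] == 0) next
      s <- shift_replicate(shift_replicate(x, i - cr, 1L), j - cc, 2L)
      out <- out + k[i, j] * s
    }
  }
  out
}

## adjoint-like operator: correlation with the same kernel (convolution
## with the flipped kernel); exact adjoint up to border replication
corr2_same_replicate <- function(x, k) {
  conv2_same_replicate(x, k[rev(seq_len(nrow(k))), rev(seq_len(ncol(k))), drop = FALSE])
}

#' Enhancement (restoration) cost
#'
#' The squared residual `||b - j (*) g||^2` between the observed degraded
#' image `b` and the candidate restored image `g` pushed through the
#' point-spread function `j` ("same"-size convolution, kernel centred at
#' its geometric middle, replicate padding).
#'
#' @param degraded observed degraded image (matrix or [image_grid]).
#' @param psf point-spread function, a non-empty numeric matrix.
#' @param candidate candidate restored image, same size as `degraded`.
#' @return The scalar cost (sum of squared differences).
#' @export
enhancement_cost <- function(degraded, psf, candidate) {
  b <- grid_values(degraded, "degraded")
  g <- grid_values(candidate, "candidate")
  if (length(psf) == 0L) stop("`psf` must be non-empty", call. = FALSE)
  psf <- as.matrix(psf)
  if (!identical(dim(b), dim(g))) {
    stop("`candidate` must match `degraded` in shape", call. = FALSE)
  }
  sum((b - conv2_same_replicate(g, psf))^2)
}

#' Restore an image by descent on the enhancement cost
#'
#' Projected gradient descent on [enhancement_cost()]: each step moves the
#' candidate along the negative gradient, clips at zero, and is accepted
#' only if the cost does not increase (the step is halved on an increase;
#' when halving is exhausted the current iterate is returned as
#' converged).  With a delta-function PSF the degraded image is already
#' optimal and is returned unchanged.  Deterministic: identical inputs
#' give identical outputs.
#'
#' @param degraded observed degraded image (matrix or [image_grid]).
#' @param psf point-spread function (numeric matrix).
#' @param iterations number of outer iterations (at least 1).
#' @param step initial gradient step size (positive).
#' @return A list with `restored` (matrix), `cost` (final cost) and
#'   `cost_trace` (cost after each accepted iteration, starting with the
#'   initial cost).
#' @export
enhance <- function(degraded, psf, iterations = 50L, step = 1.0) {
  if (iterations < 1L) stop("`iterations` must be at least 1", call. = FALSE)
  if (step <= 0) stop("`step` must be positive", call. = FALSE)
  b <- grid_values(degraded, "degraded")
  psf <- as.matrix(psf)
  g <- b
  cost <- enhancement_cost(b, psf, g)
  trace <- cost
  for (it in seq_len(iterations)) {
    r <- b - conv2_same_replicate(g, psf)
    grad <- -2 * corr2_same_replicate(r, psf)
    s <- step
    accepted <- FALSE
    for (bt in 1:40) {
      cand <- pmax(g - s * grad, 0)
      cc <- enhancement_cost(b, psf, cand)
      if (!is.finite(cc)) stop("enhancement diverged to non-finite cost",
                               call. = FALSE)
      if (cc <= cost) {
        g <- cand; cost <- cc; accepted <- TRUE
        break
      }
      s <- s / 2
    }
    trace <- c(trace, cost)
    if (!accepted) break              # converged to line-search precision
  }
  list(restored = g, cost = cost, cost_trace = trace)
}

#' Best-threshold segmentation by between-class variance
#'
#' Selects the gray threshold maximizing the between-class variance of the
#' two pixel classes it induces (Otsu's criterion), over a uniform
#' quantization of the intensity range into `levels` bins.  Ties are
#' broken toward the lowest level.  The mask is exactly
#' `image >= threshold`.
#'
#' @param image an [image_grid] (or numeric array) with at least two
#'   distinct values.
#' @param levels number of quantization levels (at least 2; default 256).
#' @return An object of class `segmentation_result`: a list with
#'   `threshold`, `mask` (logical array), `criterion_value` (between-class
#'   variance at the chosen threshold) and `levels`.
#' @export
best_threshold_segment <- function(image, levels = 256L) {
  v <- grid_values(image, "image")
  levels <- as.integer(levels)
  if (levels < 2L) stop("`levels` must be at least 2", call. = FALSE)
  rng <- range(v)
  if (rng[1] == rng[2]) {
    stop("degenerate input: image is constant, no threshold separates it",
         call. = FALSE)
  }
  width <- diff(rng) / levels
  bin <- pmin(floor((v - rng[1]) / width), levels - 1L)   # 0-based bins
  counts <- tabulate(bin + 1L, nbins = levels)
  ## bin representative = bin centre on the quantized scale
  mids <- rng[1] + (seq_len(levels) - 0.5) * width
  w <- counts / length(v)
  mu <- w * mids
  omega0 <- cumsum(w)[-levels]
  mu0 <- cumsum(mu)[-levels]
  mu_t <- sum(mu)
  omega1 <- 1 - omega0
  valid <- omega0 > 0 & omega1 > 0
  sigma_b <- rep(-Inf, levels - 1L)
  sigma_b[valid] <- (mu_t * omega0[valid] - mu0[valid])^2 /
    (omega0[valid] * omega1[valid])
  k <- which.max(sigma_b)             # which.max takes the first (lowest) tie
  threshold <- rng[1] + k * width     # lower edge of the first upper bin
  structure(list(threshold = threshold,
                 mask = array(v >= threshold, dim = dim(v)),
                 criterion_value = sigma_b[k],
                 levels = levels),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> threshold %.6g | %d/%d pixels above | between-class variance %.6g\n",
              x$threshold, sum(x$mask), length(x$mask), x$criterion_value))
  invisible(x)
}

#' Gradient-magnitude edge detection
#'
#' Flags a pixel as edge iff the central-difference gradient magnitude
#' exceeds `threshold`.  Gradients use replicate borders and unit pixel
#' steps along every axis.  When `threshold` is `NULL` it defaults to the
#' between-class variance threshold of the gradient image itself (or 0
#' when the gradient is constant, e.g. for a constant image).
#'
#' @param image an [image_grid] or numeric array.
#' @param threshold non-negative gradient cutoff, or `NULL` for the
#'   automatic default.
#' @return A logical edge map with attribute `"threshold"` (the cutoff
#'   used) and `"gradient"` (the gradient-magnitude array).
#' @export
edge_detect <- function(image, threshold = NULL) {
  v <- grid_values(image, "image")
  g2 <- 0
  for (d in seq_along(dim(v))) {
    gd <- (shift_replicate(v, -1L, d) - shift_replicate(v, 1L, d)) / 2
    g2 <- g2 + gd^2
  }
  gmag <- sqrt(g2)
  if (is.null(threshold)) {
    threshold <- if (diff(range(gmag)) == 0) 0 else
      best_threshold_segment(gmag)$threshold
  }
  if (threshold < 0) stop("`threshold` must be non-negative", call. = FALSE)
  out <- array(gmag > threshold, dim = dim(v))
  attr(out, "threshold") <- threshold
  attr(out, "gradient") <- gmag
  out
}

#' Run-length encode a binary mask
#'
#' Encodes a logical mask (flattened column-major) as runs of equal
#' values, the coding step applied to segmentation output before edge
#' detection artifacts are written.
#'
#' @param mask logical array.
#' @return A data frame with columns `value` and `length`.
#' @seealso [decode_mask_rle()]
#' @export
encode_mask_rle <- function(mask) {
  r <- rle(as.vector(mask))
  data.frame(value = r$values, length = r$lengths)
}

#' Decode a run-length encoded mask
#'
#' @param rle_df data frame from [encode_mask_rle()].
#' @param dim dimensions of the original mask.
#' @return The logical array.
#' @export
decode_mask_rle <- function(rle_df, dim) {
  array(inverse.rle(list(values = rle_df$value, lengths = rle_df$length)),
        dim = dim)
}
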