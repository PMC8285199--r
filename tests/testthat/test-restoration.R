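make_random_model <- function(P, n_frames = 2L, rows = P, seed = 1,
                              offsets = TRUE) {
  set.seed(seed)
  w <- lapply(seq_len(n_frames), function(m) matrix(rnorm(rows * P), rows, P))
  o <- if (offsets) lapply(seq_len(n_frames), function(m) rnorm(rows) / 10)
       else NULL
  acquisition_model(w, o, high_res_size = P)
}

test_that("forward observation is the stated weighted sum", {
  img <- image_grid(matrix(runif(36), 6, 6))

  ## identity weighting copies pixels
  ident <- acquisition_model(list(diag(36)), high_res_size = 36)
  expect_equal(forward_observe(img, ident)[[1]], as.vector(img$values))

  ## zero weighting returns the offsets exactly
  zmod <- acquisition_model(list(matrix(0, 5, 36)), list(1:5), high_res_size = 36)
  expect_identical(forward_observe(img, zmod)[[1]], as.numeric(1:5))

  ## brute-force triple-loop oracle
  model <- make_random_model(36, n_frames = 2, rows = 20, seed = 3)
  frames <- forward_observe(img, model)
  x <- as.vector(img$values)
  for (m in 1:2) {
    for (n in 1:20) {
      acc <- model$offsets[[m]][n]
      for (s in 1:36) acc <- acc + model$weights[[m]][n, s] * x[s]
      expect_lt(abs(frames[[m]][n] - acc), 1e-12)
    }
  }

  expect_error(forward_observe(image_grid(matrix(1, 5, 5)), ident), "pixels")
})

test_that("reconstruction inverts noiseless invertible systems", {
  img <- image_grid(matrix(runif(25), 5, 5))
  model <- make_random_model(25, n_frames = 1, rows = 25, seed = 4)
  frames <- forward_observe(img, model)
  rec <- reconstruct(frames, model)
  expect_lt(max(abs(rec$estimate - as.vector(img$values))), 1e-8)
  expect_false(rec$rank_deficient)

  ## residual orthogonal to the column space of Q
  model2 <- make_random_model(16, n_frames = 2, rows = 12, seed = 5)
  img2 <- image_grid(matrix(runif(16), 4, 4))
  frames2 <- forward_observe(img2, model2)
  frames2 <- lapply(frames2, function(fr) fr + rnorm(length(fr), sd = 0.05))
  rec2 <- reconstruct(frames2, model2)
  Q <- do.call(rbind, model2$weights)
  b <- unlist(frames2) - unlist(model2$offsets)
  resid <- b - as.vector(Q %*% rec2$estimate)
  expect_lt(max(abs(crossprod(Q, resid))), 1e-8)

  ## error grows with the offset-noise scale
  errs <- sapply(c(0, 0.01, 0.1), function(sg) {
    set.seed(9)
    fr <- lapply(forward_observe(img2, model2), function(v)
      v + rnorm(length(v), sd = sg))
    sqrt(sum((reconstruct(fr, model2)$estimate - as.vector(img2$values))^2))
  })
  expect_true(all(diff(errs) > 0))

  ## rank-deficient: warning + minimum-norm solution
  mdef <- acquisition_model(list(matrix(rnorm(32), 8, 4) %*% diag(c(1, 1, 1, 0))),
                            high_res_size = 4)
  expect_warning(reconstruct(list(rep(0, 8)), mdef), "rank-deficient")
})

test_that("enhancement cost equals a direct convolution computation", {
  set.seed(11)
  b <- matrix(runif(25), 5, 5)
  g <- matrix(runif(25), 5, 5)
  psf <- matrix(c(0, 1, 0, 1, 4, 1, 0, 1, 0) / 8, 3, 3)

  ## brute-force: flipped-kernel sliding sum with replicate padding
  manual_conv <- matrix(0, 5, 5)
  for (r in 1:5) for (c in 1:5) {
    acc <- 0
    for (i in -1:1) for (j in -1:1) {
      rr <- min(max(r - i, 1), 5)
      cc <- min(max(c - j, 1), 5)
      acc <- acc + psf[i + 2, j + 2] * g[rr, cc]
    }
    manual_conv[r, c] <- acc
  }
  expect_lt(abs(enhancement_cost(b, psf, g) - sum((b - manual_conv)^2)), 1e-12)

  ## perfect restoration gives zero cost
  expect_equal(enhancement_cost(manual_conv, psf, g), 0)
  expect_error(enhancement_cost(b, matrix(numeric(0), 0, 0), g), "non-empty")
})

test_that("enhance descends the cost and is deterministic", {
  ## delta PSF: degraded already optimal, returned unchanged
  b <- matrix(runif(36), 6, 6)
  delta <- matrix(c(0, 0, 0, 0, 1, 0, 0, 0, 0), 3, 3)
  out <- enhance(b, delta, iterations = 1)
  expect_equal(out$restored, b)
  expect_equal(out$cost, 0)

  set.seed(21)
  truth <- matrix(runif(64), 8, 8)
  psf <- matrix(1, 3, 3) / 9
  degraded <- speckleMAP:::conv2_same_replicate(truth, psf)
  degraded <- degraded + 0.01 * matrix(rnorm(64), 8, 8)
  r1 <- enhance(degraded, psf, iterations = 30, step = 0.05)
  expect_lt(r1$cost, r1$cost_trace[1])
  expect_true(all(diff(r1$cost_trace) <= 0))
  expect_true(all(r1$restored >= 0))
  r2 <- enhance(degraded, psf, iterations = 30, step = 0.05)
  expect_identical(r1$restored, r2$restored)
})

test_that("best-threshold segmentation maximizes between-class variance", {
  ## separable bimodal case
  img <- matrix(0.2, 16, 16); img[, 9:16] <- 0.8
  seg <- best_threshold_segment(img)
  expect_gt(seg$threshold, 0.2)
  expect_lt(seg$threshold, 0.8)
  expect_identical(seg$mask, img >= seg$threshold)
  expect_identical(unname(seg$mask[, 1]), rep(FALSE, 16))
  expect_identical(unname(seg$mask[, 16]), rep(TRUE, 16))

  ## exhaustive criterion scan oracle on seeded images
  otsu_oracle <- function(v, levels = 256L) {
    rng <- range(v)
    width <- diff(rng) / levels
    bin <- pmin(floor((v - rng[1]) / width), levels - 1)
    mids <- rng[1] + (0:(levels - 1) + 0.5) * width
    q <- mids[bin + 1]                       # quantized gray values
    best_k <- NA; best_val <- -Inf
    for (k in 1:(levels - 1)) {
      cut <- rng[1] + k * width
      lo <- q[q < cut]; hi <- q[q >= cut]
      if (!length(lo) || !length(hi)) next
      w0 <- length(lo) / length(q); w1 <- 1 - w0
      val <- w0 * w1 * (mean(lo) - mean(hi))^2
      if (val > best_val + 1e-15) { best_val <- val; best_k <- k }
    }
    rng[1] + best_k * width
  }
  set.seed(33)
  for (i in 1:50) {
    v <- matrix(sample(c(runif(60, 0, 0.4), runif(40, 0.6, 1))), 10, 10)
    seg <- best_threshold_segment(v)
    expect_equal(seg$threshold, otsu_oracle(as.vector(v)), tolerance = 1e-12)
  }

  ## inverting the image complements the mask (up to threshold ties)
  v <- matrix(runif(100), 10, 10)
  s1 <- best_threshold_segment(v)
  s2 <- best_threshold_segment(max(v) - v)
  ties <- abs(v - s1$threshold) < 1e-9 | abs((max(v) - v) - s2$threshold) < 1e-9
  expect_true(all((s1$mask == !s2$mask)[!ties]))

  expect_error(best_threshold_segment(matrix(1, 8, 8)), "constant")
})

test_that("edge detection flags gradient magnitude above threshold", {
  expect_true(!any(edge_detect(matrix(0.5, 12, 12))))

  ## vertical step: edges exactly on the two columns adjacent to the jump
  img <- matrix(0, 12, 12); img[, 7:12] <- 1
  em <- edge_detect(img, threshold = 0.25)
  ## brute-force central-difference loop with replicated borders
  manual <- matrix(FALSE, 12, 12)
  for (r in 1:12) for (c in 1:12) {
    gr <- (img[min(r + 1, 12), c] - img[max(r - 1, 1), c]) / 2
    gc <- (img[r, min(c + 1, 12)] - img[r, max(c - 1, 1)]) / 2
    manual[r, c] <- sqrt(gr^2 + gc^2) > 0.25
  }
  expect_identical(unclass(em)[seq_along(em)], manual[seq_along(manual)])
  expect_true(all(which(colSums(em) > 0) %in% c(6, 7)))

  ## homogeneity: doubling intensities and threshold leaves the map fixed
  set.seed(44)
  v <- matrix(runif(100), 10, 10)
  e1 <- edge_detect(v, threshold = 0.1)
  e2 <- edge_detect(2 * v, threshold = 0.2)
  expect_equal(as.vector(e1), as.vector(e2))
})

test_that("mask run-length coding round-trips", {
  m <- matrix(runif(64) > 0.5, 8, 8)
  expect_identical(decode_mask_rle(encode_mask_rle(m), dim(m)), m)
})
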