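test_that("image_grid rejects malformed inputs and keeps metadata", {
  expect_error(image_grid(1:5), "matrix")
  expect_error(image_grid(matrix(-1, 8, 8)), "negative")
  expect_error(image_grid(matrix(NA_real_, 8, 8)), "finite")
  expect_error(image_grid(matrix(1, 8, 8), spacing = c(1, -1)), "spacing")
  g <- image_grid(matrix(0.5, 8, 8), spacing = c(0.5, 1.3), modality = "T1WI")
  expect_identical(dim(g), c(8L, 8L))
  expect_equal(g$spacing, c(0.5, 1.3))
  expect_identical(g$modality, "T1WI")
})

test_that("phantoms are deterministic, bounded, and multi-region", {
  w <- make_phantom(c(64, 64), "step_wedge", seed = 0)
  expect_length(unique(as.vector(w$values)), 2L)
  expect_true(all(w$values[, 1:32] == w$values[1, 1]))
  expect_true(all(w$values[, 33:64] == w$values[1, 64]))

  for (kind in c("shepp_like", "blobs", "step_wedge")) {
    a <- make_phantom(c(64, 64), kind, seed = 7)
    b <- make_phantom(c(64, 64), kind, seed = 7)
    expect_identical(a$values, b$values)
    expect_true(all(a$values >= 0 & a$values <= 1))
  }

  ## blobs: histogram has at least 2 modes; verify by scanning the
  ## quantized levels of the raw array directly
  bl <- make_phantom(c(64, 64), "blobs", seed = 1)
  lev <- unique(round(as.vector(bl$values) * 32))
  expect_gte(length(lev), 2L)

  expect_error(make_phantom(c(64, 64), "nope"), "unknown")
  expect_error(make_phantom(c(4, 64), "blobs"), ">= 8")

  v3 <- make_phantom(c(8, 10, 8), "blobs", seed = 3)
  expect_identical(dim(v3), c(8L, 10L, 8L))
})

test_that("speckle sampler matches the Rayleigh moments and CDF", {
  par <- speckle_params(d = 1, seed = 42)
  x <- as.vector(sample_speckle_field(c(1000, 1000), par))
  n <- length(x)
  ## mean d*sqrt(pi/2), sd of the mean from the exact variance
  m_th <- sqrt(pi / 2)
  se_m <- sqrt((2 - pi / 2)) / sqrt(n)
  expect_lt(abs(mean(x) - m_th), 3 * se_m)
  ## second moment 2 d^2 = 2; Var(X^2) = E X^4 - (E X^2)^2 = 8 - 4 = 4
  se_m2 <- 2 / sqrt(n)
  expect_lt(abs(mean(x^2) - 2), 3 * se_m2)
  ## determinism
  expect_identical(x, as.vector(sample_speckle_field(c(1000, 1000), par)))
  ## sampler vs one-sided CDF: KS distance below the 1% critical value
  xs <- sort(x[1:100000])
  emp_hi <- seq_along(xs) / length(xs)
  emp_lo <- (seq_along(xs) - 1) / length(xs)
  cdf <- rayleigh_cdf(xs, 1)
  ks <- max(pmax(abs(emp_hi - cdf), abs(emp_lo - cdf)))
  expect_lt(ks, 1.6276 / sqrt(length(xs)))
  expect_error(speckle_params(d = 0), "positive")
})

test_that("apply_speckle is exactly multiplicative with zero additive noise", {
  clean <- make_phantom(c(64, 64), "blobs", seed = 5)
  par <- speckle_params(d = 0.5, seed = 11)

  ## forced unit field: identity
  ones <- array(1, dim = dim(clean$values))
  expect_identical(apply_speckle(clean, par, field = ones)$values, clean$values)

  ## zero image stays zero
  z0 <- image_grid(matrix(0, 16, 16))
  expect_true(all(apply_speckle(z0, par)$values == 0))

  ## elementwise oracle: output equals clean * field computed by a loop
  noisy <- apply_speckle(clean, par)
  field <- sample_speckle_field(dim(clean$values), par)
  expected <- clean$values
  for (i in seq_len(nrow(expected))) {
    for (j in seq_len(ncol(expected))) {
      expected[i, j] <- clean$values[i, j] * field[i, j]
    }
  }
  expect_equal(noisy$values, expected, tolerance = 0)

  ## ratio equals the field wherever the input is positive
  pos <- clean$values > 0
  expect_equal((noisy$values / clean$values)[pos], field[pos], tolerance = 1e-15)
})

test_that("log separation is additive and invertible", {
  ones <- image_grid(matrix(1, 16, 16))
  expect_true(all(log_separate(ones)$f == 0))

  clean <- make_phantom(c(32, 32), "blobs", seed = 8)
  par <- speckle_params(d = 0.4, seed = 2)
  field <- sample_speckle_field(dim(clean$values), par)
  noisy <- image_grid(clean$values * field)
  lp <- log_separate(noisy, clean = clean, field = field)

  ## round trip on positive pixels
  expect_lt(max(abs(exp(lp$f) - noisy$values) / noisy$values), 1e-12)
  ## additivity residual f = m + n on pixels untouched by flooring
  expect_lt(max(abs(lp$f - (lp$m + lp$n))), 1e-9)

  expect_error(log_separate(image_grid(matrix(0, 8, 8))), "degenerate")
})

test_that("Rayleigh density forms are correct and integrate to one", {
  d1 <- rayleigh_density(1, "one_sided")
  expect_identical(rayleigh_pdf(-1, d1), 0)
  ## analytic mode at t = d
  opt <- optimize(function(t) rayleigh_pdf(t, d1), c(0, 5), maximum = TRUE)
  expect_lt(abs(opt$maximum - 1), 1e-5)

  for (form in c("one_sided", "two_sided_normalized")) {
    dens <- rayleigh_density(0.7, form)
    lo <- if (form == "one_sided") 0 else -Inf
    q <- integrate(function(t) rayleigh_pdf(t, dens), lo, Inf,
                   rel.tol = 1e-10)
    expect_lt(abs(q$value - 1), 1e-6)
  }
  ## two-sided form is symmetric and half the one-sided height
  d2 <- rayleigh_density(0.7, "two_sided_normalized")
  expect_equal(rayleigh_pdf(0.3, d2), rayleigh_pdf(-0.3, d2))
  expect_equal(rayleigh_pdf(0.3, d2),
               rayleigh_pdf(0.3, rayleigh_density(0.7)) / 2)
  expect_error(rayleigh_density(-1), "positive")
})

test_that("unit step follows the t >= 0 convention", {
  expect_identical(unit_step(0), 1)
  expect_identical(unit_step(-3.2), 0)
  expect_identical(unit_step(5), 1)
  expect_error(unit_step(NaN), "finite")
})

test_that("estimate_d recovers the attenuation parameter", {
  expect_identical(estimate_d(c(0, 0, 0)), 0)
  expect_equal(estimate_d(c(1, 1, 1, 1)), sqrt(1 / 2))
  expect_error(estimate_d(numeric(0)), "empty")
  expect_error(estimate_d(c(1, NA, Inf)), "finite")

  set.seed(77)
  x <- 0.8 * sqrt(-2 * log(runif(1e5)))
  expect_lt(abs(estimate_d(x) - 0.8), 0.01)

  ## consistency across scales: relative error < 2% at n = 1e5
  for (d in c(0.3, 0.8, 1.5)) {
    par <- speckle_params(d = d, seed = 1000 + round(10 * d))
    s <- as.vector(sample_speckle_field(c(250, 400), par))
    expect_lt(abs(estimate_d(s) - d) / d, 0.02)
  }
})

test_that("log_speckle_moments matches simulation", {
  par <- speckle_params(d = 0.5, seed = 31)
  lg <- log(as.vector(sample_speckle_field(c(400, 250), par)))
  mom <- log_speckle_moments(0.5)
  expect_lt(abs(mean(lg) - mom$mean), 4 * mom$sd / sqrt(length(lg)))
  expect_lt(abs(sd(lg) - mom$sd), 0.01)
})
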