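## Internal separable filtering and neighborhood utilities shared by the
## denoiser, the SSIM metric and edge detection.  Convention everywhere:
## replicate padding at the borders, kernel centred at its geometric middle.

## 1-D correlation of the rows of a matrix with kernel g (odd length),
## replicate padding.
filter_rows <- function(m, g) {
  w <- length(g)
  h <- (w - 1L) %/% 2L
  n <- nrow(m)
  mp <- rbind(m[rep(1L, h), , drop = FALSE], m,
              m[rep(n, h), , drop = FALSE])
  out <- matrix(0, n, ncol(m))
  for (i in seq_len(w)) {
    out <- out + g[i] * mp[i:(i + n - 1L), , drop = FALSE]
  }
  out
}

## Apply a 1-D kernel along dimension `along` of a 2-D or 3-D array.
filter_along <- function(x, g, along) {
  dm <- dim(x)
  nd <- length(dm)
  perm <- c(along, setdiff(seq_len(nd), along))
  xp <- aperm(x, perm)
  m <- matrix(xp, nrow = dm[along])
  m <- filter_rows(m, g)
  xp <- array(m, dim = dm[perm])
  aperm(xp, order(perm))
}

gaussian_kernel_1d <- function(sigma, width = 2L * ceiling(3 * sigma) + 1L) {
  h <- (width - 1L) %/% 2L
  g <- exp(-((-h):h)^2 / (2 * sigma^2))
  g / sum(g)
}

## Separable Gaussian smoothing with replicate borders (2-D or 3-D).
gaussian_filter <- function(x, sigma, width = 2L * ceiling(3 * sigma) + 1L) {
  g <- gaussian_kernel_1d(sigma, width)
  for (d in seq_along(dim(x))) x <- filter_along(x, g, d)
  x
}

## Shift an array by `by` steps along `along`, replicating the border.
shift_replicate <- function(x, by, along) {
  dm <- dim(x)
  idx <- seq_len(dm[along]) - by
  idx <- pmin(pmax(idx, 1L), dm[along])
  args <- rep(list(quote(expr = )), length(dm))
  args[[along]] <- idx
  do.call(`[`, c(list(x), args, list(drop = FALSE)))
}

## 3^k moving-median filter (k = number of dimensions), replicate borders.
median_filter3 <- function(x) {
  dm <- dim(x)
  offs <- expand.grid(rep(list(-1:1), length(dm)))
  stack <- vapply(seq_len(nrow(offs)), function(i) {
    y <- x
    for (d in seq_along(dm)) {
      if (offs[i, d] != 0) y <- shift_replicate(y, offs[i, d], d)
    }
    as.vector(y)
  }, numeric(length(x)))
  array(apply(stack, 1L, stats::median), dim = dm)
}
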