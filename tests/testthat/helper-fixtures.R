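# Shared fixtures: the standard phantom/noise suite used by the denoising
# quality tests (3 phantom families x speckle d in {0.3, 0.5}, 64 x 64).
fixture_suite <- function(size = 64L) {
  cases <- expand.grid(kind = c("shepp_like", "blobs", "step_wedge"),
                       d = c(0.3, 0.5), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(cases)), function(i) {
    kind <- cases$kind[i]
    d <- cases$d[i]
    clean <- make_phantom(c(size, size), kind, seed = 100L + i)
    params <- speckle_params(d = d, additive_sigma = 0, seed = 200L + i)
    list(kind = kind, d = d, clean = clean,
         noisy = apply_speckle(clean, params), params = params)
  })
}

# Independent brute-force maximizer of the MAP objective on a dense grid.
dense_grid_argmax <- function(y, cfg, center = 0, n_points = 1e6) {
  hw <- if (is.null(cfg$search_halfwidth))
    5 * max(cfg$noise_d, cfg$prior_d) else cfg$search_halfwidth
  zs <- seq(y - hw, y + hw, length.out = n_points)
  obj <- map_objective(zs, y, cfg, center)
  zs[which.max(obj)]
}
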