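# Shared fixtures, all generated in code.

# small phantom patch used for network and augmentation tests
patch_phantom <- function(seed = 1L, rating = 9L, ...) {
  cfg <- phantom_config(grid_shape = c(32, 32, 32),
                        spacing_mm = c(0.8, 0.8, 0.8), seed = seed, ...)
  ph <- generate_phantom(cfg)
  if (rating < 9L)
    ph$stack <- degrade_primary(ph$stack, rating, seed = seed)
  list(stack = ph$stack, labels = ph$labels,
       subject = paste0("S", seed), side = "left")
}

# mid-size noiseless phantom for registration tests
reg_phantom <- function(seed = 5L, shape = c(48, 48, 48), spacing = 0.6) {
  cfg <- phantom_config(grid_shape = shape,
                        spacing_mm = rep(spacing, 3),
                        noise_sigma = 0, bias_field_amplitude = 0,
                        seed = seed)
  generate_phantom(cfg)
}

# smooth random field with no locally constant neighborhoods
smooth_field <- function(n = 16, seed = 1) {
  set.seed(seed)
  idx <- seq_len(n)
  f <- outer(outer(sin(idx / 2), cos(idx / 3), `+`), sin(idx / 5), `+`)
  f + array(rnorm(n^3, 0, 0.05), dim = c(n, n, n))
}

expect_transform_close <- function(est, truth, tol_mm, tol_deg) {
  res <- mtlseg:::transform_residual(est, truth)
  expect_lt(res$translation_mm, tol_mm)
  expect_lt(res$rotation_deg, tol_deg)
}
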