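test_that("phantom generation is deterministic and complete", {
  cfg <- phantom_config(seed = 3L)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a$stack$channels, b$stack$channels)
  expect_identical(a$labels$labels, b$labels$labels)
  # every gray-matter label present; only declared codes emitted
  counts <- table(a$labels$labels)
  expect_true(all(as.character(mtl_gm_labels()) %in% names(counts)))
  expect_true(all(as.integer(names(counts)) %in% mtl_labels()))
  # different seed changes the noise realization
  expect_false(identical(a$stack$channels,
                         generate_phantom(phantom_config(seed = 4L))$stack$channels))
})

test_that("noiseless phantom is piecewise constant at contrast-table values", {
  cfg <- phantom_config(noise_sigma = 0, bias_field_amplitude = 0, seed = 1)
  ph <- generate_phantom(cfg)
  lab <- ph$labels$labels
  for (ch in c(1, 2, 3, 5)) {
    expected <- array(cfg$contrast_table[lab + 1L, ch], dim = dim(lab))
    expect_equal(ph$stack$channels[, , , ch], expected)
  }
  # 3T-T2w matches inside its coverage slab and is exactly zero outside
  cov <- coverage_mask_3t(ph$stack)
  ch4 <- ph$stack$channels[, , , 4]
  expect_true(all(ch4[!cov] == 0))
  expect_equal(ch4[cov], array(cfg$contrast_table[lab + 1L, 4],
                               dim = dim(lab))[cov])
  expect_gt(mean(!cov), 0.25)  # a substantial A-P margin is uncovered
})

test_that("per-label voxel counts match an independent recount", {
  ph <- generate_phantom(phantom_config(seed = 9))
  v <- subregion_volumes(ph$labels)
  lab <- ph$labels$labels
  for (rn in v$region) {
    code <- mtl_labels()[[rn]]
    recount <- sum(as.vector(lab) == code)   # plain recount oracle
    expect_equal(v$value[v$region == rn], recount * prod(ph$labels$spacing))
  }
})

test_that("phantom config validation rejects bad inputs", {
  expect_error(phantom_config(grid_shape = c(8, 64, 64)), ">= 16")
  expect_error(phantom_config(spacing_mm = c(0, 1, 1)), "positive")
  ct <- default_contrast_table <- phantom_config()$contrast_table
  expect_error(phantom_config(contrast_table = ct[-2, ]), "every label")
})

test_that("quality degradation touches only the primary channel", {
  ph <- patch_phantom(2)
  for (r in c(2L, 5L, 8L)) {
    deg <- degrade_primary(ph$stack, r, seed = 1)
    expect_identical(deg$channels[, , , 2:5], ph$stack$channels[, , , 2:5])
    expect_false(identical(deg$channels[, , , 1], ph$stack$channels[, , , 1]))
  }
  expect_identical(degrade_primary(ph$stack, 9L), ph$stack)  # rating 9 no-op
  expect_error(degrade_primary(ph$stack, 0L), "1..9")
  expect_error(degrade_primary(ph$stack, 10L), "1..9")
})

test_that("sharpness decreases monotonically as the rating drops", {
  cfg <- phantom_config(grid_shape = c(32, 32, 32),
                        spacing_mm = c(0.8, 0.8, 0.8),
                        noise_sigma = 0, bias_field_amplitude = 0, seed = 4)
  ph <- generate_phantom(cfg)
  energies <- vapply(c(2L, 5L, 8L, 9L), function(r) {
    q <- quality_model(r)
    q$noise_sd <- 0   # isolate the blur/contrast component
    deg <- degrade_primary(ph$stack, q)
    gradient_energy(deg$channels[, , , 1], cfg$spacing_mm)
  }, numeric(1))
  expect_true(all(diff(energies) > 0))
  # quality model invariants: degradation non-increasing in rating
  blur <- vapply(1:9, function(r) quality_model(r)$blur_sigma_mm, numeric(1))
  ctr <- vapply(1:9, function(r) quality_model(r)$contrast_scale, numeric(1))
  expect_true(all(diff(blur) <= 0))
  expect_true(all(diff(ctr) >= 0))
  expect_equal(quality_model(9)$blur_sigma_mm, 0)
})

test_that("misalignment shifts content by the requested amount", {
  ph <- reg_phantom(6, shape = c(32, 32, 32), spacing = 1.0)
  # identity parameters: bit-identical under nearest resampling
  id <- apply_misalignment(ph$stack, vector("list", 5),
                           interpolation = "nearest")
  expect_identical(id$stack$channels, ph$stack$channels)
  expect_equal(id$transforms[[1]]$matrix, diag(4))
  # +3 voxel translation along A-P moves the foreground centroid by 3
  par <- list(rotation_deg = c(0, 0, 0), translation_mm = c(0, 3, 0))
  mis <- apply_misalignment(ph$stack, list(NULL, par, NULL, NULL, NULL),
                            interpolation = "nearest")
  centroid <- function(v) {
    w <- v > 0.3
    colMeans(which(w, arr.ind = TRUE))
  }
  shift <- centroid(mis$stack$channels[, , , 2]) -
    centroid(ph$stack$channels[, , , 2])
  expect_equal(unname(shift), c(0, 3, 0), tolerance = 0.1)
  # channel 1 must stay at identity; non-rigid parameters rejected
  expect_error(apply_misalignment(ph$stack, list(par, NULL, NULL, NULL, NULL)),
               "identity")
  bad <- list(rotation_deg = c(0, 0, 0), translation_mm = c(0, 0, 0),
              scale = 1.2)
  expect_error(apply_misalignment(ph$stack, list(NULL, bad, NULL, NULL, NULL)),
               "non-rigid")
})

test_that("longitudinal pairs shrink by the configured atrophy", {
  cfg <- phantom_config(grid_shape = c(48, 48, 48),
                        spacing_mm = c(0.6, 0.6, 0.6), seed = 2)
  # zero atrophy: identical label volumes
  cs0 <- cohort_spec(atrophy_rate_per_year = 0, seed = 1)
  p0 <- generate_longitudinal_pair(cfg, cs0, 1)
  expect_identical(p0$t1$labels$labels, p0$t2$labels$labels)
  # 2%/yr over 1 yr: total hippocampal volume ratio in [0.96, 1.00]
  cs <- cohort_spec(atrophy_rate_per_year = 0.02, seed = 1)
  p <- generate_longitudinal_pair(cfg, cs, 1)
  hip <- c(hippo_regions <- c("CA1", "CA2", "CA3", "DG", "SUB", "Tail"))
  r <- sum(p$volumes$v2[p$volumes$region %in% hip]) /
    sum(p$volumes$v1[p$volumes$region %in% hip])
  expect_gte(r, 0.96); expect_lte(r, 1.00)
  # reproducible
  p2 <- generate_longitudinal_pair(cfg, cs, 1)
  expect_identical(p$t2$labels$labels, p2$t2$labels$labels)
  expect_error(generate_longitudinal_pair(cfg, cs, 0), "positive")
  expect_error(cohort_spec(atrophy_rate_per_year = 0.1), "range")
})

test_that("atrophy calibration: log volume ratios regress to the true rate", {
  cfg <- phantom_config(grid_shape = c(48, 48, 48),
                        spacing_mm = c(0.6, 0.6, 0.6), seed = 3)
  rate <- 0.02
  cs <- cohort_spec(atrophy_rate_per_year = rate, seed = 1)
  hip <- c("CA1", "CA2", "CA3", "DG", "SUB", "Tail")
  intervals <- rep(c(0.5, 1, 1.5, 2, 2.5), 4)
  ratios <- vapply(seq_along(intervals), function(i) {
    cfg_i <- cfg; cfg_i$seed <- i
    p <- generate_longitudinal_pair(cfg_i, cs, intervals[i])
    sum(p$volumes$v2[p$volumes$region %in% hip]) /
      sum(p$volumes$v1[p$volumes$region %in% hip])
  }, numeric(1))
  fit <- lm(log(ratios) ~ 0 + intervals)
  est <- 1 - exp(coef(fit)[[1]])
  # voxelization error: one boundary layer relative to the structure volume
  p1 <- generate_phantom(cfg)
  hipvox <- sum(p1$labels$labels %in% mtl_labels()[hip])
  vox_err <- hipvox^(-1 / 3)   # surface/volume scaling of one voxel layer
  expect_lt(abs(est - rate), 2 * vox_err)
})

test_that("synthetic cohorts carry the configured group effect", {
  cfg <- phantom_config(seed = 1)
  # effect 0.2, negligible noise: patient/control mean ratio ~ 0.8
  cs <- cohort_spec(n_per_group = 60, effect_fraction = 0.2,
                    covariate_model = list(noise_cv = 0.001,
                                           age_slope = 0, icv_slope = 0),
                    seed = 5)
  coh <- generate_cohort(cs, cfg)
  m <- tapply(coh$table$value, coh$table$group, mean)
  expect_equal(unname(m[["A+MCI"]] / m[["A-CU"]]), 0.8, tolerance = 0.01)
  # ages within configured bounds; one row per subject/side/region
  expect_true(all(coh$table$age >= 55 & coh$table$age <= 90))
  expect_equal(nrow(coh$table), 120 * 2 * 10)
  expect_false(any(duplicated(coh$table[c("subject", "side", "region",
                                          "timepoint")])))
  expect_true(all(coh$table$value > 0))
})

test_that("null cohorts show no spurious group difference", {
  cfg <- phantom_config(seed = 1)
  set.seed(99)
  pvals <- replicate(40, {
    cs <- cohort_spec(n_per_group = 15, effect_fraction = 0,
                      seed = sample.int(1e6, 1))
    coh <- generate_cohort(cs, cfg)
    sub <- coh$table[coh$table$region == "CA1" & coh$table$side == "left", ]
    t.test(value ~ group, data = sub)$p.value
  })
  expect_lte(mean(pvals < 0.01), 0.1)   # ~1% nominal, allow sampling slack
})

test_that("rendered cohort images track the drawn volume factors", {
  cfg <- phantom_config(grid_shape = c(32, 32, 32),
                        spacing_mm = c(0.8, 0.8, 0.8), seed = 1)
  cs <- cohort_spec(n_per_group = 2, effect_fraction = 0.3,
                    covariate_model = list(noise_cv = 0.001, age_slope = 0,
                                           icv_slope = 0), seed = 3)
  coh <- generate_cohort(cs, cfg, images = TRUE)
  expect_length(coh$images, 4)
  vols <- vapply(coh$images, function(im)
    sum(subregion_volumes(im$labels)$value), numeric(1))
  f <- coh$subjects$volume_factor
  # voxelized volumes scale with the subject factor (tolerant: discretization)
  expect_equal(unname(vols / vols[1]), unname(f / f[1]), tolerance = 0.1)
})
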