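test_that("rigid transforms validate, compose and invert correctly", {
  t1 <- rigid_from_params(c(10, -5, 3), c(1, 2, -3), c(4, 4, 4), "a", "b")
  t2 <- rigid_from_params(c(-2, 8, 1), c(0.5, -1, 2), c(0, 0, 0), "b", "c")
  # composition equals the hand matrix product, with chained space ids
  comp <- compose(t1, t2)
  expect_equal(comp$matrix, t2$matrix %*% t1$matrix)
  expect_identical(comp$moving_space_id, "a")
  expect_identical(comp$fixed_space_id, "c")
  expect_error(compose(t2, t1), "space-id mismatch")
  # identity laws
  id <- identity_transform("a", "a")
  expect_equal(compose(id, t1)$matrix, t1$matrix)
  expect_equal(compose(t1, invert(t1))$matrix, diag(4), tolerance = 1e-9)
  # invariant checks
  bad <- diag(4); bad[1, 1] <- 2
  expect_error(rigid_transform(bad), "rotation")
  bad2 <- diag(4); bad2[4, 1] <- 1
  expect_error(rigid_transform(bad2), "last row")
  # text round trip
  f <- tempfile()
  write_transform(t1, f)
  expect_equal(read_transform(f)$matrix, t1$matrix, tolerance = 1e-12)
})

test_that("NMI behaves like a normalized mutual information", {
  x <- smooth_field(20, 1)
  expect_equal(nmi(x, x, 32), 2.0, tolerance = 1e-9)
  expect_equal(nmi(x, x + 5, 32), 2.0, tolerance = 1e-9)  # bijective remap
  # symmetry
  y <- smooth_field(20, 2)
  expect_equal(nmi(x, y), nmi(y, x))
  # independent noise: NMI near its lower bound of 1
  set.seed(3)
  a <- array(rnorm(40^3), c(40, 40, 40))
  b <- array(rnorm(40^3), c(40, 40, 40))
  expect_equal(nmi(a, b, 32), 1.0, tolerance = 0.02)
  expect_gt(nmi(a, b, 32), 1.0)
  # two-bin toy against hand-computed entropies
  a2 <- rep(c(0, 0, 1, 1), 25); dim(a2) <- c(10, 10, 1)
  b2 <- rep(c(0, 1, 1, 1), 25); dim(b2) <- c(10, 10, 1)
  pj <- c(0.25, 0.25, 0.5)                    # joint cells (0,0),(0,1),(1,1)
  h <- function(p) -sum(p * log(p))
  expected <- (h(c(0.5, 0.5)) + h(c(0.25, 0.75))) / h(pj)
  expect_equal(nmi(a2, b2, 8), expected, tolerance = 1e-12)
  expect_error(nmi(array(1, c(8, 8, 8)), x[1:8, 1:8, 1:8]), "constant")
})

test_that("neighborhood NCC matches its analytic limits", {
  x <- smooth_field(18, 4)
  expect_equal(neighborhood_ncc(x, x), 1.0, tolerance = 1e-6)
  expect_equal(neighborhood_ncc(x, -x), -1.0, tolerance = 1e-6)
  # invariance to affine intensity rescaling
  expect_equal(neighborhood_ncc(x, 3.2 * x + 7), 1.0, tolerance = 1e-6)
  y <- smooth_field(18, 5)
  expect_equal(neighborhood_ncc(x, y), neighborhood_ncc(2 * x - 1, y),
               tolerance = 1e-9)
  expect_error(neighborhood_ncc(x, y, radius = 0), "radius")
})

test_that("weighted NCC equals the restricted-domain metric", {
  x <- smooth_field(20, 6)
  y <- smooth_field(20, 7)
  # zero slab in the last 8 A-P slices; mask excludes it
  y2 <- y; y2[, 13:20, ] <- 0
  mask <- array(TRUE, dim = dim(y)); mask[, 13:20, ] <- FALSE
  w <- neighborhood_ncc(x, y2, 2, weight_mask = mask)
  # oracle: per-voxel local NCC restricted to mask centers, via a direct
  # (slow) window computation
  local_ncc <- function(a, b, c0) {
    wa <- a[c0[1] + (-2:2), c0[2] + (-2:2), c0[3] + (-2:2)]
    wb <- b[c0[1] + (-2:2), c0[2] + (-2:2), c0[3] + (-2:2)]
    va <- sum((wa - mean(wa))^2); vb <- sum((wb - mean(wb))^2)
    if (va <= 0 || vb <= 0) return(0)
    sum((wa - mean(wa)) * (wb - mean(wb))) / sqrt(va * vb)
  }
  centers <- expand.grid(i = 3:18, j = 3:18, k = 3:18)
  centers <- centers[mask[as.matrix(centers)], ]
  vals <- apply(as.matrix(centers), 1, function(c0) local_ncc(x, y2, c0))
  expect_equal(w, mean(vals), tolerance = 1e-10)
})

test_that("resampling preserves content under known shifts", {
  ph <- reg_phantom(8, shape = c(24, 24, 24), spacing = 1.0)
  vol <- ph$stack$channels[, , , 1]
  grid <- grid3(dim(vol), c(1, 1, 1))
  # identity, identical grids, nearest: bit-identical
  out <- resample(vol, identity_transform(), grid, "nearest",
                  moving_grid = grid)
  expect_identical(out, vol)
  # +3 voxel shift: content moves, trailing face zero-filled
  t3 <- rigid_from_params(translation_mm = c(3, 0, 0))
  sh <- resample(vol, t3, grid, "nearest", moving_grid = grid)
  expect_equal(sh[4:24, , ], vol[1:21, , ])
  expect_true(all(sh[1:3, , ] == 0))
  # round trip under linear interpolation: bounded smoothing error (on a
  # band-limited image; interpolation error concentrates at sharp edges)
  smooth <- mtlseg:::blur3d(vol, 1.2, c(1, 1, 1))
  tr <- rigid_from_params(c(3, -2, 4), c(1.3, -0.7, 0.4),
                          center = c(11.5, 11.5, 11.5))
  fwd <- resample(smooth, tr, grid, "linear", moving_grid = grid)
  back <- resample(fwd, invert(tr), grid, "linear", moving_grid = grid)
  core <- 5:20  # ignore the zero-filled boundary
  mae <- mean(abs(back[core, core, core] - smooth[core, core, core]))
  expect_lt(mae, 0.05 * diff(range(smooth)))
  # label contract
  labs <- ph$labels$labels
  expect_error(resample(labs, t3, grid, "linear", moving_grid = grid),
               "nearest")
})

test_that("rigid registration recovers identity and known motions", {
  ph <- reg_phantom(5, shape = c(40, 40, 40), spacing = 0.7)
  vol <- ph$stack$channels[, , , 1]
  grid <- mtlseg:::grid_of(ph$stack)
  # moving = fixed: transform stays at identity
  est0 <- rigid_register(vol, vol, metric_spec("NMI"),
                         reg_schedule(c(30L, 10L), c(4L, 2L)),
                         moving_grid = grid, fixed_grid = grid)
  expect_transform_close(est0, identity_transform(), 0.1 * 0.7, 0.1)
  # known translation of 3 voxels, NMI across contrasts (INV1 vs 7T-T2w)
  par <- list(rotation_deg = c(0, 0, 0), translation_mm = c(2.1, 0, -1.4))
  mis <- apply_misalignment(ph$stack, list(NULL, par, NULL, NULL, NULL))
  est <- rigid_register(mis$stack$channels[, , , 2], vol, metric_spec("NMI"),
                        reg_schedule(), moving_grid = grid, fixed_grid = grid)
  expect_transform_close(est, mis$transforms[[2]], 0.5 * 0.7, 1)
  # known rotation of 5 degrees, same-contrast NCC metric
  par2 <- list(rotation_deg = c(0, 5, 0), translation_mm = c(0, 0, 0))
  mis2 <- apply_misalignment(ph$stack, list(NULL, NULL, NULL, NULL, par2))
  est2 <- rigid_register(mis2$stack$channels[, , , 5],
                         ph$stack$channels[, , , 5], metric_spec("NCC"),
                         reg_schedule(), moving_grid = grid,
                         fixed_grid = grid)
  expect_transform_close(est2, mis2$transforms[[5]], 0.5 * 0.7, 1)
  expect_error(rigid_register(array(1, c(16, 16, 16)), vol), "constant")
})

test_that("metric value never falls below the initialization", {
  ph <- reg_phantom(9, shape = c(32, 32, 32), spacing = 0.8)
  grid <- mtlseg:::grid_of(ph$stack)
  vol <- ph$stack$channels[, , , 1]
  mov <- ph$stack$channels[, , , 2]
  init <- identity_transform()
  est <- rigid_register(mov, vol, metric_spec("NMI"), reg_schedule(),
                        init = init, moving_grid = grid, fixed_grid = grid)
  m_init <- nmi(mov, vol, 32)
  expect_gte(attr(est, "metric_value"), m_init)
})

test_that("indirect 3T-T2w mapping stays within a voxel of direct", {
  # partial-coverage channel: direct registration can be misled by the zero
  # slab; the composed path through 3T-T1w must do at least as well (+1 vox)
  ph <- reg_phantom(11, shape = c(40, 40, 40), spacing = 0.7)
  grid <- mtlseg:::grid_of(ph$stack)
  par <- list(rotation_deg = c(1.5, -1, 2), translation_mm = c(1.5, -1, 0.7))
  mis <- apply_misalignment(ph$stack, list(NULL, NULL, NULL, par, par))
  truth <- mis$transforms[[4]]
  fixed <- ph$stack$channels[, , , 1]
  t_3t1 <- rigid_register(mis$stack$channels[, , , 5], fixed,
                          metric_spec("NMI"), reg_schedule(),
                          moving_grid = grid, fixed_grid = grid)
  # 3T-T2w inherits the 3T-T1w matrix (same-session alignment)
  res_indirect <- mtlseg:::transform_residual(t_3t1, truth)
  t_direct <- rigid_register(mis$stack$channels[, , , 4], fixed,
                             metric_spec("NMI"), reg_schedule(),
                             moving_grid = grid, fixed_grid = grid)
  res_direct <- mtlseg:::transform_residual(t_direct, truth)
  expect_lte(res_indirect$translation_mm,
             res_direct$translation_mm + 0.7)
})

test_that("local refinement after whole-image registration does not hurt", {
  # patch refinement registers the full moving channel against the cropped
  # fixed patch, initialized at the whole-image result
  ph <- reg_phantom(13, shape = c(40, 40, 40), spacing = 0.7)
  grid <- mtlseg:::grid_of(ph$stack)
  par <- list(rotation_deg = c(2, 1, -2), translation_mm = c(1.2, -0.8, 1.5))
  mis <- apply_misalignment(ph$stack, list(NULL, par, NULL, NULL, NULL))
  fixed <- ph$stack$channels[, , , 1]
  roi <- roi_spec("left", c(8, 8, 8), c(32, 32, 32), grid$shape)
  patch_fixed <- crop_patch(ph$stack, roi)
  pgrid <- mtlseg:::grid_of(patch_fixed)
  refine <- function(init)
    rigid_register(mis$stack$channels[, , , 2],
                   patch_fixed$channels[, , , 1], metric_spec("NMI"),
                   reg_schedule(c(50L, 30L), c(2L, 1L)), init = init,
                   moving_grid = grid, fixed_grid = pgrid)
  # an imperfect (coarse-only) whole-image result improves under refinement
  coarse <- rigid_register(mis$stack$channels[, , , 2], fixed,
                           metric_spec("NMI"), reg_schedule(60L, 4L),
                           moving_grid = grid, fixed_grid = grid)
  res_coarse <- mtlseg:::transform_residual(coarse, mis$transforms[[2]])
  res_ref <- mtlseg:::transform_residual(refine(coarse), mis$transforms[[2]])
  expect_lt(res_ref$translation_mm, res_coarse$translation_mm)
  # an accurate init is not degraded beyond discretization level (1/4 voxel)
  full <- rigid_register(mis$stack$channels[, , , 2], fixed,
                         metric_spec("NMI"), reg_schedule(),
                         moving_grid = grid, fixed_grid = grid)
  res_full <- mtlseg:::transform_residual(full, mis$transforms[[2]])
  res_ref2 <- mtlseg:::transform_residual(refine(full), mis$transforms[[2]])
  expect_lte(res_ref2$translation_mm,
             res_full$translation_mm + 0.25 * 0.7)
})

test_that("ROI mapping dilates, clamps and follows transforms", {
  tgrid <- grid3(c(40, 40, 40), c(0.5, 0.5, 0.5))
  mask <- array(FALSE, c(40, 40, 40))
  mask[11:20, 16:25, 21:30] <- TRUE    # 0-based box [10,20) x [15,25) x [20,30)
  id <- identity_transform("template", "3T")
  id2 <- identity_transform("3T", "7T")
  roi <- map_roi(mask, tgrid, id, id2, tgrid, margin_mm = 0)
  expect_equal(roi$start, c(10L, 15L, 20L))
  expect_equal(roi$end, c(20L, 25L, 30L))
  # +5 mm translation shifts the box start by 10 voxels at 0.5 mm
  tr <- rigid_from_params(translation_mm = c(5, 0, 0),
                          moving_space_id = "3T", fixed_space_id = "7T")
  roi2 <- map_roi(mask, tgrid, id, tr, tgrid, margin_mm = 0)
  expect_equal(roi2$start[1], 20L)
  # 2 mm margin extends each side by ceil(2/0.5) = 4 voxels, clamped
  roi3 <- map_roi(mask, tgrid, id, id2, tgrid, margin_mm = 2)
  expect_equal(roi3$start, c(6L, 11L, 16L))
  expect_equal(roi3$end, c(24L, 29L, 34L))
  expect_error(map_roi(array(FALSE, c(4, 4, 4)), grid3(c(4, 4, 4)),
                       id, id2, tgrid), "empty")
})

test_that("patch cropping preserves physical coordinates", {
  ph <- reg_phantom(2, shape = c(32, 32, 32), spacing = 0.8)
  # full-grid ROI: identity crop
  full <- roi_spec("left", c(0, 0, 0), c(32, 32, 32), c(32, 32, 32))
  cp0 <- crop_patch(ph$stack, full)
  expect_identical(cp0$channels, ph$stack$channels)
  # 10-voxel box: exact shape, all channels cropped identically
  roi <- roi_spec("left", c(5, 6, 7), c(15, 16, 17), c(32, 32, 32))
  cp <- crop_patch(ph$stack, roi, ph$labels)
  expect_equal(dim(cp$stack$channels), c(10L, 10L, 10L, 5L))
  expect_identical(cp$stack$channels[, , , 3],
                   ph$stack$channels[6:15, 7:16, 8:17, 3])
  # a landmark voxel keeps its physical position
  idx <- c(8L, 9L, 10L)           # 0-based index in the patch
  phys_patch <- mtlseg:::voxel_to_phys(mtlseg:::grid_of(cp$stack), idx)
  phys_full <- mtlseg:::voxel_to_phys(mtlseg:::grid_of(ph$stack),
                                      idx + roi$start)
  expect_equal(phys_patch, phys_full)
  expect_error(crop_patch(ph$stack,
                          roi_spec("left", c(30, 0, 0), c(40, 10, 10))),
               "outside")
})
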