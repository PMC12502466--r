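# Rigid registration cascade to the 7T-T2w frame: similarity metrics
# (NMI, neighborhood-NCC, weighted-NCC), a multiresolution coordinate-descent
# optimizer over the 6 rigid parameters, ROI mapping and patch cropping.

#' Similarity metric specification
#'
#' @param kind one of `"NMI"`, `"NCC"` (neighborhood normalized
#'   cross-correlation) or `"WNCC"` (weighted-NCC with a coverage mask).
#' @param radius_voxels neighborhood half-width for the NCC kinds; the
#'   default 2 gives 5x5x5 neighborhoods.
#' @param histogram_bins NMI bin count (>= 8).
#' @param weight_mask logical array for `"WNCC"`.
#' @return A `metric_spec` list.
#' @export
metric_spec <- function(kind = c("NMI", "NCC", "WNCC"), radius_voxels = 2L,
                        histogram_bins = 32L, weight_mask = NULL) {
  kind <- match.arg(kind)
  if (radius_voxels < 1L) stopf("radius must be >= 1 voxel")
  if (histogram_bins < 8L) stopf("need >= 8 histogram bins")
  if (kind == "WNCC" && is.null(weight_mask))
    stopf("weighted-NCC needs a weight mask")
  structure(list(kind = kind, radius_voxels = as.integer(radius_voxels),
                 histogram_bins = as.integer(histogram_bins),
                 weight_mask = weight_mask),
            class = "metric_spec")
}

#' Multiresolution iteration schedule
#'
#' Iterations per pyramid level, coarse to fine. The default follows the
#' whole-brain protocol: 100, 50 and 10 iterations at 4x, 2x and full
#' resolution.
#'
#' @param iterations integer vector, one entry per level (all >= 0).
#' @param factors downsampling factor per level (same length).
#' @return A `reg_schedule` list.
#' @export
reg_schedule <- function(iterations = c(100L, 50L, 10L),
                         factors = c(4L, 2L, 1L)) {
  if (length(iterations) != length(factors) || any(iterations < 0))
    stopf("iterations and factors must match, all iterations >= 0")
  structure(list(iterations = as.integer(iterations),
                 factors = as.integer(factors)),
            class = "reg_schedule")
}

#' Normalized mutual information of two images
#'
#' `NMI = (H(a) + H(b)) / H(a, b)`, on a joint histogram whose intensity
#' range is clipped at the 1st-99th percentiles of each image. Ranges from 1
#' (independent) to 2 (identical up to a bijection).
#'
#' @param a,b 3D arrays on the same grid (any non-constant images).
#' @param bins histogram bin count.
#' @return Scalar NMI value.
#' @export
nmi <- function(a, b, bins = 32L) {
  a <- as.double(a); b <- as.double(b)
  if (length(a) != length(b)) stopf("images must be on the same grid")
  ra <- quantile(a, c(0.01, 0.99), names = FALSE)
  rb <- quantile(b, c(0.01, 0.99), names = FALSE)
  if (ra[1] >= ra[2] || rb[1] >= rb[2])
    stopf("degenerate input: (near-)constant image")
  ia <- pmin(bins - 1L, pmax(0L, floor((a - ra[1]) / (ra[2] - ra[1]) * bins)))
  ib <- pmin(bins - 1L, pmax(0L, floor((b - rb[1]) / (rb[2] - rb[1]) * bins)))
  joint <- tabulate(ia * bins + ib + 1L, nbins = bins * bins)
  pj <- joint / sum(joint)
  pa <- rowSums(matrix(pj, bins, bins, byrow = TRUE))
  pb <- colSums(matrix(pj, bins, bins, byrow = TRUE))
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  (ent(pa) + ent(pb)) / ent(pj)
}

# moving-window box sum via 1D cumulative sums along each axis
box_sum3 <- function(vol, r) {
  run_first <- function(v) {   # running sum of half-width r along axis 1
    d <- dim(v); n <- d[1]
    cs <- rbind(0, apply(matrix(v, n), 2, cumsum))
    hi <- pmin(n, seq_len(n) + r)
    lo <- pmax(0L, seq_len(n) - r - 1L)
    array(cs[hi + 1, , drop = FALSE] - cs[lo + 1, , drop = FALSE], d)
  }
  v <- run_first(vol)
  v <- run_first(aperm(v, c(2, 3, 1)))
  v <- run_first(aperm(v, c(2, 3, 1)))
  aperm(v, c(2, 3, 1))
}

#' Neighborhood normalized cross-correlation
#'
#' Mean over voxels of the local NCC computed in cubic neighborhoods of
#' half-width `radius` (default 5x5x5). Neighborhoods with zero variance in
#' either image contribute 0. With a weight mask the per-voxel values are
#' averaged with the mask as weights (the weighted-NCC variant used for
#' partial-coverage scans). Interior voxels only (full windows).
#'
#' @param a,b 3D arrays on the same grid.
#' @param radius neighborhood half-width in voxels (>= 1).
#' @param weight_mask optional numeric/logical array of per-voxel weights.
#' @return Scalar in \[-1, 1\].
#' @export
neighborhood_ncc <- function(a, b, radius = 2L, weight_mask = NULL) {
  if (radius < 1L) stopf("radius must be >= 1 voxel")
  if (!all(dim(a) == dim(b))) stopf("images must be on the same grid")
  d <- dim(a)
  if (any(d < 2 * radius + 1)) stopf("image smaller than the neighborhood")
  nwin <- (2 * radius + 1)^3
  sa <- box_sum3(a, radius); sb <- box_sum3(b, radius)
  saa <- box_sum3(a * a, radius); sbb <- box_sum3(b * b, radius)
  sab <- box_sum3(a * b, radius)
  cov <- sab - sa * sb / nwin
  va <- saa - sa^2 / nwin
  vb <- sbb - sb^2 / nwin
  eps <- 1e-12 * max(1, max(abs(a)))^2 * nwin
  ncc <- ifelse(va > eps & vb > eps, cov / sqrt(pmax(va * vb, 1e-300)), 0)
  core <- function(v) v[(radius + 1):(d[1] - radius),
                        (radius + 1):(d[2] - radius),
                        (radius + 1):(d[3] - radius)]
  ncc <- core(ncc)
  if (is.null(weight_mask)) return(mean(ncc))
  w <- core(array(as.double(weight_mask), dim = d))
  if (sum(w) <= 0) stopf("weight mask is empty on the interior")
  sum(w * ncc) / sum(w)
}

# evaluate a metric for a candidate transform: resample moving into the
# fixed grid, then score
eval_metric <- function(moving, mgrid, fixed, fgrid, matrix, metric) {
  mv <- cpp_resample(as.double(moving), dim(moving), mgrid$spacing,
                     mgrid$origin, fgrid$shape, fgrid$spacing, fgrid$origin,
                     t(solve(matrix)), 1L)
  mv <- array(mv, dim = fgrid$shape)
  switch(metric$kind,
         NMI = nmi(mv, fixed, metric$histogram_bins),
         NCC = neighborhood_ncc(mv, fixed, metric$radius_voxels),
         WNCC = neighborhood_ncc(mv, fixed, metric$radius_voxels,
                                 metric$weight_mask))
}

downsample_vol <- function(vol, f) {
  if (f == 1L) return(vol)
  d <- dim(vol)
  nd <- d %/% f
  v <- vol[seq_len(nd[1] * f), seq_len(nd[2] * f), seq_len(nd[3] * f)]
  dim(v) <- c(f, nd[1], f, nd[2], f, nd[3])
  apply(v, c(2, 4, 6), mean)
}

downsample_grid <- function(grid, f) {
  grid3(grid$shape %/% f, grid$spacing * f,
        grid$origin + (f - 1) / 2 * grid$spacing)
}

#' Rigid registration by multiresolution coordinate descent
#'
#' Estimates the rigid transform (moving physical space to fixed physical
#' space) maximizing the similarity metric, by coordinate descent over the 6
#' rigid parameters (Euler angles + translation about the fixed-image
#' center), on an image pyramid with the given iteration schedule. The
#' returned transform never scores below the initialization.
#'
#' @param moving,fixed [modality_stack()] channels as 3D arrays, or lists
#'   `list(vol, grid)`; plain arrays are taken to live on a unit grid.
#' @param metric a [metric_spec()].
#' @param schedule a [reg_schedule()].
#' @param init initial [rigid_transform()]; the default translates the
#'   moving image center onto the fixed image center.
#' @param moving_grid,fixed_grid [grid3()]s when `moving`/`fixed` are arrays.
#' @return A `rigid_transform` with attribute `metric_value`.
#' @export
rigid_register <- function(moving, fixed, metric = metric_spec("NMI"),
                           schedule = reg_schedule(), init = NULL,
                           moving_grid = NULL, fixed_grid = NULL) {
  mgrid <- moving_grid %||% grid3(dim(moving))
  fgrid <- fixed_grid %||% grid3(dim(fixed))
  if (sd(moving) == 0 || sd(fixed) == 0)
    stopf("cannot register (near-)constant images")
  center <- voxel_to_phys(fgrid, (fgrid$shape - 1) / 2)
  if (is.null(init)) {
    mc <- voxel_to_phys(mgrid, (mgrid$shape - 1) / 2)
    init <- rigid_from_params(translation_mm = center - mc, center = center)
  }
  # optimize the incremental motion on top of init: params (rx,ry,rz,tx,ty,tz)
  par <- c(0, 0, 0, 0, 0, 0)
  par_matrix <- function(p) {
    rigid_from_params(p[1:3], p[4:6], center)$matrix %*% init$matrix
  }
  best <- NA_real_
  for (lev in seq_along(schedule$factors)) {
    f <- schedule$factors[lev]
    fg <- downsample_grid(fgrid, f)
    fx <- downsample_vol(fixed, f)
    met <- metric
    if (!is.null(met$weight_mask) && f > 1L)
      met$weight_mask <- downsample_vol(array(as.double(metric$weight_mask),
                                              dim = fgrid$shape), f) > 0.5
    score <- function(p) {
      v <- try(eval_metric(moving, mgrid, fx, fg, par_matrix(p), met),
               silent = TRUE)
      if (inherits(v, "try-error") || !is.finite(v)) -Inf else v
    }
    best <- score(par)
    if (!is.finite(best))
      stopf("registration failure: non-finite similarity metric")
    step_t <- max(fg$spacing)          # one coarse voxel
    step_r <- 2.0                      # degrees
    for (it in seq_len(schedule$iterations[lev])) {
      improved <- FALSE
      for (k in 1:6) {
        st <- if (k <= 3) step_r else step_t
        for (sgn in c(1, -1)) {
          cand <- par; cand[k] <- cand[k] + sgn * st
          sc <- score(cand)
          if (sc > best + 1e-12) {
            par <- cand; best <- sc; improved <- TRUE; break
          }
        }
      }
      if (!improved) {
        step_t <- step_t / 2
        step_r <- step_r / 2
        if (step_t < 0.02 * min(fgrid$spacing) && step_r < 0.02) break
      }
    }
  }
  out <- rigid_transform(par_matrix(par), init$moving_space_id,
                         init$fixed_space_id)
  attr(out, "metric_value") <- best
  out
}

#' Resample an image through a rigid transform
#'
#' Maps `moving` onto `target_grid` through transform `t` (moving physical
#' space to target physical space). Out-of-field voxels are 0. Label images
#' must use nearest-neighbor interpolation.
#'
#' @param moving 3D array; `moving_grid` its [grid3()].
#' @param t a [rigid_transform()].
#' @param target_grid a [grid3()].
#' @param interpolation `"linear"` or `"nearest"`.
#' @param is_label set for integer label volumes; requesting linear
#'   interpolation for labels is an error.
#' @return 3D array on `target_grid`.
#' @export
resample <- function(moving, t, target_grid,
                     interpolation = c("linear", "nearest"),
                     moving_grid = NULL, is_label = is.integer(moving)) {
  interpolation <- match.arg(interpolation)
  if (is_label && interpolation == "linear")
    stopf("label maps must be resampled with nearest interpolation")
  mgrid <- moving_grid %||% grid3(dim(moving))
  out <- cpp_resample(as.double(moving), dim(moving), mgrid$spacing,
                      mgrid$origin, target_grid$shape, target_grid$spacing,
                      target_grid$origin, t(solve(t$matrix)),
                      if (interpolation == "nearest") 0L else 1L)
  out <- array(out, dim = target_grid$shape)
  if (is_label) storage.mode(out) <- "integer"
  out
}

#' Region-of-interest specification in the 7T-T2w grid
#'
#' @param side `"left"` or `"right"`.
#' @param start,end inclusive start / exclusive end voxel indices (0-based)
#'   per axis.
#' @param grid_shape grid the box must lie within.
#' @return An `roi_spec` list.
#' @export
roi_spec <- function(side, start, end, grid_shape = NULL) {
  side <- match.arg(side, c("left", "right"))
  start <- as.integer(start); end <- as.integer(end)
  if (any(end <= start)) stopf("ROI must be non-empty on each axis")
  if (any(start < 0)) stopf("ROI start before grid origin")
  if (!is.null(grid_shape) && any(end > grid_shape))
    stopf("ROI extends outside the grid")
  structure(list(side = side, start = start, end = end), class = "roi_spec")
}

#' Map a template ROI mask into the 7T-T2w grid
#'
#' Chains the template-to-subject transform with the subject's 3T-T1w to
#' 7T-T2w rigid matrix, maps every mask voxel into the 7T grid, takes the
#' bounding box, dilates it by a safety margin and clamps to the grid.
#'
#' @param template_roi logical/0-1 3D array in template space.
#' @param template_grid the template [grid3()].
#' @param template_to_subject transform (template to 3T-T1w physical space):
#'   a `rigid_transform` or any 4x4 affine matrix.
#' @param subject_3T_to_7T the subject's 3T-T1w to 7T-T2w [rigid_transform()].
#' @param target_grid the 7T-T2w [grid3()].
#' @param margin_mm isotropic dilation of the box (default 4 mm; absorbs the
#'   residual error of the affine template fit).
#' @param side which ROI this box is.
#' @return An [roi_spec()].
#' @export
map_roi <- function(template_roi, template_grid, template_to_subject,
                    subject_3T_to_7T, target_grid, margin_mm = 4,
                    side = "left") {
  m1 <- if (inherits(template_to_subject, "rigid_transform"))
    template_to_subject$matrix else as.matrix(template_to_subject)
  m <- subject_3T_to_7T$matrix %*% m1
  idx <- which(template_roi != 0, arr.ind = TRUE) - 1L
  if (nrow(idx) == 0L) stopf("empty mapped mask")
  phys <- t(t(idx) * template_grid$spacing + template_grid$origin)
  phys <- cbind(phys, 1) %*% t(m)
  vox <- t((t(phys[, 1:3, drop = FALSE]) - target_grid$origin) /
             target_grid$spacing)
  lo <- floor(apply(vox, 2, min) - margin_mm / target_grid$spacing)
  hi <- ceiling(apply(vox, 2, max) + margin_mm / target_grid$spacing) + 1
  lo <- pmax(0L, as.integer(lo))
  hi <- pmin(target_grid$shape, as.integer(hi))
  if (any(hi <= lo)) stopf("mapped ROI lies outside the target grid")
  roi_spec(side, lo, hi, target_grid$shape)
}

#' Crop a modality stack (and optionally labels) to an ROI
#'
#' All five channels are cropped identically; the origin metadata is updated
#' so physical coordinates are preserved.
#'
#' @param stack a [modality_stack()].
#' @param roi an [roi_spec()] (0-based half-open box).
#' @param labels optional [label_map()] cropped alongside.
#' @return Cropped `modality_stack`, or `list(stack, labels)` when labels are
#'   given.
#' @export
crop_patch <- function(stack, roi, labels = NULL) {
  d <- dim(stack$channels)[1:3]
  if (any(roi$start < 0) || any(roi$end > d))
    stopf("ROI box outside the grid")
  ix <- (roi$start[1] + 1):roi$end[1]
  iy <- (roi$start[2] + 1):roi$end[2]
  iz <- (roi$start[3] + 1):roi$end[3]
  grid <- grid3(c(length(ix), length(iy), length(iz)), stack$spacing,
                stack$origin + roi$start * stack$spacing)
  out <- modality_stack(stack$channels[ix, iy, iz, , drop = FALSE], grid)
  if (is.null(labels)) return(out)
  list(stack = out,
       labels = label_map(labels$labels[ix, iy, iz, drop = FALSE], grid))
}
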