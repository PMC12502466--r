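# Synthetic multi-modal phantom generator.
#
# The phantom is a parametric curved tube (hippocampus: CA1-3, DG core, SUB,
# posterior Tail segment) with adjacent cortical ribbons (ERC, BA35, BA36,
# PHC), thin sulcal labels (HS, CS) and small Cysts/MISC structures. It is
# deliberately not anatomically realistic: the downstream operators only need
# nested multi-label 3D structure with realistic cross-channel contrast
# relationships.

default_contrast_table <- function() {
  labs <- names(mtl_labels())
  tab <- rbind(
    #            7T-T2w INV1  INV2  3T-T2w 3T-T1w
    background = c(0.05, 0.10, 0.08, 0.23, 0.12),
    CA1        = c(0.90, 0.55, 0.40, 0.74, 0.60),
    CA2        = c(0.72, 0.55, 0.62, 0.63, 0.42),
    CA3        = c(0.58, 0.35, 0.62, 0.55, 0.60),
    DG         = c(0.42, 0.75, 0.50, 0.45, 0.60),
    SUB        = c(0.80, 0.55, 0.72, 0.68, 0.35),
    Tail       = c(0.52, 0.35, 0.72, 0.51, 0.55),
    ERC        = c(0.68, 0.45, 0.58, 0.61, 0.72),
    BA35       = c(0.62, 0.45, 0.38, 0.57, 0.72),
    BA36       = c(0.48, 0.65, 0.38, 0.49, 0.55),
    PHC        = c(0.36, 0.65, 0.52, 0.42, 0.40),
    HS         = c(1.00, 0.20, 0.18, 0.80, 0.15),
    CS         = c(0.95, 0.20, 0.30, 0.77, 0.15),
    Cysts      = c(0.98, 0.15, 0.85, 0.79, 0.20),
    MISC       = c(0.25, 0.40, 0.30, 0.35, 0.50))
  colnames(tab) <- mtl_channels()
  tab[labs, , drop = FALSE]
}

#' Configuration of the synthetic multi-modal phantom
#'
#' @param grid_shape voxel counts per axis (all >= 16).
#' @param spacing_mm physical voxel spacing in mm.
#' @param region_geometry named list of shape parameters: `tube_radius_mm`,
#'   `dg_frac` (dentate core as a fraction of the tube radius), `tail_frac`
#'   (posterior fraction of the tube assigned to the unpartitioned tail),
#'   `curve_amp_mm` (amplitude of the tube's anterior-posterior curvature),
#'   `ribbon_thickness_mm`, `ribbon_gap_mm`, `ribbon_halfwidth_mm` for the
#'   cortical ribbon, `y_extent` (fractional A-P extent of the structure) and
#'   `volume_scale` (global gray-matter volume factor; 1 = reference).
#' @param contrast_table labels x channels matrix of mean intensities; must
#'   define an intensity for every declared label and channel.
#' @param noise_sigma per-channel additive noise SD.
#' @param rician if `TRUE`, noise is Rician (magnitude of a complex Gaussian)
#'   instead of additive Gaussian.
#' @param bias_field_amplitude strength of the smooth multiplicative
#'   low-frequency bias field (0 disables it).
#' @param coverage_3t fractional A-P window covered by the dedicated partial
#'   coverage 3T-T2w scan; voxels outside it are exactly zero.
#' @param seed integer RNG seed; identical config and seed give bit-identical
#'   output.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(grid_shape = c(64, 64, 64),
                           spacing_mm = c(0.5, 0.5, 0.5),
                           region_geometry = list(),
                           contrast_table = default_contrast_table(),
                           noise_sigma = rep(0.02, 5),
                           rician = FALSE,
                           bias_field_amplitude = 0.05,
                           coverage_3t = c(0.30, 0.90),
                           seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 16L))
    stopf("grid_shape must be 3 integers, all >= 16")
  if (any(spacing_mm <= 0)) stopf("spacing_mm must be positive")
  geom <- utils::modifyList(list(
    tube_radius_mm = 6, dg_frac = 0.45, tail_frac = 0.2, curve_amp_mm = 3.5,
    ribbon_thickness_mm = 2.2, ribbon_gap_mm = 1.0, ribbon_halfwidth_mm = 9,
    y_extent = c(0.12, 0.88), volume_scale = 1), region_geometry)
  labs <- names(mtl_labels())
  if (!is.matrix(contrast_table) ||
      !all(labs %in% rownames(contrast_table)) ||
      ncol(contrast_table) != 5L)
    stopf("contrast_table must define an intensity for every label x channel")
  if (length(noise_sigma) == 1L) noise_sigma <- rep(noise_sigma, 5)
  structure(list(grid_shape = grid_shape, spacing_mm = as.double(spacing_mm),
                 region_geometry = geom,
                 contrast_table = contrast_table[labs, , drop = FALSE],
                 noise_sigma = as.double(noise_sigma), rician = rician,
                 bias_field_amplitude = bias_field_amplitude,
                 coverage_3t = coverage_3t, seed = as.integer(seed)),
            class = "phantom_config")
}

# Voxelize the parametric geometry into a label array.
phantom_label_array <- function(grid, geom) {
  n <- grid$shape; sp <- grid$spacing; or <- grid$origin
  x <- or[1] + (seq_len(n[1]) - 1) * sp[1]
  y <- or[2] + (seq_len(n[2]) - 1) * sp[2]
  z <- or[3] + (seq_len(n[3]) - 1) * sp[3]
  cx0 <- mean(range(x)); cz0 <- mean(range(z))
  y0 <- min(y) + geom$y_extent[1] * diff(range(y))
  y1 <- min(y) + geom$y_extent[2] * diff(range(y))
  vs <- geom$volume_scale
  rt <- geom$tube_radius_mm * sqrt(vs)
  th <- geom$ribbon_thickness_mm * vs
  gap <- geom$ribbon_gap_mm
  hw <- geom$ribbon_halfwidth_mm
  A <- geom$curve_amp_mm

  X <- array(rep(x, times = n[2] * n[3]), dim = n)
  Y <- array(rep(rep(y, each = n[1]), times = n[3]), dim = n)
  Z <- array(rep(z, each = n[1] * n[2]), dim = n)
  u <- pmin(1, pmax(0, (Y - y0) / (y1 - y0)))       # fractional A-P position
  cx <- cx0 + A * sin(pi * u)
  cz <- cz0 + 0.5 * A * cos(pi * u)
  dx <- X - cx
  dz <- Z - cz
  rad <- sqrt(dx^2 + dz^2)
  in_extent <- Y >= y0 & Y <= y1
  theta <- (atan2(dz, dx) * 180 / pi) %% 360

  L <- mtl_labels()
  lab <- array(L[["background"]], dim = n)

  # cortical ribbon below the tube, partitioned along the A-P axis
  rib <- in_extent & abs(dx) <= hw &
    Z < (cz - rt - gap) & Z >= (cz - rt - gap - th)
  ant <- u < 0.45
  lab[rib & ant & dx < 0] <- L[["ERC"]]
  lab[rib & ant & dx >= 0 & dx < hw / 2] <- L[["BA35"]]
  lab[rib & ant & dx >= hw / 2] <- L[["BA36"]]
  lab[rib & !ant & dx < hw / 2] <- L[["PHC"]]
  lab[rib & !ant & dx >= hw / 2] <- L[["BA36"]]
  # collateral sulcus: thin sheet under the ribbon
  cs <- in_extent & abs(dx) <= 3 & u >= 0.2 & u <= 0.8 &
    Z < (cz - rt - gap - th) & Z >= (cz - rt - gap - th - 0.7)
  lab[cs] <- L[["CS"]]

  # hippocampal tube
  tube <- in_extent & rad <= rt
  sub <- tube & (theta >= 230 | theta < 20)
  ca1 <- tube & theta >= 20 & theta < 120
  ca2 <- tube & theta >= 120 & theta < 170
  ca3 <- tube & theta >= 170 & theta < 230
  lab[sub] <- L[["SUB"]]
  lab[ca1] <- L[["CA1"]]
  lab[ca2] <- L[["CA2"]]
  lab[ca3] <- L[["CA3"]]
  lab[tube & rad <= geom$dg_frac * rt] <- L[["DG"]]
  # posterior tail segment is left unpartitioned
  lab[tube & u >= 1 - geom$tail_frac] <- L[["Tail"]]
  # hippocampal sulcus: thin bright rim above the tube
  hs <- in_extent & u < 1 - geom$tail_frac & rad > rt & rad <= rt + 0.7 &
    theta >= 40 & theta < 100
  lab[hs] <- L[["HS"]]
  # small cyst inside the dentate core, and a MISC plug at the anterior cap
  ym <- y0 + 0.3 * (y1 - y0)
  cyst <- sqrt(dx^2 + (Y - ym)^2 + dz^2) <= max(1, 1.4 * max(sp))
  lab[cyst] <- L[["Cysts"]]
  lab[in_extent & u < 0.05 & rad <= 0.35 * rt] <- L[["MISC"]]
  lab
}

# Smooth multiplicative bias field in [1-a, 1+a] from random low-frequency
# sinusoids (one harmonic per axis, random phase).
bias_field <- function(grid, amplitude) {
  n <- grid$shape
  ph <- runif(3, 0, 2 * pi)
  fx <- sin(2 * pi * (seq_len(n[1]) - 1) / n[1] + ph[1])
  fy <- sin(2 * pi * (seq_len(n[2]) - 1) / n[2] + ph[2])
  fz <- sin(2 * pi * (seq_len(n[3]) - 1) / n[3] + ph[3])
  f <- outer(outer(fx, fy, `+`), fz, `+`) / 3
  1 + amplitude * array(f, dim = n)
}

#' Generate a five-channel phantom and its label map
#'
#' Renders the parametric geometry into a label volume, paints each channel
#' from the contrast table, applies a smooth multiplicative bias field and
#' per-channel noise, and zeroes the 3T-T2w channel outside its simulated
#' partial-coverage slab.
#'
#' @param config a [phantom_config()].
#' @return List with elements `stack` (a [modality_stack()]) and `labels`
#'   (a [label_map()]).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  grid <- grid3(config$grid_shape, config$spacing_mm)
  lab <- phantom_label_array(grid, config$region_geometry)
  tab <- config$contrast_table
  with_seed(config$seed, {
    chans <- array(0, dim = c(grid$shape, 5L))
    for (ch in 1:5) {
      vol <- array(tab[lab + 1L, ch], dim = grid$shape)
      if (config$bias_field_amplitude > 0)
        vol <- vol * bias_field(grid, config$bias_field_amplitude)
      s <- config$noise_sigma[ch]
      if (s > 0) {
        if (isTRUE(config$rician)) {
          vol <- sqrt((vol + rnorm(length(vol), 0, s))^2 +
                        rnorm(length(vol), 0, s)^2)
        } else {
          vol <- vol + rnorm(length(vol), 0, s)
        }
        dim(vol) <- grid$shape
      }
      chans[, , , ch] <- vol
    }
    # dedicated 3T-T2w scan: exact zeros outside the covered A-P window
    ap <- axis_index(grid, "AP")
    ny <- grid$shape[ap]
    jcov <- seq_len(ny)
    covered <- jcov >= 1 + floor(config$coverage_3t[1] * (ny - 1)) &
      jcov <= 1 + ceiling(config$coverage_3t[2] * (ny - 1))
    chans[, !covered, , 4L] <- 0
    list(stack = modality_stack(chans, grid), labels = label_map(lab, grid))
  })
}

#' Coverage mask of the partial-coverage 3T-T2w channel
#'
#' Voxels where the dedicated scan has signal (non-zero slab), used as the
#' weight mask of the weighted-NCC metric.
#'
#' @param stack a [modality_stack()].
#' @return Logical 3D array.
#' @export
coverage_mask_3t <- function(stack) {
  ch <- stack_channel(stack, 4L)
  ap <- axis_index(stack, "AP")
  # a slab is zero across the full cross-section; detect per-slice support
  keep <- apply(abs(ch), ap, max) > 0
  array(keep[slice.index(ch, ap)], dim = dim(ch))
}

#' Quality model for the primary channel
#'
#' Maps the 1-9 visual quality rating onto a concrete degradation: Gaussian
#' blur, compression of inter-tissue contrast toward the image mean, and
#' graded additive noise, all confined to the 7T-T2w channel. Severity is
#' linear in (9 - rating)/8, so rating 9 means no degradation and the
#' degradation strength is non-increasing in the rating.
#'
#' The calibration is anchored so that at rating 1 the internal subfield
#' boundaries are essentially invisible (the operational meaning of a "poor"
#' rating), while ratings of 5 and above leave the anatomy clearly legible.
#'
#' @param rating integer 1-9 (9 = best).
#' @param blur_max_mm blur sigma at rating 1.
#' @param contrast_loss_max maximal fractional loss of inter-tissue contrast.
#' @param noise_max additive noise SD at rating 1.
#' @return A `quality_model` list with `rating`, `blur_sigma_mm`,
#'   `contrast_scale`, `noise_sd`.
#' @export
quality_model <- function(rating, blur_max_mm = 3, contrast_loss_max = 0.85,
                          noise_max = 0.15) {
  if (length(rating) != 1L || is.na(rating) || rating < 1 || rating > 9 ||
      rating != round(rating))
    stopf("quality rating must be an integer in 1..9")
  sev <- (9 - rating) / 8
  structure(list(rating = as.integer(rating),
                 blur_sigma_mm = blur_max_mm * sev,
                 contrast_scale = 1 - contrast_loss_max * sev,
                 noise_sd = noise_max * sev),
            class = "quality_model")
}

gaussian_kernel <- function(sigma_vox) {
  h <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-0.5 * ((-h):h / sigma_vox)^2)
  k / sum(k)
}

# Separable Gaussian blur in physical units.
blur3d <- function(vol, sigma_mm, spacing) {
  d <- dim(vol)
  out <- as.double(vol)
  for (ax in 1:3) {
    sv <- sigma_mm / spacing[ax]
    if (sv < 0.2) next
    out <- cpp_filter1d(out, d, gaussian_kernel(sv), ax - 1L)
  }
  array(out, dim = d)
}

#' Degrade the primary (7T-T2w) channel of a stack
#'
#' Applies the blur/contrast/noise degradation of a [quality_model()] to
#' channel 1 only; all other channels are returned bit-identical. A rating
#' of 9 returns the input unchanged.
#'
#' @param stack a [modality_stack()].
#' @param quality a [quality_model()] or an integer rating 1-9.
#' @param seed RNG seed for the additive noise component.
#' @return The degraded [modality_stack()].
#' @export
degrade_primary <- function(stack, quality, seed = 0L) {
  if (is.numeric(quality)) quality <- quality_model(quality)
  stopifnot(inherits(quality, "quality_model"))
  if (quality$rating == 9L) return(stack)
  vol <- stack_channel(stack, 1L)
  if (quality$blur_sigma_mm > 0)
    vol <- blur3d(vol, quality$blur_sigma_mm, stack$spacing)
  m <- mean(vol)
  vol <- m + quality$contrast_scale * (vol - m)
  if (quality$noise_sd > 0) {
    vol <- with_seed(derive_seed(seed, "degrade"),
                     vol + rnorm(length(vol), 0, quality$noise_sd))
    dim(vol) <- dim(stack$channels)[1:3]
  }
  set_stack_channel(stack, 1L, vol)
}

#' Gradient-magnitude energy of a volume
#'
#' Mean squared forward-difference gradient magnitude, in physical units;
#' a simple sharpness index used to verify that quality degradation is
#' monotone.
#'
#' @param vol 3D array; `spacing` per-axis mm.
#' @return A scalar.
#' @export
gradient_energy <- function(vol, spacing = c(1, 1, 1)) {
  d <- dim(vol)
  gx <- (vol[-1, , ] - vol[-d[1], , ]) / spacing[1]
  gy <- (vol[, -1, ] - vol[, -d[2], ]) / spacing[2]
  gz <- (vol[, , -1] - vol[, , -d[3]]) / spacing[3]
  (mean(gx^2) + mean(gy^2) + mean(gz^2))
}

#' Apply known rigid misalignments to the secondary channels
#'
#' Simulates inter-modality misalignment (the condition whole-brain
#' registration corrects): each secondary channel is resampled so that its
#' content is displaced by the given rigid motion. Channel 1 (7T-T2w)
#' defines the reference frame and must stay at identity. Ground-truth
#' transforms (moving channel space -> primary space, i.e. what registration
#' should recover) are returned for recovery tests.
#'
#' @param stack a [modality_stack()].
#' @param params list of 5 per-channel parameter sets, each `NULL` (identity)
#'   or `list(rotation_deg =, translation_mm =)`; entry 1 must be identity.
#' @param interpolation `"linear"` or `"nearest"`.
#' @return List with `stack` (misaligned) and `transforms` (list of 5
#'   `rigid_transform`s, identity in position 1).
#' @export
apply_misalignment <- function(stack, params, interpolation = "linear") {
  stopifnot(inherits(stack, "modality_stack"), length(params) == n_channels(stack))
  for (p in params) {
    if (is.null(p)) next
    extra <- setdiff(names(p), c("rotation_deg", "translation_mm"))
    if (length(extra))
      stopf("non-rigid parameters not allowed: %s",
            paste(extra, collapse = ", "))
  }
  is_id <- function(p) is.null(p) ||
    (max(abs(c(p$rotation_deg %||% 0, p$translation_mm %||% 0))) == 0)
  if (!is_id(params[[1]]))
    stopf("channel 1 defines the reference frame and must stay at identity")
  grid <- grid_of(stack)
  center <- voxel_to_phys(grid, (grid$shape - 1) / 2)
  transforms <- vector("list", n_channels(stack))
  for (ch in seq_len(n_channels(stack))) {
    p <- params[[ch]]
    if (is_id(p)) {
      transforms[[ch]] <- identity_transform(
        moving_space_id = paste0("ch", ch), fixed_space_id = "primary")
      next
    }
    motion <- rigid_from_params(p$rotation_deg %||% c(0, 0, 0),
                                p$translation_mm %||% c(0, 0, 0), center)
    # content moves forward under `motion`; the recovery transform is its
    # inverse (it maps the moved channel back onto the primary frame)
    vol <- stack_channel(stack, ch)
    out <- cpp_resample(as.double(vol), dim(vol), grid$spacing, grid$origin,
                        grid$shape, grid$spacing, grid$origin,
                        t(solve(motion$matrix)),
                        if (interpolation == "nearest") 0L else 1L)
    stack <- set_stack_channel(stack, ch, array(out, dim = dim(vol)))
    transforms[[ch]] <- rigid_transform(solve(motion$matrix),
                                        moving_space_id = paste0("ch", ch),
                                        fixed_space_id = "primary")
  }
  list(stack = stack, transforms = transforms)
}

#' Cohort specification for synthetic group studies
#'
#' @param n_per_group subjects per diagnostic group (amyloid-negative
#'   cognitively unimpaired controls vs amyloid-positive MCI patients).
#' @param effect_fraction multiplicative gray-matter volume reduction in the
#'   patient group (0 <= effect < 1).
#' @param covariate_model list: `age_range`, `age_slope` (fractional volume
#'   change per year of age), `icv_mean`, `icv_sd` (mm^3), `icv_slope`
#'   (fractional volume change per fractional ICV deviation), `noise_cv`
#'   (between-subject lognormal volume CV).
#' @param atrophy_rate_per_year fractional annual volume loss used for
#'   longitudinal pairs; must lie in `atrophy_range`.
#' @param atrophy_range admissible atrophy rates; the default reflects
#'   reported annual hippocampal loss in aging and MCI.
#' @param quality_probs sampling weights over ratings 1..9 for per-ROI 7T-T2w
#'   quality.
#' @param seed integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group = 20L, effect_fraction = 0.15,
                        covariate_model = list(),
                        atrophy_rate_per_year = 0.015,
                        atrophy_range = c(0.002, 0.0255),
                        quality_probs = c(1, 1, 2, 3, 6, 8, 6, 4, 2),
                        seed = 1L) {
  if (effect_fraction < 0 || effect_fraction >= 1)
    stopf("effect_fraction must be in [0, 1)")
  if (atrophy_rate_per_year != 0 &&
      (atrophy_rate_per_year < atrophy_range[1] ||
       atrophy_rate_per_year > atrophy_range[2]))
    stopf("atrophy_rate_per_year outside the configured range [%g, %g]",
          atrophy_range[1], atrophy_range[2])
  cov <- utils::modifyList(list(
    age_range = c(55, 90), age_slope = -0.005, icv_mean = 1.45e6,
    icv_sd = 1.3e5, icv_slope = 0.4, noise_cv = 0.08), covariate_model)
  structure(list(n_per_group = as.integer(n_per_group),
                 effect_fraction = effect_fraction, covariate_model = cov,
                 atrophy_rate_per_year = atrophy_rate_per_year,
                 atrophy_range = atrophy_range,
                 quality_probs = quality_probs / sum(quality_probs),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# reference per-region volumes (mm^3) of the phantom at volume_scale 1,
# recounted from a rendered label map and cached per config geometry
reference_region_volumes <- function(config) {
  ph <- generate_phantom(config)
  v <- subregion_volumes(ph$labels)
  setNames(v$value, v$region)
}

#' Generate a synthetic two-group cohort
#'
#' Draws per-subject covariates (age, ICV), per-ROI quality ratings and true
#' gray-matter region volumes with a multiplicative group effect, linear age
#' and ICV effects and lognormal between-subject noise. Optionally renders
#' per-subject phantom image sets whose gray-matter volume tracks the
#' subject's drawn volume factor.
#'
#' @param cohort a [cohort_spec()].
#' @param config a [phantom_config()]; defines the reference geometry.
#' @param images if `TRUE`, render a phantom stack + labels per subject
#'   (expensive; intended for small `n_per_group`).
#' @return List: `table` (long measurement table, one row per
#'   subject/side/region), `subjects` (per-subject covariates and volume
#'   factors) and, if requested, `images` (named list per subject of
#'   `list(stack, labels)`).
#' @export
generate_cohort <- function(cohort, config = phantom_config(),
                            images = FALSE) {
  stopifnot(inherits(cohort, "cohort_spec"))
  if (cohort$n_per_group < 2L) stopf("need at least 2 subjects per group")
  cv <- cohort$covariate_model
  ref <- reference_region_volumes(config)
  regions <- names(mtl_gm_labels())
  with_seed(derive_seed(cohort$seed, "cohort"), {
    n <- 2L * cohort$n_per_group
    grp <- rep(c("A-CU", "A+MCI"), each = cohort$n_per_group)
    age <- runif(n, cv$age_range[1], cv$age_range[2])
    icv <- rnorm(n, cv$icv_mean, cv$icv_sd)
    subj_noise <- exp(rnorm(n, 0, cv$noise_cv))
    eff <- ifelse(grp == "A+MCI", 1 - cohort$effect_fraction, 1)
    vol_factor <- eff * (1 + cv$age_slope * (age - mean(cv$age_range))) *
      (1 + cv$icv_slope * (icv - cv$icv_mean) / cv$icv_mean) * subj_noise
    subjects <- data.frame(
      subject = sprintf("S%03d", seq_len(n)), group = grp, age = age,
      icv = icv, volume_factor = vol_factor,
      seed = vapply(seq_len(n), function(i)
        derive_seed(cohort$seed, paste0("subj", i)), integer(1)))
    rows <- list()
    for (i in seq_len(n)) {
      for (side in c("left", "right")) {
        side_f <- exp(rnorm(1, 0, 0.02))
        rating <- sample.int(9L, 1L, prob = cohort$quality_probs)
        meas_noise <- exp(rnorm(length(regions), 0, 0.02))
        rows[[length(rows) + 1L]] <- data.frame(
          subject = subjects$subject[i], side = side, region = regions,
          measure_kind = "volume",
          value = unname(ref[regions]) * vol_factor[i] * side_f * meas_noise,
          group = grp[i], age = age[i], icv = icv[i], quality = rating,
          timepoint = 1L)
      }
    }
    table <- do.call(rbind, rows)
    out <- list(table = table, subjects = subjects)
    if (images) {
      out$images <- lapply(seq_len(n), function(i) {
        cfg <- config
        cfg$region_geometry$volume_scale <-
          config$region_geometry$volume_scale * vol_factor[i]
        cfg$seed <- subjects$seed[i]
        generate_phantom(cfg)
      })
      names(out$images) <- subjects$subject
    }
    out
  })
}

#' Generate a longitudinal phantom pair with known atrophy
#'
#' The second timepoint shrinks gray-matter structures so that each region's
#' true volume is approximately `(1 - rate)^interval` times the first
#' timepoint's, up to voxelization error.
#'
#' @param config a [phantom_config()].
#' @param cohort a [cohort_spec()]; supplies `atrophy_rate_per_year`.
#' @param interval_years positive scan interval.
#' @return List: `t1`, `t2` (each `list(stack, labels)`), `volumes` (per-region
#'   voxelized volumes at both timepoints), `expected_ratio`.
#' @export
generate_longitudinal_pair <- function(config, cohort, interval_years) {
  if (interval_years <= 0) stopf("interval_years must be positive")
  ratio <- (1 - cohort$atrophy_rate_per_year)^interval_years
  t1 <- generate_phantom(config)
  cfg2 <- config
  cfg2$region_geometry$volume_scale <-
    config$region_geometry$volume_scale * ratio
  t2 <- generate_phantom(cfg2)
  v1 <- subregion_volumes(t1$labels)
  v2 <- subregion_volumes(t2$labels)
  list(t1 = t1, t2 = t2,
       volumes = data.frame(region = v1$region, v1 = v1$value,
                            v2 = v2$value[match(v1$region, v2$region)]),
       expected_ratio = ratio)
}
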