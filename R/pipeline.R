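# End-to-end orchestration: simulate -> whole-brain registration -> ROI
# determination -> patch cropping -> local registration -> flip -> ModAug
# training -> ensembled prediction -> evaluation, with a machine-readable
# run manifest.

#' Read a NIfTI volume with its grid metadata
#'
#' @param path NIfTI-1 file.
#' @return List `vol` (array; integer arrays preserved), `grid` ([grid3()]),
#'   `affine` (4x4 sform).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  aff <- unclass(RNifti::xform(img))
  sp <- sqrt(colSums(aff[1:3, 1:3]^2))   # spacing from the affine columns
  if (any(!is.finite(sp)) || any(sp <= 0))
    stopf("malformed NIfTI header: bad pixel spacing in %s", path)
  grid <- grid3(dim(arr)[1:3], sp, aff[1:3, 4])
  list(vol = arr, grid = grid, affine = aff)
}

#' Write a volume (or label map) as NIfTI-1
#'
#' @param vol 3D array, [label_map()] (written as int16), or
#'   [modality_stack()] (written as 4D).
#' @param path output file; `grid` a [grid3()] (taken from the object when it
#'   carries one).
#' @return The path, invisibly.
#' @export
write_volume <- function(vol, path, grid = NULL) {
  if (inherits(vol, "label_map")) {
    grid <- grid %||% grid3(dim(vol$labels), vol$spacing, vol$origin)
    arr <- vol$labels
    dtype <- "int16"
  } else if (inherits(vol, "modality_stack")) {
    grid <- grid %||% grid_of(vol)
    arr <- vol$channels
    dtype <- "double"
  } else {
    grid <- grid %||% grid3(dim(vol)[1:3])
    arr <- vol
    dtype <- if (is.integer(vol)) "int16" else "double"
  }
  img <- RNifti::asNifti(arr)
  aff <- diag(4)
  diag(aff)[1:3] <- grid$spacing
  aff[1:3, 4] <- grid$origin
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' Pipeline configuration
#'
#' Nested per-module blocks with a single global seed from which every
#' module seed is derived. Defaults carry the protocol constants: channel
#' order (7T-T2w, INV1, INV2, 3T-T2w, 3T-T1w), 50% ModAug branch with equal
#' k-weights, the 100/50/10 registration schedule at 4x/2x/1x, 5
#' cross-validation folds, the quality threshold of 5, and 1.96 SD agreement
#' limits.
#'
#' @param n_train,n_test training / test subjects to simulate.
#' @param seed global seed.
#' @param patch_size cubic patch side (voxels).
#' @param epochs training epochs; `n_folds` cross-validation folds;
#'   `base_width` network width.
#' @param grid_shape,spacing_mm phantom grid.
#' @param test_quality_range inclusive rating range sampled for test-subject
#'   primaries (training primaries stay clean at 9).
#' @param modaug logical: train with ModAug.
#' @param misalign_mm,misalign_deg maximal simulated inter-modality motion.
#' @param zero_channel_for subject ids whose 3T-T1w channel is zeroed, to
#'   inject a registration failure (QC-exclusion path).
#' @param run_dir output directory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_train = 4L, n_test = 2L, seed = 1L,
                            patch_size = 32L, epochs = 10L, n_folds = 2L,
                            base_width = 8L,
                            grid_shape = c(48, 48, 48),
                            spacing_mm = c(0.7, 0.7, 0.7),
                            test_quality_range = c(2L, 8L),
                            modaug = TRUE,
                            misalign_mm = 2, misalign_deg = 3,
                            zero_channel_for = character(0),
                            run_dir = tempfile("mtlseg_run_")) {
  structure(list(n_train = as.integer(n_train), n_test = as.integer(n_test),
                 seed = as.integer(seed), patch_size = as.integer(patch_size),
                 epochs = as.integer(epochs), n_folds = as.integer(n_folds),
                 base_width = as.integer(base_width),
                 grid_shape = as.integer(grid_shape),
                 spacing_mm = spacing_mm,
                 test_quality_range = as.integer(test_quality_range),
                 modaug = isTRUE(modaug), misalign_mm = misalign_mm,
                 misalign_deg = misalign_deg,
                 zero_channel_for = zero_channel_for,
                 channel_order = mtl_channels(), run_dir = run_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file with `pipeline_config` fields.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  do.call(pipeline_config, vals[intersect(names(vals), known)])
}

simulate_subject <- function(cfg, subject, side, quality, phantom_seed) {
  pconf <- phantom_config(grid_shape = cfg$grid_shape,
                          spacing_mm = cfg$spacing_mm, seed = phantom_seed)
  ph <- generate_phantom(pconf)
  stack <- ph$stack
  if (side == "right") {
    fl <- flip_right_to_left(stack, ph$labels)  # mirror: build a right side
    stack <- fl$stack; ph$labels <- fl$labels
  }
  if (subject %in% cfg$zero_channel_for)
    stack <- set_stack_channel(stack, 5L, array(0, dim = cfg$grid_shape))
  mis <- with_seed(derive_seed(phantom_seed, "motion"), {
    rand_par <- function() list(
      rotation_deg = runif(3, -cfg$misalign_deg, cfg$misalign_deg),
      translation_mm = runif(3, -cfg$misalign_mm, cfg$misalign_mm))
    # INV1/INV2 come from one acquisition and move together, as do the two
    # 3T scans (same session, roughly aligned)
    p_7t1 <- rand_par()
    p_3t <- rand_par()
    # the dedicated 3T-T2w is only roughly aligned with 3T-T1w: small extra
    # motion that the local weighted-NCC step must absorb
    p_3t2 <- list(rotation_deg = p_3t$rotation_deg + runif(3, -0.5, 0.5),
                  translation_mm = p_3t$translation_mm + runif(3, -0.5, 0.5))
    apply_misalignment(stack, list(NULL, p_7t1, p_7t1, p_3t2, p_3t))
  })
  stack <- mis$stack
  if (quality < 9L)
    stack <- degrade_primary(stack, quality,
                             seed = derive_seed(phantom_seed, "qual"))
  list(stack = stack, labels = ph$labels, true_transforms = mis$transforms,
       quality = quality, side = side, subject = subject)
}

# three-step whole-image cascade + local refinement for one subject's stack
register_subject <- function(sub, cfg) {
  grid <- grid_of(sub$stack)
  primary <- stack_channel(sub$stack, 1L)
  sched <- reg_schedule()
  reg <- function(ch, metric)
    rigid_register(stack_channel(sub$stack, ch), primary, metric, sched,
                   moving_grid = grid, fixed_grid = grid)
  # 7T-T1w: register INV1, reuse its matrix for INV2
  t_inv1 <- reg(2L, metric_spec("NMI"))
  # 3T-T1w to 7T-T2w
  t_3t1 <- reg(5L, metric_spec("NMI"))
  # 3T-T2w inherits the 3T-T1w matrix (indirect path for partial coverage)
  out <- sub$stack
  tr <- list(identity_transform(), t_inv1, t_inv1, t_3t1, t_3t1)
  for (ch in 2:5)
    out <- set_stack_channel(out, ch,
                             resample(stack_channel(sub$stack, ch), tr[[ch]],
                                      grid, "linear", moving_grid = grid))
  sub$stack <- out
  sub$est_transforms <- tr
  sub
}

# Refine each secondary channel within the MTL patch. The moving image is
# the full (whole-registered) channel, so no context is lost to the crop;
# the fixed image is the cropped primary patch.
local_register_patch <- function(full, patch, cfg) {
  fgrid <- grid_of(full)
  pgrid <- grid_of(patch)
  primary <- stack_channel(patch, 1L)
  sched <- reg_schedule(c(100L, 50L), c(2L, 1L))
  reg <- function(ch, metric)
    rigid_register(stack_channel(full, ch), primary, metric, sched,
                   init = identity_transform(),
                   moving_grid = fgrid, fixed_grid = pgrid)
  t_inv1 <- try(reg(2L, metric_spec("NCC")), silent = TRUE)
  t_3t1 <- try(reg(5L, metric_spec("NMI")), silent = TRUE)
  cov <- coverage_mask_3t(patch)
  t_3t2 <- if (sum(cov) > 0)
    try(reg(4L, metric_spec("WNCC", weight_mask = cov)), silent = TRUE)
  else try(stop("empty coverage"), silent = TRUE)
  trs <- list(identity_transform(), t_inv1, t_inv1, t_3t2, t_3t1)
  for (ch in 2:5) {
    tr <- if (inherits(trs[[ch]], "try-error")) identity_transform()
    else trs[[ch]]
    patch <- set_stack_channel(patch, ch,
                               resample(stack_channel(full, ch), tr, pgrid,
                                        "linear", moving_grid = fgrid))
  }
  patch
}

# fixed-size patch box centered on an ROI, clamped to the grid
patch_box <- function(roi, size, grid_shape) {
  ctr <- (roi$start + roi$end) / 2
  lo <- pmax(0L, pmin(as.integer(round(ctr - size / 2)),
                      grid_shape - size))
  roi_spec(roi$side, lo, lo + size, grid_shape)
}

#' Run the end-to-end desk-scale pipeline
#'
#' Executes the stages in order (simulate, whole-brain registration, ROI
#' determination, patch cropping, local registration, right-to-left flip,
#' cross-validation training with ModAug, ensembled prediction, evaluation),
#' failing fast within a stage but excluding subjects whose registration
#' fails (QC flag in the manifest). The manifest is written even on failure.
#'
#' @param config a [pipeline_config()].
#' @return A `run_manifest` list (also written as JSON to the run directory).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$run_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config_hash = config_hash(unclass(config)),
                   version = as.character(utils::packageVersion("mtlseg")),
                   stages = list(), qc = list(excluded = character(0)),
                   outputs = character(0))
  t_all <- proc.time()[3]
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    res <- tryCatch(list(value = force(expr), ok = TRUE),
                    error = function(e) list(value = conditionMessage(e),
                                             ok = FALSE))
    manifest$stages[[name]] <<- list(ok = res$ok,
                                     seconds = round(proc.time()[3] - t0, 2),
                                     note = if (!res$ok) res$value)
    if (!res$ok) {
      manifest$qc$failed_stage <<- name
      write_manifest(manifest, config)
      stopf("stage '%s' failed: %s", name, res$value)
    }
    res$value
  }

  subjects <- stage("simulate", {
    ids <- c(sprintf("train%02d", seq_len(config$n_train)),
             sprintf("test%02d", seq_len(config$n_test)))
    split <- rep(c("train", "test"), c(config$n_train, config$n_test))
    qualities <- with_seed(derive_seed(config$seed, "quality"), {
      q <- rep(9L, length(ids))
      q[split == "test"] <- sample(
        seq(config$test_quality_range[1], config$test_quality_range[2]),
        config$n_test, replace = TRUE)
      q
    })
    lapply(seq_along(ids), function(i) {
      side <- if (i %% 2 == 0) "right" else "left"
      s <- simulate_subject(config, ids[i], side, qualities[i],
                            derive_seed(config$seed, ids[i]))
      s$split <- split[i]
      s
    })
  })

  subjects <- stage("whole_registration", {
    lapply(subjects, function(s) {
      r <- try(register_subject(s, config), silent = TRUE)
      if (inherits(r, "try-error")) {
        manifest$qc$excluded <<- c(manifest$qc$excluded, s$subject)
        return(NULL)
      }
      r
    })
  })
  subjects <- Filter(Negate(is.null), subjects)
  if (!length(subjects)) {
    write_manifest(manifest, config)
    stopf("all subjects excluded by registration QC")
  }

  patches <- stage("roi_and_crop", {
    # template = reference phantom; its gray-matter support is the ROI mask
    tconf <- phantom_config(grid_shape = config$grid_shape,
                            spacing_mm = config$spacing_mm,
                            seed = derive_seed(config$seed, "template"))
    tmpl <- generate_phantom(tconf)
    tgrid <- grid_of(tmpl$stack)
    mask <- tmpl$labels$labels > 0
    lapply(subjects, function(s) {
      grid <- grid_of(s$stack)
      # template -> subject 3T-T1w approximated through the estimated
      # 3T-T1w matrix; the margin absorbs the affine substitute's residual
      t_3t1 <- s$est_transforms[[5]]
      m <- if (s$side == "right") {
        f <- diag(4)   # template mask is left-sided; mirror for right ROIs
        f[1, 1] <- -1
        f[1, 4] <- 2 * tgrid$origin[1] + (tgrid$shape[1] - 1) * tgrid$spacing[1]
        f
      } else diag(4)
      roi <- map_roi(mask, tgrid, invert(t_3t1)$matrix %*% m, t_3t1, grid,
                     margin_mm = 2, side = s$side)
      box <- patch_box(roi, config$patch_size, grid$shape)
      cp <- crop_patch(s$stack, box, s$labels)
      s$full_stack <- s$stack
      s$stack <- cp$stack; s$labels <- cp$labels
      s
    })
  })

  patches <- stage("local_registration", {
    lapply(patches, function(s) {
      s$stack <- local_register_patch(s$full_stack, s$stack, config)
      s$full_stack <- NULL
      s
    })
  })

  samples <- stage("flip", {
    lapply(patches, function(s) {
      if (s$side == "right") {
        fl <- flip_right_to_left(s$stack, s$labels)
        s$stack <- fl$stack; s$labels <- fl$labels
      }
      s
    })
  })

  train_samples <- Filter(function(s) s$split == "train", samples)
  test_samples <- Filter(function(s) s$split == "test", samples)

  fits <- stage("train", {
    ids <- unique(vapply(train_samples, function(s) s$subject, character(1)))
    folds <- make_folds(ids, k = min(config$n_folds, length(ids)),
                        seed = config$seed)
    cfg <- net_config(patch_size = config$patch_size,
                      epochs = config$epochs,
                      base_width = config$base_width,
                      seed = derive_seed(config$seed, "net"))
    ma <- if (config$modaug)
      modaug_config(seed = derive_seed(config$seed, "modaug"))
    lapply(seq_len(max(folds) + 1L) - 1L, function(f)
      train_fold(train_samples, folds, f, cfg, ma))
  })

  preds <- stage("predict", {
    models <- lapply(fits, `[[`, "model")
    lapply(test_samples, function(s) {
      pred <- ensemble_predict(models, s$stack)
      path <- file.path(config$run_dir,
                        sprintf("pred_%s_%s.nii", s$subject, s$side))
      write_volume(pred, path)
      manifest$outputs <<- c(manifest$outputs, path)
      list(subject = s$subject, side = s$side, pred = pred, ref = s$labels,
           quality = s$quality)
    })
  })

  eval_tab <- stage("evaluate", {
    rows <- lapply(preds, function(p) {
      # empty-label warnings are routine for barely-trained tiny presets
      vols <- suppressWarnings(subregion_volumes(p$pred))
      v <- setNames(vols$value, vols$region)
      adj <- tryCatch(tail_adjust(v), error = function(e) v[hippo_subfields()])
      data.frame(subject = p$subject, side = p$side, quality = p$quality,
                 dice_fg = mean_foreground_dice(p$pred, p$ref),
                 t(adj), check.names = FALSE)
    })
    tab <- do.call(rbind, rows)
    path <- file.path(config$run_dir, "evaluation.csv")
    write.csv(tab, path, row.names = FALSE)
    val <- do.call(rbind, lapply(fits, function(f)
      data.frame(fold = f$fold, region = names(f$val_dice),
                 dice = unname(f$val_dice))))
    vpath <- file.path(config$run_dir, "validation_dice.csv")
    write.csv(val, vpath, row.names = FALSE)
    manifest$outputs <- c(manifest$outputs, path, vpath)
    tab
  })

  manifest$seconds_total <- round(proc.time()[3] - t_all, 2)
  manifest$evaluation <- file.path(config$run_dir, "evaluation.csv")
  write_manifest(manifest, config)
  manifest$table <- eval_tab
  invisible(structure(manifest, class = "run_manifest"))
}

write_manifest <- function(manifest, config) {
  jsonlite::write_json(manifest,
                       file.path(config$run_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
}

#' Quality-control contact sheet
#'
#' Renders nine equally spaced coronal slices and two sagittal slices of the
#' primary (7T-T2w) channel with the segmentation overlaid, into one raster
#' PNG, mirroring a standard segmentation QC screenshot layout.
#'
#' @param stack a [modality_stack()].
#' @param labels a [label_map()] on the same grid (may be empty).
#' @param out_path PNG output path.
#' @return List with the `panel_count` (11) and the slice indices used,
#'   invisibly; the PNG is written to `out_path`.
#' @export
qc_contact_sheet <- function(stack, labels, out_path) {
  vol <- stack_channel(stack, 1L)
  if (!all(dim(vol) == dim(labels$labels)))
    stopf("labels must be on the stack grid")
  d <- dim(vol)
  ap <- axis_index(stack, "AP"); lr <- axis_index(stack, "LR")
  cor_idx <- round(seq(1, d[ap], length.out = 11))[2:10]  # 9-quantile interior
  sag_idx <- round(d[lr] * c(1, 2) / 3)
  rng <- range(vol)
  norm <- if (diff(rng) > 0) (vol - rng[1]) / diff(rng) else vol * 0
  pal <- grDevices::col2rgb(grDevices::rainbow(14)) / 255
  render <- function(img, lab) {
    rgb <- array(rep(img, 3), c(dim(img), 3))
    fg <- lab > 0
    for (c in 1:3) {
      ch <- rgb[, , c]
      ch[fg] <- 0.55 * ch[fg] + 0.45 * pal[c, lab[fg]]
      rgb[, , c] <- ch
    }
    rgb
  }
  panels <- c(lapply(cor_idx, function(j)
    render(norm[, j, ], labels$labels[, j, ])),
    lapply(sag_idx, function(i)
      render(norm[i, , ], labels$labels[i, , ])))
  ncol <- 4; nrow <- 3
  ph <- max(vapply(panels, function(p) dim(p)[1], integer(1)))
  pw <- max(vapply(panels, function(p) dim(p)[2], integer(1)))
  sheet <- array(0, c(nrow * ph, ncol * pw, 3))
  for (i in seq_along(panels)) {
    r <- (i - 1) %/% ncol; c0 <- (i - 1) %% ncol
    p <- panels[[i]]
    sheet[r * ph + seq_len(dim(p)[1]), c0 * pw + seq_len(dim(p)[2]), ] <- p
  }
  png::writePNG(sheet, out_path)
  invisible(list(panel_count = length(panels),
                 coronal = cor_idx, sagittal = sag_idx))
}
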