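# Pre-packaged evaluation experiments: registration recovery on noiseless
# phantoms, and the ModAug robustness comparison on a quality-split cohort.
# Both are driven entirely by the synthetic generator.

#' Rigid transform recovery experiment
#'
#' Applies random rigid perturbations to a secondary channel of a noiseless
#' phantom and registers it back to the primary, comparing the estimate with
#' the known ground truth.
#'
#' @param n_cases number of random perturbations.
#' @param grid_shape,spacing_mm phantom grid (default 64 cubed).
#' @param max_translation_vox,max_rotation_deg perturbation ranges.
#' @param tol_translation_vox,tol_rotation_deg recovery tolerances.
#' @param channel which secondary channel is perturbed and registered
#'   (2 = 7T-T1w INV1; cross-contrast NMI registration).
#' @param seed RNG seed.
#' @return List: `recovered` (fraction within tolerance), `residuals`
#'   (per-case translation mm / rotation deg), `n`.
#' @export
transform_recovery_experiment <- function(n_cases = 20,
                                          grid_shape = c(64, 64, 64),
                                          spacing_mm = c(0.5, 0.5, 0.5),
                                          max_translation_vox = 5,
                                          max_rotation_deg = 8,
                                          tol_translation_vox = 0.5,
                                          tol_rotation_deg = 1,
                                          channel = 2L, seed = 1L) {
  cfg <- phantom_config(grid_shape = grid_shape, spacing_mm = spacing_mm,
                        noise_sigma = 0, bias_field_amplitude = 0,
                        seed = derive_seed(seed, "phantom"))
  ph <- generate_phantom(cfg)
  grid <- grid_of(ph$stack)
  fixed <- stack_channel(ph$stack, 1L)
  res <- with_seed(derive_seed(seed, "cases"), {
    lapply(seq_len(n_cases), function(i) {
      par <- list(rotation_deg = runif(3, -max_rotation_deg,
                                       max_rotation_deg),
                  translation_mm = runif(3, -max_translation_vox,
                                         max_translation_vox) * grid$spacing)
      params <- vector("list", 5)
      params[[channel]] <- par
      mis <- apply_misalignment(ph$stack, params)
      est <- rigid_register(stack_channel(mis$stack, channel), fixed,
                            metric_spec("NMI"), reg_schedule(),
                            moving_grid = grid, fixed_grid = grid)
      transform_residual(est, mis$transforms[[channel]])
    })
  })
  dt <- vapply(res, `[[`, numeric(1), "translation_mm")
  dr <- vapply(res, `[[`, numeric(1), "rotation_deg")
  ok <- dt < tol_translation_vox * min(grid$spacing) & dr < tol_rotation_deg
  list(recovered = mean(ok), n = n_cases,
       residuals = data.frame(translation_mm = dt, rotation_deg = dr,
                              ok = ok))
}

# one training sample at robustness-experiment scale
robustness_sample <- function(seed, rating = 9L,
                              grid_shape = c(32, 32, 32),
                              spacing_mm = c(0.8, 0.8, 0.8)) {
  cfg <- phantom_config(grid_shape = grid_shape, spacing_mm = spacing_mm,
                        seed = seed)
  ph <- generate_phantom(cfg)
  st <- ph$stack
  if (rating < 9L) st <- degrade_primary(st, rating, seed = seed)
  list(stack = st, labels = ph$labels, subject = paste0("S", seed),
       side = "left")
}

#' ModAug robustness experiment
#'
#' For each seed replicate, trains two identically seeded networks — one
#' with ModAug, one without — on subjects with clean (rating 9) primaries,
#' then compares their mean foreground Dice on test subjects whose 7T-T2w
#' channel is degraded to poor quality (ratings <= 3). Mirrors, at desk
#' scale and directionally, the finding that a multi-modality model trained
#' with channel replacement degrades far less on poor-quality primaries.
#'
#' @param n_replicates seed replicates (each trains two models).
#' @param n_train training subjects per replicate (clean primaries).
#' @param test_ratings quality ratings of the degraded test subjects.
#' @param epochs training epochs; `base_width` network width;
#'   `patch_size` patch side.
#' @param seed base seed; replicate r uses seed `seed + r - 1`.
#' @return List: `wins` (logical per replicate), `detail` (per-replicate
#'   mean degraded-case Dice for both models), `win_fraction`.
#' @export
modaug_robustness_experiment <- function(n_replicates = 5, n_train = 4,
                                         test_ratings = c(1L, 2L, 3L),
                                         epochs = 75, base_width = 6,
                                         patch_size = 32, seed = 1L) {
  detail <- lapply(seq_len(n_replicates), function(r) {
    rs <- seed + r - 1L
    train <- lapply(rs * 100 + seq_len(n_train), robustness_sample)
    test <- lapply(seq_along(test_ratings), function(i)
      robustness_sample(rs * 100 + 50 + i, test_ratings[i]))
    cfg <- net_config(base_width = base_width, patch_size = patch_size,
                      epochs = epochs, seed = rs)
    m_plain <- train_model(train, cfg)
    m_modaug <- train_model(train, cfg, modaug_config(seed = rs))
    dice_of <- function(m, s)
      mean_foreground_dice(ensemble_predict(list(m), s$stack), s$labels)
    data.frame(
      replicate = r,
      dice_plain = mean(vapply(test, function(s) dice_of(m_plain, s),
                               numeric(1))),
      dice_modaug = mean(vapply(test, function(s) dice_of(m_modaug, s),
                                numeric(1))))
  })
  detail <- do.call(rbind, detail)
  wins <- detail$dice_modaug > detail$dice_plain
  list(wins = wins, win_fraction = mean(wins), detail = detail)
}
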