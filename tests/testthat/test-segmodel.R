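test_that("Dice+BCE loss matches closed forms and hand arithmetic", {
  # perfect hard prediction: loss vanishes up to probability clipping
  lab <- array(sample(0:2, 64, TRUE), c(4, 4, 4))
  tgt <- mtlseg:::one_hot(lab, 3)
  expect_lt(dice_bce_loss(tgt, tgt), 1e-5)
  # uniform binary 0.5 prediction, single level: BCE component is ln 2
  lab2 <- array(rep(c(0L, 1L), 32), c(4, 4, 4))
  tgt2 <- mtlseg:::one_hot(lab2, 2)
  unif <- array(0.5, c(4, 4, 4, 2))
  # hand soft-Dice: each class has sum p = 32, sum t = 32, intersection 16
  eps <- 1e-5
  hand_dice <- 1 - (2 * 16 + eps) / (64 + eps)
  expect_equal(dice_bce_loss(unif, tgt2), log(2) + hand_dice,
               tolerance = 1e-9)
  # two-voxel toy, pred (0.8, 0.2) vs target (1, 0), binary one-vs-rest
  p <- array(c(0.8, 0.2, 0.2, 0.8), c(2, 1, 1, 2))
  t <- array(c(1, 0, 0, 1), c(2, 1, 1, 2))
  hand_d <- mean(c(1 - (2 * 0.8 + eps) / (2 + eps),
                   1 - (2 * 0.8 + eps) / (2 + eps)))
  hand_bce <- -mean(log(c(0.8, 0.8, 0.8, 0.8)))
  expect_equal(dice_bce_loss(p, t), hand_d + hand_bce, tolerance = 1e-12)
  # deep supervision: weights halve per level and normalize to one
  p_half <- array(c(0.8, 0.2), c(1, 1, 1, 2))
  t_full <- mtlseg:::one_hot(array(c(0L, 0L, 1L, 1L, 0L, 0L, 1L, 1L),
                                   c(2, 2, 2)), 2)
  l_full <- dice_bce_loss(tgt_p <- t_full, t_full)
  l_two <- dice_bce_loss(list(t_full, p_half), t_full)
  l_aux <- dice_bce_loss(p_half, mtlseg:::downsample_target(t_full, 1))
  expect_equal(l_two, (2 / 3) * l_full + (1 / 3) * l_aux, tolerance = 1e-12)
  expect_error(dice_bce_loss(unif, tgt), "mismatch")
})

test_that("analytic gradients agree with finite differences", {
  ns <- asNamespace("mtlseg")
  set.seed(8)
  cfg <- net_config(in_channels = 3, n_classes = 4, depth = 2,
                    base_width = 3, patch_size = 8, seed = 7)
  params <- ns$with_seed(1, ns$init_params(cfg))
  x <- array(rnorm(8^3 * 3), c(8, 8, 8, 3))
  tgt <- ns$one_hot(array(sample(0:3, 512, TRUE), c(8, 8, 8)), 4)
  fw <- ns$net_forward(params, cfg, x, keep_cache = TRUE)
  bk <- ns$net_backward(params, cfg, fw, tgt)
  flat <- ns$flatten_params(params)
  g <- ns$flatten_params(bk$grads)
  loss_at <- function(f) {
    p <- ns$unflatten_params(f, params)
    ns$net_backward(p, cfg, ns$net_forward(p, cfg, x, TRUE), tgt)$loss
  }
  idx <- sample(length(flat), 10)
  eps <- 1e-5
  for (i in idx) {
    f1 <- flat; f1[i] <- f1[i] + eps
    f2 <- flat; f2[i] <- f2[i] - eps
    num <- (loss_at(f1) - loss_at(f2)) / (2 * eps)
    expect_equal(g[i], num, tolerance = 1e-4)
  }
})

test_that("softmax outputs are normalized probabilities", {
  ns <- asNamespace("mtlseg")
  cfg <- net_config(in_channels = 5, n_classes = 15, depth = 2,
                    base_width = 4, patch_size = 16, seed = 2)
  params <- ns$with_seed(3, ns$init_params(cfg))
  x <- array(rnorm(16^3 * 5), c(16, 16, 16, 5))
  probs <- ns$net_forward(params, cfg, x)$probs
  for (p in probs) {
    sums <- apply(p, 1:3, sum)
    expect_lt(max(abs(sums - 1)), 1e-5)
    expect_gte(min(p), 0)
  }
})

test_that("fold splits partition subjects with both sides together", {
  ids <- sprintf("P%02d", 1:25)
  folds <- make_folds(ids, k = 5, seed = 3)
  expect_setequal(names(folds), ids)
  expect_equal(as.vector(table(folds)), rep(5L, 5))    # five folds of 5
  expect_identical(folds, make_folds(ids, k = 5, seed = 3))
  expect_false(identical(folds, make_folds(ids, k = 5, seed = 4)))
  # uneven splits differ by at most one
  f2 <- make_folds(sprintf("Q%02d", 1:23), k = 5, seed = 1)
  expect_lte(diff(range(table(f2))), 1)
  expect_error(make_folds(c("a", "b"), k = 5), "fewer subjects")
  # side-level samples of one subject resolve to a single fold
  samples_subj <- rep(ids[1:5], each = 2)
  expect_equal(length(unique(folds[samples_subj[1:2]])), 1L)
})

test_that("a small network memorizes a two-subject fixture", {
  samples <- lapply(1:2, function(s) patch_phantom(s))
  cfg <- net_config(patch_size = 32, epochs = 50, standard_aug = FALSE,
                    seed = 11)
  model <- train_model(samples, cfg)
  d <- vapply(samples, function(s)
    mean_foreground_dice(ensemble_predict(list(model), s$stack), s$labels),
    numeric(1))
  expect_gt(mean(d), 0.9)
  # training loss decreases in moving average over 10-iteration windows
  ma <- stats::filter(model$history$loss, rep(1 / 10, 10), sides = 1)
  ma <- ma[!is.na(ma)]
  expect_lt(ma[length(ma)], ma[1])
  expect_lt(mean(diff(ma) > 0), 0.45)   # mostly decreasing
})

test_that("training is deterministic and logs the ModAug branch rate", {
  samples <- lapply(3:4, function(s) patch_phantom(s))
  cfg <- net_config(patch_size = 32, base_width = 4, epochs = 10, seed = 5)
  m1 <- train_model(samples, cfg)
  m2 <- train_model(samples, cfg)
  expect_identical(m1$history$loss, m2$history$loss)
  expect_identical(mtlseg:::flatten_params(m1$params),
                   mtlseg:::flatten_params(m2$params))
  expect_equal(mean(m1$history$augmented), 0)
  ma <- train_model(samples, cfg, modaug_config(seed = 2))
  frac <- mean(ma$history$augmented)     # 20 Bernoulli(0.5) draws
  expect_gte(frac, 0.2); expect_lte(frac, 0.8)
  expect_false(identical(m1$history$loss, ma$history$loss))
})

test_that("ensembling averages probabilities and respects sides", {
  ns <- asNamespace("mtlseg")
  samples <- patch_phantom(6)
  cfg <- net_config(patch_size = 32, base_width = 4, epochs = 2, seed = 9)
  m1 <- train_model(list(samples), cfg)
  cfg2 <- cfg; cfg2$seed <- 10L
  m2 <- train_model(list(samples), cfg2)
  # ensemble of the same model repeated five times = single model
  p1 <- ensemble_predict(list(m1), samples$stack)
  p5 <- ensemble_predict(rep(list(m1), 5), samples$stack)
  expect_identical(p1$labels, p5$labels)
  # two-model ensemble equals the hand-averaged argmax
  pe <- ensemble_predict(list(m1, m2), samples$stack)
  st <- ns$z_normalize_stack(samples$stack)
  pa <- ns$net_forward(m1$params, m1$config, st$channels)$probs[[1]]
  pb <- ns$net_forward(m2$params, m2$config, st$channels)$probs[[1]]
  avg <- (pa + pb) / 2
  hand <- array(max.col(matrix(avg, ncol = 15), ties.method = "first") - 1L,
                dim(samples$labels$labels))
  expect_identical(pe$labels, hand)
  # right-side input: flip in, predict, flip back equals the mirrored
  # prediction of the left-side original
  right <- flip_right_to_left(samples$stack)   # build a right-side stack
  pr <- ensemble_predict(list(m1), right, side = "right")
  n <- dim(p1$labels)[1]
  expect_identical(pr$labels, p1$labels[n:1, , , drop = FALSE])
  # channel-count contract
  bad <- samples$stack
  bad$channels <- bad$channels[, , , 1:3, drop = FALSE]
  expect_error(ensemble_predict(list(m1), bad), "channel-count")
})

test_that("cross-validation folds hold out their subjects", {
  samples <- lapply(1:4, function(s) patch_phantom(s))
  folds <- make_folds(vapply(samples, `[[`, character(1), "subject"),
                      k = 2, seed = 1)
  cfg <- net_config(patch_size = 32, base_width = 4, epochs = 4, seed = 3)
  res <- train_fold(samples, folds, 0L, cfg)
  expect_s3_class(res$model, "seg_model")
  expect_true(all(res$val_dice >= 0 & res$val_dice <= 1))
  expect_true(length(res$val_dice) >= 1)
})

test_that("model checkpoints round-trip through JSON", {
  samples <- patch_phantom(7)
  cfg <- net_config(patch_size = 32, base_width = 4, epochs = 2, seed = 4)
  model <- train_model(list(samples), cfg)
  f <- tempfile(fileext = ".json")
  save_model(model, f)
  loaded <- load_model(f)
  expect_equal(mtlseg:::flatten_params(loaded$params),
               mtlseg:::flatten_params(model$params))
  expect_identical(ensemble_predict(list(loaded), samples$stack)$labels,
                   ensemble_predict(list(model), samples$stack)$labels)
})

test_that("network configuration contracts hold", {
  expect_error(net_config(patch_size = 30, depth = 3), "divisible")
  expect_error(net_config(deep_supervision_levels = 2, depth = 2),
               "deep_supervision")
  expect_error(net_config(depth = 1), "depth")
})
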