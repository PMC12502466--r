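# Small 3D encoder-decoder segmentation network with deep supervision,
# trained with a combined soft-Dice + binary cross-entropy loss. The
# backbone is a fixed plain U-Net (two 3x3x3 convolutions per encoder level,
# nearest-neighbor upsampling with skip concatenation, 1x1x1 class heads);
# forward, backward and the Adam optimizer are implemented here, with the
# convolution kernels in compiled code.

#' Network configuration
#'
#' @param in_channels input channels (5 modality channels).
#' @param n_classes label count including background.
#' @param depth number of resolution levels (encoder depth; >= 2).
#' @param base_width feature maps at full resolution; width doubles per
#'   level.
#' @param deep_supervision_levels number of auxiliary outputs (at the coarser
#'   decoder levels); must be `< depth`. Level weights halve per level and
#'   are normalized to sum 1.
#' @param patch_size cubic patch side in voxels; divisible by
#'   `2^(depth - 1)`.
#' @param epochs training epochs (desk-scale default; the full-scale regime
#'   of the protocol this mirrors runs 400).
#' @param lr Adam learning rate; `lr_decay` multiplies it at 60% and 85% of
#'   the epochs.
#' @param standard_aug apply the reduced standard augmentation (random
#'   non-L-R flips and mild intensity jitter) during training.
#' @param seed integer seed controlling initialization and data ordering.
#' @return A `net_config` list.
#' @export
net_config <- function(in_channels = 5L, n_classes = 15L, depth = 2L,
                       base_width = 8L, deep_supervision_levels = 1L,
                       patch_size = 32L, epochs = 20L, lr = 0.02,
                       lr_decay = 0.5, standard_aug = TRUE, seed = 1L) {
  if (depth < 2L) stopf("depth must be >= 2")
  if (patch_size %% (2^(depth - 1)) != 0)
    stopf("patch_size must be divisible by 2^(depth-1)")
  if (deep_supervision_levels >= depth)
    stopf("deep_supervision_levels must be < depth")
  structure(list(in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes), depth = as.integer(depth),
                 base_width = as.integer(base_width),
                 deep_supervision_levels = as.integer(deep_supervision_levels),
                 patch_size = as.integer(patch_size),
                 epochs = as.integer(epochs), lr = lr, lr_decay = lr_decay,
                 standard_aug = isTRUE(standard_aug),
                 seed = as.integer(seed)),
            class = "net_config")
}

# leaky rectifier (slope 0.01): avoids dead units at desk-scale widths
relu <- function(x) x * (0.01 + 0.99 * (x > 0))
relu_grad <- function(z) 0.01 + 0.99 * (z > 0)

conv3 <- function(x, d, cin, w, b, cout) {
  y <- cpp_conv3_fwd(x, d, cin, w, b, cout)
  dim(y) <- c(d, cout)
  y
}

avgpool2 <- function(x) {
  d <- dim(x)
  i <- seq(1, d[1], 2); j <- seq(1, d[2], 2); k <- seq(1, d[3], 2)
  (x[i, j, k, , drop = FALSE] + x[i + 1, j, k, , drop = FALSE] +
     x[i, j + 1, k, , drop = FALSE] + x[i + 1, j + 1, k, , drop = FALSE] +
     x[i, j, k + 1, , drop = FALSE] + x[i + 1, j, k + 1, , drop = FALSE] +
     x[i, j + 1, k + 1, , drop = FALSE] +
     x[i + 1, j + 1, k + 1, , drop = FALSE]) / 8
}

upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2),
    rep(seq_len(d[3]), each = 2), , drop = FALSE]
}

# transpose of upsample2: sum over each 2x2x2 block
sumpool2 <- function(x) avgpool2(x) * 8

# transpose of avgpool2: spread the gradient evenly over the block
unpool_avg <- function(g) upsample2(g) / 8

init_params <- function(cfg) {
  he <- function(dims, fan_in) array(rnorm(prod(dims), 0, sqrt(2 / fan_in)),
                                     dim = dims)
  widths <- cfg$base_width * 2^(seq_len(cfg$depth) - 1)
  enc <- vector("list", cfg$depth)
  cin <- cfg$in_channels
  for (l in seq_len(cfg$depth)) {
    w <- widths[l]
    enc[[l]] <- list(w1 = he(c(3, 3, 3, cin, w), 27 * cin), b1 = rep(0, w),
                     w2 = he(c(3, 3, 3, w, w), 27 * w), b2 = rep(0, w))
    cin <- w
  }
  dec <- vector("list", cfg$depth - 1)
  for (l in seq_len(cfg$depth - 1)) {
    cin <- widths[l] + widths[l + 1]
    dec[[l]] <- list(w = he(c(3, 3, 3, cin, widths[l]), 27 * cin),
                     b = rep(0, widths[l]))
  }
  head <- list(w = he(c(widths[1], cfg$n_classes), widths[1]),
               b = rep(0, cfg$n_classes))
  aux <- vector("list", cfg$deep_supervision_levels)
  for (j in seq_len(cfg$deep_supervision_levels))
    aux[[j]] <- list(w = he(c(widths[j + 1], cfg$n_classes), widths[j + 1]),
                     b = rep(0, cfg$n_classes))
  list(enc = enc, dec = dec, head = head, aux = aux, widths = widths)
}

conv1x1 <- function(x, w, b) {
  d <- dim(x)
  y <- matrix(x, prod(d[1:3]), d[4]) %*% w
  y <- sweep(y, 2, b, `+`)
  array(y, c(d[1:3], ncol(w)))
}

softmax4 <- function(z) {
  d <- dim(z)
  p <- cpp_softmax(z, prod(d[1:3]), d[4])
  dim(p) <- d
  p
}

# forward pass; returns per-level class probabilities and (optionally) the
# cache of intermediates needed for the backward pass
net_forward <- function(params, cfg, x, keep_cache = FALSE) {
  d0 <- dim(x)[1:3]
  cache <- list(x = x)
  enc_out <- vector("list", cfg$depth)
  pre <- list()
  cur <- x
  for (l in seq_len(cfg$depth)) {
    p <- params$enc[[l]]
    d <- dim(cur)[1:3]
    z1 <- conv3(cur, d, dim(cur)[4], p$w1, p$b1, dim(p$w1)[5])
    a1 <- relu(z1)
    z2 <- conv3(a1, d, dim(a1)[4], p$w2, p$b2, dim(p$w2)[5])
    a2 <- relu(z2)
    pre[[l]] <- list(input = cur, z1 = z1, a1 = a1, z2 = z2)
    enc_out[[l]] <- a2
    if (l < cfg$depth) cur <- avgpool2(a2)
  }
  dec_feat <- vector("list", cfg$depth)
  dec_feat[[cfg$depth]] <- enc_out[[cfg$depth]]
  dec_pre <- list()
  for (l in rev(seq_len(cfg$depth - 1))) {
    up <- upsample2(dec_feat[[l + 1]])
    cat4 <- array(c(up, enc_out[[l]]),
                  c(dim(up)[1:3], dim(up)[4] + dim(enc_out[[l]])[4]))
    p <- params$dec[[l]]
    z <- conv3(cat4, dim(cat4)[1:3], dim(cat4)[4], p$w, p$b, dim(p$w)[5])
    dec_pre[[l]] <- list(cat = cat4, z = z, n_up = dim(up)[4])
    dec_feat[[l]] <- relu(z)
  }
  logits <- list(conv1x1(dec_feat[[1]], params$head$w, params$head$b))
  for (j in seq_len(cfg$deep_supervision_levels))
    logits[[j + 1]] <- conv1x1(dec_feat[[j + 1]], params$aux[[j]]$w,
                               params$aux[[j]]$b)
  probs <- lapply(logits, softmax4)
  if (!keep_cache) return(list(probs = probs))
  list(probs = probs,
       cache = list(pre = pre, enc_out = enc_out, dec_pre = dec_pre,
                    dec_feat = dec_feat))
}

# soft-Dice + one-vs-rest BCE loss and gradient wrt probabilities
dice_bce_terms <- function(p, t, want_grad = FALSE) {
  eps <- 1e-5
  d <- dim(p); C <- d[4]
  pm <- matrix(p, ncol = C); tm <- matrix(t, ncol = C)
  inter <- colSums(pm * tm); sp <- colSums(pm); st <- colSums(tm)
  dice_c <- 1 - (2 * inter + eps) / (sp + st + eps)
  pc <- pmin(1 - 1e-7, pmax(1e-7, pm))
  n <- nrow(pm)
  bce <- -sum(tm * log(pc) + (1 - tm) * log(1 - pc)) / (n * C)
  loss <- mean(dice_c) + bce
  if (!want_grad) return(list(loss = loss))
  denom <- (sp + st + eps)
  g_dice <- -(2 * sweep(tm, 2, denom, `*`) -
                sweep(matrix(1, n, C), 2, 2 * inter + eps, `*`)) /
    matrix(denom^2, n, C, byrow = TRUE) / C
  g_bce <- (-tm / pc + (1 - tm) / (1 - pc)) / (n * C)
  list(loss = loss, grad_p = array(g_dice + g_bce, d))
}

softmax_backward <- function(p, g) {
  d <- dim(p)
  pm <- matrix(p, ncol = d[4]); gm <- matrix(g, ncol = d[4])
  array(pm * (gm - rowSums(gm * pm)), d)
}

# downsample a (soft) one-hot target by block averaging, `times` halvings
downsample_target <- function(t, times) {
  for (i in seq_len(times)) t <- avgpool2(t)
  t
}

#' Combined Dice + BCE deep-supervision loss
#'
#' `loss = sum_l w_l (softDice_l + BCE_l)`, where level l targets are
#' block-averaged to the level's resolution, and the level weights halve per
#' level and are normalized to sum 1. BCE is one-vs-rest binary
#' cross-entropy per class, with probabilities clipped at 1e-7.
#'
#' @param pred 4D probability array `(x,y,z,class)` or list of such arrays,
#'   finest level first, each level half the resolution of the previous.
#' @param target one-hot 4D array at full resolution.
#' @param level_weights optional explicit weights (normalized internally).
#' @return Scalar loss.
#' @export
dice_bce_loss <- function(pred, target, level_weights = NULL) {
  if (!is.list(pred)) pred <- list(pred)
  L <- length(pred)
  if (is.null(level_weights)) level_weights <- 2^-(seq_len(L) - 1)
  w <- level_weights / sum(level_weights)
  if (any(abs(dim(pred[[1]]) - dim(target)) > 0))
    stopf("prediction/target shape mismatch")
  total <- 0
  for (l in seq_len(L)) {
    t_l <- downsample_target(target, l - 1L)
    if (!all(dim(pred[[l]]) == dim(t_l)))
      stopf("prediction/target shape mismatch at level %d", l)
    total <- total + w[l] * dice_bce_terms(pred[[l]], t_l)$loss
  }
  total
}

one_hot <- function(labels, n_classes) {
  d <- dim(labels)
  oh <- array(0, c(d, n_classes))
  m <- matrix(oh, ncol = n_classes)
  m[cbind(seq_along(labels), as.integer(labels) + 1L)] <- 1
  array(m, c(d, n_classes))
}

# full backward pass; returns gradients in the same structure as params
net_backward <- function(params, cfg, fw, target) {
  probs <- fw$probs; cache <- fw$cache
  L <- length(probs)
  w <- 2^-(seq_len(L) - 1); w <- w / sum(w)
  loss <- 0
  g_feat <- vector("list", cfg$depth)   # grads wrt dec_feat per level
  grads <- list(enc = vector("list", cfg$depth),
                dec = vector("list", cfg$depth - 1),
                head = NULL, aux = vector("list", length(params$aux)))
  for (l in seq_len(L)) {
    t_l <- downsample_target(target, l - 1L)
    d_l <- dim(probs[[l]])
    res <- cpp_dice_bce_softmax_grad(probs[[l]], t_l,
                                     prod(d_l[1:3]), d_l[4], w[l])
    loss <- loss + w[l] * res[1]
    g_logit <- res[-1]
    dim(g_logit) <- d_l
    feat <- cache$dec_feat[[l]]
    d <- dim(feat)
    gm <- matrix(g_logit, ncol = dim(g_logit)[4])
    fm <- matrix(feat, ncol = d[4])
    hw <- if (l == 1) params$head$w else params$aux[[l - 1]]$w
    gW <- crossprod(fm, gm)
    gb <- colSums(gm)
    gf <- array(gm %*% t(hw), d)
    if (l == 1) grads$head <- list(w = gW, b = gb)
    else grads$aux[[l - 1]] <- list(w = gW, b = gb)
    g_feat[[l]] <- if (is.null(g_feat[[l]])) gf else g_feat[[l]] + gf
  }
  for (l in seq_len(cfg$depth)) if (is.null(g_feat[[l]]))
    g_feat[[l]] <- array(0, dim(cache$dec_feat[[l]]))
  # decoder backward, fine to coarse accumulation
  g_enc_out <- vector("list", cfg$depth)
  for (l in seq_len(cfg$depth - 1)) {
    dp <- cache$dec_pre[[l]]
    gz <- g_feat[[l]] * relu_grad(dp$z)
    d <- dim(dp$cat)
    grads$dec[[l]] <- local({
      g <- cpp_conv3_bwd_w(dp$cat, gz, d[1:3], d[4],
                           dim(gz)[4])
      nw <- 27 * d[4] * dim(gz)[4]
      list(w = array(g[seq_len(nw)], c(3, 3, 3, d[4], dim(gz)[4])),
           b = g[nw + seq_len(dim(gz)[4])])
    })
    gcat <- cpp_conv3_bwd_input(gz, d[1:3], d[4], params$dec[[l]]$w,
                                dim(gz)[4])
    dim(gcat) <- d
    n_up <- dp$n_up
    g_up <- gcat[, , , seq_len(n_up), drop = FALSE]
    g_enc_out[[l]] <- gcat[, , , n_up + seq_len(d[4] - n_up), drop = FALSE]
    g_feat[[l + 1]] <- g_feat[[l + 1]] + sumpool2(g_up)
  }
  g_enc_out[[cfg$depth]] <- g_feat[[cfg$depth]]
  # encoder backward, deep to shallow
  g_next_input <- NULL
  for (l in rev(seq_len(cfg$depth))) {
    g_out <- g_enc_out[[l]]
    if (!is.null(g_next_input)) g_out <- g_out + unpool_avg(g_next_input)
    pr <- cache$pre[[l]]
    d <- dim(pr$a1)[1:3]
    gz2 <- g_out * relu_grad(pr$z2)
    c1 <- dim(pr$a1)[4]; c2 <- dim(gz2)[4]
    g2 <- cpp_conv3_bwd_w(pr$a1, gz2, d, c1, c2)
    ga1 <- cpp_conv3_bwd_input(gz2, d, c1, params$enc[[l]]$w2, c2)
    dim(ga1) <- dim(pr$a1)
    gz1 <- ga1 * relu_grad(pr$z1)
    c0 <- dim(pr$input)[4]
    g1 <- cpp_conv3_bwd_w(pr$input, gz1, d, c0, c1)
    gx <- cpp_conv3_bwd_input(gz1, d, c0, params$enc[[l]]$w1, c1)
    dim(gx) <- dim(pr$input)
    n1 <- 27 * c0 * c1; n2 <- 27 * c1 * c2
    grads$enc[[l]] <- list(
      w1 = array(g1[seq_len(n1)], c(3, 3, 3, c0, c1)),
      b1 = g1[n1 + seq_len(c1)],
      w2 = array(g2[seq_len(n2)], c(3, 3, 3, c1, c2)),
      b2 = g2[n2 + seq_len(c2)])
    g_next_input <- if (l > 1) gx else NULL
  }
  list(loss = loss, grads = grads)
}

# flatten/unflatten parameter trees for the optimizer
flatten_params <- function(p) {
  unlist(list(p$enc, p$dec, p$head, p$aux), use.names = FALSE)
}

unflatten_params <- function(flat, template) {
  pos <- 0L
  fill <- function(x) {
    if (is.list(x)) return(lapply(x, fill))
    n <- length(x)
    out <- flat[pos + seq_len(n)]
    pos <<- pos + n
    if (!is.null(dim(x))) dim(out) <- dim(x)
    out
  }
  out <- template
  out$enc <- fill(template$enc)
  out$dec <- fill(template$dec)
  out$head <- fill(template$head)
  out$aux <- fill(template$aux)
  out
}

z_normalize_stack <- function(stack) {
  for (ch in seq_len(n_channels(stack))) {
    v <- stack_channel(stack, ch)
    s <- sd(v)
    if (!is.finite(s) || s < 1e-8) s <- 1
    stack <- set_stack_channel(stack, ch, (v - mean(v)) / s)
  }
  stack
}

# random flips along the non-left-right axes plus mild intensity jitter;
# the reduced "standard" augmentation surface
standard_augment <- function(x, labels) {
  for (ax in 2:3) {
    if (runif(1) < 0.5) {
      idx <- rev(seq_len(dim(x)[ax]))
      if (ax == 2) { x <- x[, idx, , , drop = FALSE]
                     labels <- labels[, idx, , drop = FALSE] }
      else         { x <- x[, , idx, , drop = FALSE]
                     labels <- labels[, , idx, drop = FALSE] }
    }
  }
  for (ch in seq_len(dim(x)[4]))
    x[, , , ch] <- x[, , , ch] * runif(1, 0.95, 1.05) + runif(1, -0.05, 0.05)
  list(x = x, labels = labels)
}

#' Split subjects into cross-validation folds
#'
#' Folds partition subjects (not patches): both sides of a subject stay in
#' the same fold. Deterministic given the seed; fold sizes differ by at most
#' one.
#'
#' @param subject_ids character vector of unique subject ids.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return A `fold_split`: named integer vector mapping subject id to fold
#'   index in `0..k-1`.
#' @export
make_folds <- function(subject_ids, k = 5L, seed = 1L) {
  subject_ids <- unique(as.character(subject_ids))
  if (length(subject_ids) < k) stopf("fewer subjects than folds")
  with_seed(derive_seed(seed, "folds"), {
    perm <- sample(subject_ids)
    folds <- setNames(rep(seq_len(k) - 1L, length.out = length(perm)), perm)
    structure(folds[subject_ids], class = "fold_split")
  })
}

new_seg_model <- function(cfg) {
  params <- with_seed(derive_seed(cfg$seed, "init"), init_params(cfg))
  structure(list(config = cfg, params = params), class = "seg_model")
}

#' @export
print.seg_model <- function(x, ...) {
  cat(sprintf("seg_model: depth %d, base width %d, %d classes, %d params\n",
              x$config$depth, x$config$base_width, x$config$n_classes,
              length(flatten_params(x$params))))
  invisible(x)
}

#' Train a segmentation model on a set of samples
#'
#' One training iteration processes one patch: per-channel z-normalization,
#' the reduced standard augmentation (random non-L-R flips, intensity
#' jitter), an optional ModAug plan, then a forward/backward pass and an
#' Adam update of the deep-supervision Dice+BCE loss.
#'
#' @param samples list of training samples, each
#'   `list(stack = modality_stack, labels = label_map, subject =, side =)`;
#'   patches must be pre-cropped and right sides pre-flipped to the left.
#' @param cfg a [net_config()].
#' @param modaug a [modaug_config()], or `NULL` to disable ModAug.
#' @return A `seg_model` with fields `params`, `config`, `history`
#'   (per-iteration loss and augmentation flags).
#' @export
train_model <- function(samples, cfg, modaug = NULL) {
  stopifnot(length(samples) >= 1L)
  model <- new_seg_model(cfg)
  flat <- flatten_params(model$params)
  m <- v <- numeric(length(flat))
  adam_t <- 0
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  history <- list(loss = numeric(0), augmented = logical(0))
  donors <- if (!is.null(modaug) && modaug$filler == "donor_image")
    samples else NULL
  with_seed(derive_seed(cfg$seed, "train"), {
    for (epoch in seq_len(cfg$epochs)) {
      lr <- cfg$lr
      if (epoch > 0.85 * cfg$epochs) lr <- lr * cfg$lr_decay^2
      else if (epoch > 0.6 * cfg$epochs) lr <- lr * cfg$lr_decay
      for (si in sample(seq_along(samples))) {
        smp <- samples[[si]]
        st <- z_normalize_stack(smp$stack)
        aug <- if (cfg$standard_aug)
          standard_augment(st$channels, smp$labels$labels)
        else list(x = st$channels, labels = smp$labels$labels)
        x <- aug$x
        augmented <- FALSE
        if (!is.null(modaug)) {
          plan <- sample_plan(modaug)
          augmented <- plan$augmented
          if (augmented) {
            tmp <- st; tmp$channels <- x
            donor <- if (!is.null(donors))
              z_normalize_stack(donors[[sample.int(length(donors), 1)]]$stack)
            tmp <- apply_plan(tmp, plan, donor = donor)
            x <- tmp$channels
          }
        }
        params <- unflatten_params(flat, model$params)
        fw <- net_forward(params, cfg, x, keep_cache = TRUE)
        tgt <- one_hot(aug$labels, cfg$n_classes)
        bk <- net_backward(params, cfg, fw, tgt)
        if (!is.finite(bk$loss)) stopf("training failure: non-finite loss")
        g <- flatten_params(bk$grads)
        gn <- sqrt(sum(g^2))            # global-norm gradient clipping
        if (gn > 5) g <- g * (5 / gn)
        adam_t <- adam_t + 1
        m <- b1 * m + (1 - b1) * g
        v <- b2 * v + (1 - b2) * g^2
        mh <- m / (1 - b1^adam_t)
        vh <- v / (1 - b2^adam_t)
        flat <- flat - lr * mh / (sqrt(vh) + eps)
        history$loss <- c(history$loss, bk$loss)
        history$augmented <- c(history$augmented, augmented)
      }
    }
  })
  model$params <- unflatten_params(flat, model$params)
  model$history <- history
  model
}

#' Train one cross-validation fold
#'
#' Trains on the subjects outside `fold` and reports per-class Dice on the
#' held-out fold.
#'
#' @param samples training samples (see [train_model()]).
#' @param folds a [make_folds()] split.
#' @param fold held-out fold index.
#' @param cfg a [net_config()]; `modaug` a [modaug_config()] or `NULL`.
#' @return List `model`, `val_dice` (named per-class mean Dice over held-out
#'   samples), `fold`.
#' @export
train_fold <- function(samples, folds, fold, cfg, modaug = NULL) {
  subj <- vapply(samples, function(s) s$subject, character(1))
  in_train <- folds[subj] != fold
  if (!any(in_train) || all(in_train)) stopf("fold split leaves no train/val data")
  model <- train_model(samples[in_train], cfg, modaug)
  val <- samples[!in_train]
  classes <- sort(unique(unlist(lapply(val, function(s)
    setdiff(unique(as.vector(s$labels$labels)), 0L)))))
  per_class <- sapply(val, function(s) {
    pred <- ensemble_predict(list(model), s$stack)
    vapply(classes, function(l) dice(pred$labels, s$labels$labels, l),
           numeric(1))
  })
  per_class <- matrix(per_class, nrow = length(classes))
  lab_names <- names(mtl_labels())[match(classes, mtl_labels())]
  list(model = model, fold = fold,
       val_dice = setNames(rowMeans(per_class), lab_names))
}

#' Ensembled inference
#'
#' Averages per-class probabilities across models and takes the per-voxel
#' argmax. Right-side inputs are flipped to the left before inference and
#' the predicted labels flipped back. ModAug is never applied at inference:
#' the full stack is always used.
#'
#' @param models list of `seg_model`s (>= 1), identical configs.
#' @param stack a [modality_stack()] patch.
#' @param side `"left"` or `"right"`.
#' @return A [label_map()] on the input grid.
#' @export
ensemble_predict <- function(models, stack, side = "left") {
  stopifnot(length(models) >= 1L)
  cfg <- models[[1]]$config
  if (n_channels(stack) != cfg$in_channels)
    stopf("channel-count mismatch: stack has %d, model expects %d",
          n_channels(stack), cfg$in_channels)
  flipped <- identical(side, "right")
  st <- if (flipped) flip_right_to_left(stack) else stack
  st <- z_normalize_stack(st)
  acc <- NULL
  for (mdl in models) {
    pr <- net_forward(mdl$params, mdl$config, st$channels)$probs[[1]]
    acc <- if (is.null(acc)) pr else acc + pr
  }
  acc <- acc / length(models)
  lab <- array(max.col(matrix(acc, ncol = dim(acc)[4]), ties.method = "first")
               - 1L, dim = dim(acc)[1:3])
  grid <- grid3(dim(lab), stack$spacing, stack$origin)
  lm <- label_map(lab, grid)
  if (flipped) {
    lm$labels <- lm$labels[rev(seq_len(dim(lab)[1])), , , drop = FALSE]
  }
  lm
}

#' Save / load a model as a JSON checkpoint with config sidecar
#'
#' Parameters are stored as a flat numeric vector alongside the architecture
#' config, seed and class map; plain text, portable.
#'
#' @param model a `seg_model`; `path` output file.
#' @return `load_model` returns the `seg_model`.
#' @export
save_model <- function(model, path) {
  obj <- list(config = unclass(model$config),
              class_map = as.list(mtl_labels()),
              params = flatten_params(model$params))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(net_config, obj$config[setdiff(names(obj$config), NULL)])
  model <- new_seg_model(cfg)
  model$params <- unflatten_params(as.numeric(obj$params), model$params)
  model
}
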