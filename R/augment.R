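# Modality augmentation (ModAug): during training, with probability
# p_augment an input enters the augmentation branch, where k of the five
# channels (k in 1..4, never all five) are replaced by filler content, so
# the network cannot over-rely on the primary channel. Inference always uses
# the full stack.

#' ModAug configuration
#'
#' @param p_augment probability of entering the augmentation branch
#'   (default 0.5).
#' @param k_weights probability weights over the number of replaced channels
#'   k in 1..4 (default uniform: each sub-branch equally likely).
#' @param filler `"gaussian_noise"` (i.i.d. standard normal on the
#'   z-normalized intensity scale), `"zeros"`, or `"donor_image"` (channels
#'   copied from another participant).
#' @param protect_primary if `TRUE`, channel 1 (7T-T2w) is never replaced.
#' @param seed integer seed for the plan stream.
#' @return A `modaug_config` list.
#' @export
modaug_config <- function(p_augment = 0.5, k_weights = rep(1, 4),
                          filler = c("gaussian_noise", "zeros", "donor_image"),
                          protect_primary = FALSE, seed = 1L) {
  filler <- match.arg(filler)
  if (p_augment < 0 || p_augment > 1) stopf("p_augment must be in [0, 1]")
  if (length(k_weights) != 4L || any(k_weights < 0) || sum(k_weights) <= 0)
    stopf("k_weights must be 4 non-negative weights")
  structure(list(p_augment = p_augment,
                 k_weights = k_weights / sum(k_weights), filler = filler,
                 protect_primary = isTRUE(protect_primary),
                 seed = as.integer(seed)),
            class = "modaug_config")
}

#' Draw one augmentation plan
#'
#' Samples the branch flag, the number of replaced channels k (1..4) and a
#' uniformly drawn channel subset of size k among the eligible channels.
#' At least one channel always survives.
#'
#' @param config a [modaug_config()].
#' @return An `aug_plan` list: `augmented`, `replaced_channels` (1-based
#'   indices, empty when not augmented), `filler`.
#' @export
sample_plan <- function(config) {
  stopifnot(inherits(config, "modaug_config"))
  augmented <- runif(1) < config$p_augment
  replaced <- integer(0)
  if (augmented) {
    k <- sample.int(4L, 1L, prob = config$k_weights)
    eligible <- if (config$protect_primary) 2:5 else 1:5
    if (k > length(eligible)) stopf("k exceeds the eligible channel count")
    replaced <- sort(eligible[sample.int(length(eligible), k)])
  }
  structure(list(augmented = augmented, replaced_channels = replaced,
                 filler = config$filler),
            class = "aug_plan")
}

#' Apply an augmentation plan to a stack
#'
#' Replaced channels are overwritten by the plan's filler; unreplaced
#' channels are returned bit-identical.
#'
#' @param stack a [modality_stack()] (z-normalized patches during training).
#' @param plan an `aug_plan` from [sample_plan()].
#' @param donor donor [modality_stack()], required iff the filler is
#'   `"donor_image"`.
#' @return The augmented stack.
#' @export
apply_plan <- function(stack, plan, donor = NULL) {
  stopifnot(inherits(plan, "aug_plan"))
  if (!length(plan$replaced_channels)) return(stack)
  if (length(plan$replaced_channels) >= n_channels(stack))
    stopf("a plan may never replace every channel")
  if (plan$filler == "donor_image" && is.null(donor))
    stopf("donor stack required for the donor_image filler")
  d <- dim(stack$channels)[1:3]
  for (ch in plan$replaced_channels) {
    filler <- switch(plan$filler,
                     gaussian_noise = array(rnorm(prod(d)), dim = d),
                     zeros = array(0, dim = d),
                     donor_image = stack_channel(donor, ch))
    stack <- set_stack_channel(stack, ch, filler)
  }
  stack
}

#' Mirror a stack (and labels) across the left-right axis
#'
#' Right-side ROIs are flipped to the left before entering the network so a
#' single model serves both sides; predictions for right-side inputs are
#' flipped back. The flip is applied identically to all channels and labels;
#' label codes are unchanged. The left-right axis is identified from grid
#' metadata and must be unambiguous.
#'
#' @param stack a [modality_stack()].
#' @param labels optional [label_map()].
#' @return The flipped stack, or `list(stack, labels)` when labels are given.
#' @export
flip_right_to_left <- function(stack, labels = NULL) {
  lr <- axis_index(stack, "LR")
  n <- dim(stack$channels)[lr]
  idx <- rev(seq_len(n))
  flip_arr <- function(a) {
    stopifnot(lr == 1L)  # axis convention: LR is the first axis
    if (length(dim(a)) == 4L) a[idx, , , , drop = FALSE]
    else a[idx, , , drop = FALSE]
  }
  stack$channels <- flip_arr(stack$channels)
  if (is.null(labels)) return(stack)
  labels$labels <- flip_arr(labels$labels)
  list(stack = stack, labels = labels)
}
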