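#' Fixed channel order of the multi-modality input stack
#'
#' The five co-registered channels, in the order the segmentation network
#' consumes them: the primary 7T-T2w contrast, the two 7T MP2RAGE inversion
#' contrasts, the dedicated partial-coverage 3T-T2w scan and the whole-brain
#' 3T-T1w scan. The order is a pipeline-wide constant.
#'
#' @return Character vector of length 5.
#' @export
mtl_channels <- function() {
  c("7T-T2w", "7T-T1w-INV1", "7T-T1w-INV2", "3T-T2w", "3T-T1w")
}

#' Label codes of the MTL segmentation protocol
#'
#' Integer codes for the hippocampal subfields (CA1-3, DG, SUB, Tail), the
#' extra-hippocampal cortical subregions (ERC, BA35, BA36, PHC) and the
#' non-gray-matter bookkeeping labels (HS, CS, Cysts, MISC), with 0 as
#' background.
#'
#' @return Named integer vector.
#' @export
mtl_labels <- function() {
  c(background = 0L, CA1 = 1L, CA2 = 2L, CA3 = 3L, DG = 4L, SUB = 5L,
    Tail = 6L, ERC = 7L, BA35 = 8L, BA36 = 9L, PHC = 10L, HS = 11L,
    CS = 12L, Cysts = 13L, MISC = 14L)
}

#' Gray-matter subset of the label protocol
#' @return Named integer vector (subfields plus cortical subregions).
#' @export
mtl_gm_labels <- function() {
  mtl_labels()[c("CA1", "CA2", "CA3", "DG", "SUB", "Tail",
                 "ERC", "BA35", "BA36", "PHC")]
}

hippo_subfields <- function() c("CA1", "CA2", "CA3", "DG", "SUB")
cortical_regions <- function() c("ERC", "BA35", "BA36", "PHC")

# Axis convention: axis 1 = left-right, axis 2 = anterior-posterior,
# axis 3 = inferior-superior.
mtl_axes <- function() c("LR", "AP", "IS")

#' Image grid descriptor
#'
#' @param shape integer voxel counts per axis (length 3).
#' @param spacing physical voxel spacing in mm per axis.
#' @param origin physical coordinate (mm) of voxel (0,0,0).
#' @return A `grid3` list with `shape`, `spacing`, `origin`, `axes`.
#' @export
grid3 <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stopf("grid shape must be 3 positive integers")
  if (any(spacing <= 0)) stopf("spacing must be positive")
  structure(list(shape = shape, spacing = as.double(spacing),
                 origin = as.double(origin), axes = mtl_axes()),
            class = "grid3")
}

grid_of <- function(x) {
  grid3(dim(x$channels)[1:3] %||% dim(x)[1:3], x$spacing, x$origin)
}

# physical coordinate of a 0-based voxel index
voxel_to_phys <- function(grid, index) grid$origin + index * grid$spacing

#' Multi-modality image stack
#'
#' Bundles the five channel volumes on a common grid. Channels are stored as
#' a 4D array `(x, y, z, channel)` in the fixed [mtl_channels()] order.
#'
#' @param channels 4D numeric array with 5 channels, or list of five 3D
#'   arrays of identical dimension.
#' @param grid a [grid3()] describing the common voxel grid.
#' @return A `modality_stack` object.
#' @export
modality_stack <- function(channels, grid) {
  if (is.list(channels)) {
    dims <- unique(lapply(channels, dim))
    if (length(dims) != 1L) stopf("channels must share one grid")
    channels <- array(unlist(channels, use.names = FALSE),
                      dim = c(dims[[1]], length(channels)))
  }
  if (length(dim(channels)) != 4L)
    stopf("channels must be a 4D array (x, y, z, channel)")
  if (!all(dim(channels)[1:3] == grid$shape))
    stopf("channel dimensions disagree with the grid")
  structure(list(channels = channels, spacing = grid$spacing,
                 origin = grid$origin, axes = grid$axes,
                 channel_names = mtl_channels()[seq_len(dim(channels)[4])]),
            class = "modality_stack")
}

#' @export
print.modality_stack <- function(x, ...) {
  cat(sprintf("modality_stack: %s voxels, spacing %s mm, %d channels\n",
              paste(dim(x$channels)[1:3], collapse = "x"),
              paste(format(x$spacing, digits = 3), collapse = "x"),
              dim(x$channels)[4]))
  invisible(x)
}

n_channels <- function(stack) dim(stack$channels)[4]

stack_channel <- function(stack, ch) stack$channels[, , , ch, drop = TRUE]

set_stack_channel <- function(stack, ch, vol) {
  stack$channels[, , , ch] <- vol
  stack
}

#' Integer label volume
#'
#' @param labels integer 3D array over the [mtl_labels()] codes.
#' @param grid a [grid3()].
#' @return A `label_map` object.
#' @export
label_map <- function(labels, grid) {
  if (length(dim(labels)) != 3L) stopf("labels must be a 3D array")
  if (!all(dim(labels) == grid$shape))
    stopf("label dimensions disagree with the grid")
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), unname(mtl_labels()))
  if (length(bad)) stopf("undeclared label codes: %s",
                         paste(bad, collapse = ", "))
  structure(list(labels = labels, spacing = grid$spacing,
                 origin = grid$origin, axes = grid$axes),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("label_map: %s voxels, %d foreground voxels\n",
              paste(dim(x$labels), collapse = "x"), sum(x$labels > 0L)))
  invisible(x)
}

# index of the named anatomical axis in grid metadata; errors if ambiguous
axis_index <- function(obj, axis = "LR") {
  axes <- obj$axes
  if (is.null(axes) || sum(axes == axis, na.rm = TRUE) != 1L)
    stopf("grid metadata does not identify a unique %s axis", axis)
  which(axes == axis)
}
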