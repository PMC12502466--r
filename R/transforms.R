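#' Rigid transform between two image spaces
#'
#' A 4x4 homogeneous matrix mapping physical coordinates of a moving image
#' into a fixed image's physical space. The upper-left 3x3 block must be a
#' proper rotation (orthogonal, determinant +1).
#'
#' @param matrix 4x4 homogeneous matrix.
#' @param moving_space_id,fixed_space_id identifiers of the grids connected.
#' @return A `rigid_transform` object.
#' @export
rigid_transform <- function(matrix, moving_space_id = "moving",
                            fixed_space_id = "fixed") {
  matrix <- unname(as.matrix(matrix))
  if (!all(dim(matrix) == c(4L, 4L))) stopf("transform matrix must be 4x4")
  if (max(abs(matrix[4, ] - c(0, 0, 0, 1))) > 1e-9)
    stopf("last row of a rigid matrix must be (0,0,0,1)")
  R <- matrix[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6)
    stopf("upper-left 3x3 block must be a proper rotation")
  structure(list(matrix = matrix, moving_space_id = moving_space_id,
                 fixed_space_id = fixed_space_id),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid_transform: %s -> %s\n", x$moving_space_id,
              x$fixed_space_id))
  print(round(x$matrix, 6))
  invisible(x)
}

#' Build a rigid transform from Euler angles and a translation
#'
#' Rotation is applied about `center` (physical mm), i.e.
#' `p' = R (p - c) + c + t`. Angles are intrinsic rotations about the x, y
#' and z axes applied in that order (Rz Ry Rx).
#'
#' @param rotation_deg rotations about x, y, z in degrees.
#' @param translation_mm translation in mm.
#' @param center rotation center in physical mm.
#' @inheritParams rigid_transform
#' @return A `rigid_transform`.
#' @export
rigid_from_params <- function(rotation_deg = c(0, 0, 0),
                              translation_mm = c(0, 0, 0),
                              center = c(0, 0, 0),
                              moving_space_id = "moving",
                              fixed_space_id = "fixed") {
  a <- rotation_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  R <- Rz %*% Ry %*% Rx
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- center - R %*% center + translation_mm
  rigid_transform(m, moving_space_id, fixed_space_id)
}

#' Compose two rigid transforms
#'
#' `compose(t_ab, t_bc)` chains a transform from space a to space b with one
#' from b to c, yielding a -> c (matrix product `M_bc %*% M_ab`). This is the
#' indirect-registration device: the 3T-T1w-to-7T-T2w matrix carries the
#' roughly aligned 3T-T2w scan into 7T-T2w space.
#'
#' @param t_ab,t_bc `rigid_transform`s with `t_ab$fixed_space_id ==
#'   t_bc$moving_space_id`.
#' @return A `rigid_transform` from `t_ab`'s moving space to `t_bc`'s fixed
#'   space.
#' @export
compose <- function(t_ab, t_bc) {
  if (!identical(t_ab$fixed_space_id, t_bc$moving_space_id))
    stopf("space-id mismatch: '%s' != '%s'", t_ab$fixed_space_id,
          t_bc$moving_space_id)
  rigid_transform(t_bc$matrix %*% t_ab$matrix,
                  moving_space_id = t_ab$moving_space_id,
                  fixed_space_id = t_bc$fixed_space_id)
}

#' Invert a rigid transform
#' @param t a `rigid_transform`.
#' @return The inverse transform (fixed and moving spaces swapped).
#' @export
invert <- function(t) {
  rigid_transform(solve(t$matrix), moving_space_id = t$fixed_space_id,
                  fixed_space_id = t$moving_space_id)
}

#' Identity transform
#' @inheritParams rigid_transform
#' @return A `rigid_transform` with the identity matrix.
#' @export
identity_transform <- function(moving_space_id = "moving",
                               fixed_space_id = "fixed") {
  rigid_transform(diag(4), moving_space_id, fixed_space_id)
}

# translation / rotation magnitude of the residual between two transforms,
# measured as max corner displacement is overkill; report translation norm
# (mm) and rotation angle (deg) of t_est composed with the inverse truth.
transform_residual <- function(t_est, t_true) {
  d <- t_est$matrix %*% solve(t_true$matrix)
  R <- d[1:3, 1:3]
  ang <- acos(min(1, max(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
  list(translation_mm = sqrt(sum(d[1:3, 4]^2)), rotation_deg = ang)
}

#' Read/write a 4x4 transform as whitespace-delimited text
#'
#' @param t a `rigid_transform`; `path` a file path.
#' @return `read_transform` returns a `rigid_transform`.
#' @export
write_transform <- function(t, path) {
  write.table(format(t$matrix, digits = 17), path, row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_transform
#' @param path file holding 4 rows of 4 numbers.
#' @export
read_transform <- function(path) {
  m <- as.matrix(read.table(path, header = FALSE))
  rigid_transform(m)
}
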