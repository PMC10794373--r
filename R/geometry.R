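#' Maze geometry for a virtual-reality elevated plus-maze
#'
#' Describes the physical plus-maze and the derived analysis parameters: zone
#' thresholds for arm membership and the occupancy-heatmap binning. The maze
#' coordinate frame has its origin at the maze centre, the x-axis along the
#' closed arms and the z-axis along the open arms; y is vertical and is
#' ignored by all planar computations.
#'
#' @param arm_length Arm length in cm, measured from the maze centre to the
#'   arm tip. The default 175 cm gives a 350 x 350 cm footprint.
#' @param arm_width Arm width in cm (default 30).
#' @param zone_threshold Axial distance in cm beyond which a sample counts as
#'   being on an arm. Default 15 cm, the half-width of the arms, i.e. the edge
#'   of the central square where the arms begin.
#' @param end_threshold Axial distance in cm defining "the end of an open
#'   arm" for the end-exploration latency. Default 160 cm (arm length minus
#'   one arm half-width).
#' @param bin_size Heatmap bin edge in cm (default 10). Must divide
#'   `2 * arm_length` evenly.
#'
#' @return An object of class `maze_geometry` with fields `arm_length`,
#'   `arm_width`, `zone_threshold`, `end_threshold`, `extent_half`,
#'   `bin_size` and `n_bins`.
#' @examples
#' geom <- maze_geometry()
#' geom$n_bins # 35
#' @export
maze_geometry <- function(arm_length = 175, arm_width = 30,
                          zone_threshold = 15, end_threshold = 160,
                          bin_size = 10) {
  stopifnot(arm_length > 0, arm_width > 0, bin_size > 0)
  if (!(zone_threshold > 0 && zone_threshold < end_threshold &&
        end_threshold <= arm_length)) {
    stop("need 0 < zone_threshold < end_threshold <= arm_length")
  }
  n_bins <- 2 * arm_length / bin_size
  if (abs(n_bins - round(n_bins)) > 1e-9) {
    stop("bin_size must divide the maze extent (2 * arm_length) evenly")
  }
  structure(
    list(arm_length = arm_length, arm_width = arm_width,
         zone_threshold = zone_threshold, end_threshold = end_threshold,
         extent_half = arm_length, bin_size = bin_size,
         n_bins = as.integer(round(n_bins))),
    class = "maze_geometry"
  )
}

#' @export
print.maze_geometry <- function(x, ...) {
  cat(sprintf(
    "<maze_geometry> %g x %g cm plus-maze (arm width %g cm)\n",
    2 * x$extent_half, 2 * x$extent_half, x$arm_width))
  cat(sprintf("  zone threshold %g cm, open-arm end threshold %g cm\n",
              x$zone_threshold, x$end_threshold))
  cat(sprintf("  heatmap: %d x %d bins of %g cm\n",
              x$n_bins, x$n_bins, x$bin_size))
  invisible(x)
}

#' Rigid calibration transform from raw tracking space to the maze frame
#'
#' The tracking system reports headset positions in an arbitrary room frame;
#' calibration aligns the coordinate axes with the physical maze arms and
#' places the origin at the maze centre. The transform is rigid: an
#' orthonormal rotation with determinant +1 followed by a translation.
#'
#' @param rotation 3x3 orthonormal rotation matrix (raw frame to maze frame).
#' @param translation Length-3 numeric, cm; maps the rotated maze-centre
#'   point to the origin.
#' @param tol Numeric tolerance for the orthonormality check.
#' @return An object of class `calibration_transform`.
#' @export
calibration_transform <- function(rotation = diag(3),
                                  translation = c(0, 0, 0),
                                  tol = 1e-8) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(identical(dim(rotation), c(3L, 3L)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > tol ||
      abs(det(rotation) - 1) > tol) {
    stop("invalid calibration: rotation must be orthonormal with det +1")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "calibration_transform")
}

#' Map raw tracking-space positions into the maze frame
#'
#' @param raw_position Length-3 numeric or an n x 3 matrix of positions (cm).
#' @param transform A [calibration_transform()].
#' @return Positions in the maze frame, same shape as the input.
#' @export
to_maze_frame <- function(raw_position, transform) {
  stopifnot(inherits(transform, "calibration_transform"))
  if (is.matrix(raw_position)) {
    stopifnot(ncol(raw_position) == 3)
    out <- raw_position %*% t(transform$rotation)
    sweep(out, 2, -transform$translation)
  } else {
    stopifnot(length(raw_position) == 3)
    as.numeric(transform$rotation %*% raw_position + transform$translation)
  }
}

#' Invert a calibration transform
#'
#' @param transform A [calibration_transform()].
#' @return The inverse `calibration_transform` (maze frame to raw frame).
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "calibration_transform"))
  rot <- t(transform$rotation)
  calibration_transform(rot, -as.numeric(rot %*% transform$translation))
}

#' Classify maze-frame positions into centre / open-arm / closed-arm zones
#'
#' A sample counts as being on an arm when its absolute position along the
#' arm axis exceeds the zone threshold: |z| for the open arms, |x| for the
#' closed arms. The vertical (y) coordinate is ignored; headset height varies
#' with posture, not location. Points nominally in both arm corridors can
#' only arise from tracking noise; they are resolved by the larger absolute
#' coordinate, ties going to open (the primary outcome).
#'
#' @param position Length-3 numeric `(x, y, z)` or an n x 3 matrix, cm,
#'   maze frame.
#' @param geometry A [maze_geometry()].
#' @return A data frame with one row per position: `kind` (factor with levels
#'   `center`, `open`, `closed`) and `arm_sign` (+1 or -1 identifying the arm
#'   of that type, `NA` for the centre).
#' @examples
#' classify_zone(c(0, 165, 100), maze_geometry()) # open, arm_sign +1
#' @export
classify_zone <- function(position, geometry) {
  stopifnot(inherits(geometry, "maze_geometry"))
  if (!is.matrix(position)) position <- matrix(position, nrow = 1)
  stopifnot(ncol(position) == 3)
  x <- position[, 1]
  z <- position[, 3]
  if (any(!is.finite(x)) || any(!is.finite(z))) {
    stop("non-finite coordinates cannot be zone-classified")
  }
  thr <- geometry$zone_threshold
  ax <- abs(x)
  az <- abs(z)
  open <- az > thr & (ax <= thr | az >= ax)
  closed <- ax > thr & !open
  kind <- rep("center", length(x))
  kind[open] <- "open"
  kind[closed] <- "closed"
  arm_sign <- rep(NA_real_, length(x))
  arm_sign[open] <- sign(z[open])
  arm_sign[closed] <- sign(x[closed])
  data.frame(kind = factor(kind, levels = c("center", "open", "closed")),
             arm_sign = arm_sign)
}

#' Test whether planar points lie on the plus-shaped maze surface
#'
#' @param x,z Numeric vectors of planar maze-frame coordinates, cm.
#' @param geometry A [maze_geometry()].
#' @return Logical vector.
#' @export
on_maze <- function(x, z, geometry) {
  hw <- geometry$arm_width / 2
  L <- geometry$arm_length
  (abs(x) <= L & abs(z) <= hw) | (abs(z) <= L & abs(x) <= hw)
}
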