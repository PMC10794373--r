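#' Heatmap bin index of a planar coordinate
#'
#' Bins are half-open 10-cm (by default) intervals covering
#' `[-extent_half, extent_half)`; coordinates beyond the maze extent (from
#' tracking noise) are clamped into the edge bins.
#'
#' @param coord Numeric vector of coordinates, cm, maze frame.
#' @param geometry A [maze_geometry()].
#' @return Integer zero-based bin indices in `[0, n_bins - 1]`.
#' @examples
#' bin_index(c(-175, 0, 174.9), maze_geometry()) # 0, 17, 34
#' @export
bin_index <- function(coord, geometry) {
  stopifnot(all(is.finite(coord)))
  idx <- floor((coord + geometry$extent_half) / geometry$bin_size)
  as.integer(pmin(pmax(idx, 0), geometry$n_bins - 1))
}

new_occupancy_map <- function(grid, geometry, normalized, n_participants) {
  structure(
    list(grid = grid, bin_size = geometry$bin_size, n_bins = geometry$n_bins,
         normalized = normalized, n_participants = n_participants),
    class = "occupancy_map"
  )
}

#' Accumulate a session into an occupancy map
#'
#' Each task sample adds one sample period (seconds) to the cell holding its
#' (x, z) position, so an unnormalized per-session map sums to the tracked
#' task time and maps are comparable across sampling rates. Rows index the
#' x (closed-arm) axis, columns the z (open-arm) axis.
#'
#' @param traj A uniformly resampled [trajectory()].
#' @param geometry A [maze_geometry()].
#' @return An `occupancy_map` with fields `grid` (n_bins x n_bins matrix of
#'   seconds), `bin_size`, `normalized = FALSE`, `n_participants = 1`.
#' @export
accumulate_occupancy <- function(traj, geometry) {
  stopifnot(inherits(traj, "trajectory"), inherits(geometry, "maze_geometry"))
  if (is.na(traj$sample_rate)) {
    stop("trajectory must be resampled to a uniform rate first")
  }
  seg <- task_segment(traj)$samples
  dt <- 1 / traj$sample_rate
  n <- geometry$n_bins
  ix <- bin_index(seg$x, geometry)
  iz <- bin_index(seg$z, geometry)
  counts <- table(factor(ix * n + iz, levels = 0:(n * n - 1)))
  grid <- matrix(as.numeric(counts) * dt, nrow = n, ncol = n, byrow = TRUE)
  new_occupancy_map(grid, geometry, normalized = FALSE, n_participants = 1L)
}

same_binning <- function(a, b) {
  a$n_bins == b$n_bins && isTRUE(all.equal(a$bin_size, b$bin_size))
}

#' Per-participant mean occupancy of a cohort
#'
#' Element-wise mean of unnormalized per-session maps: normalization divides
#' the summed occupancy by the number of participants.
#'
#' @param maps List of unnormalized `occupancy_map`s with identical binning.
#' @return A normalized `occupancy_map`; cells hold mean seconds per
#'   participant.
#' @export
cohort_mean <- function(maps) {
  stopifnot(length(maps) >= 1)
  for (m in maps) {
    stopifnot(inherits(m, "occupancy_map"))
    if (m$normalized) stop("cohort_mean expects unnormalized per-session maps")
    if (!same_binning(m, maps[[1]])) stop("maps have incompatible binning")
  }
  total <- Reduce(`+`, lapply(maps, `[[`, "grid"))
  out <- maps[[1]]
  out$grid <- total / length(maps)
  out$normalized <- TRUE
  out$n_participants <- length(maps)
  out
}

#' Difference of two cohort occupancy maps
#'
#' Subtracts the first-exposure map from the second-exposure map; cells may
#' be negative (less time spent at second exposure).
#'
#' @param second,first Normalized `occupancy_map`s with identical binning.
#' @return An `occupancy_map` whose grid is `second - first`.
#' @export
difference_map <- function(second, first) {
  stopifnot(inherits(second, "occupancy_map"), inherits(first, "occupancy_map"))
  if (!second$normalized || !first$normalized) {
    stop("difference_map expects cohort-normalized maps")
  }
  if (!same_binning(second, first)) stop("maps have incompatible binning")
  out <- second
  out$grid <- second$grid - first$grid
  out
}

#' Mask of cells with at least a minimum mean length of stay
#'
#' Rendering convenience: selects cells that were occupied and whose mean
#' length of stay reaches `min_stay` (inclusive).
#'
#' @param map An `occupancy_map`.
#' @param min_stay Minimum stay in seconds (default 0.5).
#' @return Logical matrix.
#' @export
dwell_mask <- function(map, min_stay = 0.5) {
  stopifnot(inherits(map, "occupancy_map"), min_stay >= 0)
  map$grid > 0 & map$grid >= min_stay
}

#' @export
print.occupancy_map <- function(x, ...) {
  cat(sprintf("<occupancy_map> %d x %d bins of %g cm, %s, n=%d, sum=%.2f s\n",
              x$n_bins, x$n_bins, x$bin_size,
              if (x$normalized) "normalized" else "per-session",
              x$n_participants, sum(x$grid)))
  invisible(x)
}

#' Write an occupancy map as delimited text plus a JSON sidecar
#'
#' @param map An `occupancy_map`.
#' @param path Output path for the matrix (tab-delimited, n_bins rows);
#'   metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_occupancy <- function(map, path) {
  stopifnot(inherits(map, "occupancy_map"))
  utils::write.table(format(map$grid, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  meta <- map[c("bin_size", "n_bins", "normalized", "n_participants")]
  meta$row_axis <- "x (closed arms)"
  meta$col_axis <- "z (open arms)"
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read an occupancy map written by [write_occupancy()]
#'
#' @param path Path of the matrix file; `<path>.json` must hold the sidecar.
#' @return An `occupancy_map`.
#' @export
read_occupancy <- function(path) {
  grid <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(grid) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(
    list(grid = grid, bin_size = meta$bin_size, n_bins = meta$n_bins,
         normalized = meta$normalized, n_participants = meta$n_participants),
    class = "occupancy_map"
  )
}
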