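#' Session metadata for one plus-maze exposure
#'
#' @param participant_id Opaque participant identifier.
#' @param exposure `"first"` or `"second"` testing session.
#' @param epm_version Virtual environment: `"Sea"`, `"Desert"` or
#'   `"VideoGame"`.
#' @param task_duration Task length in seconds (default 300: the exploration
#'   phase).
#' @param baseline_duration Baseline length in seconds preceding task onset
#'   (default 60: the waiting phase at the maze centre).
#' @return An object of class `session_meta`.
#' @export
session_meta <- function(participant_id,
                         exposure = c("first", "second"),
                         epm_version = c("Sea", "Desert", "VideoGame"),
                         task_duration = 300,
                         baseline_duration = 60) {
  exposure <- match.arg(exposure)
  epm_version <- match.arg(epm_version)
  stopifnot(task_duration > 0, baseline_duration >= 0)
  structure(
    list(participant_id = as.character(participant_id), exposure = exposure,
         epm_version = epm_version, task_duration = task_duration,
         baseline_duration = baseline_duration),
    class = "session_meta"
  )
}

trajectory_cols <- c("t", "x", "y", "z", "rx", "ry", "rz")

#' Construct a pose-stream trajectory
#'
#' A trajectory holds the timestamped headset pose stream of one session in
#' the maze frame: time `t` in seconds from task onset (baseline samples
#' carry negative `t`), position `(x, y, z)` in cm and orientation
#' `(rx, ry, rz)` in degrees (yaw/pitch/roll).
#'
#' @param samples Data frame with columns `t,x,y,z,rx,ry,rz`; timestamps
#'   must be strictly increasing and positions finite.
#' @param session A [session_meta()].
#' @param sample_rate Sampling rate in Hz, or `NA` if not uniform. When
#'   omitted it is inferred from the timestamps if they are uniform.
#' @param quality Optional list of data-quality notes (dropped rows, gaps).
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(samples, session, sample_rate = NULL,
                       quality = list()) {
  stopifnot(is.data.frame(samples), inherits(session, "session_meta"))
  missing_cols <- setdiff(trajectory_cols, names(samples))
  if (length(missing_cols)) {
    stop("trajectory samples lack columns: ",
         paste(missing_cols, collapse = ", "))
  }
  samples <- samples[trajectory_cols]
  if (nrow(samples)) {
    bad <- which(diff(samples$t) <= 0)
    if (length(bad)) {
      stop("timestamps not strictly increasing at rows: ",
           paste(utils::head(bad + 1, 5), collapse = ", "))
    }
    if (any(!is.finite(samples$t)) ||
        any(!is.finite(as.matrix(samples[c("x", "y", "z")])))) {
      stop("trajectory contains non-finite times or positions")
    }
  }
  if (is.null(sample_rate)) sample_rate <- infer_rate(samples$t)
  structure(
    list(samples = samples, sample_rate = sample_rate, session = session,
         quality = quality),
    class = "trajectory"
  )
}

# Reciprocal of the common inter-sample interval, or NA when not uniform.
infer_rate <- function(t, tol = 1e-9) {
  if (length(t) < 2) return(NA_real_)
  dt <- diff(t)
  if (max(dt) - min(dt) > tol) return(NA_real_)
  1 / stats::median(dt)
}

#' @export
print.trajectory <- function(x, ...) {
  s <- x$session
  cat(sprintf("<trajectory> %s / %s exposure / EPM_%s\n",
              s$participant_id, s$exposure, s$epm_version))
  cat(sprintf("  %d samples, rate %s Hz, t in [%.2f, %.2f] s\n",
              nrow(x$samples),
              ifelse(is.na(x$sample_rate), "irregular",
                     format(x$sample_rate)),
              min(x$samples$t), max(x$samples$t)))
  if (length(x$quality)) {
    cat("  quality: ",
        paste(names(x$quality), unlist(lapply(x$quality, paste, collapse = ",")),
              sep = "=", collapse = "; "), "\n", sep = "")
  }
  invisible(x)
}

#' Read a pose-stream file
#'
#' Reads a comma-delimited trajectory file with header `t,x,y,z,rx,ry,rz`
#' (seconds / cm / degrees). Rows containing non-finite values are dropped
#' and counted in the trajectory's quality report; non-monotone timestamps
#' among the retained rows are an error.
#'
#' @param path Path to the file.
#' @param session A [session_meta()] describing the recording.
#' @return A [trajectory()]; `$quality$dropped_rows` counts discarded rows.
#' @export
read_trajectory <- function(path, session) {
  if (!file.exists(path)) stop("no such trajectory file: ", path)
  raw <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "numeric")
  missing_cols <- setdiff(trajectory_cols, names(raw))
  if (length(missing_cols)) {
    stop("trajectory file ", path, " lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  raw <- raw[trajectory_cols]
  ok <- rowSums(!is.finite(as.matrix(raw))) == 0
  dropped <- sum(!ok)
  trajectory(raw[ok, , drop = FALSE], session,
             quality = list(dropped_rows = dropped))
}

#' Write a trajectory to a pose-stream file
#'
#' Values are written with 17 significant digits so that a read/write cycle
#' round-trips doubles exactly.
#'
#' @param traj A [trajectory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  s <- traj$samples
  lines <- c(paste(trajectory_cols, collapse = ","),
             do.call(paste, c(lapply(s, function(col) sprintf("%.17g", col)),
                              sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Resample a trajectory onto a uniform time grid
#'
#' Positions are linearly interpolated onto a grid at `rate` Hz spanning the
#' first to last timestamp. Orientation angles are unwrapped per component
#' before interpolation and re-wrapped to (-180, 180]. Recording gaps longer
#' than `gap_warn` seconds are still interpolated but flagged in the quality
#' report.
#'
#' @param traj A [trajectory()].
#' @param rate Target rate in Hz (default 5, the native tracking rate).
#' @param gap_warn Gap length in seconds above which a gap is flagged.
#' @return A uniformly sampled [trajectory()].
#' @export
resample_trajectory <- function(traj, rate = 5, gap_warn = 1) {
  stopifnot(inherits(traj, "trajectory"), rate > 0)
  s <- traj$samples
  if (nrow(s) < 2) stop("resampling needs at least 2 samples")
  dt <- 1 / rate
  n_steps <- floor((s$t[nrow(s)] - s$t[1]) / dt + 1e-9)
  grid <- s$t[1] + (0:n_steps) * dt
  gaps <- which(diff(s$t) > gap_warn)
  out <- data.frame(t = grid)
  for (col in c("x", "y", "z")) {
    out[[col]] <- stats::approx(s$t, s[[col]], xout = grid)$y
  }
  for (col in c("rx", "ry", "rz")) {
    unwrapped <- unwrap_degrees(s[[col]])
    ang <- stats::approx(s$t, unwrapped, xout = grid)$y
    out[[col]] <- wrap_degrees(ang)
  }
  quality <- traj$quality
  quality$interpolated_gaps_s <- round(diff(s$t)[gaps], 6)
  trajectory(out, traj$session, sample_rate = rate, quality = quality)
}

# Remove +-360 degree jumps so linear interpolation crosses the wrap point.
unwrap_degrees <- function(a) {
  if (length(a) < 2) return(a)
  d <- diff(a)
  adj <- cumsum(c(0, -360 * round(d / 360)))
  a + adj
}

wrap_degrees <- function(a) {
  w <- (a + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

#' Restrict a trajectory to its task segment
#'
#' The task segment covers `t` in `[0, task_duration)`: the half-open window
#' beginning at the scene change. Baseline samples (negative `t`) are
#' excluded.
#'
#' @param traj A [trajectory()].
#' @return A [trajectory()] containing task samples only.
#' @export
task_segment <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  keep <- traj$samples$t >= 0 & traj$samples$t < traj$session$task_duration
  trajectory(traj$samples[keep, , drop = FALSE], traj$session,
             sample_rate = traj$sample_rate, quality = traj$quality)
}
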