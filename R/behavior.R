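#' Time spent in each maze zone
#'
#' Every sample of a uniformly sampled task segment contributes one sample
#' period (1/rate seconds) to the zone it is classified into, so the three
#' dwell times partition the tracked task time.
#'
#' @param traj A uniformly resampled [trajectory()].
#' @param geometry A [maze_geometry()].
#' @return Named numeric vector `c(open=, closed=, center=)`, seconds.
#' @export
dwell_times <- function(traj, geometry) {
  z <- task_zones(traj, geometry)
  dt <- 1 / traj$sample_rate
  counts <- table(z$kind)
  c(open = dt * as.numeric(counts[["open"]]),
    closed = dt * as.numeric(counts[["closed"]]),
    center = dt * as.numeric(counts[["center"]]))
}

# Zone classification of the task segment; errors on empty/irregular input.
task_zones <- function(traj, geometry) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.na(traj$sample_rate)) {
    stop("trajectory must be resampled to a uniform rate first")
  }
  seg <- task_segment(traj)
  if (nrow(seg$samples) == 0) stop("no task samples (t >= 0) in trajectory")
  cbind(seg$samples, classify_zone(as.matrix(seg$samples[c("x", "y", "z")]),
                                   geometry))
}

#' Count arm entries
#'
#' An entry is a sample pair where sample i-1 is not in a zone of the
#' requested kind and sample i is (an absolute-value threshold crossing on
#' the relevant axis). Entries onto the + and - arms of a type accumulate
#' into one count.
#'
#' @inheritParams dwell_times
#' @param zone_kind `"open"` or `"closed"`.
#' @return Integer entry count.
#' @export
count_entries <- function(traj, geometry, zone_kind = c("open", "closed")) {
  zone_kind <- match.arg(zone_kind)
  kind <- task_zones(traj, geometry)$kind
  n <- length(kind)
  if (n < 2) stop("entry counting needs at least 2 task samples")
  sum(kind[-1] == zone_kind & kind[-n] != zone_kind)
}

#' Latency to the first open-arm visit
#'
#' Timestamp of the first task sample classified as open-arm. If the open
#' arms are never visited the latency is censored at the task duration.
#'
#' @inheritParams dwell_times
#' @return List with `latency` (s) and `censored` (logical).
#' @export
latency_first_open <- function(traj, geometry) {
  z <- task_zones(traj, geometry)
  hit <- which(z$kind == "open")
  if (length(hit)) {
    list(latency = z$t[hit[1]], censored = FALSE)
  } else {
    list(latency = traj$session$task_duration, censored = TRUE)
  }
}

#' Latency to reach the end of an open arm
#'
#' Timestamp of the first task sample with |z| at or beyond the end
#' threshold; censored at the task duration if the arm end is never reached.
#'
#' @inheritParams dwell_times
#' @return List with `latency` (s) and `censored` (logical).
#' @export
latency_end_exploration <- function(traj, geometry) {
  z <- task_zones(traj, geometry)
  hit <- which(abs(z$z) >= geometry$end_threshold)
  if (length(hit)) {
    list(latency = z$t[hit[1]], censored = FALSE)
  } else {
    list(latency = traj$session$task_duration, censored = TRUE)
  }
}

#' Total distance covered on the maze
#'
#' Sum of horizontal-plane (x, z) Euclidean step lengths over the task
#' segment. Head-height bobbing is excluded: the measure indexes locomotion.
#'
#' @inheritParams dwell_times
#' @return Distance in metres.
#' @export
total_distance <- function(traj) {
  seg <- task_segment(traj)$samples
  if (nrow(seg) < 2) stop("distance needs at least 2 task samples")
  sum(sqrt(diff(seg$x)^2 + diff(seg$z)^2)) / 100
}

#' Mean headset velocity within a zone type
#'
#' Mean of per-step horizontal speeds over steps whose both endpoints are
#' classified into the requested zone kind.
#'
#' @inheritParams count_entries
#' @return Speed in cm/s, or `NA` when no step qualifies.
#' @export
mean_velocity <- function(traj, geometry, zone_kind = c("open", "closed")) {
  zone_kind <- match.arg(zone_kind)
  z <- task_zones(traj, geometry)
  n <- nrow(z)
  if (n < 2) stop("velocity needs at least 2 task samples")
  both <- z$kind[-1] == zone_kind & z$kind[-n] == zone_kind
  if (!any(both)) return(NA_real_)
  dt <- 1 / traj$sample_rate
  speeds <- sqrt(diff(z$x)^2 + diff(z$z)^2) / dt
  mean(speeds[both])
}

#' Score one session into the full behavioural summary
#'
#' Assembles the approach-avoidance markers of a session: open/closed/centre
#' dwell times, open- and closed-arm entry counts, first-visit and
#' end-exploration latencies (censored at the task duration when the event
#' never occurs), total distance, and mean arm velocities.
#'
#' @inheritParams dwell_times
#' @return A one-row data frame of class `behavioral_summary` with columns
#'   `time_open`, `time_closed`, `time_center` (s), `entries_open`,
#'   `entries_closed`, `latency_first_open`, `latency_end_exploration` (s),
#'   `censored_latency_first`, `censored_latency_end`, `total_distance` (m),
#'   `mean_velocity_open`, `mean_velocity_closed` (cm/s).
#' @export
summarize_behavior <- function(traj, geometry) {
  dwell <- dwell_times(traj, geometry)
  lat1 <- latency_first_open(traj, geometry)
  lat2 <- latency_end_exploration(traj, geometry)
  out <- data.frame(
    time_open = dwell[["open"]],
    time_closed = dwell[["closed"]],
    time_center = dwell[["center"]],
    entries_open = count_entries(traj, geometry, "open"),
    entries_closed = count_entries(traj, geometry, "closed"),
    latency_first_open = lat1$latency,
    latency_end_exploration = lat2$latency,
    censored_latency_first = lat1$censored,
    censored_latency_end = lat2$censored,
    total_distance = total_distance(traj),
    mean_velocity_open = mean_velocity(traj, geometry, "open"),
    mean_velocity_closed = mean_velocity(traj, geometry, "closed")
  )
  class(out) <- c("behavioral_summary", class(out))
  out
}

#' Score a whole cohort of sessions
#'
#' @param trajectories List of [trajectory()] objects.
#' @param geometry A [maze_geometry()].
#' @return Data frame with one row per session: the session metadata columns
#'   (`participant_id`, `exposure`, `epm_version`) followed by the
#'   [summarize_behavior()] columns.
#' @export
score_cohort <- function(trajectories, geometry) {
  rows <- lapply(trajectories, function(traj) {
    s <- traj$session
    cbind(data.frame(participant_id = s$participant_id,
                     exposure = s$exposure, epm_version = s$epm_version),
          summarize_behavior(traj, geometry))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
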