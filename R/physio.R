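#' A timestamped physiological channel recording
#'
#' @param t Numeric vector of timestamps, seconds from task onset (negative
#'   values are baseline).
#' @param values Channel readings at each timestamp.
#' @param channel `"SCL"` (skin conductance level, microsiemens), `"HR"`
#'   (heart rate, bpm) or `"RESP"` (respiratory rate, breaths/min).
#' @return An object of class `physio_series`.
#' @export
physio_series <- function(t, values, channel = c("SCL", "HR", "RESP")) {
  channel <- match.arg(channel)
  stopifnot(length(t) == length(values), all(is.finite(t)))
  if (any(diff(t) <= 0)) stop("physio timestamps must be strictly increasing")
  structure(list(t = as.numeric(t), values = as.numeric(values),
                 channel = channel),
            class = "physio_series")
}

#' Interval means of a physiological channel
#'
#' Averages a channel over the baseline window and consecutive task windows:
#' `[-baseline_window, 0)`, then `[0, window)`, `[window, 2*window)`, ...
#' All windows are half-open so no sample is double-counted. With the
#' defaults (30 s baseline, 300 s task, 30 s windows) this yields 11 means.
#' Windows containing no sample yield `NA` and are listed in the result.
#'
#' @param series A [physio_series()].
#' @param baseline_window Baseline length in seconds (default 30).
#' @param task_duration Task length in seconds (default 300).
#' @param window Task window length in seconds (default 30).
#' @return An object of class `interval_summary`: `channel`, named numeric
#'   `means` (`baseline`, `task_0_30`, ...), `transform = "identity"`,
#'   `empty_intervals` (character).
#' @export
interval_means <- function(series, baseline_window = 30, task_duration = 300,
                           window = 30) {
  stopifnot(inherits(series, "physio_series"),
            baseline_window > 0, task_duration > 0, window > 0)
  n_task <- task_duration / window
  if (abs(n_task - round(n_task)) > 1e-9) {
    stop("window must divide task_duration evenly")
  }
  n_task <- round(n_task)
  starts <- c(-baseline_window, (0:(n_task - 1)) * window)
  ends <- c(0, (1:n_task) * window)
  labels <- c("baseline",
              sprintf("task_%g_%g", starts[-1], ends[-1]))
  means <- vapply(seq_along(starts), function(i) {
    sel <- series$t >= starts[i] & series$t < ends[i]
    if (!any(sel)) NA_real_ else mean(series$values[sel])
  }, numeric(1))
  names(means) <- labels
  structure(
    list(channel = series$channel, means = means, transform = "identity",
         empty_intervals = labels[is.na(means)]),
    class = "interval_summary"
  )
}

#' Natural-log transform of skin-conductance interval means
#'
#' SCL distributions are right-skewed; analysis is carried out on
#' ln-transformed interval means. Only the SCL channel may be transformed,
#' and all means must be positive.
#'
#' @param summary An [interval_means()] result for the SCL channel.
#' @return The summary with `means` log-transformed and `transform = "ln"`.
#' @export
log_transform <- function(summary) {
  stopifnot(inherits(summary, "interval_summary"))
  if (summary$channel != "SCL") {
    stop("log transform is defined for the SCL channel only")
  }
  if (summary$transform != "identity") stop("summary is already transformed")
  bad <- names(summary$means)[!is.na(summary$means) & summary$means <= 0]
  if (length(bad)) {
    stop("non-positive SCL mean in interval(s): ", paste(bad, collapse = ", "))
  }
  summary$means <- log(summary$means)
  summary$transform <- "ln"
  summary
}

#' Salivary alpha-amylase triplet and its task-related changes
#'
#' Saliva is sampled before (T0), directly after (T1) and 15 min after (T2)
#' behavioural testing. Values below the assay detection limit are flagged;
#' deltas involving a flagged sample are missing.
#'
#' @param t0,t1,t2 Amylase activity in U/mL.
#' @param detection_limit Assay detection limit in U/mL (default 25).
#' @return List with `delta_t1` (T1 - T0), `delta_t2` (T2 - T0), both `NA`
#'   when an involved sample is below detection, and `below_detection`, a
#'   named logical vector over T0..T2.
#' @export
amylase_deltas <- function(t0, t1, t2, detection_limit = 25) {
  stopifnot(t0 >= 0, t1 >= 0, t2 >= 0, detection_limit > 0)
  below <- c(T0 = t0 < detection_limit, T1 = t1 < detection_limit,
             T2 = t2 < detection_limit)
  list(
    delta_t1 = if (below[["T0"]] || below[["T1"]]) NA_real_ else t1 - t0,
    delta_t2 = if (below[["T0"]] || below[["T2"]]) NA_real_ else t2 - t0,
    below_detection = below
  )
}
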