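#' Pearson correlation matrix of behavioural measures across exposures
#'
#' Builds the test-retest correlation matrix: each selected measure at first
#' and second exposure becomes one variable (`<measure>.first`,
#' `<measure>.second`) and all pairwise Pearson correlations are computed
#' over participants with complete pairs. Cells with a constant variable or
#' fewer than `min_pairs` complete pairs are `NA`.
#'
#' @param table Cohort metrics table: one row per (participant, exposure)
#'   with columns `participant_id`, `exposure` and the measures.
#' @param measures Character vector of measure column names.
#' @param min_pairs Minimum complete pairs per cell (default 3).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(table, measures, min_pairs = 3) {
  wide <- exposure_wide(table, measures)
  vars <- as.matrix(wide[, -1, drop = FALSE])
  p <- ncol(vars)
  out <- matrix(NA_real_, p, p, dimnames = list(colnames(vars),
                                                colnames(vars)))
  for (i in seq_len(p)) {
    for (j in i:p) {
      ok <- stats::complete.cases(vars[, c(i, j)])
      if (i == j) {
        out[i, j] <- 1
      } else if (sum(ok) >= min_pairs &&
                 stats::sd(vars[ok, i]) > 0 && stats::sd(vars[ok, j]) > 0) {
        out[i, j] <- out[j, i] <- stats::cor(vars[ok, i], vars[ok, j])
      }
    }
  }
  out
}

# Long (participant, exposure) rows -> wide participant rows with
# <measure>.first / <measure>.second columns.
exposure_wide <- function(table, measures) {
  stopifnot(all(c("participant_id", "exposure") %in% names(table)),
            all(measures %in% names(table)))
  if (anyDuplicated(table[c("participant_id", "exposure")])) {
    stop("more than one row per participant and exposure")
  }
  ids <- unique(table$participant_id)
  out <- data.frame(participant_id = ids)
  for (m in measures) {
    for (e in c("first", "second")) {
      rows <- table[table$exposure == e, ]
      out[[paste(m, e, sep = ".")]] <-
        rows[[m]][match(ids, rows$participant_id)]
    }
  }
  out
}

#' Two-way mixed, consistency, single-measures intraclass correlation
#'
#' ICC(3,1): reliability of a single score across k occasions, from the
#' two-way (subjects x occasions) mean squares without replication,
#' `(MS_subjects - MS_error) / (MS_subjects + (k - 1) MS_error)`. The
#' consistency definition excludes the occasion variance, so an additive
#' shift between occasions does not lower the ICC. The 95% confidence
#' interval comes from F-distribution bounds on `MS_subjects / MS_error`.
#'
#' @param scores Numeric matrix, subjects x occasions (complete rows), or a
#'   data frame coercible to one.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `icc_result`: `estimate`, `ci_low`, `ci_high`,
#'   `ms_between`, `ms_error`, `n`, `k`, `conf_level`, `degenerate`.
#' @export
icc_consistency <- function(scores, conf_level = 0.95) {
  scores <- as.matrix(scores)
  if (any(!is.finite(scores))) stop("icc_consistency needs complete rows")
  n <- nrow(scores)
  k <- ncol(scores)
  stopifnot(n >= 5, k >= 2)
  grand <- mean(scores)
  row_m <- rowMeans(scores)
  col_m <- colMeans(scores)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((scores - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msb <- ss_rows / (n - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  degenerate <- msb <= 0 && mse <= 0
  if (degenerate) {
    est <- ci <- c(NA_real_, NA_real_)
    return(structure(list(estimate = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, ms_between = msb,
                          ms_error = mse, n = n, k = k,
                          conf_level = conf_level, degenerate = TRUE),
                     class = "icc_result"))
  }
  est <- (msb - mse) / (msb + (k - 1) * mse)
  alpha <- 1 - conf_level
  f_obs <- msb / mse
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  fl <- f_obs / stats::qf(1 - alpha / 2, df1, df2)
  fu <- f_obs * stats::qf(1 - alpha / 2, df2, df1)
  f_to_icc <- function(f) if (is.infinite(f)) 1 else (f - 1) / (f + k - 1)
  structure(
    list(estimate = est,
         ci_low = f_to_icc(fl),
         ci_high = f_to_icc(fu),
         ms_between = msb, ms_error = mse, n = n, k = k,
         conf_level = conf_level, degenerate = FALSE),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  if (x$degenerate) {
    cat("<icc_result> undefined (no subject and no error variance)\n")
  } else {
    cat(sprintf(
      "<icc_result> ICC(3,1) consistency = %.3f [%d%% CI %.3f-%.3f], n=%d, k=%d\n",
      x$estimate, round(100 * x$conf_level), x$ci_low, x$ci_high, x$n, x$k))
  }
  invisible(x)
}

#' Paired t-test
#'
#' Two-sided one-sample t on the paired differences; incomplete pairs are
#' dropped. Zero-variance differences are flagged as degenerate: identical
#' vectors give t = 0 and p = 1, a constant nonzero difference has no finite
#' t statistic.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with `t`, `df`, `p`, `mean_diff`, `n` and `degenerate`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) stop("paired_t needs at least 3 complete pairs")
  d <- x - y
  if (stats::sd(d) == 0) {
    t_stat <- if (mean(d) == 0) 0 else Inf * sign(mean(d))
    return(list(t = t_stat, df = n - 1,
                p = if (mean(d) == 0) 1 else NA_real_,
                mean_diff = mean(d), n = n, degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = unname(ht$estimate), n = n,
       degenerate = FALSE)
}

#' Power of the paired t-test
#'
#' Exact power from the noncentral t distribution with `n - 1` degrees of
#' freedom and noncentrality `d * sqrt(n)`.
#'
#' @param n Number of pairs.
#' @param d Effect size (Cohen's d on the differences).
#' @param alpha Type-I error rate (default 0.05).
#' @param tails 1 or 2 (default 2).
#' @return Power (probability of rejection).
#' @export
power_paired_t <- function(n, d, alpha = 0.05, tails = 2) {
  stopifnot(n >= 2, d > 0, alpha > 0, alpha < 1, tails %in% c(1, 2))
  df <- n - 1
  ncp <- d * sqrt(n)
  if (tails == 2) {
    crit <- stats::qt(1 - alpha / 2, df)
    1 - stats::pt(crit, df, ncp) + stats::pt(-crit, df, ncp)
  } else {
    crit <- stats::qt(1 - alpha, df)
    1 - stats::pt(crit, df, ncp)
  }
}

#' A priori sample size for the paired t-test
#'
#' Smallest number of pairs whose exact noncentral-t power reaches the
#' target. With a medium effect (d = 0.50), alpha = .05 two-sided and target
#' power .85 this returns 38.
#'
#' @param d Effect size (Cohen's d on the differences).
#' @param alpha Type-I error rate (default 0.05).
#' @param power Target power (default 0.85).
#' @param tails 1 or 2 (default 2).
#' @param n_max Search bound (default 1e6).
#' @return Integer sample size.
#' @export
required_n_paired_t <- function(d, alpha = 0.05, power = 0.85, tails = 2,
                                n_max = 1e6) {
  stopifnot(d > 0, power > 0, power < 1)
  # bisection on the monotone power function, then exact minimality check
  lo <- 2
  hi <- 4
  while (power_paired_t(hi, d, alpha, tails) < power) {
    lo <- hi
    hi <- hi * 2
    if (hi > n_max) stop("target power unreachable below n_max")
  }
  while (hi - lo > 1) {
    mid <- (lo + hi) %/% 2
    if (power_paired_t(mid, d, alpha, tails) >= power) hi <- mid else lo <- mid
  }
  if (power_paired_t(lo, d, alpha, tails) >= power) as.integer(lo)
  else as.integer(hi)
}
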