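#' Split-plot repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Fits the classical univariate mixed ("split-plot") ANOVA for designs with
#' one or more within-subject factors and an optional between-subjects
#' factor: the between effect is tested against the subject-within-group
#' error, each within effect (and its interaction with the between factor)
#' against the corresponding subject-by-effect error stratum. For every
#' within effect with more than one numerator degree of freedom a
#' Greenhouse-Geisser epsilon is estimated from the pooled within-group
#' covariance matrix of the orthonormal effect contrasts and applied to both
#' degrees of freedom; effects with a single degree of freedom need no
#' sphericity correction (epsilon = 1). Effect sizes are partial
#' eta-squared, `SS_effect / (SS_effect + SS_error)`.
#'
#' Participants with any missing cell are excluded listwise; the retained
#' design must be complete and balanced over the within cells.
#'
#' @param data Long-format data frame.
#' @param dv Name of the numeric dependent-variable column.
#' @param within Character vector of within-subject factor columns (order
#'   fixes the effect labels).
#' @param between Optional name of a single between-subjects factor column.
#' @param subject Name of the subject identifier column (default
#'   `"participant_id"`).
#' @return A data frame of class `rm_anova_table`, one row per effect:
#'   `effect`, `ss`, `ss_error`, `df1`, `df2`, `epsilon`, `df1_gg`, `df2_gg`,
#'   `F`, `p_uncorrected`, `p` (Greenhouse-Geisser), `partial_eta_sq`.
#'   Attribute `excluded` lists listwise-dropped subjects.
#' @export
rm_anova <- function(data, dv, within, between = NULL,
                     subject = "participant_id") {
  stopifnot(is.data.frame(data), length(within) >= 1,
            all(c(dv, within, between, subject) %in% names(data)))
  df <- data.frame(
    .subject = factor(data[[subject]]),
    .y = as.numeric(data[[dv]])
  )
  for (w in within) df[[w]] <- factor(data[[w]])
  if (!is.null(between)) df[[".group"]] <- factor(data[[between]])

  # listwise exclusion: a subject must supply exactly one finite value per
  # within cell
  n_cells <- prod(vapply(within, function(w) nlevels(df[[w]]), integer(1)))
  dfc <- df[is.finite(df$.y), , drop = FALSE]
  per_subj <- tapply(rep(1, nrow(dfc)), dfc$.subject, sum)
  cell_id <- interaction(dfc[within], drop = FALSE)
  dup <- tapply(cell_id, dfc$.subject, function(ci) anyDuplicated(ci) > 0)
  complete <- !is.na(per_subj) & per_subj == n_cells &
    !vapply(dup, isTRUE, logical(1))
  excluded <- names(per_subj)[!complete]
  df <- dfc[dfc$.subject %in% names(per_subj)[complete], , drop = FALSE]
  df$.subject <- droplevels(df$.subject)
  n_subj <- nlevels(df$.subject)
  if (n_subj < 2) stop("fewer than 2 complete subjects")
  if (!is.null(between)) {
    grp <- tapply(as.character(df$.group), df$.subject, function(g) {
      u <- unique(g)
      if (length(u) != 1) stop("between factor varies within a subject")
      u
    })
    if (any(table(grp) < 2)) {
      stop("each between-group level needs at least 2 complete subjects")
    }
  }

  # classical split-plot decomposition via aov error strata
  rhs_within <- paste(within, collapse = " * ")
  fixed <- if (is.null(between)) rhs_within
           else paste(".group *", rhs_within)
  form <- stats::as.formula(paste(
    ".y ~", fixed, "+ Error(.subject/(", rhs_within, "))"))
  fit <- stats::aov(form, data = df)
  strata <- summary(fit)

  eps <- gg_epsilons(df, within,
                     group = if (is.null(between)) NULL else ".group")

  rows <- list()
  for (stratum in strata) {
    tab <- stratum[[1]]
    terms_here <- trimws(rownames(tab))
    resid_i <- which(terms_here == "Residuals")
    if (!length(resid_i)) next
    ss_err <- tab[resid_i, "Sum Sq"]
    df_err <- tab[resid_i, "Df"]
    for (i in seq_len(nrow(tab))[-resid_i]) {
      term <- terms_here[i]
      parts <- strsplit(term, ":", fixed = TRUE)[[1]]
      wset <- intersect(parts, within)
      key <- paste(sort(wset), collapse = ":")
      e <- if (length(wset)) eps[[key]] else 1
      ss <- tab[i, "Sum Sq"]
      df1 <- tab[i, "Df"]
      f <- (ss / df1) / (ss_err / df_err)
      label <- if (is.null(between)) term
               else gsub(".group", between, term, fixed = TRUE)
      rows[[length(rows) + 1]] <- data.frame(
        effect = label, ss = ss, ss_error = ss_err,
        df1 = df1, df2 = df_err, epsilon = e,
        df1_gg = e * df1, df2_gg = e * df_err, F = f,
        p_uncorrected = stats::pf(f, df1, df_err, lower.tail = FALSE),
        p = stats::pf(f, e * df1, e * df_err, lower.tail = FALSE),
        partial_eta_sq = ss / (ss + ss_err)
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  attr(out, "n_subjects") <- n_subj
  class(out) <- c("rm_anova_table", class(out))
  out
}

# Greenhouse-Geisser epsilon per within effect, from the pooled (within
# between-group) covariance of the subject x cell score matrix projected on
# the orthonormal effect contrasts: eps = tr(T)^2 / (q * tr(T^2)).
gg_epsilons <- function(df, within, group = NULL) {
  levels_n <- vapply(within, function(w) nlevels(df[[w]]), integer(1))
  # subject x cell matrix, cells ordered first factor slowest, last fastest
  ord <- do.call(order, c(list(df$.subject), df[within]))
  d_ord <- df[ord, ]
  n_cells <- prod(levels_n)
  n_subj <- nlevels(df$.subject)
  y_mat <- matrix(d_ord$.y, nrow = n_subj, ncol = n_cells, byrow = TRUE)
  if (is.null(group)) {
    centred <- scale(y_mat, scale = FALSE)
    pooled_df <- n_subj - 1
  } else {
    g <- tapply(as.character(d_ord$.group), d_ord$.subject, `[`, 1)
    g <- g[levels(d_ord$.subject)]
    centred <- y_mat
    for (lev in unique(g)) {
      sel <- g == lev
      centred[sel, ] <- scale(y_mat[sel, , drop = FALSE], scale = FALSE)
    }
    pooled_df <- n_subj - length(unique(g))
  }
  s_mat <- crossprod(centred) / pooled_df

  contrasts <- lapply(levels_n, function(l) {
    if (l == 1) return(matrix(1, 1, 0))
    qr.Q(qr(cbind(1, stats::contr.helmert(l))))[, -1, drop = FALSE]
  })
  unit <- lapply(levels_n, function(l) matrix(1 / sqrt(l), l, 1))

  subsets <- unlist(lapply(seq_along(within), function(k) {
    utils::combn(seq_along(within), k, simplify = FALSE)
  }), recursive = FALSE)
  eps <- list()
  for (sub in subsets) {
    m <- matrix(1, 1, 1)
    for (j in seq_along(within)) {
      m <- m %x% (if (j %in% sub) contrasts[[j]] else unit[[j]])
    }
    q <- ncol(m)
    key <- paste(sort(within[sub]), collapse = ":")
    if (q <= 1) {
      eps[[key]] <- 1
    } else {
      t_mat <- crossprod(m, s_mat %*% m)
      eps[[key]] <- sum(diag(t_mat))^2 / (q * sum(t_mat^2))
    }
  }
  eps
}

#' @export
print.rm_anova_table <- function(x, digits = 4, ...) {
  cat("Split-plot repeated-measures ANOVA (Greenhouse-Geisser corrected)\n")
  cat(sprintf("  %d complete subjects", attr(x, "n_subjects")))
  if (length(attr(x, "excluded"))) {
    cat(sprintf(", %d excluded listwise", length(attr(x, "excluded"))))
  }
  cat("\n\n")
  show <- data.frame(
    effect = x$effect,
    F = round(x$F, 2),
    df1 = round(x$df1_gg, 2),
    df2 = round(x$df2_gg, 2),
    epsilon = round(x$epsilon, 3),
    p = signif(x$p, 3),
    partial_eta_sq = round(x$partial_eta_sq, 3)
  )
  print(show, row.names = FALSE)
  invisible(x)
}
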