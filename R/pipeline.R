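#' Read and validate a pipeline run configuration
#'
#' The run configuration is a plain-text YAML key/value file (or an
#' equivalent list) with top-level sections:
#' \describe{
#'   \item{`simulation`}{Cohort-simulation parameters (`n_participants`,
#'     `retest_correlation`, `exposure2_shift`, `trait_mean`, `trait_sd`);
#'     mutually exclusive with `input`.}
#'   \item{`input`}{Recorded-data mode: `cohort_table`, a delimited table
#'     with columns `participant_id,exposure,epm_version,trajectory_file`.}
#'   \item{`geometry`}{Overrides `arm_length_cm`, `arm_width_cm`,
#'     `zone_threshold_cm`, `end_threshold_cm`, `bin_size_cm`.}
#'   \item{`intervals`}{`baseline_window_s`, `task_duration_s`, `window_s`.}
#'   \item{`measures`}{Behavioural measures entering the reliability
#'     analysis.}
#'   \item{`seed`, `out_dir`}{Run seed and output directory.}
#' }
#'
#' @param config Path to a YAML file, or a named list.
#' @return A validated config list of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  has_sim <- !is.null(config$simulation)
  has_input <- !is.null(config$input)
  if (has_sim == has_input) {
    stop("config must provide exactly one of 'simulation' or 'input'")
  }
  if (is.null(config$out_dir)) stop("config needs an 'out_dir'")
  if (has_sim && is.null(config$seed)) stop("simulation mode needs a 'seed'")
  geom_args <- config$geometry
  config$geometry_obj <- maze_geometry(
    arm_length = geom_args$arm_length_cm %||% 175,
    arm_width = geom_args$arm_width_cm %||% 30,
    zone_threshold = geom_args$zone_threshold_cm %||% 15,
    end_threshold = geom_args$end_threshold_cm %||% 160,
    bin_size = geom_args$bin_size_cm %||% 10
  )
  config$intervals <- list(
    baseline_window_s = config$intervals$baseline_window_s %||% 30,
    task_duration_s = config$intervals$task_duration_s %||% 300,
    window_s = config$intervals$window_s %||% 30
  )
  config$measures <- config$measures %||%
    c("time_open", "entries_open", "latency_first_open",
      "latency_end_exploration", "total_distance", "mean_velocity_closed")
  class(config) <- c("run_config", "list")
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full scoring and reliability pipeline
#'
#' Executes the pipeline stages in order: simulate (or ingest) the pose
#' streams, score behaviour, build first/second-exposure cohort heatmaps and
#' their difference, aggregate physiology into interval means, and compute
#' the reliability statistics. All outputs are written under the configured
#' output directory along with a manifest (seed, configuration echo, config
#' hash, package version); a rerun with the same configuration reproduces
#' every numeric output exactly.
#'
#' @param config A [run_config()], a list, or a YAML path.
#' @return Invisibly, a list with the scored `metrics` table, `heatmaps`,
#'   `physio` interval table, `stats` report and the `manifest`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  geom <- config$geometry_obj
  iv <- config$intervals
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # -- ingest or simulate ----------------------------------------------------
  sim_mode <- !is.null(config$simulation)
  if (sim_mode) {
    cohort <- stage("simulate", {
      sim <- config$simulation
      cp <- cohort_params(
        n_participants = sim$n_participants %||% 39,
        trait_mean = sim$trait_mean %||% 0,
        trait_sd = sim$trait_sd %||% 1,
        retest_correlation = sim$retest_correlation %||% 0.8,
        exposure2_shift = sim$exposure2_shift %||% 0,
        seed = config$seed
      )
      simulate_cohort(cp, geometry = geom,
                      task_duration = iv$task_duration_s)
    })
    trajectories <- cohort$trajectories
    utils::write.csv(cohort$ground_truth,
                     file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE)
  } else {
    trajectories <- stage("ingest", {
      if (!file.exists(config$input$cohort_table)) {
        stop("no such cohort table: ", config$input$cohort_table)
      }
      tab <- utils::read.csv(config$input$cohort_table)
      base_dir <- dirname(config$input$cohort_table)
      lapply(seq_len(nrow(tab)), function(i) {
        sess <- session_meta(tab$participant_id[i], tab$exposure[i],
                             tab$epm_version[i],
                             task_duration = iv$task_duration_s)
        path <- tab$trajectory_file[i]
        if (!file.exists(path)) path <- file.path(base_dir, path)
        resample_trajectory(read_trajectory(path, sess))
      })
    })
  }

  # -- score -----------------------------------------------------------------
  metrics <- stage("score", score_cohort(trajectories, geom))
  utils::write.csv(metrics, file.path(out_dir, "cohort_metrics.csv"),
                   row.names = FALSE)

  # -- heatmaps --------------------------------------------------------------
  heatmaps <- stage("heatmap", {
    expo <- vapply(trajectories, function(tr) tr$session$exposure,
                   character(1))
    maps <- lapply(trajectories, accumulate_occupancy, geometry = geom)
    m_first <- cohort_mean(maps[expo == "first"])
    m_second <- cohort_mean(maps[expo == "second"])
    list(first = m_first, second = m_second,
         difference = difference_map(m_second, m_first))
  })
  for (nm in names(heatmaps)) {
    write_occupancy(heatmaps[[nm]],
                    file.path(out_dir, sprintf("heatmap_%s.tsv", nm)))
  }

  # -- physiology ------------------------------------------------------------
  physio_tab <- NULL
  if (sim_mode) {
    physio_tab <- stage("physio", {
      ids <- unique(vapply(trajectories,
                           function(tr) tr$session$participant_id,
                           character(1)))
      pg <- config$physio %||% list()
      rows <- list()
      for (channel in c("SCL", "HR", "RESP")) {
        for (id in ids) {
          for (expo in 1:2) {
            pp <- physio_gen_params(
              baseline_level = pg$baseline_level %||% 8,
              onset_response = pg$onset_response %||% 2,
              anticipation = pg$anticipation %||% 0.5,
              sensitization = pg$sensitization %||% 1,
              noise_sd = pg$noise_sd %||% 0.5,
              seed = config$seed + 7919 * expo +
                997 * match(id, ids) +
                104729 * match(channel, c("SCL", "HR", "RESP"))
            )
            series <- simulate_physio(pp, exposure = expo,
                                      channel = channel,
                                      duration = iv$task_duration_s,
                                      baseline_duration =
                                        iv$baseline_window_s)
            im <- interval_means(series, iv$baseline_window_s,
                                 iv$task_duration_s, iv$window_s)
            if (channel == "SCL") im <- log_transform(im)
            rows[[length(rows) + 1]] <- data.frame(
              participant_id = id,
              exposure = c("first", "second")[expo],
              channel = channel, interval = names(im$means),
              transform = im$transform,
              mean_level = unname(im$means))
          }
        }
      }
      do.call(rbind, rows)
    })
    utils::write.csv(physio_tab, file.path(out_dir, "physio_intervals.csv"),
                     row.names = FALSE)
  }

  # -- statistics ------------------------------------------------------------
  stats_report <- stage("stats", {
    measures <- intersect(config$measures, names(metrics))
    cormat <- pearson_matrix(metrics, measures)
    utils::write.csv(cormat, file.path(out_dir, "correlation_matrix.csv"))
    wide <- exposure_wide(metrics, measures)
    iccs <- lapply(measures, function(m) {
      scores <- as.matrix(wide[paste(m, c("first", "second"), sep = ".")])
      scores <- scores[stats::complete.cases(scores), , drop = FALSE]
      if (nrow(scores) < 5) {
        return(list(measure = m, estimate = NA, ci_low = NA, ci_high = NA,
                    n = nrow(scores), note = "fewer than 5 complete pairs"))
      }
      r <- icc_consistency(scores)
      list(measure = m, estimate = r$estimate, ci_low = r$ci_low,
           ci_high = r$ci_high, n = r$n)
    })
    report <- list(
      n_sessions = nrow(metrics),
      measures = measures,
      icc = iccs,
      power = list(d = 0.5, alpha = 0.05, target_power = 0.85,
                   required_n = required_n_paired_t(0.5, 0.05, 0.85))
    )
    if (!is.null(physio_tab)) {
      report$physio <- lapply(c("SCL", "HR", "RESP"), function(channel) {
        ch <- physio_tab[physio_tab$channel == channel, ]
        first_label <- setdiff(unique(ch$interval), "baseline")[1]
        wide_ch <- ch[ch$interval %in% c("baseline", first_label), ]
        base <- wide_ch[wide_ch$interval == "baseline" &
                          wide_ch$exposure == "first", "mean_level"]
        task1 <- wide_ch[wide_ch$interval == first_label &
                           wide_ch$exposure == "first", "mean_level"]
        pt <- paired_t(base, task1)
        aov_tab <- rm_anova(ch, dv = "mean_level",
                            within = c("interval", "exposure"),
                            subject = "participant_id")
        list(channel = channel,
             onset_t = list(t = pt$t, df = pt$df, p = pt$p),
             anova = lapply(seq_len(nrow(aov_tab)), function(i) {
               as.list(aov_tab[i, c("effect", "F", "df1_gg", "df2_gg",
                                    "epsilon", "p", "partial_eta_sq")])
             }))
      })
    }
    report
  })
  jsonlite::write_json(stats_report, file.path(out_dir, "stats_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # -- manifest --------------------------------------------------------------
  echo <- unclass(config)
  echo$geometry_obj <- unclass(geom)
  manifest <- list(
    package = "vrepm",
    version = as.character(utils::packageVersion("vrepm")),
    seed = config$seed,
    mode = if (sim_mode) "simulate" else "ingest",
    config = echo,
    config_hash = config_hash(echo)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(metrics = metrics, heatmaps = heatmaps,
                 physio = physio_tab, stats = stats_report,
                 manifest = manifest))
}

# md5 of the canonical JSON serialization of the configuration
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
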