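#' Parameters of a simulated plus-maze agent
#'
#' The agent is a heading-persistent, goal-directed random walker on the
#' plus-shaped maze surface. At the maze centre it picks a target arm; each
#' open arm is chosen with weight `1 / (1 + anxiety)` against weight 1 per
#' closed arm, so open-arm preference falls logistically in the latent
#' anxiety scale (`anxiety = exp(latent)` makes the open weight
#' `plogis(-latent)`). `anxiety = 0` makes the agent indifferent between arm
#' types; very large values eliminate open-arm visits.
#'
#' @param anxiety Open-arm avoidance strength, dimensionless, >= 0.
#' @param step_speed_mean,step_speed_sd Per-step walking speed distribution
#'   in cm/s (normal, truncated at 0). The defaults give total path lengths
#'   around 15 m per 300-s session, typical of cautious walking with
#'   frequent pausing.
#' @param dwell_persistence Probability of repeating the previous heading at
#'   each step instead of re-aiming at the current waypoint, in [0, 1).
#' @param heading_jitter_sd Angular jitter (degrees) applied when re-aiming.
#' @param reversal_prob Per-step probability of abandoning the current
#'   waypoint and heading back (partial arm visits).
#' @param seed Optional integer seed; identical seeds reproduce the
#'   trajectory exactly.
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(anxiety = 1, step_speed_mean = 5,
                         step_speed_sd = 7, dwell_persistence = 0.6,
                         heading_jitter_sd = 20, reversal_prob = 0.004,
                         seed = NULL) {
  stopifnot(anxiety >= 0, step_speed_mean > 0, step_speed_sd >= 0,
            dwell_persistence >= 0, dwell_persistence < 1,
            heading_jitter_sd >= 0, reversal_prob >= 0, reversal_prob <= 1)
  structure(list(anxiety = anxiety, step_speed_mean = step_speed_mean,
                 step_speed_sd = step_speed_sd,
                 dwell_persistence = dwell_persistence,
                 heading_jitter_sd = heading_jitter_sd,
                 reversal_prob = reversal_prob, seed = seed),
            class = "agent_params")
}

# Evaluate expr under a local RNG state seeded with `seed` (if non-NULL),
# restoring the caller's RNG stream afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulate one plus-maze exposure trajectory
#'
#' Generates a 5 Hz (by default) head-pose stream of an agent walking on the
#' plus-maze: the agent starts at the maze centre, walks toward a waypoint
#' (an arm tip or the centre) with speed and heading noise, is confined to
#' the plus-shaped surface, and on reaching the centre chooses the next arm
#' with open arms down-weighted by its anxiety parameter. Head height and
#' orientation channels carry small smooth noise; they are ingested by the
#' scoring pipeline but do not enter planar metrics.
#'
#' @param params An [agent_params()].
#' @param geometry A [maze_geometry()].
#' @param session A [session_meta()]; its task duration sets the stream
#'   length.
#' @param rate Sampling rate in Hz (default 5).
#' @return A uniformly sampled task-segment [trajectory()] (t from 0 in
#'   steps of 1/rate).
#' @export
simulate_trajectory <- function(params, geometry,
                                session = session_meta("sim"), rate = 5) {
  stopifnot(inherits(params, "agent_params"),
            inherits(geometry, "maze_geometry"))
  with_seed(params$seed, {
    n <- round(session$task_duration * rate)
    dt <- 1 / rate
    hw <- geometry$arm_width / 2
    L <- geometry$arm_length
    # arm unit vectors in (x, z): closed arms along x, open arms along z
    arms <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
    open_arm <- c(FALSE, FALSE, TRUE, TRUE)
    w_arm <- ifelse(open_arm, 1 / (1 + params$anxiety), 1)

    pos <- matrix(0, n, 2)
    p <- c(0, 0)
    heading <- 0
    have_heading <- FALSE
    # pre-drawn per-step randomness; arm choices are drawn lazily
    speeds <- pmax(0, stats::rnorm(n, params$step_speed_mean,
                                   params$step_speed_sd))
    u_rev <- stats::runif(n)
    u_pers <- stats::runif(n)
    jitter <- stats::rnorm(n, 0, params$heading_jitter_sd * pi / 180)
    choose_arm <- function() {
      a <- arms[sample.int(4, 1, prob = w_arm), ]
      a * L
    }
    waypoint <- choose_arm()
    at_center_target <- FALSE
    for (i in seq_len(n)) {
      if (sqrt(sum((p - waypoint)^2)) < hw / 2) {
        if (at_center_target) {
          waypoint <- choose_arm()
          at_center_target <- FALSE
        } else {
          waypoint <- c(0, 0)
          at_center_target <- TRUE
        }
        have_heading <- FALSE
      } else if (u_rev[i] < params$reversal_prob) {
        waypoint <- if (at_center_target) choose_arm() else c(0, 0)
        at_center_target <- !at_center_target
        have_heading <- FALSE
      }
      if (!have_heading || u_pers[i] >= params$dwell_persistence) {
        aim <- atan2(waypoint[2] - p[2], waypoint[1] - p[1])
        heading <- aim + jitter[i]
        have_heading <- TRUE
      }
      cand <- p + speeds[i] * dt * c(cos(heading), sin(heading))
      target_axis <- if (at_center_target) "center"
                     else if (waypoint[1] != 0) "x" else "z"
      p <- clamp_to_maze(cand, p, hw, L, target_axis)
      pos[i, ] <- p
    }
    t <- (seq_len(n) - 1) * dt
    samples <- data.frame(
      t = t,
      x = pos[, 1],
      y = 165 + cumsum(stats::rnorm(n, 0, 0.3)),
      z = pos[, 2],
      rx = wrap_degrees(cumsum(stats::rnorm(n, 0, 2))),
      ry = wrap_degrees(cumsum(stats::rnorm(n, 0, 1))),
      rz = wrap_degrees(cumsum(stats::rnorm(n, 0, 1)))
    )
    trajectory(samples, session, sample_rate = rate)
  })
}

# Project a candidate step onto the plus-shaped surface. An agent inside an
# arm corridor stays in that corridor (lateral coordinate clamped to the
# walls, axial to the tip); an agent in the centre square may only leave it
# through the corridor of its current target arm, so arm entries are gated
# by the arm-choice rule, never by heading noise.
clamp_to_maze <- function(cand, prev, hw, L, target_axis) {
  clamp <- function(v, lo, hi) min(max(v, lo), hi)
  in_center <- abs(prev[1]) <= hw && abs(prev[2]) <= hw
  if (!in_center) {
    if (abs(prev[1]) > hw) {
      # in a closed-arm corridor (along x)
      c(clamp(cand[1], -L, L), clamp(cand[2], -hw, hw))
    } else {
      # in an open-arm corridor (along z)
      c(clamp(cand[1], -hw, hw), clamp(cand[2], -L, L))
    }
  } else if (target_axis == "x") {
    c(clamp(cand[1], -L, L), clamp(cand[2], -hw, hw))
  } else if (target_axis == "z") {
    c(clamp(cand[1], -hw, hw), clamp(cand[2], -L, L))
  } else {
    c(clamp(cand[1], -hw, hw), clamp(cand[2], -hw, hw))
  }
}

#' Parameters of a simulated two-exposure cohort
#'
#' Latent anxiety traits are drawn per participant from a bivariate normal
#' across the two exposures with correlation `retest_correlation`; the
#' second-exposure trait is shifted by `exposure2_shift` (sensitization > 0,
#' habituation < 0). The agent's anxiety is `exp(trait)`, keeping it
#' positive and making the open-arm choice weight `plogis(-trait)`.
#'
#' @param n_participants Cohort size (default 39, split 18/21 across the
#'   Desert and VideoGame environments as in a two-version retest design).
#' @param trait_mean,trait_sd Latent trait distribution (default 0, 1).
#' @param retest_correlation Latent correlation across exposures (default
#'   0.8, the upper range of behavioural retest reliability).
#' @param exposure2_shift Additive latent shift at second exposure
#'   (default 0: stable behaviour).
#' @param version_split Named proportions per EPM version (must sum to 1).
#' @param seed Optional integer seed.
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_participants = 39, trait_mean = 0, trait_sd = 1,
                          retest_correlation = 0.8, exposure2_shift = 0,
                          version_split = c(Desert = 18 / 39,
                                            VideoGame = 21 / 39),
                          seed = NULL) {
  stopifnot(n_participants >= 2, trait_sd >= 0,
            abs(retest_correlation) <= 1,
            abs(sum(version_split) - 1) < 1e-9,
            all(names(version_split) %in% c("Sea", "Desert", "VideoGame")))
  structure(list(n_participants = n_participants, trait_mean = trait_mean,
                 trait_sd = trait_sd,
                 retest_correlation = retest_correlation,
                 exposure2_shift = exposure2_shift,
                 version_split = version_split, seed = seed),
            class = "cohort_params")
}

#' Simulate a two-exposure cohort with known ground truth
#'
#' Draws correlated latent anxiety traits, assigns EPM versions, and
#' generates one trajectory per participant and exposure, each from its own
#' recorded sub-seed.
#'
#' @param params A [cohort_params()].
#' @param agent_defaults An [agent_params()] supplying the non-anxiety
#'   movement parameters.
#' @param geometry A [maze_geometry()].
#' @param task_duration Task length per session in seconds (default 300).
#' @param rate Sampling rate in Hz (default 5).
#' @return List with `trajectories` (list of [trajectory()], one per row of
#'   the ground truth) and `ground_truth` (data frame: `participant_id`,
#'   `exposure`, `epm_version`, `latent_trait`, `anxiety`, `seed`).
#' @export
simulate_cohort <- function(params, agent_defaults = agent_params(),
                            geometry = maze_geometry(), task_duration = 300,
                            rate = 5) {
  stopifnot(inherits(params, "cohort_params"),
            inherits(agent_defaults, "agent_params"))
  with_seed(params$seed, {
    n <- params$n_participants
    rho <- params$retest_correlation
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    trait1 <- params$trait_mean + params$trait_sd * z1
    trait2 <- params$trait_mean + params$trait_sd * z2 +
      params$exposure2_shift
    counts <- diff(c(0, round(cumsum(params$version_split) * n)))
    versions <- rep(names(params$version_split), counts)
    sub_seed <- sample.int(.Machine$integer.max, 2 * n)

    ids <- sprintf("P%03d", seq_len(n))
    gt <- data.frame(
      participant_id = rep(ids, each = 2),
      exposure = rep(c("first", "second"), n),
      epm_version = rep(versions, each = 2),
      latent_trait = as.vector(rbind(trait1, trait2)),
      anxiety = exp(as.vector(rbind(trait1, trait2))),
      seed = sub_seed
    )
    trajectories <- lapply(seq_len(nrow(gt)), function(i) {
      ap <- agent_defaults
      ap$anxiety <- gt$anxiety[i]
      ap$seed <- gt$seed[i]
      sess <- session_meta(gt$participant_id[i], gt$exposure[i],
                           gt$epm_version[i], task_duration = task_duration)
      simulate_trajectory(ap, geometry, sess, rate = rate)
    })
    list(trajectories = trajectories, ground_truth = gt)
  })
}

#' Parameters of the simulated physiological response
#'
#' The generative model is piecewise constant plus white noise: a baseline
#' level before task onset and an elevated level during the task. Repeated
#' exposure adds an anticipatory baseline elevation and scales the task
#' onset response by a multiplicative sensitization factor (values < 1 model
#' habituation, e.g. the blunted second-exposure heart-rate response).
#' Defaults are on a skin-conductance-like scale (microsiemens).
#'
#' @param baseline_level Pre-task channel level (default 8).
#' @param onset_response Additive task-onset increase (default 2).
#' @param anticipation Additive baseline elevation at second exposure
#'   (default 0.5).
#' @param sensitization Multiplier on the onset response at second exposure
#'   (default 1).
#' @param noise_sd White-noise standard deviation (default 0.5).
#' @param seed Optional integer seed.
#' @return An object of class `physio_gen_params`.
#' @export
physio_gen_params <- function(baseline_level = 8, onset_response = 2,
                              anticipation = 0.5, sensitization = 1,
                              noise_sd = 0.5, seed = NULL) {
  stopifnot(noise_sd >= 0, sensitization >= 0)
  structure(list(baseline_level = baseline_level,
                 onset_response = onset_response,
                 anticipation = anticipation, sensitization = sensitization,
                 noise_sd = noise_sd, seed = seed),
            class = "physio_gen_params")
}

#' Simulate one physiological channel recording
#'
#' @param params A [physio_gen_params()].
#' @param exposure 1 (first) or 2 (second testing).
#' @param channel Channel label for the resulting series (default `"SCL"`).
#' @param duration Task length in seconds (default 300).
#' @param baseline_duration Baseline length in seconds (default 30).
#' @param rate Sampling rate in Hz (default 5).
#' @return A [physio_series()] covering `[-baseline_duration, duration)`.
#' @export
simulate_physio <- function(params, exposure = 1,
                            channel = c("SCL", "HR", "RESP"),
                            duration = 300, baseline_duration = 30,
                            rate = 5) {
  stopifnot(inherits(params, "physio_gen_params"), exposure %in% c(1, 2))
  channel <- match.arg(channel)
  with_seed(params$seed, {
    dt <- 1 / rate
    t <- seq(-baseline_duration, duration - dt, by = dt)
    base <- params$baseline_level +
      if (exposure == 2) params$anticipation else 0
    task <- base + params$onset_response *
      (if (exposure == 2) params$sensitization else 1)
    level <- ifelse(t < 0, base, task)
    physio_series(t, level + stats::rnorm(length(t), 0, params$noise_sd),
                  channel)
  })
}
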