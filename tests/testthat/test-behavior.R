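geom <- maze_geometry()

test_that("dwell times credit one sample period per sample to its zone", {
  traj <- make_traj(x = rep(0, 10), z = rep(100, 10))
  d <- dwell_times(traj, geom)
  expect_equal(d[["open"]], 2.0)
  expect_equal(d[["closed"]], 0)
  expect_equal(d[["center"]], 0)

  still <- make_traj(x = rep(0, 50), z = rep(0, 50))
  d2 <- dwell_times(still, geom)
  expect_equal(d2[["center"]], 10)
  expect_equal(sum(d2), 10)
})

test_that("entries count not-in-zone to in-zone transitions on either arm", {
  traj <- make_traj(x = rep(0, 5), z = c(0, 20, 20, 0, 20))
  expect_equal(count_entries(traj, geom, "open"), 2)
  expect_equal(count_entries(traj, geom, "closed"), 0)
  # both arms of a type pool into one count
  both <- make_traj(x = rep(0, 5), z = c(0, 100, 0, -100, 0))
  expect_equal(count_entries(both, geom, "open"), 2)
  const <- make_traj(x = rep(100, 10), z = rep(0, 10))
  expect_equal(count_entries(const, geom, "closed"), 0)
})

test_that("open-arm latencies follow the censoring convention", {
  starts_open <- make_traj(x = rep(0, 10), z = rep(50, 10),
                           task_duration = 300)
  expect_equal(latency_first_open(starts_open, geom),
               list(latency = 0, censored = FALSE))

  never <- make_traj(x = rep(100, 1500), z = rep(0, 1500),
                     task_duration = 300)
  expect_equal(latency_first_open(never, geom),
               list(latency = 300, censored = TRUE))
  expect_equal(latency_end_exploration(never, geom),
               list(latency = 300, censored = TRUE))

  # enters the open zone at a known sample
  z <- c(rep(0, 367), seq(16, 175, length.out = 400),
         rep(100, 1500 - 367 - 400))
  enters <- make_traj(x = rep(0, 1500), z = z, task_duration = 300)
  expect_equal(latency_first_open(enters, geom)$latency, 367 * 0.2)
  first_end <- which(z >= geom$end_threshold)[1]
  expect_equal(latency_end_exploration(enters, geom)$latency,
               (first_end - 1) * 0.2)
  tip <- make_traj(x = rep(0, 10), z = rep(170, 10))
  expect_equal(latency_end_exploration(tip, geom)$latency, 0)
})

test_that("distance is the horizontal path length in metres", {
  still <- make_traj(x = rep(3, 20), z = rep(8, 20))
  expect_equal(total_distance(still), 0)
  walk <- make_traj(x = rep(0, 176), z = seq(0, 175, by = 1))
  expect_equal(total_distance(walk), 1.75, tolerance = 1e-9)
  # vertical head bobbing does not add distance
  bob <- make_traj(x = rep(0, 20), z = rep(0, 20), y = runif(20, 150, 180))
  expect_equal(total_distance(bob), 0)
})

test_that("mean zone velocity averages steps fully inside the zone", {
  closed_walk <- make_traj(x = seq(30, 120, by = 2), z = rep(0, 46))
  expect_equal(mean_velocity(closed_walk, geom, "closed"), 10)
  expect_true(is.na(mean_velocity(closed_walk, geom, "open")))
})

test_that("summaries satisfy the time-partition and censoring invariants", {
  center_only <- make_traj(x = rep(0, 1500), z = rep(0, 1500),
                           task_duration = 300)
  s <- summarize_behavior(center_only, geom)
  expect_equal(s$time_open, 0)
  expect_equal(s$time_closed, 0)
  expect_equal(s$entries_open, 0)
  expect_true(s$censored_latency_first && s$censored_latency_end)
  expect_equal(s$latency_first_open, 300)

  for (seed in 1:5) {
    tr <- simulate_trajectory(agent_params(seed = seed), geom)
    s <- summarize_behavior(tr, geom)
    expect_equal(s$time_open + s$time_closed + s$time_center, 300,
                 tolerance = 0.2 / 300)
    expect_lte(s$latency_first_open, s$latency_end_exploration)
    expect_equal(s$entries_open == 0, s$time_open == 0)
  }
})

test_that("scored metrics match the brute-force per-sample oracle", {
  set.seed(31)
  for (rep in 1:8) {
    traj <- random_traj(n = 600)
    got <- summarize_behavior(traj, geom)
    want <- oracle_metrics(traj, geom)
    for (f in names(want)) {
      expect_equal(got[[f]], want[[f]], tolerance = 1e-9, label = f)
    }
  }
})

test_that("time reversal preserves dwell times and distance", {
  set.seed(32)
  traj <- random_traj(n = 500)
  rev_samples <- traj$samples
  rev_samples[, -1] <- rev_samples[nrow(rev_samples):1, -1]
  rev_traj <- trajectory(rev_samples, traj$session,
                         sample_rate = traj$sample_rate)
  expect_equal(dwell_times(rev_traj, geom), dwell_times(traj, geom))
  expect_equal(total_distance(rev_traj), total_distance(traj))
})

test_that("cohort scoring produces one labelled row per session", {
  trajs <- lapply(1:4, function(i) {
    simulate_trajectory(
      agent_params(seed = i), geom,
      session_meta(sprintf("P%d", (i + 1) %/% 2),
                   exposure = c("first", "second")[1 + (i + 1) %% 2],
                   epm_version = "Desert"))
  })
  tab <- score_cohort(trajs, geom)
  expect_equal(nrow(tab), 4)
  expect_setequal(unique(tab$exposure), c("first", "second"))
  expect_true(all(c("time_open", "entries_open", "total_distance")
                  %in% names(tab)))
})
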