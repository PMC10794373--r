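geom <- maze_geometry()

test_that("trajectory simulation is deterministic given a seed", {
  a <- simulate_trajectory(agent_params(seed = 99), geom)
  b <- simulate_trajectory(agent_params(seed = 99), geom)
  expect_identical(a$samples, b$samples)
  c <- simulate_trajectory(agent_params(seed = 100), geom)
  expect_false(identical(a$samples, c$samples))
})

test_that("simulated agents stay on the plus-shaped maze surface", {
  for (seed in 1:5) {
    tr <- simulate_trajectory(agent_params(seed = seed), geom)
    expect_true(all(on_maze(tr$samples$x, tr$samples$z, geom)))
    expect_equal(nrow(tr$samples), 1500)
    expect_equal(tr$sample_rate, 5)
  }
})

test_that("extreme anxiety eliminates open-arm time", {
  for (seed in 1:4) {
    tr <- simulate_trajectory(agent_params(anxiety = Inf, seed = seed), geom)
    expect_equal(dwell_times(tr, geom)[["open"]], 0)
    expect_equal(count_entries(tr, geom, "open"), 0)
  }
})

test_that("zero anxiety splits arm time symmetrically", {
  open_t <- closed_t <- numeric(100)
  for (seed in seq_len(100)) {
    tr <- simulate_trajectory(agent_params(anxiety = 0, seed = 1000 + seed),
                              geom)
    d <- dwell_times(tr, geom)
    open_t[seed] <- d[["open"]]
    closed_t[seed] <- d[["closed"]]
  }
  expect_lt(abs(mean(open_t) - mean(closed_t)), 0.10 * 300)
})

test_that("mean open-arm time decreases with anxiety", {
  means <- vapply(c(0, 1, 5, 100), function(anx) {
    mean(vapply(1:30, function(seed) {
      tr <- simulate_trajectory(agent_params(anxiety = anx, seed = 500 + seed),
                                geom)
      dwell_times(tr, geom)[["open"]]
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("cohorts reproduce the design: size, split, latent correlation", {
  cp <- cohort_params(seed = 71)
  sim <- simulate_cohort(cp, geometry = geom, task_duration = 20)
  gt <- sim$ground_truth
  expect_equal(nrow(gt), 78)
  expect_length(sim$trajectories, 78)
  split <- table(gt$epm_version[gt$exposure == "first"])
  expect_equal(unname(split[c("Desert", "VideoGame")]), c(18L, 21L),
               ignore_attr = TRUE)
  expect_identical(
    sim$ground_truth,
    simulate_cohort(cp, geometry = geom, task_duration = 20)$ground_truth)
})

test_that("perfect retest correlation with zero shift copies latent traits", {
  cp <- cohort_params(n_participants = 10, retest_correlation = 1,
                      exposure2_shift = 0, seed = 72)
  gt <- simulate_cohort(cp, geometry = geom, task_duration = 10)$ground_truth
  first <- gt$latent_trait[gt$exposure == "first"]
  second <- gt$latent_trait[gt$exposure == "second"]
  expect_equal(first, second, tolerance = 1e-12)

  shifted <- cohort_params(n_participants = 10, retest_correlation = 1,
                           exposure2_shift = 0.4, seed = 72)
  gt2 <- simulate_cohort(shifted, geometry = geom,
                         task_duration = 10)$ground_truth
  expect_equal(gt2$latent_trait[gt2$exposure == "second"],
               first + 0.4, tolerance = 1e-12)
})

test_that("sampled latent pairs recover the requested correlation", {
  cp <- cohort_params(n_participants = 5000, retest_correlation = 0.8,
                      seed = 73)
  # draw traits only: a 1-sample trajectory keeps this cheap
  gt <- simulate_cohort(cp, geometry = geom, task_duration = 0.2,
                        rate = 5)$ground_truth
  first <- gt$latent_trait[gt$exposure == "first"]
  second <- gt$latent_trait[gt$exposure == "second"]
  expect_equal(cor(first, second), 0.8, tolerance = 0.05)
  expect_equal(sd(first), 1, tolerance = 0.05)
  expect_equal(mean(first), 0, tolerance = 0.05)
  expect_equal(gt$anxiety, exp(gt$latent_trait))
})

test_that("noiseless physiology reproduces the programmed levels", {
  pp <- physio_gen_params(baseline_level = 6, onset_response = 1.5,
                          anticipation = 0.7, sensitization = 1.4,
                          noise_sd = 0, seed = 74)
  s1 <- simulate_physio(pp, exposure = 1)
  im1 <- interval_means(s1)
  expect_equal(unname(im1$means), c(6, rep(7.5, 10)))
  s2 <- simulate_physio(pp, exposure = 2)
  im2 <- interval_means(s2)
  expect_equal(unname(im2$means[1]), 6 + 0.7)
  expect_equal(unname(im2$means[2]), 6 + 0.7 + 1.5 * 1.4)
  # anticipation appears only in the baseline difference
  expect_equal(unname(im2$means[1] - im1$means[1]), 0.7)
})

test_that("physio simulation spans baseline and task and is seeded", {
  pp <- physio_gen_params(seed = 75)
  s <- simulate_physio(pp)
  expect_equal(min(s$t), -30)
  expect_lt(max(s$t), 300)
  expect_identical(simulate_physio(pp)$values, s$values)
})
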