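test_that("pearson matrix reproduces the textbook covariance formula", {
  set.seed(51)
  n <- 10
  tab <- data.frame(
    participant_id = rep(sprintf("p%02d", 1:n), 2),
    exposure = rep(c("first", "second"), each = n),
    a = rnorm(2 * n), b = rnorm(2 * n)
  )
  m <- pearson_matrix(tab, c("a", "b"))
  expect_equal(dim(m), c(4, 4))
  expect_equal(unname(diag(m)), rep(1, 4))
  expect_equal(m, t(m))
  # textbook oracle for one off-diagonal cell
  x <- tab$a[tab$exposure == "first"]
  y <- tab$a[tab$exposure == "second"]
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(m["a.first", "a.second"], r_hand, tolerance = 1e-12)
  # exact linear relation
  tab$c <- NA_real_
  tab$c[tab$exposure == "first"] <- x
  tab$c[tab$exposure == "second"] <- 2 * x + 1
  m2 <- pearson_matrix(tab, "c")
  expect_equal(m2["c.first", "c.second"], 1)
})

test_that("constant measures yield missing correlation cells", {
  tab <- data.frame(participant_id = rep(1:6, 2),
                    exposure = rep(c("first", "second"), each = 6),
                    a = c(rnorm(6), rep(3, 6)))
  m <- pearson_matrix(tab, "a")
  expect_true(is.na(m["a.first", "a.second"]))
  expect_equal(m["a.second", "a.second"], 1)
})

test_that("consistency ICC matches a from-scratch mean-squares decomposition", {
  # crafted 8-subject two-occasion table
  scores <- cbind(first = c(12, 15, 11, 18, 21, 14, 16, 19),
                  second = c(13, 14, 12, 19, 20, 16, 15, 21))
  r <- icc_consistency(scores)
  # independent decomposition: two-way ANOVA without replication
  n <- nrow(scores); k <- ncol(scores)
  grand <- mean(scores)
  ss_sub <- k * sum((rowMeans(scores) - grand)^2)
  ss_occ <- n * sum((colMeans(scores) - grand)^2)
  ss_err <- sum((scores - grand)^2) - ss_sub - ss_occ
  msb <- ss_sub / (n - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  expect_equal(r$estimate, (msb - mse) / (msb + (k - 1) * mse),
               tolerance = 1e-9)
  expect_equal(r$ms_between, msb, tolerance = 1e-9)
  expect_equal(r$ms_error, mse, tolerance = 1e-9)
  expect_true(r$ci_low <= r$estimate && r$estimate <= r$ci_high)
  expect_lte(r$estimate, 1)
})

test_that("consistency ICC ignores additive occasion shifts", {
  set.seed(52)
  x <- rnorm(12, 50, 8)
  expect_equal(icc_consistency(cbind(x, x))$estimate, 1)
  shifted <- icc_consistency(cbind(x, x + 7.5))
  expect_equal(shifted$estimate, 1)
  expect_equal(shifted$ci_high, 1)
})

test_that("degenerate ICC inputs are flagged, not silently numeric", {
  r <- icc_consistency(matrix(5, nrow = 6, ncol = 2))
  expect_true(r$degenerate)
  expect_true(is.na(r$estimate))
  expect_error(icc_consistency(cbind(c(1, 2, NA, 4, 5), 1:5)), "complete")
})

test_that("ICC approaches pearson r when occasions share mean and variance", {
  set.seed(53)
  n <- 4000
  rho <- 0.7
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  r_icc <- icc_consistency(cbind(x, y))$estimate
  r_pearson <- cor(x, y)
  expect_equal(r_icc, r_pearson, tolerance = 0.02)
})

test_that("paired t equals the longhand difference formula", {
  set.seed(54)
  x <- rnorm(10, 5); y <- rnorm(10, 4.5)
  res <- paired_t(x, y)
  d <- x - y
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, 9)
  expect_equal(res$p, 2 * pt(-abs(t_hand), 9), tolerance = 1e-12)
  expect_false(res$degenerate)
})

test_that("degenerate paired differences are flagged", {
  x <- c(1, 2, 3, 4)
  same <- paired_t(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_true(same$degenerate)
  shift <- paired_t(x + 2, x)
  expect_true(shift$degenerate)
  expect_true(is.infinite(shift$t))
  expect_error(paired_t(1:2, 2:3), "at least 3")
})

test_that("exact power search reproduces the planned sample sizes", {
  expect_identical(required_n_paired_t(0.5, 0.05, 0.85), 38L)
  expect_identical(required_n_paired_t(0.5, 0.05, 0.80), 34L)
})

test_that("required n is minimal and monotone in effect size", {
  for (d in c(0.3, 0.5, 0.8)) {
    n <- required_n_paired_t(d, 0.05, 0.85)
    expect_gte(power_paired_t(n, d), 0.85)
    if (n > 2) expect_lt(power_paired_t(n - 1, d), 0.85)
  }
  ns <- vapply(c(0.2, 0.35, 0.5, 0.8), required_n_paired_t,
               integer(1), alpha = 0.05, power = 0.85)
  expect_true(all(diff(ns) <= 0))
  # power monotone in n
  pw <- vapply(c(10, 20, 40, 80), power_paired_t, numeric(1), d = 0.4)
  expect_true(all(diff(pw) > 0))
})
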