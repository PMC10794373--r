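# Crafted split-plot dataset: 6 subjects, within factor with 3 levels,
# between factor with 2 groups.
make_splitplot <- function(seed = 61) {
  set.seed(seed)
  n <- 6
  d <- expand.grid(participant_id = sprintf("s%d", 1:n),
                   time = factor(c("t1", "t2", "t3")))
  d$group <- factor(ifelse(as.integer(sub("s", "", d$participant_id)) <= 3,
                           "Desert", "VideoGame"))
  subj <- rnorm(n, 0, 2)
  d$y <- subj[as.integer(sub("s", "", d$participant_id))] +
    as.numeric(d$time) * 0.8 + (d$group == "VideoGame") * 1.5 +
    rnorm(nrow(d), 0, 1)
  d
}

test_that("split-plot sums of squares match the cell-means hand computation", {
  d <- make_splitplot()
  tab <- rm_anova(d, "y", within = "time", between = "group")
  n <- 6; a <- 3; g <- 2; n_g <- 3
  grand <- mean(d$y)
  subj_means <- tapply(d$y, d$participant_id, mean)
  grp_of <- tapply(as.character(d$group), d$participant_id, `[`, 1)
  grp_means <- tapply(d$y, d$group, mean)
  time_means <- tapply(d$y, d$time, mean)
  cell_means <- tapply(d$y, list(d$group, d$time), mean)

  ss_group <- a * n_g * sum((grp_means - grand)^2)
  ss_subj_within <- a * sum((subj_means - grp_means[grp_of])^2)
  ss_time <- n * sum((time_means - grand)^2)
  ss_gt <- n_g * sum((sweep(sweep(cell_means, 1, grp_means),
                            2, time_means) + grand)^2)
  ss_err_within <- sum((d$y - subj_means[d$participant_id] -
                          cell_means[cbind(as.character(d$group),
                                           as.character(d$time))] +
                          grp_means[as.character(d$group)])^2)

  get <- function(eff) tab[tab$effect == eff, ]
  expect_equal(get("group")$ss, unname(ss_group), tolerance = 1e-9)
  expect_equal(get("group")$ss_error, unname(ss_subj_within),
               tolerance = 1e-9)
  expect_equal(get("time")$ss, unname(ss_time), tolerance = 1e-9)
  expect_equal(get("group:time")$ss, unname(ss_gt), tolerance = 1e-9)
  expect_equal(get("time")$ss_error, unname(ss_err_within), tolerance = 1e-9)
  expect_equal(get("group")$df1, 1)
  expect_equal(get("group")$df2, 4)
  expect_equal(get("time")$df1, 2)
  expect_equal(get("time")$df2, 8)
  # F and partial eta squared follow from the same quantities
  expect_equal(get("time")$F,
               (ss_time / 2) / (ss_err_within / 8), tolerance = 1e-9)
  expect_equal(get("time")$partial_eta_sq,
               ss_time / (ss_time + ss_err_within), tolerance = 1e-9)
})

test_that("the GG-corrected mixed ANOVA agrees with an independent MLM route", {
  skip_if_not_installed("car")
  d <- make_splitplot(62)
  tab <- rm_anova(d, "y", within = "time", between = "group")

  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  dw <- d[order(d$participant_id, d$time), ]
  Y <- matrix(dw$y, nrow = 6, byrow = TRUE)
  grp <- factor(tapply(as.character(dw$group), dw$participant_id, `[`, 1)
                [levels(dw$participant_id)])
  aa <- car::Anova(lm(Y ~ grp), idata = data.frame(time = factor(1:3)),
                   idesign = ~time, type = 3)
  s <- suppressWarnings(summary(aa, multivariate = FALSE))
  u <- s$univariate.tests
  expect_equal(tab[tab$effect == "time", "F"], u["time", "F value"],
               tolerance = 1e-9)
  expect_equal(tab[tab$effect == "group", "F"], u["grp", "F value"],
               tolerance = 1e-9)
  expect_equal(tab[tab$effect == "time", "epsilon"],
               unname(s$pval.adjustments["time", "GG eps"]),
               tolerance = 1e-9)
  expect_equal(tab[tab$effect == "time", "p"],
               unname(s$pval.adjustments["time", "Pr(>F[GG])"]),
               tolerance = 1e-9)
})

test_that("a two-level within factor reproduces the paired t-test", {
  set.seed(63)
  n <- 12
  x <- rnorm(n, 10, 3)
  y <- x + 0.8 + rnorm(n, 0, 1)
  d <- data.frame(participant_id = rep(sprintf("s%d", 1:n), 2),
                  exposure = rep(c("first", "second"), each = n),
                  y = c(x, y))
  tab <- rm_anova(d, "y", within = "exposure")
  pt <- paired_t(x, y)
  expect_equal(tab$F[1], pt$t^2, tolerance = 1e-6)
  expect_equal(tab$p[1], pt$p, tolerance = 1e-9)
  expect_equal(tab$epsilon[1], 1)
  expect_equal(tab$df1[1], 1)
  expect_equal(tab$df2[1], n - 1)
})

test_that("epsilon is 1 for single-df effects and in (0, 1] otherwise", {
  d <- make_splitplot(64)
  tab <- rm_anova(d, "y", within = "time", between = "group")
  eps <- tab$epsilon[tab$effect == "time"]
  expect_gt(eps, 0)
  expect_lte(eps, 1)
  # 3-level factor: GG epsilon bounded below by 1/(k-1)
  expect_gte(eps, 0.5)
  expect_equal(tab$epsilon[tab$effect == "group"], 1)
})

test_that("equal cell means with subject variance give F of zero", {
  set.seed(67)
  n <- 8
  subj <- rnorm(n, 0, 5)
  noise <- scale(matrix(rnorm(n * 3), n, 3), scale = FALSE) # zero cell means
  d <- expand.grid(participant_id = sprintf("s%d", 1:n),
                   time = factor(1:3))
  d$y <- subj[as.integer(sub("s", "", d$participant_id))] + as.vector(noise)
  tab <- rm_anova(d, "y", within = "time")
  expect_equal(tab$F[1], 0, tolerance = 1e-12)
})

test_that("incomplete subjects are excluded listwise and logged", {
  d <- make_splitplot(65)
  d <- d[!(d$participant_id == "s2" & d$time == "t2"), ]
  d$y[d$participant_id == "s5" & d$time == "t1"] <- NA
  tab <- rm_anova(d, "y", within = "time", between = "group")
  expect_setequal(attr(tab, "excluded"), c("s2", "s5"))
  expect_equal(attr(tab, "n_subjects"), 4)
  expect_error(rm_anova(d[d$participant_id %in% c("s1", "s3", "s4"), ],
                        "y", within = "time", between = "group"),
               "at least 2")
})

test_that("two within factors produce the full effect set with shared errors", {
  set.seed(66)
  n <- 6
  d <- expand.grid(participant_id = sprintf("s%d", 1:n),
                   interval = factor(1:4),
                   exposure = factor(c("first", "second")))
  d$y <- rnorm(nrow(d)) + as.numeric(d$interval) * 0.5
  tab <- rm_anova(d, "y", within = c("interval", "exposure"))
  expect_setequal(tab$effect,
                  c("interval", "exposure", "interval:exposure"))
  expect_equal(tab$df1[tab$effect == "interval"], 3)
  expect_equal(tab$df2[tab$effect == "interval"], 15)
  expect_equal(tab$df1[tab$effect == "interval:exposure"], 3)
  # interactions inherit the epsilon of their own contrast space
  expect_equal(tab$epsilon[tab$effect == "exposure"], 1)
})
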