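test_that("studentized-range quadrature reproduces independent reference values", {
  # frozen reference CDF values computed with an independent implementation
  # of the same double integral (scipy.stats.studentized_range 1.17.1)
  ref <- data.frame(
    q = c(2.5, 3.9, 1.2, 5.5, 0.8, 4.4, 6.0),
    k = c(3, 2, 4, 3, 2, 4, 2),
    df = c(10.5, 4.2, 33.7, 200.0, 2.5, 7.77, 500.0),
    p = c(0.77295009901777, 0.95170547114097, 0.16912947679196,
          0.99959889449047, 0.38167342638024, 0.94152917552793,
          0.99997367019119))
  got <- mapply(function(q, k, df) ptukey_num(q, k, df), ref$q, ref$k, ref$df)
  expect_lt(max(abs(got - ref$p)), 1e-9)
  # quantile function inverts the CDF
  expect_equal(ptukey_num(qtukey_num(0.95, 3, 30), 3, 30), 0.95,
               tolerance = 1e-9)
  # k = 2 closed form: P(Q > sqrt(2) t) = two-sided t tail
  for (tval in c(0.5, 1.7, 3.2)) {
    expect_equal(ptukey_num(sqrt(2) * tval, 2, 11.3, lower.tail = FALSE),
                 2 * pt(tval, 11.3, lower.tail = FALSE), tolerance = 1e-10)
  }
})

test_that("Welch ANOVA matches stats::oneway.test on random small datasets", {
  ds <- oracle_datasets()
  worst <- 0
  for (d in ds) {
    mine <- welch_anova(d$x, d$g)
    ref <- oneway.test(x ~ g, data.frame(x = d$x, g = d$g), var.equal = FALSE)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$df2, unname(ref$parameter[2]), tolerance = 1e-8)
    worst <- max(worst, abs(mine$p.value - ref$p.value))
  }
  expect_lt(worst, 1e-10)
})

test_that("two-group Welch F equals the square of Welch's t", {
  withr::local_seed(10)
  for (i in 1:20) {
    x <- rnorm(14, sd = 2); y <- rnorm(9, mean = 0.5)
    w <- welch_anova(c(x, y), rep(c("a", "b"), c(14, 9)))
    tt <- t.test(x, y, var.equal = FALSE)
    expect_equal(w$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(w$p.value, tt$p.value, tolerance = 1e-10)
    expect_equal(w$df2, unname(tt$parameter), tolerance = 1e-10)
  }
})

test_that("identical groups give F = 0 and p = 1", {
  w <- welch_anova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(w$statistic, 0)
  expect_equal(w$p.value, 1)
})

test_that("degenerate groups are rejected with informative errors", {
  expect_error(welch_anova(c(1, 1, 1, 2, 3, 4), rep(c("a", "b"), each = 3)),
               "zero-variance group\\(s\\): a", class = "fp_degenerate_variance")
  expect_error(welch_anova(c(1, 2, 3), c("a", "a", "b")), "fewer than 2")
  expect_error(welch_anova(1:5, rep("a", 5)), "at least 2 groups")
})

test_that("balanced equal-variance groups recover the classic ANOVA F", {
  # with two groups of equal n and equal sample variance the Welch
  # correction term vanishes and Welch F equals the classic F exactly
  x <- c(1, 2, 3, 11, 13, 15)
  g <- rep(c("a", "b"), each = 3)
  w <- welch_anova(x, g)
  classic <- anova(lm(x ~ g))
  expect_equal(w$statistic, classic$`F value`[1], tolerance = 1e-10)
  # with k >= 3 the small-sample correction decays with n: the two
  # statistics converge as groups grow at equal size and variance
  for (n_rep in c(20, 200)) {
    xx <- rep(c(0, 5, 9), each = 3 * n_rep) + rep(c(1, 2, 3), times = 3 * n_rep)
    gg <- rep(c("a", "b", "c"), each = 3 * n_rep)
    wk <- welch_anova(xx, gg)
    ck <- anova(lm(xx ~ gg))$`F value`[1]
    expect_equal(wk$statistic / ck, 1, tolerance = 2 / (3 * n_rep))
  }
})

test_that("location shifts act on contrasts, not on the F statistic", {
  withr::local_seed(3)
  x <- rnorm(30); g <- rep(c("a", "b", "c"), 10)
  w0 <- welch_anova(x, g)
  w1 <- welch_anova(x + 100, g)
  expect_equal(w0$statistic, w1$statistic, tolerance = 1e-9)
  expect_equal(w0$p.value, w1$p.value, tolerance = 1e-9)
  gh0 <- games_howell(x, g)
  x2 <- x + 5 * (g == "a")
  gh2 <- games_howell(x2, g)
  shifted <- gh0$group1 == "a"
  expect_equal(gh2$mean_diff[shifted], gh0$mean_diff[shifted] + 5,
               tolerance = 1e-9)
  expect_equal(gh2$mean_diff[!shifted], gh0$mean_diff[!shifted],
               tolerance = 1e-9)
})

test_that("Games-Howell matches the frozen reference implementation", {
  ds <- oracle_datasets()
  orc <- utils::read.csv(test_path("gh_oracle.csv"))
  worst_p <- 0; worst_diff <- 0; worst_df <- 0
  for (i in seq_along(ds)) {
    gh <- games_howell(ds[[i]]$x, ds[[i]]$g)
    o <- orc[orc$dataset == i, ]
    m <- merge(gh, o, by = c("group1", "group2"),
               suffixes = c("", ".ref"))
    expect_equal(nrow(m), nrow(gh))
    worst_p <- max(worst_p, abs(m$p_adj - m$pval))
    worst_diff <- max(worst_diff, abs(m$mean_diff - m$mean_diff.ref))
    worst_df <- max(worst_df, abs(m$df - m$df.ref))
  }
  expect_lt(worst_p, 1e-6)
  expect_lt(worst_diff, 1e-8)
  expect_lt(worst_df, 1e-6)
})

test_that("Games-Howell with two groups reduces to the Welch t-test", {
  withr::local_seed(8)
  x <- rnorm(12, sd = 3); y <- rnorm(20, mean = 1)
  gh <- games_howell(c(x, y), rep(c("a", "b"), c(12, 20)), conf.level = 0.95)
  tt <- t.test(x, y, var.equal = FALSE, conf.level = 0.95)
  expect_equal(gh$p_adj, tt$p.value, tolerance = 1e-10)
  expect_equal(c(gh$ci_low, gh$ci_high), as.numeric(tt$conf.int),
               tolerance = 1e-9)
})

test_that("identical groups yield null contrasts with CIs straddling zero", {
  x <- rep(c(1, 2, 3, 4), 3)
  g <- rep(c("a", "b", "c"), each = 4)
  gh <- games_howell(x, g)
  expect_true(all(gh$mean_diff == 0))
  expect_true(all(gh$ci_low < 0 & gh$ci_high > 0))
  expect_true(all(gh$p_adj > 0.999))
  # pair-swap antisymmetry: recompute with relabeled groups
  g2 <- c("b", "a", "c")[match(g, c("a", "b", "c"))]
  gh2 <- games_howell(x, g2)
  ab <- gh$mean_diff[gh$group1 == "a" & gh$group2 == "b"]
  ba <- gh2$mean_diff[gh2$group1 == "a" & gh2$group2 == "b"]
  expect_equal(ab, -ba)
})

test_that("phase summary reports per-phase means of both endpoints", {
  f <- tibble::tibble(
    period_start = as.Date("2017-01-01") + 0:5,
    frequency = c(2, 4, 6, 1, 3, 5),
    volume = c(0.2, 0.4, 0.6, 0.1, 0.3, 0.5),
    severity = factor(rep(c("none", "moderate"), each = 3),
                      levels = c("none", "mild", "moderate", "severe")),
    severity_merged = factor(rep(c("none", "symptomatic"), each = 3),
                             levels = c("none", "symptomatic")))
  ps <- phase_summary(f)
  expect_equal(ps$mean_frequency[ps$phase == "none"], 4)
  expect_equal(ps$mean_volume[ps$phase == "moderate"], 0.3)
  single <- phase_summary(f[f$severity == "none", ])
  expect_equal(single$mean_frequency, 4)
})
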