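test_that("default generated life chart reproduces the case-study aggregates", {
  ch <- generate_lifechart(synthetic_config(seed = 1))
  es <- episode_summary(ch)
  expect_equal(es$episodes[es$severity == "mild"], 2)
  expect_equal(es$months[es$severity == "mild"], 5)
  expect_equal(es$episodes[es$severity == "moderate"], 5)
  expect_equal(es$months[es$severity == "moderate"], 9)
  # identical to the packaged fixture layout
  expect_equal(as.data.frame(ch), as.data.frame(case_study_lifechart()))
})

test_that("zero-episode configs give an all-none chart", {
  cfg <- synthetic_config(mild_episodes = 0, mild_months = 0,
                          moderate_episodes = 0, moderate_months = 0, seed = 2)
  ch <- generate_lifechart(cfg)
  expect_true(all(ch$mania == "none"))
  expect_equal(nrow(ch), 24)
})

test_that("randomized placements keep the aggregate episode constraints", {
  cfg <- synthetic_config(seed = 1)
  withr::local_seed(500)
  for (i in 1:100) {
    ch <- generate_lifechart(cfg, randomize = TRUE)
    es <- episode_summary(ch)
    expect_equal(es$episodes[es$severity == "mild"], 2)
    expect_equal(es$months[es$severity == "mild"], 5)
    expect_equal(es$episodes[es$severity == "moderate"], 5)
    expect_equal(es$months[es$severity == "moderate"], 9)
  }
})

test_that("infeasible episode specifications are rejected", {
  expect_error(synthetic_config(months = 10), "exceed the span")
  expect_error(synthetic_config(credit_prob = c(none = 1.2)), "\\[0, 1\\]")
  expect_error(synthetic_config(months = 1, mild_episodes = 0, mild_months = 0,
                                moderate_episodes = 0, moderate_months = 0),
               "at least 2 months")
})

test_that("zero base rate produces an income-only ledger", {
  cfg <- synthetic_config(base_daily_rate = 0, months = 3, mild_episodes = 0,
                          mild_months = 0, moderate_episodes = 1,
                          moderate_months = 1, seed = 6)
  sim <- generate_ledger(generate_lifechart(cfg), cfg)
  expect_true(all(sim$ledger$direction == "income"))
  expect_equal(nrow(sim$ledger), sim$truth$income_count)
})

test_that("ground truth bookkeeping matches the emitted ledger", {
  cfg <- synthetic_config(seed = 13)
  ch <- generate_lifechart(cfg)
  sim <- generate_ledger(ch, cfg)
  led <- sim$ledger
  expect_equal(nrow(led), sim$truth$expenditure_count + sim$truth$income_count)
  expect_equal(sum(led$direction == "expenditure"), sim$truth$expenditure_count)
  # per-phase counts agree with labeling through the chart
  lab <- label_ledger(led, ch)
  expend <- lab[lab$direction == "expenditure", ]
  expect_equal(as.vector(table(factor(sim$truth$phase,
                                      levels = levels(expend$severity)))),
               as.vector(table(expend$severity)))
  # per account/direction counts
  cnt <- dplyr::count(tibble::as_tibble(as.data.frame(led)),
                      account, direction, name = "n")
  expect_equal(cnt, sim$truth$counts)
})

test_that("identical config and seed give identical output", {
  cfg <- synthetic_config(seed = 77, interval_law = "heavy_tailed")
  a <- generate_ledger(generate_lifechart(cfg), cfg)
  b <- generate_ledger(generate_lifechart(cfg), cfg)
  expect_identical(as.data.frame(a$ledger), as.data.frame(b$ledger))
  expect_identical(a$truth$counts, b$truth$counts)
  # byte-identical statement exports
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_statement_files(a$ledger, d1)
  write_statement_files(b$ledger, d2)
  f1 <- list.files(d1, full.names = TRUE); f2 <- list.files(d2, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  expect_identical(lapply(f1, readLines), lapply(f2, readLines))
})

test_that("a 24-month ledger writes 24 monthly statement files", {
  cfg <- synthetic_config(seed = 3)
  sim <- generate_ledger(generate_lifechart(cfg), cfg)
  dir <- withr::local_tempdir()
  paths <- write_statement_files(sim$ledger, dir)
  expect_length(paths, 24)
  expect_equal(basename(paths[1]), "statement_2017-01.csv")
})

test_that("daily frequency is calibrated to the none-phase target mean", {
  # lighter replicate count here; the full 50-seed calibration check runs
  # with the acceptance suite
  target <- 5.23
  means <- vapply(1:8, function(s) {
    cfg <- synthetic_config(seed = 1000 + s)
    sim <- generate_ledger(generate_lifechart(cfg), cfg)
    rates <- sim$truth$daily_rates
    none_days <- sum(rates$severity == "none")
    sum(sim$truth$phase == "none") / none_days
  }, numeric(1))
  expect_lt(abs(mean(means) - target), 0.5)
})

test_that("poisson mode at sparse rates has near-zero burstiness", {
  cfg <- synthetic_config(base_daily_rate = 0.2, months = 24, seed = 64)
  Bs <- vapply(1:10, function(s) {
    cfg$seed <- 9000 + s
    sim <- generate_ledger(generate_lifechart(cfg), cfg)
    ex <- sim$ledger[sim$ledger$direction == "expenditure", ]
    burstiness(intervals_D(ex$date))$B
  }, numeric(1))
  expect_lt(abs(mean(Bs)), 0.05)
})

test_that("heavy-tailed mode raises day-grain burstiness above the Poisson level", {
  cfg_h <- synthetic_config(seed = 1, interval_law = "heavy_tailed")
  cfg_p <- synthetic_config(seed = 1)
  b_of <- function(cfg, s) {
    cfg$seed <- s
    sim <- generate_ledger(generate_lifechart(cfg), cfg)
    ex <- sim$ledger[sim$ledger$direction == "expenditure", ]
    burstiness(intervals_D(ex$date))$B
  }
  bh <- vapply(1:5, function(s) b_of(cfg_h, 100 + s), numeric(1))
  bp <- vapply(1:5, function(s) b_of(cfg_p, 100 + s), numeric(1))
  expect_gt(mean(bh), mean(bp))
  expect_gt(mean(bh), 0.3)
  expect_lt(mean(bh), 0.5)
})
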