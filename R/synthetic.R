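#' Configuration for the synthetic mood-modulated ledger generator
#'
#' Defaults encode the reference case-study conditions: a 24-month
#' two-account ledger starting 2017-01 at a none-phase mean of 5.23
#' expenditures/day, with mild and moderate hypomanic phases multiplying
#' the rate by 1.05 and 1.02 (the observed phase-mean ratios — deliberately
#' near-null effect sizes; tests that need a detectable effect inflate the
#' multipliers explicitly). Amounts are log-normal (right-skewed positive
#' spending); the probability that a purchase goes on the credit account
#' rises with symptom severity, emulating the credit shift seen during
#' symptomatic periods.
#'
#' @param months Span length in months (>= 2).
#' @param start First month (Date or `"YYYY-MM-DD"`).
#' @param base_daily_rate None-phase mean expenditures per day.
#' @param rate_multipliers Named multipliers for `none`, `mild`,
#'   `moderate` (and optionally `severe`).
#' @param interval_law `"poisson"` (daily counts Poisson at the phase
#'   rate) or `"heavy_tailed"` (gamma-mixed Poisson daily counts, i.e.
#'   negative-binomial, producing burstier streams).
#' @param dispersion Gamma shape for `heavy_tailed`; smaller = burstier.
#'   The default 1 yields day-grain B_D around 0.3-0.5.
#' @param amount_meanlog,amount_sdlog Log-normal spending-amount
#'   parameters, either scalars or named per-severity vectors.
#' @param credit_prob Named per-severity probability a purchase is made on
#'   the credit account.
#' @param income_per_month Count of monthly income events (on the checking
#'   account).
#' @param income_meanlog,income_sdlog Log-normal income-amount parameters.
#' @param mild_episodes,mild_months Number of mild episodes and their
#'   total months (defaults: the case-study aggregates 2 episodes / 5
#'   months).
#' @param moderate_episodes,moderate_months Same for moderate (defaults 5
#'   episodes / 9 months).
#' @param seed Integer RNG seed.
#' @return A validated list of class `fp_synth_config`.
#' @export
synthetic_config <- function(months = 24,
                             start = "2017-01-01",
                             base_daily_rate = 5.23,
                             rate_multipliers = c(none = 1, mild = 1.05,
                                                  moderate = 1.02),
                             interval_law = c("poisson", "heavy_tailed"),
                             dispersion = 1,
                             amount_meanlog = log(20), amount_sdlog = 1,
                             credit_prob = c(none = 0.30, mild = 0.40,
                                             moderate = 0.45),
                             income_per_month = 2,
                             income_meanlog = log(1500), income_sdlog = 0.25,
                             mild_episodes = 2, mild_months = 5,
                             moderate_episodes = 5, moderate_months = 9,
                             seed = 1L) {
  interval_law <- match.arg(interval_law)
  if (months < 2) abort("synthetic_config: span must be at least 2 months")
  if (base_daily_rate < 0) abort("base_daily_rate must be >= 0")
  if (any(rate_multipliers < 0)) abort("rate multipliers must be >= 0")
  if (any(credit_prob < 0 | credit_prob > 1)) {
    abort("credit_prob values must be in [0, 1]")
  }
  if (dispersion <= 0) abort("dispersion must be > 0")
  need_sep <- mild_episodes + moderate_episodes - 1  # >=1 gap between runs
  if (mild_months + moderate_months + max(need_sep, 0) > months) {
    abort("synthetic_config: episode months (plus separating gaps) exceed the span")
  }
  fill_sev <- function(x, default) {
    if (length(x) == 1 && is.null(names(x))) {
      x <- stats::setNames(rep(x, 4), SEVERITY_LEVELS)
    }
    out <- stats::setNames(rep(default, 4), SEVERITY_LEVELS)
    out[names(x)] <- x
    out
  }
  structure(list(
    months = as.integer(months), start = month_floor(as.Date(start)),
    base_daily_rate = base_daily_rate,
    rate_multipliers = fill_sev(rate_multipliers, 1),
    interval_law = interval_law, dispersion = dispersion,
    amount_meanlog = fill_sev(amount_meanlog, log(20)),
    amount_sdlog = fill_sev(amount_sdlog, 1),
    credit_prob = fill_sev(credit_prob, 0.30),
    income_per_month = income_per_month,
    income_meanlog = income_meanlog, income_sdlog = income_sdlog,
    mild_episodes = mild_episodes, mild_months = mild_months,
    moderate_episodes = moderate_episodes, moderate_months = moderate_months,
    seed = as.integer(seed)), class = "fp_synth_config")
}

#' Generate a synthetic life chart
#'
#' With `randomize = FALSE` (default) and default episode counts the
#' result is exactly the packaged case-study chart layout: two mild runs
#' (3 + 2 months) and five moderate runs (2 + 1 + 2 + 2 + 2 months) over
#' 24 months. With `randomize = TRUE`, run lengths and placements are
#' drawn uniformly subject to the aggregate constraints (episode counts
#' and total months per severity, with at least one month between runs so
#' runs never merge).
#'
#' @param config A [synthetic_config()].
#' @param randomize Randomize run lengths and placement.
#' @return A `fp_lifechart`.
#' @export
generate_lifechart <- function(config = synthetic_config(),
                               randomize = FALSE) {
  stopifnot(inherits(config, "fp_synth_config"))
  months <- seq(config$start, by = "month", length.out = config$months)
  defaults_case_study <- !randomize &&
    config$months == 24 && config$mild_episodes == 2 &&
    config$mild_months == 5 && config$moderate_episodes == 5 &&
    config$moderate_months == 9
  if (defaults_case_study) {
    sev <- c("none", "mild", "mild", "mild", "none", "moderate", "moderate",
             "none", "moderate", "none", "moderate", "moderate",
             "none", "mild", "mild", "none", "moderate", "moderate",
             "none", "moderate", "moderate", "none", "none", "none")
    return(lifechart(months, sev))
  }
  if (config$mild_episodes == 0 && config$moderate_episodes == 0) {
    return(lifechart(months, "none"))
  }
  draw <- function() {
    comp <- function(total, parts) {
      # uniform composition of `total` into `parts` positive integers
      if (parts == 0) return(integer(0))
      if (parts == 1) return(total)
      cuts <- sort(sample.int(total - 1, parts - 1))
      diff(c(0, cuts, total))
    }
    lens <- c(rep("mild", config$mild_episodes),
              rep("moderate", config$moderate_episodes))
    sizes <- c(comp(config$mild_months, config$mild_episodes),
               comp(config$moderate_months, config$moderate_episodes))
    ord <- sample(seq_along(lens))
    lens <- lens[ord]; sizes <- sizes[ord]
    n_runs <- length(lens)
    spare <- config$months - sum(sizes) - (n_runs - 1)
    # distribute spare none-months over the n_runs+1 gaps (ends included)
    extra <- if (spare > 0) {
      tabulate(sample.int(n_runs + 1, spare, replace = TRUE), n_runs + 1)
    } else rep(0L, n_runs + 1)
    gaps <- extra + c(0, rep(1, n_runs - 1), 0)
    sev <- character(0)
    for (i in seq_len(n_runs)) {
      sev <- c(sev, rep("none", gaps[i]), rep(lens[i], sizes[i]))
    }
    c(sev, rep("none", gaps[n_runs + 1]))
  }
  sev <- if (randomize) draw() else with_seed_(config$seed, draw())
  lifechart(months, sev)
}

#' Generate a mood-modulated synthetic ledger
#'
#' Daily expenditure counts follow the phase-modulated counting process
#' configured by `interval_law`; amounts follow the per-phase log-normal
#' law, cent-quantized; the account is credit with the per-phase
#' probability; monthly income events are added on the checking account.
#' Every transaction description embeds a unique reference code so no two
#' synthetic transactions are ever identical rows. Fully reproducible from
#' the config seed.
#'
#' @param chart A `fp_lifechart` spanning the config months (default:
#'   [generate_lifechart()]).
#' @param config A [synthetic_config()].
#' @return A list: `ledger` (`fp_ledger`) and `truth` — bookkeeping ground
#'   truth (`phase` per transaction, per-day true rates, episode windows,
#'   income count, per phase/account/direction counts) for recovery tests.
#' @export
generate_ledger <- function(chart = NULL, config = synthetic_config()) {
  stopifnot(inherits(config, "fp_synth_config"))
  chart <- chart %||% generate_lifechart(config)
  months <- seq(config$start, by = "month", length.out = config$months)
  if (!identical(as.numeric(range(chart$month)),
                 as.numeric(range(months)))) {
    abort("generate_ledger: chart span does not match config span")
  }
  first_day <- months[1]
  last_day <- lubridate::ceiling_date(months[config$months], "month") - 1
  days <- seq(first_day, last_day, by = "day")
  sev <- as.character(severity_at(chart, days))
  rate <- config$base_daily_rate * config$rate_multipliers[sev]

  merchants <- c("GROCERY MART", "COFFEE ROASTERS", "TRANSIT AUTHORITY",
                 "ONLINE RETAIL", "PHARMACY PLUS", "BOOK NOOK",
                 "STREAMING SVC", "HARDWARE DEPOT", "CORNER DELI",
                 "GAS STATION")
  with_seed_(config$seed, {
    lambda <- if (config$interval_law == "heavy_tailed") {
      a <- config$dispersion
      rgamma(length(days), shape = a, rate = ifelse(rate > 0, a / rate, Inf))
    } else rate
    counts <- rpois(length(days), lambda)
    n_tx <- sum(counts)
    tx_day <- rep(days, counts)
    tx_sev <- rep(sev, counts)
    amounts <- pmax(0.01, round(rlnorm(n_tx,
      meanlog = config$amount_meanlog[tx_sev],
      sdlog = config$amount_sdlog[tx_sev]), 2))
    on_credit <- rbinom(n_tx, 1, config$credit_prob[tx_sev]) == 1
    desc <- sprintf("%s REF%06d", sample(merchants, n_tx, replace = TRUE),
                    seq_len(n_tx))
    expend <- tibble(date = tx_day,
                     account = c("checking", "credit")[as.integer(on_credit) + 1L],
                     direction = "expenditure", amount = amounts,
                     description = desc)
    inc <- if (config$income_per_month > 0) {
      inc_rows <- lapply(seq_along(months), function(m) {
        m_start <- months[m]
        m_days <- seq(m_start, lubridate::ceiling_date(m_start, "month") - 1,
                      by = "day")
        d <- sort(sample(m_days, config$income_per_month, replace = TRUE))
        tibble(date = d, account = "checking", direction = "income",
               amount = pmax(0.01, round(rlnorm(length(d),
                 config$income_meanlog, config$income_sdlog), 2)),
               description = sprintf("DIRECT DEPOSIT PAY%03d-%02d",
                                     m, seq_along(d)))
      })
      bind_rows(inc_rows)
    } else {
      expend[0, ]
    }
    led <- ledger(bind_rows(expend, inc))
    ep <- rle(as.character(chart$mania))
    ends <- cumsum(ep$lengths)
    starts <- ends - ep$lengths + 1
    windows <- tibble(severity = ep$values,
                      start = chart$month[starts],
                      end = lubridate::ceiling_date(chart$month[ends], "month") - 1)
    windows <- windows[windows$severity != "none", ]
    truth <- list(
      phase = tx_sev,
      daily_rates = tibble(date = days, severity = sev,
                           rate = unname(rate)),
      episode_windows = windows,
      income_count = nrow(inc),
      expenditure_count = n_tx,
      counts = dplyr::count(as_tibble(as.data.frame(led)),
                            .data$account, .data$direction,
                            name = "n"))
    list(ledger = led, truth = truth)
  })
}

split_description_ <- function(desc, max_words = 2) {
  words <- strsplit(desc, " ", fixed = TRUE)[[1]]
  if (length(words) <= max_words) return(list(head = desc, rest = character(0)))
  list(head = paste(words[seq_len(max_words)], collapse = " "),
       rest = paste(words[-seq_len(max_words)], collapse = " "))
}

#' Write a ledger as monthly statement-export files
#'
#' Emits one delimited export per calendar month, emulating the artifacts
#' of PDF table extraction: each file holds both account sections
#' introduced by marker rows (multiple accounts per file; each account
#' spans all files), and under the `"pdf_extract"` quirk profile long
#' descriptions overflow into continuation rows with empty date/amount
#' cells (one transaction across multiple physical rows). Expenditures are
#' written with negative sign, income positive. The writer is lossless:
#' parsing the files back with the matching [statement_dialect()]
#' reproduces the ledger exactly.
#'
#' @param x A non-empty `fp_ledger`.
#' @param dir Output directory (created if needed).
#' @param quirk_profile `"pdf_extract"` (continuation rows; default) or
#'   `"none"` (plain one-row-per-transaction files).
#' @return Invisibly, the written file paths (one per month).
#' @export
write_statement_files <- function(x, dir, quirk_profile = c("pdf_extract", "none")) {
  quirk_profile <- match.arg(quirk_profile)
  stopifnot(inherits(x, "fp_ledger"), nrow(x) > 0)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  months <- seq(month_floor(min(x$date)), month_floor(max(x$date)), by = "month")
  paths <- character(0)
  for (m in as.list(months)) {
    in_m <- month_floor(x$date) == m
    sub <- x[in_m, , drop = FALSE]
    lines <- character(0)
    for (acct in ACCOUNT_LEVELS) {
      rows <- sub[sub$account == acct, , drop = FALSE]
      if (nrow(rows) == 0) next
      lines <- c(lines, sprintf("# ACCOUNT: %s,,", acct))
      for (i in seq_len(nrow(rows))) {
        signed <- if (rows$direction[i] == "expenditure") -rows$amount[i] else rows$amount[i]
        if (quirk_profile == "pdf_extract") {
          parts <- split_description_(rows$description[i])
          lines <- c(lines, sprintf("%s,%s,%.2f", format(rows$date[i], "%Y-%m-%d"),
                                    parts$head, signed))
          if (length(parts$rest) > 0) {
            lines <- c(lines, sprintf(",%s,", parts$rest))
          }
        } else {
          lines <- c(lines, sprintf("%s,%s,%.2f", format(rows$date[i], "%Y-%m-%d"),
                                    rows$description[i], signed))
        }
      }
    }
    path <- file.path(dir, sprintf("statement_%s.csv", format(m, "%Y-%m")))
    writeLines(lines, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
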