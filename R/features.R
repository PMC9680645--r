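period_seq_ <- function(from, to, grain, week_start = 1) {
  unit <- switch(grain, daily = "day", weekly = "week", monthly = "month")
  floor1 <- function(d) {
    if (grain == "weekly") lubridate::floor_date(d, "week", week_start = week_start)
    else lubridate::floor_date(d, unit)
  }
  seq(floor1(from), floor1(to), by = unit)
}

period_of_ <- function(date, grain, week_start = 1) {
  switch(grain,
         daily = date,
         weekly = lubridate::floor_date(date, "week", week_start = week_start),
         monthly = month_floor(date))
}

# period-level severity: a period is labeled by the month containing the
# majority of its calendar days, ties going to the earlier month
period_severity_ <- function(period_start, grain, chart, week_start = 1) {
  if (grain != "weekly") {
    return(severity_at(chart, period_start, policy = "lenient"))
  }
  vapply(as.list(period_start), function(p) {
    days <- p + 0:6
    m <- month_floor(days)
    tab <- table(factor(format(m, "%Y-%m-%d")))
    best <- names(tab)[which.max(tab)]  # which.max takes the first (earlier) tie
    as.character(suppressWarnings(
      severity_at(chart, as.Date(best), policy = "lenient")))
  }, character(1)) |> severity_factor()
}

#' Resample labeled transactions into a feature series
#'
#' Bins labeled transactions at a daily, weekly (ISO weeks, Monday start by
#' default) or monthly grain. Every calendar period in the span is present,
#' including zero-transaction periods (required by the zero-run interval
#' scheme). Per period: `frequency` = transaction count, `volume` = sum of
#' normalized amounts, `severity` = the period's mood label (daily periods
#' take their month's severity; weekly periods spanning a month boundary
#' take the severity of the month holding the majority of their days, ties
#' to the earlier month).
#'
#' @param txns Labeled transactions from [label_ledger()] /
#'   [preprocess_ledger()].
#' @param grain `"daily"`, `"weekly"` or `"monthly"`.
#' @param chart The `fp_lifechart` used for period labels.
#' @param week_start Week anchor day (1 = Monday, ISO default).
#' @return A tibble `period_start`, `frequency`, `volume`, `severity`,
#'   `severity_merged`, with attribute `grain`. Partial edge periods are
#'   included and marked in the `partial` column.
#' @export
resample_features <- function(txns, grain = c("daily", "weekly", "monthly"),
                              chart, week_start = 1) {
  grain <- match.arg(grain)
  if (nrow(txns) == 0) {
    return(structure(tibble(period_start = as.Date(character()),
                            frequency = integer(), volume = numeric(),
                            severity = severity_factor(character()),
                            severity_merged = factor(character(),
                              levels = c("none", "symptomatic")),
                            partial = logical()),
                     grain = grain))
  }
  span <- range(txns$date)
  periods <- period_seq_(span[1], span[2], grain, week_start)
  key <- period_of_(txns$date, grain, week_start)
  vol_src <- if ("norm_amount" %in% names(txns)) txns$norm_amount else txns$amount
  agg <- tibble(period_start = key, v = vol_src) |>
    group_by(.data$period_start) |>
    summarise(frequency = dplyr::n(), volume = sum(.data$v), .groups = "drop")
  out <- tibble(period_start = periods) |>
    left_join(agg, by = "period_start") |>
    mutate(frequency = ifelse(is.na(.data$frequency), 0L, .data$frequency),
           volume = ifelse(is.na(.data$volume), 0, .data$volume))
  out$severity <- period_severity_(out$period_start, grain, chart, week_start)
  out$severity_merged <- factor(
    ifelse(out$severity == "none", "none", "symptomatic"),
    levels = c("none", "symptomatic"))
  plen <- switch(grain, daily = 1L, weekly = 7L,
                 monthly = NA_integer_)  # month length varies; computed below
  p_end <- if (grain == "monthly") {
    lubridate::ceiling_date(out$period_start, "month") - 1
  } else out$period_start + (plen - 1L)
  out$partial <- out$period_start < span[1] | p_end > span[2]
  structure(out, grain = grain)
}

#' Monthly percentage of purchases made on credit
#'
#' Per calendar month, `100 * credit count / total count` of transactions —
#' a count-based ratio (per-account amount normalization makes
#' cross-account volume ratios meaningless, so the count definition is the
#' default; a volume-based variant is available via `by`).
#'
#' @param txns Labeled transactions with an `account` column.
#' @param by `"count"` (default) or `"volume"` (shares of summed
#'   `norm_amount`; interpret with care).
#' @return A tibble `month` (first day of month), `credit_pct` in
#'   \[0, 100\]. Months in the span with zero transactions are omitted with
#'   a warning.
#' @export
credit_ratio_monthly <- function(txns, by = c("count", "volume")) {
  by <- match.arg(by)
  stopifnot("account" %in% names(txns))
  if (nrow(txns) == 0) return(tibble(month = as.Date(character()),
                                     credit_pct = numeric()))
  m_all <- seq(month_floor(min(txns$date)), month_floor(max(txns$date)), by = "month")
  w <- if (by == "count") rep(1, nrow(txns)) else txns$norm_amount
  out <- tibble(month = month_floor(txns$date),
                credit = w * (txns$account == "credit"), w = w) |>
    group_by(.data$month) |>
    summarise(credit_pct = 100 * sum(.data$credit) / sum(.data$w),
              .groups = "drop")
  n_empty <- length(m_all) - nrow(out)
  if (n_empty > 0) {
    warn(sprintf("credit_ratio_monthly: %d month(s) with zero transactions omitted", n_empty))
  }
  out
}

#' Write a per-grain feature CSV
#' @param features Output of [resample_features()].
#' @param path File path.
#' @export
write_features <- function(features, path) {
  df <- as.data.frame(features)
  df$period_start <- format(df$period_start, "%Y-%m-%d")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
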