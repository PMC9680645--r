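group_stats_ <- function(x, g) {
  g <- factor(g)
  g <- droplevels(g)
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- g[keep]
  if (nlevels(g) < 2) abort("need at least 2 groups")
  st <- tibble(
    group = levels(g),
    n = as.integer(tapply(x, g, length)),
    mean = as.numeric(tapply(x, g, mean)),
    var = as.numeric(tapply(x, g, var))
  )
  if (any(st$n < 2)) {
    abort(sprintf("group(s) with fewer than 2 observations: %s",
                  paste(st$group[st$n < 2], collapse = ", ")))
  }
  if (any(st$var == 0)) {
    abort(sprintf("zero-variance group(s): %s",
                  paste(st$group[st$var == 0], collapse = ", ")),
          class = "fp_degenerate_variance")
  }
  st
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' Compares group means without assuming equal variances or balanced
#' sizes — the appropriate test when phase groups differ in length and
#' spread. Implemented from the Welch (1951) formulas: with weights
#' `w_i = n_i / s_i^2`, the statistic is the weighted between-group mean
#' square divided by `1 + 2(k-2)/(k^2-1) * Lambda`, where
#' `Lambda = sum((1 - w_i/W)^2 / (n_i - 1))`, on `k - 1` and
#' `(k^2 - 1) / (3 * Lambda)` degrees of freedom.
#'
#' @param x Numeric response (e.g. per-period frequency or volume).
#' @param g Group labels (phase), coercible to factor; at least 2 groups
#'   with n >= 2 and positive variance each.
#' @return An object of class `fp_welch` (also `htest`-like): `statistic`
#'   (F), `df1`, `df2`, `p.value`, and the per-group summary table.
#' @examples
#' welch_anova(c(1, 2, 3, 2, 3, 4, 10, 11, 12), rep(c("a", "b", "c"), each = 3))
#' @export
welch_anova <- function(x, g) {
  st <- group_stats_(x, g)
  k <- nrow(st)
  w <- st$n / st$var
  W <- sum(w)
  m_w <- sum(w * st$mean) / W
  A <- sum(w * (st$mean - m_w)^2) / (k - 1)
  lambda <- sum((1 - w / W)^2 / (st$n - 1))
  Fstat <- A / (1 + 2 * (k - 2) / (k^2 - 1) * lambda)
  df1 <- k - 1
  df2 <- (k^2 - 1) / (3 * lambda)
  p <- pf(Fstat, df1, df2, lower.tail = FALSE)
  structure(list(statistic = Fstat, df1 = df1, df2 = df2, p.value = p,
                 groups = st, method = "Welch one-way ANOVA"),
            class = "fp_welch")
}

#' @export
print.fp_welch <- function(x, ...) {
  cat(sprintf("Welch one-way ANOVA: F(%d, %.1f) = %.4g, p = %.4g\n",
              x$df1, x$df2, x$statistic, x$p.value))
  invisible(x)
}

#' Games-Howell post-hoc pairwise comparisons
#'
#' Pairwise contrasts between all group pairs under unequal variances and
#' sizes: each pair uses the Welch-Satterthwaite degrees of freedom and
#' the studentized-range distribution with `k` groups, giving adjusted
#' p-values and simultaneous confidence intervals for the mean
#' differences. The studentized-range CDF/quantiles are computed by
#' numerical integration ([ptukey_num()], absolute accuracy below 1e-9).
#'
#' @inheritParams welch_anova
#' @param conf.level Simultaneous confidence level for the intervals.
#' @return A tibble with one row per unordered pair: `group1`, `group2`,
#'   `mean_diff` (group1 - group2), `se`, `df`, `ci_low`, `ci_high`,
#'   `p_adj`.
#' @export
games_howell <- function(x, g, conf.level = 0.95) {
  stopifnot(is_scalar_number(conf.level), conf.level > 0, conf.level < 1)
  st <- group_stats_(x, g)
  k <- nrow(st)
  pairs <- utils::combn(k, 2)
  rows <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    vi <- st$var[i] / st$n[i]
    vj <- st$var[j] / st$n[j]
    se <- sqrt(vi + vj)
    df <- (vi + vj)^2 / (vi^2 / (st$n[i] - 1) + vj^2 / (st$n[j] - 1))
    diff <- st$mean[i] - st$mean[j]
    q <- sqrt(2) * abs(diff) / se
    p <- ptukey_num(q, nmeans = k, df = df, lower.tail = FALSE)
    crit <- qtukey_num(conf.level, nmeans = k, df = df) / sqrt(2)
    tibble(group1 = st$group[i], group2 = st$group[j],
           mean_diff = diff, se = se, df = df,
           ci_low = diff - crit * se, ci_high = diff + crit * se,
           p_adj = p)
  })
  bind_rows(rows)
}

#' Per-phase means of frequency and volume
#'
#' The descriptive companion to the inference: mean per-period transaction
#' frequency and normalized volume by symptom phase.
#'
#' @param features A feature tibble from [resample_features()].
#' @param merge Use the merged two-phase labels.
#' @param digits Optional rounding for reporting; `NULL` leaves values
#'   unrounded.
#' @return A tibble `phase`, `n_periods`, `mean_frequency`, `mean_volume`.
#' @export
phase_summary <- function(features, merge = FALSE, digits = NULL) {
  lab <- if (merge) features$severity_merged else features$severity
  out <- tibble(phase = lab, f = features$frequency, v = features$volume) |>
    group_by(.data$phase) |>
    summarise(n_periods = dplyr::n(),
              mean_frequency = mean(.data$f),
              mean_volume = mean(.data$v), .groups = "drop")
  if (!is.null(digits)) {
    out$mean_frequency <- round(out$mean_frequency, digits)
    out$mean_volume <- round(out$mean_volume, digits)
  }
  out
}

#' Run the phase-comparison analysis on a feature series
#'
#' Welch ANOVA plus Games-Howell contrasts for one endpoint (frequency or
#' volume) grouped by phase, returned as a tidy results table.
#'
#' @param features A feature tibble from [resample_features()], normally
#'   daily grain.
#' @param endpoint `"frequency"` or `"volume"`.
#' @param merge Use merged two-phase labels.
#' @param alpha Significance level for the Games-Howell intervals.
#' @return A list with elements `welch` (`fp_welch`), `games_howell`
#'   (tibble), `summary` (per-phase means).
#' @export
phase_inference <- function(features, endpoint = c("frequency", "volume"),
                            merge = FALSE, alpha = 0.05) {
  endpoint <- match.arg(endpoint)
  lab <- if (merge) features$severity_merged else features$severity
  y <- features[[endpoint]]
  list(welch = welch_anova(y, lab),
       games_howell = games_howell(y, lab, conf.level = 1 - alpha),
       summary = phase_summary(features, merge = merge))
}
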