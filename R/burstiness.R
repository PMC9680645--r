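#' Inter-event intervals between successive transactions (scheme D)
#'
#' With only day-level timestamps available, the scheme-D interval is the
#' difference in days between each transaction and the next; several
#' transactions on one day yield zero-valued intervals.
#'
#' @param dates Date vector of transaction dates (sorted internally).
#' @return An `fp_intervals` list: `scheme = "D"`, `intervals` (numeric
#'   days, length n-1 for n transactions), `n` (interval count).
#' @examples
#' intervals_D(as.Date(c("2017-01-01", "2017-01-01", "2017-01-03")))
#' @export
intervals_D <- function(dates) {
  dates <- sort(as.Date(dates))
  if (length(dates) < 3) {
    abort("intervals_D: need at least 3 transactions (2 intervals)",
          class = "fp_insufficient_data")
  }
  iv <- as.numeric(diff(dates))
  structure(list(scheme = "D", intervals = iv, n = length(iv)),
            class = "fp_intervals")
}

#' Zero-expenditure run lengths as intervals (scheme C)
#'
#' The scheme-C interval is the length of a maximal run of consecutive
#' days with zero expenditure, computed on a zero-filled daily frequency
#' series. Leading/trailing zero-runs at the span edges are included by
#' default.
#'
#' @param daily A daily feature tibble from [resample_features()] (its
#'   `frequency` column is used) or a numeric vector of daily counts.
#' @param include_edges Include zero-runs touching the span edges.
#' @return An `fp_intervals` list: `scheme = "C"`, one interval per
#'   zero-run.
#' @examples
#' intervals_C(c(1, 0, 0, 2, 1, 0, 0, 3))  # runs of 2 and 2
#' @export
intervals_C <- function(daily, include_edges = TRUE) {
  counts <- if (is.data.frame(daily)) daily$frequency else as.numeric(daily)
  r <- rle(counts == 0)
  keep <- r$values
  runs <- r$lengths[keep]
  if (!include_edges && length(runs) > 0) {
    drop <- logical(length(runs))
    if (r$values[1]) drop[1] <- TRUE
    if (r$values[length(r$values)]) drop[length(runs)] <- TRUE
    runs <- runs[!drop]
  }
  if (length(runs) < 2) {
    abort("intervals_C: fewer than 2 zero-expenditure runs; burstiness undefined",
          class = "fp_insufficient_data")
  }
  structure(list(scheme = "C", intervals = as.numeric(runs), n = length(runs)),
            class = "fp_intervals")
}

#' The burstiness parameter B = (r - 1) / (r + 1)
#'
#' `r = sigma / tau` is the coefficient of variation of the inter-event
#' intervals: `tau` the mean and `sigma` the standard deviation
#' (population, n-denominator, by default). B is -1 for perfectly regular
#' intervals (sigma = 0, stability), ~0 for a memoryless process
#' (randomness), and approaches 1 only in the limit of extreme dispersion
#' (spikes).
#'
#' @param sample An `fp_intervals` object, or a numeric vector of
#'   intervals.
#' @param sd_type `"population"` (default) or `"sample"` (n-1 denominator,
#'   for sensitivity analysis).
#' @return An `fp_burstiness` list: `B`, `r`, `tau`, `sigma`, `n`,
#'   `scheme`.
#' @examples
#' burstiness(c(5, 5, 5, 5))$B   # -1: perfectly regular
#' @export
burstiness <- function(sample, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (is.numeric(sample)) {
    sample <- structure(list(scheme = NA_character_,
                             intervals = as.numeric(sample),
                             n = length(sample)),
                        class = "fp_intervals")
  }
  stopifnot(inherits(sample, "fp_intervals"))
  iv <- sample$intervals
  n <- length(iv)
  if (n < 2) {
    abort("burstiness: need at least 2 intervals", class = "fp_insufficient_data")
  }
  tau <- mean(iv)
  if (tau == 0) {
    abort("burstiness: mean interval is 0; statistic undefined",
          class = "fp_undefined_statistic")
  }
  sigma <- if (sd_type == "population") sqrt(mean((iv - tau)^2)) else sd(iv)
  r <- sigma / tau
  structure(list(B = (r - 1) / (r + 1), r = r, tau = tau, sigma = sigma,
                 n = n, scheme = sample$scheme, sd_type = sd_type),
            class = "fp_burstiness")
}

#' @export
print.fp_burstiness <- function(x, ...) {
  cat(sprintf("<burstiness%s: B = %.4f (r = %.4f, tau = %.4f, sigma = %.4f, n = %d)>\n",
              if (!is.na(x$scheme)) paste0(" ", x$scheme) else "",
              x$B, x$r, x$tau, x$sigma, x$n))
  invisible(x)
}

# burstiness row helper tolerant of insufficient data
burstiness_row_ <- function(make_sample, phase, scheme, sd_type) {
  res <- tryCatch(burstiness(make_sample(), sd_type = sd_type),
                  fp_insufficient_data = function(e) NULL,
                  fp_undefined_statistic = function(e) NULL,
                  error = function(e) NULL)
  if (is.null(res)) {
    tibble(scheme = scheme, phase = phase, n = NA_integer_, tau = NA_real_,
           sigma = NA_real_, r = NA_real_, B = NA_real_)
  } else {
    tibble(scheme = scheme, phase = phase, n = res$n, tau = res$tau,
           sigma = res$sigma, r = res$r, B = res$B)
  }
}

#' Burstiness per symptomatic phase
#'
#' Groups the transaction stream by symptomatic intensity and computes the
#' burstiness parameter on each phase's own interval sample, plus the
#' overall value. For scheme D, intervals are taken between consecutive
#' transactions within each contiguous same-phase stretch and pooled per
#' phase, so gaps spanning another phase are not attributed to any phase.
#' For scheme C, the zero-filled
#' daily series is segmented into contiguous same-phase stretches; zero
#' runs are collected within each stretch and pooled per phase (runs never
#' bridge a phase boundary).
#'
#' @param txns Labeled transactions (need `date` and `severity`).
#' @param chart The `fp_lifechart` (used to label days for scheme C).
#' @param scheme `"D"` or `"C"`.
#' @param merge Pool mild and moderate into a single `symptomatic` phase
#'   (two-phase layout).
#' @param sd_type Passed to [burstiness()].
#' @param include_edges Passed to [intervals_C()].
#' @return A tibble with one row per phase plus an `overall` row: `scheme`,
#'   `phase`, `n`, `tau`, `sigma`, `r`, `B`. Phases with insufficient
#'   intervals are flagged with NA rather than failing.
#' @export
burstiness_by_phase <- function(txns, chart, scheme = c("D", "C"),
                                merge = FALSE,
                                sd_type = c("population", "sample"),
                                include_edges = TRUE) {
  scheme <- match.arg(scheme)
  sd_type <- match.arg(sd_type)
  lab_col <- if (merge) "severity_merged" else "severity"
  stopifnot(lab_col %in% names(txns), nrow(txns) > 0)
  phases <- levels(droplevels(txns[[lab_col]]))
  if (scheme == "D") {
    # intervals between consecutive transactions inside each maximal run of
    # same-phase transactions, pooled per phase; the jump from one phase
    # segment to the next same-phase segment spans other phases and is not
    # attributed to either
    lab_chr <- as.character(txns[[lab_col]])
    seg <- cumsum(c(TRUE, lab_chr[-1] != lab_chr[-length(lab_chr)]))
    rows <- lapply(phases, function(ph) {
      make <- function() {
        iv <- unlist(lapply(split(txns$date[lab_chr == ph],
                                  seg[lab_chr == ph]), function(d) {
          if (length(d) < 2) numeric(0) else as.numeric(diff(sort(d)))
        }), use.names = FALSE)
        if (length(iv) < 2) {
          abort("insufficient intervals", class = "fp_insufficient_data")
        }
        structure(list(scheme = "D", intervals = iv, n = length(iv)),
                  class = "fp_intervals")
      }
      burstiness_row_(make, ph, "D", sd_type)
    })
    overall <- burstiness_row_(function() intervals_D(txns$date),
                               "overall", "D", sd_type)
  } else {
    span <- range(txns$date)
    days <- seq(span[1], span[2], by = "day")
    counts <- tabulate(as.integer(txns$date - span[1]) + 1L,
                       nbins = length(days))
    sev <- severity_at(chart, days, policy = "lenient")
    day_lab <- if (merge) ifelse(sev == "none", "none", "symptomatic")
               else as.character(sev)
    seg <- cumsum(c(TRUE, day_lab[-1] != day_lab[-length(day_lab)]))
    rows <- lapply(phases, function(ph) {
      make <- function() {
        runs <- unlist(lapply(split(seq_along(days)[day_lab == ph],
                                    seg[day_lab == ph]), function(i) {
          r <- rle(counts[i] == 0)
          runs_i <- r$lengths[r$values]
          if (!include_edges && length(runs_i) > 0) {
            drop <- logical(length(runs_i))
            if (r$values[1]) drop[1] <- TRUE
            if (r$values[length(r$values)]) drop[length(runs_i)] <- TRUE
            runs_i <- runs_i[!drop]
          }
          runs_i
        }), use.names = FALSE)
        if (length(runs) < 2) {
          abort("insufficient zero runs", class = "fp_insufficient_data")
        }
        structure(list(scheme = "C", intervals = as.numeric(runs),
                       n = length(runs)), class = "fp_intervals")
      }
      burstiness_row_(make, ph, "C", sd_type)
    })
    overall <- burstiness_row_(
      function() intervals_C(counts, include_edges = include_edges),
      "overall", "C", sd_type)
  }
  bind_rows(c(rows, list(overall)))
}
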