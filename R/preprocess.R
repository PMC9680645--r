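#' Keep expenditure transactions only
#'
#' Problematic financial behavior is hypothesized to show in spending, so
#' income-based transactions are omitted from analysis. The number of
#' removed rows is reported.
#'
#' @param x A `fp_ledger`.
#' @return A `fp_ledger` of expenditure transactions.
#' @export
filter_expenditure <- function(x) {
  stopifnot(inherits(x, "fp_ledger"))
  keep <- x$direction == "expenditure"
  removed <- sum(!keep)
  inform(sprintf("filter_expenditure: removed %d income transaction(s)", removed))
  out <- x[keep, , drop = FALSE]
  if (nrow(out) == 0) warn("filter_expenditure: no expenditure transactions remain")
  new_ledger(as_tibble(as.data.frame(out)))
}

#' Remove all transaction descriptions
#'
#' First half of the privacy-preserving transform: free-text descriptions
#' are the main carrier of personally identifying information and are
#' blanked; no other field is touched.
#'
#' @param x A `fp_ledger`.
#' @return A `fp_ledger` with every description set to `""`.
#' @export
strip_descriptions <- function(x) {
  stopifnot(inherits(x, "fp_ledger"))
  df <- as_tibble(as.data.frame(x))
  df$description <- rep("", nrow(df))
  new_ledger(df)
}

#' Per-account min-max normalization of amounts
#'
#' Second half of the privacy transform: raw monetary values are replaced
#' by per-account min-max rescaled values, `(x - min) / (max - min)`, so
#' each account's amounts lie in \[0, 1\] with its minimum at 0 and maximum
#' at 1. Normalization is computed once over the full analysis span.
#' An account with a single distinct amount maps to 0 (in-range, flagged
#' with a warning). `method = "divmax"` (divide by the account maximum) is
#' available for sensitivity analysis.
#'
#' @param x A `fp_ledger`, typically expenditure-only.
#' @param method `"minmax"` (default) or `"divmax"`.
#' @return The ledger with an added `norm_amount` column; downstream
#'   privacy-mode serialization drops the raw `amount`.
#' @export
normalize_amounts <- function(x, method = c("minmax", "divmax")) {
  method <- match.arg(method)
  stopifnot(inherits(x, "fp_ledger"))
  df <- as_tibble(as.data.frame(x))
  # re-normalizing an already-normalized ledger rescales norm_amount again
  # (an identity for min-max, making the transform idempotent)
  src <- if ("norm_amount" %in% names(df)) df$norm_amount else df$amount
  norm <- rep(NA_real_, nrow(df))
  for (acct in unique(df$account)) {
    i <- df$account == acct
    a <- src[i]
    lo <- min(a); hi <- max(a)
    if (hi == lo) {
      warn(sprintf("normalize_amounts: account '%s' has a single distinct amount; normalized to 0", acct))
      norm[i] <- 0
    } else if (method == "minmax") {
      norm[i] <- (a - lo) / (hi - lo)
    } else {
      norm[i] <- a / hi
    }
  }
  df$norm_amount <- norm
  new_ledger(df)
}

#' Label transactions with life-chart severity
#'
#' Attaches to each transaction the mania severity of its calendar month
#' (`none`/`mild`/`moderate`/`severe`) and the merged binary phase label
#' (`none` vs `symptomatic`), used when mild and moderate periods are
#' pooled.
#'
#' @param x A `fp_ledger`, normally after [normalize_amounts()].
#' @param chart A `fp_lifechart` covering the ledger span.
#' @param policy Out-of-span handling, see [severity_at()].
#' @return A tibble of labeled transactions: `date`, `account`,
#'   `norm_amount` (if present), `severity`, `severity_merged`, plus any
#'   other ledger columns.
#' @export
label_ledger <- function(x, chart, policy = c("strict", "lenient")) {
  stopifnot(inherits(x, "fp_ledger"))
  sev <- severity_at(chart, x$date, policy = match.arg(policy))
  out <- as_tibble(as.data.frame(x))
  out$severity <- sev
  out$severity_merged <- factor(
    ifelse(sev == "none", "none", "symptomatic"),
    levels = c("none", "symptomatic"))
  out
}

#' Full privacy-preserving preprocessing
#'
#' Convenience composition: expenditure filter, description stripping,
#' per-account normalization, then severity labeling. The filter and strip
#' steps commute; normalization is computed after income exclusion.
#'
#' @inheritParams label_ledger
#' @inheritParams normalize_amounts
#' @return A labeled transaction tibble, see [label_ledger()].
#' @export
preprocess_ledger <- function(x, chart, method = "minmax",
                              policy = "strict") {
  x |>
    filter_expenditure() |>
    strip_descriptions() |>
    normalize_amounts(method = method) |>
    label_ledger(chart, policy = policy)
}

#' Write the privacy-preserving labeled dataset
#'
#' In privacy mode (the default) only `date`, `account`, `norm_amount` and
#' `severity` are written: no description text and no raw amounts survive.
#'
#' @param labeled Output of [label_ledger()] or [preprocess_ledger()].
#' @param path File path.
#' @param privacy If `FALSE`, raw `amount` and `description` columns (if
#'   present) are retained.
#' @export
write_labeled <- function(labeled, path, privacy = TRUE) {
  cols <- if (privacy) c("date", "account", "norm_amount", "severity")
          else intersect(c("date", "account", "amount", "description",
                           "norm_amount", "severity", "severity_merged"),
                         names(labeled))
  df <- as.data.frame(labeled)[, cols]
  df$date <- format(df$date, "%Y-%m-%d")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# finpheno labeled-transactions schema v1", con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read the labeled dataset written by [write_labeled()]
#' @param path File path.
#' @return A labeled transaction tibble with `severity_merged` recomputed.
#' @export
read_labeled <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", colClasses = "character")
  out <- tibble(
    date = as.Date(df$date),
    account = df$account,
    norm_amount = if ("norm_amount" %in% names(df)) as.numeric(df$norm_amount) else NA_real_,
    severity = severity_factor(df$severity))
  out$severity_merged <- factor(
    ifelse(out$severity == "none", "none", "symptomatic"),
    levels = c("none", "symptomatic"))
  out
}
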