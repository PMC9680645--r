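#' Construct a transaction ledger
#'
#' A ledger is a tibble of dated, account-labeled monetary records — the
#' substrate of the whole pipeline. Transactions are stored with positive
#' magnitudes; the `direction` column separates expenditure from income.
#'
#' @param transactions A data frame with columns `date` (Date), `account`
#'   (`"checking"` or `"credit"`), `direction` (`"expenditure"` or
#'   `"income"`), `amount` (positive numeric magnitude), `description`
#'   (character, may be empty).
#' @return A `fp_ledger` tibble sorted ascending by date (stable with respect
#'   to input order within a date), with a `span` attribute holding the
#'   inclusive date range.
#' @examples
#' ledger(data.frame(
#'   date = as.Date(c("2017-01-03", "2017-01-02")),
#'   account = "checking", direction = "expenditure",
#'   amount = c(12.5, 3), description = c("COFFEE", "BUS")
#' ))
#' @export
ledger <- function(transactions) {
  tx <- as_tibble(transactions)
  required <- c("date", "account", "direction", "amount", "description")
  missing_cols <- setdiff(required, names(tx))
  if (length(missing_cols) > 0) {
    abort(sprintf("ledger is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  tx$date <- as.Date(tx$date)
  if (anyNA(tx$date)) abort("ledger dates must not be NA")
  if (!all(tx$account %in% ACCOUNT_LEVELS)) {
    abort(sprintf("account must be one of: %s",
                  paste(ACCOUNT_LEVELS, collapse = ", ")))
  }
  if (!all(tx$direction %in% c("expenditure", "income"))) {
    abort("direction must be 'expenditure' or 'income'")
  }
  if (any(tx$amount == 0)) abort("ledger amounts must be non-zero")
  if (any(tx$amount < 0)) abort("ledger amounts are stored as positive magnitudes")
  tx$description <- as.character(tx$description)
  tx <- tx[order(tx$date), , drop = FALSE]  # stable sort
  new_ledger(tx)
}

new_ledger <- function(tx) {
  span <- if (nrow(tx) > 0) range(tx$date) else as.Date(character())
  structure(tx, class = c("fp_ledger", class(as_tibble(tx))), span = span)
}

#' @export
print.fp_ledger <- function(x, ...) {
  sp <- attr(x, "span")
  cat(sprintf("<ledger: %d transactions%s>\n", nrow(x),
              if (length(sp) == 2) sprintf(", %s to %s", sp[1], sp[2]) else ""))
  NextMethod()
}

#' Span of a ledger
#' @param x A `fp_ledger`.
#' @return Inclusive date range (length-2 Date vector), or empty for an
#'   empty ledger.
#' @export
ledger_span <- function(x) attr(x, "span")

#' Merge per-file transaction tables into one ledger
#'
#' Concatenates transaction tables parsed from individual statement files
#' into a single globally date-sorted ledger, retaining account labels.
#' Identical rows appearing in more than one file (overlapping statement
#' periods are common in exports) are deduplicated with a warning; the
#' dedup key is (date, account, direction, amount, description), so
#' distinct same-day purchases must differ in description.
#'
#' @param per_file_transactions A list of transaction data frames (the
#'   output of [parse_statement_file()]), or a single data frame.
#' @return A `fp_ledger`. The result is invariant to the order of the input
#'   list.
#' @export
assemble_ledger <- function(per_file_transactions) {
  if (is.data.frame(per_file_transactions)) {
    per_file_transactions <- list(per_file_transactions)
  }
  key <- c("date", "account", "direction", "amount", "description")
  tagged <- purrr::imap(per_file_transactions, function(df, i) {
    df <- as_tibble(df)
    df$.file <- i
    df
  })
  all_tx <- bind_rows(tagged)
  if (nrow(all_tx) == 0) {
    return(new_ledger(tibble(date = as.Date(character()), account = character(),
                             direction = character(), amount = numeric(),
                             description = character())))
  }
  # drop rows whose full key already appeared in an *earlier* file; rows
  # within one file are never collapsed against each other
  first_file <- stats::aggregate(all_tx$.file, by = all_tx[key], FUN = min)
  names(first_file)[ncol(first_file)] <- ".first_file"
  all_tx <- left_join(all_tx, as_tibble(first_file), by = key)
  keep <- all_tx$.file == all_tx$.first_file
  n_dup <- sum(!keep)
  if (n_dup > 0) {
    warn(sprintf("assemble_ledger: removed %d duplicate row(s) repeated across files", n_dup))
  }
  all_tx <- all_tx[keep, setdiff(names(all_tx), c(".file", ".first_file"))]
  ledger(all_tx)
}

#' Read / write the canonical ledger CSV
#'
#' Canonical on-disk form: columns `date` (ISO-8601), `account`,
#' `direction`, `amount`, `description`.
#'
#' @param path File path.
#' @return `read_ledger()` returns a `fp_ledger`.
#' @export
read_ledger <- function(path) {
  df <- utils::read.csv(path, colClasses = c(
    date = "Date", account = "character", direction = "character",
    amount = "numeric", description = "character"))
  ledger(df)
}

#' @param x A `fp_ledger`.
#' @rdname read_ledger
#' @export
write_ledger <- function(x, path) {
  df <- as.data.frame(x)[, c("date", "account", "direction", "amount", "description")]
  df$date <- format(df$date, "%Y-%m-%d")
  df$amount <- sprintf("%.2f", df$amount)
  utils::write.csv(df, path, row.names = FALSE, quote = which(names(df) == "description"))
  invisible(path)
}
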