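#' Describe a statement-export dialect
#'
#' Bank-statement exports produced by PDF table extraction come with
#' artifacts: a single transaction can span multiple physical rows
#' (continuation rows), one file can contain several account sections, and
#' one account can span several files. A dialect makes the conventions of a
#' particular export explicit instead of guessing: which cell holds the
#' date/description/amount, the date format, how account-section marker
#' rows look, and how expenditure is distinguished from income.
#'
#' @param date_col,desc_col,amount_col 1-based cell indices.
#' @param date_format Format string for [base::as.Date()]; statements carry
#'   day-level resolution only.
#' @param account_marker Regex matched against a row's first cell; its first
#'   capture group names the account (`checking`/`credit`) for subsequent
#'   rows.
#' @param default_account Account assumed before any marker row; `NA` means
#'   a file without a marker is a fatal format error.
#' @param expenditure_sign `"negative"` (debits printed negative, the common
#'   export convention) or `"positive"`.
#' @param has_header Whether each file starts with a header row to skip.
#' @return A list of class `fp_dialect`.
#' @export
statement_dialect <- function(date_col = 1L, desc_col = 2L, amount_col = 3L,
                              date_format = "%Y-%m-%d",
                              account_marker = "^#\\s*ACCOUNT:\\s*([a-z]+)\\s*$",
                              default_account = NA_character_,
                              expenditure_sign = c("negative", "positive"),
                              has_header = FALSE) {
  expenditure_sign <- match.arg(expenditure_sign)
  structure(list(date_col = date_col, desc_col = desc_col,
                 amount_col = amount_col, date_format = date_format,
                 account_marker = account_marker,
                 default_account = default_account,
                 expenditure_sign = expenditure_sign,
                 has_header = has_header),
            class = "fp_dialect")
}

parse_amount_ <- function(x) {
  suppressWarnings(as.numeric(gsub("[$,]", "", x)))
}

#' Parse one statement file into transactions
#'
#' Handles the PDF-extraction artifacts described by the dialect:
#' continuation rows (date and amount cells both empty) are appended to the
#' preceding transaction's description with a single space; account-marker
#' rows switch the account label for subsequent rows; rows with an amount
#' but an unparseable date are collected as record-level problems and
#' skipped, never silently dropped.
#'
#' @param path Path to a delimited statement file, or a character matrix /
#'   data frame of raw cells (rows x cells).
#' @param dialect A [statement_dialect()].
#' @return A tibble of transactions (`date`, `account`, `direction`,
#'   `amount`, `description`) with attributes `problems` (tibble of skipped
#'   rows with reasons) and `n_records` (count of logical transaction
#'   records seen, so that `nrow(result) + nrow(problems) == n_records`).
#' @export
parse_statement_file <- function(path, dialect = statement_dialect()) {
  stopifnot(inherits(dialect, "fp_dialect"))
  empty_tx_ <- function() {
    tx <- tibble(date = as.Date(character()), account = character(),
                 direction = character(), amount = numeric(),
                 description = character())
    attr(tx, "problems") <- tibble(row_index = integer(), reason = character())
    attr(tx, "n_records") <- 0L
    tx
  }
  if (is.character(path) && length(path) == 1L && file.exists(path)) {
    if (length(readLines(path, n = 1L)) == 0L) return(empty_tx_())
    cells <- utils::read.csv(path, header = FALSE, fill = TRUE,
                             colClasses = "character",
                             blank.lines.skip = FALSE,
                             skip = if (dialect$has_header) 1L else 0L)
  } else {
    cells <- as.data.frame(path, stringsAsFactors = FALSE)
  }
  cells[] <- lapply(cells, function(col) {
    col <- as.character(col)
    col[is.na(col)] <- ""
    trimws(col)
  })
  need <- max(dialect$date_col, dialect$desc_col, dialect$amount_col)
  while (ncol(cells) < need) cells[[ncol(cells) + 1L]] <- rep("", nrow(cells))

  account <- dialect$default_account
  out <- list()
  problems <- list()
  n_records <- 0L
  for (i in seq_len(nrow(cells))) {
    row <- as.character(cells[i, ])
    first <- row[1]
    mk <- regmatches(first, regexec(dialect$account_marker, first))[[1]]
    if (length(mk) >= 2) {
      account <- mk[2]
      next
    }
    d_raw <- row[dialect$date_col]
    a_raw <- row[dialect$amount_col]
    desc <- row[dialect$desc_col]
    if (d_raw == "" && a_raw == "") {
      if (desc == "") next  # fully blank row
      if (length(out) == 0) {
        problems[[length(problems) + 1L]] <-
          tibble(row_index = i, reason = "continuation row with no preceding transaction")
        next
      }
      # continuation row: description overflow from the previous record
      out[[length(out)]]$description <-
        paste(out[[length(out)]]$description, desc)
      next
    }
    n_records <- n_records + 1L
    if (is.na(account)) {
      abort(sprintf("row %d: transaction before any account marker and no default account in dialect", i))
    }
    d <- as.Date(d_raw, format = dialect$date_format)
    a <- parse_amount_(a_raw)
    reason <- NULL
    if (is.na(d)) reason <- sprintf("unparseable date '%s'", d_raw)
    else if (is.na(a)) reason <- sprintf("unparseable amount '%s'", a_raw)
    else if (a == 0) reason <- "zero amount"
    if (!is.null(reason)) {
      problems[[length(problems) + 1L]] <- tibble(row_index = i, reason = reason)
      next
    }
    expend <- if (dialect$expenditure_sign == "negative") a < 0 else a > 0
    out[[length(out) + 1L]] <- list(
      date = d, account = account,
      direction = if (expend) "expenditure" else "income",
      amount = abs(a), description = desc)
  }
  tx <- if (length(out) > 0) {
    bind_rows(lapply(out, as_tibble))
  } else {
    tibble(date = as.Date(character()), account = character(),
           direction = character(), amount = numeric(),
           description = character())
  }
  probs <- if (length(problems) > 0) bind_rows(problems) else
    tibble(row_index = integer(), reason = character())
  if (nrow(probs) > 0) {
    warn(sprintf("parse_statement_file: skipped %d problem row(s); see attr(, 'problems')",
                 nrow(probs)))
  }
  attr(tx, "problems") <- probs
  attr(tx, "n_records") <- n_records
  tx
}

#' Parse a directory of statement files into one ledger
#'
#' Convenience wrapper: parses every file matching `pattern` in `dir` with
#' [parse_statement_file()] and joins them with [assemble_ledger()].
#'
#' @param dir Directory of statement exports.
#' @param dialect A [statement_dialect()].
#' @param pattern Filename regex, default `"\\.csv$"`.
#' @return A `fp_ledger`.
#' @export
read_statements <- function(dir, dialect = statement_dialect(),
                            pattern = "\\.csv$") {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (length(files) == 0) abort(sprintf("no statement files found in %s", dir))
  assemble_ledger(lapply(files, parse_statement_file, dialect = dialect))
}
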