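#!/usr/bin/env Rscript
# Stage 2 — ingest the statement exports back into a clean ledger.
#
# The monthly exports deliberately carry the artifacts of PDF table
# extraction (transactions spanning multiple physical rows, both accounts
# sharing each file behind marker rows). This stage parses them with the
# declared dialect, joins the monthly files, and verifies the ingest is
# lossless against the ledger written by stage 1.

suppressPackageStartupMessages(library(finpheno))

led <- read_statements("results/statements", statement_dialect())
write_ledger(led, "results/ledger.csv")

truth <- read_ledger("results/ledger_true.csv")
key <- function(l) {
  d <- as.data.frame(l)
  d <- d[do.call(order, d), ]
  rownames(d) <- NULL
  d
}
stopifnot(identical(key(led)$amount, key(truth)$amount),
          identical(key(led)$date, key(truth)$date),
          identical(key(led)$description, key(truth)$description))

cat(sprintf("Parsed %d transactions from %d monthly statements; round-trip exact\n",
            nrow(led), length(list.files("results/statements"))))
cat(sprintf("Span %s to %s; accounts: %s\n",
            ledger_span(led)[1], ledger_span(led)[2],
            paste(sort(unique(led$account)), collapse = ", ")))
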