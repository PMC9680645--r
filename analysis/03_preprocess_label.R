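#!/usr/bin/env Rscript
# Stage 3 — privacy transform and mood-severity labeling.
#
# Income transactions are dropped (spending, not earnings, is the
# behavioral signal of interest), free-text descriptions are removed, and
# amounts are min-max normalized per account so no identifying text or
# raw monetary value survives. Each remaining transaction is then labeled
# with its month's mania severity from the life chart, plus the merged
# binary phase label (none vs symptomatic).

suppressPackageStartupMessages(library(finpheno))

led <- read_ledger("results/ledger.csv")
chart <- read_lifechart("results/chart.csv")

labeled <- preprocess_ledger(led, chart)
write_labeled(labeled, "results/labeled.csv")

cat(sprintf("Labeled %d expenditure transactions (%d income rows removed)\n",
            nrow(labeled), nrow(led) - nrow(labeled)))
print(table(severity = labeled$severity))
cat("Privacy-preserving dataset written to results/labeled.csv",
    "(date, account, normalized amount, severity only)\n")
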