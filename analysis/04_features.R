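#!/usr/bin/env Rscript
# Stage 4 — resample into per-period feature series.
#
# Transaction frequency (count per period) and volume (sum of normalized
# amounts per period) at daily, weekly and monthly grains, each period
# carrying its mood-severity label, plus the monthly percentage of
# purchases made on the credit account — the debt-shift indicator.

suppressPackageStartupMessages(library(finpheno))

labeled <- read_labeled("results/labeled.csv")
chart <- read_lifechart("results/chart.csv")

for (g in c("daily", "weekly", "monthly")) {
  f <- resample_features(labeled, g, chart)
  write_features(f, sprintf("results/features_%s.csv", g))
  cat(sprintf("%-8s %4d periods, mean frequency %6.2f, mean volume %6.3f\n",
              g, nrow(f), mean(f$frequency), mean(f$volume)))
}

fd <- resample_features(labeled, "daily", chart)
cat("\nMean daily features by symptom phase:\n")
print(as.data.frame(phase_summary(fd)), digits = 3)

cr <- credit_ratio_monthly(labeled)
utils::write.csv(transform(as.data.frame(cr), month = format(month, "%Y-%m")),
                 "results/credit_ratio_monthly.csv", row.names = FALSE)
sev_m <- severity_at(chart, cr$month)
cat(sprintf("\nCredit share of purchases: %.1f%% in none months vs %.1f%% in moderate months\n",
            mean(cr$credit_pct[sev_m == "none"]),
            mean(cr$credit_pct[sev_m == "moderate"])))
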