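#!/usr/bin/env Rscript
# Stage 5 — burstiness and phase-comparison inference.
#
# Burstiness B = (r-1)/(r+1), r = sigma/tau of the inter-event intervals,
# under both interval schemes: D (day gaps between successive
# transactions) and C (lengths of zero-expenditure day runs), overall and
# per symptomatic phase. Then Welch's heteroscedastic one-way ANOVA with
# Games-Howell post-hoc contrasts for daily frequency and volume across
# phases, in the three-level and merged two-level layouts.

suppressPackageStartupMessages(library(finpheno))
suppressPackageStartupMessages(library(dplyr))

labeled <- read_labeled("results/labeled.csv")
chart <- read_lifechart("results/chart.csv")
fd <- resample_features(labeled, "daily", chart)

burst <- bind_rows(lapply(c(FALSE, TRUE), function(mg) {
  bind_rows(burstiness_by_phase(labeled, chart, "D", merge = mg),
            burstiness_by_phase(labeled, chart, "C", merge = mg)) |>
    mutate(merged = mg)
}))
utils::write.csv(burst, "results/burstiness.csv", row.names = FALSE)
cat("Burstiness by phase (merged two-phase layout):\n")
print(as.data.frame(burst[burst$merged, c("scheme", "phase", "n", "B")]),
      digits = 3, row.names = FALSE)

rows <- list()
for (ep in c("frequency", "volume")) {
  for (mg in c(FALSE, TRUE)) {
    res <- phase_inference(fd, ep, merge = mg)
    w <- res$welch
    cat(sprintf("\n%s (%s phases): Welch F(%d, %.0f) = %.2f, p = %.3f\n",
                ep, if (mg) "merged" else "three", w$df1, w$df2,
                w$statistic, w$p.value))
    print(as.data.frame(res$games_howell), digits = 3, row.names = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      endpoint = ep, merged = mg, F = w$statistic,
      df1 = w$df1, df2 = w$df2, p = w$p.value)
    gh <- res$games_howell
    gh$endpoint <- ep; gh$merged <- mg
    utils::write.csv(gh, sprintf("results/games_howell_%s_%s.csv", ep,
                                 if (mg) "merged" else "full"),
                     row.names = FALSE)
  }
}
utils::write.csv(do.call(rbind, rows), "results/welch_anova.csv",
                 row.names = FALSE)
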