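#!/usr/bin/env Rscript
# Stage 4: jackknife uncertainty and multiple comparison.
#
# Jackknifes the pest kill rate over the 15 females of each cohort
# (leave-one-out pseudovalues, t-based 95% interval) and compares the three
# rearing origins with the Newman-Keuls sequential studentized-range test.
# Writes the comparison report and a killing-parameters summary table.

library(killrate)

indir <- "results/cohorts"
dir.create("results", showWarnings = FALSE)

jk <- list()
for (trt in c("Ld", "Gd", "Po")) {
  cohort <- read_cohort(file.path(indir, paste0("cohort_", trt, ".csv")), trt)
  jk[[trt]] <- jackknife_rate(cohort, rate_kind = "km", alpha = 0.05)
  print(jk[[trt]])
}

nk <- newman_keuls(jk, alpha = 0.05)
print(nk)

report <- merge(
  nk$table,
  do.call(rbind, lapply(jk, function(j) {
    data.frame(treatment = j$treatment,
               interval_low = j$interval[1], interval_high = j$interval[2])
  })),
  by = "treatment"
)
write.csv(report[order(-report$estimate), ],
          "results/comparison.csv", row.names = FALSE)
cat("comparison written to results/comparison.csv\n")
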