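#!/usr/bin/env Rscript
# Desk calculations: the two per-group sample sizes behind the survey
# design, and the descriptive-table percentage cells recomputed from the
# published stratum counts.

suppressPackageStartupMessages(library(contactsurvey))

out <- "results/stats"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

specs <- list(
  small_effect = power_spec(0.2, power = 0.9, alpha = 0.05, sides = 2L),
  large_effect = power_spec(0.8, power = 0.9, alpha = 0.05, sides = 2L)
)
sizes <- data.frame(
  comparison = c("previous vs present survey (d = 0.2)",
    "weekday vs weekend (d = 0.8)"),
  n_per_group = vapply(specs, sample_size_two_sample_t, integer(1)),
  achieved_power = vapply(seq_along(specs), function(i) {
    power_two_sample_t(sample_size_two_sample_t(specs[[i]]), specs[[i]])
  }, numeric(1))
)
write.csv(sizes, file.path(out, "sample_sizes.csv"), row.names = FALSE)
message("per-group sample sizes at power 0.9, two-sided alpha 0.05:")
print(sizes, digits = 4)

n_during <- 1953L; n_after <- 1384L; total <- n_during + n_after
cells <- data.frame(
  cell = c("male", "urban", "weekday", "venue (during)"),
  count = c(1600L, 1713L, 2198L, 79L),
  denominator = c(total, total, total, n_during)
)
cells$percent <- table_percentage(cells$count, cells$denominator)
write.csv(cells, file.path(out, "table_percentages.csv"), row.names = FALSE)
message(sprintf("pooled total: %d", total))
print(cells)
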