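#!/usr/bin/env Rscript
# Contact-count descriptives by stratum and a negative-binomial regression
# of total daily contacts on participant covariates.

suppressPackageStartupMessages(library(contactsurvey))

data_dir <- "results/data"
out <- "results/stats"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

survey <- read_survey(file.path(data_dir, "participants.csv"),
  file.path(data_dir, "contacts.csv"))

by_stratum <- describe_by_stratum(survey)
write.csv(by_stratum, file.path(out, "count_summaries.csv"), row.names = FALSE)
message("contact-count summaries by period x day type:")
print(by_stratum, digits = 3)

pooled <- describe_counts(table(factor(survey$contacts$participant_id,
  survey$participants$participant_id)))
message(sprintf("pooled: median %g (IQR %g-%g), mean %.2f (SD %.2f)",
  pooled$median, pooled$q1, pooled$q3, pooled$mean, pooled$sd))

# Rate ratios for age group, gender, period, day type and urbanicity. The
# under-20 age groups are the ones to watch: the study period falls in the
# school summer vacation, so their simulated contacts carry no school term.
dat <- survey$participants
dat$age_group <- factor(default_age_grouping()$labels[
  assign_age_group(dat$age, default_age_grouping())],
  levels = default_age_grouping()$labels)
dat$age_band <- cut(dat$age, c(0, 20, 40, 60, Inf), right = FALSE,
  labels = c("0-19", "20-39", "40-59", "60+"))
x <- model.matrix(~ age_band + gender + period + day_type + urban, dat)
counts <- as.integer(table(factor(survey$contacts$participant_id,
  survey$participants$participant_id)))
fit <- fit_nb_glm(counts, x)
rr <- rate_ratio_table(fit)
write.csv(rr, file.path(out, "regression_rate_ratios.csv"), row.names = FALSE)
message(sprintf("NB regression converged in %d iterations, dispersion k = %.3f:",
  fit$iterations, fit$dispersion))
print(rr, digits = 3)
message("The simulated truth has no period or day-type effect, so those rate ",
  "ratios stay near 1; age-band ratios trace the assortative truth row sums.")
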