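#!/usr/bin/env Rscript
# Estimate the four stratum contact matrices (weekday W, weekend H,
# after-period A, during-period O) from the simulated survey, with
# reciprocity correction against the pyramid and bootstrap intervals, and
# summarize assortativity and relative transmission potential.

suppressPackageStartupMessages(library(contactsurvey))

data_dir <- "results/data"
out <- "results/matrices"
if (!file.exists(file.path(data_dir, "participants.csv"))) {
  stop("run analysis/01_simulate.R first")
}

cfg <- run_config(
  out_dir = out,
  participants = file.path(data_dir, "participants.csv"),
  contacts = file.path(data_dir, "contacts.csv"),
  pyramid = file.path(data_dir, "pyramid.csv"),
  bootstrap = list(B = 1000L, level = 0.95, seed = 42L)
)
bundle <- run_pipeline(cfg)

message("stratum matrices written to ", out)
print(bundle$comparison)
message("Strata share one ground truth, so diag_share is stable across strata ",
  "and every spectral ratio against W sits near 1; the matrix CSVs carry the ",
  "cellwise estimates and percentile bounds.")

# day-type weighted average matrix for an average calendar day
avg <- daytype_weighted(bundle$matrices$W, bundle$matrices$H)
write_contact_matrix(avg, file.path(out, "matrix_weighted_all.csv"))
message(sprintf("5/7-2/7 weighted matrix written; dominant eigenvalue %.2f",
  max(Mod(eigen(avg$values, only.values = TRUE)$values))))
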