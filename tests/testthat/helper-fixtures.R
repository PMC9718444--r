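# Small in-code fixtures shared across test files.

two_group_grouping <- function() age_grouping(c(0, 40), c("young", "old"))

make_participants <- function(ids, ages,
                              period = "during", day_type = "weekday",
                              weight = 1) {
  n <- length(ids)
  data.frame(
    participant_id = ids, age = ages,
    gender = rep("female", n),
    period = rep_len(period, n), day_type = rep_len(day_type, n),
    urban = rep_len(TRUE, n), diary_date = rep_len("2021-08-05", n),
    weight = rep_len(weight, n), stringsAsFactors = FALSE
  )
}

make_contacts <- function(ids, ages_lo, ages_hi = ages_lo) {
  data.frame(
    participant_id = ids, contact_age_lo = ages_lo, contact_age_hi = ages_hi,
    physical = rep_len(FALSE, length(ids)),
    setting = rep_len("other", length(ids)), stringsAsFactors = FALSE
  )
}

# Two participants in the young group reporting (2 young, 1 old) and
# (0 young, 1 old); nobody in the old group.
half_observed_survey <- function() {
  survey_table(
    make_participants(c("a", "b"), c(20, 30)),
    make_contacts(c("a", "a", "a", "b"), c(10, 15, 50, 60)),
    two_group_grouping()
  )
}

small_random_survey <- function(n = 200, seed = 11, boost = 2,
                                base_rate = 6, dispersion = 0.5) {
  truth <- build_true_matrix(two_group_grouping(),
    population_pyramid(two_group_grouping(), c(100, 60)),
    base_rate = base_rate, assortativity_boost = boost)
  generate_survey(synthetic_config(truth, n_during = ceiling(n / 2),
    n_after = floor(n / 2), dispersion = dispersion, seed = seed))
}
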