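# Oracle for the raw matrix: naive per-participant loop.
naive_raw_matrix <- function(survey, stratum = "all") {
  g <- length(survey$grouping$labels)
  keep <- switch(stratum,
    all = rep(TRUE, nrow(survey$participants)),
    W = survey$participants$day_type == "weekday",
    H = survey$participants$day_type == "weekend",
    A = survey$participants$period == "after",
    O = survey$participants$period == "during")
  out <- matrix(NA_real_, g, g)
  pg <- assign_age_group(survey$participants$age, survey$grouping)
  for (i in seq_len(g)) {
    rows <- which(keep & pg == i)
    if (!length(rows)) next
    acc <- numeric(g)
    wsum <- 0
    for (r in rows) {
      p <- survey$participants[r, ]
      own <- survey$contacts[survey$contacts$participant_id == p$participant_id, ]
      y <- numeric(g)
      if (nrow(own)) {
        mid <- (own$contact_age_lo + own$contact_age_hi) %/% 2
        cg <- assign_age_group(mid, survey$grouping)
        for (cgi in cg) y[cgi] <- y[cgi] + 1
      }
      acc <- acc + p$weight * y
      wsum <- wsum + p$weight
    }
    out[i, ] <- acc / wsum
  }
  out
}

test_that("the raw matrix is the weighted per-group mean, with missing rows NA", {
  s <- half_observed_survey()
  cm <- raw_contact_matrix(s)
  expect_equal(unname(cm$values[1, ]), c(1, 1)) # (2+0)/2 young, (1+1)/2 old
  expect_true(all(is.na(cm$values[2, ])))
  expect_equal(unname(cm$n_by_group), c(2L, 0L))
  expect_false(cm$symmetrized)
})

test_that("raw matrix is invariant to rescaling all weights", {
  s <- small_random_survey(n = 120, seed = 13)
  base <- raw_contact_matrix(s)
  s$participants$weight <- s$participants$weight * 7
  expect_equal(raw_contact_matrix(s)$values, base$values)
})

test_that("raw matrix matches the naive per-participant loop exactly", {
  for (seed in c(3, 17)) {
    s <- small_random_survey(n = 60, seed = seed)
    s$participants$weight <- runif(nrow(s$participants), 0.5, 2)
    for (stratum in c("all", "W", "O")) {
      got <- raw_contact_matrix(s, stratum)$values
      expect_equal(unname(got), naive_raw_matrix(s, stratum),
        info = paste(seed, stratum))
    }
  }
})

test_that("reciprocity correction matches the hand-computed example", {
  g <- two_group_grouping()
  pyr <- population_pyramid(g, c(100, 50))
  cm <- contactsurvey:::new_contact_matrix(
    matrix(c(0, 2, 1, 0), 2, 2, byrow = TRUE), # c_12 = 2, c_21 = 1
    g, c(3L, 2L), "all")
  d <- symmetrize_reciprocity(cm, pyr)
  expect_equal(d$values[1, 2], (2 * 100 + 1 * 50) / (2 * 100)) # 1.25
  expect_equal(d$values[2, 1], (1 * 50 + 2 * 100) / (2 * 50)) # 2.5
  expect_true(d$symmetrized)
})

test_that("symmetrization is an idempotent, total-conserving projection", {
  g <- two_group_grouping()
  pyr <- population_pyramid(g, c(100, 60))
  for (seed in 1:8) {
    set.seed(seed)
    cm <- contactsurvey:::new_contact_matrix(
      matrix(runif(4, 0, 5), 2, 2), g, c(5L, 5L), "all")
    d1 <- symmetrize_reciprocity(cm, pyr)
    n_i <- pyr$counts
    # reciprocity residual
    lhs <- d1$values * n_i
    expect_lt(max(abs(lhs - t(lhs))) / max(1, sum(lhs)), 1e-12)
    # conservation of total population contacts
    expect_equal(sum(d1$values * n_i), sum(cm$values * n_i), tolerance = 1e-9)
    # idempotence (fixed point once symmetric)
    d2 <- symmetrize_reciprocity(d1, pyr)
    expect_equal(d2$values, d1$values, tolerance = 1e-12)
  }
  # zero matrix maps to zero matrix
  z <- contactsurvey:::new_contact_matrix(matrix(0, 2, 2), g, c(1L, 1L), "all")
  expect_true(all(symmetrize_reciprocity(z, pyr)$values == 0))
})

test_that("symmetrization refuses matrices with unobserved rows, naming them", {
  pyr <- population_pyramid(two_group_grouping(), c(100, 50))
  cm <- raw_contact_matrix(half_observed_survey())
  expect_error(symmetrize_reciprocity(cm, pyr), regexp = "old",
    class = "cs_empty_stratum_error")
})

test_that("day-type weighting is the stated convex combination", {
  g <- age_grouping(0, "all")
  mk <- function(v) contactsurvey:::new_contact_matrix(matrix(v, 1, 1), g, 1L, "W")
  expect_equal(daytype_weighted(mk(7), mk(0))$values[1, 1], 5)
  expect_equal(daytype_weighted(mk(3), mk(3))$values[1, 1], 3)
  expect_equal(daytype_weighted(mk(4), mk(9), weights = c(1, 0))$values[1, 1], 4)
  expect_error(daytype_weighted(mk(1), mk(1), weights = c(0.5, 0.4)),
    class = "cs_domain_error")
})

test_that("period scaling divides by T and composes to the identity", {
  g <- age_grouping(0, "all")
  m <- contactsurvey:::new_contact_matrix(matrix(6, 1, 1), g, 1L, "all")
  expect_equal(scale_by_period(m, 1)$values, m$values)
  expect_equal(scale_by_period(m, 2)$values[1, 1], 3)
  expect_equal(scale_by_period(scale_by_period(m, 2), 0.5)$values, m$values)
  expect_equal(scale_by_period(m, 2)$period_T, 2)
  expect_error(scale_by_period(m, 0), class = "cs_domain_error")
})

test_that("estimate_strata returns reciprocal matrices and flags empty strata", {
  pyr <- population_pyramid(two_group_grouping(), c(100, 60))
  s <- small_random_survey(n = 400, seed = 6)
  est <- estimate_strata(s, pyr)
  expect_named(est, c("W", "H", "A", "O"))
  for (m in est) {
    lhs <- m$values * pyr$counts
    expect_lt(max(abs(lhs - t(lhs))) / max(1, sum(lhs)), 1e-12)
  }
  # only weekday/during participants: H and A raise empty-stratum
  only_wd <- survey_table(
    make_participants(c("a", "b"), c(20, 50)),
    make_contacts(c("a", "b"), c(20, 50)),
    two_group_grouping()
  )
  expect_equal(names(estimate_strata(only_wd, pyr, c("W", "O"))), c("W", "O"))
  expect_error(estimate_strata(only_wd, pyr, "H"), regexp = "'H'",
    class = "cs_empty_stratum_error")
  expect_error(estimate_strata(only_wd, pyr, "A"), regexp = "'A'",
    class = "cs_empty_stratum_error")
})

test_that("stratum estimates converge to the shared truth as n grows", {
  g <- two_group_grouping()
  pyr <- population_pyramid(g, c(100, 60))
  tm <- build_true_matrix(g, pyr, base_rate = 6, assortativity_boost = 2)
  err <- function(n, seed) {
    s <- generate_survey(synthetic_config(tm, n / 2, n / 2, dispersion = 0.5, seed = seed))
    est <- estimate_strata(s, pyr, c("A", "O"))
    max(abs(est$O$values - est$A$values))
  }
  # |O - A| shrinks with n: same truth underlies both periods
  expect_lt(median(sapply(1:3, err, n = 8000)), median(sapply(1:3, err, n = 500)))
})

test_that("bootstrap intervals are seed-stable and degenerate for constant data", {
  pyr <- population_pyramid(two_group_grouping(), c(100, 60))
  s <- small_random_survey(n = 150, seed = 31)
  ci1 <- bootstrap_matrix(s, pyr, "all", B = 50, seed = 7)
  ci2 <- bootstrap_matrix(s, pyr, "all", B = 50, seed = 7)
  expect_identical(ci1$lower, ci2$lower)
  expect_identical(ci1$upper, ci2$upper)
  expect_true(all(ci1$lower <= ci1$point$values + 1e-12))
  expect_true(all(ci1$upper >= ci1$point$values - 1e-12))

  # identical participants in both groups -> zero-width intervals
  ids <- sprintf("p%02d", 1:20)
  p <- make_participants(ids, rep(c(20, 50), each = 10))
  k <- make_contacts(rep(ids, each = 2), rep(c(20, 50), times = 20))
  s0 <- survey_table(p, k, two_group_grouping())
  ci0 <- bootstrap_matrix(s0, pyr, "all", B = 40, seed = 3)
  expect_equal(ci0$lower, ci0$upper, tolerance = 1e-12)

  expect_warning(bootstrap_matrix(s0, pyr, "all", B = 10, level = 0.95, seed = 1),
    regexp = "small")
})

test_that("assortativity share matches hand arithmetic and its bounds", {
  g <- two_group_grouping()
  pyr_eq <- population_pyramid(g, c(100, 100))
  mk <- function(v, sym = TRUE) {
    m <- contactsurvey:::new_contact_matrix(v, g, c(1L, 1L), "all", symmetrized = sym)
    m
  }
  expect_equal(assortativity_diag_share(mk(diag(c(2, 3))), pyr_eq), 1)
  expect_equal(assortativity_diag_share(mk(matrix(1, 2, 2)), pyr_eq), 0.5)
  pyr <- population_pyramid(g, c(100, 50))
  d <- mk(matrix(c(2, 1, 2, 4), 2, 2, byrow = TRUE))
  expect_equal(assortativity_diag_share(d, pyr), 2 / 3)
  expect_error(assortativity_diag_share(mk(matrix(0, 2, 2)), pyr),
    class = "cs_numeric_error")
  expect_error(assortativity_diag_share(mk(matrix(1, 2, 2), sym = FALSE), pyr),
    class = "cs_domain_error")
})

test_that("spectral ratio behaves like a ratio of spectral radii", {
  g <- two_group_grouping()
  mk <- function(v) contactsurvey:::new_contact_matrix(v, g, c(1L, 1L), "all",
    symmetrized = TRUE)
  a <- mk(matrix(c(2, 0, 0, 1), 2, 2))
  b <- mk(matrix(c(1, 0, 0, 1), 2, 2))
  expect_equal(spectral_ratio(a, a), 1)
  expect_equal(spectral_ratio(mk(2 * b$values), b), 2)
  expect_equal(spectral_ratio(a, b), 2)
  expect_error(spectral_ratio(a, mk(matrix(0, 2, 2))), class = "cs_domain_error")
})
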