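test_that("count summaries match their closed forms and a brute-force oracle", {
  s <- describe_counts(c(3, 3, 3))
  expect_equal(c(s$median, s$q1, s$q3, s$mean, s$sd), c(3, 3, 3, 3, 0))
  s <- describe_counts(c(0, 1, 2, 3, 4))
  expect_equal(c(s$median, s$q1, s$q3, s$mean), c(2, 1, 3, 2))
  x <- c(1, 2, 3, 4, 100)
  s <- describe_counts(x)
  expect_equal(s$mean, 22)
  expect_equal(s$sd, sqrt(sum((x - mean(x))^2) / (length(x) - 1)))
  expect_error(describe_counts(integer()), class = "cs_domain_error")

  # sort-and-interpolate oracle on random inputs
  interp_q <- function(x, p) {
    x <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[pmin(lo + 1, length(x))] - x[lo])
  }
  for (seed in 1:10) {
    set.seed(seed)
    x <- rpois(sample(3:50, 1), 5)
    s <- describe_counts(x)
    expect_equal(c(s$q1, s$median, s$q3),
      c(interp_q(x, 0.25), interp_q(x, 0.5), interp_q(x, 0.75)),
      info = paste("seed", seed))
  }
})

test_that("stratum summaries partition the pooled summary", {
  s <- small_random_survey(n = 300, seed = 12)
  by <- describe_by_stratum(s)
  expect_equal(sum(by$n), nrow(s$participants))
  pooled <- describe_counts(contactsurvey:::participant_totals(s))
  expect_equal(sum(by$n * by$mean) / sum(by$n), pooled$mean)

  one <- survey_table(make_participants("a", 20), make_contacts("a", 25),
    two_group_grouping())
  suppressMessages(by1 <- describe_by_stratum(one))
  expect_equal(nrow(by1), 1L)
  expect_equal(by1$period, "during")
})

test_that("noncentral-t power has the right null limit and monotonicity", {
  spec0 <- power_spec(1e-9, power = 0.9, alpha = 0.05, sides = 2L)
  expect_equal(power_two_sample_t(100, spec0), 0.05, tolerance = 1e-6)
  spec <- power_spec(0.2)
  pw <- power_two_sample_t(seq(10, 500, by = 10), spec)
  expect_true(all(diff(pw) > 0))
  expect_error(power_two_sample_t(1, spec), class = "cs_domain_error")
})

test_that("power agrees with the stats::power.t.test oracle", {
  for (d in c(0.2, 0.5, 0.8)) {
    for (n in c(20, 100, 527)) {
      expect_equal(
        power_two_sample_t(n, power_spec(d)),
        stats::power.t.test(n = n, delta = d, sd = 1, strict = TRUE)$power,
        tolerance = 1e-6, info = paste(d, n)
      )
    }
  }
})

test_that("sample sizes bracket the target power exactly", {
  spec <- power_spec(0.2, power = 0.9, alpha = 0.05, sides = 2L)
  n <- sample_size_two_sample_t(spec)
  expect_equal(n, 527L)
  expect_gte(power_two_sample_t(527, spec), 0.9)
  expect_lt(power_two_sample_t(526, spec), 0.9)

  expect_equal(sample_size_two_sample_t(power_spec(0.8)), 34L)

  # sample_size o power consistency and monotonicity in d
  sizes <- sapply(c(0.1, 0.2, 0.4, 0.8, 1.6), function(d) {
    spec <- power_spec(d)
    n <- sample_size_two_sample_t(spec)
    expect_gte(power_two_sample_t(n, spec), spec$power)
    if (n > 2) expect_lt(power_two_sample_t(n - 1, spec), spec$power)
    n
  })
  expect_true(all(diff(sizes) < 0))
})

test_that("table percentages reproduce printed descriptive cells", {
  expect_equal(table_percentage(1600, 3337), 47.9)
  expect_equal(table_percentage(79, 1953), 4.0)
  expect_equal(table_percentage(0, 10), 0.0)
  # half-up, not banker's: 0.25% -> 0.3%
  expect_equal(table_percentage(1, 400), 0.3)
  expect_error(table_percentage(1, 0), class = "cs_domain_error")
  expect_error(table_percentage(5, 4), class = "cs_domain_error")
})

test_that("an intercept-only fit on constant counts returns log of the mean", {
  fit <- fit_nb_glm(rep(5, 40), matrix(1, 40, 1))
  expect_equal(unname(fit$coefficients), log(5), tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("the dispersion-fixed Poisson limit matches glm(poisson) closely", {
  set.seed(42)
  n <- 400
  x <- cbind(1, rbinom(n, 1, 0.5))
  y <- rpois(n, exp(1 + 0.4 * x[, 2]))
  ours <- fit_nb_glm(y, x, k_fixed = 1e8)
  ref <- glm(y ~ x[, 2], family = poisson())
  expect_equal(unname(ours$coefficients), unname(coef(ref)), tolerance = 1e-4)
  expect_equal(unname(ours$standard_errors),
    unname(summary(ref)$coefficients[, 2]), tolerance = 1e-4)
})

test_that("the NB fit recovers simulated coefficients and matches MASS::glm.nb", {
  skip_if_not_installed("MASS")
  set.seed(7)
  n <- 5000
  x <- cbind(intercept = 1, group = rbinom(n, 1, 0.5))
  beta <- c(log(3), 0.5)
  k <- 0.5
  y <- rnbinom(n, size = k, mu = exp(drop(x %*% beta)))
  fit <- fit_nb_glm(y, x)
  expect_true(fit$converged)
  expect_true(all(abs(fit$coefficients - beta) < 3 * fit$standard_errors))
  ref <- MASS::glm.nb(y ~ x[, "group"])
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-4)
  expect_equal(fit$dispersion, ref$theta, tolerance = 1e-3)
})

test_that("Wald intervals have near-nominal empirical coverage", {
  beta <- c(log(3), 0.5)
  z95 <- qnorm(0.975)
  hit <- vapply(1:500, function(sd_) {
    set.seed(10000 + sd_)
    n <- 2000
    x <- cbind(1, rbinom(n, 1, 0.5))
    y <- rnbinom(n, size = 1, mu = exp(drop(x %*% beta)))
    fit <- fit_nb_glm(y, x)
    abs(fit$coefficients - beta) < z95 * fit$standard_errors
  }, logical(2))
  coverage <- rowMeans(hit)
  expect_true(all(coverage > 0.93 & coverage < 0.97))
})

test_that("degenerate designs are rejected with classed errors", {
  y <- rpois(20, 3)
  expect_error(fit_nb_glm(y, cbind(1, 1)[rep(1, 20), ]), class = "cs_integrity_error")
  expect_error(fit_nb_glm(y[1:2], cbind(1, 0:1, c(1, 0))), class = "cs_domain_error")
  expect_error(fit_nb_glm(c(-1, y[-1]), matrix(1, 20, 1)), class = "cs_domain_error")
})

test_that("rate-ratio tables exponentiate coefficients with Wald bounds", {
  fit <- structure(list(
    coefficients = c(a = 0, b = log(2), c = 1),
    standard_errors = c(a = 0.1, b = 1e-12, c = 0.5),
    dispersion = 1, converged = TRUE, iterations = 3
  ), class = "nb_fit")
  tab <- rate_ratio_table(fit, level = 0.95)
  expect_equal(tab$rate_ratio, c(1, 2, exp(1)))
  expect_lt(tab$lower[1], 1)
  expect_gt(tab$upper[1], 1)
  expect_equal(tab$lower[2], 2, tolerance = 1e-9)
  z <- qnorm(0.975)
  expect_equal(tab$lower[3], exp(1 - z * 0.5))
  expect_equal(tab$upper[3], exp(1 + z * 0.5))
  fit$converged <- FALSE
  expect_error(rate_ratio_table(fit), class = "cs_numeric_error")
})
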