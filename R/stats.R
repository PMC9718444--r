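# Descriptive summaries, two-sample t power/sample-size, and a log-link
# negative-binomial count regression fitted by IRLS with a profile
# dispersion update.

#' Summarize a vector of daily contact counts
#'
#' Median and quartiles by linear interpolation of order statistics
#' (`stats::quantile` type 7), standard deviation with the `n - 1`
#' denominator.
#'
#' @param counts Non-negative integer vector, length at least 1.
#' @return A `count_summary`: list with `n`, `median`, `q1`, `q3`, `mean`,
#'   `sd`.
#' @export
describe_counts <- function(counts) {
  if (length(counts) < 1L) stop_domain("cannot summarize an empty count vector")
  if (anyNA(counts) || any(counts < 0)) stop_domain("counts must be non-negative and non-missing")
  q <- unname(stats::quantile(counts, probs = c(0.25, 0.5, 0.75), type = 7))
  structure(list(
    n = length(counts), median = q[2L], q1 = q[1L], q3 = q[3L],
    mean = mean(counts), sd = stats::sd(counts)
  ), class = "count_summary")
}

#' @export
print.count_summary <- function(x, ...) {
  cat(sprintf("n = %d, median %g (IQR %g-%g), mean %.2f (SD %.2f)\n",
    x$n, x$median, x$q1, x$q3, x$mean, x$sd))
  invisible(x)
}

#' Contact-count summaries by period and day type
#'
#' Summarizes each participant's total reported contacts within each
#' populated period x day-type stratum. Unpopulated strata are omitted
#' with a message.
#'
#' @param survey A [survey_table()].
#' @return A data frame with one row per populated stratum and the
#'   [describe_counts()] fields.
#' @export
describe_by_stratum <- function(survey) {
  stopifnot(inherits(survey, "survey_table"))
  totals <- participant_totals(survey)
  p <- survey$participants
  combos <- expand.grid(period = PERIOD_LEVELS, day_type = DAY_TYPE_LEVELS,
    stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sel <- p$period == combos$period[i] & p$day_type == combos$day_type[i]
    if (!any(sel)) {
      message(sprintf("stratum %s/%s has no participants; omitted",
        combos$period[i], combos$day_type[i]))
      return(NULL)
    }
    s <- describe_counts(totals[sel])
    data.frame(period = combos$period[i], day_type = combos$day_type[i],
      n = s$n, median = s$median, q1 = s$q1, q3 = s$q3,
      mean = s$mean, sd = s$sd, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Specify a two-sample power calculation
#'
#' @param d Cohen's d (standardized mean difference), positive.
#' @param power Target power in (0, 1).
#' @param alpha Significance level in (0, 1).
#' @param sides 1 or 2.
#' @return A `power_spec` list.
#' @export
power_spec <- function(d, power = 0.9, alpha = 0.05, sides = 2L) {
  if (d <= 0) stop_domain("effect size d must be positive")
  if (power <= 0 || power >= 1) stop_domain("power must be in (0, 1)")
  if (alpha <= 0 || alpha >= 1) stop_domain("alpha must be in (0, 1)")
  if (!sides %in% c(1L, 2L)) stop_domain("sides must be 1 or 2")
  structure(list(d = d, power = power, alpha = alpha, sides = as.integer(sides)),
    class = "power_spec")
}

#' Power of the two-sample t test
#'
#' Exact power at equal group sizes from the noncentral t distribution:
#' with `n` per group, the test statistic under the alternative is
#' noncentral t with `2n - 2` degrees of freedom and noncentrality
#' `d * sqrt(n / 2)`.
#'
#' @param n_per_group Integer group size, at least 2.
#' @param spec A [power_spec()].
#' @return The power (probability of rejection under the alternative).
#' @export
power_two_sample_t <- function(n_per_group, spec) {
  stopifnot(inherits(spec, "power_spec"))
  n <- as.integer(n_per_group)
  if (any(n < 2L)) stop_domain("need at least 2 observations per group")
  df <- 2 * n - 2
  ncp <- spec$d * sqrt(n / 2)
  if (spec$sides == 2L) {
    tc <- stats::qt(1 - spec$alpha / 2, df)
    stats::pt(tc, df, ncp = ncp, lower.tail = FALSE) + stats::pt(-tc, df, ncp = ncp)
  } else {
    tc <- stats::qt(1 - spec$alpha, df)
    stats::pt(tc, df, ncp = ncp, lower.tail = FALSE)
  }
}

#' Smallest per-group sample size reaching a target power
#'
#' Finds, by bisection on the integers, the smallest equal group size `n`
#' with `power_two_sample_t(n, spec) >= spec$power`. Power is strictly
#' increasing in `n`, so the answer is unique.
#'
#' @param spec A [power_spec()].
#' @return Integer `n` per group.
#' @export
sample_size_two_sample_t <- function(spec) {
  stopifnot(inherits(spec, "power_spec"))
  lo <- 2L
  hi <- 4L
  while (power_two_sample_t(hi, spec) < spec$power) {
    lo <- hi
    hi <- hi * 2L
    if (hi > 1e8) stop_numeric("sample-size search did not converge; effect size too small")
  }
  while (hi - lo > 1L) {
    mid <- lo + (hi - lo) %/% 2L
    if (power_two_sample_t(mid, spec) >= spec$power) hi <- mid else lo <- mid
  }
  hi
}

#' Table percentage with half-up rounding to one decimal
#'
#' `100 * count / total` rounded half-up (0.05 always rounds away from
#' zero), matching how descriptive tables are conventionally printed.
#'
#' @param count Non-negative integer, at most `total`.
#' @param total Positive integer.
#' @return Percentage with one decimal.
#' @export
table_percentage <- function(count, total) {
  if (any(total <= 0)) stop_domain("total must be positive")
  if (any(count < 0) || any(count > total)) stop_domain("count must be in [0, total]")
  pct <- 100 * count / total
  floor(pct * 10 + 0.5) / 10
}

nb_loglik <- function(y, mu, k) {
  sum(lgamma(y + k) - lgamma(k) - lgamma(y + 1) +
    k * log(k / (k + mu)) + y * log(ifelse(y == 0, 1, mu / (k + mu))))
}

# Method-of-moments dispersion from squared residuals: matches
# sum (y-mu)^2 to sum (mu + mu^2/k); under-dispersion falls back to the
# Poisson limit. Used as the initializer for the profile-likelihood update.
k_moments <- function(y, mu) {
  num <- sum((y - mu)^2) - sum(mu)
  if (num <= 0) return(1e8) # under-dispersed: Poisson limit
  max(sum(mu^2) / num, 1e-8)
}

#' Negative-binomial regression by IRLS
#'
#' Fits a log-link negative-binomial GLM (`variance = mu + mu^2/k`) to
#' contact counts. Coefficients are updated by iteratively reweighted
#' least squares for fixed dispersion `k`, alternated with a dispersion
#' update: a method-of-moments start refined by univariate likelihood
#' maximization in `log k`. Wald standard errors come from the final
#' weighted information matrix.
#'
#' @param counts Non-negative integer response vector.
#' @param design Numeric model matrix (including an intercept column if
#'   wanted); must have full column rank.
#' @param max_iter Maximum number of outer iterations.
#' @param tol Convergence tolerance on the relative coefficient change.
#' @param k_fixed Optional fixed dispersion; skips the dispersion update
#'   (use a very large value for the Poisson limit).
#' @return An `nb_fit`: list with `coefficients`, `standard_errors`,
#'   `dispersion`, `vcov`, `converged`, `iterations`, `loglik`.
#' @export
fit_nb_glm <- function(counts, design, max_iter = 100L, tol = 1e-8, k_fixed = NULL) {
  y <- as.numeric(counts)
  x <- as.matrix(design)
  if (anyNA(y) || any(y < 0)) stop_domain("counts must be non-negative and non-missing")
  n <- length(y)
  p <- ncol(x)
  if (nrow(x) != n) stop_shape("design matrix rows must match the response length")
  if (n <= p) stop_domain("need more observations than covariates")
  if (qr(x)$rank < p) {
    stop_integrity("design matrix is rank deficient; drop aliased covariates")
  }

  eta <- log(pmax(y, 0.5))
  beta <- qr.solve(x, eta) # least-squares start on the log scale
  eta <- drop(x %*% beta)
  mu <- exp(eta)
  k <- if (is.null(k_fixed)) k_moments(y, mu) else k_fixed

  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    # IRLS for beta at fixed k: canonical log-link working response.
    for (inner in 1:25) {
      w <- mu / (1 + mu / k)
      z <- eta + (y - mu) / mu
      fit <- stats::lm.wfit(x, z, w)
      beta_new <- fit$coefficients
      step <- max(abs(beta_new - beta)) / max(1, max(abs(beta)))
      beta <- beta_new
      eta <- drop(x %*% beta)
      eta <- pmin(pmax(eta, -30), 30)
      mu <- exp(eta)
      if (step < tol) break
    }
    if (!is.null(k_fixed)) {
      converged <- step < sqrt(tol)
      break
    }
    k_old <- k
    k0 <- k_moments(y, mu)
    opt <- stats::optimize(function(lk) nb_loglik(y, mu, exp(lk)),
      interval = log(k0) + c(-4, 4), maximum = TRUE, tol = 1e-8)
    k <- min(max(exp(opt$maximum), 1e-8), 1e8) # cap at the Poisson limit
    # Converged when k is stable or its profile is flat (e.g. equidispersed
    # data, where any large k fits equally well).
    ll_flat <- abs(nb_loglik(y, mu, k) - nb_loglik(y, mu, k_old)) <
      1e-8 * (1 + abs(nb_loglik(y, mu, k)))
    if ((abs(log(k) - log(k_old)) < 1e-6 || ll_flat) && step < sqrt(tol)) {
      converged <- TRUE
      break
    }
  }
  if (any(!is.finite(beta))) {
    stop_numeric("negative-binomial IRLS diverged", last_beta = beta)
  }

  w <- mu / (1 + mu / k)
  info <- crossprod(x * sqrt(w))
  vcov <- tryCatch(solve(info), error = function(e) {
    stop_numeric("information matrix is singular at the final iterate")
  })
  se <- sqrt(diag(vcov))
  cn <- colnames(x)
  if (is.null(cn)) cn <- paste0("x", seq_len(p))
  names(beta) <- names(se) <- cn
  dimnames(vcov) <- list(cn, cn)
  structure(list(
    coefficients = beta, standard_errors = se, dispersion = k, vcov = vcov,
    converged = converged, iterations = iter, loglik = nb_loglik(y, mu, k)
  ), class = "nb_fit")
}

#' @export
print.nb_fit <- function(x, ...) {
  cat(sprintf("Negative-binomial GLM (log link), k = %.4g, %sconverged in %d iteration(s)\n",
    x$dispersion, if (x$converged) "" else "NOT ", x$iterations))
  print(data.frame(estimate = x$coefficients, se = x$standard_errors))
  invisible(x)
}

#' Rate-ratio table from a negative-binomial fit
#'
#' Exponentiates coefficients into rate ratios with Wald intervals:
#' `RR = exp(beta)`, `CI = exp(beta +/- z * SE)`.
#'
#' @param result An `nb_fit` from [fit_nb_glm()]; must have converged.
#' @param level Confidence level (default 0.95).
#' @return Data frame with columns `term`, `rate_ratio`, `lower`, `upper`,
#'   `log_estimate`, `se`.
#' @export
rate_ratio_table <- function(result, level = 0.95) {
  stopifnot(inherits(result, "nb_fit"))
  if (!result$converged) stop_numeric("refusing to tabulate a non-converged fit")
  if (level <= 0 || level >= 1) stop_domain("level must be in (0, 1)")
  z <- stats::qnorm(1 - (1 - level) / 2)
  b <- result$coefficients
  se <- result$standard_errors
  data.frame(
    term = names(b),
    rate_ratio = exp(b),
    lower = exp(b - z * se),
    upper = exp(b + z * se),
    log_estimate = unname(b),
    se = unname(se),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
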