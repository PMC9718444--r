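# Contact-matrix estimation. The raw matrix c_ij is the (survey-weighted)
# average number of group-j persons contacted per day by group-i
# participants. Survey estimates of c violate population reciprocity
# (c_ij N_i != c_ji N_j); symmetrize_reciprocity projects onto the
# reciprocal subspace by averaging the two population-level totals.

STRATA <- c(W = "weekday", H = "weekend", A = "after", O = "during")

new_contact_matrix <- function(values, grouping, n_by_group, stratum,
                               symmetrized = FALSE, period_T = 1) {
  dimnames(values) <- list(grouping$labels, grouping$labels)
  structure(list(
    values = values, grouping = grouping,
    n_by_group = stats::setNames(as.integer(n_by_group), grouping$labels),
    stratum = stratum, symmetrized = symmetrized, period_T = period_T
  ), class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("Contact matrix [%s]%s, T = %g day(s), n = %d participants\n",
    x$stratum, if (x$symmetrized) ", reciprocity-corrected" else " (raw)",
    x$period_T, sum(x$n_by_group)))
  print(round(x$values, digits))
  invisible(x)
}

# Logical participant selector for a stratum label; NULL selects everyone.
stratum_selector <- function(participants, stratum) {
  switch(stratum,
    all = rep(TRUE, nrow(participants)),
    W = participants$day_type == "weekday",
    H = participants$day_type == "weekend",
    A = participants$period == "after",
    O = participants$period == "during",
    stop_domain(paste0("unknown stratum: ", stratum))
  )
}

#' Raw contact matrix
#'
#' Computes `c_ij`, the weighted mean number of group-j persons contacted
#' per day by group-i participants in the selected stratum:
#' `c_ij = sum_p w_p y_pj / sum_p w_p` over selected participants `p` of
#' group i, where `y_pj` counts p's contacts with group-j persons. Rows
#' whose participant group is empty in the stratum are `NA` (missing, not
#' zero).
#'
#' @param survey A [survey_table()].
#' @param stratum One of `"all"`, `"W"` (weekday), `"H"` (weekend),
#'   `"A"` (after period), `"O"` (during period).
#' @param subset Optional logical vector over participants, combined with
#'   the stratum filter (used by the bootstrap).
#' @return A raw `contact_matrix` (not symmetrized, T = 1).
#' @export
raw_contact_matrix <- function(survey, stratum = "all", subset = NULL) {
  stopifnot(inherits(survey, "survey_table"))
  keep <- stratum_selector(survey$participants, stratum)
  if (!is.null(subset)) keep <- keep & subset
  if (!any(keep)) {
    stop_empty_stratum(paste0("stratum '", stratum, "' selects no participants"),
      stratum = stratum)
  }
  y <- participant_contact_counts(survey)
  weighted_matrix_from_counts(
    y, survey$participants$weight,
    assign_age_group(survey$participants$age, survey$grouping),
    keep, survey$grouping, stratum
  )
}

# Sum rows of `x` by group index 1..g, keeping empty groups as zero rows
# (rowsum drops absent levels).
group_rowsum <- function(x, group, g) {
  x <- as.matrix(x)
  out <- matrix(0, g, ncol(x))
  agg <- rowsum(x, group)
  out[as.integer(rownames(agg)), ] <- agg
  out
}

# Core aggregation shared by the estimator and the bootstrap: `w` are
# effective weights (survey weight times resampling multiplicity).
weighted_matrix_from_counts <- function(y, w, pgroup, keep, grouping, stratum) {
  g <- n_groups(grouping)
  w_eff <- w * keep
  num <- group_rowsum(y * w_eff, pgroup, g)
  den <- drop(group_rowsum(w_eff, pgroup, g))
  values <- num / den # rows with den == 0 become NaN -> recoded NA
  values[den == 0, ] <- NA_real_
  n_by_group <- as.integer(drop(group_rowsum((keep & w > 0) + 0, pgroup, g)))
  new_contact_matrix(values, grouping, n_by_group, stratum)
}

#' Reciprocity correction (population-level symmetrization)
#'
#' At the population level, total contacts from group i to group j must
#' equal those from j to i. The correction averages the two estimated
#' totals and converts back to a per-participant rate:
#' `d_ij = (c_ij N_i + c_ji N_j) / (2 N_i)`. The projection conserves the
#' total number of population contacts `sum_ij c_ij N_i` and is
#' idempotent.
#'
#' @param c A raw `contact_matrix` with no missing rows.
#' @param pyramid A [population_pyramid()] on the same grouping.
#' @return A symmetrized `contact_matrix`.
#' @export
symmetrize_reciprocity <- function(c, pyramid) {
  stopifnot(inherits(c, "contact_matrix"), inherits(pyramid, "population_pyramid"))
  if (!same_grouping(c$grouping, pyramid$grouping)) {
    stop_shape("pyramid grouping does not match the matrix grouping")
  }
  miss <- apply(is.na(c$values), 1L, any)
  if (any(miss)) {
    stop_empty_stratum(paste0(
      "cannot symmetrize: no participants observed in group(s) ",
      paste(c$grouping$labels[miss], collapse = ", ")
    ), groups = c$grouping$labels[miss])
  }
  n_i <- pyramid$counts
  d <- (c$values * n_i + t(c$values * n_i)) / (2 * n_i)
  out <- new_contact_matrix(d, c$grouping, c$n_by_group, c$stratum,
    symmetrized = TRUE, period_T = c$period_T)
  out
}

#' Day-type weighted average matrix
#'
#' Convex combination of a weekday and a weekend matrix, by default with
#' calendar weights 5/7 and 2/7, representing an average day of the week.
#'
#' @param w,h Weekday and weekend `contact_matrix` objects on the same
#'   grouping.
#' @param weights Length-2 non-negative weights summing to 1.
#' @return A `contact_matrix` labelled `"all"`.
#' @export
daytype_weighted <- function(w, h, weights = c(5, 2) / 7) {
  stopifnot(inherits(w, "contact_matrix"), inherits(h, "contact_matrix"))
  if (!same_grouping(w$grouping, h$grouping)) {
    stop_shape("weekday and weekend matrices use different age groupings")
  }
  if (length(weights) != 2L || any(weights < 0) || abs(sum(weights) - 1) > 1e-12) {
    stop_domain("weights must be two non-negative numbers summing to 1")
  }
  values <- weights[1L] * w$values + weights[2L] * h$values
  new_contact_matrix(values, w$grouping, w$n_by_group + h$n_by_group, "all",
    symmetrized = w$symmetrized && h$symmetrized, period_T = w$period_T)
}

#' Scale a contact matrix by its observation period
#'
#' Converts total contacts over a diary period of `T` days to a per-day
#' rate: `phi_ij = values[i,j] / T`. A one-day diary (the usual design)
#' has `T = 1` and the transform is the identity.
#'
#' @param m A `contact_matrix`.
#' @param period_T Positive observation period in days.
#' @return A `contact_matrix` with `period_T` recorded.
#' @export
scale_by_period <- function(m, period_T = 1) {
  stopifnot(inherits(m, "contact_matrix"))
  if (!is.numeric(period_T) || length(period_T) != 1L || period_T <= 0) {
    stop_domain("period T must be a positive number of days")
  }
  new_contact_matrix(m$values / period_T, m$grouping, m$n_by_group, m$stratum,
    symmetrized = m$symmetrized, period_T = period_T)
}

#' Estimate the four stratum matrices
#'
#' Computes the reciprocity-corrected contact matrix for each of the four
#' study strata: weekday diaries (W, both periods), weekend diaries (H),
#' the after period (A) and the during period (O), each with T = 1.
#'
#' @param survey A [survey_table()].
#' @param pyramid A [population_pyramid()] on the survey's grouping.
#' @param strata Character vector of stratum labels to estimate.
#' @return Named list of symmetrized `contact_matrix` objects.
#' @export
estimate_strata <- function(survey, pyramid, strata = c("W", "H", "A", "O")) {
  stopifnot(inherits(survey, "survey_table"))
  bad <- setdiff(strata, names(STRATA))
  if (length(bad)) stop_domain(paste0("unknown strata: ", paste(bad, collapse = ", ")))
  out <- lapply(strata, function(s) {
    symmetrize_reciprocity(raw_contact_matrix(survey, stratum = s), pyramid)
  })
  names(out) <- strata
  out
}

#' Percentile-bootstrap confidence intervals for a contact matrix
#'
#' Resamples participants (with all their contacts) with replacement
#' within the stratum, recomputes the symmetrized matrix for each
#' replicate, and returns elementwise percentile intervals. Reproducible
#' from `seed`.
#'
#' @param survey A [survey_table()].
#' @param pyramid A [population_pyramid()].
#' @param stratum Stratum label as in [raw_contact_matrix()].
#' @param B Number of bootstrap replicates (default 1000).
#' @param level Interval level in (0, 1).
#' @param seed Integer seed.
#' @return An object of class `matrix_ci` with elements `point`
#'   (symmetrized `contact_matrix`), `lower`, `upper`, `level`, `B`,
#'   `seed`.
#' @export
bootstrap_matrix <- function(survey, pyramid, stratum = "all", B = 1000L,
                             level = 0.95, seed = 1L) {
  stopifnot(inherits(survey, "survey_table"))
  B <- as.integer(B)
  if (B < 1L) stop_domain("B must be at least 1")
  if (level <= 0 || level >= 1) stop_domain("level must be in (0, 1)")
  if (B * (1 - level) / 2 < 1) {
    warning(sprintf("B = %d is small for %.0f%% percentile intervals; tail quantiles are extrapolated",
      B, 100 * level), call. = FALSE)
  }
  point <- symmetrize_reciprocity(raw_contact_matrix(survey, stratum = stratum), pyramid)

  keep <- stratum_selector(survey$participants, stratum)
  idx <- which(keep)
  n_s <- length(idx)
  y <- participant_contact_counts(survey)
  w <- survey$participants$weight
  pgroup <- assign_age_group(survey$participants$age, survey$grouping)
  n_i <- pyramid$counts
  g <- n_groups(survey$grouping)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  reps <- array(NA_real_, dim = c(g, g, B))
  yw <- y * w
  for (b in seq_len(B)) {
    freq <- tabulate(idx[sample.int(n_s, n_s, replace = TRUE)], nbins = nrow(y))
    num <- group_rowsum(yw * freq, pgroup, g)
    den <- drop(group_rowsum(w * freq, pgroup, g))
    cvals <- num / den
    cvals[den == 0, ] <- NA_real_
    reps[, , b] <- (cvals * n_i + t(cvals * n_i)) / (2 * n_i)
  }
  alpha <- (1 - level) / 2
  lower <- apply(reps, c(1L, 2L), stats::quantile, probs = alpha, na.rm = TRUE)
  upper <- apply(reps, c(1L, 2L), stats::quantile, probs = 1 - alpha, na.rm = TRUE)
  dimnames(lower) <- dimnames(upper) <- dimnames(point$values)
  structure(list(point = point, lower = lower, upper = upper,
    level = level, B = B, seed = as.integer(seed)), class = "matrix_ci")
}

#' @export
print.matrix_ci <- function(x, ...) {
  cat(sprintf("Bootstrap %g%% percentile intervals (B = %d, seed = %d) for:\n",
    100 * x$level, x$B, x$seed))
  print(x$point)
  invisible(x)
}

#' Population share of within-group contacts
#'
#' An assortativity summary: the fraction of all population-level contacts
#' that occur within the participant's own age group,
#' `sum_i d_ii N_i / sum_ij d_ij N_i`. 1 for purely diagonal mixing, `1/G`
#' for uniform mixing with equal group sizes.
#'
#' @param d A symmetrized `contact_matrix`.
#' @param pyramid A [population_pyramid()].
#' @return A number in `[0, 1]`.
#' @export
assortativity_diag_share <- function(d, pyramid) {
  stopifnot(inherits(d, "contact_matrix"), inherits(pyramid, "population_pyramid"))
  if (!d$symmetrized) stop_domain("assortativity share is defined for symmetrized matrices")
  n_i <- pyramid$counts
  total <- sum(d$values * n_i)
  if (total <= 0) stop_numeric("assortativity share undefined for an all-zero matrix")
  sum(diag(d$values) * n_i) / total
}

#' Dominant-eigenvalue ratio of two contact matrices
#'
#' Ratio of spectral radii `rho(a)/rho(b)`, a proxy for the relative
#' transmission potential implied by two mixing patterns (the
#' next-generation matrix of a homogeneous-susceptibility model scales
#' linearly with the contact matrix).
#'
#' @param a,b Symmetrized `contact_matrix` objects on the same grouping.
#' @return A positive real.
#' @export
spectral_ratio <- function(a, b) {
  stopifnot(inherits(a, "contact_matrix"), inherits(b, "contact_matrix"))
  if (!same_grouping(a$grouping, b$grouping)) {
    stop_shape("matrices use different age groupings")
  }
  if (!a$symmetrized || !b$symmetrized) {
    stop_domain("spectral ratio is defined for symmetrized matrices")
  }
  rho <- function(m) max(Mod(eigen(m$values, only.values = TRUE)$values))
  rb <- rho(b)
  if (rb == 0) stop_domain("denominator matrix has zero spectral radius")
  rho(a) / rb
}

#' Write a contact matrix (and optional CIs) to CSV
#'
#' Row labels are participant age groups, column labels contact age
#' groups.
#'
#' @param m A `contact_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_contact_matrix <- function(m, path) {
  stopifnot(inherits(m, "contact_matrix"))
  utils::write.csv(as.data.frame(m$values), path, row.names = TRUE,
    quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
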