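# End-to-end orchestration: simulate or read a survey, estimate the four
# stratum matrices with bootstrap intervals, summarize counts, optionally
# fit the count regression, and write a manifest-ed report bundle.

#' Build a run configuration
#'
#' Exactly one of `simulate` (a [synthetic_config()]) or the three input
#' paths must be supplied. The configuration is the single source of truth
#' for a pipeline run; identical configurations (including seeds) produce
#' numerically identical bundles.
#'
#' @param out_dir Output directory for the report bundle (created if
#'   needed).
#' @param simulate Optional [synthetic_config()] for a simulated run.
#' @param participants,contacts,pyramid Optional input CSV paths for a
#'   data-driven run (pyramid is required in both modes unless `simulate`
#'   is given, whose truth carries its own pyramid).
#' @param grouping An [age_grouping()]; defaults to 5-year bins.
#' @param strata Stratum labels to estimate.
#' @param bootstrap List with elements `B`, `level`, `seed`; `B = 0`
#'   disables bootstrap intervals.
#' @param regression Optional model formula (over participant covariates)
#'   for the negative-binomial regression of total contacts, e.g.
#'   `~ period + day_type + urban`.
#' @return A `run_config`.
#' @export
run_config <- function(out_dir, simulate = NULL, participants = NULL,
                       contacts = NULL, pyramid = NULL,
                       grouping = default_age_grouping(),
                       strata = c("W", "H", "A", "O"),
                       bootstrap = list(B = 1000L, level = 0.95, seed = 1L),
                       regression = NULL) {
  has_sim <- !is.null(simulate)
  has_paths <- !is.null(participants) || !is.null(contacts)
  if (has_sim == has_paths) {
    stop_config("exactly one of a simulate block or input paths must be given")
  }
  if (has_sim && !inherits(simulate, "synthetic_config")) {
    stop_config("simulate block must be a synthetic_config")
  }
  if (has_paths && (is.null(participants) || is.null(contacts) || is.null(pyramid))) {
    stop_config("data-driven runs need participants, contacts and pyramid paths")
  }
  for (nm in c("B", "level", "seed")) {
    if (is.null(bootstrap[[nm]])) stop_config(paste0("bootstrap block is missing '", nm, "'"))
  }
  structure(list(
    out_dir = out_dir, simulate = simulate, participants = participants,
    contacts = contacts, pyramid = pyramid, grouping = grouping,
    strata = strata, bootstrap = bootstrap, regression = regression
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Mirrors [run_config()]; the `simulate` block holds the
#' [synthetic_config()] fields plus `base_rate` and `assortativity_boost`
#' for the ground truth.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_config(paste0("config file not found: ", path))
  cfg <- yaml::read_yaml(path)
  grouping <- if (!is.null(cfg$grouping$edges)) {
    age_grouping(cfg$grouping$edges, cfg$grouping$labels)
  } else {
    default_age_grouping()
  }
  simulate <- NULL
  if (!is.null(cfg$simulate)) {
    s <- cfg$simulate
    pyramid <- if (!is.null(s$pyramid)) {
      read_pyramid(s$pyramid, grouping)
    } else {
      japan_pyramid_2015()
    }
    truth <- build_true_matrix(grouping, pyramid,
      base_rate = s$base_rate %||% DEFAULT_BASE_RATE,
      assortativity_boost = s$assortativity_boost %||% DEFAULT_ASSORTATIVITY_BOOST)
    simulate <- synthetic_config(truth,
      n_during = s$n_during %||% DEFAULT_N_DURING,
      n_after = s$n_after %||% DEFAULT_N_AFTER,
      weekday_fraction = s$weekday_fraction %||% DEFAULT_WEEKDAY_FRACTION,
      dispersion = s$dispersion %||% DEFAULT_DISPERSION_K,
      daytype_multiplier = s$daytype_multiplier %||% 1,
      period_multiplier = s$period_multiplier %||% 1,
      seed = s$seed %||% 1L)
  }
  boot <- cfg$bootstrap %||% list()
  run_config(
    out_dir = cfg$out_dir %||% ".",
    simulate = simulate,
    participants = cfg$participants, contacts = cfg$contacts,
    pyramid = cfg$pyramid, grouping = grouping,
    strata = cfg$strata %||% c("W", "H", "A", "O"),
    bootstrap = list(B = as.integer(boot$B %||% 1000L),
      level = boot$level %||% 0.95, seed = as.integer(boot$seed %||% 1L)),
    regression = if (!is.null(cfg$regression)) stats::as.formula(cfg$regression)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full estimation pipeline
#'
#' Executes read/validate (or simulate), stratum matrix estimation with
#' reciprocity correction, bootstrap intervals, count descriptives, and an
#' optional negative-binomial regression, writing all artifacts plus a
#' manifest (with seeds and package version) under `config$out_dir`.
#' Identical config and seeds give byte-identical numeric outputs. On any
#' stage error the partial outputs are removed and the error re-signalled
#' with the failing stage name.
#'
#' @param config A [run_config()].
#' @return Invisibly, a `report_bundle`: list with the matrices, CIs,
#'   summaries, regression table and manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  stage <- "configuration"
  emit <- function(writer, obj, file) {
    path <- file.path(out_dir, file)
    writer(obj, path)
    written <<- c(written, path)
    path
  }

  bundle <- tryCatch({
    if (!is.null(config$simulate)) {
      stage <- "simulate"
      survey <- generate_survey(config$simulate)
      pyramid <- config$simulate$true_mixing$pyramid
      emit(write_truth, attr(survey, "truth"), "truth.csv")
      pp <- file.path(out_dir, "participants.csv")
      cp <- file.path(out_dir, "contacts.csv")
      write_survey(survey, pp, cp)
      written <- c(written, pp, cp)
      emit(write_pyramid, pyramid, "pyramid.csv")
    } else {
      stage <- "read"
      if (is.null(config$pyramid) || !file.exists(config$pyramid)) {
        stop_io(paste0("pyramid file not found: ", config$pyramid %||% "<missing>"))
      }
      pyramid <- read_pyramid(config$pyramid, config$grouping)
      survey <- read_survey(config$participants, config$contacts, config$grouping)
    }

    stage <- "estimate"
    matrices <- estimate_strata(survey, pyramid, config$strata)
    for (s in names(matrices)) {
      emit(write_contact_matrix, matrices[[s]], paste0("matrix_", s, ".csv"))
    }

    stage <- "bootstrap"
    cis <- NULL
    if (config$bootstrap$B > 0L) {
      cis <- lapply(seq_along(config$strata), function(i) {
        s <- config$strata[i]
        ci <- bootstrap_matrix(survey, pyramid, stratum = s,
          B = config$bootstrap$B, level = config$bootstrap$level,
          seed = config$bootstrap$seed + i - 1L)
        emit(function(m, p) utils::write.csv(as.data.frame(m), p, quote = FALSE),
          ci$lower, paste0("matrix_", s, "_lower.csv"))
        emit(function(m, p) utils::write.csv(as.data.frame(m), p, quote = FALSE),
          ci$upper, paste0("matrix_", s, "_upper.csv"))
        ci
      })
      names(cis) <- config$strata
    }

    stage <- "describe"
    summaries <- describe_by_stratum(survey)
    emit(function(d, p) utils::write.csv(d, p, row.names = FALSE, quote = FALSE),
      summaries, "count_summaries.csv")

    stage <- "compare"
    comparison <- data.frame(
      stratum = names(matrices),
      diag_share = vapply(matrices, assortativity_diag_share, numeric(1), pyramid = pyramid),
      spectral_vs_first = vapply(matrices, spectral_ratio, numeric(1), b = matrices[[1L]]),
      row.names = NULL, stringsAsFactors = FALSE
    )
    emit(function(d, p) utils::write.csv(d, p, row.names = FALSE, quote = FALSE),
      comparison, "matrix_comparison.csv")

    regression <- NULL
    if (!is.null(config$regression)) {
      stage <- "regress"
      dat <- survey$participants
      dat$age_group <- factor(survey$grouping$labels[
        assign_age_group(dat$age, survey$grouping)], levels = survey$grouping$labels)
      x <- stats::model.matrix(config$regression, dat)
      fit <- fit_nb_glm(participant_totals(survey), x)
      regression <- rate_ratio_table(fit)
      emit(function(d, p) utils::write.csv(d, p, row.names = FALSE, quote = FALSE),
        regression, "regression.csv")
    }

    stage <- "manifest"
    manifest <- list(
      package_version = as.character(utils::packageVersion("contactsurvey")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed_simulate = if (!is.null(config$simulate)) config$simulate$seed,
      seed_bootstrap = config$bootstrap$seed,
      strata = as.list(config$strata),
      files = as.list(basename(written))
    )
    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
    written <- c(written, manifest_path)

    structure(list(
      survey = survey, pyramid = pyramid, matrices = matrices, cis = cis,
      summaries = summaries, comparison = comparison, regression = regression,
      manifest = manifest, out_dir = out_dir
    ), class = "report_bundle")
  }, cs_error = function(e) {
    unlink(written)
    cs_error(paste0("pipeline stage '", stage, "' failed: ", conditionMessage(e)),
      class(e)[1L], stage = stage)
  })
  invisible(bundle)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("Report bundle in '%s': %d matrices, %d summary strata%s\n",
    x$out_dir, length(x$matrices), nrow(x$summaries),
    if (is.null(x$regression)) "" else ", regression table"))
  invisible(x)
}
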