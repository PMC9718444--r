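# Diary-survey data model: one participant = one diary day; contacts are
# the persons that participant reported for that day. All downstream
# estimators consume the validated survey_table, so validation is fail-fast
# here and never repeated downstream.

PARTICIPANT_COLS <- c(
  "participant_id", "age", "gender", "period", "day_type",
  "urban", "diary_date", "weight"
)
CONTACT_COLS <- c(
  "participant_id", "contact_age_lo", "contact_age_hi", "physical", "setting"
)
PERIOD_LEVELS <- c("during", "after")
DAY_TYPE_LEVELS <- c("weekday", "weekend")

#' Construct a validated diary-survey table
#'
#' Bundles a participant table (one row per diary day) with its contact
#' table (one row per reported contact) and the age grouping used to bin
#' both sides of the contact matrix. All invariants — unique participant
#' ids, referential integrity of contacts, allowed factor levels, positive
#' weights — are enforced at construction so downstream code never sees an
#' orphan contact.
#'
#' @param participants Data frame with columns `participant_id`, `age`,
#'   `gender`, `period` (`"during"`/`"after"`), `day_type`
#'   (`"weekday"`/`"weekend"`), `urban` (logical), `diary_date`
#'   (ISO-8601 string or NA), `weight` (positive).
#' @param contacts Data frame with columns `participant_id`,
#'   `contact_age_lo`, `contact_age_hi` (single-year ages encoded
#'   `lo == hi`), `physical`, `setting`.
#' @param grouping An [age_grouping()].
#' @return An object of class `survey_table`.
#' @export
survey_table <- function(participants, contacts, grouping = default_age_grouping()) {
  stopifnot(inherits(grouping, "age_grouping"))
  participants <- as.data.frame(participants, stringsAsFactors = FALSE)
  contacts <- as.data.frame(contacts, stringsAsFactors = FALSE)

  missing_p <- setdiff(PARTICIPANT_COLS, names(participants))
  if (length(missing_p)) {
    stop_schema(paste0("participant table is missing column(s): ",
      paste(missing_p, collapse = ", ")), columns = missing_p)
  }
  missing_c <- setdiff(CONTACT_COLS, names(contacts))
  if (length(missing_c)) {
    stop_schema(paste0("contact table is missing column(s): ",
      paste(missing_c, collapse = ", ")), columns = missing_c)
  }
  participants <- participants[PARTICIPANT_COLS]
  contacts <- contacts[CONTACT_COLS]

  participants$participant_id <- as.character(participants$participant_id)
  participants$age <- as.integer(participants$age)
  participants$gender <- as.character(participants$gender)
  participants$period <- as.character(participants$period)
  participants$day_type <- as.character(participants$day_type)
  participants$urban <- as.logical(participants$urban)
  participants$diary_date <- as.character(participants$diary_date)
  participants$weight <- as.numeric(participants$weight)

  bad <- which(is.na(participants$participant_id) |
    is.na(participants$age) | participants$age < 0L |
    !(participants$period %in% PERIOD_LEVELS) |
    !(participants$day_type %in% DAY_TYPE_LEVELS) |
    is.na(participants$weight) | participants$weight <= 0)
  if (length(bad)) {
    stop_domain(paste0("invalid mandatory participant field(s) in row(s): ",
      paste(utils::head(bad, 10L), collapse = ", ")), rows = bad)
  }
  dup <- participants$participant_id[duplicated(participants$participant_id)]
  if (length(dup)) {
    stop_integrity(paste0("duplicated participant_id(s): ",
      paste(unique(dup), collapse = ", ")), ids = unique(dup))
  }

  contacts$participant_id <- as.character(contacts$participant_id)
  contacts$contact_age_lo <- as.integer(contacts$contact_age_lo)
  contacts$contact_age_hi <- as.integer(contacts$contact_age_hi)
  contacts$physical <- as.logical(contacts$physical)
  contacts$setting <- as.character(contacts$setting)

  # Missing contact ages are a data error, not something to impute: drop
  # the record but keep an audited count (respondents were asked to guess
  # an age, so a blank means the row never carried usable information).
  na_age <- is.na(contacts$contact_age_lo) | is.na(contacts$contact_age_hi)
  n_rejected <- sum(na_age)
  if (n_rejected > 0L) {
    warning(sprintf("rejected %d contact record(s) with missing contact age", n_rejected),
      call. = FALSE)
    contacts <- contacts[!na_age, , drop = FALSE]
  }
  if (any(contacts$contact_age_lo < 0L)) stop_domain("contact ages must be non-negative")
  if (any(contacts$contact_age_lo > contacts$contact_age_hi)) {
    stop_domain("contact age ranges must have lo <= hi")
  }
  orphan <- setdiff(contacts$participant_id, participants$participant_id)
  if (length(orphan)) {
    stop_integrity(paste0("contact record(s) reference unknown participant(s): ",
      paste(orphan, collapse = ", ")), ids = orphan)
  }

  rownames(participants) <- NULL
  rownames(contacts) <- NULL
  structure(
    list(participants = participants, contacts = contacts, grouping = grouping,
      n_rejected_contacts = n_rejected),
    class = "survey_table"
  )
}

#' @export
print.survey_table <- function(x, ...) {
  cat(sprintf("Diary survey: %d participants, %d contact records, %d age groups\n",
    nrow(x$participants), nrow(x$contacts), n_groups(x$grouping)))
  invisible(x)
}

empty_participants <- function() {
  data.frame(
    participant_id = character(), age = integer(), gender = character(),
    period = character(), day_type = character(), urban = logical(),
    diary_date = character(), weight = numeric(), stringsAsFactors = FALSE
  )
}

empty_contacts <- function() {
  data.frame(
    participant_id = character(), contact_age_lo = integer(),
    contact_age_hi = integer(), physical = logical(), setting = character(),
    stringsAsFactors = FALSE
  )
}

read_csv_checked <- function(path, what) {
  if (!file.exists(path)) stop_io(paste0(what, " file not found: ", path), path = path)
  utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
    fileEncoding = "UTF-8")
}

#' Read a diary survey from CSV files
#'
#' Reads the two-file survey layout (`participants.csv`, `contacts.csv`)
#' and returns a validated [survey_table()]. Rows with unparseable
#' mandatory fields raise an error rather than being silently dropped;
#' contact records with missing ages are rejected with a warning carrying
#' the rejection count.
#'
#' @param participants_path,contacts_path Paths to the CSV files.
#' @param grouping An [age_grouping()].
#' @return A `survey_table`.
#' @seealso [write_survey()] for the inverse operation.
#' @export
read_survey <- function(participants_path, contacts_path,
                        grouping = default_age_grouping()) {
  p <- read_csv_checked(participants_path, "participants")
  k <- read_csv_checked(contacts_path, "contacts")
  missing_p <- setdiff(PARTICIPANT_COLS, names(p))
  if (length(missing_p)) {
    stop_schema(paste0("participants.csv is missing column(s): ",
      paste(missing_p, collapse = ", ")), columns = missing_p)
  }
  missing_c <- setdiff(CONTACT_COLS, names(k))
  if (length(missing_c)) {
    stop_schema(paste0("contacts.csv is missing column(s): ",
      paste(missing_c, collapse = ", ")), columns = missing_c)
  }
  if (nrow(p)) {
    p$age <- suppressWarnings(as.integer(p$age))
    p$urban <- as.logical(p$urban)
    p$weight <- suppressWarnings(as.numeric(p$weight))
    p$diary_date[p$diary_date == ""] <- NA_character_
  } else {
    p <- empty_participants()
  }
  if (nrow(k)) {
    k$contact_age_lo <- suppressWarnings(as.integer(k$contact_age_lo))
    k$contact_age_hi <- suppressWarnings(as.integer(k$contact_age_hi))
    k$physical <- as.logical(k$physical)
    k$setting[k$setting == ""] <- NA_character_
  } else {
    k <- empty_contacts()
  }
  survey_table(p, k, grouping)
}

#' Write a diary survey to CSV files
#'
#' Writes the canonical two-file layout in a fixed dialect (UTF-8, comma
#' separator, header row, ISO-8601 dates) so that
#' `read_survey(write_survey(S))` round-trips exactly and repeated writes
#' are byte-identical.
#'
#' @param table A [survey_table()].
#' @param participants_path,contacts_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_survey <- function(table, participants_path, contacts_path) {
  stopifnot(inherits(table, "survey_table"))
  for (path in c(participants_path, contacts_path)) {
    dir <- dirname(path)
    if (!dir.exists(dir)) stop_io(paste0("output directory does not exist: ", dir), path = path)
  }
  utils::write.csv(table$participants, participants_path, row.names = FALSE,
    quote = FALSE, na = "", fileEncoding = "UTF-8")
  utils::write.csv(table$contacts, contacts_path, row.names = FALSE,
    quote = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(c(participants_path, contacts_path))
}

#' Construct a population pyramid
#'
#' Population counts per age group, used as the reciprocity weights when
#' symmetrizing contact matrices: the population-level contacts from group
#' i to j must equal those from j to i, and the correction averages the two
#' sides with weights proportional to group sizes.
#'
#' @param grouping An [age_grouping()].
#' @param counts Strictly positive population count per group, in grouping
#'   order.
#' @return An object of class `population_pyramid`.
#' @export
population_pyramid <- function(grouping, counts) {
  stopifnot(inherits(grouping, "age_grouping"))
  counts <- as.numeric(counts)
  if (length(counts) != n_groups(grouping)) {
    stop_schema("need exactly one population count per age group")
  }
  if (anyNA(counts) || any(counts <= 0)) {
    stop_domain("population counts must be strictly positive (reciprocity weights require N_i > 0)")
  }
  names(counts) <- grouping$labels
  structure(list(grouping = grouping, counts = counts), class = "population_pyramid")
}

#' @export
print.population_pyramid <- function(x, ...) {
  cat(sprintf("Population pyramid, %d groups, total %s\n",
    length(x$counts), format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' Read a population pyramid from CSV
#'
#' Expects columns `age_group_label` and `population`, one row per group of
#' `grouping`; labels must match the grouping exactly (order-insensitive).
#'
#' @param path Path to the pyramid CSV.
#' @param grouping An [age_grouping()].
#' @return A [population_pyramid()].
#' @export
read_pyramid <- function(path, grouping = default_age_grouping()) {
  d <- read_csv_checked(path, "pyramid")
  need <- c("age_group_label", "population")
  missing_c <- setdiff(need, names(d))
  if (length(missing_c)) {
    stop_schema(paste0("pyramid.csv is missing column(s): ",
      paste(missing_c, collapse = ", ")), columns = missing_c)
  }
  if (!setequal(d$age_group_label, grouping$labels) ||
      nrow(d) != n_groups(grouping)) {
    stop_schema(paste0("pyramid age-group labels do not match the grouping; expected: ",
      paste(grouping$labels, collapse = ", ")))
  }
  counts <- suppressWarnings(as.numeric(d$population))
  counts <- counts[match(grouping$labels, d$age_group_label)]
  population_pyramid(grouping, counts)
}

#' Write a population pyramid to CSV
#'
#' @param pyramid A [population_pyramid()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pyramid <- function(pyramid, path) {
  stopifnot(inherits(pyramid, "population_pyramid"))
  d <- data.frame(age_group_label = pyramid$grouping$labels,
    population = unname(pyramid$counts))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# Contact age ranges resolve to the group containing the integer midpoint
# floor((lo+hi)/2); single-year ages (lo == hi) fall through unchanged.
contact_group <- function(contacts, grouping) {
  mid <- (contacts$contact_age_lo + contacts$contact_age_hi) %/% 2L
  assign_age_group(mid, grouping)
}

# n x G matrix: per-participant counts of contacts by contact age group,
# rows aligned to the participant table.
participant_contact_counts <- function(survey) {
  g <- n_groups(survey$grouping)
  n <- nrow(survey$participants)
  y <- matrix(0L, n, g, dimnames = list(NULL, survey$grouping$labels))
  if (nrow(survey$contacts)) {
    row <- match(survey$contacts$participant_id, survey$participants$participant_id)
    col <- contact_group(survey$contacts, survey$grouping)
    tab <- table(factor(row, levels = seq_len(n)), factor(col, levels = seq_len(g)))
    y <- matrix(as.integer(tab), n, g, dimnames = list(NULL, survey$grouping$labels))
  }
  y
}

# Per-participant total reported contacts, aligned to the participant table.
participant_totals <- function(survey) {
  n <- nrow(survey$participants)
  if (!nrow(survey$contacts)) return(integer(n))
  row <- match(survey$contacts$participant_id, survey$participants$participant_id)
  tabulate(row, nbins = n)
}
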