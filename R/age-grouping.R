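#' Define an age grouping
#'
#' An age grouping partitions the non-negative integer ages into `G`
#' contiguous half-open bins `[edges[i], edges[i+1])`; the last bin is
#' open-ended above. Groupings label the rows and columns of every contact
#' matrix in the package.
#'
#' @param edges Integer vector of strictly increasing lower bounds in years;
#'   the first must be 0.
#' @param labels Optional character vector, one label per group. Defaults to
#'   `"0-4"`-style ranges with an open-ended `"70+"`-style last label.
#' @return An object of class `age_grouping` with elements `edges` and
#'   `labels`.
#' @examples
#' g <- age_grouping(c(0, 5, 10))
#' g$labels # "0-4" "5-9" "10+"
#' @export
age_grouping <- function(edges, labels = NULL) {
  edges <- as.integer(edges)
  if (length(edges) < 1L || anyNA(edges)) {
    stop_domain("age grouping needs at least one finite edge")
  }
  if (edges[1L] != 0L) stop_domain("first age-group edge must be 0")
  if (any(diff(edges) <= 0L)) stop_domain("age-group edges must be strictly increasing")
  g <- length(edges)
  if (is.null(labels)) {
    upper <- c(edges[-1L] - 1L, NA_integer_)
    labels <- ifelse(is.na(upper),
      paste0(edges, "+"),
      paste0(edges, "-", upper)
    )
  }
  labels <- as.character(labels)
  if (length(labels) != g) stop_domain("need exactly one label per age group")
  if (anyDuplicated(labels)) stop_domain("age-group labels must be unique")
  structure(list(edges = edges, labels = labels), class = "age_grouping")
}

#' Default 5-year age grouping
#'
#' Fifteen groups: 0-4, 5-9, ..., 65-69, 70+. Five-year bins are the
#' convention of the contact-survey literature; the exact bins used for any
#' given analysis are configurable via [age_grouping()].
#'
#' @return An `age_grouping` with 15 groups.
#' @export
default_age_grouping <- function() {
  age_grouping(seq(0L, 70L, by = 5L))
}

#' @export
print.age_grouping <- function(x, ...) {
  cat("Age grouping with", length(x$labels), "groups:",
    paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

n_groups <- function(grouping) length(grouping$edges)

#' Map ages to age-group indices
#'
#' Uses the half-open convention: age `a` belongs to group `i` when
#' `edges[i] <= a < edges[i+1]`; the last group is unbounded above.
#'
#' @param age Integer vector of ages in years, all non-negative.
#' @param grouping An [age_grouping()].
#' @return Integer vector of group indices in `1..G`.
#' @examples
#' assign_age_group(c(0, 5, 95), age_grouping(c(0, 5, 10)))
#' @export
assign_age_group <- function(age, grouping) {
  stopifnot(inherits(grouping, "age_grouping"))
  if (anyNA(age) || any(age < 0)) stop_domain("ages must be non-negative and non-missing")
  findInterval(age, grouping$edges)
}

same_grouping <- function(a, b) {
  identical(a$edges, b$edges) && identical(a$labels, b$labels)
}
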