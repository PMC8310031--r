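#' Vaccination schedule objects
#'
#' A schedule is the package's representation of a national immunization
#' calendar: an ordered table of dose definitions with, for each dose, its
#' series membership (e.g. DPT1..DPT3 belong to series "DPT"), the minimum
#' age in days, the minimum interval in days from the previous dose of the
#' same series, an optional maximum age in days, and whether the dose is
#' included in MOSV summaries. All age arithmetic is in whole days.
#'
#' @name mosv_schedule
#' @keywords internal
NULL

new_schedule <- function(doses, name = "schedule", source_note = "",
                         aliases = character()) {
  sched <- structure(
    list(doses = doses, name = name, source_note = source_note,
         aliases = aliases),
    class = "mosv_schedule"
  )
  validate_schedule(sched)
  sched
}

validate_schedule <- function(sched) {
  d <- sched$doses
  req <- c("dose", "series", "number", "min_age_days", "min_interval_days",
           "max_age_days", "summarized")
  missing_cols <- setdiff(req, names(d))
  if (length(missing_cols) > 0L) {
    stop("schedule configuration error: missing fields ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(d$dose)) {
    stop("schedule configuration error: duplicate dose name '",
         d$dose[duplicated(d$dose)][1L], "'", call. = FALSE)
  }
  if (any(d$min_age_days < 0L) || any(d$min_interval_days < 0L)) {
    stop("schedule configuration error: negative age or interval",
         call. = FALSE)
  }
  bad_max <- !is.na(d$max_age_days) & d$max_age_days <= d$min_age_days
  if (any(bad_max)) {
    stop("schedule configuration error: max_age_days must exceed ",
         "min_age_days for dose '", d$dose[bad_max][1L], "'", call. = FALSE)
  }
  standalone <- is.na(d$series)
  if (any(standalone & d$number != 1L)) {
    stop("schedule configuration error: standalone dose '",
         d$dose[standalone & d$number != 1L][1L],
         "' must have dose number 1", call. = FALSE)
  }
  # first-in-series and standalone doses have no interval constraint
  first_like <- standalone | d$number == 1L
  if (any(first_like & d$min_interval_days != 0L)) {
    stop("schedule configuration error: dose '",
         d$dose[first_like & d$min_interval_days != 0L][1L],
         "' is first in its series but has a nonzero min_interval_days",
         call. = FALSE)
  }
  if (any(!first_like & d$min_interval_days == 0L)) {
    stop("schedule configuration error: dose '",
         d$dose[!first_like & d$min_interval_days == 0L][1L],
         "' is a later series dose but has min_interval_days = 0",
         call. = FALSE)
  }
  # series dose numbers contiguous starting at 1
  for (s in unique(d$series[!standalone])) {
    nums <- sort(d$number[!is.na(d$series) & d$series == s])
    expect <- seq_along(nums)
    if (!identical(as.integer(nums), as.integer(expect))) {
      gap <- setdiff(seq_len(max(nums)), nums)[1L]
      stop("schedule configuration error: series '", s, "' is missing dose ",
           gap, " (doses present: ", paste(nums, collapse = ","), ")",
           call. = FALSE)
    }
  }
  if (length(sched$aliases) > 0L) {
    unknown <- setdiff(unname(sched$aliases), d$dose)
    if (length(unknown) > 0L) {
      stop("schedule configuration error: alias target '", unknown[1L],
           "' is not a scheduled dose", call. = FALSE)
    }
  }
  invisible(sched)
}

#' Load a vaccination schedule from a YAML or JSON configuration file
#'
#' The file holds a `name`, an optional `source_note`, a list of `doses`
#' (each with `dose`, `series` (null for standalone doses), `number`,
#' `min_age_days`, `min_interval_days`, optional `max_age_days`,
#' `summarized`, and optional `aliases` — alternative input column names,
#' e.g. mapping pentavalent doses onto the DPT series), and is validated on
#' load: dose names must be unique, series dose numbers contiguous from 1,
#' and intervals consistent with series position.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` schedule file.
#' @return A `mosv_schedule` object.
#' @examples
#' sched <- epi_schedule()
#' sched$doses
#' @export
load_schedule <- function(path) {
  if (!file.exists(path)) {
    stop("schedule configuration error: file not found: ", path,
         call. = FALSE)
  }
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$doses) || length(cfg$doses) == 0L) {
    stop("schedule configuration error: no doses defined in ", path,
         call. = FALSE)
  }
  get_or <- function(x, field, default) {
    if (is.null(x[[field]])) default else x[[field]]
  }
  doses <- do.call(rbind, lapply(cfg$doses, function(x) {
    if (is.null(x$dose)) {
      stop("schedule configuration error: dose entry without a 'dose' name",
           call. = FALSE)
    }
    data.frame(
      dose = as.character(x$dose),
      series = as.character(get_or(x, "series", NA_character_)),
      number = as.integer(get_or(x, "number", 1L)),
      min_age_days = as.integer(get_or(x, "min_age_days", 0L)),
      min_interval_days = as.integer(get_or(x, "min_interval_days", 0L)),
      max_age_days = as.integer(get_or(x, "max_age_days", NA_integer_)),
      summarized = isTRUE(get_or(x, "summarized", TRUE)),
      stringsAsFactors = FALSE
    )
  }))
  aliases <- character()
  for (x in cfg$doses) {
    if (!is.null(x$aliases)) {
      al <- as.character(unlist(x$aliases))
      aliases[al] <- as.character(x$dose)
    }
  }
  new_schedule(doses,
               name = get_or(cfg, "name", basename(path)),
               source_note = get_or(cfg, "source_note", ""),
               aliases = aliases)
}

#' Built-in EPI schedule profiles
#'
#' Loads one of the schedule configuration files shipped with the package:
#' the classic EPI calendar with BCG and an OPV birth dose at age 0 (OPV0
#' creditable only through 13 days of age), three-dose OPV and DPT series
#' from 42 days at 28-day intervals, and a first measles-containing dose at
#' 270 days (`"nigeria"`) or 365 days (`"colombia"`, MMR). Eight doses are
#' summarized for MOSV purposes (BCG, OPV1-3, DPT1-3, MCV1/MMR1); the OPV
#' birth dose participates in visit reconstruction but is not summarized.
#'
#' @param profile `"nigeria"` (measles at 9 months) or `"colombia"`
#'   (MMR at 12 months).
#' @return A `mosv_schedule`.
#' @export
epi_schedule <- function(profile = c("nigeria", "colombia")) {
  profile <- match.arg(profile)
  fn <- switch(profile,
               nigeria = "schedule_epi_nigeria.yaml",
               colombia = "schedule_epi_colombia.yaml")
  load_schedule(system.file("extdata", fn, package = "mosvkit",
                            mustWork = TRUE))
}

#' @export
print.mosv_schedule <- function(x, ...) {
  cat("<mosv_schedule> ", x$name, ": ", nrow(x$doses), " doses (",
      sum(x$doses$summarized), " summarized)\n", sep = "")
  print(x$doses, row.names = FALSE)
  if (length(x$aliases) > 0L) {
    cat("aliases:", paste(names(x$aliases), "->", x$aliases,
                          collapse = ", "), "\n")
  }
  invisible(x)
}

schedule_dose <- function(schedule, dose) {
  i <- match(dose, schedule$doses$dose)
  if (is.na(i)) {
    stop("unknown dose '", dose, "' in schedule '", schedule$name, "'",
         call. = FALSE)
  }
  schedule$doses[i, , drop = FALSE]
}

# name of the previous dose in the series, or NA for first/standalone doses
prior_dose_name <- function(schedule, dose_row) {
  if (is.na(dose_row$series) || dose_row$number == 1L) return(NA_character_)
  d <- schedule$doses
  d$dose[!is.na(d$series) & d$series == dose_row$series &
           d$number == dose_row$number - 1L]
}

#' Is a child eligible for a dose at a given visit?
#'
#' Implements the eligibility rule used throughout the MOSV analysis: a dose
#' is due at a visit when it has not already been received (as counted by the
#' caller's accounting), the child's age in days is at least the dose's
#' minimum age and no more than its maximum age (when one is set), and, for
#' the second or third dose of a series, the previous dose of that series has
#' been received strictly before the visit with at least the minimum interval
#' elapsed. A prerequisite received with an unknown date (tick-mark or recall
#' credit, encoded as an `NA` date in `prior_receipt`) satisfies the interval
#' requirement.
#'
#' @param schedule A `mosv_schedule`.
#' @param dose Dose name (must be in the schedule).
#' @param age_days Child's age in whole days at the visit (`visit_date - dob`).
#' @param prior_receipt Named `Date` vector of doses counted as received
#'   strictly before `visit_date`; an `NA` element means received on an
#'   unknown (earlier) date. Dated entries on or after `visit_date` are a
#'   contract violation and raise an error.
#' @param visit_date The visit date.
#' @return `TRUE` or `FALSE`.
#' @export
eligible_for <- function(schedule, dose, age_days, prior_receipt, visit_date) {
  if (age_days < 0) stop("age_days must be nonnegative", call. = FALSE)
  if (length(prior_receipt) > 0L) {
    pr_dates <- rep(as.Date(NA), length(prior_receipt))
    for (i in seq_along(prior_receipt)) {
      v <- prior_receipt[[i]]
      if (!is.null(v) && !all(is.na(v))) pr_dates[i] <- as.Date(v)
    }
    names(pr_dates) <- names(prior_receipt)
    if (any(!is.na(pr_dates) & pr_dates >= as.Date(visit_date))) {
      stop("contract violation: prior_receipt contains a dose dated on or ",
           "after the visit date", call. = FALSE)
    }
  } else {
    pr_dates <- stats::setNames(as.Date(character()), character())
  }
  dr <- schedule_dose(schedule, dose)
  if (dose %in% names(pr_dates)) return(FALSE)
  if (age_days < dr$min_age_days) return(FALSE)
  if (!is.na(dr$max_age_days) && age_days > dr$max_age_days) return(FALSE)
  prev <- prior_dose_name(schedule, dr)
  if (!is.na(prev)) {
    if (!prev %in% names(pr_dates)) return(FALSE)
    prev_date <- pr_dates[[prev]]
    if (!is.na(prev_date) &&
        as.integer(as.Date(visit_date) - prev_date) < dr$min_interval_days) {
      return(FALSE)
    }
  }
  TRUE
}

# Fast internal eligibility used by the visit walk: receipt is a named
# numeric vector of receipt dates (as integer days; -Inf = unknown/earlier).
.eligible_fast <- function(dose_row, prev_name, age_days, receipt_days,
                           visit_day) {
  if (dose_row$dose %in% names(receipt_days)) return(FALSE)
  if (age_days < dose_row$min_age_days) return(FALSE)
  if (!is.na(dose_row$max_age_days) && age_days > dose_row$max_age_days) {
    return(FALSE)
  }
  if (!is.na(prev_name)) {
    if (!prev_name %in% names(receipt_days)) return(FALSE)
    pd <- receipt_days[[prev_name]]
    if (is.finite(pd) && (visit_day - pd) < dose_row$min_interval_days) {
      return(FALSE)
    }
  }
  TRUE
}
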