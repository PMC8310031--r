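#' Column mapping for child-level input tables
#'
#' Describes how the columns of an input CSV map onto the fields the package
#' expects. Per-dose evidence is read from `<dose><date_suffix>` columns
#' (ISO-8601 dates; a non-blank unparseable value is treated as an illegible
#' card entry, i.e. a tick mark) and `<dose><recall_suffix>` columns
#' (caregiver recall; truthy values: yes/y/true/1).
#'
#' @param child_id,dob_year,dob_month,dob_day,survey_date,card_seen,weight,stratum_id,cluster_id
#'   Column names in the input file.
#' @param date_suffix,recall_suffix Suffixes for per-dose columns.
#' @return A named list usable as the `dialect` argument of
#'   [read_children()].
#' @export
default_dialect <- function(child_id = "child_id", dob_year = "dob_year",
                            dob_month = "dob_month", dob_day = "dob_day",
                            survey_date = "survey_date",
                            card_seen = "card_seen", weight = "weight",
                            stratum_id = "stratum_id",
                            cluster_id = "cluster_id",
                            date_suffix = "_date",
                            recall_suffix = "_recall") {
  list(child_id = child_id, dob_year = dob_year, dob_month = dob_month,
       dob_day = dob_day, survey_date = survey_date, card_seen = card_seen,
       weight = weight, stratum_id = stratum_id, cluster_id = cluster_id,
       date_suffix = date_suffix, recall_suffix = recall_suffix)
}

.truthy <- function(x) {
  tolower(trimws(as.character(x))) %in% c("yes", "y", "true", "t", "1")
}

.parse_iso_date <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(as.Date(NA), length(x))
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  if (any(ok)) {
    d <- as.Date(x[ok], format = "%Y-%m-%d")
    out[ok] <- d
  }
  out
}

new_cohort <- function(children, evidence) {
  structure(list(children = children, evidence = evidence),
            class = "mosv_cohort")
}

#' @export
print.mosv_cohort <- function(x, ...) {
  cat("<mosv_cohort> ", nrow(x$children), " children, ",
      nrow(x$evidence), " evidence entries (",
      sum(x$evidence$kind == "DATE"), " dated)\n", sep = "")
  invisible(x)
}

empty_evidence <- function() {
  data.frame(child_id = character(), dose = character(),
             kind = character(), date = as.Date(character()),
             flags = character(), stringsAsFactors = FALSE)
}

#' Read a child-level survey table
#'
#' Reads one row per surveyed child from a CSV file into a cohort object
#' holding a child table (identifiers, birth month/year/day, survey date,
#' card-seen flag, survey weight, stratum and cluster) and a long evidence
#' table with one row per dose for which any evidence exists. Evidence kinds
#' are `DATE` (a parseable ISO date on the card), `TICK` (a card entry whose
#' date is absent or illegible), and `RECALL` (caregiver report only); doses
#' with no evidence carry no row. Dose columns are matched against the
#' schedule's dose names and aliases (e.g. `Penta1_date` feeding the DPT
#' series).
#'
#' @param path CSV file path.
#' @param schedule A `mosv_schedule`; defines which dose columns are read.
#' @param dialect Column mapping, see [default_dialect()].
#' @return A `mosv_cohort` (children not yet cleaned: `dob` is `NA` until
#'   [impute_birth_day()] resolves it).
#' @export
read_children <- function(path, schedule, dialect = default_dialect()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  mandatory <- c("child_id", "dob_year", "dob_month", "survey_date",
                 "card_seen", "weight", "stratum_id", "cluster_id")
  for (f in mandatory) {
    if (!dialect[[f]] %in% names(raw)) {
      stop("input error: missing mandatory column '", dialect[[f]], "'",
           call. = FALSE)
    }
  }
  ids <- raw[[dialect$child_id]]
  if (anyDuplicated(ids)) {
    stop("input error: duplicate child_id '", ids[duplicated(ids)][1L], "'",
         call. = FALSE)
  }
  num_or_na <- function(x) suppressWarnings(as.integer(trimws(x)))
  children <- data.frame(
    child_id = ids,
    dob_year = num_or_na(raw[[dialect$dob_year]]),
    dob_month = num_or_na(raw[[dialect$dob_month]]),
    dob_day = if (dialect$dob_day %in% names(raw)) {
      num_or_na(raw[[dialect$dob_day]])
    } else NA_integer_,
    dob = as.Date(NA),
    dob_day_imputed = FALSE,
    survey_date = .parse_iso_date(raw[[dialect$survey_date]]),
    card_seen = .truthy(raw[[dialect$card_seen]]),
    weight = suppressWarnings(as.numeric(raw[[dialect$weight]])),
    stratum_id = as.character(raw[[dialect$stratum_id]]),
    cluster_id = as.character(raw[[dialect$cluster_id]]),
    stringsAsFactors = FALSE
  )
  if (any(is.na(children$weight)) || any(children$weight < 0)) {
    stop("input error: survey weights must be nonnegative numbers",
         call. = FALSE)
  }

  # map input dose names (incl. aliases) to canonical schedule dose names
  canon <- stats::setNames(schedule$doses$dose, schedule$doses$dose)
  canon <- c(canon, schedule$aliases)
  ev_list <- list()
  for (input_name in names(canon)) {
    dose <- unname(canon[[input_name]])
    dcol <- paste0(input_name, dialect$date_suffix)
    rcol <- paste0(input_name, dialect$recall_suffix)
    if (dcol %in% names(raw)) {
      val <- trimws(raw[[dcol]])
      has <- !is.na(val) & val != ""
      if (any(has)) {
        parsed <- .parse_iso_date(val[has])
        ev_list[[length(ev_list) + 1L]] <- data.frame(
          child_id = ids[has], dose = dose,
          kind = ifelse(is.na(parsed), "TICK", "DATE"),
          date = parsed, flags = "", stringsAsFactors = FALSE
        )
      }
    }
    if (rcol %in% names(raw)) {
      rec <- .truthy(raw[[rcol]])
      if (any(rec)) {
        ev_list[[length(ev_list) + 1L]] <- data.frame(
          child_id = ids[rec], dose = dose, kind = "RECALL",
          date = as.Date(NA), flags = "", stringsAsFactors = FALSE
        )
      }
    }
  }
  evidence <- if (length(ev_list) > 0L) {
    do.call(rbind, ev_list)
  } else {
    empty_evidence()
  }
  # card evidence (DATE/TICK) wins over recall for the same dose
  key <- paste(evidence$child_id, evidence$dose)
  drop <- evidence$kind == "RECALL" &
    key %in% key[evidence$kind %in% c("DATE", "TICK")]
  evidence <- evidence[!drop, , drop = FALSE]
  key <- paste(evidence$child_id, evidence$dose)
  if (anyDuplicated(key)) {
    stop("input error: multiple evidence columns resolve to the same dose ",
         "for child '", evidence$child_id[duplicated(key)][1L], "'",
         call. = FALSE)
  }
  evidence <- evidence[order(evidence$child_id, evidence$dose), ,
                       drop = FALSE]
  rownames(evidence) <- NULL
  new_cohort(children, evidence)
}

#' Impute the day of birth where only month and year are known
#'
#' Children with a full date of birth are untouched. Where the day is
#' missing, it is taken from the earliest dated birth dose (a dose with
#' minimum age 0) that falls within the reported birth month and year;
#' failing that, the first day of the month is used. Children missing the
#' birth month or year keep an unresolved (`NA`) date of birth and are
#' routed to the no-valid-birthdate exclusion by [select_cohort()]. A date
#' of birth on or after the survey date is likewise treated as unresolved.
#'
#' @param cohort A `mosv_cohort` from [read_children()].
#' @param schedule A `mosv_schedule` (identifies birth doses).
#' @return The cohort with `dob` and `dob_day_imputed` filled.
#' @export
impute_birth_day <- function(cohort, schedule) {
  ch <- cohort$children
  ev <- cohort$evidence
  birth_doses <- schedule$doses$dose[schedule$doses$min_age_days == 0L]
  bev <- ev[ev$kind == "DATE" & ev$dose %in% birth_doses, , drop = FALSE]
  mk_date <- function(y, m, d) {
    out <- as.Date(sprintf("%04d-%02d-%02d", y, m, d), optional = TRUE)
    out
  }
  for (i in seq_len(nrow(ch))) {
    y <- ch$dob_year[i]; m <- ch$dob_month[i]; d <- ch$dob_day[i]
    if (is.na(y) || is.na(m) || m < 1L || m > 12L) next
    if (!is.na(d)) {
      ch$dob[i] <- mk_date(y, m, d)
      next
    }
    cand <- bev$date[bev$child_id == ch$child_id[i]]
    cand <- cand[!is.na(cand) &
                   as.integer(format(cand, "%Y")) == y &
                   as.integer(format(cand, "%m")) == m]
    if (length(cand) > 0L) {
      ch$dob[i] <- min(cand)
    } else {
      ch$dob[i] <- mk_date(y, m, 1L)
    }
    ch$dob_day_imputed[i] <- TRUE
  }
  bad <- !is.na(ch$dob) & !is.na(ch$survey_date) & ch$dob >= ch$survey_date
  ch$dob[bad] <- as.Date(NA)
  cohort$children <- ch
  cohort
}

.add_flag <- function(flags, flag) {
  ifelse(flags == "", flag, paste(flags, flag, sep = ";"))
}

#' Remove nonsensical vaccination dates
#'
#' Demotes card dates that cannot be correct to tick marks, so the child
#' keeps credit for the dose while the impossible date no longer defines a
#' vaccination visit. Two passes, in a fixed order: (1) absolute checks —
#' any date before the child's date of birth or after the survey date is
#' demoted (flags `BEFORE_BIRTH` / `AFTER_SURVEY`); (2) series ordering —
#' within each series, scanning doses in series order, a dated dose whose
#' date is on or before the last retained dated dose of the series is
#' demoted (`OUT_OF_ORDER` if strictly earlier, `DUPLICATE_DATE_IN_SERIES`
#' if equal), and later doses continue to be checked against the last
#' retained date (the maximal consistent prefix is kept). Tick and recall
#' evidence is untouched; cleaning is total and idempotent.
#'
#' @param cohort A `mosv_cohort` with `dob` resolved (see
#'   [impute_birth_day()]; children with unresolved `dob` only get the
#'   after-survey and series checks).
#' @param schedule A `mosv_schedule`.
#' @return The cleaned cohort.
#' @export
clean_dates <- function(cohort, schedule) {
  ev <- cohort$evidence
  if (nrow(ev) == 0L) return(cohort)
  ch <- cohort$children
  dob <- ch$dob[match(ev$child_id, ch$child_id)]
  svy <- ch$survey_date[match(ev$child_id, ch$child_id)]

  is_date <- ev$kind == "DATE"
  before <- is_date & !is.na(dob) & ev$date < dob
  after <- is_date & !is.na(svy) & ev$date > svy
  ev$kind[before] <- "TICK"
  ev$flags[before] <- .add_flag(ev$flags[before], "BEFORE_BIRTH")
  ev$kind[after] <- "TICK"
  ev$flags[after] <- .add_flag(ev$flags[after], "AFTER_SURVEY")
  ev$date[before | after] <- as.Date(NA)

  # series-order pass per child x series, in dose-number order
  sd <- schedule$doses
  series_doses <- split(sd$dose[!is.na(sd$series)][order(
    sd$series[!is.na(sd$series)], sd$number[!is.na(sd$series)])],
    sort(sd$series[!is.na(sd$series)]))
  for (s in names(series_doses)) {
    doses <- series_doses[[s]]
    idx_by_child <- split(which(ev$dose %in% doses & ev$kind == "DATE"),
                          ev$child_id[ev$dose %in% doses & ev$kind == "DATE"])
    for (rows in idx_by_child) {
      rows <- rows[order(match(ev$dose[rows], doses))]
      last_retained <- as.Date(NA)
      for (r in rows) {
        d <- ev$date[r]
        if (!is.na(last_retained) && d <= last_retained) {
          ev$kind[r] <- "TICK"
          ev$flags[r] <- .add_flag(
            ev$flags[r],
            if (d < last_retained) "OUT_OF_ORDER"
            else "DUPLICATE_DATE_IN_SERIES")
          ev$date[r] <- as.Date(NA)
        } else {
          last_retained <- d
        }
      }
    }
  }
  cohort$evidence <- ev
  cohort
}

#' Age in completed calendar months
#'
#' Whole months elapsed between two dates: the calendar-month difference,
#' minus one when the day of month of `date` precedes that of `dob`.
#'
#' @param dob,date `Date` vectors.
#' @return Integer vector of completed months.
#' @export
age_completed_months <- function(dob, date) {
  dob <- as.Date(dob); date <- as.Date(date)
  y1 <- as.integer(format(dob, "%Y")); y2 <- as.integer(format(date, "%Y"))
  m1 <- as.integer(format(dob, "%m")); m2 <- as.integer(format(date, "%m"))
  d1 <- as.integer(format(dob, "%d")); d2 <- as.integer(format(date, "%d"))
  12L * (y2 - y1) + (m2 - m1) - as.integer(d2 < d1)
}

#' Select the analysis cohort
#'
#' Applies the card-based MOSV inclusion filters: the card was seen by the
#' interviewer, the date of birth is resolvable (month and year known), the
#' child's age at the survey lies in the target window in completed months
#' (default 12-23 months, i.e. `[12, 24)`), and at least one vaccination
#' date survives cleaning. Each excluded child is tallied against the first
#' filter it fails, in that order, so the tallies partition the input.
#'
#' @param cohort A cleaned `mosv_cohort`.
#' @param age_window_months Two integers `c(lo, hi)`; inclusion requires
#'   `lo <= age_months < hi`.
#' @return A list of class `mosv_cohort_selection`: `cohort` (included
#'   children only), `counts` (named integer vector: `included`,
#'   `excluded_no_card`, `excluded_no_dob`, `excluded_age`,
#'   `excluded_no_dates`), and `exclusions` (child_id, reason).
#' @export
select_cohort <- function(cohort, age_window_months = c(12L, 24L)) {
  ch <- cohort$children
  ev <- cohort$evidence
  has_date <- unique(ev$child_id[ev$kind == "DATE"])
  age_m <- rep(NA_integer_, nrow(ch))
  ok_dob <- !is.na(ch$dob) & !is.na(ch$survey_date)
  age_m[ok_dob] <- age_completed_months(ch$dob[ok_dob],
                                        ch$survey_date[ok_dob])
  reason <- rep(NA_character_, nrow(ch))
  reason[!ch$card_seen] <- "no_card"
  reason[is.na(reason) & !ok_dob] <- "no_dob"
  reason[is.na(reason) &
           (age_m < age_window_months[1L] |
              age_m >= age_window_months[2L])] <- "age"
  reason[is.na(reason) & !(ch$child_id %in% has_date)] <- "no_dates"

  included <- is.na(reason)
  counts <- c(
    included = sum(included),
    excluded_no_card = sum(reason == "no_card", na.rm = TRUE),
    excluded_no_dob = sum(reason == "no_dob", na.rm = TRUE),
    excluded_age = sum(reason == "age", na.rm = TRUE),
    excluded_no_dates = sum(reason == "no_dates", na.rm = TRUE)
  )
  kept <- ch$child_id[included]
  sel <- list(
    cohort = new_cohort(ch[included, , drop = FALSE],
                        ev[ev$child_id %in% kept, , drop = FALSE]),
    counts = counts,
    exclusions = data.frame(child_id = ch$child_id[!included],
                            reason = reason[!included],
                            stringsAsFactors = FALSE)
  )
  class(sel) <- "mosv_cohort_selection"
  sel
}

#' @export
print.mosv_cohort_selection <- function(x, ...) {
  cat("<mosv_cohort_selection>\n")
  print(x$counts)
  invisible(x)
}

#' Write a cohort back to the input CSV dialect
#'
#' @param cohort A `mosv_cohort`.
#' @param path Output CSV path.
#' @param dialect Column mapping, see [default_dialect()].
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path, dialect = default_dialect()) {
  ch <- cohort$children
  ev <- cohort$evidence
  out <- data.frame(child_id = ch$child_id, dob_year = ch$dob_year,
                    dob_month = ch$dob_month, dob_day = ch$dob_day,
                    survey_date = format(ch$survey_date, "%Y-%m-%d"),
                    card_seen = ifelse(ch$card_seen, "yes", "no"),
                    weight = ch$weight, stratum_id = ch$stratum_id,
                    cluster_id = ch$cluster_id, stringsAsFactors = FALSE)
  names(out) <- c(dialect$child_id, dialect$dob_year, dialect$dob_month,
                  dialect$dob_day, dialect$survey_date, dialect$card_seen,
                  dialect$weight, dialect$stratum_id, dialect$cluster_id)
  for (dose in unique(ev$dose)) {
    dcol <- rep("", nrow(out)); rcol <- rep("", nrow(out))
    sub <- ev[ev$dose == dose, , drop = FALSE]
    for (j in seq_len(nrow(sub))) {
      i <- match(sub$child_id[j], ch$child_id)
      if (sub$kind[j] == "DATE") {
        dcol[i] <- format(sub$date[j], "%Y-%m-%d")
      } else if (sub$kind[j] == "TICK") {
        dcol[i] <- "tick"
      } else if (sub$kind[j] == "RECALL") {
        rcol[i] <- "yes"
      }
    }
    out[[paste0(dose, dialect$date_suffix)]] <- dcol
    out[[paste0(dose, dialect$recall_suffix)]] <- rcol
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
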