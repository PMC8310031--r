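## MOSV core: visit reconstruction, crude/valid dose accounting, and
## detection of missed opportunities for simultaneous vaccination.
##
## The walk over a child's visits is deliberately scalar and explicit: the
## record sizes are tiny (a handful of visits, ~10 doses) and correctness of
## the eligibility bookkeeping is the whole point. Dates are carried as
## integer day numbers; -Inf encodes "received on an unknown, earlier date"
## (tick-mark / recall credit).

.day <- function(d) as.numeric(as.Date(d))

# Split a cleaned cohort into per-child lists used by the walks.
.child_split <- function(cohort) {
  ch <- cohort$children
  ev <- cohort$evidence
  ev_idx <- split(seq_len(nrow(ev)), factor(ev$child_id,
                                            levels = ch$child_id))
  lapply(seq_len(nrow(ch)), function(i) {
    rows <- ev_idx[[i]]
    list(child_id = ch$child_id[i],
         dob = .day(ch$dob[i]),
         survey = .day(ch$survey_date[i]),
         weight = ch$weight[i],
         stratum_id = ch$stratum_id[i],
         ev = ev[rows, , drop = FALSE])
  })
}

# Per-dose schedule lookup tables reused across children.
.sched_tables <- function(schedule) {
  d <- schedule$doses
  prev <- vapply(seq_len(nrow(d)), function(i) {
    p <- prior_dose_name(schedule, d[i, , drop = FALSE])
    if (length(p) == 0L) NA_character_ else p
  }, character(1))
  list(doses = d, prev = prev,
       summarized = d$dose[d$summarized],
       row_of = stats::setNames(seq_len(nrow(d)), d$dose))
}

# Valid-dose reallocation for one child's evidence. Returns
# list(map = data.frame(dose, date_day, counted_as),
#      counted = named numeric vector slot -> day (-Inf = unknown date)).
# Tick/recall evidence pre-fills its own slot with an unknown date (the
# child keeps credit); dated doses are then scanned in administration order
# and fill the remaining slots of their series in slot order, subject to the
# slot's minimum age and the minimum interval from the previously counted
# dose. Standalone doses are validated on age alone.
.realloc_one <- function(ev, st, dob) {
  d <- st$doses
  counted <- numeric(0)
  map <- data.frame(dose = character(), date_day = numeric(),
                    counted_as = character(), stringsAsFactors = FALSE)
  dated <- ev[ev$kind == "DATE", , drop = FALSE]
  undated <- ev[ev$kind %in% c("TICK", "RECALL"), , drop = FALSE]

  # standalone doses
  standalone <- d$dose[is.na(d$series)]
  for (i in seq_len(nrow(dated))) {
    ds <- dated$dose[i]
    if (!ds %in% standalone) next
    day <- .day(dated$date[i])
    row <- d[st$row_of[[ds]], ]
    ok <- (day - dob) >= row$min_age_days
    map <- rbind(map, data.frame(dose = ds, date_day = day,
                                 counted_as = if (ok) ds else "INVALID",
                                 stringsAsFactors = FALSE))
    if (ok) counted[ds] <- day
  }
  counted[undated$dose[undated$dose %in% standalone]] <- -Inf

  for (s in unique(d$series[!is.na(d$series)])) {
    slots <- d[!is.na(d$series) & d$series == s, , drop = FALSE]
    slots <- slots[order(slots$number), , drop = FALSE]
    k <- nrow(slots)
    fill <- rep(NA_real_, k)          # NA = unfilled; -Inf = tick credit
    # credit tick/recall evidence to its own slot
    for (j in seq_len(k)) {
      if (slots$dose[j] %in% undated$dose) fill[j] <- -Inf
    }
    sdated <- dated[dated$dose %in% slots$dose, , drop = FALSE]
    sdated <- sdated[order(.day(sdated$date)), , drop = FALSE]
    for (i in seq_len(nrow(sdated))) {
      day <- .day(sdated$date[i])
      slot <- which(is.na(fill))[1L]
      res <- "INVALID"
      if (!is.na(slot)) {
        age_ok <- (day - dob) >= slots$min_age_days[slot]
        int_ok <- slot == 1L || !is.finite(fill[slot - 1L]) ||
          (day - fill[slot - 1L]) >= slots$min_interval_days[slot]
        if (age_ok && int_ok) {
          fill[slot] <- day
          res <- slots$dose[slot]
        }
      }
      map <- rbind(map, data.frame(dose = sdated$dose[i], date_day = day,
                                   counted_as = res,
                                   stringsAsFactors = FALSE))
    }
    for (j in seq_len(k)) if (!is.na(fill[j])) counted[slots$dose[j]] <- fill[j]
  }
  list(map = map, counted = counted)
}

# Crude accounting: every dated dose counts as itself; tick/recall counts
# as received on an unknown earlier date.
.crude_counted <- function(ev) {
  counted <- numeric(0)
  dated <- ev[ev$kind == "DATE", , drop = FALSE]
  counted[dated$dose] <- .day(dated$date)
  und <- ev$dose[ev$kind %in% c("TICK", "RECALL")]
  counted[und] <- -Inf
  counted
}

# Mode-dependent accounting for one child: counted receipt map plus the
# doses counted as administered at each dated visit.
.accounting_one <- function(ev, st, dob, mode) {
  if (mode == "crude") {
    counted <- .crude_counted(ev)
    dated <- ev[ev$kind == "DATE", , drop = FALSE]
    admin <- data.frame(day = .day(dated$date), dose = dated$dose,
                        stringsAsFactors = FALSE)
  } else {
    ra <- .realloc_one(ev, st, dob)
    counted <- ra$counted
    keep <- ra$map$counted_as != "INVALID"
    admin <- data.frame(day = ra$map$date_day[keep],
                        dose = ra$map$counted_as[keep],
                        stringsAsFactors = FALSE)
  }
  list(counted = counted, admin = admin)
}

#' Reconstruct vaccination visits from dated card entries
#'
#' Every distinct vaccination date on a child's card — for any dose, whether
#' or not it is summarized for MOSV purposes — defines one visit; doses
#' sharing a date are grouped into the same visit.
#'
#' @param cohort A cleaned, selected `mosv_cohort`.
#' @return A data frame with one row per visit: `child_id`, `date`,
#'   `age_days`, `n_doses`, and `doses` (semicolon-joined dose names),
#'   ordered by child and date.
#' @export
reconstruct_visits <- function(cohort) {
  ev <- cohort$evidence
  ch <- cohort$children
  dated <- ev[ev$kind == "DATE", , drop = FALSE]
  if (nrow(dated) == 0L) {
    return(data.frame(child_id = character(), date = as.Date(character()),
                      age_days = integer(), n_doses = integer(),
                      doses = character(), stringsAsFactors = FALSE))
  }
  key <- paste(dated$child_id, format(dated$date, "%Y-%m-%d"))
  agg <- lapply(split(seq_len(nrow(dated)), key), function(idx) {
    data.frame(child_id = dated$child_id[idx[1L]],
               date = dated$date[idx[1L]],
               n_doses = length(idx),
               doses = paste(sort(dated$dose[idx]), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out$age_days <- as.integer(out$date - ch$dob[match(out$child_id,
                                                     ch$child_id)])
  out <- out[order(out$child_id, out$date),
             c("child_id", "date", "age_days", "n_doses", "doses")]
  rownames(out) <- NULL
  out
}

#' Valid-dose reallocation
#'
#' Under valid-dose accounting, doses given too early or after too short an
#' interval are invalid, and later administrations may fill earlier dose
#' slots of the series: if the documented first DPT dose was given before
#' the minimum age, the documented second dose counts as DPT1 and the third
#' as DPT2. Per series, administered dated doses are scanned in date order;
#' each one fills the lowest open slot if it meets the slot's minimum age
#' and the minimum interval from the previously counted dose, and is
#' `INVALID` otherwise. Standalone doses are validated on age alone. Tick or
#' recall evidence keeps credit for its own slot (date unknown).
#'
#' @param cohort A cleaned `mosv_cohort`.
#' @param schedule A `mosv_schedule`.
#' @return A data frame `child_id`, `dose` (as administered), `date`,
#'   `counted_as` (a dose name or `"INVALID"`).
#' @export
reallocate_valid_doses <- function(cohort, schedule) {
  st <- .sched_tables(schedule)
  kids <- .child_split(cohort)
  out <- lapply(kids, function(k) {
    m <- .realloc_one(k$ev, st, k$dob)$map
    if (nrow(m) == 0L) return(NULL)
    data.frame(child_id = k$child_id, dose = m$dose,
               date = as.Date(m$date_day, origin = "1970-01-01"),
               counted_as = m$counted_as, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(child_id = character(), dose = character(),
                      date = as.Date(character()), counted_as = character(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$child_id, out$date, out$dose), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Core walk: one row per (visit, summarized dose) pair at which the child
# was eligible for the dose, with a missed flag. Doses with tick/recall
# evidence are counted as received (unknown date) and never flagged.
.visit_table_one <- function(k, st, mode) {
  acc <- .accounting_one(k$ev, st, k$dob, mode)
  dated <- k$ev[k$ev$kind == "DATE", , drop = FALSE]
  visit_days <- sort(unique(.day(dated$date)))
  if (length(visit_days) == 0L) return(NULL)
  d <- st$doses
  sum_idx <- which(d$summarized)
  rows <- vector("list", length(visit_days) * length(sum_idx))
  n <- 0L
  for (v in visit_days) {
    age <- v - k$dob
    hist <- acc$counted[acc$counted < v]
    admin_here <- acc$admin$dose[acc$admin$day == v]
    for (j in sum_idx) {
      dose <- d$dose[j]
      if (dose %in% k$ev$dose[k$ev$kind %in% c("TICK", "RECALL")]) next
      if (.eligible_fast(d[j, ], st$prev[j], age, hist, v)) {
        n <- n + 1L
        rows[[n]] <- c(v, age, j, as.numeric(!(dose %in% admin_here)))
      }
    }
  }
  if (n == 0L) return(NULL)
  m <- do.call(rbind, rows[seq_len(n)])
  data.frame(child_id = k$child_id,
             visit_date = as.Date(m[, 1L], origin = "1970-01-01"),
             age_days = as.integer(m[, 2L]),
             dose = d$dose[m[, 3L]],
             missed = m[, 4L] == 1,
             stringsAsFactors = FALSE)
}

#' Eligible-visit table
#'
#' The visit-by-dose backbone of all MOSV indicators: one row per (visit,
#' summarized dose) combination at which the child was eligible for the
#' dose, flagged `missed` when the dose was not administered (valid mode:
#' not administered-and-counted, possibly via reallocation) at that visit.
#' Receipt history at a visit comprises doses counted as received strictly
#' before the visit date, under the chosen accounting mode.
#'
#' @param cohort A cleaned, selected `mosv_cohort`.
#' @param schedule A `mosv_schedule`.
#' @param mode `"crude"` or `"valid"`.
#' @return Data frame `child_id`, `visit_date`, `age_days`, `dose`,
#'   `missed`.
#' @export
mosv_visit_table <- function(cohort, schedule, mode = c("crude", "valid")) {
  mode <- match.arg(mode)
  st <- .sched_tables(schedule)
  kids <- .child_split(cohort)
  out <- do.call(rbind, lapply(kids, .visit_table_one, st = st, mode = mode))
  if (is.null(out)) {
    out <- data.frame(child_id = character(),
                      visit_date = as.Date(character()),
                      age_days = integer(), dose = character(),
                      missed = logical(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Detect missed opportunities for simultaneous vaccination
#'
#' Walks each child's reconstructed visits in date order. At a visit, the
#' child's receipt history is the set of doses counted as received strictly
#' before that date — under crude accounting any dated dose counts as
#' itself; under valid accounting only counted (possibly reallocated) doses
#' count. Every summarized dose for which the child was eligible but which
#' was not administered (valid mode: not administered-and-counted) at the
#' visit is a missed opportunity. One event is recorded per (child, dose):
#' the first missed visit, the number of missed visits, and whether the miss
#' was corrected — the dose (valid mode: a counted administration of the
#' dose slot) was received at a later date — with the correction date and
#' delay in days. Doses evidenced only by tick mark or caregiver recall are
#' credited as received on an unknown earlier date: they never generate
#' events and satisfy series prerequisites.
#'
#' @param cohort A cleaned, selected `mosv_cohort`.
#' @param schedule A `mosv_schedule`.
#' @param mode `"crude"` or `"valid"`.
#' @return Data frame `child_id`, `dose`, `mode`, `first_missed_date`,
#'   `n_missed_visits`, `corrected`, `correction_date`, `delay_days`.
#' @export
detect_mosvs <- function(cohort, schedule, mode = c("crude", "valid")) {
  mode <- match.arg(mode)
  st <- .sched_tables(schedule)
  kids <- .child_split(cohort)
  out <- lapply(kids, function(k) {
    vt <- .visit_table_one(k, st, mode)
    if (is.null(vt)) return(NULL)
    miss <- vt[vt$missed, , drop = FALSE]
    if (nrow(miss) == 0L) return(NULL)
    acc <- .accounting_one(k$ev, st, k$dob, mode)
    ev_rows <- lapply(split(seq_len(nrow(miss)), miss$dose), function(idx) {
      dose <- miss$dose[idx[1L]]
      first <- min(miss$visit_date[idx])
      cday <- if (dose %in% names(acc$counted)) acc$counted[[dose]] else NA
      corrected <- !is.na(cday) && is.finite(cday) && cday > .day(first)
      data.frame(
        child_id = k$child_id, dose = dose, mode = mode,
        first_missed_date = first,
        n_missed_visits = length(idx),
        corrected = corrected,
        correction_date = if (corrected) {
          as.Date(cday, origin = "1970-01-01")
        } else as.Date(NA),
        delay_days = if (corrected) {
          as.integer(cday - .day(first))
        } else NA_integer_,
        stringsAsFactors = FALSE)
    })
    do.call(rbind, ev_rows)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(child_id = character(), dose = character(),
                      mode = character(),
                      first_missed_date = as.Date(character()),
                      n_missed_visits = integer(), corrected = logical(),
                      correction_date = as.Date(character()),
                      delay_days = integer(), stringsAsFactors = FALSE)
  }
  out <- out[order(out$child_id, out$first_missed_date, out$dose), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
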