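# Brute-force day-stepping oracle for MOSV detection, independent of the
# package's incremental visit walk. Receipt maps here are plain lists of
# day numbers, with the string "unknown" for tick/recall credit; every
# visit re-derives the child's state from scratch. Eligibility is phrased
# as an earliest-eligible-day computation rather than per-condition tests.

oracle_eligible <- function(schedule, dose, dob, visit_day, receipt) {
  row <- schedule$doses[schedule$doses$dose == dose, ]
  if (dose %in% names(receipt)) return(FALSE)
  earliest <- dob + row$min_age_days
  if (!is.na(row$series) && row$number > 1L) {
    sd <- schedule$doses
    prevd <- sd$dose[!is.na(sd$series) & sd$series == row$series &
                       sd$number == row$number - 1L]
    if (!prevd %in% names(receipt)) return(FALSE)
    pd <- receipt[[prevd]]
    if (!identical(pd, "unknown")) {
      earliest <- max(earliest, pd + row$min_interval_days)
    }
  }
  if (visit_day < earliest) return(FALSE)
  if (!is.na(row$max_age_days) && visit_day > dob + row$max_age_days) {
    return(FALSE)
  }
  TRUE
}

# Valid-dose accounting redone from the rule statement: tick/recall keeps
# its own slot; dated series doses, in administration order, fill the
# lowest open slot when the slot's minimum age is met and the minimum
# interval from the previously counted (dated) dose has elapsed.
# Returns list(counted = list(slot -> day or "unknown"),
#              admin = data.frame(day, counted_as)).
oracle_valid_accounting <- function(ev, schedule, dob) {
  sd <- schedule$doses
  counted <- list()
  admin <- data.frame(day = numeric(), counted_as = character(),
                      stringsAsFactors = FALSE)
  dated <- ev[ev$kind == "DATE", , drop = FALSE]
  undated_doses <- ev$dose[ev$kind %in% c("TICK", "RECALL")]

  for (dose in sd$dose[is.na(sd$series)]) {
    if (dose %in% undated_doses) counted[[dose]] <- "unknown"
    i <- which(dated$dose == dose)
    if (length(i) == 1L) {
      day <- as.numeric(dated$date[i])
      if (day - dob >= sd$min_age_days[sd$dose == dose]) {
        counted[[dose]] <- day
        admin <- rbind(admin, data.frame(day = day, counted_as = dose,
                                         stringsAsFactors = FALSE))
      }
    }
  }
  for (s in unique(sd$series[!is.na(sd$series)])) {
    slots <- sd[!is.na(sd$series) & sd$series == s, ]
    slots <- slots[order(slots$number), ]
    assigned <- vector("list", nrow(slots))
    for (j in seq_len(nrow(slots))) {
      if (slots$dose[j] %in% undated_doses) assigned[[j]] <- "unknown"
    }
    sdd <- dated[dated$dose %in% slots$dose, , drop = FALSE]
    sdd <- sdd[order(as.numeric(sdd$date)), , drop = FALSE]
    for (i in seq_len(nrow(sdd))) {
      day <- as.numeric(sdd$date[i])
      open <- which(vapply(assigned, is.null, logical(1)))
      if (length(open) == 0L) next
      k <- open[1L]
      age_ok <- day - dob >= slots$min_age_days[k]
      int_ok <- k == 1L || identical(assigned[[k - 1L]], "unknown") ||
        day - assigned[[k - 1L]] >= slots$min_interval_days[k]
      if (age_ok && int_ok) {
        assigned[[k]] <- day
        admin <- rbind(admin, data.frame(day = day,
                                         counted_as = slots$dose[k],
                                         stringsAsFactors = FALSE))
      }
    }
    for (j in seq_len(nrow(slots))) {
      if (!is.null(assigned[[j]])) counted[[slots$dose[j]]] <- assigned[[j]]
    }
  }
  list(counted = counted, admin = admin)
}

oracle_crude_accounting <- function(ev) {
  counted <- list()
  dated <- ev[ev$kind == "DATE", , drop = FALSE]
  for (i in seq_len(nrow(dated))) {
    counted[[dated$dose[i]]] <- as.numeric(dated$date[i])
  }
  for (dose in ev$dose[ev$kind %in% c("TICK", "RECALL")]) {
    counted[[dose]] <- "unknown"
  }
  admin <- data.frame(day = as.numeric(dated$date), counted_as = dated$dose,
                      stringsAsFactors = FALSE)
  list(counted = counted, admin = admin)
}

oracle_detect <- function(cohort, schedule, mode) {
  out <- NULL
  for (i in seq_len(nrow(cohort$children))) {
    ch <- cohort$children[i, ]
    ev <- cohort$evidence[cohort$evidence$child_id == ch$child_id, ,
                          drop = FALSE]
    dob <- as.numeric(ch$dob)
    acc <- if (mode == "crude") oracle_crude_accounting(ev) else {
      oracle_valid_accounting(ev, schedule, dob)
    }
    visit_days <- sort(unique(as.numeric(ev$date[ev$kind == "DATE"])))
    tickish <- ev$dose[ev$kind %in% c("TICK", "RECALL")]
    sum_doses <- schedule$doses$dose[schedule$doses$summarized]
    misses <- NULL
    for (v in visit_days) {
      receipt <- acc$counted[vapply(acc$counted, function(x) {
        identical(x, "unknown") || x < v
      }, logical(1))]
      given <- acc$admin$counted_as[acc$admin$day == v]
      for (dose in setdiff(sum_doses, tickish)) {
        if (oracle_eligible(schedule, dose, dob, v, receipt) &&
            !dose %in% given) {
          misses <- rbind(misses, data.frame(dose = dose, day = v,
                                             stringsAsFactors = FALSE))
        }
      }
    }
    if (is.null(misses)) next
    for (dose in unique(misses$dose)) {
      days <- misses$day[misses$dose == dose]
      first <- min(days)
      cday <- acc$counted[[dose]]
      corr <- !is.null(cday) && !identical(cday, "unknown") && cday > first
      out <- rbind(out, data.frame(
        child_id = ch$child_id, dose = dose,
        first_missed_date = as.Date(first, origin = "1970-01-01"),
        n_missed_visits = length(days),
        corrected = corr,
        correction_date = if (corr) as.Date(cday, origin = "1970-01-01")
        else as.Date(NA),
        delay_days = if (corr) as.integer(cday - first) else NA_integer_,
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) {
    out <- data.frame(child_id = character(), dose = character(),
                      first_missed_date = as.Date(character()),
                      n_missed_visits = integer(), corrected = logical(),
                      correction_date = as.Date(character()),
                      delay_days = integer(), stringsAsFactors = FALSE)
  }
  canon_events(out)
}
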