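# In-code fixture builders: tiny cohorts with fully specified evidence.

test_schedule <- function() epi_schedule("nigeria")

# One child with resolved dob. `dates` is a named list: dose -> Date, or an
# integer age in days (converted to dob + age). `ticks`/`recalls` are dose
# name vectors.
synth_child <- function(id = "A", dob = as.Date("2017-06-01"),
                        survey = as.Date("2018-09-01"), card = TRUE,
                        weight = 1, stratum = "s1", cluster = "c1",
                        dates = list(), ticks = character(),
                        recalls = character()) {
  ev <- NULL
  for (dose in names(dates)) {
    v <- dates[[dose]]
    day <- if (inherits(v, "Date")) v else dob + as.integer(v)
    ev <- rbind(ev, data.frame(child_id = id, dose = dose, kind = "DATE",
                               date = day, flags = "",
                               stringsAsFactors = FALSE))
  }
  for (dose in ticks) {
    ev <- rbind(ev, data.frame(child_id = id, dose = dose, kind = "TICK",
                               date = as.Date(NA), flags = "",
                               stringsAsFactors = FALSE))
  }
  for (dose in recalls) {
    ev <- rbind(ev, data.frame(child_id = id, dose = dose, kind = "RECALL",
                               date = as.Date(NA), flags = "",
                               stringsAsFactors = FALSE))
  }
  list(
    child = data.frame(
      child_id = id,
      dob_year = as.integer(format(dob, "%Y")),
      dob_month = as.integer(format(dob, "%m")),
      dob_day = as.integer(format(dob, "%d")),
      dob = dob, dob_day_imputed = FALSE, survey_date = survey,
      card_seen = card, weight = weight, stratum_id = stratum,
      cluster_id = cluster, stringsAsFactors = FALSE),
    evidence = ev)
}

make_cohort <- function(...) {
  kids <- list(...)
  children <- do.call(rbind, lapply(kids, `[[`, "child"))
  evidence <- do.call(rbind, lapply(kids, `[[`, "evidence"))
  if (is.null(evidence)) {
    evidence <- data.frame(child_id = character(), dose = character(),
                           kind = character(), date = as.Date(character()),
                           flags = character(), stringsAsFactors = FALSE)
  }
  structure(list(children = children, evidence = evidence),
            class = "mosv_cohort")
}

# Run the cleaning + selection half of the pipeline on a generated cohort.
prepare_cohort <- function(cohort, schedule) {
  cohort <- impute_birth_day(cohort, schedule)
  cohort <- clean_dates(cohort, schedule)
  select_cohort(cohort)$cohort
}

# Sort an event table into a canonical order for exact comparison.
canon_events <- function(ev) {
  ev <- ev[order(ev$child_id, ev$dose), , drop = FALSE]
  rownames(ev) <- NULL
  ev[, c("child_id", "dose", "first_missed_date", "n_missed_visits",
         "corrected", "correction_date", "delay_days")]
}
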