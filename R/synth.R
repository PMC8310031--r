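#' Parameters for the synthetic cohort generator
#'
#' Bundles and validates the knobs of [generate_cohort()]. Defaults emulate
#' a DHS-like 12-23-month cohort vaccinated along the classic EPI calendar:
#' schedule-anchored visits at birth, 6, 10, 14 and 39 weeks with normally
#' jittered timing (truncated at +/-21 days) and per-visit dropout; partial
#' card availability; per-dose, per-eligible-visit miss probabilities with
#' later corrections; occasional date-recording errors; and lognormal
#' survey weights over two strata.
#'
#' @param n_children Number of children.
#' @param seed Integer seed; the generator is deterministic given it.
#' @param survey_date Survey/interview date (single date for all children).
#' @param card_prob Probability a child's card is available (card-less
#'   children carry caregiver recall only and are excluded by the card
#'   filter downstream).
#' @param visit_ages_days Target ages (days) of potential vaccination
#'   visits.
#' @param jitter_sd_days SD of the normal jitter on visit ages; draws are
#'   truncated at +/-21 days.
#' @param attendance_dropout Probability each potential visit is skipped.
#' @param miss_prob Named numeric vector: per-eligible-visit probability
#'   that a due dose is missed, by dose; doses not named never miss.
#' @param correction_prob Probability a previously missed dose is
#'   administered at each later visit where it is again due.
#' @param date_error_rate Probability each recorded date is corrupted
#'   (before-birth, after-survey, or swap-within-series, equal shares).
#' @param weight_model `"equal"` or `"lognormal"`.
#' @param weight_sd SD (log scale) for lognormal weights.
#' @param strata Named numeric vector of stratum proportions (must sum
#'   to 1).
#' @return A validated list of class `synth_params`.
#' @export
synth_params <- function(n_children = 1000L,
                         seed = 20210716L,
                         survey_date = as.Date("2018-09-01"),
                         card_prob = 0.6,
                         visit_ages_days = c(0L, 42L, 70L, 98L, 273L),
                         jitter_sd_days = 7,
                         attendance_dropout = 0.08,
                         miss_prob = c(BCG = 0.12, OPV1 = 0.15, OPV2 = 0.1,
                                       OPV3 = 0.1, DPT1 = 0.15, DPT2 = 0.1,
                                       DPT3 = 0.1, MCV1 = 0.18),
                         correction_prob = 0.5,
                         date_error_rate = 0.02,
                         weight_model = c("lognormal", "equal"),
                         weight_sd = 0.5,
                         strata = c(north = 0.5, south = 0.5)) {
  weight_model <- match.arg(weight_model)
  p <- list(n_children = as.integer(n_children), seed = as.integer(seed),
            survey_date = as.Date(survey_date), card_prob = card_prob,
            visit_ages_days = as.integer(visit_ages_days),
            jitter_sd_days = jitter_sd_days,
            attendance_dropout = attendance_dropout,
            miss_prob = miss_prob, correction_prob = correction_prob,
            date_error_rate = date_error_rate,
            weight_model = weight_model, weight_sd = weight_sd,
            strata = strata)
  probs <- c(p$card_prob, p$attendance_dropout, p$correction_prob,
             p$date_error_rate, p$miss_prob)
  if (any(probs < 0) || any(probs > 1)) {
    stop("synthetic parameter error: probabilities must lie in [0, 1]",
         call. = FALSE)
  }
  if (length(p$visit_ages_days) == 0L) {
    stop("synthetic parameter error: at least one visit age is required",
         call. = FALSE)
  }
  if (is.unsorted(p$visit_ages_days, strictly = TRUE)) {
    stop("synthetic parameter error: visit ages must be strictly increasing",
         call. = FALSE)
  }
  if (abs(sum(p$strata) - 1) > 1e-8 || is.null(names(p$strata))) {
    stop("synthetic parameter error: strata must be a named vector of ",
         "proportions summing to 1", call. = FALSE)
  }
  class(p) <- "synth_params"
  p
}

# jitter truncated at +/- limit days
.trunc_jitter <- function(n, sd, limit = 21) {
  z <- stats::rnorm(n, 0, sd)
  bad <- abs(z) > limit
  tries <- 0L
  while (any(bad) && tries < 50L) {
    z[bad] <- stats::rnorm(sum(bad), 0, sd)
    bad <- abs(z) > limit
    tries <- tries + 1L
  }
  z[bad] <- 0
  round(z)
}

#' Generate a DHS-like synthetic cohort with known MOSV ground truth
#'
#' Simulates one child at a time: a date of birth placing the child at
#' 12-23 completed months at the survey; attended visits at jittered target
#' ages; at each attended visit every due dose (eligible under the schedule
#' given the child's true receipt history) is administered unless a miss
#' event fires, and previously missed doses are retried with the correction
#' probability. A visit at which no dose ends up administered leaves no
#' dated record and so contributes no truth events (it is invisible to any
#' card-based analysis). Card-holding children record one dated card entry
#' per administered dose; card-less children carry recall evidence only.
#' Date-recording errors are injected last, into the recorded card only —
#' the truth table always reflects the uncorrupted history.
#'
#' @param params A [synth_params()] object.
#' @param schedule A `mosv_schedule`; defaults to [epi_schedule()].
#' @return List of class `synth_cohort`: `cohort` (a `mosv_cohort` in the
#'   exact shape [read_children()] produces), `truth` (list: `visits`,
#'   `events` — true MOSV events with correction status — and `anomalies`,
#'   the injected date errors), and `params`.
#' @export
generate_cohort <- function(params = synth_params(),
                            schedule = epi_schedule()) {
  stopifnot(inherits(params, "synth_params"))
  set.seed(params$seed)
  st <- .sched_tables(schedule)
  d <- st$doses
  svy <- .day(params$survey_date)
  n <- params$n_children

  children <- vector("list", n)
  evidence <- vector("list", n)
  truth_visits <- vector("list", n)
  truth_events <- vector("list", n)
  anomalies <- vector("list", n)

  strat_names <- names(params$strata)
  for (i in seq_len(n)) {
    id <- sprintf("C%05d", i)
    # dob: age at survey in [12, 24) completed months
    repeat {
      dob <- svy - sample(366:730, 1L)
      am <- age_completed_months(as.Date(dob, origin = "1970-01-01"),
                                 params$survey_date)
      if (am >= 12L && am < 24L) break
    }
    stratum <- sample(strat_names, 1L, prob = params$strata)
    cluster <- paste0(stratum, "-", sample.int(10L, 1L))
    wgt <- if (params$weight_model == "equal") 1 else {
      stats::rlnorm(1L, 0, params$weight_sd)
    }
    card <- stats::runif(1L) < params$card_prob

    ages <- params$visit_ages_days +
      .trunc_jitter(length(params$visit_ages_days), params$jitter_sd_days)
    ages <- pmax(ages, 0L)
    attend <- stats::runif(length(ages)) >= params$attendance_dropout
    vdays <- sort(unique(dob + ages[attend]))
    vdays <- vdays[vdays <= svy & vdays >= dob]

    received <- numeric(0)        # dose -> day administered (truth)
    active <- list()              # dose -> list(first, n)
    done_events <- list()
    kept_visits <- list()
    for (v in vdays) {
      age <- v - dob
      snapshot <- received
      give <- character(0)
      miss_here <- character(0)
      for (j in seq_len(nrow(d))) {
        dose <- d$dose[j]
        if (!.eligible_fast(d[j, ], st$prev[j], age, snapshot, v)) next
        was_missed <- dose %in% names(active)
        p_give <- if (was_missed) params$correction_prob else {
          1 - (if (dose %in% names(params$miss_prob)) {
            params$miss_prob[[dose]]
          } else 0)
        }
        if (stats::runif(1L) < p_give) {
          give <- c(give, dose)
        } else if (d$summarized[j]) {
          miss_here <- c(miss_here, dose)
        }
      }
      if (length(give) == 0L) next  # no dose given: no record of the visit
      received[give] <- v
      kept_visits[[length(kept_visits) + 1L]] <-
        data.frame(child_id = id,
                   date = as.Date(v, origin = "1970-01-01"),
                   age_days = as.integer(age),
                   doses = paste(sort(give), collapse = ";"),
                   stringsAsFactors = FALSE)
      for (dose in miss_here) {
        if (dose %in% names(active)) {
          active[[dose]]$n <- active[[dose]]$n + 1L
        } else {
          active[[dose]] <- list(first = v, n = 1L)
        }
      }
      for (dose in intersect(give, names(active))) {
        a <- active[[dose]]
        done_events[[length(done_events) + 1L]] <-
          data.frame(child_id = id, dose = dose,
                     first_missed_date = as.Date(a$first,
                                                 origin = "1970-01-01"),
                     n_missed_visits = a$n, corrected = TRUE,
                     correction_date = as.Date(v, origin = "1970-01-01"),
                     delay_days = as.integer(v - a$first),
                     stringsAsFactors = FALSE)
        active[[dose]] <- NULL
      }
    }
    for (dose in names(active)) {
      a <- active[[dose]]
      done_events[[length(done_events) + 1L]] <-
        data.frame(child_id = id, dose = dose,
                   first_missed_date = as.Date(a$first,
                                               origin = "1970-01-01"),
                   n_missed_visits = a$n, corrected = FALSE,
                   correction_date = as.Date(NA),
                   delay_days = NA_integer_, stringsAsFactors = FALSE)
    }

    # recorded evidence (date errors are injected in a later pass so the
    # truth simulation consumes an identical RNG stream at any error rate)
    ev <- NULL
    if (length(received) > 0L) {
      if (card) {
        ev <- data.frame(child_id = id, dose = names(received),
                         kind = "DATE",
                         date = as.Date(unname(received),
                                        origin = "1970-01-01"),
                         flags = "", stringsAsFactors = FALSE)
      } else {
        ev <- data.frame(child_id = id, dose = names(received),
                         kind = "RECALL", date = as.Date(NA), flags = "",
                         stringsAsFactors = FALSE)
      }
    }

    dob_date <- as.Date(dob, origin = "1970-01-01")
    children[[i]] <- data.frame(
      child_id = id,
      dob_year = as.integer(format(dob_date, "%Y")),
      dob_month = as.integer(format(dob_date, "%m")),
      dob_day = as.integer(format(dob_date, "%d")),
      dob = as.Date(NA), dob_day_imputed = FALSE,
      survey_date = params$survey_date,
      card_seen = card, weight = wgt, stratum_id = stratum,
      cluster_id = cluster, stringsAsFactors = FALSE)
    evidence[[i]] <- ev
    truth_visits[[i]] <- if (length(kept_visits) > 0L) {
      do.call(rbind, kept_visits)
    } else NULL
    truth_events[[i]] <- if (length(done_events) > 0L) {
      do.call(rbind, done_events)
    } else NULL
  }

  # corruption pass: per recorded card date, with probability
  # date_error_rate replace it by a before-birth or after-survey date or
  # swap it with another dated dose of the same series (equal shares; a
  # swap with no series mate falls back to a before-birth error)
  dob_day_of <- stats::setNames(
    .day(as.Date(sprintf("%04d-%02d-%02d",
                         vapply(children, function(x) x$dob_year, 1L),
                         vapply(children, function(x) x$dob_month, 1L),
                         vapply(children, function(x) x$dob_day, 1L)))),
    vapply(children, function(x) x$child_id, ""))
  for (i in seq_len(n)) {
    ev <- evidence[[i]]
    if (is.null(ev) || nrow(ev) == 0L || ev$kind[1L] != "DATE") next
    id <- ev$child_id[1L]
    dob <- dob_day_of[[id]]
    for (r in seq_len(nrow(ev))) {
      if (stats::runif(1L) >= params$date_error_rate) next
      dose <- ev$dose[r]
      type <- sample(c("before_birth", "after_survey", "series_swap"), 1L)
      if (type == "series_swap") {
        j <- st$row_of[[dose]]
        mates <- if (is.na(d$series[j])) character(0) else {
          d$dose[!is.na(d$series) & d$series == d$series[j] &
                   d$dose != dose]
        }
        mate_rows <- which(ev$dose %in% mates)
        if (length(mate_rows) > 0L) {
          o <- mate_rows[1L]
          tmp <- ev$date[r]
          ev$date[r] <- ev$date[o]
          ev$date[o] <- tmp
        } else {
          type <- "before_birth"
        }
      }
      if (type == "before_birth") {
        ev$date[r] <- as.Date(dob - sample.int(60L, 1L),
                              origin = "1970-01-01")
      } else if (type == "after_survey") {
        ev$date[r] <- as.Date(svy + sample.int(60L, 1L),
                              origin = "1970-01-01")
      }
      anomalies[[i]] <- rbind(anomalies[[i]],
                              data.frame(child_id = id, dose = dose,
                                         type = type,
                                         stringsAsFactors = FALSE))
    }
    evidence[[i]] <- ev
  }

  bind <- function(lst, proto) {
    out <- do.call(rbind, lst)
    if (is.null(out)) proto else out
  }
  ev_all <- bind(evidence, empty_evidence())
  ev_all <- ev_all[order(ev_all$child_id, ev_all$dose), , drop = FALSE]
  rownames(ev_all) <- NULL
  out <- list(
    cohort = new_cohort(do.call(rbind, children), ev_all),
    truth = list(
      visits = bind(truth_visits,
                    data.frame(child_id = character(),
                               date = as.Date(character()),
                               age_days = integer(), doses = character(),
                               stringsAsFactors = FALSE)),
      events = bind(truth_events,
                    data.frame(child_id = character(), dose = character(),
                               first_missed_date = as.Date(character()),
                               n_missed_visits = integer(),
                               corrected = logical(),
                               correction_date = as.Date(character()),
                               delay_days = integer(),
                               stringsAsFactors = FALSE)),
      anomalies = bind(anomalies,
                       data.frame(child_id = character(),
                                  dose = character(), type = character(),
                                  stringsAsFactors = FALSE))),
    params = params)
  class(out) <- "synth_cohort"
  out
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat("<synth_cohort> ", nrow(x$cohort$children), " children, ",
      nrow(x$truth$events), " true MOSV events, ",
      nrow(x$truth$anomalies), " injected date errors\n", sep = "")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits the child-level input CSV in the dialect [read_children()] expects,
#' plus the ground-truth event and anomaly tables.
#'
#' @param synth A `synth_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synth <- function(synth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort_csv(synth$cohort, file.path(dir, "children.csv"))
  tr <- synth$truth$events
  tr$first_missed_date <- format(tr$first_missed_date, "%Y-%m-%d")
  tr$correction_date <- format(tr$correction_date, "%Y-%m-%d")
  utils::write.csv(tr, file.path(dir, "truth_events.csv"),
                   row.names = FALSE)
  utils::write.csv(synth$truth$anomalies,
                   file.path(dir, "truth_anomalies.csv"), row.names = FALSE)
  invisible(dir)
}
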