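## Visit-based and child-based MOSV indicators, counterfactual achievable
## coverage, and time-to-correction distributions.
##
## Point estimates only: survey weights enter as child-level multipliers
## (visits inherit the child's weight); no variance estimation is attempted.
## Weighted and unweighted variants are always reported side by side.

.prop <- function(num, den) if (den > 0) num / den else NA_real_

.child_weights <- function(cohort) {
  stats::setNames(cohort$children$weight, cohort$children$child_id)
}

#' Visit-based MOSV indicators
#'
#' From the eligible-visit table: per dose, VB1 is the proportion of visits
#' at which the child was eligible for the dose that resulted in a MOSV for
#' it. Across doses, with the set of visits at which the child was eligible
#' for at least one summarized dose as denominator, VB2 is the proportion of
#' such visits with at least one MOSV, VB3 the mean number of MOSVs per
#' eligible visit, and 1/VB3 the average number of vaccination visits
#' between MOSVs (`NA` when VB3 is 0). Weighted variants multiply each visit
#' by its child's survey weight.
#'
#' @param cohort A cleaned, selected `mosv_cohort`.
#' @param schedule A `mosv_schedule`.
#' @param mode `"crude"` or `"valid"`.
#' @param visit_table Optionally a precomputed [mosv_visit_table()].
#' @return List of class `mosv_vb`: `per_dose` (dose, eligible-visit and
#'   MOSV counts, `vb1`, `vb1_weighted`) and `overall` (counts, `vb2`,
#'   `vb3`, `vb3_inverse` and weighted variants).
#' @export
visit_based <- function(cohort, schedule, mode = c("crude", "valid"),
                        visit_table = NULL) {
  mode <- match.arg(mode)
  vt <- if (is.null(visit_table)) {
    mosv_visit_table(cohort, schedule, mode)
  } else visit_table
  w <- .child_weights(cohort)
  vt$w <- unname(w[vt$child_id])
  doses <- schedule$doses$dose[schedule$doses$summarized]

  per_dose <- do.call(rbind, lapply(doses, function(d) {
    sub <- vt[vt$dose == d, , drop = FALSE]
    data.frame(
      dose = d, mode = mode,
      n_eligible_visits = nrow(sub),
      n_mosv = sum(sub$missed),
      vb1 = .prop(sum(sub$missed), nrow(sub)),
      vb1_weighted = .prop(sum(sub$w[sub$missed]), sum(sub$w)),
      stringsAsFactors = FALSE)
  }))

  if (nrow(vt) > 0L) {
    key <- paste(vt$child_id, vt$visit_date)
    n_miss <- tapply(vt$missed, key, sum)
    vw <- tapply(vt$w, key, function(x) x[1L])
    n_vis <- length(n_miss)
    any_miss <- n_miss > 0
    vb2 <- .prop(sum(any_miss), n_vis)
    vb3 <- sum(n_miss) / n_vis
    vb2_w <- .prop(sum(vw[any_miss]), sum(vw))
    vb3_w <- sum(vw * n_miss) / sum(vw)
  } else {
    n_vis <- 0L
    vb2 <- vb3 <- vb2_w <- vb3_w <- NA_real_
  }
  inv <- function(x) if (is.na(x) || x == 0) NA_real_ else 1 / x
  overall <- data.frame(
    mode = mode, n_eligible_visits = n_vis,
    n_mosv = if (n_vis > 0) sum(vt$missed) else 0L,
    vb2 = vb2, vb3 = vb3, vb3_inverse = inv(vb3),
    vb2_weighted = vb2_w, vb3_weighted = vb3_w,
    vb3_inverse_weighted = inv(vb3_w),
    stringsAsFactors = FALSE)
  structure(list(per_dose = per_dose, overall = overall), class = "mosv_vb")
}

#' Child-based MOSV indicators
#'
#' Per dose, CB1 is the proportion — among children who had at least one
#' vaccination visit at which they were eligible for the dose — who
#' experienced at least one MOSV for it, split into corrected (the dose was
#' received by the time of the survey) and uncorrected parts. Overall, CB2
#' is the proportion of children (among those with at least one
#' dose-eligible visit) who experienced at least one MOSV for any summarized
#' dose, split by whether all, some, or none of the child's MOSVs were
#' corrected.
#'
#' @inheritParams visit_based
#' @param events Optionally precomputed [detect_mosvs()] output.
#' @return List of class `mosv_cb`: `per_dose` (counts, `cb1`,
#'   `cb1_corrected`, `cb1_uncorrected` plus weighted variants) and
#'   `overall` (counts, `cb2` and its all/some/none-corrected split, plus
#'   weighted variants).
#' @export
child_based <- function(cohort, schedule, mode = c("crude", "valid"),
                        visit_table = NULL, events = NULL) {
  mode <- match.arg(mode)
  vt <- if (is.null(visit_table)) {
    mosv_visit_table(cohort, schedule, mode)
  } else visit_table
  evs <- if (is.null(events)) detect_mosvs(cohort, schedule, mode) else events
  w <- .child_weights(cohort)
  doses <- schedule$doses$dose[schedule$doses$summarized]

  per_dose <- do.call(rbind, lapply(doses, function(d) {
    denom_ids <- unique(vt$child_id[vt$dose == d])
    sub <- evs[evs$dose == d, , drop = FALSE]
    wc <- sum(w[denom_ids])
    data.frame(
      dose = d, mode = mode,
      n_children_eligible = length(denom_ids),
      n_mosv_children = nrow(sub),
      n_corrected = sum(sub$corrected),
      n_uncorrected = sum(!sub$corrected),
      cb1 = .prop(nrow(sub), length(denom_ids)),
      cb1_corrected = .prop(sum(sub$corrected), length(denom_ids)),
      cb1_uncorrected = .prop(sum(!sub$corrected), length(denom_ids)),
      cb1_weighted = .prop(sum(w[sub$child_id]), wc),
      cb1_corrected_weighted = .prop(sum(w[sub$child_id[sub$corrected]]), wc),
      cb1_uncorrected_weighted =
        .prop(sum(w[sub$child_id[!sub$corrected]]), wc),
      stringsAsFactors = FALSE)
  }))

  denom_ids <- unique(vt$child_id)
  wc <- sum(w[denom_ids])
  corr_by_child <- tapply(evs$corrected, evs$child_id, function(x) {
    if (all(x)) "all" else if (any(x)) "some" else "none"
  })
  cls_ids <- names(corr_by_child)
  n_evch <- length(cls_ids)
  n_of <- function(cls) sum(corr_by_child == cls)
  w_of <- function(cls) sum(w[cls_ids[corr_by_child == cls]])
  overall <- data.frame(
    mode = mode,
    n_children_eligible = length(denom_ids),
    n_mosv_children = n_evch,
    n_all_corrected = n_of("all"),
    n_some_corrected = n_of("some"),
    n_none_corrected = n_of("none"),
    cb2 = .prop(n_evch, length(denom_ids)),
    cb2_all_corrected = .prop(n_of("all"), length(denom_ids)),
    cb2_some_corrected = .prop(n_of("some"), length(denom_ids)),
    cb2_none_corrected = .prop(n_of("none"), length(denom_ids)),
    cb2_weighted = .prop(sum(w[cls_ids]), wc),
    cb2_all_corrected_weighted = .prop(w_of("all"), wc),
    cb2_some_corrected_weighted = .prop(w_of("some"), wc),
    cb2_none_corrected_weighted = .prop(w_of("none"), wc),
    stringsAsFactors = FALSE)
  structure(list(per_dose = per_dose, overall = overall), class = "mosv_cb")
}

# Counterfactual walk for one child: credit every summarized dose the child
# was eligible for at each visit, assuming every previously eligible dose
# had also been received (counterfactual receipts dated at the crediting
# visit). Observed receipts enter the history as they occur, so the
# counterfactual never un-receives a dose; the potential receipt set is the
# union of counterfactual credits and observed (mode-counted) receipts.
.potential_one <- function(k, st, mode) {
  acc <- .accounting_one(k$ev, st, k$dob, mode)
  dated <- k$ev[k$ev$kind == "DATE", , drop = FALSE]
  visit_days <- sort(unique(.day(dated$date)))
  d <- st$doses
  sum_idx <- which(d$summarized)
  # start from tick/recall credit (and, in valid mode, tick-filled slots)
  cf <- acc$counted[!is.finite(acc$counted)]
  for (v in visit_days) {
    age <- v - k$dob
    obs_before <- acc$counted[is.finite(acc$counted) & acc$counted < v]
    hist <- cf
    add <- setdiff(names(obs_before), names(hist))
    hist[add] <- obs_before[add]
    hist <- hist[hist < v]
    for (j in sum_idx) {
      dose <- d$dose[j]
      if (dose %in% names(cf)) next
      if (.eligible_fast(d[j, ], st$prev[j], age, hist, v)) cf[dose] <- v
    }
  }
  list(observed = names(acc$counted), potential = union(names(cf),
                                                        names(acc$counted)))
}

#' Observed versus potential (achievable) coverage
#'
#' Re-estimates coverage under the counterfactual that the child received
#' every summarized dose they were age- and interval-eligible for at each of
#' their vaccination visits, assuming they had also received every eligible
#' dose at every previous visit. Observed coverage counts doses under the
#' chosen accounting (crude: any evidence including tick marks and recall;
#' valid: counted valid doses, including tick credit). Potential coverage is
#' the union of observed receipt and counterfactual credits, so it can never
#' fall below observed coverage.
#'
#' @inheritParams visit_based
#' @return Data frame per summarized dose: observed and potential coverage
#'   proportions (weighted and unweighted) and their difference (weighted).
#' @export
potential_coverage <- function(cohort, schedule, mode = c("crude", "valid")) {
  mode <- match.arg(mode)
  st <- .sched_tables(schedule)
  kids <- .child_split(cohort)
  w <- .child_weights(cohort)
  doses <- schedule$doses$dose[schedule$doses$summarized]
  n <- length(kids)
  obs <- matrix(FALSE, n, length(doses), dimnames = list(NULL, doses))
  pot <- obs
  for (i in seq_len(n)) {
    r <- .potential_one(kids[[i]], st, mode)
    obs[i, intersect(r$observed, doses)] <- TRUE
    pot[i, intersect(r$potential, doses)] <- TRUE
  }
  wv <- unname(w[vapply(kids, `[[`, "", "child_id")])
  wsum <- sum(wv)
  do.call(rbind, lapply(doses, function(d) {
    data.frame(
      dose = d, mode = mode, n_children = n,
      observed = .prop(sum(obs[, d]), n),
      potential = .prop(sum(pot[, d]), n),
      observed_weighted = .prop(sum(wv[obs[, d]]), wsum),
      potential_weighted = .prop(sum(wv[pot[, d]]), wsum),
      difference = .prop(sum(pot[, d]), n) - .prop(sum(obs[, d]), n),
      difference_weighted = .prop(sum(wv[pot[, d]]), wsum) -
        .prop(sum(wv[obs[, d]]), wsum),
      stringsAsFactors = FALSE)
  }))
}

#' Time from first missed opportunity to correction
#'
#' For corrected MOSVs of one dose: the empirical cumulative distribution of
#' the delay in days between the first missed opportunity and the date the
#' dose was finally received, with inverse-ECDF (type-1) quantiles at the
#' 25th, 50th, 75th and 90th percentiles. Counts are unweighted. A
#' distribution based on fewer than 25 corrected events is flagged
#' `small_n`.
#'
#' @param events Output of [detect_mosvs()].
#' @param dose Dose name.
#' @return List of class `mosv_delay`: `dose`, `n_corrected`, `ecdf`
#'   (delay_days, cum_fraction), `quantiles` (named: q25, q50, q75, q90),
#'   `small_n`.
#' @export
time_to_correction <- function(events, dose) {
  delays <- sort(events$delay_days[events$dose == dose & events$corrected])
  n <- length(delays)
  if (n == 0L) {
    out <- list(dose = dose, n_corrected = 0L,
                ecdf = data.frame(delay_days = integer(),
                                  cum_fraction = numeric()),
                quantiles = c(q25 = NA_real_, q50 = NA_real_,
                              q75 = NA_real_, q90 = NA_real_),
                small_n = TRUE)
    class(out) <- "mosv_delay"
    return(out)
  }
  ux <- unique(delays)
  cum <- cumsum(tabulate(match(delays, ux))) / n
  qt <- vapply(c(0.25, 0.5, 0.75, 0.9),
               function(p) as.numeric(delays[ceiling(p * n)]), numeric(1))
  out <- list(dose = dose, n_corrected = n,
              ecdf = data.frame(delay_days = ux, cum_fraction = cum),
              quantiles = stats::setNames(qt, c("q25", "q50", "q75", "q90")),
              small_n = n < 25L)
  class(out) <- "mosv_delay"
  out
}

#' @export
print.mosv_delay <- function(x, ...) {
  cat("<mosv_delay> ", x$dose, ": n=", x$n_corrected,
      if (x$small_n) " (small n)" else "", "\n", sep = "")
  print(x$quantiles)
  invisible(x)
}

.subset_cohort <- function(cohort, ids) {
  new_cohort(cohort$children[cohort$children$child_id %in% ids, ,
                             drop = FALSE],
             cohort$evidence[cohort$evidence$child_id %in% ids, ,
                             drop = FALSE])
}

#' Run all indicators per stratum
#'
#' Computes visit-based and child-based indicators, potential coverage and
#' per-dose time-to-correction for the whole cohort and for each stratum. A
#' `strata_spec` may define super-strata as unions of stratum identifiers
#' (e.g. north = several regions); children belonging to no super-stratum
#' are kept in the overall results but excluded from the stratified
#' comparison only. Without a spec, each distinct `stratum_id` forms its own
#' stratum.
#'
#' @inheritParams visit_based
#' @param strata_spec `NULL`, or a named list mapping super-stratum names to
#'   character vectors of `stratum_id` values. Referencing a stratum absent
#'   from the data is an error.
#' @return List of class `mosv_indicator_table`: tidy data frames `vb1`,
#'   `vb_overall`, `cb1`, `cb_overall`, `coverage`, `delay_quantiles`,
#'   `delay_ecdf`, each with a `stratum` column (`"overall"` plus one row
#'   set per stratum), and `events` (all strata pooled).
#' @export
stratified_run <- function(cohort, schedule, mode = c("crude", "valid"),
                           strata_spec = NULL) {
  mode <- match.arg(mode)
  present <- unique(cohort$children$stratum_id)
  if (is.null(strata_spec)) {
    strata_spec <- stats::setNames(as.list(sort(present)), sort(present))
  } else {
    unknown <- setdiff(unique(unlist(strata_spec)), present)
    if (length(unknown) > 0L) {
      stop("strata specification error: unknown stratum '", unknown[1L],
           "'", call. = FALSE)
    }
  }
  groups <- c(list(overall = present), strata_spec)
  doses <- schedule$doses$dose[schedule$doses$summarized]

  acc <- list(vb1 = NULL, vb_overall = NULL, cb1 = NULL, cb_overall = NULL,
              coverage = NULL, delay_quantiles = NULL, delay_ecdf = NULL)
  events_all <- NULL
  for (g in names(groups)) {
    ids <- cohort$children$child_id[cohort$children$stratum_id %in%
                                      groups[[g]]]
    sub <- .subset_cohort(cohort, ids)
    vt <- mosv_visit_table(sub, schedule, mode)
    evs <- detect_mosvs(sub, schedule, mode)
    vb <- visit_based(sub, schedule, mode, visit_table = vt)
    cb <- child_based(sub, schedule, mode, visit_table = vt, events = evs)
    cov <- potential_coverage(sub, schedule, mode)
    dq <- do.call(rbind, lapply(doses, function(d) {
      tt <- time_to_correction(evs, d)
      data.frame(dose = d, mode = mode, n_corrected = tt$n_corrected,
                 q25 = tt$quantiles[["q25"]], q50 = tt$quantiles[["q50"]],
                 q75 = tt$quantiles[["q75"]], q90 = tt$quantiles[["q90"]],
                 small_n = tt$small_n, stringsAsFactors = FALSE)
    }))
    de <- do.call(rbind, lapply(doses, function(d) {
      tt <- time_to_correction(evs, d)
      if (nrow(tt$ecdf) == 0L) return(NULL)
      data.frame(dose = d, mode = mode, delay_days = tt$ecdf$delay_days,
                 cum_fraction = tt$ecdf$cum_fraction, n = tt$n_corrected,
                 stringsAsFactors = FALSE)
    }))
    tag <- function(df) {
      if (is.null(df) || nrow(df) == 0L) return(NULL)
      cbind(stratum = g, df, stringsAsFactors = FALSE)
    }
    acc$vb1 <- rbind(acc$vb1, tag(vb$per_dose))
    acc$vb_overall <- rbind(acc$vb_overall, tag(vb$overall))
    acc$cb1 <- rbind(acc$cb1, tag(cb$per_dose))
    acc$cb_overall <- rbind(acc$cb_overall, tag(cb$overall))
    acc$coverage <- rbind(acc$coverage, tag(cov))
    acc$delay_quantiles <- rbind(acc$delay_quantiles, tag(dq))
    acc$delay_ecdf <- rbind(acc$delay_ecdf, tag(de))
    if (g == "overall") events_all <- evs
  }
  acc$events <- events_all
  class(acc) <- "mosv_indicator_table"
  acc
}
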