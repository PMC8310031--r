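write_input_csv <- function(rows, cols) {
  f <- tempfile(fileext = ".csv")
  df <- as.data.frame(rows, stringsAsFactors = FALSE)
  names(df) <- cols
  utils::write.csv(df, f, row.names = FALSE)
  f
}

basic_csv <- function(...) {
  extra <- list(...)
  base <- list(child_id = "K1", dob_year = "2017", dob_month = "3",
               dob_day = "15", survey_date = "2018-06-01",
               card_seen = "yes", weight = "1.5", stratum_id = "s1",
               cluster_id = "c1")
  all <- c(base, extra)
  write_input_csv(all, names(all))
}

test_that("evidence kinds are read from date and recall columns", {
  sched <- test_schedule()
  f <- basic_csv(BCG_date = "2017-03-16", DPT1_date = "",
                 OPV1_date = "12/??/2017", OPV2_recall = "yes",
                 MCV1_recall = "no")
  co <- read_children(f, sched)
  ev <- co$evidence
  expect_equal(ev$kind[ev$dose == "BCG"], "DATE")
  expect_equal(ev$date[ev$dose == "BCG"], as.Date("2017-03-16"))
  # blank cell: no evidence row at all
  expect_false("DPT1" %in% ev$dose)
  # illegible date becomes a tick with no anomaly flags
  expect_equal(ev$kind[ev$dose == "OPV1"], "TICK")
  expect_equal(ev$flags[ev$dose == "OPV1"], "")
  expect_equal(ev$kind[ev$dose == "OPV2"], "RECALL")
  expect_false("MCV1" %in% ev$dose)
  expect_equal(co$children$weight, 1.5)
})

test_that("alias columns feed the canonical dose", {
  sched <- test_schedule()
  f <- basic_csv(Penta1_date = "2017-05-01")
  co <- read_children(f, sched)
  expect_equal(co$evidence$dose, "DPT1")
})

test_that("missing columns and duplicate ids are input errors", {
  sched <- test_schedule()
  f <- write_input_csv(list(child_id = "K1", dob_year = "2017"),
                       c("child_id", "dob_year"))
  expect_error(read_children(f, sched), "dob_month")
  df <- list(child_id = c("K1", "K1"), dob_year = c("2017", "2017"),
             dob_month = c("3", "4"), dob_day = c("1", "2"),
             survey_date = c("2018-06-01", "2018-06-01"),
             card_seen = c("yes", "yes"), weight = c("1", "1"),
             stratum_id = c("s1", "s1"), cluster_id = c("c1", "c1"))
  f2 <- write_input_csv(df, names(df))
  expect_error(read_children(f2, sched), "duplicate child_id")
})

test_that("day of birth is imputed from a same-month birth dose, else day 1", {
  sched <- test_schedule()
  mk <- function(day, bcg) {
    k <- synth_child(dob = as.Date("1990-03-15"), dates = bcg,
                     survey = as.Date("1991-06-01"))
    k$child$dob_day <- day
    k$child$dob <- as.Date(NA)
    make_cohort(k)
  }
  # dated birth dose inside the reported birth month
  co <- impute_birth_day(mk(NA, list(BCG = as.Date("1990-03-15"))), sched)
  expect_equal(co$children$dob, as.Date("1990-03-15"))
  expect_true(co$children$dob_day_imputed)
  # no birth doses: first day of the month
  co <- impute_birth_day(mk(NA, list(DPT1 = as.Date("1990-05-02"))), sched)
  expect_equal(co$children$dob, as.Date("1990-03-01"))
  # birth dose dated outside the birth month: first day of the month
  co <- impute_birth_day(mk(NA, list(BCG = as.Date("1990-05-02"))), sched)
  expect_equal(co$children$dob, as.Date("1990-03-01"))
  # day present: untouched
  co <- impute_birth_day(mk(10L, list(BCG = as.Date("1990-03-15"))), sched)
  expect_equal(co$children$dob, as.Date("1990-03-10"))
  expect_false(co$children$dob_day_imputed)
})

test_that("cleaning demotes impossible and out-of-order dates to ticks", {
  sched <- test_schedule()
  dob <- as.Date("2017-03-01")
  co <- make_cohort(synth_child(
    dob = dob,
    dates = list(BCG = as.Date("2017-02-20"),        # before birth
                 OPV1 = as.Date("2019-01-01"),       # after survey
                 DPT1 = as.Date("2017-06-01"),
                 DPT2 = as.Date("2017-05-20"),       # out of order
                 DPT3 = as.Date("2017-07-01"))))     # checked vs DPT1
  cl <- clean_dates(co, sched)
  ev <- cl$evidence
  g <- function(d, col) ev[[col]][ev$dose == d]
  expect_equal(g("BCG", "kind"), "TICK")
  expect_equal(g("BCG", "flags"), "BEFORE_BIRTH")
  expect_equal(g("OPV1", "kind"), "TICK")
  expect_equal(g("OPV1", "flags"), "AFTER_SURVEY")
  expect_equal(g("DPT2", "kind"), "TICK")
  expect_equal(g("DPT2", "flags"), "OUT_OF_ORDER")
  # DPT3 is re-checked against the last retained dose (DPT1) and kept
  expect_equal(g("DPT3", "kind"), "DATE")
  expect_equal(g("DPT3", "date"), as.Date("2017-07-01"))
})

test_that("duplicate consecutive series dates demote the later dose", {
  sched <- test_schedule()
  co <- make_cohort(synth_child(
    dob = as.Date("2017-03-01"),
    dates = list(DPT1 = as.Date("2017-07-01"),
                 DPT2 = as.Date("2017-08-01"),
                 DPT3 = as.Date("2017-08-01"))))
  cl <- clean_dates(co, sched)
  ev <- cl$evidence
  expect_equal(ev$kind[ev$dose == "DPT3"], "TICK")
  expect_equal(ev$flags[ev$dose == "DPT3"], "DUPLICATE_DATE_IN_SERIES")
  expect_equal(ev$kind[ev$dose == "DPT2"], "DATE")
})

test_that("cleaning is idempotent, total, and preserves dose credit", {
  sched <- test_schedule()
  set.seed(7)
  g <- generate_cohort(synth_params(n_children = 120, seed = 11,
                                    date_error_rate = 0.3), sched)
  co <- impute_birth_day(g$cohort, sched)
  once <- clean_dates(co, sched)
  twice <- clean_dates(once, sched)
  expect_identical(once$evidence, twice$evidence)
  # a clean record passes through unchanged
  ok <- make_cohort(synth_child(dates = list(BCG = 1L, DPT1 = 60L,
                                             DPT2 = 90L, DPT3 = 120L)))
  expect_identical(clean_dates(ok, sched)$evidence, ok$evidence)
  # credit preserved: the multiset of doses with any evidence is unchanged
  before <- table(co$evidence$dose[co$evidence$kind != "NONE"])
  after <- table(once$evidence$dose[once$evidence$kind != "NONE"])
  expect_identical(before, after)
})

test_that("cohort selection applies the card, dob, age and dates filters", {
  sched <- test_schedule()
  svy <- as.Date("2018-09-01")
  kids <- list(
    ok = synth_child(id = "ok", dob = svy - 500,
                     dates = list(BCG = 1L)),
    nocard = synth_child(id = "nocard", dob = svy - 500, card = FALSE,
                         dates = list(BCG = 1L)),
    tickonly = synth_child(id = "tickonly", dob = svy - 500,
                           ticks = "BCG"),
    tooold = synth_child(id = "tooold", dob = seq(svy, by = "-26 months",
                                                  length.out = 2)[2L],
                         dates = list(BCG = 1L)),
    nodob = local({
      k <- synth_child(id = "nodob", dob = svy - 500,
                       dates = list(BCG = 1L))
      k$child$dob <- as.Date(NA)
      k
    })
  )
  co <- do.call(make_cohort, unname(kids))
  sel <- select_cohort(co)
  expect_equal(unname(sel$counts["included"]), 1L)
  expect_equal(unname(sel$counts["excluded_no_card"]), 1L)
  expect_equal(unname(sel$counts["excluded_no_dob"]), 1L)
  expect_equal(unname(sel$counts["excluded_age"]), 1L)
  expect_equal(unname(sel$counts["excluded_no_dates"]), 1L)
  expect_equal(sum(sel$counts), nrow(co$children))
  expect_equal(sel$cohort$children$child_id, "ok")
  expect_setequal(sel$exclusions$reason,
                  c("no_card", "no_dob", "age", "no_dates"))
})

test_that("completed-month ages adjust for the day of month", {
  expect_equal(age_completed_months(as.Date("2017-03-15"),
                                    as.Date("2018-03-14")), 11L)
  expect_equal(age_completed_months(as.Date("2017-03-15"),
                                    as.Date("2018-03-15")), 12L)
  expect_equal(age_completed_months(as.Date("2017-03-15"),
                                    as.Date("2019-03-14")), 23L)
})

test_that("a cohort round-trips through the CSV dialect", {
  sched <- test_schedule()
  g <- generate_cohort(synth_params(n_children = 40, seed = 3,
                                    date_error_rate = 0.1), sched)
  f <- tempfile(fileext = ".csv")
  write_cohort_csv(g$cohort, f)
  back <- read_children(f, sched)
  expect_equal(back$children$child_id, g$cohort$children$child_id)
  expect_equal(back$children$weight, round(g$cohort$children$weight, 15),
               tolerance = 1e-6)
  a <- g$cohort$evidence[order(g$cohort$evidence$child_id,
                               g$cohort$evidence$dose), ]
  b <- back$evidence[order(back$evidence$child_id, back$evidence$dose), ]
  expect_equal(a$dose, b$dose)
  expect_equal(a$kind, b$kind)
  expect_equal(a$date, b$date)
})
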