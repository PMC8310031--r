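test_that("VB1 counts dose-eligible visits across children", {
  sched <- test_schedule()
  # A: visits at 42 d {OPV1} (DPT1 missed) and 80 d {DPT1} -> 1 of 2
  # DPT1-eligible visits missed; B: 42 d {DPT1, OPV1} -> 0 of 1
  co <- make_cohort(
    synth_child(id = "A", dates = list(OPV1 = 42L, DPT1 = 80L)),
    synth_child(id = "B", dates = list(DPT1 = 42L, OPV1 = 42L)))
  vb <- visit_based(co, sched, "crude")
  dpt1 <- vb$per_dose[vb$per_dose$dose == "DPT1", ]
  expect_equal(dpt1$n_eligible_visits, 3L)
  expect_equal(dpt1$n_mosv, 1L)
  expect_equal(dpt1$vb1, 1 / 3)
  expect_equal(dpt1$vb1_weighted, 1 / 3)  # equal weights
})

test_that("two misses at every eligible visit give VB2 = 1, VB3 = 2", {
  sched <- test_schedule()
  # single visit at 42 d administering OPV1 only: BCG and DPT1 missed
  co <- make_cohort(synth_child(dates = list(OPV1 = 42L)))
  vb <- visit_based(co, sched, "crude")
  expect_equal(vb$overall$vb2, 1)
  expect_equal(vb$overall$vb3, 2)
  expect_equal(vb$overall$vb3_inverse, 0.5)
})

test_that("a cohort with no events reports zero VB and undefined 1/VB3", {
  sched <- test_schedule()
  co <- make_cohort(synth_child(dates = list(BCG = 0L, OPV1 = 42L,
                                             DPT1 = 42L, OPV2 = 70L,
                                             DPT2 = 70L, OPV3 = 98L,
                                             DPT3 = 98L, MCV1 = 273L)))
  vb <- visit_based(co, sched, "crude")
  expect_equal(vb$overall$vb2, 0)
  expect_equal(vb$overall$vb3, 0)
  expect_true(is.na(vb$overall$vb3_inverse))
  expect_true(all(vb$per_dose$n_mosv == 0L))
})

test_that("VB3 never falls below VB2 and zero denominators give NA", {
  sched <- test_schedule()
  g <- generate_cohort(synth_params(n_children = 150, seed = 31), sched)
  co <- prepare_cohort(g$cohort, sched)
  for (m in c("crude", "valid")) {
    vb <- visit_based(co, sched, m)
    expect_gte(vb$overall$vb3, vb$overall$vb2)
    expect_gte(vb$overall$vb3_weighted, vb$overall$vb2_weighted)
  }
  empty <- make_cohort(synth_child(ticks = "BCG"))
  vb0 <- visit_based(empty, sched, "crude")
  expect_true(is.na(vb0$overall$vb2))
  expect_equal(vb0$per_dose$n_eligible_visits, rep(0L, 8L))
})

test_that("CB2 splits children by correction status", {
  sched <- test_schedule()
  co <- make_cohort(
    # A: OPV1 missed at 42 d, received at 80 d -> corrected
    synth_child(id = "A", dates = list(DPT1 = 42L, OPV1 = 80L)),
    # B: OPV1 missed at 42 d, never received -> uncorrected
    synth_child(id = "B", dates = list(DPT1 = 42L, BCG = 0L)),
    # C: no event
    synth_child(id = "C", dates = list(BCG = 0L, OPV1 = 42L, DPT1 = 42L)))
  cb <- child_based(co, sched, "crude")
  ov <- cb$overall
  # B misses BCG too? no: BCG administered at 0 d. A misses BCG at both
  # visits (uncorrected) -> A is "some", B is "none"
  expect_equal(ov$n_children_eligible, 3L)
  expect_equal(ov$cb2, 2 / 3)
  expect_equal(ov$cb2_some_corrected, 1 / 3)
  expect_equal(ov$cb2_none_corrected, 1 / 3)
  expect_equal(ov$cb2_all_corrected, 0)
  # per-dose split sums to the headline CB1
  pd <- cb$per_dose
  expect_equal(pd$cb1_corrected + pd$cb1_uncorrected, pd$cb1)
  opv1 <- pd[pd$dose == "OPV1", ]
  expect_equal(opv1$n_children_eligible, 3L)
  expect_equal(opv1$cb1, 2 / 3)
  expect_equal(opv1$cb1_corrected, 1 / 3)
})

test_that("a cohort whose events are all corrected has no 'none' share", {
  sched <- test_schedule()
  co <- make_cohort(
    synth_child(id = "A", dates = list(DPT1 = 42L, OPV1 = 80L, BCG = 1L,
                                       DPT2 = 80L, OPV2 = 110L,
                                       DPT3 = 110L, OPV3 = 140L,
                                       MCV1 = 280L)))
  cb <- child_based(co, sched, "crude")
  expect_gt(cb$overall$cb2, 0)
  expect_equal(cb$overall$cb2_none_corrected, 0)
  expect_equal(cb$overall$cb2_some_corrected, 0)
  expect_equal(cb$overall$cb2, cb$overall$cb2_all_corrected)
})

test_that("counterfactual coverage credits doses due at attended visits", {
  sched <- test_schedule()
  co <- make_cohort(synth_child(dates = list(BCG = 42L, OPV1 = 100L,
                                             DPT1 = 100L)))
  pc <- potential_coverage(co, sched, "crude")
  g <- function(d, col) pc[[col]][pc$dose == d]
  # observed: BCG, OPV1, DPT1 only
  expect_equal(g("DPT2", "observed"), 0)
  # counterfactual: OPV1+DPT1 creditable at 42 d, so OPV2/DPT2 at 100 d
  expect_equal(g("DPT2", "potential"), 1)
  expect_equal(g("OPV2", "potential"), 1)
  expect_equal(g("DPT3", "potential"), 0)
  expect_equal(g("DPT1", "difference"), 0)
})

test_that("a fully vaccinated child gains nothing counterfactually", {
  sched <- test_schedule()
  co <- make_cohort(synth_child(dates = list(BCG = 0L, OPV1 = 42L,
                                             DPT1 = 42L, OPV2 = 70L,
                                             DPT2 = 70L, OPV3 = 98L,
                                             DPT3 = 98L, MCV1 = 273L)))
  for (m in c("crude", "valid")) {
    pc <- potential_coverage(co, sched, m)
    expect_equal(pc$observed, pc$potential)
    expect_true(all(pc$difference == 0))
  }
})

test_that("potential coverage never falls below observed", {
  sched <- test_schedule()
  for (seed in c(13, 77)) {
    g <- generate_cohort(synth_params(n_children = 150, seed = seed,
                                      date_error_rate = 0.05), sched)
    co <- prepare_cohort(g$cohort, sched)
    for (m in c("crude", "valid")) {
      pc <- potential_coverage(co, sched, m)
      expect_true(all(pc$potential >= pc$observed))
      expect_true(all(pc$potential_weighted >= pc$observed_weighted))
      expect_equal(pc$difference, pc$potential - pc$observed)
    }
  }
})

test_that("delay quantiles follow the inverse-ECDF rule", {
  ev <- data.frame(child_id = letters[1:4], dose = "DPT1",
                   corrected = TRUE, delay_days = c(10L, 20L, 30L, 40L),
                   stringsAsFactors = FALSE)
  tt <- time_to_correction(ev, "DPT1")
  expect_equal(unname(tt$quantiles), c(10, 20, 30, 40))
  expect_equal(tt$ecdf$cum_fraction, c(0.25, 0.5, 0.75, 1))
  expect_true(tt$small_n)

  one <- time_to_correction(data.frame(child_id = "a", dose = "X",
                                       corrected = TRUE, delay_days = 28L),
                            "X")
  expect_equal(unname(one$quantiles[["q50"]]), 28)
  expect_equal(nrow(one$ecdf), 1L)
  expect_equal(one$ecdf$cum_fraction, 1)
})

test_that("small-n masking triggers strictly below 25 corrected events", {
  mk <- function(n) data.frame(child_id = as.character(seq_len(n)),
                               dose = rep("D", n),
                               corrected = rep(TRUE, n),
                               delay_days = seq_len(n),
                               stringsAsFactors = FALSE)
  expect_true(time_to_correction(mk(24L), "D")$small_n)
  expect_false(time_to_correction(mk(25L), "D")$small_n)
  empty <- time_to_correction(mk(0L), "D")
  expect_equal(empty$n_corrected, 0L)
  expect_true(all(is.na(empty$quantiles)))
})

test_that("with equal weights the weighted estimates coincide exactly", {
  sched <- test_schedule()
  g <- generate_cohort(synth_params(n_children = 150, seed = 41,
                                    weight_model = "equal"), sched)
  co <- prepare_cohort(g$cohort, sched)
  vb <- visit_based(co, sched, "crude")
  expect_equal(vb$per_dose$vb1_weighted, vb$per_dose$vb1)
  expect_equal(vb$overall$vb2_weighted, vb$overall$vb2)
  expect_equal(vb$overall$vb3_weighted, vb$overall$vb3)
  cb <- child_based(co, sched, "crude")
  expect_equal(cb$overall$cb2_weighted, cb$overall$cb2)
  expect_equal(cb$per_dose$cb1_weighted, cb$per_dose$cb1)
  pc <- potential_coverage(co, sched, "crude")
  expect_equal(pc$observed_weighted, pc$observed)
  expect_equal(pc$potential_weighted, pc$potential)
})

test_that("stratified counts add up and super-strata behave", {
  sched <- test_schedule()
  g <- generate_cohort(synth_params(n_children = 200, seed = 55), sched)
  co <- prepare_cohort(g$cohort, sched)
  tab <- stratified_run(co, sched, "crude")
  vb1 <- tab$vb1
  for (d in unique(vb1$dose)) {
    sub <- vb1[vb1$dose == d, ]
    expect_equal(sub$n_mosv[sub$stratum == "overall"],
                 sum(sub$n_mosv[sub$stratum != "overall"]))
    expect_equal(sub$n_eligible_visits[sub$stratum == "overall"],
                 sum(sub$n_eligible_visits[sub$stratum != "overall"]))
  }
  # a super-stratum covering everything equals the overall rows
  tab2 <- stratified_run(co, sched, "crude",
                         strata_spec = list(all = c("north", "south")))
  ov <- tab2$vb1[tab2$vb1$stratum == "overall",
                 setdiff(names(tab2$vb1), "stratum")]
  al <- tab2$vb1[tab2$vb1$stratum == "all",
                 setdiff(names(tab2$vb1), "stratum")]
  rownames(ov) <- rownames(al) <- NULL
  expect_equal(ov, al)
})

test_that("children outside every super-stratum stay in national results", {
  sched <- test_schedule()
  g <- generate_cohort(synth_params(
    n_children = 150, seed = 67,
    strata = c(north = 0.4, south = 0.4, central = 0.2)), sched)
  co <- prepare_cohort(g$cohort, sched)
  spec <- list(north = "north", south = "south")
  tab <- stratified_run(co, sched, "crude", strata_spec = spec)
  ov <- tab$cb_overall
  n_overall <- ov$n_children_eligible[ov$stratum == "overall"]
  n_sub <- sum(ov$n_children_eligible[ov$stratum != "overall"])
  expect_gt(n_overall, n_sub)  # central children only in the overall rows
  expect_error(
    stratified_run(co, sched, "crude", strata_spec = list(x = "east")),
    "unknown stratum")
})
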