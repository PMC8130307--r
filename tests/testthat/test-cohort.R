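cohort_store <- function() {
  make_store(
    10,
    drug_exposures = data.frame(
      person_id = c("p01", "p01", "p02", "p03", "p04"),
      drug_code = c("target", "target", "target", "cisplatin", "target"),
      start_date = c("2015-01-01", "2016-05-01", "2018-12-01", "2015-01-01",
                     "2014-06-01")),
    conditions = data.frame(
      person_id = c("p01", "p02", "p04", "p05", "p06"),
      condition_code = c("EAR_DISORDER", "EAR_DISORDER", "EAR_DISORDER",
                         "MS", "EAR_SURGERY"),
      date = c("2015-04-11", "2018-12-01", "2015-08-05", "2014-02-01",
               "2014-02-01")))
}

test_that("case definition filters in order and tallies each step once", {
  st <- cohort_store()
  cd <- case_definition(systemic_disease_codes = "MS",
                        ear_surgery_codes = "EAR_SURGERY",
                        ototoxic_drug_codes = "cisplatin")
  res <- apply_case_definition(st, cd)
  expect_equal(unname(res$tally),
               c(1, 1, 1))  # p05 systemic, p06 surgery, p03 ototoxic
  expect_equal(nrow(res$store$persons), 7)
  expect_false(any(c("p03", "p05", "p06") %in% res$store$persons$person_id))

  # empty exclusion sets leave the store unchanged
  res0 <- apply_case_definition(st, case_definition())
  expect_equal(unname(res0$tally), c(0, 0, 0))
  expect_equal(res0$store$persons, st$persons)

  # a person matching two criteria is counted at the first matching step
  st2 <- make_store(2,
    drug_exposures = data.frame(person_id = "p01", drug_code = "cisplatin",
                                start_date = "2015-01-01"),
    conditions = data.frame(person_id = "p01", condition_code = "MS",
                            date = "2015-01-01"))
  res2 <- apply_case_definition(st2, cd)
  expect_equal(unname(res2$tally), c(1, 0, 0))

  # idempotence
  res3 <- apply_case_definition(res$store, cd)
  expect_equal(unname(res3$tally), c(0, 0, 0))
  expect_equal(res3$store$persons, res$store$persons)
})

test_that("analysis table anchors at first prescription and applies the window", {
  st <- cohort_store()
  tab <- build_analysis_table(st, "target", "EAR_DISORDER")
  exp_rows <- tab[tab$exposed == 1, ]
  expect_setequal(exp_rows$person_id, c("p01", "p02", "p04"))

  p01 <- exp_rows[exp_rows$person_id == "p01", ]
  expect_equal(p01$index_date, as.Date("2015-01-01"))  # first of two scripts
  expect_equal(p01$time_days, 100)
  expect_equal(p01$event, 1L)
  expect_equal(p01$outcome, 1L)

  # event after the window: still a Cox event, but outcome flag 0
  p04 <- exp_rows[exp_rows$person_id == "p04", ]
  expect_equal(p04$time_days, as.numeric(as.Date("2015-08-05") -
                                           as.Date("2014-06-01")))
  expect_gt(p04$time_days, 365)
  expect_equal(p04$event, 1L)
  expect_equal(p04$outcome, 0L)

  # same-day event gets time 1 (p02 indexed and diagnosed 2018-12-01)
  p02 <- exp_rows[exp_rows$person_id == "p02", ]
  expect_equal(p02$time_days, 1)
  expect_equal(p02$event, 1L)

  # censoring arithmetic for a no-event patient
  st3 <- make_store(2, drug_exposures = data.frame(
    person_id = "p01", drug_code = "d", start_date = "2018-12-01"))
  t3 <- build_analysis_table(st3, "d", "EAR_DISORDER")
  expect_equal(t3$time_days[t3$exposed == 1], 30)
  expect_equal(t3$event[t3$exposed == 1], 0L)

  # unexposed pool flagged with NA outcome columns
  expect_true(all(is.na(tab$time_days[tab$exposed == 0])))
  expect_warning(build_analysis_table(st, "nosuchdrug", "EAR_DISORDER"),
                 "no persons exposed")
})

test_that("no-event follow-up always spans index to study end", {
  set.seed(31)
  st <- generate_ehr(ehr_sim_config(
    n_patients = 300, seed = 31,
    drugs = list(d = list(prevalence = 0.3, log_hr = 0)),
    baseline_event_hazard = 2e-4))
  tab <- build_analysis_table(st, "d", "EAR_DISORDER")
  noev <- tab[tab$exposed == 1 & tab$event == 0, ]
  expect_gt(nrow(noev), 0)
  expect_equal(noev$time_days,
               pmax(1, as.numeric(st$study_end - noev$index_date)))
  # outcome=1 implies event within the window
  ev <- tab[tab$exposed == 1 & tab$outcome == 1, ]
  expect_true(all(ev$event == 1L & ev$time_days <= 365))
})

test_that("controls inherit their partner's index date and own outcomes", {
  st <- make_store(
    4,
    drug_exposures = data.frame(person_id = "p01", drug_code = "d",
                                start_date = "2016-03-01"),
    conditions = data.frame(person_id = c("p02", "p03"),
                            condition_code = "EAR_DISORDER",
                            date = c("2016-04-20", "2015-01-01")))
  tab <- build_analysis_table(st, "d", "EAR_DISORDER")
  pairs <- data.frame(exposed_id = "p01", control_id = "p02")
  ctrl <- assign_control_index_dates(pairs, tab, st, "EAR_DISORDER")
  expect_equal(ctrl$index_date, as.Date("2016-03-01"))
  expect_equal(ctrl$event, 1L)
  expect_equal(ctrl$time_days, 50)
  expect_equal(ctrl$outcome, 1L)

  # control whose only event precedes the index is event-free going forward
  ctrl2 <- assign_control_index_dates(
    data.frame(exposed_id = "p01", control_id = "p03"), tab, st,
    "EAR_DISORDER")
  expect_equal(ctrl2$event, 0L)
  expect_equal(ctrl2$time_days,
               as.numeric(as.Date("2018-12-31") - as.Date("2016-03-01")))

  # empty pair set
  expect_equal(nrow(assign_control_index_dates(
    data.frame(exposed_id = character(), control_id = character()),
    tab, st, "EAR_DISORDER")), 0)
})

test_that("diagnosis and PTA outcome streams are computable independently", {
  meas <- data.frame(person_id = "p02", date = "2016-06-01",
                     measurement_code = "PTA_CLASS",
                     value_categorical = "L", value_numeric = NA_real_)
  st <- make_store(
    3,
    drug_exposures = data.frame(person_id = c("p01", "p02"), drug_code = "d",
                                start_date = "2016-01-01"),
    conditions = data.frame(person_id = "p01",
                            condition_code = "EAR_DISORDER",
                            date = "2016-02-01"),
    measurements = meas)
  t_dx <- build_analysis_table(st, "d", "EAR_DISORDER",
                               outcome_source = "diagnosis")
  t_pta <- build_analysis_table(st, "d", "EAR_DISORDER",
                                outcome_source = "pta")
  t_both <- build_analysis_table(st, "d", "EAR_DISORDER",
                                 outcome_source = "both")
  get_ev <- function(t, id) t$event[t$person_id == id]
  expect_equal(get_ev(t_dx, "p01"), 1L); expect_equal(get_ev(t_dx, "p02"), 0L)
  expect_equal(get_ev(t_pta, "p01"), 0L); expect_equal(get_ev(t_pta, "p02"), 1L)
  expect_equal(get_ev(t_both, "p01"), 1L)
  expect_equal(get_ev(t_both, "p02"), 1L)
})

test_that("target-drug selection applies all four conditions", {
  fitted <- data.frame(
    drug_code = c("nortriptyline", "cimetidine", "borderline", "known",
                  "insig"),
    hr = c(8.06, 0.74, 1.5, 3.0, 1.4),
    p_value = c(0.001, 0.01, 0.04, 0.001, 0.20),
    n_exposed = c(255, 500, 100, 400, 300))
  out <- select_target_drugs(fitted$drug_code, fitted, known_ototoxic = "known")
  expect_equal(out$selected,
               c(TRUE,    # HR>1, p<0.05, not listed, n>100
                 FALSE,   # HR<1
                 FALSE,   # n_exposed must exceed 100
                 FALSE,   # on the known-ototoxic list
                 FALSE))  # p >= 0.05
  expect_error(select_target_drugs(c("nortriptyline", "missing"), fitted, NULL),
               "missing", class = "adrsignal_validation_error")
})
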