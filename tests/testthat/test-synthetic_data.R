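test_that("config validation catches impossible parameters", {
  expect_error(ehr_sim_config(n_patients = 0), "n_patients",
               class = "adrsignal_validation_error")
  expect_error(ehr_sim_config(baseline_event_hazard = 0), "hazard",
               class = "adrsignal_validation_error")
  expect_error(ehr_sim_config(drugs = list(d = list(prevalence = 1.2,
                                                    log_hr = 0))),
               "prevalence", class = "adrsignal_validation_error")
  expect_error(srs_sim_config(n_reports = -1), "n_reports",
               class = "adrsignal_validation_error")
  expect_error(srs_sim_config(drug_probs = c(d = 0)), "probabilities",
               class = "adrsignal_validation_error")
  # a planted pair referencing an unknown drug fails fast
  expect_error(srs_sim_config(planted = data.frame(
    drug = "ghost", reaction = "ear_disorder", log_ror = 1)),
    "planted", class = "adrsignal_validation_error")
  # incompatible planted odds ratio (infinite) is rejected
  expect_error(srs_sim_config(planted = data.frame(
    drug = "drug_a", reaction = "ear_disorder", log_ror = Inf)),
    "odds ratio", class = "adrsignal_validation_error")
})

test_that("generators are deterministic given the seed", {
  cfg <- ehr_sim_config(n_patients = 10, seed = 99,
                        drugs = list(d = list(prevalence = 0.4, log_hr = 1)),
                        pta = list(fraction = 0.5))
  s1 <- generate_audiograms(generate_ehr(cfg), cfg)
  s2 <- generate_audiograms(generate_ehr(cfg), cfg)
  expect_identical(s1$persons, s2$persons)
  expect_identical(s1$drug_exposures, s2$drug_exposures)
  expect_identical(s1$conditions, s2$conditions)
  expect_identical(s1$measurements, s2$measurements)
  expect_identical(s1$audiograms, s2$audiograms)

  scfg <- srs_sim_config(n_reports = 500, seed = 7,
                         drug_probs = c(a = 0.1, b = 0.05),
                         reaction_probs = c(r = 0.05))
  expect_identical(generate_srs(scfg), generate_srs(scfg))
})

test_that("empirical exposure prevalence is calibrated to the config", {
  n <- 20000
  for (prev in c(0.02, 0.10)) {
    cfg <- ehr_sim_config(
      n_patients = n, seed = 3,
      drugs = list(d = list(prevalence = prev, log_hr = 0)),
      exposure_coefs = c(age = 0.04, visits = 0.02))
    st <- generate_ehr(cfg)
    phat <- length(unique(st$drug_exposures$person_id)) / n
    se <- sqrt(prev * (1 - prev) / n)
    expect_lt(abs(phat - prev), 3 * se)
  }
})

test_that("srs marginals and planted reporting odds ratio are honoured", {
  cfg <- srs_sim_config(
    n_reports = 200000, seed = 11,
    drug_probs = c(nortriptyline = 0.02, other = 0.05),
    reaction_probs = c(ear_disorder = 0.02),
    planted = data.frame(drug = "nortriptyline", reaction = "ear_disorder",
                         log_ror = log(1.94)))
  reps <- generate_srs(cfg)
  # marginal calibration within 3 SE
  for (nm in names(cfg$drug_probs)) {
    p <- cfg$drug_probs[[nm]]
    phat <- mean(has_code_vec(reps$drugs, nm))
    expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / nrow(reps)))
  }
  est <- ror(build_contingency(reps, "nortriptyline", "ear_disorder"))
  expect_gt(est$estimate, 1.8); expect_lt(est$estimate, 2.1)
  expect_true(est$ci_low < 1.94 && 1.94 < est$ci_high)
  # unplanted drug stays null
  est0 <- ror(build_contingency(reps, "other", "ear_disorder"))
  expect_true(est0$ci_low < 1 && 1 < est0$ci_high)
})

test_that("null planted reporting association yields a CI covering 1", {
  cfg <- srs_sim_config(n_reports = 50000, seed = 21,
                        drug_probs = c(a = 0.03),
                        reaction_probs = c(r = 0.03),
                        planted = data.frame(drug = "a", reaction = "r",
                                             log_ror = 0))
  est <- ror(build_contingency(generate_srs(cfg), "a", "r"))
  expect_true(est$ci_low < 1 && 1 < est$ci_high)
})

test_that("srs reports survive a csv round trip", {
  reps <- generate_srs(srs_sim_config(n_reports = 200, seed = 5,
                                      drug_probs = c(a = 0.2, b = 0.1),
                                      reaction_probs = c(r = 0.1)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_srs_reports(reps, f)
  expect_equal(as.data.frame(read_srs_reports(f)), as.data.frame(reps))
})

test_that("planted survival effect is recovered through the full EHR arm", {
  cfg <- ehr_sim_config(
    n_patients = 5000, seed = 17,
    drugs = list(d = list(prevalence = 0.2, log_hr = log(2))),
    baseline_event_hazard = 2e-4)
  st <- generate_ehr(cfg)
  tab <- build_analysis_table(st, "d", "EAR_DISORDER")
  mc <- match_1to1(fit_propensity(tab), tab)
  rows <- rbind(tab[match(mc$pairs$exposed_id, tab$person_id), ],
                assign_control_index_dates(mc, tab, st, "EAR_DISORDER"))
  fit <- fit_cox(rows)
  expect_gt(fit$hr, 1.8); expect_lt(fit$hr, 2.2)
})

test_that("audiogram simulation responds to the planted elevation probability", {
  base <- ehr_sim_config(
    n_patients = 300, seed = 23,
    drugs = list(d = list(prevalence = 0.5, log_hr = 0)),
    pta = list(fraction = 1, baseline_abnormal_prob = 0,
               exposed_abnormal_prob = 0, effect_drugs = "d"))
  st0 <- generate_audiograms(generate_ehr(base), base)
  expect_true(all(st0$measurements$value_categorical == "NORMAL"))

  allabn <- base
  allabn$pta$baseline_abnormal_prob <- 1
  allabn$pta$exposed_abnormal_prob <- 1
  st1 <- generate_audiograms(generate_ehr(allabn), allabn)
  expect_true(all(st1$measurements$value_categorical != "NORMAL"))

  # planted PTA-only effect still produces an elevated hazard ratio through
  # the abnormal-hearing-test outcome stream
  pta_eff <- ehr_sim_config(
    n_patients = 6000, seed = 29,
    drugs = list(d = list(prevalence = 0.2, log_hr = 0)),
    baseline_event_hazard = 1e-6,
    pta = list(fraction = 0.5, baseline_abnormal_prob = 0.03,
               exposed_abnormal_prob = 0.25, effect_drugs = "d"))
  st2 <- generate_audiograms(generate_ehr(pta_eff), pta_eff)
  tab <- build_analysis_table(st2, "d", "EAR_DISORDER",
                              outcome_source = "pta")
  mc <- match_1to1(fit_propensity(tab), tab)
  rows <- rbind(tab[match(mc$pairs$exposed_id, tab$person_id), ],
                assign_control_index_dates(mc, tab, st2, "EAR_DISORDER",
                                           outcome_source = "pta"))
  fit <- fit_cox(rows)
  expect_gt(fit$hr, 1)
  expect_lt(fit$p_value, 0.05)
})
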