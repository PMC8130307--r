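#' Configuration for the synthetic EHR generator
#'
#' Describes a hospital-style cohort with covariate-confounded drug exposure
#' and time-to-event ear-disorder outcomes. Covariate distributions default to
#' a middle-aged outpatient population (age about 52 +/- 16 years, about
#' 10 +/- 9 outpatient visits, about 2 +/- 6 hospital days).
#'
#' @param n_patients number of patients.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @param study_start,study_end observation window.
#' @param drugs named list; each element is `list(prevalence =, log_hr =)`
#'   giving the exposure prevalence and the true log hazard ratio on the
#'   ear-disorder outcome for that drug.
#' @param baseline_event_hazard baseline outcome hazard in events per
#'   person-day for an average unexposed patient.
#' @param exposure_coefs,outcome_coefs named numeric vectors
#'   (`sex_male`, `age`, `visits`, `hospitalization`): log-odds (exposure) and
#'   log-hazard (outcome) effects per unit of the mean-centred covariate.
#'   Nonzero values in both make the covariate a confounder.
#' @param outcome_code condition code written for ear-disorder events.
#' @param pta list controlling audiometry simulation: `fraction` of patients
#'   with a hearing test, `baseline_abnormal_prob`, `exposed_abnormal_prob`
#'   (applies to patients exposed to `effect_drugs`, tested after exposure),
#'   `effect_drugs` character vector.
#' @return an `ehr_sim_config` object.
#' @export
ehr_sim_config <- function(n_patients = 50000, seed = 1,
                           study_start = "2014-01-01", study_end = "2018-12-31",
                           drugs = list(drug_a = list(prevalence = 0.05,
                                                      log_hr = 0)),
                           baseline_event_hazard = 5e-5,
                           exposure_coefs = c(sex_male = 0, age = 0, visits = 0,
                                              hospitalization = 0),
                           outcome_coefs = c(sex_male = 0, age = 0, visits = 0,
                                             hospitalization = 0),
                           outcome_code = "EAR_DISORDER",
                           pta = list(fraction = 0, baseline_abnormal_prob = 0.05,
                                      exposed_abnormal_prob = 0.05,
                                      effect_drugs = character())) {
  cfg <- structure(list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    study_start = as_iso_date(study_start), study_end = as_iso_date(study_end),
    drugs = drugs, baseline_event_hazard = baseline_event_hazard,
    exposure_coefs = complete_coefs(exposure_coefs),
    outcome_coefs = complete_coefs(outcome_coefs),
    outcome_code = outcome_code,
    pta = utils::modifyList(list(fraction = 0, baseline_abnormal_prob = 0.05,
                                 exposed_abnormal_prob = 0.05,
                                 effect_drugs = character()), pta)
  ), class = "ehr_sim_config")
  if (cfg$n_patients <= 0) stop_validation("n_patients must be > 0")
  if (cfg$baseline_event_hazard <= 0) stop_validation("hazard must be > 0")
  prevs <- vapply(cfg$drugs, `[[`, 0, "prevalence")
  if (any(prevs <= 0 | prevs >= 1)) {
    stop_validation("exposure prevalences must lie in (0, 1)")
  }
  pr <- unlist(cfg$pta[c("fraction", "baseline_abnormal_prob",
                         "exposed_abnormal_prob")])
  if (any(pr < 0 | pr > 1)) stop_validation("PTA probabilities must be in [0,1]")
  cfg
}

complete_coefs <- function(x) {
  full <- c(sex_male = 0, age = 0, visits = 0, hospitalization = 0)
  full[names(x)] <- x
  full
}

# covariate matrix centred at the population means used by the generator
centred_covariates <- function(persons, index_year = NULL) {
  age <- if (is.null(index_year)) 2014 - persons$birth_year
         else index_year - persons$birth_year
  cbind(sex_male = as.numeric(persons$sex == "male") - 0.5,
        age = age - 52,
        visits = persons$n_outpatient_visits - 10,
        hospitalization = persons$hospitalization_days - 2)
}

# intercept such that mean exposure probability hits the target prevalence
calibrate_intercept <- function(lp, prevalence) {
  stats::uniroot(function(a) mean(stats::plogis(a + lp)) - prevalence,
                 interval = c(-30, 30), tol = 1e-10)$root
}

#' Generate a synthetic EHR cohort
#'
#' Simulates persons, confounded drug exposures and ear-disorder condition
#' occurrences. Exposure is assigned by a logistic model on the four matching
#' covariates; each exposed patient receives a single index prescription at
#' their entry date. Outcome events arise from a homogeneous Poisson process
#' over each patient's window at rate
#' `baseline_event_hazard * exp(outcome_coefs . x + sum(log_hr * exposed))`,
#' so time from any index date to the first subsequent event is exponential
#' with that rate (the proportional-hazards structure the downstream Cox model
#' assumes).
#'
#' @param config an [ehr_sim_config()].
#' @return a [cdm_store()]; patient entry dates are attached as attribute
#'   `"entry_dates"`.
#' @export
generate_ehr <- function(config) {
  stopifnot(inherits(config, "ehr_sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  persons <- data.frame(
    person_id = sprintf("P%07d", seq_len(n)),
    sex = ifelse(stats::runif(n) < 0.5, "male", "female"),
    birth_year = NA_integer_,
    n_outpatient_visits = stats::rnbinom(n, mu = 10, size = 1.41),
    hospitalization_days = stats::rnbinom(n, mu = 2, size = 0.118),
    stringsAsFactors = FALSE
  )
  age <- pmin(pmax(round(stats::rnorm(n, 52, 16)), 18), 90)
  persons$birth_year <- as.integer(2014 - age)

  window_days <- as.integer(config$study_end - config$study_start)
  entry <- config$study_start + sample.int(window_days + 1L, n, replace = TRUE) - 1L

  x <- centred_covariates(persons)
  exposed <- matrix(FALSE, n, length(config$drugs),
                    dimnames = list(NULL, names(config$drugs)))
  for (d in names(config$drugs)) {
    lp <- drop(x %*% config$exposure_coefs)
    a <- calibrate_intercept(lp, config$drugs[[d]]$prevalence)
    exposed[, d] <- stats::runif(n) < stats::plogis(a + lp)
  }
  drug_rows <- do.call(rbind, lapply(names(config$drugs), function(d) {
    idx <- which(exposed[, d])
    data.frame(person_id = persons$person_id[idx], drug_code = d,
               start_date = entry[idx], stringsAsFactors = FALSE)
  }))

  log_hr_total <- drop(exposed %*% vapply(config$drugs, `[[`, 0, "log_hr"))
  rate <- config$baseline_event_hazard *
    exp(drop(x %*% config$outcome_coefs) + log_hr_total)
  # homogeneous Poisson event process over the WHOLE study window, so that
  # time from any index date (own or inherited by a matched control) to the
  # first subsequent event is exponential at the person's rate
  dur <- as.numeric(config$study_end - config$study_start)
  n_events <- stats::rpois(n, rate * dur)
  ev_person <- rep(seq_len(n), n_events)
  cond_rows <- if (length(ev_person) > 0) {
    data.frame(person_id = persons$person_id[ev_person],
               condition_code = config$outcome_code,
               date = config$study_start +
                 ceiling(stats::runif(length(ev_person)) * dur),
               stringsAsFactors = FALSE)
  } else NULL

  store <- cdm_store(persons = persons, drug_exposures = drug_rows,
                     conditions = cond_rows,
                     study_start = config$study_start,
                     study_end = config$study_end)
  attr(store, "entry_dates") <-
    stats::setNames(entry, persons$person_id)
  store
}

#' Attach simulated audiograms to a synthetic EHR store
#'
#' Gives a configured fraction of patients one pure-tone audiometry test.
#' Patients exposed to a drug in `config$pta$effect_drugs` are tested after
#' their first exposure and turn abnormal with `exposed_abnormal_prob`; all
#' other tested patients use `baseline_abnormal_prob`. Thresholds are drawn on
#' the clinical 5 dB grid; abnormal ears carry at least one threshold above
#' 20 dB HL. The raw audiograms are kept in `store$audiograms` and their
#' categorical classification is appended to the measurement table.
#'
#' @param store a [cdm_store()] from [generate_ehr()].
#' @param config the same [ehr_sim_config()].
#' @return the store with `measurements` extended and `audiograms` attached.
#' @export
generate_audiograms <- function(store, config) {
  stopifnot(inherits(store, "cdm_store"), inherits(config, "ehr_sim_config"))
  pta <- config$pta
  if (pta$fraction <= 0 || nrow(store$persons) == 0) return(store)
  set.seed(config$seed + 1L)
  n_tested <- max(1L, round(pta$fraction * nrow(store$persons)))
  tested <- sort(sample(store$persons$person_id, n_tested))

  first_eff <- store$drug_exposures[
    store$drug_exposures$drug_code %in% pta$effect_drugs, ]
  first_exposure <- if (nrow(first_eff) > 0) {
    tapply(first_eff$start_date, first_eff$person_id, min)
  } else NULL

  normal_ear <- function() pmin(pmax(5 * round(stats::rnorm(6, 10, 3) / 5), -10), 20)
  abnormal_ear <- function() {
    th <- normal_ear()
    k <- sample.int(6, 1)
    hi <- sample.int(6, k)
    th[hi] <- pmin(pmax(5 * round(stats::rnorm(k, 40, 10) / 5), 25), 120)
    th
  }
  rows <- lapply(tested, function(pid) {
    exp_date <- if (!is.null(first_exposure) && pid %in% names(first_exposure)) {
      as.Date(first_exposure[[pid]], origin = "1970-01-01")
    } else NULL
    if (!is.null(exp_date)) {
      gap <- as.numeric(store$study_end - exp_date)
      date <- exp_date + ceiling(stats::runif(1) * max(gap, 1))
      p_abn <- pta$exposed_abnormal_prob
    } else {
      date <- store$study_start +
        sample.int(as.integer(store$study_end - store$study_start), 1)
      p_abn <- pta$baseline_abnormal_prob
    }
    if (stats::runif(1) < p_abn) {
      pattern <- sample(c("L", "R", "LR"), 1, prob = c(0.25, 0.25, 0.5))
      lt <- if (pattern %in% c("L", "LR")) abnormal_ear() else normal_ear()
      rt <- if (pattern %in% c("R", "LR")) abnormal_ear() else normal_ear()
    } else {
      lt <- normal_ear(); rt <- normal_ear()
    }
    data.frame(person_id = pid, date = date, ear = c("left", "right"),
               rbind(lt, rt), stringsAsFactors = FALSE, row.names = NULL)
  })
  audiograms <- do.call(rbind, rows)
  names(audiograms)[4:9] <- paste0("f", PTA_FREQUENCIES)
  meas <- audiograms_to_measurements(audiograms)
  store$measurements <- rbind(store$measurements, meas)
  store$audiograms <- audiograms
  store
}

#' Configuration for the synthetic spontaneous-report generator
#'
#' Describes an SRS corpus (already deduplicated, FAERS-style DEMO/DRUG/REAC
#' roles collapsed to one row per report) with independent background drug and
#' reaction reporting plus planted drug-reaction associations of known
#' reporting odds ratio.
#'
#' @param n_reports number of case reports.
#' @param seed integer seed.
#' @param drug_probs named numeric vector of marginal per-report drug
#'   mention probabilities.
#' @param reaction_probs named numeric vector of marginal reaction
#'   probabilities.
#' @param planted data frame with columns `drug`, `reaction`, `log_ror`; each
#'   reaction may be planted against at most one drug. The generator solves for
#'   the conditional reporting probabilities that achieve the requested
#'   population reporting odds ratio while preserving the reaction's marginal.
#' @param sex_probs probabilities for male/female/unknown (defaults follow the
#'   sex mix typical of a large SRS corpus).
#' @return an `srs_sim_config` object.
#' @export
srs_sim_config <- function(n_reports = 100000, seed = 1,
                           drug_probs = c(drug_a = 0.01),
                           reaction_probs = c(ear_disorder = 0.005),
                           planted = NULL,
                           sex_probs = c(male = 0.343, female = 0.551,
                                         unknown = 0.106)) {
  if (n_reports <= 0) stop_validation("n_reports must be > 0")
  if (any(drug_probs <= 0 | drug_probs >= 1) ||
      any(reaction_probs <= 0 | reaction_probs >= 1)) {
    stop_validation("marginal probabilities must lie in (0, 1)")
  }
  sex_probs <- sex_probs / sum(sex_probs)
  if (!is.null(planted)) {
    planted <- as.data.frame(planted, stringsAsFactors = FALSE)
    stopifnot(all(c("drug", "reaction", "log_ror") %in% names(planted)))
    if (anyDuplicated(planted$reaction)) {
      stop_validation("each reaction may be planted against at most one drug")
    }
    if (!all(planted$drug %in% names(drug_probs)) ||
        !all(planted$reaction %in% names(reaction_probs))) {
      stop_validation("planted pairs must reference configured drugs/reactions")
    }
    # solve conditionals up front so incompatible configs fail fast
    for (i in seq_len(nrow(planted))) {
      solve_planted_probs(drug_probs[[planted$drug[i]]],
                          reaction_probs[[planted$reaction[i]]],
                          exp(planted$log_ror[i]))
    }
  }
  structure(list(n_reports = as.integer(n_reports), seed = as.integer(seed),
                 drug_probs = drug_probs, reaction_probs = reaction_probs,
                 planted = planted, sex_probs = sex_probs),
            class = "srs_sim_config")
}

# Given P(drug)=p_d, marginal P(reaction)=p_r and a target odds ratio,
# find p1 = P(reaction | drug) and p0 = P(reaction | no drug) with
# odds(p1)/odds(p0) = or and p_d*p1 + (1-p_d)*p0 = p_r.
solve_planted_probs <- function(p_d, p_r, or) {
  if (!is.finite(or) || or <= 0) {
    stop_validation("planted odds ratio must be finite and positive")
  }
  f <- function(p0) {
    o0 <- p0 / (1 - p0)
    p1 <- or * o0 / (1 + or * o0)
    p_d * p1 + (1 - p_d) * p0 - p_r
  }
  eps <- 1e-12
  if (f(eps) > 0 || f(1 - eps) < 0) {
    stop_validation(
      "planted odds ratio %.3g incompatible with marginals P(drug)=%.3g, P(reaction)=%.3g",
      or, p_d, p_r)
  }
  p0 <- stats::uniroot(f, c(eps, 1 - eps), tol = 1e-12)$root
  o0 <- p0 / (1 - p0)
  p1 <- or * o0 / (1 + or * o0)
  if (p0 <= 0 || p0 >= 1 || p1 <= 0 || p1 >= 1) {
    stop_validation("required conditional probability outside (0, 1)")
  }
  c(p0 = p0, p1 = p1)
}

#' Generate a synthetic spontaneous-report corpus
#'
#' Draws independent drug mentions per report, then reaction mentions; for a
#' planted drug-reaction pair the reaction probability is raised among reports
#' mentioning the drug (and lowered otherwise) so the population reporting
#' odds ratio equals `exp(log_ror)` while the reaction keeps its configured
#' marginal frequency.
#'
#' @param config an [srs_sim_config()].
#' @return a data frame of class `srs_reports` with columns `report_id`, `sex`,
#'   `drugs`, `reactions` (pipe-delimited code sets).
#' @export
generate_srs <- function(config) {
  stopifnot(inherits(config, "srs_sim_config"))
  set.seed(config$seed)
  n <- config$n_reports
  sex <- sample(names(config$sex_probs), n, replace = TRUE,
                prob = config$sex_probs)
  drug_mat <- vapply(config$drug_probs,
                     function(p) stats::runif(n) < p, logical(n))
  drug_mat <- matrix(drug_mat, nrow = n,
                     dimnames = list(NULL, names(config$drug_probs)))
  reac_mat <- matrix(FALSE, n, length(config$reaction_probs),
                     dimnames = list(NULL, names(config$reaction_probs)))
  for (r in names(config$reaction_probs)) {
    pl <- config$planted
    i <- if (!is.null(pl)) match(r, pl$reaction) else NA_integer_
    if (!is.na(i)) {
      pp <- solve_planted_probs(config$drug_probs[[pl$drug[i]]],
                                config$reaction_probs[[r]],
                                exp(pl$log_ror[i]))
      p <- ifelse(drug_mat[, pl$drug[i]], pp[["p1"]], pp[["p0"]])
    } else {
      p <- config$reaction_probs[[r]]
    }
    reac_mat[, r] <- stats::runif(n) < p
  }
  join <- function(mat) {
    codes <- colnames(mat)
    apply(mat, 1, function(row) paste(codes[row], collapse = "|"))
  }
  structure(data.frame(report_id = sprintf("R%08d", seq_len(n)), sex = sex,
                       drugs = join(drug_mat), reactions = join(reac_mat),
                       stringsAsFactors = FALSE),
            class = c("srs_reports", "data.frame"))
}

#' Read/write spontaneous reports
#'
#' `srs_reports.csv` carries one row per report: `report_id`, `sex`, and
#' pipe-delimited `drugs` and `reactions` code sets.
#'
#' @param reports an `srs_reports` data frame.
#' @param file path to `srs_reports.csv`.
#' @return `read_srs_reports` returns an `srs_reports` data frame;
#'   `write_srs_reports` returns `file` invisibly.
#' @export
write_srs_reports <- function(reports, file) {
  utils::write.csv(as.data.frame(reports), file, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(file)
}

#' @rdname write_srs_reports
#' @export
read_srs_reports <- function(file) {
  x <- utils::read.csv(file, colClasses = "character")
  need <- c("report_id", "sex", "drugs", "reactions")
  if (!all(need %in% names(x))) {
    stop_validation("srs_reports file must have columns %s",
                    paste(need, collapse = ", "))
  }
  if (anyDuplicated(x$report_id)) stop_validation("duplicated report_id")
  x$drugs[is.na(x$drugs)] <- ""
  x$reactions[is.na(x$reactions)] <- ""
  structure(x[need], class = c("srs_reports", "data.frame"))
}
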