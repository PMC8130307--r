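#' Case definition: exclusion code lists
#'
#' Patients are excluded, in order, when they (1) carry a condition code for a
#' systemic disease known to cause ear disorders (e.g. multiple sclerosis,
#' Lyme disease, polyarteritis nodosa), (2) carry an ear-surgery code
#' (otitis media surgery), or (3) were exposed to a drug already known to be
#' ototoxic (e.g. interferon, cisplatin, cyclosporine, vinblastine).
#'
#' @param systemic_disease_codes,ear_surgery_codes character vectors of
#'   condition codes.
#' @param ototoxic_drug_codes character vector of drug codes.
#' @return an object of class `case_definition`.
#' @export
case_definition <- function(systemic_disease_codes = character(),
                            ear_surgery_codes = character(),
                            ototoxic_drug_codes = character()) {
  structure(list(systemic_disease_codes = as.character(systemic_disease_codes),
                 ear_surgery_codes = as.character(ear_surgery_codes),
                 ototoxic_drug_codes = as.character(ototoxic_drug_codes)),
            class = "case_definition")
}

#' Apply the case definition to a store
#'
#' Removes persons matching each exclusion criterion in the fixed order
#' systemic disease, then ear surgery, then known-ototoxic exposure. A person
#' matching several criteria is counted once, at the first matching step. All
#' child tables are filtered to the remaining persons, so the operation is
#' idempotent.
#'
#' @param store a [cdm_store()].
#' @param case_def a [case_definition()].
#' @return list with `store` (filtered) and `tally`, a named integer vector of
#'   exclusion counts per step (`systemic_disease`, `ear_surgery`,
#'   `ototoxic_drug`).
#' @export
apply_case_definition <- function(store, case_def) {
  stopifnot(inherits(store, "cdm_store"), inherits(case_def, "case_definition"))
  keep <- store$persons$person_id
  excl_cond <- function(codes) {
    unique(store$conditions$person_id[
      store$conditions$condition_code %in% codes])
  }
  step1 <- intersect(keep, excl_cond(case_def$systemic_disease_codes))
  keep <- setdiff(keep, step1)
  step2 <- intersect(keep, excl_cond(case_def$ear_surgery_codes))
  keep <- setdiff(keep, step2)
  step3 <- intersect(keep, unique(store$drug_exposures$person_id[
    store$drug_exposures$drug_code %in% case_def$ototoxic_drug_codes]))
  keep <- setdiff(keep, step3)
  filt <- function(tab) tab[tab$person_id %in% keep, , drop = FALSE]
  out <- store
  out$persons <- filt(store$persons)
  out$drug_exposures <- filt(store$drug_exposures)
  out$conditions <- filt(store$conditions)
  out$measurements <- filt(store$measurements)
  rownames(out$persons) <- rownames(out$drug_exposures) <-
    rownames(out$conditions) <- rownames(out$measurements) <- NULL
  list(store = out,
       tally = c(systemic_disease = length(step1),
                 ear_surgery = length(step2),
                 ototoxic_drug = length(step3)))
}

# first qualifying event date per person, strictly from index onward
first_event_dates <- function(store, outcome_codes,
                              outcome_source = c("both", "diagnosis", "pta")) {
  outcome_source <- match.arg(outcome_source)
  dx <- if (outcome_source %in% c("both", "diagnosis")) {
    store$conditions[store$conditions$condition_code %in% outcome_codes,
                     c("person_id", "date")]
  } else NULL
  pta <- if (outcome_source %in% c("both", "pta")) {
    m <- store$measurements
    m <- m[!is.na(m$value_categorical) &
             m$measurement_code == PTA_MEASUREMENT_CODE &
             m$value_categorical != "NORMAL", c("person_id", "date")]
    m
  } else NULL
  ev <- rbind(dx, pta)
  if (is.null(ev) || nrow(ev) == 0) {
    return(data.frame(person_id = character(), date = as.Date(character())))
  }
  ev[order(ev$person_id, ev$date), ]
}

# outcome/event/time for given persons and index dates
outcome_from_index <- function(events, person_id, index_date, study_end,
                               window_days) {
  event <- integer(length(person_id))
  outcome <- integer(length(person_id))
  time_days <- numeric(length(person_id))
  ev_split <- split(as.numeric(events$date), events$person_id)
  for (i in seq_along(person_id)) {
    idx <- as.numeric(index_date[i])
    ev <- ev_split[[person_id[i]]]
    ev <- ev[ev >= idx]
    if (length(ev) > 0) {
      event[i] <- 1L
      time_days[i] <- max(1, min(ev) - idx)
      outcome[i] <- as.integer(time_days[i] <= window_days)
    } else {
      event[i] <- 0L
      outcome[i] <- 0L
      time_days[i] <- max(1, as.numeric(study_end) - idx)
    }
  }
  data.frame(outcome = outcome, event = event, time_days = time_days)
}

analysis_covariates <- function(persons, index_year) {
  data.frame(sex = persons$sex,
             age = index_year - persons$birth_year,
             n_outpatient_visits = persons$n_outpatient_visits,
             hospitalization_days = persons$hospitalization_days,
             stringsAsFactors = FALSE)
}

#' Build the drug-level analysis table
#'
#' For one candidate drug: exposed patients are anchored at their first
#' prescription (the index date); the outcome event is the first ear-disorder
#' diagnosis or first abnormal hearing test on or after the index. `event`
#' flags any such event over full follow-up, `time_days` runs from the index to
#' the first event or to administrative censoring at `study_end`, and
#' `outcome` flags an event inside the `window_days` risk window (the 2x2-table
#' outcome). Same-day events get `time_days = 1`. Unexposed persons are
#' returned as the matching pool with `exposed = 0` and `NA` index/outcome
#' columns (filled in by [assign_control_index_dates()] after matching).
#'
#' @param store a filtered [cdm_store()].
#' @param drug_code candidate drug.
#' @param outcome_codes condition codes defining the ADR outcome.
#' @param window_days outcome risk window (default 365).
#' @param outcome_source use `"diagnosis"` codes, abnormal `"pta"` tests, or
#'   `"both"` (default) as the event source; the two streams are also
#'   analyzable independently.
#' @return data frame of analysis rows (`person_id`, `exposed`, `index_date`,
#'   `outcome`, `event`, `time_days`, covariates). Zero exposed persons yields
#'   an empty exposed stratum with a warning.
#' @export
build_analysis_table <- function(store, drug_code, outcome_codes,
                                 window_days = 365,
                                 outcome_source = c("both", "diagnosis", "pta")) {
  outcome_source <- match.arg(outcome_source)
  stopifnot(window_days > 0)
  de <- store$drug_exposures[store$drug_exposures$drug_code == drug_code, ]
  if (nrow(de) == 0) {
    warning(sprintf("no persons exposed to '%s'", drug_code))
  }
  index <- tapply(as.numeric(de$start_date), de$person_id, min)
  exposed_ids <- names(index)
  pe <- store$persons[match(exposed_ids, store$persons$person_id), ]
  events <- first_event_dates(store, outcome_codes, outcome_source)
  index_date <- as.Date(as.numeric(index), origin = "1970-01-01")
  exp_rows <- if (length(exposed_ids) > 0) {
    cbind(data.frame(person_id = exposed_ids, exposed = 1L,
                     index_date = index_date, stringsAsFactors = FALSE),
          outcome_from_index(events, exposed_ids, index_date, store$study_end,
                             window_days),
          analysis_covariates(pe, as.integer(format(index_date, "%Y"))))
  } else NULL
  pool_ids <- setdiff(store$persons$person_id, exposed_ids)
  pp <- store$persons[match(pool_ids, store$persons$person_id), ]
  # controls have no index date yet; age them at the exposed group's median
  # index year so propensity covariates are comparable across arms
  pool_year <- if (length(exposed_ids) > 0) {
    as.integer(stats::median(as.integer(format(index_date, "%Y"))))
  } else as.integer(format(store$study_start, "%Y"))
  pool_rows <- if (length(pool_ids) > 0) {
    cbind(data.frame(person_id = pool_ids, exposed = 0L,
                     index_date = as.Date(NA), stringsAsFactors = FALSE),
          data.frame(outcome = NA_integer_, event = NA_integer_,
                     time_days = NA_real_),
          analysis_covariates(pp, pool_year))
  } else NULL
  out <- rbind(exp_rows, pool_rows)
  rownames(out) <- NULL
  attr(out, "drug_code") <- drug_code
  attr(out, "window_days") <- window_days
  attr(out, "outcome_source") <- outcome_source
  out
}

#' Assign index dates and outcomes to matched controls
#'
#' Each matched control inherits the prescription (index) date of its exposed
#' partner; outcome, event and follow-up time are then computed exactly as for
#' exposed rows. Exposed rows without a match are dropped with a warning.
#'
#' @param cohort a [match_1to1()] result (or its `pairs` data frame with
#'   columns `exposed_id`, `control_id`).
#' @param analysis_table output of [build_analysis_table()] for the same drug.
#' @param store the [cdm_store()] the table was built from.
#' @param outcome_codes,window_days,outcome_source as in
#'   [build_analysis_table()]; defaults are read from the table's attributes.
#' @return data frame of control analysis rows (`exposed = 0`), aligned with
#'   the pair order.
#' @export
assign_control_index_dates <- function(cohort, analysis_table, store,
                                       outcome_codes,
                                       window_days = attr(analysis_table, "window_days"),
                                       outcome_source = attr(analysis_table, "outcome_source")) {
  pairs <- if (inherits(cohort, "matched_cohort")) cohort$pairs else cohort
  if (is.null(pairs) || nrow(pairs) == 0) {
    out <- analysis_table[0, ]
    return(out)
  }
  exp_rows <- analysis_table[analysis_table$exposed == 1L, ]
  m <- match(pairs$exposed_id, exp_rows$person_id)
  if (anyNA(m)) {
    warning("dropping pairs whose exposed member is not in the analysis table")
    pairs <- pairs[!is.na(m), ]
    m <- m[!is.na(m)]
  }
  index_date <- exp_rows$index_date[m]
  ctrl <- store$persons[match(pairs$control_id, store$persons$person_id), ]
  events <- first_event_dates(store, outcome_codes, outcome_source)
  out <- cbind(
    data.frame(person_id = pairs$control_id, exposed = 0L,
               index_date = index_date, stringsAsFactors = FALSE),
    outcome_from_index(events, pairs$control_id, index_date, store$study_end,
                       window_days),
    analysis_covariates(ctrl, as.integer(format(index_date, "%Y"))))
  rownames(out) <- NULL
  out
}

#' Target-drug selection filter
#'
#' A candidate becomes a drug of interest when its estimated hazard ratio
#' exceeds 1, the Wald p-value is below 0.05, it is not already on the known
#' ototoxic list, and it was prescribed to more than `min_exposed` patients.
#'
#' @param candidates character vector of candidate drug codes.
#' @param fitted_results data frame with one row per candidate: `drug_code`,
#'   `hr`, `p_value`, `n_exposed`.
#' @param known_ototoxic character vector of drugs already documented as
#'   ototoxic.
#' @param min_exposed exposure-count threshold (strictly more than; default
#'   100).
#' @return data frame with the inputs plus `in_known_ototoxic_list` and
#'   `selected`.
#' @export
select_target_drugs <- function(candidates, fitted_results, known_ototoxic,
                                min_exposed = 100) {
  m <- match(candidates, fitted_results$drug_code)
  if (anyNA(m)) {
    stop_validation("no fitted result for candidate(s): %s",
                    paste(candidates[is.na(m)], collapse = ", "))
  }
  r <- fitted_results[m, ]
  known <- r$drug_code %in% known_ototoxic
  data.frame(drug_code = r$drug_code, hr_estimate = r$hr, p_value = r$p_value,
             n_exposed = r$n_exposed, in_known_ototoxic_list = known,
             selected = r$hr > 1 & r$p_value < 0.05 & !known &
               r$n_exposed > min_exposed,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read a one-code-per-line list file
#'
#' Blank lines and `#` comments are ignored.
#'
#' @param file path.
#' @return character vector of codes.
#' @export
read_code_list <- function(file) {
  x <- trimws(readLines(file, warn = FALSE))
  x[x != "" & !startsWith(x, "#")]
}
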