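#' Pipeline configuration
#'
#' Bundles everything one end-to-end signal detection run needs: data inputs
#' (either simulation configs or paths to on-disk extracts), the candidate
#' drug list, the code lists of the case definition, and tuning parameters.
#' Confidence intervals are two-sided 95\% throughout, and significance is CI
#' exclusion of 1 (equivalently p < 0.05), with no multiplicity correction.
#'
#' @param candidate_drugs character vector of drug codes screened for signals.
#' @param outcome_codes EHR condition codes defining the ADR outcome.
#' @param adr_code SRS reaction code for the same ADR.
#' @param sim_ehr an [ehr_sim_config()], or `NULL` when reading from
#'   `ehr_dir`.
#' @param sim_srs an [srs_sim_config()], or `NULL` when reading from
#'   `srs_file`.
#' @param ehr_dir directory readable by [read_cdm_store()] (used when
#'   `sim_ehr` is `NULL`).
#' @param srs_file CSV readable by [read_srs_reports()] (used when `sim_srs`
#'   is `NULL`).
#' @param case_def a [case_definition()].
#' @param window_days outcome risk window in days (default 365).
#' @param caliper_sd matching caliper in SD of the logit propensity score.
#' @param seed master seed; overrides the seeds inside `sim_ehr`/`sim_srs`
#'   so one integer reproduces the whole run.
#' @param out_dir where [run_pipeline()] persists intermediates; `NULL` keeps
#'   everything in memory.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(candidate_drugs,
                            outcome_codes = "EAR_DISORDER",
                            adr_code = "ear_disorder",
                            sim_ehr = NULL, sim_srs = NULL,
                            ehr_dir = NULL, srs_file = NULL,
                            case_def = case_definition(),
                            window_days = 365, caliper_sd = 0.2,
                            seed = 1, out_dir = NULL) {
  if (is.null(sim_ehr) && is.null(ehr_dir)) {
    stop_validation("either sim_ehr or ehr_dir must be given")
  }
  if (is.null(sim_srs) && is.null(srs_file)) {
    stop_validation("either sim_srs or srs_file must be given")
  }
  if (window_days <= 0) stop_validation("window_days must be > 0")
  if (!is.null(sim_ehr)) sim_ehr$seed <- as.integer(seed)
  if (!is.null(sim_srs)) sim_srs$seed <- as.integer(seed) + 1000L
  structure(list(candidate_drugs = candidate_drugs,
                 outcome_codes = outcome_codes, adr_code = adr_code,
                 sim_ehr = sim_ehr, sim_srs = sim_srs,
                 ehr_dir = ehr_dir, srs_file = srs_file,
                 case_def = case_def, window_days = window_days,
                 caliper_sd = caliper_sd, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' The file mirrors the arguments of [pipeline_config()]; `sim_ehr`, `sim_srs`
#' and `case_def` are given as nested maps, and `sim_ehr$drugs` as a map from
#' drug code to `{prevalence, log_hr}`. See `inst/extdata/demo_config.yaml`
#' for a worked example.
#'
#' @param file path to a `.yaml`/`.yml` or `.json` file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(file) {
  cfg <- if (grepl("\\.ya?ml$", file)) yaml::read_yaml(file)
         else jsonlite::fromJSON(file, simplifyVector = TRUE)
  sim_ehr <- if (!is.null(cfg$sim_ehr)) {
    se <- cfg$sim_ehr
    se$drugs <- lapply(se$drugs, function(d) {
      list(prevalence = d$prevalence, log_hr = d$log_hr %||% 0)
    })
    se$exposure_coefs <- unlist(se$exposure_coefs) %||% c(sex_male = 0)
    se$outcome_coefs <- unlist(se$outcome_coefs) %||% c(sex_male = 0)
    se$pta <- se$pta %||% list(fraction = 0)
    do.call(ehr_sim_config, se)
  }
  sim_srs <- if (!is.null(cfg$sim_srs)) {
    ss <- cfg$sim_srs
    ss$drug_probs <- unlist(ss$drug_probs)
    ss$reaction_probs <- unlist(ss$reaction_probs)
    if (!is.null(ss$planted) && !is.data.frame(ss$planted)) {
      ss$planted <- do.call(rbind, lapply(ss$planted, function(p) {
        data.frame(drug = p$drug, reaction = p$reaction, log_ror = p$log_ror,
                   stringsAsFactors = FALSE)
      }))
    }
    if (!is.null(ss$sex_probs)) ss$sex_probs <- unlist(ss$sex_probs)
    do.call(srs_sim_config, ss)
  }
  cd <- cfg$case_def %||% list()
  pipeline_config(
    candidate_drugs = cfg$candidate_drugs,
    outcome_codes = cfg$outcome_codes %||% "EAR_DISORDER",
    adr_code = cfg$adr_code %||% "ear_disorder",
    sim_ehr = sim_ehr, sim_srs = sim_srs,
    ehr_dir = cfg$ehr_dir, srs_file = cfg$srs_file,
    case_def = case_definition(cd$systemic_disease_codes %||% character(),
                               cd$ear_surgery_codes %||% character(),
                               cd$ototoxic_drug_codes %||% character()),
    window_days = cfg$window_days %||% 365,
    caliper_sd = cfg$caliper_sd %||% 0.2,
    seed = cfg$seed %||% 1, out_dir = cfg$out_dir)
}

sig_flag <- function(ci_low, ci_high) {
  !is.na(ci_low) & !is.na(ci_high) & (ci_low > 1 | ci_high < 1)
}

ehr_signal_for_drug <- function(store, drug, config, verbose = TRUE) {
  tab <- build_analysis_table(store, drug, config$outcome_codes,
                              config$window_days)
  n_exposed <- sum(tab$exposed == 1L)
  ps <- fit_propensity(tab)
  mc <- match_1to1(ps, tab, config$caliper_sd)
  if (nrow(mc$pairs) == 0) stop_validation("no matched pairs for '%s'", drug)
  bal <- balance_diagnostics(mc, tab)
  exp_rows <- tab[match(mc$pairs$exposed_id, tab$person_id), ]
  ctl_rows <- assign_control_index_dates(mc, tab, store, config$outcome_codes,
                                         config$window_days)
  cohort_rows <- rbind(exp_rows, ctl_rows)
  cox <- fit_cox(cohort_rows)
  # matched-cohort 2x2 on the windowed outcome, for meta-analysis
  a <- sum(exp_rows$outcome); b <- nrow(exp_rows) - a
  cc <- sum(ctl_rows$outcome); d <- nrow(ctl_rows) - cc
  if (verbose) {
    message(sprintf("  [%s] exposed %d, matched pairs %d, events %d, HR %.3f",
                    drug, n_exposed, nrow(mc$pairs), cox$n_events, cox$hr))
  }
  list(n_exposed = n_exposed, cohort = mc, balance = bal, cox = cox,
       table = contingency_table(a, b, cc, d), rows = cohort_rows)
}

#' Run the full signal-detection pipeline
#'
#' Executes the stages in order -- simulate/ingest, audiometry conversion,
#' case-definition filtering, per-drug cohort construction, propensity
#' matching, Cox estimation, SRS disproportionality, and per-drug
#' meta-analysis -- and assembles the per-drug signal report. Every stage logs
#' its row counts (the attrition trail); with `out_dir` set, all intermediates
#' are persisted as CSV. The run is deterministic given `config$seed`.
#'
#' A drug whose cohort is degenerate (no exposed persons, no events, or no
#' possible matches) is reported as an `NA` row with a warning rather than
#' aborting; a failure of a whole stage aborts with the stage name, leaving
#' earlier stages persisted.
#'
#' @param config a [pipeline_config()].
#' @param verbose emit per-stage progress messages (default `TRUE`).
#' @return an object of class `signal_report`: `table` (one row per drug),
#'   `demographics` (EHR and SRS sex tables), `attrition`, `balance`,
#'   `meta` (list of `meta_result`s), `out_dir`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  out_dir <- config$out_dir
  persist <- !is.null(out_dir)
  if (persist) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) if (persist) {
    utils::write.csv(df, file.path(out_dir, f), row.names = FALSE, quote = FALSE,
                     na = "")
  }

  store <- stage("ingest", {
    if (!is.null(config$sim_ehr)) {
      s <- generate_ehr(config$sim_ehr)
      generate_audiograms(s, config$sim_ehr)
    } else read_cdm_store(config$ehr_dir)
  })
  n0 <- nrow(store$persons)
  say("[ingest] EHR: %d persons, %d exposures, %d conditions, %d measurements",
      n0, nrow(store$drug_exposures), nrow(store$conditions),
      nrow(store$measurements))

  reports <- stage("ingest_srs", {
    if (!is.null(config$sim_srs)) generate_srs(config$sim_srs)
    else read_srs_reports(config$srs_file)
  })
  say("[ingest] SRS: %d reports", nrow(reports))

  filt <- stage("case_definition", apply_case_definition(store, config$case_def))
  store_f <- filt$store
  attrition <- data.frame(
    stage = c("initial", names(filt$tally)),
    n_excluded = c(0L, unname(filt$tally)),
    n_remaining = n0 - cumsum(c(0L, unname(filt$tally))))
  say("[case_definition] excluded %s; %d persons remain",
      paste(sprintf("%s=%d", names(filt$tally), filt$tally), collapse = ", "),
      nrow(store_f$persons))
  if (persist) {
    write_cdm_store(store_f, file.path(out_dir, "filtered_store"))
    wr(attrition, "attrition.csv")
  }

  drugs <- config$candidate_drugs
  results <- vector("list", length(drugs))
  names(results) <- drugs
  meta <- list()
  rows <- lapply(drugs, function(drug) {
    na_row <- data.frame(
      drug = drug, n_exposed = NA_integer_, n_pairs = NA_integer_,
      n_events = NA_integer_,
      ehr_hr = NA_real_, ehr_ci_low = NA_real_, ehr_ci_high = NA_real_,
      ehr_p = NA_real_, ehr_sig = NA,
      ehr_a = NA_real_, ehr_b = NA_real_, ehr_c = NA_real_, ehr_d = NA_real_,
      srs_a = NA_real_, srs_b = NA_real_, srs_c = NA_real_, srs_d = NA_real_,
      srs_ror = NA_real_, srs_ci_low = NA_real_, srs_ci_high = NA_real_,
      srs_p = NA_real_, srs_sig = NA,
      rr_fixed = NA_real_, rr_fixed_ci_low = NA_real_,
      rr_fixed_ci_high = NA_real_, rr_fixed_sig = NA,
      rr_random = NA_real_, rr_random_ci_low = NA_real_,
      rr_random_ci_high = NA_real_, rr_random_sig = NA,
      q = NA_real_, tau2 = NA_real_, i2 = NA_real_,
      stringsAsFactors = FALSE)
    ehr <- tryCatch(ehr_signal_for_drug(store_f, drug, config, verbose),
                    error = function(e) {
                      warning(sprintf("EHR estimation failed for '%s': %s",
                                      drug, conditionMessage(e)))
                      NULL
                    })
    srs_tab <- build_contingency(reports, drug, config$adr_code)
    srs <- tryCatch(ror(srs_tab), error = function(e) {
      warning(sprintf("ROR failed for '%s': %s", drug, conditionMessage(e)))
      NULL
    })
    if (is.null(ehr) && is.null(srs)) return(na_row)
    row <- na_row
    if (!is.null(ehr)) {
      results[[drug]] <<- ehr
      row$n_exposed <- ehr$n_exposed
      row$n_pairs <- nrow(ehr$cohort$pairs)
      row$n_events <- ehr$cox$n_events
      row$ehr_hr <- ehr$cox$hr
      row$ehr_ci_low <- ehr$cox$ci95[["low"]]
      row$ehr_ci_high <- ehr$cox$ci95[["high"]]
      row$ehr_p <- ehr$cox$p_value
      row$ehr_sig <- sig_flag(row$ehr_ci_low, row$ehr_ci_high)
      row[c("ehr_a", "ehr_b", "ehr_c", "ehr_d")] <-
        unlist(ehr$table[c("a", "b", "c", "d")])
    }
    if (!is.null(srs)) {
      row[c("srs_a", "srs_b", "srs_c", "srs_d")] <-
        unlist(srs_tab[c("a", "b", "c", "d")])
      row$srs_ror <- srs$estimate
      row$srs_ci_low <- srs$ci_low
      row$srs_ci_high <- srs$ci_high
      row$srs_p <- srs$p_value
      row$srs_sig <- sig_flag(srs$ci_low, srs$ci_high)
    }
    if (!is.null(ehr) && !is.null(srs)) {
      mr <- tryCatch(
        meta_analyze(list(study_input("EHR", ehr$table),
                          study_input("SRS", srs_tab))),
        error = function(e) NULL)
      if (!is.null(mr)) {
        meta[[drug]] <<- mr
        row$rr_fixed <- mr$fixed$estimate
        row$rr_fixed_ci_low <- mr$fixed$ci_low
        row$rr_fixed_ci_high <- mr$fixed$ci_high
        row$rr_fixed_sig <- sig_flag(mr$fixed$ci_low, mr$fixed$ci_high)
        row$rr_random <- mr$random$estimate
        row$rr_random_ci_low <- mr$random$ci_low
        row$rr_random_ci_high <- mr$random$ci_high
        row$rr_random_sig <- sig_flag(mr$random$ci_low, mr$random$ci_high)
        row$q <- mr$q; row$tau2 <- mr$tau2; row$i2 <- mr$i2
      }
    }
    row
  })
  table <- do.call(rbind, rows)

  demographics <- list(
    ehr = summarize_demographics(store_f),
    srs = summarize_demographics(reports))

  if (persist) {
    wr(table, "signal_report.csv")
    pairs_all <- do.call(rbind, lapply(names(Filter(Negate(is.null), results)),
      function(d) cbind(drug = d, results[[d]]$cohort$pairs)))
    if (!is.null(pairs_all)) wr(pairs_all, "matched_pairs.csv")
    bal_all <- do.call(rbind, lapply(names(Filter(Negate(is.null), results)),
      function(d) cbind(drug = d, results[[d]]$balance)))
    if (!is.null(bal_all)) wr(bal_all, "balance.csv")
    cox_tab <- table[c("drug", "ehr_hr", "ehr_ci_low", "ehr_ci_high", "ehr_p",
                       "n_exposed", "n_events")]
    names(cox_tab) <- c("drug", "hr", "ci_low", "ci_high", "p", "n_exposed",
                        "n_events")
    wr(cox_tab, "cox_results.csv")
    sig_tab <- table[c("drug", "srs_a", "srs_b", "srs_c", "srs_d", "srs_ror",
                       "srs_ci_low", "srs_ci_high", "srs_p")]
    names(sig_tab) <- c("drug", "a", "b", "c", "d", "estimate", "ci_low",
                        "ci_high", "p")
    sig_tab <- cbind(adr = config$adr_code, source = "SRS", measure = "ROR",
                     sig_tab)
    wr(sig_tab[c("drug", "adr", "source", "measure", "a", "b", "c", "d",
                 "estimate", "ci_low", "ci_high", "p")], "signals.csv")
    wr(table[c("drug", "rr_fixed", "rr_fixed_ci_low", "rr_fixed_ci_high",
               "rr_random", "rr_random_ci_low", "rr_random_ci_high",
               "q", "tau2", "i2")], "meta_results.csv")
    if (length(meta) > 0) wr(forest_table(meta), "forest_table.csv")
    wr(demographics$ehr, "demographics_ehr.csv")
    wr(demographics$srs, "demographics_srs.csv")
  }

  structure(list(table = table, demographics = demographics,
                 attrition = attrition,
                 balance = lapply(Filter(Negate(is.null), results), `[[`,
                                  "balance"),
                 meta = meta, out_dir = out_dir, seed = config$seed),
            class = "signal_report")
}

#' Render a signal report as text
#'
#' One line per drug in the layout of a drug-safety summary table: hazard
#' ratio from the matched EHR cohort, reporting odds ratio from the SRS
#' corpus, and the pooled fixed/random risk ratios, a star marking estimates
#' whose 95\% CI excludes 1 (p < 0.05), followed by the demographics block.
#'
#' @param report a `signal_report` from [run_pipeline()].
#' @return the lines, invisibly (also printed).
#' @export
render_report <- function(report) {
  stopifnot(inherits(report, "signal_report"))
  fmt <- function(est, lo, hi, sig) {
    ifelse(is.na(est), "-",
           sprintf("%.2f (%.2f-%.2f)%s", est, lo, hi,
                   ifelse(!is.na(sig) & sig, "*", "")))
  }
  t <- report$table
  lines <- c(
    sprintf("%-14s %-22s %-22s %-22s %-22s", "Drug", "EHR HR (95% CI)",
            "SRS ROR (95% CI)", "RR fixed (95% CI)", "RR random (95% CI)"),
    if (nrow(t) > 0) sprintf("%-14s %-22s %-22s %-22s %-22s", t$drug,
            fmt(t$ehr_hr, t$ehr_ci_low, t$ehr_ci_high, t$ehr_sig),
            fmt(t$srs_ror, t$srs_ci_low, t$srs_ci_high, t$srs_sig),
            fmt(t$rr_fixed, t$rr_fixed_ci_low, t$rr_fixed_ci_high,
                t$rr_fixed_sig),
            fmt(t$rr_random, t$rr_random_ci_low, t$rr_random_ci_high,
                t$rr_random_sig)),
    "* 95% CI excludes 1 (p < 0.05)", "",
    "EHR population by sex:",
    sprintf("  %-8s %10d (%.1f%%)", report$demographics$ehr$sex,
            report$demographics$ehr$n, report$demographics$ehr$pct),
    "SRS reports by sex:",
    sprintf("  %-8s %10d (%.1f%%)", report$demographics$srs$sex,
            report$demographics$srs$n, report$demographics$srs$pct))
  cat(lines, sep = "\n")
  invisible(lines)
}

#' @export
print.signal_report <- function(x, ...) {
  render_report(x)
  invisible(x)
}
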