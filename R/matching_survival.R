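#' Fit the propensity model
#'
#' Logistic regression of exposure on the four stated covariates (sex, age,
#' outpatient visit count, hospitalization days), fitted by maximum likelihood
#' (iteratively reweighted least squares via [stats::glm()]).
#'
#' @param rows analysis rows with columns `exposed`, `sex`, `age`,
#'   `n_outpatient_visits`, `hospitalization_days` (see
#'   [build_analysis_table()]).
#' @return an object of class `propensity_model`: `coefficients`, per-person
#'   `scores` (probability of exposure, named by `person_id`), `converged`,
#'   and the underlying `fit`.
#' @export
fit_propensity <- function(rows) {
  if (length(unique(rows$exposed)) < 2) {
    stop_validation("need both exposed and unexposed rows to fit a propensity model")
  }
  if (!all(is.finite(rows$age)) || !all(is.finite(rows$n_outpatient_visits)) ||
      !all(is.finite(rows$hospitalization_days))) {
    stop_validation("non-finite covariate values")
  }
  dat <- data.frame(exposed = rows$exposed,
                    sex_male = as.numeric(rows$sex == "male"),
                    age = rows$age,
                    n_outpatient_visits = rows$n_outpatient_visits,
                    hospitalization_days = rows$hospitalization_days)
  fit <- suppressWarnings(
    stats::glm(exposed ~ sex_male + age + n_outpatient_visits +
                 hospitalization_days, family = stats::binomial(), data = dat,
               control = stats::glm.control(epsilon = 1e-10, maxit = 50)))
  scores <- stats::fitted(fit)
  sep_eps <- 1e-8
  if (any(scores < sep_eps) || any(scores > 1 - sep_eps) ||
      any(abs(stats::coef(fit)[-1]) > 15)) {
    stop_validation(paste0(
      "(quasi-)complete separation in the propensity model: fitted ",
      "probabilities reach 0/1; largest |coefficient| = %.2f"),
      max(abs(stats::coef(fit)[-1])))
  }
  if (!fit$converged) stop_validation("propensity model did not converge")
  structure(list(coefficients = stats::coef(fit),
                 scores = stats::setNames(scores, rows$person_id),
                 converged = fit$converged, fit = fit),
            class = "propensity_model")
}

#' @export
print.propensity_model <- function(x, ...) {
  cat("Propensity model (logistic):\n")
  print(round(x$coefficients, 4))
  cat(sprintf("%d scores in [%.3f, %.3f]\n", length(x$scores),
              min(x$scores), max(x$scores)))
  invisible(x)
}

#' 1:1 propensity-score matching
#'
#' Greedy nearest-neighbour matching without replacement on the logit of the
#' propensity score, with a caliper of `caliper_sd` standard deviations of the
#' logit score. Exposed subjects are processed in descending score order (ties
#' broken by `person_id`); each takes the nearest available control inside the
#' caliper (distance ties broken by lower control `person_id`). The procedure
#' is fully deterministic.
#'
#' @param model a [fit_propensity()] result.
#' @param rows the analysis rows the model was fitted on.
#' @param caliper_sd caliper width in SD of the logit score (default 0.2); use
#'   `Inf` to disable.
#' @return an object of class `matched_cohort`: `pairs` (data frame
#'   `exposed_id`, `control_id`, `distance`), `caliper_used` (on the logit
#'   scale), `n_unmatched`.
#' @export
match_1to1 <- function(model, rows, caliper_sd = 0.2) {
  stopifnot(inherits(model, "propensity_model"))
  lg <- stats::qlogis(model$scores[rows$person_id])
  caliper <- caliper_sd * stats::sd(lg)
  exp_idx <- which(rows$exposed == 1L)
  ctl_idx <- which(rows$exposed == 0L)
  # exposed processed by descending score, then person_id
  exp_idx <- exp_idx[order(-lg[exp_idx], rows$person_id[exp_idx])]
  # controls sorted by logit (ties by person_id) for nearest-neighbour scans
  ctl_idx <- ctl_idx[order(lg[ctl_idx], rows$person_id[ctl_idx])]
  ctl_lg <- unname(lg[ctl_idx])
  nc <- length(ctl_idx)
  available <- rep(TRUE, nc)
  pairs_e <- character(0); pairs_c <- character(0); dist <- numeric(0)
  n_unmatched <- 0L
  for (i in exp_idx) {
    x <- unname(lg[i])
    pos <- findInterval(x, ctl_lg)
    lo <- pos; hi <- pos + 1L
    while (lo >= 1 && !available[lo]) lo <- lo - 1L
    while (hi <= nc && !available[hi]) hi <- hi + 1L
    d_lo <- if (lo >= 1) abs(x - ctl_lg[lo]) else Inf
    d_hi <- if (hi <= nc) abs(x - ctl_lg[hi]) else Inf
    pick <- if (d_lo < d_hi) lo
            else if (d_hi < d_lo) hi
            else if (is.finite(d_lo)) {
              # equidistant: lower control person_id wins
              ids <- rows$person_id[ctl_idx[c(lo, hi)]]
              if (ids[1] <= ids[2]) lo else hi
            } else NA_integer_
    if (is.na(pick) || abs(x - ctl_lg[pick]) > caliper) {
      n_unmatched <- n_unmatched + 1L
      next
    }
    available[pick] <- FALSE
    pairs_e <- c(pairs_e, rows$person_id[i])
    pairs_c <- c(pairs_c, rows$person_id[ctl_idx[pick]])
    dist <- c(dist, abs(x - ctl_lg[pick]))
  }
  if (length(pairs_e) == 0) warning("no matches possible")
  structure(list(pairs = data.frame(exposed_id = pairs_e, control_id = pairs_c,
                                    distance = dist, stringsAsFactors = FALSE),
                 caliper_used = caliper, n_unmatched = n_unmatched),
            class = "matched_cohort")
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat(sprintf("Matched cohort: %d pairs, %d exposed unmatched (caliper %.4f on logit scale)\n",
              nrow(x$pairs), x$n_unmatched, x$caliper_used))
  invisible(x)
}

smd_one <- function(x_e, x_c) {
  pooled <- sqrt((stats::var(x_e) + stats::var(x_c)) / 2)
  if (!is.finite(pooled) || pooled == 0) {
    return(c(smd = 0, degenerate = 1))
  }
  c(smd = (mean(x_e) - mean(x_c)) / pooled, degenerate = 0)
}

#' Covariate balance before and after matching
#'
#' Standardized mean differences (difference in means over the pooled standard
#' deviation, sex coded 0/1) for each matching covariate, computed on the full
#' exposed/unexposed rows and again on the matched pairs. Zero pooled SD is
#' reported as SMD 0 with `degenerate = TRUE`.
#'
#' @param cohort a [match_1to1()] result.
#' @param rows the analysis rows used for matching.
#' @return data frame: `covariate`, `smd_before`, `smd_after`, `degenerate`.
#' @export
balance_diagnostics <- function(cohort, rows) {
  covs <- list(sex_male = as.numeric(rows$sex == "male"), age = rows$age,
               n_outpatient_visits = rows$n_outpatient_visits,
               hospitalization_days = rows$hospitalization_days)
  e_all <- rows$exposed == 1L
  i_e <- match(cohort$pairs$exposed_id, rows$person_id)
  i_c <- match(cohort$pairs$control_id, rows$person_id)
  out <- lapply(names(covs), function(nm) {
    x <- covs[[nm]]
    before <- smd_one(x[e_all], x[!e_all])
    after <- smd_one(x[i_e], x[i_c])
    data.frame(covariate = nm, smd_before = unname(before["smd"]),
               smd_after = unname(after["smd"]),
               degenerate = before["degenerate"] == 1 | after["degenerate"] == 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Cox proportional-hazards fit for the exposure effect
#'
#' Maximizes the Cox partial likelihood (Efron correction for tied event times
#' by default) for the matched cohort. After 1:1 matching the model contains
#' only the exposure term; set `adjust_covariates = TRUE` to additionally
#' adjust for the four matching covariates.
#'
#' @param rows analysis rows with `time_days`, `event`, `exposed` (and
#'   covariates if adjusting).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param adjust_covariates include sex/age/visits/hospitalization terms.
#' @return an object of class `cox_fit`: `log_hr`, `hr`, `se_log_hr`, `ci95`,
#'   `p_value` (Wald), `n`, `n_events`, and the underlying [survival::coxph()]
#'   fit.
#' @export
fit_cox <- function(rows, ties = c("efron", "breslow"),
                    adjust_covariates = FALSE) {
  ties <- match.arg(ties)
  if (any(rows$time_days <= 0)) stop_validation("nonpositive follow-up time")
  if (sum(rows$event) == 0) stop_validation("no events in the cohort")
  dat <- data.frame(time = rows$time_days, event = rows$event,
                    exposed = rows$exposed,
                    sex_male = as.numeric(rows$sex == "male"),
                    age = rows$age,
                    n_outpatient_visits = rows$n_outpatient_visits,
                    hospitalization_days = rows$hospitalization_days)
  fml <- if (adjust_covariates) {
    survival::Surv(time, event) ~ exposed + sex_male + age +
      n_outpatient_visits + hospitalization_days
  } else survival::Surv(time, event) ~ exposed
  fit <- tryCatch(
    survival::coxph(fml, data = dat, ties = ties,
                    control = survival::coxph.control(eps = 1e-10,
                                                      iter.max = 50)),
    warning = function(w) {
      if (grepl("converge|infinit", conditionMessage(w))) {
        stop_validation("Cox fit did not converge: %s", conditionMessage(w))
      }
      suppressWarnings(
        survival::coxph(fml, data = dat, ties = ties,
                        control = survival::coxph.control(eps = 1e-10,
                                                          iter.max = 50)))
    })
  b <- stats::coef(fit)[["exposed"]]
  se <- sqrt(stats::vcov(fit)["exposed", "exposed"])
  if (!is.finite(b) || !is.finite(se)) {
    stop_validation("Cox fit returned non-finite estimate")
  }
  z <- stats::qnorm(0.975)
  structure(list(log_hr = b, hr = exp(b), se_log_hr = se,
                 ci95 = c(low = exp(b - z * se), high = exp(b + z * se)),
                 p_value = 2 * stats::pnorm(-abs(b) / se),
                 n = nrow(dat), n_events = sum(dat$event), fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH: HR = %.3f (95%% CI %.3f-%.3f), p = %.3g (%d events / %d subjects)\n",
              x$hr, x$ci95[["low"]], x$ci95[["high"]], x$p_value, x$n_events,
              x$n))
  invisible(x)
}
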