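# Small hand-built fixtures and independent oracles used across the suite.

make_persons <- function(ids, sex = "female", birth_year = 1970L,
                         visits = 5L, hosp = 0L) {
  data.frame(person_id = ids,
             sex = rep_len(sex, length(ids)),
             birth_year = rep_len(as.integer(birth_year), length(ids)),
             n_outpatient_visits = rep_len(as.integer(visits), length(ids)),
             hospitalization_days = rep_len(as.integer(hosp), length(ids)),
             stringsAsFactors = FALSE)
}

make_store <- function(n = 3, drug_exposures = NULL, conditions = NULL,
                       measurements = NULL) {
  cdm_store(persons = make_persons(sprintf("p%02d", seq_len(n))),
            drug_exposures = drug_exposures, conditions = conditions,
            measurements = measurements,
            study_start = "2014-01-01", study_end = "2018-12-31")
}

make_reports <- function(drugs, reactions, sex = "female") {
  structure(data.frame(report_id = sprintf("r%03d", seq_along(drugs)),
                       sex = rep_len(sex, length(drugs)),
                       drugs = drugs, reactions = reactions,
                       stringsAsFactors = FALSE),
            class = c("srs_reports", "data.frame"))
}

# flat audiogram thresholds at the six standard frequencies
flat_thresholds <- function(db) {
  stats::setNames(rep(db, 6), c(250, 500, 1000, 2000, 4000, 8000))
}

has_code_vec <- function(codes, code) {
  grepl(paste0("|", code, "|"), paste0("|", codes, "|"), fixed = TRUE)
}

# ---- independent oracles -------------------------------------------------

# closed-form ROR recomputation (kept separate from the package code path)
oracle_ror <- function(a, b, c, d) {
  if (any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  est <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(est = est,
       lo = exp(log(est) - qnorm(0.975) * se),
       hi = exp(log(est) + qnorm(0.975) * se),
       p = 2 * pnorm(-abs(log(est)) / se))
}

oracle_rr <- function(a, b, c, d) {
  if (any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  est <- (a / (a + b)) / (c / (c + d))
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  list(est = est,
       lo = exp(log(est) - qnorm(0.975) * se),
       hi = exp(log(est) + qnorm(0.975) * se))
}

# Cox partial log-likelihood for a binary covariate, no tied event times:
# logPL(b) = sum over events i of [b x_i - log(n0_i + n1_i exp(b))] where
# n0/n1 count unexposed/exposed subjects still at risk at t_i.
oracle_cox_grid <- function(time, event, exposed,
                            grid = seq(-5, 5, by = 1e-4)) {
  stopifnot(!any(duplicated(time[event == 1])))
  ev <- which(event == 1)
  logpl <- numeric(length(grid))
  eb <- exp(grid)
  for (i in ev) {
    at_risk <- time >= time[i]
    n1 <- sum(exposed[at_risk] == 1)
    n0 <- sum(at_risk) - n1
    logpl <- logpl + grid * exposed[i] - log(n0 + n1 * eb)
  }
  grid[which.max(logpl)]
}

# exhaustive minimal-total-distance 1:1 assignment over all pairings
oracle_optimal_match <- function(exp_lg, ctl_lg, caliper) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[i], p))
    }))
  }
  best <- NULL; best_d <- Inf
  for (p in perms(seq_along(ctl_lg))) {
    d <- abs(exp_lg - ctl_lg[p[seq_along(exp_lg)]])
    if (any(d > caliper)) next
    if (sum(d) < best_d) { best_d <- sum(d); best <- p[seq_along(exp_lg)] }
  }
  list(assignment = best, total = best_d)
}

# quick synthetic cohort for Cox recovery checks: exponential times, binary
# exposure, uniform censoring
sim_exp_cohort <- function(n_per_arm, true_hr, base_rate = 0.02,
                           cens_time = 100) {
  exposed <- rep(c(0, 1), each = n_per_arm)
  t_event <- rexp(2 * n_per_arm, rate = base_rate * true_hr^exposed)
  time <- pmin(t_event, cens_time)
  data.frame(time_days = time, event = as.integer(t_event <= cens_time),
             exposed = exposed,
             sex = "female", age = 50,
             n_outpatient_visits = 0L, hospitalization_days = 0L)
}
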