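ps_rows <- function(n, beta_age = 0, prev = 0.3, seed = 1) {
  set.seed(seed)
  age <- rnorm(n, 50, 10)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  visits <- rpois(n, 6)
  hosp <- rpois(n, 2)
  lp <- qlogis(prev) + beta_age * (age - 50)
  data.frame(person_id = sprintf("x%05d", seq_len(n)),
             exposed = as.integer(runif(n) < plogis(lp)),
             sex = sex, age = age, n_outpatient_visits = visits,
             hospitalization_days = hosp, stringsAsFactors = FALSE)
}

test_that("propensity model recovers null and planted coefficients", {
  rows <- ps_rows(2000, beta_age = 0, prev = 0.3, seed = 5)
  m <- fit_propensity(rows)
  expect_true(m$converged)
  se <- sqrt(diag(vcov(m$fit)))
  expect_lt(abs(m$coefficients[["age"]]), 2 * se[["age"]])
  expect_equal(mean(m$scores), mean(rows$exposed), tolerance = 0.01)

  rows2 <- ps_rows(4000, beta_age = 0.05, prev = 0.3, seed = 6)
  m2 <- fit_propensity(rows2)
  se2 <- sqrt(diag(vcov(m2$fit)))
  expect_lt(abs(m2$coefficients[["age"]] - 0.05), 2 * se2[["age"]])
})

test_that("propensity model rejects degenerate inputs", {
  rows <- ps_rows(100)
  rows$exposed <- 1L
  expect_error(fit_propensity(rows), "both exposed",
               class = "adrsignal_validation_error")
  rows2 <- ps_rows(100)
  rows2$exposed <- as.integer(rows2$age > 50)  # perfectly separated
  expect_error(fit_propensity(rows2), "separation",
               class = "adrsignal_validation_error")
  rows3 <- ps_rows(100)
  rows3$age[1] <- NA
  expect_error(fit_propensity(rows3), "non-finite",
               class = "adrsignal_validation_error")
})

test_that("matching is 1:1 without replacement and respects the caliper", {
  rows <- ps_rows(600, beta_age = 0.03, seed = 7)
  m <- fit_propensity(rows)
  mc <- match_1to1(m, rows)
  expect_s3_class(mc, "matched_cohort")
  ids <- c(mc$pairs$exposed_id, mc$pairs$control_id)
  expect_false(any(duplicated(ids)))
  expect_lte(nrow(mc$pairs), min(sum(rows$exposed), sum(!rows$exposed)))
  expect_true(all(mc$pairs$distance <= mc$caliper_used))

  # far-outlying exposed subject goes unmatched under the caliper
  rows_o <- rbind(rows[rows$exposed == 0, ][1:20, ],
                  data.frame(person_id = "far", exposed = 1L, sex = "male",
                             age = 50, n_outpatient_visits = 6,
                             hospitalization_days = 2))
  sc <- c(plogis(seq(-1, 1, length.out = 20)), 0.999999)
  mdl <- structure(list(scores = setNames(sc, rows_o$person_id),
                        coefficients = NULL, converged = TRUE),
                   class = "propensity_model")
  expect_warning(mc_o <- match_1to1(mdl, rows_o, caliper_sd = 0.2),
                 "no matches")
  expect_equal(mc_o$n_unmatched, 1L)
  expect_equal(nrow(mc_o$pairs), 0)
})

test_that("identical score distributions match everyone", {
  rows <- ps_rows(400, beta_age = 0, seed = 8)
  ne <- sum(rows$exposed)
  rows <- rbind(rows[rows$exposed == 1, ],
                transform(rows[rows$exposed == 1, ],
                          exposed = 0L,
                          person_id = paste0(person_id, "c")))
  m <- fit_propensity(rows)
  mc <- match_1to1(m, rows)
  expect_equal(nrow(mc$pairs), ne)
  expect_equal(mc$n_unmatched, 0L)
})

test_that("greedy matching equals the brute-force optimum on a small fixture", {
  # well-separated score clusters: greedy and optimal assignments coincide
  scores <- c(e1 = 0.80, e2 = 0.55, e3 = 0.30,
              c1 = 0.78, c2 = 0.52, c3 = 0.33, c4 = 0.10)
  rows <- data.frame(person_id = names(scores),
                     exposed = c(1L, 1L, 1L, 0L, 0L, 0L, 0L),
                     sex = "female", age = 50, n_outpatient_visits = 0,
                     hospitalization_days = 0, stringsAsFactors = FALSE)
  mdl <- structure(list(scores = scores, converged = TRUE),
                   class = "propensity_model")
  mc <- match_1to1(mdl, rows, caliper_sd = Inf)
  lg <- qlogis(scores)
  oracle <- oracle_optimal_match(lg[1:3], lg[4:7], caliper = Inf)
  expect_equal(mc$pairs$control_id[match(c("e1", "e2", "e3"),
                                         mc$pairs$exposed_id)],
               names(scores)[3 + oracle$assignment])
  expect_equal(sum(mc$pairs$distance), oracle$total, tolerance = 1e-12)
})

test_that("matching is deterministic and improves covariate balance", {
  rows <- ps_rows(3000, beta_age = 0.06, prev = 0.25, seed = 9)
  m <- fit_propensity(rows)
  mc1 <- match_1to1(m, rows)
  mc2 <- match_1to1(m, rows)
  expect_identical(mc1$pairs, mc2$pairs)
  bal <- balance_diagnostics(mc1, rows)
  age_row <- bal[bal$covariate == "age", ]
  expect_gt(abs(age_row$smd_before), 0.2)
  expect_lt(abs(age_row$smd_after), abs(age_row$smd_before))
  # identical groups give SMD exactly 0
  same <- rbind(rows[rows$exposed == 1, ],
                transform(rows[rows$exposed == 1, ], exposed = 0L,
                          person_id = paste0(person_id, "c")))
  mc3 <- match_1to1(fit_propensity(same), same)
  bal3 <- balance_diagnostics(mc3, same)
  expect_true(all(abs(bal3$smd_after) < 1e-10))
  # zero-variance covariate is flagged, not NaN
  expect_true(all(is.finite(bal3$smd_after)))
})

test_that("cox fit matches a grid-search partial-likelihood oracle", {
  rows <- data.frame(
    time_days = c(3, 5, 8, 11, 14, 17, 21, 30),
    event = c(1L, 1L, 0L, 1L, 1L, 0L, 1L, 0L),
    exposed = c(1L, 1L, 1L, 0L, 1L, 0L, 0L, 0L),
    sex = "female", age = 50, n_outpatient_visits = 0,
    hospitalization_days = 0)
  fit <- fit_cox(rows)
  b_star <- oracle_cox_grid(rows$time_days, rows$event, rows$exposed)
  expect_equal(fit$log_hr, b_star, tolerance = 1e-3)
  expect_equal(fit$ci95[["low"]],
               exp(fit$log_hr - qnorm(0.975) * fit$se_log_hr))
  expect_equal(fit$n_events, 5L)
})

test_that("cox fit is symmetric, relabel- and rescale-invariant", {
  rows <- sim_exp_cohort(60, true_hr = 1)
  rows$time_days <- rows$time_days + seq_len(nrow(rows)) * 1e-6  # break ties
  # two identical event-time groups give HR == 1 exactly
  sym <- data.frame(time_days = rep(c(2, 4, 6, 9), 2),
                    event = 1L, exposed = rep(c(0L, 1L), each = 4),
                    sex = "female", age = 50, n_outpatient_visits = 0,
                    hospitalization_days = 0)
  expect_equal(fit_cox(sym)$hr, 1.0, tolerance = 1e-8)

  f1 <- fit_cox(rows)
  rows2 <- rows[sample(nrow(rows)), ]  # relabeling / reordering
  f2 <- fit_cox(rows2)
  expect_equal(f2$log_hr, f1$log_hr, tolerance = 1e-10)
  rows3 <- rows
  rows3$time_days <- rows3$time_days * 37.5  # uniform time rescaling
  f3 <- fit_cox(rows3)
  expect_equal(f3$log_hr, f1$log_hr, tolerance = 1e-8)
})

test_that("cox fit rejects no-event and nonpositive-time inputs", {
  rows <- sim_exp_cohort(10, 1)
  rows$event <- 0L
  expect_error(fit_cox(rows), "no events",
               class = "adrsignal_validation_error")
  rows2 <- sim_exp_cohort(10, 1)
  rows2$time_days[1] <- 0
  expect_error(fit_cox(rows2), "time", class = "adrsignal_validation_error")
})

test_that("cox estimate recovers a planted hazard ratio", {
  set.seed(123)
  rows <- sim_exp_cohort(2000, true_hr = 2)
  fit <- fit_cox(rows)
  expect_gt(fit$hr, 1.8); expect_lt(fit$hr, 2.2)
  expect_true(fit$ci95[["low"]] < 2 && 2 < fit$ci95[["high"]])
})
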