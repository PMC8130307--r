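#' Drug-ADR 2x2 contingency table
#'
#' The four report counts underlying a disproportionality statistic:
#' `a` = drug and ADR, `b` = drug without ADR, `c` = ADR without drug,
#' `d` = neither. Every report contributes to exactly one cell.
#'
#' @param a,b,c,d nonnegative counts.
#' @param corrected has the 0.5 continuity correction already been applied?
#' @return an object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d, corrected = FALSE) {
  cells <- as.numeric(c(a = a, b = b, c = c, d = d))
  if (any(!is.finite(cells)) || any(cells < 0)) {
    stop_validation("contingency cells must be nonnegative")
  }
  structure(list(a = cells[1], b = cells[2], c = cells[3], d = cells[4],
                 corrected = corrected),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("drug", "no drug"), c("ADR", "no ADR")))
  print(m)
  if (x$corrected) cat("(0.5 continuity correction applied)\n")
  invisible(x)
}

# Haldane-Anscombe: add 0.5 to all four cells when any cell is zero
apply_continuity <- function(tab) {
  if (!tab$corrected && any(c(tab$a, tab$b, tab$c, tab$d) == 0)) {
    tab <- contingency_table(tab$a + 0.5, tab$b + 0.5, tab$c + 0.5, tab$d + 0.5,
                             corrected = TRUE)
  }
  tab
}

#' Build a drug-ADR contingency table from spontaneous reports
#'
#' Each report is counted once; membership is exact code match within the
#' report's drug and reaction sets.
#'
#' @param reports an `srs_reports` data frame (see [generate_srs()]).
#' @param drug_code,adr_code codes of the pair of interest.
#' @return a [contingency_table()] whose cells sum to `nrow(reports)`.
#' @export
build_contingency <- function(reports, drug_code, adr_code) {
  if (nrow(reports) == 0) stop_validation("empty report set")
  dr <- has_code(reports$drugs, drug_code)
  re <- has_code(reports$reactions, adr_code)
  contingency_table(a = sum(dr & re), b = sum(dr & !re),
                    c = sum(!dr & re), d = sum(!dr & !re))
}

#' An effect estimate with its confidence interval
#'
#' @param measure `"ROR"`, `"RR"` or `"HR"`.
#' @param estimate point estimate (> 0).
#' @param ci_low,ci_high Wald 95\% confidence limits.
#' @param p_value two-sided Wald p-value.
#' @param source `"EHR"`, `"SRS"` or `"META"`.
#' @param table the contingency table the estimate came from, if any.
#' @return an object of class `signal_estimate`.
#' @export
signal_estimate <- function(measure, estimate, ci_low, ci_high, p_value,
                            source = NA_character_, table = NULL) {
  structure(list(measure = measure, estimate = estimate,
                 ci_low = ci_low, ci_high = ci_high, p_value = p_value,
                 source = source, table = table),
            class = "signal_estimate")
}

#' @export
print.signal_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("%s = %.*f (95%% CI %.*f-%.*f), p = %.3g%s\n",
              x$measure, digits, x$estimate, digits, x$ci_low, digits,
              x$ci_high, x$p_value,
              if (!is.na(x$source)) paste0(" [", x$source, "]") else ""))
  invisible(x)
}

wald_estimate <- function(measure, log_est, se, source, table) {
  z <- stats::qnorm(0.975)
  signal_estimate(measure, exp(log_est),
                  ci_low = exp(log_est - z * se),
                  ci_high = exp(log_est + z * se),
                  p_value = 2 * stats::pnorm(-abs(log_est) / se),
                  source = source, table = table)
}

#' Reporting odds ratio
#'
#' `ROR = (a*d)/(b*c)` with a Wald confidence interval on the log scale,
#' `SE(log ROR) = sqrt(1/a + 1/b + 1/c + 1/d)`. Tables containing a zero cell
#' receive the 0.5 continuity correction (all four cells) first, so the
#' estimate is always finite.
#'
#' @param table a [contingency_table()].
#' @param source label recorded on the estimate.
#' @return a [signal_estimate()] with `measure = "ROR"`.
#' @examples
#' ror(contingency_table(10, 90, 50, 850))
#' @export
ror <- function(table, source = "SRS") {
  if (table$a + table$b + table$c + table$d == 0) {
    stop_validation("all-zero contingency table")
  }
  tab <- apply_continuity(table)
  log_est <- log(tab$a) + log(tab$d) - log(tab$b) - log(tab$c)
  se <- sqrt(1 / tab$a + 1 / tab$b + 1 / tab$c + 1 / tab$d)
  wald_estimate("ROR", log_est, se, source, tab)
}

#' Risk ratio from a 2x2 table
#'
#' `RR = (a/(a+b)) / (c/(c+d))` with Wald confidence interval,
#' `SE(log RR) = sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))`. Continuity correction
#' as in [ror()]. Requires both arms nonempty before correction.
#'
#' @inheritParams ror
#' @return a [signal_estimate()] with `measure = "RR"`.
#' @export
risk_ratio <- function(table, source = NA_character_) {
  if (table$a + table$b == 0 || table$c + table$d == 0) {
    stop_validation("risk ratio undefined: empty arm")
  }
  tab <- apply_continuity(table)
  log_est <- log(tab$a / (tab$a + tab$b)) - log(tab$c / (tab$c + tab$d))
  se <- sqrt(1 / tab$a - 1 / (tab$a + tab$b) + 1 / tab$c - 1 / (tab$c + tab$d))
  wald_estimate("RR", log_est, se, source, tab)
}
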