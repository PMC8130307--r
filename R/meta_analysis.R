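#' Bundle a contingency table as one study for pooling
#'
#' @param label source name (e.g. `"EHR"`, `"SRS"`).
#' @param table a [contingency_table()].
#' @return an object of class `study_input`.
#' @export
study_input <- function(label, table) {
  stopifnot(inherits(table, "contingency_table"))
  structure(list(label = label, table = table), class = "study_input")
}

check_studies <- function(studies) {
  if (length(studies) == 0) stop_validation("need at least one study")
  lapply(studies, function(s) {
    stopifnot(inherits(s, "study_input"))
    if (s$table$a + s$table$b == 0 || s$table$c + s$table$d == 0) {
      stop_validation("study '%s' has an empty arm", s$label)
    }
    s
  })
}

# per-study log RR and variance, continuity-corrected only where a cell is zero
study_log_rr <- function(studies) {
  t(vapply(studies, function(s) {
    tab <- apply_continuity(s$table)
    y <- log(tab$a / (tab$a + tab$b)) - log(tab$c / (tab$c + tab$d))
    v <- 1 / tab$a - 1 / (tab$a + tab$b) + 1 / tab$c - 1 / (tab$c + tab$d)
    c(y = y, v = v)
  }, c(y = 0, v = 0)))
}

#' Mantel-Haenszel fixed-effect pooled risk ratio
#'
#' Pools stratified 2x2 tables on the count scale:
#' `RR_MH = sum(a_i (c_i+d_i)/n_i) / sum(c_i (a_i+b_i)/n_i)`, with the
#' Greenland-Robins variance estimator for `log RR_MH` and a Wald 95\% CI.
#' With a single study this reduces exactly to [risk_ratio()].
#'
#' @param studies list of [study_input()]s.
#' @return a [signal_estimate()] with `measure = "RR"`, `source = "META"`.
#' @export
pool_fixed_mh <- function(studies) {
  studies <- check_studies(studies)
  cells <- lapply(studies, function(s) apply_continuity(s$table))
  R <- vapply(cells, function(t) t$a * (t$c + t$d) / (t$a + t$b + t$c + t$d), 0)
  S <- vapply(cells, function(t) t$c * (t$a + t$b) / (t$a + t$b + t$c + t$d), 0)
  P <- vapply(cells, function(t) {
    n <- t$a + t$b + t$c + t$d
    ((t$a + t$b) * (t$c + t$d) * (t$a + t$c) - t$a * t$c * n) / n^2
  }, 0)
  if (sum(R) == 0 || sum(S) == 0) {
    stop_validation("Mantel-Haenszel pooled risk ratio undefined: no events")
  }
  log_est <- log(sum(R)) - log(sum(S))
  se <- sqrt(sum(P) / (sum(R) * sum(S)))
  wald_estimate("RR", log_est, se, "META", NULL)
}

#' Heterogeneity statistics across studies
#'
#' Cochran's Q on inverse-variance weighted log risk ratios, the
#' DerSimonian-Laird moment estimator of the between-study variance
#' `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))`, and
#' `I2 = max(0, (Q - (k-1))/Q)`. With fewer than two studies Q is undefined
#' (`NA`) and `tau2 = i2 = 0`.
#'
#' @inheritParams pool_fixed_mh
#' @return list with `q`, `tau2`, `i2`, `k`.
#' @export
heterogeneity <- function(studies) {
  studies <- check_studies(studies)
  k <- length(studies)
  if (k < 2) return(list(q = NA_real_, tau2 = 0, i2 = 0, k = k))
  yv <- study_log_rr(studies)
  w <- 1 / yv[, "v"]
  ybar <- sum(w * yv[, "y"]) / sum(w)
  q <- sum(w * (yv[, "y"] - ybar)^2)
  tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  i2 <- if (q > 0) max(0, (q - (k - 1)) / q) else 0
  list(q = q, tau2 = tau2, i2 = i2, k = k)
}

#' DerSimonian-Laird random-effects pooled risk ratio
#'
#' Inverse-variance pooling of per-study log risk ratios with weights
#' `1/(v_i + tau2)`, `tau2` from [heterogeneity()]. When the studies are
#' homogeneous (`Q <= k-1`) the estimate coincides with the inverse-variance
#' fixed-effect estimate; with one study it is that study's [risk_ratio()].
#'
#' @inheritParams pool_fixed_mh
#' @return a [signal_estimate()] with `tau2` attached as attribute `"tau2"`.
#' @export
pool_random_dl <- function(studies) {
  studies <- check_studies(studies)
  het <- heterogeneity(studies)
  yv <- study_log_rr(studies)
  w <- 1 / (yv[, "v"] + het$tau2)
  log_est <- sum(w * yv[, "y"]) / sum(w)
  se <- sqrt(1 / sum(w))
  out <- wald_estimate("RR", log_est, se, "META", NULL)
  attr(out, "tau2") <- het$tau2
  out
}

#' Pool one drug's per-source tables into a meta-analysis result
#'
#' @inheritParams pool_fixed_mh
#' @return an object of class `meta_result`: fixed (Mantel-Haenszel) and
#'   random (DerSimonian-Laird) pooled risk ratios, heterogeneity statistics
#'   and the per-study inputs.
#' @export
meta_analyze <- function(studies) {
  studies <- check_studies(studies)
  het <- heterogeneity(studies)
  structure(list(fixed = pool_fixed_mh(studies),
                 random = pool_random_dl(studies),
                 q = het$q, tau2 = het$tau2, i2 = het$i2, k = het$k,
                 studies = studies),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("Meta-analysis of %d studies\n", x$k))
  cat(sprintf("  fixed (MH):  RR %.3f (%.3f-%.3f)\n",
              x$fixed$estimate, x$fixed$ci_low, x$fixed$ci_high))
  cat(sprintf("  random (DL): RR %.3f (%.3f-%.3f)\n",
              x$random$estimate, x$random$ci_low, x$random$ci_high))
  cat(sprintf("  Q = %s, tau2 = %.4g, I2 = %.1f%%\n",
              if (is.na(x$q)) "undefined" else sprintf("%.3f", x$q),
              x$tau2, 100 * x$i2))
  invisible(x)
}

#' Forest-plot table
#'
#' Flattens meta-analysis results into the rows a forest plot draws: one row
#' per study with its risk ratio, CI and percentage weight under each model,
#' then the two pooled rows. Weights sum to 100 within each model. Fixed
#' weights are the Mantel-Haenszel ones (`c_i (a_i+b_i)/n_i`, i.e. the
#' contribution to the pooled denominator); random weights are
#' `1/(v_i + tau2)`.
#'
#' @param meta_results a single `meta_result` or a named list of them (one per
#'   drug).
#' @return data frame with columns `drug`, `row_type` (`study`/`pooled`),
#'   `label`, `rr`, `ci_low`, `ci_high`, `weight_fixed_pct`,
#'   `weight_random_pct`.
#' @export
forest_table <- function(meta_results) {
  if (inherits(meta_results, "meta_result")) {
    meta_results <- list(drug = meta_results)
  }
  if (length(meta_results) == 0) stop_validation("no meta-analysis results")
  rows <- lapply(names(meta_results), function(drug) {
    m <- meta_results[[drug]]
    cells <- lapply(m$studies, function(s) apply_continuity(s$table))
    S <- vapply(cells, function(t) t$c * (t$a + t$b) / (t$a + t$b + t$c + t$d), 0)
    yv <- study_log_rr(m$studies)
    wr <- 1 / (yv[, "v"] + m$tau2)
    per_study <- do.call(rbind, lapply(seq_along(m$studies), function(i) {
      est <- risk_ratio(m$studies[[i]]$table)
      data.frame(drug = drug, row_type = "study", label = m$studies[[i]]$label,
                 rr = est$estimate, ci_low = est$ci_low, ci_high = est$ci_high,
                 weight_fixed_pct = 100 * S[i] / sum(S),
                 weight_random_pct = 100 * wr[i] / sum(wr),
                 stringsAsFactors = FALSE)
    }))
    pooled <- data.frame(
      drug = drug, row_type = "pooled",
      label = c("Fixed effect (MH)", "Random effects (DL)"),
      rr = c(m$fixed$estimate, m$random$estimate),
      ci_low = c(m$fixed$ci_low, m$random$ci_low),
      ci_high = c(m$fixed$ci_high, m$random$ci_high),
      weight_fixed_pct = c(100, NA), weight_random_pct = c(NA, 100),
      stringsAsFactors = FALSE)
    rbind(per_study, pooled)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
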