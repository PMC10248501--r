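## Sensitivity battery: Cochran's Q heterogeneity test, MR-Egger intercept
## (pleiotropy) test, leave-one-out analysis, and funnel-plot data.

#' Cochran's Q heterogeneity test
#'
#' Q = sum of w_j (theta_j - beta_IVW)^2 with the fixed-effect IVW estimate;
#' upper-tail chi-square p on J - 1 degrees of freedom.  Equals the Q
#' reported by [mr_ivw()] on the same instruments.
#'
#' @param insts Harmonized-instrument data.frame (at least 2 rows).
#' @return List `q_stat`, `q_df`, `q_p`.
#' @export
cochrans_q <- function(insts) {
  fit <- mr_ivw(insts)
  list(q_stat = fit$q_stat, q_df = fit$q_df, q_p = fit$q_p)
}

#' Leave-one-out IVW analysis
#'
#' Re-estimates the IVW effect J times, each time excluding one instrument;
#' when only one instrument remains the single-SNP Wald ratio (normal
#' p-value) is reported instead.  A flag is raised when any exclusion
#' changes the direction of the IVW estimate or moves it across the
#' significance boundary `alpha` — an explicit, testable stand-in for the
#' qualitative judgement that the causal estimate is driven by one SNP.
#'
#' @param insts Harmonized-instrument data.frame (at least 2 rows).
#' @param alpha Significance boundary for the flag (default 0.05).
#' @return List with `loo` (data.frame `excluded_snp, beta, se, or, ci_low,
#'   ci_high, pvalue, n_snps`) and `loo_flag` (logical).
#' @export
leave_one_out <- function(insts, alpha = 0.05) {
  check_instruments(insts, 2L, "leave-one-out")
  full <- mr_ivw(insts)$estimate
  rows <- lapply(seq_len(nrow(insts)), function(j) {
    rest <- insts[-j, , drop = FALSE]
    est <- if (nrow(rest) >= 2) {
      mr_ivw(rest)$estimate
    } else {
      wr <- wald_ratio(rest)
      mr_estimate("Wald", wr$theta, wr$se,
                  2 * stats::pnorm(-abs(wr$theta / wr$se)), 1L)
    }
    data.frame(excluded_snp = insts$snp_id[j], beta = est$beta, se = est$se,
               or = est$or_value, ci_low = est$or_low, ci_high = est$or_high,
               pvalue = est$pvalue, n_snps = est$n_snps,
               stringsAsFactors = FALSE)
  })
  loo <- do.call(rbind, rows)
  flag <- any(sign(loo$beta) != sign(full$beta) |
                ((loo$pvalue < alpha) != (full$pvalue < alpha)))
  list(loo = loo, loo_flag = flag)
}

#' Funnel-plot data
#'
#' Per-SNP Wald ratio against its precision (1/se); under balanced
#' pleiotropy the points scatter symmetrically around the pooled estimate.
#' Emitted as a table; rendering is left to the caller.
#'
#' @param insts Harmonized-instrument data.frame (at least 1 row).
#' @return data.frame `snp_id, theta, precision`.
#' @export
funnel_data <- function(insts) {
  if (nrow(insts) < 1)
    mr_stop("funnel_data requires at least 1 instrument",
            "mrscreen_insufficient_instruments")
  wr <- wald_ratio(insts)
  data.frame(snp_id = wr$snp_id, theta = wr$theta, precision = 1 / wr$se,
             stringsAsFactors = FALSE)
}

#' Full sensitivity report for one exposure
#'
#' Bundles Cochran's Q, the MR-Egger intercept test, the leave-one-out
#' analysis, and the funnel data.
#'
#' @param insts Harmonized-instrument data.frame (at least 3 rows for the
#'   Egger intercept; Q and leave-one-out need 2).
#' @param alpha Significance boundary for the leave-one-out flag.
#' @return Object of class `sensitivity_report`: `q_stat, q_df, q_p,
#'   egger_intercept, egger_intercept_se, egger_intercept_p, loo, loo_flag,
#'   funnel`.  Egger fields are `NA` when fewer than 3 instruments.
#' @export
sensitivity_report <- function(insts, alpha = 0.05) {
  q <- cochrans_q(insts)
  eg <- if (nrow(insts) >= 3) mr_egger(insts) else NULL
  lo <- leave_one_out(insts, alpha = alpha)
  structure(list(
    q_stat = q$q_stat, q_df = q$q_df, q_p = q$q_p,
    egger_intercept = if (is.null(eg)) NA_real_ else eg$intercept,
    egger_intercept_se = if (is.null(eg)) NA_real_ else eg$intercept_se,
    egger_intercept_p = if (is.null(eg)) NA_real_ else eg$intercept_p,
    loo = lo$loo, loo_flag = lo$loo_flag,
    funnel = funnel_data(insts)
  ), class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.3f (df %d), p = %.3g\n",
              x$q_stat, x$q_df, x$q_p))
  cat(sprintf("Egger intercept = %.4f (SE %.4f), p = %.3g\n",
              x$egger_intercept, x$egger_intercept_se, x$egger_intercept_p))
  cat(sprintf("Leave-one-out flag: %s; %d funnel points\n",
              x$loo_flag, nrow(x$funnel)))
  invisible(x)
}
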