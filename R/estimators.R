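## Causal-effect estimators on harmonized instruments: per-SNP Wald ratio,
## random-effects inverse-variance weighting (IVW), weighted median (WM),
## MR-Egger regression, and odds-ratio-scale reporting.
##
## Conventions shared by all estimators:
##  * the Wald-ratio SE is first order (se_out/|beta_exp|), which makes IVW
##    identical to weighted regression of beta_out on beta_exp through the
##    origin with weights se_out^-2 — exploited as an independent oracle in
##    the tests;
##  * "random effects" means a multiplicative overdispersion scale floored
##    at 1, so under-dispersion never shrinks a standard error.

#' Construct an MR causal-effect estimate
#'
#' Packages a point estimate on the log-odds-per-SD scale together with its
#' confidence interval, p-value, and odds-ratio-scale transforms.
#'
#' @param method One of `"IVW"`, `"WM"`, `"MR-Egger"`, `"Wald"`.
#' @param beta Causal effect (log-odds of the outcome per SD of exposure).
#' @param se Standard error of `beta`.
#' @param pvalue Two-sided p-value.
#' @param n_snps Number of instruments used.
#' @param crit Critical value for the confidence interval (1.96 for normal
#'   95%; a t quantile for MR-Egger).
#' @return An object of class `mr_estimate` with fields `method, beta, se,
#'   ci_low, ci_high, or_value, or_low, or_high, pvalue, n_snps`.
#' @export
mr_estimate <- function(method, beta, se, pvalue, n_snps, crit = 1.96) {
  or <- to_odds_ratio(beta, se, crit)
  structure(list(method = method, beta = beta, se = se,
                 ci_low = beta - crit * se, ci_high = beta + crit * se,
                 or_value = or[["or_value"]], or_low = or[["or_low"]],
                 or_high = or[["or_high"]],
                 pvalue = pvalue, n_snps = n_snps),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s estimate (%d SNPs): OR %.3f [%.3f, %.3f], p = %.3g\n",
              x$method, x$n_snps, x$or_value, x$or_low, x$or_high,
              x$pvalue))
  invisible(x)
}

#' Effect and confidence interval on the odds-ratio scale
#'
#' @param beta Log-odds effect.
#' @param se Its standard error (> 0).
#' @param crit Critical value (default 1.96).
#' @return Named numeric vector `or_value, or_low, or_high`.
#' @export
to_odds_ratio <- function(beta, se, crit = 1.96) {
  if (any(se <= 0))
    mr_stop("se must be strictly positive", "mrscreen_domain_error")
  c(or_value = exp(beta), or_low = exp(beta - crit * se),
    or_high = exp(beta + crit * se))
}

check_instruments <- function(insts, min_n, method) {
  if (nrow(insts) < min_n)
    mr_stop(sprintf("%s requires at least %d instruments (got %d)",
                    method, min_n, nrow(insts)),
            "mrscreen_insufficient_instruments")
  if (any(insts$se_exp <= 0) || any(insts$se_out <= 0))
    mr_stop("instrument standard errors must be strictly positive",
            "mrscreen_domain_error")
}

#' Per-SNP Wald ratio estimates
#'
#' theta = beta_out / beta_exp with first-order SE = se_out / |beta_exp| and
#' inverse-variance weight.
#'
#' @param insts Harmonized-instrument data.frame (see [harmonize_pair()]).
#' @return data.frame `snp_id, theta, se, weight`.
#' @export
wald_ratio <- function(insts) {
  if (any(insts$beta_exp == 0))
    mr_stop("beta_exp = 0: degenerate instrument, Wald ratio undefined",
            "mrscreen_degenerate_instrument")
  theta <- insts$beta_out / insts$beta_exp
  se <- insts$se_out / abs(insts$beta_exp)
  data.frame(snp_id = insts$snp_id, theta = theta, se = se,
             weight = se^-2, stringsAsFactors = FALSE)
}

#' Random-effects inverse-variance-weighted estimate
#'
#' The precision-weighted mean of the Wald ratios.  With ratios
#' \eqn{\theta_j} and weights \eqn{w_j = se_j^{-2}}:
#' \eqn{\hat\beta = \sum w_j \theta_j / \sum w_j},
#' \eqn{SE_{fixed} = (\sum w_j)^{-1/2}},
#' Cochran's \eqn{Q = \sum w_j (\theta_j - \hat\beta)^2}, multiplicative
#' random-effects scale \eqn{\phi = \max(1, \sqrt{Q/(J-1)})},
#' \eqn{SE = SE_{fixed}\,\phi}; normal p-value and 95% CI.
#'
#' @param insts Harmonized-instrument data.frame (at least 2 rows).
#' @return List of class `mr_ivw_result`: `estimate` ([mr_estimate()],
#'   method `"IVW"`), `q_stat`, `q_df`, `q_p`, `phi`, `se_fixed`.
#' @export
mr_ivw <- function(insts) {
  check_instruments(insts, 2L, "IVW")
  wr <- wald_ratio(insts)
  w <- wr$weight
  beta <- sum(w * wr$theta) / sum(w)
  se_fixed <- sum(w)^-0.5
  q <- sum(w * (wr$theta - beta)^2)
  j <- nrow(insts)
  phi <- max(1, sqrt(q / (j - 1)))
  se <- se_fixed * phi
  p <- 2 * stats::pnorm(-abs(beta / se))
  structure(list(
    estimate = mr_estimate("IVW", beta, se, p, j, crit = 1.96),
    q_stat = q, q_df = j - 1L,
    q_p = stats::pchisq(q, df = j - 1, lower.tail = FALSE),
    phi = phi, se_fixed = se_fixed
  ), class = "mr_ivw_result")
}

#' Weighted median of a set of values
#'
#' Sorts the values ascending (carrying their weights); with cumulative
#' weights \eqn{S_j} and total \eqn{S}, defines
#' \eqn{p_j = (S_j - w_j/2)/S} and returns the value linearly interpolated
#' at \eqn{p = 0.5} (the boundary value when 0.5 lies outside
#' \eqn{[p_1, p_J]}).
#'
#' @param values Numeric vector (length >= 1).
#' @param weights Strictly positive weights, same length.
#' @return The weighted median.
#' @export
weighted_median_value <- function(values, weights) {
  if (length(values) == 0 || length(values) != length(weights))
    mr_stop("values and weights must be non-empty and the same length",
            "mrscreen_domain_error")
  if (any(weights <= 0))
    mr_stop("weights must be strictly positive", "mrscreen_domain_error")
  ord <- order(values)
  v <- values[ord]; w <- weights[ord]
  p <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= p[1]) return(v[1])
  if (0.5 >= p[length(p)]) return(v[length(v)])
  stats::approx(p, v, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median causal estimate
#'
#' Point estimate: the [weighted_median_value()] of the Wald ratios with
#' inverse-variance weights.  Consistent when instruments carrying at least
#' half the weight are valid.  The SE comes from a parametric bootstrap:
#' each replicate redraws every ratio from Normal(theta_j, se_j) and
#' recomputes the weighted median; SE is the standard deviation of the
#' replicates.  p-value and CI use the normal approximation.
#'
#' @param insts Harmonized-instrument data.frame (at least 3 rows).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Optional seed making the bootstrap reproducible; the global
#'   RNG state is restored afterwards.
#' @return An [mr_estimate()] with method `"WM"`.
#' @export
mr_weighted_median <- function(insts, n_boot = 1000, seed = NULL) {
  check_instruments(insts, 3L, "weighted median")
  wr <- wald_ratio(insts)
  beta <- weighted_median_value(wr$theta, wr$weight)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      theta_b <- stats::rnorm(length(wr$theta), mean = wr$theta, sd = wr$se)
      weighted_median_value(theta_b, wr$weight)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  p <- 2 * stats::pnorm(-abs(beta / se))
  mr_estimate("WM", beta, se, p, nrow(insts), crit = 1.96)
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome effects on the exposure effects
#' with a free intercept and weights `se_out^-2`, after orienting every
#' instrument so that `beta_exp >= 0` (required for the intercept to
#' estimate average directional pleiotropy).  Coefficient SEs are scaled by
#' the multiplicative overdispersion factor
#' \eqn{\phi_E = \max(1, \sqrt{RSS_w/(J-2)})}; p-values and the CI
#' multiplier use the t distribution with J - 2 degrees of freedom
#' (configurable via `ci_type`).
#'
#' @param insts Harmonized-instrument data.frame (at least 3 rows).
#' @param ci_type `"t"` (default) or `"normal"` for the slope CI multiplier.
#' @return List of class `mr_egger_result`: `slope` ([mr_estimate()],
#'   method `"MR-Egger"`), `intercept`, `intercept_se`, `intercept_p`,
#'   `phi`, `df`.
#' @export
mr_egger <- function(insts, ci_type = c("t", "normal")) {
  ci_type <- match.arg(ci_type)
  check_instruments(insts, 3L, "MR-Egger")
  sgn <- ifelse(insts$beta_exp < 0, -1, 1)
  x <- insts$beta_exp * sgn
  y <- insts$beta_out * sgn
  w <- insts$se_out^-2
  if (stats::var(x) == 0)
    mr_stop("beta_exp has zero variance: MR-Egger slope not identifiable",
            "mrscreen_collinearity_error")
  X <- cbind(intercept = 1, slope = x)
  xtwx <- crossprod(X, w * X)
  coefs <- drop(solve(xtwx, crossprod(X, w * y)))
  fitted <- drop(X %*% coefs)
  j <- nrow(insts)
  df <- j - 2L
  rss_w <- sum(w * (y - fitted)^2)
  phi <- max(1, sqrt(rss_w / df))
  covmat <- solve(xtwx) * phi^2
  ses <- sqrt(diag(covmat))
  pvals <- 2 * stats::pt(-abs(coefs / ses), df = df)
  crit <- if (ci_type == "t") stats::qt(0.975, df = df) else 1.96
  structure(list(
    slope = mr_estimate("MR-Egger", coefs[["slope"]], ses[["slope"]],
                        pvals[["slope"]], j, crit = crit),
    intercept = coefs[["intercept"]],
    intercept_se = ses[["intercept"]],
    intercept_p = pvals[["intercept"]],
    phi = phi, df = df
  ), class = "mr_egger_result")
}
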