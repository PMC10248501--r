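## Synthetic GWAS summary statistics with known ground truth.
##
## The generator works at the summary-statistic level (not genotypes): per
## SNP j it draws a minor allele frequency, a true SNP->exposure effect
## gamma_j, and — for a configurable "invalid" fraction — a direct
## SNP->outcome (horizontal-pleiotropy) effect alpha_j, independent of
## gamma_j so the InSIDE condition holds by default.  The true outcome
## effect is Gamma_j = theta * gamma_j + alpha_j.  Observed effects are
## drawn Normal(truth, se) with the standard per-allele variance
## approximation for a standardized trait,
##   se = (2 * maf * (1 - maf) * N)^(-1/2),
## for the exposure and (on the log-odds scale) the outcome alike.

#' Simulation configuration
#'
#' Defaults emulate a microbiome-GWAS exposure (N = 18,340) and a
#' periodontitis-scale case-control outcome (N = 45,563) with strong,
#' mutually independent instruments.  `gamma_mean = 0.12, gamma_sd = 0.03`
#' give per-SNP F statistics of roughly 40-150 at these sample sizes,
#' matching instruments that survived an F >= 10 screen.
#'
#' @param n_snps Number of instruments J.
#' @param theta True causal effect (log-odds of outcome per SD exposure).
#' @param gamma_mean,gamma_sd Normal distribution of true SNP-exposure
#'   effects (per-SD units).
#' @param pleiotropy_mean,pleiotropy_sd Normal distribution of direct
#'   SNP-outcome effects for invalid SNPs (log-odds units).
#' @param invalid_fraction Share of SNPs with nonzero pleiotropy, in
#'   \[0, 1\]; the first `round(invalid_fraction * n_snps)` SNPs are invalid.
#' @param n_exposure,n_outcome GWAS sample sizes.
#' @param maf_low,maf_high Uniform minor-allele-frequency bounds,
#'   0 < maf_low <= maf_high <= 0.5.
#' @param palindromic_fraction Expected share of A/T-or-C/G SNPs.
#' @param se_scale Multiplier on the sampling noise (0 = noiseless limit:
#'   observed effects equal the truth while reported SEs keep their nominal
#'   values).
#' @param inside_violation Correlation introduced between gamma and alpha
#'   (0 = InSIDE holds); implemented as alpha <- alpha +
#'   `inside_violation` * (gamma - gamma_mean).
#' @param seed Optional integer seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_snps = 15, theta = 0,
                       gamma_mean = 0.12, gamma_sd = 0.03,
                       pleiotropy_mean = 0, pleiotropy_sd = 0,
                       invalid_fraction = 0,
                       n_exposure = 18340, n_outcome = 45563,
                       maf_low = 0.05, maf_high = 0.5,
                       palindromic_fraction = 0.2,
                       se_scale = 1, inside_violation = 0, seed = NULL) {
  if (n_snps < 1)
    mr_stop("n_snps must be at least 1", "mrscreen_domain_error")
  if (invalid_fraction < 0 || invalid_fraction > 1)
    mr_stop("invalid_fraction must lie in [0,1]", "mrscreen_domain_error")
  if (maf_low <= 0 || maf_low > maf_high || maf_high > 0.5)
    mr_stop("require 0 < maf_low <= maf_high <= 0.5",
            "mrscreen_domain_error")
  if (n_exposure < 3 || n_outcome < 3)
    mr_stop("sample sizes must be at least 3", "mrscreen_domain_error")
  if (se_scale < 0)
    mr_stop("se_scale must be non-negative", "mrscreen_domain_error")
  structure(list(n_snps = as.integer(n_snps), theta = theta,
                 gamma_mean = gamma_mean, gamma_sd = gamma_sd,
                 pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd,
                 invalid_fraction = invalid_fraction,
                 n_exposure = n_exposure, n_outcome = n_outcome,
                 maf_low = maf_low, maf_high = maf_high,
                 palindromic_fraction = palindromic_fraction,
                 se_scale = se_scale, inside_violation = inside_violation,
                 seed = seed),
            class = "sim_config")
}

PALINDROMIC_PAIRS <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
                            ncol = 2, byrow = TRUE)
NONPALINDROMIC_PAIRS <- matrix(c("A", "C", "A", "G", "C", "A", "C", "T",
                                 "G", "A", "G", "T", "T", "C", "T", "G"),
                               ncol = 2, byrow = TRUE)

#' Simulate a two-sample MR study
#'
#' Draws a complete pair of exposure and outcome summary-statistics tables
#' with known truth.  Instruments are placed far apart on alternating
#' chromosomes (mutually unlinked), matching the post-clumping independence
#' the estimators assume.  Fully reproducible given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return Object of class `simulated_study`: `exposure_stats` and
#'   `outcome_stats` (canonical summary-statistics data.frames),
#'   `truth` (list `theta`, per-SNP `gamma`, `alpha`, `invalid_ids`), and
#'   `ld` (an empty [ld_table()]: instruments are independent).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    j <- config$n_snps
    snp_id <- sprintf("rs%05d", seq_len(j))
    chrom <- as.character(((seq_len(j) - 1) %% 22) + 1)
    pos <- 1e6 + seq_len(j) * 2e6   # >> any clumping window apart per chrom

    maf <- stats::runif(j, config$maf_low, config$maf_high)
    gamma <- stats::rnorm(j, config$gamma_mean, config$gamma_sd)
    n_invalid <- round(config$invalid_fraction * j)
    alpha <- numeric(j)
    if (n_invalid > 0)
      alpha[seq_len(n_invalid)] <- stats::rnorm(n_invalid,
                                                config$pleiotropy_mean,
                                                config$pleiotropy_sd)
    if (config$inside_violation != 0 && n_invalid > 0) {
      idx <- seq_len(n_invalid)
      alpha[idx] <- alpha[idx] +
        config$inside_violation * (gamma[idx] - config$gamma_mean)
    }
    big_gamma <- config$theta * gamma + alpha

    se_exp <- (2 * maf * (1 - maf) * config$n_exposure)^-0.5
    se_out <- (2 * maf * (1 - maf) * config$n_outcome)^-0.5
    beta_exp <- gamma + config$se_scale * stats::rnorm(j, 0, se_exp)
    beta_out <- big_gamma + config$se_scale * stats::rnorm(j, 0, se_out)

    pal <- stats::runif(j) < config$palindromic_fraction
    pick <- function(is_pal) {
      m <- if (is_pal) PALINDROMIC_PAIRS else NONPALINDROMIC_PAIRS
      m[sample.int(nrow(m), 1L), ]
    }
    alleles <- t(vapply(pal, pick, character(2)))

    ## effect allele is the minor or major allele at random
    minor_is_effect <- stats::runif(j) < 0.5
    eaf <- ifelse(minor_is_effect, maf, 1 - maf)

    mk <- function(beta, se, n) data.frame(
      snp_id = snp_id, chrom = chrom, pos = pos,
      effect_allele = alleles[, 1], other_allele = alleles[, 2],
      eaf = eaf, beta = beta, se = se,
      pvalue = derive_pvalue(beta, se), n = n,
      stringsAsFactors = FALSE)

    structure(list(
      exposure_stats = mk(beta_exp, se_exp, config$n_exposure),
      outcome_stats = mk(beta_out, se_out, config$n_outcome),
      truth = list(theta = config$theta, gamma = gamma, alpha = alpha,
                   invalid_ids = snp_id[seq_len(j) <= n_invalid]),
      ld = ld_table(),
      config = config
    ), class = "simulated_study")
  })
}

#' Simulate one LD block
#'
#' Emits evenly spaced positions on one chromosome and a symmetric LD table
#' with r-squared decaying exponentially with distance:
#' r2(d kb) = `r2_zero` * exp(-`decay` * d).  With the defaults (spacing
#' 50 kb, decay 0.025/kb) adjacent SNPs have r2 of about 0.27 and SNPs two
#' or more slots apart fall below 0.1, so any block of 3 or more SNPs
#' contains at least one pair above and one below the conventional 0.1
#' pruning threshold.
#'
#' @param n_snps Block size (>= 1).
#' @param decay Exponential decay rate per kb (default 0.025; 0 = all
#'   off-diagonal r2 equal to `r2_zero`).
#' @param r2_zero r-squared at zero distance between distinct SNPs
#'   (default 0.95).
#' @param spacing_kb Distance between adjacent SNPs in kb (default 50).
#' @param chrom Chromosome label (default "1").
#' @param start_pos Position of the first SNP (default 1e6).
#' @param seed Unused by the deterministic layout but accepted for
#'   interface stability.
#' @return List with `positions` (data.frame `snp_id, chrom, pos`) and
#'   `ld` (an [ld_table()]).
#' @export
simulate_ld_block <- function(n_snps, decay = 0.025, r2_zero = 0.95,
                              spacing_kb = 50, chrom = "1",
                              start_pos = 1e6, seed = NULL) {
  if (n_snps < 1)
    mr_stop("n_snps must be at least 1", "mrscreen_domain_error")
  snp_id <- sprintf("blk%03d", seq_len(n_snps))
  pos <- start_pos + (seq_len(n_snps) - 1) * spacing_kb * 1000
  pairs <- NULL
  if (n_snps >= 2) {
    idx <- utils::combn(n_snps, 2)
    d_kb <- abs(pos[idx[1, ]] - pos[idx[2, ]]) / 1000
    pairs <- data.frame(snp_a = snp_id[idx[1, ]], snp_b = snp_id[idx[2, ]],
                        r2 = pmin(1, r2_zero * exp(-decay * d_kb)),
                        stringsAsFactors = FALSE)
  }
  list(positions = data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                              stringsAsFactors = FALSE),
       ld = ld_table(pairs),
       pairs = pairs)
}

#' Write a simulated study to disk
#'
#' Writes `exposure.tsv`, `outcome.tsv`, `ld.tsv` (empty pair table) and
#' `truth.json` under a prefix.
#'
#' @param study A [simulate_study()] result.
#' @param out_prefix Directory (created if needed).
#' @export
write_simulated_study <- function(study, out_prefix) {
  stopifnot(inherits(study, "simulated_study"))
  dir.create(out_prefix, recursive = TRUE, showWarnings = FALSE)
  cols <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
            "eaf", "beta", "se", "pvalue", "n")
  write_table(study$exposure_stats, file.path(out_prefix, "exposure.tsv"),
              cols, digits = 10)
  write_table(study$outcome_stats, file.path(out_prefix, "outcome.tsv"),
              cols, digits = 10)
  write_table(data.frame(snp_a = character(0), snp_b = character(0),
                         r2 = numeric(0)),
              file.path(out_prefix, "ld.tsv"))
  jsonlite::write_json(study$truth, file.path(out_prefix, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
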