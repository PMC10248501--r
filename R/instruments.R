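## Instrument selection for one exposure: p-value thresholding, greedy LD
## clumping, instrument-strength (R^2, F) filtering, and exclusion of
## confounder-associated SNPs.

#' Instrument-selection configuration
#'
#' Thresholds follow the conventional relaxed-instrument screen for
#' microbiome-scale exposures: genome-wide suggestive significance
#' p < 1e-5 (few taxa have genome-wide significant hits), LD pruning at
#' r^2 < 0.1 within a 500 kb window, and elimination of weak instruments
#' with F < 10.  All inequalities are strict in the stated direction:
#' p < `p_threshold` kept, r^2 >= `r2_max` pruned, F < `f_min` removed
#' (so F = 10 is kept).
#'
#' @param p_threshold Exposure-association significance cutoff (default 1e-5).
#' @param r2_max LD pruning threshold (default 0.1).
#' @param window_kb Clumping window half-width in kilobases (default 500).
#' @param f_min Minimum F statistic (default 10).
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(p_threshold = 1e-5, r2_max = 0.1,
                             window_kb = 500, f_min = 10) {
  if (p_threshold <= 0 || p_threshold >= 1)
    mr_stop("p_threshold must be in (0,1)", "mrscreen_config_error")
  if (r2_max < 0 || r2_max > 1)
    mr_stop("r2_max must be in [0,1]", "mrscreen_config_error")
  if (window_kb <= 0)
    mr_stop("window_kb must be positive", "mrscreen_config_error")
  if (f_min < 0)
    mr_stop("f_min must be non-negative", "mrscreen_config_error")
  structure(list(p_threshold = p_threshold, r2_max = r2_max,
                 window_kb = window_kb, f_min = f_min),
            class = "selection_config")
}

#' Pairwise LD table
#'
#' Symmetric lookup of r-squared keyed by unordered SNP pairs; absent pairs
#' mean r^2 = 0 and r^2(a, a) = 1 by definition.
#'
#' @param pairs Optional data.frame with columns `snp_a`, `snp_b`, `r2`.
#' @return An object of class `ld_table`.
#' @export
ld_table <- function(pairs = NULL) {
  env <- new.env(parent = emptyenv())
  obj <- structure(list(env = env), class = "ld_table")
  if (!is.null(pairs)) {
    stopifnot(all(c("snp_a", "snp_b", "r2") %in% names(pairs)))
    if (any(pairs$r2 < 0 | pairs$r2 > 1))
      mr_stop("r2 values must lie in [0,1]", "mrscreen_domain_error")
    for (i in seq_len(nrow(pairs))) {
      a <- pairs$snp_a[i]; b <- pairs$snp_b[i]
      if (a == b) next   # diagonal is implicit
      key <- paste(sort(c(a, b)), collapse = "\r")
      assign(key, pairs$r2[i], envir = env)
    }
  }
  obj
}

#' Look up pairwise r-squared
#'
#' @param ld An [ld_table()].
#' @param a,b SNP ids.
#' @return r^2 in \[0, 1\]; 1 when `a == b`, 0 when the pair is absent.
#' @export
ld_r2 <- function(ld, a, b) {
  stopifnot(inherits(ld, "ld_table"))
  if (a == b) return(1)
  key <- paste(sort(c(a, b)), collapse = "\r")
  if (exists(key, envir = ld$env, inherits = FALSE))
    get(key, envir = ld$env) else 0
}

#' Read a long-format LD table (columns snp_a, snp_b, r2)
#'
#' @param path Path to a TSV file.
#' @return An [ld_table()].
#' @export
read_ld_table <- function(path) {
  ld_table(read_table_tsv(path))
}

#' Read a SNP exclusion list
#'
#' One SNP id per line; `#` starts a comment.
#'
#' @param path Path to a text file.
#' @return Character vector of SNP ids.
#' @export
read_exclusion_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' Keep records significantly associated with the exposure
#'
#' Strict inequality: records with `pvalue < p_threshold` are kept, input
#' order preserved.
#'
#' @param records Canonical summary-statistics data.frame.
#' @param p_threshold Cutoff.
#' @return Filtered data.frame (possibly empty).
#' @export
select_by_pvalue <- function(records, p_threshold = 1e-5) {
  records[!is.na(records$pvalue) & records$pvalue < p_threshold, ,
          drop = FALSE]
}

#' Greedy LD clumping
#'
#' Candidates are sorted by ascending p (ties: chrom, pos, snp_id); the best
#' remaining SNP becomes an index and every remaining SNP on the same
#' chromosome within `window_kb` kilobases (inclusive, position-to-position)
#' with r^2 at or above `r2_max` is discarded.  SNPs on different chromosomes
#' are never pruned against each other.  Output is sorted by (chrom, pos).
#'
#' @param records Canonical summary-statistics data.frame with non-missing
#'   `chrom` and `pos`.
#' @param ld An [ld_table()].
#' @param config A [selection_config()].
#' @return Clumped data.frame sorted by (chrom, pos).
#' @export
ld_clump <- function(records, ld = ld_table(), config = selection_config()) {
  if (nrow(records) == 0) return(records)
  if (any(is.na(records$chrom)) || any(is.na(records$pos)))
    mr_stop("ld_clump requires chrom and pos on every record",
            "mrscreen_input_error")
  ord <- order(records$pvalue, records$chrom, records$pos, records$snp_id)
  cand <- records[ord, , drop = FALSE]
  window_bp <- config$window_kb * 1000
  keep <- character(0)
  alive <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!alive[i]) next
    keep <- c(keep, cand$snp_id[i])
    alive[i] <- FALSE
    j <- which(alive)
    if (length(j) == 0) break
    same_chr <- cand$chrom[j] == cand$chrom[i]
    near <- abs(cand$pos[j] - cand$pos[i]) <= window_bp
    for (k in j[same_chr & near]) {
      if (ld_r2(ld, cand$snp_id[i], cand$snp_id[k]) >= config$r2_max)
        alive[k] <- FALSE
    }
  }
  out <- records[records$snp_id %in% keep, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Variance of the exposure explained by one instrument
#'
#' R^2 = beta^2 / (beta^2 + se^2 * n).
#'
#' @param beta Exposure effect estimate(s).
#' @param se Standard error(s), strictly positive.
#' @param n Sample size(s), at least 3.
#' @return R^2 value(s) in \[0, 1).
#' @export
explained_variance <- function(beta, se, n) {
  if (any(!is.finite(se)) || any(se <= 0))
    mr_stop("se must be strictly positive", "mrscreen_domain_error")
  if (any(!is.finite(n)) || any(n < 3))
    mr_stop("n must be at least 3", "mrscreen_domain_error")
  beta^2 / (beta^2 + se^2 * n)
}

#' Instrument-strength F statistic
#'
#' F = R^2 / (1 - R^2) * (N - 2).
#'
#' @param r_squared Explained variance(s) in \[0, 1).
#' @param n Sample size(s), at least 3.
#' @return F value(s), non-negative.
#' @export
f_statistic <- function(r_squared, n) {
  if (any(!is.finite(r_squared)) || any(r_squared < 0) || any(r_squared >= 1))
    mr_stop("r_squared must lie in [0,1)", "mrscreen_domain_error")
  if (any(!is.finite(n)) || any(n < 3))
    mr_stop("n must be at least 3", "mrscreen_domain_error")
  r_squared / (1 - r_squared) * (n - 2)
}

#' Eliminate weak instruments by F statistic
#'
#' Computes per-SNP explained variance and F; records with F below
#' `config$f_min` are eliminated (F equal to the threshold is kept).
#'
#' @param records Canonical summary-statistics data.frame.
#' @param meta A [study_meta()] supplying `default_n` for records without a
#'   per-SNP sample size.
#' @param config A [selection_config()].
#' @return List with `kept` (surviving records) and `strengths` (data.frame
#'   `snp_id`, `n`, `r_squared`, `f_stat` for every input record).
#' @export
filter_weak_instruments <- function(records, meta,
                                    config = selection_config()) {
  if (nrow(records) == 0)
    return(list(kept = records,
                strengths = data.frame(snp_id = character(0), n = numeric(0),
                                       r_squared = numeric(0),
                                       f_stat = numeric(0))))
  n_used <- ifelse(is.na(records$n), meta$default_n, records$n)
  if (any(is.na(n_used)))
    mr_stop("sample size missing and no default_n in study metadata",
            "mrscreen_config_error")
  r2 <- explained_variance(records$beta, records$se, n_used)
  f <- f_statistic(r2, n_used)
  strengths <- data.frame(snp_id = records$snp_id, n = n_used,
                          r_squared = r2, f_stat = f,
                          stringsAsFactors = FALSE)
  list(kept = records[f >= config$f_min, , drop = FALSE],
       strengths = strengths)
}

#' Remove SNPs on an exclusion list
#'
#' Typically a user-supplied list of variants associated with confounders of
#' the exposure-outcome relationship (e.g. from a phenome-wide lookup).
#'
#' @param records Canonical summary-statistics data.frame.
#' @param exclusion_ids Character vector of SNP ids to remove.
#' @return Filtered data.frame; ids on the list but absent from `records`
#'   trigger a warning.
#' @export
filter_excluded <- function(records, exclusion_ids = character(0)) {
  if (length(exclusion_ids) == 0) return(records)
  absent <- setdiff(exclusion_ids, records$snp_id)
  if (length(absent) > 0)
    mr_warn(sprintf("exclusion id(s) not present in records: %s",
                    paste(absent, collapse = ", ")),
            "mrscreen_exclusion_warning")
  records[!(records$snp_id %in% exclusion_ids), , drop = FALSE]
}
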