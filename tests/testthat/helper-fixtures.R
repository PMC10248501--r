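# Fixture builders and independent oracles shared across test files.

make_records <- function(snp_id, chrom = "1", pos = seq_along(snp_id) * 1e6,
                         ea = "A", oa = "G", eaf = 0.3, beta = 0.1,
                         se = 0.02, pvalue = NULL, n = 10000) {
  df <- data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                   effect_allele = ea, other_allele = oa, eaf = eaf,
                   beta = beta, se = se,
                   pvalue = NA_real_, n = n, stringsAsFactors = FALSE)
  df$pvalue <- if (is.null(pvalue)) derive_pvalue(df$beta, df$se) else pvalue
  df
}

make_insts <- function(beta_exp, beta_out, se_exp = 0.02, se_out = 0.05,
                       snp_id = sprintf("rs%d", seq_along(beta_exp))) {
  data.frame(snp_id = snp_id, chrom = "1",
             pos = seq_along(beta_exp) * 1e6,
             effect_allele = "A", other_allele = "G",
             beta_exp = beta_exp, se_exp = se_exp,
             beta_out = beta_out, se_out = se_out,
             eaf_exp = 0.3, swapped = FALSE, strand_flipped = FALSE,
             palindromic = FALSE, stringsAsFactors = FALSE)
}

# Random well-conditioned instrument sets for property tests.
random_insts <- function(j) {
  make_insts(beta_exp = runif(j, 0.05, 0.3) * sample(c(-1, 1), j, TRUE),
             beta_out = rnorm(j, 0, 0.1),
             se_exp = runif(j, 0.01, 0.05),
             se_out = runif(j, 0.02, 0.1))
}

# Oracle: IVW as weighted regression of beta_out on beta_exp through the
# origin with weights se_out^-2 (lm is an independent code path).
oracle_ivw_beta <- function(insts) {
  fit <- lm(beta_out ~ 0 + beta_exp, data = insts,
            weights = insts$se_out^-2)
  unname(coef(fit)[1])
}

# Oracle: MR-Egger via lm with intercept after beta_exp >= 0 orientation.
oracle_egger <- function(insts) {
  sgn <- ifelse(insts$beta_exp < 0, -1, 1)
  d <- data.frame(x = insts$beta_exp * sgn, y = insts$beta_out * sgn,
                  w = insts$se_out^-2)
  fit <- lm(y ~ x, data = d, weights = d$w)
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]))
}

# Oracle: weighted median by dense expansion of the interpolation rule.
oracle_weighted_median <- function(values, weights) {
  ord <- order(values)
  v <- values[ord]; w <- weights[ord]
  p <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= p[1]) return(v[1])
  if (0.5 >= p[length(p)]) return(v[length(v)])
  i <- max(which(p <= 0.5))
  v[i] + (v[i + 1] - v[i]) * (0.5 - p[i]) / (p[i + 1] - p[i])
}

# Oracle: direct transliteration of the greedy clumping rule, kept
# deliberately naive (repeated scans, no early exits).
oracle_clump_ids <- function(records, ld, r2_max, window_kb) {
  pool <- records[order(records$pvalue, records$chrom, records$pos,
                        records$snp_id), , drop = FALSE]
  kept <- character(0)
  while (nrow(pool) > 0) {
    idx <- pool[1, ]
    kept <- c(kept, idx$snp_id)
    drop <- vapply(seq_len(nrow(pool)), function(i) {
      if (i == 1) return(TRUE)
      r <- pool[i, ]
      r$chrom == idx$chrom &&
        abs(r$pos - idx$pos) <= window_kb * 1000 &&
        ld_r2(ld, idx$snp_id, r$snp_id) >= r2_max
    }, logical(1))
    pool <- pool[!drop, , drop = FALSE]
  }
  sort(kept)
}

est_fields <- function(e) c(beta = e$beta, se = e$se, p = e$pvalue)
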