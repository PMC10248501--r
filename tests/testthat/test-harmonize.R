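mk_rec <- function(snp = "rs1", ea = "A", oa = "G", beta = 0.1, se = 0.02,
                   eaf = 0.3, chrom = "1", pos = 1e6) {
  data.frame(snp_id = snp, chrom = chrom, pos = pos, effect_allele = ea,
             other_allele = oa, eaf = eaf, beta = beta, se = se,
             pvalue = derive_pvalue(beta, se), n = 1e4,
             stringsAsFactors = FALSE)
}

test_that("harmonize_pair handles identity, swap, strand flip, palindrome", {
  ex <- mk_rec(ea = "A", oa = "G", beta = 0.1)

  # (a) identical orientation: pass-through
  r <- harmonize_pair(ex, mk_rec(ea = "A", oa = "G", beta = -0.05))
  expect_equal(r$status, "ok")
  expect_equal(r$instrument$beta_out, -0.05)
  expect_false(r$instrument$swapped || r$instrument$strand_flipped)

  # (b) swapped alleles: sign change
  r <- harmonize_pair(ex, mk_rec(ea = "G", oa = "A", beta = -0.05,
                                 eaf = 0.7))
  expect_equal(r$instrument$beta_out, 0.05)
  expect_true(r$instrument$swapped)

  # (c) strand flip without swap: G/T vs C/A, same-direction frequencies
  ex2 <- mk_rec(ea = "G", oa = "T", eaf = 0.3)
  r <- harmonize_pair(ex2, mk_rec(ea = "C", oa = "A", beta = 0.07,
                                  eaf = 0.31))
  expect_equal(r$status, "ok")
  expect_equal(r$instrument$beta_out, 0.07)  # no sign change
  expect_true(r$instrument$strand_flipped)
  expect_false(r$instrument$swapped)

  # strand flip plus swap
  r <- harmonize_pair(ex2, mk_rec(ea = "A", oa = "C", beta = 0.07,
                                  eaf = 0.69))
  expect_equal(r$instrument$beta_out, -0.07)
  expect_true(r$instrument$strand_flipped && r$instrument$swapped)

  # (e) incompatible allele sets
  r <- harmonize_pair(ex, mk_rec(ea = "A", oa = "C"))
  expect_equal(r$status, "drop_incompatible")

  # snp_id mismatch is a usage error
  expect_error(harmonize_pair(ex, mk_rec(snp = "rs2")),
               class = "mrscreen_usage_error")
})

test_that("palindromic SNPs resolve by allele frequency or drop", {
  pal <- mk_rec(ea = "A", oa = "T", eaf = 0.2, beta = 0.1)

  # ambiguous frequency: dropped
  amb <- mk_rec(ea = "A", oa = "T", eaf = 0.50)
  expect_equal(harmonize_pair(amb, mk_rec(ea = "A", oa = "T", eaf = 0.2),
                              tolerance = 0.08)$status, "drop_palindromic")
  # boundary of the ambiguity zone (0.42..0.58 inclusive at default 0.08)
  amb2 <- mk_rec(ea = "A", oa = "T", eaf = 0.42)
  expect_equal(harmonize_pair(amb2, mk_rec(ea = "A", oa = "T", eaf = 0.2)
                              )$status, "drop_palindromic")
  # missing outcome EAF: dropped
  expect_equal(harmonize_pair(pal, mk_rec(ea = "A", oa = "T",
                                          eaf = NA))$status,
               "drop_palindromic")

  # frequencies agree: no flip
  r <- harmonize_pair(pal, mk_rec(ea = "A", oa = "T", beta = 0.05,
                                  eaf = 0.22))
  expect_equal(r$instrument$beta_out, 0.05)
  expect_true(r$instrument$palindromic)

  # frequencies disagree (outcome on opposite strand): flip the sign
  r <- harmonize_pair(pal, mk_rec(ea = "A", oa = "T", beta = 0.05,
                                  eaf = 0.78))
  expect_equal(r$instrument$beta_out, -0.05)

  # swapped labels plus agreeing post-swap frequency
  r <- harmonize_pair(pal, mk_rec(ea = "T", oa = "A", beta = 0.05,
                                  eaf = 0.78))
  expect_equal(r$instrument$beta_out, -0.05)  # swap only

  # drop_all_palindromic switch drops even resolvable palindromes
  expect_equal(harmonize_pair(pal, mk_rec(ea = "A", oa = "T", eaf = 0.22),
                              drop_all_palindromic = TRUE)$status,
               "drop_palindromic")
})

test_that("representation invariance: re-expressed outcome gives the same instrument", {
  set.seed(7)
  for (i in 1:20) {
    ex <- mk_rec(ea = "A", oa = "G", beta = rnorm(1, 0, 0.1),
                 eaf = runif(1, 0.05, 0.95))
    out1 <- mk_rec(ea = "A", oa = "G", beta = rnorm(1, 0, 0.1),
                   eaf = runif(1, 0.05, 0.95))
    out2 <- out1
    out2$effect_allele <- out1$other_allele
    out2$other_allele <- out1$effect_allele
    out2$beta <- -out1$beta
    out2$eaf <- 1 - out1$eaf
    a <- harmonize_pair(ex, out1)$instrument
    b <- harmonize_pair(ex, out2)$instrument
    cols <- c("beta_exp", "se_exp", "beta_out", "se_out", "eaf_exp")
    expect_equal(a[, cols], b[, cols])
  }
})

test_that("harmonize_all joins, sorts, and reconciles its report", {
  # disjoint sets: everything dropped-unmatched
  ex <- rbind(mk_rec("rs1"), mk_rec("rs2", pos = 2e6))
  out <- mk_rec("rs9")
  h <- harmonize_all(ex, out)
  expect_equal(h$report$n_harmonized, 0)
  expect_equal(h$report$n_dropped_unmatched, 2)

  # identical well-oriented sets: all harmonized
  ex5 <- do.call(rbind, lapply(1:5, function(i)
    mk_rec(sprintf("rs%d", i), pos = i * 1e6)))
  h <- harmonize_all(ex5, ex5)
  expect_equal(h$report$n_harmonized, 5)
  expect_equal(nrow(h$instruments), 5)

  # mixed case: identity + swap + palindromic-ambiguous + incompatible
  ex4 <- rbind(mk_rec("a", ea = "A", oa = "G", pos = 1e6),
               mk_rec("b", ea = "A", oa = "G", pos = 2e6),
               mk_rec("c", ea = "A", oa = "T", eaf = 0.5, pos = 3e6),
               mk_rec("d", ea = "A", oa = "G", pos = 4e6))
  out4 <- rbind(mk_rec("a", ea = "A", oa = "G"),
                mk_rec("b", ea = "G", oa = "A", eaf = 0.7),
                mk_rec("c", ea = "A", oa = "T", eaf = 0.2),
                mk_rec("d", ea = "A", oa = "C"))
  h <- harmonize_all(ex4, out4)
  expect_equal(h$report$n_harmonized, 2)
  expect_equal(h$report$n_dropped_palindromic_ambiguous, 1)
  expect_equal(h$report$n_dropped_incompatible, 1)
  expect_equal(h$report$n_input,
               h$report$n_harmonized + h$report$n_dropped_unmatched +
                 h$report$n_dropped_palindromic_ambiguous +
                 h$report$n_dropped_incompatible)
  # sorted by (chrom, pos)
  expect_false(is.unsorted(order(h$instruments$chrom, h$instruments$pos)))
})

test_that("estimators are invariant to swap/strand re-encoding end-to-end", {
  set.seed(11)
  j <- 8
  ex <- do.call(rbind, lapply(1:j, function(i)
    mk_rec(sprintf("rs%d", i), ea = "A", oa = "G", pos = i * 1e6,
           beta = runif(1, 0.05, 0.2), eaf = runif(1, 0.1, 0.9))))
  out_clean <- do.call(rbind, lapply(1:j, function(i)
    mk_rec(sprintf("rs%d", i), ea = "A", oa = "G",
           beta = rnorm(1, 0.05, 0.02), eaf = ex$eaf[i])))
  # re-encode a subset of outcome rows: swap some, strand-flip others
  out_enc <- out_clean
  for (i in c(2, 5)) {  # swap
    out_enc$effect_allele[i] <- "G"; out_enc$other_allele[i] <- "A"
    out_enc$beta[i] <- -out_enc$beta[i]
    out_enc$eaf[i] <- 1 - out_enc$eaf[i]
  }
  for (i in c(3, 7)) {  # strand flip
    out_enc$effect_allele[i] <- "T"; out_enc$other_allele[i] <- "C"
  }
  i1 <- harmonize_all(ex, out_clean)$instruments
  i2 <- harmonize_all(ex, out_enc)$instruments
  expect_equal(mr_ivw(i1)$estimate$beta, mr_ivw(i2)$estimate$beta)
  expect_equal(mr_egger(i1)$intercept, mr_egger(i2)$intercept)
  expect_equal(mr_weighted_median(i1, n_boot = 50, seed = 1)$beta,
               mr_weighted_median(i2, n_boot = 50, seed = 1)$beta)
})
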