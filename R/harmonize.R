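## Harmonization of exposure and outcome summary statistics onto a common
## effect allele: allele swaps, strand flips, palindromic-SNP resolution.

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(ea, oa) unname(COMPLEMENT[ea]) == oa

#' Harmonize one exposure/outcome record pair
#'
#' Aligns the outcome effect onto the exposure's effect allele:
#' \enumerate{
#'   \item identical alleles, same orientation: pass through;
#'   \item alleles swapped: negate the outcome beta, flip the outcome EAF;
#'   \item alleles match only after complementing the outcome pair
#'     (reported on the opposite strand): complement, then as above;
#'   \item palindromic SNP (A/T or C/G): strand cannot be inferred from
#'     alleles, so orientation is taken from allele frequencies — dropped as
#'     ambiguous when either EAF is missing or within
#'     `0.5 +/- tolerance`, otherwise oriented so both EAFs fall on the same
#'     side of 0.5;
#'   \item anything else: dropped as incompatible.
#' }
#'
#' @param exp,out Single-row canonical summary-statistic records (as
#'   data.frame rows or named lists) sharing `snp_id`.
#' @param tolerance Palindrome ambiguity half-width (default 0.08: drop when
#'   EAF lies in \[0.42, 0.58\]).
#' @param drop_all_palindromic Drop every palindromic SNP regardless of EAF.
#' @return A list with `status` (`"ok"`, `"drop_palindromic"` or
#'   `"drop_incompatible"`) and, when `"ok"`, `instrument`: a one-row
#'   data.frame with columns `snp_id, chrom, pos, effect_allele,
#'   other_allele, beta_exp, se_exp, beta_out, se_out, eaf_exp, swapped,
#'   strand_flipped, palindromic`.
#' @export
harmonize_pair <- function(exp, out, tolerance = 0.08,
                           drop_all_palindromic = FALSE) {
  if (exp$snp_id != out$snp_id)
    mr_stop("snp_id mismatch between exposure and outcome records",
            "mrscreen_usage_error")
  ea_x <- exp$effect_allele; oa_x <- exp$other_allele
  ea_y <- out$effect_allele; oa_y <- out$other_allele
  beta_out <- out$beta
  eaf_out <- out$eaf
  swapped <- FALSE; flipped <- FALSE
  palindromic <- is_palindromic(ea_x, oa_x)

  if (palindromic) {
    if (drop_all_palindromic)
      return(list(status = "drop_palindromic"))
    ## For a palindromic pair the complement equals the swap, so label
    ## alignment alone cannot fix the strand; EAF agreement must decide.
    if (ea_y == ea_x && oa_y == oa_x) {
      ## aligned on labels
    } else if (ea_y == oa_x && oa_y == ea_x) {
      beta_out <- -beta_out
      if (!is.na(eaf_out)) eaf_out <- 1 - eaf_out
      swapped <- TRUE
    } else {
      return(list(status = "drop_incompatible"))
    }
    ## inclusive boundary with a tiny guard against FP representation of
    ## the tolerance (0.42 must count as ambiguous at tolerance 0.08)
    ambiguous <- function(f) is.na(f) || abs(f - 0.5) <= tolerance + 1e-12
    if (ambiguous(exp$eaf) || ambiguous(eaf_out))
      return(list(status = "drop_palindromic"))
    if ((exp$eaf < 0.5) != (eaf_out < 0.5)) {
      ## outcome reported on the other strand: flip
      beta_out <- -beta_out
      eaf_out <- 1 - eaf_out
      flipped <- TRUE
    }
  } else {
    if (ea_y == ea_x && oa_y == oa_x) {
      ## pass through
    } else if (ea_y == oa_x && oa_y == ea_x) {
      beta_out <- -beta_out
      if (!is.na(eaf_out)) eaf_out <- 1 - eaf_out
      swapped <- TRUE
    } else {
      ea_c <- unname(COMPLEMENT[ea_y]); oa_c <- unname(COMPLEMENT[oa_y])
      if (ea_c == ea_x && oa_c == oa_x) {
        flipped <- TRUE
      } else if (ea_c == oa_x && oa_c == ea_x) {
        beta_out <- -beta_out
        if (!is.na(eaf_out)) eaf_out <- 1 - eaf_out
        swapped <- TRUE; flipped <- TRUE
      } else {
        return(list(status = "drop_incompatible"))
      }
    }
  }

  inst <- data.frame(
    snp_id = exp$snp_id,
    chrom = if (!is.null(exp$chrom)) exp$chrom else NA_character_,
    pos = if (!is.null(exp$pos)) exp$pos else NA_real_,
    effect_allele = ea_x, other_allele = oa_x,
    beta_exp = exp$beta, se_exp = exp$se,
    beta_out = beta_out, se_out = out$se,
    eaf_exp = exp$eaf,
    swapped = swapped, strand_flipped = flipped, palindromic = palindromic,
    stringsAsFactors = FALSE
  )
  list(status = "ok", instrument = inst)
}

#' Harmonize all shared SNPs between two summary-statistics tables
#'
#' Joins on `snp_id` (exposure SNPs absent from the outcome are counted as
#' unmatched drops), applies [harmonize_pair()] to every match, and returns
#' the harmonized instruments sorted by (chrom, pos) along with a report
#' whose counts always reconcile:
#' `n_input = n_harmonized + n_dropped_unmatched +
#' n_dropped_palindromic_ambiguous + n_dropped_incompatible`.
#'
#' @param exp_records,out_records Canonical summary-statistics data.frames.
#' @param tolerance,drop_all_palindromic Passed to [harmonize_pair()].
#' @return List with `instruments` (data.frame, see [harmonize_pair()]) and
#'   `report` (counts plus a per-SNP `actions` data.frame).
#' @export
harmonize_all <- function(exp_records, out_records, tolerance = 0.08,
                          drop_all_palindromic = FALSE) {
  n_input <- nrow(exp_records)
  out_idx <- match(exp_records$snp_id, out_records$snp_id)
  actions <- data.frame(snp_id = exp_records$snp_id,
                        action = NA_character_, stringsAsFactors = FALSE)
  insts <- vector("list", n_input)
  counts <- c(ok = 0L, drop_unmatched = 0L, drop_palindromic = 0L,
              drop_incompatible = 0L)
  for (i in seq_len(n_input)) {
    if (is.na(out_idx[i])) {
      actions$action[i] <- "drop_unmatched"
      counts["drop_unmatched"] <- counts["drop_unmatched"] + 1L
      next
    }
    res <- harmonize_pair(exp_records[i, ], out_records[out_idx[i], ],
                          tolerance = tolerance,
                          drop_all_palindromic = drop_all_palindromic)
    actions$action[i] <- if (res$status == "ok") "harmonized" else res$status
    counts[if (res$status == "ok") "ok" else res$status] <-
      counts[if (res$status == "ok") "ok" else res$status] + 1L
    if (res$status == "ok") insts[[i]] <- res$instrument
  }
  insts <- insts[!vapply(insts, is.null, logical(1))]
  instruments <- if (length(insts) > 0) do.call(rbind, insts) else
    data.frame(snp_id = character(0), chrom = character(0), pos = numeric(0),
               effect_allele = character(0), other_allele = character(0),
               beta_exp = numeric(0), se_exp = numeric(0),
               beta_out = numeric(0), se_out = numeric(0),
               eaf_exp = numeric(0), swapped = logical(0),
               strand_flipped = logical(0), palindromic = logical(0),
               stringsAsFactors = FALSE)
  if (nrow(instruments) > 0) {
    instruments <- instruments[order(instruments$chrom, instruments$pos), ,
                               drop = FALSE]
    rownames(instruments) <- NULL
  }
  report <- list(
    n_input = n_input,
    n_harmonized = unname(counts["ok"]),
    n_dropped_unmatched = unname(counts["drop_unmatched"]),
    n_dropped_palindromic_ambiguous = unname(counts["drop_palindromic"]),
    n_dropped_incompatible = unname(counts["drop_incompatible"]),
    actions = actions
  )
  stopifnot(report$n_input == report$n_harmonized +
              report$n_dropped_unmatched +
              report$n_dropped_palindromic_ambiguous +
              report$n_dropped_incompatible)
  list(instruments = instruments, report = report)
}
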