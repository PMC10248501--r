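## Per-exposure pipeline and multi-exposure screening with the
## evidence-classification rule: a significant IVW estimate whose direction
## is shared by the WM and MR-Egger point estimates counts as causal
## evidence; a significant IVW estimate with a direction-discordant Egger
## point estimate keeps its category but carries a caution flag.

#' Classify the evidence for one exposure
#'
#' Category is decided by the IVW estimate alone: `"risk"` when
#' `p < alpha` and OR > 1, `"protective"` when `p < alpha` and OR < 1,
#' otherwise `"null"`.  `wm_confirmed` records whether the weighted median
#' is itself significant in the IVW direction; `direction_concordant`
#' whether both WM and MR-Egger point estimates share the IVW direction
#' (point estimates only — an insignificant but same-direction estimate
#' still concords); `caution` flags significant exposures whose Egger
#' direction is reversed, without demoting them.
#'
#' @param ivw,wm,egger [mr_estimate()] objects (WM/Egger may be `NULL` when
#'   too few instruments were available; concordance fields are then `NA`).
#' @param alpha Two-sided significance level (default 0.05).
#' @return Object of class `evidence_classification`: `category`,
#'   `wm_confirmed`, `direction_concordant`, `caution`.
#' @export
classify_evidence <- function(ivw, wm, egger, alpha = 0.05) {
  stopifnot(inherits(ivw, "mr_estimate"))
  significant <- ivw$pvalue < alpha
  category <- if (!significant) "null"
    else if (ivw$beta > 0) "risk" else "protective"
  dir_ivw <- sign(ivw$beta)
  wm_confirmed <- if (is.null(wm)) NA else
    (wm$pvalue < alpha && sign(wm$beta) == dir_ivw)
  direction_concordant <- if (is.null(wm) || is.null(egger)) NA else
    (sign(wm$beta) == dir_ivw && sign(egger$beta) == dir_ivw)
  caution <- if (is.na(direction_concordant)) NA else
    (category != "null" && !direction_concordant)
  structure(list(category = category, wm_confirmed = wm_confirmed,
                 direction_concordant = direction_concordant,
                 caution = caution),
            class = "evidence_classification")
}

#' Run the full pipeline for one exposure
#'
#' Executes instrument selection (p-value threshold, LD clumping, weak
#' instrument filter, exclusion list), harmonization, the three estimators,
#' the sensitivity battery, and evidence classification.  An exposure
#' ending with fewer than 2 harmonized instruments is marked not-analyzable
#' rather than raising an error, so a screen over many exposures always
#' completes.
#'
#' @param exp_stats,out_stats Canonical summary-statistics data.frames for
#'   the exposure and the outcome.
#' @param meta [study_meta()] of the exposure study (supplies `default_n`
#'   for the F statistic).
#' @param config A [selection_config()].
#' @param ld An [ld_table()] (default: empty, i.e. unlinked SNPs).
#' @param exclusions Character vector of confounder-associated SNP ids.
#' @param tolerance Palindrome ambiguity half-width (see
#'   [harmonize_pair()]).
#' @param drop_all_palindromic See [harmonize_all()].
#' @param n_boot Weighted-median bootstrap replicates.
#' @param alpha Significance level.
#' @param seed Seed for the weighted-median bootstrap.
#' @param exposure_name,taxonomic_level Metadata carried into the result.
#' @return Object of class `exposure_result` with fields `exposure_name`,
#'   `taxonomic_level`, `analyzable`, `ivw`, `wm`, `egger` (full
#'   [mr_egger()] result), `sensitivity`, `classification`,
#'   `n_instruments_initial`, `n_instruments_final`, `strengths`,
#'   `harmonization_report`.
#' @export
run_exposure <- function(exp_stats, out_stats, meta,
                         config = selection_config(), ld = ld_table(),
                         exclusions = character(0), tolerance = 0.08,
                         drop_all_palindromic = FALSE, n_boot = 1000,
                         alpha = 0.05, seed = NULL,
                         exposure_name = meta$trait_name,
                         taxonomic_level = NA_character_) {
  sel <- select_by_pvalue(exp_stats, config$p_threshold)
  n_initial <- nrow(sel)
  if (n_initial > 0) sel <- ld_clump(sel, ld, config)
  fw <- filter_weak_instruments(sel, meta, config)
  sel <- fw$kept
  sel <- suppressWarnings(filter_excluded(sel, exclusions))

  harm <- harmonize_all(sel, out_stats, tolerance = tolerance,
                        drop_all_palindromic = drop_all_palindromic)
  insts <- harm$instruments
  n_final <- nrow(insts)

  base <- list(exposure_name = exposure_name,
               taxonomic_level = taxonomic_level,
               n_instruments_initial = n_initial,
               n_instruments_final = n_final,
               strengths = fw$strengths,
               harmonization_report = harm$report)

  if (n_final < 2) {
    return(structure(c(base, list(analyzable = FALSE, ivw = NULL, wm = NULL,
                                  egger = NULL, sensitivity = NULL,
                                  classification = NULL)),
                     class = "exposure_result"))
  }

  ivw <- mr_ivw(insts)
  wm <- if (n_final >= 3) mr_weighted_median(insts, n_boot = n_boot,
                                             seed = seed) else NULL
  egger <- if (n_final >= 3) mr_egger(insts) else NULL
  sens <- sensitivity_report(insts, alpha = alpha)
  cls <- classify_evidence(ivw$estimate, wm,
                           if (is.null(egger)) NULL else egger$slope,
                           alpha = alpha)
  structure(c(base, list(analyzable = TRUE, ivw = ivw, wm = wm,
                         egger = egger, sensitivity = sens,
                         classification = cls, instruments = insts)),
            class = "exposure_result")
}

#' @export
print.exposure_result <- function(x, ...) {
  cat(sprintf("Exposure: %s (%d -> %d instruments)\n", x$exposure_name,
              x$n_instruments_initial, x$n_instruments_final))
  if (!x$analyzable) {
    cat("  not analyzable (< 2 harmonized instruments)\n")
    return(invisible(x))
  }
  print(x$ivw$estimate)
  if (!is.null(x$wm)) print(x$wm)
  if (!is.null(x$egger)) print(x$egger$slope)
  cat(sprintf("  classification: %s%s\n", x$classification$category,
              if (isTRUE(x$classification$caution)) " (caution)" else ""))
  invisible(x)
}

derive_exposure_seed <- function(base_seed, exposure_name) {
  as.integer((as.numeric(base_seed) + stable_hash(exposure_name)) %%
               2147483647)
}

#' Screen many exposures against one outcome
#'
#' Runs [run_exposure()] per exposure with a per-exposure seed derived from
#' the base seed and a stable hash of the exposure name, so results are
#' invariant to exposure ordering and to splitting the set across
#' invocations.  Raw p-values are reported throughout (no multiple-testing
#' correction drives classification); a Benjamini-Hochberg column over the
#' IVW p-values is emitted as optional extra output.
#'
#' @param exposures Named list of canonical exposure summary-statistics
#'   data.frames.
#' @param out_stats Outcome summary-statistics data.frame.
#' @param meta [study_meta()] shared by the exposure studies (or a named
#'   list of one per exposure).
#' @param config,ld,exclusions,tolerance,drop_all_palindromic,n_boot,alpha
#'   Passed to [run_exposure()].
#' @param taxonomic_levels Optional named character vector of levels.
#' @param seed Base seed.
#' @param out_dir Optional directory; when given, writes `results.tsv`,
#'   `sensitivity.tsv`, `loo.tsv`, `funnel.tsv`, `classification.tsv`.
#' @return Object of class `mr_screen`: list of `exposure_result`s plus the
#'   assembled `results`, `sensitivity`, `loo`, `funnel`, `classification`
#'   data.frames.
#' @export
screen_all <- function(exposures, out_stats, meta,
                       config = selection_config(), ld = ld_table(),
                       exclusions = character(0), tolerance = 0.08,
                       drop_all_palindromic = FALSE, n_boot = 1000,
                       alpha = 0.05, taxonomic_levels = NULL,
                       seed = 1, out_dir = NULL) {
  if (length(exposures) < 1)
    mr_stop("at least one exposure is required", "mrscreen_usage_error")
  if (is.null(names(exposures)) || any(!nzchar(names(exposures))))
    mr_stop("exposures must be a named list", "mrscreen_usage_error")

  results <- lapply(names(exposures), function(nm) {
    m <- if (inherits(meta, "study_meta")) meta else meta[[nm]]
    lvl <- if (is.null(taxonomic_levels)) NA_character_
      else unname(taxonomic_levels[nm])
    run_exposure(exposures[[nm]], out_stats, m, config = config, ld = ld,
                 exclusions = exclusions, tolerance = tolerance,
                 drop_all_palindromic = drop_all_palindromic,
                 n_boot = n_boot, alpha = alpha,
                 seed = derive_exposure_seed(seed, nm),
                 exposure_name = nm, taxonomic_level = lvl)
  })
  names(results) <- names(exposures)

  tables <- assemble_screen_tables(results, alpha = alpha)
  out <- structure(c(list(exposure_results = results), tables,
                     list(alpha = alpha, seed = seed)),
                   class = "mr_screen")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table(tables$results, file.path(out_dir, "results.tsv"))
    write_table(tables$sensitivity, file.path(out_dir, "sensitivity.tsv"))
    write_table(tables$loo, file.path(out_dir, "loo.tsv"))
    write_table(tables$funnel, file.path(out_dir, "funnel.tsv"))
    write_table(tables$classification,
                file.path(out_dir, "classification.tsv"))
  }
  out
}

est_row <- function(exposure, est) {
  data.frame(exposure = exposure, method = est$method, n_snps = est$n_snps,
             or = est$or_value, ci_low = est$or_low, ci_high = est$or_high,
             pvalue = est$pvalue, stringsAsFactors = FALSE)
}

assemble_screen_tables <- function(results, alpha = 0.05) {
  res_rows <- list(); sens_rows <- list(); loo_rows <- list()
  funnel_rows <- list(); cls_rows <- list()
  for (r in results) {
    if (!r$analyzable) next
    nm <- r$exposure_name
    ests <- list(r$ivw$estimate, r$wm,
                 if (is.null(r$egger)) NULL else r$egger$slope)
    res_rows[[nm]] <- do.call(rbind, lapply(Filter(Negate(is.null), ests),
                                            function(e) est_row(nm, e)))
    s <- r$sensitivity
    sens_rows[[nm]] <- data.frame(
      exposure = nm, intercept = s$egger_intercept,
      intercept_p = s$egger_intercept_p, q_stat = s$q_stat, q_p = s$q_p,
      stringsAsFactors = FALSE)
    loo_rows[[nm]] <- cbind(exposure = nm,
                            s$loo[, c("excluded_snp", "or", "ci_low",
                                      "ci_high", "pvalue")])
    funnel_rows[[nm]] <- cbind(exposure = nm,
                               s$funnel[, c("snp_id", "theta", "precision")])
    c <- r$classification
    cls_rows[[nm]] <- data.frame(
      exposure = nm, level = r$taxonomic_level, category = c$category,
      ivw_or = r$ivw$estimate$or_value, ivw_p = r$ivw$estimate$pvalue,
      wm_confirmed = c$wm_confirmed,
      direction_concordant = c$direction_concordant, caution = c$caution,
      stringsAsFactors = FALSE)
  }
  bind <- function(lst, proto) if (length(lst) > 0) {
    df <- do.call(rbind, lst); rownames(df) <- NULL; df
  } else proto
  classification <- bind(cls_rows, data.frame(
    exposure = character(0), level = character(0), category = character(0),
    ivw_or = numeric(0), ivw_p = numeric(0), wm_confirmed = logical(0),
    direction_concordant = logical(0), caution = logical(0)))
  if (nrow(classification) > 0)
    classification$ivw_p_bh <- stats::p.adjust(classification$ivw_p,
                                               method = "BH")
  list(
    results = bind(res_rows, data.frame(
      exposure = character(0), method = character(0), n_snps = integer(0),
      or = numeric(0), ci_low = numeric(0), ci_high = numeric(0),
      pvalue = numeric(0))),
    sensitivity = bind(sens_rows, data.frame(
      exposure = character(0), intercept = numeric(0),
      intercept_p = numeric(0), q_stat = numeric(0), q_p = numeric(0))),
    loo = bind(loo_rows, data.frame(
      exposure = character(0), excluded_snp = character(0), or = numeric(0),
      ci_low = numeric(0), ci_high = numeric(0), pvalue = numeric(0))),
    funnel = bind(funnel_rows, data.frame(
      exposure = character(0), snp_id = character(0), theta = numeric(0),
      precision = numeric(0))),
    classification = classification
  )
}

#' @export
print.mr_screen <- function(x, ...) {
  n <- length(x$exposure_results)
  cls <- x$classification
  cat(sprintf("MR screen: %d exposure(s), %d analyzable\n", n, nrow(cls)))
  if (nrow(cls) > 0) {
    tab <- table(factor(cls$category,
                        levels = c("risk", "protective", "null")))
    cat(sprintf("  risk: %d, protective: %d, null: %d (caution-flagged: %d)\n",
                tab[["risk"]], tab[["protective"]], tab[["null"]],
                sum(cls$caution, na.rm = TRUE)))
  }
  invisible(x)
}
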