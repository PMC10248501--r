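## Reading, validating and writing GWAS summary-statistic tables.
##
## Canonical in-memory representation of a summary-statistics table is a
## data.frame with columns
##   snp_id, chrom, pos, effect_allele, other_allele, eaf, beta, se, pvalue, n
## one row per SNP.  `chrom`, `pos`, `eaf` may be NA; `pvalue` and `n` are
## always filled (derived from beta/se resp. study metadata when absent from
## the input file).

VALID_BASES <- c("A", "C", "G", "T")

#' Column mapping for a summary-statistics file
#'
#' Maps the canonical field names used throughout the package to the column
#' headers of a particular GWAS summary-statistics release.  `snp`, `ea`,
#' `oa`, `beta` and `se` are mandatory; the rest may be `NA` (absent from the
#' file).
#'
#' @param snp,chr,pos,ea,oa,eaf,beta,se,p,n Column header in the input file
#'   holding the corresponding canonical field (`NA` = not present).
#' @param delim Field delimiter (default tab).
#' @param na_token String representing missing values in the file.
#' @return An object of class `column_map`.
#' @examples
#' cm <- column_map(snp = "SNP", ea = "A1", oa = "A2",
#'                  beta = "BETA", se = "SE", p = "P")
#' @export
column_map <- function(snp = "snp_id", chr = "chrom", pos = "pos",
                       ea = "effect_allele", oa = "other_allele",
                       eaf = "eaf", beta = "beta", se = "se",
                       p = "pvalue", n = "n",
                       delim = "\t", na_token = "NA") {
  cm <- list(snp = snp, chr = chr, pos = pos, ea = ea, oa = oa, eaf = eaf,
             beta = beta, se = se, p = p, n = n,
             delim = delim, na_token = na_token)
  mandatory <- c("snp", "ea", "oa", "beta", "se")
  for (f in mandatory) {
    if (is.null(cm[[f]]) || is.na(cm[[f]]))
      mr_stop(sprintf("column_map field '%s' is mandatory", f),
              "mrscreen_config_error")
  }
  structure(cm, class = "column_map")
}

#' Read a column map from a JSON configuration file
#'
#' The JSON object may carry any subset of the [column_map()] arguments.
#'
#' @param path Path to a JSON file.
#' @return A `column_map` object.
#' @export
read_column_map <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(column_map, cfg)
}

#' Study-level metadata
#'
#' @param trait_name Name of the trait.
#' @param default_n Sample size used for SNPs whose per-SNP `n` is absent;
#'   must be at least 3 when given (the F-statistic formula needs N - 2 > 0).
#' @param trait_type `"continuous"` (e.g. a standardized abundance) or
#'   `"binary"` (effects on the log-odds scale).
#' @return An object of class `study_meta`.
#' @export
study_meta <- function(trait_name, default_n = NA_real_,
                       trait_type = c("continuous", "binary")) {
  trait_type <- match.arg(trait_type)
  if (!is.na(default_n) && default_n < 3)
    mr_stop("default_n must be >= 3", "mrscreen_config_error")
  structure(list(trait_name = trait_name, default_n = default_n,
                 trait_type = trait_type),
            class = "study_meta")
}

#' Two-sided p-value from an effect estimate and its standard error
#'
#' Computes `2 * pnorm(-|beta/se|)`, the two-sided normal p-value.  Used to
#' fill in p-values when the input file lacks a p column and to check stored
#' p-values for consistency.
#'
#' @param beta Effect estimate(s).
#' @param se Standard error(s), all strictly positive.
#' @return p-value(s) in (0, 1].
#' @export
derive_pvalue <- function(beta, se) {
  if (any(!is.finite(se)) || any(se <= 0))
    mr_stop("se must be strictly positive", "mrscreen_domain_error")
  2 * stats::pnorm(-abs(beta / se))
}

#' Read and validate a GWAS summary-statistics table
#'
#' Reads a delimited text file (optionally gzip-compressed), maps its columns
#' to the canonical schema, and validates every row.  Rows violating the
#' record invariants (non-positive SE, non-SNV or identical alleles, allele
#' frequency outside \[0, 1\], position < 1, missing beta/se) are rejected and
#' counted, never silently dropped.  Duplicate SNP ids are resolved by keeping
#' the smallest p-value (ties: first occurrence).  Missing p-values are
#' derived with [derive_pvalue()]; missing sample sizes fall back to
#' `meta$default_n`.  Stored p-values disagreeing with `2*pnorm(-|beta/se|)`
#' by more than two-fold are flagged with a warning but kept (published
#' summary statistics often store truncated p-values).
#'
#' @param path Path to a tab/comma-delimited file with a header; `.gz`
#'   accepted.
#' @param map A [column_map()].
#' @param meta A [study_meta()].
#' @return A list of class `mr_sumstats` with elements
#'   \describe{
#'     \item{records}{data.frame in the canonical schema, valid rows only}
#'     \item{n_input}{number of data rows read}
#'     \item{n_rejected}{rows failing validation}
#'     \item{rejections}{data.frame (`snp_id`, `reason`) for each rejection}
#'     \item{n_duplicates_dropped}{rows dropped by the dedup rule}
#'     \item{n_pvalue_inconsistent}{rows whose stored p disagreed two-fold}
#'   }
#' @export
read_summary_stats <- function(path, map = column_map(), meta) {
  if (!inherits(map, "column_map"))
    mr_stop("map must be a column_map object", "mrscreen_config_error")
  if (!inherits(meta, "study_meta"))
    mr_stop("meta must be a study_meta object", "mrscreen_config_error")
  if (!file.exists(path))
    mr_stop(sprintf("file not found: %s", path), "mrscreen_io_error")

  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  raw <- utils::read.table(con, header = TRUE, sep = map$delim,
                           na.strings = map$na_token, quote = "",
                           comment.char = "", check.names = FALSE,
                           colClasses = "character",
                           stringsAsFactors = FALSE)

  mandatory <- c(snp = map$snp, ea = map$ea, oa = map$oa,
                 beta = map$beta, se = map$se)
  missing_cols <- setdiff(unname(mandatory), names(raw))
  if (length(missing_cols) > 0)
    mr_stop(sprintf("mandatory column(s) absent from header: %s",
                    paste(missing_cols, collapse = ", ")),
            "mrscreen_config_error")

  grab <- function(field, as_num = FALSE) {
    col <- map[[field]]
    if (is.null(col) || is.na(col) || !(col %in% names(raw)))
      return(rep(NA_character_, nrow(raw)))
    v <- raw[[col]]
    v
  }
  num <- function(x) suppressWarnings(as.numeric(x))

  rec <- data.frame(
    snp_id = grab("snp"),
    chrom = grab("chr"),
    pos = num(grab("pos")),
    effect_allele = toupper(grab("ea")),
    other_allele = toupper(grab("oa")),
    eaf = num(grab("eaf")),
    beta = num(grab("beta")),
    se = num(grab("se")),
    pvalue = num(grab("p")),
    n = num(grab("n")),
    stringsAsFactors = FALSE
  )
  n_input <- nrow(rec)

  ## Row validation: collect the first failing reason per row.
  reason <- rep(NA_character_, n_input)
  flag <- function(bad, why) reason[is.na(reason) & bad] <<- why
  flag(is.na(rec$snp_id) | rec$snp_id == "", "missing snp_id")
  flag(!is.na(rec$pos) & rec$pos < 1, "pos < 1")
  flag(!(rec$effect_allele %in% VALID_BASES), "effect_allele not a single base")
  flag(!(rec$other_allele %in% VALID_BASES), "other_allele not a single base")
  flag(rec$effect_allele == rec$other_allele, "identical alleles")
  flag(is.na(rec$beta), "missing beta")
  flag(is.na(rec$se) | rec$se <= 0, "se not strictly positive")
  flag(!is.na(rec$eaf) & (rec$eaf < 0 | rec$eaf > 1), "eaf outside [0,1]")
  flag(!is.na(rec$pvalue) & (rec$pvalue <= 0 | rec$pvalue > 1),
       "pvalue outside (0,1]")
  flag(!is.na(rec$n) & rec$n <= 0, "non-positive n")

  rejections <- data.frame(snp_id = rec$snp_id[!is.na(reason)],
                           reason = reason[!is.na(reason)],
                           stringsAsFactors = FALSE)
  rec <- rec[is.na(reason), , drop = FALSE]

  if (nrow(rec) == 0)
    mr_stop("no valid rows in input", "mrscreen_empty_input_error")

  ## Fill p and n.
  derived <- derive_pvalue(rec$beta, rec$se)
  n_incons <- sum(!is.na(rec$pvalue) & derived > 0 &
                    (rec$pvalue / derived > 2 | rec$pvalue / derived < 0.5))
  if (n_incons > 0)
    mr_warn(sprintf(
      "%d stored p-value(s) disagree with 2*pnorm(-|beta/se|) by > two-fold",
      n_incons), "mrscreen_pvalue_inconsistency")
  rec$pvalue[is.na(rec$pvalue)] <- derived[is.na(rec$pvalue)]
  rec$n[is.na(rec$n)] <- meta$default_n

  ## Deduplicate on snp_id: smallest p wins, ties broken by file order.
  ord <- order(rec$pvalue, seq_len(nrow(rec)))
  keep <- !duplicated(rec$snp_id[ord])
  n_dup <- sum(!keep)
  rec <- rec[sort(ord[keep]), , drop = FALSE]
  rownames(rec) <- NULL

  structure(list(records = rec,
                 n_input = n_input,
                 n_rejected = nrow(rejections),
                 rejections = rejections,
                 n_duplicates_dropped = n_dup,
                 n_pvalue_inconsistent = n_incons,
                 meta = meta),
            class = "mr_sumstats")
}

#' @export
print.mr_sumstats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (%s)\n",
              x$meta$trait_name, x$meta$trait_type))
  cat(sprintf("  %d rows read, %d valid, %d rejected, %d duplicates dropped\n",
              x$n_input, nrow(x$records), x$n_rejected,
              x$n_duplicates_dropped))
  invisible(x)
}

#' Write a result table as TSV
#'
#' Deterministic tab-delimited UTF-8 output with Unix newlines; numeric
#' columns are rounded to `digits` significant figures so that write/read
#' round-trips are exact at that precision.
#'
#' @param rows A data.frame.
#' @param path Output path.
#' @param columns Ordered column names to write (default: all, as-is).
#' @param digits Significant figures for numeric columns (default 6).
#' @export
write_table <- function(rows, path, columns = names(rows), digits = 6) {
  missing_cols <- setdiff(columns, names(rows))
  if (length(missing_cols) > 0)
    mr_stop(sprintf("rows lack column(s): %s",
                    paste(missing_cols, collapse = ", ")),
            "mrscreen_config_error")
  out <- rows[, columns, drop = FALSE]
  for (j in seq_along(out)) {
    if (!is.numeric(out[[j]])) next
    v <- signif(out[[j]], digits)
    if (all(is.na(v) | (v == round(v) & abs(v) < 1e15))) {
      ## whole numbers (positions, sample sizes): plain notation
      chr <- format(v, scientific = FALSE, trim = TRUE)
      chr[is.na(v)] <- NA
      v <- chr
    }
    out[[j]] <- v
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", eol = "\n")
  invisible(NULL)
}

#' Read a table written by [write_table()]
#'
#' @param path Path to a TSV file.
#' @return A data.frame.
#' @export
read_table_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
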