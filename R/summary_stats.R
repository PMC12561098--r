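#' Construct a GWAS summary-statistics table
#'
#' A `summary_stats` object holds one trait's per-variant association
#' statistics: variant identifier, alleles, effect size (log odds ratio for
#' binary traits), its standard error, p-value, and optionally effect-allele
#' frequency and per-variant sample size. It is the unit every downstream
#' stage (instrument selection, harmonization, MR, colocalization, LD-score
#' regression) consumes.
#'
#' Rows violating the record invariants (non-positive `se`, `p` outside
#' `(0, 1]`, identical effect and other alleles, `eaf` outside `(0, 1)`,
#' duplicated `rsid`, non-finite `beta`) are dropped with a message; the
#' number dropped is retained in the `n_dropped` field.
#'
#' @param records data.frame with columns `rsid`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `pval`, and optionally
#'   `eaf` and `n`.
#' @param trait_id Character label for the trait.
#' @param trait_type `"quantitative"` or `"binary"`. Binary-trait effects are
#'   interpreted as log odds ratios throughout.
#' @param sample_size_default Positive scalar used where per-row `n` is
#'   missing.
#' @return An object of class `summary_stats` with fields `trait_id`,
#'   `records`, `trait_type`, `sample_size_default`, `n_dropped`.
#' @examples
#' df <- data.frame(
#'   rsid = c("rs1", "rs2"), chrom = "1", pos = c(100L, 200L),
#'   effect_allele = c("A", "C"), other_allele = c("G", "T"),
#'   eaf = c(0.3, 0.4), beta = c(0.1, -0.05), se = c(0.01, 0.02),
#'   pval = c(1e-20, 0.01), n = 50000
#' )
#' ss <- summary_stats(df, trait_id = "bmi")
#' ss
#' @export
summary_stats <- function(records, trait_id = "trait",
                          trait_type = c("quantitative", "binary"),
                          sample_size_default = NA_real_) {
  trait_type <- match.arg(trait_type)
  assert_that(is.data.frame(records), "records must be a data.frame")
  needed <- c("rsid", "effect_allele", "other_allele", "beta", "se", "pval")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0L) {
    stop("summary statistics are missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(records) == 0L) stop("empty summary-statistics table", call. = FALSE)
  for (col in c("chrom", "pos", "eaf", "n")) {
    if (!col %in% names(records)) records[[col]] <- NA
  }
  records$rsid <- as.character(records$rsid)
  records$chrom <- as.character(records$chrom)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    records[[col]] <- suppressWarnings(as.numeric(records[[col]]))
  }

  ok <- is.finite(records$beta) &
    is.finite(records$se) & records$se > 0 &
    is.finite(records$pval) & records$pval > 0 & records$pval <= 1 &
    records$effect_allele %in% c("A", "C", "G", "T") &
    records$other_allele %in% c("A", "C", "G", "T") &
    records$effect_allele != records$other_allele &
    (is.na(records$eaf) | (records$eaf > 0 & records$eaf < 1)) &
    !duplicated(records$rsid)
  n_dropped <- sum(!ok)
  if (n_dropped > 0L) {
    mrt_message(sprintf("summary_stats[%s]: dropped %d invalid row(s)",
                        trait_id, n_dropped))
  }
  records <- records[ok, , drop = FALSE]
  if (nrow(records) == 0L) {
    stop("no valid rows remain after validation", call. = FALSE)
  }
  rownames(records) <- NULL
  structure(
    list(trait_id = trait_id, records = records, trait_type = trait_type,
         sample_size_default = sample_size_default, n_dropped = n_dropped),
    class = "summary_stats"
  )
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (%s)\n", x$trait_id, x$trait_type))
  cat(sprintf("  %d variants (%d dropped on read)\n",
              nrow(x$records), x$n_dropped))
  if (!is.na(x$sample_size_default)) {
    cat(sprintf("  default sample size: %g\n", x$sample_size_default))
  }
  invisible(x)
}

# Default column dialect: GWAS-SSF style names.
ssf_dialect <- function() {
  list(rsid = "rsid", chrom = "chromosome", pos = "base_pair_location",
       effect_allele = "effect_allele", other_allele = "other_allele",
       beta = "beta", se = "standard_error", pval = "p_value",
       eaf = "effect_allele_frequency", n = "n", or = NULL)
}

#' Read GWAS summary statistics from delimited text
#'
#' Reads a tab- or comma-delimited file with a header row and maps its columns
#' onto the canonical summary-statistics fields via a configurable dialect.
#' The default dialect expects GWAS-SSF-style names (`chromosome`,
#' `base_pair_location`, `effect_allele`, `other_allele`, `beta`,
#' `standard_error`, `p_value`, `effect_allele_frequency`, `n`). When the file
#' reports odds ratios instead of log-odds effects, set the dialect entry
#' `or` to the OR column name and `beta` is computed as `log(OR)`.
#'
#' @param path Path to a delimited text file with a header.
#' @param dialect Named list overriding entries of the default mapping.
#'   Names are canonical fields; values are column names in the file.
#' @param trait_id,trait_type,sample_size_default Passed to [summary_stats()].
#' @param sep Field separator; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @return A validated [summary_stats()] object. Unrecognized columns are kept
#'   in `records` as opaque metadata.
#' @export
read_summary_stats <- function(path, dialect = list(), trait_id = NULL,
                               trait_type = c("quantitative", "binary"),
                               sample_size_default = NA_real_, sep = NULL) {
  trait_type <- match.arg(trait_type)
  assert_that(file.exists(path), paste0("file not found: ", path))
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  if (nrow(raw) == 0L) stop("empty summary-statistics table", call. = FALSE)
  map <- utils::modifyList(ssf_dialect(), dialect)

  use_or <- !is.null(map$or)
  mandatory <- c("rsid", "effect_allele", "other_allele", "se", "pval",
                 if (use_or) NULL else "beta")
  for (field in mandatory) {
    if (!map[[field]] %in% names(raw)) {
      stop(sprintf("mandatory column '%s' (field '%s') not found in %s",
                   map[[field]], field, path), call. = FALSE)
    }
  }
  out <- data.frame(rsid = raw[[map$rsid]], stringsAsFactors = FALSE)
  for (field in c("chrom", "pos", "effect_allele", "other_allele",
                  "eaf", "se", "pval", "n")) {
    col <- map[[field]]
    out[[field]] <- if (!is.null(col) && col %in% names(raw)) raw[[col]] else NA
  }
  out$beta <- if (use_or) {
    if (!map$or %in% names(raw)) {
      stop(sprintf("mandatory column '%s' (field 'or') not found in %s",
                   map$or, path), call. = FALSE)
    }
    log(suppressWarnings(as.numeric(raw[[map$or]])))
  } else {
    raw[[map$beta]]
  }
  mapped <- unlist(map[!vapply(map, is.null, logical(1))], use.names = FALSE)
  extra <- setdiff(names(raw), mapped)
  for (col in extra) out[[paste0("meta.", col)]] <- raw[[col]]

  summary_stats(out, trait_id = trait_id %||% basename(path),
                trait_type = trait_type,
                sample_size_default = sample_size_default)
}

#' Write summary statistics as GWAS-SSF-style TSV
#'
#' @param ss A [summary_stats()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(ss, path) {
  stopifnot(inherits(ss, "summary_stats"))
  rec <- ss$records
  out <- data.frame(
    rsid = rec$rsid, chromosome = rec$chrom, base_pair_location = rec$pos,
    effect_allele = rec$effect_allele, other_allele = rec$other_allele,
    effect_allele_frequency = rec$eaf, beta = rec$beta,
    standard_error = rec$se, p_value = rec$pval, n = rec$n,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict summary statistics to a genomic window
#'
#' Subsets a summary-statistics table to the closed interval
#' `[center - half_width, center + half_width]` on one chromosome, the
#' regional input used by colocalization. The default half-width of 250 kb
#' gives a 500 kb window.
#'
#' @param ss A [summary_stats()] object with `chrom` and `pos` populated.
#' @param chrom Chromosome label.
#' @param center Center position (1-based).
#' @param half_width Window half-width in base pairs.
#' @return A `summary_stats` object restricted to the window, with a `window`
#'   attribute recording `(chrom, center, half_width)`.
#' @export
region_stats <- function(ss, chrom, center, half_width = 250000) {
  stopifnot(inherits(ss, "summary_stats"))
  rec <- ss$records
  keep <- !is.na(rec$chrom) & rec$chrom == as.character(chrom) &
    !is.na(rec$pos) & rec$pos >= center - half_width &
    rec$pos <= center + half_width
  if (!any(keep)) {
    stop(sprintf("no variants of %s in %s:%d-%d", ss$trait_id,
                 chrom, center - half_width, center + half_width),
         call. = FALSE)
  }
  out <- ss
  out$records <- rec[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  attr(out, "window") <- list(chrom = as.character(chrom), center = center,
                              half_width = half_width)
  out
}
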