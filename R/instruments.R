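#' Single-instrument F statistic
#'
#' Approximate instrument-strength F statistic for one variant,
#' `(beta / se)^2`. Values above the conventional screen of 10 indicate a
#' strong instrument; weak-instrument bias grows as F falls.
#'
#' @param beta Per-allele effect estimate.
#' @param se Its standard error (> 0).
#' @return The F statistic (vectorized).
#' @examples
#' f_statistic(0.1, 0.02) # 25
#' @export
f_statistic <- function(beta, se) {
  assert_that(all(se > 0), "se must be positive")
  (beta / se)^2
}

#' Variance in a standardized trait explained by one variant
#'
#' For a variant with effect-allele frequency `eaf` and standardized
#' per-allele effect `beta`, the explained variance is
#' `2 * eaf * (1 - eaf) * beta^2`. Summed over an instrument set it gives the
#' cumulative R-squared used for power and F-statistic screens. The caller is
#' responsible for the trait being on a unit-variance scale.
#'
#' @param beta Standardized per-allele effect (vectorized).
#' @param eaf Effect-allele frequency in `(0, 1)`; `NA` contributions are
#'   excluded from totals with a warning by [select_instruments()].
#' @return Per-variant explained variance.
#' @examples
#' variance_explained(0.1, 0.5) # 0.005
#' @export
variance_explained <- function(beta, eaf) {
  assert_that(all(is.na(eaf) | (eaf > 0 & eaf < 1)),
              "eaf must lie in (0,1) where present")
  2 * eaf * (1 - eaf) * beta^2
}

#' Select genetic instruments for an exposure
#'
#' Keeps variants associated with the exposure at `p <= p_threshold`, then
#' greedily prunes for linkage disequilibrium: variants are visited in order
#' of ascending p-value (ties broken by rsid) and one is retained only if its
#' squared correlation with every previously retained variant is below
#' `clump_r2`. Variants absent from the LD matrix are treated as independent.
#' Per-variant F statistics and the cumulative variance explained are
#' computed on the retained set.
#'
#' @param ss A [summary_stats()] object for the exposure.
#' @param p_threshold Selection p-value; default `5e-8`, the conventional
#'   genome-wide significance level.
#' @param clump_r2 LD pruning threshold; default `0.001`.
#' @param ld Optional square symmetric LD (r-squared) matrix with unit
#'   diagonal, dimnames keyed by rsid.
#' @return An object of class `instrument_set`: fields `exposure_id`,
#'   `instruments` (the retained records plus `f_stat` and `r2` columns),
#'   `p_threshold`, `clump_r2`, `f_stats`, `r2_total`.
#' @export
select_instruments <- function(ss, p_threshold = 5e-8, clump_r2 = 0.001,
                               ld = NULL) {
  stopifnot(inherits(ss, "summary_stats"))
  assert_that(p_threshold > 0 && p_threshold < 1,
              "p_threshold must lie in (0,1)")
  rec <- ss$records
  cand <- rec[rec$pval <= p_threshold, , drop = FALSE]
  if (nrow(cand) == 0L) {
    stop(sprintf("no variant of %s passes p <= %g", ss$trait_id, p_threshold),
         call. = FALSE)
  }
  cand <- cand[order(cand$pval, cand$rsid), , drop = FALSE]

  if (!is.null(ld)) {
    assert_that(is.matrix(ld) && nrow(ld) == ncol(ld),
                "ld must be a square matrix")
    assert_that(max(abs(ld - t(ld))) < 1e-8, "ld must be symmetric")
    assert_that(max(abs(diag(ld) - 1)) < 1e-8, "ld must have unit diagonal")
    kept <- character(0)
    keep_row <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      id <- cand$rsid[i]
      in_ld <- id %in% rownames(ld)
      prior <- intersect(kept, rownames(ld))
      indep <- !in_ld || length(prior) == 0L ||
        all(abs(ld[id, prior]) < clump_r2)
      keep_row[i] <- indep
      if (indep) kept <- c(kept, id)
    }
    cand <- cand[keep_row, , drop = FALSE]
  }

  cand$f_stat <- f_statistic(cand$beta, cand$se)
  cand$r2 <- variance_explained(cand$beta, cand$eaf)
  if (anyNA(cand$r2)) {
    warning(sprintf("%d instrument(s) of %s lack eaf; excluded from r2 total",
                    sum(is.na(cand$r2)), ss$trait_id), call. = FALSE)
  }
  rownames(cand) <- NULL
  structure(
    list(exposure_id = ss$trait_id, instruments = cand,
         p_threshold = p_threshold, clump_r2 = clump_r2,
         f_stats = stats::setNames(cand$f_stat, cand$rsid),
         r2_total = sum(cand$r2, na.rm = TRUE)),
    class = "instrument_set"
  )
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Instrument set for %s: %d variants (p <= %g, clump r2 < %g)\n",
              x$exposure_id, nrow(x$instruments), x$p_threshold, x$clump_r2))
  cat(sprintf("  min F = %.1f, cumulative r2 = %.4f\n",
              min(x$f_stats), x$r2_total))
  invisible(x)
}
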