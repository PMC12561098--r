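is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize exposure instruments with outcome summary statistics
#'
#' Aligns each exposure instrument with the matching outcome record so that
#' both effects are expressed per copy of the same effect allele. Exact allele
#' matches are kept; reversed pairs (effect and other allele swapped) have the
#' outcome effect sign-flipped and its allele frequency complemented;
#' palindromic variants (A/T or C/G), whose strand cannot be resolved from
#' alleles alone, are kept only when both allele frequencies are available,
#' both fall outside the ambiguity window around 0.5, and both lie on the same
#' side of 0.5 — otherwise they are dropped. Allele sets that cannot be
#' reconciled are dropped as mismatches, and instruments absent from the
#' outcome table are dropped with a logged count. No exclusion is silent:
#' every instrument appears in the output with an `action` label.
#'
#' @param exposure_iv An [select_instruments()] result (or a `summary_stats`
#'   object, in which case all its records are used as instruments).
#' @param outcome A [summary_stats()] object for the outcome trait.
#' @param palindrome_eaf_window Half-width of the ambiguity window: variants
#'   with allele frequency in `[0.5 - w, 0.5 + w]` are treated as
#'   strand-ambiguous. Default 0.08.
#' @return An object of class `harmonized_set` with fields `exposure_id`,
#'   `outcome_id`, `outcome_type`, `rows` (all instruments with columns
#'   `rsid, beta_exp, se_exp, eaf_exp, beta_out, se_out, eaf_out, action`),
#'   and `n_absent`. Retained rows have `action` `"kept"` or `"flipped"`.
#' @export
harmonize <- function(exposure_iv, outcome, palindrome_eaf_window = 0.08) {
  exp_rec <- if (inherits(exposure_iv, "instrument_set")) {
    exposure_iv$instruments
  } else if (inherits(exposure_iv, "summary_stats")) {
    exposure_iv$records
  } else stop("exposure_iv must be an instrument_set or summary_stats",
              call. = FALSE)
  exposure_id <- if (inherits(exposure_iv, "instrument_set")) {
    exposure_iv$exposure_id
  } else exposure_iv$trait_id
  stopifnot(inherits(outcome, "summary_stats"))
  out_rec <- outcome$records
  w <- palindrome_eaf_window

  idx <- match(exp_rec$rsid, out_rec$rsid)
  n_absent <- sum(is.na(idx))
  if (n_absent > 0L) {
    mrt_message(sprintf("harmonize[%s ~ %s]: %d instrument(s) absent from outcome",
                        exposure_id, outcome$trait_id, n_absent))
  }
  present <- !is.na(idx)
  ex <- exp_rec[present, , drop = FALSE]
  ou <- out_rec[idx[present], , drop = FALSE]

  n <- nrow(ex)
  action <- character(n)
  beta_out <- ou$beta
  eaf_out <- ou$eaf
  direct <- ex$effect_allele == ou$effect_allele &
    ex$other_allele == ou$other_allele
  reversed <- ex$effect_allele == ou$other_allele &
    ex$other_allele == ou$effect_allele
  palin <- is_palindromic(ex$effect_allele, ex$other_allele)

  for (i in seq_len(n)) {
    if (!direct[i] && !reversed[i]) {
      action[i] <- "dropped_mismatch"
    } else if (palin[i]) {
      e1 <- ex$eaf[i]; e2 <- ou$eaf[i]
      unambiguous <- !is.na(e1) && !is.na(e2) &&
        abs(e1 - 0.5) > w && abs(e2 - 0.5) > w &&
        sign(e1 - 0.5) == sign(e2 - 0.5)
      if (!unambiguous) {
        action[i] <- "dropped_palindromic"
      } else if (direct[i]) {
        action[i] <- "kept"
      } else {
        # reversed coding of the same strand-resolved allele
        action[i] <- "flipped"
        beta_out[i] <- -beta_out[i]
        if (!is.na(eaf_out[i])) eaf_out[i] <- 1 - eaf_out[i]
      }
    } else if (direct[i]) {
      action[i] <- "kept"
    } else {
      action[i] <- "flipped"
      beta_out[i] <- -beta_out[i]
      if (!is.na(eaf_out[i])) eaf_out[i] <- 1 - eaf_out[i]
    }
  }

  rows <- data.frame(
    rsid = ex$rsid,
    effect_allele = ex$effect_allele, other_allele = ex$other_allele,
    beta_exp = ex$beta, se_exp = ex$se, eaf_exp = ex$eaf,
    pval_exp = ex$pval,
    beta_out = beta_out, se_out = ou$se, eaf_out = eaf_out,
    pval_out = ou$pval,
    action = action, stringsAsFactors = FALSE
  )
  structure(
    list(exposure_id = exposure_id, outcome_id = outcome$trait_id,
         outcome_type = outcome$trait_type, rows = rows,
         n_absent = n_absent),
    class = "harmonized_set"
  )
}

#' Retained rows of a harmonized set
#'
#' @param hs A [harmonize()] result.
#' @return The subset of `hs$rows` with action `kept` or `flipped`.
#' @export
harmonized_rows <- function(hs) {
  stopifnot(inherits(hs, "harmonized_set"))
  hs$rows[hs$rows$action %in% c("kept", "flipped"), , drop = FALSE]
}

#' @export
print.harmonized_set <- function(x, ...) {
  tab <- table(factor(x$rows$action,
                      levels = c("kept", "flipped", "dropped_palindromic",
                                 "dropped_mismatch")))
  cat(sprintf("Harmonized set: %s ~ %s (%s outcome)\n",
              x$exposure_id, x$outcome_id, x$outcome_type))
  cat(sprintf("  kept %d, flipped %d, dropped %d palindromic, %d mismatch, %d absent\n",
              tab[["kept"]], tab[["flipped"]], tab[["dropped_palindromic"]],
              tab[["dropped_mismatch"]], x$n_absent))
  invisible(x)
}

#' Serialize a harmonized set to TSV (plus a JSON-lines exclusion log)
#'
#' @param hs A [harmonize()] result.
#' @param path Output TSV path; the exclusion log is written alongside as
#'   `<path>.exclusions.jsonl` with one JSON object per excluded variant.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(hs, path) {
  stopifnot(inherits(hs, "harmonized_set"))
  utils::write.table(hs$rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  excl <- hs$rows[!hs$rows$action %in% c("kept", "flipped"), , drop = FALSE]
  log_path <- paste0(path, ".exclusions.jsonl")
  lines <- vapply(seq_len(nrow(excl)), function(i) {
    jsonlite::toJSON(list(rsid = excl$rsid[i], action = excl$action[i],
                          exposure = hs$exposure_id, outcome = hs$outcome_id),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, log_path)
  invisible(path)
}
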