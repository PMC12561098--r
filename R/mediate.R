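#' Product-of-coefficients mediation with delta-method inference
#'
#' Decomposes a total causal effect into the part transmitted through a
#' mediator and the rest. Given the step-1 effect `beta1` (exposure ->
#' mediator), the step-2 effect `beta2` (mediator -> outcome, estimated with
#' the step-1 instruments excluded), and the total effect `beta3`
#' (exposure -> outcome), the indirect effect is `beta1 * beta2` and the
#' mediation proportion is `beta1 * beta2 / beta3`. The three estimates come
#' from separate GWAS samples, so delta-method variances treat them as
#' independent:
#' `se_indirect = sqrt(beta1^2 * se2^2 + beta2^2 * se1^2)`, and the
#' proportion variance adds the `se3` term
#' `(beta1 * beta2 / beta3^2)^2 * se3^2` by default
#' (`proportion_se3_term = FALSE` drops it). For a binary outcome all
#' effects must already be on the log-odds scale.
#'
#' @param beta1,se1 Step-1 effect and standard error.
#' @param beta2,se2 Step-2 effect and standard error.
#' @param beta3,se3 Total effect and standard error.
#' @param exposure_id,mediator_id,outcome_id Optional labels.
#' @param proportion_se3_term Include total-effect uncertainty in the
#'   proportion interval (default `TRUE`).
#' @return An object of class `mr_mediation`: `indirect`, `indirect_se`,
#'   `indirect_ci`, `indirect_p`, `proportion`, `proportion_se`,
#'   `proportion_ci`, `proportion_pct` (percentage), `significant` (indirect
#'   CI excludes zero), and flags `proportion_defined` (`FALSE` when
#'   `beta3 = 0`) and `inconsistent` (`TRUE` when `|proportion| > 1`,
#'   indicating direct and indirect effects of opposite sign or an
#'   understated total).
#' @examples
#' m <- mediate(0.368, 0.047, 0.421, 0.134, log(1.267), 0.059)
#' m$proportion_pct
#' @export
mediate <- function(beta1, se1, beta2, se2, beta3, se3,
                    exposure_id = "exposure", mediator_id = "mediator",
                    outcome_id = "outcome", proportion_se3_term = TRUE) {
  assert_that(se1 > 0 && se2 > 0 && se3 > 0, "standard errors must be positive")
  indirect <- beta1 * beta2
  indirect_se <- sqrt(beta1^2 * se2^2 + beta2^2 * se1^2)
  ici <- ci95(indirect, indirect_se)
  significant <- ici[[1]] > 0 || ici[[2]] < 0

  proportion_defined <- beta3 != 0
  if (proportion_defined) {
    proportion <- indirect / beta3
    pvar <- (beta2 / beta3)^2 * se1^2 + (beta1 / beta3)^2 * se2^2
    if (proportion_se3_term) pvar <- pvar + (indirect / beta3^2)^2 * se3^2
    proportion_se <- sqrt(pvar)
    pci <- ci95(proportion, proportion_se)
  } else {
    proportion <- NA_real_; proportion_se <- NA_real_
    pci <- c(NA_real_, NA_real_)
    warning("beta3 = 0: mediation proportion undefined", call. = FALSE)
  }
  inconsistent <- isTRUE(abs(proportion) > 1)
  if (inconsistent) {
    warning("inconsistent mediation: |proportion| > 1", call. = FALSE)
  }
  structure(
    list(exposure_id = exposure_id, mediator_id = mediator_id,
         outcome_id = outcome_id,
         beta1 = beta1, se1 = se1, beta2 = beta2, se2 = se2,
         beta3 = beta3, se3 = se3,
         indirect = indirect, indirect_se = indirect_se,
         indirect_ci = ici, indirect_p = z_pvalue(indirect, indirect_se),
         proportion = proportion, proportion_se = proportion_se,
         proportion_ci = pci, proportion_pct = 100 * proportion,
         significant = significant,
         proportion_defined = proportion_defined,
         inconsistent = inconsistent),
    class = "mr_mediation"
  )
}

#' Mediation from fitted MR estimates
#'
#' Convenience wrapper extracting `(beta, se)` from three
#' [mr_fit()] results: step 1 (exposure -> mediator), step 2
#' (mediator -> outcome) and the total effect (exposure -> outcome).
#'
#' @param fit1,fit2,fit3 `mr_estimate` objects.
#' @inheritParams mediate
#' @return An `mr_mediation` object, see [mediate()].
#' @export
mediate_estimates <- function(fit1, fit2, fit3, proportion_se3_term = TRUE) {
  stopifnot(inherits(fit1, "mr_estimate"), inherits(fit2, "mr_estimate"),
            inherits(fit3, "mr_estimate"))
  mediate(fit1$beta, fit1$se, fit2$beta, fit2$se, fit3$beta, fit3$se,
          exposure_id = fit1$exposure_id, mediator_id = fit1$outcome_id,
          outcome_id = fit3$outcome_id,
          proportion_se3_term = proportion_se3_term)
}

#' @export
print.mr_mediation <- function(x, ...) {
  cat(sprintf("Mediation: %s -> %s -> %s\n",
              x$exposure_id, x$mediator_id, x$outcome_id))
  cat(sprintf("  beta1 = %.4f, beta2 = %.4f, total beta3 = %.4f\n",
              x$beta1, x$beta2, x$beta3))
  cat(sprintf("  indirect = %.4f (se %.4f), 95%% CI [%.4f, %.4f], p = %.3g%s\n",
              x$indirect, x$indirect_se, x$indirect_ci[[1]],
              x$indirect_ci[[2]], x$indirect_p,
              if (x$significant) " *" else ""))
  if (x$proportion_defined) {
    cat(sprintf("  proportion mediated = %.3f%% (95%% CI %.3f%%, %.3f%%)%s\n",
                x$proportion_pct, 100 * x$proportion_ci[[1]],
                100 * x$proportion_ci[[2]],
                if (x$inconsistent) " [inconsistent]" else ""))
  } else {
    cat("  proportion undefined (total effect is zero)\n")
  }
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment (a thin wrapper over
#' `stats::p.adjust(method = "BH")`); output order matches input order and
#' adjusted values are never below the raw p-values.
#'
#' @param pvals Numeric vector of p-values in `(0, 1]`.
#' @return Adjusted q-values in input order.
#' @export
bh_fdr <- function(pvals) {
  assert_that(all(pvals > 0 & pvals <= 1), "p-values must lie in (0,1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Exclude step-1 instruments from a step-2 instrument set
#'
#' In two-step mediation the instruments used for the mediator -> outcome
#' stage must not overlap those that defined the exposure -> mediator stage;
#' this removes any shared variants and errors if nothing remains.
#'
#' @param step1_iv,step2_iv [select_instruments()] results.
#' @return `step2_iv` without the overlapping variants; the removed rsids are
#'   attached as attribute `"removed"`.
#' @export
exclude_step1_instruments <- function(step1_iv, step2_iv) {
  stopifnot(inherits(step1_iv, "instrument_set"),
            inherits(step2_iv, "instrument_set"))
  overlap <- intersect(step2_iv$instruments$rsid, step1_iv$instruments$rsid)
  keep <- !step2_iv$instruments$rsid %in% overlap
  if (!any(keep)) {
    stop(sprintf("no step-2 instruments remain after excluding %d step-1 variant(s): %s",
                 length(overlap), paste(overlap, collapse = ", ")),
         call. = FALSE)
  }
  if (length(overlap) > 0L) {
    mrt_message(sprintf("exclude_step1_instruments: removed %d shared variant(s)",
                        length(overlap)))
  }
  out <- step2_iv
  out$instruments <- step2_iv$instruments[keep, , drop = FALSE]
  rownames(out$instruments) <- NULL
  out$f_stats <- out$f_stats[keep]
  out$r2_total <- sum(out$instruments$r2, na.rm = TRUE)
  attr(out, "removed") <- overlap
  out
}

#' Screen step-1 results across a metabolome family
#'
#' Applies Benjamini-Hochberg adjustment across all metabolites tested for
#' one phenotype, separately to the primary-method and BWMR p-values, and
#' keeps a metabolite only when both adjusted values fall below `fdr_q` and
#' the two effect estimates agree in sign. Discordant-sign pairs are excluded
#' and flagged.
#'
#' @param results data.frame with one row per metabolite: columns `id`,
#'   `beta_primary`, `p_primary`, `beta_bwmr`, `p_bwmr`.
#' @param fdr_q FDR threshold (default 0.05).
#' @return The input with added columns `q_primary`, `q_bwmr`, `concordant`,
#'   `selected`.
#' @export
screen_step1 <- function(results, fdr_q = 0.05) {
  needed <- c("id", "beta_primary", "p_primary", "beta_bwmr", "p_bwmr")
  stopifnot(all(needed %in% names(results)))
  results$q_primary <- bh_fdr(results$p_primary)
  results$q_bwmr <- bh_fdr(results$p_bwmr)
  results$concordant <- sign(results$beta_primary) == sign(results$beta_bwmr)
  results$selected <- results$q_primary < fdr_q & results$q_bwmr < fdr_q &
    results$concordant
  n_disc <- sum(results$q_primary < fdr_q & results$q_bwmr < fdr_q &
                  !results$concordant)
  if (n_disc > 0L) {
    mrt_message(sprintf("screen_step1: %d metabolite(s) excluded for discordant sign",
                        n_disc))
  }
  results
}

#' Identify mediators shared across phenotypes
#'
#' Groups candidate mediators by the set of phenotypes they are significantly
#' associated with, keeping those associated with at least `min_phenotypes`
#' phenotypes and excluding membership patterns listed in `exclude_patterns`
#' (by default the adiposity-only pair BMI+WC, whose overlap is expected from
#' phenotypic redundancy rather than shared biology).
#'
#' @param sets Named list of character vectors: per-phenotype significant
#'   mediator identifiers (>= 2 phenotypes).
#' @param min_phenotypes Minimum number of phenotype memberships (default 2).
#' @param exclude_patterns List of character vectors; a mediator whose
#'   membership equals one of these sets (exactly) is excluded.
#' @return A list: `membership` (data.frame `id`, `phenotypes`, `n`,
#'   `retained`), `groups` (named list of mediator vectors keyed by the
#'   sorted membership signature, retained mediators only).
#' @export
shared_mediators <- function(sets, min_phenotypes = 2L,
                             exclude_patterns = list(c("BMI", "WC"))) {
  assert_that(length(sets) >= 2L && !is.null(names(sets)),
              "sets must be a named list covering >= 2 phenotypes")
  ids <- sort(unique(unlist(sets)))
  membership <- lapply(ids, function(id) {
    names(sets)[vapply(sets, function(s) id %in% s, logical(1))]
  })
  sig <- vapply(membership, function(m) paste(sort(m), collapse = "+"),
                character(1))
  excl_sigs <- vapply(exclude_patterns,
                      function(p) paste(sort(p), collapse = "+"), character(1))
  n <- lengths(membership)
  retained <- n >= min_phenotypes & !sig %in% excl_sigs
  df <- data.frame(id = ids, phenotypes = sig, n = n, retained = retained,
                   stringsAsFactors = FALSE)
  groups <- split(ids[retained], sig[retained])
  list(membership = df, groups = groups)
}

#' Apply the reverse-causality filter to a mediation triangle
#'
#' A candidate triangle is excluded when the mediator shows a significant
#' reverse causal effect on its phenotype (or, optionally, when the outcome
#' shows one on the mediator): such pairs cannot be interpreted as
#' phenotype -> mediator -> outcome. The exclusion is per
#' phenotype-mediator pair — the same mediator can remain a valid mediator
#' for another phenotype.
#'
#' @param triangle A list or one-row data.frame describing the triangle (any
#'   fields; `reverse_excluded` is set on it).
#' @param reverse_p_mediator_phenotype P-value of the mediator -> phenotype
#'   reverse MR.
#' @param reverse_p_outcome_mediator Optional p-value of the
#'   outcome -> mediator reverse MR.
#' @param alpha Significance level for exclusion (default 0.05).
#' @return The triangle with `reverse_excluded` (logical) and
#'   `reverse_reason` set.
#' @export
reverse_mr_filter <- function(triangle, reverse_p_mediator_phenotype,
                              reverse_p_outcome_mediator = NA_real_,
                              alpha = 0.05) {
  rev_mp <- isTRUE(reverse_p_mediator_phenotype < alpha)
  rev_om <- isTRUE(reverse_p_outcome_mediator < alpha)
  triangle$reverse_excluded <- rev_mp || rev_om
  triangle$reverse_reason <- if (rev_mp) {
    "mediator has a significant reverse effect on the phenotype"
  } else if (rev_om) {
    "outcome has a significant reverse effect on the mediator"
  } else NA_character_
  triangle
}

#' Assign the evidence tier of a mediation triangle
#'
#' Two stars (highest evidence) when the mediator both passed colocalization
#' with the outcome (tier `"colocalized"` or `"suggestive"`) and replicated
#' in the external validation set; one star when exactly one of the two
#' holds; none otherwise.
#'
#' @param triangle List or one-row data.frame with fields `coloc_tier`
#'   (`"colocalized"`, `"suggestive"`, or `"none"`) and `validated_external`
#'   (logical).
#' @return The triangle with `evidence_tier` set to `"two_star"`,
#'   `"one_star"`, or `"none"`.
#' @export
assign_evidence_tier <- function(triangle) {
  assert_that(!is.null(triangle$coloc_tier) &&
                !is.null(triangle$validated_external),
              "triangle needs coloc_tier and validated_external")
  coloc_pass <- triangle$coloc_tier %in% c("colocalized", "suggestive")
  validated <- isTRUE(triangle$validated_external)
  triangle$evidence_tier <- if (coloc_pass && validated) "two_star"
  else if (coloc_pass || validated) "one_star"
  else "none"
  triangle
}
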