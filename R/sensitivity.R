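get_mr_rows <- function(hs, min_n = 2L, what = "this diagnostic") {
  rows <- if (inherits(hs, "harmonized_set")) harmonized_rows(hs) else
    as.data.frame(hs)
  stopifnot(all(c("beta_exp", "se_exp", "beta_out", "se_out") %in% names(rows)))
  if (nrow(rows) < min_n) {
    stop(sprintf("%s requires at least %d instruments; %d supplied",
                 what, min_n, nrow(rows)), call. = FALSE)
  }
  rows
}

#' Cochran's Q heterogeneity statistic about the IVW fit
#'
#' Computed on the Wald-ratio scale: `Q = sum w_j (ratio_j - beta_ivw)^2`
#' with `w_j = 1 / se_ratio_j^2` and `se_ratio_j = se_out_j / |beta_exp_j|`
#' (first order). Under homogeneity Q is chi-square with `n - 1` degrees of
#' freedom; excess heterogeneity signals invalid instruments or pleiotropy.
#'
#' @param hs A [harmonize()] result or compatible data.frame.
#' @return A list with `q`, `df`, `p`.
#' @export
cochran_q <- function(hs) {
  rows <- get_mr_rows(hs, 2L, "cochran_q")
  w <- (rows$beta_exp / rows$se_out)^2
  ratio <- rows$beta_out / rows$beta_exp
  beta <- sum(w * ratio) / sum(w)
  q <- sum(w * (ratio - beta)^2)
  df <- nrow(rows) - 1L
  list(q = q, df = df, p = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Rucker's Q: residual heterogeneity about the MR-Egger fit
#'
#' The weighted residual sum of squares of the Egger regression (weights
#' `1/se_out^2`, the regression weight scale), chi-square with `n - 2`
#' degrees of freedom. It is never larger than the corresponding
#' intercept-free statistic on the same weight scale, and the drop measures
#' how much heterogeneity the intercept (directional pleiotropy) absorbs.
#'
#' @param hs A [harmonize()] result or compatible data.frame.
#' @return A list with `q`, `df`, `p`.
#' @export
rucker_q <- function(hs) {
  rows <- get_mr_rows(hs, 3L, "rucker_q")
  fit <- egger_engine(rows$beta_exp, rows$beta_out, rows$se_out)
  list(q = fit$q_rucker, df = fit$df,
       p = stats::pchisq(fit$q_rucker, fit$df, lower.tail = FALSE))
}

presso_engine <- function(rows, n_sim, seed) {
  # canonical variant order so the simulated null (and hence every p-value)
  # is invariant to input row order
  ids <- as.character(rows$rsid %||% seq_len(nrow(rows)))
  ord <- order(ids)
  rows <- rows[ord, , drop = FALSE]
  bx <- rows$beta_exp; by <- rows$beta_out; sy <- rows$se_out
  n <- length(bx)
  cj <- bx / sy^2
  dj <- bx^2 / sy^2
  sxy <- sum(by * cj); sxx <- sum(dj)

  loo_rss <- function(by_vec, sxy_vec = sum(by_vec * cj)) {
    beta_loo <- (sxy_vec - by_vec * cj) / (sxx - dj)
    r <- (by_vec - beta_loo * bx) / sy
    list(rss = sum(r^2), r2 = r^2)
  }
  obs <- loo_rss(by)
  beta_loo_obs <- (sxy - by * cj) / (sxx - dj)

  withr::with_seed(seed, {
    by_sim <- matrix(stats::rnorm(n_sim * n,
                                  mean = rep(beta_loo_obs * bx, each = n_sim),
                                  sd = rep(sy, each = n_sim)),
                     nrow = n_sim)
    sxy_sim <- as.vector(by_sim %*% cj)
    beta_loo_sim <- (sxy_sim - sweep(by_sim, 2, cj, `*`)) /
      matrix(sxx - dj, n_sim, n, byrow = TRUE)
    r_sim <- (by_sim - sweep(beta_loo_sim, 2, bx, `*`)) /
      matrix(sy, n_sim, n, byrow = TRUE)
    rss_sim <- rowSums(r_sim^2)
    r2_sim <- r_sim^2
  })

  global_p <- (1 + sum(rss_sim >= obs$rss)) / (n_sim + 1)
  snp_p <- (1 + colSums(r2_sim >= matrix(obs$r2, n_sim, n, byrow = TRUE))) /
    (n_sim + 1)
  # map per-variant quantities back to the caller's row order
  inv <- order(ord)
  list(global_p = global_p, snp_p = snp_p[inv], obs_rss = obs$rss,
       obs_r2 = obs$r2[inv])
}

#' MR-PRESSO-style global pleiotropy test
#'
#' The observed residual sum of squares is built leave-one-out: each
#' variant's outcome effect is compared with the prediction from the IVW fit
#' excluding that variant, standardized by its standard error. Its null
#' distribution comes from `n_sim` parametric simulations drawing
#' `beta_out_j ~ Normal(beta_loo_j * beta_exp_j, se_out_j^2)` and recomputing
#' the statistic the same way; the p-value uses the `+1` correction so it is
#' never exactly zero.
#'
#' @param hs A [harmonize()] result or compatible data.frame (>= 4 rows).
#' @param n_sim Number of null simulations (>= 100).
#' @param seed Seed making the simulated null reproducible.
#' @return The global test p-value.
#' @export
presso_global <- function(hs, n_sim = 1000L, seed) {
  rows <- get_mr_rows(hs, 4L, "presso_global")
  assert_that(n_sim >= 100L, "n_sim below 100 gives an unstable p-value")
  presso_engine(rows, n_sim, seed)$global_p
}

#' MR-PRESSO-style per-variant outlier test
#'
#' Each variant's observed leave-one-out standardized squared residual is
#' compared with its own simulated null; p-values are Bonferroni-adjusted
#' across variants, and variants significant at the adjusted level are
#' flagged as outliers. Removing the flagged variants and refitting IVW gives
#' the outlier-corrected estimate.
#'
#' @inheritParams presso_global
#' @param alpha Familywise flagging level (default 0.05).
#' @return A list: `table` (data.frame `rsid`, `p`, `p_bonferroni`,
#'   `outlier`), `outliers` (rsid vector), `corrected` (IVW `mr_estimate`
#'   without the flagged variants, or `NULL` if nothing was flagged or fewer
#'   than 2 variants remain).
#' @export
presso_outlier <- function(hs, n_sim = 1000L, seed, alpha = 0.05) {
  rows <- get_mr_rows(hs, 4L, "presso_outlier")
  assert_that(n_sim >= 100L, "n_sim below 100 gives an unstable p-value")
  eng <- presso_engine(rows, n_sim, seed)
  ids <- rows$rsid %||% as.character(seq_len(nrow(rows)))
  p_bonf <- pmin(1, eng$snp_p * nrow(rows))
  tab <- data.frame(rsid = ids, p = eng$snp_p, p_bonferroni = p_bonf,
                    outlier = p_bonf < alpha, stringsAsFactors = FALSE)
  corrected <- NULL
  if (any(tab$outlier) && sum(!tab$outlier) >= 2L) {
    kept <- rows[!tab$outlier, , drop = FALSE]
    corrected <- mr_fit(kept, method = "ivw_mre")
  }
  list(table = tab, outliers = ids[tab$outlier], corrected = corrected)
}

#' Leave-one-out IVW analysis
#'
#' Refits the multiplicative random-effects IVW estimator with each
#' instrument excluded in turn. A left-out variant is flagged when its
#' removal flips the sign of the estimate or moves it outside the full-set
#' 95% confidence interval — evidence the full-set result is driven by that
#' single variant.
#'
#' @param hs A [harmonize()] result or compatible data.frame (>= 3 rows).
#' @return A data.frame with one row per left-out variant: `rsid`, `beta`,
#'   `se`, `ci_low`, `ci_high`, `flagged`; the full-set fit is attached as
#'   attribute `"full"`.
#' @export
leave_one_out <- function(hs) {
  rows <- get_mr_rows(hs, 3L, "leave_one_out")
  ids <- rows$rsid %||% as.character(seq_len(nrow(rows)))
  full <- mr_fit(rows, method = "ivw_mre")
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(j) {
    fit <- mr_fit(rows[-j, , drop = FALSE], method = "ivw_mre")
    data.frame(rsid = ids[j], beta = fit$beta, se = fit$se,
               ci_low = fit$ci_low, ci_high = fit$ci_high,
               stringsAsFactors = FALSE)
  }))
  out$flagged <- sign(out$beta) != sign(full$beta) |
    out$beta < full$ci_low | out$beta > full$ci_high
  attr(out, "full") <- full
  out
}

#' Choose the primary causal-inference method from diagnostics
#'
#' Decision rule: when neither the global pleiotropy test nor the Egger
#' intercept shows evidence of horizontal pleiotropy, the multiplicative
#' random-effects IVW estimate is primary. A significant Egger intercept
#' (directional pleiotropy) promotes the Egger slope to primary. A
#' significant global test with a non-significant intercept — pleiotropy
#' and heterogeneity without a clear direction — falls back to the weighted
#' median, which tolerates up to half-invalid weight.
#'
#' @param report A [mr_sensitivity()] result or list containing
#'   `presso_global_p` and `egger_intercept_p`.
#' @param alpha Diagnostic significance level (default 0.05).
#' @return A list with `chosen_method` and `rationale`.
#' @export
select_method <- function(report, alpha = 0.05) {
  need <- c("presso_global_p", "egger_intercept_p")
  missing <- need[vapply(need, function(f) is.null(report[[f]]) ||
                           is.na(report[[f]]), logical(1))]
  if (length(missing) > 0L) {
    stop("sensitivity report is missing diagnostics: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  pg <- report$presso_global_p
  pe <- report$egger_intercept_p
  if (pe <= alpha) {
    list(chosen_method = "egger",
         rationale = sprintf(
           "Egger intercept p = %.3g <= %.2f: directional pleiotropy; using the pleiotropy-adjusted Egger slope",
           pe, alpha))
  } else if (pg > alpha) {
    list(chosen_method = "ivw_mre",
         rationale = sprintf(
           "no pleiotropy evidence (global p = %.3g, intercept p = %.3g > %.2f): IVW primary",
           pg, pe, alpha))
  } else {
    list(chosen_method = "weighted_median",
         rationale = sprintf(
           "global pleiotropy p = %.3g <= %.2f with non-directional intercept: weighted median primary",
           pg, alpha))
  }
}

#' Full sensitivity analysis of a harmonized instrument set
#'
#' Runs Cochran's Q, Rucker's Q, the Egger intercept test, the global and
#' per-variant MR-PRESSO-style tests, and leave-one-out, then applies the
#' method-selection rule of [select_method()].
#'
#' @param hs A [harmonize()] result (>= 4 retained instruments for the
#'   pleiotropy simulations; >= 3 for the rest).
#' @param n_sim Simulations for the global/outlier tests.
#' @param seed Seed for the simulated nulls.
#' @param alpha Diagnostic significance level.
#' @return An object of class `sensitivity_report` with fields `q`, `q_df`,
#'   `q_p`, `rucker_q`, `rucker_df`, `rucker_p`, `egger_intercept`,
#'   `egger_intercept_p`, `presso_global_p`, `presso_outliers`, `loo`,
#'   `chosen_method`, `rationale`.
#' @export
mr_sensitivity <- function(hs, n_sim = 1000L, seed, alpha = 0.05) {
  rows <- get_mr_rows(hs, 4L, "mr_sensitivity")
  cq <- cochran_q(rows)
  rq <- rucker_q(rows)
  egger <- mr_fit(rows, method = "egger")
  po <- presso_outlier(rows, n_sim = n_sim, seed = seed, alpha = alpha)
  eng_p <- presso_global(rows, n_sim = n_sim, seed = seed)
  loo <- leave_one_out(rows)
  report <- list(
    q = cq$q, q_df = cq$df, q_p = cq$p,
    rucker_q = rq$q, rucker_df = rq$df, rucker_p = rq$p,
    egger_intercept = egger$intercept,
    egger_intercept_se = egger$intercept_se,
    egger_intercept_p = egger$intercept_p,
    presso_global_p = eng_p, presso_outliers = po$outliers,
    presso_table = po$table, presso_corrected = po$corrected,
    loo = loo, n_snp = nrow(rows), alpha = alpha
  )
  sel <- select_method(report, alpha = alpha)
  report$chosen_method <- sel$chosen_method
  report$rationale <- sel$rationale
  structure(report, class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("Sensitivity report (%d SNPs)\n", x$n_snp))
  cat(sprintf("  Cochran Q = %.3f (df %d, p = %.3g); Rucker Q = %.3f (df %d, p = %.3g)\n",
              x$q, x$q_df, x$q_p, x$rucker_q, x$rucker_df, x$rucker_p))
  cat(sprintf("  Egger intercept = %.4f (p = %.3g); global pleiotropy p = %.3g\n",
              x$egger_intercept, x$egger_intercept_p, x$presso_global_p))
  if (length(x$presso_outliers) > 0L) {
    cat("  outliers:", paste(x$presso_outliers, collapse = ", "), "\n")
  }
  cat(sprintf("  flagged leave-one-out variants: %d\n", sum(x$loo$flagged)))
  cat(sprintf("  chosen method: %s\n    (%s)\n", x$chosen_method, x$rationale))
  invisible(x)
}
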