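#' Wald ratio estimate from a single instrument
#'
#' The base-case causal estimate from one variant: the ratio of the outcome
#' to the exposure association, `beta_out / beta_exp`. The first-order
#' standard error `se_out / |beta_exp|` ignores uncertainty in the exposure
#' association; the second-order (delta-method) error adds it and is always
#' at least as large.
#'
#' @param beta_exp,se_exp Exposure association and its standard error.
#' @param beta_out,se_out Outcome association and its standard error.
#' @param second_order If `TRUE`, include the exposure-uncertainty term
#'   `beta_out^2 * se_exp^2 / beta_exp^4` in the variance.
#' @return A list with `beta`, `se`, `ci_low`, `ci_high`, `pval`.
#' @examples
#' wald_ratio(0.2, 0.05, 0.05, 0.01)
#' @export
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out,
                       second_order = FALSE) {
  assert_that(all(beta_exp != 0), "beta_exp must be nonzero for a Wald ratio")
  beta <- beta_out / beta_exp
  var1 <- se_out^2 / beta_exp^2
  se <- if (second_order) {
    sqrt(var1 + beta_out^2 * se_exp^2 / beta_exp^4)
  } else sqrt(var1)
  ci <- ci95(beta, se)
  list(beta = beta, se = se, ci_low = ci[[1]], ci_high = ci[[2]],
       pval = z_pvalue(beta, se))
}

# --- internal estimator engines (operate on numeric vectors) ---------------

ivw_engine <- function(bx, by, sy, random_effects = TRUE) {
  den <- sum(bx^2 / sy^2)
  beta <- sum(bx * by / sy^2) / den
  se_fe <- 1 / sqrt(den)
  q <- sum((by - beta * bx)^2 / sy^2)
  n <- length(bx)
  se <- if (random_effects && n > 1L) {
    se_fe * sqrt(max(1, q / (n - 1L)))
  } else se_fe
  list(beta = beta, se = se, se_fe = se_fe, q = q, df = n - 1L)
}

egger_engine <- function(bx, by, sy) {
  # orient so all exposure effects are non-negative
  flip <- sign(bx) < 0
  bx <- abs(bx)
  by <- ifelse(flip, -by, by)
  if (stats::sd(bx) < .Machine$double.eps^0.5 * max(abs(bx), 1)) {
    stop("MR-Egger design is degenerate: all exposure effects equal",
         call. = FALSE)
  }
  w <- 1 / sy^2
  fit <- stats::lm(by ~ bx, weights = w)
  n <- length(bx)
  q_rucker <- sum(w * stats::residuals(fit)^2)
  sigma <- sqrt(q_rucker / (n - 2L))
  sm <- summary(fit)$coefficients
  # multiplicative random effects: never deflate below the fixed-effect error
  infl <- 1 / min(1, sigma)
  list(intercept = sm[1, 1], intercept_se = sm[1, 2] * infl,
       slope = sm[2, 1], slope_se = sm[2, 2] * infl,
       q_rucker = q_rucker, df = n - 2L)
}

weighted_median_engine <- function(ratio, w) {
  o <- order(ratio)
  ratio <- ratio[o]
  w <- w[o] / sum(w)
  cw <- cumsum(w) - 0.5 * w
  if (cw[1] >= 0.5) return(ratio[1])
  below <- max(which(cw < 0.5))
  if (below == length(ratio)) return(ratio[length(ratio)])
  ratio[below] + (ratio[below + 1L] - ratio[below]) *
    (0.5 - cw[below]) / (cw[below + 1L] - cw[below])
}

#' Fit a two-sample Mendelian randomization estimator
#'
#' The central fitting function: estimates the causal effect of the exposure
#' on the outcome from a harmonized instrument set by one of six methods.
#'
#' * `ivw_mre` (default) / `ivw_fe` — inverse-variance weighted: the
#'   zero-intercept regression of outcome on exposure effects with weights
#'   `1/se_out^2`. The multiplicative random-effects variant inflates the
#'   fixed-effect standard error by `sqrt(max(1, Q/(n-1)))`, absorbing
#'   balanced heterogeneity.
#' * `egger` — weighted regression with a free intercept; the intercept tests
#'   directional pleiotropy and the slope is the pleiotropy-adjusted effect.
#'   Instruments are oriented so all exposure effects are non-negative, and
#'   inference uses the t distribution with `n-2` degrees of freedom.
#' * `weighted_median` — the weighted median of per-variant Wald ratios,
#'   consistent when at least half the total weight comes from valid
#'   instruments; its standard error comes from a seeded parametric
#'   bootstrap.
#' * `bwmr` — Bayesian outlier-robust estimator, see [bwmr()].
#' * `wald` — single-instrument Wald ratio (requires exactly one retained
#'   instrument).
#'
#' For binary outcomes (log-odds effects) the returned object also carries
#' the estimate on the odds-ratio scale.
#'
#' @param hs A [harmonize()] result (or a data.frame with columns `beta_exp`,
#'   `se_exp`, `beta_out`, `se_out`).
#' @param method One of `"ivw_mre"`, `"ivw_fe"`, `"egger"`,
#'   `"weighted_median"`, `"bwmr"`, `"wald"`.
#' @param n_boot Bootstrap resamples for the weighted-median standard error.
#' @param seed Seed for the bootstrap / posterior computation; required for
#'   `weighted_median`.
#' @param prior_config Prior settings for `bwmr`, see [bwmr()].
#' @param allow_single Permit `ivw` fits with one instrument (diagnostic use;
#'   reduces exactly to the Wald ratio).
#' @return An object of class `mr_estimate`: fields `exposure_id`,
#'   `outcome_id`, `method`, `beta`, `se`, `ci_low`, `ci_high`, `pval`,
#'   `n_snp`; `q`, `q_df` for IVW; `intercept`, `intercept_se`,
#'   `intercept_p` for Egger; `or`, `or_ci_low`, `or_ci_high` when the
#'   outcome is binary; `outlier_weights` for BWMR.
#' @examples
#' rows <- data.frame(beta_exp = c(0.1, 0.2, 0.15),
#'                    se_exp = 0.01,
#'                    beta_out = c(0.025, 0.05, 0.0375),
#'                    se_out = c(0.01, 0.02, 0.015))
#' fit <- mr_fit(rows, method = "ivw_mre")
#' coef(fit)
#' @export
mr_fit <- function(hs, method = c("ivw_mre", "ivw_fe", "egger",
                                  "weighted_median", "bwmr", "wald"),
                   n_boot = 1000L, seed = NULL, prior_config = list(),
                   allow_single = FALSE) {
  method <- match.arg(method)
  if (inherits(hs, "harmonized_set")) {
    rows <- harmonized_rows(hs)
    exposure_id <- hs$exposure_id
    outcome_id <- hs$outcome_id
    outcome_type <- hs$outcome_type
  } else {
    rows <- as.data.frame(hs)
    exposure_id <- attr(hs, "exposure_id") %||% "exposure"
    outcome_id <- attr(hs, "outcome_id") %||% "outcome"
    outcome_type <- attr(hs, "outcome_type") %||% "quantitative"
  }
  needed <- c("beta_exp", "se_exp", "beta_out", "se_out")
  stopifnot(all(needed %in% names(rows)))
  n <- nrow(rows)
  min_n <- switch(method, wald = 1L, ivw_fe = 2L, ivw_mre = 2L, 3L)
  if (method %in% c("ivw_fe", "ivw_mre") && allow_single) min_n <- 1L
  if (n < min_n) {
    stop(sprintf("%s requires at least %d instrument(s); %d supplied",
                 method, min_n, n), call. = FALSE)
  }
  bx <- rows$beta_exp; sx <- rows$se_exp
  by <- rows$beta_out; sy <- rows$se_out

  est <- list(exposure_id = exposure_id, outcome_id = outcome_id,
              method = method, n_snp = n)

  if (method == "wald") {
    if (n != 1L) stop("wald requires exactly one instrument", call. = FALSE)
    wr <- wald_ratio(bx, sx, by, sy)
    est <- c(est, wr)
  } else if (method %in% c("ivw_fe", "ivw_mre")) {
    fit <- ivw_engine(bx, by, sy, random_effects = method == "ivw_mre")
    ci <- ci95(fit$beta, fit$se)
    est <- c(est, list(beta = fit$beta, se = fit$se, ci_low = ci[[1]],
                       ci_high = ci[[2]], pval = z_pvalue(fit$beta, fit$se),
                       q = fit$q, q_df = fit$df))
  } else if (method == "egger") {
    fit <- egger_engine(bx, by, sy)
    tq <- stats::qt(0.975, df = fit$df)
    est <- c(est, list(
      beta = fit$slope, se = fit$slope_se,
      ci_low = fit$slope - tq * fit$slope_se,
      ci_high = fit$slope + tq * fit$slope_se,
      pval = 2 * stats::pt(-abs(fit$slope / fit$slope_se), df = fit$df),
      intercept = fit$intercept, intercept_se = fit$intercept_se,
      intercept_p = 2 * stats::pt(-abs(fit$intercept / fit$intercept_se),
                                  df = fit$df),
      q = fit$q_rucker, q_df = fit$df))
  } else if (method == "weighted_median") {
    assert_that(!is.null(seed), "weighted_median requires an explicit seed")
    ratio <- by / bx
    w <- (bx / sy)^2                     # 1 / se_ratio^2, first order
    beta <- weighted_median_engine(ratio, w)
    boots <- withr::with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        bxb <- stats::rnorm(n, bx, sx)
        byb <- stats::rnorm(n, by, sy)
        weighted_median_engine(byb / bxb, (bxb / sy)^2)
      }, numeric(1))
    })
    se <- stats::sd(boots)
    ci <- ci95(beta, se)
    est <- c(est, list(beta = beta, se = se, ci_low = ci[[1]],
                       ci_high = ci[[2]], pval = z_pvalue(beta, se),
                       n_boot = n_boot))
  } else if (method == "bwmr") {
    fit <- bwmr(rows, prior_config = prior_config, seed = seed)
    est <- c(est, fit)
  }

  if (identical(outcome_type, "binary")) {
    est$or <- exp(est$beta)
    est$or_ci_low <- exp(est$ci_low)
    est$or_ci_high <- exp(est$ci_high)
  }
  structure(est, class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("MR estimate [%s]: %s -> %s (%d SNPs)\n",
              x$method, x$exposure_id, x$outcome_id, x$n_snp))
  cat(sprintf("  beta = %.*f (se %.*f), 95%% CI [%.*f, %.*f], p = %.3g\n",
              digits, x$beta, digits, x$se, digits, x$ci_low,
              digits, x$ci_high, x$pval))
  if (!is.null(x$or)) {
    cat(sprintf("  OR = %.*f, 95%% CI [%.*f, %.*f]\n",
                digits, x$or, digits, x$or_ci_low, digits, x$or_ci_high))
  }
  if (!is.null(x$intercept)) {
    cat(sprintf("  Egger intercept = %.*f (se %.*f), p = %.3g\n",
                digits, x$intercept, digits, x$intercept_se, x$intercept_p))
  }
  invisible(x)
}

#' @export
coef.mr_estimate <- function(object, ...) {
  out <- c(beta = object$beta)
  if (!is.null(object$intercept)) out <- c(out, intercept = object$intercept)
  out
}

#' @export
confint.mr_estimate <- function(object, parm = "beta", level = 0.95, ...) {
  stopifnot(identical(level, 0.95))
  matrix(c(object$ci_low, object$ci_high), nrow = 1,
         dimnames = list("beta", c("2.5 %", "97.5 %")))
}

#' @export
summary.mr_estimate <- function(object, ...) {
  object
}

#' Flatten MR estimates into a forest table
#'
#' Builds the flat per-method result table (exposure, outcome, method, number
#' of SNPs, effect, standard error, confidence limits, p-value, and the
#' odds-ratio scale where the outcome is binary) used for forest-plot style
#' reporting.
#'
#' @param ... `mr_estimate` objects, or a single list of them.
#' @return A data.frame with one row per estimate.
#' @export
forest_table <- function(...) {
  ests <- list(...)
  if (length(ests) == 1L && !inherits(ests[[1]], "mr_estimate")) {
    ests <- ests[[1]]
  }
  do.call(rbind, lapply(ests, function(e) {
    data.frame(
      exposure = e$exposure_id, outcome = e$outcome_id, method = e$method,
      n_snp = e$n_snp, beta = e$beta, se = e$se,
      ci_low = e$ci_low, ci_high = e$ci_high, pval = e$pval,
      or = e$or %||% NA_real_, or_ci_low = e$or_ci_low %||% NA_real_,
      or_ci_high = e$or_ci_high %||% NA_real_,
      egger_intercept = e$intercept %||% NA_real_,
      egger_intercept_p = e$intercept_p %||% NA_real_,
      stringsAsFactors = FALSE
    )
  }))
}
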