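#' Construct an LD-score table
#'
#' @param scores data.frame with columns `rsid` and `ldscore` (each variant's
#'   summed squared correlation with the variants tagging it; at least 1,
#'   since a variant tags itself).
#' @param m_total Total number of variants the scores represent (defaults to
#'   the number of rows; at least the number of rows).
#' @return An object of class `ld_score_table`.
#' @export
ld_score_table <- function(scores, m_total = nrow(scores)) {
  stopifnot(is.data.frame(scores),
            all(c("rsid", "ldscore") %in% names(scores)))
  assert_that(all(scores$ldscore >= 1 - 1e-6),
              "ld scores must be >= 1 (a variant tags at least itself)")
  assert_that(m_total >= nrow(scores),
              "m_total must be at least the number of scored variants")
  assert_that(!anyDuplicated(scores$rsid), "duplicate rsid in LD-score table")
  structure(list(scores = scores, m_total = m_total),
            class = "ld_score_table")
}

#' Read a two-column LD-score TSV (rsid, L2)
#'
#' @param path TSV path with header columns `rsid` and `L2` (or `ldscore`).
#' @param m_total See [ld_score_table()].
#' @return An `ld_score_table`.
#' @export
read_ld_scores <- function(path, m_total = NULL) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  l2_col <- intersect(c("L2", "ldscore", "l2"), names(raw))[1]
  assert_that(!is.na(l2_col), "LD-score file needs an 'L2' or 'ldscore' column")
  scores <- data.frame(rsid = as.character(raw$rsid),
                       ldscore = as.numeric(raw[[l2_col]]),
                       stringsAsFactors = FALSE)
  ld_score_table(scores, m_total = m_total %||% nrow(scores))
}

# weighted least squares y ~ 1 + x; returns c(intercept, slope)
wls2 <- function(x, y, w) {
  sw <- sum(w); sx <- sum(w * x); sy <- sum(w * y)
  sxx <- sum(w * x^2); sxy <- sum(w * x * y)
  det <- sw * sxx - sx^2
  c((sxx * sy - sx * sxy) / det, (sw * sxy - sx * sy) / det)
}

# contiguous equal-count block assignment
jk_blocks <- function(n, n_blocks) {
  n_blocks <- max(2L, min(n_blocks, n))
  sort(rep_len(seq_len(n_blocks), n))
}

ldsc_prepare <- function(ss, ld) {
  stopifnot(inherits(ss, "summary_stats"), inherits(ld, "ld_score_table"))
  rec <- ss$records
  idx <- match(rec$rsid, ld$scores$rsid)
  keep <- !is.na(idx)
  rec <- rec[keep, , drop = FALSE]
  ell <- ld$scores$ldscore[idx[keep]]
  n_var <- ifelse(is.na(rec$n), ss$sample_size_default, rec$n)
  assert_that(!anyNA(n_var), "per-variant sample size required for LDSC")
  if (nrow(rec) < 200L) {
    stop(sprintf("only %d variants overlap the LD-score table; >= 200 required",
                 nrow(rec)), call. = FALSE)
  }
  list(rsid = rec$rsid, z = rec$beta / rec$se, ell = ell, n = n_var,
       m = ld$m_total)
}

# core single-trait fit: chi^2_j on N_j * l_j / M with iterated LDSC weights;
# returns the fitted coefficients and the final weights
h2_fit <- function(z, ell, n, m, n_iter = 2L, constrain_intercept = FALSE) {
  chi2 <- z^2
  x <- n * ell / m
  fit_once <- function(w) {
    if (constrain_intercept) {
      c(1, sum(w * x * (chi2 - 1)) / sum(w * x^2))
    } else {
      wls2(x, chi2, w)
    }
  }
  w <- rep(1, length(x))
  co <- fit_once(w)
  for (it in seq_len(n_iter)) {
    h2 <- max(co[2], 0)
    w <- 1 / (1 + h2 * x)^2
    co <- fit_once(w)
  }
  list(intercept = co[1], h2 = co[2], w = w, x = x, y = chi2,
       constrain_intercept = constrain_intercept)
}

#' Single-trait heritability by simplified LD-score regression
#'
#' Regresses per-variant association chi-square statistics on
#' `N_j * l_j / M` (sample size times LD score over the number of variants):
#' the slope estimates the SNP heritability `h2` and the free intercept
#' absorbs confounding inflation (it is 1 under pure polygenicity). Weights
#' use the standard heteroskedasticity form `1 / (1 + N h2 l / M)^2`,
#' iterated twice from an ordinary least-squares start. Standard errors come
#' from a delete-one block jackknife over contiguous equal-count blocks.
#' Binary traits are analysed on the observed scale.
#'
#' @param ss A [summary_stats()] object with per-variant sample sizes (or a
#'   `sample_size_default`).
#' @param ld An [ld_score_table()].
#' @param n_blocks Number of jackknife blocks (default 200).
#' @param constrain_intercept Fix the intercept at 1 (no confounding
#'   inflation) instead of estimating it freely.
#' @return A list: `h2`, `h2_se`, `intercept`, `intercept_se`, `n_snp`,
#'   `n_blocks`.
#' @export
ldsc_h2 <- function(ss, ld, n_blocks = 200L, constrain_intercept = FALSE) {
  d <- ldsc_prepare(ss, ld)
  fit <- h2_fit(d$z, d$ell, d$n, d$m,
                constrain_intercept = constrain_intercept)
  blocks <- jk_blocks(length(d$z), n_blocks)
  nb <- max(blocks)
  reps <- vapply(seq_len(nb), function(b) {
    k <- blocks != b
    co <- if (constrain_intercept) {
      c(1, sum(fit$w[k] * fit$x[k] * (fit$y[k] - 1)) /
          sum(fit$w[k] * fit$x[k]^2))
    } else {
      wls2(fit$x[k], fit$y[k], fit$w[k])
    }
    c(co[1], co[2])
  }, numeric(2))
  se <- sqrt((nb - 1) / nb * rowSums((reps - rowMeans(reps))^2))
  list(h2 = fit$h2, h2_se = se[2], intercept = fit$intercept,
       intercept_se = se[1], n_snp = length(d$z), n_blocks = nb)
}

#' Cross-trait genetic correlation by simplified LD-score regression
#'
#' Regresses the per-variant product of z-statistics on
#' `sqrt(N1 * N2) * l_j / M`; the slope estimates the genetic covariance, and
#' the genetic correlation is `rg = cov_g / sqrt(h2_1 * h2_2)` with the
#' single-trait heritabilities fit by [ldsc_h2()]'s model on the same
#' variants. Sample overlap is absorbed by the free intercept. The jackknife
#' recomputes all three regressions per deleted block, so the reported
#' standard error propagates heritability uncertainty. Estimates of `rg`
#' outside `[-1, 1]` are flagged and values are clipped at `[-1.25, 1.25]`.
#'
#' @param ss1,ss2 [summary_stats()] objects for the two traits.
#' @param ld An [ld_score_table()] covering both.
#' @param n_blocks Number of jackknife blocks.
#' @return An object of class `ldsc_result`: `h2_1`, `h2_1_se`, `h2_2`,
#'   `h2_2_se`, `gencov`, `rg`, `rg_se`, `rg_p`, `intercept` (product
#'   regression), `n_snp`, `out_of_bounds` flag.
#' @export
ldsc_rg <- function(ss1, ss2, ld, n_blocks = 200L) {
  d1 <- ldsc_prepare(ss1, ld)
  d2 <- ldsc_prepare(ss2, ld)
  shared <- intersect(d1$rsid, d2$rsid)
  i1 <- match(shared, d1$rsid)
  i2 <- match(shared, d2$rsid)
  z1 <- d1$z[i1]; n1 <- d1$n[i1]; ell <- d1$ell[i1]
  z2 <- d2$z[i2]; n2 <- d2$n[i2]
  if (length(z1) < 200L) {
    stop("fewer than 200 shared variants for genetic correlation",
         call. = FALSE)
  }
  m <- ld$m_total

  f1 <- h2_fit(z1, ell, n1, m)
  f2 <- h2_fit(z2, ell, n2, m)
  xg <- sqrt(n1 * n2) * ell / m
  wg <- sqrt(f1$w * f2$w)
  cog <- wls2(xg, z1 * z2, wg)

  rg_of <- function(h2a, h2b, gencov) {
    if (h2a <= 0 || h2b <= 0) return(NA_real_)
    gencov / sqrt(h2a * h2b)
  }
  rg <- rg_of(f1$h2, f2$h2, cog[2])

  blocks <- jk_blocks(length(z1), n_blocks)
  nb <- max(blocks)
  reps <- vapply(seq_len(nb), function(b) {
    k <- blocks != b
    a <- wls2(f1$x[k], f1$y[k], f1$w[k])[2]
    bb <- wls2(f2$x[k], f2$y[k], f2$w[k])[2]
    g <- wls2(xg[k], (z1 * z2)[k], wg[k])[2]
    rg_of(a, bb, g)
  }, numeric(1))
  h2reps1 <- vapply(seq_len(nb), function(b) {
    k <- blocks != b; wls2(f1$x[k], f1$y[k], f1$w[k])[2]
  }, numeric(1))
  h2reps2 <- vapply(seq_len(nb), function(b) {
    k <- blocks != b; wls2(f2$x[k], f2$y[k], f2$w[k])[2]
  }, numeric(1))
  jk_se <- function(r) {
    r <- r[is.finite(r)]
    if (length(r) < 2L) return(NA_real_)
    sqrt((length(r) - 1) / length(r) * sum((r - mean(r))^2))
  }
  rg_se <- jk_se(reps)

  out_of_bounds <- is.finite(rg) && abs(rg) > 1
  if (is.finite(rg)) rg <- max(-1.25, min(1.25, rg))
  rg_p <- if (is.finite(rg) && is.finite(rg_se) && rg_se > 0) {
    z_pvalue(rg, rg_se)
  } else NA_real_
  if (is.na(rg)) {
    warning("non-positive heritability estimate: rg undefined", call. = FALSE)
  }
  structure(
    list(h2_1 = f1$h2, h2_1_se = jk_se(h2reps1),
         h2_2 = f2$h2, h2_2_se = jk_se(h2reps2),
         gencov = cog[2], intercept = cog[1],
         rg = rg, rg_se = rg_se, rg_p = rg_p,
         n_snp = length(z1), n_blocks = nb,
         out_of_bounds = out_of_bounds),
    class = "ldsc_result"
  )
}

#' @export
print.ldsc_result <- function(x, ...) {
  cat(sprintf("LDSC genetic correlation (%d variants, %d jackknife blocks)\n",
              x$n_snp, x$n_blocks))
  cat(sprintf("  h2: %.4f (se %.4f) / %.4f (se %.4f)\n",
              x$h2_1, x$h2_1_se, x$h2_2, x$h2_2_se))
  cat(sprintf("  rg = %.4f (se %.4f), p = %.3g%s\n", x$rg, x$rg_se, x$rg_p,
              if (isTRUE(x$out_of_bounds)) " [outside [-1,1], clipped]" else ""))
  invisible(x)
}

#' Bonferroni per-test significance threshold
#'
#' @param alpha Familywise significance level in `(0, 1)`.
#' @param m Number of tests (>= 1).
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 6) # 8.33e-3
#' @export
bonferroni_threshold <- function(alpha, m) {
  assert_that(alpha > 0 && alpha < 1, "alpha must lie in (0,1)")
  assert_that(m >= 1, "m must be at least 1")
  alpha / m
}
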