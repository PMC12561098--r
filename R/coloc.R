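#' Wakefield approximate Bayes factor
#'
#' Log approximate Bayes factor for association at one variant, comparing
#' `beta ~ Normal(0, se^2 + W)` (true effect present, with prior effect
#' variance `W = prior_sd^2`) against the null `beta ~ Normal(0, se^2)`:
#' `log ABF = 0.5 * (log(se^2 / (se^2 + W)) + z^2 * W / (se^2 + W))` with
#' `z = beta / se`.
#'
#' @param beta,se Association estimate and standard error (vectorized).
#' @param prior_sd Prior standard deviation of the true effect; conventional
#'   values are 0.15 for quantitative traits and 0.2 for binary (log-odds)
#'   traits.
#' @return Log Bayes factor(s).
#' @examples
#' wakefield_abf(0.5, 0.1, prior_sd = 0.2) # z = 5
#' @export
wakefield_abf <- function(beta, se, prior_sd = 0.15) {
  assert_that(all(se > 0), "se must be positive")
  assert_that(all(prior_sd > 0), "prior_sd must be positive")
  W <- prior_sd^2
  shrink <- W / (se^2 + W)
  z <- beta / se
  0.5 * (log(1 - shrink) + z^2 * shrink)
}

# stable log(exp(a) - exp(b)) for a >= b
log_diff_exp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Bayesian colocalization of two traits over a region
#'
#' Tests whether two traits share a single causal variant in a genomic window
#' by the standard five-hypothesis enumeration: H0 no association with either
#' trait, H1/H2 association with one trait only, H3 two distinct causal
#' variants, H4 one shared causal variant. Per-variant evidence is the
#' Wakefield approximate Bayes factor; per-hypothesis sums are accumulated in
#' log space and weighted by the prior probabilities that a variant is causal
#' for trait 1 (`p1`), trait 2 (`p2`), or both (`p12`).
#'
#' @param r1,r2 [summary_stats()] objects (typically [region_stats()]
#'   windows) for the two traits. Variants are intersected on rsid and
#'   required to carry the same allele pair (in either order).
#' @param priors Numeric vector `c(p1, p2, p12)`; defaults
#'   `c(1e-4, 1e-4, 1e-5)`.
#' @param prior_sd Optional length-2 vector of effect prior standard
#'   deviations; defaults to 0.15 per quantitative and 0.2 per binary trait.
#' @return An object of class `coloc_result`: `pph0`..`pph4` (posterior
#'   probabilities summing to one), `n_snps_shared`, `top_shared_snp` (the
#'   variant maximizing the per-variant H4 contribution), `priors`, and
#'   `single_snp` (flag: with one shared variant H3 is structurally zero).
#' @export
coloc_abf <- function(r1, r2, priors = c(1e-4, 1e-4, 1e-5),
                      prior_sd = NULL) {
  stopifnot(inherits(r1, "summary_stats"), inherits(r2, "summary_stats"))
  assert_that(length(priors) == 3L && all(priors > 0),
              "priors must be three positive numbers (p1, p2, p12)")
  p1 <- priors[[1]]; p2 <- priors[[2]]; p12 <- priors[[3]]
  assert_that(p12 <= min(p1, p2), "p12 must not exceed min(p1, p2)")
  if (is.null(prior_sd)) {
    prior_sd <- c(if (r1$trait_type == "binary") 0.2 else 0.15,
                  if (r2$trait_type == "binary") 0.2 else 0.15)
  }

  a <- r1$records; b <- r2$records
  idx <- match(a$rsid, b$rsid)
  ok <- !is.na(idx)
  a <- a[ok, , drop = FALSE]; b <- b[idx[ok], , drop = FALSE]
  same <- (a$effect_allele == b$effect_allele &
             a$other_allele == b$other_allele) |
    (a$effect_allele == b$other_allele & a$other_allele == b$effect_allele)
  a <- a[same, , drop = FALSE]; b <- b[same, , drop = FALSE]
  n <- nrow(a)
  if (n == 0L) {
    stop("no shared variants between the two regions", call. = FALSE)
  }

  l1 <- wakefield_abf(a$beta, a$se, prior_sd[[1]])
  l2 <- wakefield_abf(b$beta, b$se, prior_sd[[2]])

  lse1 <- log_sum_exp(l1)
  lse2 <- log_sum_exp(l2)
  lse12 <- log_sum_exp(l1 + l2)
  lh <- c(
    h0 = 0,
    h1 = log(p1) + lse1,
    h2 = log(p2) + lse2,
    h3 = log(p1) + log(p2) + log_diff_exp(lse1 + lse2, lse12),
    h4 = log(p12) + lse12
  )
  post <- exp(lh - log_sum_exp(lh))
  post <- post / sum(post)

  structure(
    list(pph0 = post[["h0"]], pph1 = post[["h1"]], pph2 = post[["h2"]],
         pph3 = post[["h3"]], pph4 = post[["h4"]],
         n_snps_shared = n, top_shared_snp = a$rsid[which.max(l1 + l2)],
         priors = c(p1 = p1, p2 = p2, p12 = p12),
         single_snp = n == 1L,
         per_snp = data.frame(rsid = a$rsid, labf1 = l1, labf2 = l2,
                              labf_sum = l1 + l2, stringsAsFactors = FALSE)),
    class = "coloc_result"
  )
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("Colocalization over %d shared variants%s\n", x$n_snps_shared,
              if (x$single_snp) " (single variant: H3 structurally zero)" else ""))
  cat(sprintf("  PPH0..PPH4: %.3f %.3f %.3f %.3f %.3f\n",
              x$pph0, x$pph1, x$pph2, x$pph3, x$pph4))
  cat(sprintf("  top shared variant: %s; tier: %s\n",
              x$top_shared_snp, coloc_tier(x)))
  invisible(x)
}

#' Evidence tier from a colocalization posterior
#'
#' `"colocalized"` when PPH4 >= 0.8, `"suggestive"` when 0.5 <= PPH4 < 0.8,
#' `"none"` otherwise.
#'
#' @param x A [coloc_abf()] result or a PPH4 value.
#' @return Character tier.
#' @export
coloc_tier <- function(x) {
  pph4 <- if (inherits(x, "coloc_result")) x$pph4 else x
  if (pph4 >= 0.8) "colocalized" else if (pph4 >= 0.5) "suggestive" else "none"
}

#' Read a regional slice of a summary-statistics file
#'
#' Convenience wrapper: [read_summary_stats()] restricted to a
#' `"chrom:start-end"` region string (closed interval).
#'
#' @inheritParams read_summary_stats
#' @param region Region string, e.g. `"11:61300000-61800000"`.
#' @return A [summary_stats()] object restricted to the region.
#' @export
read_region_stats <- function(path, region, dialect = list(), trait_id = NULL,
                              trait_type = c("quantitative", "binary"),
                              sample_size_default = NA_real_) {
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  assert_that(length(m) == 4L, "region must look like 'chrom:start-end'")
  start <- as.numeric(m[3]); end <- as.numeric(m[4])
  ss <- read_summary_stats(path, dialect = dialect, trait_id = trait_id,
                           trait_type = trait_type,
                           sample_size_default = sample_size_default)
  region_stats(ss, chrom = m[2], center = (start + end) / 2,
               half_width = (end - start) / 2)
}
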