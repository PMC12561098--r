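#' Ground truth for a simulated mediation triangle
#'
#' Encodes the generative parameters of an exposure -> mediator -> outcome
#' structural model. The total exposure -> outcome effect is the identity
#' `theta_total = theta_direct + theta_xm * theta_my`, asserted at
#' construction, and the true mediation proportion is
#' `theta_xm * theta_my / theta_total`.
#'
#' Defaults emulate the study design this package targets: a large
#' anthropometric exposure GWAS (300,000 individuals, 100 instruments
#' explaining 6% of variance), a moderately sized plasma-metabolite GWAS
#' (8,000 individuals, 20 strong metabolite loci explaining 15% of variance —
#' metabolite architectures are dominated by few large-effect loci), and a
#' binary disease outcome GWAS of 26,554 individuals with effects on the
#' log-odds scale.
#'
#' @param theta_xm True exposure -> mediator effect.
#' @param theta_my True mediator -> outcome effect.
#' @param theta_direct Direct exposure -> outcome effect.
#' @param n_snp_x,n_snp_m Numbers of exposure and mediator-specific
#'   instruments (each >= 3).
#' @param r2_exposure,r2_mediator Variance explained by each instrument panel
#'   in its own trait.
#' @param pleiotropy List: `mode` (`"none"`, `"balanced"`, `"directional"`,
#'   `"correlated"`), `sd` (scale of the direct variant -> outcome effects),
#'   `mean` (directional shift), `cor` (correlation with instrument strength
#'   for the `"correlated"` mode, which violates the InSIDE assumption).
#' @param sample_sizes Named vector: `exposure`, `mediator`, `outcome`.
#' @param maf_range Allele frequencies are drawn uniformly on this range.
#' @param seed Integer seed; generation is a pure function of
#'   (parameters, seed).
#' @return An object of class `simulation_truth`.
#' @export
simulation_truth <- function(theta_xm = 0.3, theta_my = 0.25,
                             theta_direct = 0.175,
                             n_snp_x = 100L, n_snp_m = 20L,
                             r2_exposure = 0.06, r2_mediator = 0.15,
                             pleiotropy = list(mode = "none", sd = 0,
                                               mean = 0, cor = 0.5),
                             sample_sizes = c(exposure = 3e5, mediator = 8e3,
                                              outcome = 26554),
                             maf_range = c(0.05, 0.5), seed = 1L) {
  pleiotropy <- utils::modifyList(
    list(mode = "none", sd = 0, mean = 0, cor = 0.5), pleiotropy)
  assert_that(pleiotropy$mode %in% c("none", "balanced", "directional",
                                     "correlated"),
              "unknown pleiotropy mode")
  assert_that(n_snp_x >= 3L && n_snp_m >= 3L,
              "instrument counts must be >= 3")
  assert_that(all(c("exposure", "mediator", "outcome") %in%
                    names(sample_sizes)),
              "sample_sizes must name exposure, mediator, outcome")
  theta_total <- theta_direct + theta_xm * theta_my
  truth <- list(theta_xm = theta_xm, theta_my = theta_my,
                theta_direct = theta_direct, theta_total = theta_total,
                proportion = if (theta_total != 0) {
                  theta_xm * theta_my / theta_total
                } else NA_real_,
                n_snp_x = as.integer(n_snp_x), n_snp_m = as.integer(n_snp_m),
                r2_exposure = r2_exposure, r2_mediator = r2_mediator,
                pleiotropy = pleiotropy, sample_sizes = sample_sizes,
                maf_range = maf_range, seed = as.integer(seed))
  stopifnot(isTRUE(all.equal(truth$theta_total,
                             theta_direct + theta_xm * theta_my)))
  structure(truth, class = "simulation_truth")
}

# non-palindromic allele pairs: strand-ambiguous variants are assumed
# excluded by upstream QC
allele_pairs <- function(n) {
  pairs <- rbind(c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
                 c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))
  pairs[sample.int(nrow(pairs), n, replace = TRUE), , drop = FALSE]
}

# scale raw normal draws so the panel explains exactly r2_target
scale_to_r2 <- function(raw, maf, r2_target) {
  raw * sqrt(r2_target / sum(2 * maf * (1 - maf) * raw^2))
}

gwas_se <- function(maf, n) 1 / sqrt(2 * maf * (1 - maf) * n)

make_ss <- function(rsid, chrom, pos, alleles, maf, true_beta, n, trait_id,
                    trait_type) {
  se <- gwas_se(maf, n)
  beta <- stats::rnorm(length(true_beta), true_beta, se)
  summary_stats(
    data.frame(rsid = rsid, chrom = chrom, pos = pos,
               effect_allele = alleles[, 1], other_allele = alleles[, 2],
               eaf = maf, beta = beta, se = se,
               pval = pmax(2 * stats::pnorm(-abs(beta / se)), 1e-300), n = n,
               stringsAsFactors = FALSE),
    trait_id = trait_id, trait_type = trait_type,
    sample_size_default = n)
}

#' Simulate GWAS summary statistics for a mediation triangle
#'
#' Generates three summary-statistics tables — exposure, mediator, and
#' (binary) outcome — sharing variants and alleles, under the structural
#' model encoded in a [simulation_truth()]. Exposure instruments receive
#' effects `gamma_j ~ Normal(0, s^2)` rescaled so the panel explains the
#' target variance; the mediator inherits `theta_xm * gamma_j` from them plus
#' its own specific instruments; the outcome receives
#' `theta_direct * gamma_j + theta_my * (mediator effect)` plus a per-variant
#' pleiotropy term on the exposure instruments (zero-mean when balanced,
#' shifted when directional, correlated with instrument strength when the
#' InSIDE assumption is violated). Observed effects add sampling noise with
#' `se_j = 1 / sqrt(2 * maf_j * (1 - maf_j) * N)`.
#'
#' @param truth A [simulation_truth()] object.
#' @return A list `exposure`, `mediator`, `outcome` (each a
#'   [summary_stats()]), plus `truth` and `true_effects` (per-variant true
#'   effect table).
#' @export
simulate_triangle <- function(truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  withr::with_seed(truth$seed, {
    nx <- truth$n_snp_x; nm <- truth$n_snp_m
    n_all <- nx + nm
    rsid <- sprintf("rs%06d", seq_len(n_all))
    chrom <- as.character(rep_len(1:22, n_all))
    pos <- seq_len(n_all) * 100000L
    alleles <- allele_pairs(n_all)
    maf <- stats::runif(n_all, truth$maf_range[1], truth$maf_range[2])

    ix <- seq_len(nx)
    im <- nx + seq_len(nm)
    gamma <- numeric(n_all)
    delta <- numeric(n_all)
    # exposure effects coded per exposure-increasing allele (the orientation
    # convention directional pleiotropy is defined against)
    gamma[ix] <- scale_to_r2(abs(stats::rnorm(nx)), maf[ix],
                             truth$r2_exposure)
    delta[im] <- scale_to_r2(stats::rnorm(nm), maf[im], truth$r2_mediator)

    pl <- truth$pleiotropy
    alpha <- numeric(n_all)
    if (pl$mode == "balanced") {
      alpha[ix] <- stats::rnorm(nx, 0, pl$sd)
    } else if (pl$mode == "directional") {
      alpha[ix] <- stats::rnorm(nx, pl$mean, pl$sd)
    } else if (pl$mode == "correlated") {
      g_std <- (gamma[ix] - mean(gamma[ix])) / stats::sd(gamma[ix])
      alpha[ix] <- pl$mean + pl$sd *
        (pl$cor * g_std + sqrt(1 - pl$cor^2) * stats::rnorm(nx))
    }

    beta_x <- gamma
    beta_m <- truth$theta_xm * gamma + delta
    beta_y <- truth$theta_direct * gamma + truth$theta_my * beta_m + alpha

    ns <- truth$sample_sizes
    exposure <- make_ss(rsid, chrom, pos, alleles, maf, beta_x,
                        ns[["exposure"]], "exposure", "quantitative")
    mediator <- make_ss(rsid, chrom, pos, alleles, maf, beta_m,
                        ns[["mediator"]], "mediator", "quantitative")
    outcome <- make_ss(rsid, chrom, pos, alleles, maf, beta_y,
                       ns[["outcome"]], "outcome", "binary")
    list(exposure = exposure, mediator = mediator, outcome = outcome,
         truth = truth,
         true_effects = data.frame(rsid = rsid, maf = maf, beta_x = beta_x,
                                   beta_m = beta_m, beta_y = beta_y,
                                   pleiotropy = alpha,
                                   stringsAsFactors = FALSE))
  })
}

#' Simulate a pair of regional association profiles for colocalization
#'
#' Builds an LD-free 500 kb region for two traits. When `shared = TRUE` a
#' single variant carries the association signal in both traits; otherwise
#' two distinct variants do. All other variants are pure noise
#' (`z ~ Normal(0, 1)`).
#'
#' @param shared Logical: one shared causal variant vs two distinct ones.
#' @param n_snp Number of variants in the region.
#' @param z_strength Expected z-statistic at the causal variant(s).
#' @param seed Integer seed.
#' @param n1,n2 GWAS sample sizes used to convert z to (beta, se).
#' @return A list of two [summary_stats()] objects (`trait1`, `trait2`) plus
#'   `causal` (the causal rsid(s)).
#' @export
simulate_coloc_region <- function(shared = TRUE, n_snp = 100L,
                                  z_strength = 10, seed = 1L,
                                  n1 = 10000, n2 = 10000) {
  assert_that(n_snp >= 1L, "n_snp must be >= 1")
  withr::with_seed(seed, {
    rsid <- sprintf("rs%06d", seq_len(n_snp))
    chrom <- rep("1", n_snp)
    center <- 1e6
    pos <- as.integer(round(seq(center - 250000, center + 250000,
                                length.out = n_snp)))
    alleles <- allele_pairs(n_snp)
    maf <- stats::runif(n_snp, 0.05, 0.5)

    c1 <- 1L
    c2 <- if (shared || n_snp == 1L) c1 else 2L
    mu1 <- numeric(n_snp); mu1[c1] <- z_strength
    mu2 <- numeric(n_snp); mu2[c2] <- z_strength
    z1 <- stats::rnorm(n_snp, mu1, 1)
    z2 <- stats::rnorm(n_snp, mu2, 1)

    to_ss <- function(z, n, id) {
      se <- gwas_se(maf, n)
      summary_stats(
        data.frame(rsid = rsid, chrom = chrom, pos = pos,
                   effect_allele = alleles[, 1], other_allele = alleles[, 2],
                   eaf = maf, beta = z * se, se = se,
                   pval = pmax(2 * stats::pnorm(-abs(z)), 1e-300), n = n,
                   stringsAsFactors = FALSE),
        trait_id = id, trait_type = "quantitative", sample_size_default = n)
    }
    list(trait1 = to_ss(z1, n1, "trait1"), trait2 = to_ss(z2, n2, "trait2"),
         causal = unique(rsid[c(c1, c2)]))
  })
}

#' Simulate a summary-statistics pair under the LD-score regression model
#'
#' Draws LD scores `l_j = 1 + Gamma(shape 2, rate 0.02)` (positive, mean
#' about 100, resembling genome-wide LD-score distributions) and per-variant
#' z-statistic pairs with marginal variance `1 + N h2 l_j / M` and
#' cross-trait covariance `rg * sqrt(h2_1 h2_2) * sqrt(N1 N2) * l_j / M`,
#' the generative model simplified LD-score regression inverts.
#'
#' @param h2_1,h2_2 True heritabilities in `[0, 1)`.
#' @param rg True genetic correlation, `|rg| <= 1`.
#' @param m Number of variants (also used as the total M).
#' @param n1,n2 GWAS sample sizes.
#' @param seed Integer seed.
#' @return A list: `trait1`, `trait2` ([summary_stats()]), `ld`
#'   (an [ld_score_table()]).
#' @export
simulate_ldsc_pair <- function(h2_1 = 0.25, h2_2 = 0.25, rg = 0.47,
                               m = 5000L, n1 = 50000, n2 = 50000, seed = 1L) {
  assert_that(abs(rg) <= 1, "|rg| must be <= 1")
  assert_that(h2_1 >= 0 && h2_1 < 1 && h2_2 >= 0 && h2_2 < 1,
              "heritabilities must lie in [0, 1)")
  withr::with_seed(seed, {
    rsid <- sprintf("rs%07d", seq_len(m))
    ell <- 1 + stats::rgamma(m, shape = 2, rate = 0.02)
    v1 <- 1 + n1 * h2_1 * ell / m
    v2 <- 1 + n2 * h2_2 * ell / m
    cv <- rg * sqrt(h2_1 * h2_2) * sqrt(n1 * n2) * ell / m
    a <- stats::rnorm(m); b <- stats::rnorm(m)
    z1 <- sqrt(v1) * a
    z2 <- cv / sqrt(v1) * a + sqrt(pmax(v2 - cv^2 / v1, 0)) * b

    maf <- stats::runif(m, 0.05, 0.5)
    alleles <- allele_pairs(m)
    to_ss <- function(z, n, id) {
      se <- gwas_se(maf, n)
      summary_stats(
        data.frame(rsid = rsid, chrom = "1", pos = seq_len(m) * 1000L,
                   effect_allele = alleles[, 1], other_allele = alleles[, 2],
                   eaf = maf, beta = z * se, se = se,
                   pval = pmax(2 * stats::pnorm(-abs(z)), 1e-300), n = n,
                   stringsAsFactors = FALSE),
        trait_id = id, trait_type = "quantitative", sample_size_default = n)
    }
    list(trait1 = to_ss(z1, n1, "trait1"), trait2 = to_ss(z2, n2, "trait2"),
         ld = ld_score_table(data.frame(rsid = rsid, ldscore = ell,
                                        stringsAsFactors = FALSE),
                             m_total = m))
  })
}
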