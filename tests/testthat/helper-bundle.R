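# Multi-trait synthetic bundle for pipeline tests: n_pheno phenotypes and
# n_metab metabolites sharing one (binary) outcome. Metabolite 1 is the
# planted mediator of every phenotype (true mediation proportion
# theta_xm*theta_my / (theta_direct + theta_xm*theta_my)); the others are
# genetically driven but causally inert.
simulate_bundle <- function(seed, n_pheno = 2L, n_metab = 3L,
                            n_snp_x = 60L, n_snp_m = 15L,
                            theta_xm = 0.3, theta_my = 0.25,
                            theta_direct = 0.175,
                            n_exposure = 3e5, n_mediator = 8e3,
                            n_outcome = 26554, n_validation = 185616) {
  withr::with_seed(seed, {
    n_all <- n_pheno * n_snp_x + n_metab * n_snp_m
    rsid <- sprintf("rs%06d", seq_len(n_all))
    chrom <- as.character(rep_len(1:22, n_all))
    pos <- seq_len(n_all) * 100000L
    pairs <- rbind(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"))
    alleles <- pairs[sample.int(4L, n_all, replace = TRUE), , drop = FALSE]
    maf <- runif(n_all, 0.05, 0.5)
    scale_r2 <- function(raw, maf, r2) {
      raw * sqrt(r2 / sum(2 * maf * (1 - maf) * raw^2))
    }
    mk <- function(true_beta, n, id, type) {
      se <- 1 / sqrt(2 * maf * (1 - maf) * n)
      beta <- rnorm(n_all, true_beta, se)
      summary_stats(data.frame(
        rsid = rsid, chrom = chrom, pos = pos,
        effect_allele = alleles[, 1], other_allele = alleles[, 2],
        eaf = maf, beta = beta, se = se,
        pval = pmax(2 * pnorm(-abs(beta / se)), 1e-300), n = n,
        stringsAsFactors = FALSE), trait_id = id, trait_type = type,
        sample_size_default = n)
    }

    gammas <- matrix(0, n_all, n_pheno)
    for (k in seq_len(n_pheno)) {
      idx <- (k - 1L) * n_snp_x + seq_len(n_snp_x)
      gammas[idx, k] <- scale_r2(rnorm(n_snp_x), maf[idx], 0.06)
    }
    deltas <- matrix(0, n_all, n_metab)
    for (m in seq_len(n_metab)) {
      idx <- n_pheno * n_snp_x + (m - 1L) * n_snp_m + seq_len(n_snp_m)
      deltas[idx, m] <- scale_r2(rnorm(n_snp_m), maf[idx], 0.15)
    }

    beta_metab <- deltas
    beta_metab[, 1] <- beta_metab[, 1] + theta_xm * rowSums(gammas)
    beta_y <- theta_direct * rowSums(gammas) + theta_my * beta_metab[, 1]

    phenotypes <- lapply(seq_len(n_pheno), function(k) {
      mk(gammas[, k], n_exposure, sprintf("pheno%d", k), "quantitative")
    })
    names(phenotypes) <- sprintf("pheno%d", seq_len(n_pheno))
    metabolites <- lapply(seq_len(n_metab), function(m) {
      mk(beta_metab[, m], n_mediator, sprintf("met%d", m), "quantitative")
    })
    names(metabolites) <- sprintf("met%d", seq_len(n_metab))

    list(traits = list(
      outcome = mk(beta_y, n_outcome, "outcome", "binary"),
      outcome_validation = mk(beta_y, n_validation, "outcome_validation",
                              "binary"),
      phenotypes = phenotypes, metabolites = metabolites),
      truth = list(theta_xm = theta_xm, theta_my = theta_my,
                   theta_direct = theta_direct,
                   proportion = theta_xm * theta_my /
                     (theta_direct + theta_xm * theta_my),
                   mediator = "met1"))
  })
}
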