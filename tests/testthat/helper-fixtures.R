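# Shared fixtures built in code. Messages from validation/harmonization are
# suppressed package-wide during tests.
options(mrtriad.quiet = TRUE)

# minimal well-formed summary-statistics data.frame
toy_records <- function(n = 3L, seed = 1L) {
  withr::with_seed(seed, {
    data.frame(
      rsid = sprintf("rs%d", seq_len(n)),
      chrom = "1", pos = seq_len(n) * 1000L,
      effect_allele = rep(c("A", "C", "G"), length.out = n),
      other_allele = rep(c("G", "T", "A"), length.out = n),
      eaf = runif(n, 0.1, 0.45),
      beta = rnorm(n, 0, 0.1), se = runif(n, 0.01, 0.05),
      pval = runif(n, 1e-10, 0.5), n = 10000,
      stringsAsFactors = FALSE
    )
  })
}

# harmonized-style rows with exact proportional structure beta_out = k*beta_exp
proportional_rows <- function(k = 0.25, n = 5L, seed = 2L) {
  withr::with_seed(seed, {
    bx <- runif(n, 0.05, 0.2)
    data.frame(beta_exp = bx, se_exp = 0.005, beta_out = k * bx,
               se_out = runif(n, 0.005, 0.02), stringsAsFactors = FALSE)
  })
}

# noisy null-pleiotropy harmonized rows with true effect theta
mr_rows <- function(n = 30L, theta = 0.25, seed = 3L, sy = 0.01, sx = 0.003) {
  withr::with_seed(seed, {
    bx <- rnorm(n, 0, 0.07)
    by <- rnorm(n, theta * bx, sy)
    data.frame(rsid = sprintf("rs%d", seq_len(n)),
               beta_exp = bx + rnorm(n, 0, sx), se_exp = sx,
               beta_out = by, se_out = sy, stringsAsFactors = FALSE)
  })
}
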