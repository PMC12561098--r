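test_that("well-formed tables pass through and invalid rows are dropped with a count", {
  df <- toy_records(3)
  ss <- summary_stats(df, trait_id = "t")
  expect_s3_class(ss, "summary_stats")
  expect_equal(nrow(ss$records), 3L)
  expect_equal(ss$n_dropped, 0L)

  df_bad <- rbind(df, df[1, ])
  df_bad$rsid[4] <- "rs_bad"
  df_bad$se[4] <- 0
  ss2 <- summary_stats(df_bad, trait_id = "t")
  expect_equal(ss2$n_dropped, 1L)
  expect_false("rs_bad" %in% ss2$records$rsid)

  df_dup <- rbind(df, df[1, ])          # duplicate rsid
  expect_equal(summary_stats(df_dup)$n_dropped, 1L)

  df$pval[1] <- 0                       # p must be in (0, 1]
  expect_equal(summary_stats(df)$n_dropped, 1L)
})

test_that("reading maps dialects, transforms OR columns, and errors usefully", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- toy_records(4)
  names(df) <- c("rsid", "chromosome", "base_pair_location", "effect_allele",
                 "other_allele", "effect_allele_frequency", "beta",
                 "standard_error", "p_value", "n")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ss <- read_summary_stats(path, trait_id = "x")
  expect_equal(nrow(ss$records), 4L)
  expect_equal(ss$records$beta, toy_records(4)$beta)

  # odds-ratio input: beta = ln(OR); ln(1.267) = 0.23663 to 5 decimals
  df_or <- df
  df_or$beta <- NULL
  df_or$odds_ratio <- 1.267
  write.table(df_or, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ss_or <- read_summary_stats(path, dialect = list(or = "odds_ratio"),
                              trait_type = "binary")
  expect_equal(ss_or$records$beta, rep(0.23663, 4), tolerance = 1e-4)

  df_miss <- df
  df_miss$standard_error <- NULL
  write.table(df_miss, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_summary_stats(path), "standard_error")

  writeLines(paste(names(df), collapse = "\t"), path)
  expect_error(read_summary_stats(path), "empty")
})

test_that("summary statistics round-trip through the TSV writer", {
  ss <- summary_stats(toy_records(5), trait_id = "rt")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(ss, path)
  back <- read_summary_stats(path, trait_id = "rt")
  expect_equal(back$records[c("rsid", "beta", "se", "pval")],
               ss$records[c("rsid", "beta", "se", "pval")])
})

test_that("instrument selection thresholds, clumps greedily, and is order-invariant", {
  df <- toy_records(5)
  df$pval <- c(1e-9, 1e-8, 1e-7, 1e-6, 0.5)
  ss <- summary_stats(df)
  iv <- select_instruments(ss, p_threshold = 5e-8)
  expect_equal(nrow(iv$instruments), 2L)

  # pairwise r2 = 0.9 above clump threshold: only the smaller p survives
  ld <- matrix(c(1, 0.9, 0.9, 1), 2, 2,
               dimnames = list(c("rs1", "rs2"), c("rs1", "rs2")))
  iv2 <- select_instruments(summary_stats(df[1:2, ]), p_threshold = 1e-6,
                            clump_r2 = 0.001, ld = ld)
  expect_equal(iv2$instruments$rsid, "rs1")

  expect_error(select_instruments(ss, p_threshold = 1e-12), "no variant")

  # greedy oracle on a random 10x10 r2 matrix
  withr::with_seed(42, {
    df10 <- toy_records(10)
    df10$pval <- runif(10, 1e-12, 1e-8)
    a <- matrix(runif(100, 0, 0.6), 10)
    r2m <- (a + t(a)) / 2
    diag(r2m) <- 1
    dimnames(r2m) <- list(df10$rsid, df10$rsid)
  })
  greedy_oracle <- function(df10, r2m, thr) {
    ord <- order(df10$pval, df10$rsid)
    kept <- character(0)
    for (id in df10$rsid[ord]) {
      if (all(r2m[id, kept] < thr) || length(kept) == 0L) kept <- c(kept, id)
    }
    kept
  }
  iv10 <- select_instruments(summary_stats(df10), p_threshold = 1e-6,
                             clump_r2 = 0.1, ld = r2m)
  oracle <- greedy_oracle(df10, r2m, 0.1)
  expect_setequal(iv10$instruments$rsid, oracle)

  shuffled <- summary_stats(df10[sample(10), ])
  iv10b <- select_instruments(shuffled, p_threshold = 1e-6, clump_r2 = 0.1,
                              ld = r2m)
  expect_setequal(iv10b$instruments$rsid, iv10$instruments$rsid)
})

test_that("F statistics and explained variance follow their closed forms", {
  expect_equal(f_statistic(0.1, 0.02), 25)
  expect_equal(f_statistic(-0.1, 0.02), 25)
  expect_equal(f_statistic(0.0447, 0.01), 19.98, tolerance = 1e-3)
  expect_lt(f_statistic(0.0447, 0.01), 20)

  expect_equal(variance_explained(0.1, 0.5), 0.005)
  expect_equal(variance_explained(0, 0.3), 0)

  # panel total recovers the generative r2 within sampling error
  tri <- simulate_triangle(simulation_truth(seed = 11))
  iv <- select_instruments(tri$exposure, p_threshold = 0.999)  # keep ~all
  true_r2 <- 0.06
  exposure_rows <- iv$instruments[iv$instruments$rsid %in%
                                    tri$true_effects$rsid[tri$true_effects$beta_x != 0], ]
  expect_equal(sum(variance_explained(exposure_rows$beta, exposure_rows$eaf)),
               true_r2, tolerance = 0.25 * true_r2)
})

test_that("harmonization flips, drops, and is involution-safe", {
  exp_df <- data.frame(rsid = c("rs1", "rs2", "rs3", "rs4"), chrom = "1",
                       pos = 1:4 * 100L,
                       effect_allele = c("A", "A", "A", "A"),
                       other_allele = c("G", "T", "G", "G"),
                       eaf = c(0.3, 0.5, 0.3, 0.3),
                       beta = 0.10, se = 0.01, pval = 1e-10, n = 1e4,
                       stringsAsFactors = FALSE)
  out_df <- data.frame(rsid = c("rs1", "rs2", "rs3"), chrom = "1",
                       pos = 1:3 * 100L,
                       effect_allele = c("G", "A", "A"),
                       other_allele = c("A", "T", "C"),
                       eaf = c(0.7, 0.5, 0.3),
                       beta = c(-0.05, 0.02, 0.02), se = 0.01, pval = 0.01,
                       n = 1e4, stringsAsFactors = FALSE)
  hs <- harmonize(summary_stats(exp_df), summary_stats(out_df))
  rows <- hs$rows
  expect_equal(rows$action[rows$rsid == "rs1"], "flipped")
  expect_equal(rows$beta_out[rows$rsid == "rs1"], 0.05)
  expect_equal(rows$eaf_out[rows$rsid == "rs1"], 0.3)
  expect_equal(rows$action[rows$rsid == "rs2"], "dropped_palindromic")
  expect_equal(rows$action[rows$rsid == "rs3"], "dropped_mismatch")
  expect_equal(hs$n_absent, 1L)

  # involution: re-harmonizing the already-aligned pair changes nothing
  kept <- harmonized_rows(hs)
  out_aligned <- out_df[out_df$rsid %in% kept$rsid, ]
  out_aligned$effect_allele <- "A"; out_aligned$other_allele <- "G"
  out_aligned$beta <- kept$beta_out; out_aligned$eaf <- kept$eaf_out
  hs2 <- harmonize(summary_stats(exp_df), summary_stats(out_aligned))
  kept2 <- harmonized_rows(hs2)
  expect_equal(kept2$beta_out, kept$beta_out)
  expect_equal(kept2$action, "kept")
})

test_that("flipping every outcome allele coding leaves the harmonized effects unchanged", {
  tri <- simulate_triangle(simulation_truth(seed = 21, n_snp_x = 20L,
                                            n_snp_m = 5L))
  iv <- select_instruments(tri$exposure, p_threshold = 1e-4)
  hs1 <- harmonize(iv, tri$outcome)

  flipped <- tri$outcome
  flipped$records <- within(flipped$records, {
    tmp <- effect_allele
    effect_allele <- other_allele
    other_allele <- tmp
    rm(tmp)
    beta <- -beta
    eaf <- 1 - eaf
  })
  hs2 <- harmonize(iv, flipped)
  r1 <- harmonized_rows(hs1); r2 <- harmonized_rows(hs2)
  expect_equal(r1$rsid, r2$rsid)
  expect_equal(r1$beta_out, r2$beta_out)
  expect_equal(r1$eaf_out, r2$eaf_out)
})

test_that("region restriction keeps the closed window and errors when empty", {
  ss <- summary_stats(toy_records(10))
  ss$records$pos <- 1:10 * 1000L
  r <- region_stats(ss, chrom = "1", center = 5000, half_width = 2000)
  expect_equal(r$records$pos, c(3000, 4000, 5000, 6000, 7000))
  expect_error(region_stats(ss, chrom = "2", center = 5000, 2000),
               "no variants")
})
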