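test_that("the coefficient-product decomposition reproduces its identities", {
  m <- mediate(0.368, 0.047, 0.421, 0.134, log(1.267), 0.0594)
  expect_equal(m$indirect, 0.368 * 0.421)
  expect_equal(m$proportion * m$beta3, m$indirect)   # exact identity
  expect_equal(m$proportion_pct, 65.49, tolerance = 0.1 / 65.49)
  expect_true(m$significant)
  expect_false(m$inconsistent)

  m0 <- mediate(0, 0.05, 0.2, 0.04, 0.25, 0.05)
  expect_equal(m0$indirect, 0)
  expect_equal(m0$proportion, 0)
  expect_false(m0$significant)

  expect_warning(mz <- mediate(0.3, 0.05, 0.2, 0.04, 0, 0.05), "undefined")
  expect_false(mz$proportion_defined)
  expect_true(is.na(mz$proportion))

  expect_warning(mi <- mediate(0.5, 0.01, 0.9, 0.01, 0.2, 0.01),
                 "inconsistent")
  expect_true(mi$inconsistent)
  expect_gt(abs(mi$proportion), 1)
})

test_that("delta-method errors agree with Monte-Carlo propagation", {
  expect_equal(mediate(0.3, 0.05, 0.2, 0.04, 1, 1)$indirect_se,
               sqrt(0.000244))
  expect_equal(mediate(0.3, 0.05, 0.2, 0.04, 1, 1)$indirect_se, 0.015620,
               tolerance = 1e-4)

  # moderate relative errors (the regime of genome-wide significant MR
  # effects); the first-order method omits the s1^2 s2^2 cross term
  grid <- expand.grid(b1 = c(0.1, 0.368, -0.25), rel1 = c(0.05, 0.125),
                      b2 = c(0.25, 0.421), rel2 = c(0.05, 0.125))
  withr::with_seed(100, {
    for (i in seq_len(nrow(grid))) {
      g <- grid[i, ]
      s1 <- abs(g$b1) * g$rel1; s2 <- abs(g$b2) * g$rel2
      mc_se <- sd(rnorm(1e6, g$b1, s1) * rnorm(1e6, g$b2, s2))
      dm_se <- mediate(g$b1, s1, g$b2, s2, 1, 1)$indirect_se
      expect_equal(dm_se, mc_se, tolerance = 0.01)
    }
  })
})

test_that("the proportion interval responds to total-effect uncertainty", {
  with_se3 <- mediate(0.3, 0.05, 0.2, 0.04, 0.25, 0.05)
  without_se3 <- mediate(0.3, 0.05, 0.2, 0.04, 0.25, 0.05,
                         proportion_se3_term = FALSE)
  expect_gt(with_se3$proportion_se, without_se3$proportion_se)
  expect_equal(with_se3$proportion, without_se3$proportion)
})

test_that("BH adjustment matches a brute-force step-up oracle", {
  step_up <- function(p) {       # independent textbook implementation
    m <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
    out <- numeric(m)
    out[o] <- pmin(q, 1)
    out
  }
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  withr::with_seed(8, {
    for (i in 1:10) {
      p <- runif(sample(2:50, 1))
      expect_equal(bh_fdr(p), step_up(p))
      expect_true(all(bh_fdr(p) >= p))
      perm <- sample(length(p))
      expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
    }
  })
  expect_error(bh_fdr(c(0.5, 0)), "0,1")
})

test_that("step-1 instruments are excluded from the step-2 set", {
  df <- toy_records(10)
  df$pval <- rep(1e-10, 10)
  iv_all <- select_instruments(summary_stats(df))
  first3 <- iv_all$instruments$rsid[1:3]
  iv_a <- iv_all; iv_a$instruments <- iv_all$instruments[1:3, ]
  iv_b <- iv_all
  out <- exclude_step1_instruments(iv_a, iv_b)
  expect_equal(nrow(out$instruments), 7L)
  expect_setequal(attr(out, "removed"), first3)

  iv_disjoint <- iv_all; iv_disjoint$instruments <- iv_all$instruments[4:10, ]
  out2 <- exclude_step1_instruments(iv_a, iv_disjoint)
  expect_equal(nrow(out2$instruments), 7L)
  expect_length(attr(out2, "removed"), 0L)

  iv_sub <- iv_all; iv_sub$instruments <- iv_all$instruments[1:2, ]
  expect_error(exclude_step1_instruments(iv_a, iv_sub), "no step-2")
})

test_that("the metabolome screen enforces the dual-significance conjunction with sign concordance", {
  res <- data.frame(id = c("m1", "m2", "m3", "m4"),
                    beta_primary = c(0.4, 0.3, 0.5, 0.1),
                    p_primary = c(1e-6, 1e-5, 1e-6, 0.4),
                    beta_bwmr = c(0.38, 0.25, -0.45, 0.1),
                    p_bwmr = c(1e-5, 0.8, 1e-6, 0.5))
  sc <- screen_step1(res)
  expect_true(sc$selected[sc$id == "m1"])
  expect_false(sc$selected[sc$id == "m2"])   # bwmr not significant
  expect_false(sc$selected[sc$id == "m3"])   # discordant sign
  expect_false(sc$selected[sc$id == "m4"])   # neither significant

  # planted positives among a null metabolome keep the empirical FDR at bay
  withr::with_seed(55, {
    m_total <- 1400L; m_true <- 50L
    is_true <- seq_len(m_total) <= m_true
    fdrs <- replicate(10, {
      z1 <- rnorm(m_total, ifelse(is_true, 6, 0))
      z2 <- rnorm(m_total, ifelse(is_true, 6, 0))
      tab <- data.frame(id = as.character(seq_len(m_total)),
                        beta_primary = z1, p_primary = 2 * pnorm(-abs(z1)),
                        beta_bwmr = z2, p_bwmr = 2 * pnorm(-abs(z2)))
      sel <- screen_step1(tab)$selected
      if (!any(sel)) 0 else sum(sel & !is_true) / sum(sel)
    })
    expect_lte(mean(fdrs), 0.05 + 2 * sd(fdrs) / sqrt(10))
  })
})

test_that("shared-mediator grouping applies the joint-association rule", {
  sets <- list(BMI = c("a", "b", "c", "d"), WC = c("a", "b", "d"),
               BMR = c("a", "c"), MetS = c("a", "d", "e"))
  sm <- shared_mediators(sets)
  mem <- sm$membership
  expect_equal(mem$phenotypes[mem$id == "a"], "BMI+BMR+MetS+WC")
  expect_true(mem$retained[mem$id == "a"])
  expect_false(mem$retained[mem$id == "b"])   # BMI and WC only: excluded
  expect_true(mem$retained[mem$id == "c"])    # BMI + BMR
  expect_true(mem$retained[mem$id == "d"])    # BMI + WC + MetS
  expect_false(mem$retained[mem$id == "e"])   # single phenotype

  # brute-force set-algebra oracle over group sizes
  oracle_groups <- table(vapply(c("a", "c", "d"), function(id) {
    paste(sort(names(sets)[vapply(sets, function(s) id %in% s, logical(1))]),
          collapse = "+")
  }, character(1)))
  expect_equal(lengths(sm$groups)[names(oracle_groups)],
               c(oracle_groups))
})

test_that("reverse-causality exclusion is per phenotype-mediator pair", {
  tr <- list(exposure = "BMI", mediator = "phosphate_mannose")
  kept <- reverse_mr_filter(tr, reverse_p_mediator_phenotype = 0.4)
  expect_false(kept$reverse_excluded)
  gone <- reverse_mr_filter(tr, reverse_p_mediator_phenotype = 0.0005)
  expect_true(gone$reverse_excluded)
  # same mediator, different phenotype, non-significant reverse: retained
  tr2 <- list(exposure = "MetS", mediator = "phosphate_mannose")
  kept2 <- reverse_mr_filter(tr2, reverse_p_mediator_phenotype = 0.2)
  expect_false(kept2$reverse_excluded)
  gone2 <- reverse_mr_filter(tr, 0.5, reverse_p_outcome_mediator = 0.001)
  expect_true(gone2$reverse_excluded)
})

test_that("evidence tiers combine colocalization and external validation", {
  base <- list(coloc_tier = "colocalized", validated_external = TRUE)
  expect_equal(assign_evidence_tier(base)$evidence_tier, "two_star")
  expect_equal(assign_evidence_tier(
    list(coloc_tier = "suggestive", validated_external = FALSE))$evidence_tier,
    "one_star")
  expect_equal(assign_evidence_tier(
    list(coloc_tier = "none", validated_external = TRUE))$evidence_tier,
    "one_star")
  expect_equal(assign_evidence_tier(
    list(coloc_tier = "none", validated_external = FALSE))$evidence_tier,
    "none")
  expect_error(assign_evidence_tier(list(coloc_tier = "none")),
               "validated_external")
})
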