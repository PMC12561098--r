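test_that("Wald ratio arithmetic, null case, and second-order error ordering", {
  wr <- wald_ratio(0.2, 0.05, 0.05, 0.01)
  expect_equal(wr$beta, 0.25)
  expect_equal(wr$se, 0.05)

  wr0 <- wald_ratio(0.2, 0.05, 0, 0.01)
  expect_equal(wr0$beta, 0)
  expect_equal(wr0$pval, 1)

  wr2 <- wald_ratio(0.2, 0.05, 0.05, 0.01, second_order = TRUE)
  # delta-method oracle: var = se_out^2/bx^2 + by^2 se_x^2 / bx^4
  expect_equal(wr2$se, sqrt(0.01^2 / 0.04 + 0.05^2 * 0.05^2 / 0.2^4))
  expect_gt(wr2$se, wr$se)

  expect_error(wald_ratio(0, 0.05, 0.1, 0.01), "nonzero")
})

test_that("IVW matches its closed form and a generic WLS oracle", {
  rows <- data.frame(beta_exp = c(0.1, 0.2, 0.15), se_exp = 0.01,
                     beta_out = c(0.02, 0.06, 0.03),
                     se_out = c(0.01, 0.02, 0.015))
  fit <- mr_fit(rows, method = "ivw_mre")
  expect_equal(fit$beta, 70 / 300)           # sum(bx*by/sy^2)/sum(bx^2/sy^2)
  expect_equal(fit$beta, 0.23333, tolerance = 1e-4)

  # equivalence with lm's zero-intercept weighted regression on random inputs
  withr::with_seed(7, {
    for (i in 1:20) {
      n <- sample(3:40, 1)
      d <- data.frame(beta_exp = rnorm(n, 0, 0.1), se_exp = 0.01,
                      beta_out = rnorm(n, 0, 0.05),
                      se_out = runif(n, 0.005, 0.05))
      f <- mr_fit(d, method = "ivw_fe")
      wls <- lm(beta_out ~ 0 + beta_exp, data = d, weights = 1 / d$se_out^2)
      expect_equal(f$beta, unname(coef(wls)), tolerance = 1e-10)
    }
  })
})

test_that("exact proportional data collapse all estimators to the same value", {
  rows <- proportional_rows(k = 0.25, n = 6)
  ivw_fe <- mr_fit(rows, method = "ivw_fe")
  ivw_re <- mr_fit(rows, method = "ivw_mre")
  egger <- mr_fit(rows, method = "egger")
  wm <- mr_fit(rows, method = "weighted_median", seed = 1)
  expect_equal(ivw_fe$beta, 0.25)
  expect_equal(ivw_fe$q, 0, tolerance = 1e-20)
  expect_equal(ivw_fe$se, ivw_re$se)          # Q = 0: no inflation
  expect_equal(egger$beta, 0.25, tolerance = 1e-10)
  expect_equal(egger$intercept, 0, tolerance = 1e-12)
  expect_equal(wm$beta, 0.25, tolerance = 1e-12)
})

test_that("Egger recovers exact affine data and rejects degenerate designs", {
  withr::with_seed(5, bx <- runif(4, 0.05, 0.2))
  rows <- data.frame(beta_exp = bx, se_exp = 0.005,
                     beta_out = 0.01 + 0.30 * bx, se_out = 0.01)
  fit <- mr_fit(rows, method = "egger")
  expect_equal(fit$intercept, 0.01, tolerance = 1e-10)
  expect_equal(fit$beta, 0.30, tolerance = 1e-10)
  expect_equal(rucker_q(rows)$q, 0, tolerance = 1e-18)

  rows$beta_exp <- 0.1
  expect_error(mr_fit(rows, method = "egger"), "degenerate")
})

test_that("weighted median interpolates correctly and ignores weights for constant ratios", {
  rows <- data.frame(beta_exp = 1, se_exp = 1e-6,
                     beta_out = c(0.1, 0.2, 0.3), se_out = 1)
  wm <- mr_fit(rows, method = "weighted_median", seed = 1, n_boot = 50)
  expect_equal(wm$beta, 0.2)

  rows2 <- data.frame(beta_exp = c(1, 2, 4), se_exp = 1e-6,
                      beta_out = 0.7 * c(1, 2, 4),
                      se_out = c(0.5, 0.1, 0.9))
  wm2 <- mr_fit(rows2, method = "weighted_median", seed = 1, n_boot = 50)
  expect_equal(wm2$beta, 0.7, tolerance = 1e-12)
})

test_that("estimators are scale- and sign-equivariant in the outcome", {
  withr::with_seed(31, {
    for (i in 1:5) {
      d <- mr_rows(n = 15, theta = 0.3, seed = 100 + i)
      k <- runif(1, 0.5, 3)
      d_scaled <- within(d, {beta_out <- k * beta_out; se_out <- k * se_out})
      d_neg <- within(d, beta_out <- -beta_out)
      for (m in c("ivw_mre", "egger", "weighted_median")) {
        f <- mr_fit(d, method = m, seed = 9, n_boot = 100)
        fs <- mr_fit(d_scaled, method = m, seed = 9, n_boot = 100)
        fn <- mr_fit(d_neg, method = m, seed = 9, n_boot = 100)
        expect_equal(fs$beta, k * f$beta, tolerance = 1e-8)
        expect_equal(fs$se, k * f$se, tolerance = 1e-8)
        expect_equal(fn$beta, -f$beta, tolerance = 1e-8)
      }
      fb <- bwmr(d)
      fbs <- bwmr(d_scaled)
      expect_equal(fbs$beta, k * fb$beta, tolerance = 0.02 * abs(k * fb$beta))
    }
  })
})

test_that("single-instrument IVW reduces exactly to the Wald ratio", {
  d <- data.frame(beta_exp = 0.2, se_exp = 0.05, beta_out = 0.05,
                  se_out = 0.01)
  expect_error(mr_fit(d, method = "ivw_fe"), "at least 2")
  f <- mr_fit(d, method = "ivw_fe", allow_single = TRUE)
  wr <- wald_ratio(0.2, 0.05, 0.05, 0.01)
  expect_equal(f$beta, wr$beta)
  expect_equal(f$se, wr$se)
})

test_that("estimators recover a planted causal effect with many strong instruments", {
  tri <- simulate_triangle(simulation_truth(
    theta_xm = 0, theta_my = 0, theta_direct = 0.25, seed = 55,
    sample_sizes = c(exposure = 3e5, mediator = 8e3, outcome = 5e5)))
  hs <- harmonize(select_instruments(tri$exposure), tri$outcome)
  for (m in c("ivw_mre", "egger", "weighted_median", "bwmr")) {
    f <- mr_fit(hs, method = m, seed = 2, n_boot = 200)
    expect_lt(abs(f$beta - 0.25), 3 * f$se)
  }
})

test_that("BWMR tracks IVW without pleiotropy and downweights a gross outlier", {
  d <- mr_rows(n = 50, theta = 0.25, seed = 77)
  bw <- bwmr(d)
  iv <- mr_fit(d, method = "ivw_fe")
  expect_lt(abs(bw$beta - iv$beta), iv$se)

  d2 <- mr_rows(n = 20, theta = 0.25, seed = 78)
  j <- 7L
  d2$beta_out[j] <- d2$beta_out[j] + 0.1    # gross pleiotropic outlier
  bw2 <- bwmr(d2)
  expect_equal(unname(which.min(bw2$outlier_weights)), j)
  expect_gt(bw2$tau, 0)

  expect_error(bwmr(d2[1:2, ]), "at least 3")
})

test_that("the odds-ratio scale is attached for binary outcomes", {
  tri <- simulate_triangle(simulation_truth(seed = 3))
  hs <- harmonize(select_instruments(tri$exposure), tri$outcome)
  f <- mr_fit(hs, method = "ivw_mre")
  expect_equal(f$or, exp(f$beta))
  expect_equal(f$or_ci_low, exp(f$ci_low))
  tab <- forest_table(list(f))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$or, f$or)
})
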