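test_that("Cochran's Q matches hand arithmetic and an independent oracle", {
  d <- data.frame(beta_exp = 1, se_exp = 1e-6,
                  beta_out = c(0.2, 0.3), se_out = 0.05)
  q <- cochran_q(d)
  expect_equal(q$q, 2)           # beta_hat = 0.25, 2 * (0.05/0.05)^2 * ...
  expect_equal(q$df, 1L)
  expect_equal(q$p, pchisq(2, 1, lower.tail = FALSE))
  expect_equal(q$p, 0.157, tolerance = 5e-3)

  # textbook oracle on Wald ratios, written independently of the engine
  d2 <- mr_rows(n = 12, seed = 61)
  r <- d2$beta_out / d2$beta_exp
  w <- (d2$beta_exp / d2$se_out)^2
  oracle <- sum(w * (r - sum(w * r) / sum(w))^2)
  expect_equal(cochran_q(d2)$q, oracle, tolerance = 1e-12)

  expect_equal(cochran_q(proportional_rows())$q, 0, tolerance = 1e-20)
  expect_equal(cochran_q(proportional_rows())$p, 1)
})

test_that("Rucker's Q vanishes on affine data and never exceeds the intercept-free statistic", {
  withr::with_seed(13, bx <- runif(3, 0.05, 0.2))
  affine3 <- data.frame(beta_exp = bx, se_exp = 0.005,
                        beta_out = 0.02 + 0.4 * bx, se_out = 0.01)
  rq <- rucker_q(affine3)
  expect_equal(rq$q, 0, tolerance = 1e-18)
  expect_equal(rq$df, 1L)
  expect_equal(rq$p, 1)

  # directional pleiotropy: the intercept absorbs heterogeneity
  tri <- simulate_triangle(simulation_truth(
    seed = 19, pleiotropy = list(mode = "directional", mean = 0.05,
                                 sd = 0.002)))
  hs <- harmonize(select_instruments(tri$exposure), tri$outcome)
  rows <- harmonized_rows(hs)
  ivw <- mr_fit(rows, method = "ivw_fe")
  q_reg_scale <- sum((rows$beta_out - ivw$beta * rows$beta_exp)^2 /
                       rows$se_out^2)
  rq2 <- rucker_q(rows)
  expect_lt(rq2$q, q_reg_scale)
  expect_lt(rq2$q, 0.5 * q_reg_scale)   # most heterogeneity is directional
})

test_that("the global pleiotropy test is seeded, deterministic, and powered against an outlier", {
  d <- mr_rows(n = 20, seed = 41)
  p1 <- presso_global(d, n_sim = 300, seed = 5)
  p2 <- presso_global(d, n_sim = 300, seed = 5)
  expect_identical(p1, p2)
  expect_gt(p1, 0)
  expect_error(presso_global(d, n_sim = 50, seed = 1), "unstable")
  expect_error(presso_global(d[1:3, ], n_sim = 300, seed = 1), "at least 4")

  hits <- vapply(1:20, function(s) {
    d <- mr_rows(n = 20, theta = 0.25, seed = 200 + s)
    j <- which.max(d$beta_exp)
    d$beta_out[j] <- 5 * 0.25 * d$beta_exp[j]   # ratio 5x the true effect
    presso_global(d, n_sim = 300, seed = s) < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("the outlier test flags the planted variant and is row-order invariant", {
  d <- mr_rows(n = 20, theta = 0.25, seed = 210)
  j <- which.max(d$beta_exp)
  d$beta_out[j] <- 5 * 0.25 * d$beta_exp[j]
  po <- presso_outlier(d, n_sim = 500, seed = 3)
  expect_true(d$rsid[j] %in% po$outliers)
  # the planted variant attains the minimum empirical p (ties possible at
  # the 1/(n_sim+1) floor)
  expect_equal(po$table$p[j], min(po$table$p))
  expect_s3_class(po$corrected, "mr_estimate")
  expect_lt(abs(po$corrected$beta - 0.25), 3 * po$corrected$se)

  perm <- sample(nrow(d))
  po2 <- presso_outlier(d[perm, ], n_sim = 500, seed = 3)
  expect_setequal(po2$outliers, po$outliers)

  clean <- mr_rows(n = 20, seed = 211)
  po3 <- presso_outlier(clean, n_sim = 500, seed = 3)
  expect_length(po3$outliers, 0)
})

test_that("leave-one-out returns one estimate per variant and flags dominant outliers", {
  d3 <- mr_rows(n = 3, seed = 71)
  expect_equal(nrow(leave_one_out(d3)), 3L)

  clean <- mr_rows(n = 15, seed = 72)
  expect_false(any(leave_one_out(clean)$flagged))

  ident <- data.frame(beta_exp = rep(0.1, 5), se_exp = 0.01,
                      beta_out = rep(0.025, 5), se_out = 0.01)
  loo_i <- leave_one_out(ident)
  expect_equal(length(unique(round(loo_i$beta, 12))), 1L)

  dom <- mr_rows(n = 10, theta = 0.1, seed = 73, sy = 0.002)
  j <- which.max(dom$beta_exp)
  dom$beta_out[j] <- 10 * 0.1 * dom$beta_exp[j]
  loo_d <- leave_one_out(dom)
  expect_true(loo_d$flagged[j])
})

test_that("method selection follows the pleiotropy decision table", {
  pick <- function(pg, pe) {
    select_method(list(presso_global_p = pg, egger_intercept_p = pe))
  }
  expect_equal(pick(0.4, 0.6)$chosen_method, "ivw_mre")
  expect_equal(pick(0.5, 0.042)$chosen_method, "egger")
  expect_equal(pick(0.01, 0.3)$chosen_method, "weighted_median")
  expect_match(pick(0.01, 0.3)$rationale, "weighted median")
  expect_error(select_method(list(presso_global_p = 0.4)), "egger_intercept_p")
})

test_that("the combined sensitivity report is internally consistent", {
  tri <- simulate_triangle(simulation_truth(seed = 23))
  hs <- harmonize(select_instruments(tri$exposure), tri$outcome)
  rep <- mr_sensitivity(hs, n_sim = 300, seed = 8)
  expect_s3_class(rep, "sensitivity_report")
  expect_equal(rep$q_df, rep$n_snp - 1L)
  expect_equal(rep$rucker_df, rep$n_snp - 2L)
  expect_gte(rep$q, 0)
  # the Egger fit nests the zero-intercept IVW fit, so its residual Q is
  # never larger than Cochran's Q
  expect_lte(rep$rucker_q, rep$q + 1e-9)
  expect_true(rep$chosen_method %in% c("ivw_mre", "egger", "weighted_median"))
  expect_equal(nrow(rep$loo), rep$n_snp)
})
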