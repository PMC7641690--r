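test_that("Wald ratio and delta-method SE match closed forms and a Monte-Carlo oracle", {
  # exposure measured without error: both modes give se_Gamma / gamma
  w <- wald_ratio(1, 0, 0.5, 0.1)
  expect_equal(w$ratio, 0.5)
  expect_equal(w$se, 0.1)
  expect_equal(wald_ratio(1, 0, 0.5, 0.1, se_mode = "first_order")$se, 0.1)
  # zero numerator: full delta collapses to the first-order term
  w0 <- wald_ratio(0.4, 0.05, 0, 0.01)
  expect_equal(w0$ratio, 0)
  expect_equal(w0$se, 0.01 / 0.4)
  # closed form for a strong instrument, checked against simulation
  w2 <- wald_ratio(0.33, 0.03, 0.02, 0.005)
  expect_equal(w2$se,
               sqrt(0.005^2 / 0.33^2 + 0.02^2 * 0.03^2 / 0.33^4))
  mc <- oracle_ratio_sd(0.33, 0.03, 0.02, 0.005)
  expect_equal(w2$se, mc, tolerance = 0.02)
  # zero exposure beta is an error naming the SNP
  expect_error(wald_ratio(c(0.3, 0), c(0.01, 0.01), c(0.1, 0.1),
                          c(0.01, 0.01), rsid = c("rsA", "rsB")), "rsB")
})

test_that("fixed-effect IVW reduces and pools correctly", {
  # J = 1 reduces to the single Wald estimate
  h1 <- make_h(0.33, 0.03, 0.02, 0.005)
  e1 <- ivw_fixed(h1)
  w1 <- wald_ratio(0.33, 0.03, 0.02, 0.005)
  expect_equal(e1$beta, w1$ratio)
  expect_equal(e1$se, w1$se)
  # equal weights give the plain mean with se / sqrt(J)
  h3 <- make_h(rep(1, 3), rep(0, 3), c(0.1, 0.2, 0.3), rep(0.1, 3))
  e3 <- ivw_fixed(h3)
  expect_equal(e3$beta, 0.2)
  expect_equal(e3$se, 0.1 / sqrt(3))
  expect_equal(e3$n_snps, 3)
})

test_that("IVW agrees with a brute-force weighted mean on random instances", {
  set.seed(101)
  for (i in 1:100) {
    J <- sample(3:10, 1)
    h <- make_h(gamma = runif(J, 0.1, 0.5), se_gamma = runif(J, 0.005, 0.03),
                Gamma = rnorm(J, 0, 0.01), se_Gamma = runif(J, 1e-3, 5e-3))
    est <- ivw_fixed(h)
    w <- wald_ratio(h$gamma, h$se_gamma, h$Gamma, h$se_Gamma)
    o <- oracle_ivw(w$ratio, w$se)
    expect_equal(est$beta, o$beta, tolerance = 1e-12)
    expect_equal(est$se, o$se, tolerance = 1e-12)
  }
})

test_that("simple median point estimate and bootstrap SE behave", {
  h <- make_h(rep(1, 3), rep(0, 3), c(1, 2, 3), rep(0.5, 3))
  est <- simple_median(h, B = 500, seed = 1)
  expect_equal(est$beta, 2)
  # degenerate: identical ratios with vanishing SEs give vanishing se
  h0 <- make_h(rep(1, 3), rep(0, 3), rep(1.5, 3), rep(1e-12, 3))
  expect_lt(simple_median(h0, B = 200, seed = 1)$se, 1e-10)
  expect_error(simple_median(h, B = 50, seed = 1), "B >= 100")
  expect_error(simple_median(h, B = 500), "seed")
  # bootstrap SE stabilizes: B = 5000 within 5% of a 50,000-replicate run
  h2 <- make_h(c(0.3, 0.25, 0.2), c(0.01, 0.01, 0.01),
               c(0.01, 0.006, 0.002), c(0.002, 0.002, 0.002))
  se5k <- simple_median(h2, B = 5000, seed = 11)$se
  w <- wald_ratio(h2$gamma, h2$se_gamma, h2$Gamma, h2$se_Gamma)
  set.seed(99)
  ref <- replicate(50000, median(rnorm(3, w$ratio, w$se)))
  expect_equal(se5k, sd(ref), tolerance = 0.05)
})

test_that("weighted median point estimate follows the interpolation rule", {
  expect_equal(weighted_median_point(c(1, 2, 3), rep(1, 3)), 2)
  # hand-computed: s = (0.2, 0.55, 0.8, 0.95), interpolate in [1, 2]
  expect_equal(weighted_median_point(c(1, 2, 3, 10), c(0.4, 0.3, 0.2, 0.1)),
               1 + 0.3 / 0.35)
  expect_equal(weighted_median_point(5, 2), 5)
  # dominant weight drives the estimate to that ratio in the limit
  expect_equal(weighted_median_point(c(1, 2, 3), c(100, 1, 1)),
               1 + 1 / 50.5)
  expect_equal(weighted_median_point(c(1, 2, 3), c(1e8, 1, 1)), 1,
               tolerance = 1e-6)
  expect_error(weighted_median_point(numeric(0), numeric(0)), "empty")
  # unsorted input is sorted internally
  expect_equal(weighted_median_point(c(3, 1, 10, 2), c(0.2, 0.4, 0.1, 0.3)),
               1 + 0.3 / 0.35)
})

test_that("weighted median agrees with a root-finding oracle on random instances", {
  set.seed(202)
  for (i in 1:100) {
    J <- sample(3:10, 1)
    r <- rnorm(J)
    w <- runif(J, 0.1, 5)
    est <- weighted_median_point(r, w)
    expect_equal(est, oracle_weighted_median(r, w), tolerance = 1e-10)
    # grid search over the cumulative-weight objective |S(theta) - 0.5|
    # lands on the same point up to the grid resolution
    grid <- seq(min(r), max(r), length.out = 4001)
    obj <- abs(wm_cumweight(grid, r, w) - 0.5)
    expect_lt(abs(est - grid[which.min(obj)]), diff(range(r)) / 4000 + 1e-12)
  }
})

test_that("weighted median estimator reduces, respects limits, and bootstraps", {
  # equal SEs: identical to the simple median point estimate
  h <- make_h(rep(1, 5), rep(0, 5), c(0.1, 0.4, 0.2, 0.5, 0.3), rep(0.1, 5))
  wm <- weighted_median(h, B = 200, seed = 3)
  sm <- simple_median(h, B = 200, seed = 3)
  expect_equal(wm$beta, sm$beta)
  # near-infinite weight pins the estimate to that SNP's ratio
  h2 <- make_h(rep(1, 3), rep(0, 3), c(0.1, 0.5, 0.9),
               c(1e-8, 0.1, 0.1))
  expect_equal(weighted_median(h2, B = 200, seed = 3)$beta, 0.1,
               tolerance = 1e-6)
  expect_error(weighted_median(h, B = 10, seed = 1), "B >= 100")
})

test_that("weighted median resists a pleiotropic minority", {
  # 4 of 10 instruments strongly pleiotropic (ratio shift far beyond the
  # ratio sampling noise); over seeded replicates the point estimate stays
  # inside the span of the 6 valid SNPs' ratios
  inside <- 0
  for (rep in 1:100) {
    set.seed(rep)
    J <- 10
    gamma <- runif(J, 0.2, 0.4)
    alpha <- c(rep(0.03, 4), rep(0, 6))
    theta <- 0.05
    g_hat <- rnorm(J, gamma, 0.01)
    G_hat <- rnorm(J, theta * gamma + alpha, 0.002)
    h <- make_h(g_hat, rep(0.01, J), G_hat, rep(0.002, J))
    w <- wald_ratio(h$gamma, h$se_gamma, h$Gamma, h$se_Gamma)
    est <- weighted_median_point(w$ratio, 1 / w$se^2)
    valid <- w$ratio[5:10]
    if (est >= min(valid) && est <= max(valid)) inside <- inside + 1
  }
  expect_gte(inside, 95)
})

test_that("MR-Egger recovers exact lines and matches the normal-equations oracle", {
  # exact line: intercept 0.01, slope 0.1
  gamma <- c(0.1, 0.2, 0.3, 0.4)
  h <- make_h(gamma, rep(0.01, 4), 0.01 + 0.1 * gamma,
              c(0.002, 0.004, 0.003, 0.005))
  e <- egger(h)
  expect_equal(e$slope$beta, 0.1, tolerance = 1e-12)
  expect_equal(e$intercept$estimate, 0.01, tolerance = 1e-12)
  # noisy points against explicit normal equations
  set.seed(303)
  for (i in 1:50) {
    J <- sample(3:10, 1)
    h <- make_h(runif(J, 0.1, 0.5), rep(0.01, J),
                rnorm(J, 0, 0.01), runif(J, 1e-3, 5e-3))
    e <- egger(h)
    o <- oracle_wls(h$gamma, h$Gamma, 1 / h$se_Gamma^2)
    expect_equal(e$slope$beta, o$slope, tolerance = 1e-10)
    expect_equal(e$intercept$estimate, o$intercept, tolerance = 1e-10)
    expect_equal(e$intercept$se, o$se[1], tolerance = 1e-10)
    expect_equal(e$slope$se, o$se[2], tolerance = 1e-10)
  }
  # guard rails
  expect_error(egger(make_h(c(0.1, 0.2), rep(0.01, 2), c(0, 0),
                            rep(0.002, 2))), "at least 3")
  h_neg <- make_h(c(0.1, -0.2, 0.3), rep(0.01, 3), rep(0.01, 3),
                  rep(0.002, 3))
  expect_error(egger(h_neg), "orient")
  expect_true(egger(make_h(c(0.1, 0.2, 0.3), rep(0.01, 3), rep(0.01, 3),
                           rep(0.002, 3)))$low_df)
})

test_that("odds-scale transform matches normal theory", {
  null <- to_odds_scale(0, 0.1)
  expect_equal(null$or_point, 1)
  expect_equal(null$pvalue, 1)
  t <- to_odds_scale(0.1, 0.05)
  expect_equal(t$or_point, exp(0.1))
  expect_equal(t$ci_low, exp(0.1 - qnorm(0.975) * 0.05))
  expect_equal(t$ci_high, exp(0.1 + qnorm(0.975) * 0.05))
  expect_equal(t$pvalue, 2 * pnorm(-2))
  # CI is log-symmetric around the point estimate
  expect_equal(t$ci_low * t$ci_high, exp(2 * 0.1))
  expect_error(to_odds_scale(0.1, 0.05, level = 1.2), "level")
})

test_that("sex-difference z-test is antisymmetric and null on equality", {
  m <- ivw_fixed(make_h(0.3, 0.01, 0.006, 0.002))
  f <- ivw_fixed(make_h(0.3, 0.01, 0.006, 0.002))
  eq <- sex_difference_test(m, f)
  expect_equal(eq$z, 0)
  expect_equal(eq$pvalue, 1)
  f2 <- ivw_fixed(make_h(0.3, 0.01, 0.000, 0.002))
  d1 <- sex_difference_test(m, f2)
  d2 <- sex_difference_test(f2, m)
  expect_equal(d1$z, -d2$z)
  expect_equal(d1$pvalue, d2$pvalue)
  # closed form: equal SEs, beta difference 0.2 at se 0.1 each
  a <- ivw_fixed(make_h(1, 0, 0.2, 0.1))
  b <- ivw_fixed(make_h(1, 0, 0.0, 0.1))
  z <- sex_difference_test(a, b)
  expect_equal(z$z, sqrt(2))
  expect_equal(z$pvalue, 2 * pnorm(-sqrt(2)))
  sm <- simple_median(make_h(rep(1, 3), rep(0, 3), 1:3, rep(0.1, 3)),
                      B = 200, seed = 1)
  expect_error(sex_difference_test(m, sm), "same method")
})

test_that("estimators share reduction, ordering, and equivariance invariants", {
  set.seed(404)
  for (i in 1:25) {
    J <- sample(3:8, 1)
    h <- make_h(runif(J, 0.1, 0.5), runif(J, 0.005, 0.02),
                rnorm(J, 0.003, 0.01), runif(J, 1e-3, 5e-3))
    w <- wald_ratio(h$gamma, h$se_gamma, h$Gamma, h$se_Gamma)
    ivw <- ivw_fixed(h)
    # fixed-effect pooling only accumulates precision
    expect_lte(ivw$se, min(w$se) + 1e-15)
    # weighted median stays within the ratio span
    wm <- weighted_median_point(w$ratio, 1 / w$se^2)
    expect_gte(wm, min(w$ratio))
    expect_lte(wm, max(w$ratio))
    # sign equivariance: negating every outcome beta negates each beta and
    # preserves each SE and p-value
    h_neg <- h; h_neg$Gamma <- -h$Gamma
    ivw_n <- ivw_fixed(h_neg)
    expect_equal(ivw_n$beta, -ivw$beta)
    expect_equal(ivw_n$se, ivw$se)
    expect_equal(ivw_n$pvalue, ivw$pvalue)
    e <- egger(h); e_n <- egger(h_neg)
    expect_equal(e_n$slope$beta, -e$slope$beta)
    expect_equal(e_n$slope$se, e$slope$se)
    expect_equal(e_n$intercept$pvalue, e$intercept$pvalue)
  }
  # J = 1 reduction chain
  h1 <- make_h(0.3, 0.01, 0.006, 0.002)
  w1 <- wald_ratio(0.3, 0.01, 0.006, 0.002)
  expect_equal(ivw_fixed(h1)$beta, w1$ratio)
  expect_equal(suppressWarnings(simple_median(h1, B = 200, seed = 5))$beta,
               w1$ratio)
  expect_equal(suppressWarnings(weighted_median(h1, B = 200, seed = 5))$beta,
               w1$ratio)
})

test_that("bootstrap SEs are bit-identical under identical seeds", {
  h <- make_h(c(0.3, 0.25, 0.2), c(0.01, 0.012, 0.009),
              c(0.01, 0.006, 0.002), c(0.002, 0.003, 0.002))
  a <- simple_median(h, B = 1000, seed = 77)
  b <- simple_median(h, B = 1000, seed = 77)
  expect_identical(a$se, b$se)
  c1 <- weighted_median(h, B = 1000, seed = 77)
  c2 <- weighted_median(h, B = 1000, seed = 77)
  expect_identical(c1$se, c2$se)
  # and different seeds genuinely resample
  expect_false(identical(a$se, simple_median(h, B = 1000, seed = 78)$se))
})
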