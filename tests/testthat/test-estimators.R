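test_that("the Wald ratio and its first-order standard error are exact", {
  v <- list(gamma = 0.1, se_gamma = 0.01, big_gamma = 0.05, se_big_gamma = 0.02)
  r <- mr_wald_ratio(v)
  expect_equal(r$beta, 0.5)
  expect_equal(r$se, 0.2)

  v0 <- v; v0$big_gamma <- 0
  expect_equal(mr_wald_ratio(v0)$beta, 0)

  # scale invariance of the ratio
  v2 <- v; v2$gamma <- 0.2; v2$big_gamma <- 0.1
  expect_equal(mr_wald_ratio(v2)$beta, r$beta)

  v$gamma <- 0
  expect_error(mr_wald_ratio(v), "gamma = 0")
})

test_that("IVW reduces to known closed forms", {
  h1 <- harmonized_set(0.1, 0.01, 0.05, 0.02)
  expect_equal(mr_ivw(h1, model = "fixed")$beta, mr_wald_ratio(h1$variants)$beta)
  expect_equal(mr_ivw(h1, model = "fixed")$se, mr_wald_ratio(h1$variants)$se)

  # two identical ratios 0.5 with ratio-SE 0.2: mean 0.5, se 0.2/sqrt(2), Q = 0
  h2 <- harmonized_set(c(1, 1), c(0.01, 0.01), c(0.5, 0.5), c(0.2, 0.2))
  fx <- mr_ivw(h2, model = "fixed")
  rnd <- mr_ivw(h2, model = "random")
  expect_equal(fx$beta, 0.5)
  expect_equal(fx$se, 0.2 / sqrt(2))
  expect_equal(rnd$se, fx$se)  # Q = 0, overdispersion floored at 1

  expect_error(mr_ivw(h1, model = "random"), "at least 2")
})

test_that("IVW agrees with weighted least squares through the origin", {
  for (seed in 1:25) {
    h <- random_harmonized(sample(4:30, 1), seed = 700 + seed)
    v <- h$variants
    w <- 1 / v$se_big_gamma^2
    fit <- lm(big_gamma ~ 0 + gamma, data = v, weights = w)
    est <- mr_ivw(h, model = "random")
    expect_equal(est$beta, unname(coef(fit)[1]), tolerance = 1e-12)
    # lm's slope SE is the unfloored multiplicative-overdispersion SE
    se_fixed <- sqrt(1 / sum(w * v$gamma^2))
    expect_equal(est$se, max(se_fixed, summary(fit)$coefficients[1, 2]),
                 tolerance = 1e-10)
    # direct one-dimensional minimization of the weighted RSS
    opt <- optimize(function(b) sum(w * (v$big_gamma - b * v$gamma)^2),
                    interval = range(v$big_gamma / v$gamma) + c(-1, 1))
    expect_equal(est$beta, opt$minimum, tolerance = 1e-6)
  }
})

test_that("IVW fixed equals the precision-weighted mean of Wald ratios", {
  h <- random_harmonized(12, seed = 77)
  v <- h$variants
  ratio <- v$big_gamma / v$gamma
  w <- v$gamma^2 / v$se_big_gamma^2  # first-order inverse ratio-variances
  expect_equal(mr_ivw(h, model = "fixed")$beta, sum(w * ratio) / sum(w),
               tolerance = 1e-10)
})

test_that("MR-Egger recovers exact linear data and matches the WLS oracle", {
  gamma <- c(0.05, 0.1, 0.15, 0.2, 0.25)
  h <- harmonized_set(gamma, rep(0.01, 5), 0.1 + 0.4 * gamma, rep(0.02, 5))
  fit <- mr_egger(h)
  expect_equal(fit$result$beta, 0.4, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.1, tolerance = 1e-10)
  expect_lt(fit$sigma, 1e-6)

  for (seed in 1:25) {
    h <- random_harmonized(sample(4:30, 1), seed = 800 + seed)
    v <- h$variants
    flip <- ifelse(v$gamma < 0, -1, 1)   # orientation gamma >= 0
    x <- v$gamma * flip; y <- v$big_gamma * flip
    w <- 1 / v$se_big_gamma^2
    fit_lm <- lm(y ~ x, weights = w)
    fit <- mr_egger(h)
    expect_equal(fit$result$beta, unname(coef(fit_lm)[2]), tolerance = 1e-10)
    expect_equal(fit$intercept, unname(coef(fit_lm)[1]), tolerance = 1e-10)
    # SEs: lm's are the unfloored overdispersion SEs
    sm <- summary(fit_lm)$coefficients
    infl <- max(1, summary(fit_lm)$sigma) / summary(fit_lm)$sigma
    expect_equal(fit$result$se, sm[2, 2] * infl, tolerance = 1e-10)
    expect_equal(fit$intercept_se, sm[1, 2] * infl, tolerance = 1e-10)
  }
  expect_error(mr_egger(harmonized_set(c(1, 1), c(1, 1), c(1, 1), c(1, 1))),
               "at least 3")
})

test_that("under balanced pleiotropy the Egger intercept covers zero", {
  hits <- 0L
  n_rep <- 100L
  for (r in seq_len(n_rep)) {
    sim <- simulate_pair(scenario_config(n_snps = 25, beta_causal = 0.3,
                                         pleiotropy_sd = 0.02,
                                         seed = 5000 + r))
    idx <- !sim$truth$is_decoy
    h <- harmonized_set(sim$exposure$records$beta[idx],
                        sim$exposure$records$se[idx],
                        sim$outcome$records$beta[idx],
                        sim$outcome$records$se[idx])
    fit <- mr_egger(h)
    if (abs(fit$intercept) <= 2 * fit$intercept_se) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("the weighted median interpolates the Bowden quantile formula", {
  # plain median at equal weights
  h <- harmonized_set(c(1, 1, 1), c(0.01, 0.01, 0.01), c(0.1, 0.2, 0.3),
                      c(0.5, 0.5, 0.5))
  expect_equal(mr_weighted_median(h, n_boot = 200, seed = 1)$beta, 0.2)

  # hand-evaluated interpolation: ratios {0, 1}, normalized weights {.75, .25}
  expect_equal(metabomr:::weighted_median_estimate(c(0, 1), c(3, 1)), 0.25)
  expect_equal(metabomr:::weighted_median_estimate(c(1, 0), c(1, 3)), 0.25)

  # permutation invariance and seed determinism
  h <- random_harmonized(9, seed = 55)
  est1 <- mr_weighted_median(h, n_boot = 300, seed = 42)
  perm <- h
  perm$variants <- perm$variants[sample(9), ]
  est2 <- mr_weighted_median(perm, n_boot = 300, seed = 42)
  expect_equal(est1$beta, est2$beta)
  est3 <- mr_weighted_median(h, n_boot = 300, seed = 42)
  expect_identical(est1$se, est3$se)
  expect_error(mr_weighted_median(h, n_boot = 300), "seed")
})

test_that("MR-PRESSO leaves clean data uncorrected and flags a gross outlier", {
  # outlier-free by construction: every residual is within 1.5 outcome-SEs
  j <- 20
  gamma <- seq(0.05, 0.3, length.out = j)
  se_bg <- rep(0.02, j)
  z <- seq(-1.5, 1.5, length.out = j)[order(rep(1:4, 5))]  # bounded, mixed
  h <- harmonized_set(gamma, rep(0.01, j), 0.3 * gamma + z * se_bg, se_bg)
  pr <- mr_presso(h, n_sim = 600, seed = 7)
  expect_length(pr$report$outlier_ids, 0)
  expect_equal(pr$corrected$beta, pr$raw$beta)
  expect_gt(pr$report$global_p, 0.05)

  # plant one variant with a pleiotropic offset of 12 outcome-SEs
  ho <- h
  ho$variants$big_gamma[5] <- ho$variants$big_gamma[5] +
    12 * ho$variants$se_big_gamma[5]
  pro <- mr_presso(ho, n_sim = 600, seed = 7)
  expect_true(ho$variants$variant_id[5] %in% pro$report$outlier_ids)
  expect_lt(pro$report$global_p, 0.05)
  # the corrected estimate moves back toward the clean-data estimate
  expect_lt(abs(pro$corrected$beta - pr$raw$beta),
            abs(pro$raw$beta - pr$raw$beta))
  expect_false(is.na(pro$report$distortion_p))

  expect_error(mr_presso(harmonized_set(1:3, rep(1, 3), 1:3, rep(1, 3)),
                         n_sim = 600, seed = 1), "at least 4")
})

test_that("every estimator reports OR = exp(beta) with mapped CI bounds", {
  h <- random_harmonized(10, seed = 13)
  fits <- list(
    mr_ivw(h), mr_egger(h)$result,
    mr_weighted_median(h, n_boot = 200, seed = 2),
    mr_presso(h, n_sim = 300, seed = 3)$raw
  )
  for (f in fits) {
    expect_equal(f$odds_ratio, exp(f$beta))
    expect_equal(f$or_ci_low, exp(f$ci_low))
    expect_equal(f$or_ci_high, exp(f$ci_high))
    expect_lt(f$ci_low, f$ci_high)
    expect_true(f$pval > 0 && f$pval <= 1)
  }
})

test_that("all estimators agree when every per-variant ratio is identical", {
  gamma <- c(0.1, 0.15, 0.2, 0.25, 0.3)
  h <- harmonized_set(gamma, rep(0.01, 5), 0.4 * gamma, rep(0.02, 5))
  expect_equal(mr_ivw(h)$beta, 0.4, tolerance = 1e-12)
  expect_equal(mr_egger(h)$result$beta, 0.4, tolerance = 1e-10)
  expect_equal(mr_weighted_median(h, n_boot = 200, seed = 4)$beta, 0.4,
               tolerance = 1e-12)
})
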