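test_that("Wald ratio follows the delta method in both signs", {
  h <- make_hset(0.5, 0.01, 0.25, 0.05)
  wr <- wald_ratio(h)
  expect_equal(wr$beta, 0.5)
  expect_equal(wr$se, 0.1)
  wr <- wald_ratio(make_hset(-0.2, 0.01, 0.1, 0.02))
  expect_equal(wr$beta, -0.5)
  expect_equal(wr$se, 0.1)
  # published-scale inputs: plain division
  wr <- wald_ratio(make_hset(0.1583, 0.0073, -0.0015, 4e-4))
  expect_equal(wr$beta, -0.0015 / 0.1583)
  expect_equal(wr$se, 4e-4 / 0.1583)
  expect_error(wald_ratio(make_hset(0, 0.01, 0.1, 0.02)),
               class = "mrkit_domain_error")
})

test_that("IVW reduces to the Wald ratio and to weighted ratio means", {
  h1 <- make_hset(0.5, 0.01, 0.25, 0.05)
  expect_equal(ivw_fixed(h1)$beta, wald_ratio(h1)$beta)
  expect_equal(ivw_fixed(h1)$se, wald_ratio(h1)$se)
  # equal IVW weights (bx/se_out)^2 and ratios 0.4, 0.6 average to 0.5
  h2 <- make_hset(c(0.1, 0.1), c(0.01, 0.01), c(0.04, 0.06), c(0.002, 0.002))
  expect_equal(ivw_fixed(h2)$beta, 0.5)
  # precision-weighted mean of per-SNP ratios
  h <- rand_hset(16, seed = 4)
  rt <- ratio_table(h)
  expect_equal(ivw_fixed(h)$beta,
               sum(rt$theta * rt$weight) / sum(rt$weight))
})

test_that("IVW equals the zero-intercept weighted least squares oracle", {
  for (seed in 1:20) {
    h <- rand_hset(16, seed = seed)
    v <- kept_variants(h)
    fit <- lm(beta_out ~ 0 + beta_exp, data = v, weights = v$se_out^-2)
    est <- ivw_fixed(h)
    expect_equal(est$beta, unname(coef(fit)), tolerance = 1e-8)
  }
})

test_that("Egger point estimates equal weighted least squares with intercept", {
  for (seed in 1:20) {
    h <- rand_hset(16, seed = 100 + seed)
    v <- kept_variants(h)
    s <- sign(v$beta_exp)
    d <- data.frame(x = v$beta_exp * s, y = v$beta_out * s)
    fit <- lm(y ~ x, data = d, weights = v$se_out^-2)
    est <- egger(h, n_boot = 100, seed = 1)
    expect_equal(est$beta, unname(coef(fit)[2]), tolerance = 1e-8)
    expect_equal(est$intercept, unname(coef(fit)[1]), tolerance = 1e-8)
  }
})

test_that("Egger recovers a noise-free linear law exactly and is seed-stable", {
  bx <- seq(0.05, 0.16, length.out = 8)
  by <- 0.003 - 0.02 * bx # intercept c = 0.003, slope theta = -0.02
  h <- make_hset(bx, rep(0.005, 8), by, rep(5e-4, 8))
  est <- egger(h, n_boot = 200, seed = 7)
  expect_equal(est$beta, -0.02, tolerance = 1e-12)
  expect_equal(est$intercept, 0.003, tolerance = 1e-12)
  est2 <- egger(h, n_boot = 200, seed = 7)
  expect_identical(est$se, est2$se)
  expect_identical(est$intercept_se, est2$intercept_se)
  est3 <- egger(h, n_boot = 200, seed = 8)
  expect_false(est$se == est3$se)
  expect_error(egger(make_hset(c(0.1, 0.2), c(0.01, 0.01),
                               c(0.01, 0.02), c(0.001, 0.001))),
               class = "mrkit_insufficient_error")
})

test_that("Egger with the intercept constrained to zero is IVW", {
  h <- rand_hset(16, seed = 9)
  v <- kept_variants(h)
  s <- sign(v$beta_exp)
  fit0 <- lm(I(v$beta_out * s) ~ 0 + I(v$beta_exp * s),
             weights = v$se_out^-2)
  expect_equal(ivw_fixed(h)$beta, unname(coef(fit0)), tolerance = 1e-10)
})

test_that("weighted median matches simple and dominant-weight cases", {
  h <- make_hset(c(1, 1, 1), c(0.01, 0.01, 0.01),
                 c(0.1, 0.2, 0.9), c(0.01, 0.01, 0.01))
  est <- weighted_median(h, penalized = FALSE, n_boot = 100, seed = 1)
  expect_equal(est$beta, 0.2)
  # one variant holding >50% of total weight, the rest split evenly: its ratio
  se_out <- c(0.02, 0.005, 0.02) # middle variant weight 0.89
  h <- make_hset(c(1, 1, 1), c(0.01, 0.01, 0.01),
                 c(0.1, 0.5, 0.9), se_out)
  est <- weighted_median(h, penalized = FALSE, n_boot = 100, seed = 1)
  expect_equal(est$beta, 0.5)
  # equal weights, odd count: the sample median
  theta <- c(-0.3, 0.05, 0.2, 0.4, 0.9)
  h <- make_hset(rep(1, 5), rep(0.01, 5), theta, rep(0.01, 5))
  est <- weighted_median(h, penalized = FALSE, n_boot = 100, seed = 1)
  expect_equal(est$beta, median(theta))
})

test_that("penalization leaves homogeneous sets alone and tames outliers", {
  h <- make_hset(rep(1, 5), rep(0.01, 5), rep(0.5, 5), rep(0.01, 5))
  pen <- weighted_median(h, penalized = TRUE, n_boot = 100, seed = 1)
  unpen <- weighted_median(h, penalized = FALSE, n_boot = 100, seed = 1)
  expect_equal(pen$beta, 0.5)
  expect_equal(unpen$beta, 0.5)
  # 9 concordant ratios + 1 gross outlier at equal precision
  h <- make_hset(rep(1, 10), rep(0.01, 10),
                 c(rep(0.5, 9), 5), rep(0.05, 10))
  pen <- weighted_median(h, penalized = TRUE, n_boot = 100, seed = 1)
  unpen <- weighted_median(h, penalized = FALSE, n_boot = 100, seed = 1)
  expect_true(abs(pen$beta - 0.5) <= abs(unpen$beta - 0.5))
  expect_lt(abs(pen$beta - 0.5), 0.01)
})

test_that("weighted median equals the brute-force interpolation oracle", {
  for (seed in 1:20) {
    h <- rand_hset(16, seed = 200 + seed)
    rt <- ratio_table(h)
    est <- weighted_median(h, penalized = FALSE, n_boot = 100, seed = 1)
    expect_equal(est$beta, oracle_weighted_median(rt$theta, rt$weight),
                 tolerance = 1e-8)
  }
})

test_that("contamination mixture locates the majority group", {
  h <- make_hset(rep(1, 6), rep(0.01, 6), rep(0.5, 6), rep(0.004, 6))
  est <- contamination_mixture(h, psi = 0.5)
  expect_equal(est$beta, 0.5, tolerance = 1e-3)
  expect_equal(length(est$ci_segments), 1L)
  expect_true(est$ci_low <= 0.5 && 0.5 <= est$ci_high)
  # 70% of variants at 0.5, 30% displaced to 3.0, distinct precisions
  h <- make_hset(rep(1, 10), rep(0.01, 10),
                 c(rep(0.5, 7), rep(3, 3)),
                 c(rep(0.05, 7), rep(0.1, 3)))
  est <- contamination_mixture(h)
  expect_equal(est$beta, 0.5, tolerance = 0.05)
  expect_setequal(est$valid_variants, sprintf("rs%03d", 1:7))
  # confidence set always contains the estimate
  expect_true(any(vapply(est$ci_segments, function(s)
    s[1] <= est$beta && est$beta <= s[2], logical(1))))
  expect_error(contamination_mixture(h, psi = -1),
               class = "mrkit_domain_error")
})

test_that("contamination mixture agrees with a 10x finer grid search", {
  for (seed in 1:20) {
    h <- rand_hset(16, seed = 300 + seed)
    est <- contamination_mixture(h, grid_points = 2001)
    # independent exhaustive search on a 10x resolution over the same span
    rt <- ratio_table(h)
    psi <- est$psi
    pad <- 2 * max(rt$se_theta)
    fine <- seq(min(rt$theta) - pad, max(rt$theta) + pad,
                length.out = 20001)
    ll <- vapply(fine, function(th) {
      sum(pmax(-(rt$theta - th)^2 / (2 * rt$se_theta^2) - log(rt$se_theta),
               -rt$theta^2 / (2 * (rt$se_theta^2 + psi^2)) -
                 0.5 * log(rt$se_theta^2 + psi^2)))
    }, numeric(1))
    expect_lt(abs(est$beta - fine[which.max(ll)]), est$grid_step)
  }
})

test_that("percent transformation is the exact exp scale change", {
  e <- mr_estimate("ivw_fixed", 0, 0.001, 1, 5)
  expect_equal(transform_pct(e)$pct_beta, 0)
  e <- mr_estimate("ivw_fixed", 0.01, 0.001, 0.1, 5)
  expect_equal(transform_pct(e)$pct_beta, 1.005017, tolerance = 1e-6)
  e <- mr_estimate("ivw_fixed", -0.009545, 0.001, 0.1, 5)
  expect_equal(transform_pct(e)$pct_beta, 100 * (exp(-0.009545) - 1))
  expect_equal(round(transform_pct(e)$pct_beta, 2), -0.95)
  ci <- transform_pct(e)$pct_ci
  expect_true(ci[1] < transform_pct(e)$pct_beta &&
                transform_pct(e)$pct_beta < ci[2])
})

test_that("the method suite runs in reporting order, deterministically", {
  h <- rand_hset(16, seed = 10)
  ests <- run_all_methods(h, mr_config(seed = 5, n_boot = 200))
  expect_equal(names(ests), c("ivw_fixed", "egger",
                              "penalized_weighted_median",
                              "contamination_mixture"))
  expect_true(all(vapply(ests, function(e) !is.null(e$pct_beta), logical(1))))
  expect_true(is.numeric(ests$egger$intercept_pval))
  ests2 <- run_all_methods(h, mr_config(seed = 5, n_boot = 200))
  expect_identical(mr_table(ests), mr_table(ests2))
  # single variant: error unless the Wald fallback is requested
  h1 <- make_hset(0.5, 0.01, 0.25, 0.05)
  expect_error(run_all_methods(h1), class = "mrkit_insufficient_error")
  fb <- run_all_methods(h1, mr_config(fallback_wald = TRUE))
  expect_equal(names(fb), "wald_ratio")
  expect_equal(fb$wald_ratio$beta, 0.5)
})

test_that("estimates are scale- and sign-equivariant", {
  h <- rand_hset(12, seed = 11)
  cfg <- mr_config(seed = 3, n_boot = 200)
  base <- run_all_methods(h, cfg)
  c0 <- 2.5
  hs <- h
  hs$variants$beta_exp <- hs$variants$beta_exp * c0
  hs$variants$se_exp <- hs$variants$se_exp * c0
  scaled <- run_all_methods(hs, cfg)
  for (m in c("ivw_fixed", "egger", "penalized_weighted_median")) {
    expect_equal(scaled[[m]]$beta, base[[m]]$beta / c0, tolerance = 1e-8)
  }
  expect_equal(scaled$contamination_mixture$beta,
               base$contamination_mixture$beta / c0,
               tolerance = 2 * base$contamination_mixture$grid_step)
  hn <- h
  hn$variants$beta_out <- -hn$variants$beta_out
  neg <- run_all_methods(hn, cfg)
  for (m in c("ivw_fixed", "egger", "penalized_weighted_median")) {
    expect_equal(neg[[m]]$beta, -base[[m]]$beta, tolerance = 1e-8)
  }
  # the IVW CI reflects exactly; bootstrap CIs reflect up to Monte-Carlo
  # error in the replicate SEs
  expect_equal(neg$ivw_fixed$ci_low, -base$ivw_fixed$ci_high)
  for (m in c("egger", "penalized_weighted_median")) {
    expect_lt(abs(neg[[m]]$ci_low + base[[m]]$ci_high),
              0.5 * base[[m]]$se)
  }
})
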