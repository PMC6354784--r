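test_that("zero-uncertainty engine equals the product-of-coefficients form", {
  pair <- fake_pair(a_touch = 0.5, a_pain = 0.7, b_touch = 0.4, b_pain = 0.5,
                    cp_touch = 0.3, cp_pain = 0.2)
  est <- estimate_effects(pair$med, pair$out, n_sims = 50, seed = 1)
  expect_equal(est$point["touch", "me"], 0.5 * 0.4, tolerance = 1e-10)
  expect_equal(est$point["touch", "de"], 0.3, tolerance = 1e-10)
  expect_equal(est$point["touch", "te"], 0.5, tolerance = 1e-10)
  expect_equal(est$point["touch", "prop"], 0.4, tolerance = 1e-10)
  expect_equal(est$point["pain", "me"], 0.35, tolerance = 1e-10)
  expect_equal(est$point["pain", "prop"], 0.35 / 0.55, tolerance = 1e-10)
  # degenerate CIs collapse onto the point
  expect_equal(est$ci$me["pain", "lo"], 0.35, tolerance = 1e-10)
})

test_that("a zero mediator->outcome path yields no mediation", {
  pair <- fake_pair(0.5, 0.5, 0, 0, 0.3, 0.3)
  est <- estimate_effects(pair$med, pair$out, n_sims = 10, seed = 1)
  expect_equal(unname(est$point[, "me"]), c(0, 0))
  expect_equal(unname(est$point[, "prop"]), c(0, 0))
  expect_equal(est$point[, "de"], est$point[, "te"])
})

test_that("parameter draws are deterministic, unbiased, and PSD-checked", {
  beta <- c(`(Intercept)` = 0, x = 1)
  V <- matrix(c(0.04, 0.01, 0.01, 0.09), 2)
  fit <- fake_fit(beta, V)
  expect_identical(draw_parameters(fit, 100, seed = 3),
                   draw_parameters(fit, 100, seed = 3))
  # zero covariance: every draw equals beta
  d0 <- draw_parameters(fake_fit(beta), 5, seed = 1)
  expect_true(all(d0[, 1] == 0 & d0[, 2] == 1))
  # large-sample moments converge to (beta, vcov)
  dd <- draw_parameters(fit, 1e5, seed = 9)
  expect_equal(colMeans(dd), beta, tolerance = 0.01)
  expect_equal(stats::cov(dd), V, tolerance = 0.05, ignore_attr = TRUE)
  # indefinite covariance is rejected, not repaired
  Vbad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(draw_parameters(fake_fit(beta, Vbad), 10, seed = 1),
               "positive semi-definite")
})

test_that("total effect decomposes additively for every single draw", {
  pair <- fake_pair(0.4, 0.6, 0.3, 0.5, 0.2, 0.1, vcov_scale = 0.02)
  est <- estimate_effects(pair$med, pair$out, n_sims = 500, seed = 12)
  expect_identical(est$draws$te, est$draws$me + est$draws$de)
  expect_true(all(est$ci$me[, "lo"] <= est$point[, "me"] &
                    est$point[, "me"] <= est$ci$me[, "hi"]))
})

test_that("modality difference p handles ties, extremes and CIs", {
  # identical pain and touch effects: all differences zero, p = 1
  pair <- fake_pair(0.5, 0.5, 0.4, 0.4, 0.3, 0.3)
  est <- estimate_effects(pair$med, pair$out, n_sims = 1000, seed = 2)
  expect_equal(modality_difference_p(est, "me")$p_value, 1)
  # every difference positive: p floors at 2/n_sims, reported as inequality
  pair <- fake_pair(0.2, 0.7, 0.2, 0.6, 0.3, 0.3)
  est <- estimate_effects(pair$med, pair$out, n_sims = 1000, seed = 2)
  res <- modality_difference_p(est, "me")
  expect_equal(res$p_value, 2 / 1000)
  expect_true(res$below_floor)
  expect_match(res$p_label, "^< 0.002")
  expect_false(res$ci_overlap)
})

test_that("modality-difference p values are uniform under the null", {
  # null calibration: the true pain and touch paths are equal, and each
  # replicate's *estimated* coefficients are resampled from their sampling
  # distribution, as they would vary over repeated experiments; the
  # Monte-Carlo tail probability should then be ~ U(0,1) across replicates.
  # Coefficient SEs (~0.07) are set to the scale the paradigm produces;
  # the quasi-Bayesian p is only asymptotically calibrated and becomes
  # conservative when SEs rival the paths themselves.
  base <- fake_pair(0.4, 0.4, 0.3, 0.3, 0.2, 0.2, vcov_scale = 0.005)
  set.seed(2024)
  pvals <- vapply(1:400, function(r) {
    pair <- base
    pair$med$beta[] <- MASS::mvrnorm(1, base$med$beta, base$med$vcov_beta)
    pair$out$beta[] <- MASS::mvrnorm(1, base$out$beta, base$out$vcov_beta)
    est <- estimate_effects(pair$med, pair$out, n_sims = 200, seed = 1000 + r)
    modality_difference_p(est, "me")$p_value
  }, 0)
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("back-transformation rescales by the stored stratum SD", {
  pair <- fake_pair(0.5, 0.5, 0.3, 0.3, cp_touch = -0.15, cp_pain = -0.15)
  pair$out$outcome <- "z_rt"; pair$med$outcome <- "z_rating"
  pair$out$mediator <- "z_rating"
  est <- estimate_effects(pair$med, pair$out, n_sims = 10, seed = 1)
  zs <- data.frame(group = "patient",
                   modality = rep(c("pain", "touch"), each = 2),
                   variable = rep(c("rating", "rt_ms"), 2),
                   mean = c(50, 400, 40, 380), sd = c(20, 100, 15, 100))
  rep_ <- backtransform(est, zs, group = "patient")
  expect_equal(rep_$units, "ms")
  expect_equal(unname(rep_$point["pain", "de"]), -15, tolerance = 1e-10)
  expect_equal(unname(rep_$point["touch", "de"]), -15, tolerance = 1e-10)
  # zero effect stays zero in any units; round trip recovers the z-scale
  expect_equal(unname(rep_$point[, "me"] / rep_$sd_used),
               unname(est$point[, "me"]), tolerance = 1e-12)
})

test_that("mediation on generated data is reproducible and coding-invariant", {
  cfg <- trial_config(n_subjects_per_group = 5, n_blocks = 1)
  pp <- quiet_preprocess(generate_trials(cfg, seed = 14))
  f1 <- mediate_trials(pp$table, "behavior_perception", group = "patient",
                       n_sims = 200, seed = 3)
  f2 <- mediate_trials(pp$table, "behavior_perception", group = "patient",
                       n_sims = 200, seed = 3)
  expect_identical(f1$estimate$point, f2$estimate$point)
  expect_s3_class(f1, "moderated_mediation")
  expect_false(is.null(f1$units))   # z-score metadata flowed through
  # reaction-time SD is on the ms scale, so original units are plausible ms
  expect_equal(rownames(f1$estimate$point), c("pain", "touch"))
})
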