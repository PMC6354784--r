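test_that("default paradigm dimensions match the design", {
  cfg <- trial_config(n_subjects_per_group = 2)
  d <- generate_trials(cfg, seed = 1)
  expect_equal(nrow(d), 4 * 216)                       # 216 trials/subject
  per <- table(d$subject_id, d$modality)
  expect_true(all(per == 108))                         # 108 per modality
  per_block <- table(d$subject_id, d$block)
  expect_true(all(per_block == 54))                    # 54-trial blocks
  expect_setequal(unique(d$group[startsWith(d$subject_id, "P")]), "patient")
})

test_that("generation is deterministic given seed and config", {
  cfg <- trial_config(n_subjects_per_group = 2, n_blocks = 1)
  expect_identical(generate_trials(cfg, seed = 9), generate_trials(cfg, seed = 9))
  d1 <- generate_trials(cfg, seed = 9)
  d2 <- generate_trials(cfg, seed = 10)
  expect_false(identical(d1$rating, d2$rating))
})

test_that("degenerate noiseless configuration maps to the anchors exactly", {
  cfg <- uniform_config(0, 0, 0,
                        n_subjects_per_group = 2, n_blocks = 1,
                        sd_subject_intercept_m = 0, sd_subject_slope_m = 0,
                        sd_subject_intercept_y = 0, sd_subject_slope_y = 0,
                        sd_resid_m = 0, sd_resid_y = 0,
                        misident_rate = 0, zero_rating_rate = 0)
  d <- generate_trials(cfg, seed = 4)
  expect_true(all(d$rating == 50))     # mid anchor
  expect_true(all(d$rt_ms == 500))
  expect_true(all(d$modality_correct))
})

test_that("plain least squares on generated data recovers the total slope", {
  # a = 0.5, b = 0.4, c' = 0.1: total standardized effect 0.3 per level
  cfg <- uniform_config(0.5, 0.4, 0.1, n_subjects_per_group = 20,
                        n_blocks = 2, misident_rate = 0, zero_rating_rate = 0)
  d <- generate_trials(cfg, seed = 21)
  d <- d[d$modality == "pain" & d$group == "patient", ]
  sd_y <- latent_sds(cfg)
  sd_y <- sd_y$sd_y[sd_y$group == "patient" & sd_y$modality == "pain"]
  fit <- stats::lm(scale(rating) ~ I(intensity_level - 2), data = d)
  slope <- summary(fit)$coefficients[2, ]
  expect_lt(abs(slope["Estimate"] - 0.3 / sd_y), 2 * slope["Std. Error"])
})

test_that("misidentification and zero-rating rates are honoured", {
  cfg <- trial_config(n_subjects_per_group = 10, misident_rate = 0.05,
                      zero_rating_rate = 0.02)
  d <- generate_trials(cfg, seed = 33)
  n <- nrow(d)
  for (spec in list(c(mean(!d$modality_correct), 0.05))) {
    tol <- 3 * sqrt(spec[2] * (1 - spec[2]) / n)
    expect_lt(abs(spec[1] - spec[2]), tol)
  }
  # zero ratings occur at >= the configured rate (clipping can add a few)
  expect_gt(mean(d$rating == 0), 0.02 - 3 * sqrt(0.02 * 0.98 / n))
})

test_that("per-cell observable means converge to the configured structure", {
  cfg <- trial_config(n_subjects_per_group = 200, n_blocks = 1,
                      misident_rate = 0, zero_rating_rate = 0)
  d <- generate_trials(cfg, seed = 55)
  d <- d[d$group == "patient" & d$modality == "pain", ]
  p <- cfg$paths$patient$pain
  tau_y <- p[["c_prime"]] + p[["a"]] * p[["b"]]   # rating latent slope
  tau_m <- p[["a"]]                               # behavior latent slope
  for (x in c(-1, 0, 1)) {
    cell <- d[d$intensity_level == x + 2, ]
    subj_means <- tapply(cell$rating, cell$subject_id, mean)
    se <- stats::sd(subj_means) / sqrt(length(subj_means))
    expect_lt(abs(mean(subj_means) - (50 + 15 * tau_y * x)), 3 * se)
    subj_rt <- tapply(cell$rt_ms, cell$subject_id, mean)
    se_rt <- stats::sd(subj_rt) / sqrt(length(subj_rt))
    expect_lt(abs(mean(subj_rt) - (500 - 100 * tau_m * x)), 3 * se_rt)
  }
})

test_that("block sequences satisfy both run-length constraints", {
  for (method in c("greedy", "rejection")) {
    s <- pseudorandom_sequence(trials_per_cell = if (method == "greedy") 9 else 3,
                               seed = 7, method = method)
    expect_lte(max(rle(s$intensity_level)$lengths), 2)
    expect_lte(max(rle(s$modality)$lengths), 3)
    expect_equal(nrow(s), if (method == "greedy") 54 else 18)
    # per-cell counts preserved
    expect_true(all(table(s$modality, s$intensity_level) ==
                      if (method == "greedy") 9 else 3))
    expect_identical(s, pseudorandom_sequence(
      trials_per_cell = if (method == "greedy") 9 else 3,
      seed = 7, method = method))
  }
})

test_that("trivial and unsatisfiable sequence requests behave as specified", {
  counts <- matrix(0L, 2, 3, dimnames = list(c("pain", "touch"), 1:3))
  counts["pain", 1] <- 1L
  s <- pseudorandom_sequence(counts, seed = 1)
  expect_equal(nrow(s), 1)
  expect_equal(s$modality, "pain")
  counts["pain", 1] <- 5L   # 5 same-intensity trials cannot satisfy run <= 2
  expect_error(pseudorandom_sequence(counts, seed = 1, max_tries = 50),
               "no valid sequence")
})

test_that("intensity calibration inverts the fitted rating line", {
  # identity line: targets are returned as-is
  expect_equal(calibrate_intensities(1:40, 1:40, max_magnitude = 600),
               c(30, 50, 70))
  # rating = 0.1 * magnitude: inversion with the 600 mJ cap clipping level 3
  mags <- seq(100, 700, by = 50)
  expect_equal(calibrate_intensities(mags, 0.1 * mags, max_magnitude = 600),
               c(300, 500, 600))
  # noisy points around a known line recover the noiseless inversion
  set.seed(11)
  m <- runif(20, 100, 600)
  r <- 5 + 0.1 * m + rnorm(20, 0, 1)
  got <- calibrate_intensities(m, r, max_magnitude = 600)
  expect_equal(got, (c(30, 50, 70) - 5) / 0.1, tolerance = 0.05)
  # perception must increase with intensity
  expect_error(calibrate_intensities(1:10, 10:1), "increase")
})

test_that("generator configs round-trip through JSON files", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    n_subjects_per_group = 5, n_blocks = 2, direction = "perception_mediates",
    misident_rate = 0.1,
    paths = list(patient = list(pain = list(a = 0.3, b = 0.2, c_prime = 0.1),
                                touch = list(a = 0.1, b = 0.1, c_prime = 0.2)),
                 control = list(pain = list(a = 0.3, b = 0.2, c_prime = 0.1),
                                touch = list(a = 0.1, b = 0.1, c_prime = 0.2)))),
    path, auto_unbox = TRUE)
  cfg <- read_trial_config(path)
  expect_s3_class(cfg, "trial_config")
  expect_equal(cfg$n_subjects_per_group, 5L)
  expect_equal(cfg$direction, "perception_mediates")
  expect_equal(unname(cfg$paths$patient$pain["b"]), 0.2)
  expect_equal(cfg$n_blocks, 2L)          # overridden
  expect_equal(cfg$rt_mean_ms, 500)       # default retained
  d <- generate_trials(cfg, seed = 2)
  expect_equal(nrow(d), 10 * 2 * 54)
  # unknown fields are rejected, not silently dropped
  jsonlite::write_json(list(n_sujets = 4), path, auto_unbox = TRUE)
  expect_error(read_trial_config(path), "unknown config field")
})
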