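test_that("cell means equal hand-computed averages and ignore trial order", {
  d <- make_trials(12, modality = rep(c("pain", "touch"), each = 6),
                   intensity_level = rep(1:3, 4),
                   rating = 1:12, rt_ms = (1:12) * 100)
  cm <- cell_means(d)
  expect_equal(nrow(cm), 6)
  # pain x level 1 trials are rows 1 and 4: mean rating 2.5
  expect_equal(cm$rating[cm$modality == "pain" & cm$intensity_level == 1], 2.5)
  # touch x level 3 trials are rows 9 and 12: mean RT (900 + 1200)/2
  expect_equal(cm$rt_ms[cm$modality == "touch" & cm$intensity_level == 3], 1050)
  cm2 <- cell_means(d[rev(seq_len(nrow(d))), ])
  expect_equal(cm2, cm, ignore_attr = TRUE)
})

test_that("subjects with empty cells are dropped listwise", {
  d <- rbind(make_trials(12, subject_id = "S1",
                         modality = rep(c("pain", "touch"), each = 6),
                         intensity_level = rep(1:3, 4)),
             make_trials(4, subject_id = "S2", modality = "pain",
                         intensity_level = c(1, 2, 3, 1)))
  expect_message(cm <- cell_means(d), "S2")
  expect_setequal(unique(cm$subject_id), "S1")
})

test_that("constant data give an all-zero ANOVA decomposition", {
  d <- make_trials(48, subject_id = rep(sprintf("S%d", 1:4), each = 12),
                   group = rep(c("patient", "control"), each = 24),
                   modality = rep(rep(c("pain", "touch"), each = 6), 4),
                   intensity_level = rep(1:3, 16))
  cm <- cell_means(d)           # every rating is 50
  tab <- mixed_anova(cm, "rating")
  expect_true(all(tab$ss < 1e-20))
  expect_true(all(tab$F == 0))
  expect_true(all(tab$p == 1))
})

test_that("the SS decomposition matches the independent means oracle", {
  set.seed(99)
  cells <- expand.grid(subject_id = sprintf("S%d", 1:4),
                       modality = c("pain", "touch"),
                       intensity_level = 1:3, stringsAsFactors = FALSE)
  cells$group <- ifelse(cells$subject_id %in% c("S1", "S2"),
                        "patient", "control")
  cells$rating <- rnorm(24, 50, 10)
  cells$rt_ms <- rnorm(24, 400, 60)
  tab <- mixed_anova(cells, "rating")
  oracle <- anova_oracle(cells, "rating")
  for (eff in c("group", "modality", "group:modality", "intensity",
                "group:intensity", "modality:intensity",
                "group:modality:intensity")) {
    expect_equal(tab$ss[tab$effect == eff], oracle[[eff]],
                 tolerance = 1e-10, label = paste("SS", eff))
  }
  expect_equal(tab$error_ss[tab$effect == "group"], oracle$subj_err,
               tolerance = 1e-10)
  # partition identity: effects + error strata = total SS
  total <- sum(tab$ss) + sum(tab$error_ss[!duplicated(tab$error_ss)])
  expect_equal(total, oracle$total, tolerance = 1e-10)
})

test_that("F values are invariant to affine rescaling of the response", {
  set.seed(7)
  cells <- expand.grid(subject_id = sprintf("S%d", 1:6),
                       modality = c("pain", "touch"),
                       intensity_level = 1:3, stringsAsFactors = FALSE)
  cells$group <- ifelse(cells$subject_id %in% sprintf("S%d", 1:3),
                        "patient", "control")
  cells$rating <- rnorm(36, 50, 10)
  cells$rt_ms <- 0
  t1 <- mixed_anova(cells, "rating")
  cells$rating <- 3 * cells$rating + 7
  t2 <- mixed_anova(cells, "rating")
  expect_equal(t2$F, t1$F, tolerance = 1e-8)
  expect_equal(t2$p, t1$p, tolerance = 1e-8)
})

test_that("a pure group shift loads only on the group main effect", {
  set.seed(12)
  n <- 20
  cells <- expand.grid(subject_id = sprintf("S%02d", 1:(2 * n)),
                       modality = c("pain", "touch"),
                       intensity_level = 1:3, stringsAsFactors = FALSE)
  cells$group <- ifelse(cells$subject_id %in% sprintf("S%02d", 1:n),
                        "patient", "control")
  shift <- ifelse(cells$group == "patient", 8, 0)
  cells$rating <- 50 + shift + rnorm(nrow(cells), 0, 3)
  cells$rt_ms <- 0
  tab <- mixed_anova(cells, "rating")
  expect_lt(tab$p[tab$effect == "group"], 1e-6)
  expect_true(all(tab$p[tab$effect != "group"] > 0.001))
})

test_that("Greenhouse-Geisser epsilon is sane and only corrects within effects", {
  set.seed(3)
  cells <- expand.grid(subject_id = sprintf("S%d", 1:10),
                       modality = c("pain", "touch"),
                       intensity_level = 1:3, stringsAsFactors = FALSE)
  cells$group <- ifelse(cells$subject_id %in% sprintf("S%d", 1:5),
                        "patient", "control")
  cells$rating <- rnorm(60, 50, 5)
  cells$rt_ms <- 0
  tab <- mixed_anova(cells, "rating", gg = TRUE)
  eps <- tab$gg_epsilon[tab$effect == "intensity"]
  expect_gte(eps, 1 / 2)        # lower bound 1/(k-1) for k = 3
  expect_lte(eps, 1 + 1e-8)
  expect_true(is.na(tab$gg_epsilon[tab$effect == "group"]))
  # a 2-level within factor is always spherical: epsilon = 1
  expect_equal(tab$gg_epsilon[tab$effect == "modality"], 1, tolerance = 1e-8)
})

test_that("pearson correlation matches the textbook formula", {
  x <- c(1, 2, 4, 7, 9)
  y <- c(2, 1, 5, 6, 10)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_hand <- r_hand * sqrt(3 / (1 - r_hand^2))
  p_hand <- 2 * stats::pt(-abs(t_hand), df = 3)
  got <- pearson_correlations(x, y)
  expect_equal(got$r, r_hand, tolerance = 1e-12)
  expect_equal(got$p, p_hand, tolerance = 1e-12)
  expect_equal(got$df, 3)
  # perfect linearity
  expect_equal(pearson_correlations(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  # independence at large n
  set.seed(5)
  expect_lt(abs(pearson_correlations(rnorm(2000), rnorm(2000))$r), 0.08)
  expect_error(pearson_correlations(c(1, 1, 1), c(1, 2, 3)), "variance")
})
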