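## Moderated multilevel mediation with quasi-Bayesian Monte-Carlo inference.
##
## The mediator model gives the stimulus->mediator path a(w) and the
## outcome model the mediator->outcome path b(w) and direct path c'(w),
## each moderated by modality w. Inference propagates draws from the
## asymptotic normal of each model's fixed effects through the effect
## formulas: per draw k and modality w,
##   ME_k(w) = a_k(w) b_k(w),  DE_k(w) = c'_k(w),  TE_k = ME_k + DE_k,
##   prop_k(w) = ME_k(w) / TE_k(w).
## Because the outcome model carries no stimulus-by-mediator interaction,
## TE = ME + DE holds exactly for every draw.

#' Draw fixed-effect vectors from a fitted model
#'
#' Quasi-Bayesian parameter draws: samples from the multivariate normal
#' with mean `beta` and covariance `vcov_beta`. Deterministic given `seed`.
#' A covariance that is not positive semi-definite (beyond numerical
#' tolerance) is an error — it is never silently repaired.
#'
#' @param fit an [fit_lmm()] result.
#' @param n_sims number of draws (>= 2).
#' @param seed RNG seed.
#' @return `n_sims` x p matrix of draws, columns named as `fit$beta`.
#' @export
draw_parameters <- function(fit, n_sims, seed = NULL) {
  stopifnot(inherits(fit, "lmm_fit"), n_sims >= 2)
  if (!isTRUE(fit$converged)) stop("cannot draw from a non-converged fit")
  V <- (fit$vcov_beta + t(fit$vcov_beta)) / 2
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop("vcov_beta is not positive semi-definite")
  }
  draws <- with_seed(seed,
    MASS::mvrnorm(n_sims, mu = fit$beta, Sigma = V, tol = 1e-6))
  colnames(draws) <- names(fit$beta)
  draws
}

## column lookup tolerant of interaction-term orderings ("x:w" vs "w:x")
draw_col <- function(draws, a, b = NULL) {
  nm <- if (is.null(b)) a else c(paste(a, b, sep = ":"), paste(b, a, sep = ":"))
  hit <- intersect(nm, colnames(draws))
  if (length(hit) == 0) {
    if (is.null(b)) stop("coefficient ", a, " not found")
    return(rep(0, nrow(draws)))
  }
  draws[, hit[1]]
}

#' Moderated mediation effects from a fitted model pair
#'
#' Computes mediation (ME), direct (DE) and total (TE) effects and the
#' proportion mediated at each modality, with percentile Monte-Carlo
#' confidence intervals, from a mediator-model / outcome-model pair fitted
#' on the same single-group table with the same moderator coding. Draws
#' for the two models are independent (the models are fitted separately).
#'
#' Point estimates are the draw means for ME/DE/TE and the draw *median*
#' for the proportion mediated, whose ratio distribution is heavy-tailed;
#' draws with |TE| < 1e-12 are excluded from the proportion distribution
#' (the count is recorded). An effect is flagged significant when its 95%
#' interval excludes zero.
#'
#' @param mediator_fit [fit_lmm()] fit of the mediator on `x * w`.
#' @param outcome_fit [fit_lmm()] fit of the outcome on `x * w + m * w`.
#' @param n_sims number of Monte-Carlo draws (default 1000).
#' @param seed RNG seed.
#' @param level confidence level (default 0.95).
#' @return an object of class `"mediation_estimate"`.
#' @export
estimate_effects <- function(mediator_fit, outcome_fit, n_sims = 1000,
                             seed = NULL, level = 0.95) {
  stopifnot(inherits(mediator_fit, "lmm_fit"), inherits(outcome_fit, "lmm_fit"))
  if (!identical(mediator_fit$coding, outcome_fit$coding)) {
    stop("mediator and outcome fits use different moderator codings")
  }
  if (is.null(outcome_fit$mediator)) {
    stop("outcome_fit carries no mediator term")
  }
  seeds <- if (is.null(seed)) c(NA, NA) else derive_seeds(seed, 2)
  A <- draw_parameters(mediator_fit, n_sims,
                       if (is.null(seed)) NULL else seeds[1])
  B <- draw_parameters(outcome_fit, n_sims,
                       if (is.null(seed)) NULL else seeds[2])
  wlev <- moderator_levels(mediator_fit$coding)
  eff <- c("me", "de", "te", "prop")
  draws <- lapply(eff, function(.) matrix(NA_real_, n_sims, length(wlev),
                                          dimnames = list(NULL, names(wlev))))
  names(draws) <- eff
  for (j in seq_along(wlev)) {
    w <- wlev[j]
    a <- draw_col(A, "x") + w * draw_col(A, "x", "w")
    b <- draw_col(B, "m") + w * draw_col(B, "m", "w")
    cp <- draw_col(B, "x") + w * draw_col(B, "x", "w")
    draws$me[, j] <- a * b
    draws$de[, j] <- cp
    draws$te[, j] <- a * b + cp
    p <- (a * b) / draws$te[, j]
    p[abs(draws$te[, j]) < 1e-12] <- NA
    draws$prop[, j] <- p
  }
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  point <- sapply(draws[c("me", "de", "te")], colMeans)
  point <- cbind(point, prop = apply(draws$prop, 2, stats::median, na.rm = TRUE))
  ci <- lapply(draws, function(m)
    t(apply(m, 2, stats::quantile, probs = probs, na.rm = TRUE, names = FALSE)))
  for (e in eff) colnames(ci[[e]]) <- c("lo", "hi")
  structure(list(
    point = point,                     # levels x c(me, de, te, prop)
    ci = ci,                           # per effect: levels x c(lo, hi)
    draws = draws,
    n_sims = n_sims,
    seed = seed,
    level = level,
    coding = mediator_fit$coding,
    moderator_values = wlev,
    outcome = outcome_fit$outcome,
    mediator = outcome_fit$mediator,
    n_prop_excluded = colSums(is.na(draws$prop)),
    significant_me = ci$me[, "lo"] > 0 | ci$me[, "hi"] < 0,
    significant_de = ci$de[, "lo"] > 0 | ci$de[, "hi"] < 0
  ), class = "mediation_estimate")
}

#' @export
print.mediation_estimate <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Moderated mediation estimate (%d Monte-Carlo draws, %.0f%% CIs)\n",
    x$n_sims, 100 * x$level))
  cat("  mediator:", x$mediator, "  outcome:", x$outcome, "\n")
  for (lv in rownames(x$point)) {
    cat(sprintf("  %-5s", lv))
    for (e in c("me", "de", "te", "prop")) {
      cat(sprintf(" %s=%7.3f [%7.3f; %7.3f]", toupper(e),
                  x$point[lv, e], x$ci[[e]][lv, "lo"], x$ci[[e]][lv, "hi"]))
    }
    cat("\n")
  }
  invisible(x)
}

#' Modality difference of a mediation effect
#'
#' Subtracts the Monte-Carlo draws of an effect for touch from those for
#' pain and summarizes the difference distribution: two-sided p value
#' `2 * min(#{d > 0}, #{d < 0}) / n` (zero draws split evenly), floored at
#' `2 / n_sims` and reported as an inequality there, plus a percentile CI
#' of the difference. `ci_overlap` additionally reports the quick
#' non-overlap screen of the two per-modality intervals.
#'
#' @param estimate a [estimate_effects()] result.
#' @param effect `"me"`, `"de"`, `"te"` or `"prop"`.
#' @return list with `difference` (point), `ci`, `p_value`, `p_label`,
#'   `below_floor`, `ci_overlap`, and for `"prop"` a `high_exclusion`
#'   warning flag when more than 20% of draws were excluded.
#' @export
modality_difference_p <- function(estimate,
                                  effect = c("me", "de", "te", "prop")) {
  effect <- match.arg(effect)
  stopifnot(inherits(estimate, "mediation_estimate"))
  dm <- estimate$draws[[effect]]
  if (!all(c("pain", "touch") %in% colnames(dm))) {
    stop("estimate lacks pain/touch draw columns")
  }
  d <- dm[, "pain"] - dm[, "touch"]
  d <- d[!is.na(d)]
  n <- length(d)
  if (n == 0) stop("no usable draws for effect ", effect)
  n0 <- sum(d == 0)
  raw <- 2 * min(sum(d > 0) + n0 / 2, sum(d < 0) + n0 / 2) / n
  floor_p <- 2 / estimate$n_sims
  p <- min(max(raw, floor_p), 1)
  probs <- c((1 - estimate$level) / 2, 1 - (1 - estimate$level) / 2)
  ci <- stats::quantile(d, probs, names = FALSE)
  overlap <- max(estimate$ci[[effect]][, "lo"]) <=
    min(estimate$ci[[effect]][, "hi"])
  out <- list(
    effect = effect,
    difference = if (effect == "prop") stats::median(d) else mean(d),
    ci = ci,
    p_value = p,
    p_label = if (raw < floor_p) paste0("< ", format(floor_p)) else format(p),
    below_floor = raw < floor_p,
    n_used = n,
    ci_overlap = overlap
  )
  if (effect == "prop") {
    excl <- estimate$n_sims - n
    out$high_exclusion <- excl > 0.2 * estimate$n_sims
    if (out$high_exclusion) {
      warning("more than 20% of proportion-mediated draws were excluded; ",
              "the p value may be unreliable")
    }
  }
  out
}

#' Express standardized mediation effects in original units
#'
#' Multiplies the standardized ME/DE/TE (points and CIs) by the stratum SD
#' of the outcome variable stored by [zscore_by_stratum()], giving the
#' average effect of a one-level stimulus-intensity increase in original
#' units: ms for reaction-time outcomes, NRS points for rating outcomes.
#' The proportion mediated is unitless and unchanged.
#'
#' @param estimate a [estimate_effects()] result.
#' @param z_stats the `z_stats` data frame from the preprocessed table's
#'   metadata (`trial_meta(table)$z_stats`), or the table itself.
#' @param group group whose strata to use (when `z_stats` is stratified by
#'   group).
#' @return an object of class `"original_units_report"`: per modality,
#'   ME/DE/TE points and CIs in outcome units, plus the SDs used.
#' @export
backtransform <- function(estimate, z_stats, group = NULL) {
  stopifnot(inherits(estimate, "mediation_estimate"))
  if (is.data.frame(z_stats) && !is.null(z_stats$variable)) {
    zs <- z_stats
  } else {
    zs <- trial_meta(z_stats)$z_stats
    if (is.null(zs)) stop("no z-score metadata; run zscore_by_stratum() first")
  }
  var <- sub("^z_(rating)$", "\\1", estimate$outcome)
  var <- if (var == "z_rt") "rt_ms" else var
  units <- if (var == "rt_ms") "ms" else "NRS points"
  rows <- zs[zs$variable == var, , drop = FALSE]
  if (!is.null(group) && "group" %in% names(rows)) {
    rows <- rows[rows$group == group, , drop = FALSE]
  }
  lv <- rownames(estimate$point)
  sds <- vapply(lv, function(m) {
    r <- if ("modality" %in% names(rows)) rows[rows$modality == m, , drop = FALSE]
         else rows
    if (nrow(r) != 1) {
      stop("cannot resolve a unique ", var, " SD for modality ", m,
           if (!is.null(group)) paste0(" in group ", group) else "",
           " from z-score metadata")
    }
    r$sd
  }, 0)
  point <- estimate$point[, c("me", "de", "te"), drop = FALSE] * sds
  ci <- lapply(estimate$ci[c("me", "de", "te")], function(m) m * sds)
  structure(list(point = point, ci = ci, sd_used = sds, variable = var,
                 units = units, level = estimate$level),
            class = "original_units_report")
}

#' @export
print.original_units_report <- function(x, ...) {
  cat("Effects in original units (", x$units, " per one intensity level)\n",
      sep = "")
  for (lv in rownames(x$point)) {
    cat(sprintf("  %-5s ME=%8.2f [%8.2f; %8.2f]  DE=%8.2f [%8.2f; %8.2f]\n",
                lv, x$point[lv, "me"], x$ci$me[lv, "lo"], x$ci$me[lv, "hi"],
                x$point[lv, "de"], x$ci$de[lv, "lo"], x$ci$de[lv, "hi"]))
  }
  invisible(x)
}

## ------------------------------------------------------------------------

#' Moderated multilevel mediation of trial-level data
#'
#' The package's central fitting function. For one group of a preprocessed
#' trial table, fits the mediator and outcome linear mixed models for the
#' chosen model direction, runs quasi-Bayesian Monte-Carlo inference for
#' the moderated mediation decomposition, and (when z-score metadata is
#' available) expresses the effects in original units.
#'
#' Model directions: the *perception-behavior* model asks to what extent
#' perceptual ratings mediate the effect of stimulus intensity on reaction
#' times (mediator `z_rating`, outcome `z_rt`); the *behavior-perception*
#' model asks to what extent motor responses mediate the effect on
#' ratings (mediator `z_rt`, outcome `z_rating`).
#'
#' @param table preprocessed trial table ([preprocess_trials()]).
#' @param direction `"perception_behavior"` or `"behavior_perception"`.
#' @param group `"patient"`, `"control"`, or `NULL` if the table holds one
#'   group only.
#' @param n_sims Monte-Carlo draws (default 1000).
#' @param seed RNG seed.
#' @param coding moderator coding ([moderator_coding()]).
#' @param random random-effect structure ([fit_lmm()]).
#' @param level confidence level.
#' @param control optional [lme4::lmerControl()] passed to the fits.
#' @return an object of class `"moderated_mediation"` with components
#'   `mediator_fit`, `outcome_fit`, `estimate` ([estimate_effects()]),
#'   `units` ([backtransform()] result or `NULL`), `direction`, `group`.
#' @export
#' @examples
#' cfg <- trial_config(n_subjects_per_group = 6, n_blocks = 2)
#' pp <- preprocess_trials(generate_trials(cfg, seed = 7))
#' fit <- mediate_trials(pp$table, "behavior_perception", group = "patient",
#'                       n_sims = 200, seed = 1)
#' fit
mediate_trials <- function(table,
                           direction = c("perception_behavior",
                                         "behavior_perception"),
                           group = NULL, n_sims = 1000, seed = NULL,
                           coding = c("reference", "effect"),
                           random = c("intercept_slope", "intercept"),
                           level = 0.95, control = NULL) {
  direction <- match.arg(direction)
  coding <- match.arg(coding)
  random <- match.arg(random)
  meta <- trial_meta(table)
  if (!is.null(group)) {
    table_g <- table[table$group == group, , drop = FALSE]
    if (nrow(table_g) == 0) stop("no trials for group ", group)
  } else {
    if (length(unique(table$group)) > 1) {
      stop("table holds both groups; pass group = \"patient\" or \"control\"")
    }
    table_g <- table
    group <- unique(table$group)
  }
  vars <- switch(direction,
                 perception_behavior = c(m = "z_rating", y = "z_rt"),
                 behavior_perception = c(m = "z_rt", y = "z_rating"))
  mediator_fit <- fit_lmm(table_g, outcome = vars[["m"]], mediator = NULL,
                          coding = coding, random = random, control = control)
  outcome_fit <- fit_lmm(table_g, outcome = vars[["y"]],
                         mediator = vars[["m"]], coding = coding,
                         random = random, control = control)
  est <- estimate_effects(mediator_fit, outcome_fit, n_sims = n_sims,
                          seed = seed, level = level)
  units <- if (!is.null(meta$z_stats)) {
    backtransform(est, meta$z_stats, group = group)
  }
  structure(list(
    direction = direction,
    group = group,
    mediator_fit = mediator_fit,
    outcome_fit = outcome_fit,
    estimate = est,
    units = units,
    n_sims = n_sims,
    seed = seed,
    coding = coding
  ), class = "moderated_mediation")
}

#' @export
print.moderated_mediation <- function(x, ...) {
  cat("Moderated multilevel mediation (",
      sub("_", "-", x$direction), " model, group: ", x$group, ")\n", sep = "")
  print(x$estimate)
  if (!is.null(x$units)) print(x$units)
  invisible(x)
}

#' @export
summary.moderated_mediation <- function(object, ...) {
  est <- object$estimate
  tab <- do.call(rbind, lapply(rownames(est$point), function(lv) {
    data.frame(
      modality = lv,
      effect = c("ME", "DE", "TE", "prop_mediated"),
      estimate = as.numeric(est$point[lv, c("me", "de", "te", "prop")]),
      ci_lo = vapply(c("me", "de", "te", "prop"),
                     function(e) est$ci[[e]][lv, "lo"], 0),
      ci_hi = vapply(c("me", "de", "te", "prop"),
                     function(e) est$ci[[e]][lv, "hi"], 0),
      stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  p_me <- modality_difference_p(est, "me")
  structure(list(direction = object$direction, group = object$group,
                 effects = tab,
                 significant_me = est$significant_me,
                 significant_de = est$significant_de,
                 modality_p_me = p_me$p_value,
                 n_sims = est$n_sims),
            class = "summary.moderated_mediation")
}

#' @export
print.summary.moderated_mediation <- function(x, ...) {
  cat("Moderated mediation summary (", sub("_", "-", x$direction),
      ", group: ", x$group, ")\n", sep = "")
  print(x$effects, digits = 3)
  cat("significant ME:",
      paste(names(x$significant_me), x$significant_me, collapse = ", "), "\n")
  cat("modality difference of ME: p =", format(x$modality_p_me), "\n")
  invisible(x)
}

#' @export
coef.moderated_mediation <- function(object, ...) object$estimate$point

#' @export
confint.moderated_mediation <- function(object, parm = c("me", "de", "te",
                                                         "prop"), ...) {
  parm <- match.arg(parm)
  object$estimate$ci[[parm]]
}

#' @export
plot.moderated_mediation <- function(x, effect = "me", ...) {
  dm <- x$estimate$draws[[effect]]
  dens <- apply(dm, 2, function(col) stats::density(col[!is.na(col)]))
  xr <- range(vapply(dens, function(d) range(d$x), c(0, 0)))
  yr <- c(0, max(vapply(dens, function(d) max(d$y), 0)))
  graphics::plot(NA, xlim = xr, ylim = yr, xlab = toupper(effect),
                 ylab = "Monte-Carlo density",
                 main = paste("Draw distributions,",
                              sub("_", "-", x$direction), "model"), ...)
  for (j in seq_along(dens)) {
    graphics::lines(dens[[j]], col = j + 1, lwd = 2)
  }
  graphics::abline(v = 0, lty = 3)
  graphics::legend("topright", legend = colnames(dm),
                   col = seq_along(dens) + 1, lwd = 2, bty = "n")
  invisible(x)
}
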