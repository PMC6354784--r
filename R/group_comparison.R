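## Permutation test for the group difference in proportion mediated.
##
## Group labels are permuted at the subject level (all of a subject's
## trials move together) and the full per-group mediation pipeline is
## re-run for each relabeling. The linear mixed models depend only on the
## relabeling, so their fits are memoized per distinct relabeling (bounded
## cache); the Monte-Carlo draws are cheap and, by default, re-randomized
## for every permutation.

#' Random subject-level group relabeling
#'
#' Uniformly samples which subjects are assigned the first group label,
#' preserving the observed group sizes.
#'
#' @param subjects character vector of subject ids (one entry per subject).
#' @param n_group1 number of subjects assigned to the first group.
#' @param seed RNG seed.
#' @return character vector: the subjects relabeled into group 1.
#' @export
permute_group_labels <- function(subjects, n_group1, seed = NULL) {
  stopifnot(n_group1 >= 1, n_group1 < length(subjects))
  with_seed(seed, sort(sample(subjects, n_group1)))
}

## deterministic small integer derived from a relabeling, used under the
## "per_relabeling" seed policy so the statistic is a pure function of the
## relabeling
relabel_seed <- function(base_seed, group1_ids, all_ids) {
  idx <- sort(match(group1_ids, all_ids))
  key <- sum(idx * seq_along(idx)) %% 1000003L
  as.integer((as.numeric(base_seed) * 31 + key) %% 2147483646) + 1L
}

#' Permutation test of the group difference in proportion mediated
#'
#' Computes the observed patients-minus-controls difference of the
#' proportion mediated for one model direction and one modality, then
#' permutes group labels over subjects `n_perm` times, re-running both
#' groups' mediation analyses per permutation with `n_sims_inner`
#' Monte-Carlo draws, and reports
#' `p = (number of qualifying permutations + 1) / (n_perm + 1)`.
#' Sidedness: `"two_sided_abs"` (default) counts permutations with
#' `|d_perm| >= |d_obs|`; `"one_sided_exceed"` counts `d_perm >= d_obs`.
#'
#' With `method = "exact"` all distinct relabelings are enumerated instead
#' (feasible only for small groups) and
#' `p = #\{relabelings qualifying\} / #\{relabelings\}`; the identity
#' relabeling qualifies by construction, so p > 0. Exact enumeration uses
#' the `"per_relabeling"` seed policy so the statistic is a well-defined
#' function of the relabeling.
#'
#' @param table preprocessed two-group trial table.
#' @param direction model direction, see [mediate_trials()].
#' @param modality `"pain"` or `"touch"`.
#' @param n_perm number of permutations (default 1000).
#' @param n_sims_inner Monte-Carlo draws inside each permutation (default
#'   200; the proportion-mediated point, a draw median, stabilizes quickly).
#' @param sidedness `"two_sided_abs"` or `"one_sided_exceed"`.
#' @param seed RNG seed.
#' @param method `"monte_carlo"` (default) or `"exact"` enumeration.
#' @param inner_seed_policy `"per_permutation"` (default for Monte Carlo:
#'   fresh parameter draws each permutation, so tied statistics have
#'   probability zero) or `"per_relabeling"` (draw seed derived from the
#'   relabeling itself; forced for `method = "exact"`).
#' @param memoize_fits_below memoize the fitted models per distinct
#'   relabeling when the number of distinct relabelings is at most this
#'   (default 256).
#' @param random random-effect structure for the inner fits.
#' @param coding moderator coding.
#' @return an object of class `"permutation_result"`: `observed_diff`,
#'   `perm_diffs`, `p_value`, `n_perm`, `sidedness`, `method`, `n_failed`.
#' @export
permutation_test <- function(table,
                             direction = c("perception_behavior",
                                           "behavior_perception"),
                             modality = c("pain", "touch"),
                             n_perm = 1000, n_sims_inner = 200,
                             sidedness = c("two_sided_abs",
                                           "one_sided_exceed"),
                             seed = NULL, method = c("monte_carlo", "exact"),
                             inner_seed_policy = c("per_permutation",
                                                   "per_relabeling"),
                             memoize_fits_below = 256,
                             random = c("intercept_slope", "intercept"),
                             coding = c("reference", "effect")) {
  direction <- match.arg(direction)
  modality <- match.arg(modality)
  sidedness <- match.arg(sidedness)
  method <- match.arg(method)
  inner_seed_policy <- match.arg(inner_seed_policy)
  random <- match.arg(random)
  coding <- match.arg(coding)
  if (method == "exact") inner_seed_policy <- "per_relabeling"
  subj <- unique(table[, c("subject_id", "group")])
  subj <- subj[order(subj$subject_id), ]
  if (length(unique(subj$group)) != 2) stop("need a two-group table")
  all_ids <- subj$subject_id
  n1 <- sum(subj$group == "patient")
  base_seed <- seed %||% 0L
  vars <- switch(direction,
                 perception_behavior = c(m = "z_rating", y = "z_rt"),
                 behavior_perception = c(m = "z_rt", y = "z_rating"))
  ctrl <- lme4::lmerControl(
    calc.derivs = FALSE,
    check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4))

  fit_pair <- function(ids) {
    ## mediator + outcome fits for the subjects in `ids` (one relabeled group)
    sub <- table[table$subject_id %in% ids, , drop = FALSE]
    tryCatch(list(
      med = fit_lmm(sub, outcome = vars[["m"]], mediator = NULL,
                    coding = coding, random = random, control = ctrl),
      out = fit_lmm(sub, outcome = vars[["y"]], mediator = vars[["m"]],
                    coding = coding, random = random, control = ctrl)
    ), error = function(e) NULL)
  }

  n_distinct <- choose(length(all_ids), n1)
  use_memo <- is.finite(n_distinct) && n_distinct <= memoize_fits_below
  cache <- new.env(parent = emptyenv())
  fits_for <- function(group1_ids) {
    group2_ids <- setdiff(all_ids, group1_ids)
    get1 <- function(ids) {
      if (!use_memo) return(fit_pair(ids))
      k <- paste(ids, collapse = "|")
      if (is.null(cache[[k]])) cache[[k]] <- list(value = fit_pair(ids))
      cache[[k]]$value
    }
    list(get1(sort(group1_ids)), get1(sort(group2_ids)))
  }

  ## under the per_relabeling policy the statistic itself is deterministic
  ## per relabeling, so it can be memoized one level up
  scache <- new.env(parent = emptyenv())
  prop_diff <- function(group1_ids, draw_seed) {
    if (inner_seed_policy == "per_relabeling" && use_memo) {
      k <- paste(sort(group1_ids), collapse = "|")
      if (is.null(scache[[k]])) {
        scache[[k]] <- list(value = prop_diff_raw(group1_ids, draw_seed))
      }
      return(scache[[k]]$value)
    }
    prop_diff_raw(group1_ids, draw_seed)
  }

  prop_diff_raw <- function(group1_ids, draw_seed) {
    fits <- fits_for(group1_ids)
    if (is.null(fits[[1]]) || is.null(fits[[2]])) return(NA_real_)
    sds <- derive_seeds(draw_seed, 2)
    vals <- vapply(1:2, function(i) {
      est <- tryCatch(
        estimate_effects(fits[[i]]$med, fits[[i]]$out,
                         n_sims = n_sims_inner, seed = sds[i]),
        error = function(e) NULL)
      if (is.null(est)) return(NA_real_)
      est$point[modality, "prop"]
    }, 0)
    vals[1] - vals[2]
  }

  seed_for <- function(group1_ids, perm_seed) {
    if (inner_seed_policy == "per_relabeling") {
      relabel_seed(base_seed, group1_ids, all_ids)
    } else {
      perm_seed
    }
  }

  obs_ids <- subj$subject_id[subj$group == "patient"]
  obs_seed <- seed_for(obs_ids, derive_seeds(base_seed + 2L, 1))
  observed <- prop_diff(obs_ids, obs_seed)
  if (is.na(observed)) stop("mediation failed on the observed grouping")

  count_q <- function(perm, obs) {
    if (sidedness == "two_sided_abs") sum(abs(perm) >= abs(obs) - 1e-12)
    else sum(perm >= obs - 1e-12)
  }

  n_failed <- 0L
  if (method == "exact") {
    if (n_distinct > 1e5) stop("exact enumeration infeasible: ",
                               n_distinct, " relabelings")
    combs <- utils::combn(all_ids, n1, simplify = FALSE)
    perm_diffs <- vapply(combs, function(ids)
      prop_diff(ids, seed_for(ids, NULL)), 0)
    n_failed <- sum(is.na(perm_diffs))
    if (n_failed > 0.1 * length(perm_diffs)) {
      stop("more than 10% of relabelings failed to converge")
    }
    ok <- !is.na(perm_diffs)
    p <- count_q(perm_diffs[ok], observed) / sum(ok)
    n_used <- sum(ok)
  } else {
    perm_seeds <- derive_seeds(base_seed + 1L, 2L * n_perm)
    perm_diffs <- numeric(n_perm)
    for (i in seq_len(n_perm)) {
      d <- NA_real_
      for (retry in 1:3) {
        ids <- permute_group_labels(all_ids, n1,
                                    seed = perm_seeds[i] + (retry - 1L))
        d <- prop_diff(ids, seed_for(ids, perm_seeds[n_perm + i] + retry))
        if (!is.na(d)) break
      }
      if (is.na(d)) n_failed <- n_failed + 1L
      perm_diffs[i] <- d
    }
    if (n_failed > 0.1 * n_perm) {
      stop("more than 10% of permutations failed to converge")
    }
    ok <- !is.na(perm_diffs)
    p <- (count_q(perm_diffs[ok], observed) + 1) / (sum(ok) + 1)
    n_used <- sum(ok)
  }
  structure(list(
    observed_diff = observed,
    perm_diffs = perm_diffs,
    p_value = p,
    n_perm = n_used,
    sidedness = sidedness,
    method = method,
    inner_seed_policy = inner_seed_policy,
    direction = direction,
    modality = modality,
    n_sims_inner = n_sims_inner,
    seed = seed,
    n_failed = n_failed
  ), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("Permutation test of the group difference in proportion mediated\n")
  cat(sprintf("  model: %s, modality: %s\n", sub("_", "-", x$direction),
              x$modality))
  cat(sprintf("  observed difference (patients - controls): %.4f\n",
              x$observed_diff))
  cat(sprintf("  %s, %d %s, inner draws %d\n", x$sidedness, x$n_perm,
              if (x$method == "exact") "relabelings (exact)" else
                "permutations", x$n_sims_inner))
  cat(sprintf("  p = %.4g\n", x$p_value))
  invisible(x)
}
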