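## Orchestration: full analysis pipeline and simulation-based power.

#' Run the full analysis pipeline
#'
#' Generate-or-read, exclude, center, z-score, then per group and model
#' direction: fit the mixed models, run Monte-Carlo mediation, compute
#' modality-difference p values and original-unit effects; optionally run
#' the permutation tests of the group difference in proportion mediated;
#' and compute the repeated-measures ANOVAs on cell means. One master seed
#' deterministically derives every stage seed (see [derive_seeds()]), so a
#' bundle is reproducible bit-for-bit from its manifest.
#'
#' @param input a [trial_config()] (data are generated), a path to a trial
#'   CSV, or a trial-table data frame.
#' @param seed master seed (required).
#' @param directions model directions to run.
#' @param n_sims Monte-Carlo draws for the headline estimates.
#' @param n_perm permutations for the group test; `0` skips it.
#' @param n_sims_inner Monte-Carlo draws inside permutations.
#' @param sidedness permutation sidedness, see [permutation_test()].
#' @param rt_outlier_pool,coding,random passed through to the stages.
#' @param out_dir optional directory: the generated/filtered table (CSV)
#'   and a JSON results summary are written there.
#' @return an object of class `"results_bundle"`.
#' @export
run_full_analysis <- function(input, seed,
                              directions = c("perception_behavior",
                                             "behavior_perception"),
                              n_sims = 1000, n_perm = 0, n_sims_inner = 200,
                              sidedness = "two_sided_abs",
                              rt_outlier_pool = "modality",
                              coding = "reference",
                              random = "intercept_slope",
                              out_dir = NULL) {
  stopifnot(!missing(seed))
  seeds <- derive_seeds(seed, 4)
  raw <- if (inherits(input, "trial_config")) {
    generate_trials(input, seed = seeds[1])
  } else if (is.character(input)) {
    read_trials(input, strict = FALSE)
  } else if (is.data.frame(input)) {
    input
  } else stop("input must be a trial_config, a file path, or a data frame")

  pp <- preprocess_trials(raw, rt_outlier_pool = rt_outlier_pool)
  groups <- intersect(GROUP_LEVELS, unique(pp$table$group))
  med_seeds <- derive_seeds(seeds[2], length(groups) * length(directions))
  mediations <- list()
  k <- 0L
  for (g in groups) {
    for (dir in directions) {
      k <- k + 1L
      fit <- mediate_trials(pp$table, direction = dir, group = g,
                            n_sims = n_sims, seed = med_seeds[k],
                            coding = coding, random = random)
      effs <- c("me", "de", "prop")
      fit$modality_p <- lapply(
        stats::setNames(effs, effs),
        function(e) modality_difference_p(fit$estimate, e))
      mediations[[paste(g, dir, sep = ".")]] <- fit
    }
  }

  permutations <- list()
  if (n_perm > 0 && length(groups) == 2) {
    perm_seeds <- derive_seeds(seeds[3], length(directions) * 2L)
    k <- 0L
    for (dir in directions) {
      for (m in MODALITY_LEVELS) {
        k <- k + 1L
        permutations[[paste(dir, m, sep = ".")]] <-
          permutation_test(pp$table, direction = dir, modality = m,
                           n_perm = n_perm, n_sims_inner = n_sims_inner,
                           sidedness = sidedness, seed = perm_seeds[k],
                           random = random, coding = coding)
      }
    }
  }

  cells <- cell_means(pp$table)
  anovas <- list(rating = mixed_anova(cells, "rating"),
                 rt_ms = mixed_anova(cells, "rt_ms"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("psymediate")),
    r_version = as.character(getRversion()),
    master_seed = as.integer(seed),
    stage_seeds = seeds,
    config_hash = config_hash(list(
      input = if (inherits(input, "trial_config")) unclass(input) else "file",
      directions = directions, n_sims = n_sims, n_perm = n_perm,
      n_sims_inner = n_sims_inner, sidedness = sidedness,
      rt_outlier_pool = rt_outlier_pool, coding = coding, random = random)),
    n_trials_input = nrow(raw),
    n_trials_retained = pp$report$n_retained
  )

  bundle <- structure(list(
    exclusion = pp$report,
    mediations = mediations,
    permutations = permutations,
    anovas = anovas,
    cells = cells,
    table = pp$table,
    manifest = manifest
  ), class = "results_bundle")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trials(pp$table, file.path(out_dir, "trials_preprocessed.csv"))
    jsonlite::write_json(bundle_summary(bundle),
                         file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  bundle
}

#' Plain-list summary of a results bundle (JSON-ready)
#'
#' @param bundle a [run_full_analysis()] result.
#' @return nested list of scalars and vectors.
#' @export
bundle_summary <- function(bundle) {
  med <- lapply(bundle$mediations, function(f) {
    est <- f$estimate
    list(
      direction = f$direction, group = f$group,
      point = as.data.frame.table(est$point, responseName = "value"),
      ci = lapply(est$ci, function(m) as.data.frame(m)),
      significant_me = as.list(est$significant_me),
      modality_p = lapply(f$modality_p, function(p)
        list(p_value = p$p_value, difference = p$difference)),
      original_units = if (!is.null(f$units)) {
        list(variable = f$units$variable, units = f$units$units,
             point = as.data.frame(f$units$point))
      }
    )
  })
  perm <- lapply(bundle$permutations, function(p) {
    list(observed_diff = p$observed_diff, p_value = p$p_value,
         n_perm = p$n_perm, sidedness = p$sidedness)
  })
  anova <- lapply(bundle$anovas, function(a) as.data.frame(a))
  list(
    exclusion = bundle$exclusion[c("n_input", "n_misidentified",
                                   "n_zero_rating", "n_rt_outlier",
                                   "n_retained")],
    mediation = med,
    permutation = perm,
    anova = anova,
    manifest = bundle$manifest
  )
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("== psymediate results bundle ==\n\n")
  print(x$exclusion)
  for (nm in names(x$mediations)) {
    cat("\n")
    print(x$mediations[[nm]])
  }
  for (nm in names(x$permutations)) {
    cat("\n")
    print(x$permutations[[nm]])
  }
  cat("\nmanifest: seed", x$manifest$master_seed, "config",
      substr(x$manifest$config_hash, 1, 8), "\n")
  invisible(x)
}

#' Simulation-based power analysis for the mediation design
#'
#' For each row of a design grid (subjects per group, a- and b-paths,
#' trials per cell per block), repeatedly generates data, runs the full
#' preprocessing and mediation pipeline on the patient group, and records
#' how often the mediation effect is significant (its CI excludes zero)
#' for the chosen modality. With `a = b = 0` the reported power is the
#' empirical type-I error of the CI-based test.
#'
#' @param base_config a [trial_config()] used for every non-grid setting.
#' @param grid data frame with any of the columns `n_subjects`, `a`, `b`,
#'   `n_trials` (trials per cell per block).
#' @param n_replicates simulated datasets per grid point.
#' @param seed master seed.
#' @param direction model direction analysed.
#' @param modality modality whose ME is tested.
#' @param n_sims Monte-Carlo draws per replicate.
#' @return the grid with an added `power` column (and `n_replicates`).
#' @export
power_analysis <- function(base_config, grid, n_replicates = 100, seed = 1,
                           direction = "behavior_perception",
                           modality = "pain", n_sims = 300) {
  stopifnot(inherits(base_config, "trial_config"), is.data.frame(grid))
  grid$power <- NA_real_
  seeds <- derive_seeds(seed, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- base_config
    if (!is.null(grid$n_subjects)) {
      cfg$n_subjects_per_group <- as.integer(grid$n_subjects[i])
    }
    if (!is.null(grid$n_trials)) {
      cfg$trials_per_cell_per_block <- as.integer(grid$n_trials[i])
    }
    for (g in GROUP_LEVELS) {
      if (!is.null(grid$a)) cfg$paths[[g]][[modality]]["a"] <- grid$a[i]
      if (!is.null(grid$b)) cfg$paths[[g]][[modality]]["b"] <- grid$b[i]
    }
    rep_seeds <- derive_seeds(seeds[i], n_replicates)
    hits <- vapply(seq_len(n_replicates), function(r) {
      d <- generate_trials(cfg, seed = rep_seeds[r])
      d <- d[d$group == "patient", , drop = FALSE]
      pp <- suppressWarnings(preprocess_trials(d))
      fit <- tryCatch(
        mediate_trials(pp$table, direction = direction, group = "patient",
                       n_sims = n_sims, seed = rep_seeds[r]),
        error = function(e) NULL)
      if (is.null(fit)) return(NA)
      unname(fit$estimate$significant_me[modality])
    }, NA)
    grid$power[i] <- mean(hits, na.rm = TRUE)
  }
  grid$n_replicates <- n_replicates
  grid
}
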