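## Trial exclusion, intensity centering, and stratified z-scoring.

#' Apply the trial-exclusion rules
#'
#' Excludes, in this order: (1) trials whose modality was not correctly
#' identified; (2) trials rated 0; (3) reaction-time outliers — per subject
#' (and by default per modality), trials whose RT lies more than 2 sample
#' SDs from that subject's mean RT, with mean and SD computed over the
#' trials surviving rules (1)-(2). The outlier pass is a single pass: the
#' mean and SD are not recomputed after removals, and a trial is counted
#' under the first rule that catches it.
#'
#' Cells with fewer than 3 surviving trials before step (3) are left
#' untrimmed with a warning. Exclusion must run exactly once: a
#' processing-stage flag is stored in the table's metadata and a second
#' call errors, since re-trimming an already trimmed RT distribution would
#' remove additional trials.
#'
#' @param table a trial-table data frame.
#' @param rt_outlier_pool `"modality"` (default): outlier mean/SD per
#'   subject x modality; `"all"`: per subject, pooling modalities.
#' @return list with elements `table` (the filtered trial table) and
#'   `report` (an `"exclusion_report"`: counts per rule and retained trial
#'   counts per subject x modality x intensity cell).
#' @export
exclude_trials <- function(table, rt_outlier_pool = c("modality", "all")) {
  rt_outlier_pool <- match.arg(rt_outlier_pool)
  if (nrow(table) == 0) stop("empty trial table")
  if (isTRUE(trial_meta(table)$excluded)) {
    stop("exclude_trials() was already applied to this table; ",
         "the exclusion step must run exactly once")
  }
  n_input <- nrow(table)
  status <- rep("retained", n_input)
  status[!table$modality_correct] <- "misidentified"
  status[status == "retained" & table$rating == 0] <- "zero_rating"
  surv <- status == "retained"
  key <- if (rt_outlier_pool == "modality") {
    paste(table$subject_id, table$modality)
  } else {
    table$subject_id
  }
  skipped <- character(0)
  for (k in unique(key[surv])) {
    i <- which(surv & key == k)
    if (length(i) < 3) {
      skipped <- c(skipped, k)
      next
    }
    mu <- mean(table$rt_ms[i])
    sd_ <- stats::sd(table$rt_ms[i])
    out <- abs(table$rt_ms[i] - mu) > 2 * sd_
    status[i[out]] <- "rt_outlier"
  }
  if (length(skipped)) {
    warning("RT-outlier step skipped for cell(s) with < 3 surviving trials: ",
            paste(skipped, collapse = ", "))
  }
  keep <- status == "retained"
  kept <- table[keep, , drop = FALSE]
  rownames(kept) <- NULL
  counts <- table(subject_id = kept$subject_id, modality = kept$modality,
                  intensity_level = kept$intensity_level)
  report <- structure(list(
    n_input = n_input,
    n_misidentified = sum(status == "misidentified"),
    n_zero_rating = sum(status == "zero_rating"),
    n_rt_outlier = sum(status == "rt_outlier"),
    n_retained = sum(keep),
    rt_outlier_pool = rt_outlier_pool,
    skipped_cells = skipped,
    per_cell_counts = counts
  ), class = "exclusion_report")
  meta <- trial_meta(table)
  meta$excluded <- TRUE
  meta$exclusion <- report[c("n_input", "n_misidentified", "n_zero_rating",
                             "n_rt_outlier", "n_retained")]
  trial_meta(kept) <- meta
  list(table = kept, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Trial exclusion report\n")
  cat(sprintf("  input trials     %6d\n", x$n_input))
  cat(sprintf("  misidentified    %6d\n", x$n_misidentified))
  cat(sprintf("  zero ratings     %6d\n", x$n_zero_rating))
  cat(sprintf("  RT outliers (2SD)%6d  (pool: %s)\n",
              x$n_rt_outlier, x$rt_outlier_pool))
  cat(sprintf("  retained         %6d  (%.1f%%)\n", x$n_retained,
              100 * x$n_retained / x$n_input))
  invisible(x)
}

#' Center stimulus intensity
#'
#' Adds a `centered_intensity` column mapping intensity level 1/2/3 to
#' -1/0/+1. All other columns are unchanged.
#'
#' @param table a trial-table data frame.
#' @return the table with a `centered_intensity` column.
#' @export
center_intensity <- function(table) {
  if (!all(table$intensity_level %in% 1:3)) {
    stop("intensity_level must be in {1, 2, 3}")
  }
  table$centered_intensity <- table$intensity_level - 2L
  table
}

#' Z-score ratings and reaction times within strata
#'
#' Standardizes `rating` and `rt_ms` within each stratum (default: group x
#' modality, so that modality- or group-specific differences in rating and
#' RT distributions do not leak into the standardized variables), using the
#' sample SD (denominator n - 1). Adds `z_rating` and `z_rt` columns,
#' preserves the originals, and stores the stratum means and SDs in the
#' table's metadata so that standardized effects can later be expressed in
#' original units (NRS points, ms).
#'
#' @param table a trial-table data frame.
#' @param strata character vector of column names defining the strata
#'   (default `c("group", "modality")`).
#' @return the table with `z_rating` and `z_rt` columns and `z_stats` in
#'   its metadata.
#' @export
zscore_by_stratum <- function(table, strata = c("group", "modality")) {
  stopifnot(all(strata %in% names(table)))
  key <- interaction(table[strata], drop = TRUE, sep = ":")
  stats_rows <- list()
  table$z_rating <- NA_real_
  table$z_rt <- NA_real_
  for (k in levels(key)) {
    i <- which(key == k)
    if (length(i) < 2) stop("stratum ", k, " has fewer than 2 trials")
    for (v in c("rating", "rt_ms")) {
      mu <- mean(table[[v]][i])
      sd_ <- stats::sd(table[[v]][i])
      if (sd_ == 0) stop("zero variance for ", v, " in stratum ", k)
      zcol <- if (v == "rating") "z_rating" else "z_rt"
      table[[zcol]][i] <- (table[[v]][i] - mu) / sd_
      stats_rows[[length(stats_rows) + 1L]] <- data.frame(
        stratum = k, variable = v, mean = mu, sd = sd_,
        stringsAsFactors = FALSE)
    }
  }
  zs <- do.call(rbind, stats_rows)
  zs <- cbind(do.call(rbind, strsplit(zs$stratum, ":", fixed = TRUE)), zs)
  colnames(zs)[seq_along(strata)] <- strata
  meta <- trial_meta(table)
  meta$z_strata <- strata
  meta$z_stats <- zs
  trial_meta(table) <- meta
  table
}

#' Full preprocessing pipeline
#'
#' Convenience wrapper: [exclude_trials()], [center_intensity()],
#' [zscore_by_stratum()], in that order.
#'
#' @inheritParams exclude_trials
#' @inheritParams zscore_by_stratum
#' @return list with `table` (preprocessed trial table) and `report`
#'   (exclusion report).
#' @export
preprocess_trials <- function(table, rt_outlier_pool = c("modality", "all"),
                              strata = c("group", "modality")) {
  ex <- exclude_trials(table, rt_outlier_pool = rt_outlier_pool)
  out <- zscore_by_stratum(center_intensity(ex$table), strata = strata)
  list(table = out, report = ex$report)
}
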