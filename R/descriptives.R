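## Supporting statistics: subject-level cell means, mixed between-within
## repeated-measures ANOVA, and Pearson correlations for covariate checks.

#' Subject-level cell means
#'
#' Aggregates retained trials to per-subject means of rating and reaction
#' time in each of the 6 within-subject cells (2 modalities x 3 intensity
#' levels). Subjects with any empty cell are dropped listwise (their ids
#' are recorded in the `dropped` attribute and reported via a message).
#'
#' @param table a (preprocessed) trial table.
#' @return data frame with columns `subject_id`, `group`, `modality`,
#'   `intensity_level`, `rating`, `rt_ms` — one row per subject x cell.
#' @export
cell_means <- function(table) {
  agg <- stats::aggregate(
    table[, c("rating", "rt_ms")],
    by = list(subject_id = table$subject_id, group = table$group,
              modality = table$modality,
              intensity_level = table$intensity_level),
    FUN = mean)
  n_cells <- table(agg$subject_id)
  dropped <- names(n_cells)[n_cells < 6]
  if (length(dropped)) {
    message("cell_means: dropped subject(s) with empty cells: ",
            paste(dropped, collapse = ", "))
    agg <- agg[!(agg$subject_id %in% dropped), , drop = FALSE]
  }
  agg <- agg[order(agg$subject_id, agg$modality, agg$intensity_level), ]
  rownames(agg) <- NULL
  attr(agg, "dropped") <- dropped
  agg
}

#' Mixed between-within repeated-measures ANOVA
#'
#' Classical univariate mixed-design decomposition on subject-level cell
#' means: the between-subject factor group is tested against
#' subjects-within-groups; each within-subject effect (modality, intensity,
#' their interaction, and their interactions with group) is tested against
#' its own subject-by-effect error stratum. F tests are uncorrected by
#' default; `gg = TRUE` additionally applies the Greenhouse-Geisser
#' sphericity correction to within-effect p values.
#'
#' @param cells a [cell_means()] data frame.
#' @param variable `"rating"` or `"rt_ms"`.
#' @param gg logical; add Greenhouse-Geisser-corrected p values.
#' @return an object of class `"anova_table"`: data frame with one row per
#'   effect (`df`, `ss`, `ms`, `error_df`, `error_ss`, `F`, `p`,
#'   `partial_eta_sq`, optionally `gg_epsilon`, `p_gg`).
#' @export
mixed_anova <- function(cells, variable = c("rating", "rt_ms"), gg = FALSE) {
  variable <- match.arg(variable)
  d <- data.frame(
    value = cells[[variable]],
    subject = factor(cells$subject_id),
    group = factor(cells$group),
    modality = factor(cells$modality),
    intensity = factor(cells$intensity_level)
  )
  if (any(table(d$subject) != 6)) {
    stop("design unbalanced: every subject needs all 6 cells ",
         "(use cell_means(), which drops incomplete subjects)")
  }
  if (min(table(unique(d[, c("subject", "group")])$group)) < 2) {
    stop("need at least 2 subjects per group")
  }
  fit <- stats::aov(value ~ group * modality * intensity +
                      Error(subject / (modality * intensity)), data = d)
  rows <- list()
  for (stratum in summary(fit)) {
    tab <- stratum[[1]]
    eff <- trimws(rownames(tab))
    res <- eff == "Residuals"
    err_df <- tab[res, "Df"]; err_ss <- tab[res, "Sum Sq"]
    for (i in which(!res)) {
      ss <- tab[i, "Sum Sq"]
      ms <- tab[i, "Mean Sq"]
      ms_err <- err_ss / err_df
      degenerate <- ss < 1e-12
      F_ <- if (degenerate) 0 else ms / ms_err
      p <- if (degenerate) 1 else
        stats::pf(F_, tab[i, "Df"], err_df, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        effect = eff[i], df = tab[i, "Df"], ss = ss, ms = ms,
        error_df = err_df, error_ss = err_ss, F = F_, p = p,
        partial_eta_sq = if (ss + err_ss > 0) ss / (ss + err_ss) else 0,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (gg) {
    out$gg_epsilon <- NA_real_
    out$p_gg <- out$p
    eps <- gg_epsilons(d, variable = "value")
    for (i in seq_len(nrow(out))) {
      within <- gsub("group:?", "", out$effect[i])
      within <- gsub("^:|:$", "", within)
      if (within %in% names(eps)) {
        e <- eps[[within]]
        out$gg_epsilon[i] <- e
        if (out$F[i] > 0) {
          out$p_gg[i] <- stats::pf(out$F[i], e * out$df[i],
                                   e * out$error_df[i], lower.tail = FALSE)
        }
      }
    }
  }
  rownames(out) <- NULL
  class(out) <- c("anova_table", "data.frame")
  out
}

## Greenhouse-Geisser epsilon per within-subject effect, from the pooled
## within-group covariance of the 6 cell scores.
gg_epsilons <- function(d, variable) {
  ## subjects x cells score matrix, cells ordered intensity-major
  key <- interaction(d$modality, d$intensity, sep = ".")
  mat <- matrix(NA_real_, nrow = nlevels(d$subject), ncol = nlevels(key),
                dimnames = list(levels(d$subject), levels(key)))
  mat[cbind(as.integer(d$subject), as.integer(key))] <- d[[variable]]
  grp <- d$group[match(rownames(mat), d$subject)]
  S <- Reduce(`+`, lapply(split.data.frame(mat, grp), function(m) {
    stats::cov(m) * (nrow(m) - 1)
  })) / (nrow(mat) - nlevels(grp))
  cm <- function(k) {  # orthonormal polynomial-style contrasts, k-1 x k
    t(qr.Q(qr(cbind(1, stats::contr.poly(k))))[, -1, drop = FALSE])
  }
  nm <- nlevels(d$modality); ni <- nlevels(d$intensity)
  ones_m <- matrix(1 / sqrt(nm), 1, nm); ones_i <- matrix(1 / sqrt(ni), 1, ni)
  C <- list(
    modality = kronecker(ones_i, cm(nm)),
    intensity = kronecker(cm(ni), ones_m),
    `modality:intensity` = kronecker(cm(ni), cm(nm))
  )
  lapply(C, function(Cm) {
    E <- Cm %*% S %*% t(Cm)
    sum(diag(E))^2 / (nrow(E) * sum(E^2))
  })
}

#' @export
print.anova_table <- function(x, ...) {
  cat("Mixed between-within repeated-measures ANOVA\n")
  y <- as.data.frame(x)
  y$ss <- signif(y$ss, 5); y$ms <- signif(y$ms, 5)
  y$F <- round(y$F, 2); y$p <- signif(y$p, 3)
  y$partial_eta_sq <- round(y$partial_eta_sq, 3)
  y$error_ss <- signif(y$error_ss, 5)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Pearson correlation with two-sided p value
#'
#' Sample Pearson correlation and the two-sided p value from the t
#' transform with n - 2 degrees of freedom, for per-subject covariate
#' checks (e.g. medication load vs averaged ratings).
#'
#' @param x,y paired numeric vectors (>= 3 complete pairs, both with
#'   nonzero variance).
#' @return list with `r`, `p`, `n`, `df`, `t`.
#' @export
pearson_correlations <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       df = unname(ct$parameter), t = unname(ct$statistic))
}
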