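## Linear mixed models behind the mediation engine.
##
## Two models per group: a mediator model z_m ~ x * w and an outcome model
## z_y ~ x * w + m * w, each with per-subject random intercepts and
## (by default) random intensity slopes, fitted by REML via lme4::lmer.
## The mediation engine consumes only the minimal fit contract stored in
## an "lmm_fit" object: fixed effects, their model-based covariance, and
## variance components.

#' Numeric coding of the moderator (stimulus modality)
#'
#' @param modality character vector of `"pain"` / `"touch"`.
#' @param coding `"reference"` (touch = 0, pain = 1, default) or `"effect"`
#'   (touch = -0.5, pain = +0.5). Per-modality mediation paths are invariant
#'   to this choice.
#' @return numeric vector.
#' @export
moderator_coding <- function(modality, coding = c("reference", "effect")) {
  coding <- match.arg(coding)
  if (!all(modality %in% MODALITY_LEVELS)) stop("unknown modality value")
  w <- as.numeric(modality == "pain")
  if (coding == "effect") w <- w - 0.5
  w
}

#' Numeric moderator values at which effects are evaluated
#' @keywords internal
#' @noRd
moderator_levels <- function(coding) {
  c(pain = moderator_coding("pain", coding),
    touch = moderator_coding("touch", coding))
}

#' Fit a linear mixed model for the mediation pipeline
#'
#' Fits `outcome ~ x * w [+ m * w] + (1 + x | subject)` by REML (default)
#' on a preprocessed single-group trial table, where `x` is centered
#' intensity, `w` the numeric modality code and `m` the standardized
#' mediator. With all random-effect variances truly zero and balanced data
#' the fixed effects equal the ordinary-least-squares solution; the
#' returned covariance is the standard model-based covariance of the fixed
#' effects. If the optimizer fails to converge, the model is refitted
#' without the random intensity slope; if that also fails, an error is
#' raised.
#'
#' @param table preprocessed trial table (needs `centered_intensity`,
#'   `z_rating`, `z_rt`).
#' @param outcome name of the response column (e.g. `"z_rt"`).
#' @param mediator optional name of the mediator column; when given, `m`
#'   and `m:w` enter the fixed effects (outcome model).
#' @param coding moderator coding, see [moderator_coding()].
#' @param random `"intercept_slope"` (default) or `"intercept"`.
#' @param reml logical, REML (default) or ML.
#' @param control an optional [lme4::lmerControl()] object.
#' @return an object of class `"lmm_fit"`: list with `beta`, `vcov_beta`,
#'   `sigma2_resid`, `random_effect_variances`, `loglik`, `converged`,
#'   `n_obs`, `n_subjects`, `formula`, `coding`, and the underlying
#'   `merMod` fit in `$fit`.
#' @export
fit_lmm <- function(table, outcome, mediator = NULL,
                    coding = c("reference", "effect"),
                    random = c("intercept_slope", "intercept"),
                    reml = TRUE, control = NULL) {
  coding <- match.arg(coding)
  random <- match.arg(random)
  need <- c("centered_intensity", outcome, mediator, "subject_id", "modality")
  missing <- setdiff(need, names(table))
  if (length(missing)) {
    stop("table lacks column(s) ", paste(missing, collapse = ", "),
         "; run preprocess_trials() first")
  }
  if (length(unique(table$subject_id)) < 2) stop("need at least 2 subjects")
  d <- data.frame(
    y = table[[outcome]],
    x = table$centered_intensity,
    w = moderator_coding(table$modality, coding),
    subject = factor(table$subject_id)
  )
  rhs <- "x * w"
  if (!is.null(mediator)) {
    d$m <- table[[mediator]]
    rhs <- paste(rhs, "+ m * w")
  }
  re <- if (random == "intercept_slope") "(1 + x | subject)" else
    "(1 | subject)"
  form <- stats::as.formula(paste("y ~", rhs, "+", re))
  ctrl <- control %||% lme4::lmerControl(
    calc.derivs = FALSE,
    check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4))
  fit <- try_lmer(form, d, reml, ctrl)
  converged <- attr(fit, "converged")
  if (!converged && random == "intercept_slope") {
    form2 <- stats::as.formula(paste("y ~", rhs, "+ (1 | subject)"))
    refit <- try_lmer(form2, d, reml, ctrl)
    if (attr(refit, "converged")) {
      message("fit_lmm: random intensity slope dropped after non-convergence")
      fit <- refit
      form <- form2
      converged <- TRUE
    }
  }
  if (inherits(fit, "error")) {
    stop("linear mixed model failed to fit: ", conditionMessage(fit))
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  rev_ <- vc$vcov[is.na(vc$var2) & vc$grp != "Residual"]
  names(rev_) <- vc$var1[is.na(vc$var2) & vc$grp != "Residual"]
  structure(list(
    beta = lme4::fixef(fit),
    vcov_beta = as.matrix(stats::vcov(fit)),
    sigma2_resid = stats::sigma(fit)^2,
    random_effect_variances = rev_,
    loglik = as.numeric(stats::logLik(fit)),
    converged = converged,
    n_obs = nrow(d),
    n_subjects = nlevels(d$subject),
    outcome = outcome,
    mediator = mediator,
    formula = form,
    coding = coding,
    reml = reml,
    fit = fit
  ), class = "lmm_fit")
}

try_lmer <- function(formula, data, reml, control) {
  warned <- FALSE
  fit <- withCallingHandlers(
    tryCatch(lme4::lmer(formula, data = data, REML = reml, control = control),
             error = function(e) e),
    warning = function(w) {
      if (grepl("converge", conditionMessage(w), ignore.case = TRUE)) {
        warned <<- TRUE
      }
      invokeRestart("muffleWarning")
    })
  attr(fit, "converged") <- !inherits(fit, "error") && !warned
  fit
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Linear mixed model (", if (x$reml) "REML" else "ML", "): ",
      deparse(x$formula), "\n", sep = "")
  cat(sprintf("  %d observations, %d subjects; converged: %s\n",
              x$n_obs, x$n_subjects, x$converged))
  out <- cbind(estimate = x$beta, se = sqrt(diag(x$vcov_beta)))
  print(round(out, 4))
  cat("Random-effect variances:",
      paste(sprintf("%s=%.4g", names(x$random_effect_variances),
                    x$random_effect_variances), collapse = ", "),
      "; residual", signif(x$sigma2_resid, 4), "\n")
  invisible(x)
}

#' @export
coef.lmm_fit <- function(object, ...) object$beta

#' @export
vcov.lmm_fit <- function(object, ...) object$vcov_beta

#' @export
logLik.lmm_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$beta), class = "logLik")
}
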