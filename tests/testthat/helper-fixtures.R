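# Shared fixture builders. All fixtures are constructed in code; nothing is
# read from disk except where file I/O itself is under test.

# minimal hand-built trial table
make_trials <- function(n, subject_id = "S1", group = "patient",
                        modality = "pain", intensity_level = 2,
                        stimulus_magnitude = 500, rating = 50, rt_ms = 400,
                        modality_correct = TRUE, block = 1) {
  d <- data.frame(
    subject_id = rep_len(subject_id, n),
    group = rep_len(group, n),
    modality = rep_len(modality, n),
    intensity_level = rep_len(as.integer(intensity_level), n),
    stimulus_magnitude = rep_len(stimulus_magnitude, n),
    rating = rep_len(rating, n),
    rt_ms = rep_len(rt_ms, n),
    modality_correct = rep_len(modality_correct, n),
    block = rep_len(as.integer(block), n),
    stringsAsFactors = FALSE
  )
  d$trial <- stats::ave(seq_len(n), d$subject_id, d$block, FUN = seq_along)
  d
}

# config with every mediation path identical across groups and modalities
uniform_config <- function(a, b, c_prime, ...) {
  p <- path_coef(a, b, c_prime)
  trial_config(paths = list(patient = list(pain = p, touch = p),
                            control = list(pain = p, touch = p)), ...)
}

# synthetic lmm_fit with hand-set coefficients (zero-uncertainty oracle)
fake_fit <- function(beta, vcov = NULL, coding = "reference",
                     outcome = "z_rating", mediator = NULL) {
  if (is.null(vcov)) vcov <- matrix(0, length(beta), length(beta))
  dimnames(vcov) <- list(names(beta), names(beta))
  structure(list(beta = beta, vcov_beta = vcov, sigma2_resid = 1,
                 random_effect_variances = c(`(Intercept)` = 0),
                 loglik = NA_real_, converged = TRUE,
                 n_obs = 100L, n_subjects = 10L, outcome = outcome,
                 mediator = mediator, formula = NULL, coding = coding,
                 reml = TRUE, fit = NULL),
            class = "lmm_fit")
}

# mediator/outcome fake-fit pair with per-level paths
# a etc. given as c(touch = , pain = ) values; reference coding
fake_pair <- function(a_touch, a_pain, b_touch, b_pain, cp_touch, cp_pain,
                      vcov_scale = 0) {
  med_beta <- c(`(Intercept)` = 0, x = a_touch, w = 0,
                `x:w` = a_pain - a_touch)
  out_beta <- c(`(Intercept)` = 0, x = cp_touch, w = 0, m = b_touch,
                `x:w` = cp_pain - cp_touch, `w:m` = b_pain - b_touch)
  list(
    med = fake_fit(med_beta, diag(vcov_scale, 4, 4) |>
                     `dimnames<-`(list(names(med_beta), names(med_beta))),
                   outcome = "z_rt"),
    out = fake_fit(out_beta, diag(vcov_scale, 6, 6) |>
                     `dimnames<-`(list(names(out_beta), names(out_beta))),
                   outcome = "z_rating", mediator = "z_rt")
  )
}

quiet_preprocess <- function(d, ...) {
  suppressWarnings(suppressMessages(preprocess_trials(d, ...)))
}
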