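## Synthetic trial generator.
##
## Emulates the two-group (chronic pain patients vs healthy controls),
## two-modality (laser pain / von Frey touch), three-intensity paradigm:
## 4 blocks of 54 pseudorandomized trials (9 per modality x intensity cell),
## i.e. 108 pain and 108 touch trials per subject. The mediation structure
## is generated on standardized latent scales and mapped affinely to
## observable ratings (0-100 NRS) and reaction times (ms).

#' Path coefficients for one group x modality cell
#'
#' @param a standardized stimulus-to-mediator slope per intensity level.
#' @param b standardized mediator-to-outcome slope.
#' @param c_prime standardized direct stimulus-to-outcome slope.
#' @return named numeric vector `c(a, b, c_prime)`.
#' @export
path_coef <- function(a, b, c_prime) {
  c(a = as.numeric(a), b = as.numeric(b), c_prime = as.numeric(c_prime))
}

#' Path coefficients implying a given proportion mediated
#'
#' Convenience constructor: given the target proportion mediated
#' `prop = ab / (ab + c')`, the total standardized effect and the a-path,
#' solves for b and c'.
#'
#' @param prop target proportion mediated.
#' @param total total standardized effect (`ab + c'`) per intensity level.
#' @param a stimulus-to-mediator slope.
#' @return named numeric vector as [path_coef()].
#' @export
#' @examples
#' p <- path_coef_for_prop(0.46, total = 0.147, a = 0.22)
#' unname(p["a"] * p["b"] / (p["a"] * p["b"] + p["c_prime"]))  # 0.46
path_coef_for_prop <- function(prop, total, a) {
  stopifnot(a != 0)
  me <- prop * total
  path_coef(a = a, b = me / a, c_prime = total - me)
}

default_paths <- function() {
  ## Back-computed from the published patient/control estimates of the
  ## behavior-perception model (mediator = reaction time, outcome = rating):
  ## a = total stimulus->behavior effect, b = ME / a, c' = DE.
  list(
    patient = list(pain  = path_coef(0.220, 0.30455, 0.08),
                   touch = path_coef(0.112, 0.06250, 0.32)),
    control = list(pain  = path_coef(0.140, 0.35714, 0.11),
                   touch = path_coef(0.040, -0.12500, 0.34))
  )
}

default_magnitudes <- function() {
  ## Mean (SD) calibrated stimulus magnitudes per intensity level:
  ## laser energies in mJ, von Frey forces in mN.
  list(
    patient = list(pain  = list(mean = c(479, 525, 571), sd = c(57, 59, 62)),
                   touch = list(mean = c(188, 290, 456), sd = c(73, 81, 91))),
    control = list(pain  = list(mean = c(490, 535, 581), sd = c(39, 37, 36)),
                   touch = list(mean = c(190, 306, 505), sd = c(68, 60, 32)))
  )
}

#' Configuration of the synthetic paradigm
#'
#' Full parameterization of the trial generator. The defaults reproduce the
#' paradigm's design (22 subjects per group, 4 blocks x 54 trials, 9 trials
#' per modality x intensity cell per block) and a mediation structure whose
#' per-modality proportions mediated match published patient/control
#' estimates (about 46\%/2\% for patients and 29\%/-2\% for controls in the
#' behavior-mediates direction).
#'
#' The generative model, per trial with centered intensity
#' \eqn{x \in \{-1, 0, 1\}}:
#' \deqn{M = a x + u_{0i} + u_{1i} x + \epsilon, \quad
#'       Y = c' x + b M + v_{0i} + v_{1i} x + \eta,}
#' with subject random effects \eqn{u, v} and residuals on standardized
#' latent scales. If `direction = "behavior_mediates"`, M maps to reaction
#' time (negated: a larger standardized behavior latent means a *faster*
#' response) and Y to the rating; `"perception_mediates"` swaps the roles;
#' `"none"` forces `b = 0`. Ratings are mapped affinely to the NRS
#' (`rating_anchor[2] + rating_scale * latent`, clipped to \[0, 100\]);
#' reaction times to `rt_mean_ms - rt_sd_ms * latent`, floored at 100 ms.
#'
#' @param n_subjects_per_group subjects per group (paradigm: 22).
#' @param n_blocks experimental blocks (paradigm: 4).
#' @param trials_per_cell_per_block trials per modality x intensity cell per
#'   block (paradigm: 9, i.e. 54-trial blocks and 108 trials per modality).
#' @param direction which observable is the mediator: `"behavior_mediates"`
#'   (reaction time mediates the intensity effect on ratings),
#'   `"perception_mediates"` (ratings mediate the effect on reaction times)
#'   or `"none"`.
#' @param paths nested list `paths[[group]][[modality]]` of [path_coef()]
#'   vectors on the standardized latent scale.
#' @param sd_subject_intercept_m,sd_subject_slope_m subject random-effect
#'   SDs for the mediator latent.
#' @param sd_subject_intercept_y,sd_subject_slope_y subject random-effect
#'   SDs for the outcome latent.
#' @param sd_resid_m,sd_resid_y trial-level residual SDs (latent scale).
#' @param rating_anchor calibration targets for low/medium/high ratings;
#'   the middle anchor centers the NRS map.
#' @param rating_scale NRS points per standardized latent unit.
#' @param rt_mean_ms mean reaction time in ms.
#' @param rt_sd_ms ms per standardized latent unit (approximately the
#'   observed RT standard deviation).
#' @param misident_rate probability a trial's modality is misidentified.
#' @param zero_rating_rate probability a trial is rated 0.
#' @param magnitudes nested list `magnitudes[[group]][[modality]]` with
#'   `mean` and `sd` triples of calibrated stimulus magnitudes per level.
#' @param order_method block-sequence sampler passed to
#'   [pseudorandom_sequence()]: `"greedy"` (default), `"rejection"`, or
#'   `"none"` for unconstrained shuffling.
#' @param seed default RNG seed used by [generate_trials()] when no seed is
#'   passed there.
#' @return an object of class `"trial_config"`.
#' @export
trial_config <- function(n_subjects_per_group = 22L,
                         n_blocks = 4L,
                         trials_per_cell_per_block = 9L,
                         direction = c("behavior_mediates",
                                       "perception_mediates", "none"),
                         paths = default_paths(),
                         sd_subject_intercept_m = 0.3,
                         sd_subject_slope_m = 0.1,
                         sd_subject_intercept_y = 0.3,
                         sd_subject_slope_y = 0.1,
                         sd_resid_m = 0.93,
                         sd_resid_y = 0.90,
                         rating_anchor = c(30, 50, 70),
                         rating_scale = 15,
                         rt_mean_ms = 500,
                         rt_sd_ms = 100,
                         misident_rate = 0.03,
                         zero_rating_rate = 0.01,
                         magnitudes = default_magnitudes(),
                         order_method = c("greedy", "rejection", "none"),
                         seed = NULL) {
  cfg <- list(
    n_subjects_per_group = as.integer(n_subjects_per_group),
    n_blocks = as.integer(n_blocks),
    trials_per_cell_per_block = as.integer(trials_per_cell_per_block),
    direction = match.arg(direction),
    paths = paths,
    sd_subject_intercept_m = sd_subject_intercept_m,
    sd_subject_slope_m = sd_subject_slope_m,
    sd_subject_intercept_y = sd_subject_intercept_y,
    sd_subject_slope_y = sd_subject_slope_y,
    sd_resid_m = sd_resid_m,
    sd_resid_y = sd_resid_y,
    rating_anchor = rating_anchor,
    rating_scale = rating_scale,
    rt_mean_ms = rt_mean_ms,
    rt_sd_ms = rt_sd_ms,
    misident_rate = misident_rate,
    zero_rating_rate = zero_rating_rate,
    magnitudes = magnitudes,
    order_method = match.arg(order_method),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "trial_config")
}

validate_config <- function(cfg) {
  sds <- c(cfg$sd_subject_intercept_m, cfg$sd_subject_slope_m,
           cfg$sd_subject_intercept_y, cfg$sd_subject_slope_y)
  if (any(sds < 0)) stop("random-effect SDs must be >= 0")
  if (cfg$sd_resid_m < 0 || cfg$sd_resid_y < 0) {
    ## zero residual SD is allowed: the fully degenerate noiseless case is
    ## useful for testing the observable maps
    stop("residual SDs must be >= 0")
  }
  for (r in c(cfg$misident_rate, cfg$zero_rating_rate)) {
    if (r < 0 || r >= 1) stop("rates must lie in [0, 1)")
  }
  if (length(cfg$rating_anchor) != 3 || any(diff(cfg$rating_anchor) <= 0)) {
    stop("rating_anchor must be three increasing values")
  }
  if (cfg$n_subjects_per_group < 1 || cfg$n_blocks < 1 ||
      cfg$trials_per_cell_per_block < 1) {
    stop("design counts must be positive integers")
  }
  for (g in GROUP_LEVELS) {
    for (m in MODALITY_LEVELS) {
      p <- cfg$paths[[g]][[m]]
      if (is.null(p) || !all(c("a", "b", "c_prime") %in% names(p))) {
        stop("paths must provide a/b/c_prime for ", g, " x ", m)
      }
    }
  }
  invisible(cfg)
}

#' @export
print.trial_config <- function(x, ...) {
  cat("Synthetic paradigm configuration\n")
  cat(sprintf("  %d + %d subjects; %d blocks x %d trials (%d per cell)\n",
              x$n_subjects_per_group, x$n_subjects_per_group, x$n_blocks,
              2L * 3L * x$trials_per_cell_per_block,
              x$trials_per_cell_per_block))
  cat("  mediation direction:", x$direction, "\n")
  for (g in GROUP_LEVELS) {
    for (m in MODALITY_LEVELS) {
      p <- x$paths[[g]][[m]]
      me <- p["a"] * p["b"]
      cat(sprintf("  %s/%-5s a=%6.3f b=%6.3f c'=%6.3f  (ME=%6.3f, prop=%6.3f)\n",
                  g, m, p["a"], p["b"], p["c_prime"], me,
                  me / (me + p["c_prime"])))
    }
  }
  invisible(x)
}

#' Population SDs of the latent variables implied by a configuration
#'
#' Closed-form standard deviations of the mediator and outcome latents under
#' the generative model (balanced centered intensity, Var(x) = 2/3),
#' per group and modality. Useful for converting configured path
#' coefficients to the z-score scale the analysis estimates on: the
#' standardized mediation effect is `a * b / sd_y`.
#'
#' @param config a [trial_config()].
#' @return data frame with columns `group`, `modality`, `sd_m`, `sd_y`.
#' @export
latent_sds <- function(config) {
  vx <- 2 / 3
  out <- expand.grid(group = GROUP_LEVELS, modality = MODALITY_LEVELS,
                     stringsAsFactors = FALSE)
  out$sd_m <- NA_real_
  out$sd_y <- NA_real_
  for (i in seq_len(nrow(out))) {
    p <- config$paths[[out$group[i]]][[out$modality[i]]]
    b <- if (config$direction == "none") 0 else p[["b"]]
    vm <- p[["a"]]^2 * vx + config$sd_subject_intercept_m^2 +
      config$sd_subject_slope_m^2 * vx + config$sd_resid_m^2
    vy <- (p[["c_prime"]] + b * p[["a"]])^2 * vx +
      config$sd_subject_intercept_y^2 + b^2 * config$sd_subject_intercept_m^2 +
      (config$sd_subject_slope_y^2 + b^2 * config$sd_subject_slope_m^2) * vx +
      b^2 * config$sd_resid_m^2 + config$sd_resid_y^2
    out$sd_m[i] <- sqrt(vm)
    out$sd_y[i] <- sqrt(vy)
  }
  out
}

## Block sequences ---------------------------------------------------------

max_run <- function(x) if (length(x) == 0) 0L else max(rle(x)$lengths)

#' Pseudorandom block sequence with run-length constraints
#'
#' Samples an ordering of one block's trials — a multiset of
#' (modality, intensity) cells — such that no more than two consecutive
#' trials share an intensity and no more than three share a modality.
#' `method = "rejection"` repeatedly shuffles whole permutations until the
#' constraints hold (uniform over valid sequences, but slow for standard
#' 54-trial blocks); `"greedy"` (default) builds the sequence left to right,
#' drawing each trial uniformly from the cells still available that do not
#' violate a constraint, restarting on dead ends.
#'
#' @param counts named integer matrix or table of trials per cell with rows
#'   = modalities and columns = intensity levels, or `NULL` for the standard
#'   block (`trials_per_cell` per cell).
#' @param trials_per_cell used when `counts` is `NULL` (default 9).
#' @param seed RNG seed (the sequence is deterministic given the seed).
#' @param method `"greedy"` or `"rejection"`.
#' @param max_tries bound on restarts/rejections before giving up.
#' @param max_intensity_run,max_modality_run the run-length caps.
#' @return data frame with columns `modality` and `intensity_level`, one row
#'   per trial, in presentation order.
#' @export
#' @examples
#' s <- pseudorandom_sequence(seed = 1)
#' max(rle(s$intensity_level)$lengths) # <= 2
pseudorandom_sequence <- function(counts = NULL, trials_per_cell = 9L,
                                  seed = NULL,
                                  method = c("greedy", "rejection"),
                                  max_tries = 10000L,
                                  max_intensity_run = 2L,
                                  max_modality_run = 3L) {
  method <- match.arg(method)
  if (is.null(counts)) {
    counts <- matrix(as.integer(trials_per_cell), nrow = 2, ncol = 3,
                     dimnames = list(MODALITY_LEVELS, 1:3))
  }
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (any(counts < 0)) stop("cell counts must be non-negative")
  cells <- which(counts > 0, arr.ind = TRUE)
  n <- sum(counts)
  mk <- function(idx) {
    data.frame(modality = rownames(counts)[idx[, 1]],
               intensity_level = as.integer(colnames(counts)[idx[, 2]]),
               stringsAsFactors = FALSE)
  }
  ## flat cell index per trial
  pool <- rep(seq_len(nrow(cells)), counts[cells])
  if (n <= 1) return(mk(cells[pool, , drop = FALSE]))
  valid <- function(mod, int) {
    max_run(mod) <= max_modality_run && max_run(int) <= max_intensity_run
  }
  with_seed(seed, {
    if (method == "rejection") {
      for (try in seq_len(max_tries)) {
        perm <- pool[sample.int(n)]
        mod <- cells[perm, 1]; int <- cells[perm, 2]
        if (valid(mod, int)) return(mk(cells[perm, , drop = FALSE]))
      }
      stop("no valid sequence found in ", max_tries, " rejections")
    }
    seq_idx <- greedy_sequence(cells[, 1], cells[, 2], counts[cells],
                               max_modality_run, max_intensity_run,
                               max_tries)
    mk(cells[seq_idx, , drop = FALSE])
  })
}

## Constrained left-to-right sampler over cell indices, using the ambient
## RNG stream. `mods`/`ints` give each cell's modality and intensity code,
## `left0` the trials per cell. Returns cell indices in presentation order.
greedy_sequence <- function(mods, ints, left0, max_modality_run,
                            max_intensity_run, max_tries = 10000L) {
  n <- sum(left0)
  n_cell <- length(left0)
  for (try in seq_len(max_tries)) {
    left <- left0
    seq_idx <- integer(n)
    mod_run <- 0L; int_run <- 0L; last_mod <- 0L; last_int <- 0L
    ok <- TRUE
    for (k in seq_len(n)) {
      cand_ok <- left > 0L
      if (mod_run >= max_modality_run) cand_ok <- cand_ok & (mods != last_mod)
      if (int_run >= max_intensity_run) cand_ok <- cand_ok & (ints != last_int)
      cand <- seq_len(n_cell)[cand_ok]
      if (!length(cand)) { ok <- FALSE; break }
      pick <- if (length(cand) == 1L) cand else
        cand[sample.int(length(cand), 1L, prob = left[cand])]
      seq_idx[k] <- pick
      left[pick] <- left[pick] - 1L
      mod_run <- if (mods[pick] == last_mod) mod_run + 1L else 1L
      int_run <- if (ints[pick] == last_int) int_run + 1L else 1L
      last_mod <- mods[pick]; last_int <- ints[pick]
    }
    if (ok) return(seq_idx)
  }
  stop("no valid sequence found in ", max_tries, " restarts")
}

## Dataset generation ------------------------------------------------------

#' Generate a synthetic trial table
#'
#' Draws a full two-group dataset from the generative model described in
#' [trial_config()]. Deterministic given `seed`: the same seed and
#' configuration yield a byte-identical table.
#'
#' @param config a [trial_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return a trial-table data frame (columns as [read_trials()], plus
#'   `trial`, the within-block presentation index) whose `meta` attribute
#'   records the seed, configuration hash and sign conventions.
#' @export
#' @examples
#' cfg <- trial_config(n_subjects_per_group = 2, n_blocks = 1)
#' d <- generate_trials(cfg, seed = 1)
#' nrow(d)  # 2 groups x 2 subjects x 54 trials
generate_trials <- function(config, seed = NULL) {
  stopifnot(inherits(config, "trial_config"))
  validate_config(config)
  seed <- seed %||% config$seed
  if (is.null(seed)) stop("a seed is required (in the config or as argument)")
  nspg <- config$n_subjects_per_group
  tpc <- config$trials_per_cell_per_block
  n_per_block <- 2L * 3L * tpc
  subj_seeds <- derive_seeds(seed, 2L * nspg + 1L)
  rows <- vector("list", 2L * nspg)
  si <- 0L
  for (g in GROUP_LEVELS) {
    for (s in seq_len(nspg)) {
      si <- si + 1L
      rows[[si]] <- generate_subject(config, g, s, subj_seeds[si])
    }
  }
  d <- do.call(rbind, rows)
  rownames(d) <- NULL
  trial_meta(d) <- list(
    generator = "psymediate::generate_trials",
    seed = as.integer(seed),
    config_hash = config_hash(unclass(config)),
    direction = config$direction,
    sign_convention = paste(
      "standardized behavior latent is the negated RT scale:",
      "larger latent = faster response")
  )
  d
}

generate_subject <- function(config, group, s_index, seed) {
  with_seed(seed, {
    id <- sprintf("%s%02d", if (group == "patient") "P" else "C", s_index)
    tpc <- config$trials_per_cell_per_block
    n_per_block <- 6L * tpc
    ## calibrated magnitudes: fixed per subject x modality x level
    mag <- matrix(NA_real_, 2, 3)
    for (mi in 1:2) {
      spec <- config$magnitudes[[group]][[MODALITY_LEVELS[mi]]]
      v <- stats::rnorm(3, spec$mean, spec$sd)
      mag[mi, ] <- pmin(pmax(v, 1), MAX_MAGNITUDE[[MODALITY_LEVELS[mi]]])
    }
    ## subject random effects (shared across modalities)
    u0 <- stats::rnorm(1, 0, config$sd_subject_intercept_m)
    u1 <- stats::rnorm(1, 0, config$sd_subject_slope_m)
    v0 <- stats::rnorm(1, 0, config$sd_subject_intercept_y)
    v1 <- stats::rnorm(1, 0, config$sd_subject_slope_y)
    ## cell codes: rows = 6 cells (modality-major), columns mod/int
    cell_mod <- rep(1:2, 3)
    cell_int <- rep(1:3, each = 2)
    left0 <- rep(as.integer(tpc), 6)
    mod_i <- integer(0); int_i <- integer(0)
    for (b in seq_len(config$n_blocks)) {
      idx <- if (config$order_method == "none") {
        rep(1:6, tpc)[sample.int(n_per_block)]
      } else if (config$order_method == "rejection") {
        pool <- rep(1:6, tpc)
        repeat {
          perm <- pool[sample.int(n_per_block)]
          if (max_run(cell_mod[perm]) <= 3L && max_run(cell_int[perm]) <= 2L)
            break
        }
        perm
      } else {
        greedy_sequence(cell_mod, cell_int, left0, 3L, 2L)
      }
      mod_i <- c(mod_i, cell_mod[idx]); int_i <- c(int_i, cell_int[idx])
    }
    n <- length(mod_i)
    x <- int_i - 2L
    p <- config$paths[[group]]
    pm <- vapply(MODALITY_LEVELS,
                 function(m) p[[m]][c("a", "b", "c_prime")], numeric(3))
    a <- pm["a", mod_i]
    b_ <- if (config$direction == "none") rep(0, n) else pm["b", mod_i]
    cp <- pm["c_prime", mod_i]
    m_lat <- a * x + u0 + u1 * x + stats::rnorm(n, 0, config$sd_resid_m)
    y_lat <- cp * x + b_ * m_lat + v0 + v1 * x +
      stats::rnorm(n, 0, config$sd_resid_y)
    if (config$direction == "perception_mediates") {
      p_lat <- m_lat; b_lat <- y_lat
    } else {
      b_lat <- m_lat; p_lat <- y_lat
    }
    rating <- config$rating_anchor[2] + config$rating_scale * p_lat
    rating <- pmin(pmax(rating, 0), 100)
    rt <- pmax(config$rt_mean_ms - config$rt_sd_ms * b_lat, 100)
    miss <- stats::runif(n) < config$misident_rate
    zero <- stats::runif(n) < config$zero_rating_rate
    rating[zero] <- 0
    data.frame(
      subject_id = id,
      group = group,
      modality = MODALITY_LEVELS[mod_i],
      intensity_level = int_i,
      stimulus_magnitude = mag[cbind(mod_i, int_i)],
      rating = rating,
      rt_ms = rt,
      modality_correct = !miss,
      block = rep(seq_len(config$n_blocks), each = n_per_block),
      trial = rep(seq_len(n_per_block), config$n_blocks),
      stringsAsFactors = FALSE
    )
  })
}

#' Read a generator configuration from a JSON or YAML file
#'
#' The file holds any subset of [trial_config()]'s arguments by name;
#' unnamed settings keep their defaults. Path tables are nested maps
#' `paths: group: modality: {a, b, c_prime}`; magnitude tables are nested
#' maps with `mean` and `sd` triples. YAML files require the `yaml`
#' package.
#'
#' @param path file ending in `.json`, `.yaml` or `.yml`.
#' @return a validated `"trial_config"` object.
#' @export
read_trial_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  unknown <- setdiff(names(raw), names(formals(trial_config)))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$paths)) {
    raw$paths <- lapply(raw$paths, function(g)
      lapply(g, function(p) path_coef(p[["a"]], p[["b"]], p[["c_prime"]])))
  }
  do.call(trial_config, raw)
}

## Intensity calibration ---------------------------------------------------

#' Calibrate stimulus magnitudes from rating data
#'
#' Regresses ratings on physical stimulus magnitude (ordinary least
#' squares) and inverts the fitted line at the target ratings, emulating
#' the per-subject calibration procedure that selects low/medium/high
#' magnitudes aiming at ratings of 30, 50 and 70. Magnitudes are clipped
#' from above at the device maximum.
#'
#' @param magnitude,rating paired calibration observations (>= 2 distinct
#'   magnitudes).
#' @param targets target ratings (default `c(30, 50, 70)`).
#' @param max_magnitude device cap (600 mJ for laser, 512 mN for von Frey).
#' @return numeric vector of calibrated magnitudes, one per target.
#' @export
#' @examples
#' calibrate_intensities(1:20, 0.1 * (1:20), targets = c(1, 1.5, 2),
#'                       max_magnitude = 600)
calibrate_intensities <- function(magnitude, rating,
                                  targets = c(30, 50, 70),
                                  max_magnitude = 600) {
  stopifnot(length(magnitude) == length(rating))
  if (length(unique(magnitude)) < 2) {
    stop("need at least 2 distinct magnitudes to calibrate")
  }
  fit <- stats::lm(rating ~ magnitude)
  beta <- stats::coef(fit)
  if (!is.finite(beta[2]) || beta[2] <= 0) {
    stop("calibration failed: ratings do not increase with magnitude")
  }
  pmin((targets - beta[1]) / beta[2], max_magnitude)
}
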