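#' @keywords internal
"_PACKAGE"

## Reproducibility helpers -------------------------------------------------

#' Run code with a local RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's
#' RNG state afterwards, so library code never perturbs the global stream.
#'
#' @param seed integer seed, or `NULL` to leave the RNG alone.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive child seeds from a master seed
#'
#' Expands one master seed into `n` per-stage seeds by seeding the RNG with
#' the master and drawing `n` integers uniformly below 2^31 - 1. Every
#' stochastic stage of the pipeline takes one child seed, so the whole
#' analysis is reproducible from a single integer.
#'
#' @param master integer master seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`.
#' @export
#' @examples
#' derive_seeds(42, 3)
derive_seeds <- function(master, n) {
  stopifnot(is.numeric(master), length(master) == 1, n >= 1)
  with_seed(as.integer(master), sample.int(2147483646L, n))
}

## Trial-table metadata ----------------------------------------------------

#' Get or set trial-table metadata
#'
#' Trial tables are plain data frames carrying a `meta` attribute: a named
#' list recording provenance (generator seed and configuration hash, or
#' source file), processing-stage flags, and the stratum means/SDs stored by
#' [zscore_by_stratum()] for later back-transformation.
#'
#' @param table a trial-table data frame.
#' @param value a named list.
#' @return `trial_meta` returns the metadata list (possibly empty).
#' @export
trial_meta <- function(table) {
  m <- attr(table, "meta", exact = TRUE)
  if (is.null(m)) list() else m
}

#' @rdname trial_meta
#' @export
`trial_meta<-` <- function(table, value) {
  stopifnot(is.list(value))
  attr(table, "meta") <- value
  table
}

#' Stable hash of a configuration object
#'
#' MD5 of the serialized object, used in run manifests so that a result
#' bundle records exactly which analysis options produced it.
#'
#' @param x any serializable R object.
#' @return a character scalar (32 hex digits).
#' @keywords internal
#' @noRd
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  ## strip environments (e.g. formulas) that would make the hash unstable
  saveRDS(x, f, version = 3, compress = FALSE)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
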