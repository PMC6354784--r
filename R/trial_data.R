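## Trial-level data: the pipeline's universal currency is a data frame with
## one row per stimulus trial and (at least) the nine canonical columns.

TRIAL_COLUMNS <- c("subject_id", "group", "modality", "intensity_level",
                   "stimulus_magnitude", "rating", "rt_ms",
                   "modality_correct", "block")

GROUP_LEVELS    <- c("patient", "control")
MODALITY_LEVELS <- c("pain", "touch")

## Paradigm caps on physical stimulus magnitude (laser energy in mJ,
## von Frey force in mN).
MAX_MAGNITUDE <- c(pain = 600, touch = 512)

#' Row-wise validation of a trial table
#'
#' Checks each row of a trial-table data frame against the domain
#' invariants: rating in \[0, 100\], strictly positive reaction time,
#' intensity level in \{1, 2, 3\}, known group and modality labels, block in
#' \{1, ..., 4\}, and (when `paradigm = TRUE`) stimulus magnitude within the
#' paradigm caps of 600 mJ (pain) and 512 mN (touch).
#'
#' @param table data frame with the nine trial columns.
#' @param paradigm logical; also enforce the magnitude caps.
#' @return logical vector, `TRUE` for valid rows, with a `"reasons"`
#'   attribute giving the first violated rule per invalid row.
#' @export
validate_trials <- function(table, paradigm = TRUE) {
  n <- nrow(table)
  reasons <- rep(NA_character_, n)
  flag <- function(bad, why) {
    bad[is.na(bad)] <- TRUE
    reasons[bad & is.na(reasons)] <<- why
  }
  flag(!(table$group %in% GROUP_LEVELS), "unknown group")
  flag(!(table$modality %in% MODALITY_LEVELS), "unknown modality")
  flag(!(table$intensity_level %in% 1:3), "intensity_level not in 1..3")
  flag(table$rating < 0 | table$rating > 100, "rating outside [0,100]")
  flag(table$rt_ms <= 0, "rt_ms not positive")
  flag(table$stimulus_magnitude < 0, "negative stimulus_magnitude")
  flag(!(table$block %in% 1:4), "block not in 1..4")
  flag(is.na(table$modality_correct), "missing modality_correct")
  if (paradigm) {
    cap <- MAX_MAGNITUDE[as.character(table$modality)]
    flag(table$stimulus_magnitude > cap, "magnitude exceeds paradigm cap")
  }
  ok <- is.na(reasons)
  ## a subject may belong to exactly one group
  tab <- unique(table[ok, c("subject_id", "group")])
  dup <- tab$subject_id[duplicated(tab$subject_id)]
  if (length(dup)) flag(ok & table$subject_id %in% dup, "subject in two groups")
  ok <- is.na(reasons)
  attr(ok, "reasons") <- reasons
  ok
}

#' Read a trial table from CSV
#'
#' Reads a comma-separated file with a header containing the nine canonical
#' trial columns (`subject_id`, `group`, `modality`, `intensity_level`,
#' `stimulus_magnitude`, `rating`, `rt_ms`, `modality_correct`, `block`).
#' Extra columns are preserved. In strict mode any row violating a domain
#' invariant is an error; in lenient mode offending rows are dropped and the
#' number of drops is reported via a message and the table's metadata.
#'
#' @param path path to a CSV file.
#' @param strict logical; reject invalid rows (`TRUE`, default) or drop
#'   them (`FALSE`).
#' @param paradigm logical; enforce the paradigm's magnitude caps.
#' @return a trial-table data frame with a `meta` attribute recording the
#'   source file and any drop counts.
#' @seealso [write_trials()]
#' @export
read_trials <- function(path, strict = TRUE, paradigm = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(TRIAL_COLUMNS, names(d))
  if (length(missing)) {
    stop("trial file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(d) == 0) {
    trial_meta(d) <- list(source = path, n_dropped = 0L)
    return(d)
  }
  d$subject_id <- as.character(d$subject_id)
  d$modality_correct <- as.logical(d$modality_correct)
  for (col in c("intensity_level", "block")) d[[col]] <- as.integer(d[[col]])
  for (col in c("stimulus_magnitude", "rating", "rt_ms")) {
    d[[col]] <- as.numeric(d[[col]])
  }
  ok <- validate_trials(d, paradigm = paradigm)
  if (!all(ok)) {
    reasons <- attr(ok, "reasons")
    if (strict) {
      i <- which(!ok)[1]
      stop("invalid trial at row ", i, ": ", reasons[i])
    }
    message("read_trials: dropped ", sum(!ok), " invalid row(s)")
    d <- d[ok, , drop = FALSE]
    rownames(d) <- NULL
  }
  trial_meta(d) <- list(source = path, n_dropped = sum(!ok))
  d
}

#' Write a trial table to CSV
#'
#' Writes a trial table as an RFC-4180-style CSV with a header row. Numeric
#' fields are serialized at full precision (17 significant digits) so that
#' `read_trials(write_trials(t))` reproduces `t` exactly.
#'
#' @param table a trial-table data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(table, path) {
  missing <- setdiff(TRIAL_COLUMNS, names(table))
  if (length(missing)) {
    stop("table lacks required column(s): ", paste(missing, collapse = ", "))
  }
  out <- table
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      out[[col]] <- formatC(out[[col]], digits = 17, format = "g")
    }
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write trial table to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}
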