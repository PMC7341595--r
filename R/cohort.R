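#' Cohorts of irregular multivariate patient time series
#'
#' A cohort is a long-format tibble with one row per observation and columns
#' `patient_id` (character), `covariate` (character), `time_hours`
#' (non-negative numeric, hours since admission) and `value` (numeric, in
#' covariate-native units). The ordered set of modelled covariates is carried
#' in the `"covariates"` attribute: its order defines the covariate index
#' d = 1..D that the block-structured kernel relies on, and is shared by every
#' patient in the cohort.
#'
#' `as_cohort()` validates a data frame and attaches the covariate ordering;
#' rows whose covariate is not in `covariates` are dropped, and rows are
#' sorted by patient, covariate (in `covariates` order) and time.
#'
#' @param x A data frame with columns `patient_id`, `covariate`, `time_hours`,
#'   `value`.
#' @param covariates Optional character vector fixing the covariate ordering.
#'   Defaults to the covariates present, in first-appearance order.
#' @return A tibble of class `medgp_cohort` with a `"covariates"` attribute.
#' @examples
#' df <- tibble::tibble(
#'   patient_id = "p1", covariate = c("hr", "hr", "hct"),
#'   time_hours = c(4, 1, 2), value = c(80, 76, 31)
#' )
#' as_cohort(df)
#' @export
as_cohort <- function(x, covariates = NULL) {
  required <- c("patient_id", "covariate", "time_hours", "value")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "cohort input is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ), class = "medgp_format_error")
  }
  x <- tibble::as_tibble(x)[required]
  x$patient_id <- as.character(x$patient_id)
  x$covariate <- as.character(x$covariate)
  if (nrow(x) == 0) {
    x$time_hours <- as.numeric(x$time_hours)
    x$value <- as.numeric(x$value)
  }
  if (!is.numeric(x$time_hours)) {
    bad <- which(is.na(suppressWarnings(as.numeric(x$time_hours))))
    abort(paste0("non-numeric time_hours at row(s): ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "medgp_parse_error")
  }
  if (!is.numeric(x$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(x$value))))
    abort(paste0("non-numeric value at row(s): ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "medgp_parse_error")
  }
  if (anyNA(x$time_hours) || anyNA(x$value)) {
    abort("missing time_hours or value entries", class = "medgp_parse_error")
  }
  if (any(x$time_hours < 0)) {
    abort("negative observation times are invalid (hours since admission)",
          class = "medgp_validation_error")
  }
  if (is.null(covariates)) {
    covariates <- unique(x$covariate)
  }
  x <- x[x$covariate %in% covariates, , drop = FALSE]
  x <- x[order(x$patient_id, match(x$covariate, covariates), x$time_hours), ]
  structure(x,
    covariates = as.character(covariates),
    class = c("medgp_cohort", class(tibble::tibble()))
  )
}

#' @export
print.medgp_cohort <- function(x, ...) {
  covs <- attr(x, "covariates")
  cat(sprintf("<medgp_cohort> %d patients, %d covariates, %d observations\n",
              length(unique(x$patient_id)), length(covs), nrow(x)))
  NextMethod()
}

#' Covariates modelled by a cohort, model or prior
#'
#' @param x A `medgp_cohort`, `medgp_model` or `medgp_prior`.
#' @return Character vector of covariate names in model order.
#' @export
covariates <- function(x) {
  if (inherits(x, "medgp_cohort")) return(attr(x, "covariates"))
  if (!is.null(x$covariate_names)) return(x$covariate_names)
  abort("no covariate ordering found on this object")
}

#' Read a cohort from a delimited long-format file
#'
#' Expects a header with columns `patient_id`, `covariate`, `time_hours`,
#' `value`. The delimiter is auto-detected (comma or tab) unless given.
#'
#' @param path Path to a CSV/TSV file.
#' @param covariates Optional covariate names to keep (and their order); others
#'   are dropped. Defaults to all covariates present.
#' @param delim Optional delimiter; `NULL` auto-detects from the header line.
#' @param clip Optional named list of `c(min, max)` ranges per covariate;
#'   observations outside their covariate's range are dropped (artifact
#'   filtering, disabled by default).
#' @return A [as_cohort()] tibble.
#' @export
read_cohort <- function(path, covariates = NULL, delim = NULL, clip = NULL) {
  if (!file.exists(path)) {
    abort(paste0("input file not found: ", path), class = "medgp_io_error")
  }
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  co <- as_cohort(df, covariates = covariates)
  if (!is.null(clip)) {
    keep <- rep(TRUE, nrow(co))
    for (cv in names(clip)) {
      rng <- clip[[cv]]
      idx <- co$covariate == cv
      keep[idx] <- co$value[idx] >= rng[1] & co$value[idx] <= rng[2]
    }
    co <- as_cohort(co[keep, ], covariates = attr(co, "covariates"))
  }
  co
}

#' Write a cohort to a delimited long-format file
#'
#' Emits the same format [read_cohort()] accepts; reading the file back yields
#' the identical cohort (up to row order).
#'
#' @param cohort A `medgp_cohort`.
#' @param path Output path; `.tsv` extension selects tab delimiting.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "medgp_cohort"))
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  out <- tibble::as_tibble(cohort)
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}

#' Split a cohort into per-patient tibbles
#'
#' @param cohort A `medgp_cohort`.
#' @return Named list of per-patient `medgp_cohort` tibbles (same covariate
#'   ordering), one per unique `patient_id`.
#' @export
cohort_split <- function(cohort) {
  covs <- attr(cohort, "covariates")
  ids <- unique(cohort$patient_id)
  out <- lapply(ids, function(id) {
    as_cohort(cohort[cohort$patient_id == id, ], covariates = covs)
  })
  names(out) <- ids
  out
}

#' Flatten one patient's series into stacked vectors
#'
#' Concatenates the per-covariate observation vectors in covariate order
#' d = 1..D, the layout the block-structured multi-output kernel operates on.
#'
#' @param patient A single-patient `medgp_cohort` (or long tibble) for one
#'   patient.
#' @param covariates Covariate ordering; defaults to the cohort attribute.
#' @return A tibble with columns `time_hours`, `value`, `cov_index` (integer
#'   in 1..D) and `covariate`, with rows grouped by covariate then sorted by
#'   time within covariate.
#' @export
flatten <- function(patient, covariates = NULL) {
  if (is.null(covariates)) covariates <- attr(patient, "covariates")
  stopifnot(!is.null(covariates))
  if (length(unique(patient$patient_id)) > 1) {
    abort("flatten() expects observations from a single patient")
  }
  d <- match(patient$covariate, covariates)
  if (anyNA(d)) abort("patient has covariates outside the model's ordering")
  ord <- order(d, patient$time_hours)
  tibble::tibble(
    time_hours = patient$time_hours[ord],
    value = patient$value[ord],
    cov_index = d[ord],
    covariate = covariates[d[ord]]
  )
}

#' Invert [flatten()] back to a long patient tibble
#'
#' @param flat A tibble as returned by [flatten()].
#' @param patient_id Patient id to attach.
#' @param covariates Covariate ordering for the resulting cohort attribute.
#' @return A single-patient `medgp_cohort`.
#' @export
unflatten <- function(flat, patient_id = "patient", covariates = NULL) {
  if (is.null(covariates)) covariates <- unique(flat$covariate)
  as_cohort(tibble::tibble(
    patient_id = patient_id,
    covariate = flat$covariate,
    time_hours = flat$time_hours,
    value = flat$value
  ), covariates = covariates)
}

# Internal: flatten to bare vectors (times, values, covariate index) for the
# numerical core. Duplicated timestamps are kept as distinct observations.
flatten_vectors <- function(patient, covariates) {
  d <- match(patient$covariate, covariates)
  ord <- order(d, patient$time_hours)
  list(
    x = as.numeric(patient$time_hours[ord]),
    y = as.numeric(patient$value[ord]),
    d = as.integer(d[ord])
  )
}
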