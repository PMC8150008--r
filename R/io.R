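#' Read and write study datasets as CSV
#'
#' Study datasets travel as plain CSV with columns `study_id`, `y`,
#' `x1`..`xp`; moderator tables as CSV with columns `study_id`, `m`. These
#' are the formats the command-line interface exchanges.
#'
#' @param path File path.
#' @return `read_study_csv()` returns a tibble; writers return the input
#'   invisibly.
#' @name study_io
NULL

#' @rdname study_io
#' @export
read_study_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("study_id", "y")
  if (!all(need %in% names(out)) || length(predictor_cols(out)) == 0) {
    stop("expected columns study_id, y, x1..xp in ", path, call. = FALSE)
  }
  if (anyNA(out)) stop("missing values in ", path, call. = FALSE)
  out
}

#' @rdname study_io
#' @param x A study tibble (or `swip_database`, whose stacked studies are
#'   written).
#' @export
write_study_csv <- function(x, path) {
  d <- if (inherits(x, "swip_database")) x$studies else x
  readr::write_csv(d, path)
  invisible(x)
}

#' @rdname study_io
#' @export
read_moderators_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("study_id", "m") %in% names(out))) {
    stop("expected columns study_id, m in ", path, call. = FALSE)
  }
  out
}

#' Write a database of previous studies to a directory
#'
#' Writes `studies.csv` (stacked studies) and `moderators.csv`, and returns
#' the directory path.
#'
#' @param db A `swip_database`.
#' @param dir Output directory (created if needed).
#' @export
write_database <- function(db, dir) {
  stopifnot(inherits(db, "swip_database"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(db$studies, file.path(dir, "studies.csv"))
  readr::write_csv(db$moderators, file.path(dir, "moderators.csv"))
  invisible(dir)
}

#' Read a database of previous studies from a directory
#'
#' Counterpart of [write_database()]: expects `studies.csv` and optionally
#' `moderators.csv`.
#'
#' @param dir Directory path.
#' @return A `swip_database` (with empty `true_betas`).
#' @export
read_database <- function(dir) {
  studies <- read_study_csv(file.path(dir, "studies.csv"))
  mpath <- file.path(dir, "moderators.csv")
  moderators <- if (file.exists(mpath)) read_moderators_csv(mpath) else NULL
  structure(
    list(studies = studies, moderators = moderators,
         true_betas = tibble::tibble()),
    class = "swip_database"
  )
}
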