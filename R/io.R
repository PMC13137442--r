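#' Trajectory CSV I/O
#'
#' Trajectories are written with header `time,S,N,I,T,R`, fixed decimal
#' notation with a configurable number of digits, '.' decimal separator and
#' LF line endings, so identical inputs give byte-identical files.
#'
#' @param traj A `snitr_trajectory` (or data frame with those columns).
#' @param path Output file.
#' @param digits Decimal digits written (default 6).
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns a tibble `time,S,N,I,T,R`.
#' @export
write_trajectory <- function(traj, path, digits = 6) {
  cols <- c("time", "S", "N", "I", "T", "R")
  stopifnot(all(cols %in% names(traj)))
  write_fixed_csv(as.data.frame(traj)[cols], path, digits)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- read_checked_csv(path, c("time", "S", "N", "I", "T", "R"))
  if (is.unsorted(df$time, strictly = TRUE)) {
    stop("time column must be strictly increasing", call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Observed-series CSV I/O
#'
#' Series files use header `time,value`; the window metadata (bin width,
#' fit/validation window ends, population) travels in a JSON sidecar at
#' `<path>.json`.
#'
#' @param series A `snitr_series`.
#' @param path Output CSV path (sidecar written at `<path>.json`).
#' @param digits Decimal digits written.
#' @return `write_series()` returns `path` invisibly; `read_series()`
#'   returns a `snitr_series`.
#' @export
write_series <- function(series, path, digits = 8) {
  stopifnot(all(c("time", "value") %in% names(series)))
  write_fixed_csv(as.data.frame(series)[c("time", "value")], path, digits)
  meta <- list(bin_width = attr(series, "bin_width"),
               fit_window_end = attr(series, "fit_window_end"),
               validation_end = attr(series, "validation_end"),
               population = attr(series, "population"))
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  df <- read_checked_csv(path, c("time", "value"))
  if (is.unsorted(df$time, strictly = TRUE)) {
    stop("time column must be strictly increasing", call. = FALSE)
  }
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop("missing JSON sidecar: ", sidecar, call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  need <- c("bin_width", "fit_window_end", "validation_end", "population")
  missing_keys <- setdiff(need, names(meta))
  if (length(missing_keys) > 0) {
    stop("sidecar missing key(s): ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  }
  new_snitr_series(tibble::as_tibble(df),
                   bin_width = meta$bin_width,
                   fit_window_end = meta$fit_window_end,
                   validation_end = meta$validation_end,
                   population = meta$population)
}

# deterministic fixed-notation CSV writer
write_fixed_csv <- function(df, path, digits) {
  header <- paste(names(df), collapse = ",")
  body <- do.call(paste, c(lapply(df, function(x) {
    sprintf(paste0("%.", digits, "f"), x)
  }), sep = ","))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

read_checked_csv <- function(path, cols) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = NA, stringsAsFactors = FALSE)
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- df[cols]
  bad <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (length(bad) > 0) {
    stop("non-numeric values in column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(df)) stop("non-numeric or missing cells in ", path,
                      call. = FALSE)
  df
}
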