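#' Read a temperature-logger CSV export
#'
#' Expects a two-column CSV (`timestamp`, `temperature_C`) with strictly
#' increasing timestamps on a 1-minute grid.  Gaps, duplicates or non-monotone
#' rows are ingestion errors (the pipeline does not impute missing samples);
#' the offending rows are named in the error.  The logger's quantization step
#' is inferred from the value grid as the greatest common divisor of the
#' pairwise differences of the recorded temperatures.
#'
#' @param path Path to the CSV file.
#' @param tolerance_s Allowed deviation from 60-s spacing, seconds.
#' @return A `temperature_series` tibble (see [simulate_subject()]).
#' @export
read_logger_csv <- function(path, tolerance_s = 1) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(raw) < 2)
    abort("logger CSV must have columns timestamp, temperature_C")
  ts <- parse_iso8601(raw[[1]])
  if (anyNA(ts))
    abort(sprintf("unparseable timestamps at rows: %s",
                  paste(head(which(is.na(ts)), 5), collapse = ", ")))
  d <- diff(as.numeric(ts))
  if (any(d <= 0)) {
    bad <- which(d <= 0) + 1
    abort(sprintf("non-monotone or duplicate timestamps at rows: %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  off <- which(abs(d - 60) > tolerance_s)
  if (length(off) > 0)
    abort(sprintf("sampling gaps (not 1-min spacing) after rows: %s",
                  paste(head(off, 5), collapse = ", ")))
  values <- as.numeric(raw[[2]])
  if (anyNA(values))
    abort("missing temperature values are not allowed")
  new_temperature_series(values,
                         subject_id = tools::file_path_sans_ext(basename(path)),
                         quantization_step = infer_quantization_step(values))
}

parse_iso8601 <- function(x) {
  x <- sub("Z$", "", x)
  x <- sub("T", " ", x, fixed = TRUE)
  as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
}

#' Infer the quantization step of a recorded value grid
#'
#' Numeric GCD (with floating-point tolerance) of the differences between
#' sorted unique values; returns `NA` for a constant series.
#'
#' @param values Numeric vector.
#' @param tol Relative tolerance for the Euclidean GCD recursion.
#' @return The inferred step, or `NA_real_`.
#' @export
infer_quantization_step <- function(values, tol = 1e-6) {
  d <- diff(sort(unique(round(values, 9))))
  if (length(d) == 0) return(NA_real_)
  g <- d[1]
  eps <- tol * max(d)
  for (v in d[-1]) {
    a <- max(g, v); b <- min(g, v)
    while (b > eps) {
      r <- a - floor(a / b + eps) * b
      a <- b
      b <- r
    }
    g <- a
  }
  g
}

#' Write a temperature series as a logger-style CSV
#'
#' Two columns, ISO-8601 UTC timestamps on a 1-minute grid and temperature in
#' degC.
#'
#' @param series A `temperature_series` tibble.
#' @param path Output path.
#' @param start Origin timestamp (POSIXct).
#' @return `path`, invisibly.
#' @export
write_logger_csv <- function(series, path,
                             start = as.POSIXct("2022-01-01 00:00:00", tz = "UTC")) {
  ts <- format(start + series$minute * 60, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(data.frame(timestamp = ts,
                              temperature_C = series$temperature),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulated cohort to disk
#'
#' One CSV per subject plus a cohort `manifest.csv` (`subject_id`, `label`,
#' `braden`, `file`) and a JSON run manifest recording the seed.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param seed Seed recorded in the run manifest.
#' @return The manifest tibble, invisibly.
#' @export
write_cohort <- function(cohort, dir, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(dir, paste0(cohort$subject_id, ".csv"))
  purrr::walk2(cohort$series, files, write_logger_csv)
  manifest <- tibble(subject_id = cohort$subject_id,
                     label = as.character(cohort$group),
                     braden = cohort$braden,
                     file = basename(files))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(list(seed = seed, n_subjects = nrow(cohort),
                            written = format(Sys.time(), tz = "UTC")),
                       file.path(dir, "run_manifest.json"), auto_unbox = TRUE)
  invisible(manifest)
}
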