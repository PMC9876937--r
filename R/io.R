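#' Read raw-trace, environment and metadata CSV files
#'
#' Readers for the on-disk schemas produced by [write_cohort()] (and by any
#' logger export following the same layout): `trace_<id>_<day>.csv` with
#' ISO-8601 timestamps, O2 fractions and zero-check flags; `env_<id>.csv`
#' with nest/enclosure temperature and humidity; `metadata.csv` with one row
#' per individual.
#'
#' @param file path to a CSV file.
#' @param tz time zone the timestamps should carry.
#' @return a data.frame in the corresponding in-memory schema.
#' @name cohort-io
NULL

parse_iso <- function(x, tz) {
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S%z", tz = tz)
  if (anyNA(out)) stop("unparseable ISO-8601 timestamp(s)", call. = FALSE)
  out
}

#' @rdname cohort-io
#' @export
read_trace_csv <- function(file, tz = "Europe/Berlin") {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  stopifnot(all(c("timestamp", "o2_fraction", "is_zero_check") %in% names(d)))
  d$timestamp <- parse_iso(d$timestamp, tz)
  d$is_zero_check <- as.logical(d$is_zero_check)
  d
}

#' @rdname cohort-io
#' @export
read_env_csv <- function(file, tz = "Europe/Berlin") {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  stopifnot(all(c("timestamp", "t_nest_c", "t_a_c") %in% names(d)))
  d$timestamp <- parse_iso(d$timestamp, tz)
  d
}

#' @rdname cohort-io
#' @export
read_metadata_csv <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  d$date_in <- as.Date(d$date_in)
  d$date_out <- as.Date(d$date_out)
  d
}

#' Read a whole cohort directory written by [write_cohort()]
#'
#' @param dir directory holding `trace_*.csv`, `env_*.csv`, `metadata.csv`
#'   and (optionally) `truth.json`.
#' @param tz time zone of the site.
#' @return list with `traces`, `env`, `metadata` and, when `truth.json` is
#'   present, `truth` (random effects and per-trace occupancy).
#' @export
read_cohort <- function(dir, tz = "Europe/Berlin") {
  tf <- list.files(dir, "^trace_.*\\.csv$", full.names = TRUE)
  ef <- list.files(dir, "^env_.*\\.csv$", full.names = TRUE)
  stopifnot(length(tf) > 0, length(ef) > 0)
  traces <- lapply(tf, read_trace_csv, tz = tz)
  names(traces) <- sub("^trace_(.*)\\.csv$", "\\1", basename(tf))
  env <- lapply(ef, read_env_csv, tz = tz)
  names(env) <- sub("^env_(.*)\\.csv$", "\\1", basename(ef))
  out <- list(traces = traces, env = env,
              metadata = read_metadata_csv(file.path(dir, "metadata.csv")))
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) {
    tr <- jsonlite::read_json(tj, simplifyVector = TRUE)
    out$truth <- list(random_effects = tr$random_effects,
                      params = tr$params,
                      occupancy = tr$occupancy)
  }
  out
}
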