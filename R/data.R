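#' Long-format longitudinal dataset
#'
#' Container for a longitudinal outcome in long format: one element per
#' observation, with subjects indexed in order of first appearance. All
#' model code consumes this structure.
#'
#' @param subject_id vector of subject identifiers (one per observation).
#' @param time numeric vector of observation times (e.g. study week, with 0
#'   the first week).
#' @param y numeric outcome vector (possibly log-transformed upstream).
#' @param allow_empty allow a dataset with zero observations (used by
#'   filtering helpers); defaults to `FALSE`.
#' @return an object of class `lcls_data` with fields `subject_ids` (per
#'   observation), `times`, `outcomes`, `subject_index` (observation ->
#'   subject ordinal), `subjects` (unique ids in first-appearance order),
#'   `n_per_subject` and `n_subjects`.
#' @export
#' @examples
#' lcls_data(c("a", "a", "b"), c(0, 1, 0), c(7.1, 7.0, 7.4))
lcls_data <- function(subject_id, time, y, allow_empty = FALSE) {
  n <- length(y)
  if (length(subject_id) != n || length(time) != n)
    stop("'subject_id', 'time' and 'y' must have equal lengths")
  if (n == 0L) {
    if (!allow_empty) stop("empty input: no observations")
    return(structure(list(subject_ids = subject_id, times = numeric(0),
                          outcomes = numeric(0), subject_index = integer(0),
                          subjects = unique(subject_id),
                          n_per_subject = integer(0), n_subjects = 0L,
                          time_unique = numeric(0), time_index = integer(0)),
                     class = "lcls_data"))
  }
  time <- as.numeric(time); y <- as.numeric(y)
  if (!all(is.finite(time))) stop("'time' must be finite")
  if (!all(is.finite(y))) stop("'y' (outcome) must be finite")
  subjects <- unique(subject_id)
  idx <- match(subject_id, subjects)
  n_per <- tabulate(idx, nbins = length(subjects))
  tu <- sort(unique(time))
  structure(list(subject_ids = subject_id, times = time, outcomes = y,
                 subject_index = idx, subjects = subjects,
                 n_per_subject = n_per, n_subjects = length(subjects),
                 time_unique = tu, time_index = match(time, tu)),
            class = "lcls_data")
}

#' @export
print.lcls_data <- function(x, ...) {
  cat(sprintf("lcls_data: %d observations from %d subject(s)\n",
              length(x$outcomes), x$n_subjects))
  if (x$n_subjects > 0)
    cat(sprintf("  observations per subject: %d-%d (mean %.1f); time range [%g, %g]\n",
                min(x$n_per_subject), max(x$n_per_subject),
                mean(x$n_per_subject), min(x$times), max(x$times)))
  invisible(x)
}

#' @export
as.data.frame.lcls_data <- function(x, ...) {
  data.frame(subject_id = x$subject_ids, time = x$times, y = x$outcomes,
             stringsAsFactors = FALSE)
}

#' Read a long-format CSV into an `lcls_data` object
#'
#' Expects a header with columns `subject_id`, `time`, `y`; extra columns
#' are ignored. Subjects are ordered by first appearance.
#'
#' @param path path to a CSV file.
#' @return an `lcls_data` object.
#' @export
read_long_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty input: '", path, "' contains no data rows")
  need <- c("subject_id", "time", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  for (col in c("time", "y")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop(sprintf("non-numeric '%s' value at data row %d: '%s'",
                     col, bad[1], v[bad[1]]))
      df[[col]] <- vn
    }
    if (anyNA(df[[col]]))
      stop(sprintf("missing '%s' value at data row %d", col,
                   which(is.na(df[[col]]))[1]))
  }
  lcls_data(df$subject_id, df$time, df$y)
}

#' Write an `lcls_data` object as a long-format CSV
#'
#' @param data an `lcls_data` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(data, path) {
  write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
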