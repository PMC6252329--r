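#' Construct a trial set
#'
#' A `trial_set` holds one condition's epoched recordings for a single
#' sensor: a numeric matrix with one trial per row, plus the timing
#' metadata needed to interpret the columns as a time axis. Time zero is
#' the stimulus onset; `onset_index` gives the onset sample (1-based, so
#' `onset_index = 1` means the epoch starts at the onset, as in a purely
#' post-stimulus epoch).
#'
#' @param data Numeric matrix, `n_trials x n_samples`; one trial per row.
#'   At least 2 trials and 3 samples; all values finite.
#' @param sampling_rate Sampling rate in Hz.
#' @param onset_index 1-based column index of the stimulus onset sample.
#' @param condition,sensor,subject Optional label strings.
#'
#' @return An object of class `trial_set` with elements `data`,
#'   `sampling_rate`, `onset_index`, `times` (seconds, 0 at onset),
#'   `condition`, `sensor`, `subject`.
#' @examples
#' ts <- trial_set(matrix(rnorm(20), 4, 5), sampling_rate = 512)
#' ts$times
#' @export
trial_set <- function(data, sampling_rate, onset_index = 1L,
                      condition = NA_character_, sensor = NA_character_,
                      subject = NA_character_) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 2L) {
    stop("trial_set needs at least 2 trials (rows), got ", nrow(data),
         call. = FALSE)
  }
  if (ncol(data) < 3L) {
    stop("trial_set needs at least 3 samples (columns), got ", ncol(data),
         call. = FALSE)
  }
  if (!all(is.finite(data))) {
    stop("trial_set data must be finite (no NA/NaN/Inf)", call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be a single positive number (Hz)", call. = FALSE)
  }
  onset_index <- as.integer(onset_index)
  if (onset_index < 1L || onset_index > ncol(data)) {
    stop("onset_index must lie within 1..n_samples", call. = FALSE)
  }
  times <- (seq_len(ncol(data)) - onset_index) / sampling_rate
  structure(
    list(data = data, sampling_rate = as.numeric(sampling_rate),
         onset_index = onset_index, times = times,
         condition = condition, sensor = sensor, subject = subject),
    class = "trial_set"
  )
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf(
    "<trial_set> %d trials x %d samples @ %g Hz (%.1f ms epoch)\n",
    nrow(x$data), ncol(x$data), x$sampling_rate,
    1000 * ncol(x$data) / x$sampling_rate))
  lbl <- c(subject = x$subject, condition = x$condition, sensor = x$sensor)
  lbl <- lbl[!is.na(lbl)]
  if (length(lbl)) {
    cat("  ", paste(names(lbl), lbl, sep = ": ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.trial_set <- function(x) dim(x$data)

#' Tidy a trial set into long format
#'
#' @param x A [trial_set()].
#' @param ... Unused.
#' @return A tibble with columns `trial`, `time`, `value`.
#' @export
tidy.trial_set <- function(x, ...) {
  tibble::tibble(
    trial = rep(seq_len(nrow(x$data)), times = ncol(x$data)),
    time = rep(x$times, each = nrow(x$data)),
    value = as.vector(x$data)
  )
}

# Auto-detect the delimiter of a delimited text matrix (tab or comma).
.detect_sep <- function(first_line) {
  if (grepl("\t", first_line)) "\t" else ","
}

#' Read a trial set from a delimited text matrix
#'
#' The file holds one trial per row, numeric values separated by commas or
#' tabs (auto-detected). Metadata is taken either from arguments or, when
#' present, from a YAML sidecar `<path>.meta.yaml` written by
#' [write_trialset()]; explicit arguments override the sidecar.
#'
#' @param path Path to the matrix file.
#' @param sampling_rate,onset_index,condition,sensor,subject Metadata; see
#'   [trial_set()]. `sampling_rate` is required unless a sidecar exists.
#' @return A [trial_set()].
#' @export
read_trialset <- function(path, sampling_rate = NULL, onset_index = NULL,
                          condition = NULL, sensor = NULL, subject = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty trial file: ", path, call. = FALSE)
  sep <- .detect_sep(lines[[1L]])
  rows <- strsplit(lines, sep, fixed = TRUE)
  len <- lengths(rows)
  if (length(unique(len)) != 1L) {
    stop(sprintf("ragged rows in %s: row lengths {%s}", path,
                 paste(unique(len), collapse = ",")), call. = FALSE)
  }
  vals <- suppressWarnings(lapply(rows, as.numeric))
  bad <- which(vapply(vals, anyNA, logical(1)))
  if (length(bad)) {
    col <- which(is.na(vals[[bad[1L]]]))[1L]
    stop(sprintf("non-numeric cell in %s at row %d, col %d", path,
                 bad[1L], col), call. = FALSE)
  }
  data <- do.call(rbind, vals)
  if (nrow(data) < 2L) {
    stop("trial file must contain at least 2 trials", call. = FALSE)
  }

  meta <- list()
  sidecar <- paste0(path, ".meta.yaml")
  if (file.exists(sidecar)) meta <- yaml::read_yaml(sidecar)
  pick <- function(arg, key, default = NULL) {
    if (!is.null(arg)) arg else if (!is.null(meta[[key]])) meta[[key]]
    else default
  }
  sampling_rate <- pick(sampling_rate, "sampling_rate")
  if (is.null(sampling_rate)) {
    stop("sampling_rate not given and no metadata sidecar found for ", path,
         call. = FALSE)
  }
  trial_set(data,
            sampling_rate = sampling_rate,
            onset_index = pick(onset_index, "onset_index", 1L),
            condition = pick(condition, "condition", NA_character_),
            sensor = pick(sensor, "sensor", NA_character_),
            subject = pick(subject, "subject", NA_character_))
}

#' Write a trial set as delimited text plus a metadata sidecar
#'
#' Writes `ts$data` one trial per row (tab-separated, full double
#' precision) and a YAML sidecar `<path>.meta.yaml` holding the sampling
#' rate, onset index and labels, so [read_trialset()] can restore the
#' object without extra arguments.
#'
#' @param ts A [trial_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trialset <- function(ts, path) {
  stopifnot(inherits(ts, "trial_set"))
  lines <- apply(ts$data, 1L, function(r) {
    paste(formatC(r, format = "g", digits = 17), collapse = "\t")
  })
  tryCatch(writeLines(lines, path),
           error = function(e) stop("cannot write ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
  meta <- list(sampling_rate = ts$sampling_rate,
               onset_index = ts$onset_index,
               condition = ts$condition, sensor = ts$sensor,
               subject = ts$subject)
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}
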