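#' Pipeline configuration
#'
#' Bundles the tunable settings of the mining pipeline. Defaults are the
#' settings that maximized signal-to-noise in the reference analysis:
#' zero-phase FIR band-pass of design order 2 over 0.5-45 Hz, hub degree
#' threshold k = 4.
#'
#' @param filter_kind `"FIR"` or `"IIR"` (Butterworth band-pass).
#' @param filter_order Design order (the zero-phase forward-backward pass
#'   doubles the effective magnitude order). The optimization grid uses
#'   1-3; any integer >= 1 is accepted.
#' @param band Length-2 numeric, `(low, high)` band edges in Hz.
#' @param degree_k Hub degree threshold, integer in 1..8.
#' @param baseline_window Length-2 numeric window in seconds (half-open
#'   `[start, end)`), or `NULL` to use the first 25 ms of the epoch.
#' @param polarity `"negative"`, `"positive"` or `"absolute"` peak search.
#' @param post_stimulus_window Length-2 numeric window (s) for the peak
#'   search, half-open.
#' @param concatenate Filter the trials joined end-to-end and re-split
#'   (the reference procedure) rather than trial-by-trial.
#' @param seed Integer seed recorded in result provenance.
#'
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(filter_kind = c("FIR", "IIR"),
                            filter_order = 2L,
                            band = c(0.5, 45),
                            degree_k = 4L,
                            baseline_window = NULL,
                            polarity = c("negative", "positive", "absolute"),
                            post_stimulus_window = c(0, 0.4),
                            concatenate = TRUE,
                            seed = 1L) {
  filter_kind <- toupper(filter_kind)
  filter_kind <- match.arg(filter_kind, c("FIR", "IIR"))
  polarity <- match.arg(polarity)
  filter_order <- as.integer(filter_order)
  if (filter_order < 1L) stop("filter_order must be >= 1", call. = FALSE)
  band <- as.numeric(band)
  if (length(band) != 2L || !all(is.finite(band)) ||
      band[1L] <= 0 || band[1L] >= band[2L]) {
    stop("band must be (low, high) with 0 < low < high", call. = FALSE)
  }
  degree_k <- as.integer(degree_k)
  if (degree_k < 1L || degree_k > 8L) {
    stop("degree_k must lie in 1..8", call. = FALSE)
  }
  if (!is.null(baseline_window)) {
    baseline_window <- as.numeric(baseline_window)
    if (length(baseline_window) != 2L ||
        baseline_window[1L] >= baseline_window[2L]) {
      stop("baseline_window must be (start, end) with start < end",
           call. = FALSE)
    }
  }
  post_stimulus_window <- as.numeric(post_stimulus_window)
  if (length(post_stimulus_window) != 2L ||
      post_stimulus_window[1L] >= post_stimulus_window[2L]) {
    stop("post_stimulus_window must be (start, end) with start < end",
         call. = FALSE)
  }
  structure(
    list(filter_kind = filter_kind, filter_order = filter_order,
         band = band, degree_k = degree_k,
         baseline_window = baseline_window, polarity = polarity,
         post_stimulus_window = post_stimulus_window,
         concatenate = isTRUE(concatenate), seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf(
    "<pipeline_config> %s order %d, band %g-%g Hz, k = %d, polarity %s\n",
    x$filter_kind, x$filter_order, x$band[1L], x$band[2L], x$degree_k,
    x$polarity))
  invisible(x)
}

#' Read a pipeline configuration from a YAML file
#'
#' Absent keys fall back to the [pipeline_config()] defaults; unknown keys
#' raise an error so typos do not silently vanish.
#'
#' @param path Path to a YAML key/value document.
#' @return A [pipeline_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, raw)
}
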