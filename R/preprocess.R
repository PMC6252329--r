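#' Design a band-pass filter for zero-phase trial filtering
#'
#' Two families are supported. `"IIR"` is a Butterworth band-pass of the
#' given design order (from [signal::butter()]). `"FIR"` is a linear-phase
#' windowed-sinc band-pass whose tap count follows the EEG convention of
#' tying filter length to the low cut-off:
#' `taps = order * 3 * round(fs / low)` (rounded up to odd). The FIR taps
#' are re-centered (`h - mean(h)`) so the DC gain is exactly zero; the
#' perturbation elsewhere is negligible at these lengths.
#'
#' @param kind `"FIR"` or `"IIR"`.
#' @param order Design order, integer >= 1. The grid used by
#'   [optimize_settings()] restricts it to 1-3.
#' @param band `(low, high)` edges in Hz, strictly inside (0, Nyquist).
#' @param sampling_rate Sampling rate in Hz.
#' @return An opaque `trial_filter` handle reusable across trial sets with
#'   the same sampling rate.
#' @examples
#' f <- design_filter("IIR", 1, c(0.5, 45), 512)
#' @export
design_filter <- function(kind = c("FIR", "IIR"), order, band, sampling_rate) {
  kind <- match.arg(toupper(kind), c("FIR", "IIR"))
  order <- as.integer(order)
  if (order < 1L) stop("filter order must be >= 1", call. = FALSE)
  band <- as.numeric(band)
  nyq <- sampling_rate / 2
  if (length(band) != 2L || band[1L] <= 0 || band[1L] >= band[2L]) {
    stop("band must satisfy 0 < low < high", call. = FALSE)
  }
  if (band[2L] >= nyq) {
    stop(sprintf("band edge %g Hz is at or above Nyquist (%g Hz)",
                 band[2L], nyq), call. = FALSE)
  }
  wn <- band / nyq
  if (kind == "IIR") {
    bt <- signal::butter(order, wn, type = "pass")
    if (max(Mod(polyroot(rev(bt$a)))) >= 1) {
      stop("unstable IIR design at this order/band", call. = FALSE)
    }
    coef <- list(b = bt$b, a = bt$a)
  } else {
    taps <- order * 3L * round(sampling_rate / band[1L])
    if (taps %% 2L == 0L) taps <- taps + 1L          # odd => integer delay
    h <- signal::fir1(taps - 1L, wn, type = "pass")
    h <- h - mean(h)                                  # exact zero DC gain
    if (max(abs(h - rev(h))) > 1e-12) {
      stop("FIR design lost linear-phase symmetry", call. = FALSE)
    }
    coef <- list(h = h)
  }
  structure(
    list(kind = kind, order = order, band = band,
         sampling_rate = sampling_rate, coef = coef),
    class = "trial_filter"
  )
}

#' @export
print.trial_filter <- function(x, ...) {
  extra <- if (x$kind == "FIR") sprintf(", %d taps", length(x$coef$h)) else ""
  cat(sprintf("<trial_filter> %s order %d, %g-%g Hz @ %g Hz%s\n",
              x$kind, x$order, x$band[1L], x$band[2L], x$sampling_rate,
              extra))
  invisible(x)
}

# Reflection padding length used around each filtered segment.
.pad_length <- function(filt, n) {
  p <- 3 * max(1L, filt$order) * round(filt$sampling_rate / filt$band[1L])
  min(p, n - 1L)
}

# One forward pass of the filter over a plain numeric vector.
.filter_once <- function(filt, x) {
  if (filt$kind == "IIR") {
    as.numeric(signal::filter(filt$coef$b, filt$coef$a, x))
  } else {
    h <- filt$coef$h
    delay <- (length(h) - 1L) / 2L
    y <- stats::convolve(x, rev(h), type = "open")
    y[(delay + 1L):(delay + length(x))]
  }
}

# Zero-phase (forward-backward) filtering of one vector with reflection
# padding; FIR passes are already delay-compensated so the backward pass
# only squares the magnitude response.
.filtfilt_padded <- function(filt, x) {
  n <- length(x)
  p <- .pad_length(filt, n)
  if (n < 3L || p < 1L) stop("segment too short to filter", call. = FALSE)
  xp <- c(2 * x[1L] - x[(p + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - p)])
  y <- .filter_once(filt, xp)
  y <- rev(.filter_once(filt, rev(y)))
  y[(p + 1L):(p + n)]
}

#' Zero-phase band-pass filtering of a trial set
#'
#' Applies the designed filter forward and backward so the net phase
#' response is zero (a symmetric pulse keeps its peak sample; the
#' effective magnitude order doubles). With `concatenate = TRUE` the
#' trials are joined end-to-end, filtered once, and re-split — the
#' procedure used on the reference recordings; otherwise each trial is
#' filtered on its own. Edge transients are controlled by reflection
#' padding of length `3 * order * round(fs/low)`, capped at segment
#' length - 1.
#'
#' @param ts A [trial_set()].
#' @param filt A [design_filter()] handle (its sampling rate must match),
#'   or a [pipeline_config()] from which one is designed.
#' @param concatenate Join trials before filtering (default `TRUE`).
#' @return The filtered [trial_set()].
#' @export
zero_phase_filter <- function(ts, filt, concatenate = TRUE) {
  stopifnot(inherits(ts, "trial_set"))
  if (inherits(filt, "pipeline_config")) {
    concatenate <- filt$concatenate
    filt <- design_filter(filt$filter_kind, filt$filter_order, filt$band,
                          ts$sampling_rate)
  }
  stopifnot(inherits(filt, "trial_filter"))
  if (!isTRUE(all.equal(filt$sampling_rate, ts$sampling_rate))) {
    stop("filter was designed for a different sampling rate", call. = FALSE)
  }
  ns <- ncol(ts$data)
  if (concatenate) {
    x <- as.vector(t(ts$data))                 # trials end-to-end
    if (length(x) <= .fir_min_length(filt)) {
      stop("concatenated trials too short for this FIR length",
           call. = FALSE)
    }
    y <- .filtfilt_padded(filt, x)
    out <- matrix(y, nrow = nrow(ts$data), byrow = TRUE)
  } else {
    if (ns <= .fir_min_length(filt)) {
      stop("trials too short for this FIR length; use concatenate = TRUE ",
           "or a higher low edge", call. = FALSE)
    }
    out <- t(apply(ts$data, 1L, function(r) .filtfilt_padded(filt, r)))
  }
  ts$data <- out
  ts
}

.fir_min_length <- function(filt) {
  if (filt$kind == "FIR") length(filt$coef$h) else 9L
}

#' Baseline-correct each trial
#'
#' Subtracts, per trial, the mean over the samples falling in a half-open
#' time window `[start, end)` (seconds, 0 = stimulus onset). When the
#' epoch has no pre-stimulus segment the default window is the first
#' 25 ms of the epoch, the samples least driven by the response.
#'
#' @param ts A [trial_set()].
#' @param window Length-2 numeric `(start, end)` in seconds, or `NULL`
#'   for the first 25 ms of the epoch.
#' @return The corrected [trial_set()].
#' @export
baseline_correct <- function(ts, window = NULL) {
  stopifnot(inherits(ts, "trial_set"))
  if (is.null(window)) {
    window <- c(ts$times[1L], ts$times[1L] + 0.025)
  }
  idx <- which(ts$times >= window[1L] & ts$times < window[2L])
  if (!length(idx)) {
    stop(sprintf("baseline window [%g, %g) does not intersect the epoch",
                 window[1L], window[2L]), call. = FALSE)
  }
  means <- rowMeans(ts$data[, idx, drop = FALSE])
  ts$data <- ts$data - means
  ts
}

#' Remove the DC offset of each trial
#'
#' Subtracts each trial's mean over its full extent.
#'
#' @param ts A [trial_set()].
#' @return The zero-mean [trial_set()].
#' @export
remove_dc <- function(ts) {
  stopifnot(inherits(ts, "trial_set"))
  ts$data <- ts$data - rowMeans(ts$data)
  ts
}
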