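#' Peak amplitude and latency of an averaged waveform
#'
#' Finds the global extremum of the requested polarity inside a
#' post-onset search window (half-open `[start, end)` in seconds):
#' the maximum for `"positive"`, the minimum for `"negative"`, the
#' largest `|x|` for `"absolute"`. Ties are broken toward the earliest
#' latency. A flat window raises a degenerate-peak warning and returns
#' its earliest sample.
#'
#' @param waveform Numeric series (e.g. an [grand_average()] waveform),
#'   or an `evoked_estimate` (then `fs`/`onset_index` are taken from it).
#' @param fs Sampling rate in Hz.
#' @param onset_index 1-based index of the stimulus onset sample.
#' @param window Length-2 numeric `(start, end)` in seconds post-onset.
#' @param polarity `"negative"`, `"positive"` or `"absolute"`.
#' @return A `peak_estimate`: list with `amplitude` (signed, signal
#'   units), `latency` (seconds post-onset), `polarity`, `window`.
#' @examples
#' t <- seq(0, 0.4, by = 1/512)
#' w <- -exp(-(t - 0.15)^2 / (2 * 0.02^2))
#' peak_estimate(w, 512, 1, c(0, 0.4), "negative")
#' @export
peak_estimate <- function(waveform, fs = NULL, onset_index = NULL,
                          window = c(0, 0.4),
                          polarity = c("negative", "positive", "absolute")) {
  polarity <- match.arg(polarity)
  if (inherits(waveform, "evoked_estimate")) {
    fs <- waveform$sampling_rate
    onset_index <- waveform$onset_index
    waveform <- waveform$waveform
  }
  if (is.null(fs) || is.null(onset_index)) {
    stop("fs and onset_index are required for a plain numeric waveform",
         call. = FALSE)
  }
  times <- (seq_along(waveform) - onset_index) / fs
  idx <- which(times >= window[1L] & times < window[2L])
  if (!length(idx)) {
    stop(sprintf("search window [%g, %g) lies outside the epoch",
                 window[1L], window[2L]), call. = FALSE)
  }
  seg <- waveform[idx]
  score <- switch(polarity, positive = seg, negative = -seg,
                  absolute = abs(seg))
  if (max(score) - min(score) == 0) {
    warning("flat waveform in the search window; returning its first sample")
  }
  at <- idx[which.max(score)]  # which.max takes the earliest tie
  structure(
    list(amplitude = waveform[at], latency = times[at],
         polarity = polarity, window = window),
    class = "peak_estimate"
  )
}

#' @export
print.peak_estimate <- function(x, ...) {
  cat(sprintf("<peak_estimate> amplitude %.4g at %.1f ms (%s polarity)\n",
              x$amplitude, 1000 * x$latency, x$polarity))
  invisible(x)
}

#' Coefficient of variation of a group of estimates
#'
#' Two conventions are offered. `"paper"` is mean / sd — the form used in
#' the reference tables, which is the reciprocal of the textbook CV and
#' grows as the group gets *more* consistent. `"conventional"` is the
#' textbook sd / mean. The sd is the unbiased sample standard deviation.
#' The two are reciprocals whenever both are defined.
#'
#' @param values Numeric vector, `n >= 2`.
#' @param convention `"paper"` (mean/sd) or `"conventional"` (sd/mean).
#' @return A single number.
#' @examples
#' cv(c(2, 4))                     # 3 / sqrt(2)
#' cv(c(2, 4), "conventional")     # sqrt(2) / 3
#' @export
cv <- function(values, convention = c("paper", "conventional")) {
  convention <- match.arg(convention)
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  m <- mean(values)
  s <- stats::sd(values)
  denom <- if (convention == "paper") s else m
  if (denom == 0) {
    stop("undefined CV: zero ",
         if (convention == "paper") "standard deviation" else "mean",
         call. = FALSE)
  }
  if (convention == "paper") m / s else s / m
}

# Default analysis bands (Hz): the customary EEG division of 0.5-45 Hz.
.default_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha1 = c(8, 10),
       alpha2 = c(10, 13), beta1 = c(13, 20), beta2 = c(20, 30),
       gamma = c(30, 45))
}

#' Band-limited signal power of a waveform
#'
#' Periodogram-based power per frequency band: the one-sided periodogram
#' `|FFT|^2 / (n * fs)` (DC and Nyquist unhalved, interior bins doubled)
#' is integrated over each band (half-open `[lo, hi)` in Hz, times the
#' bin width `fs/n`). Summed over a full partition of `(0, Nyquist)` the
#' band powers recover the total power `mean(x^2)` up to the DC term
#' (Parseval).
#'
#' @param waveform Numeric series.
#' @param fs Sampling rate in Hz.
#' @param bands Named list of `(lo, hi)` pairs in Hz; default the seven
#'   delta-gamma bands over 0.5-45 Hz.
#' @return A tibble with columns `band`, `lo`, `hi`, `power`.
#' @export
band_power <- function(waveform, fs, bands = .default_bands()) {
  n <- length(waveform)
  nyq <- fs / 2
  for (b in bands) {
    if (b[1L] < 0 || b[2L] > nyq || b[1L] >= b[2L]) {
      stop(sprintf("band (%g, %g) outside (0, Nyquist = %g)",
                   b[1L], b[2L], nyq), call. = FALSE)
    }
  }
  spec <- Mod(stats::fft(waveform))^2 / (n * fs)
  nf <- floor(n / 2) + 1L
  freqs <- (seq_len(nf) - 1L) * fs / n
  pgram <- spec[seq_len(nf)]
  dbl <- rep(2, nf)
  dbl[1L] <- 1
  if (n %% 2L == 0L) dbl[nf] <- 1
  pgram <- pgram * dbl            # one-sided PSD, signal^2 / Hz
  df <- fs / n
  rows <- purrr::imap(bands, function(b, nm) {
    sel <- freqs >= b[1L] & freqs < b[2L]
    tibble::tibble(band = nm, lo = b[1L], hi = b[2L],
                   power = sum(pgram[sel]) * df)
  })
  dplyr::bind_rows(rows)
}
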