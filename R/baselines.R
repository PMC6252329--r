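# Comparator single-trial miners: PCA reconstruction, SVD components,
# and regression on mean/derivative (MLR) or on principal components of a
# shifted/compressed variability matrix (MLRd).

.evoked_from <- function(ts, waveform, n_selected, selected = integer()) {
  structure(
    list(waveform = as.numeric(waveform), times = ts$times,
         sampling_rate = ts$sampling_rate, onset_index = ts$onset_index,
         n_selected = n_selected, selected = selected),
    class = "evoked_estimate")
}

#' PCA-denoised evoked estimate
#'
#' Centers the trial matrix, takes its principal components, keeps the
#' smallest leading set whose cumulative explained variance exceeds
#' `variance_threshold`, reconstructs every trial from that set, and
#' averages the reconstructions (adding the mean back).
#'
#' @param ts A [trial_set()].
#' @param variance_threshold Fraction in (0, 1]; `1` keeps every
#'   component (exact reconstruction).
#' @return An `evoked_estimate` with extra fields `n_components`,
#'   `explained` (per-component variance fractions, summing to 1) and
#'   `scores`/`loadings` so individual component time courses remain
#'   retrievable.
#' @export
pca_baseline <- function(ts, variance_threshold = 0.95) {
  stopifnot(inherits(ts, "trial_set"))
  if (variance_threshold <= 0 || variance_threshold > 1) {
    stop("variance_threshold must lie in (0, 1]", call. = FALSE)
  }
  if (nrow(ts$data) <= 2L) stop("need more than 2 trials", call. = FALSE)
  pc <- stats::prcomp(ts$data, center = TRUE, scale. = FALSE)
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  ncomp <- if (variance_threshold == 1) length(explained) else
    which(cumsum(explained) > variance_threshold)[1L]
  keep <- seq_len(ncomp)
  recon <- pc$x[, keep, drop = FALSE] %*% t(pc$rotation[, keep, drop = FALSE])
  recon <- sweep(recon, 2L, pc$center, "+")
  out <- .evoked_from(ts, colMeans(recon), nrow(ts$data))
  out$n_components <- ncomp
  out$explained <- explained
  out$scores <- pc$x
  out$loadings <- pc$rotation
  out
}

#' Component time series from the SVD of the trial matrix
#'
#' Right singular vectors (sample-domain) of the raw trial matrix,
#' scaled by their singular values. When several components are
#' requested their scaled time courses are averaged, mirroring the usage
#' of mid-rank components (e.g. the 4th and 5th) as a denoised waveform.
#'
#' @param ts A [trial_set()].
#' @param components Integer vector of component indices (within the
#'   numerical rank of the matrix).
#' @return An `evoked_estimate` whose waveform is the (averaged) scaled
#'   component time series, with field `components`.
#' @export
svd_baseline <- function(ts, components = c(4L, 5L)) {
  stopifnot(inherits(ts, "trial_set"))
  components <- as.integer(components)
  sv <- svd(ts$data)
  rank <- sum(sv$d > sv$d[1L] * max(dim(ts$data)) * .Machine$double.eps)
  if (any(components < 1L | components > rank)) {
    stop(sprintf("component indices must lie in 1..%d (numerical rank)",
                 rank), call. = FALSE)
  }
  comp <- sweep(sv$v[, components, drop = FALSE], 2L, sv$d[components], "*")
  out <- .evoked_from(ts, rowMeans(comp), length(components))
  out$components <- components
  out
}

# Least-squares fit of each trial (restricted to idx) on the columns of X;
# returns fitted values (n_trials x length(idx)) and the coefficients.
.fit_trials <- function(data, idx, X) {
  qr_X <- qr(X)
  if (qr_X$rank < ncol(X)) {
    stop("degenerate regressor set (rank ", qr_X$rank, " < ", ncol(X), ")",
         call. = FALSE)
  }
  B <- qr.coef(qr_X, t(data[, idx, drop = FALSE]))
  list(fitted = t(X %*% B), coef = t(B))
}

#' Evoked estimate by multiple linear regression on the mean and its
#' derivative
#'
#' Builds two regressors from the within-interval average waveform: the
#' average itself and its temporal derivative (central differences).
#' Each trial is least-squares fitted on the pair within the interval;
#' the fitted trials are averaged. Samples outside the interval are zero
#' in the returned waveform.
#'
#' @param ts A [trial_set()].
#' @param interval Post-stimulus interval `(start, end)` in seconds,
#'   half-open; must lie within the epoch.
#' @return An `evoked_estimate` with field `coef` (n_trials x 2 fitted
#'   coefficients).
#' @export
mlr_baseline <- function(ts, interval = c(0, 0.3)) {
  stopifnot(inherits(ts, "trial_set"))
  idx <- which(ts$times >= interval[1L] & ts$times < interval[2L])
  if (!length(idx) || interval[2L] > max(ts$times) + 1 / ts$sampling_rate) {
    stop(sprintf("interval [%g, %g) does not fit the epoch (0..%g s)",
                 interval[1L], interval[2L], max(ts$times)), call. = FALSE)
  }
  avg <- colMeans(ts$data[, idx, drop = FALSE])
  n <- length(avg)
  deriv <- c(avg[2L] - avg[1L],
             (avg[3L:n] - avg[1L:(n - 2L)]) / 2,
             avg[n] - avg[n - 1L]) * ts$sampling_rate
  if (stats::sd(deriv) == 0) {
    stop("flat average: derivative regressor is degenerate", call. = FALSE)
  }
  fit <- .fit_trials(ts$data, idx, cbind(mean = avg, deriv = deriv))
  wave <- numeric(ncol(ts$data))
  wave[idx] <- colMeans(fit$fitted)
  out <- .evoked_from(ts, wave, nrow(ts$data))
  out$coef <- fit$coef
  out$interval <- interval
  out
}

#' Evoked estimate by regression on a shifted/compressed variability basis
#'
#' The MLR-with-dispersion variant: (1) the within-interval average
#' waveform is shifted over `shift_grid` and time-compressed over
#' `compress_grid` (linear resampling about the interval start), every
#' variant stacked into a variability matrix of
#' `length(shift_grid) * length(compress_grid)` rows; (2) principal
#' components of that stack are taken (row order is immaterial); (3) the
#' three leading components become regressors; (4) each trial is
#' least-squares fitted within the interval and the fitted trials
#' averaged.
#'
#' @param ts A [trial_set()].
#' @param interval Post-stimulus interval (s), half-open; clipped to the
#'   epoch.
#' @param shift_grid Latency shifts in seconds (default -50..50 ms in
#'   5 ms steps).
#' @param compress_grid Time-compression factors (default 0.8..1.2).
#' @return An `evoked_estimate` with fields `coef` (n_trials x 3),
#'   `variability_matrix`, `regressors`.
#' @export
mlrd_baseline <- function(ts, interval = c(0, 0.5),
                          shift_grid = seq(-0.05, 0.05, by = 0.005),
                          compress_grid = c(0.8, 0.9, 1.0, 1.1, 1.2)) {
  stopifnot(inherits(ts, "trial_set"))
  if (!length(shift_grid) || !length(compress_grid)) {
    stop("shift and compression grids must be non-empty", call. = FALSE)
  }
  interval[2L] <- min(interval[2L], max(ts$times) + 1 / ts$sampling_rate)
  idx <- which(ts$times >= interval[1L] & ts$times < interval[2L])
  if (length(idx) < 4L) stop("interval too short", call. = FALSE)
  avg <- colMeans(ts$data[, idx, drop = FALSE])
  tt <- ts$times[idx]
  t0 <- tt[1L]
  variants <- tidyr::expand_grid(shift = shift_grid,
                                 compress = compress_grid)
  V <- do.call(rbind, purrr::pmap(variants, function(shift, compress) {
    # sample the average at compressed, shifted time points; flat beyond
    src <- t0 + (tt - t0) * compress + shift
    stats::approx(tt, avg, xout = src, rule = 2)$y
  }))
  if (nrow(V) < 3L) {
    stop("variability matrix has rank < 3; enlarge the shift or ",
         "compression grids", call. = FALSE)
  }
  pc <- stats::prcomp(V, center = TRUE, scale. = FALSE)
  if (sum(pc$sdev > pc$sdev[1L] * 1e-8, na.rm = TRUE) < 3L) {
    stop("variability matrix has rank < 3; enlarge the shift or ",
         "compression grids", call. = FALSE)
  }
  X <- pc$rotation[, 1:3, drop = FALSE]
  fit <- .fit_trials(ts$data, idx, X)
  wave <- numeric(ncol(ts$data))
  wave[idx] <- colMeans(fit$fitted)
  out <- .evoked_from(ts, wave, nrow(ts$data))
  out$coef <- fit$coef
  out$variability_matrix <- V
  out$regressors <- X
  out$interval <- interval
  out
}
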