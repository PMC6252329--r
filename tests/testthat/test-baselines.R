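# Rank-1 fixture: every trial is a scaled copy of the same template.
rank1_trialset <- function(n = 12, seed = 1) {
  set.seed(seed)
  a <- runif(n, 0.5, 2)
  tpl <- mmn_template()
  list(ts = trial_set(outer(a, tpl), 512), a = a, template = tpl)
}

cosine <- function(x, y) abs(sum(x * y)) / sqrt(sum(x^2) * sum(y^2))

test_that("PCA baseline: rank-1 data needs one component and reconstructs
           exactly", {
  fx <- rank1_trialset()
  est <- pca_baseline(fx$ts)
  expect_identical(est$n_components, 1L)
  expect_equal(est$waveform, mean(fx$a) * fx$template, tolerance = 1e-9)
  expect_gt(cosine(est$waveform, fx$template), 0.999)

  # threshold 1 keeps everything: reconstruction equals the plain mean
  noisy <- random_trialset(10, 40, seed = 2)
  all_comp <- pca_baseline(noisy, variance_threshold = 1)
  expect_equal(all_comp$waveform, colMeans(noisy$data), tolerance = 1e-9)
  expect_equal(sum(all_comp$explained), 1, tolerance = 1e-9)

  expect_error(pca_baseline(noisy, variance_threshold = 1.5), "0, 1")
  expect_error(pca_baseline(trial_set(matrix(rnorm(8), 2, 4), 512)),
               "more than 2 trials")
})

test_that("SVD baseline: leading component of rank-1 data is the template", {
  fx <- rank1_trialset()
  est <- svd_baseline(fx$ts, components = 1L)
  expect_gt(cosine(est$waveform, fx$template), 0.999)

  # requesting components beyond the numerical rank fails
  lowrank <- trial_set(outer(runif(8), 1:20) +
                         outer(runif(8), sin(1:20)) +
                         outer(runif(8), cos(1:20)), 512)
  expect_error(svd_baseline(lowrank, components = c(4L, 5L)), "rank")
})

test_that("MLR baseline recovers per-trial scales on noiseless rank-1 data", {
  fx <- rank1_trialset()
  est <- mlr_baseline(fx$ts, interval = c(0, 0.3))
  idx <- which(fx$ts$times >= 0 & fx$ts$times < 0.3)
  expect_equal(est$waveform[idx], mean(fx$a) * fx$template[idx],
               tolerance = 1e-9)
  # fitted mean-regressor coefficients recover each scale up to the
  # common normalization a_i / mean(a)
  expect_equal(est$coef[, "mean"] / est$coef[1, "mean"],
               fx$a / fx$a[1], tolerance = 1e-9)
  expect_gt(cosine(est$waveform[idx], fx$template[idx]), 0.999)

  expect_error(mlr_baseline(fx$ts, interval = c(0, 1)), "does not fit")
  flat <- trial_set(matrix(rep(c(1, 2), each = 20), 2, 20, byrow = TRUE),
                    512)
  expect_error(mlr_baseline(flat, interval = c(0, 0.03)), "degenerate")
})

test_that("MLR projects out regressor-orthogonal noise", {
  fx <- rank1_trialset(n = 30, seed = 5)
  idx <- which(fx$ts$times >= 0 & fx$ts$times < 0.3)
  set.seed(6)
  # noise orthogonalized against the two regressors inside the interval
  avg <- colMeans(fx$ts$data[, idx])
  n <- length(avg)
  deriv <- c(avg[2] - avg[1], (avg[3:n] - avg[1:(n - 2)]) / 2,
             avg[n] - avg[n - 1])
  X <- cbind(avg, deriv)
  P <- X %*% solve(crossprod(X)) %*% t(X)
  E <- matrix(rnorm(nrow(fx$ts$data) * n), nrow(fx$ts$data), n)
  E <- E %*% (diag(n) - P)          # orthogonal to both regressors
  E <- sweep(E, 2L, colMeans(E))    # zero-sum: the average is unchanged
  noisy <- fx$ts
  noisy$data[, idx] <- noisy$data[, idx] + E
  est <- mlr_baseline(noisy, interval = c(0, 0.3))
  expect_equal(est$waveform[idx], mean(fx$a) * fx$template[idx],
               tolerance = 1e-8)
})

test_that("MLRd: variability-matrix geometry and latency recovery", {
  fx <- rank1_trialset()
  shift_grid <- seq(-0.05, 0.05, by = 0.01)
  est <- mlrd_baseline(fx$ts, shift_grid = shift_grid,
                       compress_grid = c(0.9, 1.0, 1.1))
  expect_identical(nrow(est$variability_matrix),
                   length(shift_grid) * 3L)
  expect_identical(ncol(est$coef), 3L)

  # trials shifted by grid values, no noise: fitted average peaks at the
  # mean true shift
  shifts <- rep(c(-0.02, 0, 0.02), length.out = 8)
  tt <- (seq_len(205) - 1) / 512
  sh <- t(vapply(shifts, function(s) {
    sigma <- 0.060 / (2 * sqrt(2 * log(2)))
    -exp(-(tt - 0.150 - s)^2 / (2 * sigma^2))
  }, numeric(205)))
  ts2 <- trial_set(sh, 512)
  est2 <- mlrd_baseline(ts2, shift_grid = shift_grid,
                        compress_grid = c(0.9, 1.0, 1.1))
  pk <- peak_estimate(est2$waveform, 512, 1L, c(0.05, 0.35), "negative")
  expect_lt(abs(pk$latency - (0.150 + mean(shifts))), 1.5 / 512)

  expect_error(mlrd_baseline(fx$ts, shift_grid = 0, compress_grid = 1),
               "rank < 3")
})

test_that("the three baselines agree on noiseless rank-1 data", {
  fx <- rank1_trialset(seed = 9)
  idx <- which(fx$ts$times >= 0 & fx$ts$times < 0.3)
  p <- pca_baseline(fx$ts)$waveform[idx]
  s <- svd_baseline(fx$ts, 1L)$waveform[idx]
  m <- mlr_baseline(fx$ts, c(0, 0.3))$waveform[idx]
  tpl <- fx$template[idx]
  expect_gt(cosine(p, tpl), 0.999)
  expect_gt(cosine(s, tpl), 0.999)
  expect_gt(cosine(m, tpl), 0.999)
})
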