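test_that("design_filter validates bands and produces the stated designs", {
  f <- design_filter("IIR", 1, c(0.5, 45), 512)
  expect_identical(f$kind, "IIR")
  # stable Butterworth: poles inside the unit circle
  expect_lt(max(Mod(polyroot(rev(f$coef$a)))), 1)

  g <- design_filter("FIR", 2, c(0.5, 45), 512)
  h <- g$coef$h
  expect_equal(h, rev(h))                    # linear phase (symmetric taps)
  expect_equal(sum(h), 0, tolerance = 1e-15) # exact DC null
  expect_identical(length(h), as.integer(2 * 3 * round(512 / 0.5) + 1))

  expect_error(design_filter("FIR", 2, c(0.5, 300), 512), "Nyquist")
  expect_error(design_filter("IIR", 0, c(0.5, 45), 512), "order")
  expect_error(design_filter("IIR", 1, c(45, 0.5), 512), "low < high")
})

test_that("zero-phase filtering keeps a symmetric pulse's argmax", {
  n <- 1024
  x <- exp(-((seq_len(n) - 400)^2) / (2 * 20^2))
  ts <- trial_set(rbind(x, x), 512)
  for (spec in list(design_filter("IIR", 1, c(0.5, 45), 512),
                    design_filter("FIR", 1, c(2, 45), 512))) {
    out <- zero_phase_filter(ts, spec, concatenate = FALSE)
    expect_identical(which.max(out$data[1, ]), which.max(x))
  }
})

test_that("band-pass response: out-of-band tones and DC are annihilated", {
  fs <- 512
  n <- 8192
  tt <- (seq_len(n) - 1) / fs
  tone100 <- sin(2 * pi * 100 * tt)
  ts <- trial_set(rbind(tone100, tone100), fs)
  # steady-state region: beyond the FIR kernel reach and the slow ringing
  # of the near-unit-circle 0.5 Hz IIR poles
  mid <- 3000:(n - 3000)
  for (spec in list(design_filter("IIR", 3, c(0.5, 45), fs),
                    design_filter("FIR", 2, c(2, 45), fs))) {
    out <- zero_phase_filter(ts, spec, concatenate = FALSE)
    expect_lt(sqrt(mean(out$data[1, mid]^2)) / sqrt(mean(tone100[mid]^2)),
              0.01)
  }

  # constant trials through the 0.5 Hz high-pass edge, both families
  dc <- trial_set(matrix(1, 128, 205), fs)
  for (spec in list(design_filter("FIR", 2, c(0.5, 45), fs),
                    design_filter("IIR", 2, c(0.5, 45), fs))) {
    res <- zero_phase_filter(dc, spec, concatenate = TRUE)
    expect_lt(max(abs(res$data)), 1e-6)
  }
})

test_that("filtering is linear", {
  set.seed(42)
  fs <- 512
  x <- rnorm(512); y <- rnorm(512)
  f <- design_filter("IIR", 2, c(0.5, 45), fs)
  lin <- function(v) {
    zero_phase_filter(trial_set(rbind(v, v), fs), f,
                      concatenate = FALSE)$data[1, ]
  }
  lhs <- lin(3 * x - 2 * y)
  rhs <- 3 * lin(x) - 2 * lin(y)
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("per-trial FIR filtering refuses too-short trials", {
  ts <- trial_set(matrix(rnorm(2 * 205), 2, 205), 512)
  f <- design_filter("FIR", 2, c(0.5, 45), 512)  # 6145 taps
  expect_error(zero_phase_filter(ts, f, concatenate = FALSE), "too short")
})

test_that("baseline correction subtracts the window mean per trial", {
  ts <- trial_set(rbind(c(1, 1, 1, 5), c(2, 2, 2, 0)), sampling_rate = 1)
  out <- baseline_correct(ts, window = c(0, 3))  # first 3 samples
  expect_equal(out$data, rbind(c(0, 0, 0, 4), c(0, 0, 0, -2)))

  # already zero-mean window: unchanged; and idempotence on random data
  expect_equal(baseline_correct(out, c(0, 3))$data, out$data)
  r <- random_trialset(128, 205, seed = 5)
  b <- baseline_correct(r)
  idx <- which(b$times >= b$times[1] & b$times < b$times[1] + 0.025)
  expect_lt(max(abs(rowMeans(b$data[, idx]))), 1e-12)
  expect_equal(baseline_correct(b)$data, b$data, tolerance = 1e-12)

  expect_error(baseline_correct(ts, c(10, 11)), "does not intersect")
})

test_that("remove_dc zeroes every trial mean and is idempotent", {
  expect_equal(remove_dc(trial_set(rbind(c(2, 2, 2), c(1, 2, 3)), 1))$data,
               rbind(c(0, 0, 0), c(-1, 0, 1)))
  r <- remove_dc(random_trialset(50, 64, seed = 9))
  expect_lt(max(abs(rowMeans(r$data))), 1e-12)
  expect_equal(remove_dc(r)$data, r$data, tolerance = 1e-12)
})
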