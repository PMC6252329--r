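test_that("SNR formula: hand-computed example and degenerate cases", {
  ts <- trial_set(rbind(c(1, 1, 0), c(-1, 3, 0)), 512)
  expect_equal(trial_snr(ts), 2, tolerance = 1e-14)

  x <- rnorm(30)
  expect_warning(capped <- trial_snr(trial_set(rbind(x, x, x), 512)),
                 "zero residual")
  expect_identical(capped, 1e12)

  expect_error(trial_snr(ts, 1L), "2 selected trials")
})

test_that("SNR strictly decreases as additive noise variance grows", {
  set.seed(4)
  template <- mmn_template()
  sigs <- sapply(c(0.05, 0.1, 0.2, 0.4, 0.8), function(s) {
    noisy <- t(replicate(40, template + rnorm(205, sd = s)))
    trial_snr(trial_set(noisy, 512))
  })
  expect_true(all(diff(sigs) < 0))
})

test_that("grand_average is the sample-wise mean of the selection", {
  ts <- trial_set(rbind(c(0, 2, 1), c(2, 0, 1), c(5, 5, 5)), 512)
  expect_equal(grand_average(ts, 1:2)$waveform, c(1, 1, 1))
  expect_equal(grand_average(ts, 3L)$waveform, c(5, 5, 5))
  expect_error(grand_average(ts, integer()), "empty")
  expect_error(grand_average(ts, 9L), "out of range")

  # mean-of-all decomposes into selected/unselected weighted means
  r <- random_trialset(20, 30, seed = 6)
  sel <- 1:7
  lhs <- colMeans(r$data)
  rhs <- (7 * grand_average(r, sel)$waveform +
            13 * grand_average(r, 8:20)$waveform) / 20
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("select_trials is deterministic and permutation-equivariant", {
  sim <- simulate_trials(sim_config(n_trials = 48L, seed = 19))
  cfg <- pipeline_config(degree_k = 3)
  s1 <- select_trials(sim$trials, cfg)
  s2 <- select_trials(sim$trials, cfg)
  expect_identical(s1$selected, s2$selected)

  # the core chain (DM -> MDS -> GG -> hubs) is permutation-equivariant;
  # tested without the filter stage, whose concatenated application mixes
  # information across trial boundaries by design
  c1 <- select_trials(sim$trials, cfg, filter = FALSE)
  set.seed(1)
  perm <- sample(48)
  shuffled <- sim$trials
  shuffled$data <- sim$trials$data[perm, ]
  s3 <- select_trials(shuffled, cfg, filter = FALSE)
  expect_setequal(perm[s3$selected], c1$selected)
})

test_that("identical trials collapse to one representative expanded to all", {
  x <- mmn_template()
  ts <- trial_set(matrix(rep(x, each = 16), 16, 205), 512)
  sel <- select_trials(ts, pipeline_config(), filter = FALSE)
  expect_identical(sel$selected, 1:16)
})

test_that("hub selection shrinks as the degree threshold rises", {
  sim <- simulate_trials(sim_config(seed = 7))
  n3 <- length(select_trials(sim$trials, pipeline_config(degree_k = 3))$selected)
  n4 <- length(select_trials(sim$trials, pipeline_config(degree_k = 4))$selected)
  expect_gt(n4, 1); expect_lt(n4, 128)
  expect_lt(n4, n3)
})

test_that("tidy/glance expose the mining result as tibbles", {
  sim <- simulate_trials(sim_config(n_trials = 32L, seed = 2))
  res <- mine_trials(sim$trials, pipeline_config(degree_k = 2))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 32L)
  expect_identical(sum(td$hub), length(res$selection$selected))
  expect_true(all(td$degree[td$hub] >= 2))
  gl <- glance(res)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$n_selected, length(res$selection$selected))
})

test_that("optimizer: one-cell grid scores the unique winner 100", {
  sim <- simulate_trials(sim_config(n_trials = 32L, seed = 23))
  cells <- list(fz_dev = sim$trials)
  opt <- optimize_settings(cells)
  expect_identical(opt$n_cells, 1L)
  expect_identical(nrow(opt$scores), 24L)

  # independent exhaustive evaluation of the same grid
  best <- NULL; best_snr <- -Inf
  for (fk in c("FIR", "IIR")) for (ord in 1:3) for (k in 1:4) {
    cfg <- pipeline_config(filter_kind = fk, filter_order = ord,
                           degree_k = k)
    snr <- tryCatch({
      sel <- select_trials(sim$trials, cfg)
      trial_snr(attr(sel, "filtered"), sel)
    }, error = function(e) NA_real_)
    if (is.finite(snr) && snr > best_snr) {
      best_snr <- snr; best <- c(fk, ord, k)
    }
  }
  w <- opt$winner
  expect_identical(c(w$filter_kind, w$order, w$k),
                   c(best[1], as.integer(best[2]), as.integer(best[3])),
                   ignore_attr = TRUE)
  expect_equal(w$score, 100)
  # in a one-cell grid with a unique max, every other combo scores 0
  expect_identical(sum(opt$scores$score == 100), 1L)
  expect_true(all(opt$scores$score %in% c(0, 100)))
})

test_that("optimizer winner does not depend on cell order", {
  s1 <- simulate_trials(sim_config(n_trials = 24L, seed = 31))
  s2 <- simulate_trials(sim_config(n_trials = 24L, snr_target = 2,
                                   seed = 32))
  a <- optimize_settings(list(one = s1$trials, two = s2$trials))
  b <- optimize_settings(list(two = s2$trials, one = s1$trials))
  expect_identical(a$winner, b$winner)
  expect_identical(dplyr::arrange(a$scores, filter_kind, order, k),
                   dplyr::arrange(b$scores, filter_kind, order, k))
})

test_that("subsampling curve has the 17-point grid and matches the full
           run at 100%", {
  sim <- simulate_trials(sim_config(n_trials = 64L, seed = 13))
  cfg <- pipeline_config(degree_k = 3)
  curve <- subsampling_curve(sim$trials, cfg)
  expect_identical(nrow(curve), 17L)
  expect_equal(curve$fraction, seq(0.20, 1.00, by = 0.05))
  full <- mine_trials(sim$trials, cfg)
  last <- curve[nrow(curve), ]
  expect_equal(last$snr, full$snr)
  expect_equal(last$amplitude, full$peak$amplitude)
  expect_equal(last$latency, full$peak$latency)
})

test_that("late-curve amplitude estimates are near the full-set estimate", {
  sim <- simulate_trials(sim_config(seed = 29, snr_target = 2))
  curve <- subsampling_curve(sim$trials,
                             fractions = c(0.85, 0.90, 0.95, 1.00))
  ref <- curve$amplitude[curve$fraction == 1]
  expect_true(all(abs(curve$amplitude - ref) <= 0.10 * abs(ref)))
})
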