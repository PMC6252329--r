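#' Select representative trials by the graph-based pipeline
#'
#' Runs the full mining chain on one condition's epochs:
#' zero-phase band-pass filter, baseline correction, pairwise
#' distance-correlation distances ([similarity_matrix()]), planar
#' embedding by classical MDS ([mds_embed()]), Gabriel graph
#' ([gabriel_graph()]), and hub selection by degree threshold
#' ([select_hubs()]). Every stage is deterministic, so repeated runs on
#' the same input are bit-identical, and permuting the trial order
#' permutes the selection accordingly.
#'
#' If all trials embed to a single point (e.g. identical trials) the
#' degenerate graph has no edges to threshold; the single representative
#' is selected and expanded back to all trials.
#'
#' @param ts A [trial_set()].
#' @param cfg A [pipeline_config()].
#' @param filter Apply the filtering/baseline stages (set `FALSE` when
#'   `ts` is already preprocessed).
#' @return A [select_hubs()] result with the embedded coordinates
#'   attached as attribute `"points"` and the filtered set as `"filtered"`.
#' @export
select_trials <- function(ts, cfg = pipeline_config(), filter = TRUE) {
  stopifnot(inherits(ts, "trial_set"), inherits(cfg, "pipeline_config"))
  if (filter) {
    ts <- zero_phase_filter(ts, cfg)
    ts <- baseline_correct(ts, cfg$baseline_window)
  }
  dm <- similarity_matrix(ts)
  pts <- suppressWarnings(mds_embed(dm))
  if (max(abs(sweep(pts, 2L, pts[1L, ]))) == 0) {
    # all trials coincide: the lone representative stands for everyone
    sel <- structure(
      list(selected = seq_len(nrow(ts$data)), k = cfg$degree_k,
           degrees = tibble::tibble(node = 1L, degree = 0L)),
      class = "hub_selection")
  } else {
    g <- gabriel_graph(pts)
    sel <- tryCatch(
      select_hubs(g, cfg$degree_k),
      error = function(e) stop(conditionMessage(e),
                               "; consider degree_k = ", cfg$degree_k - 1L,
                               call. = FALSE))
  }
  attr(sel, "points") <- pts
  attr(sel, "filtered") <- ts
  sel
}

#' Average the selected trials into an evoked estimate
#'
#' @param ts A [trial_set()] (use the filtered set carried by
#'   [select_trials()] for a fully preprocessed average).
#' @param sel A `hub_selection` or integer vector of trial indices.
#' @return An `evoked_estimate`: list with `waveform`, `times`,
#'   `sampling_rate`, `onset_index`, `n_selected`, `selected`.
#' @export
grand_average <- function(ts, sel) {
  stopifnot(inherits(ts, "trial_set"))
  idx <- if (inherits(sel, "hub_selection")) sel$selected else
    as.integer(sel)
  if (!length(idx)) stop("empty selection", call. = FALSE)
  if (any(idx < 1L | idx > nrow(ts$data))) {
    stop("selection indices out of range", call. = FALSE)
  }
  structure(
    list(waveform = colMeans(ts$data[idx, , drop = FALSE]),
         times = ts$times, sampling_rate = ts$sampling_rate,
         onset_index = ts$onset_index,
         n_selected = length(idx), selected = idx),
    class = "evoked_estimate"
  )
}

#' @export
print.evoked_estimate <- function(x, ...) {
  cat(sprintf("<evoked_estimate> mean of %d trial(s), %d samples @ %g Hz\n",
              x$n_selected, length(x$waveform), x$sampling_rate))
  invisible(x)
}

#' Signal-to-noise ratio of a trial selection
#'
#' `SNR = P_signal / P_noise`: the mean squared value of the
#' selected-trial average, over the mean (across selected trials) of the
#' mean squared residual trial - average. Identical trials give zero
#' residual power; the ratio is then capped at `1e12` with a warning.
#' With `sel = NULL` all trials are used — the "plain average" reference
#' the hub selection is compared against.
#'
#' @param ts A [trial_set()].
#' @param sel A `hub_selection`, an integer index vector, or `NULL` for
#'   all trials. At least 2 trials must be selected.
#' @return A single non-negative number.
#' @export
trial_snr <- function(ts, sel = NULL) {
  stopifnot(inherits(ts, "trial_set"))
  idx <- if (is.null(sel)) seq_len(nrow(ts$data))
         else if (inherits(sel, "hub_selection")) sel$selected
         else as.integer(sel)
  if (length(idx) < 2L) {
    stop("SNR needs >= 2 selected trials (noise power is undefined for 1)",
         call. = FALSE)
  }
  x <- ts$data[idx, , drop = FALSE]
  avg <- colMeans(x)
  p_signal <- mean(avg^2)
  resid <- sweep(x, 2L, avg)
  p_noise <- mean(rowMeans(resid^2))
  if (p_noise == 0) {
    warning("zero residual power (identical selected trials); SNR capped")
    return(1e12)
  }
  p_signal / p_noise
}

#' Run the whole mining pipeline and report the result
#'
#' Convenience wrapper: [select_trials()], [grand_average()] on the
#' filtered trials, [trial_snr()], peak estimation
#' ([peak_estimate()]) and hub-scatter variability
#' ([hub_variability_ge()]), bundled with the configuration for
#' replayability.
#'
#' @param ts A [trial_set()].
#' @param cfg A [pipeline_config()].
#' @param filter Apply the filtering/baseline stages (see
#'   [select_trials()]).
#' @return An `st_mining` object; see [tidy.st_mining()] and
#'   [glance.st_mining()].
#' @export
mine_trials <- function(ts, cfg = pipeline_config(), filter = TRUE) {
  sel <- select_trials(ts, cfg, filter = filter)
  fts <- attr(sel, "filtered")
  avg <- grand_average(fts, sel)
  snr <- trial_snr(fts, sel)
  peak <- peak_estimate(avg$waveform, fts$sampling_rate, fts$onset_index,
                        window = cfg$post_stimulus_window,
                        polarity = cfg$polarity)
  pts <- attr(sel, "points")
  ge <- if (length(sel$selected) >= 2L && nrow(unique(pts)) > 1L) {
    suppressWarnings(hub_variability_ge(pts, sel))
  } else NA_real_
  structure(
    list(selection = sel, average = avg, snr = snr, peak = peak, ge = ge,
         points = pts, config = cfg,
         snr_all = trial_snr(fts, NULL),
         trial_set = fts),
    class = "st_mining"
  )
}

#' @export
print.st_mining <- function(x, ...) {
  cat(sprintf(
    paste0("<st_mining> %d/%d trials selected (k = %d)\n",
           "  SNR %.3f (all-trial SNR %.3f), amplitude %.3f, ",
           "latency %.1f ms, GE %.3f\n"),
    length(x$selection$selected), nrow(x$trial_set$data),
    x$config$degree_k, x$snr, x$snr_all, x$peak$amplitude,
    1000 * x$peak$latency, x$ge))
  invisible(x)
}

#' Per-trial table for a mining result
#'
#' @param x An [mine_trials()] result.
#' @param ... Unused.
#' @return A tibble with one row per trial: embedded coordinates,
#'   Gabriel degree, and hub status.
#' @export
tidy.st_mining <- function(x, ...) {
  pts <- x$points
  map <- x$selection$degrees
  # degree per original trial (duplicates share the collapsed node degree)
  key <- paste(pts[, 1L], pts[, 2L], sep = "\r")
  node <- match(key, key[!duplicated(key)])
  deg <- map$degree[node]
  is_hub <- seq_len(nrow(pts)) %in% x$selection$selected
  tibble::tibble(
    trial = seq_len(nrow(pts)),
    x = pts[, 1L], y = pts[, 2L],
    degree = deg,
    hub = is_hub
  )
}

#' One-row summary of a mining result
#'
#' @param x An [mine_trials()] result.
#' @param ... Unused.
#' @return A one-row tibble: selection size, SNR of selection and of the
#'   all-trial average, peak amplitude/latency, variability GE.
#' @export
glance.st_mining <- function(x, ...) {
  tibble::tibble(
    n_trials = nrow(x$trial_set$data),
    n_selected = length(x$selection$selected),
    degree_k = x$config$degree_k,
    snr = x$snr, snr_all = x$snr_all,
    amplitude = x$peak$amplitude, latency = x$peak$latency,
    ge = x$ge
  )
}

# The 24-combination settings grid: filter kind x order x degree k.
.settings_grid <- function() {
  g <- expand.grid(filter_kind = c("FIR", "IIR"), order = 1:3, k = 1:4,
                   stringsAsFactors = FALSE)
  tibble::as_tibble(g)
}

#' Optimize filter and degree settings by SNR attainment
#'
#' For every cell of a (stimulus x sensor) collection, runs the mining
#' pipeline under all 24 combinations of filter kind (FIR/IIR), design
#' order (1-3) and degree threshold k (1-4), all at the configured band.
#' Each combination is scored as the percentage of cells in which it
#' attains the cell's maximum SNR; the winner is the top-scoring
#' combination, ties broken toward FIR over IIR, lower order, higher k.
#'
#' A combination that fails in a cell (e.g. an empty hub set at that k)
#' simply does not score there; a cell failing under every combination is
#' excluded with a warning.
#'
#' @param cells A named list of [trial_set()]s, one per
#'   (stimulus, sensor) cell.
#' @param base_cfg Settings shared by all combinations (band, baseline,
#'   windows); its filter/order/k fields are overridden by the grid.
#' @return An `optimization_result`: list with `grid` (tibble: one row
#'   per combo x cell with the attained SNR), `scores` (tibble: combo,
#'   score percentage), and `winner` (one-row tibble).
#' @export
optimize_settings <- function(cells, base_cfg = pipeline_config()) {
  if (!length(cells)) stop("need at least one cell", call. = FALSE)
  if (is.null(names(cells))) names(cells) <- paste0("cell", seq_along(cells))
  combos <- .settings_grid()
  per_cell <- purrr::imap(cells, function(ts, cell) {
    snrs <- purrr::pmap_dbl(combos, function(filter_kind, order, k) {
      cfg <- base_cfg
      cfg$filter_kind <- filter_kind
      cfg$filter_order <- as.integer(order)
      cfg$degree_k <- as.integer(k)
      tryCatch({
        sel <- select_trials(ts, cfg)
        trial_snr(attr(sel, "filtered"), sel)
      }, error = function(e) NA_real_)
    })
    dplyr::mutate(combos, cell = cell, snr = snrs)
  })
  grid <- dplyr::bind_rows(per_cell)
  ok_cells <- grid |>
    dplyr::summarise(any_ok = any(is.finite(.data$snr)),
                     .by = "cell")
  dropped <- ok_cells$cell[!ok_cells$any_ok]
  if (length(dropped)) {
    warning("cell(s) failed under every combination and were excluded: ",
            paste(dropped, collapse = ", "))
    grid <- dplyr::filter(grid, !.data$cell %in% dropped)
  }
  if (!nrow(grid)) stop("no cell succeeded under any combination",
                        call. = FALSE)
  n_cells <- length(unique(grid$cell))
  attain <- grid |>
    dplyr::mutate(best = .data$snr >= max(.data$snr, na.rm = TRUE) &
                    is.finite(.data$snr), .by = "cell")
  scores <- attain |>
    dplyr::summarise(score = 100 * sum(.data$best) / n_cells,
                     .by = c("filter_kind", "order", "k"))
  # tie-break: FIR before IIR, lower order, higher k
  scores <- scores[order(-scores$score,
                         scores$filter_kind != "FIR",
                         scores$order, -scores$k), ]
  winner <- scores[1L, ]
  structure(list(grid = grid, scores = tibble::as_tibble(scores),
                 winner = tibble::as_tibble(winner), n_cells = n_cells),
            class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  w <- x$winner
  cat(sprintf(
    "<optimization_result> %d cell(s); winner %s order %d, k = %d (score %.2f)\n",
    x$n_cells, w$filter_kind, w$order, w$k, w$score))
  invisible(x)
}

#' Trial-subsampling reliability curve
#'
#' Preprocesses the full set once (filtering belongs to the recording,
#' not to the subset), then reruns the selection pipeline on the first
#' `ceiling(f * n)` trials (acquisition order) for each fraction `f`,
#' tracking how peak amplitude, latency and SNR stabilize as trials
#' accumulate. The default grid is 20% to 100% in steps of 5%
#' (17 fractions). Fractions yielding fewer than 4 trials are skipped
#' with a message.
#'
#' @param ts A [trial_set()].
#' @param cfg A [pipeline_config()].
#' @param fractions Numeric vector of fractions in (0, 1].
#' @param filter Apply the filtering/baseline stages to the full set
#'   before subsampling.
#' @return A tibble with columns `fraction`, `n_trials`, `n_selected`,
#'   `amplitude`, `latency`, `snr`.
#' @export
subsampling_curve <- function(ts, cfg = pipeline_config(),
                              fractions = seq(0.20, 1.00, by = 0.05),
                              filter = TRUE) {
  stopifnot(inherits(ts, "trial_set"))
  if (filter) {
    ts <- zero_phase_filter(ts, cfg)
    ts <- baseline_correct(ts, cfg$baseline_window)
  }
  n <- nrow(ts$data)
  rows <- purrr::map(fractions, function(f) {
    m <- ceiling(f * n)
    if (m < 4L) {
      message(sprintf("fraction %.2f yields %d < 4 trials; skipped", f, m))
      return(NULL)
    }
    sub <- ts
    sub$data <- ts$data[seq_len(m), , drop = FALSE]
    res <- mine_trials(sub, cfg, filter = FALSE)
    tibble::tibble(fraction = f, n_trials = m,
                   n_selected = length(res$selection$selected),
                   amplitude = res$peak$amplitude,
                   latency = res$peak$latency,
                   snr = res$snr)
  })
  dplyr::bind_rows(rows)
}
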