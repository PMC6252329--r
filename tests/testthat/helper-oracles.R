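# Independent reference implementations used as test oracles. These are
# deliberately written in a different style from the package code (plain
# per-pair / per-triple loops, no shared helpers) so that agreement is a
# genuine cross-check and not the same code twice.

# Naive sample distance correlation: explicit double centering per pair.
oracle_dcor <- function(x, y) {
  n <- length(x)
  dx <- abs(outer(x, x, "-"))
  dy <- abs(outer(y, y, "-"))
  A <- matrix(0, n, n)
  B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      A[i, j] <- dx[i, j] - mean(dx[i, ]) - mean(dx[, j]) + mean(dx)
      B[i, j] <- dy[i, j] - mean(dy[i, ]) - mean(dy[, j]) + mean(dy)
    }
  }
  dcov2 <- sum(A * B) / n^2
  dvx <- sum(A * A) / n^2
  dvy <- sum(B * B) / n^2
  if (dvx <= 0 || dvy <= 0) return(0)
  sqrt(max(0, dcov2 / sqrt(dvx * dvy)))
}

oracle_similarity_matrix <- function(data) {
  n <- nrow(data)
  dm <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) dm[i, j] <- 1 - oracle_dcor(data[i, ], data[j, ])
    }
  }
  dm
}

# Brute-force Gabriel predicate: edge (i, j) unless some third point lies
# strictly inside the closed diametral disk.
oracle_gabriel_edges <- function(points, tol = 1e-9) {
  n <- nrow(points)
  d2 <- function(a, b) sum((points[a, ] - points[b, ])^2)
  edges <- NULL
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- TRUE
      for (k in seq_len(n)) {
        if (k == i || k == j) next
        if (d2(i, k) + d2(j, k) < d2(i, j) * (1 - tol)) { ok <- FALSE; break }
      }
      if (ok) edges <- rbind(edges, c(i, j))
    }
  }
  if (is.null(edges)) matrix(integer(), 0L, 2L) else edges
}

# Brute-force lune predicate for the relative neighborhood graph.
oracle_rng_edges <- function(points, tol = 1e-9) {
  n <- nrow(points)
  d2 <- function(a, b) sum((points[a, ] - points[b, ])^2)
  edges <- NULL
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- TRUE
      for (k in seq_len(n)) {
        if (k == i || k == j) next
        if (max(d2(i, k), d2(j, k)) < d2(i, j) * (1 - tol)) {
          ok <- FALSE; break
        }
      }
      if (ok) edges <- rbind(edges, c(i, j))
    }
  }
  if (is.null(edges)) matrix(integer(), 0L, 2L) else edges
}

# Canonical sorted edge-list representation for set comparison.
edge_key <- function(edges) {
  if (!nrow(edges)) return(character())
  sort(paste(pmin(edges[, 1L], edges[, 2L]),
             pmax(edges[, 1L], edges[, 2L]), sep = "-"))
}

# Is `a` an edge-subset of `b`?
edges_subset <- function(a, b) all(edge_key(a) %in% edge_key(b))

# Small random trial set fixture.
random_trialset <- function(n_trials = 10, n_samples = 40, seed = 1,
                            fs = 512) {
  set.seed(seed)
  trial_set(matrix(rnorm(n_trials * n_samples), n_trials, n_samples),
            sampling_rate = fs)
}
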