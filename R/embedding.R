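# Double-center a pairwise-distance matrix: a_kl - rowmean - colmean + mean.
.dcenter <- function(d) {
  rm <- rowMeans(d); gm <- mean(d)
  d - outer(rm, rm, "+") + gm
}

#' Sample distance correlation between two series
#'
#' The (biased, V-statistic) sample distance correlation of Szekely &
#' Rizzo: pairwise absolute-difference matrices of each series are
#' double-centered; their mean elementwise product is the squared distance
#' covariance, normalized by the geometric mean of the two distance
#' variances. The result lies in `[0, 1]`, equals 1 for any affine
#' relationship `y = a + b x` (`b != 0`), and is 0 by convention when
#' either series is constant (the estimator is 0/0 there); a warning is
#' raised in that case.
#'
#' @param x,y Numeric vectors of equal length `n >= 4`.
#' @return A single number in `[0, 1]`.
#' @examples
#' x <- rnorm(50)
#' distance_correlation(x, 2 - 3 * x)  # 1
#' @export
distance_correlation <- function(x, y) {
  if (length(x) != length(y)) {
    stop("series lengths differ: ", length(x), " vs ", length(y),
         call. = FALSE)
  }
  if (length(x) < 4L) stop("need n >= 4 samples", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("series must be finite", call. = FALSE)
  }
  A <- .dcenter(abs(outer(x, x, "-")))
  B <- .dcenter(abs(outer(y, y, "-")))
  dvar_x <- mean(A * A)
  dvar_y <- mean(B * B)
  if (dvar_x <= 0 || dvar_y <= 0) {
    warning("constant series: distance correlation set to 0 by convention")
    return(0)
  }
  dcov2 <- mean(A * B)
  r2 <- dcov2 / sqrt(dvar_x * dvar_y)
  sqrt(max(0, min(1, r2)))
}

#' Pairwise trial distance matrix (1 - distance correlation)
#'
#' Computes the symmetric trial-by-trial distance matrix
#' `dm[i, j] = 1 - dCor(trial_i, trial_j)`. A dependence estimator is
#' turned into a distance by the canonical `1 - dCor` conversion, keeping
#' entries in `[0, 1]` with 0 on the diagonal. Internally each trial's
#' double-centered distance matrix is computed once and all pairwise
#' distance covariances are obtained in a single cross-product, so the
#' cost is one `m^2 x n` matrix product rather than `n^2` separate
#' estimator calls.
#'
#' Constant trials (zero distance variance) are assigned distance 1 to
#' every other trial, with a warning.
#'
#' @param ts A [trial_set()] (or a plain numeric matrix, one trial per
#'   row).
#' @return A symmetric `n x n` matrix of class `trial_dm` with zero
#'   diagonal and entries in `[0, 1]`.
#' @export
similarity_matrix <- function(ts) {
  data <- if (inherits(ts, "trial_set")) ts$data else as.matrix(ts)
  n <- nrow(data); m <- ncol(data)
  if (m < 4L) stop("trials must have >= 4 samples", call. = FALSE)
  V <- matrix(0, m * m, n)
  for (i in seq_len(n)) {
    V[, i] <- as.vector(.dcenter(abs(outer(data[i, ], data[i, ], "-"))))
  }
  G <- crossprod(V) / (m * m)   # G[i,j] = dCov^2(trial_i, trial_j)
  dv <- diag(G)
  const <- dv <= 0
  if (any(const)) {
    warning(sum(const), " constant trial(s): assigned distance 1 to all ",
            "other trials")
    dv[const] <- 1  # placeholder; rows overwritten below
  }
  r2 <- G / sqrt(outer(dv, dv))
  r2[r2 < 0] <- 0
  r2[r2 > 1] <- 1
  dm <- 1 - sqrt(r2)
  dm[const, ] <- 1
  dm[, const] <- 1
  diag(dm) <- 0
  dm <- (dm + t(dm)) / 2
  structure(dm, class = c("trial_dm", "matrix", "array"))
}

#' @export
print.trial_dm <- function(x, ...) {
  cat(sprintf("<trial_dm> %d x %d (1 - distance correlation)\n",
              nrow(x), ncol(x)))
  invisible(x)
}

# Deterministic axis-sign convention: flip each axis so its largest-
# magnitude coordinate is positive; break magnitude ties toward the lower
# point index.
.fix_signs <- function(coords) {
  for (j in seq_len(ncol(coords))) {
    a <- abs(coords[, j])
    i <- which(a == max(a))[1L]
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  coords
}

#' Embed a trial distance matrix in the plane by classical MDS
#'
#' Classical (Torgerson) scaling: the squared-distance matrix is
#' double-centered and the two leading non-negative eigenpairs give the
#' coordinates (eigenvector times sqrt(eigenvalue)), via
#' [stats::cmdscale()]. The embedding is deterministic; the residual axis
#' sign ambiguity is fixed by flipping each axis so its largest-magnitude
#' coordinate is positive. If fewer than 2 positive eigenvalues exist
#' (e.g. all trials identical) the missing axis is a zero column and a
#' warning notes the degenerate embedding.
#'
#' @param dm A symmetric distance matrix ([similarity_matrix()] output or
#'   any `dist`-like square matrix).
#' @param dim Embedding dimension; the mining method is defined on the
#'   plane, so only `2` is supported.
#' @return An `n x 2` coordinate matrix of class `point_set`.
#' @export
mds_embed <- function(dm, dim = 2L) {
  dm <- as.matrix(dm)
  if (dim != 2L) stop("the method is defined on the plane; dim must be 2",
                      call. = FALSE)
  n <- nrow(dm)
  if (max(abs(dm)) == 0) {
    coords <- matrix(0, n, 2L)
  } else {
    fit <- stats::cmdscale(dm, k = 2L, eig = TRUE)
    pos <- sum(fit$eig > 1e-12)
    coords <- matrix(0, n, 2L)
    if (pos == 0L) {
      warning("degenerate embedding: no positive eigenvalue; ",
              "all points placed at the origin")
    } else {
      got <- min(2L, ncol(fit$points), pos)
      coords[, seq_len(got)] <- fit$points[, seq_len(got), drop = FALSE]
      if (pos < 2L) {
        warning("degenerate embedding: only 1 positive eigenvalue; ",
                "second axis set to 0")
      }
    }
  }
  coords <- .fix_signs(coords)
  dimnames(coords) <- list(NULL, c("x", "y"))
  structure(coords, class = c("point_set", "matrix", "array"))
}
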