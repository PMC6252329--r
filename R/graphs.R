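# Internal constructor for a proximity graph over 2D points.
# edges: 2-column integer matrix of unordered pairs (i < j).
.trial_graph <- function(points, edges, kind, collapsed_map = NULL) {
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges)) {
    edges <- t(apply(edges, 1L, sort))
    edges <- unique(edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE])
  }
  structure(
    list(points = points, edges = edges, n = nrow(points), kind = kind,
         collapsed_map = collapsed_map),
    class = "trial_graph"
  )
}

#' @export
print.trial_graph <- function(x, ...) {
  cat(sprintf("<trial_graph> %s: %d nodes, %d edges\n", x$kind, x$n,
              nrow(x$edges)))
  invisible(x)
}

#' Edge list of a proximity graph as a tibble
#'
#' @param x A `trial_graph`.
#' @param ... Unused.
#' @return A tibble with columns `from`, `to`, `length` (Euclidean).
#' @export
tidy.trial_graph <- function(x, ...) {
  e <- x$edges
  len <- sqrt(rowSums((x$points[e[, 1L], , drop = FALSE] -
                         x$points[e[, 2L], , drop = FALSE])^2))
  tibble::tibble(from = e[, 1L], to = e[, 2L], length = len)
}

# Collapse exactly-coincident points; returns list(points, map) where
# map[i] is the representative node of original point i.
.collapse_duplicates <- function(points) {
  key <- paste(points[, 1L], points[, 2L], sep = "\r")
  map <- match(key, key[!duplicated(key)])
  if (max(map) < nrow(points)) {
    warning(nrow(points) - max(map),
            " coincident point(s) collapsed before graph construction")
  }
  list(points = points[!duplicated(key), , drop = FALSE], map = map)
}

.check_points <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("points must be n x 2", call. = FALSE)
  if (!all(is.finite(points))) stop("points must be finite", call. = FALSE)
  if (nrow(points) < 2L) stop("need at least 2 points", call. = FALSE)
  points
}

# Relative tolerance on the squared-distance predicates: a point exactly
# on the diametral circle / lune boundary does not block the edge.
.GG_TOL <- 1e-9

#' Gabriel graph of a planar point set
#'
#' Nodes `p, q` are joined iff no third point lies strictly inside the
#' closed disk with diameter `pq`; equivalently
#' `d(p,q)^2 < d(p,k)^2 + d(q,k)^2` for every other point `k`. Boundary
#' points (relative tolerance 1e-9 on the squared distances) do not block
#' an edge. The Gabriel graph contains the Euclidean minimum spanning
#' tree, so it is always connected. Coincident points are collapsed to a
#' single node (with a warning); `collapsed_map` in the result maps each
#' original point to its representative node.
#'
#' @param points An `n x 2` numeric matrix (e.g. [mds_embed()] output).
#' @return A `trial_graph` of kind `"GG"`.
#' @export
gabriel_graph <- function(points) {
  points <- .check_points(points)
  cd <- .collapse_duplicates(points)
  p <- cd$points
  n <- nrow(p)
  if (n == 2L) {
    return(.trial_graph(p, cbind(1L, 2L), "GG", cd$map))
  }
  D2 <- as.matrix(stats::dist(p))^2
  edges <- .gabriel_edges(D2)
  .trial_graph(p, edges, "GG", cd$map)
}

# Vectorized Gabriel predicate: for each i, S = D2[i,] + D2 gives
# S[j, k] = d_ik^2 + d_jk^2; edge (i,j) survives iff
# min_k S[j, k] >= d_ij^2 (1 - tol), k != i, j.
.gabriel_edges <- function(D2) {
  n <- nrow(D2)
  out <- vector("list", n)
  for (i in seq_len(n - 1L)) {
    S <- D2 + rep(D2[i, ], each = n)   # S[j,k] = d_jk^2 + d_ik^2
    S[, i] <- Inf
    diag(S) <- Inf                     # k == j excluded (contributes d_ij^2)
    js <- (i + 1L):n
    blocked <- apply(S[js, , drop = FALSE], 1L, min) <
      D2[i, js] * (1 - .GG_TOL)
    keep <- js[!blocked]
    if (length(keep)) out[[i]] <- cbind(i, keep)
  }
  do.call(rbind, c(out, list(matrix(integer(), 0L, 2L))))
}

#' Relative neighborhood graph of a planar point set
#'
#' Nodes `p, q` are joined iff the lune — the intersection of the two
#' disks of radius `d(p,q)` centered at `p` and `q` — contains no other
#' point: no `k` with `max(d(p,k), d(q,k)) < d(p,q)`. The RNG is a
#' subgraph of the Gabriel graph. Boundary points do not block an edge
#' (same tolerance convention as [gabriel_graph()]).
#'
#' @inheritParams gabriel_graph
#' @return A `trial_graph` of kind `"RNG"`.
#' @export
rng_graph <- function(points) {
  points <- .check_points(points)
  cd <- .collapse_duplicates(points)
  p <- cd$points
  n <- nrow(p)
  if (n == 2L) {
    return(.trial_graph(p, cbind(1L, 2L), "RNG", cd$map))
  }
  D2 <- as.matrix(stats::dist(p))^2
  out <- vector("list", n)
  for (i in seq_len(n - 1L)) {
    M <- pmax(D2, rep(D2[i, ], each = n))  # M[j,k] = max(d_jk^2, d_ik^2)
    M[, i] <- Inf
    diag(M) <- Inf
    js <- (i + 1L):n
    blocked <- apply(M[js, , drop = FALSE], 1L, min) <
      D2[i, js] * (1 - .GG_TOL)
    keep <- js[!blocked]
    if (length(keep)) out[[i]] <- cbind(i, keep)
  }
  edges <- do.call(rbind, c(out, list(matrix(integer(), 0L, 2L))))
  .trial_graph(p, edges, "RNG", cd$map)
}

#' Euclidean minimum spanning tree of a planar point set
#'
#' The spanning tree minimizing total Euclidean edge length, computed by
#' [igraph::mst()] on the complete distance graph. Always `n - 1` edges.
#'
#' @inheritParams gabriel_graph
#' @return A `trial_graph` of kind `"EMST"`.
#' @export
emst_graph <- function(points) {
  points <- .check_points(points)
  cd <- .collapse_duplicates(points)
  p <- cd$points
  n <- nrow(p)
  d <- as.matrix(stats::dist(p))
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE)
  mst <- igraph::mst(g, weights = igraph::E(g)$weight)
  edges <- igraph::as_edgelist(mst, names = FALSE)
  .trial_graph(p, edges, "EMST", cd$map)
}

#' Delaunay triangulation edge set of a planar point set
#'
#' Delaunay edges via [deldir::deldir()]. If all points are collinear the
#' triangulation is undefined; the fallback is the path graph along the
#' line (with a warning), which preserves the containment chain
#' EMST \eqn{\subseteq} RNG \eqn{\subseteq} GG \eqn{\subseteq} DT.
#'
#' @inheritParams gabriel_graph
#' @return A `trial_graph` of kind `"DT"`.
#' @export
delaunay_graph <- function(points) {
  points <- .check_points(points)
  cd <- .collapse_duplicates(points)
  p <- cd$points
  n <- nrow(p)
  if (n == 2L) {
    return(.trial_graph(p, cbind(1L, 2L), "DT", cd$map))
  }
  ctr <- sweep(p, 2L, colMeans(p))
  if (min(svd(ctr)$d) < 1e-12 * max(1, max(svd(ctr)$d))) {
    warning("all points collinear: Delaunay falls back to the path graph")
    ord <- order(p %*% prcomp(p, center = TRUE)$rotation[, 1L])
    edges <- cbind(ord[-n], ord[-1L])
    return(.trial_graph(p, edges, "DT", cd$map))
  }
  dd <- deldir::deldir(p[, 1L], p[, 2L], suppressMsge = TRUE)
  edges <- as.matrix(dd$delsgs[, c("ind1", "ind2")])
  .trial_graph(p, edges, "DT", cd$map)
}

#' Node degrees of a proximity graph
#'
#' @param g A `trial_graph`.
#' @return A tibble with columns `node` and `degree`.
#' @export
degree_table <- function(g) {
  stopifnot(inherits(g, "trial_graph"))
  deg <- tabulate(c(g$edges[, 1L], g$edges[, 2L]), nbins = g$n)
  tibble::tibble(node = seq_len(g$n), degree = deg)
}

#' Select hub nodes by degree threshold
#'
#' Hubs are the nodes whose degree in the proximity graph is at least
#' `k`: the trials sitting in the core of the embedded cloud, each
#' directly similar to several distinct neighbors. If the graph was built
#' from points with coincident duplicates, every duplicate inherits its
#' representative's hub status.
#'
#' @param g A `trial_graph`.
#' @param k Degree threshold, integer >= 1.
#' @return A `hub_selection`: list with `selected` (original point
#'   indices), `k`, and `degrees` (the [degree_table()] tibble).
#' @export
select_hubs <- function(g, k) {
  stopifnot(inherits(g, "trial_graph"))
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  dt <- degree_table(g)
  sel_nodes <- dt$node[dt$degree >= k]
  if (!length(sel_nodes)) {
    stop(sprintf(
      "no node has degree >= %d; lower k (max degree here is %d)",
      k, max(dt$degree)), call. = FALSE)
  }
  map <- g$collapsed_map
  selected <- if (is.null(map)) sel_nodes else which(map %in% sel_nodes)
  structure(list(selected = as.integer(selected), k = k, degrees = dt),
            class = "hub_selection")
}

#' @export
print.hub_selection <- function(x, ...) {
  cat(sprintf("<hub_selection> %d trial(s) with degree >= %d\n",
              length(x$selected), x$k))
  invisible(x)
}

#' Weighted global efficiency of a graph
#'
#' The inverse of the harmonic mean of shortest-path lengths:
#' `GE = (1/N) * sum_i [ sum_{j != i} 1/d_ij ] / (N - 1)`, with `d_ij`
#' the shortest-path length between `i` and `j`; disconnected pairs
#' contribute 0 (the `1/Inf = 0` convention). With unit edge lengths on a
#' complete graph GE is 1.
#'
#' @param g A `trial_graph`, or a list with `n` and a 2-column `edges`
#'   matrix.
#' @param lengths Optional positive edge lengths, one per edge row;
#'   default is the Euclidean length of each edge (unit lengths if the
#'   graph has no points).
#' @return A single number; in `[0, 1]` whenever all lengths are >= 1.
#' @export
global_efficiency <- function(g, lengths = NULL) {
  n <- g$n
  e <- g$edges
  if (n < 2L) stop("need at least 2 nodes", call. = FALSE)
  if (is.null(lengths)) {
    lengths <- if (!is.null(g$points) && nrow(e)) {
      sqrt(rowSums((g$points[e[, 1L], , drop = FALSE] -
                      g$points[e[, 2L], , drop = FALSE])^2))
    } else {
      rep(1, nrow(e))
    }
  }
  if (nrow(e) && any(lengths <= 0)) {
    stop("edge lengths must be positive", call. = FALSE)
  }
  fin <- is.finite(lengths)
  ig <- igraph::make_empty_graph(n, directed = FALSE)
  if (any(fin)) {
    ig <- igraph::add_edges(ig, t(e[fin, , drop = FALSE]))
    igraph::E(ig)$weight <- lengths[fin]
  }
  d <- igraph::distances(ig, weights = if (any(fin)) igraph::E(ig)$weight
                                       else NULL)
  inv <- 1 / d
  diag(inv) <- 0
  mean(rowSums(inv) / (n - 1))
}

#' Hub-scatter variability as weighted global efficiency
#'
#' Quantifies how tightly the selected hub trials cluster in the embedded
#' plane. Pairwise Euclidean distances among hub coordinates are
#' normalized by their maximum (`w_hat = d/d_max`), inverted into
#' functional weights `w = 1 - w_hat`, and turned into edge lengths
#' `1/w`; the most distant pair gets `w = 0`, i.e. no direct edge. The
#' global efficiency of that weighted graph is returned: higher GE means
#' hubs sit closer together, i.e. less trial-to-trial variability. The
#' value is invariant to uniform scaling of the coordinates.
#'
#' @param points Embedded coordinates (`n x 2`), e.g. [mds_embed()]
#'   output.
#' @param hubs A [select_hubs()] result, or an integer vector of hub
#'   indices (>= 2 of them).
#' @return A single number; all-coincident hubs give 1 (maximal
#'   compactness, with a warning).
#' @export
hub_variability_ge <- function(points, hubs) {
  points <- as.matrix(points)
  idx <- if (inherits(hubs, "hub_selection")) hubs$selected else
    as.integer(hubs)
  if (length(idx) < 2L) stop("need at least 2 hubs", call. = FALSE)
  p <- points[idx, , drop = FALSE]
  d <- as.matrix(stats::dist(p))
  dmax <- max(d)
  if (dmax == 0) {
    warning("all hubs coincident: variability GE set to 1")
    return(1)
  }
  w <- 1 - d / dmax
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  wij <- w[pairs]
  keep <- wij > 0
  g <- list(n = nrow(p), edges = pairs[keep, , drop = FALSE])
  global_efficiency(g, lengths = 1 / wij[keep])
}
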