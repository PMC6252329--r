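test_that("Gabriel graph fixtures: pairs, collinear triples, open triangles", {
  expect_equal(gabriel_graph(rbind(c(0, 0), c(1, 0)))$edges,
               cbind(1L, 2L), ignore_attr = TRUE)

  # middle point blocks the long edge
  col3 <- rbind(c(0, 0), c(1, 0), c(3, 0))
  expect_identical(edge_key(gabriel_graph(col3)$edges), c("1-2", "2-3"))
  expect_identical(edge_key(oracle_gabriel_edges(col3)), c("1-2", "2-3"))

  # all three diametral disks empty: complete triangle
  tri <- rbind(c(0, 0), c(4, 0), c(1, 2))
  expect_identical(edge_key(gabriel_graph(tri)$edges),
                   c("1-2", "1-3", "2-3"))
  expect_identical(edge_key(oracle_gabriel_edges(tri)),
                   c("1-2", "1-3", "2-3"))

  expect_error(gabriel_graph(rbind(c(0, 0))), "at least 2")
})

test_that("GG and RNG agree with brute-force predicate oracles on random
           point sets", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(10:80, 1)
    pts <- matrix(runif(2 * n), n, 2)
    expect_identical(edge_key(gabriel_graph(pts)$edges),
                     edge_key(oracle_gabriel_edges(pts)))
    expect_identical(edge_key(rng_graph(pts)$edges),
                     edge_key(oracle_rng_edges(pts)))
  }
})

test_that("containment chain EMST within RNG within GG within DT", {
  for (seed in 1:10) {
    set.seed(100 + seed)
    pts <- matrix(rnorm(2 * 60), 60, 2)
    emst <- emst_graph(pts)$edges
    rng <- rng_graph(pts)$edges
    gg <- gabriel_graph(pts)$edges
    dt <- delaunay_graph(pts)$edges
    expect_true(edges_subset(emst, rng))
    expect_true(edges_subset(rng, gg))
    expect_true(edges_subset(gg, dt))
  }
})

test_that("EMST is a tree and minimizes total length (enumeration oracle)", {
  set.seed(5)
  for (rep in 1:5) {
    pts <- matrix(runif(8), 4, 2)
    g <- emst_graph(pts)
    expect_identical(nrow(g$edges), 3L)
    # enumerate all 16 labelled spanning trees of K4 (Cayley: 4^2)
    len <- function(e) sum(sqrt(rowSums(
      (pts[e[, 1], , drop = FALSE] - pts[e[, 2], , drop = FALSE])^2)))
    all_edges <- t(combn(4, 2))
    best <- Inf
    for (pick in combn(6, 3, simplify = FALSE)) {
      e <- all_edges[pick, , drop = FALSE]
      ig <- igraph::graph_from_edgelist(e, directed = FALSE)
      if (igraph::vcount(ig) == 4 && igraph::is_connected(ig)) {
        best <- min(best, len(e))
      }
    }
    expect_equal(len(g$edges), best, tolerance = 1e-12)
  }
})

test_that("Delaunay fallback covers collinear input", {
  expect_warning(g <- delaunay_graph(rbind(c(0, 0), c(1, 1), c(3, 3))),
                 "collinear")
  expect_identical(edge_key(g$edges), c("1-2", "2-3"))
})

test_that("coincident points are collapsed and re-expanded into selections", {
  pts <- rbind(c(0, 0), c(0, 0), c(1, 0), c(2, 0), c(2, 0), c(2, 0))
  expect_warning(g <- gabriel_graph(pts), "coincident")
  expect_identical(g$n, 3L)  # three distinct locations
  sel <- select_hubs(g, 2)
  # the middle location is the only degree-2 node; it has one duplicate set
  expect_identical(sel$selected, 3L)
  sel1 <- select_hubs(g, 1)
  expect_identical(sel1$selected, 1:6)  # every duplicate inherits hub status
})

test_that("hub selection thresholds degrees with the documented contracts", {
  path3 <- rbind(c(0, 0), c(1, 0), c(3, 0))
  g <- gabriel_graph(path3)
  expect_identical(select_hubs(g, 2)$selected, 2L)   # middle of the path
  expect_identical(select_hubs(g, 1)$selected, 1:3)  # GG is connected
  expect_error(select_hubs(g, 3), "lower k")

  set.seed(77)
  pts <- matrix(rnorm(2 * 128), 128, 2)
  gg <- gabriel_graph(pts)
  sizes <- vapply(1:4, function(k) length(select_hubs(gg, k)$selected),
                  numeric(1))
  expect_true(all(diff(sizes) <= 0))          # non-increasing in k
  expect_lt(sizes[4], sizes[3])               # strictly at this n
})

test_that("global efficiency analytic values", {
  path <- list(n = 3L, edges = rbind(c(1L, 2L), c(2L, 3L)))
  expect_equal(global_efficiency(path, lengths = c(1, 1)), 5 / 6,
               tolerance = 1e-12)

  complete5 <- list(n = 5L, edges = t(combn(5L, 2L)))
  expect_equal(global_efficiency(complete5, lengths = rep(1, 10)), 1,
               tolerance = 1e-12)

  expect_equal(global_efficiency(list(n = 2L,
                                      edges = matrix(integer(), 0, 2))), 0)
})

test_that("global efficiency never increases when an edge lengthens", {
  set.seed(9)
  edges <- t(combn(6L, 2L))
  for (rep in 1:20) {
    len <- runif(nrow(edges), 1, 3)
    g <- list(n = 6L, edges = edges)
    ge1 <- global_efficiency(g, lengths = len)
    expect_gte(ge1, 0); expect_lte(ge1, 1)  # lengths >= 1
    len2 <- len
    i <- sample(nrow(edges), 1)
    len2[i] <- len2[i] + runif(1, 0.1, 2)
    expect_lte(global_efficiency(g, lengths = len2), ge1 + 1e-12)
  }
})

test_that("hub-scatter variability GE: worked case, forced zero, scale
           invariance", {
  hubs <- rbind(c(0, 0), c(1, 0), c(2, 0))
  expect_equal(hub_variability_ge(hubs, 1:3), (0.5 + 0.5 + 0.25) / 3,
               tolerance = 1e-12)

  expect_equal(hub_variability_ge(rbind(c(0, 0), c(5, 2)), 1:2), 0)

  set.seed(13)
  p <- matrix(rnorm(12), 6, 2)
  base <- hub_variability_ge(p, 1:6)
  expect_equal(hub_variability_ge(p * 37.5, 1:6), base, tolerance = 1e-12)

  expect_warning(v <- hub_variability_ge(rbind(c(1, 1), c(1, 1)), 1:2),
                 "coincident")
  expect_identical(v, 1)
  expect_error(hub_variability_ge(p, 1L), "at least 2")
})
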