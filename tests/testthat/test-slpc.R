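clique_graph <- function(prefix, n) {
  pairs <- t(combn(sprintf("%s%d", prefix, 1:n), 2))
  list(a = pairs[, 1], b = pairs[, 2])
}

# a scorer that rewards internal edge count: strictly increasing along
# clique growth, so expansion recovers planted cliques
edge_count_scorer <- function(max_pos = 6) {
  coef <- setNames(numeric(12), c("(Intercept)",
                                  ppicomplex:::topo_feature_names))
  coef["n_edges"] <- 1
  structure(list(coef = coef, max_positive_size = max_pos),
            class = "complex_scorer")
}

test_that("negative subgraph sampling is reproducible, size-true and avoids positives", {
  g <- igraph::sample_gnp(10, 0.4)
  igraph::V(g)$name <- letters[1:10]
  expect_length(sample_negative_subgraphs(g, 3, 0, seed = 1), 0)

  pos <- list(c("a", "b", "c"))
  neg <- sample_negative_subgraphs(g, 3, 5, seed = 4, positives = pos)
  expect_length(neg, 5)
  expect_true(all(lengths(neg) == 3))
  expect_false(any(vapply(neg, function(x) setequal(x, pos[[1]]), logical(1))))
  expect_identical(sample_negative_subgraphs(g, 3, 5, seed = 4,
                                             positives = pos), neg)
  expect_error(sample_negative_subgraphs(g, 11, 1, seed = 1), "exceeds")
})

test_that("negative 3-sets on K5 are uniform over all 10 subsets", {
  k5 <- clique_graph("k", 5)
  g <- graph_from_pairs(k5$a, k5$b)
  draws <- sample_negative_subgraphs(g, 3, 10000, seed = 6)
  keys <- vapply(draws, paste, "", collapse = "+")
  counts <- table(keys)
  expect_length(counts, 10)
  sigma <- sqrt(10000 * 0.1 * 0.9)
  expect_true(all(abs(counts - 1000) <= 3 * sigma))
})

test_that("the eleven features match first-principles recomputation", {
  tri <- clique_graph("t", 3)
  g <- graph_from_pairs(c(tri$a, "t1"), c(tri$b, "x"))
  f <- topo_features(c("t1", "t2", "t3"), g)
  expect_equal(f[["density"]], 1)
  expect_equal(f[["mean_clustering"]], 1)
  expect_equal(f[["n_edges"]], 3)
  expect_equal(f[["mean_external_degree"]], 1 / 3)
  expect_equal(f[["mean_edge_weight"]], 1)

  f0 <- topo_features(c("t2", "t3", "x"), g) # t2-t3 edge only
  expect_equal(f0[["n_edges"]], 1)
  expect_equal(f0[["lcc_fraction"]], 2 / 3)

  g0 <- igraph::add_vertices(g, 2)
  g0 <- igraph::set_vertex_attr(g0, "name", 5:6, c("y", "z"))
  fz <- topo_features(c("x", "y", "z"), g0) # no internal edges
  expect_equal(fz[["density"]], 0)
  expect_equal(fz[["mean_internal_degree"]], 0)
  expect_equal(fz[["mean_edge_weight"]], 0)

  set.seed(53)
  for (rep_i in 1:20) {
    n <- 18
    g2 <- igraph::sample_gnp(n, 0.3)
    igraph::V(g2)$name <- sprintf("v%02d", 1:n)
    if (rep_i %% 2 == 0) igraph::E(g2)$weight <- runif(igraph::ecount(g2))
    cx <- sample(igraph::V(g2)$name, 6)
    expect_equal(unname(topo_features(cx, g2)),
                 unname(oracle_topo(cx, g2)), tolerance = 1e-12)
  }
  expect_error(topo_features(c("v01", "nope"), g2), "nope")
})

test_that("the trained scorer separates cohesive from edgeless training classes", {
  set.seed(59)
  g <- igraph::sample_gnp(60, 0.02)
  igraph::V(g)$name <- sprintf("s%02d", 1:60)
  # plant 4 cliques of size 5 among the first 20 nodes
  for (i in 0:3) {
    mem <- sprintf("s%02d", (i * 5 + 1):(i * 5 + 5))
    for (u in 1:4) for (v in (u + 1):5) {
      if (!igraph::are_adjacent(g, mem[u], mem[v])) {
        g <- igraph::add_edges(g, c(mem[u], mem[v]))
      }
    }
  }
  pos <- lapply(0:3, function(i) sprintf("s%02d", (i * 5 + 1):(i * 5 + 5)))
  neg <- sample_negative_subgraphs(g, 5, 6, seed = 2, positives = pos)
  mid <- degrade_gold(pos, 0.4, seed = 3, nodes = igraph::V(g)$name)
  train <- labeled_complex_set(pos, mid, neg)
  scorer <- suppressMessages(train_scorer(train, g, seed = 1))
  expect_gt(min(predict(scorer, pos, g)), max(predict(scorer, neg, g)))
  expect_identical(predict(scorer, pos, g), predict(scorer, pos, g))
})

test_that("a single informative feature yields near-perfect ordinary least squares", {
  # isolated pairs whose edge weight equals the class target exactly
  a <- sprintf("a%d", 1:4); b <- sprintf("b%d", 1:4)
  c_ <- sprintf("c%d", 1:4); d <- sprintf("d%d", 1:4)
  e <- sprintf("e%d", 1:4); f <- sprintf("f%d", 1:4)
  g <- graph_from_pairs(c(a, c_, e), c(b, d, f),
                        weights = rep(c(1, 0.5, 1e-6), each = 4))
  train <- labeled_complex_set(
    positives = mapply(c, a, b, SIMPLIFY = FALSE),
    intermediates = mapply(c, c_, d, SIMPLIFY = FALSE),
    negatives = mapply(c, e, f, SIMPLIFY = FALSE))
  scorer <- suppressMessages(suppressWarnings(
    train_scorer(train, g, seed = 1, lambda = 0)))
  expect_gte(scorer$r_squared, 0.99)
})

test_that("seeds are exactly the above-mean-degree nodes", {
  star <- graph_from_pairs(rep("h", 3), c("x", "y", "z"))
  expect_identical(select_seeds(star), list("h"))

  path <- graph_from_pairs(c("a", "b"), c("b", "c"))
  expect_identical(select_seeds(path), list("b"))

  ring <- igraph::make_ring(6)
  igraph::V(ring)$name <- letters[1:6]
  expect_warning(seeds <- select_seeds(ring), "no node")
  expect_length(seeds, 0)
})

test_that("greedy expansion recovers a planted clique and honours bounds", {
  k6 <- clique_graph("c", 6)
  g <- graph_from_pairs(c(k6$a, "c1"), c(k6$b, "x"))
  scorer <- edge_count_scorer(max_pos = 3)
  got <- expand_seed("c3", g, scorer) # max_size = 6
  expect_setequal(got, sprintf("c%d", 1:6))

  expect_identical(expand_seed("c3", g, scorer, max_size = 1), "c3")

  g_iso <- igraph::add_vertices(g, 1)
  g_iso <- igraph::set_vertex_attr(g_iso, "name", igraph::vcount(g_iso), "iso")
  expect_identical(expand_seed("iso", g_iso, scorer), "iso")
})

test_that("expanded complexes induce connected subgraphs containing the seed", {
  set.seed(61)
  g <- igraph::sample_gnp(40, 0.12)
  igraph::V(g)$name <- sprintf("n%02d", 1:40)
  scorer <- edge_count_scorer(max_pos = 4)
  for (s in sample(igraph::V(g)$name, 10)) {
    cx <- expand_seed(s, g, scorer)
    expect_true(s %in% cx)
    sub <- igraph::induced_subgraph(g, cx)
    expect_true(igraph::is_connected(sub))
  }
})

test_that("candidate detection finds planted cliques, dedups, and handles edge cases", {
  k1 <- clique_graph("a", 6)
  k2 <- clique_graph("b", 6)
  g <- graph_from_pairs(c(k1$a, k2$a, "a1", "z1"), c(k1$b, k2$b, "z1", "z2"))
  scorer <- edge_count_scorer(max_pos = 3)
  cands <- detect_candidates(g, scorer)
  expect_length(cands, 2)
  keys <- vapply(cands, paste, "", collapse = "+")
  expect_setequal(keys, c(paste(sprintf("a%d", 1:6), collapse = "+"),
                          paste(sprintf("b%d", 1:6), collapse = "+")))
  expect_true(all(vapply(cands, function(cx) !is.null(attr(cx, "score")),
                         logical(1))))

  empty <- igraph::make_empty_graph(0, directed = FALSE)
  out <- suppressWarnings(detect_candidates(empty, scorer))
  expect_length(out, 0)

  # identical results on repeated calls
  expect_identical(detect_candidates(g, scorer), cands)
})

test_that("the full detector recovers planted complexes across seeded replicates", {
  bat <- pipeline_battery()
  f_slpc <- vapply(bat, `[[`, numeric(1), "f_slpc")
  expect_gte(sum(f_slpc >= 0.5), 8)
})
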