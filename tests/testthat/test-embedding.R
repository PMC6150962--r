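test_that("second-order transition probabilities follow the p/q bias rules", {
  # triangle: previous = a, current = b; c is adjacent to a, so alpha = 1
  tri <- graph_from_pairs(c("a", "a", "b"), c("b", "c", "c"))
  tp <- build_transition_probs(tri, node2vec_params(p = 1, q = 8))
  pr <- transition_probs(tp, prev = "a", cur = "b")
  expect_equal(pr[["a"]], 0.5)
  expect_equal(pr[["c"]], 0.5)

  # path a-b-c: from b with previous a, c is at distance 2 from a
  path <- graph_from_pairs(c("a", "b"), c("b", "c"))
  tp2 <- build_transition_probs(path, node2vec_params(p = 4, q = 8))
  pr2 <- transition_probs(tp2, prev = "a", cur = "b")
  expect_equal(pr2[["a"]], 2 / 3)
  expect_equal(pr2[["c"]], 1 / 3)

  # p = q = 1 reduces to a uniform walk over neighbours
  star <- graph_from_pairs(rep("h", 3), c("x", "y", "z"))
  tp3 <- build_transition_probs(star, node2vec_params(p = 1, q = 1))
  pr3 <- transition_probs(tp3, prev = "x", cur = "h")
  expect_equal(unname(pr3), rep(1 / 3, 3))
})

test_that("transition distributions are proper for every (prev, cur) pair", {
  set.seed(11)
  g <- igraph::sample_gnp(15, 0.3)
  igraph::V(g)$name <- sprintf("n%02d", 1:15)
  tp <- build_transition_probs(g, node2vec_params(p = 2, q = 0.5))
  el <- igraph::as_edgelist(g)
  for (r in seq_len(nrow(el))) {
    for (dir in list(el[r, ], rev(el[r, ]))) {
      pr <- transition_probs(tp, prev = dir[1], cur = dir[2])
      expect_equal(sum(pr), 1, tolerance = 1e-12)
      expect_true(all(pr >= 0))
    }
  }
})

test_that("walk corpora respect adjacency, counts, and the seed", {
  # single edge: walks alternate between the two endpoints
  g <- graph_from_pairs("a", "b")
  p <- node2vec_params(r = 3, l = 4, d = 2)
  walks <- simulate_walks(g, p, seed = 1)
  expect_length(walks, 6)
  for (w in walks) {
    expect_true(identical(w, c("a", "b", "a", "b")) ||
                  identical(w, c("b", "a", "b", "a")))
  }

  # isolated node: r single-node walks
  g2 <- igraph::add_vertices(g, 1)
  g2 <- igraph::set_vertex_attr(g2, "name", igraph::vcount(g2), "z")
  walks2 <- simulate_walks(g2, p, seed = 1)
  expect_equal(sum(vapply(walks2, function(w) identical(w, "z"), logical(1))),
               3)

  # every consecutive pair in every walk is an edge
  set.seed(3)
  g3 <- igraph::sample_gnp(20, 0.2)
  igraph::V(g3)$name <- sprintf("v%02d", 1:20)
  walks3 <- simulate_walks(g3, node2vec_params(r = 2, l = 8, d = 4), seed = 9)
  for (w in walks3) {
    if (length(w) < 2) next
    for (i in seq_len(length(w) - 1)) {
      expect_true(igraph::are_adjacent(g3, w[i], w[i + 1]))
    }
  }

  # determinism
  expect_identical(simulate_walks(g3, node2vec_params(r = 2, l = 8, d = 4),
                                  seed = 9),
                   walks3)
})

test_that("first steps from a star hub are uniform (alias-sampling Monte Carlo)", {
  star <- graph_from_pairs(rep("h", 3), c("x", "y", "z"))
  p <- node2vec_params(p = 1, q = 1, r = 4000, l = 2, d = 2)
  walks <- simulate_walks(star, p, seed = 21)
  first <- vapply(walks[vapply(walks, function(w) w[1] == "h", logical(1))],
                  `[`, "", 2L)
  counts <- table(factor(first, levels = c("x", "y", "z")))
  n <- sum(counts)
  sigma <- sqrt(n * (1 / 3) * (2 / 3))
  expect_true(all(abs(counts - n / 3) <= 3 * sigma))
})

test_that("unbiased walks converge to the degree-proportional stationary law", {
  # connected, non-bipartite small graph; chi-squared on thinned visits
  g <- graph_from_pairs(c("a", "a", "b", "b", "c", "d"),
                        c("b", "c", "c", "d", "d", "e"))
  p <- node2vec_params(p = 1, q = 1, r = 5, l = 5001, d = 2)
  walks <- simulate_walks(g, p, seed = 33)
  visits <- unlist(lapply(walks, function(w) w[seq(11, length(w), by = 10)]))
  deg <- igraph::degree(g)
  expected <- deg[names(deg)] / (2 * igraph::ecount(g))
  counts <- table(factor(visits, levels = names(deg)))
  chi <- sum((counts - length(visits) * expected)^2 /
               (length(visits) * expected))
  # 4 degrees of freedom, alpha = 0.01
  expect_lt(chi, qchisq(0.99, df = length(deg) - 1))
})

test_that("skip-gram embeddings separate two disjoint cliques and are reproducible", {
  k1 <- t(combn(sprintf("a%d", 1:8), 2))
  k2 <- t(combn(sprintf("b%d", 1:8), 2))
  g <- graph_from_pairs(c(k1[, 1], k2[, 1]), c(k1[, 2], k2[, 2]))
  p <- node2vec_params(d = 16, r = 8, l = 10)
  walks <- simulate_walks(g, p, seed = 2)
  emb <- train_embeddings(walks, p, seed = 2)
  expect_equal(dim(emb), c(16L, 16L))

  a_names <- sprintf("a%d", 1:8)
  b_names <- sprintf("b%d", 1:8)
  within <- c()
  between <- c()
  for (i in 1:8) {
    for (j in 1:8) {
      if (i < j) {
        within <- c(within,
                    cosine_similarity(emb[a_names[i], ], emb[a_names[j], ]),
                    cosine_similarity(emb[b_names[i], ], emb[b_names[j], ]))
      }
      between <- c(between,
                   cosine_similarity(emb[a_names[i], ], emb[b_names[j], ]))
    }
  }
  expect_gt(mean(within), mean(between))

  expect_identical(train_embeddings(walks, p, seed = 2), emb)

  # d = 1 is honoured
  p1 <- node2vec_params(d = 1, r = 2, l = 5)
  emb1 <- train_embeddings(simulate_walks(g, p1, seed = 3), p1, seed = 3)
  expect_equal(ncol(emb1), 1L)
})

test_that("cosine similarity matches its formula, bounds and conventions", {
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 2, 2), c(2, 4, 4)), 1)
  expect_equal(cosine_similarity(c(1, 1), c(1, 0)), sqrt(2) / 2,
               tolerance = 1e-10)
  expect_error(cosine_similarity(c(1, 2), c(1, 2, 3)), "length")
  expect_equal(cosine_similarity(c(0, 0), c(1, 2)), 0)

  set.seed(17)
  for (i in 1:50) {
    x <- rnorm(8); y <- rnorm(8)
    expect_equal(cosine_similarity(x, y), oracle_cosine(x, y),
                 tolerance = 1e-12)
    expect_equal(cosine_similarity(x, y), cosine_similarity(y, x))
    expect_lte(abs(cosine_similarity(x, y)), 1 + 1e-12)
    expect_equal(cosine_similarity(x, x), 1, tolerance = 1e-12)
  }
})

test_that("complex vectors pool member embeddings per strategy", {
  emb <- rbind(p1 = c(1, 5, 0), p2 = c(3, 2, -1))
  expect_equal(complex_vector(c("p1", "p2"), emb, "max"), c(3, 5, 0))
  expect_equal(complex_vector(c("p1", "p2"), emb, "min"), c(1, 2, -1))
  expect_equal(complex_vector("p1", emb, "max"), c(1, 5, 0))

  set.seed(23)
  emb2 <- matrix(rnorm(5 * 7), 5, 7, dimnames = list(letters[1:5], NULL))
  for (strat in c("max", "min", "average")) {
    got <- complex_vector(letters[1:5], emb2, strat)
    want <- oracle_pool(lapply(1:5, function(i) emb2[i, ]), strat)
    expect_equal(got, want, tolerance = 1e-12)
    # permutation invariance
    expect_equal(complex_vector(sample(letters[1:5]), emb2, strat), got)
  }
  # max pooling is monotone in membership
  sub <- complex_vector(letters[1:3], emb2, "max")
  full <- complex_vector(letters[1:5], emb2, "max")
  expect_true(all(full >= sub - 1e-15))

  expect_error(complex_vector(c("a", "zz"), emb2), "zz")
  expect_error(complex_vector(character(0), emb2), "empty")
})
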