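# Independent brute-force oracles and tiny graph builders used across tests.
# These deliberately avoid the package's own code paths.

graph_from_pairs <- function(a, b, weights = NULL) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = a, to = b, stringsAsFactors = FALSE),
    directed = FALSE)
  if (!is.null(weights)) igraph::E(g)$weight <- weights
  g
}

oracle_cosine <- function(x, y) {
  num <- 0; sx <- 0; sy <- 0
  for (i in seq_along(x)) {
    num <- num + x[i] * y[i]
    sx <- sx + x[i]^2
    sy <- sy + y[i]^2
  }
  num / (sqrt(sx) * sqrt(sy))
}

oracle_pool <- function(vecs, strategy) {
  d <- length(vecs[[1]])
  out <- numeric(d)
  for (j in seq_len(d)) {
    col <- vapply(vecs, `[`, numeric(1), j)
    out[j] <- switch(strategy, max = max(col), min = min(col),
                     average = mean(col))
  }
  out
}

oracle_na <- function(p, q) {
  length(intersect(p, q))^2 / (length(p) * length(q))
}

# O(|pred| * |gold|) reference matcher
oracle_match <- function(pred, gold, thr) {
  mp <- 0
  for (p in pred) {
    if (any(vapply(gold, function(g) oracle_na(p, g) >= thr, logical(1)))) {
      mp <- mp + 1
    }
  }
  mg <- 0
  for (g in gold) {
    if (length(pred) > 0 &&
        any(vapply(pred, function(p) oracle_na(p, g) >= thr, logical(1)))) {
      mg <- mg + 1
    }
  }
  prec <- if (length(pred) == 0) 0 else mp / length(pred)
  rec <- mg / length(gold)
  f <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  list(precision = prec, recall = rec, f_score = f)
}

oracle_adjustcd <- function(g, u, v) {
  nb <- function(x) igraph::neighbors(g, x)$name
  n_avg <- mean(igraph::degree(g))
  2 * length(intersect(nb(u), nb(v))) /
    (max(length(nb(u)), n_avg) + max(length(nb(v)), n_avg))
}

# Direct implementation of the iterative common-neighbour recursion:
# P(0) = adjacency indicator; p(k)_uv = 1 - prod over common neighbours l
# of (1 - p(k-1)_ul * p(k-1)_vl).
oracle_pe <- function(g, iterations) {
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  el <- igraph::as_edgelist(g)
  for (r in seq_len(nrow(el))) {
    A[el[r, 1], el[r, 2]] <- 1
    A[el[r, 2], el[r, 1]] <- 1
  }
  P <- A
  for (k in seq_len(iterations)) {
    Pn <- matrix(0, n, n, dimnames = list(nodes, nodes))
    for (u in seq_len(n)) {
      for (v in seq_len(n)) {
        if (u == v) next
        prod_ <- 1
        for (l in seq_len(n)) {
          if (A[u, l] == 1 && A[v, l] == 1) {
            prod_ <- prod_ * (1 - P[u, l] * P[v, l])
          }
        }
        Pn[u, v] <- 1 - prod_
      }
    }
    P <- Pn
  }
  P
}

# 11 features recomputed from first principles with igraph
oracle_topo <- function(cx, net) {
  sub <- igraph::induced_subgraph(net, cx)
  m <- length(cx)
  e <- igraph::ecount(sub)
  ideg <- igraph::degree(sub)
  dens <- if (m > 1) e / choose(m, 2) else 0
  cl <- igraph::transitivity(sub, type = "local", isolates = "zero")
  comp <- igraph::components(sub)
  ext <- sum(igraph::degree(net, cx)) - 2 * e
  weighted <- "weight" %in% igraph::edge_attr_names(net)
  mw <- if (e == 0) 0 else if (weighted) mean(igraph::E(sub)$weight) else 1
  c(m, e, dens, mean(ideg), mean((ideg - mean(ideg))^2), max(ideg),
    mean(cl), max(comp$csize) / m, ext / m,
    if (e + ext == 0) 0 else e / (e + ext), mw)
}
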