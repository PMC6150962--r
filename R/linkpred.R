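#' Hide edges while keeping the network connected
#'
#' Removes `floor(fraction * |E|)` edges one at a time, choosing uniformly
#' among edges that are not bridges of the current network, so the remainder
#' stays connected. A disconnected input is reduced to its largest connected
#' component with a warning. If the target count cannot be reached (all
#' remaining edges are bridges) fewer edges are hidden, with a warning.
#'
#' @param net Undirected [igraph::graph].
#' @param fraction Fraction of edges to hide, in `(0, 1)`.
#' @param seed Integer seed.
#' @return List with `network` (the reduced graph) and `hidden` (a
#'   2-column character matrix of hidden-edge endpoints).
#' @export
hide_edges <- function(net, fraction, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  if (!igraph::is_connected(net)) {
    warning("network is disconnected; using its largest connected component")
    comp <- igraph::components(net)
    net <- igraph::induced_subgraph(
      net, which(comp$membership == which.max(comp$csize)))
  }
  target <- floor(fraction * igraph::ecount(net))
  set.seed(seed)
  hidden <- matrix(character(0), ncol = 2)
  g <- net
  for (i in seq_len(target)) {
    br <- igraph::bridges(g)
    eligible <- setdiff(seq_len(igraph::ecount(g)), as.integer(br))
    if (length(eligible) == 0) {
      warning("only ", nrow(hidden), " of ", target,
              " edges could be hidden without disconnecting the network")
      break
    }
    eid <- eligible[sample.int(length(eligible), 1L)]
    ends <- igraph::ends(g, eid)
    hidden <- rbind(hidden, ends)
    g <- igraph::delete_edges(g, eid)
  }
  list(network = g, hidden = hidden)
}

#' AdjustCD common-neighbour score
#'
#' `2 |N_u intersect N_v| / (max(|N_u|, N_avg) + max(|N_v|, N_avg))`, where
#' `N_avg` is the mean neighbourhood size over all nodes. Penalizes sparsely
#' connected nodes by flooring their neighbourhood size at the network
#' average.
#'
#' @param net Undirected [igraph::graph].
#' @param u,v Node IDs.
#' @return A non-negative number; symmetric in `u`, `v`.
#' @export
adjustcd_score <- function(net, u, v) {
  make_adjustcd_scorer(net)(u, v)
}

#' @rdname adjustcd_score
#' @return `make_adjustcd_scorer` returns a scorer `function(u, vs)`
#'   vectorized over the second argument, for use with [rank_evaluate()].
#' @export
make_adjustcd_scorer <- function(net) {
  nodes <- igraph::V(net)$name
  adj <- lapply(igraph::adjacent_vertices(net, igraph::V(net)),
                function(x) as.integer(x))
  names(adj) <- nodes
  n_avg <- mean(lengths(adj))
  function(u, vs) {
    nu <- adj[[u]]
    du <- max(length(nu), n_avg)
    vapply(vs, function(v) {
      nv <- adj[[v]]
      2 * length(intersect(nu, nv)) / (du + max(length(nv), n_avg))
    }, numeric(1), USE.NAMES = FALSE)
  }
}

#' Iterative PE-measure scores
#'
#' Starting from the adjacency indicator `P(0)`, iterates
#' `p(k)_uv = 1 - prod_l (1 - p(k-1)_ul * p(k-1)_vl)` over all common
#' neighbours `l` of `u` and `v` (an empty product gives score 0). Two
#' iterations are the conventional setting.
#'
#' @param net Undirected [igraph::graph].
#' @param iterations Number of iterations `k` (default 2).
#' @return Symmetric numeric matrix of scores with node-ID dimnames (zero
#'   diagonal).
#' @export
pe_scores <- function(net, iterations = 2L) {
  stopifnot(iterations >= 1)
  nodes <- igraph::V(net)$name
  n <- length(nodes)
  adj <- lapply(igraph::adjacent_vertices(net, igraph::V(net)),
                function(x) as.integer(x))
  P <- matrix(0, n, n, dimnames = list(nodes, nodes))
  el <- igraph::as_edgelist(net, names = FALSE)
  P[el] <- 1; P[el[, 2:1, drop = FALSE]] <- 1
  for (k in seq_len(iterations)) {
    prodmat <- matrix(1, n, n)
    for (l in seq_len(n)) {
      nb <- adj[[l]]
      if (length(nb) < 2) next
      b <- P[nb, l]
      prodmat[nb, nb] <- prodmat[nb, nb] * (1 - outer(b, b))
    }
    P <- 1 - prodmat
    diag(P) <- 0
    dimnames(P) <- list(nodes, nodes)
  }
  P
}

#' @rdname pe_scores
#' @return `make_pe_scorer` returns a scorer `function(u, vs)` over the
#'   precomputed score matrix.
#' @export
make_pe_scorer <- function(net, iterations = 2L) {
  P <- pe_scores(net, iterations)
  function(u, vs) unname(P[u, vs])
}

#' Embedding-cosine pair scorer
#'
#' Scores a node pair by the cosine similarity of their embeddings;
#' unembedded nodes score 0 with a warning.
#'
#' @param emb Embedding matrix with node-ID rownames.
#' @param u,v Node IDs.
#' @return `cosine_pair_score` returns one number; `make_cosine_scorer`
#'   returns a vectorized scorer `function(u, vs)`.
#' @export
cosine_pair_score <- function(emb, u, v) {
  make_cosine_scorer(emb)(u, v)
}

#' @rdname cosine_pair_score
#' @export
make_cosine_scorer <- function(emb) {
  function(u, vs) {
    if (!u %in% rownames(emb)) {
      warning("node without embedding scored 0: ", u)
      return(rep(0, length(vs)))
    }
    x <- emb[u, ]
    vapply(vs, function(v) {
      if (!v %in% rownames(emb)) {
        warning("node without embedding scored 0: ", v)
        return(0)
      }
      cosine_similarity(x, emb[v, ])
    }, numeric(1), USE.NAMES = FALSE)
  }
}

#' Random-vector baseline scorer
#'
#' Assigns every node an i.i.d. uniform random vector of dimension `d` and
#' scores pairs by cosine similarity — the chance baseline for the
#' link-prediction benchmark.
#'
#' @param nodes Character vector of node IDs.
#' @param d Vector dimension (default 64).
#' @param seed Integer seed.
#' @return A scorer `function(u, vs)`.
#' @export
make_random_scorer <- function(nodes, d = 64L, seed = 1L) {
  set.seed(seed)
  emb <- matrix(runif(length(nodes) * d, -1, 1), length(nodes), d,
                dimnames = list(nodes, NULL))
  make_cosine_scorer(emb)
}

#' Rank hidden edges against sampled non-neighbour candidates
#'
#' For each hidden edge `(u, v)`, `n_candidates` nodes not adjacent to `u`
#' in the reduced network (and distinct from `u` and `v`) are sampled; the
#' true pair's score is ranked (descending, ties by mean rank) among the
#' `n_candidates + 1` scored pairs. Reports the mean rank of the true edges
#' and `Hits@N`, the percentage ranked in the top `N`.
#'
#' @param scorer A `function(u, vs)` pair scorer (see the scorer
#'   factories).
#' @param net The reduced network from [hide_edges()].
#' @param hidden 2-column character matrix of hidden edges.
#' @param n_candidates Candidate nodes sampled per hidden edge (default
#'   100).
#' @param hits_levels Integer vector of `N` values for `Hits@N`.
#' @param seed Integer seed for candidate sampling.
#' @return List of class `linkpred_result`: `mean_ranking`, `hits_at`
#'   (named percentages), `n_hidden`, `n_candidates_per_pair`.
#' @export
rank_evaluate <- function(scorer, net, hidden, n_candidates = 100L,
                          hits_levels = c(1L, 10L, 50L), seed = 1L) {
  if (nrow(hidden) == 0) stop("no hidden edges to evaluate")
  nodes <- igraph::V(net)$name
  adj <- lapply(igraph::adjacent_vertices(net, igraph::V(net)),
                function(x) as.integer(x))
  names(adj) <- nodes
  idx <- seq_along(nodes)
  set.seed(seed)
  ranks <- numeric(nrow(hidden))
  short <- FALSE
  for (i in seq_len(nrow(hidden))) {
    u <- hidden[i, 1]; v <- hidden[i, 2]
    ineligible <- c(adj[[u]], match(u, nodes), match(v, nodes))
    pool <- idx[-ineligible]
    if (length(pool) < n_candidates) short <- TRUE
    cand <- nodes[pool[sample.int(length(pool),
                                  min(n_candidates, length(pool)))]]
    scores <- scorer(u, c(v, cand))
    ranks[i] <- rank(-scores, ties.method = "average")[1]
  }
  if (short) warning("fewer than n_candidates eligible non-neighbours ",
                     "for some hidden edges; used all available")
  hits <- vapply(hits_levels, function(N) 100 * mean(ranks <= N), numeric(1))
  structure(list(mean_ranking = mean(ranks),
                 hits_at = setNames(hits, paste0("hits@", hits_levels)),
                 n_hidden = nrow(hidden),
                 n_candidates_per_pair = n_candidates,
                 ranks = ranks),
            class = "linkpred_result")
}

#' @export
print.linkpred_result <- function(x, ...) {
  cat("Link-prediction benchmark:", x$n_hidden, "hidden edges,",
      x$n_candidates_per_pair, "candidates per pair\n")
  cat(sprintf("  mean ranking %.2f\n", x$mean_ranking))
  for (nm in names(x$hits_at)) {
    cat(sprintf("  %s: %.1f%%\n", nm, x$hits_at[[nm]]))
  }
  invisible(x)
}
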