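#' node2vec hyperparameters
#'
#' Defaults follow the settings used for PPI networks: return parameter
#' `p = 1`, in-out parameter `q = 8` (favouring breadth-first, structurally
#' similar neighbourhoods), `r = 10` walks per node of length `l = 10`,
#' skip-gram window `k = 10`, and embedding dimension `d = 64`.
#'
#' @param p Return parameter (> 0). Larger `p` makes the walk less likely to
#'   revisit the previous node.
#' @param q In-out parameter (> 0). Larger `q` keeps the walk close to the
#'   start (breadth-first-like exploration).
#' @param r Number of walks started at each node.
#' @param l Walk length in nodes.
#' @param k Skip-gram window size.
#' @param d Embedding dimension.
#' @param negative Number of negative samples per positive pair.
#' @param epochs Training epochs over the walk corpus.
#' @param alpha Initial SGD learning rate (linearly decayed).
#' @return A list of class `node2vec_params`.
#' @export
node2vec_params <- function(p = 1, q = 8, r = 10, l = 10, k = 10, d = 64,
                            negative = 5, epochs = 5, alpha = 0.025) {
  stopifnot(p > 0, q > 0, r >= 1, l >= 2, k >= 1, d >= 1,
            negative >= 1, epochs >= 1, alpha > 0)
  structure(list(p = p, q = q, r = as.integer(r), l = as.integer(l),
                 k = as.integer(k), d = as.integer(d),
                 negative = as.integer(negative),
                 epochs = as.integer(epochs), alpha = alpha),
            class = "node2vec_params")
}

# ---- alias method (Vose) -------------------------------------------------
# O(K) setup, O(1) sampling of a discrete distribution.

alias_setup <- function(probs) {
  K <- length(probs)
  probs <- probs / sum(probs)
  q <- probs * K
  alias <- integer(K)
  small <- which(q < 1)
  large <- which(q >= 1)
  while (length(small) > 0 && length(large) > 0) {
    s <- small[length(small)]; small <- small[-length(small)]
    l <- large[length(large)]
    alias[s] <- l
    q[l] <- q[l] - (1 - q[s])
    if (q[l] < 1) {
      large <- large[-length(large)]
      small <- c(small, l)
    }
  }
  q[q > 1] <- 1
  q[c(small, large)] <- 1
  list(prob = q, alias = alias)
}

alias_draw <- function(tbl) {
  i <- sample.int(length(tbl$prob), 1L)
  if (stats::runif(1) < tbl$prob[i]) i else tbl$alias[i]
}

# ---- transition probabilities --------------------------------------------

#' Build second-order biased-walk transition probabilities
#'
#' For a walk that moved from node `t` to node `v`, the unnormalized
#' probability of stepping to neighbour `x` of `v` is `w(v,x) * alpha` with
#' `alpha = 1/p` if `x = t`, `alpha = 1` if `x` is adjacent to `t`, and
#' `alpha = 1/q` otherwise (edge weights `w` default to 1). Probabilities are
#' normalized over the neighbours of `v` and stored as alias tables for O(1)
#' sampling.
#'
#' @param net Undirected [igraph::graph] with vertex names.
#' @param params A [node2vec_params()] object.
#' @return An opaque transition structure consumed by [simulate_walks()];
#'   inspect individual distributions with [transition_probs()].
#' @export
build_transition_probs <- function(net, params = node2vec_params()) {
  n <- igraph::vcount(net)
  if (n == 0) stop("network is empty")
  nodes <- igraph::V(net)$name
  adj <- lapply(igraph::adjacent_vertices(net, igraph::V(net)),
                function(vs) sort(as.integer(vs)))
  weighted <- "weight" %in% igraph::edge_attr_names(net)
  wadj <- vector("list", n)
  for (v in seq_len(n)) {
    if (weighted && length(adj[[v]]) > 0) {
      eids <- igraph::get_edge_ids(net, rbind(rep(v, length(adj[[v]])),
                                              adj[[v]]))
      wadj[[v]] <- igraph::E(net)$weight[eids]
    } else {
      wadj[[v]] <- rep(1, length(adj[[v]]))
    }
  }
  first <- vector("list", n)   # alias table for the first (memoryless) step
  second <- vector("list", n)  # second[[v]][[i]]: previous node = adj[[v]][i]
  for (v in seq_len(n)) {
    nb <- adj[[v]]
    if (length(nb) == 0) next
    first[[v]] <- c(alias_setup(wadj[[v]]), list(probs = wadj[[v]] / sum(wadj[[v]])))
    tabs <- vector("list", length(nb))
    for (i in seq_along(nb)) {
      t_node <- nb[i]
      alpha <- ifelse(nb == t_node, 1 / params$p,
                      ifelse(nb %in% adj[[t_node]], 1, 1 / params$q))
      uw <- wadj[[v]] * alpha
      tabs[[i]] <- c(alias_setup(uw), list(probs = uw / sum(uw)))
    }
    second[[v]] <- tabs
  }
  structure(list(nodes = nodes, adj = adj, first = first, second = second,
                 params = params),
            class = "node2vec_transitions")
}

#' Inspect one transition distribution
#'
#' @param tp Structure from [build_transition_probs()].
#' @param prev Previous node ID, or `NULL` for the first-step distribution.
#' @param cur Current node ID.
#' @return Named numeric vector of next-step probabilities over the
#'   neighbours of `cur`.
#' @export
transition_probs <- function(tp, prev, cur) {
  v <- match(cur, tp$nodes)
  if (is.na(v)) stop("unknown node: ", cur)
  nb <- tp$adj[[v]]
  if (length(nb) == 0) return(setNames(numeric(0), character(0)))
  if (is.null(prev)) {
    return(setNames(tp$first[[v]]$probs, tp$nodes[nb]))
  }
  t_idx <- match(match(prev, tp$nodes), nb)
  if (is.na(t_idx)) stop("'prev' is not a neighbour of 'cur'")
  setNames(tp$second[[v]][[t_idx]]$probs, tp$nodes[nb])
}

#' Simulate biased random walks
#'
#' Starts `r` walks of length `l` at every node, sampling each step from the
#' alias tables of [build_transition_probs()]. The first step is drawn
#' weight-proportionally (uniformly when unweighted); walks from isolated
#' nodes are the single-node sequence.
#'
#' @param net Undirected [igraph::graph] with vertex names.
#' @param params A [node2vec_params()] object.
#' @param seed Integer seed; identical seeds give identical corpora.
#' @param tp Optional precomputed [build_transition_probs()] structure.
#' @return List of character vectors (the walk corpus), `r * vcount(net)`
#'   walks, grouped by start node.
#' @export
simulate_walks <- function(net, params = node2vec_params(), seed = 1L,
                           tp = NULL) {
  if (is.null(tp)) tp <- build_transition_probs(net, params)
  n <- length(tp$nodes)
  set.seed(seed)
  walks <- vector("list", n * params$r)
  w <- 0L
  for (v0 in seq_len(n)) {
    for (rep_i in seq_len(params$r)) {
      w <- w + 1L
      if (length(tp$adj[[v0]]) == 0) {
        walks[[w]] <- tp$nodes[v0]
        next
      }
      wk <- integer(params$l)
      wk[1] <- v0
      wk[2] <- tp$adj[[v0]][alias_draw(tp$first[[v0]])]
      if (params$l > 2) {
        for (s in 3:params$l) {
          cur <- wk[s - 1L]
          prev <- wk[s - 2L]
          nb <- tp$adj[[cur]]
          if (length(nb) == 0) { wk <- wk[seq_len(s - 1L)]; break }
          t_idx <- match(prev, nb)
          wk[s] <- nb[alias_draw(tp$second[[cur]][[t_idx]])]
        }
      }
      walks[[w]] <- tp$nodes[wk]
    }
  }
  walks
}

#' Train skip-gram embeddings on a walk corpus
#'
#' Skip-gram with negative sampling over walk contexts (window `k`), trained
#' by single-threaded SGD with a linearly decaying learning rate; fixed seeds
#' give bit-identical embeddings. Only nodes that appear in the corpus are
#' embedded.
#'
#' @param walks Walk corpus from [simulate_walks()].
#' @param params A [node2vec_params()] object.
#' @param seed Integer seed for initialization and negative sampling.
#' @return Numeric matrix, one row per embedded node (rownames are node IDs),
#'   `d` columns.
#' @export
train_embeddings <- function(walks, params = node2vec_params(), seed = 1L) {
  if (length(walks) == 0) stop("empty walk corpus")
  vocab <- sort(unique(unlist(walks)))
  iwalks <- lapply(walks, function(w) match(w, vocab) - 1L)
  emb <- .sgns_train(iwalks, length(vocab), params$d, params$k,
                     params$negative, params$epochs, params$alpha,
                     as.integer(seed))
  rownames(emb) <- vocab
  emb
}

#' Learn node embeddings for a network
#'
#' Convenience wrapper: [build_transition_probs()] then [simulate_walks()]
#' then [train_embeddings()]. Nodes absent from every walk (isolated nodes)
#' receive the zero vector, with a warning, so that every network node has a
#' row.
#'
#' @inheritParams simulate_walks
#' @return Numeric embedding matrix covering all network nodes.
#' @export
node2vec <- function(net, params = node2vec_params(), seed = 1L) {
  walks <- simulate_walks(net, params, seed = derive_seed(seed, "walks"))
  emb <- train_embeddings(walks, params, seed = derive_seed(seed, "sgns"))
  all_nodes <- sort(igraph::V(net)$name)
  missing <- setdiff(all_nodes, rownames(emb))
  if (length(missing) > 0) {
    warning(length(missing),
            " node(s) absent from the walk corpus embedded as zero vectors")
    zero <- matrix(0, length(missing), params$d,
                   dimnames = list(missing, NULL))
    emb <- rbind(emb, zero)
  }
  emb[all_nodes, , drop = FALSE]
}

#' Cosine similarity between two vectors
#'
#' `sum(x*y) / (sqrt(sum(x^2)) * sqrt(sum(y^2)))`. If either vector is all
#' zero the similarity is defined as 0 (no evidence of association) rather
#' than an error, so degenerate embeddings rank lowest instead of crashing
#' downstream refinement.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A number in `[-1, 1]`.
#' @export
cosine_similarity <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length")
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(0)
  sum(x * y) / (nx * ny)
}

#' Pool member embeddings into a complex vector
#'
#' Stacks the member embeddings into a matrix `Z` (one row per member) and
#' pools each column with the chosen strategy. Max pooling, the default,
#' gathers the strongest feature activations across subunits and performed
#' best for downstream classification; min and average are the alternatives.
#'
#' @param cx Character vector of member IDs (a complex).
#' @param emb Embedding matrix with node-ID rownames.
#' @param strategy `"max"` (default), `"min"` or `"average"`.
#' @return Numeric vector of length `ncol(emb)`.
#' @export
complex_vector <- function(cx, emb, strategy = c("max", "min", "average")) {
  strategy <- match.arg(strategy)
  if (length(cx) == 0) stop("empty complex")
  missing <- setdiff(cx, rownames(emb))
  if (length(missing) > 0) {
    stop("members without embeddings: ", paste(missing, collapse = ", "))
  }
  Z <- emb[cx, , drop = FALSE]
  switch(strategy,
         max = apply(Z, 2, max),
         min = apply(Z, 2, min),
         average = colMeans(Z))
}
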