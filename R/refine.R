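#' Weight network edges by embedding cosine similarity
#'
#' Every edge `(u, v)` receives weight `cosine_similarity(emb[u,], emb[v,])`;
#' the topology is unchanged. Endpoints with all-zero embeddings yield
#' weight 0.
#'
#' @param net Undirected [igraph::graph] with vertex names.
#' @param emb Embedding matrix covering all network nodes.
#' @return The same graph with an edge `weight` attribute.
#' @export
weight_edges <- function(net, emb) {
  missing <- setdiff(igraph::V(net)$name, rownames(emb))
  if (length(missing) > 0) {
    stop("nodes without embeddings: ", paste(head(missing, 5), collapse = ", "))
  }
  el <- igraph::as_edgelist(net)
  if (nrow(el) == 0) return(net)
  A <- emb[el[, 1], , drop = FALSE]
  B <- emb[el[, 2], , drop = FALSE]
  num <- rowSums(A * B)
  den <- sqrt(rowSums(A^2)) * sqrt(rowSums(B^2))
  w <- ifelse(den == 0, 0, num / den)
  igraph::E(net)$weight <- w
  net
}

#' Drop low-similarity edges
#'
#' Keeps exactly the edges whose weight is `>= simi_thres` (non-strict, so a
#' threshold of -1 is the identity). Nodes are retained even when they become
#' isolated; the number of removed edges is reported via [message()].
#'
#' @param wnet Weighted [igraph::graph] (see [weight_edges()]).
#' @param simi_thres Similarity threshold in `[-1, 1]`.
#' @return The filtered graph.
#' @export
filter_edges <- function(wnet, simi_thres) {
  if (!"weight" %in% igraph::edge_attr_names(wnet)) {
    stop("network has no edge weights; run weight_edges() first")
  }
  drop <- which(igraph::E(wnet)$weight < simi_thres)
  message(length(drop), " edge(s) filtered at similarity threshold ",
          simi_thres)
  igraph::delete_edges(wnet, drop)
}

#' Add the most-similar missing neighbour per node
#'
#' For each node `u`, the non-neighbour `v*` with the highest embedding
#' cosine similarity is found; the edge `u - v*` is added when that
#' similarity is strictly greater than `simi_thres` (strict, so a threshold
#' of 1 adds nothing). Symmetric duplicates are added once; nodes with
#' all-zero embeddings contribute no candidate. New edges carry their cosine
#' similarity as weight when the input network is weighted.
#'
#' @param net Undirected [igraph::graph] with vertex names.
#' @param emb Embedding matrix covering all network nodes.
#' @param simi_thres Similarity threshold in `[-1, 1]`.
#' @return The augmented graph.
#' @export
augment_edges <- function(net, emb, simi_thres) {
  nodes <- igraph::V(net)$name
  missing <- setdiff(nodes, rownames(emb))
  if (length(missing) > 0) {
    stop("nodes without embeddings: ", paste(head(missing, 5), collapse = ", "))
  }
  E0 <- emb[nodes, , drop = FALSE]
  nrm <- sqrt(rowSums(E0^2))
  unit <- E0 / ifelse(nrm == 0, 1, nrm)
  S <- tcrossprod(unit)               # cosine similarities, zero rows -> 0
  S[nrm == 0, ] <- 0
  S[, nrm == 0] <- 0
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  A <- A[nodes, nodes]
  S[as.matrix(A) > 0] <- -Inf         # existing neighbours ineligible
  diag(S) <- -Inf
  new_a <- character(); new_b <- character(); new_w <- numeric()
  for (i in seq_along(nodes)) {
    if (nrm[i] == 0) next
    j <- which.max(S[i, ])
    if (is.finite(S[i, j]) && S[i, j] > simi_thres) {
      new_a <- c(new_a, nodes[i]); new_b <- c(new_b, nodes[j])
      new_w <- c(new_w, S[i, j])
    }
  }
  if (length(new_a) == 0) {
    message("0 edge(s) added at similarity threshold ", simi_thres)
    return(net)
  }
  key <- paste(pmin(new_a, new_b), pmax(new_a, new_b))
  keep <- !duplicated(key)
  new_a <- new_a[keep]; new_b <- new_b[keep]; new_w <- new_w[keep]
  message(length(new_a), " edge(s) added at similarity threshold ",
          simi_thres)
  weighted <- "weight" %in% igraph::edge_attr_names(net)
  ids <- as.vector(rbind(new_a, new_b))
  if (weighted) {
    igraph::add_edges(net, ids, attr = list(weight = new_w))
  } else {
    igraph::add_edges(net, ids)
  }
}

#' Refinement configuration
#'
#' At least one of the two thresholds must be set. The order is always
#' filter-then-add: low-similarity existing edges are removed first, then
#' high-similarity new edges are introduced on the filtered network.
#'
#' @param filter_thres Threshold for [filter_edges()], or `NULL` to skip.
#' @param add_thres Threshold for [augment_edges()], or `NULL` to skip.
#' @return A list of class `refinement_config`.
#' @export
refinement_config <- function(filter_thres = NULL, add_thres = NULL) {
  if (is.null(filter_thres) && is.null(add_thres)) {
    stop("set at least one of filter_thres / add_thres")
  }
  stopifnot(is.null(filter_thres) ||
              (filter_thres >= -1 && filter_thres <= 1),
            is.null(add_thres) || (add_thres >= -1 && add_thres <= 1))
  structure(list(filter_thres = filter_thres, add_thres = add_thres,
                 order = "filter_then_add"),
            class = "refinement_config")
}

#' Filter then augment a network by embedding similarity
#'
#' Applies [filter_edges()] (when `filter_thres` is set) and then
#' [augment_edges()] on the filtered network (when `add_thres` is set).
#'
#' @param net Undirected [igraph::graph] with vertex names.
#' @param emb Embedding matrix covering all network nodes.
#' @param config A [refinement_config()].
#' @return The refined graph, with attribute `"refine_report"` holding the
#'   removed/added edge counts.
#' @export
refine_network <- function(net, emb, config) {
  stopifnot(inherits(config, "refinement_config"))
  removed <- 0L; added <- 0L
  out <- net
  if (!is.null(config$filter_thres)) {
    if (!"weight" %in% igraph::edge_attr_names(out)) {
      out <- weight_edges(out, emb)
    }
    before <- igraph::ecount(out)
    out <- filter_edges(out, config$filter_thres)
    removed <- before - igraph::ecount(out)
  }
  if (!is.null(config$add_thres)) {
    before <- igraph::ecount(out)
    out <- augment_edges(out, emb, config$add_thres)
    added <- igraph::ecount(out) - before
  }
  attr(out, "refine_report") <- list(edges_removed = removed,
                                     edges_added = added,
                                     edges_final = igraph::ecount(out))
  out
}
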