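#' Three-class training set for the supervised detector
#'
#' Positives are known (gold-standard) complexes; intermediates are complex
#' candidates of middling quality (e.g. output of another detector, or
#' noise-degraded gold complexes); negatives are random node sets.
#'
#' @param positives,intermediates,negatives Lists of character vectors.
#' @return A list of class `labeled_complex_set`.
#' @export
labeled_complex_set <- function(positives, intermediates, negatives) {
  for (nm in c("positives", "intermediates", "negatives")) {
    val <- get(nm)
    if (length(val) == 0) stop("class '", nm, "' is empty")
    if (any(lengths(val) < 2)) stop("class '", nm, "' has a complex with < 2 members")
  }
  structure(list(positives = positives, intermediates = intermediates,
                 negatives = negatives),
            class = "labeled_complex_set")
}

# CSR adjacency for fast repeated feature evaluation.
network_csr <- function(net) {
  nodes <- igraph::V(net)$name
  n <- length(nodes)
  el <- igraph::as_edgelist(net, names = FALSE)
  weighted <- "weight" %in% igraph::edge_attr_names(net)
  from <- c(el[, 1], el[, 2])
  to <- c(el[, 2], el[, 1])
  o <- order(from, to)
  ptr <- c(0L, cumsum(tabulate(from, nbins = n)))
  ew <- numeric(0)
  if (weighted && nrow(el) > 0) {
    w2 <- rep(igraph::E(net)$weight, 2)
    ew <- w2[o]
  }
  list(ptr = as.integer(ptr), idx = as.integer(to[o] - 1L), ew = ew,
       nodes = nodes, n = n)
}

topo_feature_names <- c(
  "n_nodes", "n_edges", "density", "mean_internal_degree",
  "var_internal_degree", "max_internal_degree", "mean_clustering",
  "lcc_fraction", "mean_external_degree", "internal_ratio",
  "mean_edge_weight")

#' Eleven topological features of an induced subgraph
#'
#' Features of the subgraph induced by a complex's members, covering the
#' density, connectivity and separation axes used to score complex
#' candidates: (1) node count, (2) internal edge count, (3) density,
#' (4) mean internal degree, (5) population variance of internal degree,
#' (6) maximum internal degree, (7) mean local clustering coefficient,
#' (8) fraction of members in the largest connected component, (9) mean
#' external degree (edges leaving the complex, per member), (10) ratio of
#' internal edges to internal + boundary edges, and (11) mean internal edge
#' weight (1 on unweighted networks, 0 when there are no internal edges).
#'
#' @param cx Character vector of member IDs.
#' @param net Undirected [igraph::graph] containing all members.
#' @param csr Optional precomputed adjacency from the internal CSR builder
#'   (used by the detector for speed).
#' @return Named numeric vector of length 11; all entries finite.
#' @export
topo_features <- function(cx, net, csr = NULL) {
  if (is.null(csr)) csr <- network_csr(net)
  mi <- match(unique(cx), csr$nodes)
  if (anyNA(mi)) stop("complex member(s) outside the network: ",
                      paste(unique(cx)[is.na(mi)], collapse = ", "))
  .topo_features_csr(csr$ptr, csr$idx, csr$ew, as.integer(mi - 1L), csr$n)
}

#' Sample random node sets as negative training examples
#'
#' Each negative is a uniformly random node set whose size is drawn with
#' replacement from `size_pool`; node sets identical to a supplied positive
#' complex are rejected and resampled.
#'
#' @param net Undirected [igraph::graph].
#' @param size_pool Integer vector of candidate sizes (each >= 2).
#' @param count Number of negatives to draw.
#' @param seed Integer seed.
#' @param positives Optional list of complexes the negatives must differ
#'   from.
#' @return List of `count` character vectors.
#' @export
sample_negative_subgraphs <- function(net, size_pool, count, seed = 1L,
                                      positives = list()) {
  stopifnot(count >= 0, all(size_pool >= 2))
  nodes <- igraph::V(net)$name
  if (any(size_pool > length(nodes))) {
    stop("requested negative size exceeds the number of network nodes")
  }
  if (count == 0) return(list())
  pos_keys <- vapply(positives, function(p) paste(sort(p), collapse = "\r"), "")
  set.seed(seed)
  out <- vector("list", count)
  for (i in seq_len(count)) {
    repeat {
      sz <- size_pool[sample.int(length(size_pool), 1L)]
      cand <- sort(sample(nodes, sz))
      if (!(paste(cand, collapse = "\r") %in% pos_keys)) break
    }
    out[[i]] <- cand
  }
  out
}

#' Train the regression scorer over topological features
#'
#' Fits a linear regression of class targets (positive = 1,
#' intermediate = 0.5, negative = 0) on the eleven [topo_features()] of every
#' training complex. By default the fit is ridge-regularized on standardized
#' features (`lambda = 0.1`): complex training sets are typically small
#' (tens of rows) while the eleven features are strongly collinear, and
#' unregularized least squares then produces sign-flipped coefficient pairs
#' whose score landscape derails greedy expansion. `lambda = 0` gives plain
#' least squares. Constant feature columns are tolerated (their coefficients
#' are dropped, with a warning under `lambda = 0`). The training R-squared
#' is reported via [message()].
#'
#' @param train A [labeled_complex_set()].
#' @param net Network on which features are computed.
#' @param seed Integer seed, recorded in the scorer metadata.
#' @param lambda Ridge penalty on standardized features (0 = ordinary least
#'   squares).
#' @return An object of class `complex_scorer`.
#' @export
train_scorer <- function(train, net, seed = 1L, lambda = 0.1) {
  stopifnot(inherits(train, "labeled_complex_set"), lambda >= 0)
  csr <- network_csr(net)
  all_cx <- c(train$positives, train$intermediates, train$negatives)
  y <- rep(c(1, 0.5, 0), c(length(train$positives),
                           length(train$intermediates),
                           length(train$negatives)))
  X <- t(vapply(all_cx, topo_features, numeric(11), net = net, csr = csr))
  colnames(X) <- topo_feature_names
  if (lambda == 0) {
    fit <- lm(y ~ ., data = as.data.frame(X))
    coefs <- stats::coef(fit)
    if (anyNA(coefs)) {
      warning("degenerate (constant) feature column(s): ",
              paste(names(coefs)[is.na(coefs)], collapse = ", "))
      coefs[is.na(coefs)] <- 0
    }
  } else {
    mu <- colMeans(X)
    sdv <- apply(X, 2, stats::sd)
    sdv[sdv == 0] <- 1
    Xs <- scale(X, mu, sdv)
    beta_s <- solve(crossprod(Xs) + lambda * nrow(X) * diag(ncol(X)),
                    crossprod(Xs, y - mean(y)))
    beta <- drop(beta_s) / sdv
    coefs <- c("(Intercept)" = mean(y) - sum(beta * mu), beta)
  }
  pred <- coefs[1] + X %*% coefs[-1]
  r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  message("scorer training R-squared: ", round(r2, 4))
  structure(list(coef = coefs, r_squared = r2,
                 family = if (lambda == 0) "ols" else "ridge",
                 lambda = lambda, seed = seed,
                 max_positive_size = max(lengths(train$positives))),
            class = "complex_scorer")
}

#' Score complexes with a trained scorer
#'
#' @param object A `complex_scorer`.
#' @param complexes List of character vectors (or one character vector).
#' @param net Network on which features are computed.
#' @param ... Unused.
#' @return Numeric vector of scores.
#' @export
predict.complex_scorer <- function(object, complexes, net, ...) {
  if (is.character(complexes)) complexes <- list(complexes)
  csr <- network_csr(net)
  vapply(complexes, function(cx) {
    f <- topo_features(cx, net, csr = csr)
    unname(object$coef[1] + sum(object$coef[-1] * f))
  }, numeric(1))
}

score_members_csr <- function(scorer, members0, csr) {
  f <- .topo_features_csr(csr$ptr, csr$idx, csr$ew, members0, csr$n)
  unname(scorer$coef[1] + sum(scorer$coef[-1] * f))
}

#' Select seed nodes for complex expansion
#'
#' Nodes whose degree exceeds the network's mean degree (`2|E|/|V|`,
#' strictly) become singleton seeds.
#'
#' @param net Undirected [igraph::graph].
#' @return List of single-member character vectors; empty (with a warning)
#'   for regular graphs.
#' @export
select_seeds <- function(net) {
  deg <- igraph::degree(net)
  mean_deg <- 2 * igraph::ecount(net) / igraph::vcount(net)
  sel <- igraph::V(net)$name[deg > mean_deg]
  if (length(sel) == 0) {
    warning("no node exceeds the mean degree; no seeds selected")
    return(list())
  }
  lapply(sort(sel), function(x) x)
}

expand_members_csr <- function(members0, csr, scorer, max_size, tol) {
  memb <- rep(FALSE, csr$n)
  memb[members0 + 1L] <- TRUE
  cur_score <- score_members_csr(scorer, members0, csr)
  boundary <- unique(unlist(lapply(members0, function(v) {
    csr$idx[seq.int(csr$ptr[v + 1L] + 1L, length.out = csr$ptr[v + 2L] - csr$ptr[v + 1L])]
  })))
  boundary <- boundary[!memb[boundary + 1L]]
  while (length(members0) < max_size && length(boundary) > 0) {
    scores <- vapply(boundary, function(c0)
      score_members_csr(scorer, c(members0, c0), csr), numeric(1))
    best <- max(scores)
    if (best <= cur_score + tol) break
    cand <- boundary[scores == best]
    pick <- cand[order(csr$nodes[cand + 1L])][1]
    members0 <- c(members0, pick)
    memb[pick + 1L] <- TRUE
    cur_score <- best
    nb <- csr$idx[seq.int(csr$ptr[pick + 1L] + 1L,
                          length.out = csr$ptr[pick + 2L] - csr$ptr[pick + 1L])]
    boundary <- unique(c(boundary[boundary != pick], nb[!memb[nb + 1L]]))
    boundary <- boundary[!memb[boundary + 1L]]
  }
  members0
}

#' Greedily expand a seed into a candidate complex
#'
#' Repeatedly adds the neighbouring node that yields the largest increase in
#' the scorer's value; stops when no candidate improves the score by more
#' than `tol` or the complex reaches `max_size`. Equal gains are broken by
#' the lexicographically smallest node ID, so expansion is deterministic.
#'
#' @param seed Character vector of starting members (usually a singleton).
#' @param net Undirected [igraph::graph].
#' @param scorer A trained `complex_scorer`.
#' @param max_size Maximum complex size; defaults to twice the largest
#'   positive training complex recorded in the scorer.
#' @param tol Minimum score improvement to continue expanding.
#' @return Character vector of member IDs (always contains the seed and
#'   induces a connected subgraph around it).
#' @export
expand_seed <- function(seed, net, scorer, max_size = NULL, tol = 0.02) {
  csr <- network_csr(net)
  if (is.null(max_size)) max_size <- 2L * scorer$max_positive_size
  mi <- match(seed, csr$nodes)
  if (anyNA(mi)) stop("seed member(s) outside the network")
  sort(csr$nodes[expand_members_csr(as.integer(mi - 1L), csr, scorer,
                                    max_size, tol) + 1L])
}

#' Detect candidate complexes by scorer-guided seed expansion
#'
#' Expands every [select_seeds()] seed with [expand_seed()], drops results
#' smaller than `min_size`, and removes exact duplicate member sets. Each
#' returned complex carries its scorer value as attribute `"score"`.
#'
#' @param net Undirected [igraph::graph].
#' @param scorer A trained `complex_scorer`.
#' @param min_size Minimum candidate size (gold complexes start at size 3).
#' @param max_size Maximum candidate size; defaults to twice the largest
#'   positive training complex.
#' @param tol Minimum score improvement to continue expanding.
#' @return List of character vectors, each with attribute `"score"`.
#' @export
detect_candidates <- function(net, scorer, min_size = 3L, max_size = NULL,
                              tol = 0.02) {
  stopifnot(inherits(scorer, "complex_scorer"))
  if (is.null(max_size)) max_size <- 2L * scorer$max_positive_size
  seeds <- select_seeds(net)
  if (length(seeds) == 0) {
    warning("no seeds; returning no candidates")
    return(list())
  }
  csr <- network_csr(net)
  out <- list()
  seen <- character(0)
  for (s in seeds) {
    m0 <- as.integer(match(s, csr$nodes) - 1L)
    mem <- expand_members_csr(m0, csr, scorer, max_size, tol)
    if (length(mem) < min_size) next
    cx <- sort(csr$nodes[mem + 1L])
    key <- paste(cx, collapse = "\r")
    if (key %in% seen) next
    seen <- c(seen, key)
    attr(cx, "score") <- score_members_csr(scorer, mem, csr)
    out[[length(out) + 1L]] <- cx
  }
  out
}
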