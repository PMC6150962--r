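#' Synthetic planted-complex network configuration
#'
#' A planted-partition style generator: complexes are node sets with
#' internal edge probability `p_within`, embedded in an Erdos-Renyi
#' background at `p_background`, optionally with extra uniformly random
#' noise edges. The defaults emulate a desk-scale sparse PPI network with
#' dense complexes of realistic sizes.
#'
#' @param n_nodes Total nodes in the network (default 500).
#' @param n_complexes Number of planted complexes (default 20).
#' @param size_min,size_max Complex size range (default 5-15; gold
#'   complexes in curated catalogues start at size 3).
#' @param p_within Edge probability inside a complex (default 0.8).
#' @param p_background Edge probability elsewhere (default 0.01).
#' @param noise_edge_fraction Extra random edges as a fraction of the edge
#'   count (default 0).
#' @param overlap_fraction Fraction of complexes that share one member with
#'   an earlier complex (default 0).
#' @param seed Integer seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_nodes = 500L, n_complexes = 20L, size_min = 5L,
                         size_max = 15L, p_within = 0.8,
                         p_background = 0.01, noise_edge_fraction = 0,
                         overlap_fraction = 0, seed = 1L) {
  stopifnot(size_min >= 3, size_max >= size_min,
            p_background >= 0, p_background < p_within, p_within <= 1,
            noise_edge_fraction >= 0, noise_edge_fraction < 1,
            overlap_fraction >= 0, overlap_fraction <= 1)
  structure(list(n_nodes = as.integer(n_nodes),
                 n_complexes = as.integer(n_complexes),
                 size_min = as.integer(size_min),
                 size_max = as.integer(size_max),
                 p_within = p_within, p_background = p_background,
                 noise_edge_fraction = noise_edge_fraction,
                 overlap_fraction = overlap_fraction,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic PPI network with planted complexes
#'
#' Complex member sets are disjoint (up to `overlap_fraction` single shared
#' members); internal pairs receive edges with probability `p_within`, all
#' other pairs with probability `p_background`, and
#' `noise_edge_fraction * |E|` additional edges are drawn uniformly from the
#' remaining non-edges. Intermediate-class training complexes are the
#' planted complexes with 30% of their members resampled.
#'
#' @param config A [synth_config()].
#' @return List with `network` (igraph), `gold` (list of planted
#'   complexes), `intermediates` (noise-degraded copies) and `edge_origin`
#'   (character vector aligned with the network's edges:
#'   `"planted"`, `"background"` or `"noise"`).
#' @export
generate_synthetic_ppi <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_nodes
  nodes <- sprintf("P%04d", seq_len(n))
  gold <- list()
  if (config$n_complexes > 0) {
    sizes <- sample(config$size_min:config$size_max, config$n_complexes,
                    replace = TRUE)
    if (sum(sizes) > n) {
      stop("planted complexes need ", sum(sizes), " nodes but only ", n,
           " are available")
    }
    pool <- sample(nodes, sum(sizes))
    off <- c(0L, cumsum(sizes))
    for (i in seq_len(config$n_complexes)) {
      mem <- pool[(off[i] + 1):off[i + 1]]
      if (i > 1 && config$overlap_fraction > 0 &&
          runif(1) < config$overlap_fraction) {
        donor <- gold[[sample.int(i - 1L, 1L)]]
        mem[1] <- donor[sample.int(length(donor), 1L)]
        mem <- unique(mem)
      }
      gold[[i]] <- sort(mem)
    }
  }
  # all unordered pairs, internal pairs flagged
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  internal_full <- logical(n * n) # flags on the full n x n grid
  node_idx <- setNames(seq_len(n), nodes)
  for (cx in gold) {
    ids <- sort(node_idx[cx])
    if (length(ids) >= 2) {
      cp <- t(utils::combn(ids, 2))
      internal_full[(cp[, 2] - 1) * n + cp[, 1]] <- TRUE
    }
  }
  internal <- internal_full[(pr[, 2] - 1) * n + pr[, 1]]
  p <- ifelse(internal, config$p_within, config$p_background)
  draw <- runif(nrow(pr)) < p
  ei <- pr[draw, , drop = FALSE]
  origin <- ifelse(internal[draw], "planted", "background")
  if (config$noise_edge_fraction > 0 && nrow(ei) > 0) {
    k <- round(config$noise_edge_fraction * nrow(ei))
    open <- which(!draw)
    k <- min(k, length(open))
    pick <- open[sample.int(length(open), k)]
    ei <- rbind(ei, pr[pick, , drop = FALSE])
    origin <- c(origin, rep("noise", k))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = nodes[ei[, 1]], to = nodes[ei[, 2]],
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  igraph::E(g)$origin <- origin
  intermediates <- if (length(gold) > 0) {
    degrade_gold(gold, 0.3, seed = derive_seed(config$seed, "intermediates"),
                 nodes = nodes)
  } else {
    list()
  }
  list(network = g, gold = gold, intermediates = intermediates,
       edge_origin = origin)
}

#' Degrade complexes by resampling members
#'
#' Replaces `ceiling(member_noise * size)` members of each complex with
#' random nodes outside it, preserving sizes — used to fabricate
#' intermediate-quality training complexes.
#'
#' @param gold List of character vectors.
#' @param member_noise Fraction of members to replace, in `[0, 1)`.
#' @param seed Integer seed.
#' @param nodes Node universe to draw replacements from.
#' @return List of degraded complexes (same lengths as `gold`).
#' @export
degrade_gold <- function(gold, member_noise = 0.3, seed = 1L, nodes) {
  stopifnot(member_noise >= 0, member_noise < 1)
  if (member_noise == 0) return(gold)
  set.seed(seed)
  lapply(gold, function(cx) {
    k <- ceiling(member_noise * length(cx))
    keep <- sample(cx, length(cx) - k)
    repl <- sample(setdiff(nodes, cx), k)
    sort(c(keep, repl))
  })
}
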