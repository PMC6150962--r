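#' Full-pipeline configuration
#'
#' Bundles the parameters of every stage of the detection pipeline:
#' embedding, network refinement, supervised seed expansion, complex-vector
#' classification, and evaluation. A single global `seed` fans out to
#' deterministic per-stage seeds so stages can be re-run independently.
#'
#' @param node2vec A [node2vec_params()] object.
#' @param refine A [refinement_config()], or `NULL` to leave the network
#'   unchanged.
#' @param n_negatives Number of negative training subgraphs; `NULL` means
#'   one per positive complex.
#' @param intermediate_noise Membership-noise level used to fabricate
#'   intermediate training complexes when none are supplied.
#' @param min_size,max_size Candidate size bounds for [detect_candidates()]
#'   (`max_size = NULL` defaults to twice the largest positive).
#' @param tol Expansion stopping tolerance.
#' @param classifier A [classifier_config()].
#' @param na_thres Neighborhood-affinity matching threshold.
#' @param seed Global integer seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(node2vec = node2vec_params(), refine = NULL,
                            n_negatives = NULL, intermediate_noise = 0.3,
                            min_size = 3L, max_size = NULL, tol = 0.02,
                            classifier = classifier_config(),
                            na_thres = 0.25, seed = 1L) {
  stopifnot(inherits(node2vec, "node2vec_params"),
            is.null(refine) || inherits(refine, "refinement_config"),
            inherits(classifier, "classifier_config"),
            na_thres > 0, na_thres <= 1, min_size >= 2, tol >= 0)
  structure(list(node2vec = node2vec, refine = refine,
                 n_negatives = n_negatives,
                 intermediate_noise = intermediate_noise,
                 min_size = as.integer(min_size), max_size = max_size,
                 tol = tol, classifier = classifier, na_thres = na_thres,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full complex-detection pipeline
#'
#' Executes embed, refine, detect (supervised seed expansion), classify
#' (complex-vector filtering) and evaluate in sequence:
#' 1. node embeddings are learned on the input network;
#' 2. the network is optionally filtered/augmented by embedding similarity;
#' 3. a regression scorer is trained on positives, intermediates and random
#'    negatives, then above-average-degree seeds are greedily expanded into
#'    candidate complexes;
#' 4. a three-class classifier over pooled complex vectors keeps the
#'    candidates labelled positive;
#' 5. both the raw candidates and the filtered predictions are matched
#'    against the gold standard.
#'
#' Identical inputs, configuration and seed reproduce identical predictions.
#'
#' @param net Undirected [igraph::graph] with vertex names.
#' @param positives List of training-positive complexes.
#' @param intermediates Optional list of intermediate-class complexes; when
#'   `NULL` they are fabricated by [degrade_gold()] from the positives.
#' @param gold Gold standard for evaluation (defaults to `positives`).
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_report` with stage blocks: `embedding`
#'   (summary), `refinement` (edge counts), `detection` (scorer and
#'   candidates), `classification` (counts), `evaluation`
#'   (`slpc_only` and `final` [match_and_score()] reports), plus
#'   `candidates`, `predicted`, `config` and per-stage `seeds`.
#' @export
run_pipeline <- function(net, positives, intermediates = NULL,
                         gold = positives, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- list(embed = derive_seed(config$seed, "embed"),
                negatives = derive_seed(config$seed, "negatives"),
                intermediates = derive_seed(config$seed, "intermediates"),
                scorer = derive_seed(config$seed, "scorer"),
                classifier = derive_seed(config$seed, "classifier"))

  emb <- node2vec(net, config$node2vec, seed = seeds$embed)

  if (!is.null(config$refine)) {
    refined <- refine_network(net, emb, config$refine)
    refine_report <- attr(refined, "refine_report")
  } else {
    refined <- net
    refine_report <- list(edges_removed = 0L, edges_added = 0L,
                          edges_final = igraph::ecount(net))
  }

  if (is.null(intermediates)) {
    intermediates <- degrade_gold(positives, config$intermediate_noise,
                                  seed = seeds$intermediates,
                                  nodes = igraph::V(net)$name)
  }
  n_neg <- if (is.null(config$n_negatives)) length(positives) else
    config$n_negatives
  negatives <- sample_negative_subgraphs(
    refined, size_pool = lengths(positives), count = n_neg,
    seed = seeds$negatives, positives = positives)
  train <- labeled_complex_set(positives, intermediates, negatives)

  scorer <- train_scorer(train, refined, seed = seeds$scorer)
  candidates <- detect_candidates(refined, scorer,
                                  min_size = config$min_size,
                                  max_size = config$max_size,
                                  tol = config$tol)

  clf_config <- config$classifier
  clf_config$seed <- seeds$classifier
  tm <- build_training_matrix(train, emb,
                              strategy = clf_config$vector_strategy)
  classifier <- train_classifier(tm$rows, tm$labels, clf_config)
  predicted <- filter_candidates(candidates, emb, classifier)

  eval_slpc <- match_and_score(candidates, gold, config$na_thres)
  eval_final <- match_and_score(predicted, gold, config$na_thres)

  structure(list(
    embedding = list(n_embedded = nrow(emb), d = ncol(emb)),
    refinement = refine_report,
    detection = list(n_seeds = length(select_seeds(refined)),
                     n_candidates = length(candidates),
                     scorer_r_squared = scorer$r_squared),
    classification = list(n_predicted = length(predicted),
                          model = clf_config$model,
                          n_trees = clf_config$n_trees),
    evaluation = list(slpc_only = eval_slpc, final = eval_final),
    candidates = candidates, predicted = predicted,
    embeddings = emb, network = refined,
    config = config, seeds = seeds),
    class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Complex-detection pipeline report\n")
  cat(sprintf("  embedded %d nodes in %d dimensions\n",
              x$embedding$n_embedded, x$embedding$d))
  cat(sprintf("  refinement: %d edge(s) removed, %d added, %d final\n",
              x$refinement$edges_removed, x$refinement$edges_added,
              x$refinement$edges_final))
  cat(sprintf("  detection: %d seed(s) -> %d candidate(s) (scorer R2 %.3f)\n",
              x$detection$n_seeds, x$detection$n_candidates,
              x$detection$scorer_r_squared))
  cat(sprintf("  classification (%s): %d candidate(s) kept as positive\n",
              x$classification$model, x$classification$n_predicted))
  cat("  seed-expansion output:\n")
  print(x$evaluation$slpc_only)
  cat("  after classifier filtering:\n")
  print(x$evaluation$final)
  invisible(x)
}
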