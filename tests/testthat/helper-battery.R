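# Expensive multi-seed fixtures computed once per test run and shared between
# module property tests and the acceptance suite.

.battery_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, expr) {
  if (!exists(name, envir = .battery_cache)) {
    assign(name, force(expr), envir = .battery_cache)
  }
  get(name, envir = .battery_cache)
}

# Full pipeline on the default planted-complex fixture, 10 seeds: train on
# half the planted complexes, detect on the similarity-weighted network
# filtered at cosine 0.70, classify with the random forest, evaluate against
# the full gold standard.
pipeline_battery <- function() {
  cached_fixture("pipeline", {
    res <- lapply(1:10, function(s) {
      syn <- generate_synthetic_ppi(synth_config(seed = s))
      train_pos <- syn$gold[seq(1, length(syn$gold), by = 2)]
      mid <- syn$intermediates[seq(1, length(syn$gold), by = 2)]
      cfg <- pipeline_config(refine = refinement_config(filter_thres = 0.7),
                             seed = s)
      rep <- suppressMessages(suppressWarnings(
        run_pipeline(syn$network, train_pos, intermediates = mid,
                     gold = syn$gold, config = cfg)))
      list(f_slpc = rep$evaluation$slpc_only$f_score,
           f_final = rep$evaluation$final$f_score,
           n_candidates = rep$detection$n_candidates,
           n_predicted = rep$classification$n_predicted)
    })
    res
  })
}

# Link prediction with 10% hidden edges on the default fixture, 10 seeds:
# embedding-cosine scorer vs the random-vector baseline.
linkpred_battery <- function() {
  cached_fixture("linkpred", {
    lapply(1:10, function(s) {
      syn <- generate_synthetic_ppi(synth_config(seed = s))
      hid <- suppressWarnings(hide_edges(syn$network, 0.1, seed = s))
      emb <- suppressWarnings(node2vec(hid$network, seed = s))
      cos <- rank_evaluate(make_cosine_scorer(emb), hid$network, hid$hidden,
                           seed = s)
      rnd <- rank_evaluate(
        make_random_scorer(igraph::V(hid$network)$name, seed = s),
        hid$network, hid$hidden, seed = s)
      list(cosine = cos$mean_ranking, random = rnd$mean_ranking,
           hits = cos$hits_at)
    })
  })
}
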