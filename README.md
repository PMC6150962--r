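# ppicomplex

Protein complexes — stable assemblies of physically interacting proteins —
leave a footprint in protein–protein interaction (PPI) networks, but many
true complexes are not dense subgraphs and raw PPI data carry many
unreliable edges, so purely topological clustering struggles. `ppicomplex`
implements a supervised, embedding-guided detection pipeline for R users
working with PPI edge lists and curated complex catalogues:

1. **Node embeddings.** Every protein gets a d-dimensional vector from
   biased second-order random walks (return parameter *p*, in-out parameter
   *q*, alias sampling for O(1) steps) trained with skip-gram and negative
   sampling. Defaults: *p* = 1, *q* = 8, *r* = 10 walks of length *l* = 10
   per node, window *k* = 10, *d* = 64.
2. **Edge reliability.** Each interaction (u, v) is weighted by the cosine
   similarity of its endpoint embeddings,
   `sim(X, Y) = Σxᵢyᵢ / (√Σxᵢ² · √Σyᵢ²)`; low-similarity edges can be
   filtered out and each node's most-similar missing partner can be added
   (`filter_edges()`, `augment_edges()`, `refine_network()`).
3. **Supervised seed expansion.** A regression over eleven topological
   features of induced subgraphs, trained on positive / intermediate /
   negative complexes (targets 1 / 0.5 / 0), scores candidate subgraphs;
   nodes with above-average degree seed a greedy expansion that adds the
   best-scoring neighbour until no addition improves the score
   (`train_scorer()`, `detect_candidates()`).
4. **Complex-vector classification.** Each candidate is summarised by
   column-wise max pooling of its members' embeddings (the complex vector,
   `complex_vector()`); a 1000-tree random forest trained on the same three
   classes keeps only candidates labelled positive (`filter_candidates()`).
5. **Evaluation.** A prediction *p* matches a gold complex *q* when the
   neighborhood affinity `NA(p,q) = |p∩q|² / (|p|·|q|)` is at least 0.25;
   precision, recall and `F = 2PR/(P+R)` are reported
   (`match_and_score()`).

A link-prediction benchmark (`hide_edges()`, `rank_evaluate()`) compares
the embedding-cosine scorer against the common-neighbour baselines
AdjustCD — `2|N_u∩N_v| / (max(|N_u|,N_avg) + max(|N_v|,N_avg))` — and the
iterative PE-measure `p(k)_uv = 1 − Π_l (1 − p(k−1)_ul · p(k−1)_vl)`
(two iterations), reporting the mean ranking of hidden edges among 100
sampled non-neighbours and Hits@{1, 10, 50}. A planted-complex generator
(`generate_synthetic_ppi()`) makes the whole pipeline testable without any
external database.

## Worked example

```r
library(ppicomplex)

syn  <- generate_synthetic_ppi(synth_config(seed = 1))   # 500 proteins, 20 planted complexes
half <- seq(1, 20, by = 2)                               # train on half the catalogue
cfg  <- pipeline_config(refine = refinement_config(filter_thres = 0.7), seed = 1)
report <- run_pipeline(syn$network, syn$gold[half],
                       intermediates = syn$intermediates[half],
                       gold = syn$gold, config = cfg)
report
#> Complex-detection pipeline report
#>   embedded 500 nodes in 64 dimensions
#>   refinement: 626 edge(s) removed, 0 added, 1391 final
#>   detection: 197 seed(s) -> 52 candidate(s) (scorer R2 0.989)
#>   classification (rf): 52 candidate(s) kept as positive
#>   seed-expansion output:
#> Complex-set evaluation (NA >= 0.25 )
#>   predicted: 52 (matched 23)   gold: 20 (matched 13)
#>   precision 0.4423   recall 0.6500   F-score 0.5264
#>   after classifier filtering:
#> Complex-set evaluation (NA >= 0.25 )
#>   predicted: 52 (matched 23)   gold: 20 (matched 13)
#>   precision 0.4423   recall 0.6500   F-score 0.5264
```

Reading the report: 626 of 2,017 edges fell below the similarity threshold
0.7 and were removed as unreliable; 197 above-average-degree proteins
seeded greedy expansion, which produced 52 distinct candidates; the forest
found all of them complex-like; 13 of the 20 planted complexes were
recovered at neighborhood affinity ≥ 0.25, giving F = 0.53 against a gold
standard of which the pipeline saw only half during training.

The same pipeline is scriptable from a shell via `exec/ppicomplex`
(subcommands `synth`, `embed`, `refine`, `detect`, `classify`, `evaluate`,
`linkpred`, `run`).

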