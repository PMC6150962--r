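#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Eleven induced-subgraph features used by the supervised complex scorer.
// The graph arrives in CSR form (0-based): adj_ptr has length n+1 and
// adj_idx[adj_ptr[v] .. adj_ptr[v+1]-1] are the neighbours of v; ew carries
// per-incidence edge weights aligned with adj_idx (length 0 => unweighted).
// members is a 0-based vector of distinct node indices.

// [[Rcpp::export(name = ".topo_features_csr")]]
NumericVector topo_features_csr(IntegerVector adj_ptr, IntegerVector adj_idx,
                                NumericVector ew, IntegerVector members,
                                int n_nodes) {
  const int m = members.size();
  std::vector<int> memb_pos(n_nodes, -1); // node -> position within complex
  for (int i = 0; i < m; ++i) memb_pos[members[i]] = i;

  std::vector<int> ideg(m, 0);
  double int_edges2 = 0.0, ext_edges = 0.0, wsum = 0.0;
  for (int i = 0; i < m; ++i) {
    int v = members[i];
    for (int e = adj_ptr[v]; e < adj_ptr[v + 1]; ++e) {
      int u = adj_idx[e];
      if (memb_pos[u] >= 0) {
        ++ideg[i];
        int_edges2 += 1.0;
        wsum += ew.size() ? ew[e] : 1.0;
      } else {
        ext_edges += 1.0;
      }
    }
  }
  const double n_int = int_edges2 / 2.0; // each internal edge seen twice

  double mean_ideg = 0.0, max_ideg = 0.0;
  for (int i = 0; i < m; ++i) {
    mean_ideg += ideg[i];
    if (ideg[i] > max_ideg) max_ideg = ideg[i];
  }
  mean_ideg /= m;
  double var_ideg = 0.0;
  for (int i = 0; i < m; ++i) {
    double d = ideg[i] - mean_ideg;
    var_ideg += d * d;
  }
  var_ideg /= m; // population variance

  const double density = (m > 1) ? n_int / (m * (m - 1.0) / 2.0) : 0.0;

  // mean local clustering coefficient within the induced subgraph
  double clust_sum = 0.0;
  std::vector<char> is_int_nb(n_nodes, 0);
  for (int i = 0; i < m; ++i) {
    int v = members[i];
    if (ideg[i] < 2) continue;
    std::vector<int> nb;
    nb.reserve(ideg[i]);
    for (int e = adj_ptr[v]; e < adj_ptr[v + 1]; ++e)
      if (memb_pos[adj_idx[e]] >= 0) { nb.push_back(adj_idx[e]); is_int_nb[adj_idx[e]] = 1; }
    double links = 0.0;
    for (int u : nb)
      for (int e = adj_ptr[u]; e < adj_ptr[u + 1]; ++e)
        if (memb_pos[adj_idx[e]] >= 0 && is_int_nb[adj_idx[e]]) links += 1.0;
    for (int u : nb) is_int_nb[u] = 0;
    links /= 2.0;
    clust_sum += links / (ideg[i] * (ideg[i] - 1.0) / 2.0);
  }
  const double mean_clust = clust_sum / m;

  // largest connected component of the induced subgraph (BFS)
  std::vector<int> comp(m, -1), queue_;
  int best_cc = 0;
  for (int i = 0; i < m; ++i) {
    if (comp[i] >= 0) continue;
    int sz = 0;
    queue_.clear();
    queue_.push_back(i);
    comp[i] = i;
    while (!queue_.empty()) {
      int cur = queue_.back();
      queue_.pop_back();
      ++sz;
      int v = members[cur];
      for (int e = adj_ptr[v]; e < adj_ptr[v + 1]; ++e) {
        int j = memb_pos[adj_idx[e]];
        if (j >= 0 && comp[j] < 0) { comp[j] = i; queue_.push_back(j); }
      }
    }
    if (sz > best_cc) best_cc = sz;
  }

  const double mean_ext = ext_edges / m;
  const double tot_bnd = n_int + ext_edges;
  const double int_ratio = tot_bnd > 0 ? n_int / tot_bnd : 0.0;
  const double mean_w = n_int > 0 ? wsum / int_edges2 : 0.0;

  NumericVector out = NumericVector::create(
      _["n_nodes"] = static_cast<double>(m),
      _["n_edges"] = n_int,
      _["density"] = density,
      _["mean_internal_degree"] = mean_ideg,
      _["var_internal_degree"] = var_ideg,
      _["max_internal_degree"] = max_ideg,
      _["mean_clustering"] = mean_clust,
      _["lcc_fraction"] = static_cast<double>(best_cc) / m,
      _["mean_external_degree"] = mean_ext,
      _["internal_ratio"] = int_ratio,
      _["mean_edge_weight"] = mean_w);
  return out;
}
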