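#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// All-pairs shortest-path distances by repeated Dijkstra on the directed
// graph with edge costs given in `cost` (0 entries = no edge). Used for the
// gamma term of the path attenuation; the test-suite oracle recomputes the
// same distances with an independent Floyd-Warshall.

// [[Rcpp::export]]
NumericMatrix dijkstra_all(NumericMatrix cost) {
  const int n = cost.nrow();
  NumericMatrix D(n, n);
  std::fill(D.begin(), D.end(), R_PosInf);

  // adjacency lists
  std::vector<std::vector<std::pair<int, double> > > adj(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && cost(i, j) > 0) adj[i].push_back(std::make_pair(j, cost(i, j)));

  typedef std::pair<double, int> Item; // (distance, node)
  for (int s = 0; s < n; ++s) {
    std::priority_queue<Item, std::vector<Item>, std::greater<Item> > pq;
    D(s, s) = 0.0;
    pq.push(std::make_pair(0.0, s));
    while (!pq.empty()) {
      Item top = pq.top(); pq.pop();
      double du = top.first; int u = top.second;
      if (du > D(s, u)) continue;
      for (size_t z = 0; z < adj[u].size(); ++z) {
        int v = adj[u][z].first;
        double nd = du + adj[u][z].second;
        if (nd < D(s, v)) { D(s, v) = nd; pq.push(std::make_pair(nd, v)); }
      }
    }
  }
  return D;
}

// Random walks with a return policy, driven by R's RNG for reproducibility.
// At each step: with probability return_prob the walker steps back to its
// previous position; otherwise it moves to an out-neighbour with probability
// proportional to the outgoing weight (inverse-CDF draw). Sink nodes halt
// the walk.
//
// Returns a list of 1-based integer walks, ordered walk-repeat-major then
// start-node (rep 1 nodes 1..n, rep 2 nodes 1..n, ...).

// [[Rcpp::export]]
List walk_core(NumericMatrix W, int walks_per_node, int walk_length,
               double return_prob) {
  RNGScope scope;
  const int n = W.nrow();

  std::vector<std::vector<int> > nbr(n);
  std::vector<std::vector<double> > cum(n);
  for (int i = 0; i < n; ++i) {
    double tot = 0.0;
    for (int j = 0; j < n; ++j)
      if (W(i, j) > 0) { nbr[i].push_back(j); tot += W(i, j); }
    double acc = 0.0;
    for (size_t z = 0; z < nbr[i].size(); ++z) {
      acc += W(i, nbr[i][z]) / tot;
      cum[i].push_back(acc);
    }
    if (!cum[i].empty()) cum[i].back() = 1.0; // guard rounding
  }

  List walks(n * walks_per_node);
  std::vector<int> buf(walk_length);
  int z = 0;
  for (int rep = 0; rep < walks_per_node; ++rep) {
    for (int start = 0; start < n; ++start) {
      buf[0] = start;
      int prev = -1, len = 1;
      while (len < walk_length) {
        int cur = buf[len - 1];
        int nxt;
        if (prev >= 0 && unif_rand() < return_prob) {
          nxt = prev;
        } else {
          if (nbr[cur].empty()) break;
          double r = unif_rand();
          size_t lo = std::lower_bound(cum[cur].begin(), cum[cur].end(), r) -
                      cum[cur].begin();
          if (lo >= nbr[cur].size()) lo = nbr[cur].size() - 1;
          nxt = nbr[cur][lo];
        }
        buf[len++] = nxt;
        prev = cur;
      }
      IntegerVector w(len);
      for (int t = 0; t < len; ++t) w[t] = buf[t] + 1;
      walks[z++] = w;
    }
  }
  return walks;
}
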