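#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Clique counting over vertex bitmasks (n <= 30). Cliques are enumerated in
// increasing vertex order: at each node of the recursion the candidate set
// holds only vertices greater than every clique member and adjacent to all
// of them, so each clique is visited exactly once. A branch is abandoned as
// soon as the candidate set empties (the pruning that keeps the full
// 24-compound, sizes 2..10 enumeration cheap).

static void clique_rec(const std::vector<uint32_t>& adj, uint32_t cand,
                       int size, int kmax, std::vector<double>& counts) {
    uint32_t c = cand;
    while (c) {
        int v = __builtin_ctz(c);
        c &= c - 1;
        counts[size + 1] += 1.0;
        if (size + 1 < kmax) {
            uint32_t nc = c & adj[v];
            if (nc) clique_rec(adj, nc, size + 1, kmax, counts);
        }
    }
}

// [[Rcpp::export]]
NumericVector clique_counts_cpp(IntegerVector adj_masks, int kmax) {
    int n = adj_masks.size();
    if (n > 30) stop("clique_counts_cpp: at most 30 vertices supported");
    if (kmax < 1) stop("clique_counts_cpp: kmax must be >= 1");
    std::vector<uint32_t> adj(n);
    for (int i = 0; i < n; ++i) adj[i] = (uint32_t)adj_masks[i];
    std::vector<double> counts(kmax + 1, 0.0);
    uint32_t all = (n == 32) ? ~0u : ((1u << n) - 1u);
    clique_rec(adj, all, 0, kmax, counts);
    NumericVector out(kmax);
    for (int k = 1; k <= kmax; ++k) out[k - 1] = counts[k];
    return out;
}
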