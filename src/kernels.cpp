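#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Likelihood-ratio (G2) or Pearson (X2) statistic for x (x) y | z, where the
// conditioning configuration of each observation has been collapsed into a
// single 1-based stratum index.  Zero observed cells contribute nothing to G2;
// strata where x or y is constant contribute nothing to either statistic
// (their expected counts equal the observed counts on the non-empty margin).
// [[Rcpp::export]]
double ct_stat_cpp(IntegerVector x, IntegerVector y, IntegerVector zidx,
                   int rx, int ry, int nz, bool pearson) {
    const int n = x.size();
    std::vector<double> cell((size_t)rx * ry * nz, 0.0);
    std::vector<double> mx((size_t)rx * nz, 0.0), my((size_t)ry * nz, 0.0);
    std::vector<double> mz((size_t)nz, 0.0);
    for (int i = 0; i < n; ++i) {
        int xi = x[i] - 1, yi = y[i] - 1, zi = zidx[i] - 1;
        cell[(size_t)zi * rx * ry + (size_t)yi * rx + xi] += 1.0;
        mx[(size_t)zi * rx + xi] += 1.0;
        my[(size_t)zi * ry + yi] += 1.0;
        mz[zi] += 1.0;
    }
    double stat = 0.0;
    for (int zi = 0; zi < nz; ++zi) {
        if (mz[zi] <= 0) continue;
        for (int yi = 0; yi < ry; ++yi) {
            double cy = my[(size_t)zi * ry + yi];
            if (cy <= 0) continue;
            for (int xi = 0; xi < rx; ++xi) {
                double cx = mx[(size_t)zi * rx + xi];
                if (cx <= 0) continue;
                double o = cell[(size_t)zi * rx * ry + (size_t)yi * rx + xi];
                double e = cx * cy / mz[zi];
                if (pearson) {
                    stat += (o - e) * (o - e) / e;
                } else if (o > 0) {
                    stat += 2.0 * o * std::log(o / e);
                }
            }
        }
    }
    return stat;
}

// d-separation of x and y given z, by ancestral moralization: restrict to the
// ancestral closure of {x, y} union z, moralize (marry co-parents, drop
// directions), delete z, and test undirected connectivity of x and y.
// `parents` is a list of 0-based integer vectors; x, y and z are 0-based.
// [[Rcpp::export]]
bool dsep_cpp(List parents, int x, int y, IntegerVector z) {
    const int n = parents.size();
    std::vector<std::vector<int> > pa(n);
    for (int i = 0; i < n; ++i) pa[i] = as<std::vector<int> >(parents[i]);

    // ancestral closure of {x, y} union z
    std::vector<char> anc(n, 0);
    std::vector<int> stack;
    stack.push_back(x); stack.push_back(y);
    for (int i = 0; i < z.size(); ++i) stack.push_back(z[i]);
    while (!stack.empty()) {
        int v = stack.back(); stack.pop_back();
        if (anc[v]) continue;
        anc[v] = 1;
        for (size_t k = 0; k < pa[v].size(); ++k) stack.push_back(pa[v][k]);
    }

    // moral graph on the ancestral set
    std::vector<std::vector<int> > adj(n);
    for (int v = 0; v < n; ++v) {
        if (!anc[v]) continue;
        const std::vector<int>& p = pa[v];
        for (size_t a = 0; a < p.size(); ++a) {
            adj[v].push_back(p[a]);
            adj[p[a]].push_back(v);
            for (size_t b = a + 1; b < p.size(); ++b) {
                adj[p[a]].push_back(p[b]);
                adj[p[b]].push_back(p[a]);
            }
        }
    }

    std::vector<char> blocked(n, 0);
    for (int i = 0; i < z.size(); ++i) blocked[z[i]] = 1;

    std::vector<char> seen(n, 0);
    std::queue<int> q;
    q.push(x); seen[x] = 1;
    while (!q.empty()) {
        int v = q.front(); q.pop();
        for (size_t k = 0; k < adj[v].size(); ++k) {
            int w = adj[v][k];
            if (!anc[w] || seen[w] || blocked[w]) continue;
            if (w == y) return false;
            seen[w] = 1;
            q.push(w);
        }
    }
    return true;
}
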