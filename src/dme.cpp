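#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Fibers are packed as a flat double array, fiber-major then point-major:
// coordinate c of point p of fiber f sits at ((f * np) + p) * 3 + c.
// All kernels assume every fiber has the same point count np.

static inline double dme_flat(const double* a, const double* b, int np) {
    double fwd = 0.0, rev = 0.0;
    for (int p = 0; p < np; ++p) {
        const double* ap = a + 3 * p;
        const double* bf = b + 3 * p;
        const double* br = b + 3 * (np - 1 - p);
        double dx = ap[0] - bf[0], dy = ap[1] - bf[1], dz = ap[2] - bf[2];
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 > fwd) fwd = d2;
        dx = ap[0] - br[0]; dy = ap[1] - br[1]; dz = ap[2] - br[2];
        d2 = dx * dx + dy * dy + dz * dz;
        if (d2 > rev) rev = d2;
    }
    return std::sqrt(fwd < rev ? fwd : rev);
}

// Symmetrized maximum corresponding-point distance between two fibers.
// [[Rcpp::export]]
double cpp_dme(NumericMatrix a, NumericMatrix b) {
    int np = a.nrow();
    if (b.nrow() != np) stop("fibers must share the same point count");
    std::vector<double> fa(3 * np), fb(3 * np);
    for (int p = 0; p < np; ++p)
        for (int c = 0; c < 3; ++c) {
            fa[3 * p + c] = a(p, c);
            fb[3 * p + c] = b(p, c);
        }
    return dme_flat(fa.data(), fb.data(), np);
}

// All pairs (i < j) with d_ME <= dmax, in lexicographic (i, j) order.
// [[Rcpp::export]]
List cpp_sparse_pairwise(NumericVector coords, int nfib, int np, double dmax) {
    const double* x = coords.begin();
    std::vector<int> vi, vj;
    std::vector<double> vd;
    for (int i = 0; i < nfib; ++i) {
        const double* fi = x + (size_t)i * np * 3;
        for (int j = i + 1; j < nfib; ++j) {
            double d = dme_flat(fi, x + (size_t)j * np * 3, np);
            if (d <= dmax) {
                vi.push_back(i + 1);
                vj.push_back(j + 1);
                vd.push_back(d);
            }
        }
    }
    return List::create(_["i"] = wrap(vi), _["j"] = wrap(vj), _["d"] = wrap(vd));
}

// Full cross d_ME matrix (rows: fibers of A, cols: fibers of B).
// [[Rcpp::export]]
NumericMatrix cpp_cross_dme(NumericVector ca, int na, NumericVector cb, int nb,
                            int np) {
    NumericMatrix out(na, nb);
    const double* xa = ca.begin();
    const double* xb = cb.begin();
    for (int i = 0; i < na; ++i)
        for (int j = 0; j < nb; ++j)
            out(i, j) = dme_flat(xa + (size_t)i * np * 3,
                                 xb + (size_t)j * np * 3, np);
    return out;
}

// Minimum d_ME from each fiber of A to the set B.
// [[Rcpp::export]]
NumericVector cpp_cross_min(NumericVector ca, int na, NumericVector cb, int nb,
                            int np) {
    NumericVector out(na);
    const double* xa = ca.begin();
    const double* xb = cb.begin();
    for (int i = 0; i < na; ++i) {
        double best = R_PosInf;
        const double* fi = xa + (size_t)i * np * 3;
        for (int j = 0; j < nb; ++j) {
            double d = dme_flat(fi, xb + (size_t)j * np * 3, np);
            if (d < best) best = d;
        }
        out[i] = best;
    }
    return out;
}

// Maximum pairwise d_ME within a fiber set, with early exit once the
// running maximum exceeds stop_above (the caller only needs to compare
// the result against that bound).
// [[Rcpp::export]]
double cpp_max_pairwise(NumericVector coords, int nfib, int np,
                        double stop_above) {
    const double* x = coords.begin();
    double best = 0.0;
    for (int i = 0; i < nfib; ++i) {
        const double* fi = x + (size_t)i * np * 3;
        for (int j = i + 1; j < nfib; ++j) {
            double d = dme_flat(fi, x + (size_t)j * np * 3, np);
            if (d > best) {
                best = d;
                if (best > stop_above) return best;
            }
        }
    }
    return best;
}

// Average-link agglomerative clustering on a sparse affinity graph.
// ei/ej are 1-based element indices, ea the affinities in (0, 1].
// Cluster-pair affinities are the mean of the original edge affinities
// between the two clusters, weighted by the number of stored edges
// (absent edges contribute nothing); on a complete graph this is exactly
// size-weighted UPGMA. At each step the pair with the highest current
// affinity merges; ties go to the pair whose clusters contain the
// smallest original element indices (lexicographic).
// Returns a merge table: node id (leaves are 1..n, internal nodes n+k),
// left child, right child, affinity at merge. One root remains per
// connected component of the graph.
// [[Rcpp::export]]
NumericMatrix cpp_average_link(int n, IntegerVector ei, IntegerVector ej,
                               NumericVector ea) {
    if (n > 8000) stop("dense working matrices would exceed memory for n > 8000");
    size_t nn = (size_t)n * n;
    std::vector<double> A(nn, -1.0);  // -1 marks an absent edge
    std::vector<double> W(nn, 0.0);
    for (int e = 0; e < ei.size(); ++e) {
        int i = ei[e] - 1, j = ej[e] - 1;
        if (i == j) stop("self edge");
        if (i > j) std::swap(i, j);
        A[(size_t)i * n + j] = ea[e];
        A[(size_t)j * n + i] = ea[e];
        W[(size_t)i * n + j] = 1.0;
        W[(size_t)j * n + i] = 1.0;
    }
    std::vector<bool> active(n, true);
    std::vector<int> cid(n), csize(n, 1);
    for (int i = 0; i < n; ++i) cid[i] = i + 1;
    // rowmax[i]: best affinity over active j > i; -1 if none
    std::vector<double> rowmax(n, -1.0);
    std::vector<int> rowarg(n, -1);
    auto recompute_row = [&](int i) {
        rowmax[i] = -1.0; rowarg[i] = -1;
        for (int j = i + 1; j < n; ++j) {
            if (!active[j]) continue;
            double a = A[(size_t)i * n + j];
            if (a > rowmax[i]) { rowmax[i] = a; rowarg[i] = j; }
        }
    };
    for (int i = 0; i < n; ++i) recompute_row(i);
    std::vector<double> merges;
    int nmerge = 0;
    for (int it = 0; it < n - 1; ++it) {
        // global best: scan rows ascending so ties pick the lowest (i, j)
        double best = -1.0; int u = -1;
        for (int i = 0; i < n; ++i) {
            if (active[i] && rowmax[i] > best) { best = rowmax[i]; u = i; }
        }
        if (u < 0 || best < 0.0) break;  // no edges left across clusters
        int v = rowarg[u];
        // merge slot v into slot u (u < v); the slot index is the smallest
        // original element index of the merged cluster
        double wa_uv = W[(size_t)u * n + v];
        for (int w = 0; w < n; ++w) {
            if (!active[w] || w == u || w == v) continue;
            double wu = W[(size_t)u * n + w], wv = W[(size_t)v * n + w];
            double ws = wu + wv;
            if (ws > 0.0) {
                double au = A[(size_t)u * n + w], av = A[(size_t)v * n + w];
                double a = ((wu > 0 ? wu * au : 0.0) + (wv > 0 ? wv * av : 0.0)) / ws;
                A[(size_t)u * n + w] = a; A[(size_t)w * n + u] = a;
                W[(size_t)u * n + w] = ws; W[(size_t)w * n + u] = ws;
            }
        }
        active[v] = false;
        ++nmerge;
        merges.push_back(n + nmerge);       // node id
        merges.push_back(cid[u]);           // left child (lower slot)
        merges.push_back(cid[v]);           // right child
        merges.push_back(best);             // affinity at merge
        cid[u] = n + nmerge;
        csize[u] += csize[v];
        W[(size_t)u * n + v] = 0.0; W[(size_t)v * n + u] = 0.0;
        A[(size_t)u * n + v] = -1.0; A[(size_t)v * n + u] = -1.0;
        recompute_row(u);
        for (int r = 0; r < u; ++r) {
            if (!active[r]) continue;
            if (rowarg[r] == u || rowarg[r] == v) recompute_row(r);
            else {
                double a = A[(size_t)r * n + u];
                if (a > rowmax[r]) { rowmax[r] = a; rowarg[r] = u; }
            }
        }
        for (int r = u + 1; r < n; ++r) {
            if (!active[r] || r == v) continue;
            if (rowarg[r] == v) recompute_row(r);
        }
    }
    int k = nmerge;
    NumericMatrix out(k, 4);
    for (int m = 0; m < k; ++m)
        for (int c = 0; c < 4; ++c) out(m, c) = merges[4 * m + c];
    colnames(out) = CharacterVector::create("node", "left", "right", "affinity");
    return out;
}
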