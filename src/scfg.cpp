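#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// CYK-style alignment of a nested-pair profile (compiled guide tree) to one
// target strand. Node types: 0 MATL, 1 MATR, 2 MATP, 3 BIF, 4 END, 5 ROOT.
// S[v][x, y] = best score of aligning the subtree of v to target[x, y)
// (0-based half-open). Consensus columns may be deleted (gap penalty, twice
// for a pair); extra target bases inside the hit are insertions. In model-
// local mode any subtree may be aligned on its own: all columns outside it
// are truncated free of charge.
// [[Rcpp::export]]
List cpp_cm_align(IntegerVector ntype, IntegerVector child1, IntegerVector child2,
                  NumericMatrix singleE, NumericMatrix pairE,
                  double gapPenalty, double insertPenalty,
                  IntegerVector ncols, IntegerVector postorder,
                  std::string target, bool localModel) {
    const double NEG = -std::numeric_limits<double>::infinity();
    int nNodes = ntype.size();
    int T = (int)target.size();
    int W = T + 1;
    std::vector<int> tb(T);
    for (int i = 0; i < T; ++i) {
        switch (target[i]) {
        case 'A': tb[i] = 0; break; case 'C': tb[i] = 1; break;
        case 'G': tb[i] = 2; break; case 'T': tb[i] = 3; break;
        default: tb[i] = 4; break;
        }
    }
    std::vector<std::vector<double> > S(nNodes);
    std::vector<bool> done(nNodes, false);
    double bestScore = NEG; int bestX = 0, bestY = 0, bestNode = -1;
    int root = postorder[nNodes - 1] - 1;

    for (int pi = 0; pi < nNodes; ++pi) {
        int v = postorder[pi] - 1;
        int ty = ntype[v];
        int c1 = child1[v] - 1, c2 = child2[v] - 1;
        S[v].assign((size_t)W * W, NEG);
        std::vector<double>& Sv = S[v];
        const std::vector<double>* Sc1 = (c1 >= 0) ? &S[c1] : 0;
        const std::vector<double>* Sc2 = (c2 >= 0) ? &S[c2] : 0;
        for (int len = 0; len <= T; ++len) {
            for (int x = 0; x + len <= T; ++x) {
                int y = x + len;
                size_t id = (size_t)x * W + y;
                double best = NEG;
                if (ty == 4) {                       // END
                    best = insertPenalty * len;
                } else if (ty == 5) {                // ROOT: transparent
                    best = (*Sc1)[id];
                } else if (ty == 0) {                // MATL
                    double o = gapPenalty + (*Sc1)[id];
                    if (o > best) best = o;
                    if (len >= 1) {
                        o = singleE(tb[x], v) + (*Sc1)[(size_t)(x + 1) * W + y];
                        if (o > best) best = o;
                        o = insertPenalty + Sv[(size_t)(x + 1) * W + y];
                        if (o > best) best = o;
                    }
                } else if (ty == 1) {                // MATR
                    double o = gapPenalty + (*Sc1)[id];
                    if (o > best) best = o;
                    if (len >= 1) {
                        o = singleE(tb[y - 1], v) + (*Sc1)[(size_t)x * W + (y - 1)];
                        if (o > best) best = o;
                        o = insertPenalty + Sv[(size_t)x * W + (y - 1)];
                        if (o > best) best = o;
                    }
                } else if (ty == 2) {                // MATP
                    double o = 2.0 * gapPenalty + (*Sc1)[id];
                    if (o > best) best = o;
                    if (len >= 2) {
                        o = pairE(tb[x] * 5 + tb[y - 1], v)
                            + (*Sc1)[(size_t)(x + 1) * W + (y - 1)];
                        if (o > best) best = o;
                    }
                    if (len >= 1) {
                        o = insertPenalty + Sv[(size_t)(x + 1) * W + y];
                        if (o > best) best = o;
                        o = insertPenalty + Sv[(size_t)x * W + (y - 1)];
                        if (o > best) best = o;
                    }
                } else {                             // BIF
                    for (int m = x; m <= y; ++m) {
                        double o = (*Sc1)[(size_t)x * W + m] + (*Sc2)[(size_t)m * W + y];
                        if (o > best) best = o;
                    }
                }
                Sv[id] = best;
            }
        }
        done[v] = true;
        // candidate answers from this node
        bool eligible = localModel ? (ncols[v] > 0) : (v == root);
        if (eligible) {
            for (int x = 0; x <= T; ++x) {
                int ymin = localModel ? x + 1 : x;  // local hits span >=1 base
                for (int y = ymin; y <= T; ++y) {
                    double val = Sv[(size_t)x * W + y];
                    if (val > bestScore) { bestScore = val; bestX = x; bestY = y; bestNode = v; }
                }
            }
        }
        // free children: each node has exactly one parent
        if (c1 >= 0) { std::vector<double>().swap(S[c1]); }
        if (c2 >= 0) { std::vector<double>().swap(S[c2]); }
    }
    return List::create(_["score"] = bestScore, _["x"] = bestX, _["y"] = bestY,
                        _["node"] = bestNode + 1);
}

// Position-specific profile Smith-Waterman (structure ignored): a cheap
// O(L * T) upper-stage filter before the cubic SCFG alignment. Linear gap
// penalty; profile rows A,C,G,T,N.
// [[Rcpp::export]]
double cpp_profile_sw(NumericMatrix prof, std::string target, double gapPen) {
    int L = prof.ncol();
    int T = (int)target.size();
    std::vector<double> prev(L + 1, 0.0), cur(L + 1, 0.0);
    double best = 0.0;
    for (int j = 1; j <= T; ++j) {
        int b;
        switch (target[j - 1]) {
        case 'A': b = 0; break; case 'C': b = 1; break;
        case 'G': b = 2; break; case 'T': b = 3; break;
        default: b = 4; break;
        }
        cur[0] = 0.0;
        for (int i = 1; i <= L; ++i) {
            double v = prev[i - 1] + prof(b, i - 1);
            double d = cur[i - 1] + gapPen;   // delete model column
            double in = prev[i] + gapPen;     // insert target base
            if (d > v) v = d;
            if (in > v) v = in;
            if (v < 0.0) v = 0.0;
            cur[i] = v;
            if (v > best) best = v;
        }
        std::swap(prev, cur);
    }
    return best;
}
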