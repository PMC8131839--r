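#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Smith-Waterman with affine gaps under the read-mapper convention:
// a gap of length g costs -(gap_open + g * gap_extend), i.e. the first gap
// base pays both terms. Returns the optimal score with 0-based half-open
// query/target spans. 'N' matches nothing (scored as mismatch).
// [[Rcpp::export]]
List cpp_local_align(std::string q, std::string t, double match,
                     double mismatch, double gap_open, double gap_extend) {
    int n = (int)q.size(), m = (int)t.size();
    const double NEG = -std::numeric_limits<double>::infinity();
    // rolling rows; origins track the (qstart, tstart) of each running alignment
    std::vector<double> Hprev(m + 1, 0.0), Hcur(m + 1, 0.0);
    std::vector<double> Eprev(m + 1, NEG), Ecur(m + 1, NEG);  // gap in query
    std::vector<double> Fprev(m + 1, NEG), Fcur(m + 1, NEG);  // gap in target
    std::vector<int> HoqP(m + 1, 0), HotP(m + 1, 0), HoqC(m + 1, 0), HotC(m + 1, 0);
    std::vector<int> EoqP(m + 1, 0), EotP(m + 1, 0), EoqC(m + 1, 0), EotC(m + 1, 0);
    std::vector<int> FoqP(m + 1, 0), FotP(m + 1, 0), FoqC(m + 1, 0), FotC(m + 1, 0);
    for (int j = 0; j <= m; ++j) HotP[j] = j;  // row 0: fresh starts at (0, j)

    double best = 0.0;
    int bqe = 0, bte = 0, bqs = 0, bts = 0;
    double gfirst = gap_open + gap_extend;  // both negative magnitudes passed as negatives

    for (int i = 1; i <= n; ++i) {
        Hcur[0] = 0.0; Ecur[0] = NEG; Fcur[0] = NEG;
        HoqC[0] = i; HotC[0] = 0;
        for (int j = 1; j <= m; ++j) {
            // E: alignment ends consuming t[j-1] with a gap in the query
            double e_open = Hcur[j - 1] + gfirst;
            double e_ext  = Ecur[j - 1] + gap_extend;
            if (e_open >= e_ext) { Ecur[j] = e_open; EoqC[j] = HoqC[j - 1]; EotC[j] = HotC[j - 1]; }
            else                 { Ecur[j] = e_ext;  EoqC[j] = EoqC[j - 1]; EotC[j] = EotC[j - 1]; }
            // F: ends consuming q[i-1] with a gap in the target
            double f_open = Hprev[j] + gfirst;
            double f_ext  = Fprev[j] + gap_extend;
            if (f_open >= f_ext) { Fcur[j] = f_open; FoqC[j] = HoqP[j]; FotC[j] = HotP[j]; }
            else                 { Fcur[j] = f_ext;  FoqC[j] = FoqP[j]; FotC[j] = FotP[j]; }
            // H
            char cq = q[i - 1], ct = t[j - 1];
            double sub = (cq == ct && cq != 'N') ? match : mismatch;
            double diag = Hprev[j - 1] + sub;
            int oq, ot;
            double h = diag; oq = HoqP[j - 1]; ot = HotP[j - 1];
            if (Ecur[j] > h) { h = Ecur[j]; oq = EoqC[j]; ot = EotC[j]; }
            if (Fcur[j] > h) { h = Fcur[j]; oq = FoqC[j]; ot = FotC[j]; }
            if (h < 0.0) { h = 0.0; oq = i; ot = j; }
            Hcur[j] = h; HoqC[j] = oq; HotC[j] = ot;
            if (h > best) { best = h; bqe = i; bte = j; bqs = oq; bts = ot; }
        }
        std::swap(Hprev, Hcur); std::swap(Eprev, Ecur); std::swap(Fprev, Fcur);
        std::swap(HoqP, HoqC); std::swap(HotP, HotC);
        std::swap(EoqP, EoqC); std::swap(EotP, EotC);
        std::swap(FoqP, FoqC); std::swap(FotP, FotC);
    }
    return List::create(
        _["score"] = best,
        _["query_start"] = bqs, _["query_end"] = bqe,
        _["target_start"] = bts, _["target_end"] = bte);
}
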