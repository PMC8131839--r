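#include <Rcpp.h>
#include <unordered_map>
#include <string>
using namespace Rcpp;

static inline int base_code(char c) {
    switch (c) { case 'A': return 0; case 'C': return 1;
                 case 'G': return 2; case 'T': return 3; default: return -1; }
}

static std::string decode_kmer(uint64_t x, int k) {
    static const char b[] = "ACGT";
    std::string s(k, 'A');
    for (int i = k - 1; i >= 0; --i) { s[i] = b[x & 3ULL]; x >>= 2; }
    return s;
}

static inline uint64_t revcomp_code(uint64_t x, int k) {
    uint64_t r = 0;
    for (int i = 0; i < k; ++i) { r = (r << 2) | (3ULL - (x & 3ULL)); x >>= 2; }
    return r;
}

// k-mer multiplicities over a read set; k-mers containing N are skipped.
// With canonical=TRUE a k-mer and its reverse complement are pooled and the
// lexicographically smaller encoding is reported.
// [[Rcpp::export]]
DataFrame cpp_count_kmers(CharacterVector seqs, int k, bool canonical) {
    if (k < 2 || k > 31) stop("k must be in [2, 31]");
    std::unordered_map<uint64_t, int> counts;
    uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    for (int si = 0; si < seqs.size(); ++si) {
        std::string s = as<std::string>(seqs[si]);
        int n = (int)s.size();
        if (n < k) continue;
        uint64_t cur = 0; int valid = 0;
        for (int i = 0; i < n; ++i) {
            int c = base_code(s[i]);
            if (c < 0) { valid = 0; cur = 0; continue; }
            cur = ((cur << 2) | (uint64_t)c) & mask;
            if (++valid >= k) {
                uint64_t key = cur;
                if (canonical) { uint64_t rc = revcomp_code(cur, k); if (rc < key) key = rc; }
                counts[key]++;
            }
        }
    }
    int n = (int)counts.size();
    CharacterVector kmer(n); IntegerVector count(n);
    int i = 0;
    for (auto& kv : counts) { kmer[i] = decode_kmer(kv.first, k); count[i] = kv.second; ++i; }
    return DataFrame::create(_["kmer"] = kmer, _["count"] = count,
                             _["stringsAsFactors"] = false);
}
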