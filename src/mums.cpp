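#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Suffix array by prefix doubling, O(n log^2 n); robust on repetitive input.
static std::vector<int> build_suffix_array(const std::string& s) {
    int n = (int) s.size();
    std::vector<int> sa(n), rnk(n), tmp(n);
    for (int i = 0; i < n; ++i) { sa[i] = i; rnk[i] = (unsigned char) s[i]; }
    for (int k = 1;; k <<= 1) {
        auto cmp = [&](int a, int b) {
            if (rnk[a] != rnk[b]) return rnk[a] < rnk[b];
            int ra = a + k < n ? rnk[a + k] : -1;
            int rb = b + k < n ? rnk[b + k] : -1;
            return ra < rb;
        };
        std::sort(sa.begin(), sa.end(), cmp);
        tmp[sa[0]] = 0;
        for (int i = 1; i < n; ++i)
            tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
        rnk = tmp;
        if (rnk[sa[n - 1]] == n - 1) break;
        if (k >= n) break;
    }
    return sa;
}

// Kasai LCP: lcp[i] = longest common prefix of suffixes sa[i-1] and sa[i].
static std::vector<int> build_lcp(const std::string& s, const std::vector<int>& sa) {
    int n = (int) s.size();
    std::vector<int> rnk(n), lcp(n, 0);
    for (int i = 0; i < n; ++i) rnk[sa[i]] = i;
    int h = 0;
    for (int i = 0; i < n; ++i) {
        if (rnk[i] > 0) {
            int j = sa[rnk[i] - 1];
            while (i + h < n && j + h < n && s[i + h] == s[j + h]) ++h;
            lcp[rnk[i]] = h;
            if (h > 0) --h;
        } else h = 0;
    }
    return lcp;
}

//' @noRd
// [[Rcpp::export(name = ".mums_one_strand")]]
DataFrame mums_one_strand(std::string ref, std::string query, int min_len) {
    // Concatenate with sentinels that cannot occur in DNA so no match spans them.
    int nr = (int) ref.size();
    std::string s = ref + '\x01' + query + '\x02';
    int n = (int) s.size();
    std::vector<int> sa = build_suffix_array(s);
    std::vector<int> lcp = build_lcp(s, sa);

    std::vector<int> rs, qs, len;
    for (int i = 1; i < n; ++i) {
        int L = lcp[i];
        if (L < min_len) continue;
        int a = sa[i - 1], b = sa[i];
        bool a_ref = a < nr, b_ref = b < nr;
        if (a_ref == b_ref) continue;                   // need one suffix per sequence
        // unique: no other suffix shares an L-prefix with this pair
        if (lcp[i - 1] >= L) continue;
        if (i + 1 < n && lcp[i + 1] >= L) continue;
        // left-maximal: preceding characters differ (or hit a boundary)
        if (a > 0 && b > 0 && s[a - 1] == s[b - 1]) continue;
        int pr = a_ref ? a : b;
        int pq = (a_ref ? b : a) - nr - 1;
        rs.push_back(pr + 1);                           // 1-based
        qs.push_back(pq + 1);
        len.push_back(L);
    }
    return DataFrame::create(_["ref_start"] = rs, _["query_start"] = qs,
                             _["length"] = len);
}
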