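#include <Rcpp.h>
#include <string>
#include <vector>
#include <limits>
using namespace Rcpp;

// Gotoh global alignment with affine gaps. The first base of a gap costs
// gap_open, each further base gap_ext. Returns the score, the aligned
// strings, and column counts used for percent-identity bookkeeping.
// [[Rcpp::export(name = ".nw_align")]]
List nw_align(std::string a, std::string b,
              double match = 1.0, double mismatch = -1.0,
              double gap_open = -2.0, double gap_ext = -2.0) {
    int n = (int) a.size(), m = (int) b.size();
    const double NEG = -std::numeric_limits<double>::infinity();
    // M: a[i] aligned to b[j]; X: gap in b (consume a); Y: gap in a (consume b)
    std::vector<double> M((n + 1) * (m + 1), NEG), X((n + 1) * (m + 1), NEG),
        Y((n + 1) * (m + 1), NEG);
    std::vector<unsigned char> tbM((n + 1) * (m + 1), 0),
        tbX((n + 1) * (m + 1), 0), tbY((n + 1) * (m + 1), 0);
    auto at = [m](int i, int j) { return i * (m + 1) + j; };
    M[at(0, 0)] = 0.0;
    for (int i = 1; i <= n; ++i) {
        X[at(i, 0)] = gap_open + gap_ext * (i - 1);
        tbX[at(i, 0)] = 1;
    }
    for (int j = 1; j <= m; ++j) {
        Y[at(0, j)] = gap_open + gap_ext * (j - 1);
        tbY[at(0, j)] = 2;
    }
    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            double sub = (a[i - 1] == b[j - 1]) ? match : mismatch;
            // M
            double m0 = M[at(i - 1, j - 1)], m1 = X[at(i - 1, j - 1)],
                   m2 = Y[at(i - 1, j - 1)];
            double best = m0; unsigned char tb = 0;
            if (m1 > best) { best = m1; tb = 1; }
            if (m2 > best) { best = m2; tb = 2; }
            M[at(i, j)] = best + sub; tbM[at(i, j)] = tb;
            // X (gap in b)
            double xo = M[at(i - 1, j)] + gap_open, xy = Y[at(i - 1, j)] + gap_open,
                   xe = X[at(i - 1, j)] + gap_ext;
            if (xo >= xe && xo >= xy) { X[at(i, j)] = xo; tbX[at(i, j)] = 0; }
            else if (xe >= xy)        { X[at(i, j)] = xe; tbX[at(i, j)] = 1; }
            else                      { X[at(i, j)] = xy; tbX[at(i, j)] = 2; }
            // Y (gap in a)
            double yo = M[at(i, j - 1)] + gap_open, yx = X[at(i, j - 1)] + gap_open,
                   ye = Y[at(i, j - 1)] + gap_ext;
            if (yo >= ye && yo >= yx) { Y[at(i, j)] = yo; tbY[at(i, j)] = 0; }
            else if (ye >= yx)        { Y[at(i, j)] = ye; tbY[at(i, j)] = 1; }
            else                      { Y[at(i, j)] = yx; tbY[at(i, j)] = 2; }
        }
    }
    double sM = M[at(n, m)], sX = X[at(n, m)], sY = Y[at(n, m)];
    int state = 0; double score = sM;
    if (sX > score) { score = sX; state = 1; }
    if (sY > score) { score = sY; state = 2; }
    // traceback
    std::string ra, rb;
    int i = n, j = m;
    while (i > 0 || j > 0) {
        if (state == 0) {
            unsigned char tb = tbM[at(i, j)];
            ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
            --i; --j; state = tb;
        } else if (state == 1) {
            unsigned char tb = tbX[at(i, j)];
            ra.push_back(a[i - 1]); rb.push_back('-');
            --i; state = tb;
        } else {
            unsigned char tb = tbY[at(i, j)];
            ra.push_back('-'); rb.push_back(b[j - 1]);
            --j; state = tb;
        }
    }
    std::reverse(ra.begin(), ra.end());
    std::reverse(rb.begin(), rb.end());
    int matched = 0, columns = (int) ra.size();
    for (int k = 0; k < columns; ++k)
        if (ra[k] == rb[k] && ra[k] != '-') ++matched;
    return List::create(_["score"] = score, _["aligned_a"] = ra,
                        _["aligned_b"] = rb, _["matched"] = matched,
                        _["columns"] = columns);
}
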