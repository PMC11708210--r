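#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Suffix-array construction (SA-IS, Nong-Zhang-Chan induced sorting) over an
// integer alphabet. s has values in [0, K); s[n-1] must be 0 and unique.
static void sa_is(const int* s, int* SA, int n, int K) {
    if (n == 1) { SA[0] = 0; return; }
    std::vector<char> t(n);
    t[n - 1] = 1;
    t[n - 2] = 0;
    for (int i = n - 3; i >= 0; --i)
        t[i] = (s[i] < s[i + 1]) || (s[i] == s[i + 1] && t[i + 1]);
    std::vector<int> bkt(K);
    auto get_bkt = [&](bool end) {
        std::fill(bkt.begin(), bkt.end(), 0);
        for (int i = 0; i < n; ++i) bkt[s[i]]++;
        int sum = 0;
        for (int i = 0; i < K; ++i) { sum += bkt[i]; bkt[i] = end ? sum : sum - bkt[i]; }
    };
    auto is_lms = [&](int i) { return i > 0 && t[i] && !t[i - 1]; };
    auto induce = [&]() {
        get_bkt(false);
        for (int i = 0; i < n; ++i) {
            int j = SA[i] - 1;
            if (SA[i] > 0 && !t[j]) SA[bkt[s[j]]++] = j;
        }
        get_bkt(true);
        for (int i = n - 1; i >= 0; --i) {
            int j = SA[i] - 1;
            if (SA[i] > 0 && t[j]) SA[--bkt[s[j]]] = j;
        }
    };

    std::fill(SA, SA + n, -1);
    get_bkt(true);
    for (int i = 1; i < n; ++i)
        if (is_lms(i)) SA[--bkt[s[i]]] = i;
    induce();

    // compact sorted LMS suffixes into SA[0..n1)
    int n1 = 0;
    for (int i = 0; i < n; ++i)
        if (is_lms(SA[i])) SA[n1++] = SA[i];
    std::fill(SA + n1, SA + n, -1);

    // name LMS substrings
    int name = 0, prev = -1;
    for (int i = 0; i < n1; ++i) {
        int pos = SA[i];
        bool diff = false;
        for (int d = 0; d < n; ++d) {
            if (prev == -1 || s[pos + d] != s[prev + d] || t[pos + d] != t[prev + d]) {
                diff = true;
                break;
            }
            if (d > 0 && (is_lms(pos + d) || is_lms(prev + d))) break;
        }
        if (diff) { name++; prev = pos; }
        SA[n1 + pos / 2] = name - 1;
    }
    for (int i = n - 1, j = n - 1; i >= n1; --i)
        if (SA[i] >= 0) SA[j--] = SA[i];

    // recurse on the reduced string if names are not yet unique
    int* SA1 = SA;
    int* s1 = SA + n - n1;
    if (name < n1) {
        sa_is(s1, SA1, n1, name);
    } else {
        for (int i = 0; i < n1; ++i) SA1[s1[i]] = i;
    }

    // map reduced-suffix order back to LMS positions and induce the rest
    for (int i = 1, j = 0; i < n; ++i)
        if (is_lms(i)) s1[j++] = i;
    for (int i = 0; i < n1; ++i) SA1[i] = s1[SA1[i]];
    std::fill(SA + n1, SA + n, -1);
    get_bkt(true);
    for (int i = n1 - 1; i >= 0; --i) {
        int j = SA[i];
        SA[i] = -1;
        SA[--bkt[s[j]]] = j;
    }
    induce();
}

// Kasai's algorithm: lcp[r] = LCP of suffixes ranked r-1 and r.
static void kasai(const std::vector<int>& s, const std::vector<int>& sa,
                  const std::vector<int>& rank, std::vector<int>& lcp) {
    int n = (int)s.size(), h = 0;
    for (int i = 0; i < n; ++i) {
        if (rank[i] > 0) {
            int j = sa[rank[i] - 1];
            while (i + h < n && j + h < n && s[i + h] == s[j + h]) ++h;
            lcp[rank[i]] = h;
            if (h > 0) --h;
        } else {
            h = 0;
            lcp[0] = 0;
        }
    }
}

// Matching statistics for every forward-strand position of a genome.
//
// seqs: list of integer vectors, one per chromosome, with A,C,G,T = 1..4 and
// N = 0. The text indexed is the concatenation of all chromosomes and their
// reverse complements. Every N and every inter-segment separator receives a
// unique integer symbol, so no match crosses a chromosome boundary, a strand
// boundary, or an N, and N matches nothing (not even another N).
//
// MS[i] = length of the longest prefix of the suffix at i that also occurs
// at some other text position = max LCP with the two suffix-array neighbours.
// [[Rcpp::export(name = ".Call_matching_stats")]]
List cpp_matching_stats(List seqs) {
    int nrec = seqs.size();
    std::vector<IntegerVector> recs(nrec);
    long long total = 0;
    for (int r = 0; r < nrec; ++r) {
        recs[r] = seqs[r];
        total += recs[r].size();
    }
    long long n_ll = 2 * total + 2 * nrec + 1;  // fwd + rc, separator after each, terminal
    if (n_ll > INT32_MAX - 2)
        stop("genome too large for 32-bit suffix array (%lld positions)", n_ll);
    int n = (int)n_ll;

    std::vector<int> s(n);
    int pos = 0;
    int special = 5;  // 1..4 bases; 0 terminal; >=5 unique symbols
    std::vector<int> offsets(nrec);
    for (int r = 0; r < nrec; ++r) {
        offsets[r] = pos;
        const IntegerVector& v = recs[r];
        for (int i = 0; i < v.size(); ++i)
            s[pos++] = (v[i] >= 1 && v[i] <= 4) ? v[i] : special++;
        s[pos++] = special++;
    }
    static const int comp[5] = {0, 4, 3, 2, 1};  // A<->T, C<->G
    for (int r = 0; r < nrec; ++r) {
        const IntegerVector& v = recs[r];
        for (int i = v.size() - 1; i >= 0; --i) {
            int b = v[i];
            s[pos++] = (b >= 1 && b <= 4) ? comp[b] : special++;
        }
        s[pos++] = special++;
    }
    s[pos++] = 0;

    std::vector<int> sa(n);
    sa_is(s.data(), sa.data(), n, special);
    std::vector<int> rank(n), lcp(n, 0);
    for (int i = 0; i < n; ++i) rank[sa[i]] = i;
    kasai(s, sa, rank, lcp);

    List out(nrec);
    for (int r = 0; r < nrec; ++r) {
        int len = recs[r].size();
        IntegerVector ms(len);
        int off = offsets[r];
        for (int i = 0; i < len; ++i) {
            int rk = rank[off + i];
            int m = lcp[rk];
            if (rk + 1 < n && lcp[rk + 1] > m) m = lcp[rk + 1];
            ms[i] = m;
        }
        out[r] = ms;
    }
    out.names() = seqs.names();
    return out;
}

// Greedy left-to-right factorization of [from, to) (0-based half-open):
// the factor at p spans max(MS[p], 1) positions, the next factor starts
// right after it. Returns 0-based factor starts and lengths.
// [[Rcpp::export(name = ".Call_factorize")]]
List cpp_factorize(IntegerVector ms, int from, int to) {
    std::vector<int> starts, lens;
    int p = from;
    while (p < to) {
        int l = ms[p] > 1 ? ms[p] : 1;
        if (p + l > to) l = to - p;
        starts.push_back(p);
        lens.push_back(l);
        p += l;
    }
    return List::create(_["start"] = wrap(starts), _["length"] = wrap(lens));
}
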