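#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
#include <climits>

using namespace Rcpp;

// Unit-cost Levenshtein distance; strings here are short (monomer-scale),
// so a plain O(nm) row-rolling DP is fine.
static int lev(const std::string &a, const std::string &b) {
    const int n = (int)a.size(), m = (int)b.size();
    std::vector<int> prev(m + 1), cur(m + 1);
    for (int j = 0; j <= m; ++j) prev[j] = j;
    for (int i = 1; i <= n; ++i) {
        cur[0] = i;
        for (int j = 1; j <= m; ++j) {
            int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
            cur[j] = std::min(sub, std::min(prev[j], cur[j - 1]) + 1);
        }
        std::swap(prev, cur);
    }
    return prev[m];
}

// [[Rcpp::export(name = ".edit_dist_cpp")]]
IntegerVector edit_dist_cpp(std::string x, std::vector<std::string> ys) {
    IntegerVector out(ys.size());
    for (size_t i = 0; i < ys.size(); ++i) out[i] = lev(x, ys[i]);
    return out;
}

// Greedy left-to-right tiling of an array sequence into monomer calls
// with a one-step lookahead.  At each offset, windows of length |m|-1,
// |m|, |m|+1 are scored against every catalog monomer; candidates are
// ranked by (own distance + best distance of the following window), which
// keeps the tiler in frame when an edited monomer shares a prefix with a
// shorter catalog monomer (e.g. TTTAGGA vs TTTAGG).  Remaining ties break
// by (smaller own distance, canonical monomer first, window length ==
// monomer length, longer window, longer monomer, lexicographically smaller
// monomer).  N never matches (lev treats it as a mismatch).

static int best_window_dist(const std::string &seq, int pos,
                            const std::vector<std::string> &monomers) {
    const int n = (int)seq.size();
    if (pos >= n) return 0;                    // nothing left to explain
    int best = INT_MAX;
    for (size_t k = 0; k < monomers.size(); ++k) {
        int ml = (int)monomers[k].size();
        for (int dl = -1; dl <= 1; ++dl) {
            int L = ml + dl;
            if (L < 1) continue;
            if (L > n - pos) L = n - pos;
            int d = lev(seq.substr(pos, L), monomers[k]);
            if (d < best) best = d;
        }
    }
    return best;
}

// [[Rcpp::export(name = ".decompose_greedy_cpp")]]
List decompose_greedy_cpp(std::string seq,
                          std::vector<std::string> monomers,
                          LogicalVector canon) {
    const int n = (int)seq.size();
    const int K = (int)monomers.size();
    std::vector<int> offs, lens, midx, dists;
    int pos = 0;
    while (pos < n) {
        int rem = n - pos;
        int bscore = INT_MAX, bd = INT_MAX, bk = -1, bl = -1;
        for (int k = 0; k < K; ++k) {
            int ml = (int)monomers[k].size();
            for (int dl = -1; dl <= 1; ++dl) {
                int L = ml + dl;
                if (L < 1) continue;
                if (L > rem) L = rem;           // clamp at sequence end
                std::string w = seq.substr(pos, L);
                int d = lev(w, monomers[k]);
                int score = d + best_window_dist(seq, pos + L, monomers);
                // on score ties the canonical monomer leads: a full-length
                // near-canonical window beats a shorter degenerate window
                // that would push the tiling out of frame
                bool better = false;
                if (score < bscore) better = true;
                else if (score == bscore) {
                    bool cNew = canon[k], cOld = canon[bk];
                    if (cNew != cOld) better = cNew;
                    else {
                        int mlOld = (int)monomers[bk].size();
                        bool exactNew = (L == ml),
                             exactOld = (bl == mlOld);
                        if (exactNew != exactOld) better = exactNew;
                        else if (L != bl) better = (L > bl);
                        else if (ml != mlOld) better = (ml > mlOld);
                        else better = (monomers[k] < monomers[bk]);
                    }
                }
                if (better) { bscore = score; bd = d; bk = k; bl = L; }
            }
        }
        offs.push_back(pos);
        lens.push_back(bl);
        midx.push_back(bk + 1);
        dists.push_back(bd);
        pos += bl;
    }
    return List::create(_["offset"] = wrap(offs), _["len"] = wrap(lens),
                        _["monomer"] = wrap(midx), _["dist"] = wrap(dists));
}

// Banded global alignment (unit costs) of `a` (truth) vs `b` (read) with
// traceback, returning operation counts.  The band of half-width `band` is
// centred on the interpolated diagonal j ~ i*m/n, so a uniform indel drift
// stays mid-band.  `edge` reports whether the optimal path touched the band
// boundary (caller should widen and retry).
// [[Rcpp::export(name = ".banded_align_cpp")]]
List banded_align_cpp(std::string a, std::string b, int band) {
    const int n = (int)a.size(), m = (int)b.size();
    const int w = 2 * band + 1;
    const int INF = INT_MAX / 4;
    std::vector<int> Sprev(w, INF), Scur(w, INF);
    std::vector<unsigned char> T((size_t)(n + 1) * w, 0);
    std::vector<int> lo(n + 1), hi(n + 1);
    for (int i = 0; i <= n; ++i) {
        int c = n ? (int)((long long)i * m / n) : 0;
        lo[i] = std::max(0, c - band);
        hi[i] = std::min(m, c + band);
    }
    // row 0
    for (int j = lo[0]; j <= hi[0]; ++j) {
        Sprev[j - lo[0]] = j;
        T[j - lo[0]] = 3;
    }
    T[0] = 0;
    for (int i = 1; i <= n; ++i) {
        const char ai = a[i - 1];
        const int l = lo[i], h = hi[i], lp = lo[i - 1], hp = hi[i - 1];
        unsigned char *Ti = &T[(size_t)i * w];
        std::fill(Scur.begin(), Scur.end(), INF);
        for (int j = l; j <= h; ++j) {
            // on cost ties prefer gap moves over a mismatching diagonal:
            // a deletion-insertion pair then stays a deletion plus an
            // insertion instead of collapsing into two substitutions
            int best = INF; unsigned char tb = 0;
            bool bestMismatch = false;
            if (j >= 1 && j - 1 >= lp && j - 1 <= hp) {
                bool mm = (ai != b[j - 1]);
                int v = Sprev[j - 1 - lp] + (mm ? 1 : 0);
                if (v < best) { best = v; tb = 1; bestMismatch = mm; }
            }
            if (j >= lp && j <= hp) {
                int v = Sprev[j - lp] + 1;
                if (v < best || (v == best && bestMismatch)) {
                    best = v; tb = 2; bestMismatch = false;  // up: deletion
                }
            }
            if (j - 1 >= l) {
                int v = Scur[j - 1 - l] + 1;
                if (v < best || (v == best && bestMismatch)) {
                    best = v; tb = 3; bestMismatch = false;  // left: insertion
                }
            }
            Scur[j - l] = best; Ti[j - l] = tb;
        }
        std::swap(Sprev, Scur);
    }
    if (m < lo[n] || m > hi[n])
        stop("band too narrow for sequence length difference");
    const int cost = Sprev[m - lo[n]];
    // traceback
    int i = n, j = m;
    int matches = 0, mism = 0, ins = 0, del = 0;
    bool edge = false;
    while (i > 0 || j > 0) {
        if ((j == lo[i] && lo[i] > 0) || (j == hi[i] && hi[i] < m)) edge = true;
        unsigned char tb = T[(size_t)i * w + (j - lo[i])];
        if (tb == 1)      { (a[i-1] == b[j-1] ? matches : mism)++; --i; --j; }
        else if (tb == 2) { ++del; --i; }
        else if (tb == 3) { ++ins; --j; }
        else break;
    }
    return List::create(
        _["cost"] = cost,
        _["matches"] = matches, _["mismatches"] = mism,
        _["insertions"] = ins, _["deletions"] = del,
        _["edge"] = edge);
}

// Wraparound dynamic programming: align `s` against a cyclic template,
// free starting phase (row 0 scores 0 in every column), best end column.
// Template-position deletions that would wrap within a single row are
// resolved by a second, improvement-only sweep per row.
// [[Rcpp::export(name = ".wraparound_align_cpp")]]
List wraparound_align_cpp(std::string s, std::string tmpl,
                          int match, int mismatch, int gap) {
    const int n = (int)s.size(), p = (int)tmpl.size();
    if (p < 1) stop("empty template");
    const int NEG = INT_MIN / 4;
    std::vector<int> S((size_t)(n + 1) * p, NEG);
    std::vector<unsigned char> T((size_t)(n + 1) * p, 0);
    auto at = [&](int i, int t) { return (size_t)i * p + t; };
    for (int t = 0; t < p; ++t) S[at(0, t)] = 0;                // free phase
    for (int i = 1; i <= n; ++i) {
        for (int t = 0; t < p; ++t) {
            int tp = (t == 0) ? p - 1 : t - 1;
            int best = S[at(i - 1, tp)] + (s[i - 1] == tmpl[t] ? match : mismatch);
            unsigned char tb = 1;                               // diag
            int v = S[at(i - 1, t)] + gap;                      // up: insertion
            if (v > best) { best = v; tb = 2; }
            if (t > 0) {
                v = S[at(i, t - 1)] + gap;                      // left: deletion
                if (v > best) { best = v; tb = 3; }
            }
            S[at(i, t)] = best; T[at(i, t)] = tb;
        }
        // improvement sweep for deletions wrapping across the copy boundary
        for (int sweep = 0; sweep < 2; ++sweep) {
            bool improved = false;
            int v = S[at(i, p - 1)] + gap;
            if (v > S[at(i, 0)]) { S[at(i, 0)] = v; T[at(i, 0)] = 4; improved = true; }
            for (int t = 1; t < p; ++t) {
                v = S[at(i, t - 1)] + gap;
                if (v > S[at(i, t)]) { S[at(i, t)] = v; T[at(i, t)] = 3; improved = true; }
            }
            if (!improved) break;
        }
    }
    int bt = 0;
    for (int t = 1; t < p; ++t) if (S[at(n, t)] > S[at(n, bt)]) bt = t;
    // traceback with per-column base tallies
    IntegerMatrix counts(5, p);                 // rows: A,C,G,T,del
    auto baseRow = [&](char c) {
        switch (c) { case 'A': return 0; case 'C': return 1;
                     case 'G': return 2; case 'T': return 3; }
        return -1;
    };
    int i = n, t = bt;
    int matches = 0, mism = 0, ins = 0, del = 0, alen = 0;
    while (i > 0) {
        unsigned char tb = T[at(i, t)];
        if (tb == 1) {
            int r = baseRow(s[i - 1]);
            if (r >= 0) counts(r, t)++;
            (s[i - 1] == tmpl[t] ? matches : mism)++;
            --i; t = (t == 0) ? p - 1 : t - 1; ++alen;
        } else if (tb == 2) { ++ins; --i; ++alen; }
        else if (tb == 3) { counts(4, t)++; ++del; t = t - 1; ++alen; }
        else if (tb == 4) { counts(4, t)++; ++del; t = p - 1; ++alen; }
        else break;
    }
    return List::create(
        _["score"] = S[at(n, bt)], _["end_col"] = bt + 1,
        _["counts"] = counts,
        _["matches"] = matches, _["mismatches"] = mism,
        _["insertions"] = ins, _["deletions"] = del,
        _["aln_len"] = alen);
}
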