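#include <Rcpp.h>
#include <cstdint>
#include <unordered_set>
#include <vector>
#include <cmath>
#include <string>

using namespace Rcpp;

// 2-bit base encoding; -1 for anything outside {A,C,G,T}
static inline int base_code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

static const int NEG_INF = INT_MIN / 4;

// Affine-gap pairwise alignment.
//
// Scores: match/mismatch per column; a gap of length L costs
// gapOpen + L * gapExt (both negative).  mode "global" is Needleman-Wunsch
// over both sequences; mode "glocal" aligns the full pattern against a
// subregion of the subject (subject overhangs are free and excluded from
// the column count), which is the read-mapping case.
//
// Returns score, matches, columns (alignment columns incl. gap columns over
// the aligned region), sstart/send (1-based subject coordinates of the
// aligned region) and a SAM-style CIGAR (pattern as query).
// [[Rcpp::export(name = ".cppAlign")]]
List cppAlign(std::string pattern, std::string subject,
              int match = 1, int mismatch = -2,
              int gapOpen = -5, int gapExt = -2,
              bool glocal = false) {
    const int m = (int) pattern.size();
    const int n = (int) subject.size();
    if (m == 0 || n == 0)
        stop("empty sequence in alignment");

    const size_t W = (size_t)(n + 1);
    std::vector<int> M((m + 1) * W, NEG_INF), Ix((m + 1) * W, NEG_INF),
        Iy((m + 1) * W, NEG_INF);
    // traceback: which state the best path came from (0=M,1=Ix,2=Iy)
    std::vector<uint8_t> tM((m + 1) * W), tX((m + 1) * W), tY((m + 1) * W);

    M[0] = 0;
    for (int i = 1; i <= m; ++i) {
        Ix[i * W] = gapOpen + i * gapExt;
        tX[i * W] = (i == 1) ? 0 : 1;
    }
    for (int j = 1; j <= n; ++j) {
        if (glocal) {
            M[j] = 0;          // free subject prefix: start anywhere
        } else {
            Iy[j] = gapOpen + j * gapExt;
            tY[j] = (j == 1) ? 0 : 2;
        }
    }

    for (int i = 1; i <= m; ++i) {
        const char pc = pattern[(size_t)(i - 1)];
        for (int j = 1; j <= n; ++j) {
            const size_t c = i * W + j, d = (i - 1) * W + (j - 1),
                up = (i - 1) * W + j, lf = i * W + (j - 1);
            const int s = (base_code(pc) >= 0 &&
                           base_code(pc) == base_code(subject[(size_t)(j - 1)]))
                ? match : mismatch;
            // M: diagonal step
            int best = M[d]; uint8_t tb = 0;
            if (Ix[d] > best) { best = Ix[d]; tb = 1; }
            if (Iy[d] > best) { best = Iy[d]; tb = 2; }
            if (best > NEG_INF) { M[c] = best + s; tM[c] = tb; }
            // Ix: gap in subject (pattern char over '-')
            int open = std::max(M[up], Iy[up]);
            uint8_t ot = (M[up] >= Iy[up]) ? 0 : 2;
            int ext = Ix[up];
            if (open + gapOpen + gapExt >= ext + gapExt && open > NEG_INF) {
                Ix[c] = open + gapOpen + gapExt; tX[c] = ot;
            } else if (ext > NEG_INF) {
                Ix[c] = ext + gapExt; tX[c] = 1;
            }
            // Iy: gap in pattern (subject char over '-')
            open = std::max(M[lf], Ix[lf]);
            ot = (M[lf] >= Ix[lf]) ? 0 : 1;
            ext = Iy[lf];
            if (open + gapOpen + gapExt >= ext + gapExt && open > NEG_INF) {
                Iy[c] = open + gapOpen + gapExt; tY[c] = ot;
            } else if (ext > NEG_INF) {
                Iy[c] = ext + gapExt; tY[c] = 2;
            }
        }
    }

    // pick end cell
    int ei = m, ej = n, state = 0, score;
    if (glocal) {
        score = NEG_INF;
        for (int j = 0; j <= n; ++j) {
            const size_t c = m * W + j;
            int b = M[c]; int st = 0;
            if (Ix[c] > b) { b = Ix[c]; st = 1; }
            // Iy at the very end would be a subject overhang; skip it
            if (b > score) { score = b; ej = j; state = st; }
        }
    } else {
        const size_t c = m * W + n;
        score = M[c]; state = 0;
        if (Ix[c] > score) { score = Ix[c]; state = 1; }
        if (Iy[c] > score) { score = Iy[c]; state = 2; }
    }

    // traceback
    int i = ei, j = ej, matches = 0, columns = 0;
    std::string ops;
    while (i > 0 || j > 0) {
        if (glocal && i == 0) break;   // free subject prefix
        const size_t c = i * W + j;
        if (state == 0) {
            if (i == 0 && j == 0) break;
            if (glocal && i == 0) break;
            ++columns; ops.push_back('M');
            if (base_code(pattern[(size_t)(i - 1)]) >= 0 &&
                base_code(pattern[(size_t)(i - 1)]) ==
                base_code(subject[(size_t)(j - 1)])) ++matches;
            state = tM[c]; --i; --j;
        } else if (state == 1) {
            ++columns; ops.push_back('I');
            state = tX[c]; --i;
        } else {
            ++columns; ops.push_back('D');
            state = tY[c]; --j;
        }
        if (glocal && i == 0) break;
    }
    const int sstart = j + 1, send = ej;

    // compress ops (reversed) into CIGAR
    std::string cigar;
    for (size_t a = ops.size(); a > 0;) {
        const char op = ops[a - 1];
        size_t b = a;
        while (b > 0 && ops[b - 1] == op) --b;
        cigar += std::to_string(a - b) + op;
        a = b;
    }
    if (cigar.empty()) cigar = "*";

    return List::create(_["score"] = score, _["matches"] = matches,
                        _["columns"] = columns, _["sstart"] = sstart,
                        _["send"] = send, _["cigar"] = cigar);
}

// Sliding-window k-mer entropy.  For every window of length `window`
// (step 1) returns the Shannon entropy H (bits) of the literal k-mer
// counts inside the window and the number of valid (ACGT-only) k-mers.
// Maintains H incrementally via H = log2(T) - S/T with S = sum c*log2(c).
// [[Rcpp::export(name = ".cppWindowEntropy")]]
NumericMatrix cppWindowEntropy(std::string seq, int k, int window) {
    const int L = (int) seq.size();
    if (k < 1 || k > 15) stop("k must be in [1, 15]");
    if (window < k) stop("window shorter than k");
    if (L < window) window = L;
    const int nkmer = L - k + 1;
    if (nkmer < 1) stop("sequence shorter than k");

    // k-mer code at each position, -1 if the window contains non-ACGT
    std::vector<int64_t> code((size_t) nkmer, -1);
    const int64_t mask = ((int64_t)1 << (2 * k)) - 1;
    int64_t cur = 0; int run = 0;
    for (int i = 0; i < L; ++i) {
        const int b = base_code(seq[(size_t)i]);
        if (b < 0) { run = 0; cur = 0; continue; }
        cur = ((cur << 2) | b) & mask;
        ++run;
        if (run >= k) code[(size_t)(i - k + 1)] = cur;
    }

    const int kPerWin = window - k + 1;
    const int nWin = nkmer - kPerWin + 1;
    std::vector<int> cnt((size_t)1 << (2 * k), 0);
    NumericMatrix out(nWin, 2);
    double S = 0.0; int T = 0;
    auto add = [&](int64_t cd, int sign) {
        if (cd < 0) return;
        int &c = cnt[(size_t)cd];
        if (c > 1) S -= c * std::log2((double)c);
        c += sign; T += sign;
        if (c > 1) S += c * std::log2((double)c);
    };
    for (int p = 0; p < kPerWin; ++p) add(code[(size_t)p], +1);
    for (int w = 0; w < nWin; ++w) {
        out(w, 0) = (T > 0) ? (std::log2((double)T) - S / T) : 0.0;
        out(w, 1) = T;
        if (w + 1 < nWin) {
            add(code[(size_t)w], -1);
            add(code[(size_t)(w + kPerWin)], +1);
        }
    }
    return out;
}

static inline bool kmer_code_at(const std::string &s, size_t pos, int l,
                                uint64_t &out) {
    uint64_t c = 0;
    for (int i = 0; i < l; ++i) {
        const int b = base_code(s[pos + (size_t)i]);
        if (b < 0) return false;
        c = (c << 2) | (uint64_t)b;
    }
    out = c;
    return true;
}

static bool set_query(const std::unordered_set<uint64_t> &set, uint64_t code,
                      int l, int maxHamming) {
    if (set.count(code)) return true;
    if (maxHamming < 1) return false;
    for (int i = 0; i < l; ++i) {
        const uint64_t base = (code >> (2 * (l - 1 - i))) & 3ULL;
        for (uint64_t b = 0; b < 4; ++b) {
            if (b == base) continue;
            const uint64_t alt = (code & ~(3ULL << (2 * (l - 1 - i)))) |
                (b << (2 * (l - 1 - i)));
            if (set.count(alt)) return true;
        }
    }
    return false;
}

// Positions of a sequence covered by vector k-mers: full-length k anywhere,
// shortened k-mers (down to kEnd) only when anchored at either sequence end,
// all within Hamming distance <= maxHamming.  Returns 1-based [start, end]
// intervals (unmerged).
// [[Rcpp::export(name = ".cppVectorHits")]]
IntegerMatrix cppVectorHits(std::string seq, CharacterVector vectors,
                            int k = 27, int kEnd = 11, int maxHamming = 1) {
    if (kEnd > k) stop("kEnd must be <= k");
    if (k > 31) stop("k must be <= 31");
    // per-length k-mer sets over all vector sequences
    std::vector<std::unordered_set<uint64_t>> sets((size_t)(k + 1));
    for (int vi = 0; vi < vectors.size(); ++vi) {
        const std::string v = as<std::string>(vectors[vi]);
        for (int l = kEnd; l <= k; ++l) {
            if ((int)v.size() < l) continue;
            for (size_t p = 0; p + (size_t)l <= v.size(); ++p) {
                uint64_t c;
                if (kmer_code_at(v, p, l, c)) sets[(size_t)l].insert(c);
            }
        }
    }
    const int L = (int) seq.size();
    std::vector<std::pair<int,int>> ivs;
    // full-length k-mers anywhere
    for (int p = 0; p + k <= L; ++p) {
        uint64_t c;
        if (!kmer_code_at(seq, (size_t)p, k, c)) continue;
        if (set_query(sets[(size_t)k], c, k, maxHamming))
            ivs.push_back({p + 1, p + k});
    }
    // shortened end-anchored k-mers
    for (int l = kEnd; l < k; ++l) {
        if (L < l) continue;
        uint64_t c;
        if (kmer_code_at(seq, 0, l, c) &&
            set_query(sets[(size_t)l], c, l, maxHamming))
            ivs.push_back({1, l});
        if (kmer_code_at(seq, (size_t)(L - l), l, c) &&
            set_query(sets[(size_t)l], c, l, maxHamming))
            ivs.push_back({L - l + 1, L});
    }
    IntegerMatrix out((int)ivs.size(), 2);
    for (size_t i = 0; i < ivs.size(); ++i) {
        out((int)i, 0) = ivs[i].first;
        out((int)i, 1) = ivs[i].second;
    }
    return out;
}
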