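#include <Rcpp.h>
#include <vector>
#include <utility>

using namespace Rcpp;

// Watson-Crick + G.U wobble on the DNA alphabet (T read as U).
static inline bool can_pair(char a, char b) {
    switch (a) {
    case 'A': return b == 'T';
    case 'T': return b == 'A' || b == 'G';
    case 'G': return b == 'C' || b == 'T';
    case 'C': return b == 'G';
    default: return false;
    }
}

// Base-pair maximization (Nussinov) with a minimum loop of `min_loop`
// unpaired positions between the two bases of any pair. Returns the pair set
// of one maximal nested structure as an m x 2 matrix of 0-based positions
// (i < j). Traceback prefers pairing the outermost bases first, so a planted
// inverted repeat is recovered as one contiguous helix.
// [[Rcpp::export]]
IntegerMatrix nussinov_pairs(std::string seq, int min_loop = 3) {
    const int n = (int) seq.size();
    if (n > 8000)
        stop("region too long for O(n^3) base-pair maximization (%d nt > 8000)", n);
    if (n == 0) return IntegerMatrix(0, 2);

    std::vector<int> E((size_t) n * n, 0);
    // E[i][j] = max pairs in seq[i..j]; recurrence splits on the partner of i.
    for (int span = min_loop + 1; span < n; ++span) {
        for (int i = 0; i + span < n; ++i) {
            const int j = i + span;
            int best = E[(size_t)(i + 1) * n + j];  // i unpaired
            for (int k = i + min_loop + 1; k <= j; ++k) {
                if (!can_pair(seq[i], seq[k])) continue;
                int v = 1 + E[(size_t)(i + 1) * n + (k - 1)];
                if (k < j) v += E[(size_t)(k + 1) * n + j];
                if (v > best) best = v;
            }
            E[(size_t) i * n + j] = best;
        }
    }

    std::vector<std::pair<int,int> > pairs;
    std::vector<std::pair<int,int> > stack;
    stack.push_back(std::make_pair(0, n - 1));
    while (!stack.empty()) {
        int i = stack.back().first, j = stack.back().second;
        stack.pop_back();
        if (j - i <= min_loop) continue;
        const int e = E[(size_t) i * n + j];
        if (e == 0) continue;
        // prefer closing (i, j): recovers stacked helices of inverted repeats
        if (can_pair(seq[i], seq[j]) &&
            e == 1 + E[(size_t)(i + 1) * n + (j - 1)]) {
            pairs.push_back(std::make_pair(i, j));
            stack.push_back(std::make_pair(i + 1, j - 1));
            continue;
        }
        if (e == E[(size_t)(i + 1) * n + j]) {
            stack.push_back(std::make_pair(i + 1, j));
            continue;
        }
        bool found = false;
        for (int k = i + min_loop + 1; k <= j && !found; ++k) {
            if (!can_pair(seq[i], seq[k])) continue;
            int v = 1 + E[(size_t)(i + 1) * n + (k - 1)];
            if (k < j) v += E[(size_t)(k + 1) * n + j];
            if (v == e) {
                pairs.push_back(std::make_pair(i, k));
                stack.push_back(std::make_pair(i + 1, k - 1));
                if (k < j) stack.push_back(std::make_pair(k + 1, j));
                found = true;
            }
        }
        if (!found) stop("internal error: traceback failed at (%d, %d)", i, j);
    }

    IntegerMatrix out((int) pairs.size(), 2);
    for (size_t p = 0; p < pairs.size(); ++p) {
        out(p, 0) = pairs[p].first;
        out(p, 1) = pairs[p].second;
    }
    return out;
}
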