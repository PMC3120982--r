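#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Greedy nearest-neighbor matching without replacement on a 1-d distance.
//
// treated:  logit propensity scores of treated subjects, already permuted
//           into processing order.
// controls: logit propensity scores of controls, sorted ascending.
// caliper:  maximum |treated - control| allowed (>= 0).
// orig_idx: 1-based original row index of each sorted control; exact
//           distance ties are broken toward the lowest original index,
//           including ties among equal-valued controls.
//
// Returns, for each treated subject, the position (1-based) of the matched
// control in the sorted `controls` vector, or 0 if no eligible control
// remains. Each control is used at most once.
//
// Candidates are located by binary search; removals use a "next live index"
// array with path compression plus live `prev` links, so a full pass is
// O((nT + nC) log nC) amortised apart from scans over runs of exactly equal
// scores (short in continuous data).

static int find_live(std::vector<int>& nxt_live, const std::vector<bool>& dead,
                     int j) {
    int r = j;
    while (r < (int)nxt_live.size() && dead[r]) r = nxt_live[r];
    while (j < r) { int t = nxt_live[j]; nxt_live[j] = r; j = t; }
    return r;
}

// [[Rcpp::export]]
IntegerVector greedy_match_cpp(NumericVector treated, NumericVector controls,
                               double caliper, IntegerVector orig_idx) {
    const int nT = treated.size();
    const int nC = controls.size();
    IntegerVector out(nT, 0);
    if (nC == 0) return out;

    std::vector<bool> dead(nC + 1, false);   // slot nC = virtual tail
    std::vector<int> nxt_live(nC + 1);
    std::vector<int> prev_live(nC + 1);
    for (int i = 0; i <= nC; ++i) { nxt_live[i] = i + 1; prev_live[i] = i - 1; }

    // lowest original index among live controls sharing the value at live
    // position `p`, scanning leftward (prev links) and rightward (live finds)
    auto best_in_run = [&](int p) {
        int best = p;
        const double v = controls[p];
        for (int q = prev_live[p]; q >= 0 && controls[q] == v; q = prev_live[q])
            if (orig_idx[q] < orig_idx[best]) best = q;
        for (int q = find_live(nxt_live, dead, p + 1);
             q < nC && controls[q] == v;
             q = find_live(nxt_live, dead, q + 1))
            if (orig_idx[q] < orig_idx[best]) best = q;
        return best;
    };

    const double* cbeg = controls.begin();
    for (int t = 0; t < nT; ++t) {
        const double v = treated[t];
        int j = (int)(std::lower_bound(cbeg, cbeg + nC, v) - cbeg);
        int r = find_live(nxt_live, dead, j);        // first live >= j
        int l = (r <= nC) ? prev_live[r] : nC - 1;   // last live < r

        double dl = (l >= 0) ? v - controls[l] : R_PosInf;
        double dr = (r < nC) ? controls[r] - v : R_PosInf;
        if (dl > caliper) dl = R_PosInf;
        if (dr > caliper) dr = R_PosInf;
        if (dl == R_PosInf && dr == R_PosInf) continue;

        int pick;
        if (dl < dr) pick = best_in_run(l);
        else if (dr < dl) pick = best_in_run(r);
        else {
            int bl = best_in_run(l), br = best_in_run(r);
            pick = (orig_idx[bl] < orig_idx[br]) ? bl : br;
        }

        out[t] = pick + 1;
        dead[pick] = true;
        int nl = find_live(nxt_live, dead, pick + 1);
        int pl = prev_live[pick];
        if (nl <= nC) prev_live[nl] = pl;
    }
    return out;
}
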