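#include <Rcpp.h>
#include <cstdint>
#include <functional>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Exact frontier dynamic program for minimum-weight exact cover by blocks.
//
// Blocks are (row mask, start column, end column, cost) over an m x w
// window, m <= 30. Columns are processed left to right; a state at column
// boundary c is the set of selected blocks whose interval strictly crosses
// the boundary (their row masks are pairwise disjoint), each represented
// by (mask, end). At column c, rows not covered by crossing blocks must
// be covered by blocks starting exactly at c; every way of partitioning
// those rows by start-c blocks is enumerated by depth-first search over
// the lowest free row. States are deduplicated by their canonical
// (mask, end) list keeping the cheapest cost, so the recursion never
// revisits equivalent futures. The optimum is exact; a configurable state
// cap aborts the computation (caller falls back to branch-and-bound).

namespace {

typedef std::pair<double, int> Unused;

struct Cand {
    uint32_t mask;
    int b, e;
    double cost;
};

struct State {
    std::vector<uint64_t> parts;   // (mask << 32) | end, sorted
    double cost;
    int prev;                      // index into the global trace
    std::vector<int> chosenHere;   // candidates selected at this column
};

struct VecHash {
    size_t operator()(const std::vector<uint64_t> &v) const {
        size_t h = 1469598103934665603ull;
        for (uint64_t x : v) {
            h ^= (size_t)(x ^ (x >> 29));
            h *= 1099511628211ull;
        }
        return h;
    }
};

} // namespace

// [[Rcpp::export(name = ".frontierExactCover")]]
List frontierExactCover(IntegerVector masks, IntegerVector bs,
                        IntegerVector es, NumericVector costs, int m,
                        int w, double maxStates) {
    int nCand = masks.size();
    if (m > 30) stop("frontier DP supports at most 30 rows");
    uint32_t full = (m == 32) ? 0xffffffffu : ((1u << m) - 1u);
    std::vector<std::vector<int>> byStart(w + 1);
    std::vector<Cand> cand(nCand);
    for (int j = 0; j < nCand; ++j) {
        cand[j] = {(uint32_t)masks[j], bs[j], es[j], costs[j]};
        byStart[bs[j]].push_back(j);
    }

    // trace of states across all columns, for solution recovery
    std::vector<State> trace;
    trace.push_back({{}, 0.0, -1, {}});
    std::vector<int> frontier = {0};     // indices into trace
    bool overflow = false;

    for (int c = 1; c <= w && !overflow; ++c) {
        std::unordered_map<std::vector<uint64_t>, int, VecHash> next;
        for (int si : frontier) {
            // copy: trace may reallocate while expanding
            const std::vector<uint64_t> parts = trace[si].parts;
            const double baseCost = trace[si].cost;
            uint32_t coveredHere = 0;
            std::vector<uint64_t> keep;   // parts crossing boundary c
            for (uint64_t pt : parts) {
                uint32_t mk = (uint32_t)(pt >> 32);
                int end = (int)(pt & 0xffffffffu);
                coveredHere |= mk;
                if (end > c) keep.push_back(pt);
            }
            uint32_t free0 = full & ~coveredHere;
            // DFS over partitions of the free rows by blocks starting at c
            std::vector<int> sel;
            std::function<void(uint32_t, double)> rec =
                [&](uint32_t freeRows, double cost) {
                if (overflow) return;
                if (freeRows == 0) {
                    std::vector<uint64_t> key = keep;
                    for (int j : sel)
                        if (cand[j].e > c)
                            key.push_back(((uint64_t)cand[j].mask << 32) |
                                          (uint32_t)cand[j].e);
                    std::sort(key.begin(), key.end());
                    auto it = next.find(key);
                    if (it == next.end()) {
                        if ((double)trace.size() > maxStates) {
                            overflow = true;
                            return;
                        }
                        trace.push_back({key, cost, si, sel});
                        next.emplace(std::move(key), (int)trace.size() - 1);
                    } else if (cost < trace[it->second].cost - 1e-12) {
                        trace[it->second].cost = cost;
                        trace[it->second].prev = si;
                        trace[it->second].chosenHere = sel;
                    }
                    return;
                }
                int r = __builtin_ctz(freeRows);   // lowest free row
                for (int j : byStart[c]) {
                    uint32_t mk = cand[j].mask;
                    if (!(mk & (1u << r))) continue;
                    if (mk & ~freeRows) continue;
                    sel.push_back(j);
                    rec(freeRows & ~mk, cost + cand[j].cost);
                    sel.pop_back();
                }
            };
            rec(free0, baseCost);
        }
        frontier.clear();
        for (auto &kv : next) frontier.push_back(kv.second);
        std::sort(frontier.begin(), frontier.end());
        if (frontier.empty() && !overflow)
            stop("infeasible: no exact cover (column %d)", c);
    }

    if (overflow)
        return List::create(_["ok"] = false);

    // final states must have no part crossing beyond column w
    int bestIdx = -1;
    for (int si : frontier) {
        if (!trace[si].parts.empty()) continue;
        if (bestIdx < 0 || trace[si].cost < trace[bestIdx].cost - 1e-12)
            bestIdx = si;
    }
    if (bestIdx < 0) stop("infeasible: open block at the window end");
    std::vector<int> selected;
    for (int si = bestIdx; si >= 0; si = trace[si].prev)
        for (int j : trace[si].chosenHere) selected.push_back(j);
    std::sort(selected.begin(), selected.end());
    IntegerVector sel(selected.size());
    for (size_t i = 0; i < selected.size(); ++i) sel[i] = selected[i] + 1;
    return List::create(_["ok"] = true, _["selected"] = sel,
                        _["value"] = trace[bestIdx].cost,
                        _["optimal"] = true,
                        _["states"] = (double)trace.size());
}
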