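#include <Rcpp.h>
#include <chrono>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Exact branch-and-bound for minimum-weight exact cover.
//
// Candidates are cell sets over cells 1..nCells with nonnegative costs.
// Lower bound: a dual vector u (one value per cell) with nonnegative
// reduced costs cost_j - sum_{c in j} u_c for every candidate j is dual
// feasible, so any exact cover of a cell set S costs at least
// sum_{c in S} u_c. The root dual is built by dual ascent (alternating
// sweep directions) and yields an O(1)-updatable bound during the search;
// at each node one more ascent pass over the subproblem (available
// candidates, uncovered cells) tightens it before branching. When all
// costs are integral the bound is rounded up. Branching: pick the
// uncovered cell with the fewest available candidates, try its candidates
// cheapest reduced-cost first (candidate index as tie-break), so the
// search and the reported optimum are deterministic. An optional warm
// start (any known exact cover, e.g. the one-character blocks) seeds the
// incumbent so a time-limited run always returns a valid cover.

namespace {

struct Problem {
    int nCells;
    std::vector<std::vector<int>> cells;    // 0-based cells per candidate
    std::vector<double> cost;
    std::vector<std::vector<int>> byCell;   // candidates per cell
    std::vector<double> u;                  // root dual values per cell
    std::vector<double> rc;                 // root reduced costs per cand
    bool integral;
};

struct Search {
    const Problem *p;
    std::vector<char> covered;
    std::vector<int> covCnt;                // covered cells per candidate
    std::vector<int> chosen, bestChosen;
    std::vector<double> rcNode;             // scratch for the node pass
    double best, remBound;
    long long nodes;
    bool timedOut;
    std::chrono::steady_clock::time_point deadline;

    bool pruned(double lb) const {
        if (p->integral) lb = std::ceil(lb - 1e-9);
        return lb >= best - 1e-9;
    }

    void place(int j) {
        for (int c : p->cells[j]) {
            covered[c] = 1;
            remBound -= p->u[c];
            for (int j2 : p->byCell[c]) ++covCnt[j2];
        }
        chosen.push_back(j);
    }

    void unplace(int j) {
        for (int c : p->cells[j]) {
            covered[c] = 0;
            remBound += p->u[c];
            for (int j2 : p->byCell[c]) --covCnt[j2];
        }
        chosen.pop_back();
    }

    void dfs(double costSoFar, int nCovered) {
        if (timedOut) return;
        if (++nodes % 4096 == 0 &&
            std::chrono::steady_clock::now() > deadline) {
            timedOut = true;
            return;
        }
        if (nCovered == p->nCells) {
            if (costSoFar < best - 1e-9) {
                best = costSoFar;
                bestChosen = chosen;
            }
            return;
        }
        if (pruned(costSoFar + remBound)) return;

        // one dual-ascent pass on the subproblem: for each uncovered cell
        // take the smallest residual reduced cost among its available
        // candidates and charge it to the bound
        double extra = 0.0;
        int pick = -1, nAvail = -1;
        int nCand = (int)p->cells.size();
        for (int j = 0; j < nCand; ++j) rcNode[j] = p->rc[j];
        for (int c = 0; c < p->nCells; ++c) {
            if (covered[c]) continue;
            double s = R_PosInf;
            int k = 0;
            for (int j : p->byCell[c])
                if (covCnt[j] == 0) { ++k; if (rcNode[j] < s) s = rcNode[j]; }
            if (k == 0) return;  // dead end under current selection
            if (nAvail < 0 || k < nAvail) { pick = c; nAvail = k; }
            if (s > 0) {
                extra += s;
                for (int j : p->byCell[c]) if (covCnt[j] == 0) rcNode[j] -= s;
            }
        }
        if (pruned(costSoFar + remBound + extra)) return;

        // branch over the candidates of the most constrained cell,
        // smallest node reduced cost first, index as tie-break
        std::vector<std::pair<double, int>> branch;
        branch.reserve(nAvail);
        for (int j : p->byCell[pick])
            if (covCnt[j] == 0) branch.push_back({rcNode[j], j});
        std::stable_sort(branch.begin(), branch.end(),
                         [](const std::pair<double, int> &a,
                            const std::pair<double, int> &b) {
                             return a.first < b.first;
                         });
        for (auto &br : branch) {
            int j = br.second;
            if (covCnt[j] != 0) continue;  // covered by a sibling? undone;
                                           // defensive only
            place(j);
            dfs(costSoFar + p->cost[j], nCovered + (int)p->cells[j].size());
            unplace(j);
            if (timedOut) return;
        }
    }
};

} // namespace

// [[Rcpp::export(name = ".bbExactCover")]]
List bbExactCover(List cellSets, NumericVector costs, int nCells,
                  double timeLimit, IntegerVector warmStart) {
    Problem p;
    p.nCells = nCells;
    int nCand = cellSets.size();
    p.cells.resize(nCand);
    p.cost.assign(costs.begin(), costs.end());
    p.integral = true;
    for (double c : p.cost)
        if (std::fabs(c - std::round(c)) > 1e-9) { p.integral = false; break; }
    for (int j = 0; j < nCand; ++j) {
        IntegerVector v = cellSets[j];
        p.cells[j].reserve(v.size());
        for (int x : v) p.cells[j].push_back(x - 1);
    }
    p.byCell.resize(nCells);
    for (int j = 0; j < nCand; ++j)
        for (int c : p.cells[j]) p.byCell[c].push_back(j);
    for (int c = 0; c < nCells; ++c)
        if (p.byCell[c].empty())
            stop("infeasible: cell %d covered by no candidate", c + 1);

    // root dual ascent, alternating sweep direction
    p.u.assign(nCells, 0.0);
    p.rc = p.cost;
    for (int pass = 0; pass < 40; ++pass) {
        double gain = 0.0;
        for (int i = 0; i < nCells; ++i) {
            int c = (pass % 2 == 0) ? i : nCells - 1 - i;
            double s = R_PosInf;
            for (int j : p.byCell[c]) if (p.rc[j] < s) s = p.rc[j];
            if (s > 1e-12) {
                p.u[c] += s;
                gain += s;
                for (int j : p.byCell[c]) p.rc[j] -= s;
            }
        }
        if (gain < 1e-9) break;
    }

    Search s;
    s.p = &p;
    s.covered.assign(nCells, 0);
    s.covCnt.assign(nCand, 0);
    s.rcNode.assign(nCand, 0.0);
    s.best = R_PosInf;
    s.remBound = 0.0;
    for (int c = 0; c < nCells; ++c) s.remBound += p.u[c];
    s.nodes = 0;
    s.timedOut = false;
    s.deadline = std::chrono::steady_clock::now() +
        std::chrono::milliseconds((long long)(timeLimit * 1000.0));

    if (warmStart.size() > 0) {
        double wcost = 0.0;
        for (int j : warmStart) wcost += p.cost[j - 1];
        s.best = wcost;
        s.bestChosen.reserve(warmStart.size());
        for (int j : warmStart) s.bestChosen.push_back(j - 1);
    }

    s.dfs(0.0, 0);

    if (!R_FINITE(s.best))
        stop("no exact cover found (instance infeasible or time limit too small)");
    IntegerVector sel(s.bestChosen.size());
    for (size_t i = 0; i < s.bestChosen.size(); ++i)
        sel[i] = s.bestChosen[i] + 1;
    return List::create(_["selected"] = sel, _["value"] = s.best,
                        _["optimal"] = !s.timedOut,
                        _["nodes"] = (double)s.nodes);
}
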