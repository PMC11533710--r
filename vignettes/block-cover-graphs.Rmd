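---
title: "Building variation graphs from MSAs by minimum-weight block covers"
author: "blockgraph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building variation graphs from MSAs by minimum-weight block covers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blockgraph)
```

## The model

A pangenome variation graph is a labeled directed graph together with one
distinguished walk per input genome, such that concatenating the labels
along a walk spells that genome. `blockgraph` builds such a graph from a
multiple sequence alignment (MSA): an $m \times n$ matrix $\mathcal{T}$
over $\{A,C,G,T,N,-\}$ where row $i$ is a gapped expansion of input
sequence $s_i$, no column consists only of gaps, and (we additionally
require) no row consists only of gaps.

The central object is the **block** $(K, b, e)$: a nonempty set of rows
$K$ and a 1-based inclusive column interval $[b, e]$ on which all rows of
$K$ spell the same gapped string (the block's *label*). Throughout the
package, the gap symbol `-` (and `N`) is an ordinary character during
block computation; gaps only disappear when labels are turned into graph
node labels.

An **exact cover** $\mathcal{C}$ is a set of pairwise non-overlapping
blocks covering every cell $(r, c)$ of the MSA exactly once. From an
exact cover the variation graph follows mechanically: one node per block,
labeled by the block's label; an arc between blocks on consecutive
columns ($e_1 = b_2 - 1$) sharing at least one row; and the walk of row
$r$ visits $r$'s blocks in column order. This graph is acyclic by
construction and *lossless*: each walk spells its row, so after deleting
gaps it spells the input sequence.

The **minimum-weight block cover** (MWBC) problem asks for the exact
cover, drawn from a candidate set $\mathcal{B}$, minimizing an objective
$f(\mathcal{C}) = \sum_{(K,b,e) \in \mathcal{C}} w(K,b,e)$. Five weights
are supported (`objectiveSpec()`), writing $\gamma$ for the label without
gaps:

| name       | block weight                                        | intent |
|------------|-----------------------------------------------------|--------|
| `blocks`   | $1$                                                 | fewest nodes |
| `weighted` | $\Delta$ if $|\gamma| \le q$, else $1$              | penalize short labels (seeding) |
| `depth`    | $\Delta$ if $|K| \le \lfloor p\,m \rfloor$, else $1$ | penalize low-coverage nodes |
| `strings`  | $|\gamma|$                                          | shortest total label length |
| `pstrings` | $|\gamma| / |K|$                                    | label length per supported row |

Defaults $q = 20$, $\Delta = 1000$, $p = 0.11$ follow the experimental
settings the method was introduced with. Two readings of the depth
threshold circulate — an absolute row count and a fraction of the input
sequences — so both are exposed: the default penalizes blocks with at
most $\lfloor p\,m \rfloor$ rows, and `depthMinCount` switches to a
literal row-count threshold. Similarly, the weighted penalty is applied
to the *ungapped* label length $|\gamma|$, not to the column span
$e - b + 1$; the two differ exactly on blocks containing gaps. $\Delta =
1$ is accepted and turns the penalty off (then `weighted` coincides with
`blocks`), which is also how the degenerate identity is tested.

## Candidate blocks

All blocks of an MSA are exponentially many, so the solver works on a
curated candidate set, assembled by `buildInstances()`:

1. **Maximal blocks** (`enumerateMaximalBlocks()`): blocks not
   extensible in rows or columns. A block is maximal iff its row set is a
   full equivalence class of "rows equal on $[b,e]$" and the class is not
   constant at columns $b-1$ and $e+1$. The enumerator sweeps start
   columns and refines the row partition column by column — $O(n^2 m)$
   at worst, linear in practice for closely related rows because the
   sweep stops once all classes are singletons. A brute-force enumerator
   (`bruteForceMaximalBlocks()`) exists purely as a testing oracle.
   One-row maximal blocks (necessarily whole-row blocks) encode entire
   genomes as single nodes and are discarded.
2. **Pairwise decomposition** (`decomposeAll()`): each overlapping pair
   of maximal blocks contributes sub-blocks, in one pass (products are
   not re-decomposed). The *row-maximal* strategy keeps the parts of
   each parent outside the partner's columns; the *complete* strategy
   additionally forms blocks on the intersection/difference row sets
   over both parents' intervals and their shared columns, and is always
   a superset of the row-maximal result. Candidates whose rows do not
   agree on their interval are not blocks and are dropped; candidates
   are also required to lie inside one of their parents, which keeps
   every product within the cells the pair already covers. Pairs are
   canonicalized by sorting on $(b, e, \min K)$ before the case split,
   so decomposition is symmetric in its arguments even when both blocks
   start at the same column (the case split itself is asymmetric there).
3. **Short fallback blocks** (`addShortBlocks()`): for each row, one-row
   blocks over the maximal intervals not covered by any $\ge 2$-row
   maximal block (coverage is judged against the maximal blocks, not the
   decomposition products); and for every column $b$ and every character
   $\sigma$ present there (gap included), the one-character block
   $(K_\sigma, b, b)$ — at most six per column. The one-character blocks
   alone partition every column, so **every instance is feasible by
   construction**; the solver reporting infeasibility is treated as an
   internal error, not a user error.

## Vertical blocks and windows

A **vertical block** spans all $m$ rows; its columns are exactly the
columns where the alignment is constant. With threshold $\alpha$
(`findVerticalBlocks()`), every maximal constant run of at least
$\alpha$ columns is forced into the cover and splits the MSA into free
windows that are solved independently (`splitByVertical()`,
`buildInstances()`); maximal blocks, decompositions and fallback blocks
are computed per window, treating the window as an alignment in its own
right. `alphaBreakpoints()` reports the widths of the widest free window
as a step function of $\alpha$ — the practical dial between solve cost
(wide windows) and forced graph structure (many forced nodes).

Setting `alpha = "disabled"` (internally $\alpha = n + 1$) forces
nothing. A numeric $\alpha$ is always taken literally, including
$\alpha = n$, where a genome-length constant alignment would still be
forced; the sentinel exists precisely because "no forcing" and "a very
large threshold" are different requests.

## Solving

`solveInstance()` finds a provably optimal exact cover with two exact
engines behind one interface:

* a **frontier dynamic program** over columns (default for $m \le 30$):
  the state at a column boundary is the set of selected blocks whose
  interval crosses it, recorded as (row-set, end-column) pairs; rows not
  covered by crossing blocks must be covered by blocks starting at the
  next column, and all ways to do so are enumerated, with states
  deduplicated to the cheapest cost. Exact for every objective; gives up
  (to the fallback) if the state count exceeds $2 \times 10^6$.
* a **branch-and-bound** fallback: depth-first search branching on the
  uncovered cell with fewest available candidates, bounded by a
  dual-ascent lower bound (a per-cell dual vector with nonnegative
  reduced costs, tightened by one ascent pass per node) with integer
  rounding when all weights are integral. The always-feasible
  one-character cover seeds the incumbent, so a run that hits its time
  limit still returns a valid (flagged non-optimal) cover.

Both engines are deterministic: candidates are ordered by
$(b, e, \min K)$ and all tie-breaks are by candidate index, so the
optimal *value* and the returned cover are reproducible. When several
optimal covers exist, which one is returned is an artifact of that
ordering and is not otherwise meaningful; comparisons across settings
should compare objective values, not block sets. Fractional weights
(`pstrings`) are handled in floating point with a $10^{-6}$ agreement
check between the engine's value and a re-evaluation of the returned
cover; exact covers are additionally verified cell by cell after every
solve, independent of the engine's own bookkeeping.

A third, deliberately naive engine (`solveExhaustive()`, plain
depth-first enumeration in R) and an unrestricted-candidate oracle
(`solveGmwbcOracle()`, every block of the MSA) exist for validation on
tiny inputs; the test suite cross-checks all engines against them.

## Post-processing

`postprocessGraph()` applies, in order: removal of nodes whose label is
entirely gaps (walks skip them; arcs are maintained as exactly the pairs
consecutive on some walk, which rewires chains of removed nodes
transitively); gap-stripping of the remaining labels (no label can
become empty — such a node would have been all-gaps and already
removed); and unipath collapse — an arc $(u, v)$ with out-degree 1,
in-degree 1, no walk ending at $u$ and no walk starting at $v$ is merged
until none remains. The two walk-end guards are not part of the textbook
"collapse non-branching paths" description, but without them a walk
terminating mid-chain would be spliced incorrectly; with them,
losslessness provably survives post-processing. Merged nodes keep the
smallest participating id, so GFA output is stable.

## GFA and metrics

`writeGfa()` emits GFA1 with `S`/`L`/`P` records in deterministic order
(paths carry all-forward orientations — the graph is built from a
single-strand MSA, so there is nothing bidirected to represent).
`computeGraphMetrics()` reports node count, total label length,
potential seeds of length $k$ (default 20), and node-depth counts.
Potential seeds are counted by position within labels,
$\sum_v \max(0, |\lambda(v)| - k + 1)$, because seed-and-extend mappers
consume occurrences; counting *distinct* $k$-mers is a defensible
alternative reading and is available as `seedMode = "distinct"`
(positions $\ge$ distinct always). A node counts toward the depth metric
when at least $\lceil t \cdot \#\text{walks} \rceil$ walks traverse it.

## The synthetic generator

`simulateMsa()` draws a random ancestor and derives each row by per-cell
substitutions (default 0.05) and deletion gaps (default rate 0.02,
length $\le 3$) — rates chosen as plausible for a set of closely related
viral genomes, which is the regime block covers are designed for. Gaps
are planted directly as alignment cells, so the alignment is exact by
construction (no realignment step) and intervals passed as
`sharedSegments` stay mutation-free — a segment shared by all rows is
guaranteed to reappear as a vertical block. Two deliberate
simplifications: insertions are not modeled (every column descends from
one ancestor position), and there is no phylogenetic correlation between
rows (star topology). Passing tests on this generator therefore says
nothing about alignment *quality* on real data — the method consumes
whatever MSA it is given, and a poor upstream alignment gives a poor
graph; alignment construction is explicitly out of scope.

The fixed 5×9 example alignment (`runningExample()`) is a reconstruction
from its documented facts — its five ungapped sequences and its three
named maximal blocks — and those facts, not the particular gap
placement, are what the tests assert. One consequence worth noting: the
two named overlapping blocks share row 2, which pins column 2 to `A` in
every row, so the example necessarily contains single-column vertical
runs (columns 2 and 5) besides the documented columns 7–8; at
$\alpha = 1$ its widest free window is 2 columns.

## Problem sizes and numerical choices

The validation battery used by the tests and the acceptance script
consists of synthetic alignments with $m \in [2, 8]$ rows and
$n \in [10, 60]$ columns, cycling through all
objective × decomposition × $\alpha \in \{1, 3, \text{disabled}\}$
combinations; exhaustive-oracle comparisons run on instances of at most
30 cells and the unrestricted-candidate oracle on at most 20 cells
(beyond that, enumerating every exact cover is pointless as a test).
These sizes keep a full validation run in minutes on one core while
still producing windows with hundreds of candidate blocks. Tolerances:
objective values are compared at $10^{-6}$; all other assertions are
exact (integer counts, set equality, string identity).

## Known limitations

* Solve cost grows quickly with window width; the design assumes users
  control it with $\alpha$, exactly as the breakpoint report suggests.
  The frontier DP removes the worst behavior at validation scale, but
  adversarial candidate sets can still exceed its state cap and fall
  back to branch-and-bound with a time limit.
* The graph is acyclic and single-stranded; reverse complements, cycles
  and graph editing beyond the described post-processing are out of
  scope.
* Only the DNA alphabet extended with `N` and `-` is supported.
* `alpha` forcing assumes the forced vertical blocks are what the user
  wants as shared nodes; the solver never reconsiders them.
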