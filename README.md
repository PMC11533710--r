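# blockgraph

Build acyclic pangenome **variation graphs** from a multiple sequence
alignment (MSA) by solving a **minimum-weight exact block cover**.

## The problem

Given an MSA `T` (m rows × n columns over `{A,C,G,T,N,-}`), a *block*
`(K, b, e)` is a set of rows `K` and a column interval `[b, e]` on which
all rows of `K` spell the same gapped string. An *exact cover* is a set of
pairwise non-overlapping blocks covering every MSA cell exactly once; it
converts mechanically into a variation graph — one node per block (labeled
by the block's string), arcs between column-adjacent blocks sharing a row,
and one walk per input sequence — that is acyclic and **lossless**: each
walk spells its input genome.

The package selects the cover by exact optimization over a candidate set
built from **maximal blocks**, their pairwise **decompositions**
(`row-maximal` or the larger `complete` strategy), and short fallback
blocks that guarantee feasibility:

    min  Σ_{(K,b,e) ∈ C} w(K,b,e)   s.t.  every cell covered exactly once

with five selectable weights `w`: `blocks` (1 per block), `weighted`
(Δ if the ungapped label is ≤ q, else 1), `depth` (Δ for blocks with at
most ⌊p·m⌋ rows), `strings` (ungapped label length) and `pstrings`
(label length / row count); defaults q = 20, Δ = 1000, p = 0.11.
*Vertical blocks* — constant alignment runs spanning all rows of at least
`alpha` columns — can be forced into the cover, which splits the MSA into
independently solved windows (`alphaBreakpoints()` reports the trade-off).
The optimizer is an exact frontier dynamic program over columns with a
dual-ascent branch-and-bound fallback; returned covers are re-verified
cell by cell. See the vignette (`vignettes/block-cover-graphs.Rmd`) for
the full method description.

Intended users: anyone constructing pangenome graphs from a precomputed
MSA (e.g. closely related viral or bacterial genomes) who wants explicit,
tunable control over what becomes a node. Alignment construction is out
of scope — the MSA is the input.

## Worked example

```r
library(blockgraph)

msa <- runningExample()        # fixed 5 x 9 example alignment
msa
#> MSA: 5 sequences x 9 columns
#>   [1] circle  AA--CCGA-
#>   [2] square  AA-AC-GAT
#>   ...

enumerateMaximalBlocks(msa)[[5]]
#> Block({2,3,4}, 2..9)

findVerticalBlocks(msa, alpha = 2)[[1]]
#> Block({1,2,3,4,5}, 7..8)

cover <- solveMsaCover(msa, "blocks", alpha = 2)
cover
#> BlockCover: 16 blocks, objective value 16 (optimal)

graph <- postprocessGraph(buildGraph(msa, cover))
graph
#> VariationGraph: 12 nodes, 15 arcs, 5 walks

walkLabel(graph, 5)            # walks spell the input sequences
#> [1] "AATCCGGAA"

unlist(computeGraphMetrics(graph, k = 3)[1:5])
#>              n_nodes   total_label_length      potential_seeds
#>                   12                   14                    0
#> depth_fraction_nodes  all_sequences_nodes
#>                   12                    3
```

The cover uses 16 blocks (the forced vertical block `7..8` among them);
after removing gap-only nodes, stripping gaps and collapsing unipaths the
graph has 12 nodes whose labels total 14 characters, 3 of which lie on
every walk. No label reaches 3 characters, so there are no 3-mer seeds —
on this toy alignment variation is dense; on realistic inputs the
`weighted` objective trades node count for seed-bearing labels.

For a shell workflow, the same pipeline runs as

```sh
inst/scripts/blockgraph-cli build --msa aln.fa --objective blocks \
    --alpha 25 --decomposition row-maximal --out-dir out/
```

writing `graph.gfa` (GFA1 with one `P` line per sequence),
`metrics.json`/`.tsv`, `solve_report.json` and `config.json`.

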