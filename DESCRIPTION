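Package: blockgraph
Title: Pangenome Variation Graphs from MSAs via Minimum-Weight Block Covers
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Constructs acyclic pangenome variation graphs from a multiple
    sequence alignment by selecting an exact cover of the alignment with
    blocks (row sets spelling a common gapped string over a column
    interval). Candidate blocks are maximal blocks, their row-maximal or
    complete pairwise decompositions, and short fallback blocks; the
    minimum-weight exact cover is found by an exact branch-and-bound
    solver under five selectable objective functions. Long vertical
    blocks (shared by all rows) can be forced into the cover to split the
    alignment into independently solvable windows. The resulting graph is
    post-processed (indel-node removal, label stripping, unipath
    collapse) and serialized to GFA1 with one path per input sequence,
    together with summary metrics (vertex count, label length, potential
    k-mer seeds, node depth).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, Rcpp, Biostrings, jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), igraph, optparse
biocViews: Alignment, Genetics, Software, GraphAndNetwork
Config/testthat/edition: 3
RoxygenNote: 7.3.3
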