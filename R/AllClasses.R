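#' @import methods
#' @importFrom stats runif
#' @importFrom utils head tail
NULL

MSA_ALPHABET <- c("A", "C", "G", "T", "N", "-")

#' MSA: a validated multiple sequence alignment
#'
#' An \code{MSA} holds an aligned set of DNA sequences as an m x n character
#' matrix over the indel-extended alphabet \{A,C,G,T,N,-\}. All rows have the
#' same length, every column carries at least one non-indel character, and
#' every row carries at least one non-indel character. Coordinates are
#' 1-based with closed column intervals throughout the package.
#'
#' @slot ids character vector of sequence identifiers (one per row, file order).
#' @slot chars m x n matrix of single characters.
#'
#' @seealso [readMsa()], [msaFromStrings()], [ungapped()], [msaSlice()]
#' @exportClass MSA
setClass("MSA", representation(ids = "character", chars = "matrix"))

setValidity("MSA", function(object) {
    ch <- object@chars
    if (!is.character(ch)) return("chars must be a character matrix")
    if (nrow(ch) < 1L || ncol(ch) < 1L) return("MSA must have >= 1 row and column")
    if (length(object@ids) != nrow(ch)) return("one id per row required")
    if (!all(ch %in% MSA_ALPHABET))
        return("characters outside alphabet {A,C,G,T,N,-}")
    if (any(colSums(ch != "-") == 0L))
        return("column with only indels")
    if (any(rowSums(ch != "-") == 0L))
        return("row with only indels")
    TRUE
})

#' Block: rows spelling a common string over a column interval
#'
#' A block \code{(K, b, e)} is a nonempty set of MSA row indices \code{K} and
#' an inclusive column interval \code{[b, e]} on which all rows of \code{K}
#' spell the same gapped string. The object stores only the coordinates;
#' agreement of the rows is checked against a concrete [MSA] by
#' [makeBlock()] and [isBlockValid()].
#'
#' @slot rows sorted integer vector of 1-based row indices.
#' @slot start,end 1-based inclusive column interval.
#'
#' @exportClass Block
setClass("Block", representation(rows = "integer", start = "integer",
                                 end = "integer"))

setValidity("Block", function(object) {
    if (length(object@rows) == 0L) return("empty row set")
    if (any(object@rows < 1L)) return("row indices must be >= 1")
    if (anyDuplicated(object@rows)) return("duplicated row indices")
    if (is.unsorted(object@rows)) return("row indices must be sorted")
    if (length(object@start) != 1L || length(object@end) != 1L)
        return("start/end must be scalars")
    if (is.na(object@start) || is.na(object@end) ||
        object@start < 1L || object@end < object@start)
        return("need 1 <= start <= end")
    TRUE
})

#' ObjectiveSpec: objective function for the minimum-weight block cover
#'
#' Encodes which of the five objective functions scores a candidate block,
#' together with its tuning parameters:
#' \describe{
#'   \item{blocks}{every block costs 1 (minimize the number of blocks).}
#'   \item{weighted}{a block costs \code{delta} if its ungapped label length
#'     is at most \code{q}, else 1 (penalize short labels).}
#'   \item{depth}{a block costs \code{delta} if it is used by at most
#'     \code{floor(p * m)} rows (or at most \code{depthMinCount} rows when
#'     that is set), else 1 (penalize low-coverage blocks).}
#'   \item{strings}{a block costs its ungapped label length.}
#'   \item{pstrings}{penalized strings: ungapped label length divided by the
#'     number of rows of the block.}
#' }
#'
#' @slot name one of "blocks", "weighted", "depth", "strings", "pstrings".
#' @slot q label-length threshold of the weighted objective (default 20).
#' @slot delta penalty \eqn{\Delta > 1} (default 1000).
#' @slot p coverage fraction in (0, 1] of the depth objective (default 0.11).
#' @slot depthMinCount NA, or an absolute row-count threshold that replaces
#'   \code{floor(p * m)} in the depth objective.
#'
#' @exportClass ObjectiveSpec
setClass("ObjectiveSpec", representation(name = "character", q = "numeric",
                                         delta = "numeric", p = "numeric",
                                         depthMinCount = "numeric"))

setValidity("ObjectiveSpec", function(object) {
    if (!object@name %in% c("blocks", "weighted", "depth", "strings", "pstrings"))
        return("unknown objective name")
    if (object@q < 1) return("q must be >= 1")
    # delta = 1 turns the penalty off (weighted degenerates to blocks)
    if (object@delta < 1) return("delta must be >= 1")
    if (object@p <= 0 || object@p > 1) return("p must be in (0, 1]")
    TRUE
})

#' MWBCInstance: one exact-cover problem over a column window
#'
#' The solver input for one free window of the alignment: the parent [MSA],
#' the global column window \code{[windowStart, windowEnd]}, and the
#' deduplicated candidate blocks (global coordinates, all inside the
#' window). Forced vertical blocks never appear here; they bypass the
#' solver and are merged into the global cover by [buildInstances()] /
#' [solveMsaCover()].
#'
#' @slot msa the parent MSA.
#' @slot windowStart,windowEnd global column interval of this window.
#' @slot candidates list of [Block] candidates.
#'
#' @exportClass MWBCInstance
setClass("MWBCInstance", representation(msa = "MSA", windowStart = "integer",
                                        windowEnd = "integer",
                                        candidates = "list"))

#' BlockCover: an exact cover together with its objective value
#'
#' @slot blocks list of pairwise non-overlapping [Block]s covering every cell
#'   of their region exactly once.
#' @slot objectiveValue value of the objective over \code{blocks}.
#' @slot optimal TRUE unless the solver stopped at its node budget with an
#'   incumbent it could not prove optimal.
#'
#' @exportClass BlockCover
setClass("BlockCover", representation(blocks = "list",
                                      objectiveValue = "numeric",
                                      optimal = "logical"))

#' VariationGraph: labeled DAG with one walk per input sequence
#'
#' Nodes carry string labels; arcs are ordered node pairs; each input row of
#' the source MSA contributes one walk (a node-id sequence). The graph is
#' acyclic and lossless: concatenating the labels along row r's walk and
#' deleting indels yields the ungapped input sequence of row r, before and
#' after [postprocessGraph()].
#'
#' @slot nodeIds integer node identifiers (stable across post-processing).
#' @slot labels character labels, parallel to \code{nodeIds}.
#' @slot arcs 2-column integer matrix of (from, to) node ids.
#' @slot walks list of integer vectors of node ids, one per input row.
#' @slot walkIds character identifiers of the walks (sequence names).
#'
#' @exportClass VariationGraph
setClass("VariationGraph", representation(nodeIds = "integer",
                                          labels = "character",
                                          arcs = "matrix",
                                          walks = "list",
                                          walkIds = "character"))

setValidity("VariationGraph", function(object) {
    if (length(object@nodeIds) != length(object@labels))
        return("one label per node id")
    if (anyDuplicated(object@nodeIds)) return("duplicated node ids")
    if (ncol(object@arcs) != 2L) return("arcs must have 2 columns")
    known <- object@nodeIds
    if (length(object@arcs) && !all(object@arcs %in% known))
        return("arc endpoint not a node")
    if (!all(unlist(object@walks) %in% known))
        return("walk node not a node")
    if (length(object@walks) != length(object@walkIds))
        return("one id per walk")
    TRUE
})

setMethod("show", "MSA", function(object) {
    cat(sprintf("MSA: %d sequences x %d columns\n",
                nrow(object@chars), ncol(object@chars)))
    ids <- object@ids
    for (i in head(seq_along(ids), 6L)) {
        row <- paste(object@chars[i, ], collapse = "")
        if (nchar(row) > 60L) row <- paste0(substr(row, 1L, 57L), "...")
        cat(sprintf("  [%d] %s  %s\n", i, ids[i], row))
    }
    if (length(ids) > 6L) cat(sprintf("  ... and %d more\n", length(ids) - 6L))
})

setMethod("show", "Block", function(object) {
    cat(sprintf("Block({%s}, %d..%d)\n",
                paste(object@rows, collapse = ","),
                object@start, object@end))
})

setMethod("show", "ObjectiveSpec", function(object) {
    extra <- switch(object@name,
        weighted = sprintf(" (q=%g, delta=%g)", object@q, object@delta),
        depth = if (is.na(object@depthMinCount))
                    sprintf(" (p=%g, delta=%g)", object@p, object@delta)
                else sprintf(" (min count=%g, delta=%g)",
                             object@depthMinCount, object@delta),
        "")
    cat(sprintf("ObjectiveSpec: %s%s\n", object@name, extra))
})

setMethod("show", "MWBCInstance", function(object) {
    cat(sprintf("MWBCInstance: window %d..%d, %d candidate blocks\n",
                object@windowStart, object@windowEnd,
                length(object@candidates)))
})

setMethod("show", "BlockCover", function(object) {
    cat(sprintf("BlockCover: %d blocks, objective value %g%s\n",
                length(object@blocks), object@objectiveValue,
                if (object@optimal) " (optimal)" else " (incumbent)"))
})

setMethod("show", "VariationGraph", function(object) {
    cat(sprintf("VariationGraph: %d nodes, %d arcs, %d walks\n",
                length(object@nodeIds), nrow(object@arcs),
                length(object@walks)))
})

#' @describeIn MSA-class dimensions (rows, columns) of the alignment
#' @param x an MSA
#' @export
setMethod("dim", "MSA", function(x) dim(x@chars))
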