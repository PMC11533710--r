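# Pairwise decomposition of overlapping maximal blocks into smaller
# candidate blocks. A pair is canonicalized by sorting on (start, end,
# smallest row) before applying the case analysis, which makes the result
# symmetric in its two arguments even when the blocks start at the same
# column.

canonicalPair <- function(l1, l2) {
    key <- function(x) c(x@start, x@end, x@rows[1L])
    k1 <- key(l1); k2 <- key(l2)
    swap <- FALSE
    for (i in 1:3) {
        if (k1[i] < k2[i]) break
        if (k1[i] > k2[i]) { swap <- TRUE; break }
    }
    if (swap) list(l1 = l2, l2 = l1) else list(l1 = l1, l2 = l2)
}

#' Row-maximal decomposition of a pair of overlapping blocks
#'
#' With the pair ordered so that \code{b1 <= b2}, emits the sub-blocks
#' \code{(K1, b1, b2-1)} (when \code{b1 < b2}), \code{(K2, e1+1, e2)} (when
#' \code{e1 < e2}) and \code{(K1, e2+1, e1)} (when \code{e2 < e1}); each
#' keeps the full row set of the parent it lies in, and all columns of the
#' intersection are excluded. More than one case can fire; all firing cases
#' are returned.
#'
#' @param msa an [MSA].
#' @param l1,l2 overlapping [Block]s (order irrelevant).
#' @return list of [Block]s (possibly empty, e.g. for identical inputs).
#' @export
rowMaximalDecompose <- function(msa, l1, l2) {
    if (!blocksOverlap(l1, l2)) stop("blocks do not overlap")
    p <- canonicalPair(l1, l2); l1 <- p$l1; l2 <- p$l2
    b1 <- l1@start; e1 <- l1@end; b2 <- l2@start; e2 <- l2@end
    out <- list()
    if (b1 < b2) out[[length(out) + 1L]] <- newBlock(l1@rows, b1, b2 - 1L)
    if (e1 < e2) out[[length(out) + 1L]] <- newBlock(l2@rows, e1 + 1L, e2)
    if (e2 < e1) out[[length(out) + 1L]] <- newBlock(l1@rows, e2 + 1L, e1)
    dedupBlocks(out)
}

#' Complete decomposition of a pair of overlapping blocks
#'
#' Extends [rowMaximalDecompose()] with blocks over the intersection of the
#' pair: with \code{b1 <= b2} and writing \eqn{I = K1 \cap K2},
#' \eqn{D1 = K1 \setminus K2}, \eqn{D2 = K2 \setminus K1}, the candidates
#' are \code{(I,b1,e1)}, \code{(I,b2,e2)}, \code{(D1,b1,e1)},
#' \code{(D1,b2,e2)}, \code{(D2,b1,e1)}, \code{(D2,b2,e2)} for each
#' nonempty row set, plus \code{(I,b2,e1)}, \code{(D1,b2,e1)},
#' \code{(D2,b2,e1)} when additionally \code{b2 < e1}. A candidate is kept
#' only if it is an actual block (its rows agree on its interval — the
#' difference row sets need not agree on the partner's interval) and its
#' cells lie inside one of the two parents, so every product is fully
#' contained in at least one parent block.
#'
#' @inheritParams rowMaximalDecompose
#' @return list of [Block]s, a superset of the row-maximal result.
#' @export
completeDecompose <- function(msa, l1, l2) {
    if (!blocksOverlap(l1, l2)) stop("blocks do not overlap")
    p <- canonicalPair(l1, l2); l1 <- p$l1; l2 <- p$l2
    b1 <- l1@start; e1 <- l1@end; b2 <- l2@start; e2 <- l2@end
    out <- rowMaximalDecompose(msa, l1, l2)
    sets <- list(intersect(l1@rows, l2@rows),
                 setdiff(l1@rows, l2@rows),
                 setdiff(l2@rows, l1@rows))
    within <- function(K, b, e, parent)
        all(K %in% parent@rows) && b >= parent@start && e <= parent@end
    addIfBlock <- function(K, b, e) {
        if (length(K) == 0L) return()
        if (!within(K, b, e, l1) && !within(K, b, e, l2)) return()
        cand <- newBlock(K, b, e)
        if (isBlockValid(msa, cand))
            out[[length(out) + 1L]] <<- cand
    }
    for (K in sets) {
        addIfBlock(K, b1, e1)
        addIfBlock(K, b2, e2)
        if (b2 < e1) addIfBlock(K, b2, e1)
    }
    dedupBlocks(out)
}

#' Decompose every overlapping pair of a set of maximal blocks
#'
#' One pass over the unordered pairs of \code{maximal}: each overlapping
#' pair contributes its pairwise decomposition; products are not themselves
#' decomposed. The result is the input united with all products,
#' deduplicated.
#'
#' @param msa an [MSA].
#' @param maximal list of maximal [Block]s (e.g. from
#'   [enumerateMaximalBlocks()]).
#' @param strategy \code{"row-maximal"} or \code{"complete"}; the complete
#'   strategy always yields a superset of the row-maximal one.
#' @return deduplicated list of [Block]s containing \code{maximal}.
#' @export
decomposeAll <- function(msa, maximal, strategy = c("row-maximal", "complete")) {
    strategy <- match.arg(strategy)
    decompose <- if (strategy == "complete") completeDecompose
                 else rowMaximalDecompose
    nb <- length(maximal)
    out <- maximal
    if (nb >= 2L) {
        bs <- vapply(maximal, function(x) x@start, integer(1L))
        es <- vapply(maximal, function(x) x@end, integer(1L))
        for (i in seq_len(nb - 1L)) for (j in (i + 1L):nb) {
            if (bs[i] > es[j] || bs[j] > es[i]) next
            if (!length(intersect(maximal[[i]]@rows, maximal[[j]]@rows))) next
            out <- c(out, decompose(msa, maximal[[i]], maximal[[j]]))
        }
    }
    sortBlocks(dedupBlocks(out))
}
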