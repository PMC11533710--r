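# From a global exact cover to a variation graph, and its post-processing.
# Arcs are, at every stage, exactly the pairs of nodes consecutive on some
# walk; for the freshly built graph this coincides with the textbook rule
# (column-adjacent blocks sharing a row).

arcsFromWalks <- function(walks) {
    pairs <- lapply(walks, function(w) {
        if (length(w) < 2L) return(NULL)
        cbind(w[-length(w)], w[-1L])
    })
    a <- do.call(rbind, pairs)
    if (is.null(a)) return(matrix(integer(), 0L, 2L))
    unique(a)
}

#' Build the variation graph of an exact cover
#'
#' One node per cover block, labeled by the block's gapped label; the walk
#' of row r visits r's blocks in column order; arcs connect blocks on
#' consecutive columns (e1 = b2 - 1) sharing at least one row, which is
#' exactly the set of pairs consecutive on some walk. Node ids are assigned
#' by sorting blocks on (start, end, smallest row).
#'
#' @param msa an [MSA].
#' @param cover a [BlockCover] (or list of [Block]s) that exactly covers
#'   the whole alignment, forced vertical blocks included.
#' @return a [VariationGraph] whose labels may still contain indels.
#' @examples
#' cov <- solveMsaCover(runningExample(), "blocks", alpha = 2)
#' buildGraph(runningExample(), cov)
#' @export
buildGraph <- function(msa, cover) {
    blocks <- if (is(cover, "BlockCover")) cover@blocks else cover
    ok <- checkExactCover(msa, blocks)
    if (!isTRUE(ok)) stop("cover is not an exact cover of the MSA: ", ok)
    blocks <- sortBlocks(blocks)
    labels <- vapply(blocks, function(x) blockLabel(msa, x)$gapped,
                     character(1L))
    starts <- vapply(blocks, function(x) x@start, integer(1L))
    m <- nrow(msa)
    walks <- vector("list", m)
    for (i in seq_along(blocks))
        for (r in blocks[[i]]@rows)
            walks[[r]] <- c(walks[[r]], i)
    walks <- lapply(walks, function(w) w[order(starts[w])])
    new("VariationGraph", nodeIds = seq_along(blocks), labels = labels,
        arcs = arcsFromWalks(walks), walks = walks, walkIds = msa@ids)
}

#' Post-process a variation graph
#'
#' Three steps, in order: (1) nodes whose label is entirely indels are
#' removed, walks skip them and arcs are rewired so every walk stays a path
#' (chains of removed nodes rewire transitively); (2) indels are stripped
#' from the remaining labels; (3) every non-branching arc (u, v) with
#' outdegree(u) = 1, indegree(v) = 1, no walk ending at u and no walk
#' starting at v is collapsed into one node (labels concatenated, walks
#' spliced, smallest id kept), until none remains. Acyclicity and
#' losslessness are preserved.
#'
#' @param graph a [VariationGraph] from [buildGraph()].
#' @return a [VariationGraph] with indel-free, nonempty labels.
#' @export
postprocessGraph <- function(graph) {
    ids <- graph@nodeIds
    labels <- graph@labels
    walks <- graph@walks
    # (1) drop all-indel nodes
    allIndel <- ids[vapply(strsplit(labels, "", fixed = TRUE),
                           function(v) all(v == "-"), logical(1L))]
    if (length(allIndel)) {
        keep <- !(ids %in% allIndel)
        ids <- ids[keep]; labels <- labels[keep]
        walks <- lapply(walks, function(w) w[!(w %in% allIndel)])
    }
    # (2) strip indels from surviving labels
    labels <- gsub("-", "", labels, fixed = TRUE)
    # (3) unipath collapse
    repeat {
        arcs <- arcsFromWalks(walks)
        if (nrow(arcs) == 0L) break
        outdeg <- table(factor(arcs[, 1L], levels = ids))
        indeg <- table(factor(arcs[, 2L], levels = ids))
        wStart <- unique(vapply(walks, function(w) w[1L], integer(1L)))
        wEnd <- unique(vapply(walks, function(w) w[length(w)], integer(1L)))
        merged <- FALSE
        for (a in seq_len(nrow(arcs))) {
            u <- arcs[a, 1L]; v <- arcs[a, 2L]
            if (outdeg[as.character(u)] != 1L) next
            if (indeg[as.character(v)] != 1L) next
            if (u %in% wEnd || v %in% wStart) next
            newId <- min(u, v)
            iu <- match(u, ids); iv <- match(v, ids)
            labels[iu] <- paste0(labels[iu], labels[iv])
            ids[iu] <- newId
            ids <- ids[-iv]; labels <- labels[-iv]
            # each v is preceded by u and each u followed by v (the guards
            # ensure it), so splicing is: drop v, relabel u
            walks <- lapply(walks, function(w) {
                w <- w[w != v]
                w[w == u] <- newId
                w
            })
            merged <- TRUE
            break
        }
        if (!merged) break
    }
    walks <- lapply(walks, as.integer)
    new("VariationGraph", nodeIds = as.integer(ids), labels = labels,
        arcs = arcsFromWalks(walks), walks = walks,
        walkIds = graph@walkIds)
}

#' Node labels of a variation graph
#' @param graph a [VariationGraph].
#' @return character vector named by node id.
#' @export
graphLabels <- function(graph) stats::setNames(graph@labels, graph@nodeIds)

#' Arcs of a variation graph
#' @param graph a [VariationGraph].
#' @return 2-column integer matrix of (from, to) node ids.
#' @export
graphArcs <- function(graph) graph@arcs

#' Walks of a variation graph
#' @param graph a [VariationGraph].
#' @return list of integer node-id vectors, named by sequence id.
#' @export
graphWalks <- function(graph) stats::setNames(graph@walks, graph@walkIds)

#' String spelled by one walk
#'
#' Concatenates the labels along walk \code{i} and deletes indels; for a
#' graph built from an exact cover this equals the ungapped input sequence
#' of row \code{i}, before and after post-processing.
#'
#' @param graph a [VariationGraph].
#' @param i walk index (input row index).
#' @return character scalar.
#' @export
walkLabel <- function(graph, i) {
    lab <- graph@labels[match(graph@walks[[i]], graph@nodeIds)]
    gsub("-", "", paste(lab, collapse = ""), fixed = TRUE)
}

#' Is a variation graph acyclic?
#'
#' Kahn's algorithm on the arc set.
#'
#' @param graph a [VariationGraph].
#' @return logical scalar.
#' @export
isAcyclicGraph <- function(graph) {
    ids <- graph@nodeIds
    arcs <- graph@arcs
    indeg <- stats::setNames(integer(length(ids)), ids)
    if (nrow(arcs)) {
        t <- table(arcs[, 2L])
        indeg[names(t)] <- as.integer(t)
    }
    queue <- ids[indeg == 0L]
    seen <- 0L
    while (length(queue)) {
        v <- queue[1L]; queue <- queue[-1L]
        seen <- seen + 1L
        if (nrow(arcs)) {
            succ <- arcs[arcs[, 1L] == v, 2L]
            for (s in succ) {
                key <- as.character(s)
                indeg[key] <- indeg[key] - 1L
                if (indeg[key] == 0L) queue <- c(queue, s)
            }
        }
    }
    seen == length(ids)
}
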