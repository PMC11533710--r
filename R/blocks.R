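# Block algebra: construction, labels, overlap, maximality, enumeration.
# The indel '-' (and N) are ordinary characters for everything in this file;
# gaps only disappear in ungapped labels and later in graph post-processing.

blockKey <- function(block) {
    paste0(block@start, ":", block@end, ":",
           paste(block@rows, collapse = ","))
}

dedupBlocks <- function(blocks) {
    if (length(blocks) == 0L) return(list())
    blocks[!duplicated(vapply(blocks, blockKey, character(1L)))]
}

sortBlocks <- function(blocks) {
    if (length(blocks) <= 1L) return(blocks)
    b <- vapply(blocks, function(x) x@start, integer(1L))
    e <- vapply(blocks, function(x) x@end, integer(1L))
    k <- vapply(blocks, function(x) x@rows[1L], integer(1L))
    nr <- vapply(blocks, function(x) length(x@rows), integer(1L))
    blocks[order(b, e, k, nr)]
}

newBlock <- function(rows, b, e)
    new("Block", rows = as.integer(sort.int(unique(as.integer(rows)))),
        start = as.integer(b), end = as.integer(e))

#' Do the rows of a candidate block agree on its interval?
#'
#' Checks the defining property of a block: every row of K spells the same
#' gapped string over [b, e].
#'
#' @param msa an [MSA].
#' @param block a [Block] (coordinates assumed in range for \code{msa}).
#' @return TRUE iff all rows agree on the interval.
#' @export
isBlockValid <- function(msa, block) {
    sub <- msa@chars[block@rows, block@start:block@end, drop = FALSE]
    if (nrow(sub) == 1L) return(TRUE)
    all(sub[rep(1L, nrow(sub) - 1L), , drop = FALSE] ==
        sub[-1L, , drop = FALSE])
}

#' Construct a block, checking row agreement against the MSA
#'
#' @param msa an [MSA].
#' @param K nonempty set of 1-based row indices.
#' @param b,e 1-based inclusive column interval.
#' @return a [Block].
#' @examples
#' makeBlock(runningExample(), c(2, 3, 4), 2, 9)
#' @export
makeBlock <- function(msa, K, b, e) {
    K <- as.integer(K); b <- as.integer(b); e <- as.integer(e)
    if (length(K) == 0L) stop("K must be nonempty")
    if (any(K < 1L) || any(K > nrow(msa))) stop("row index out of range")
    if (b < 1L || e > ncol(msa) || b > e) stop("column interval out of range")
    blk <- newBlock(K, b, e)
    if (!isBlockValid(msa, blk))
        stop("not a block: rows disagree on [", b, ", ", e, "]")
    blk
}

#' Label of a block
#'
#' The gapped label is the common string the block's rows spell on its
#' interval; the ungapped label removes indels and is what ends up as a
#' graph node label.
#'
#' @param msa an [MSA].
#' @param block a valid [Block].
#' @return list with \code{gapped}, \code{ungapped} and
#'   \code{ungappedLength} (which is at most \code{e - b + 1}).
#' @export
blockLabel <- function(msa, block) {
    v <- msa@chars[block@rows[1L], block@start:block@end]
    ung <- v[v != "-"]
    list(gapped = paste(v, collapse = ""),
         ungapped = paste(ung, collapse = ""),
         ungappedLength = length(ung))
}

#' Do two blocks overlap?
#'
#' Blocks overlap iff they share at least one MSA cell: their row sets
#' intersect and their column intervals intersect.
#'
#' @param b1,b2 [Block]s of the same MSA.
#' @return logical scalar.
#' @export
blocksOverlap <- function(b1, b2) {
    if (b1@start > b2@end || b2@start > b1@end) return(FALSE)
    length(intersect(b1@rows, b2@rows)) > 0L
}

#' Test the three maximality conditions of a block
#'
#' A block (K, b, e) is maximal iff (i) no row outside K spells the block's
#' label on [b, e] (row-maximality), (ii) b = 1 or two rows of K differ at
#' column b - 1 (left-maximality), and (iii) e = n or two rows of K differ
#' at column e + 1 (right-maximality).
#'
#' @param msa an [MSA].
#' @param block a valid [Block].
#' @return logical scalar.
#' @export
isMaximalBlock <- function(msa, block) {
    ch <- msa@chars
    K <- block@rows; b <- block@start; e <- block@end
    out <- setdiff(seq_len(nrow(ch)), K)
    if (length(out)) {
        lab <- ch[K[1L], b:e]
        for (h in out)
            if (all(ch[h, b:e] == lab)) return(FALSE)
    }
    if (b > 1L && length(unique(ch[K, b - 1L])) == 1L) return(FALSE)
    if (e < ncol(ch) && length(unique(ch[K, e + 1L])) == 1L) return(FALSE)
    TRUE
}

# split each class of row indices by the characters of one column
refineClasses <- function(classes, colChars) {
    out <- vector("list", 0L)
    for (cl in classes) {
        if (length(cl) == 1L) { out[[length(out) + 1L]] <- cl; next }
        pieces <- split(cl, colChars[cl])
        for (p in pieces) out[[length(out) + 1L]] <- p
    }
    out
}

#' Enumerate all maximal blocks of an MSA
#'
#' Column-sweep enumeration: for each start column b the rows are
#' partitioned by the string read since b (partition refinement column by
#' column); each class is a row-maximal block by construction, and it is
#' reported when it is also left- and right-maximal. '-' and N are treated
#' exactly like A, C, G, T.
#'
#' @param msa an [MSA].
#' @param minRows report only blocks with at least this many rows (1 or 2;
#'   default 2 — one-row maximal blocks are whole-genome vertices and are
#'   discarded by the pipeline).
#' @param from,to restrict the sweep to a global column window; reported
#'   blocks use global coordinates and lie entirely inside the window.
#' @return list of [Block]s, sorted by (start, end, smallest row).
#' @examples
#' enumerateMaximalBlocks(runningExample())
#' @export
enumerateMaximalBlocks <- function(msa, minRows = 2L, from = 1L,
                                   to = ncol(msa)) {
    stopifnot(minRows %in% c(1L, 2L), from >= 1L, to <= ncol(msa), from <= to)
    ch <- msa@chars
    m <- nrow(ch)
    res <- list()
    # a window [from, to] is treated as a subMSA in its own right: columns
    # outside it are never consulted, so maximality is relative to the window
    for (b in from:to) {
        classes <- list(seq_len(m))
        for (e in b:to) {
            classes <- refineClasses(classes, ch[, e])
            for (K in classes) {
                if (length(K) < minRows) next
                # left-maximality: window start, or K not constant at b-1
                if (b > from && length(unique(ch[K, b - 1L])) == 1L) next
                # right-maximality: window end, or K splits at e+1
                if (e < to && length(unique(ch[K, e + 1L])) == 1L) next
                res[[length(res) + 1L]] <- newBlock(K, b, e)
            }
            # once every class is a single row, larger e can only yield
            # one-row blocks ending exactly at the window end
            if (minRows >= 2L && all(lengths(classes) == 1L)) break
        }
    }
    sortBlocks(res)
}

#' Brute-force maximal-block enumeration (testing oracle)
#'
#' Exhausts every column interval, computes the row-equivalence classes on
#' it by direct string comparison, and keeps the classes that pass
#' [isMaximalBlock()]. Guarded to small inputs.
#'
#' @param msa an [MSA] with \code{m * n <= 200}.
#' @param minRows minimum number of rows (1 or 2).
#' @return list of [Block]s, sorted by (start, end, smallest row).
#' @export
bruteForceMaximalBlocks <- function(msa, minRows = 2L) {
    m <- nrow(msa); n <- ncol(msa)
    if (m * n > 200L) stop("instance too large for brute force (m*n > 200)")
    res <- list()
    for (b in seq_len(n)) for (e in b:n) {
        slices <- apply(msa@chars[, b:e, drop = FALSE], 1L, paste,
                        collapse = "")
        for (K in split(seq_len(m), slices)) {
            if (length(K) < minRows) next
            blk <- newBlock(K, b, e)
            if (isMaximalBlock(msa, blk))
                res[[length(res) + 1L]] <- blk
        }
    }
    sortBlocks(res)
}

#' Dump blocks as a tab-separated table
#'
#' Columns \code{b e rows label} (rows comma-joined, 1-based); an optional
#' \code{origin} column records where each block came from.
#'
#' @param msa an [MSA].
#' @param blocks list of [Block]s.
#' @param path output path, or NULL to return the data frame.
#' @param origin optional character vector parallel to \code{blocks}.
#' @return the data frame, invisibly when written to \code{path}.
#' @export
blocksToTable <- function(msa, blocks, path = NULL, origin = NULL) {
    df <- data.frame(
        b = vapply(blocks, function(x) x@start, integer(1L)),
        e = vapply(blocks, function(x) x@end, integer(1L)),
        rows = vapply(blocks, function(x) paste(x@rows, collapse = ","),
                      character(1L)),
        label = vapply(blocks, function(x) blockLabel(msa, x)$gapped,
                       character(1L)))
    if (!is.null(origin)) df$origin <- origin
    if (is.null(path)) return(df)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(df)
}
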