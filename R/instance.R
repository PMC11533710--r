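# Assembling solver instances: forced vertical blocks, window splitting,
# and completion of the candidate set with one-row and one-character
# fallback blocks (which by themselves always form an exact cover, so every
# instance is feasible by construction).

#' Find maximal vertical blocks of at least alpha columns
#'
#' A vertical block spans all m rows; its columns are exactly the columns
#' where all rows carry the same character. Maximal runs of such columns of
#' length >= alpha are returned; they are forced into the final cover and
#' delimit the independently solved windows.
#'
#' @param msa an [MSA].
#' @param alpha minimum number of columns (>= 1), or \code{"disabled"} /
#'   \code{NA} to force nothing (equivalent to \code{alpha = ncol(msa)+1}).
#' @return list of [Block]s with the full row set, pairwise non-overlapping.
#' @examples
#' findVerticalBlocks(runningExample(), alpha = 2)
#' @export
findVerticalBlocks <- function(msa, alpha) {
    if (identical(alpha, "disabled") || is.na(alpha)) return(list())
    alpha <- as.integer(alpha)
    stopifnot(alpha >= 1L)
    ch <- msa@chars
    const <- apply(ch, 2L, function(col) all(col == col[1L]))
    out <- list()
    r <- rle(const)
    pos <- cumsum(c(1L, r$lengths))
    for (i in seq_along(r$values)) {
        if (r$values[i] && r$lengths[i] >= alpha)
            out[[length(out) + 1L]] <-
                newBlock(seq_len(nrow(ch)), pos[i], pos[i] + r$lengths[i] - 1L)
    }
    out
}

#' Partition the columns into forced and free windows
#'
#' @param msa an [MSA].
#' @param forced list of non-overlapping vertical [Block]s (see
#'   [findVerticalBlocks()]).
#' @return data frame with columns \code{start}, \code{end}, \code{role}
#'   ("forced-vertical" or "free"), ordered left to right, tiling
#'   \code{[1, ncol(msa)]}; zero-width free windows are omitted.
#' @export
splitByVertical <- function(msa, forced) {
    n <- ncol(msa)
    if (length(forced) == 0L)
        return(data.frame(start = 1L, end = n, role = "free"))
    fb <- vapply(forced, function(x) x@start, integer(1L))
    fe <- vapply(forced, function(x) x@end, integer(1L))
    o <- order(fb)
    fb <- fb[o]; fe <- fe[o]
    start <- integer(); end <- integer(); role <- character()
    cur <- 1L
    for (i in seq_along(fb)) {
        if (cur < fb[i]) {
            start <- c(start, cur); end <- c(end, fb[i] - 1L)
            role <- c(role, "free")
        }
        start <- c(start, fb[i]); end <- c(end, fe[i])
        role <- c(role, "forced-vertical")
        cur <- fe[i] + 1L
    }
    if (cur <= n) {
        start <- c(start, cur); end <- c(end, n); role <- c(role, "free")
    }
    data.frame(start = start, end = end, role = role)
}

#' Width of the widest free window at a given alpha
#'
#' @param msa an [MSA].
#' @param alpha vertical-block length threshold (or \code{"disabled"}).
#' @return integer; 0 when the forced blocks tile the whole alignment.
#' @export
longestFreeWindow <- function(msa, alpha) {
    w <- splitByVertical(msa, findVerticalBlocks(msa, alpha))
    free <- w[w$role == "free", , drop = FALSE]
    if (nrow(free) == 0L) return(0L)
    max(free$end - free$start + 1L)
}

#' Breakpoints of alpha
#'
#' The values of alpha at which [longestFreeWindow()] changes, with the new
#' value — the step function that guides the choice of alpha: larger alpha
#' forces fewer vertical blocks, so the widest window that must be solved
#' as one exact-cover instance grows.
#'
#' @param msa an [MSA].
#' @return data frame with columns \code{alpha} and
#'   \code{longest_free_window}, non-decreasing in both.
#' @export
alphaBreakpoints <- function(msa) {
    vb <- findVerticalBlocks(msa, 1L)
    lens <- sort(unique(vapply(vb, function(x) x@end - x@start + 1L,
                               integer(1L))))
    cand <- sort(unique(c(1L, lens + 1L)))
    vals <- vapply(cand, function(a) as.integer(longestFreeWindow(msa, a)),
                   integer(1L))
    keep <- c(TRUE, diff(vals) != 0L)
    data.frame(alpha = cand[keep], longest_free_window = vals[keep])
}

# rows carrying each distinct character of one column -> one-character blocks
oneCharBlocksForColumn <- function(ch, col) {
    unname(lapply(split(seq_len(nrow(ch)), ch[, col]),
                  function(K) newBlock(K, col, col)))
}

#' Complete a candidate set with one-row and one-character blocks
#'
#' Guarantees feasibility of the exact-cover instance: one-row blocks
#' \code{({r}, b, e)} are added for every maximal interval of row r (within
#' the window) not covered by any maximal block of at least two rows, and
#' one-character blocks \code{(K_sigma, b, b)} for every column b and every
#' character sigma occurring there (indel included; at most 6 per column).
#' The one-character blocks alone partition every column, so the completed
#' set always contains an exact cover.
#'
#' @param msa an [MSA].
#' @param candidates list of [Block]s (maximal blocks and decomposition
#'   products).
#' @param maximal the maximal blocks with >= 2 rows that coverage is judged
#'   against; defaults to the members of \code{candidates} with >= 2 rows
#'   that pass [isMaximalBlock()].
#' @param from,to column window (defaults: whole alignment).
#' @return deduplicated, sorted list of [Block]s.
#' @export
addShortBlocks <- function(msa, candidates, maximal = NULL,
                           from = 1L, to = ncol(msa)) {
    ch <- msa@chars
    m <- nrow(ch)
    if (is.null(maximal))
        maximal <- Filter(function(x) length(x@rows) >= 2L &&
                                      isMaximalBlock(msa, x), candidates)
    covered <- matrix(FALSE, m, to - from + 1L)
    for (blk in maximal)
        covered[blk@rows, (blk@start:blk@end) - from + 1L] <- TRUE
    out <- candidates
    for (r in seq_len(m)) {
        runs <- rle(!covered[r, ])
        pos <- cumsum(c(from, runs$lengths))
        for (i in seq_along(runs$values))
            if (runs$values[i])
                out[[length(out) + 1L]] <-
                    newBlock(r, pos[i], pos[i] + runs$lengths[i] - 1L)
    }
    for (col in from:to)
        out <- c(out, oneCharBlocksForColumn(ch, col))
    sortBlocks(dedupBlocks(out))
}

#' Build the exact-cover instances of an alignment
#'
#' The full instance-construction pipeline: vertical blocks of at least
#' \code{alpha} columns are forced and split the alignment into free
#' windows; independently in each window, maximal blocks are enumerated
#' (one-row maximal blocks are discarded), every overlapping pair is
#' decomposed under \code{strategy}, and the set is completed with one-row
#' and one-character blocks.
#'
#' @param msa an [MSA].
#' @param alpha vertical-block threshold, or \code{"disabled"} (no forced
#'   blocks, a single window).
#' @param strategy \code{"row-maximal"} or \code{"complete"}.
#' @param minRows minimum rows for enumerated maximal blocks (default 2;
#'   with 1, one-row maximal blocks are still discarded by policy before
#'   completion).
#' @return list with \code{instances} (list of [MWBCInstance], one per free
#'   window), \code{forced} (list of forced vertical [Block]s) and
#'   \code{windows} (the [splitByVertical()] table).
#' @examples
#' buildInstances(runningExample(), alpha = 2)
#' @export
buildInstances <- function(msa, alpha = "disabled",
                           strategy = c("row-maximal", "complete"),
                           minRows = 2L) {
    strategy <- match.arg(strategy)
    forced <- findVerticalBlocks(msa, alpha)
    windows <- splitByVertical(msa, forced)
    free <- windows[windows$role == "free", , drop = FALSE]
    instances <- vector("list", nrow(free))
    for (i in seq_len(nrow(free))) {
        from <- free$start[i]; to <- free$end[i]
        maximal <- enumerateMaximalBlocks(msa, minRows = minRows,
                                          from = from, to = to)
        maximal <- Filter(function(x) length(x@rows) >= 2L, maximal)
        cands <- decomposeAll(msa, maximal, strategy)
        cands <- addShortBlocks(msa, cands, maximal = maximal,
                                from = from, to = to)
        instances[[i]] <- new("MWBCInstance", msa = msa,
                              windowStart = as.integer(from),
                              windowEnd = as.integer(to),
                              candidates = cands)
    }
    list(instances = instances, forced = forced, windows = windows)
}
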