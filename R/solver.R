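#' @useDynLib blockgraph, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Construct an objective specification
#'
#' @param name one of \code{"blocks"}, \code{"weighted"}, \code{"depth"},
#'   \code{"strings"}, \code{"pstrings"}.
#' @param q label-length threshold of the weighted objective.
#' @param delta penalty for short / shallow blocks (> 1).
#' @param p coverage fraction of the depth objective.
#' @param depthMinCount optional absolute row-count threshold for the depth
#'   objective (replaces \code{floor(p * m)}).
#' @return an [ObjectiveSpec].
#' @examples
#' objectiveSpec("weighted", q = 20, delta = 1000)
#' @export
objectiveSpec <- function(name = c("blocks", "weighted", "depth", "strings",
                                   "pstrings"),
                          q = 20, delta = 1000, p = 0.11,
                          depthMinCount = NA_real_) {
    name <- match.arg(name)
    new("ObjectiveSpec", name = name, q = as.numeric(q),
        delta = as.numeric(delta), p = as.numeric(p),
        depthMinCount = as.numeric(depthMinCount))
}

asObjective <- function(obj) {
    if (is(obj, "ObjectiveSpec")) obj else objectiveSpec(obj)
}

#' Cost coefficient of one block under an objective
#'
#' \code{blocks}: 1. \code{weighted}: \code{delta} if the ungapped label
#' length is at most \code{q}, else 1. \code{depth}: \code{delta} if the
#' block has at most \code{floor(p * m)} rows (or at most
#' \code{depthMinCount}), else 1. \code{strings}: ungapped label length.
#' \code{pstrings}: ungapped label length divided by the number of rows.
#'
#' @param msa an [MSA].
#' @param block a [Block].
#' @param objective an [ObjectiveSpec] or objective name.
#' @return numeric cost.
#' @export
blockCost <- function(msa, block, objective = "blocks") {
    obj <- asObjective(objective)
    gamma <- blockLabel(msa, block)$ungappedLength
    nr <- length(block@rows)
    switch(obj@name,
        blocks = 1,
        weighted = if (gamma <= obj@q) obj@delta else 1,
        depth = {
            thr <- if (is.na(obj@depthMinCount)) floor(obj@p * nrow(msa))
                   else obj@depthMinCount
            if (nr <= thr) obj@delta else 1
        },
        strings = as.numeric(gamma),
        pstrings = gamma / nr)
}

blockCosts <- function(msa, blocks, objective)
    unname(vapply(blocks, blockCost, numeric(1L), msa = msa,
                  objective = objective))

# 1-based cell indices of a block inside a column window
blockCells <- function(block, from, m) {
    cols <- block@start:block@end
    as.integer(outer(block@rows, (cols - from) * m, `+`))
}

#' Check that a set of blocks is an exact cover of a region
#'
#' Every cell (row, column) of the region must be covered by exactly one
#' block; equivalently the blocks are pairwise non-overlapping and cover
#' everything.
#'
#' @param msa an [MSA].
#' @param blocks list of [Block]s.
#' @param from,to column window (defaults: whole alignment).
#' @return TRUE, or a character message describing the first violation.
#' @export
checkExactCover <- function(msa, blocks, from = 1L, to = ncol(msa)) {
    m <- nrow(msa)
    counts <- integer(m * (to - from + 1L))
    for (blk in blocks) {
        if (blk@start < from || blk@end > to)
            return(sprintf("block %s outside window [%d, %d]",
                           blockKey(blk), from, to))
        idx <- blockCells(blk, from, m)
        counts[idx] <- counts[idx] + 1L
    }
    if (any(counts == 0L)) return("uncovered cell(s)")
    if (any(counts > 1L)) return("cell(s) covered more than once")
    TRUE
}

#' Solve one exact-cover instance to optimality
#'
#' Minimum-weight exact cover over the instance's candidate blocks, by the
#' package's exact branch-and-bound solver. The returned cover is verified
#' cell-by-cell and its objective value is recomputed independently of the
#' solver's bookkeeping; a disagreement beyond 1e-6 is an internal error.
#' The result is deterministic for a fixed instance and objective;
#' \code{solverSeed} is accepted for interface stability but the default
#' backend does not use randomness.
#'
#' @param instance an [MWBCInstance] from [buildInstances()].
#' @param objective an [ObjectiveSpec] or objective name.
#' @param timeLimit seconds before the branch-and-bound engine returns its
#'   best incumbent flagged non-optimal (the DP engine is exact and fast
#'   or gives up to the fallback; it ignores the limit).
#' @param solverSeed unused by the deterministic default backends.
#' @param engine \code{"auto"} (frontier DP when applicable, else
#'   branch-and-bound), or force \code{"dp"} / \code{"bb"}.
#' @return a [BlockCover] (blocks in global MSA coordinates).
#' @export
solveInstance <- function(instance, objective = "blocks", timeLimit = 600,
                          solverSeed = 0L,
                          engine = c("auto", "dp", "bb")) {
    engine <- match.arg(engine)
    obj <- asObjective(objective)
    msa <- instance@msa
    m <- nrow(msa)
    from <- instance@windowStart; to <- instance@windowEnd
    cand <- instance@candidates
    if (length(cand) == 0L) stop("instance has no candidate blocks")
    costs <- blockCosts(msa, cand, obj)
    res <- NULL
    if (engine == "dp" && m > 30L)
        stop("the DP engine supports at most 30 rows")
    if (engine != "bb" && m <= 30L) {
        # frontier DP over columns: exact and fast when the number of
        # distinct crossing-block frontiers stays moderate
        masks <- vapply(cand, function(x)
            as.integer(sum(bitwShiftL(1L, x@rows - 1L))), integer(1L))
        dp <- .frontierExactCover(masks,
                                  vapply(cand, function(x) x@start,
                                         integer(1L)) - from + 1L,
                                  vapply(cand, function(x) x@end,
                                         integer(1L)) - from + 1L,
                                  costs, m, to - from + 1L, 2e6)
        if (isTRUE(dp$ok)) res <- dp
        else if (engine == "dp")
            stop("the DP engine exceeded its state cap on this instance")
    }
    if (is.null(res)) {
        # branch-and-bound fallback (m > 30, or DP state cap exceeded);
        # the one-character blocks form a feasible cover and are handed to
        # the solver as a warm start, so a time-limited run still returns
        # a valid cover
        cells <- lapply(cand, blockCells, from = from, m = m)
        keyOf <- vapply(cand, blockKey, character(1L))
        warm <- integer()
        for (col in from:to) {
            oc <- oneCharBlocksForColumn(msa@chars, col)
            idx <- match(vapply(oc, blockKey, character(1L)), keyOf)
            if (anyNA(idx)) { warm <- integer(); break }  # instance not
                                                          # pipeline-built
            warm <- c(warm, idx)
        }
        res <- .bbExactCover(cells, costs, m * (to - from + 1L),
                             as.numeric(timeLimit), warm)
    }
    blocks <- cand[res$selected]
    ok <- checkExactCover(msa, blocks, from, to)
    if (!isTRUE(ok)) stop("internal error: solver returned a non-cover: ", ok)
    value <- sum(blockCosts(msa, blocks, obj))
    if (abs(value - res$value) > 1e-6)
        stop("internal error: objective value mismatch (",
             value, " vs ", res$value, ")")
    new("BlockCover", blocks = sortBlocks(blocks), objectiveValue = value,
        optimal = isTRUE(res$optimal))
}

# plain depth-first enumeration of every exact cover over a candidate list;
# independent of the C++ solver (used as its oracle on tiny instances)
exhaustiveMinCover <- function(msa, cand, obj, from, to) {
    m <- nrow(msa)
    nCells <- m * (to - from + 1L)
    cells <- lapply(cand, blockCells, from = from, m = m)
    costs <- blockCosts(msa, cand, obj)
    byCell <- vector("list", nCells)
    for (j in seq_along(cand))
        for (c in cells[[j]])
            byCell[[c]] <- c(byCell[[c]], j)
    best <- Inf; bestSel <- NULL
    covered <- logical(nCells)
    rec <- function(sel, cost) {
        cell <- which(!covered)[1L]
        if (is.na(cell)) {
            if (cost < best) { best <<- cost; bestSel <<- sel }
            return(invisible())
        }
        for (j in byCell[[cell]]) {
            cc <- cells[[j]]
            if (any(covered[cc])) next
            covered[cc] <<- TRUE
            rec(c(sel, j), cost + costs[j])
            covered[cc] <<- FALSE
        }
    }
    rec(integer(), 0)
    if (!is.finite(best)) return(NULL)
    new("BlockCover", blocks = sortBlocks(cand[bestSel]),
        objectiveValue = best, optimal = TRUE)
}

#' Exhaustive exact-cover oracle for tiny instances
#'
#' Enumerates every exact cover constructible from the instance's
#' candidates by depth-first search over cells and returns a cheapest one.
#' Guarded to windows of at most 30 cells; used as the independent check of
#' [solveInstance()].
#'
#' @inheritParams solveInstance
#' @return a [BlockCover], or NULL if no exact cover exists.
#' @export
solveExhaustive <- function(instance, objective = "blocks") {
    m <- nrow(instance@msa)
    w <- instance@windowEnd - instance@windowStart + 1L
    if (m * w > 30L) stop("instance too large for exhaustive search (> 30 cells)")
    exhaustiveMinCover(instance@msa, instance@candidates,
                       asObjective(objective),
                       instance@windowStart, instance@windowEnd)
}

# all blocks of an MSA: every interval, every nonempty subset of every
# row-agreement class
enumerateAllBlocks <- function(msa) {
    m <- nrow(msa); n <- ncol(msa)
    res <- list()
    for (b in seq_len(n)) for (e in b:n) {
        slices <- apply(msa@chars[, b:e, drop = FALSE], 1L, paste,
                        collapse = "")
        for (K in split(seq_len(m), slices)) {
            for (sz in seq_along(K)) {
                combs <- utils::combn(K, sz, simplify = FALSE)
                for (s in combs)
                    res[[length(res) + 1L]] <- newBlock(s, b, e)
            }
        }
    }
    sortBlocks(res)
}

#' Global optimum over all blocks (tiny-instance oracle)
#'
#' Solves the unrestricted problem: the candidate set is every block of the
#' MSA, enumerated exhaustively, and the minimum is found by exhaustive
#' search. By definition the optimum is at most the optimum of any
#' restricted candidate set. Guarded to at most 20 cells.
#'
#' @param msa an [MSA] with \code{m * n <= 20}.
#' @param objective an [ObjectiveSpec] or objective name.
#' @return a [BlockCover].
#' @export
solveGmwbcOracle <- function(msa, objective = "blocks") {
    if (nrow(msa) * ncol(msa) > 20L)
        stop("instance too large for the G-MWBC oracle (> 20 cells)")
    exhaustiveMinCover(msa, enumerateAllBlocks(msa), asObjective(objective),
                       1L, ncol(msa))
}

#' Solve an MSA end-to-end into a global exact cover
#'
#' Builds the instances ([buildInstances()]), solves every free window
#' independently, and merges the window covers with the forced vertical
#' blocks into one global exact cover of the alignment. The reported
#' objective value is the objective evaluated over all blocks of the global
#' cover (forced blocks included).
#'
#' @param msa an [MSA].
#' @param objective an [ObjectiveSpec] or objective name.
#' @param alpha vertical-block threshold or \code{"disabled"}.
#' @param strategy decomposition strategy.
#' @param timeLimit per-window solver time limit in seconds.
#' @param solverSeed forwarded to [solveInstance()].
#' @return a [BlockCover] covering the whole alignment.
#' @examples
#' solveMsaCover(runningExample(), "blocks", alpha = 2)
#' @export
solveMsaCover <- function(msa, objective = "blocks", alpha = "disabled",
                          strategy = c("row-maximal", "complete"),
                          timeLimit = 600, solverSeed = 0L) {
    strategy <- match.arg(strategy)
    obj <- asObjective(objective)
    built <- buildInstances(msa, alpha = alpha, strategy = strategy)
    covers <- lapply(built$instances, solveInstance, objective = obj,
                     timeLimit = timeLimit, solverSeed = solverSeed)
    blocks <- c(built$forced, unlist(lapply(covers, function(x) x@blocks)))
    ok <- checkExactCover(msa, blocks)
    if (!isTRUE(ok)) stop("internal error: merged cover invalid: ", ok)
    new("BlockCover", blocks = sortBlocks(blocks),
        objectiveValue = sum(blockCosts(msa, blocks, obj)),
        optimal = all(vapply(covers, function(x) x@optimal, logical(1L))))
}

#' Blocks of a cover
#' @param cover a [BlockCover].
#' @return list of [Block]s.
#' @export
coverBlocks <- function(cover) cover@blocks

#' Objective value of a cover
#' @param cover a [BlockCover].
#' @return numeric scalar.
#' @export
objectiveValue <- function(cover) cover@objectiveValue
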