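# Test data: the fixed 5 x 9 running example and a synthetic-MSA generator
# with planted block structure.

#' The 5 x 9 example alignment
#'
#' A small fixed alignment of five short sequences (AACCGA, AAACGAT,
#' GAACGAT, CAACGAT, AATCCGGAA) used throughout the documentation and
#' tests. Notable structure: ({1,2,5},1,2), ({2,3,4},2,9) and
#' ({1,2,3,4,5},7,8) are maximal blocks, the first two pairs overlap, and
#' columns 7-8 form a vertical block (all rows identical).
#'
#' @return an [MSA] with rows \code{AA--CCGA-}, \code{AA-AC-GAT},
#'   \code{GA-AC-GAT}, \code{CA-AC-GAT}, \code{AATCCGGAA}.
#' @examples
#' runningExample()
#' @export
runningExample <- function() {
    msaFromStrings(c("AA--CCGA-", "AA-AC-GAT", "GA-AC-GAT", "CA-AC-GAT",
                     "AATCCGGAA"),
                   ids = c("circle", "square", "diamond", "triangle",
                           "nabla"))
}

#' Parameters of the synthetic-MSA generator
#'
#' @param m number of rows (>= 2).
#' @param coreLength alignment length before mutation (columns).
#' @param substitutionRate per-cell substitution probability.
#' @param indelRate per-cell probability of starting a deletion gap.
#' @param indelMaxLen maximum gap length (columns).
#' @param sharedSegments list of \code{list(rows=, start=, end=)} intervals
#'   kept mutation-free in the given rows (alignment coordinates); use
#'   \code{rows = seq_len(m)} to plant a vertical block.
#' @param seed random seed; identical parameters and seed give an
#'   identical alignment.
#' @return a list of class \code{"blockgraphSimParams"}.
#' @export
simulationParams <- function(m = 6L, coreLength = 40L,
                             substitutionRate = 0.05, indelRate = 0.02,
                             indelMaxLen = 3L, sharedSegments = list(),
                             seed = 1L) {
    stopifnot(m >= 2L, coreLength >= 1L,
              substitutionRate >= 0, substitutionRate <= 1,
              indelRate >= 0, indelRate <= 1, indelMaxLen >= 1L)
    structure(list(m = as.integer(m), coreLength = as.integer(coreLength),
                   substitutionRate = substitutionRate,
                   indelRate = indelRate,
                   indelMaxLen = as.integer(indelMaxLen),
                   sharedSegments = sharedSegments,
                   seed = as.integer(seed)),
              class = "blockgraphSimParams")
}

withLocalSeed <- function(seed, expr) {
    hasOld <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (hasOld) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (hasOld) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    expr
}

#' Simulate an MSA with planted block structure
#'
#' Draws a random ancestor over \{A,C,G,T\} and derives each row by
#' per-cell substitutions and deletion gaps; gaps are planted directly as
#' alignment cells, so alignment coordinates are exact (no realignment) and
#' the planted \code{sharedSegments} are mutation-free in their rows — a
#' segment shared by all rows is recoverable as a vertical block.
#' Insertions are not modeled: every column of the alignment descends from
#' one ancestor position. Degenerate draws (an all-indel column or row) are
#' rejected and redrawn a bounded number of times.
#'
#' @param params a [simulationParams()] object.
#' @return an [MSA] passing strict validation.
#' @examples
#' simulateMsa(simulationParams(m = 4, coreLength = 20, seed = 7))
#' @export
simulateMsa <- function(params) {
    stopifnot(inherits(params, "blockgraphSimParams"))
    bases <- c("A", "C", "G", "T")
    n <- params$coreLength
    m <- params$m
    protected <- matrix(FALSE, m, n)
    for (seg in params$sharedSegments) {
        stopifnot(seg$start >= 1L, seg$end <= n, seg$start <= seg$end)
        protected[seg$rows, seg$start:seg$end] <- TRUE
    }
    withLocalSeed(params$seed, {
        for (attempt in 1:50) {
            ancestor <- sample(bases, n, replace = TRUE)
            ch <- matrix(rep(ancestor, each = m), m, n)
            for (r in seq_len(m)) {
                j <- 1L
                while (j <= n) {
                    if (!protected[r, j]) {
                        if (runif(1L) < params$indelRate) {
                            len <- sample.int(params$indelMaxLen, 1L)
                            stretch <- j:min(n, j + len - 1L)
                            stretch <- stretch[!protected[r, stretch]]
                            ch[r, stretch] <- "-"
                            j <- j + len
                            next
                        }
                        if (runif(1L) < params$substitutionRate)
                            ch[r, j] <- sample(setdiff(bases, ch[r, j]), 1L)
                    }
                    j <- j + 1L
                }
            }
            okCols <- all(colSums(ch != "-") > 0L)
            okRows <- all(rowSums(ch != "-") > 0L)
            if (okCols && okRows)
                return(msaFromStrings(apply(ch, 1L, paste, collapse = ""),
                                      ids = paste0("sim", seq_len(m)),
                                      strict = TRUE))
        }
        stop("degenerate parameters: could not draw a valid MSA in 50 attempts")
    })
}
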