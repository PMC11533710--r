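# Shared helpers: tiny random MSAs, block comparison, and the memoized
# synthetic battery used by the acceptance tests.

blockTriple <- function(b) list(rows = b@rows, start = b@start, end = b@end)

blockSetKeys <- function(blocks)
    sort(vapply(blocks, function(x)
        paste(x@start, x@end, paste(x@rows, collapse = ","), sep = ":"),
        character(1L)))

expectSameBlockSet <- function(got, want) {
    expect_identical(blockSetKeys(got), blockSetKeys(want))
}

# random small MSA over an arbitrary alphabet subset (gaps included),
# redrawn until strictly valid
randomSmallMsa <- function(m, n, seed, alphabet = c("A", "C", "-")) {
    set.seed(seed)
    repeat {
        ch <- matrix(sample(alphabet, m * n, replace = TRUE), m, n)
        ok <- all(colSums(ch != "-") > 0L) && all(rowSums(ch != "-") > 0L)
        if (ok)
            return(msaFromStrings(apply(ch, 1L, paste, collapse = "")))
    }
}

# ---- synthetic battery ------------------------------------------------
# 100 MSAs with m in 2..8 and n in 10..60, each assigned one
# (objective, decomposition, alpha) combination so that the grid
# {5 objectives} x {row-maximal, complete} x {alpha 1, 3, disabled} is
# cycled across the battery. Solved once and memoized; several acceptance
# criteria read different aspects of the same runs.

.batteryCache <- new.env(parent = emptyenv())

batterySpec <- function(nMsa = 100L) {
    objs <- c("blocks", "weighted", "depth", "strings", "pstrings")
    strats <- c("row-maximal", "complete")
    alphas <- list(1L, 3L, "disabled")
    lapply(seq_len(nMsa), function(i) {
        list(i = i,
             m = 2L + (i %% 7L),
             n = 10L + ((i * 7L) %% 51L),
             objective = objs[1L + (i %% 5L)],
             strategy = strats[1L + (i %% 2L)],
             alpha = alphas[[1L + (i %% 3L)]],
             seed = 20000L + i)
    })
}

batteryMsa <- function(spec)
    simulateMsa(simulationParams(m = spec$m, coreLength = spec$n,
                                 substitutionRate = 0.05,
                                 indelRate = 0.02, indelMaxLen = 3L,
                                 seed = spec$seed))

batteryRuns <- function() {
    if (!is.null(.batteryCache$runs)) return(.batteryCache$runs)
    runs <- lapply(batterySpec(), function(spec) {
        msa <- batteryMsa(spec)
        cover <- solveMsaCover(msa, spec$objective, alpha = spec$alpha,
                               strategy = spec$strategy, timeLimit = 60)
        graph <- buildGraph(msa, cover)
        post <- postprocessGraph(graph)
        list(spec = spec, msa = msa, cover = cover, graph = graph,
             post = post)
    })
    .batteryCache$runs <- runs
    runs
}
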