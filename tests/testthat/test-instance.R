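test_that("vertical blocks are the maximal all-rows-identical runs", {
    msa <- runningExample()
    # columns 2, 5 and 7-8 are constant across all five rows
    expectSameBlockSet(findVerticalBlocks(msa, 1),
                       list(makeBlock(msa, 1:5, 2, 2),
                            makeBlock(msa, 1:5, 5, 5),
                            makeBlock(msa, 1:5, 7, 8)))
    expectSameBlockSet(findVerticalBlocks(msa, 2),
                       list(makeBlock(msa, 1:5, 7, 8)))
    expect_length(findVerticalBlocks(msa, 3), 0L)
    expect_length(findVerticalBlocks(msa, "disabled"), 0L)

    same <- msaFromStrings(c("ACGT", "ACGT", "ACGT"))
    expectSameBlockSet(findVerticalBlocks(same, 1),
                       list(makeBlock(same, 1:3, 1, 4)))
})

test_that("window splitting tiles the columns without gaps or overlap", {
    msa <- runningExample()
    w <- splitByVertical(msa, findVerticalBlocks(msa, 2))
    expect_identical(w$start, c(1L, 7L, 9L))
    expect_identical(w$end, c(6L, 8L, 9L))
    expect_identical(w$role, c("free", "forced-vertical", "free"))

    w0 <- splitByVertical(msa, list())
    expect_identical(w0, data.frame(start = 1L, end = 9L, role = "free"))

    same <- msaFromStrings(c("ACGT", "ACGT"))
    wf <- splitByVertical(same, findVerticalBlocks(same, 1))
    expect_identical(wf$role, "forced-vertical")

    for (s in 1:10) {
        rmsa <- batteryMsa(list(m = 2 + s %% 4, n = 15 + s, seed = 800 + s))
        for (a in c(1, 2, 4)) {
            wr <- splitByVertical(rmsa, findVerticalBlocks(rmsa, a))
            expect_identical(wr$start[1L], 1L)
            expect_identical(wr$end[nrow(wr)], ncol(rmsa))
            if (nrow(wr) > 1L)
                expect_identical(wr$start[-1L], wr$end[-nrow(wr)] + 1L)
        }
    }
})

test_that("the longest free window steps up with alpha", {
    msa <- runningExample()
    # forced runs have lengths 1, 1 and 2, hence the window widths
    expect_identical(longestFreeWindow(msa, 1), 2L)
    expect_identical(longestFreeWindow(msa, 2), 6L)
    expect_identical(longestFreeWindow(msa, 3), 9L)
    bp <- alphaBreakpoints(msa)
    expect_identical(bp$alpha, c(1L, 2L, 3L))
    expect_identical(bp$longest_free_window, c(2L, 6L, 9L))

    # no vertical column at all: a single step at alpha = 1
    nov <- msaFromStrings(c("ACGT", "TGCA"))
    expect_identical(alphaBreakpoints(nov),
                     data.frame(alpha = 1L, longest_free_window = 4L))

    # identical rows: fully forced until alpha exceeds n
    same <- msaFromStrings(c("ACGTA", "ACGTA"))
    expect_identical(alphaBreakpoints(same),
                     data.frame(alpha = c(1L, 6L),
                                longest_free_window = c(0L, 5L)))
})

test_that("longestFreeWindow is non-decreasing and breakpoints match a sweep", {
    for (s in 1:20) {
        msa <- batteryMsa(list(m = 2 + s %% 5, n = 12 + s, seed = 900 + s))
        n <- ncol(msa)
        vals <- vapply(1:(n + 1L), function(a)
            as.integer(longestFreeWindow(msa, a)), integer(1L))
        expect_true(all(diff(vals) >= 0L))
        # reconstruct the full step function from the breakpoint table
        bp <- alphaBreakpoints(msa)
        stepFn <- vapply(1:(n + 1L), function(a) {
            i <- findInterval(a, bp$alpha)
            if (i == 0L) 0L else bp$longest_free_window[i]
        }, integer(1L))
        expect_identical(stepFn, vals)
    }
})

test_that("one-character blocks partition each column", {
    msa <- runningExample()
    got <- addShortBlocks(msa, list(), maximal = list())
    oneChar <- Filter(function(b) b@start == b@end, got)
    col1 <- Filter(function(b) b@start == 1L, oneChar)
    expectSameBlockSet(col1, list(makeBlock(msa, c(1, 2, 5), 1, 1),
                                  makeBlock(msa, 3, 1, 1),
                                  makeBlock(msa, 4, 1, 1)))
    # a constant column yields exactly one block with all rows
    col7 <- Filter(function(b) b@start == 7L && b@end == 7L, oneChar)
    expectSameBlockSet(col7, list(makeBlock(msa, 1:5, 7, 7)))
    # per column: at most 6 blocks, and they partition the rows
    for (col in seq_len(ncol(msa))) {
        cb <- Filter(function(b) b@start == col && b@end == col, oneChar)
        expect_lte(length(cb), 6L)
        expect_identical(sort(unlist(lapply(cb, function(b) b@rows))),
                         seq_len(nrow(msa)))
    }
    # ... so the one-character blocks alone are an exact cover
    expect_true(isTRUE(checkExactCover(msa, oneChar)))
})

test_that("one-row blocks fill exactly what >=2-row maximal blocks miss", {
    msa <- runningExample()
    maximal <- enumerateMaximalBlocks(msa, minRows = 2)
    got <- addShortBlocks(msa, maximal, maximal = maximal)
    oneRow <- Filter(function(b) length(b@rows) == 1L && b@start < b@end,
                     got)
    covered <- matrix(FALSE, nrow(msa), ncol(msa))
    for (b in maximal) covered[b@rows, b@start:b@end] <- TRUE
    for (b in oneRow) {
        expect_true(all(!covered[b@rows, b@start:b@end]))
        # maximality of the uncovered interval: flanks covered or at ends
        if (b@start > 1L) expect_true(covered[b@rows, b@start - 1L])
        if (b@end < ncol(msa)) expect_true(covered[b@rows, b@end + 1L])
    }
})

test_that("instances are built per free window and are always feasible", {
    msa <- runningExample()
    built <- buildInstances(msa, alpha = 2)
    expect_length(built$instances, 2L)
    expect_length(built$forced, 1L)
    expect_identical(built$instances[[1L]]@windowStart, 1L)
    expect_identical(built$instances[[1L]]@windowEnd, 6L)
    expect_identical(built$instances[[2L]]@windowStart, 9L)

    whole <- buildInstances(msa, alpha = "disabled")
    expect_length(whole$instances, 1L)
    expect_length(whole$forced, 0L)
    expect_identical(whole$instances[[1L]]@windowEnd, 9L)

    for (built in list(built, whole))
        for (inst in built$instances) {
            oneChar <- Filter(function(b) b@start == b@end,
                              inst@candidates)
            oneChar <- Filter(function(b) {
                K <- which(msaChars(msa)[, b@start] ==
                           msaChars(msa)[b@rows[1L], b@start])
                identical(b@rows, K)
            }, oneChar)
            expect_true(isTRUE(checkExactCover(msa, oneChar,
                                               inst@windowStart,
                                               inst@windowEnd)))
            # no candidate leaves its window
            for (b in inst@candidates) {
                expect_gte(b@start, inst@windowStart)
                expect_lte(b@end, inst@windowEnd)
            }
        }
})
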