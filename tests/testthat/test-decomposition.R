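fixturePairs <- function() {
    msa <- runningExample()
    list(msa = msa,
         l1 = makeBlock(msa, c(1, 2, 5), 1, 2),   # left pair, non-nested
         l2 = makeBlock(msa, c(2, 3, 4), 2, 9),
         l3 = makeBlock(msa, 1:5, 7, 8))          # nested with l2
}

test_that("row-maximal decomposition matches the hand-derived sets", {
    fx <- fixturePairs()
    expectSameBlockSet(rowMaximalDecompose(fx$msa, fx$l1, fx$l2),
                       list(makeBlock(fx$msa, c(1, 2, 5), 1, 1),
                            makeBlock(fx$msa, c(2, 3, 4), 3, 9)))
    expectSameBlockSet(rowMaximalDecompose(fx$msa, fx$l2, fx$l3),
                       list(makeBlock(fx$msa, c(2, 3, 4), 2, 6),
                            makeBlock(fx$msa, c(2, 3, 4), 9, 9)))
    # two identical blocks decompose to nothing
    expect_length(rowMaximalDecompose(fx$msa, fx$l2, fx$l2), 0L)
    # non-overlapping input is a precondition violation
    expect_error(rowMaximalDecompose(fx$msa, fx$l1, fx$l3), "overlap")
})

test_that("complete decomposition adds exactly the valid intersection blocks", {
    fx <- fixturePairs()
    msa <- fx$msa
    got <- completeDecompose(msa, fx$l2, fx$l3)
    expectSameBlockSet(got, list(
        makeBlock(msa, c(2, 3, 4), 2, 6),  # row-maximal part
        makeBlock(msa, c(2, 3, 4), 9, 9),
        makeBlock(msa, c(2, 3, 4), 2, 9),  # intersection row set
        makeBlock(msa, c(2, 3, 4), 7, 8),
        makeBlock(msa, c(1, 5), 7, 8),     # difference row set, valid
        makeBlock(msa, c(2, 3, 4), 7, 9)))
    # ({1,5},2,9) and ({1,5},7,9) are not blocks (rows 1 and 5 disagree)
    expect_false(isBlockValid(msa, new("Block", rows = c(1L, 5L),
                                       start = 2L, end = 9L)))
    expect_false(isBlockValid(msa, new("Block", rows = c(1L, 5L),
                                       start = 7L, end = 9L)))

    got <- completeDecompose(msa, fx$l1, fx$l2)
    expectSameBlockSet(got, list(
        makeBlock(msa, c(1, 2, 5), 1, 1),  # row-maximal part
        makeBlock(msa, c(2, 3, 4), 3, 9),
        makeBlock(msa, 2, 1, 2),           # intersection {2}
        makeBlock(msa, 2, 2, 9),
        makeBlock(msa, c(1, 5), 1, 2),     # valid difference candidates
        makeBlock(msa, c(3, 4), 2, 9)))

    # identical inputs with equal rows: only the block itself remains
    expectSameBlockSet(completeDecompose(msa, fx$l2, fx$l2), list(fx$l2))
})

test_that("decomposition is symmetric and its products are valid and contained", {
    for (s in 1:12) {
        msa <- randomSmallMsa(m = 3 + s %% 3, n = 5 + s %% 4,
                              seed = 600 + s,
                              alphabet = c("A", "C", "G", "-"))
        mb <- enumerateMaximalBlocks(msa, minRows = 2)
        if (length(mb) < 2L) next
        for (i in seq_len(length(mb) - 1L)) for (j in (i + 1L):length(mb)) {
            if (!blocksOverlap(mb[[i]], mb[[j]])) next
            for (fn in list(rowMaximalDecompose, completeDecompose)) {
                ab <- fn(msa, mb[[i]], mb[[j]])
                ba <- fn(msa, mb[[j]], mb[[i]])
                expectSameBlockSet(ab, ba)
                for (blk in ab) {
                    expect_true(isBlockValid(msa, blk))
                    # cells contained in the union of the parents' cells
                    inParent <- function(p)
                        all(blk@rows %in% p@rows) &&
                            blk@start >= p@start && blk@end <= p@end
                    expect_true(inParent(mb[[i]]) || inParent(mb[[j]]))
                }
            }
            # row-maximal products of one pair are pairwise non-overlapping
            rmd <- rowMaximalDecompose(msa, mb[[i]], mb[[j]])
            if (length(rmd) >= 2L)
                for (a in seq_len(length(rmd) - 1L))
                    for (b in (a + 1L):length(rmd))
                        expect_false(blocksOverlap(rmd[[a]], rmd[[b]]))
            # complete is a superset of row-maximal, per pair
            expect_true(all(blockSetKeys(rmd) %in%
                            blockSetKeys(completeDecompose(msa, mb[[i]],
                                                           mb[[j]]))))
        }
    }
})

test_that("decomposeAll unions the pairwise products over maximal blocks", {
    fx <- fixturePairs()
    maximal <- list(fx$l1, fx$l2, fx$l3)
    got <- decomposeAll(fx$msa, maximal, "row-maximal")
    want <- c(maximal,
              rowMaximalDecompose(fx$msa, fx$l1, fx$l2),
              rowMaximalDecompose(fx$msa, fx$l2, fx$l3))
    # (l1, l3) share rows but not columns, so they contribute nothing
    expect_false(blocksOverlap(fx$l1, fx$l3))
    expectSameBlockSet(got, want)

    # no overlapping pair: output equals input
    msa <- msaFromStrings(c("ACGT", "ACAT"))
    mb <- enumerateMaximalBlocks(msa)
    expect_length(mb, 2L)
    expect_false(blocksOverlap(mb[[1L]], mb[[2L]]))
    expectSameBlockSet(decomposeAll(msa, mb, "row-maximal"), mb)

    # complete output contains row-maximal output, globally
    for (s in 1:8) {
        rmsa <- randomSmallMsa(m = 4, n = 7, seed = 700 + s)
        mb <- enumerateMaximalBlocks(rmsa, minRows = 2)
        expect_true(all(blockSetKeys(decomposeAll(rmsa, mb, "row-maximal"))
                        %in%
                        blockSetKeys(decomposeAll(rmsa, mb, "complete"))))
    }
})
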