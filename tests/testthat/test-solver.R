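test_that("block costs implement the five objective functions", {
    msa <- runningExample()
    blk <- makeBlock(msa, 1:5, 7, 8)        # ungapped label GA, length 2
    b234 <- makeBlock(msa, c(2, 3, 4), 2, 9)  # ungapped length 6, 3 rows

    expect_identical(blockCost(msa, blk, "blocks"), 1)
    # short label (2 <= q = 20) pays the penalty
    expect_identical(blockCost(msa, blk, objectiveSpec("weighted")), 1000)
    longq <- objectiveSpec("weighted", q = 1)
    expect_identical(blockCost(msa, blk, longq), 1)       # 2 > q = 1
    expect_identical(blockCost(msa, b234, "strings"), 6)
    expect_identical(blockCost(msa, b234, "pstrings"), 2)  # 6 / 3
    # depth: threshold floor(p * m) = floor(0.11 * 5) = 0 -> no penalty
    expect_identical(blockCost(msa, makeBlock(msa, 3, 1, 1), "depth"), 1)
    deep <- objectiveSpec("depth", p = 0.5)   # floor(2.5) = 2
    expect_identical(blockCost(msa, makeBlock(msa, 3, 1, 1), deep), 1000)
    expect_identical(blockCost(msa, b234, deep), 1)
    # literal row-count mode
    cnt <- objectiveSpec("depth", depthMinCount = 3)
    expect_identical(blockCost(msa, b234, cnt), 1000)
})

test_that("tiny pipelines solve to the known optima", {
    two <- msaFromStrings(c("AC", "AC"))
    inst <- buildInstances(two, alpha = "disabled")$instances[[1L]]
    cov <- solveInstance(inst, "blocks")
    expect_identical(cov@objectiveValue, 1)
    expectSameBlockSet(cov@blocks, list(makeBlock(two, 1:2, 1, 2)))

    mism <- msaFromStrings(c("AC", "AG"))
    inst <- buildInstances(mism, alpha = "disabled")$instances[[1L]]
    expect_identical(solveInstance(inst, "blocks")@objectiveValue, 3)
    expect_identical(solveInstance(inst, "strings")@objectiveValue, 3)
})

test_that("both exact engines agree with the exhaustive oracle", {
    objs <- c("blocks", "weighted", "depth", "strings", "pstrings")
    for (s in 1:30) {
        msa <- randomSmallMsa(m = 2 + s %% 2, n = 2 + s %% 3,
                              seed = 1100 + s,
                              alphabet = c("A", "C", "G", "-"))
        for (strat in c("row-maximal", "complete")) {
            inst <- buildInstances(msa, alpha = "disabled",
                                   strategy = strat)$instances[[1L]]
            for (o in objs) {
                oracle <- solveExhaustive(inst, o)
                expect_false(is.null(oracle))
                dp <- solveInstance(inst, o, engine = "dp")
                bb <- solveInstance(inst, o, engine = "bb")
                expect_equal(dp@objectiveValue, oracle@objectiveValue,
                             tolerance = 1e-9)
                expect_equal(bb@objectiveValue, oracle@objectiveValue,
                             tolerance = 1e-9)
                # returned covers are exact and their value re-evaluates
                ok <- checkExactCover(msa, dp@blocks)
                expect_true(isTRUE(ok))
                expect_equal(sum(vapply(dp@blocks, blockCost, numeric(1L),
                                        msa = msa, objective = o)),
                             dp@objectiveValue, tolerance = 1e-9)
            }
        }
    }
})

test_that("the unrestricted optimum never exceeds the pipeline optimum", {
    objs <- c("blocks", "weighted", "depth", "strings", "pstrings")
    for (s in 1:20) {
        msa <- randomSmallMsa(m = 2 + s %% 2, n = 2 + s %% 3,
                              seed = 1200 + s,
                              alphabet = c("A", "C", "-"))
        inst <- buildInstances(msa, alpha = "disabled")$instances[[1L]]
        for (o in objs) {
            gm <- solveGmwbcOracle(msa, o)
            expect_lte(gm@objectiveValue,
                       solveInstance(inst, o)@objectiveValue + 1e-9)
        }
    }
    expect_identical(solveGmwbcOracle(msaFromStrings(c("AC", "AC")),
                                      "blocks")@objectiveValue, 1)
    # single row: the whole genome is one block
    expect_identical(solveGmwbcOracle(msaFromStrings("ACGT"),
                                      "blocks")@objectiveValue, 1)
    expect_error(solveGmwbcOracle(msaFromStrings(c(strrep("A", 11),
                                                   strrep("A", 11))),
                                  "blocks"), "too large")
})

test_that("a larger candidate set never worsens the optimum", {
    objs <- c("blocks", "weighted", "depth", "strings", "pstrings")
    for (s in 1:6) {
        msa <- batteryMsa(list(m = 3 + s %% 4, n = 14 + 3 * s,
                               seed = 1300 + s))
        instR <- buildInstances(msa, alpha = "disabled",
                                strategy = "row-maximal")$instances[[1L]]
        instC <- buildInstances(msa, alpha = "disabled",
                                strategy = "complete")$instances[[1L]]
        for (o in objs) {
            covR <- solveInstance(instR, o)
            covC <- solveInstance(instC, o)
            expect_true(covR@optimal && covC@optimal)
            expect_lte(covC@objectiveValue, covR@objectiveValue + 1e-9)
        }
    }
})

test_that("weighted with delta = 1 degenerates to the blocks objective", {
    for (s in 1:5) {
        msa <- batteryMsa(list(m = 2 + s, n = 12 + 2 * s, seed = 1400 + s))
        inst <- buildInstances(msa, alpha = "disabled")$instances[[1L]]
        expect_equal(
            solveInstance(inst, objectiveSpec("weighted",
                                              delta = 1))@objectiveValue,
            solveInstance(inst, "blocks")@objectiveValue)
    }
})

test_that("window covers merge with forced blocks into a global cover", {
    msa <- runningExample()
    cov <- solveMsaCover(msa, "blocks", alpha = 2)
    expect_true(isTRUE(checkExactCover(msa, cov@blocks)))
    # the forced vertical block is part of the solution
    expect_true("7:8:1,2,3,4,5" %in% blockSetKeys(cov@blocks))
    # solving twice is deterministic
    cov2 <- solveMsaCover(msa, "blocks", alpha = 2)
    expect_identical(blockSetKeys(cov@blocks), blockSetKeys(cov2@blocks))
    expect_identical(cov@objectiveValue, cov2@objectiveValue)
})
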