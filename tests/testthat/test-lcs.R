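test_that("position masks mark each base's positions and nothing else", {
    pm <- computePM("ACCA")
    mm <- maskMatrix(pm)
    expect_identical(which(mm["A", ]), c(1L, 4L))
    expect_identical(which(mm["C", ]), c(2L, 3L))
    expect_false(any(mm["G", ]) || any(mm["T", ]))

    expect_identical(unname(maskMatrix(computePM("AAAA"))["A", ]),
                     rep(TRUE, 4))

    # N positions are set in no mask; masks are pairwise disjoint and the
    # OR covers exactly the non-N positions
    mmN <- maskMatrix(computePM("ANG"))
    expect_identical(colSums(mmN), c(1, 0, 1))
    expect_true(mmN["A", 1] && mmN["G", 3])

    set.seed(5)
    for (w in c(8L, 64L)) {
        x <- randomSeq(133, nProb = 0.1)
        mm <- maskMatrix(computePM(x, w = w))
        expect_true(all(colSums(mm) <= 1))
        expect_identical(unname(colSums(mm) == 1),
                         strsplit(x, "")[[1]] != "N")
    }
})

test_that("the LCS length of ATCAGTC and CTAGAC is 4 by both kernels", {
    expect_identical(llcsDP("ATCAGTC", "CTAGAC"), 4L)
    expect_identical(llcsBitparallel("ATCAGTC", "CTAGAC"), 4L)
    expect_identical(llcsBitparallel(computePM("ATCAGTC"), "CTAGAC"), 4L)
})

test_that("degenerate LCS inputs behave by definition", {
    expect_identical(llcsDP("ACGT", ""), 0L)
    expect_identical(llcsBitparallel("", "ACGT"), 0L)
    expect_identical(llcsDP("ACGT", "ACGT"), 4L)
    # N matches nothing, including another N
    expect_identical(llcsDP("NNNN", "NNNN"), 0L)
    expect_identical(llcsBitparallel("ANA", "ANA"), 2L)
})

test_that("bit-parallel kernel equals the DP on random pairs across block widths", {
    set.seed(101)
    for (i in 1:300) {
        x <- randomSeq(sample(1:320, 1), nProb = 0.03)
        y <- randomSeq(sample(1:320, 1), nProb = 0.03)
        expect_identical(llcsBitparallel(x, y), llcsDP(x, y))
    }
    # narrow blocks force carry/borrow chaining across many words
    for (w in c(8L, 16L, 32L)) {
        for (i in 1:60) {
            x <- randomSeq(sample((2 * w):(5 * w), 1))
            y <- randomSeq(sample(1:(4 * w), 1))
            expect_identical(llcsBitparallel(x, y, w = w), llcsDP(x, y))
        }
    }
})

test_that("both kernels agree with an independent alignment-based LCS oracle", {
    set.seed(202)
    for (i in 1:40) {
        x <- randomSeq(sample(1:90, 1), nProb = 0.05)
        y <- randomSeq(sample(1:90, 1), nProb = 0.05)
        ref <- oracleLLCS(x, y)
        expect_identical(llcsDP(x, y), ref)
        expect_identical(llcsBitparallel(x, y), ref)
    }
})

test_that("LCS length is symmetric and bounded by the shorter length", {
    set.seed(303)
    for (i in 1:100) {
        x <- randomSeq(sample(1:120, 1))
        y <- randomSeq(sample(1:120, 1))
        l <- llcsBitparallel(x, y)
        expect_identical(l, llcsBitparallel(y, x))
        expect_lte(l, min(nchar(x), nchar(y)))
        expect_identical(llcsBitparallel(x, x), nchar(x))
    }
})

test_that("the LCS filter prunes the worked example but never a truly similar pair", {
    # LLCS = 4, shorter length 6: bound 0.667 < 0.9 -> prune
    expect_false(lcsFilter("ATCAGTC", "CTAGAC", s = 0.9))
    expect_true(lcsFilter("ACGTACGT", "ACGTACGT", s = 1))

    # no false negatives: a pair whose alignment identity reaches s always
    # passes, because LLCS/n bounds the identity from above
    set.seed(404)
    for (s in c(0.8, 0.9, 0.95)) {
        for (i in 1:120) {
            x <- randomSeq(sample(40:150, 1))
            y <- if (i %% 2) mutateSequence(x, runif(1, 0, 0.25), 0.01)
                 else randomSeq(sample(40:150, 1))
            id <- alignmentIdentity(alignAffine(x, y))
            if (id >= s) expect_true(lcsFilter(x, y, s = s))
        }
    }
})
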