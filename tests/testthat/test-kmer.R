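test_that("every k-th word of a representative is registered, plus the tail window", {
    # k = 2, "ACGTAC": stride positions 0, 2, 4 land exactly on the end
    tab <- shortWordTable(2)
    registerRepresentative(tab, "ACGTAC", 1)
    ent <- wordEntries(tab)
    expect_identical(ent$pos[order(ent$pos)], c(0L, 2L, 4L))
    expect_identical(ent$code[order(ent$pos)],
                     kmerCode(c("AC", "GT", "AC")))

    # k = 3, length 7: stride gives 0 and 3; 7 - 3 = 4 is not a multiple of
    # 3, so the final window at position 4 is registered too
    tab3 <- shortWordTable(3)
    registerRepresentative(tab3, "ACGTACG", 1)
    ent3 <- wordEntries(tab3)
    expect_identical(sort(ent3$pos), c(0L, 3L, 4L))
    expect_identical(ent3$code[order(ent3$pos)],
                     kmerCode(c("ACG", "TAC", "ACG")))

    # words containing N are skipped
    tabN <- shortWordTable(2)
    registerRepresentative(tabN, "ANGT", 1)
    entN <- wordEntries(tabN)
    expect_identical(entN$pos, 2L)
    expect_identical(entN$code, kmerCode("GT"))
})

test_that("candidate counts follow the once-per-query-position rule", {
    tab <- shortWordTable(2)
    registerRepresentative(tab, "ACGTAC", 1)

    # query "TTAC": words TT, TA, AC -> one common word (AC)
    hits <- findCandidates(tab, "TTAC", t = 1)
    expect_identical(hits$rep, 1L)
    expect_identical(hits$count, 1L)

    # query "ACAC": AC occurs at two query positions -> count 2, even though
    # AC is also registered twice for the representative
    hits2 <- findCandidates(tab, "ACAC", t = 2)
    expect_identical(hits2$count, 2L)

    # a threshold above the sharable word count excludes the representative
    expect_identical(nrow(findCandidates(tab, "ACAC", t = 5)), 0L)

    # queries shorter than k have no candidates
    expect_identical(nrow(findCandidates(tab, "A", t = 1)), 0L)
})

test_that("representatives shorter than k are registered with zero words, with a warning", {
    tab <- shortWordTable(9)
    expect_warning(n <- registerRepresentative(tab, "ACGT", 1),
                   "shorter than k")
    expect_identical(n, 0L)
    expect_identical(nrow(wordEntries(tab)), 0L)
})

test_that("registration count and candidate retrieval obey the filter's contracts", {
    set.seed(42)
    for (k in c(3L, 5L, 9L)) {
        tab <- shortWordTable(k)
        lens <- sample(k:200, 25)
        reps <- vapply(lens, randomSeq, character(1))
        for (i in seq_along(reps)) registerRepresentative(tab, reps[i], i)
        ent <- wordEntries(tab)

        # per-representative registration count is ceil((L-k+1)/k), plus at
        # most one tail word -- about 1/k of an all-words index
        counts <- tabulate(ent$rep, nbins = length(reps))
        expected <- ceiling((lens - k + 1) / k)
        expect_true(all(counts >= expected & counts <= expected + 1))
        # registered positions are stride multiples except at most one tail
        offstride <- tapply(ent$pos %% k != 0, ent$rep, sum)
        expect_true(all(offstride <= 1))

        # monotone in t: candidates at t+1 are a subset of candidates at t
        for (q in vapply(sample(60:200, 5), randomSeq, character(1))) {
            c1 <- findCandidates(tab, q, t = 1)
            c3 <- findCandidates(tab, q, t = 3)
            expect_true(all(c3$rep %in% c1$rep))
            expect_true(all(c1$count[match(c3$rep, c1$rep)] >= 3))
        }

        # a representative identical to the query always passes for
        # t <= ceil((L-k+1)/k): no false negative on exact duplicates
        for (i in sample(seq_along(reps), 5)) {
            tmax <- ceiling((lens[i] - k + 1) / k)
            hits <- findCandidates(tab, reps[i], t = tmax)
            expect_true(i %in% hits$rep)
        }
    }
})

test_that("the default common-word threshold follows read length", {
    expect_identical(defaultWordThreshold(c(100L, 150L, 400L)), c(1L, 1L, 4L))
    expect_identical(defaultWordThreshold(200L), 1L)
    expect_identical(defaultWordThreshold(201L), 4L)
    expect_error(defaultWordThreshold(0), "positive")
})
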