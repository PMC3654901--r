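test_that("read-set generation is fully reproducible from its seed", {
    a <- generateReadSet(nSeeds = 4, readsPerSeed = 3, readLength = 80,
                         seed = 123)
    b <- generateReadSet(nSeeds = 4, readsPerSeed = 3, readLength = 80,
                         seed = 123)
    expect_identical(as.character(a$sequences), as.character(b$sequences))
    expect_identical(a$labels, b$labels)
    c <- generateReadSet(nSeeds = 4, readsPerSeed = 3, readLength = 80,
                         seed = 124)
    expect_false(identical(as.character(a$sequences),
                           as.character(c$sequences)))
})

test_that("degenerate generator configurations behave by definition", {
    one <- generateReadSet(nSeeds = 1, readsPerSeed = 0, readLength = 50,
                           seed = 2)
    expect_length(one$sequences, 1L)
    expect_identical(unname(one$labels), 1L)

    # zero mutation: every read equals its seed
    pure <- generateReadSet(nSeeds = 3, readsPerSeed = 4, readLength = 60,
                            subRate = 0, indelRate = 0, seed = 5)
    seedSeq <- as.character(pure$seedSequences)
    expect_identical(unname(as.character(pure$sequences)),
                     unname(seedSeq[pure$labels]))
})

test_that("forced substitution changes every position", {
    set.seed(9)
    x <- randomSeq(200)
    m <- mutateSequence(x, subRate = 1, indelRate = 0)
    expect_identical(nchar(m), nchar(x))
    expect_true(all(strsplit(m, "")[[1]] != strsplit(x, "")[[1]]))
    expect_identical(mutateSequence(x, 0, 0), x)
})

test_that("mutant identity concentrates at 1 - subRate - indelRate", {
    set.seed(10)
    x <- randomSeq(150)
    ids <- replicate(500, {
        alignmentIdentity(alignAffine(mutateSequence(x, 0.03, 0), x))
    })
    expect_gt(mean(ids), 0.955)
    expect_lt(mean(ids), 0.985)
    # within 3 standard errors of the per-base expectation
    se <- sd(ids) / sqrt(length(ids))
    expect_lt(abs(mean(ids) - 0.97), 3 * se + 0.005)
})

test_that("generated clusters are internally tight and mutually divergent", {
    rs <- generateReadSet(nSeeds = 20, readsPerSeed = 10, readLength = 150,
                          subRate = 0.03, indelRate = 0.005,
                          minSeedDivergence = 0.2, seed = 7)
    expect_length(rs$sequences, 220L)
    expect_identical(as.integer(table(rs$labels)), rep(11L, 20L))

    seqs <- as.character(rs$sequences)
    seeds <- as.character(rs$seedSequences)
    # within-cluster: reads stay close to their seed
    within <- vapply(seq_along(seqs), function(i)
        alignmentIdentity(alignAffine(seqs[i], seeds[rs$labels[i]])),
        numeric(1))
    expect_true(all(within >= 0.9))
    # cross-cluster: seed pairs capped by the divergence constraint, and
    # reads from different seeds stay well apart
    cross <- combn(seq_along(seeds), 2, function(p)
        alignmentIdentity(alignAffine(seeds[p[1]], seeds[p[2]])))
    expect_true(all(cross <= 0.8))
    set.seed(33)
    pick <- replicate(100, sample(length(seqs), 2), simplify = FALSE)
    pick <- Filter(function(p) rs$labels[p[1]] != rs$labels[p[2]], pick)
    crossReads <- vapply(pick, function(p)
        alignmentIdentity(alignAffine(seqs[p[1]], seqs[p[2]])), numeric(1))
    expect_true(all(crossReads <= 0.8))
})

test_that("impossible divergence demands fail with advice instead of looping", {
    # only four single-base seeds can be pairwise dissimilar; a fifth must
    # exhaust the retry cap
    expect_error(
        generateReadSet(nSeeds = 5, readsPerSeed = 0, readLength = 1,
                        minSeedDivergence = 0.99, seed = 1, maxTries = 25),
        "lower 'nSeeds' or 'minSeedDivergence'")
})
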