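test_that("trivial inputs cluster by definition", {
    expect_identical(nClusters(clusterGreedy(character(0))), 0L)

    cs <- clusterGreedy(c(a = "ACGTACGTACGT", b = "ACGTACGTACGT"),
                        s = 0.9, k = 2, t = 1)
    expect_identical(nClusters(cs), 1L)
    expect_identical(unname(assignments(cs)), c(1L, 1L))
    expect_identical(unname(identities(cs)), c(1, 1))
})

test_that("the ground-truth partition of a synthetic read set is recovered exactly", {
    rs <- generateReadSet(nSeeds = 20, readsPerSeed = 10, readLength = 150,
                          subRate = 0.03, indelRate = 0,
                          minSeedDivergence = 0.2, seed = 19)
    cs <- clusterGreedy(rs$sequences, s = 0.9, k = 9, t = 1)
    expect_identical(nClusters(cs), 20L)
    expect_identical(ariIndex(assignments(cs), rs$labels), 1)

    # partition: every read in exactly one cluster, sizes sum to n
    expect_identical(sum(lengths(clusterMembers(cs))),
                     length(rs$sequences))
    expect_identical(sort(unique(unname(assignments(cs)))), 1:20)

    # representative immutability: representative i belongs to cluster i
    # and is the first-processed member of its cluster
    expect_identical(unname(assignments(cs))[representatives(cs)], 1:20)
    ord <- order(-Biostrings::width(rs$sequences))
    firstProcessed <- vapply(clusterMembers(cs), function(m)
        m[which.min(match(m, ord))], integer(1))
    expect_identical(unname(firstProcessed),
                     representatives(cs))
})

test_that("every stored member re-aligns to its representative at >= s", {
    rs <- generateReadSet(nSeeds = 10, readsPerSeed = 8, readLength = 120,
                          seed = 3)
    cs <- clusterGreedy(rs$sequences, s = 0.9, k = 9, t = 1)
    v <- verifyClusters(cs)
    expect_identical(v$nViolations, 0L)
    expect_true(v$partitionOK)
    expect_identical(v$nMembers, length(rs$sequences) - nClusters(cs))

    # stored identities match a re-alignment
    reps <- representatives(cs)
    for (i in sample(seq_along(rs$sequences), 10)) {
        r <- reps[assignments(cs)[i]]
        expected <- if (i == r) 1 else
            alignmentIdentity(alignAffine(rs$sequences[[i]],
                                          rs$sequences[[r]]))
        expect_equal(unname(identities(cs)[i]), expected)
    }
})

test_that("sequence ordering policies are stable and honored", {
    x <- c(a = paste(rep("A", 100), collapse = ""),
           b = paste(rep("C", 400), collapse = ""),
           c = paste(rep("G", 150), collapse = ""))
    expect_identical(names(orderSequences(x, "length_desc")),
                     c("b", "c", "a"))
    expect_identical(names(orderSequences(x, "input")), c("a", "b", "c"))
    # ties keep input order
    y <- c(p = "ACGT", q = "TTTT", r = "GG")
    expect_identical(names(orderSequences(y, "length_desc")),
                     c("p", "q", "r"))
})

test_that("reads shorter than k and all-N reads found singleton clusters", {
    reads <- c(tiny1 = "ACG", tiny2 = "ACG",
               nn = "NNNNNNNNNNNNNNNN",
               ok1 = "ACGTACGTACGTACGT", ok2 = "ACGTACGTACGTACGT")
    cs <- clusterGreedy(reads, s = 0.9, k = 9, t = 1, ordering = "input")
    a <- assignments(cs)
    # the two identical short reads cannot pass the word filter: singletons
    expect_false(a[["tiny1"]] == a[["tiny2"]])
    expect_identical(sum(a == a[["nn"]]), 1L)
    expect_identical(a[["ok1"]], a[["ok2"]])
    expect_identical(nClusters(cs), 4L)
})

test_that("raising s cannot merge clusters when the word filter is degenerate", {
    rs <- generateReadSet(nSeeds = 8, readsPerSeed = 5, readLength = 60,
                          subRate = 0.05, indelRate = 0, seed = 21)
    ncl <- vapply(c(0.85, 0.9, 0.95, 1.0), function(s)
        nClusters(clusterGreedy(rs$sequences, s = s, k = 1, t = 1,
                                ordering = "input")), integer(1))
    expect_true(all(diff(ncl) >= 0))
})

test_that("best-hit assignment picks the highest-identity representative", {
    # A and B differ at 10 scattered positions (identity 0.875 < 0.9), so
    # each founds a cluster; the query reverts 2 of those positions toward
    # A, leaving it at exactly 0.9 to A and 0.975 to the later cluster B
    flip <- function(b) chartr("ACGT", "CGTA", b)
    repA <- paste(rep("ACGTAACCGGTTACGT", 5), collapse = "")   # 80 bases
    pos <- seq(4, 76, by = 8)
    repB <- repA
    for (p in pos) substr(repB, p, p) <- flip(substr(repA, p, p))
    query <- repB
    for (p in pos[1:2]) substr(query, p, p) <- substr(repA, p, p)
    reads <- c(A = repA, B = repB, q = query)
    first <- clusterGreedy(reads, s = 0.9, k = 4, t = 1, ordering = "input",
                           assignment = "first")
    best <- clusterGreedy(reads, s = 0.9, k = 4, t = 1, ordering = "input",
                          assignment = "best")
    expect_identical(unname(assignments(first)[["q"]]),
                     unname(assignments(first)[["A"]]))
    expect_identical(unname(assignments(best)[["q"]]),
                     unname(assignments(best)[["B"]]))
    expect_gte(identities(best)[["q"]], identities(first)[["q"]])
})

test_that("the filter cascade only ever narrows the candidate stream", {
    rs <- generateReadSet(nSeeds = 15, readsPerSeed = 6, readLength = 100,
                          seed = 9)
    cs <- clusterGreedy(rs$sequences, s = 0.9, k = 9, t = 1)
    st <- filterStats(cs)
    expect_lte(st[["lcs_pass_pairs"]], st[["shortword_pairs"]])
    expect_lte(st[["accepted_pairs"]], st[["aligned_pairs"]])
    expect_identical(st[["aligned_pairs"]], st[["lcs_pass_pairs"]])
})
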