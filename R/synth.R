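#' Mutate a read with substitutions and indels
#'
#' Per position: with probability `subRate` the base is replaced by a
#' uniformly chosen different base; with probability `indelRate / 2` the
#' base is deleted; with probability `indelRate / 2` a uniform random base
#' is inserted after it.  The expected identity of the mutant to the
#' original is approximately `1 - subRate - indelRate`.  Draws come from
#' the current RNG stream, so results are reproducible under `set.seed()`.
#'
#' @param x a single base string over A/C/G/T.
#' @param subRate per-base substitution probability in `[0, 1]`.
#' @param indelRate per-base insertion/deletion probability in `[0, 1)`.
#' @return The mutated base string.
#' @examples
#' set.seed(1)
#' mutateSequence("ACGTACGTACGT", subRate = 0.25, indelRate = 0)
#' @export
mutateSequence <- function(x, subRate = 0.03, indelRate = 0.005) {
    if (subRate < 0 || subRate > 1 || indelRate < 0 || indelRate >= 1)
        stop("'subRate' must be in [0, 1] and 'indelRate' in [0, 1)")
    x <- .seqChar1(x)
    b <- strsplit(x, "", fixed = TRUE)[[1]]
    L <- length(b)
    if (L == 0L) return("")
    codes <- match(b, BASES) - 1L
    shift <- sample.int(3L, L, replace = TRUE)          # 1..3: never the same base
    subbed <- BASES[((codes + shift) %% 4L) + 1L]
    doSub <- runif(L) < subRate & !is.na(codes)         # N positions never substituted
    b[doSub] <- subbed[doSub]
    doDel <- runif(L) < indelRate / 2
    doIns <- runif(L) < indelRate / 2
    insBase <- BASES[sample.int(4L, L, replace = TRUE)]
    pieces <- rbind(ifelse(doDel, "", b), ifelse(doIns, insBase, ""))
    paste(pieces, collapse = "")
}

#' Generate a synthetic read set with ground-truth clusters
#'
#' Draws `nSeeds` uniform-random seed sequences, rejection-sampling each new
#' seed until its alignment identity to every accepted seed is at most
#' `1 - minSeedDivergence`, then emits each seed together with
#' `readsPerSeed` mutated copies ([mutateSequence()]).  Records are
#' shuffled deterministically.  This emulates the cluster structure of a
#' deduplication workload — groups of reads from the same origin differing
#' by sequencing errors — with known labels, so cluster recovery can be
#' scored (e.g. by the adjusted Rand index) without external data.
#'
#' @param nSeeds number of clusters (seed sequences); default 20.
#' @param readsPerSeed mutated copies per seed; default 10.
#' @param readLength seed length in bases; default 150.
#' @param subRate per-base substitution rate of the copies; default 0.03.
#' @param indelRate per-base indel rate of the copies; default 0.005.
#' @param minSeedDivergence minimum dissimilarity between seeds: every seed
#'   pair must have alignment identity <= `1 - minSeedDivergence`; default
#'   0.2.
#' @param seed RNG seed for full reproducibility.
#' @param scheme [ScoringScheme-class] used for the seed-divergence check.
#' @param maxTries rejection-sampling cap per seed before giving up.
#' @return A list with `sequences` (named [Biostrings::DNAStringSet]),
#'   `labels` (integer vector parallel to `sequences`; reads from seed i
#'   are labelled i), and `seedSequences` (the unmutated seeds).
#' @examples
#' rs <- generateReadSet(nSeeds = 3, readsPerSeed = 2, readLength = 60,
#'                       seed = 42)
#' table(rs$labels)
#' @export
generateReadSet <- function(nSeeds = 20, readsPerSeed = 10, readLength = 150,
                            subRate = 0.03, indelRate = 0.005,
                            minSeedDivergence = 0.2, seed = 1L,
                            scheme = scoringScheme(), maxTries = 1000L) {
    stopifnot(nSeeds >= 1, readsPerSeed >= 0, readLength >= 1,
              subRate >= 0, subRate < 1, indelRate >= 0, indelRate < 1,
              minSeedDivergence >= 0, minSeedDivergence < 1)
    set.seed(as.integer(seed))
    maxId <- 1 - minSeedDivergence
    seeds <- character(0)
    for (i in seq_len(nSeeds)) {
        tries <- 0L
        repeat {
            tries <- tries + 1L
            if (tries > maxTries)
                stop(paste("could not draw sufficiently divergent seeds;",
                           "lower 'nSeeds' or 'minSeedDivergence'"))
            cand <- paste(BASES[sample.int(4L, readLength, replace = TRUE)],
                          collapse = "")
            if (length(seeds) == 0L) break
            ids <- cpp_identity_vs_set(cand, seeds, scheme@match,
                                       scheme@mismatch, scheme@gapOpen,
                                       scheme@gapExtend, scheme@endGapsFree)
            if (all(ids <= maxId)) break
        }
        seeds <- c(seeds, cand)
    }
    labels <- integer(0)
    reads <- character(0)
    for (i in seq_len(nSeeds)) {
        reads <- c(reads, seeds[i])
        labels <- c(labels, i)
        if (readsPerSeed > 0) {
            reads <- c(reads, vapply(seq_len(readsPerSeed), function(j)
                mutateSequence(seeds[i], subRate, indelRate), character(1)))
            labels <- c(labels, rep.int(i, readsPerSeed))
        }
    }
    perm <- sample.int(length(reads))
    reads <- reads[perm]
    labels <- labels[perm]
    ids <- sprintf("read%0*d", nchar(length(reads)), seq_along(reads))
    names(reads) <- ids
    names(labels) <- ids
    list(sequences = Biostrings::DNAStringSet(reads), labels = labels,
         seedSequences = Biostrings::DNAStringSet(
             structure(seeds, names = sprintf("seed%d", seq_len(nSeeds)))))
}
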