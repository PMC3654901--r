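# Independent oracles used across the suite.  They deliberately take
# different routes than the package kernels they check.

BASES4 <- c("A", "C", "G", "T")

randomSeq <- function(len, nProb = 0) {
    alph <- c(BASES4, "N")
    prob <- c(rep((1 - nProb) / 4, 4), nProb)
    paste(sample(alph, len, replace = TRUE, prob = prob), collapse = "")
}

# LCS length via Biostrings::pairwiseAlignment: with zero gap costs and a
# prohibitive mismatch score, the optimal global score equals the maximum
# number of matched columns, i.e. the LCS length.  N matches nothing.
oracleLLCS <- function(x, y) {
    if (nchar(x) == 0L || nchar(y) == 0L) return(0L)
    alph <- c(BASES4, "N")
    mat <- matrix(-1e6, 5, 5, dimnames = list(alph, alph))
    diag(mat) <- 1
    mat["N", "N"] <- -1e6
    as.integer(Biostrings::pairwiseAlignment(
        Biostrings::BString(x), Biostrings::BString(y),
        substitutionMatrix = mat, gapOpening = 0, gapExtension = 0,
        type = "global", scoreOnly = TRUE))
}

# ---- brute-force affine alignment oracle ----
#
# Enumerates every monotone alignment path for sequence lengths (m, n) as a
# string of moves (M = diagonal, X = consume x, Y = consume y), and scores
# a pair against all paths.  A gap run is charged gapOpen + len * gapExtend;
# with free end gaps the first run (if the path starts with gaps) and the
# last run (if it ends with gaps) cost nothing.

.pathCache <- new.env(parent = emptyenv())

.enumPaths <- function(m, n) {
    key <- paste(m, n)
    if (!is.null(.pathCache[[key]])) return(.pathCache[[key]])
    paths <- list()
    recurse <- function(i, j, moves) {
        if (i == m && j == n) {
            paths[[length(paths) + 1L]] <<- moves
            return(invisible(NULL))
        }
        if (i < m && j < n) recurse(i + 1L, j + 1L, c(moves, "M"))
        if (i < m) recurse(i + 1L, j, c(moves, "X"))
        if (j < n) recurse(i, j + 1L, c(moves, "Y"))
    }
    recurse(0L, 0L, character(0))

    # Flatten to vectors so pairs can be scored without per-path loops:
    # per path, the (i, j) of its diagonal columns plus gap-run summaries
    # under both end-gap conventions.
    perPath <- lapply(paths, function(mv) {
        i <- cumsum(mv != "Y")
        j <- cumsum(mv != "X")
        # gap runs are per move type: switching between an x-gap and a
        # y-gap opens a new gap
        runs <- rle(mv)
        gapRun <- runs$values != "M"
        lens <- runs$lengths[gapRun]
        nRuns <- length(lens)
        leadFree <- nRuns > 0 && gapRun[1]
        trailFree <- nRuns > 0 && gapRun[length(gapRun)]
        freeRuns <- 0L
        freeBases <- 0L
        if (nRuns > 0) {
            if (leadFree) { freeRuns <- freeRuns + 1L; freeBases <- freeBases + lens[1] }
            if (trailFree && !(leadFree && nRuns == 1L)) {
                freeRuns <- freeRuns + 1L
                freeBases <- freeBases + lens[nRuns]
            }
        }
        list(di = i[mv == "M"], dj = j[mv == "M"],
             allRuns = nRuns, allBases = sum(lens),
             intRuns = nRuns - freeRuns, intBases = sum(lens) - freeBases)
    })
    nPaths <- length(perPath)
    nDiag <- vapply(perPath, function(p) length(p$di), integer(1))
    info <- list(
        nPaths = nPaths, nDiag = nDiag,
        di = unlist(lapply(perPath, `[[`, "di")),
        dj = unlist(lapply(perPath, `[[`, "dj")),
        pid = rep.int(seq_len(nPaths), nDiag),
        allRuns = vapply(perPath, `[[`, integer(1), "allRuns"),
        allBases = vapply(perPath, function(p) as.integer(p$allBases),
                          integer(1)),
        intRuns = vapply(perPath, function(p) as.integer(p$intRuns),
                         integer(1)),
        intBases = vapply(perPath, function(p) as.integer(p$intBases),
                          integer(1)))
    .pathCache[[key]] <- info
    info
}

# Maximum score over all alignments, plus the match counts achieved by the
# score-optimal paths.
bruteAffine <- function(x, y, scheme = scoringScheme()) {
    xb <- strsplit(x, "")[[1]]
    yb <- strsplit(y, "")[[1]]
    p <- .enumPaths(length(xb), length(yb))
    matches <- numeric(p$nPaths)
    if (length(p$di)) {
        eq <- as.numeric(xb[p$di] == yb[p$dj] & xb[p$di] != "N")
        agg <- rowsum(eq, p$pid)
        matches[as.integer(rownames(agg))] <- agg[, 1]
    }
    runs <- if (scheme@endGapsFree) p$intRuns else p$allRuns
    bases <- if (scheme@endGapsFree) p$intBases else p$allBases
    scores <- matches * scheme@match + (p$nDiag - matches) * scheme@mismatch +
        runs * scheme@gapOpen + bases * scheme@gapExtend
    best <- max(scores)
    list(score = best,
         optMatches = sort(unique(as.integer(matches[scores == best]))))
}

ariIndex <- function(a, b) mclust::adjustedRandIndex(a, b)
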