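#' Greedy incremental clustering at an identity threshold
#'
#' Processes reads one at a time (after [orderSequences()] reordering).
#' Each read is compared against existing cluster representatives through a
#' cascade: the short-word filter proposes representatives sharing at least
#' `t` k-mers; the LCS filter discards candidates whose identity upper
#' bound `LLCS / n` falls below `s`; survivors are aligned with affine gap
#' penalties, and the read joins the first cluster whose alignment identity
#' reaches `s` (or the best-identity cluster with
#' `assignment = "best"`).  A read joining no cluster founds a new one,
#' becomes its representative — representatives are never updated — and is
#' registered in the short word table.  The result therefore depends on the
#' processing order.
#'
#' Reads shorter than `k` (or all-N reads, whose k-mers are all skipped)
#' can match no candidate and found singleton clusters.
#'
#' @param x reads: a named [Biostrings::DNAStringSet], a named character
#'   vector, or a FASTA/FASTQ path (read with [readSequences()]).
#' @param s identity threshold in (0, 1]; default 0.9.
#' @param k short word length in bases, 1..12; default 9.
#' @param t common-word threshold; `"auto"` (default) applies
#'   [defaultWordThreshold()] to the median read length.
#' @param scheme alignment [ScoringScheme-class].
#' @param ordering `"length_desc"` (default; stable sort by decreasing
#'   length) or `"input"` (file order).
#' @param assignment `"first"` (default; join the earliest-created
#'   qualifying cluster) or `"best"` (highest identity, earliest cluster at
#'   ties).
#' @param wordWidth block width of the bit-parallel LCS kernel (default 64).
#' @param verbose log progress and per-stage filter counts with `message()`.
#' @return A [ClusterSet-class].
#' @examples
#' reads <- c(a1 = "ACGTACGTACGTACGT", a2 = "ACGTACGTACGTACGT",
#'            b1 = "TTGGCCAATTGGCCAA")
#' cs <- clusterGreedy(reads, s = 0.9, k = 4, t = 1)
#' nClusters(cs)
#' assignments(cs)
#' @export
clusterGreedy <- function(x, s = 0.9, k = 9L, t = "auto",
                          scheme = scoringScheme(),
                          ordering = c("length_desc", "input"),
                          assignment = c("first", "best"),
                          wordWidth = 64L, verbose = FALSE) {
    ordering <- match.arg(ordering)
    assignment <- match.arg(assignment)
    if (is.character(x) && length(x) == 1L && is.null(names(x)) &&
        file.exists(x))
        x <- readSequences(x)
    seqs <- .seqChar(x, default_prefix = "seq")
    if (length(s) != 1L || is.na(s) || s <= 0 || s > 1)
        stop("'s' must be a single value in (0, 1]")
    k <- as.integer(k)
    if (is.na(k) || k < 1L || k > 12L)
        stop("'k' must be an integer between 1 and 12")
    stopifnot(methods::is(scheme, "ScoringScheme"))
    methods::validObject(scheme)
    wordWidth <- as.integer(wordWidth)
    if (!(wordWidth %in% c(8L, 16L, 32L, 64L)))
        stop("'wordWidth' must be one of 8, 16, 32, 64")
    if (identical(t, "auto")) {
        t <- if (length(seqs) == 0L) 1L
             else defaultWordThreshold(max(1L, stats::median(nchar(seqs))))
    }
    t <- as.integer(t)
    if (is.na(t) || t < 1L)
        stop("'t' must be a positive integer or \"auto\"")

    ord <- .orderIndices(nchar(seqs), ordering)
    res <- cpp_cluster_greedy(unname(seqs[ord]), s, k, t,
                              scheme@match, scheme@mismatch, scheme@gapOpen,
                              scheme@gapExtend, scheme@endGapsFree,
                              assignment == "best", wordWidth)

    n <- length(seqs)
    assign <- integer(n)
    ident <- numeric(n)
    assign[ord] <- res$assign + 1L
    ident[ord] <- res$identity
    reps <- ord[res$reps + 1L]

    params <- list(s = s, k = k, t = t, ordering = ordering,
                   assignment = assignment, wordWidth = wordWidth,
                   match = scheme@match, mismatch = scheme@mismatch,
                   gapOpen = scheme@gapOpen, gapExtend = scheme@gapExtend,
                   endGapsFree = scheme@endGapsFree)
    out <- new("ClusterSet", sequences = Biostrings::DNAStringSet(seqs),
               assignments = assign, identities = ident,
               representatives = as.integer(reps), params = params,
               stats = res$stats)
    if (verbose) {
        st <- res$stats
        message(sprintf(
            paste0("clustered %d reads into %d clusters ",
                   "(short-word candidate pairs %g; LCS-filter survivors %g; ",
                   "alignments %g; accepted %g)"),
            n, length(reps), st[["shortword_pairs"]], st[["lcs_pass_pairs"]],
            st[["aligned_pairs"]], st[["accepted_pairs"]]))
    }
    out
}

.orderIndices <- function(widths, policy) {
    switch(policy,
        input = seq_along(widths),
        length_desc = order(-widths))  # order() is stable: ties keep input order
}

#' Reorder reads for clustering
#'
#' Greedy incremental clustering depends on the processing order.
#' `"length_desc"` (the CD-HIT convention, and [clusterGreedy()]'s default)
#' sorts by decreasing length with a stable sort, so longer reads become
#' representatives and absorb shorter ones; `"input"` keeps the given
#' order.
#'
#' @param x a [Biostrings::DNAStringSet] or character vector of reads.
#' @param policy `"length_desc"` or `"input"`.
#' @return `x`, permuted.
#' @examples
#' orderSequences(c(a = "ACG", b = "ACGTACG", c = "ACGTA"), "length_desc")
#' @export
orderSequences <- function(x, policy = c("length_desc", "input")) {
    policy <- match.arg(policy)
    widths <- if (methods::is(x, "XStringSet")) Biostrings::width(x)
              else nchar(x)
    x[.orderIndices(widths, policy)]
}

# ---- ClusterSet accessors ----

#' @rdname lcsclust-generics
#' @export
setMethod("nClusters", "ClusterSet",
          function(x) length(x@representatives))

#' @rdname lcsclust-generics
#' @export
setMethod("representatives", "ClusterSet", function(x) x@representatives)

#' @rdname lcsclust-generics
#' @export
setMethod("repSequences", "ClusterSet",
          function(x) x@sequences[x@representatives])

#' @rdname lcsclust-generics
#' @export
setMethod("assignments", "ClusterSet", function(x) {
    out <- x@assignments
    names(out) <- names(x@sequences)
    out
})

#' @rdname lcsclust-generics
#' @export
setMethod("identities", "ClusterSet", function(x) {
    out <- x@identities
    names(out) <- names(x@sequences)
    out
})

#' @rdname lcsclust-generics
#' @export
setMethod("clusterMembers", "ClusterSet",
          function(x) split(seq_along(x@assignments), x@assignments))

#' @rdname lcsclust-generics
#' @export
setMethod("runParams", "ClusterSet", function(x) x@params)

#' @rdname lcsclust-generics
#' @export
setMethod("filterStats", "ClusterSet", function(x) x@stats)

setMethod("show", "ClusterSet", function(object) {
    n <- length(object@sequences)
    k <- length(object@representatives)
    cat(sprintf("ClusterSet: %d reads in %d clusters (s = %g, k = %d, t = %d)\n",
                n, k, object@params$s, object@params$k, object@params$t))
    if (k > 0) {
        sizes <- tabulate(object@assignments, nbins = k)
        cat(sprintf("  cluster sizes: largest %d, singletons %d\n",
                    max(sizes), sum(sizes == 1L)))
        st <- object@stats
        cat(sprintf("  filter cascade: %g short-word pairs -> %g LCS survivors -> %g accepted\n",
                    st[["shortword_pairs"]], st[["lcs_pass_pairs"]],
                    st[["accepted_pairs"]]))
    }
    invisible(NULL)
})

#' @describeIn verifyClusters Re-align every member to its cluster
#'   representative and check the clustering contract: each stored member
#'   has identity at least `s`, and the assignments form a partition of the
#'   input.
#' @param x a [ClusterSet-class].
#' @param s identity threshold; defaults to the threshold the run used.
#' @param scheme [ScoringScheme-class]; defaults to the scheme the run used.
#' @return A list with `nMembers`, `nViolations`, `violations` (a
#'   `data.frame` of offending members), and `partitionOK`.
#' @export
setMethod("verifyClusters", "ClusterSet",
    function(x, s = NULL, scheme = NULL, ...) {
        p <- x@params
        if (is.null(s)) s <- p$s
        if (is.null(scheme))
            scheme <- scoringScheme(p$match, p$mismatch, p$gapOpen,
                                    p$gapExtend, p$endGapsFree)
        seqs <- as.character(x@sequences)
        .verifyMembership(seqs, x@assignments, x@representatives, s, scheme)
    })

.verifyMembership <- function(seqs, assign, reps, s, scheme) {
    n <- length(seqs)
    partitionOK <- !anyNA(assign) && length(assign) == n &&
        all(assign >= 1L & assign <= length(reps)) &&
        identical(sort(unique(assign[reps])), seq_along(reps))
    bad <- list()
    checked <- 0L
    for (ci in seq_along(reps)) {
        members <- which(assign == ci)
        members <- setdiff(members, reps[ci])
        if (length(members) == 0L) next
        ids <- cpp_identity_vs_set(seqs[reps[ci]], unname(seqs[members]),
                                   scheme@match, scheme@mismatch,
                                   scheme@gapOpen, scheme@gapExtend,
                                   scheme@endGapsFree)
        checked <- checked + length(members)
        low <- which(is.na(ids) | ids < s)
        if (length(low))
            bad[[length(bad) + 1L]] <- data.frame(
                cluster = ci, member = members[low],
                identity = ids[low])
    }
    violations <- if (length(bad)) do.call(rbind, bad)
                  else data.frame(cluster = integer(0), member = integer(0),
                                  identity = numeric(0))
    list(nMembers = checked, nViolations = nrow(violations),
         violations = violations, partitionOK = partitionOK)
}

#' Verify a written clustering against its input reads
#'
#' Standalone check of the on-disk output: parses a `.clstr` membership
#' file, re-aligns every member read to its cluster representative, and
#' reports members whose identity falls below `s`, plus whether the
#' membership is a partition of the input read set.
#'
#' @param fastaPath the input reads (FASTA/FASTQ) the clustering was run on.
#' @param clstrPath the `.clstr` file written by [writeClusters()].
#' @param s identity threshold the run used.
#' @param scheme alignment [ScoringScheme-class] the run used.
#' @return As [verifyClusters()].
#' @export
verifyClusterFiles <- function(fastaPath, clstrPath, s = 0.9,
                               scheme = scoringScheme()) {
    reads <- readSequences(fastaPath)
    memb <- readClstr(clstrPath)
    ids <- names(reads)
    idx <- match(memb$id, ids)
    if (anyNA(idx))
        stop(sprintf(".clstr names %d read(s) absent from '%s'",
                     sum(is.na(idx)), fastaPath))
    n <- length(reads)
    assign <- rep(NA_integer_, n)
    assign[idx] <- memb$cluster + 1L
    repRows <- memb[memb$isRep, , drop = FALSE]
    repRows <- repRows[order(repRows$cluster), , drop = FALSE]
    reps <- match(repRows$id, ids)
    .verifyMembership(as.character(reads), assign, reps, s, scheme)
}
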