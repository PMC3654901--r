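#' Scoring scheme for affine-gap alignment
#'
#' Parameters of the global affine-gap aligner.  A gap of length `L` costs
#' `gapOpen + L * gapExtend` (both are penalties, i.e. non-positive).  With
#' `endGapsFree = TRUE` (the default) leading and trailing gaps — read
#' overhangs — cost nothing, which is the natural choice when the identity
#' denominator is the shorter sequence length.
#'
#' @slot match numeric(1), reward for an identical aligned pair (> 0).
#' @slot mismatch numeric(1), penalty for a mismatched pair (<= 0).
#' @slot gapOpen numeric(1), penalty for opening a gap (<= gapExtend).
#' @slot gapExtend numeric(1), penalty per gapped base (<= 0).
#' @slot endGapsFree logical(1), whether terminal gaps are free.
#'
#' @seealso [scoringScheme()], [alignAffine()]
#' @exportClass ScoringScheme
setClass("ScoringScheme",
    representation(match = "numeric", mismatch = "numeric",
                   gapOpen = "numeric", gapExtend = "numeric",
                   endGapsFree = "logical"))

setValidity("ScoringScheme", function(object) {
    msg <- character(0)
    if (length(object@match) != 1L || object@match <= 0)
        msg <- c(msg, "'match' must be a single positive number")
    if (length(object@mismatch) != 1L || object@mismatch > 0)
        msg <- c(msg, "'mismatch' must be a single non-positive number")
    if (length(object@gapExtend) != 1L || object@gapExtend > 0)
        msg <- c(msg, "'gapExtend' must be a single non-positive number")
    if (length(object@gapOpen) != 1L || object@gapOpen > object@gapExtend)
        msg <- c(msg, "'gapOpen' must be <= 'gapExtend' (both penalties)")
    if (length(object@endGapsFree) != 1L || is.na(object@endGapsFree))
        msg <- c(msg, "'endGapsFree' must be TRUE or FALSE")
    if (length(msg)) msg else TRUE
})

#' Construct a ScoringScheme
#'
#' @param match reward for a match (default +2).
#' @param mismatch penalty for a mismatch (default -2).
#' @param gapOpen gap-opening penalty (default -6).
#' @param gapExtend per-base gap-extension penalty (default -1).
#' @param endGapsFree free terminal gaps (default `TRUE`).
#' @return A [ScoringScheme-class] object.
#' @examples
#' scoringScheme()
#' scoringScheme(match = 1, mismatch = -1, gapOpen = -4, gapExtend = -1)
#' @export
scoringScheme <- function(match = 2, mismatch = -2, gapOpen = -6,
                          gapExtend = -1, endGapsFree = TRUE) {
    new("ScoringScheme", match = as.numeric(match),
        mismatch = as.numeric(mismatch), gapOpen = as.numeric(gapOpen),
        gapExtend = as.numeric(gapExtend),
        endGapsFree = as.logical(endGapsFree))
}

#' Result of one affine-gap alignment
#'
#' @slot score numeric(1), optimal alignment score under the scheme.
#' @slot matches integer(1), identical aligned base pairs in the reported
#'   traceback.
#' @slot alignedLength integer(1), alignment columns including overhangs.
#' @slot identity numeric(1), `matches / min(m, n)` — matches divided by the
#'   shorter sequence length.
#'
#' @seealso [alignAffine()]
#' @exportClass AffineAlignment
setClass("AffineAlignment",
    representation(score = "numeric", matches = "integer",
                   alignedLength = "integer", identity = "numeric"))

setValidity("AffineAlignment", function(object) {
    if (object@matches < 0L)
        return("'matches' must be non-negative")
    if (object@identity < 0 || object@identity > 1)
        return("'identity' must lie in [0, 1]")
    TRUE
})

#' Per-base position masks of a sequence
#'
#' Bit masks over a sequence X, one per base: bit `i` (least significant bit
#' = position 0) of mask `b` is set iff position `i + 1` of X carries base
#' `b`.  Masks are stored as little-endian 64-bit blocks each carrying `w`
#' usable bits, so that the bit-parallel LCS kernel can chain arithmetic
#' carries and borrows across blocks.  Ambiguous positions (N) are set in no
#' mask.  Build with [computePM()]; inspect with [maskMatrix()].
#'
#' @slot masks named list of four raw vectors (A, C, G, T), the packed
#'   blocks.
#' @slot m integer(1), length of the indexed sequence.
#' @slot w integer(1), usable bits per block (8, 16, 32 or 64).
#'
#' @exportClass PositionMaskSet
setClass("PositionMaskSet",
    representation(masks = "list", m = "integer", w = "integer"))

setValidity("PositionMaskSet", function(object) {
    if (length(object@masks) != 4L ||
        !identical(names(object@masks), c("A", "C", "G", "T")))
        return("'masks' must be a list of four raw vectors named A, C, G, T")
    if (!all(vapply(object@masks, is.raw, logical(1))))
        return("'masks' must contain raw vectors")
    if (!(object@w %in% c(8L, 16L, 32L, 64L)))
        return("'w' must be one of 8, 16, 32, 64")
    nblocks <- if (object@m == 0L) 0L else ((object@m + object@w - 1L) %/% object@w)
    if (!all(lengths(object@masks) == 8L * nblocks))
        return("mask byte length inconsistent with 'm' and 'w'")
    TRUE
})

#' Short word table
#'
#' Index from k-mer code (radix-4 over A=0, C=1, G=2, T=3; 4^k addressable
#' codes) to the cluster representatives registered under that code.  Only
#' every k-th k-mer of a representative is registered (plus the final window
#' when the last stride does not land on the sequence end), which shrinks
#' the table to about 1/k of an all-k-mer index.  Queries enumerate all
#' their k-mers; see [findCandidates()].
#'
#' The table is a mutable handle: [registerRepresentative()] updates it in
#' place.
#'
#' @slot k integer(1), word length in bases (1..12).
#' @slot ptr external pointer to the index structure.
#'
#' @seealso [shortWordTable()]
#' @exportClass ShortWordTable
setClass("ShortWordTable",
    representation(k = "integer", ptr = "externalptr"))

#' Greedy clustering result
#'
#' Partition of the input reads into clusters, each with an immutable
#' representative (the first read assigned to it).
#'
#' @slot sequences the input reads, a [Biostrings::DNAStringSet] in input
#'   order.
#' @slot assignments integer vector, cluster index (1-based, creation order)
#'   per input read.
#' @slot identities numeric vector, alignment identity of each read to its
#'   cluster representative (1 for representatives themselves).
#' @slot representatives integer vector, input index of each cluster's
#'   representative, in cluster-creation order.
#' @slot params named list, the run configuration.
#' @slot stats named numeric, per-stage pair counts (candidates from the
#'   short-word filter, LCS-filter survivors, alignments performed,
#'   accepted pairs).
#'
#' @seealso [clusterGreedy()], [writeClusters()], [verifyClusters()]
#' @exportClass ClusterSet
setClass("ClusterSet",
    representation(sequences = "DNAStringSet", assignments = "integer",
                   identities = "numeric", representatives = "integer",
                   params = "list", stats = "numeric"))

setValidity("ClusterSet", function(object) {
    n <- length(object@sequences)
    k <- length(object@representatives)
    msg <- character(0)
    if (length(object@assignments) != n)
        msg <- c(msg, "one assignment per sequence required")
    if (length(object@identities) != n)
        msg <- c(msg, "one identity per sequence required")
    if (n > 0 && (anyNA(object@assignments) ||
                  any(object@assignments < 1L | object@assignments > k)))
        msg <- c(msg, "assignments must index clusters 1..nClusters")
    if (k > 0 && !identical(object@assignments[object@representatives],
                            seq_len(k)))
        msg <- c(msg, "representative i must be assigned to cluster i")
    if (n > 0 && any(object@identities < 0 | object@identities > 1))
        msg <- c(msg, "identities must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})
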