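#' Optimal affine-gap alignment of two reads
#'
#' Global three-state (Gotoh) dynamic programming under an affine gap model:
#' a gap of length L costs `gapOpen + L * gapExtend`.  With
#' `endGapsFree = TRUE` (the default) terminal gaps are free, so reads of
#' unequal length are not penalized for overhangs.  The reported identity is
#' the number of matched columns divided by the shorter sequence length,
#' taken from a single score-maximizing traceback that prefers the
#' match/mismatch state over gap states at ties.  N aligned to anything —
#' including another N — scores and counts as a mismatch.
#'
#' @param q,r the two sequences (character or `DNAString(Set)`); both must
#'   be non-empty.
#' @param scheme a [ScoringScheme-class]; defaults to
#'   match +2, mismatch -2, gap open -6, gap extend -1, free end gaps.
#' @return An [AffineAlignment-class] with the score, match count, aligned
#'   length (columns, overhangs included) and identity.
#' @examples
#' alignAffine("ACGT", "ACCT")           # 3 matches, identity 0.75
#' alignAffine("AAAA", "AA")             # identity 2/2 = 1 (free end gaps)
#' @export
alignAffine <- function(q, r, scheme = scoringScheme()) {
    qs <- .seqChar1(q, "q")
    rs <- .seqChar1(r, "r")
    if (nchar(qs) == 0L || nchar(rs) == 0L)
        stop("'q' and 'r' must be non-empty sequences")
    stopifnot(methods::is(scheme, "ScoringScheme"))
    methods::validObject(scheme)
    res <- cpp_align_affine(qs, rs, scheme@match, scheme@mismatch,
                            scheme@gapOpen, scheme@gapExtend,
                            scheme@endGapsFree)
    n <- min(nchar(qs), nchar(rs))
    new("AffineAlignment", score = res$score,
        matches = as.integer(res$matches),
        alignedLength = as.integer(res$aligned_length),
        identity = res$matches / n)
}

#' @describeIn alignAffine Same-cluster decision: is the identity at least
#'   the clustering threshold `s`?  The boundary is inclusive.
#' @param x an [AffineAlignment-class] or a bare identity value.
#' @param s identity threshold in (0, 1].
#' @export
identityCheck <- function(x, s) {
    if (length(s) != 1L || is.na(s) || s <= 0 || s > 1)
        stop("'s' must be a single value in (0, 1]")
    id <- if (methods::is(x, "AffineAlignment")) x@identity else as.numeric(x)
    id >= s
}

#' @rdname lcsclust-generics
#' @export
setMethod("alignmentScore", "AffineAlignment", function(x) x@score)

#' @rdname lcsclust-generics
#' @export
setMethod("alignmentMatches", "AffineAlignment", function(x) x@matches)

#' @rdname lcsclust-generics
#' @export
setMethod("alignedLength", "AffineAlignment", function(x) x@alignedLength)

#' @rdname lcsclust-generics
#' @export
setMethod("alignmentIdentity", "AffineAlignment", function(x) x@identity)

setMethod("show", "AffineAlignment", function(object) {
    cat(sprintf(
        "AffineAlignment: score %.1f, %d matches over %d columns, identity %.4f\n",
        object@score, object@matches, object@alignedLength, object@identity))
    invisible(NULL)
})
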