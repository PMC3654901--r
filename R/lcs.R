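#' Build the position masks of a sequence
#'
#' Precomputes, for each base, a bit mask over the sequence X marking the
#' positions carrying that base (bit 0 = first position).  The masks are
#' the only per-sequence state the bit-parallel LCS kernel needs, so in the
#' clustering loop they are computed once per cluster representative and
#' reused for every query compared against it.  Cost is O(sigma * m / w + m).
#'
#' @param x a single sequence (character or `DNAString(Set)`).
#' @param w usable bits per block: 8, 16, 32 or 64 (default).  Smaller
#'   blocks exercise multi-block carry chaining and exist mainly for
#'   testing; 64 is always fastest.
#' @return A [PositionMaskSet-class].
#' @examples
#' pm <- computePM("ACCA")
#' maskMatrix(pm)
#' @export
computePM <- function(x, w = 64L) {
    seq <- .seqChar1(x)
    w <- as.integer(w)
    if (!(w %in% c(8L, 16L, 32L, 64L)))
        stop("'w' must be one of 8, 16, 32, 64")
    res <- cpp_compute_pm(seq, w)
    new("PositionMaskSet", masks = res$masks, m = as.integer(res$m), w = w)
}

#' @describeIn computePM Decode a [PositionMaskSet-class] into a 4 x m
#'   logical matrix (rows A, C, G, T) for inspection; column i is all-FALSE
#'   at N positions.
#' @export
setMethod("maskMatrix", "PositionMaskSet", function(x) {
    m <- x@m
    out <- matrix(FALSE, nrow = 4L, ncol = m,
                  dimnames = list(BASES, NULL))
    if (m == 0L) return(out)
    for (b in seq_len(4L)) {
        bits <- as.logical(rawToBits(x@masks[[b]]))
        # block l contributes bits (l-1)*64 + 1..w of the raw layout
        nblocks <- length(x@masks[[b]]) %/% 8L
        keep <- unlist(lapply(seq_len(nblocks) - 1L,
                              function(l) l * 64L + seq_len(x@w)))
        bits <- bits[keep][seq_len(m)]
        out[b, ] <- bits
    }
    out
})

setMethod("show", "PositionMaskSet", function(object) {
    cat(sprintf("PositionMaskSet: m = %d positions, w = %d-bit blocks (%d block%s)\n",
                object@m, object@w,
                ceiling(object@m / object@w),
                if (ceiling(object@m / object@w) == 1L) "" else "s"))
    invisible(NULL)
})

#' LCS length by dynamic programming
#'
#' Classic O(mn) recurrence for the length of the longest common
#' subsequence: 0 at an empty prefix; diagonal + 1 when the last symbols
#' match; otherwise the maximum of dropping one symbol from either side.
#' Serves as the ground-truth oracle for [llcsBitparallel()].  N matches
#' nothing, not even another N.
#'
#' @param x,y sequences (character or `DNAString(Set)`); either may be
#'   empty.
#' @return Integer LCS length.
#' @examples
#' llcsDP("ATCAGTC", "CTAGAC")  # 4 ("TAGC")
#' @export
llcsDP <- function(x, y) {
    cpp_llcs_dp(.seqChar1(x, "x"), .seqChar1(y, "y"))
}

#' LCS length by the bit-parallel kernel
#'
#' Computes the same quantity as [llcsDP()] in O(sigma * m / w) time per
#' query symbol by packing the DP column state into w-bit blocks: per
#' symbol of `y`, one masked AND plus one blocked addition and subtraction
#' (with carries and borrows propagated across adjacent blocks) advance all
#' m cells at once, and the LCS length is read off as the number of cleared
#' bits in the final state vector.
#'
#' @param x a [PositionMaskSet-class] from [computePM()], or a sequence
#'   (in which case the masks are built on the fly).
#' @param y the query sequence.
#' @param w block width when `x` is a sequence; see [computePM()].
#' @return Integer LCS length, identical to `llcsDP(x, y)` for all inputs.
#' @examples
#' llcsBitparallel("ATCAGTC", "CTAGAC")           # 4
#' pm <- computePM("ATCAGTC")
#' llcsBitparallel(pm, "CTAGAC")                  # same, masks reused
#' @export
llcsBitparallel <- function(x, y, w = 64L) {
    if (!methods::is(x, "PositionMaskSet"))
        x <- computePM(x, w = w)
    cpp_llcs_bitparallel(x@masks, x@m, x@w, .seqChar1(y, "y"))
}

#' LCS filter: can this pair still reach identity s?
#'
#' The LCS length is the number of matches in the match-maximizing
#' alignment, so `LLCS(q, r) / n`, with n the shorter sequence length, is
#' an upper bound on the alignment identity of the pair.  A pair whose
#' bound falls below the clustering threshold `s` cannot reach identity
#' `s` and is discarded; pairs with true identity >= s always pass (no
#' false negatives).
#'
#' @param q,r the two sequences (the masks of `r` may be supplied directly
#'   as a [PositionMaskSet-class] built from it).
#' @param s identity threshold in (0, 1].
#' @param w block width for the kernel (default 64).
#' @return `TRUE` (pass: alignment still needed) or `FALSE` (prune).
#' @examples
#' lcsFilter("ATCAGTC", "CTAGAC", s = 0.9)  # FALSE: 4/6 < 0.9
#' lcsFilter("ACGTAC", "ACGTAC", s = 1)     # TRUE
#' @export
lcsFilter <- function(q, r, s, w = 64L) {
    if (length(s) != 1L || is.na(s) || s <= 0 || s > 1)
        stop("'s' must be a single value in (0, 1]")
    qs <- .seqChar1(q, "q")
    if (methods::is(r, "PositionMaskSet")) {
        n <- min(nchar(qs), r@m)
        if (n == 0L) return(FALSE)
        llcs <- cpp_llcs_bitparallel(r@masks, r@m, r@w, qs)
    } else {
        rs <- .seqChar1(r, "r")
        n <- min(nchar(qs), nchar(rs))
        if (n == 0L) return(FALSE)
        llcs <- llcsBitparallel(rs, qs, w = w)
    }
    (llcs / n) >= s
}
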