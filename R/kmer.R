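#' Create an empty short word table
#'
#' Builds the direct-address k-mer index used by the modified short-word
#' filter: 4^k buckets, addressed by the radix-4 code of a k-mer.  Cluster
#' representatives are added with [registerRepresentative()] and queried
#' with [findCandidates()].
#'
#' @param k word length in bases; 1 to 12 (default 9).
#' @return A [ShortWordTable-class] handle.
#' @examples
#' tab <- shortWordTable(2)
#' registerRepresentative(tab, "ACGTAC", 1)
#' findCandidates(tab, "TTAC", t = 1)
#' @export
shortWordTable <- function(k = 9L) {
    k <- as.integer(k)
    if (is.na(k) || k < 1L || k > 12L)
        stop("'k' must be an integer between 1 and 12")
    new("ShortWordTable", k = k, ptr = cpp_swt_create(k))
}

#' @describeIn shortWordTable Register a representative: every k-th k-mer
#'   (positions 0, k, 2k, ... in 0-based coordinates) is indexed, plus the
#'   final k-mer ending at the last base when the last stride does not land
#'   there.  Words containing N are skipped.  A representative shorter than
#'   k is registered with zero words (with a warning).  The table is
#'   updated in place; the number of words registered is returned invisibly.
#' @param table a [ShortWordTable-class].
#' @param rep,query a single sequence (character or `DNAString(Set)`).
#' @param repIndex 1-based index of the representative being registered.
#' @export
setMethod("registerRepresentative", "ShortWordTable",
    function(table, rep, repIndex, ...) {
        seq <- .seqChar1(rep, "rep")
        repIndex <- as.integer(repIndex)
        if (is.na(repIndex) || repIndex < 1L)
            stop("'repIndex' must be a positive integer")
        nwords <- cpp_swt_register(table@ptr, seq, repIndex - 1L)
        if (nchar(seq) < table@k)
            warning(sprintf(
                "representative %d is shorter than k = %d; registered with zero words",
                repIndex, table@k))
        invisible(nwords)
    })

#' @describeIn shortWordTable Enumerate all k-mers of `query` (every
#'   position) and return the representatives sharing at least `t` of them.
#'   A match is counted once per query position whose word is registered
#'   for that representative.  Queries shorter than k return no candidates.
#' @param t minimum number of common k-mers (>= 1).
#' @return `findCandidates` returns a `data.frame` with columns `rep`
#'   (1-based representative index, in creation order) and `count`.
#' @export
setMethod("findCandidates", "ShortWordTable",
    function(table, query, t, ...) {
        seq <- .seqChar1(query, "query")
        t <- as.integer(t)
        if (is.na(t) || t < 1L)
            stop("'t' must be a positive integer")
        hits <- cpp_swt_find(table@ptr, seq, t)
        data.frame(rep = hits$rep + 1L, count = hits$count)
    })

#' @describeIn shortWordTable All registered words as a `data.frame` with
#'   columns `code` (radix-4 k-mer code), `rep` (1-based) and `pos`
#'   (0-based registered position).
#' @export
setMethod("wordEntries", "ShortWordTable", function(table) {
    df <- cpp_swt_entries(table@ptr)
    df$rep <- df$rep + 1L
    df
})

#' @describeIn shortWordTable The word length k.
#' @export
setMethod("wordLength", "ShortWordTable", function(table) table@k)

setMethod("show", "ShortWordTable", function(object) {
    df <- cpp_swt_entries(object@ptr)
    cat(sprintf("ShortWordTable: k = %d (%s buckets), %d representatives, %d words\n",
                object@k, format(4^object@k, big.mark = ","),
                cpp_swt_nreps(object@ptr), nrow(df)))
    invisible(NULL)
})

#' Default common-word threshold for a read length
#'
#' The number of shared k-mers required by the short-word filter.  Because
#' only every k-th word of a representative is indexed, the threshold is set
#' low: 1 for reads up to 200 bases, 4 for longer reads.  As a guideline,
#' when porting a threshold t' from an all-k-mer filter (CD-HIT's), use
#' roughly `ceiling(t' / k)`.
#'
#' @param readLength read length(s) in bases (>= 1).
#' @return Integer vector of thresholds, one per length.
#' @examples
#' defaultWordThreshold(c(100, 150, 400))
#' @export
defaultWordThreshold <- function(readLength) {
    readLength <- as.integer(readLength)
    if (anyNA(readLength) || any(readLength < 1L))
        stop("'readLength' must contain positive integers")
    ifelse(readLength <= 200L, 1L, 4L)
}

#' Decimal code of a k-mer
#'
#' Radix-4 integer code (A=0, C=1, G=2, T=3) of a word, as used by the
#' short word table.  Words containing N have no code (`NA`).
#'
#' @param word character vector of equal-length DNA words.
#' @return numeric vector of codes in `[0, 4^k)`, `NA` for words with N.
#' @examples
#' kmerCode(c("AC", "GT", "AN"))
#' @export
kmerCode <- function(word) {
    word <- normalizeBases(word)
    vapply(word, function(wd) {
        codes <- match(strsplit(wd, "")[[1]], BASES) - 1
        if (anyNA(codes)) return(NA_real_)
        sum(codes * 4^(rev(seq_along(codes)) - 1))
    }, numeric(1), USE.NAMES = FALSE)
}
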