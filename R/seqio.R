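BASES <- c("A", "C", "G", "T")

#' Normalize base strings to the A/C/G/T/N alphabet
#'
#' Uppercases, maps U to T (RNA input), and maps every remaining character
#' that is not A, C, G or T — IUPAC ambiguity codes included — to N.
#'
#' @param x character vector of base strings.
#' @return character vector of the same length, names preserved.
#' @examples
#' normalizeBases(c("acgu", "ACRGT"))
#' @export
normalizeBases <- function(x) {
    out <- chartr("U", "T", toupper(x))
    gsub("[^ACGT]", "N", out, perl = TRUE)
}

# Coerce sequence input (character / DNAStringSet / XStringSet) to a named,
# normalized character vector.
.seqChar <- function(x, default_prefix = "seq") {
    if (methods::is(x, "XStringSet")) {
        nm <- names(x)
        x <- as.character(x)
        names(x) <- nm
    } else if (methods::is(x, "XString")) {
        x <- as.character(x)
    }
    if (!is.character(x))
        stop("sequences must be a character vector or a DNAStringSet")
    if (is.null(names(x)) && length(x) > 0)
        names(x) <- sprintf("%s%d", default_prefix, seq_along(x))
    normalizeBases(x)
}

# Single-sequence variant.
.seqChar1 <- function(x, arg = "sequence") {
    x <- .seqChar(x)
    if (length(x) != 1L)
        stop(sprintf("'%s' must be a single sequence", arg))
    unname(x)
}

#' Read DNA reads from FASTA or FASTQ
#'
#' Reads are returned in file order (clustering is order-dependent, so the
#' on-disk order is meaningful).  Bases are normalized with
#' [normalizeBases()]: lowercase is uppercased, U becomes T, and any other
#' non-ACGT character becomes N.  FASTQ quality strings are discarded.
#' Record identifiers are truncated at the first whitespace.
#'
#' @param path path to the sequence file.
#' @param format `"fasta"`, `"fastq"`, or `"auto"` (default), which detects
#'   the format from the first non-blank character (`>` versus `@`).
#' @return A named [Biostrings::DNAStringSet] in file order; an empty file
#'   yields an empty set.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">r1", "ACGT", ">r2", "acgtn"), fa)
#' readSequences(fa)
#' @export
readSequences <- function(path, format = c("auto", "fasta", "fastq")) {
    format <- match.arg(format)
    if (!file.exists(path))
        stop(sprintf("input file not found: %s", path))
    if (file.size(path) == 0L)
        return(Biostrings::DNAStringSet())
    if (format == "auto") {
        con <- file(path, "r")
        on.exit(close(con), add = TRUE)
        first <- ""
        repeat {
            line <- readLines(con, n = 1L)
            if (length(line) == 0L)
                return(Biostrings::DNAStringSet())
            line <- trimws(line)
            if (nzchar(line)) { first <- substr(line, 1L, 1L); break }
        }
        format <- switch(first,
            ">" = "fasta",
            "@" = "fastq",
            stop(sprintf(paste0("cannot detect format of '%s': first ",
                                "non-blank character is '%s', expected ",
                                "'>' (FASTA) or '@' (FASTQ)"), path, first)))
    }
    raw <- tryCatch(
        Biostrings::readBStringSet(path, format = format),
        error = function(e)
            stop(sprintf("failed to parse '%s' as %s: %s",
                         path, format, conditionMessage(e)), call. = FALSE))
    seqs <- normalizeBases(as.character(raw))
    names(seqs) <- sub("\\s.*$", "", names(raw))
    Biostrings::DNAStringSet(seqs)
}

#' @describeIn writeClusters Write a [ClusterSet-class] as a representative
#'   FASTA (`<outPrefix>`) plus a CD-HIT compatible `<outPrefix>.clstr`
#'   membership file.
#' @param x a [ClusterSet-class].
#' @param outPrefix output path prefix; the representative FASTA is written
#'   to `outPrefix` and the membership list to `paste0(outPrefix, ".clstr")`.
#' @return `writeClusters` invisibly returns the two paths written.
#' @export
setMethod("writeClusters", "ClusterSet", function(x, outPrefix, ...) {
    reps <- x@representatives
    fa <- x@sequences[reps]
    Biostrings::writeXStringSet(fa, filepath = outPrefix, format = "fasta")
    ids <- names(x@sequences)
    widths <- Biostrings::width(x@sequences)
    lines <- character(0)
    for (ci in seq_along(reps)) {
        members <- which(x@assignments == ci)
        # representative first, then members in input order
        members <- c(reps[ci], setdiff(members, reps[ci]))
        lines <- c(lines, sprintf(">Cluster %d", ci - 1L))
        ann <- ifelse(members == reps[ci], "*",
                      sprintf("at +/%.2f%%", 100 * x@identities[members]))
        lines <- c(lines, sprintf("%d\t%dnt, >%s... %s",
                                  seq_along(members) - 1L, widths[members],
                                  ids[members], ann))
    }
    clstr <- paste0(outPrefix, ".clstr")
    writeLines(lines, clstr)
    invisible(c(fasta = outPrefix, clstr = clstr))
})

#' Parse a CD-HIT style `.clstr` file
#'
#' Reads the membership list written by [writeClusters()] (or by CD-HIT
#' itself, for DNA runs) back into a table.
#'
#' @param path path to a `.clstr` file.
#' @return A `data.frame` with one row per member: `cluster` (0-based
#'   cluster number), `id`, `length` (bases), `isRep` (logical), and
#'   `identity` (fraction in `[0, 1]`; `NA` for representatives).
#' @examples
#' tf <- tempfile()
#' writeLines(c(">Cluster 0", "0\t4nt, >r1... *", "1\t4nt, >r2... at +/100.00%"),
#'            tf)
#' readClstr(tf)
#' @export
readClstr <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    cluster <- -1L
    out <- list()
    for (ln in lines) {
        if (startsWith(ln, ">Cluster")) {
            cluster <- as.integer(sub("^>Cluster\\s+", "", ln))
            next
        }
        if (cluster < 0L)
            stop(sprintf("malformed .clstr: member line before any cluster header in '%s'", path))
        m <- regmatches(ln, regexec(
            "^\\d+\t(\\d+)nt, >(.*)\\.\\.\\. (\\*|at [+-]/([0-9.]+)%)$", ln))[[1]]
        if (length(m) == 0L)
            stop(sprintf("malformed .clstr line: '%s'", ln))
        isRep <- m[4] == "*"
        out[[length(out) + 1L]] <- data.frame(
            cluster = cluster, id = m[3], length = as.integer(m[2]),
            isRep = isRep,
            identity = if (isRep) NA_real_ else as.numeric(m[5]) / 100,
            stringsAsFactors = FALSE)
    }
    if (length(out) == 0L)
        return(data.frame(cluster = integer(0), id = character(0),
                          length = integer(0), isRep = logical(0),
                          identity = numeric(0)))
    do.call(rbind, out)
}
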