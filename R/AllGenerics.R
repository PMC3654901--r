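#' @name lcsclust-generics
#' @title Generics defined by lcsclust
#' @description Accessor and operation generics for the package's S4
#'   classes; see the class pages for details.
#' @param x,table,object an lcsclust object.
#' @param ... passed to methods.
#' @keywords internal
NULL

#' @rdname lcsclust-generics
#' @export
setGeneric("registerRepresentative",
           function(table, rep, repIndex, ...)
               standardGeneric("registerRepresentative"))

#' @rdname lcsclust-generics
#' @export
setGeneric("findCandidates",
           function(table, query, t, ...) standardGeneric("findCandidates"))

#' @rdname lcsclust-generics
#' @export
setGeneric("wordEntries", function(table) standardGeneric("wordEntries"))

#' @rdname lcsclust-generics
#' @export
setGeneric("wordLength", function(table) standardGeneric("wordLength"))

#' @rdname lcsclust-generics
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))

#' @rdname lcsclust-generics
#' @export
setGeneric("alignmentScore", function(x) standardGeneric("alignmentScore"))

#' @rdname lcsclust-generics
#' @export
setGeneric("alignmentMatches", function(x) standardGeneric("alignmentMatches"))

#' @rdname lcsclust-generics
#' @export
setGeneric("alignedLength", function(x) standardGeneric("alignedLength"))

#' @rdname lcsclust-generics
#' @export
setGeneric("alignmentIdentity",
           function(x) standardGeneric("alignmentIdentity"))

#' @rdname lcsclust-generics
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @rdname lcsclust-generics
#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))

#' @rdname lcsclust-generics
#' @export
setGeneric("repSequences", function(x) standardGeneric("repSequences"))

#' @rdname lcsclust-generics
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))

#' @rdname lcsclust-generics
#' @export
setGeneric("identities", function(x) standardGeneric("identities"))

#' @rdname lcsclust-generics
#' @export
setGeneric("clusterMembers", function(x) standardGeneric("clusterMembers"))

#' @rdname lcsclust-generics
#' @export
setGeneric("runParams", function(x) standardGeneric("runParams"))

#' @rdname lcsclust-generics
#' @export
setGeneric("filterStats", function(x) standardGeneric("filterStats"))

#' @rdname lcsclust-generics
#' @export
setGeneric("writeClusters",
           function(x, outPrefix, ...) standardGeneric("writeClusters"))

#' @rdname lcsclust-generics
#' @export
setGeneric("verifyClusters",
           function(x, ...) standardGeneric("verifyClusters"))
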