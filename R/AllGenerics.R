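#' @include AllClasses.R
NULL

#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @export
setGeneric("vSegments", function(x) standardGeneric("vSegments"))
#' @export
setGeneric("jSegments", function(x) standardGeneric("jSegments"))
#' @export
setGeneric("segmentNames", function(x, class = c("V", "J"))
  standardGeneric("segmentNames"))
#' @export
setGeneric("anchorOffset", function(x, gene) standardGeneric("anchorOffset"))
#' @export
setGeneric("cloneTable", function(x) standardGeneric("cloneTable"))
#' @export
setGeneric("readOrigin", function(x) standardGeneric("readOrigin"))
#' @export
setGeneric("errorPositions", function(x) standardGeneric("errorPositions"))
#' @export
setGeneric("clonotypes", function(x) standardGeneric("clonotypes"))
#' @export
setGeneric("totalCounted", function(x) standardGeneric("totalCounted"))
#' @export
setGeneric("nFailed", function(x) standardGeneric("nFailed"))
#' @export
setGeneric("vjCounts", function(x) standardGeneric("vjCounts"))
#' @export
setGeneric("vjUsage", function(x) standardGeneric("vjUsage"))
#' @export
setGeneric("computeFrequencies", function(x) standardGeneric("computeFrequencies"))

## ---- accessors -----------------------------------------------------------

#' Accessors for TRAReference
#'
#' @param x A \linkS4class{TRAReference}.
#' @param class Segment class, \code{"V"} or \code{"J"}.
#' @param gene A gene symbol (normalized or not).
#' @return \code{vSegments}/\code{jSegments} return a named
#'   \code{DNAStringSet}; \code{segmentNames} a character vector;
#'   \code{anchorOffset} the 1-based start of the anchor codon.
#' @name TRAReference-accessors
#' @aliases vSegments jSegments segmentNames anchorOffset
#' @examples
#' ref <- buildMockReference(3, 3, seed = 1)
#' segmentNames(ref, "V")
#' anchorOffset(ref, "TRAV1")
NULL

#' @rdname TRAReference-accessors
#' @export
setMethod("vSegments", "TRAReference", function(x) {
  seg <- x@segments[S4Vectors::mcols(x@segments)$class == "V"]
  names(seg) <- S4Vectors::mcols(seg)$gene
  seg
})

#' @rdname TRAReference-accessors
#' @export
setMethod("jSegments", "TRAReference", function(x) {
  seg <- x@segments[S4Vectors::mcols(x@segments)$class == "J"]
  names(seg) <- S4Vectors::mcols(seg)$gene
  seg
})

#' @rdname TRAReference-accessors
#' @export
setMethod("segmentNames", "TRAReference", function(x, class = c("V", "J")) {
  class <- match.arg(class)
  mc <- S4Vectors::mcols(x@segments)
  mc$gene[mc$class == class]
})

#' @rdname TRAReference-accessors
#' @export
setMethod("anchorOffset", "TRAReference", function(x, gene) {
  mc <- S4Vectors::mcols(x@segments)
  i <- match(normalizeGeneName(gene), mc$gene)
  if (anyNA(i)) stop("unknown gene: ", paste(gene[is.na(i)], collapse = ", "))
  mc$anchor[i]
})

.refSegment <- function(x, gene) {
  mc <- S4Vectors::mcols(x@segments)
  i <- match(normalizeGeneName(gene), mc$gene)
  if (is.na(i)) stop("unknown gene: ", gene)
  list(gene = mc$gene[i], class = mc$class[i], anchor = mc$anchor[i],
       seq = as.character(x@segments[[i]]))
}

#' @export
setMethod("sampleId", "GroundTruth", function(x) x@sampleId)
#' @export
setMethod("sampleId", "RepertoireProfile", function(x) x@sampleId)
#' @export
setMethod("cloneTable", "GroundTruth", function(x) x@clones)
#' @export
setMethod("readOrigin", "GroundTruth", function(x) x@readOrigin)
#' @export
setMethod("errorPositions", "GroundTruth", function(x) x@errorPositions)
#' @export
setMethod("clonotypes", "RepertoireProfile", function(x) x@clonotypes)
#' @export
setMethod("totalCounted", "RepertoireProfile", function(x) x@totalCounted)
#' @export
setMethod("nFailed", "RepertoireProfile", function(x) x@nFailed)
#' @export
setMethod("vjCounts", "RepertoireProfile", function(x) x@vjMatrix)

## ---- show ----------------------------------------------------------------

setMethod("show", "TRAReference", function(object) {
  mc <- S4Vectors::mcols(object@segments)
  cat("TRAReference [", object@versionTag, "]: ",
      sum(mc$class == "V"), " V, ", sum(mc$class == "J"), " J segments\n",
      sep = "")
  cat("  V:", paste(head(mc$gene[mc$class == "V"], 8), collapse = " "), "\n")
  cat("  J:", paste(head(mc$gene[mc$class == "J"], 8), collapse = " "), "\n")
})

setMethod("show", "SimulationParam", function(object) {
  cat("SimulationParam: ", object@nClones, " clones, ", object@nReads,
      " reads, ", object@abundanceLaw, "(", object@abundanceParam, ")",
      ", error ", object@errorRate, ", seed ", object@seed, "\n", sep = "")
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth '", object@sampleId, "': ", nrow(object@clones),
      " true clones, ", nrow(object@readOrigin), " reads\n", sep = "")
})

setMethod("show", "RepertoireProfile", function(object) {
  cat("RepertoireProfile '", object@sampleId, "': ",
      nrow(object@clonotypes), " clonotypes over ", object@totalCounted,
      " productive reads (", object@nFailed, " excluded)\n", sep = "")
  if (nrow(object@clonotypes))
    print(utils::head(as.data.frame(object@clonotypes), 5))
})
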