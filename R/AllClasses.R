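#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata
#' @importFrom BiocGenerics score
#' @importFrom IRanges IntegerList
#' @importFrom Biostrings DNAStringSet DNAString
#' @importFrom BiocGenerics start end width
#' @importFrom stats rbinom rmultinom rgamma xtabs
#' @importFrom utils head write.table read.delim packageVersion
NULL

#' TRAV/TRAJ reference set
#'
#' Holds the TRAV and TRAJ germline nucleotide segments against which reads
#' are aligned, together with the anchor metadata that defines the CDR3:
#' for a V segment the 1-based start of the codon encoding the conserved
#' cysteine (IMGT position 104), for a J segment the start of the codon
#' encoding the conserved phenylalanine (IMGT position 118), which must be
#' followed by a glycine codon.
#'
#' The \code{segments} slot is a \link[Biostrings]{DNAStringSet} whose
#' \code{mcols} carry \code{gene} (normalized symbol), \code{class}
#' (\code{"V"} or \code{"J"}), \code{anchor} (1-based codon start) and
#' \code{functional} (logical). Validity enforces the anchor-codon identity
#' rules (Cys for V; Phe followed by Gly for J), a pure A/C/G/T alphabet,
#' uniqueness of normalized gene names, and the presence of at least one V
#' and one J segment.
#'
#' @slot segments A \code{DNAStringSet} with per-segment metadata columns.
#' @slot versionTag Free-text tag identifying the reference snapshot.
#' @seealso [buildMockReference()], [loadReferenceFasta()]
#' @export
setClass("TRAReference",
  representation(segments = "DNAStringSet", versionTag = "character"))

.validTRAReference <- function(object) {
  msgs <- character(0)
  seg <- object@segments
  mc <- S4Vectors::mcols(seg)
  need <- c("gene", "class", "anchor", "functional")
  if (!all(need %in% colnames(mc)))
    return(paste("segments mcols must contain:", paste(need, collapse = ", ")))
  if (length(seg) == 0) return("reference must contain at least one segment")
  if (!all(mc$class %in% c("V", "J")))
    msgs <- c(msgs, "segment class must be 'V' or 'J'")
  if (sum(mc$class == "V") < 1 || sum(mc$class == "J") < 1)
    msgs <- c(msgs, "need at least one V and one J segment")
  if (anyDuplicated(mc$gene))
    msgs <- c(msgs, "gene names must be unique after normalization")
  sq <- as.character(seg)
  if (any(nchar(sq) == 0) || any(grepl("[^ACGT]", sq)))
    msgs <- c(msgs, "sequences must be non-empty over {A,C,G,T}")
  if (length(msgs)) return(msgs)
  for (i in seq_along(seg)) {
    err <- .checkSegment(mc$gene[i], mc$class[i], sq[i], mc$anchor[i])
    if (!is.null(err)) msgs <- c(msgs, err)
  }
  if (length(msgs)) msgs else TRUE
}

## one-record anchor validation, shared with loadReferenceFasta()
.checkSegment <- function(gene, class, seq, anchor) {
  if (is.na(anchor) || anchor < 1L || anchor + 2L > nchar(seq))
    return(sprintf("%s: anchor codon (start %s) not fully inside sequence",
                   gene, anchor))
  codon <- substr(seq, anchor, anchor + 2L)
  if (class == "V") {
    if (!codon %in% c("TGT", "TGC"))
      return(sprintf("%s: V anchor codon %s does not encode Cys (IMGT 104)",
                     gene, codon))
  } else {
    if (translateCodons(codon) != "F")
      return(sprintf("%s: J anchor codon %s does not encode Phe (IMGT 118)",
                     gene, codon))
    if (anchor + 5L > nchar(seq))
      return(sprintf("%s: no codon after the J anchor (Gly expected)", gene))
    nxt <- substr(seq, anchor + 3L, anchor + 5L)
    if (translateCodons(nxt) != "G")
      return(sprintf("%s: codon after J anchor (%s) does not encode Gly",
                     gene, nxt))
  }
  NULL
}

setValidity("TRAReference", .validTRAReference)

#' Simulation parameters for a synthetic TRA repertoire
#'
#' Bundles the generator settings for [simulateSample()] and
#' [simulateCrossReactiveExperiment()]. Defaults describe one inflamed-tissue
#' amplicon library: 200 clones sequenced to 20,000 merged reads with a
#' geometrically skewed abundance distribution, junctional trimming up to
#' 6 nt per side, N-insertions up to 12 nt, a per-base substitution error of
#' 0.3%, 300 nt maximum read length, 5% MAIT and 5% iNKT spike-ins, and 20%
#' of clones shared between the two sensitization groups.
#'
#' @slot nClones Number of distinct true clones per sample.
#' @slot nReads Number of sequencing reads per sample.
#' @slot abundanceLaw \code{"geometric"} or \code{"dirichlet"}.
#' @slot abundanceParam Decay ratio (geometric) or concentration (dirichlet).
#' @slot trimMax Maximum nucleotides trimmed from the V 3' and J 5' ends.
#' @slot insertMax Maximum non-templated N-region nucleotides.
#' @slot errorRate Per-base substitution probability, in [0, 0.1].
#' @slot readLength Maximum read length in nucleotides.
#' @slot spikeMait,spikeInkt Frequency of the MAIT (TRAV1-TRAJ33) and iNKT
#'   (TRAV11-TRAJ18) spike-in clones.
#' @slot sharedFraction Fraction of clones planted in both groups.
#' @slot seed Integer seed making every draw reproducible.
#' @export
setClass("SimulationParam",
  representation(nClones = "integer", nReads = "integer",
                 abundanceLaw = "character", abundanceParam = "numeric",
                 trimMax = "integer", insertMax = "integer",
                 errorRate = "numeric", readLength = "integer",
                 spikeMait = "numeric", spikeInkt = "numeric",
                 sharedFraction = "numeric", seed = "integer"))

.validSimulationParam <- function(object) {
  msgs <- character(0)
  if (object@nClones < 1L) msgs <- c(msgs, "nClones must be >= 1")
  if (object@nReads < 1L) msgs <- c(msgs, "nReads must be >= 1")
  if (!object@abundanceLaw %in% c("geometric", "dirichlet"))
    msgs <- c(msgs, "abundanceLaw must be 'geometric' or 'dirichlet'")
  if (!is.finite(object@abundanceParam) || object@abundanceParam <= 0)
    msgs <- c(msgs, "abundanceParam must be positive")
  if (object@abundanceLaw == "geometric" && object@abundanceParam >= 1)
    msgs <- c(msgs, "geometric abundanceParam must be in (0,1)")
  if (object@trimMax < 0L) msgs <- c(msgs, "trimMax must be >= 0")
  if (object@insertMax < 0L) msgs <- c(msgs, "insertMax must be >= 0")
  if (object@errorRate < 0 || object@errorRate > 0.1)
    msgs <- c(msgs, "errorRate must be in [0, 0.1]")
  if (object@readLength < 30L) msgs <- c(msgs, "readLength must be >= 30")
  p <- c(object@spikeMait, object@spikeInkt, object@sharedFraction)
  if (any(p < 0) || any(p > 1))
    msgs <- c(msgs, "spike/shared proportions must be in [0,1]")
  if (object@spikeMait + object@spikeInkt + object@sharedFraction > 1)
    msgs <- c(msgs, "spikeMait + spikeInkt + sharedFraction must be <= 1")
  if (length(msgs)) msgs else TRUE
}
setValidity("SimulationParam", .validSimulationParam)

#' @describeIn SimulationParam-class Constructor with the package defaults.
#' @param nClones,nReads,abundanceLaw,abundanceParam,trimMax,insertMax,errorRate,readLength,spikeMait,spikeInkt,sharedFraction,seed
#'   See the corresponding slots.
#' @return A validated \code{SimulationParam} object.
#' @examples
#' SimulationParam(nClones = 10, nReads = 500, seed = 42)
#' @export
SimulationParam <- function(nClones = 200L, nReads = 20000L,
                            abundanceLaw = "geometric", abundanceParam = 0.95,
                            trimMax = 6L, insertMax = 12L, errorRate = 0.003,
                            readLength = 300L, spikeMait = 0.05,
                            spikeInkt = 0.05, sharedFraction = 0.2,
                            seed = 1L) {
  new("SimulationParam", nClones = as.integer(nClones),
      nReads = as.integer(nReads), abundanceLaw = abundanceLaw,
      abundanceParam = abundanceParam, trimMax = as.integer(trimMax),
      insertMax = as.integer(insertMax), errorRate = errorRate,
      readLength = as.integer(readLength), spikeMait = spikeMait,
      spikeInkt = spikeInkt, sharedFraction = sharedFraction,
      seed = as.integer(seed))
}

#' Ground truth of a simulated repertoire sample
#'
#' Records everything the simulator knows so recovery can be scored exactly:
#' the true clone table (gene calls, junction nucleotides, CDR3 amino acids,
#' frequency), the clone of origin of every read, and the 1-based positions
#' at which substitution errors were introduced into each read.
#'
#' @slot sampleId Sample identifier.
#' @slot clones A \code{DataFrame} with columns \code{v_name}, \code{j_name},
#'   \code{junction_nt}, \code{cdr3_aa}, \code{frequency}, \code{productive},
#'   \code{clone_seq}.
#' @slot readOrigin A \code{DataFrame} with columns \code{read_id},
#'   \code{clone_index} (row in \code{clones}).
#' @slot errorPositions An \code{IntegerList}, one element per read.
#' @export
setClass("GroundTruth",
  representation(sampleId = "character", clones = "DataFrame",
                 readOrigin = "DataFrame", errorPositions = "IntegerList"))

.validGroundTruth <- function(object) {
  msgs <- character(0)
  cl <- object@clones
  if (nrow(cl) && abs(sum(cl$frequency) - 1) > 1e-9)
    msgs <- c(msgs, "clone frequencies must sum to 1")
  if (nrow(object@readOrigin)) {
    idx <- object@readOrigin$clone_index
    if (any(is.na(idx)) || any(idx < 1L) || any(idx > nrow(cl)))
      msgs <- c(msgs, "every read must map to exactly one clone")
  }
  if (length(object@errorPositions) != nrow(object@readOrigin))
    msgs <- c(msgs, "errorPositions must have one element per read")
  if (length(msgs)) msgs else TRUE
}
setValidity("GroundTruth", .validGroundTruth)

#' Clonotype profile of one repertoire sample
#'
#' The unit of counting follows the unique-read definition used in TRA
#' repertoire sequencing: reads sharing the same TRAV gene, TRAJ gene and
#' deduced CDR3 amino-acid sequence are one clonotype. Clonotypes are ranked
#' by copy number (ties broken lexicographically on the key for
#' reproducibility) and carry percentage occurrence frequencies over all
#' productive counted reads.
#'
#' @slot sampleId Sample identifier.
#' @slot clonotypes A \code{DataFrame} with columns \code{rank},
#'   \code{v_call}, \code{j_call}, \code{junction_aa}, \code{copy_count},
#'   \code{frequency_pct}.
#' @slot totalCounted Number of productive reads counted.
#' @slot nFailed Number of reads excluded (nonproductive or unassigned).
#' @slot vjMatrix Integer matrix of summed copy counts, V genes x J genes.
#' @seealso [buildClonotypes()], [vjUsage()], [topClonotypeTable()]
#' @export
setClass("RepertoireProfile",
  representation(sampleId = "character", clonotypes = "DataFrame",
                 totalCounted = "integer", nFailed = "integer",
                 vjMatrix = "matrix"))

.validRepertoireProfile <- function(object) {
  msgs <- character(0)
  ct <- object@clonotypes
  if (nrow(ct)) {
    key <- paste(ct$v_call, ct$j_call, ct$junction_aa, sep = "\r")
    if (anyDuplicated(key)) msgs <- c(msgs, "clonotype keys must be unique")
    if (sum(ct$copy_count) != object@totalCounted)
      msgs <- c(msgs, "copy counts must sum to totalCounted")
    if (abs(sum(ct$frequency_pct) - 100) > 1e-6)
      msgs <- c(msgs, "frequencies must sum to 100")
    if (ct$copy_count[1L] != max(ct$copy_count))
      msgs <- c(msgs, "rank 1 must have the maximal copy count")
    if (sum(object@vjMatrix) != object@totalCounted)
      msgs <- c(msgs, "vjMatrix grand total must equal totalCounted")
  } else if (object@totalCounted != 0L) {
    msgs <- c(msgs, "empty profile must have totalCounted = 0")
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("RepertoireProfile", .validRepertoireProfile)
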