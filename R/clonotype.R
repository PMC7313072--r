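## Clonotype collapse, counting, ranking, frequencies and V-J usage.
##
## A unique clonotype is defined by literal identity of the normalized TRAV
## gene, TRAJ gene and deduced CDR3 amino-acid sequence ("no identity in
## TRAV and TRAJ and a deduced amino acid sequence of CDR3"): no fuzzy CDR3
## clustering, and nucleotide-level sub-variants of the same amino-acid
## junction are merged. Frequencies are percentages over productive counted
## reads; nonproductive and unassigned reads are tallied separately.

#' Collapse read annotations into a ranked clonotype profile
#'
#' Productive annotations are grouped by exact
#' \code{(v_call, j_call, junction_aa)} equality; the copy number of each
#' clonotype is its group size. Clonotypes are ranked by copy count
#' descending, ties broken by the lexicographic order of the key (C locale)
#' so that ranking is reproducible, and percentage occurrence frequencies
#' are computed over all counted reads. The V-J usage matrix of summed
#' copy counts is built alongside.
#'
#' @param annotations A data.frame as returned by [annotateReads()].
#' @param sampleId Sample identifier for the profile.
#' @return A \linkS4class{RepertoireProfile}; an empty one (zero counted
#'   reads) when no annotation is productive.
#' @examples
#' ann <- data.frame(sequence_id = paste0("r", 1:4),
#'   v_call = "TRAV1", j_call = "TRAJ33",
#'   junction = NA, junction_aa = c("CAAF", "CAAF", "CAAF", "CWAF"),
#'   productive = TRUE, fail_reason = "none")
#' clonotypes(buildClonotypes(ann, "demo"))
#' @export
buildClonotypes <- function(annotations, sampleId = "sample") {
  stopifnot(all(c("v_call", "j_call", "junction_aa", "productive") %in%
                names(annotations)))
  ok <- annotations$productive & !is.na(annotations$junction_aa) &
    !is.na(annotations$v_call) & !is.na(annotations$j_call)
  prod <- annotations[ok, , drop = FALSE]
  nFailed <- sum(!ok)
  if (nrow(prod) == 0L) {
    return(new("RepertoireProfile", sampleId = sampleId,
               clonotypes = S4Vectors::DataFrame(
                 rank = integer(0), v_call = character(0),
                 j_call = character(0), junction_aa = character(0),
                 copy_count = integer(0), frequency_pct = numeric(0)),
               totalCounted = 0L, nFailed = as.integer(nFailed),
               vjMatrix = matrix(0L, 0, 0)))
  }
  v <- normalizeGeneName(prod$v_call)
  j <- normalizeGeneName(prod$j_call)
  key <- paste(v, j, prod$junction_aa, sep = "\r")
  agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
  parts <- strsplit(agg$key, "\r", fixed = TRUE)
  df <- data.frame(v_call = vapply(parts, `[`, "", 1L),
                   j_call = vapply(parts, `[`, "", 2L),
                   junction_aa = vapply(parts, `[`, "", 3L),
                   copy_count = as.integer(agg$Freq),
                   stringsAsFactors = FALSE)
  ord <- order(-df$copy_count, df$v_call, df$j_call, df$junction_aa,
               method = "radix")
  df <- df[ord, , drop = FALSE]
  total <- sum(df$copy_count)
  ct <- S4Vectors::DataFrame(
    rank = seq_len(nrow(df)), v_call = df$v_call, j_call = df$j_call,
    junction_aa = df$junction_aa, copy_count = df$copy_count,
    frequency_pct = 100 * df$copy_count / total)
  vj <- stats::xtabs(copy_count ~ v_call + j_call, data = df)
  vjm <- matrix(as.integer(vj), nrow(vj), ncol(vj),
                dimnames = dimnames(vj))
  prof <- new("RepertoireProfile", sampleId = sampleId, clonotypes = ct,
              totalCounted = as.integer(total),
              nFailed = as.integer(nFailed), vjMatrix = vjm)
  methods::validObject(prof)
  prof
}

#' @describeIn buildClonotypes Recompute percentage frequencies from the
#'   copy counts (idempotent); errors on an all-zero profile.
#' @param x A \linkS4class{RepertoireProfile}.
#' @export
setMethod("computeFrequencies", "RepertoireProfile", function(x) {
  if (x@totalCounted < 1L)
    stop("undefined frequency: profile has zero counted reads")
  ct <- x@clonotypes
  ct$frequency_pct <- 100 * ct$copy_count / x@totalCounted
  x@clonotypes <- ct
  methods::validObject(x)
  x
})

#' @describeIn buildClonotypes V-J usage as percentages of counted reads
#'   (cells sum to 100).
#' @export
setMethod("vjUsage", "RepertoireProfile", function(x) {
  if (x@totalCounted < 1L)
    stop("undefined frequency: profile has zero counted reads")
  100 * x@vjMatrix / x@totalCounted
})

#' Rebuild a profile from a written clonotype table
#'
#' Inverse of [writeClonotypeTsv()] up to the number of failed reads, which
#' a clonotype table does not carry.
#'
#' @param df A data.frame with columns \code{v_call}, \code{j_call},
#'   \code{junction_aa}, \code{copy_count} (e.g. from [readTsvReport()]).
#' @param sampleId Sample identifier; when \code{df} has a
#'   \code{sample_id} column its first value is the default.
#' @return A \linkS4class{RepertoireProfile}.
#' @export
profileFromClonotypeTable <- function(df, sampleId = NULL) {
  if (is.null(sampleId))
    sampleId <- if ("sample_id" %in% names(df) && nrow(df))
      as.character(df$sample_id[1L]) else "sample"
  ann <- data.frame(
    sequence_id = sprintf("row_%06d", seq_len(sum(df$copy_count))),
    v_call = rep(df$v_call, df$copy_count),
    j_call = rep(df$j_call, df$copy_count),
    junction = NA_character_,
    junction_aa = rep(df$junction_aa, df$copy_count),
    productive = TRUE, fail_reason = "none", stringsAsFactors = FALSE)
  buildClonotypes(ann, sampleId)
}
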