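## Invariant T-cell flagging and cross-sample shared clonotypes.
##
## MAIT and iNKT cells carry canonical semi-invariant TRA chains and are
## recognized here purely by their V-J gene pair (Trav1-Traj33 for MAIT,
## Trav11d-Traj18 for iNKT); the CDR3 is not consulted. Sharing between two
## samples is defined at the clonotype-key level -- identical (V, J,
## CDR3aa) -- with no frequency threshold.

#' Default invariant T-cell rules
#'
#' MAIT: TRAV1 + TRAJ33; iNKT: TRAV11 + TRAJ18. The mouse duplicate-locus
#' suffix (Trav11d) is absorbed by [defaultGeneAliases()].
#'
#' @return A data.frame with columns \code{label}, \code{v_name},
#'   \code{j_name}.
#' @export
defaultInvariantRules <- function() {
  data.frame(label = c("MAIT", "iNKT"),
             v_name = c("TRAV1", "TRAV11"),
             j_name = c("TRAJ33", "TRAJ18"),
             stringsAsFactors = FALSE)
}

#' Default gene-name alias table
#'
#' Maps duplicate-locus mouse namings onto the reference symbols used here
#' (TRAV11D and TRAV11D-1 stand for the TRAV11 locus). User-extensible:
#' pass your own named character vector wherever aliases are accepted.
#'
#' @return Named character vector, \code{alias -> canonical}.
#' @export
defaultGeneAliases <- function() {
  c(TRAV11D = "TRAV11", `TRAV11D-1` = "TRAV11")
}

.applyAliases <- function(x, aliases) {
  hit <- match(x, names(aliases))
  x[!is.na(hit)] <- aliases[hit[!is.na(hit)]]
  x
}

#' Read an invariant-rules file
#'
#' Three-column TSV: \code{label}, \code{v_name}, \code{j_name}. An empty
#' file (header only) yields zero rules, i.e. no invariant labels.
#'
#' @param path TSV path.
#' @return A rules data.frame as in [defaultInvariantRules()].
#' @export
readInvariantRules <- function(path) {
  df <- readTsvReport(path)
  stopifnot(all(c("label", "v_name", "j_name") %in% names(df)))
  df[, c("label", "v_name", "j_name")]
}

#' Flag invariant T-cell clonotypes by V-J pair
#'
#' Returns, for each clonotype, the label of the first rule whose
#' normalized (V, J) pair matches; \code{NA} otherwise. Deterministic and
#' independent of clonotype frequency.
#'
#' @param vCall,jCall Character vectors of gene calls (recycled to common
#'   length).
#' @param rules Rules data.frame, see [defaultInvariantRules()].
#' @param aliases Named alias vector, see [defaultGeneAliases()].
#' @return Character vector of labels or \code{NA}.
#' @examples
#' flagInvariant(c("Trav1", "TRAV11D", "TRAV8D-1"),
#'               c("TRAJ33", "TRAJ18", "TRAJ49"))
#' @export
flagInvariant <- function(vCall, jCall, rules = defaultInvariantRules(),
                          aliases = defaultGeneAliases()) {
  n <- max(length(vCall), length(jCall))
  v <- .applyAliases(normalizeGeneName(rep_len(vCall, n)), aliases)
  j <- .applyAliases(normalizeGeneName(rep_len(jCall, n)), aliases)
  out <- rep(NA_character_, n)
  if (nrow(rules) == 0L) return(out)
  rv <- .applyAliases(normalizeGeneName(rules$v_name), aliases)
  rj <- .applyAliases(normalizeGeneName(rules$j_name), aliases)
  key <- paste(v, j, sep = "\r")
  rkey <- paste(rv, rj, sep = "\r")
  hit <- match(key, rkey)          # first matching rule wins
  out[!is.na(hit)] <- rules$label[hit[!is.na(hit)]]
  out
}

#' Find clonotypes shared between two samples
#'
#' The exact key-set intersection on (v_call, j_call, junction_aa), with
#' the percentage frequency in each sample attached, ordered by the
#' smaller of the two frequencies, descending. Symmetric in its arguments
#' up to column swap.
#'
#' @param profileA,profileB \linkS4class{RepertoireProfile} objects.
#' @return A data.frame with columns \code{sample_a}, \code{sample_b},
#'   \code{v_call}, \code{j_call}, \code{junction_aa}, \code{freq_in_a},
#'   \code{freq_in_b}.
#' @examples
#' ref <- buildMockReference(5, 5, seed = 1)
#' xp <- simulateCrossReactiveExperiment(
#'   SimulationParam(nClones = 10, nReads = 300, errorRate = 0,
#'                   sharedFraction = 0.3), ref)
#' a <- buildClonotypes(annotateReads(xp[[1]]$reads, ref), "Ni-Pd")
#' b <- buildClonotypes(annotateReads(xp[[2]]$reads, ref), "Cr-Pd")
#' findSharedClonotypes(a, b)
#' @export
findSharedClonotypes <- function(profileA, profileB) {
  ca <- as.data.frame(clonotypes(profileA))
  cb <- as.data.frame(clonotypes(profileB))
  m <- merge(ca[, c("v_call", "j_call", "junction_aa", "frequency_pct")],
             cb[, c("v_call", "j_call", "junction_aa", "frequency_pct")],
             by = c("v_call", "j_call", "junction_aa"),
             suffixes = c("_a", "_b"))
  out <- data.frame(sample_a = rep(sampleId(profileA), nrow(m)),
                    sample_b = rep(sampleId(profileB), nrow(m)),
                    v_call = m$v_call, j_call = m$j_call,
                    junction_aa = m$junction_aa,
                    freq_in_a = m$frequency_pct_a,
                    freq_in_b = m$frequency_pct_b,
                    stringsAsFactors = FALSE)
  ord <- order(-pmin(out$freq_in_a, out$freq_in_b), out$v_call, out$j_call,
               out$junction_aa, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top clonotypes with invariant labels
#'
#' The first \code{k} clonotypes by rank, annotated with the invariant
#' T-cell label (MAIT/iNKT) where the V-J pair matches a rule. Requests
#' beyond the table size return the full table.
#'
#' @param profile A \linkS4class{RepertoireProfile}.
#' @param k Number of rows requested (>= 1).
#' @param rules,aliases See [flagInvariant()].
#' @return A data.frame with the clonotype columns plus \code{label}.
#' @export
topClonotypeTable <- function(profile, k = 10L,
                              rules = defaultInvariantRules(),
                              aliases = defaultGeneAliases()) {
  if (k < 1L) stop("k must be >= 1")
  ct <- as.data.frame(clonotypes(profile))
  ct <- utils::head(ct, k)
  ct$label <- flagInvariant(ct$v_call, ct$j_call, rules, aliases)
  rownames(ct) <- NULL
  ct
}
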