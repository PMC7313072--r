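## Reference construction and I/O.
##
## A reference is a set of TRAV/TRAJ germline nucleotide segments with the
## anchor-codon coordinate carried as explicit metadata (full IMGT gap
## numbering is deliberately out of scope: the Cys-104 / Phe-118 anchors are
## the only numbering facts the pipeline needs). Resolution is gene-level:
## alleles collapse to one sequence per gene.

## run code under a temporary RNG state so generators are deterministic
## under their own seed without disturbing the caller's stream
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

.newReference <- function(gene, class, seq, anchor, functional, versionTag) {
  seg <- Biostrings::DNAStringSet(seq)
  names(seg) <- gene
  S4Vectors::mcols(seg) <- S4Vectors::DataFrame(
    gene = gene, class = class, anchor = as.integer(anchor),
    functional = functional)
  new("TRAReference", segments = seg, versionTag = versionTag)
}

## random in-frame codons avoiding stops (used for the CDR3-contributing
## V 3' tails and J 5' heads, which real germline segments keep open)
.randomCodons <- function(nCodons) {
  if (nCodons <= 0) return("")
  bases <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  ok <- setdiff(all3, c("TAA", "TAG", "TGA"))
  paste(sample(ok, nCodons, replace = TRUE), collapse = "")
}

## gene names guaranteed to be present (headline, invariant and dominant
## clonotype genes of the murine metal-allergy analysis) followed by fillers
.mockVNames <- function(n) {
  req <- c("TRAV1", "TRAV5-1", "TRAV8D-1", "TRAV11")
  fill <- paste0("TRAV", setdiff(2:40, c(1, 5, 8, 11)))
  head(c(req, fill), n)
}
.mockJNames <- function(n) {
  req <- c("TRAJ18", "TRAJ33", "TRAJ37", "TRAJ49")
  fill <- paste0("TRAJ", setdiff(2:60, c(18, 33, 37, 49)))
  head(c(req, fill), n)
}

#' Build a mock TRAV/TRAJ reference set
#'
#' Generates a deterministic, fully validated reference without any external
#' download. Segments are random A/C/G/T sequences with correct anchor
#' codons planted: every V ends in a Cys codon (TGT/TGC) followed by a short
#' 3' tail (6-12 nt, so junctional trimming never deletes the anchor), and
#' every J starts with a short 5' head (6-12 nt) before a Phe codon
#' (TTT/TTC) immediately followed by a Gly codon. When at least 4 segments
#' of a class are requested, the gene names include the headline clonotype
#' genes TRAV1, TRAV5-1, TRAV8D-1, TRAV11 and TRAJ18, TRAJ33, TRAJ37,
#' TRAJ49, so invariant (MAIT/iNKT) and dominant cross-reactive clonotypes
#' can be simulated.
#'
#' Unlike real germline V genes, mock segments are unrelated random
#' sequences; see the package vignette for what this does and does not
#' stress in segment assignment.
#'
#' @param nV,nJ Number of V and J segments (each >= 1).
#' @param seed Integer seed; the same seed reproduces the set exactly.
#' @return A \linkS4class{TRAReference}.
#' @examples
#' ref <- buildMockReference(5, 5, seed = 1)
#' segmentNames(ref, "J")
#' @export
buildMockReference <- function(nV = 8L, nJ = 8L, seed = 1L) {
  if (nV < 1L || nJ < 1L) stop("nV and nJ must be >= 1")
  .withSeed(seed, {
    vn <- .mockVNames(nV)
    jn <- .mockJNames(nJ)
    vanchor <- integer(nV); vseq <- character(nV)
    for (i in seq_len(nV)) {
      pre <- sample(90:110, 1L)           # region upstream of Cys-104
      tailCod <- sample(2:4, 1L)          # trimmable, stop-free 3' tail
      vseq[i] <- paste0(.randomDna(pre), sample(c("TGT", "TGC"), 1L),
                        .randomCodons(tailCod))
      vanchor[i] <- pre + 1L
    }
    janchor <- integer(nJ); jseq <- character(nJ)
    for (i in seq_len(nJ)) {
      headCod <- sample(2:4, 1L)          # trimmable, stop-free 5' head
      rest <- sample(36:45, 1L)           # FR4 tail after the F-G motif
      jseq[i] <- paste0(.randomCodons(headCod), sample(c("TTT", "TTC"), 1L),
                        paste0("GG", sample(c("A", "C", "G", "T"), 1L)),
                        .randomDna(rest))
      janchor[i] <- 3L * headCod + 1L
    }
    ref <- .newReference(
      gene = c(vn, jn), class = rep(c("V", "J"), c(nV, nJ)),
      seq = c(vseq, jseq), anchor = c(vanchor, janchor),
      functional = rep(TRUE, nV + nJ),
      versionTag = sprintf("mock-%dV-%dJ-seed%d", nV, nJ, seed))
    methods::validObject(ref)
    ref
  })
}

#' Load a TRAV/TRAJ reference from FASTA
#'
#' Two input dialects are accepted: headers of the form
#' \code{gene|V|anchor} / \code{gene|J|anchor} with a 1-based anchor-codon
#' start, or plain gene-name headers plus a sidecar \code{anchors} table.
#' Gene names are normalized with [normalizeGeneName()]. Every record is
#' validated against the anchor invariants (Cys codon for V; Phe + Gly
#' codons for J); offending records are reported per gene and the load
#' fails.
#'
#' @param path Path to a FASTA file.
#' @param anchors Optional data.frame with columns \code{gene} and
#'   \code{anchor} (1-based anchor codon start), and optionally
#'   \code{class}; required when headers do not carry anchors.
#' @param versionTag Free-text tag recorded on the reference.
#' @return A validated \linkS4class{TRAReference}.
#' @seealso [writeReferenceFasta()]
#' @export
loadReferenceFasta <- function(path, anchors = NULL,
                               versionTag = basename(path)) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (length(seqs) == 0) stop("no FASTA records in ", path)
  hdr <- names(seqs)
  if (all(grepl("\\|", hdr))) {
    parts <- strsplit(hdr, "|", fixed = TRUE)
    bad <- lengths(parts) != 3
    if (any(bad))
      stop("malformed headers (expect gene|class|anchor): ",
           paste(hdr[bad], collapse = ", "))
    gene <- normalizeGeneName(vapply(parts, `[`, "", 1L))
    class <- vapply(parts, `[`, "", 2L)
    anchor <- suppressWarnings(as.integer(vapply(parts, `[`, "", 3L)))
  } else {
    if (is.null(anchors))
      stop("plain FASTA headers require an 'anchors' sidecar table")
    gene <- normalizeGeneName(sub("\\s.*$", "", hdr))
    i <- match(gene, normalizeGeneName(anchors$gene))
    if (anyNA(i))
      stop("missing anchor entry for gene(s): ",
           paste(gene[is.na(i)], collapse = ", "))
    anchor <- as.integer(anchors$anchor[i])
    class <- if ("class" %in% names(anchors)) as.character(anchors$class[i])
             else ifelse(grepl("^TRAV", gene), "V",
                         ifelse(grepl("^TRAJ", gene), "J", NA_character_))
    if (anyNA(class))
      stop("cannot infer segment class for: ",
           paste(gene[is.na(class)], collapse = ", "))
  }
  sq <- as.character(seqs)
  reports <- character(0)
  for (k in seq_along(sq)) {
    if (is.na(anchor[k])) {
      reports <- c(reports, sprintf("%s: missing/non-numeric anchor", gene[k]))
      next
    }
    if (!class[k] %in% c("V", "J")) {
      reports <- c(reports, sprintf("%s: bad segment class '%s'",
                                    gene[k], class[k]))
      next
    }
    if (grepl("[^ACGT]", sq[k]) || !nzchar(sq[k])) {
      reports <- c(reports, sprintf("%s: sequence not over {A,C,G,T}", gene[k]))
      next
    }
    err <- .checkSegment(gene[k], class[k], sq[k], anchor[k])
    if (!is.null(err)) reports <- c(reports, err)
  }
  if (length(reports))
    stop("reference validation failed:\n  ",
         paste(reports, collapse = "\n  "))
  ref <- .newReference(gene, class, sq, anchor,
                       functional = rep(TRUE, length(gene)),
                       versionTag = versionTag)
  methods::validObject(ref)
  ref
}

#' Write a reference set to FASTA
#'
#' Uses the \code{gene|class|anchor} header dialect read back by
#' [loadReferenceFasta()]; the round trip reproduces names, sequences and
#' anchors exactly.
#'
#' @param ref A \linkS4class{TRAReference}.
#' @param path Output FASTA path.
#' @return Invisibly, \code{path}.
#' @export
writeReferenceFasta <- function(ref, path) {
  stopifnot(is(ref, "TRAReference"))
  mc <- S4Vectors::mcols(ref@segments)
  out <- ref@segments
  names(out) <- sprintf("%s|%s|%d", mc$gene, mc$class, mc$anchor)
  Biostrings::writeXStringSet(out, path, format = "fasta")
  invisible(path)
}
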