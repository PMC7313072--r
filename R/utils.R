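#' Normalize a TRAV/TRAJ gene name
#'
#' Uppercases and strips any allele suffix (\code{"*NN"}), so mixed stylings
#' such as \code{"Trav8d-1"} and \code{"TRAJ33*01"} collapse to the
#' gene-level symbols used throughout the package. Idempotent and
#' vectorized.
#'
#' @param raw Character vector of gene names.
#' @return Character vector of normalized names.
#' @examples
#' normalizeGeneName(c("Trav8d-1", "TRAJ33*01", "TRAV1"))
#' @export
normalizeGeneName <- function(raw) {
  if (length(raw) == 0) return(character(0))
  if (any(is.na(raw)) || any(!nzchar(trimws(raw))))
    stop("invalid gene name: empty or NA")
  sub("\\*.*$", "", toupper(trimws(raw)))
}

#' Translate a nucleotide string codon-by-codon
#'
#' Standard genetic code; stop codons translate to \code{"*"}.
#'
#' @param nt Character vector of nucleotide strings, each with length a
#'   multiple of 3 over \{A,C,G,T\}.
#' @return Character vector of amino-acid strings.
#' @examples
#' translateCodons(c("TGT", "TTTGGT", "TAA"))
#' @export
translateCodons <- function(nt) {
  if (length(nt) == 0) return(character(0))
  if (any(is.na(nt)) || any(nchar(nt) %% 3 != 0) || any(grepl("[^ACGT]", nt)))
    stop("translateCodons: length must be a multiple of 3 over {A,C,G,T}")
  out <- character(length(nt))
  nz <- nchar(nt) > 0
  if (any(nz))
    out[nz] <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(nt[nz]), no.init.codon = TRUE))
  out
}

.randomDna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## short stable hash of the parameter set, for output file headers
.paramHash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 5381
  for (v in utf8ToInt(s)) h <- (h * 33 + v) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.toolVersion <- function() {
  as.character(utils::packageVersion("TRArep"))
}

#' Write a TSV report with a provenance header
#'
#' All pipeline outputs carry comment lines recording the tool version, the
#' seed, and a hash of the run parameters, so a run can be identified from
#' any of its files.
#'
#' @param df A data.frame.
#' @param path Output path.
#' @param seed Integer seed recorded in the header (NA if not applicable).
#' @param params List of parameters hashed into the header.
#' @return Invisibly, \code{path}.
#' @export
writeTsvReport <- function(df, path, seed = NA_integer_, params = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# TRArep %s", .toolVersion()), con)
  writeLines(sprintf("# seed=%s param_hash=%s", seed, .paramHash(params)), con)
  utils::write.table(as.data.frame(df), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a TSV report written by [writeTsvReport()]
#'
#' @param path Input path. Comment lines starting with \code{#} are skipped.
#' @return A data.frame.
#' @export
readTsvReport <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = "")
}
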