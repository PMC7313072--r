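## Standard-format I/O: FASTA/FASTQ reads, AIRR Rearrangement TSV, ground
## truth and report tables. FASTQ is written with a constant quality "I";
## gzip input is transparent through Biostrings.

#' Write simulated reads as FASTQ
#'
#' @param reads A named \code{DNAStringSet}.
#' @param path Output path (\code{.gz} for compressed).
#' @return Invisibly, \code{path}.
#' @export
writeReadsFastq <- function(reads, path) {
  qual <- Biostrings::PhredQuality(
    vapply(Biostrings::width(reads), function(w) strrep("I", w), ""))
  Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read amplicon reads from FASTA or FASTQ
#'
#' The format is taken from the file extension
#' (\code{.fastq}/\code{.fq} vs \code{.fasta}/\code{.fa}/\code{.fna}), with
#' a first-character sniff (\code{@} vs \code{>}) as fallback; qualities
#' are ignored. Gzip-compressed files are handled transparently.
#'
#' @param path Input path.
#' @return A named \code{DNAStringSet}.
#' @export
readReads <- function(path) {
  base <- sub("\\.(gz|bz2)$", "", path, ignore.case = TRUE)
  fmt <- if (grepl("\\.(fastq|fq)$", base, ignore.case = TRUE)) "fastq"
    else if (grepl("\\.(fasta|fa|fna)$", base, ignore.case = TRUE)) "fasta"
    else {
      con <- gzfile(path, "rt")
      on.exit(close(con))
      first <- readLines(con, n = 1L)
      if (length(first) && startsWith(first, "@")) "fastq" else "fasta"
    }
  ## an empty file is an empty read set in either format
  con2 <- gzfile(path, "rt")
  empty <- length(readLines(con2, n = 1L)) == 0L
  close(con2)
  if (empty) return(Biostrings::DNAStringSet())
  reads <- Biostrings::readDNAStringSet(path, format = fmt)
  ## FASTA descriptions: keep the identifier token only
  names(reads) <- sub("\\s.*$", "", names(reads))
  reads
}

#' Write / read annotations as AIRR Rearrangement TSV
#'
#' Columns \code{sequence_id}, \code{v_call}, \code{j_call},
#' \code{junction}, \code{junction_aa}, \code{productive} (AIRR "T"/"F"
#' encoding), plus the non-standard \code{fail_reason}. A provenance
#' header comment records the tool version, seed and parameter hash.
#'
#' @param annotations A data.frame from [annotateReads()].
#' @param path Output path.
#' @param seed,params Provenance recorded in the header.
#' @return Invisibly, \code{path}.
#' @export
writeAirrTsv <- function(annotations, path, seed = NA_integer_,
                         params = list()) {
  df <- annotations
  df$productive <- ifelse(df$productive, "T", "F")
  writeTsvReport(df, path, seed = seed, params = params)
}

#' @rdname writeAirrTsv
#' @return \code{readAirrTsv}: the annotations data.frame with
#'   \code{productive} as logical.
#' @export
readAirrTsv <- function(path) {
  df <- readTsvReport(path)
  if (nrow(df) == 0L) return(.emptyAnnotation(character(0)))
  df$productive <- df$productive == "T" | df$productive == "TRUE"
  for (col in c("v_call", "j_call", "junction", "junction_aa"))
    df[[col]] <- as.character(df[[col]])
  df$sequence_id <- as.character(df$sequence_id)
  df
}

#' Write a ranked clonotype table
#'
#' One row per clonotype: \code{sample_id}, \code{rank}, \code{v_call},
#' \code{j_call}, \code{junction_aa}, \code{copy_count},
#' \code{frequency_pct}.
#'
#' @param profile A \linkS4class{RepertoireProfile}.
#' @param path Output path.
#' @param seed,params Provenance recorded in the header.
#' @return Invisibly, \code{path}.
#' @export
writeClonotypeTsv <- function(profile, path, seed = NA_integer_,
                              params = list()) {
  ct <- as.data.frame(clonotypes(profile))
  df <- cbind(sample_id = rep(sampleId(profile), nrow(ct)), ct)
  writeTsvReport(df, path, seed = seed, params = params)
}

#' Write a V-J usage matrix as long-format TSV
#'
#' @param profile A \linkS4class{RepertoireProfile}.
#' @param path Output path.
#' @param seed,params Provenance recorded in the header.
#' @return Invisibly, \code{path}.
#' @export
writeVJMatrixTsv <- function(profile, path, seed = NA_integer_,
                             params = list()) {
  pct <- vjUsage(profile)
  df <- as.data.frame(as.table(pct), stringsAsFactors = FALSE)
  names(df) <- c("v_call", "j_call", "usage_pct")
  df <- cbind(sample_id = rep(sampleId(profile), nrow(df)), df)
  writeTsvReport(df, path, seed = seed, params = params)
}

#' Write the ground truth of a simulated sample
#'
#' Two TSV files: the true clone table (\code{<prefix>_clones.tsv}) and the
#' read-origin map (\code{<prefix>_read_origin.tsv}).
#'
#' @param truth A \linkS4class{GroundTruth}.
#' @param prefix Output path prefix.
#' @param seed,params Provenance recorded in the headers.
#' @return Invisibly, the two paths.
#' @export
writeGroundTruthTsv <- function(truth, prefix, seed = NA_integer_,
                                params = list()) {
  cl <- as.data.frame(cloneTable(truth))
  cl <- cbind(sample_id = rep(sampleId(truth), nrow(cl)),
              clone_index = seq_len(nrow(cl)), cl)
  p1 <- paste0(prefix, "_clones.tsv")
  writeTsvReport(cl, p1, seed = seed, params = params)
  ro <- as.data.frame(readOrigin(truth))
  ro$n_errors <- lengths(errorPositions(truth))
  ro$error_positions <- vapply(as.list(errorPositions(truth)),
                               paste, "", collapse = ",")
  p2 <- paste0(prefix, "_read_origin.tsv")
  writeTsvReport(ro, p2, seed = seed, params = params)
  invisible(c(p1, p2))
}
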