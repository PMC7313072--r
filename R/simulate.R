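## Ground-truthed TRA amplicon read simulator.
##
## Emulates the statistical structure a repertoire analysis of inflamed-skin
## T cells has to cope with: a few dominant clonotypes over a skewed
## background, junctional trimming and non-templated insertion, invariant
## (MAIT/iNKT) spike-ins, clones planted in both sensitization groups, and
## per-base substitution sequencing error. Merged single reads are
## simulated directly (paired-end merging is treated as standard upstream
## preprocessing); the error model is substitution-only and uniform.

.lawFrequencies <- function(n, law, par) {
  if (n < 1L) stop("need at least one clone")
  if (law == "geometric") {
    w <- par^(0:(n - 1L))
  } else {
    w <- pmax(stats::rgamma(n, shape = par), 1e-12)
  }
  w / sum(w)
}

#' Sample clone frequencies under the configured abundance law
#'
#' Geometric law: sorted frequencies decay by the ratio
#' \code{abundanceParam}; Dirichlet law: a symmetric Dirichlet draw with
#' concentration \code{abundanceParam}. Deterministic for a fixed seed.
#'
#' @param param A \linkS4class{SimulationParam}.
#' @return Numeric vector of length \code{nClones}, strictly positive,
#'   summing to 1.
#' @examples
#' sampleCloneFrequencies(SimulationParam(nClones = 3, abundanceParam = 0.5))
#' @export
sampleCloneFrequencies <- function(param) {
  methods::validObject(param)
  .withSeed(param@seed,
            .lawFrequencies(param@nClones, param@abundanceLaw,
                            param@abundanceParam))
}

#' Recombine a V and a J segment into a clone
#'
#' Builds the clone sequence \code{V[1..len(V)-trimV] + insert +
#' J[trimJ+1..]} and derives the CDR3 spanning the V Cys codon through the
#' J Phe codon inclusive. With \code{requireProductive = TRUE} the insert is
#' redrawn (length within the frame-compatible residue class up to
#' \code{insertMax}, bases uniform) until the junction is in frame and free
#' of stop codons; a bounded number of draws guards against degenerate
#' inputs. Trims that would delete an anchor codon are an error.
#'
#' @param reference A \linkS4class{TRAReference}.
#' @param vName,jName Gene symbols present in the reference.
#' @param trimV,trimJ Nucleotides trimmed from the V 3' / J 5' end.
#' @param insertNt N-region nucleotides, or \code{NULL} to draw randomly
#'   (uses the current RNG stream).
#' @param requireProductive Redraw the insert until productive.
#' @param insertMax Maximum insert length considered when (re)drawing.
#' @param maxTries Bound on productive redraws before failing.
#' @return A list with \code{v_name}, \code{j_name}, \code{sequence},
#'   \code{junction_nt}, \code{cdr3_aa}, \code{productive},
#'   \code{cdr3_start}, \code{cdr3_end} (1-based on \code{sequence}),
#'   \code{trim_v}, \code{trim_j}, \code{insert_nt}.
#' @examples
#' ref <- buildMockReference(2, 2, seed = 1)
#' cl <- recombineClone(ref, "TRAV1", "TRAJ18", trimV = 2, trimJ = 1)
#' cl$cdr3_aa
#' @export
recombineClone <- function(reference, vName, jName, trimV = 0L, trimJ = 0L,
                           insertNt = NULL, requireProductive = TRUE,
                           insertMax = 12L, maxTries = 50L) {
  v <- .refSegment(reference, vName)
  j <- .refSegment(reference, jName)
  if (v$class != "V" || j$class != "J")
    stop("vName must be a V segment and jName a J segment")
  trimV <- as.integer(trimV); trimJ <- as.integer(trimJ)
  vlen <- nchar(v$seq)
  maxTrimV <- vlen - (v$anchor + 2L)
  maxTrimJ <- j$anchor - 1L
  if (trimV < 0L || trimV > maxTrimV)
    stop("junction error: trimV would delete the V anchor codon")
  if (trimJ < 0L || trimJ > maxTrimJ)
    stop("junction error: trimJ would delete the J anchor codon")
  if (!is.null(insertNt) && grepl("[^ACGT]", insertNt))
    stop("insertNt must be over {A,C,G,T}")
  vpart <- substr(v$seq, 1L, vlen - trimV)
  jpart <- substr(j$seq, trimJ + 1L, nchar(j$seq))
  vtail <- nchar(vpart) - v$anchor + 1L           # Cys codon .. V end
  jhead <- (j$anchor + 2L) - trimJ                # J start .. Phe codon end
  need <- (3L - (vtail + jhead) %% 3L) %% 3L      # insert residue for frame

  assemble <- function(ins) {
    seqn <- paste0(vpart, ins, jpart)
    len3 <- vtail + nchar(ins) + jhead
    cdr3 <- substr(seqn, v$anchor, v$anchor + len3 - 1L)
    inframe <- nchar(cdr3) %% 3L == 0L
    aa <- if (inframe) translateCodons(cdr3) else ""
    list(sequence = seqn, junction_nt = cdr3, aa = aa,
         productive = inframe && !grepl("\\*", aa),
         cdr3_start = v$anchor, cdr3_end = v$anchor + len3 - 1L)
  }

  drawInsert <- function() {
    lens <- seq(0L, insertMax)
    lens <- lens[lens %% 3L == need]
    if (!length(lens))
      stop("retry-exhausted: no frame-compatible insert length <= insertMax")
    .randomDna(sample(rep(lens, 2L), 1L))  # rep() guards length-1 sample()
  }

  ins <- if (is.null(insertNt)) drawInsert() else insertNt
  res <- assemble(ins)
  if (requireProductive && !res$productive) {
    ok <- FALSE
    for (k in seq_len(maxTries)) {
      ins <- drawInsert()
      res <- assemble(ins)
      if (res$productive) { ok <- TRUE; break }
    }
    if (!ok) stop("retry-exhausted: no productive junction after ",
                  maxTries, " draws")
  }
  list(v_name = v$gene, j_name = j$gene, sequence = res$sequence,
       junction_nt = res$junction_nt,
       cdr3_aa = if (res$productive) res$aa else "",
       productive = res$productive,
       cdr3_start = res$cdr3_start, cdr3_end = res$cdr3_end,
       trim_v = trimV, trim_j = trimJ, insert_nt = ins)
}

.cloneKey <- function(v, j, aa) paste(v, j, aa, sep = "\r")

## draw one productive clone, redrawing until its clonotype key is unseen
.drawClone <- function(reference, param, vName = NULL, jName = NULL,
                       seen = character(0), productive = TRUE) {
  vAll <- segmentNames(reference, "V")
  jAll <- segmentNames(reference, "J")
  for (k in seq_len(200L)) {
    vn <- if (is.null(vName)) sample(rep(vAll, 2L), 1L) else vName
    jn <- if (is.null(jName)) sample(rep(jAll, 2L), 1L) else jName
    v <- .refSegment(reference, vn)
    j <- .refSegment(reference, jn)
    tv <- sample.int(min(param@trimMax,
                         nchar(v$seq) - v$anchor - 2L) + 1L, 1L) - 1L
    tj <- sample.int(min(param@trimMax, j$anchor - 1L) + 1L, 1L) - 1L
    cl <- if (productive) {
      recombineClone(reference, vn, jn, tv, tj, insertNt = NULL,
                     requireProductive = TRUE, insertMax = param@insertMax)
    } else {
      ## frame-shifted junction: insert length forced off the in-frame class
      v2 <- .refSegment(reference, vn)
      vtail <- nchar(v2$seq) - tv - v2$anchor + 1L
      jhead <- j$anchor + 2L - tj
      need <- (3L - (vtail + jhead) %% 3L) %% 3L
      lens <- setdiff(seq(0L, param@insertMax), seq(0L, param@insertMax)[
        seq(0L, param@insertMax) %% 3L == need])
      recombineClone(reference, vn, jn, tv, tj,
                     insertNt = .randomDna(sample(rep(lens, 2L), 1L)),
                     requireProductive = FALSE, insertMax = param@insertMax)
    }
    key <- .cloneKey(cl$v_name, cl$j_name,
                     if (cl$productive) cl$cdr3_aa else cl$junction_nt)
    if (!key %in% seen) return(cl)
  }
  stop("could not draw a clone with an unseen clonotype key")
}

.clonesToDF <- function(clones, freqs) {
  S4Vectors::DataFrame(
    v_name = vapply(clones, `[[`, "", "v_name"),
    j_name = vapply(clones, `[[`, "", "j_name"),
    junction_nt = vapply(clones, `[[`, "", "junction_nt"),
    cdr3_aa = vapply(clones, `[[`, "", "cdr3_aa"),
    frequency = freqs,
    productive = vapply(clones, `[[`, TRUE, "productive"),
    clone_seq = vapply(clones, `[[`, "", "sequence"),
    cdr3_start = vapply(clones, `[[`, 1L, "cdr3_start"),
    cdr3_end = vapply(clones, `[[`, 1L, "cdr3_end"))
}

.spikeSpecs <- function(param) {
  out <- list()
  if (param@spikeMait > 0)
    out <- c(out, list(list(v = "TRAV1", j = "TRAJ33", f = param@spikeMait,
                            label = "MAIT")))
  if (param@spikeInkt > 0)
    out <- c(out, list(list(v = "TRAV11", j = "TRAJ18", f = param@spikeInkt,
                            label = "iNKT")))
  out
}

.checkSpikeGenes <- function(param, reference) {
  for (sp in .spikeSpecs(param)) {
    if (!sp$v %in% segmentNames(reference, "V") ||
        !sp$j %in% segmentNames(reference, "J"))
      stop("configuration error: spike-in genes ", sp$v, "/", sp$j,
           " absent from the reference")
  }
}

## single-sample clone set: spikes first, then law-distributed background
.makeCloneSet <- function(param, reference, seen = character(0),
                          nonproductiveFraction = 0) {
  .checkSpikeGenes(param, reference)
  spikes <- .spikeSpecs(param)
  nBack <- param@nClones - length(spikes)
  if (nBack < 1L)
    stop("nClones too small for the configured spike-ins")
  clones <- list(); freqs <- numeric(0)
  for (sp in spikes) {
    cl <- .drawClone(reference, param, sp$v, sp$j, seen)
    seen <- c(seen, .cloneKey(cl$v_name, cl$j_name, cl$cdr3_aa))
    clones <- c(clones, list(cl)); freqs <- c(freqs, sp$f)
  }
  spikeMass <- sum(vapply(spikes, `[[`, 0, "f"))
  back <- .lawFrequencies(nBack, param@abundanceLaw, param@abundanceParam) *
    (1 - spikeMass)
  nNon <- round(nonproductiveFraction * nBack)
  for (i in seq_len(nBack)) {
    cl <- .drawClone(reference, param, seen = seen, productive = i > nNon)
    seen <- c(seen, .cloneKey(cl$v_name, cl$j_name,
                              if (cl$productive) cl$cdr3_aa else cl$junction_nt))
    clones <- c(clones, list(cl)); freqs <- c(freqs, back[i])
  }
  .clonesToDF(clones, freqs)
}

## multinomial reads with logged substitution errors, from the current RNG
.readsFromClones <- function(clones, param, sampleId) {
  cover <- clones$cdr3_end + 3L               # junction + following Gly codon
  if (any(cover > param@readLength))
    stop("configuration error: read_length ", param@readLength,
         " does not cover the junction of every clone (need >= ",
         max(cover), ")")
  counts <- as.integer(stats::rmultinom(1L, param@nReads, clones$frequency))
  origin <- rep(seq_len(nrow(clones)), counts)
  seqs <- substr(clones$clone_seq[origin], 1L, param@readLength)
  widths <- nchar(seqs)
  n <- length(seqs)
  nerr <- stats::rbinom(n, widths, param@errorRate)
  errPos <- vector("list", n)
  idx <- which(nerr > 0L)
  if (length(idx)) {
    bases <- c("A", "C", "G", "T")
    spl <- strsplit(seqs[idx], "", fixed = TRUE)
    for (k in seq_along(idx)) {
      i <- idx[k]
      pos <- sort(sample.int(widths[i], nerr[i]))
      errPos[[i]] <- pos
      ch <- spl[[k]]
      for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
      spl[[k]] <- ch
    }
    seqs[idx] <- vapply(spl, paste, "", collapse = "")
  }
  errPos[lengths(errPos) == 0L] <- list(integer(0))
  ids <- sprintf("%s_read_%06d", sampleId, seq_len(n))
  reads <- Biostrings::DNAStringSet(seqs)
  names(reads) <- ids
  truth <- new("GroundTruth", sampleId = sampleId, clones = clones,
               readOrigin = S4Vectors::DataFrame(read_id = ids,
                                                 clone_index = origin),
               errorPositions = IRanges::IntegerList(errPos))
  methods::validObject(truth)
  list(reads = reads, truth = truth)
}

#' Simulate one TRA repertoire sample
#'
#' Draws a clone set (invariant spike-ins plus a law-distributed
#' background), realizes read counts by multinomial sampling of the true
#' frequencies, and emits each read as the clone sequence truncated at
#' \code{readLength} with i.i.d. per-base substitution errors, all logged
#' in the ground truth. Deterministic for a fixed \code{seed}.
#'
#' @param param A \linkS4class{SimulationParam}.
#' @param reference A \linkS4class{TRAReference} containing the spike-in
#'   genes whenever the spike proportions are positive.
#' @param sampleId Sample identifier used in read names.
#' @param nonproductiveFraction Fraction of background clones built with a
#'   frame-shifted junction (default 0: productive-only simulation).
#' @return A list with \code{reads} (a named \code{DNAStringSet}) and
#'   \code{truth} (a \linkS4class{GroundTruth}).
#' @examples
#' ref <- buildMockReference(5, 5, seed = 1)
#' sim <- simulateSample(SimulationParam(nClones = 10, nReads = 100), ref)
#' sim$truth
#' @export
simulateSample <- function(param, reference, sampleId = "S1",
                           nonproductiveFraction = 0) {
  methods::validObject(param)
  .withSeed(param@seed, {
    clones <- .makeCloneSet(param, reference,
                            nonproductiveFraction = nonproductiveFraction)
    .readsFromClones(clones, param, sampleId)
  })
}

#' Simulate the two-group cross-reactivity experiment
#'
#' Produces the "Ni-Pd" and "Cr-Pd" samples whose true clone sets intersect
#' in exactly \code{round(sharedFraction * nClones)} clones with identical
#' (V, J, CDR3aa) keys. When the reference carries the dominant
#' cross-reactive genes, a (TRAV8D-1, TRAJ49) and a (TRAV5-1, TRAJ37) clone
#' are planted at the \code{dominantFreqs} frequencies in both groups; they
#' are drawn from the shared quota when it admits them, and per-group
#' otherwise. All other non-shared clonotype keys are distinct between the
#' groups by construction.
#'
#' @param param A \linkS4class{SimulationParam} (with
#'   \code{sharedFraction > 0} for a cross-reactivity test).
#' @param reference A \linkS4class{TRAReference}.
#' @param dominantFreqs Frequencies of the two planted dominant clones.
#' @return A named list of two \code{list(reads, truth)} elements,
#'   \code{"Ni-Pd"} and \code{"Cr-Pd"}.
#' @examples
#' ref <- buildMockReference(5, 5, seed = 1)
#' par <- SimulationParam(nClones = 10, nReads = 200, sharedFraction = 0.3)
#' xp <- simulateCrossReactiveExperiment(par, ref)
#' names(xp)
#' @export
simulateCrossReactiveExperiment <- function(param, reference,
                                            dominantFreqs = c(0.20, 0.15)) {
  methods::validObject(param)
  .checkSpikeGenes(param, reference)
  .withSeed(param@seed, {
    vAll <- segmentNames(reference, "V")
    jAll <- segmentNames(reference, "J")
    domSpecs <- Filter(function(d) d[1] %in% vAll && d[2] %in% jAll,
                       list(c("TRAV8D-1", "TRAJ49"), c("TRAV5-1", "TRAJ37")))
    nDom <- length(domSpecs)
    nShared <- as.integer(round(param@sharedFraction * param@nClones))
    nDomShared <- min(nDom, nShared)
    nSharedReg <- nShared - nDomShared
    spikes <- .spikeSpecs(param)
    nPriv <- param@nClones - nShared - (nDom - nDomShared) - length(spikes)
    if (nPriv < 0L)
      stop("configuration error: nClones too small for shared, dominant ",
           "and spike-in clones")
    domMass <- sum(dominantFreqs[seq_len(nDom)])
    spikeMass <- sum(vapply(spikes, `[[`, 0, "f"))
    if (domMass + spikeMass >= 1)
      stop("dominant and spike frequencies exceed the total")

    seen <- character(0)
    register <- function(cl) {
      seen <<- c(seen, .cloneKey(cl$v_name, cl$j_name, cl$cdr3_aa))
      cl
    }
    sharedDom <- lapply(seq_len(nDomShared), function(k)
      register(.drawClone(reference, param, domSpecs[[k]][1],
                          domSpecs[[k]][2], seen)))
    sharedReg <- lapply(seq_len(nSharedReg), function(k)
      register(.drawClone(reference, param, seen = seen)))

    buildSample <- function(sid) {
      doms <- sharedDom
      if (nDom > nDomShared) {
        extra <- lapply(seq(nDomShared + 1L, nDom), function(k)
          register(.drawClone(reference, param, domSpecs[[k]][1],
                              domSpecs[[k]][2], seen)))
        doms <- c(doms, extra)
      }
      spk <- lapply(spikes, function(sp)
        register(.drawClone(reference, param, sp$v, sp$j, seen)))
      priv <- lapply(seq_len(nPriv), function(k)
        register(.drawClone(reference, param, seen = seen)))
      backMass <- 1 - domMass - spikeMass
      nBack <- nSharedReg + nPriv
      backF <- if (nBack)
        .lawFrequencies(nBack, param@abundanceLaw, param@abundanceParam) *
          backMass
      else numeric(0)
      clones <- c(doms, spk, sharedReg, priv)
      freqs <- c(dominantFreqs[seq_len(nDom)],
                 vapply(spikes, `[[`, 0, "f"), backF)
      df <- .clonesToDF(clones, freqs)
      .readsFromClones(df, param, sid)
    }
    out <- list(buildSample("Ni-Pd"), buildSample("Cr-Pd"))
    names(out) <- c("Ni-Pd", "Cr-Pd")
    out
  })
}
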