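## Independent oracles used by the tests. The alignment oracle is a
## from-scratch Gotoh dynamic program (affine gaps, local), written without
## any use of the package's alignment path: a gap of length L costs
## |gapOpen| + L * |gapExt|, N never matches.

## plain triple-loop Gotoh, used to validate the vectorized oracle below
swOracleNaive <- function(a, b, match = 2, mismatch = -1,
                          gapOpen = -4, gapExt = -1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  open <- -gapOpen; ext <- -gapExt
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  acgt <- c("A", "C", "G", "T")
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      s <- if (A[i - 1] == B[j - 1] && A[i - 1] %in% acgt) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

## column-vectorized Gotoh (same recurrences; the vertical-gap state is
## rebuilt from the gap-free column scores by a running-max identity, which
## is exact because opening a gap directly after closing one in the same
## direction is always dominated by extending it)
swOracle <- function(a, b, match = 2, mismatch = -1,
                     gapOpen = -4, gapExt = -1) {
  A <- utf8ToInt(a); B <- utf8ToInt(b)
  n <- length(A); m <- length(B)
  open <- -gapOpen; ext <- -gapExt
  acgt <- utf8ToInt("ACGT")
  ii <- seq_len(n)
  Hprev <- numeric(n + 1L)          # H[ , j-1], rows 0..n
  Eprev <- rep(-Inf, n + 1L)
  best <- 0
  for (j in seq_len(m)) {
    s <- ifelse(A == B[j] & A %in% acgt, match, mismatch)
    Ecol <- pmax(Hprev - open - ext, Eprev - ext)   # rows 0..n, uses col j-1
    Htmp <- pmax(0, Hprev[ii] + s, Ecol[ii + 1L])
    C <- cummax(c(-Inf, Htmp[-n] + ext * ii[-n]))   # max_{k<i}(Htmp[k]+ext*k)
    Fcol <- C - open - ext * ii
    Hcol <- pmax(Htmp, Fcol)
    best <- max(best, Hcol)
    Hprev <- c(0, Hcol)
    Eprev <- c(-Inf, Ecol[ii + 1L])
  }
  best
}

randomDnaStr <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

## brute-force shared-clonotype oracle: all-pairs comparison of two
## clonotype tables on the (v_call, j_call, junction_aa) key
bruteSharedOracle <- function(ctA, ctB) {
  out <- character(0)
  for (i in seq_len(nrow(ctA))) {
    for (k in seq_len(nrow(ctB))) {
      if (ctA$v_call[i] == ctB$v_call[k] &&
          ctA$j_call[i] == ctB$j_call[k] &&
          ctA$junction_aa[i] == ctB$junction_aa[k])
        out <- c(out, paste(ctA$v_call[i], ctA$j_call[i],
                            ctA$junction_aa[i], sep = "|"))
    }
  }
  sort(unique(out))
}
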