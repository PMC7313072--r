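test_that("clone frequencies follow the abundance law and normalize", {
  expect_equal(
    sampleCloneFrequencies(SimulationParam(nClones = 1)), 1.0)
  expect_equal(
    sampleCloneFrequencies(SimulationParam(nClones = 3,
                                           abundanceLaw = "geometric",
                                           abundanceParam = 0.5)),
    c(4, 2, 1) / 7)
  for (law in c("geometric", "dirichlet")) {
    f <- sampleCloneFrequencies(SimulationParam(nClones = 50,
                                                abundanceLaw = law,
                                                abundanceParam = 0.9,
                                                seed = 5))
    expect_length(f, 50)
    expect_true(all(f > 0))
    expect_equal(sum(f), 1, tolerance = 1e-9)
  }
  expect_error(SimulationParam(nClones = 10, errorRate = 0.5), "errorRate")
  expect_error(SimulationParam(spikeMait = 0.6, spikeInkt = 0.3,
                               sharedFraction = 0.3), "<= 1")
})

test_that("recombination joins trimmed segments and honours the frame", {
  ref <- tinyReference()
  ## no trimming, no insert: CDR3 is the direct V-tail + J-head translation
  cl <- recombineClone(ref, "TRAV1", "TRAJ18", trimV = 0, trimJ = 0,
                       insertNt = "")
  expect_identical(cl$junction_nt, "TGTAAAAAATTT")
  expect_identical(cl$cdr3_aa, "CKKF")
  expect_true(startsWith(cl$cdr3_aa, "C"))
  expect_true(endsWith(cl$cdr3_aa, "F"))
  ## clone sequence is the exact concatenation
  v <- as.character(vSegments(ref)[["TRAV1"]])
  j <- as.character(jSegments(ref)[["TRAJ18"]])
  expect_identical(cl$sequence, paste0(v, j))
  ## a 1-nt insert breaks frame; the insert is redrawn into the
  ## frame-compatible length class (0 mod 3 here)
  set.seed(1)
  cl2 <- recombineClone(ref, "TRAV1", "TRAJ18", trimV = 1, trimJ = 2,
                        insertNt = "A", requireProductive = TRUE)
  expect_true(cl2$productive)
  expect_identical(nchar(cl2$junction_nt) %% 3L, 0L)
  ## enumeration: with these trims only insert lengths 0,3,6,9,12 keep frame
  vtail <- 3 + 3 - 1   # Cys codon + remaining tail after trimV=1
  jhead <- 4 + 2 - 2   # J head after trimJ=2 through the Phe codon
  expect_identical(nchar(cl2$insert_nt) %% 3L,
                   as.integer((3L - (vtail + jhead) %% 3L) %% 3L))
  ## trimming through an anchor is a junction error
  expect_error(recombineClone(ref, "TRAV1", "TRAJ18", trimV = 4),
               "junction")
  expect_error(recombineClone(ref, "TRAV1", "TRAJ18", trimJ = 4),
               "junction")
})

test_that("simulated samples are deterministic and conserve read counts", {
  ref <- buildMockReference(6, 6, seed = 2)
  par <- SimulationParam(nClones = 20, nReads = 500, seed = 9)
  s1 <- simulateSample(par, ref, "A")
  s2 <- simulateSample(par, ref, "A")
  expect_identical(as.character(s1$reads), as.character(s2$reads))
  expect_identical(as.data.frame(cloneTable(s1$truth)),
                   as.data.frame(cloneTable(s2$truth)))
  expect_identical(as.list(errorPositions(s1$truth)),
                   as.list(errorPositions(s2$truth)))
  ## conservation and frequency contract
  expect_identical(length(s1$reads), 500L)
  expect_identical(nrow(readOrigin(s1$truth)), 500L)
  expect_equal(sum(cloneTable(s1$truth)$frequency), 1, tolerance = 1e-9)
  ## a different seed changes the data
  s3 <- simulateSample(SimulationParam(nClones = 20, nReads = 500,
                                       seed = 10), ref, "A")
  expect_false(identical(as.character(s1$reads), as.character(s3$reads)))
})

test_that("single-clone zero-error sample is n identical copies", {
  ref <- buildMockReference(2, 2, seed = 4)
  par <- SimulationParam(nClones = 1, nReads = 10, errorRate = 0,
                         spikeMait = 0, spikeInkt = 0, seed = 6)
  sim <- simulateSample(par, ref)
  expect_identical(length(unique(as.character(sim$reads))), 1L)
  cl <- cloneTable(sim$truth)
  expect_equal(cl$frequency, 1)
  expect_identical(unique(as.character(sim$reads)),
                   substr(cl$clone_seq, 1, 300))
})

test_that("substitution errors match the logged positions and the rate", {
  ref <- buildMockReference(6, 6, seed = 2)
  par <- SimulationParam(nClones = 10, nReads = 2000, errorRate = 0.01,
                         seed = 21)
  sim <- simulateSample(par, ref)
  tr <- cloneTable(sim$truth)
  ro <- readOrigin(sim$truth)
  reads <- as.character(sim$reads)
  true <- substr(tr$clone_seq[ro$clone_index], 1, 300)
  ep <- as.list(errorPositions(sim$truth))
  ## every read differs from its clone exactly at the logged offsets
  for (i in seq(1, length(reads), by = 37)) {
    d <- which(strsplit(reads[i], "")[[1]] != strsplit(true[i], "")[[1]])
    expect_identical(d, as.integer(ep[[i]]))
  }
  ## pooled per-base error frequency is within 3 binomial SEs of the rate
  nBases <- sum(nchar(reads))
  nErr <- sum(lengths(ep))
  p <- par@errorRate
  expect_lt(abs(nErr / nBases - p), 3 * sqrt(p * (1 - p) / nBases))
  ## mean errors per read matches width * rate
  expect_equal(mean(lengths(ep)), mean(nchar(reads)) * p, tolerance = 0.15)
})

test_that("invariant spike-ins occupy their configured share of reads", {
  ref <- buildMockReference(6, 6, seed = 2)
  par <- SimulationParam(nClones = 20, nReads = 5000, errorRate = 0,
                         spikeMait = 0.2, spikeInkt = 0.1, seed = 13)
  sim <- simulateSample(par, ref)
  tr <- cloneTable(sim$truth)
  ro <- readOrigin(sim$truth)
  mait <- tr$v_name == "TRAV1" & tr$j_name == "TRAJ33"
  frac <- mean(mait[ro$clone_index])
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / 5000))
  ## spike genes must exist in the reference
  tiny <- tinyReference()   # has TRAJ18/TRAJ33 but no TRAV11
  expect_error(simulateSample(SimulationParam(nClones = 5, nReads = 10,
                                              spikeInkt = 0.1), tiny),
               "configuration error")
})

test_that("cross-reactive experiment plants exactly the shared clones", {
  ref <- buildMockReference(8, 8, seed = 1)
  par <- SimulationParam(nClones = 10, nReads = 400, errorRate = 0,
                         sharedFraction = 0.3, seed = 2)
  xp <- simulateCrossReactiveExperiment(par, ref)
  expect_named(xp, c("Ni-Pd", "Cr-Pd"))
  key <- function(t) paste(cloneTable(t)$v_name, cloneTable(t)$j_name,
                           cloneTable(t)$cdr3_aa, sep = "|")
  shared <- intersect(key(xp[[1]]$truth), key(xp[[2]]$truth))
  expect_length(shared, 3L)
  ## the planted dominants are present in both samples
  for (s in xp) {
    cl <- cloneTable(s$truth)
    expect_true(any(cl$v_name == "TRAV8D-1" & cl$j_name == "TRAJ49"))
    expect_true(any(cl$v_name == "TRAV5-1" & cl$j_name == "TRAJ37"))
    expect_equal(sum(cl$frequency), 1, tolerance = 1e-9)
    expect_identical(nrow(cl), 10L)
  }
  ## disjoint construction when sharing and spikes are off
  par0 <- SimulationParam(nClones = 8, nReads = 100, errorRate = 0,
                          sharedFraction = 0, spikeMait = 0, spikeInkt = 0,
                          seed = 2)
  xp0 <- simulateCrossReactiveExperiment(par0, ref)
  expect_length(intersect(key(xp0[[1]]$truth), key(xp0[[2]]$truth)), 0L)
})

test_that("a read length that cannot cover the junction is rejected", {
  ref <- buildMockReference(4, 4, seed = 5)
  par <- SimulationParam(nClones = 5, nReads = 10, readLength = 60, seed = 1)
  expect_error(simulateSample(par, ref), "configuration error")
})
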