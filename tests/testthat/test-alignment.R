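test_that("self-alignment and single substitutions score as expected", {
  set.seed(7)
  seg <- randomDnaStr(30)
  al <- alignSegment(seg, seg)
  expect_equal(al$score, 60)          # 30 matches at +2
  expect_equal(al$identity, 1.0)
  expect_equal(al$readStart, 1)
  expect_equal(al$readEnd, 30)
  ## one substitution in the middle keeps the full-length path optimal
  read <- seg
  substr(read, 15, 15) <- setdiff(c("A", "C", "G", "T"),
                                  substr(seg, 15, 15))[1]
  al2 <- alignSegment(read, seg)
  expect_equal(al2$score, 57)         # 29 * 2 - 1
  expect_equal(al2$score, swOracle(read, seg))
  ## an N base scores as a mismatch
  readN <- seg
  substr(readN, 15, 15) <- "N"
  expect_equal(alignSegment(readN, seg)$score, swOracle(readN, seg))
  expect_error(alignSegment("", seg), "empty")
})

test_that("the vectorized DP oracle agrees with the naive Gotoh DP", {
  set.seed(11)
  for (k in 1:25) {
    a <- randomDnaStr(sample(5:25, 1))
    b <- randomDnaStr(sample(5:25, 1))
    expect_equal(swOracle(a, b), swOracleNaive(a, b))
  }
  ## including related pairs with indels
  for (k in 1:10) {
    b <- randomDnaStr(30)
    a <- paste0(substr(b, 1, 12), substr(b, 15, 30))   # 2-nt deletion
    expect_equal(swOracle(a, b), swOracleNaive(a, b))
  }
})

test_that("alignment scores equal the exhaustive DP oracle on random pairs", {
  set.seed(20)
  for (k in 1:40) {
    read <- randomDnaStr(sample(20:60, 1))
    seg <- randomDnaStr(sample(20:60, 1))
    expect_equal(alignSegment(read, seg)$score, swOracle(read, seg))
  }
  ## unrelated 30-mers stay far below the acceptance threshold
  set.seed(21)
  scores <- replicate(20, alignSegment(randomDnaStr(30),
                                       randomDnaStr(30))$score)
  expect_true(all(scores < 40))
})

test_that("segment assignment recovers an exact V+J concatenation", {
  ref <- buildMockReference(6, 6, seed = 8)
  v <- as.character(vSegments(ref)[["TRAV3"]])
  j <- as.character(jSegments(ref)[["TRAJ33"]])
  got <- assignSegments(paste0(v, j), ref)
  expect_identical(got$v$gene, "TRAV3")
  expect_identical(got$j$gene, "TRAJ33")
  expect_equal(got$v$identity, 1.0)
  expect_equal(got$j$identity, 1.0)
  ## the exact-match gene beats a 1-nt variant
  v2 <- v
  substr(v2, 40, 40) <- setdiff(c("A", "C", "G", "T"), substr(v, 40, 40))[1]
  ref2 <- makeTestReference(
    v = c(TRAV3 = v, TRAV30 = v2),
    j = c(TRAJ33 = j),
    vAnchor = rep(anchorOffset(ref, "TRAV3"), 2),
    jAnchor = anchorOffset(ref, "TRAJ33"))
  expect_identical(assignSegments(paste0(v, j), ref2)$v$gene, "TRAV3")
})

test_that("score-and-identity ties resolve to the ASCII-smaller gene name", {
  set.seed(31)
  v <- paste0(randomDnaStr(40), "TGT", "AAAAAA")
  j <- paste0("AAAAAA", "TTT", "GGA", randomDnaStr(20))
  ## TRAV2 and TRAV10 carry identical sequences: a forced tie
  ref <- makeTestReference(v = c(TRAV2 = v, TRAV10 = v),
                           j = c(TRAJ2 = j), vAnchor = c(41L, 41L),
                           jAnchor = 7L)
  got <- assignSegments(paste0(v, j), ref)
  expect_identical(got$v$gene, "TRAV10")   # "TRAV10" < "TRAV2" in ASCII
})

test_that("codon translation follows the standard genetic code", {
  expect_identical(translateCodons("TGT"), "C")
  expect_identical(translateCodons("TTTGGT"), "FG")
  expect_identical(translateCodons("TAA"), "*")
  expect_identical(translateCodons(c("ATG", "TGCAAATTC")), c("M", "CKF"))
  expect_error(translateCodons("AC"), "multiple of 3")
  expect_error(translateCodons("ACN"), "multiple of 3|A,C,G,T")
})

test_that("annotation recovers error-free reads and flags failure modes", {
  ref <- buildMockReference(6, 6, seed = 8)
  par <- SimulationParam(nClones = 15, nReads = 1000, errorRate = 0,
                         seed = 17)
  sim <- simulateSample(par, ref)
  ann <- annotateReads(sim$reads, ref)
  expect_identical(nrow(ann), 1000L)
  expect_true(all(ann$productive))
  expect_equal(recoveryRate(ann, sim$truth), 1.0)
  ## junction equals the true junction nucleotides too
  tr <- cloneTable(sim$truth)
  ro <- readOrigin(sim$truth)
  expect_identical(ann$junction, tr$junction_nt[ro$clone_index])
  ## a bare V segment has no J
  bare <- as.character(vSegments(ref)[["TRAV1"]])
  annV <- annotateReads(bare, ref)
  expect_identical(annV$fail_reason, "no_j")
  expect_identical(annV$v_call, "TRAV1")
  ## random 300-mers essentially never annotate
  set.seed(40)
  rnd <- vapply(1:100, function(i) randomDnaStr(300), "")
  annR <- annotateReads(rnd, ref)
  expect_gte(sum(annR$fail_reason %in% c("no_v", "no_j", "low_score")), 99)
  expect_lte(mean(annR$productive), 0.01)
})

test_that("CDR3 extraction flags stop codons and frame shifts", {
  ref <- tinyReference()
  v <- as.character(vSegments(ref)[["TRAV1"]])
  j <- as.character(jSegments(ref)[["TRAJ18"]])
  ## in-frame TAA inserted at the junction
  readStop <- paste0(v, "TAA", j)
  annS <- annotateReads(readStop, ref)
  expect_false(annS$productive)
  expect_identical(annS$fail_reason, "stop_codon")
  ## 1-nt insert: CDR3 span of 13 nt is out of frame
  readOof <- paste0(v, "A", j)
  annO <- annotateReads(readOof, ref)
  expect_false(annO$productive)
  expect_identical(annO$fail_reason, "out_of_frame")
  ## single-read API agrees with the batch annotation
  sel <- assignSegments(readStop, ref)
  cd <- extractCDR3(readStop, sel$v, sel$j)
  expect_identical(cd$fail_reason, "stop_codon")
  expect_error(extractCDR3(readStop, NULL, sel$j), "required")
})

test_that("assignment accuracy degrades monotonically with error rate", {
  ref <- buildMockReference(6, 6, seed = 8)
  rates <- c(0, 0.005, 0.01, 0.02)
  acc <- vapply(rates, function(e) {
    par <- SimulationParam(nClones = 15, nReads = 400, errorRate = e,
                           seed = 23)
    sim <- simulateSample(par, ref)
    recoveryRate(annotateReads(sim$reads, ref), sim$truth)
  }, 0)
  expect_equal(acc[1], 1.0)
  expect_true(all(diff(acc) <= 1e-9))
})
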