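mkAnn <- function(v, j, aa, productive = TRUE) {
  n <- max(length(v), length(j), length(aa))
  data.frame(sequence_id = sprintf("r%03d", seq_len(n)),
             v_call = rep_len(v, n), j_call = rep_len(j, n),
             junction = NA_character_, junction_aa = rep_len(aa, n),
             productive = rep_len(productive, n),
             fail_reason = ifelse(rep_len(productive, n), "none", "no_v"),
             stringsAsFactors = FALSE)
}

test_that("clonotypes are counted, ranked and expressed as percentages", {
  ann <- rbind(mkAnn("TRAV1", "TRAJ33", "CAAF")[rep(1, 3), ],
               mkAnn("TRAV2", "TRAJ18", "CWWF"))
  prof <- buildClonotypes(ann, "s")
  ct <- clonotypes(prof)
  expect_identical(ct$copy_count, c(3L, 1L))
  expect_equal(ct$frequency_pct, c(75, 25))
  expect_identical(ct$rank, 1:2)
  expect_identical(totalCounted(prof), 4L)
  ## degenerate case: everything identical
  one <- buildClonotypes(mkAnn("TRAV1", "TRAJ33", "CAAF")[rep(1, 7), ], "s")
  expect_identical(nrow(clonotypes(one)), 1L)
  expect_equal(clonotypes(one)$frequency_pct, 100)
  ## ties rank deterministically by key
  tie <- buildClonotypes(rbind(mkAnn("TRAV2", "TRAJ2", "CAF"),
                               mkAnn("TRAV1", "TRAJ2", "CAF")), "s")
  expect_identical(clonotypes(tie)$v_call, c("TRAV1", "TRAV2"))
})

test_that("nonproductive reads are excluded but tallied", {
  ann <- rbind(mkAnn("TRAV1", "TRAJ33", "CAAF"),
               mkAnn("TRAV2", "TRAJ18", NA_character_, productive = FALSE))
  prof <- buildClonotypes(ann, "s")
  expect_identical(totalCounted(prof), 1L)
  expect_identical(nFailed(prof), 1L)
  ## empty productive set gives an empty profile, not an error
  empty <- buildClonotypes(mkAnn("TRAV1", "TRAJ33", NA_character_,
                                 productive = FALSE), "s")
  expect_identical(totalCounted(empty), 0L)
  expect_identical(nrow(clonotypes(empty)), 0L)
  expect_error(computeFrequencies(empty), "zero")
  expect_error(vjUsage(empty), "zero")
})

test_that("clonotyping is invariant to annotation order and merges by key", {
  ref <- buildMockReference(6, 6, seed = 8)
  sim <- simulateSample(SimulationParam(nClones = 12, nReads = 600,
                                        errorRate = 0, seed = 31), ref)
  ann <- annotateReads(sim$reads, ref)
  p1 <- buildClonotypes(ann, "s")
  set.seed(1)
  p2 <- buildClonotypes(ann[sample.int(nrow(ann)), ], "s")
  expect_identical(as.data.frame(clonotypes(p1)),
                   as.data.frame(clonotypes(p2)))
  expect_identical(vjCounts(p1), vjCounts(p2))
  ## merge property: profiling a concatenation = summing per-key counts
  annA <- ann[1:250, ]; annB <- ann[251:600, ]
  pa <- clonotypes(buildClonotypes(annA, "a"))
  pb <- clonotypes(buildClonotypes(annB, "b"))
  pall <- clonotypes(buildClonotypes(rbind(annA, annB), "ab"))
  key <- function(x) paste(x$v_call, x$j_call, x$junction_aa, sep = "|")
  merged <- tapply(c(pa$copy_count, pb$copy_count), c(key(pa), key(pb)), sum)
  expect_identical(sort(as.integer(merged[key(pall)])),
                   sort(as.integer(pall$copy_count)))
  expect_identical(sum(pall$copy_count), sum(pa$copy_count) +
                     sum(pb$copy_count))
})

test_that("frequencies are idempotent and sum to 100", {
  ann <- mkAnn(c("TRAV1", "TRAV1", "TRAV2", "TRAV3"),
               c("TRAJ2", "TRAJ2", "TRAJ3", "TRAJ4"),
               c("CAF", "CAF", "CBF", "CCF"))
  prof <- buildClonotypes(ann, "s")
  again <- computeFrequencies(prof)
  expect_equal(clonotypes(again)$frequency_pct,
               clonotypes(prof)$frequency_pct)
  expect_equal(sum(clonotypes(prof)$frequency_pct), 100, tolerance = 1e-6)
})

test_that("the V-J usage matrix reflects the clone mixture", {
  ## single clonotype: its cell is 100
  p1 <- buildClonotypes(mkAnn("TRAV1", "TRAJ33", "CAAF"), "s")
  expect_equal(as.numeric(vjUsage(p1)), 100)
  ## same V, two Js, equal counts: two cells at 50
  p2 <- buildClonotypes(mkAnn(c("TRAV1", "TRAV1"), c("TRAJ2", "TRAJ3"),
                              c("CAF", "CBF")), "s")
  expect_equal(sort(as.numeric(vjUsage(p2))), c(50, 50))
  ## simulated mixture: per-cell usage within 3 binomial SEs of the truth
  ref <- buildMockReference(6, 6, seed = 8)
  par <- SimulationParam(nClones = 12, nReads = 4000, errorRate = 0,
                         seed = 33)
  sim <- simulateSample(par, ref)
  prof <- buildClonotypes(annotateReads(sim$reads, ref), "s")
  usage <- vjUsage(prof) / 100
  tr <- cloneTable(sim$truth)
  pTrue <- tapply(tr$frequency, list(tr$v_name, tr$j_name), sum)
  for (v in rownames(usage)) for (j in colnames(usage)) {
    p <- pTrue[v, j]
    if (is.na(p)) p <- 0
    expect_lt(abs(usage[v, j] - p),
              3 * sqrt(max(p * (1 - p), 1e-6) / 4000) + 1e-9)
  }
  expect_equal(sum(vjUsage(prof)), 100, tolerance = 1e-6)
})

test_that("zero-error clonotype tables equal the ground truth by key", {
  ref <- buildMockReference(6, 6, seed = 8)
  for (seed in 1:3) {
    sim <- simulateSample(SimulationParam(nClones = 15, nReads = 800,
                                          errorRate = 0, seed = seed), ref)
    prof <- buildClonotypes(annotateReads(sim$reads, ref), "s")
    ct <- clonotypes(prof)
    got <- structure(as.integer(ct$copy_count),
                     names = paste(ct$v_call, ct$j_call, ct$junction_aa,
                                   sep = "|"))
    want <- truthKeyCounts(sim$truth)
    expect_identical(sort(names(got)), sort(names(want)))
    expect_identical(got[names(want)], structure(as.integer(want),
                                                 names = names(want)))
  }
})
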