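# Hierarchical alignment construction: templates, ownership,
# lineage-specific emissions, node weights, insert-region patterns.

# Two subgroups over a 5-column core; group B carries a W insert after
# core position 2 that group A lacks.
himsaFixture <- function() {
  a <- setNames(rep("ACDEF", 6), paste0("a", 1:6))
  b <- setNames(rep("ACWDEF", 6), paste0("b", 1:6))
  ss <- SequenceSet(c(a, b))
  mm <- rbind(matrix(rep(1:5, each = 6), 6, 5),
              matrix(rep(c(1L, 2L, 4L, 5L, 6L), each = 6), 6, 5))
  rownames(mm) <- seqIds(ss)
  aln <- AlignmentState(mm)
  hier <- new("Hierarchy", parent = c(0L, 1L, 1L, 1L),
              labels = as.character(1:4), reject = 4L,
              assignments = rep(c(2L, 3L), each = 6), heightLimit = 5L)
  pats <- PatternSet(list(list(), list(), list(), list()))
  list(ss = ss, aln = aln, hier = hier, pats = pats)
}

test_that("unrefined sub-alignments give identity templates", {
  fx <- himsaFixture()
  hm <- initHiMSA(fx$ss, fx$aln, fx$hier, fx$pats)
  hm <- buildTemplates(hm)
  expect_identical(hm@templates[[2]], 1:5)
  expect_identical(hm@templates[[3]], 1:5)
})

test_that("a child-only column becomes an insert in the template", {
  fx <- himsaFixture()
  hm <- initHiMSA(fx$ss, fx$aln, fx$hier, fx$pats)
  # give node 3 a sub-alignment with the W aligned as an extra column
  mmB <- matrix(rep(c(1L, 2L, 3L, 4L, 5L, 6L), each = 6), 6, 6)
  hm@subAlignments[[3]] <- AlignmentState(mmB)
  hm <- buildTemplates(hm)
  expect_identical(hm@templates[[3]], c(1L, 2L, NA, 3L, 4L, 5L))
})

test_that("template composition along a lineage equals the direct map", {
  fx <- himsaFixture()
  # three-level lineage: root(1) -> mid(2) -> leaf(5)
  hier <- new("Hierarchy", parent = c(0L, 1L, 1L, 1L, 2L),
              labels = as.character(1:5), reject = 4L,
              assignments = c(rep(2L, 3), rep(5L, 3), rep(3L, 6)),
              heightLimit = 5L)
  pats <- PatternSet(replicate(5, list(), simplify = FALSE))
  hm <- initHiMSA(fx$ss, fx$aln, hier, pats)
  hm <- buildTemplates(hm)
  composed <- hiMSA:::mapColumnsToAncestor(hm, 5L, 1L)
  viaMid <- hm@templates[[2]][hm@templates[[5]]]
  expect_identical(composed, viaMid)
})

test_that("inconsistent shared-sequence mappings error in strict mode", {
  fx <- himsaFixture()
  hm <- initHiMSA(fx$ss, fx$aln, fx$hier, fx$pats)
  # corrupt node 2's sub-alignment so its rows disagree about column 3
  mmA <- matchMap(hm@subAlignments[[2]])
  mmA[1, 3] <- 4L; mmA[1, 4] <- NA  # row 1 puts position 4 in column 3
  hm@subAlignments[[2]] <- AlignmentState(mmA)
  expect_error(buildTemplates(hm, strict = TRUE), "a1")
  # default: majority vote resolves it
  hm2 <- buildTemplates(hm)
  expect_identical(hm2@templates[[2]], 1:5)
})

test_that("insert-region pattern search finds invariant residues", {
  fx <- himsaFixture()
  hm <- initHiMSA(fx$ss, fx$aln, fx$hier, fx$pats)
  mmB <- matrix(rep(1:6, each = 6), 6, 6)
  hm@subAlignments[[3]] <- AlignmentState(mmB)
  hm <- buildTemplates(hm)
  found <- patternSearchInsertRegions(hm, 3L)
  expect_true("3" %in% names(found))
  expect_true("W" %in% found[["3"]])
  # non-insert columns are untouched by this operation
  expect_false(any(setdiff(names(found), "3") %in% as.character(c(1, 2, 4, 5, 6))))
  # a background-like insert region yields nothing
  hmA <- hm
  found2 <- patternSearchInsertRegions(hmA, 2L)
  expect_length(found2, 0) # node 2 has no insert columns at all
})

test_that("the assembled hiHMM has lineage-specific emissions and weights", {
  fx <- himsaFixture()
  # discriminating pattern at flat column 1 for node 2
  pats <- PatternSet(list(list(), list(`1` = "A"), list(), list()))
  hm <- initHiMSA(fx$ss, fx$aln, fx$hier, pats)
  mmB <- matrix(rep(1:6, each = 6), 6, 6)
  hm@subAlignments[[3]] <- AlignmentState(mmB)
  hm <- buildTemplates(hm)
  ip <- replicate(4, list(), simplify = FALSE)
  ip[[3]] <- patternSearchInsertRegions(hm, 3L)
  hh <- assembleHiHMM(hm, ip)
  # the W column of node 3 is owned by node 3 and estimated from its
  # subtree only: W dominates
  wCol <- 3L
  expect_equal(hh@ownership[[3]][wCol], 3L)
  expect_gt(hh@emissions[[3]][wCol, match("W", hiMSA:::AA_ALPHABET20)], 0.5)
  # a root-owned column has identical emissions in every node's HMM
  expect_equal(hh@ownership[[2]][2], 1L)
  rootColIn3 <- which(hm@templates[[3]] == 2L)
  expect_equal(hh@emissions[[2]][2, ], hh@emissions[[3]][rootColIn3, ],
               tolerance = 1e-12)
  # a column patterned by node 2 is owned by node 2 (not the root)
  expect_equal(hh@ownership[[2]][1], 2L)

  # node weights proportional to effective assigned fractions
  fx2 <- himsaFixture()
  hier <- fx2$hier
  hier@assignments <- c(rep(2L, 6), rep(3L, 6))
  ssW <- SequenceSet(setNames(as.character(sequences(fx2$ss)), seqIds(fx2$ss)),
                     weights = c(rep(1, 6), rep(1 / 3, 6)))
  hmW <- buildTemplates(initHiMSA(ssW, fx2$aln, hier, fx2$pats))
  hhW <- assembleHiHMM(hmW)
  expect_equal(unname(hhW@nodeWeights[c(1, 2, 3)]), c(0, 0.75, 0.25))
  expect_equal(sum(hhW@nodeWeights), 1)
})

test_that("purged duplicates are re-threaded into the final sub-alignment", {
  set.seed(61)
  base <- randomBackgroundSeqs(5, 30, seed = 61)
  dup <- as.character(sequences(base))[c(1, 1, 2)]
  ss <- SequenceSet(setNames(c(as.character(sequences(base)), dup),
                             paste0("s", 1:8)))
  aln <- AlignmentState(matrix(rep(1:30, each = 8), 8, 30))
  hier <- new("Hierarchy", parent = c(0L, 1L, 1L),
              labels = as.character(1:3), reject = 3L,
              assignments = rep(2L, 8), heightLimit = 5L)
  pats <- PatternSet(replicate(3, list(), simplify = FALSE))
  hm <- initHiMSA(ss, aln, hier, pats)
  cfg <- SamplerConfig(refineSweeps = 1L)
  hm <- refineSubgroupAlignments(hm, 2L, cfg)
  sub <- hm@subAlignments[[2]]
  expect_equal(nrow(matchMap(sub)), 8L) # everyone present after re-threading
  expect_true(all(rowSums(!is.na(matchMap(sub))) > 0))
})

test_that("sequences emitted by a planted hiHMM score best under their own node", {
  pl <- plantModel(syntheticSpec(nLeaves = 2L, seqsPerLeaf = 10L,
                                 coreLength = 40L, nLeafPatternCols = 6L,
                                 nRootPatternCols = 10L, indelRate = 0),
                   seed = 71)
  em <- emitSequences(pl, seed = 72)
  ri <- hiMSA:::residueIndexMatrix(em$seqs, em$truth)
  logLikUnder <- function(k, leaf) {
    em20 <- pl$hihmm@emissions[[leaf + 1L]]
    sum(log(em20[cbind(seq_len(ncol(ri)), ri[k, ])]), na.rm = TRUE)
  }
  own <- vapply(seq_len(nrow(ri)), function(k) logLikUnder(k, em$labels[k]),
                numeric(1))
  other <- vapply(seq_len(nrow(ri)), function(k)
    logLikUnder(k, 3L - em$labels[k]), numeric(1))
  expect_gt(mean(own - other), 0)
  expect_gt(mean(own > other), 0.9)
})
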