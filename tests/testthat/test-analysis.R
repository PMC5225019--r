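# Delta-BILD functional-specificity statistics and contrast-alignment
# rendering.

# 2 major subgroups, w = 3; column 1 is the specificity-determining one
profileFixture <- function(nPer = 10) {
  g1 <- setNames(rep("RAD", nPer), paste0("g1_", seq_len(nPer)))
  g2 <- setNames(rep("EAD", nPer), paste0("g2_", seq_len(nPer)))
  ss <- SequenceSet(c(g1, g2))
  aln <- AlignmentState(matrix(rep(1:3, each = 2 * nPer), 2 * nPer, 3))
  hier <- new("Hierarchy", parent = c(0L, 1L, 1L, 1L),
              labels = as.character(1:4), reject = 4L,
              assignments = rep(c(2L, 3L), each = nPer), heightLimit = 5L)
  list(ss = ss, aln = aln, hier = hier)
}

test_that("Delta-BILD matches its three-term closed form", {
  fx <- profileFixture(20)
  half <- DirichletMixture(1, rep(0.5, 20))
  unif <- rep(1 / 20, 20)
  d <- deltaBild(fx$ss, fx$aln, fx$hier, 2L, 1L, half, unif)
  # independent gamma-ratio evaluation: BILD(20 R) + BILD(20 E) - BILD(mix)
  bild1 <- function(counts) {
    (lgamma(10) - lgamma(10 + sum(counts)) +
       sum(lgamma(counts + 0.5) - lgamma(0.5))) / log(2) -
      sum(counts) * log2(1 / 20)
  }
  cR <- numeric(20); cR[15] <- 20
  cE <- numeric(20); cE[4] <- 20
  expect_equal(d, bild1(cR) + bild1(cE) - bild1(cR + cE), tolerance = 1e-10)
  expect_gt(d, 0)

  # symmetry: the contrast of one major subgroup equals its complement's
  d2 <- deltaBild(fx$ss, fx$aln, fx$hier, 3L, 1L, half, unif)
  expect_equal(d, d2, tolerance = 1e-12)

  # a subgroup with no residues at the column scores 0 by convention
  mm <- matchMap(fx$aln)
  mm[1:20, 1] <- NA_integer_ # group 1 deleted at column 1
  d0 <- deltaBild(fx$ss, AlignmentState(mm), fx$hier, 2L, 1L, half, unif)
  expect_equal(d0, 0)
})

test_that("the profile normalizes to [0, 100], preserves ranks, and flags", {
  fx <- profileFixture(20)
  prof <- deltaBildProfile(fx$ss, fx$aln, fx$hier)
  expect_equal(nrow(prof), 3)
  expect_equal(min(prof$normalized), 0)
  expect_equal(max(prof$normalized), 100)
  # affine normalization preserves rank order
  expect_identical(order(prof$raw), order(prof$normalized))
  # flags are exactly the > mean + 2 SD rule on normalized scores
  thr <- mean(prof$normalized) + 2 * sd(prof$normalized)
  expect_identical(prof$flag, prof$normalized > thr)
  # the discriminating column ranks highest
  expect_equal(which.max(prof$normalized), 1L)
})

test_that("a degenerate profile warns and returns zeros", {
  nPer <- 6
  ss <- SequenceSet(setNames(rep("AAA", 2 * nPer),
                             paste0("s", seq_len(2 * nPer))))
  aln <- AlignmentState(matrix(rep(1:3, each = 2 * nPer), 2 * nPer, 3))
  hier <- new("Hierarchy", parent = c(0L, 1L, 1L, 1L),
              labels = as.character(1:4), reject = 4L,
              assignments = rep(c(2L, 3L), each = nPer), heightLimit = 5L)
  expect_warning(prof <- deltaBildProfile(ss, aln, hier), "degenerate")
  expect_true(all(prof$normalized == 0))

  hier1 <- new("Hierarchy", parent = c(0L, 1L, 1L),
               labels = as.character(1:3), reject = 3L,
               assignments = rep(2L, 2 * nPer), heightLimit = 5L)
  expect_error(deltaBildProfile(ss, aln, hier1), "two major subgroups")
})

test_that("rendering shows consensus residues with frequency digits in tenths", {
  # column 1: G at 65%, A at 25%, rest scattered; column 2: 20 x 5%
  fgCounts <- matrix(0, 2, 20)
  fgCounts[1, match("G", AA20)] <- 65
  fgCounts[1, match("A", AA20)] <- 25
  fgCounts[1, match("S", AA20)] <- 10
  fgCounts[2, ] <- 5
  ca <- new("ContrastAlignment", node = 2L, foreground = "s1",
            background = character(0), patternColumns = 1L,
            patternSets = list("G"), divergence = 1.2,
            fgCounts = fgCounts, bgCounts = matrix(0, 2, 20))
  ss <- SequenceSet(c(s1 = "GA"))
  aln <- AlignmentState(matrix(1:2, 1, 2))
  txt <- renderContrastAlignment(ca, ss, aln)
  cons1 <- grep("^consensus1", txt, value = TRUE)
  cons2 <- grep("^consensus2", txt, value = TRUE)
  freq1 <- grep("^freq1", txt, value = TRUE)
  freq2 <- grep("^freq2", txt, value = TRUE)
  getCol <- function(line, j) substring(line, 13 + j, 13 + j)
  expect_equal(getCol(cons1, 1), "G")
  expect_equal(getCol(cons2, 1), "A")
  expect_equal(getCol(freq1, 1), "6")
  expect_equal(getCol(freq2, 1), "2")
  # nothing reaches the 10% threshold in column 2
  expect_equal(getCol(cons1, 2), " ")
  # pattern dot marks column 1 only
  pat <- grep("^pattern", txt, value = TRUE)
  expect_equal(getCol(pat, 1), ".")
  expect_equal(getCol(pat, 2), " ")
})

test_that("frequency digits satisfy d <= 10 f < d + 1", {
  for (f in seq(0.005, 0.995, by = 0.01)) {
    d <- hiMSA:::freqDigit(f)
    expect_true(d <= 10 * f && 10 * f < d + 1)
  }
})

test_that("lineage rendering emits one block per node, marking owned columns once", {
  nPer <- 8
  g1 <- setNames(rep("RAD", nPer), paste0("g1_", seq_len(nPer)))
  g2 <- setNames(rep("EAD", nPer), paste0("g2_", seq_len(nPer)))
  ss <- SequenceSet(c(g1, g2))
  aln <- AlignmentState(matrix(rep(1:3, each = 2 * nPer), 2 * nPer, 3))
  hier <- new("Hierarchy", parent = c(0L, 1L, 1L, 1L),
              labels = as.character(1:4), reject = 4L,
              assignments = rep(c(2L, 3L), each = nPer), heightLimit = 5L)
  # root patterns column 3; node 2 patterns columns 3 (shared) and 1
  pats <- PatternSet(list(list(`3` = "D"), list(`3` = "D", `1` = "R"),
                          list(), list()))
  txt <- renderLineage(ss, aln, hier, leaf = 2L, pats)
  headers <- grep("^contrast node", txt)
  expect_length(headers, 2) # root block + leaf block
  patLines <- grep("^pattern", txt, value = TRUE)
  getCol <- function(line, j) substring(line, 13 + j, 13 + j)
  # column 3 is owned by the root: dotted in block 1, not in block 2
  expect_equal(getCol(patLines[1], 3), ".")
  expect_equal(getCol(patLines[2], 3), " ")
  # column 1 belongs to the leaf
  expect_equal(getCol(patLines[2], 1), ".")

  rtf <- renderLineage(ss, aln, hier, leaf = 2L, pats, format = "rtf")
  expect_true(any(grepl("\\\\rtf1", rtf)))
})

test_that("RTF frequency digits use the black/red/gray color classes", {
  lines <- c("freq1        568", "consensus1   GAD")
  rtf <- hiMSA:::renderRTF(lines)
  freqLine <- rtf[grepl("cf1", rtf) | grepl("cf2", rtf)][1]
  expect_true(grepl("\\{\\\\cf1 5\\}", freqLine))
  expect_true(grepl("\\{\\\\cf1 6\\}", freqLine))
  expect_true(grepl("\\{\\\\cf2 8\\}", freqLine))
  # consensus lines are not digit-colored
  expect_false(grepl("cf1", rtf[grepl("consensus1", rtf)][1]))
})
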