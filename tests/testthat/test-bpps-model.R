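# The BPPS likelihood, residue-set catalog, node priors, contrast
# alignments.

# small fixture: root(1) with children 2 and 3, reject 4; three R-rich
# sequences at node 2, three E-rich at node 3
bppsToy <- function() {
  ss <- SequenceSet(c(f1 = "RA", f2 = "RA", f3 = "RA",
                      b1 = "EA", b2 = "EA", b3 = "EA"))
  aln <- AlignmentState(matrix(rep(1:2, each = 6), 6, 2))
  hier <- new("Hierarchy", parent = c(0L, 1L, 1L, 1L),
              labels = as.character(1:4), reject = 4L,
              assignments = c(2L, 2L, 2L, 3L, 3L, 3L), heightLimit = 5L)
  pats <- PatternSet(list(list(), list(`1` = "R"), list(), list()))
  list(ss = ss, aln = aln, hier = hier, pats = pats)
}

test_that("the residue-set catalog has singletons and a decreasing size prior", {
  cat20 <- allowedResidueSets()
  sizes <- vapply(cat20$sets, length, integer(1))
  singles <- unlist(cat20$sets[sizes == 1])
  expect_setequal(singles, strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  expect_equal(sum(cat20$priors), 1)
  p1 <- cat20$priors[sizes == 1][1]
  p3 <- cat20$priors[sizes == 3][1]
  expect_gt(p1, p3)
  # every multi-residue set's prior sits below every smaller set's
  expect_true(all(diff(tapply(cat20$priors, sizes, mean)) < 0))
})

test_that("node assignment priors follow the 0.25/0.70/rest split", {
  h7 <- new("Hierarchy", parent = c(0L, rep(1L, 6)),
            labels = as.character(1:7), reject = 2L,
            assignments = integer(0), heightLimit = 5L)
  pri <- nodeAssignmentPriors(h7)
  expect_equal(pri[1], 0.25)
  expect_equal(pri[2], 0.70)
  expect_equal(unname(pri[3:7]), rep(0.01, 5))
  expect_equal(sum(pri), 1)

  h2 <- Hierarchy(parent = 0L, assignments = integer(0))
  pri2 <- nodeAssignmentPriors(h2)
  expect_equal(pri2[1], 0.25 / 0.95)
  expect_equal(pri2[2], 0.70 / 0.95)
  expect_equal(sum(pri2), 1)
})

test_that("the BPPS log-likelihood matches a hand-evaluated toy", {
  toy <- bppsToy()
  bg <- standardBackground()
  # explicit compositions so the hand computation is exact
  th2 <- matrix(0.05, 2, 20); th2[1, ] <- c(rep(0.01, 20)); th2[1, 4] <- 0.81
  th2 <- th2 / rowSums(th2)
  thetas <- list(matrix(bg, 2, 20, byrow = TRUE), th2,
                 matrix(bg, 2, 20, byrow = TRUE), NULL)
  ll <- logLikelihoodBPPS(toy$ss, toy$aln, toy$hier, toy$pats,
                          alphas = c(0, 0, 0, 0), thetas = thetas)
  # hand sum over the three contrasts (natural log); alphabet indices:
  # A = 1, E = 4, R = 15
  hand <- 0
  # root contrast: all six sequences, both columns, theta = bg; no pattern
  hand <- hand + 3 * (log(bg[["R"]]) + log(bg[["A"]])) +
    3 * (log(bg[["E"]]) + log(bg[["A"]]))
  # node-2 contrast: fg = f1..f3, bg = b1..b3 under theta2
  hand <- hand + 3 * (log(th2[1, 15]) + log(th2[2, 1])) +
    3 * (log(th2[1, 4]) + log(th2[2, 1]))
  # pattern term at column 1, alpha = 0: each fg sequence scores
  # log(1 / th2[1, R])
  hand <- hand + 3 * (log(1) - log(th2[1, 15]))
  # node-3 contrast: fg = b1..b3, bg = f1..f3, theta = standard background
  th3 <- thetas[[3]]
  hand <- hand + 3 * (log(th3[1, 4]) + log(th3[2, 1])) +
    3 * (log(th3[1, 15]) + log(th3[2, 1]))
  expect_equal(ll, unname(hand), tolerance = 1e-10)
})

test_that("an empty pattern reduces to the background composition terms", {
  toy <- bppsToy()
  emptyPats <- PatternSet(replicate(4, list(), simplify = FALSE))
  thetas <- hiMSA:::contrastThetas(
    hiMSA:::residueIndexMatrix(toy$ss, toy$aln), toy$ss@weights, toy$hier,
    standardBackground())
  llEmpty <- logLikelihoodBPPS(toy$ss, toy$aln, toy$hier, emptyPats,
                               alphas = rep(0.1, 4), thetas = thetas)
  llPat <- logLikelihoodBPPS(toy$ss, toy$aln, toy$hier, toy$pats,
                             alphas = rep(1, 4), thetas = thetas)
  # with alpha at its background-only extreme the pattern term is 0 per
  # sequence, so the two coincide
  expect_equal(llEmpty, llPat, tolerance = 1e-10)
})

test_that("the likelihood is invariant to column order", {
  toy <- bppsToy()
  ll1 <- logLikelihoodBPPS(toy$ss, toy$aln, toy$hier, toy$pats,
                           alphas = rep(0.2, 4))
  # the same data with the two columns swapped
  ssSwap <- SequenceSet(c(f1 = "AR", f2 = "AR", f3 = "AR",
                          b1 = "AE", b2 = "AE", b3 = "AE"))
  patsSwap <- PatternSet(list(list(), list(`2` = "R"), list(), list()))
  ll2 <- logLikelihoodBPPS(ssSwap, toy$aln, toy$hier, patsSwap,
                           alphas = rep(0.2, 4))
  expect_equal(ll1, ll2, tolerance = 1e-10)
})

test_that("alpha bounds and assignment consistency are enforced", {
  toy <- bppsToy()
  expect_error(logLikelihoodBPPS(toy$ss, toy$aln, toy$hier, toy$pats,
                                 alphas = c(0, 1.2, 0, 0)), "alpha")
  badHier <- toy$hier
  badHier@assignments <- badHier@assignments[-1]
  expect_error(logLikelihoodBPPS(toy$ss, toy$aln, badHier, toy$pats,
                                 alphas = rep(0, 4)), "exactly one node")
})

test_that("contrast alignments partition sequences correctly", {
  toy <- bppsToy()
  ca <- buildContrastAlignment(toy$ss, toy$aln, toy$hier, 2L, toy$pats)
  expect_setequal(ca@foreground, c("f1", "f2", "f3"))
  expect_setequal(ca@background, c("b1", "b2", "b3"))
  # fg, bg and non-participating partition all sequences
  part <- hiMSA:::contrastPartition(toy$hier, 2L)
  all6 <- seqIds(toy$ss)
  nonPart <- setdiff(all6, c(ca@foreground, ca@background))
  expect_setequal(c(ca@foreground, ca@background, nonPart), all6)
  expect_length(intersect(ca@foreground, ca@background), 0)

  # root contrast: background is the standard-frequency model
  caRoot <- buildContrastAlignment(toy$ss, toy$aln, toy$hier, 1L, toy$pats)
  expect_length(caRoot@background, 0)
  expect_equal(sum(caRoot@bgCounts), 0)

  expect_error(buildContrastAlignment(toy$ss, toy$aln, toy$hier, 4L, toy$pats),
               "reject")
})

test_that("identical fg and bg compositions give near-zero divergence", {
  ss <- SequenceSet(setNames(rep("RA", 8), paste0("s", 1:8)))
  aln <- AlignmentState(matrix(rep(1:2, each = 8), 8, 2))
  hier <- new("Hierarchy", parent = c(0L, 1L, 1L, 1L),
              labels = as.character(1:4), reject = 4L,
              assignments = rep(c(2L, 3L), each = 4), heightLimit = 5L)
  pats <- PatternSet(list(list(), list(`1` = "R"), list(), list()))
  ca <- buildContrastAlignment(ss, aln, hier, 2L, pats,
                               alphas = rep(0.95, 4))
  expect_lt(max(ca@divergence), 0.2)
})
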