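# Hierarchy MCMC: structural moves, assignment and pattern sampling,
# annealing, determinism, conservation.

# 8 sequences at the root of a bare hierarchy
moveFixture <- function() {
  ss <- SequenceSet(setNames(c(rep("GADE", 4), rep("PADE", 4)),
                             paste0("s", 1:8)))
  aln <- AlignmentState(matrix(rep(1:4, each = 8), 8, 4))
  hier <- Hierarchy(parent = 0L, assignments = rep(1L, 8))
  list(ss = ss, aln = aln, hier = hier)
}

test_that("structural moves preserve hierarchy invariants", {
  fx <- moveFixture()
  set.seed(2)
  res <- proposeMove(fx$ss, fx$aln, fx$hier, "add_leaf", node = 1L)
  expect_true(res$ok)
  expect_equal(nodeCount(res$hierarchy), 3L)
  expect_equal(parentMap(res$hierarchy)[3L], 1L)
  expect_equal(length(assignments(res$hierarchy)), 8L)

  # delete a leaf: its sequences go to the parent, exactly
  h2 <- res$hierarchy
  leafSeqs <- which(assignments(h2) == 3L)
  res2 <- proposeMove(fx$ss, fx$aln, h2, "delete_node", node = 3L,
                      patterns = res$patterns, alphas = res$alphas)
  expect_true(res2$ok)
  expect_equal(nodeCount(res2$hierarchy), 2L)
  expect_true(all(assignments(res2$hierarchy)[leafSeqs] == 1L))
  expect_equal(sum(assignments(res2$hierarchy) == 1L),
               sum(assignments(h2) %in% c(1L, 3L)))

  # a move that would exceed the height limit is signalled, not raised
  hChain <- new("Hierarchy", parent = c(0L, 1L, 2L, 1L, 1L),
                labels = as.character(1:5), reject = 5L,
                assignments = rep(1L, 8), heightLimit = 3L)
  cfg3 <- SamplerConfig(heightLimit = 3L)
  res3 <- proposeMove(fx$ss, fx$aln, hChain, "move_subtree", node = 2L,
                      newParent = 4L, config = cfg3)
  # subtree (2,3) under node 4 (depth 2) puts node 3 at depth 4 > 3
  expect_false(res3$ok)
})

test_that("assignment sampling matches the enumerated two-leaf conditional", {
  # leaves discriminated at columns 1-3: G's for node 2, P's for node 3
  ss <- SequenceSet(setNames(c(rep("GGGA", 6), rep("PPPA", 6)),
                             paste0("s", 1:12)))
  aln <- AlignmentState(matrix(rep(1:4, each = 12), 12, 4))
  hier <- new("Hierarchy", parent = c(0L, 1L, 1L, 1L),
              labels = as.character(1:4), reject = 4L,
              assignments = rep(c(2L, 3L), each = 6), heightLimit = 5L)
  pats <- PatternSet(list(list(),
                          list(`1` = "G", `2` = "G", `3` = "G"),
                          list(`1` = "P", `2` = "P", `3` = "P"), list()))
  alphas <- rep(0.05, 4)
  cfg <- SamplerConfig()
  # direct enumeration of the conditional for sequence 1 (a G sequence):
  # p(z) proportional to 2^(w * (pattern-ratio + log2 prior))
  ri <- hiMSA:::residueIndexMatrix(ss, aln)
  st <- hiMSA:::bppsState(ss, aln, cfg, hier, pats, alphas)
  th <- hiMSA:::stateThetas(st)
  sm <- hiMSA:::scoreMatrixState(st, th)
  pri <- hiMSA:::statePriors(st)
  lw <- ss@weights[1] * (sm[1, ] + log2(pri))
  pEnum <- 2^(lw - max(lw)); pEnum <- pEnum / sum(pEnum)
  expect_gt(pEnum[2], 0.9) # a perfect pattern match goes to its node
  set.seed(77)
  draws <- replicate(300, {
    h <- sampleSequenceAssignments(ss, aln, hier, pats, alphas, cfg)
    assignments(h)[1]
  })
  emp <- mean(draws == 2L)
  se <- sqrt(pEnum[2] * (1 - pEnum[2]) / 300)
  expect_lt(abs(emp - pEnum[2]), 3 * se + 0.01)

  # identical sequences receive identical conditional distributions
  expect_equal(sm[1, ], sm[2, ])
})

test_that("featureless sequences favor the reject node by prior", {
  ss <- randomBackgroundSeqs(8, 30, seed = 5)
  aln <- AlignmentState(t(vapply(1:8, function(k) 1:30, integer(30))))
  hier <- Hierarchy(parent = 0L, assignments = rep(1L, 8))
  pats <- PatternSet(replicate(2, list(), simplify = FALSE))
  cfg <- SamplerConfig()
  st <- hiMSA:::bppsState(ss, aln, cfg, hier, pats, rep(0.1, 2))
  sm <- hiMSA:::scoreMatrixState(st, hiMSA:::stateThetas(st))
  pri <- hiMSA:::statePriors(st)
  # with no patterns the conditional is the prior: reject (0.70) dominates
  expect_true(all(sm == 0))
  expect_equal(which.max(pri), rejectNode(hier))
})

test_that("pattern sampling discriminates, abstains, and respects the cap", {
  # one strongly discriminating column
  ss <- SequenceSet(setNames(c(rep("GADE", 8), rep("PADE", 8)),
                             paste0("s", 1:16)))
  aln <- AlignmentState(matrix(rep(1:4, each = 16), 16, 4))
  hier <- new("Hierarchy", parent = c(0L, 1L, 1L, 1L),
              labels = as.character(1:4), reject = 4L,
              assignments = rep(c(2L, 3L), each = 8), heightLimit = 5L)
  set.seed(11)
  pats <- samplePatterns(ss, aln, hier, node = 2L, temperature = 0.05)
  expect_true("1" %in% names(pats@patterns[[2]]))
  expect_true("G" %in% pats@patterns[[2]][["1"]])

  # fg identical to bg: the pattern cost goes unpaid, nothing selected
  ssSame <- SequenceSet(setNames(rep("GADE", 16), paste0("s", 1:16)))
  set.seed(12)
  patsSame <- samplePatterns(ssSame, aln, hier, node = 2L, temperature = 0.05)
  expect_length(patsSame@patterns[[2]], 0)

  # m + 1 strongly discriminating columns with cap m: exactly m retained
  ssMany <- SequenceSet(setNames(c(rep("GGGG", 8), rep("PPPP", 8)),
                                 paste0("s", 1:16)))
  cfgCap <- SamplerConfig(maxPatterns = 3L)
  set.seed(13)
  patsCap <- samplePatterns(ssMany, aln, hier, node = 2L, config = cfgCap,
                            temperature = 0.05)
  expect_length(patsCap@patterns[[2]], 3L)
})

test_that("annealing at vanishing temperature accepts only improving moves", {
  set.seed(1)
  expect_true(hiMSA:::acceptMH(0.5, 1e-6))
  expect_true(hiMSA:::acceptMH(0, 1e-6))
  expect_false(any(replicate(50, hiMSA:::acceptMH(-0.5, 1e-3))))
  # at high temperature worsening moves are sometimes accepted
  expect_true(any(replicate(200, hiMSA:::acceptMH(-0.5, 5))))
})

test_that("the full run is deterministic given the seed and conserves sequences", {
  spec <- syntheticSpec(nLeaves = 2L, seqsPerLeaf = 14L, coreLength = 40L,
                        nLeafPatternCols = 5L, nRootPatternCols = 10L)
  em <- emitSequences(plantModel(spec, seed = 21), seed = 22)
  cfg <- SamplerConfig(minLeafSequences = 8L, msaSweeps = 4L,
                       stallCycles = 4L, maxCycles = 12L)
  fit1 <- runHiMSA(em$seqs, cfg, seed = 33, hierarchical = FALSE)
  fit2 <- runHiMSA(em$seqs, cfg, seed = 33, hierarchical = FALSE)
  expect_identical(fit1@trace, fit2@trace)
  expect_identical(assignments(fit1@hierarchy), assignments(fit2@hierarchy))
  expect_identical(matchMap(fit1@alignment), matchMap(fit2@alignment))
  # sequence conservation at the end of sampling
  expect_equal(length(assignments(fit1@hierarchy)), length(em$seqs))
  expect_equal(sum(tabulate(assignments(fit1@hierarchy),
                            nodeCount(fit1@hierarchy))), length(em$seqs))
  # the best-visited penalized posterior is the running maximum of the trace
  expect_true(max(fit1@trace$bits) >= fit1@trace$bits[1])
})

test_that("empty input is rejected", {
  expect_error(runHiMSA(SequenceSet(character(0))), "empty")
})
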