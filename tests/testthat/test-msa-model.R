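# The MSA statistical model: column marginals, transition prior, joint
# posterior, Gibbs resampling, BILD scores.

unitTrans <- c(mm = 1, mi = 1, md = 1, im = 1, ii = 1, dm = 1, dd = 1)

test_that("column marginal matches its gamma-ratio closed forms", {
  pr <- defaultEmissionPrior()
  expect_equal(logColumnMarginal(rep(0, 20), pr), 0)

  # one observation: predictive equals the prior mean (background)
  cts <- numeric(20); cts[1] <- 1
  expect_equal(logColumnMarginal(cts, pr), log(standardBackground()[["A"]]),
               tolerance = 1e-12)

  # A=2, C=1 under Dirichlet(1,...,1)
  cts <- numeric(20); cts[1] <- 2; cts[2] <- 1
  flat <- DirichletMixture(1, rep(1, 20))
  expect_equal(logColumnMarginal(cts, flat),
               lgamma(20) - lgamma(23) + lgamma(3) + lgamma(2),
               tolerance = 1e-12)

  # mixture: log-sum of component marginals
  mix <- DirichletMixture(c(0.3, 0.7), rbind(rep(1, 20), rep(0.5, 20)))
  byHand <- log(0.3 * exp(logColumnMarginal(cts, DirichletMixture(1, rep(1, 20)))) +
                0.7 * exp(logColumnMarginal(cts, DirichletMixture(1, rep(0.5, 20)))))
  expect_equal(logColumnMarginal(cts, mix), byHand, tolerance = 1e-12)

  expect_error(logColumnMarginal(c(-1, rep(0, 19)), pr), "negative")
})

test_that("transition prior reproduces the per-position gamma blocks", {
  z <- list(mm = 0, mi = 0, md = 0, im = 0, ii = 0, dm = 0, dd = 0)
  expect_equal(logTransitionPrior(z, unitTrans), 0)

  one <- z; one$mm <- 1
  expect_equal(logTransitionPrior(one, unitTrans), log(1 / 3), tolerance = 1e-12)

  # positional factorization: two blocks sum
  two <- list(mm = c(1, 1), mi = c(0, 0), md = c(0, 0), im = c(0, 0),
              ii = c(0, 0), dm = c(0, 0), dd = c(0, 0))
  expect_equal(logTransitionPrior(two, unitTrans), 2 * log(1 / 3),
               tolerance = 1e-12)

  # concatenation property on arbitrary blocks
  set.seed(4)
  a <- lapply(z, function(x) rpois(3, 2))
  b <- lapply(z, function(x) rpois(2, 1))
  ab <- Map(c, a, b)
  expect_equal(logTransitionPrior(ab, unitTrans),
               logTransitionPrior(a, unitTrans) + logTransitionPrior(b, unitTrans),
               tolerance = 1e-10)

  expect_error(logTransitionPrior(z, c(unitTrans[-1], mm = 0)), "positive")
})

test_that("log joint decomposes into columns, background and transitions", {
  ss <- SequenceSet(c(s1 = "AC", s2 = "AC"))
  aln <- AlignmentState(matrix(c(1L, 2L, 1L, 2L), 2, 2, byrow = TRUE))
  pr <- defaultEmissionPrior()
  bg <- standardBackground()
  lj <- logJointAlignment(ss, aln, pr, unitTrans, bg)
  # by hand: two columns with counts {A:2} and {C:2}; no unaligned
  # residues; transitions: per sequence M0->M1->M2->End, i.e. one mm at
  # each of blocks 0,1,2, two sequences
  ctsA <- numeric(20); ctsA[1] <- 2
  ctsC <- numeric(20); ctsC[2] <- 2
  tc <- list(mm = c(2, 2, 2), mi = rep(0, 3), md = rep(0, 3), im = rep(0, 3),
             ii = rep(0, 3), dm = rep(0, 3), dd = rep(0, 3))
  expect_equal(lj, logColumnMarginal(ctsA, pr) + logColumnMarginal(ctsC, pr) +
                 logTransitionPrior(tc, unitTrans), tolerance = 1e-12)

  # zero columns: background term only
  aln0 <- AlignmentState(matrix(integer(0), 2, 0))
  lb <- log(bg)
  expect_equal(logJointAlignment(ss, aln0, pr, unitTrans, bg),
               2 * (lb[["A"]] + lb[["C"]]) +
                 logTransitionPrior(
                   list(mm = 0, mi = 2, md = 0, im = 2, ii = 2, dm = 0, dd = 0),
                   unitTrans),
               tolerance = 1e-12)
})

test_that("joint posterior ratios match exhaustive enumeration", {
  pr <- defaultEmissionPrior()
  bg <- standardBackground()
  prVec <- 2 * bg # the single-component pseudocounts
  set.seed(99)
  for (trial in 1:6) {
    K <- sample(2:3, 1)
    w <- sample(1:2, 1)
    lens <- sample(2:4, K, replace = TRUE)
    seqsChars <- vapply(lens, function(L)
      paste(sample(AA20, L, replace = TRUE), collapse = ""), "")
    ss <- SequenceSet(setNames(seqsChars, paste0("s", 1:K)))
    rowsPer <- lapply(lens, oLegalRows, w = w)
    # sample a handful of joint configurations
    for (rep in 1:8) {
      rows <- do.call(rbind, lapply(rowsPer, function(rl)
        rl[[sample.int(length(rl), 1)]]))
      rows2 <- do.call(rbind, lapply(rowsPer, function(rl)
        rl[[sample.int(length(rl), 1)]]))
      pkgRatio <- logJointAlignment(ss, AlignmentState(rows), pr, unitTrans, bg) -
        logJointAlignment(ss, AlignmentState(rows2), pr, unitTrans, bg)
      oraRatio <- oJointLog(seqsChars, rows, prVec, unitTrans, bg) -
        oJointLog(seqsChars, rows2, prVec, unitTrans, bg)
      expect_equal(pkgRatio, oraRatio, tolerance = 1e-10)
    }
  }
})

test_that("resampling requires an rng acknowledgement and handles the degenerate path", {
  ss <- SequenceSet(c(s1 = "A", s2 = "C"))
  aln <- AlignmentState(matrix(1L, 2, 1))
  expect_error(resampleSequencePath(ss, aln, 2, rng = NULL), "rng")
  # a length-1 sequence against one column has a single legal path
  set.seed(10)
  for (i in 1:10) {
    aln <- resampleSequencePath(ss, aln, 2)
    expect_identical(unname(matchMap(aln)[2, ]), 1L)
  }
})

test_that("empirical resampling frequencies match the enumerated conditional", {
  ss <- SequenceSet(c(s1 = "ACD", s2 = "CAD"))
  w <- 2L
  mm1 <- c(1L, 2L)
  rows2 <- oLegalRows(3, 2)
  pr <- defaultEmissionPrior()
  bg <- standardBackground()
  tp <- SamplerConfig()@transPrior
  lj <- vapply(rows2, function(r2)
    logJointAlignment(ss, AlignmentState(rbind(mm1, r2)), pr, tp, bg),
    numeric(1))
  p <- exp(lj - max(lj)); p <- p / sum(p)
  set.seed(123)
  counts <- numeric(length(rows2))
  keys <- vapply(rows2, function(r) paste(ifelse(is.na(r), 0L, r), collapse = ","), "")
  aln <- AlignmentState(rbind(mm1, rows2[[which.max(p)]]))
  N <- 3000
  for (i in seq_len(N)) {
    aln <- resampleSequencePath(ss, aln, 2, pr, tp, bg)
    k <- match(paste(ifelse(is.na(matchMap(aln)[2, ]), 0L, matchMap(aln)[2, ]),
                     collapse = ","), keys)
    counts[k] <- counts[k] + 1
  }
  emp <- counts / N
  se <- sqrt(p * (1 - p) / N)
  expect_true(all(abs(emp - p) <= 3 * se + 1e-9))
})

test_that("BILD scores measure information against the null", {
  pr <- defaultEmissionPrior()
  null <- standardBackground()
  expect_equal(bildScore(rep(0, 20), pr, null), 0)

  # one observation with a prior whose mean equals the null: 0 bits
  cts <- numeric(20); cts[5] <- 1
  expect_equal(bildScore(cts, pr, null), 0, tolerance = 1e-12)

  # ten identical residues under Dirichlet(0.5), uniform null: gamma-ratio
  # closed form, positive
  cts <- numeric(20); cts[2] <- 10
  half <- DirichletMixture(1, rep(0.5, 20))
  byHand <- (lgamma(10) - lgamma(20) + lgamma(10.5) - lgamma(0.5)) / log(2) -
    10 * log2(1 / 20)
  expect_equal(bildScore(cts, half, rep(1 / 20, 20)), byHand, tolerance = 1e-10)
  expect_gt(bildScore(cts, half, rep(1 / 20, 20)), 0)

  # monotonicity in n once positive
  scores <- vapply(2:30, function(n) {
    cc <- numeric(20); cc[2] <- n
    bildScore(cc, half, rep(1 / 20, 20))
  }, numeric(1))
  pos <- which(scores > 0)
  expect_true(all(diff(scores[min(pos):length(scores)]) > 0))

  expect_error(bildScore(cts, pr, c(0, rep(1 / 19, 19))), "sum to 1|zero null")
})
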