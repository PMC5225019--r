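# The full hiMSA pipeline: flat MSA sampling, redundancy weighting, BPPS
# hierarchy sampling with simulated annealing, hierarchical refinement,
# final pattern re-sampling, and the itemized description-length ledger.

# data and path description length of an alignment, in bits
#' @keywords internal
alignmentBitsParts <- function(seqs, aln, prior, transPrior, background) {
  ri <- residueIndexMatrix(seqs, aln)
  cc <- countsFromIndex(ri, seqs@weights)
  colTerm <- sum(vapply(seq_len(nrow(cc)), function(j)
    logColumnMarginal(cc[j, ], prior), numeric(1)))
  bgTerm <- backgroundTerm(seqs, aln, background)
  pathTerm <- logTransitionPrior(transitionCounts(seqs, aln), transPrior)
  list(dataBits = -(colTerm + bgTerm) / log(2), pathBits = -pathTerm / log(2))
}

#' Run the full hiMSA sampler
#'
#' The complete pipeline: (1) flat MSA sampling (Gibbs over single-sequence
#' paths with MDL-gated architecture adjustment), (2) redundancy
#' down-weighting, (3) BPPS hierarchy sampling with simulated annealing
#' over tree moves, (4) hierarchical sub-alignment refinement and
#' insert-region pattern search, and (5) a final pattern re-sampling pass.
#' Deterministic given \code{seed}.  On unrelated (background-like) input
#' the selected model is the null hierarchy: every sequence in the reject
#' node and no subgroups.
#'
#' @param seqs A \code{SequenceSet}, or a path to a FASTA file.
#' @param config A \code{SamplerConfig}.
#' @param seed Integer seed (forwarded to \code{set.seed}).
#' @param alignment Optional pre-built \code{AlignmentState} (skips step 1).
#' @param hierarchical Build the hierarchical alignment and hiHMM (step 4);
#'   disable for flat partitioning only.
#' @return A \code{HiMSAFit}.
#' @export
runHiMSA <- function(seqs, config = SamplerConfig(), seed = 1L,
                     alignment = NULL, hierarchical = TRUE) {
  if (is.character(seqs)) seqs <- readProteinFasta(seqs)
  stopifnot(is(seqs, "SequenceSet"))
  if (length(seqs) == 0L) stop("empty input")
  set.seed(seed)
  prior <- defaultEmissionPrior(config@emissionPriorMass)
  tp <- config@transPrior
  bg <- standardBackground()
  if (is.null(alignment)) {
    aln <- alignSequences(seqs, sweeps = config@msaSweeps, prior = prior,
                          transPrior = tp, background = bg)
  } else aln <- alignment
  seqs <- computeSequenceWeights(seqs, aln)
  if (length(unique(as.character(sequences(seqs)))) == 1L) {
    # degenerate input: a single distinct sequence carries no partition
    # information, so the fitted model is the bare root hierarchy
    hier <- Hierarchy(parent = 0L,
                      assignments = rep(1L, length(seqs)),
                      heightLimit = config@heightLimit)
    pats <- PatternSet(replicate(2, list(), simplify = FALSE),
                       config@maxPatterns)
    parts <- alignmentBitsParts(seqs, aln, prior, tp, bg)
    ledger <- totalModelDL(
      nodeCountBits = nodeCountDLBits(2L, config@geometricFactor),
      treeBits = treeBitsFor(2L),
      assignmentBits = assignmentDLBits(
        2L, effectiveSize(seqs), priors = nodeAssignmentPriors(
          hier, config@rootPrior, config@rejectPrior),
        nodes = hier@assignments, weights = seqs@weights),
      pathBits = parts$pathBits, dataBits = parts$dataBits)
    return(new("HiMSAFit", hierarchy = hier, patterns = pats,
               alignment = aln, seqs = seqs, ledger = ledger,
               trace = data.frame(cycle = 0L, bits = 0, nodes = 2L),
               alphas = rep(0.1, 2L), himsa = NULL, hihmm = NULL,
               config = config))
  }
  fitted <- bppsFit(seqs, aln, config)
  state <- fitted$state
  # final pattern re-sampling at low temperature (greedy limit)
  thetas <- stateThetas(state)
  for (z in setdiff(seq_along(state$parent), state$reject)) {
    state <- samplePatternsState(state, z, thetas, temperature = 0.05)
    state <- updateAlphaState(state, z, thetas)
  }
  state <- applyNullRule(state, seqs, aln)
  hier <- stateHierarchy(state)
  pats <- statePatterns(state)
  himsaOut <- NULL
  hihmmOut <- NULL
  if (hierarchical && length(state$parent) > 2L) {
    hb <- buildHiMSA(seqs, aln, hier, pats, config)
    himsaOut <- hb$himsa
    hihmmOut <- hb$hihmm
  }
  n <- length(state$parent)
  parts <- alignmentBitsParts(seqs, aln, prior, tp, bg)
  pri <- statePriors(state)
  ledger <- totalModelDL(
    nodeCountBits = nodeCountDLBits(n, config@geometricFactor),
    treeBits = treeBitsFor(n),
    patternBits = sum(vapply(setdiff(seq_len(n), state$reject), function(z)
      patternDLActualBits(state, z), numeric(1))),
    assignmentBits = assignmentDLBits(n, effectiveSize(seqs), priors = pri,
                                      nodes = state$assign,
                                      weights = seqs@weights),
    pathBits = parts$pathBits, dataBits = parts$dataBits)
  new("HiMSAFit", hierarchy = hier, patterns = pats, alignment = aln,
      seqs = seqs, ledger = ledger, trace = fitted$trace,
      alphas = state$alpha, himsa = himsaOut, hihmm = hihmmOut,
      config = config)
}
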