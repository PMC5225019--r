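# The MSA statistical model: Dirichlet(-mixture) column marginals, the
# integrated position-specific transition prior, the joint alignment
# posterior, exact single-sequence Gibbs resampling (forward proposal plus
# Metropolis-Hastings correction), and BILD column scores.
#
# All probabilities stay in natural-log space; information scores are
# reported in bits (log2).

#' Log marginal probability of a column under a Dirichlet mixture
#'
#' The fully normalized Dirichlet-multinomial marginal: a log-sum over
#' mixture components of
#' \code{Gamma(|b|)/Gamma(n+|b|) * prod_i Gamma(h_i+b_i)/Gamma(b_i)}.
#' Ratios of this quantity between alignment states give the column
#' posterior used by the Gibbs sampler; its absolute value is the data
#' description length (in nats) used by the MDL accounting.
#'
#' @param counts Length-20 vector of non-negative (possibly weighted) counts.
#' @param prior A \code{DirichletMixture}.
#' @return Log (natural) marginal probability.
#' @examples
#' logColumnMarginal(rep(0, 20), defaultEmissionPrior())  # 0: empty product
#' @export
logColumnMarginal <- function(counts, prior) {
  if (any(counts < 0)) stop("negative counts are not allowed")
  stopifnot(is(prior, "DirichletMixture"))
  n <- sum(counts)
  comp <- vapply(seq_along(prior@weights), function(c) {
    b <- prior@alpha[c, ]
    lgamma(sum(b)) - lgamma(n + sum(b)) +
      sum(lgamma(counts + b) - lgamma(b))
  }, numeric(1))
  logSumExp(log(prior@weights) + comp)
}

# Per-column Dirichlet-multinomial quantities under the mixture,
# vectorized over a w x 20 count matrix.  Returns the w x 20 matrix of log
# predictive probabilities p(r | counts_j) together with the per-column,
# per-component log joint weights lm (log w_c + log marginal_c(counts_j)),
# which other routines reuse to form marginal ratios.
#' @keywords internal
emissionProfile <- function(countsMat, prior) {
  w <- nrow(countsMat)
  nc <- length(prior@weights)
  n <- rowSums(countsMat)
  lm <- matrix(0, w, nc)
  pred <- matrix(0, w, 20L)
  for (c in seq_len(nc)) {
    b <- prior@alpha[c, ]
    lm[, c] <- log(prior@weights[c]) + lgamma(sum(b)) - lgamma(n + sum(b)) +
      rowSums(lgamma(sweep(countsMat, 2, b, "+"))) - sum(lgamma(b))
  }
  if (w > 0) {
    mx <- apply(lm, 1, max)
    pw <- exp(lm - mx)
    pw <- pw / rowSums(pw)
    for (c in seq_len(nc)) {
      b <- prior@alpha[c, ]
      pc <- sweep(countsMat, 2, b, "+") / (n + sum(b))
      pred <- pred + pw[, c] * pc
    }
  }
  list(logPred = log(pred), lm = lm, n = n)
}

#' @keywords internal
columnPredictive <- function(countsMat, prior) {
  emissionProfile(countsMat, prior)$logPred
}

# ---- transition counts -----------------------------------------------------

# Transition counts of an alignment: a list of seven length-(w+1) vectors
# (blocks 0..w; block 0 leaves Begin, block w enters End).  Weighted by
# sequence weights.
#' @keywords internal
transitionCounts <- function(seqs, aln) {
  mm <- matchMap(aln)
  lens <- Biostrings::width(sequences(seqs))
  wts <- seqs@weights
  w <- ncol(mm)
  tc <- list(mm = numeric(w + 1), mi = numeric(w + 1), md = numeric(w + 1),
             im = numeric(w + 1), ii = numeric(w + 1),
             dm = numeric(w + 1), dd = numeric(w + 1))
  for (k in seq_len(nrow(mm)))
    tc <- addPathCounts(tc, mm[k, ], lens[k], wts[k])
  tc
}

# Add (sign * weight) times sequence k's path transitions to tc.
# prev state encoded as 1 = match(-like), 2 = delete.
#' @keywords internal
addPathCounts <- function(tc, row, len, weight) {
  w <- length(row)
  pos <- 0L
  prev <- 1L # Begin behaves as a match state at block 0
  for (j in seq_len(w + 1)) {
    matched <- if (j <= w) !is.na(row[j]) else TRUE # End behaves as match
    b <- j # block index (j - 1) + 1 for R indexing
    if (j == w + 1L) {
      nIns <- len - pos
    } else if (matched) {
      nIns <- row[j] - pos - 1L
    } else nIns <- 0L
    if (nIns > 0) {
      # inserts at I_block, entered from prev (must be match by legality)
      tc$mi[b] <- tc$mi[b] + weight
      if (nIns > 1) tc$ii[b] <- tc$ii[b] + weight * (nIns - 1)
      tc$im[b] <- tc$im[b] + weight
      prev <- 1L
      pos <- pos + nIns
    }
    if (j == w + 1L) {
      if (nIns == 0) {
        if (prev == 1L) tc$mm[b] <- tc$mm[b] + weight
        else tc$dm[b] <- tc$dm[b] + weight
      }
      break
    }
    if (matched) {
      if (nIns == 0) {
        if (prev == 1L) tc$mm[b] <- tc$mm[b] + weight
        else tc$dm[b] <- tc$dm[b] + weight
      }
      prev <- 1L
      pos <- row[j]
    } else {
      if (prev == 1L) tc$md[b] <- tc$md[b] + weight
      else tc$dd[b] <- tc$dd[b] + weight
      prev <- 2L
    }
  }
  tc
}

#' Log of the integrated position-specific transition prior
#'
#' The product over positions of three Dirichlet-multinomial blocks (for
#' transitions leaving match, insert and delete states), with the
#' position-specific transition probabilities integrated out against
#' Dirichlet priors given by the pseudocounts.
#'
#' @param tc List of seven per-block count vectors
#'   (\code{mm, mi, md, im, ii, dm, dd}), e.g. from an alignment.
#' @param priors Named numeric of positive pseudocounts
#'   (\code{mm, mi, md, im, ii, dm, dd}).
#' @return Log (natural) prior probability of the paths.
#' @examples
#' tc <- list(mm = 1, mi = 0, md = 0, im = 0, ii = 0, dm = 0, dd = 0)
#' exp(logTransitionPrior(tc, c(mm = 1, mi = 1, md = 1,
#'                              im = 1, ii = 1, dm = 1, dd = 1)))  # 1/3
#' @export
logTransitionPrior <- function(tc, priors) {
  if (any(priors <= 0)) stop("transition pseudocounts must be positive")
  nm <- priors[["mm"]] + priors[["mi"]] + priors[["md"]]
  ni <- priors[["im"]] + priors[["ii"]]
  nd <- priors[["dm"]] + priors[["dd"]]
  mBlock <- lgamma(tc$mm + priors[["mm"]]) + lgamma(tc$mi + priors[["mi"]]) +
    lgamma(tc$md + priors[["md"]]) + lgamma(nm) -
    lgamma(tc$mm + tc$mi + tc$md + nm) -
    lgamma(priors[["mm"]]) - lgamma(priors[["mi"]]) - lgamma(priors[["md"]])
  iBlock <- lgamma(tc$ii + priors[["ii"]]) + lgamma(tc$im + priors[["im"]]) +
    lgamma(ni) - lgamma(tc$im + tc$ii + ni) -
    lgamma(priors[["ii"]]) - lgamma(priors[["im"]])
  dBlock <- lgamma(tc$dd + priors[["dd"]]) + lgamma(tc$dm + priors[["dm"]]) +
    lgamma(nd) - lgamma(tc$dd + tc$dm + nd) -
    lgamma(priors[["dd"]]) - lgamma(priors[["dm"]])
  sum(mBlock) + sum(iBlock) + sum(dBlock)
}

# log transition predictive matrix ((w+1) x 7) given counts tc and priors.
#' @keywords internal
transitionPredictive <- function(tc, priors) {
  nm <- priors[["mm"]] + priors[["mi"]] + priors[["md"]]
  ni <- priors[["im"]] + priors[["ii"]]
  nd <- priors[["dm"]] + priors[["dd"]]
  mTot <- tc$mm + tc$mi + tc$md + nm
  iTot <- tc$im + tc$ii + ni
  dTot <- tc$dm + tc$dd + nd
  out <- cbind(mm = log((tc$mm + priors[["mm"]]) / mTot),
               mi = log((tc$mi + priors[["mi"]]) / mTot),
               md = log((tc$md + priors[["md"]]) / mTot),
               im = log((tc$im + priors[["im"]]) / iTot),
               ii = log((tc$ii + priors[["ii"]]) / iTot),
               dm = log((tc$dm + priors[["dm"]]) / dTot),
               dd = log((tc$dd + priors[["dd"]]) / dTot))
  out
}

# ---- joint posterior -------------------------------------------------------

#' Log joint posterior of an alignment state
#'
#' Sum over match columns of the Dirichlet-mixture column marginal, plus
#' the background term for unaligned (insert) residues under the fixed
#' standard composition, plus the integrated transition prior.  This is
#' the sampler's target, up to an additive constant.
#'
#' @param seqs A \code{SequenceSet}.
#' @param aln The matching \code{AlignmentState}.
#' @param prior Emission \code{DirichletMixture}.
#' @param transPrior Named transition pseudocounts.
#' @param background Fixed background composition for unaligned residues.
#' @return Log (natural) unnormalized posterior.
#' @export
logJointAlignment <- function(seqs, aln, prior = defaultEmissionPrior(),
                              transPrior = SamplerConfig()@transPrior,
                              background = standardBackground()) {
  mm <- matchMap(aln)
  if (nrow(mm) != length(seqs))
    stop("alignment and sequence set are inconsistent")
  ri <- residueIndexMatrix(seqs, aln)
  cc <- countsFromIndex(ri, seqs@weights)
  colTerm <- sum(vapply(seq_len(nrow(cc)), function(j)
    logColumnMarginal(cc[j, ], prior), numeric(1)))
  bgTerm <- backgroundTerm(seqs, aln, background)
  colTerm + bgTerm + logTransitionPrior(transitionCounts(seqs, aln), transPrior)
}

# weighted log-probability of all unaligned residues under the background
#' @keywords internal
backgroundTerm <- function(seqs, aln, background) {
  mm <- matchMap(aln)
  s <- as.character(sequences(seqs))
  lb <- log(background)
  total <- 0
  for (k in seq_len(nrow(mm))) {
    codes <- encodeResidues(s[k])
    aligned <- mm[k, !is.na(mm[k, ])]
    unal <- codes[setdiff(seq_along(codes), aligned)]
    unal <- unal[!is.na(unal)]
    if (length(unal)) total <- total + seqs@weights[k] * sum(lb[unal])
  }
  total
}

# ---- Gibbs resampling ------------------------------------------------------

# Contribution of one sequence's path to the log joint, conditional on the
# other sequences' counts.  countsMinus: w x 20; tcMinus: transition counts
# without sequence k; prof: emissionProfile(countsMinus, prior), reused
# across the proposal and both MH evaluations.
#' @keywords internal
pathConditionalLogProb <- function(row, codes, weight, countsMinus, tcMinus,
                                   prior, transPrior, background,
                                   prof = NULL) {
  if (is.null(prof)) prof <- emissionProfile(countsMinus, prior)
  matched <- which(!is.na(row))
  matched <- matched[!is.na(codes[row[matched]])]
  colTerm <- 0
  if (length(matched)) {
    r <- codes[row[matched]]
    nc <- length(prior@weights)
    lmPlus <- matrix(0, length(matched), nc)
    for (c in seq_len(nc)) {
      b <- prior@alpha[c, ]
      sb <- sum(b)
      old <- countsMinus[cbind(matched, r)] + b[r]
      lmPlus[, c] <- prof$lm[matched, c] +
        lgamma(prof$n[matched] + sb) - lgamma(prof$n[matched] + weight + sb) +
        lgamma(old + weight) - lgamma(old)
    }
    margPlus <- apply(lmPlus, 1, logSumExp)
    margBase <- apply(prof$lm[matched, , drop = FALSE], 1, logSumExp)
    colTerm <- sum(margPlus - margBase)
  }
  aligned <- row[!is.na(row)]
  unal <- codes[setdiff(seq_along(codes), aligned)]
  unal <- unal[!is.na(unal)]
  bgTerm <- if (length(unal)) weight * sum(log(background)[unal]) else 0
  tcPlus <- addPathCounts(tcMinus, row, length(codes), weight)
  colTerm + bgTerm + logTransitionPrior(tcPlus, transPrior) -
    logTransitionPrior(tcMinus, transPrior)
}

#' Resample one sequence's alignment path
#'
#' Draws sequence \code{k}'s path from its conditional posterior given all
#' other sequences: a forward pass over the profile inferred from the
#' remaining sequences proposes a path by stochastic traceback, and a
#' Metropolis-Hastings step corrects the proposal so that detailed balance
#' holds exactly with respect to \code{exp(logJointAlignment)}.
#'
#' @param seqs A \code{SequenceSet} (K >= 2).
#' @param aln Current \code{AlignmentState}.
#' @param k Sequence index to resample.
#' @param prior Emission \code{DirichletMixture}.
#' @param transPrior Named transition pseudocounts.
#' @param background Fixed background composition.
#' @param rng Set to \code{TRUE} to acknowledge that R's RNG stream is used;
#'   every stochastic operation in the package draws from the seeded R
#'   generator (reproducibility contract).
#' @return The updated \code{AlignmentState}.
#' @export
resampleSequencePath <- function(seqs, aln, k, prior = defaultEmissionPrior(),
                                 transPrior = SamplerConfig()@transPrior,
                                 background = standardBackground(),
                                 rng = TRUE) {
  if (is.null(rng) || !isTRUE(rng))
    stop("explicit rng acknowledgement required: pass rng = TRUE after set.seed()")
  mm <- matchMap(aln)
  if (nrow(mm) < 2) stop("resampling requires at least two sequences")
  ri <- residueIndexMatrix(seqs, aln)
  riMinus <- ri[-k, , drop = FALSE]
  countsMinus <- countsFromIndex(riMinus, seqs@weights[-k])
  sMinus <- new("SequenceSet", seqs = seqs@seqs[-k], weights = seqs@weights[-k])
  alnMinus <- AlignmentState(mm[-k, , drop = FALSE])
  tcMinus <- transitionCounts(sMinus, alnMinus)
  st <- resampleCore(seqs, mm[k, ], k, countsMinus, tcMinus, prior,
                     transPrior, background)
  mm[k, ] <- st
  AlignmentState(mm)
}

# Shared core: returns the (possibly unchanged) new row for sequence k.
#' @keywords internal
resampleCore <- function(seqs, oldRow, k, countsMinus, tcMinus, prior,
                         transPrior, background) {
  codes <- encodeResidues(as.character(sequences(seqs))[k])
  wgt <- seqs@weights[k]
  prof <- emissionProfile(countsMinus, prior)
  logTrans <- transitionPredictive(tcMinus, transPrior)
  prop <- .dpAlign(prof$logPred, log(background), logTrans,
                   ifelse(is.na(codes), 0L, codes), 0L, integer(0))
  newRow <- prop$path
  newRow[newRow == 0L] <- NA_integer_
  if (identical(newRow, unname(oldRow))) return(newRow)
  oldEval <- .dpAlign(prof$logPred, log(background), logTrans,
                      ifelse(is.na(codes), 0L, codes), 2L,
                      ifelse(is.na(oldRow), 0L, as.integer(oldRow)))
  lpNew <- pathConditionalLogProb(newRow, codes, wgt, countsMinus, tcMinus,
                                  prior, transPrior, background, prof)
  lpOld <- pathConditionalLogProb(oldRow, codes, wgt, countsMinus, tcMinus,
                                  prior, transPrior, background, prof)
  logA <- (lpNew - lpOld) + (oldEval$logq - prop$logq)
  if (is.finite(logA) && (logA >= 0 || log(runif(1)) < logA)) newRow else oldRow
}

# Viterbi threading of one sequence against a fixed profile.
#' @keywords internal
viterbiThread <- function(codes, countsMat, tc, prior, transPrior, background) {
  logEmis <- columnPredictive(countsMat, prior)
  logTrans <- transitionPredictive(tc, transPrior)
  out <- .dpAlign(logEmis, log(background), logTrans,
                  ifelse(is.na(codes), 0L, codes), 1L, integer(0))
  row <- out$path
  row[row == 0L] <- NA_integer_
  row
}

# ---- BILD ------------------------------------------------------------------

#' BILD column score (Bayesian Integral Log-odds), in bits
#'
#' \code{log2} of the ratio between the Dirichlet-mixture marginal of the
#' column counts (hypothesis: related residues) and the product of null
#' frequencies (hypothesis: unrelated residues).
#'
#' @param counts Length-20 vector of non-negative weighted counts.
#' @param prior A \code{DirichletMixture}.
#' @param null Background frequencies (positive, summing to 1).
#' @return Score in bits; 0 for an empty column.
#' @examples
#' cts <- numeric(20); cts[2] <- 10   # ten cysteines
#' bildScore(cts, defaultEmissionPrior(), standardBackground()) > 0
#' @export
bildScore <- function(counts, prior = defaultEmissionPrior(),
                      null = standardBackground()) {
  if (any(null <= 0) || abs(sum(null) - 1) > 1e-6)
    stop("null frequencies must be positive and sum to 1")
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (any(counts > 0 & null == 0)) stop("zero null frequency with non-zero count")
  lm <- logColumnMarginal(counts, prior)
  lnull <- sum(counts * log(null))
  (lm - lnull) / log(2)
}
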