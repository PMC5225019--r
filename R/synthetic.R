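# Synthetic fixture generator: plants a known hierarchy with
# specificity-determining pattern columns and per-column emission
# profiles, emits sequences along HMM paths with indel noise, and scores
# how well an inferred model recovers the planted truth.

#' Default synthetic model specification
#'
#' The standard study conditions: 3 leaves of 60 sequences under the root,
#' a 120-column core, 8 leaf-discriminating pattern columns at strength
#' 0.9 (shared specificity-determining positions: the same columns carry a
#' different conserved residue in each leaf), 30 family-wide conserved
#' columns at strength 0.9 (the root's signature), remaining columns drawn
#' from a Dirichlet with concentration 10 around the standard background,
#' and indel rate 0.02.
#'
#' @param nLeaves,seqsPerLeaf,coreLength,nLeafPatternCols,nRootPatternCols,
#'   strength,indelRate,profileConcentration,insertRegions Override any
#'   default.
#' @return A list specification for \code{\link{plantModel}}.
#' @export
syntheticSpec <- function(nLeaves = 3L, seqsPerLeaf = 60L, coreLength = 120L,
                          nLeafPatternCols = 8L, nRootPatternCols = 30L,
                          strength = 0.9, indelRate = 0.02,
                          profileConcentration = 10,
                          insertRegions = list()) {
  list(nLeaves = as.integer(nLeaves), seqsPerLeaf = as.integer(seqsPerLeaf),
       coreLength = as.integer(coreLength),
       nLeafPatternCols = as.integer(nLeafPatternCols),
       nRootPatternCols = as.integer(nRootPatternCols),
       strength = strength, indelRate = indelRate,
       profileConcentration = profileConcentration,
       insertRegions = insertRegions)
}

#' @keywords internal
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha)
  if (sum(g) <= 0) g <- alpha
  g / sum(g)
}

#' Plant a synthetic hierarchical model
#'
#' Deterministic given the seed; returns the realized \code{PlantedModel}
#' together with the corresponding \code{HiHMM} (lineage-specific
#' emissions consistent with column ownership: leaf pattern columns are
#' owned by leaves, family-conserved columns by the root).
#'
#' @param spec A specification from \code{\link{syntheticSpec}}.
#' @param seed Integer seed.
#' @return List with elements \code{model} (a \code{PlantedModel}) and
#'   \code{hihmm} (a \code{HiHMM}).
#' @export
plantModel <- function(spec = syntheticSpec(), seed = 1L) {
  stopifnot(spec$strength > 0, spec$strength <= 1, spec$coreLength >= 1,
            spec$seqsPerLeaf >= 1)
  if (spec$nLeafPatternCols + spec$nRootPatternCols > spec$coreLength)
    stop("more pattern columns than core columns")
  set.seed(seed)
  bg <- standardBackground()
  w <- spec$coreLength
  cols <- sample.int(w, spec$nRootPatternCols + spec$nLeafPatternCols)
  rootCols <- sort(cols[seq_len(spec$nRootPatternCols)])
  leafCols <- sort(setdiff(cols, rootCols))
  rootRes <- AA_ALPHABET20[sample.int(20, length(rootCols), replace = TRUE,
                                      prob = bg)]
  leafRes <- matrix("", length(leafCols), spec$nLeaves)
  for (ci in seq_along(leafCols))
    leafRes[ci, ] <- AA_ALPHABET20[sample.int(20, spec$nLeaves)]
  profile <- t(vapply(seq_len(w), function(j)
    rdirichlet1(spec$profileConcentration * bg), numeric(20)))
  for (ci in seq_along(rootCols)) {
    r <- match(rootRes[ci], AA_ALPHABET20)
    row <- (1 - spec$strength) * bg
    row[r] <- row[r] + spec$strength
    profile[rootCols[ci], ] <- row
  }
  for (ci in seq_along(leafCols)) profile[leafCols[ci], ] <- bg
  model <- new("PlantedModel", nLeaves = spec$nLeaves,
               seqsPerLeaf = spec$seqsPerLeaf, coreLength = w,
               leafPatternColumns = as.integer(leafCols),
               leafPatternResidues = leafRes,
               rootPatternColumns = as.integer(rootCols),
               rootPatternResidues = rootRes, strength = spec$strength,
               profile = profile, indelRate = spec$indelRate,
               background = bg, insertRegions = spec$insertRegions,
               seed = as.integer(seed))
  # matching hiHMM: root(1), leaves(2..nLeaves+1), reject(last)
  parent <- c(0L, rep(1L, spec$nLeaves), 1L)
  rej <- spec$nLeaves + 2L
  hier <- new("Hierarchy", parent = parent,
              labels = as.character(seq_along(parent)),
              reject = rej, assignments = integer(0), heightLimit = 5L)
  emissions <- vector("list", length(parent))
  ownership <- vector("list", length(parent))
  emissions[[1]] <- profile
  ownership[[1]] <- rep(1L, w)
  ownership[[1]][rootCols] <- 1L
  for (l in seq_len(spec$nLeaves)) {
    em <- profile
    for (ci in seq_along(leafCols)) {
      r <- match(leafRes[ci, l], AA_ALPHABET20)
      row <- (1 - spec$strength) * bg
      row[r] <- row[r] + spec$strength
      em[leafCols[ci], ] <- row
    }
    emissions[[l + 1L]] <- em
    own <- rep(1L, w)
    own[leafCols] <- l + 1L
    ownership[[l + 1L]] <- own
  }
  nw <- numeric(length(parent))
  nw[2:(spec$nLeaves + 1L)] <- 1 / spec$nLeaves
  hihmm <- new("HiHMM", hierarchy = hier, emissions = emissions,
               transitions = replicate(length(parent), list(),
                                       simplify = FALSE),
               ownership = ownership, nodeWeights = nw)
  list(model = model, hihmm = hihmm)
}

#' Emit sequences from a planted model
#'
#' Samples sequences along HMM paths: each core column emits from its
#' (leaf-specific) distribution, is deleted with the indel rate, and is
#' followed by a geometric run of background insert residues with the same
#' rate.  True node labels and the true alignment are recorded.
#'
#' @param planted Result of \code{\link{plantModel}} (or its \code{model}).
#' @param seed Integer seed.
#' @return List: \code{seqs} (a \code{SequenceSet}), \code{labels}
#'   (true leaf index per sequence), \code{truth} (the true
#'   \code{AlignmentState}), \code{model}.
#' @export
emitSequences <- function(planted, seed = 1L) {
  model <- if (is(planted, "PlantedModel")) planted else planted$model
  hihmm <- if (is(planted, "PlantedModel")) NULL else planted$hihmm
  if (is.null(hihmm)) hihmm <- plantModel(
    syntheticSpec(nLeaves = model@nLeaves, seqsPerLeaf = model@seqsPerLeaf,
                  coreLength = model@coreLength),
    model@seed)$hihmm
  set.seed(seed)
  w <- model@coreLength
  bg <- model@background
  K <- model@nLeaves * model@seqsPerLeaf
  res <- character(K)
  labels <- integer(K)
  mm <- matrix(NA_integer_, K, w)
  ids <- character(K)
  k <- 0L
  for (l in seq_len(model@nLeaves)) {
    em <- hihmm@emissions[[l + 1L]]
    for (i in seq_len(model@seqsPerLeaf)) {
      k <- k + 1L
      ids[k] <- sprintf("L%d_s%03d", l, i)
      labels[k] <- l
      chars <- character(0)
      pos <- 0L
      addInserts <- function(chars, pos) {
        while (runif(1) < model@indelRate) {
          chars <- c(chars, AA_ALPHABET20[sample.int(20, 1, prob = bg)])
          pos <- pos + 1L
        }
        list(chars = chars, pos = pos)
      }
      st <- addInserts(chars, pos); chars <- st$chars; pos <- st$pos
      for (j in seq_len(w)) {
        if (runif(1) < model@indelRate) {
          mm[k, j] <- NA_integer_ # deletion: no insert run may follow
          next
        }
        chars <- c(chars, AA_ALPHABET20[sample.int(20, 1, prob = em[j, ])])
        pos <- pos + 1L
        mm[k, j] <- pos
        st <- addInserts(chars, pos); chars <- st$chars; pos <- st$pos
      }
      # leaf-specific insert regions (position = after that core column)
      ir <- model@insertRegions
      if (length(ir) >= l && length(ir[[l]])) {
        reg <- ir[[l]]
        at <- reg$position
        resid <- if (!is.null(reg$residue)) rep(reg$residue, reg$length)
                 else AA_ALPHABET20[sample.int(20, reg$length, replace = TRUE,
                                               prob = bg)]
        anchor <- mm[k, seq_len(at)]
        anchor <- anchor[!is.na(anchor)]
        cut <- if (length(anchor)) max(anchor) else 0L
        chars <- append(chars, resid, after = cut)
        shift <- mm[k, ] > cut & !is.na(mm[k, ])
        mm[k, which(shift)] <- mm[k, which(shift)] + reg$length
        pos <- pos + reg$length
      }
      res[k] <- paste(chars, collapse = "")
    }
  }
  rownames(mm) <- ids
  list(seqs = SequenceSet(setNames(res, ids)), labels = labels,
       truth = AlignmentState(mm), model = model)
}

#' Score recovery of a planted model
#'
#' Compares an inferred hierarchy/patterns/alignment with the planted
#' truth: adjusted Rand index between true and inferred assignments,
#' pattern-column recall and precision (a planted column counts as
#' recovered if any non-reject node selects it, after mapping columns
#' through the alignments, with a residue set overlapping the planted
#' residues), and core-column alignment accuracy.
#'
#' @param truth Result of \code{\link{emitSequences}}.
#' @param fit A \code{HiMSAFit}, or a list with elements
#'   \code{hierarchy}, \code{patterns}, \code{alignment}.
#' @return List: \code{ari}, \code{patternRecall}, \code{patternPrecision},
#'   \code{columnAccuracy}.
#' @export
scoreRecovery <- function(truth, fit) {
  hier <- if (is(fit, "HiMSAFit")) fit@hierarchy else fit$hierarchy
  pats <- if (is(fit, "HiMSAFit")) fit@patterns else fit$patterns
  aln <- if (is(fit, "HiMSAFit")) fit@alignment else fit$alignment
  mmT <- matchMap(truth$truth)
  mmI <- matchMap(aln)
  if (nrow(mmT) != nrow(mmI)) stop("sequence sets do not match")
  if (!is.null(rownames(mmI)) &&
      !identical(rownames(mmT), rownames(mmI))) {
    ord <- match(rownames(mmT), rownames(mmI))
    if (anyNA(ord)) stop("sequence ids do not match")
    mmI <- mmI[ord, , drop = FALSE]
    assignI <- hier@assignments[ord]
  } else assignI <- hier@assignments
  ari <- mclust::adjustedRandIndex(truth$labels, assignI)
  # map true core columns to inferred columns by modal position
  model <- truth$model
  K <- nrow(mmT)
  colMapOf <- function(cTrue) {
    hits <- integer(0)
    for (k in seq_len(K)) {
      p <- mmT[k, cTrue]
      if (is.na(p)) next
      ic <- which(mmI[k, ] == p)
      if (length(ic)) hits <- c(hits, ic)
    }
    if (!length(hits)) return(c(NA_integer_, 0))
    tab <- table(hits)
    c(as.integer(names(tab)[which.max(tab)]), max(tab) / sum(!is.na(mmT[, cTrue])))
  }
  plantedCols <- model@leafPatternColumns
  plantedRes <- lapply(seq_along(plantedCols), function(ci)
    model@leafPatternResidues[ci, ])
  inferredPatCols <- integer(0)
  inferredSets <- list()
  for (z in setdiff(seq_len(nodeCount(hier)), rejectNode(hier))) {
    pz <- pats@patterns[[z]]
    if (length(pz)) {
      inferredPatCols <- c(inferredPatCols, as.integer(names(pz)))
      inferredSets <- c(inferredSets, unname(pz))
    }
  }
  recovered <- logical(length(plantedCols))
  for (ci in seq_along(plantedCols)) {
    mp <- colMapOf(plantedCols[ci])[1]
    if (is.na(mp)) next
    hit <- which(inferredPatCols == mp)
    for (hh in hit) {
      if (length(intersect(inferredSets[[hh]], plantedRes[[ci]]))) {
        recovered[ci] <- TRUE
        break
      }
    }
  }
  recall <- if (length(plantedCols)) mean(recovered) else NA_real_
  # precision: inferred pattern columns that map back to planted
  # discriminating or family-conserved columns
  allPlanted <- c(model@leafPatternColumns, model@rootPatternColumns)
  mappedPlanted <- vapply(allPlanted, function(cT) colMapOf(cT)[1], numeric(1))
  precision <- if (length(inferredPatCols))
    mean(inferredPatCols %in% mappedPlanted) else NA_real_
  accs <- vapply(seq_len(model@coreLength), function(cT) colMapOf(cT)[2],
                 numeric(1))
  list(ari = ari, patternRecall = recall, patternPrecision = precision,
       columnAccuracy = mean(accs, na.rm = TRUE))
}
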