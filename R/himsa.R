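# Converting a partitioned flat MSA into a hierarchical MSA (hiMSA) and
# hierarchical HMM (hiHMM): recursive subgroup realignment, parent-child
# column templates, pattern search in subgroup-specific insert regions,
# lineage-specific emission tables, and node weights.

# restriction of an alignment to a subset of rows
#' @keywords internal
restrictAlignment <- function(aln, rows) {
  AlignmentState(matchMap(aln)[rows, , drop = FALSE])
}

#' @keywords internal
subsetSeqs <- function(seqs, idx) {
  new("SequenceSet", seqs = seqs@seqs[idx], weights = seqs@weights[idx])
}

# fraction identity between two rows of a residue-index matrix
#' @keywords internal
rowIdentity <- function(ri, i, j) {
  ok <- !is.na(ri[i, ]) & !is.na(ri[j, ])
  if (!any(ok)) return(0)
  mean(ri[i, ok] == ri[j, ok])
}

#' Initialize a hierarchical alignment
#'
#' Builds the starting \code{HiMSA}: each node's sub-alignment is the flat
#' alignment restricted to its subtree's sequences (the reject node keeps
#' its own members), with identity templates.  Refinement then proceeds
#' top-down via \code{\link{refineSubgroupAlignments}}.
#'
#' @param seqs A \code{SequenceSet}.
#' @param aln The flat \code{AlignmentState}.
#' @param hierarchy A \code{Hierarchy}.
#' @param patterns A \code{PatternSet} in flat-alignment coordinates.
#' @return A \code{HiMSA}.
#' @export
initHiMSA <- function(seqs, aln, hierarchy, patterns) {
  n <- nodeCount(hierarchy)
  rej <- rejectNode(hierarchy)
  subMembers <- vector("list", n)
  subAlignments <- vector("list", n)
  templates <- vector("list", n)
  for (z in seq_len(n)) {
    mem <- if (z == rej) which(hierarchy@assignments == rej)
           else which(hierarchy@assignments %in%
                        setdiff(subtreeNodes(hierarchy, z), rej))
    subMembers[[z]] <- mem
    subAlignments[[z]] <- restrictAlignment(aln, mem)
    templates[[z]] <- seq_len(numColumns(aln)) # identity until refined
  }
  templates[[rootNode(hierarchy)]] <- seq_len(numColumns(aln))
  new("HiMSA", hierarchy = hierarchy, subAlignments = subAlignments,
      subMembers = subMembers, templates = templates,
      patterns = patterns, seqs = seqs)
}

#' Refine one subgroup's sub-alignment
#'
#' Realigns the node's sequences by MSA sampling started from the parent's
#' alignment: highly similar sequences (>= \code{purgeIdentity}) are purged
#' first, Gibbs sweeps and MDL-gated architecture adjustment follow
#' (subgroup-specific conserved regions gain match columns only when their
#' information exceeds the path cost; subgroup-wide deleted regions lose
#' columns), and purged duplicates are re-threaded by Viterbi.
#'
#' @param himsa A \code{HiMSA} (in progress).
#' @param node Node to refine.
#' @param config A \code{SamplerConfig}.
#' @return The updated \code{HiMSA}.
#' @export
refineSubgroupAlignments <- function(himsa, node, config = SamplerConfig()) {
  mem <- himsa@subMembers[[node]]
  if (length(mem) < 2L) {
    # too small to refine: keep the parent's restriction unchanged
    return(himsa)
  }
  seqsSub <- subsetSeqs(himsa@seqs, mem)
  aln <- himsa@subAlignments[[node]]
  prior <- defaultEmissionPrior(config@emissionPriorMass)
  tp <- config@transPrior
  bg <- standardBackground()
  # purge near-duplicates
  ri <- residueIndexMatrix(seqsSub, aln)
  keep <- integer(0)
  purged <- integer(0)
  for (i in seq_along(mem)) {
    dup <- FALSE
    for (k in keep) {
      if (rowIdentity(ri, i, k) >= config@purgeIdentity) { dup <- TRUE; break }
    }
    if (dup) purged <- c(purged, i) else keep <- c(keep, i)
  }
  seqsKeep <- subsetSeqs(seqsSub, keep)
  alnKeep <- restrictAlignment(aln, keep)
  if (length(keep) >= 2L) {
    for (sw in seq_len(config@refineSweeps))
      alnKeep <- gibbsSweep(seqsKeep, alnKeep, prior, tp, bg)
    alnKeep <- adjustArchitecture(seqsKeep, alnKeep, prior, tp, bg)
  }
  # re-thread purged duplicates against the refined profile
  wNew <- numColumns(alnKeep)
  mmNew <- matrix(NA_integer_, length(mem), wNew)
  mmNew[keep, ] <- matchMap(alnKeep)
  if (length(purged)) {
    counts <- columnCounts(seqsKeep, alnKeep)
    tc <- transitionCounts(seqsKeep, alnKeep)
    s <- as.character(sequences(seqsSub))
    for (i in purged)
      mmNew[i, ] <- viterbiThread(encodeResidues(s[i]), counts, tc,
                                  prior, tp, bg)
  }
  himsa@subAlignments[[node]] <- AlignmentState(mmNew)
  himsa
}

#' Build parent-child column templates
#'
#' For each node, maps its sub-alignment columns to its parent's columns
#' using the residue coordinates of shared sequences (sub-alignments share
#' their sequences by construction, so the mapping is determined, not
#' estimated).  Columns absent from the parent are node-local inserts (NA);
#' parent columns missing from the child are child-deleted.
#'
#' @param himsa A \code{HiMSA} with refined sub-alignments.
#' @param strict With \code{TRUE}, an inconsistent residue mapping for a
#'   shared sequence raises an error naming the sequence and column; the
#'   default resolves by majority vote (columns without a majority become
#'   inserts).
#' @return The updated \code{HiMSA}.
#' @export
buildTemplates <- function(himsa, strict = FALSE) {
  hier <- himsa@hierarchy
  root <- rootNode(hier)
  ids <- seqIds(himsa@seqs)
  for (z in setdiff(seq_len(nodeCount(hier)), c(root, rejectNode(hier)))) {
    par <- hier@parent[z]
    mmC <- matchMap(himsa@subAlignments[[z]])
    mmP <- matchMap(himsa@subAlignments[[par]])
    memC <- himsa@subMembers[[z]]
    memP <- himsa@subMembers[[par]]
    rowInP <- match(memC, memP)
    wC <- ncol(mmC)
    tpl <- rep(NA_integer_, wC)
    for (j in seq_len(wC)) {
      votes <- integer(0)
      for (i in seq_along(memC)) {
        p <- mmC[i, j]
        if (is.na(p) || is.na(rowInP[i])) next
        pc <- which(mmP[rowInP[i], ] == p)
        votes <- c(votes, if (length(pc)) pc else NA_integer_)
      }
      votesOK <- votes[!is.na(votes)]
      if (!length(votesOK)) next
      tab <- table(votesOK)
      top <- as.integer(names(tab)[which.max(tab)])
      frac <- max(tab) / length(votes)
      if (strict && length(unique(votesOK)) > 1L) {
        badSeq <- memC[which(votes != top)[1]]
        stop(sprintf("inconsistent column mapping for sequence '%s' at column %d of node %d",
                     ids[badSeq], j, z))
      }
      if (frac >= 0.5) tpl[j] <- top
    }
    # enforce monotonicity of the mapped columns
    last <- 0L
    for (j in seq_len(wC)) {
      if (!is.na(tpl[j])) {
        if (tpl[j] <= last) tpl[j] <- NA_integer_ else last <- tpl[j]
      }
    }
    himsa@templates[[z]] <- tpl
  }
  himsa@templates[[root]] <-
    seq_len(numColumns(himsa@subAlignments[[root]]))
  himsa
}

# map columns of node z to an ancestor's coordinates (NA once lost);
# anc must lie on z's lineage.  z's template maps to its parent.
#' @keywords internal
mapColumnsToAncestor <- function(himsa, z, anc) {
  hier <- himsa@hierarchy
  cols <- seq_len(numColumns(himsa@subAlignments[[z]]))
  cur <- cols
  node <- z
  while (node != anc) {
    tpl <- himsa@templates[[node]]
    cur <- ifelse(is.na(cur), NA_integer_, tpl[cur])
    node <- hier@parent[node]
    if (node == 0L) stop("ancestor not on lineage")
  }
  cur
}

# translate flat (root-coordinate) patterns into each node's own
# coordinates
#' @keywords internal
nodeCoordinatePatterns <- function(himsa) {
  hier <- himsa@hierarchy
  root <- rootNode(hier)
  n <- nodeCount(hier)
  out <- replicate(n, list(), simplify = FALSE)
  for (z in setdiff(seq_len(n), rejectNode(hier))) {
    pat <- himsa@patterns@patterns[[z]]
    if (!length(pat)) next
    toRoot <- mapColumnsToAncestor(himsa, z, root)
    flatCols <- as.integer(names(pat))
    newPat <- list()
    for (ci in seq_along(flatCols)) {
      local <- which(toRoot == flatCols[ci])
      if (length(local) == 1L)
        newPat[[as.character(local)]] <- pat[[ci]]
    }
    out[[z]] <- newPat
  }
  out
}

#' Search for patterns inside subgroup-specific insert regions
#'
#' Columns of a node's sub-alignment that are absent from its parent
#' (template NA) are scored for discriminating patterns against the
#' standard amino-acid frequencies (these regions have no background
#' alignment).  Sets are drawn as in pattern sampling; only columns whose
#' information gain exceeds the pattern description cost are added.
#'
#' @param himsa A \code{HiMSA} with templates built.
#' @param node Node to search.
#' @param config A \code{SamplerConfig}.
#' @return Named list (column index, in the node's own coordinates, as
#'   character) of residue sets added.
#' @export
patternSearchInsertRegions <- function(himsa, node,
                                       config = SamplerConfig()) {
  tpl <- himsa@templates[[node]]
  insertCols <- which(is.na(tpl))
  if (node == rootNode(himsa@hierarchy) || !length(insertCols))
    return(list())
  mem <- himsa@subMembers[[node]]
  seqsSub <- subsetSeqs(himsa@seqs, mem)
  cts <- columnCounts(seqsSub, himsa@subAlignments[[node]])
  bg <- standardBackground()
  catalog <- allowedResidueSets(config@setPriorDecay)
  p <- config@patternPrior
  out <- list()
  for (j in insertCols) {
    if (sum(cts[j, ]) <= 0) next
    cons <- which.max(cts[j, ])
    cand <- which(vapply(catalog$sets, function(s)
      AA_ALPHABET20[cons] %in% s, logical(1)))
    netBits <- vapply(cand, function(ci)
      patternGainBits(catalog$sets[[ci]], cts[j, ], bg, 0.1,
                      config@alphaMixing) +
        log2(p) + log2(catalog$priors[ci]) - log2(1 - p), numeric(1))
    if (max(netBits) > 0)
      out[[as.character(j)]] <- catalog$sets[[cand[which.max(netBits)]]]
  }
  out
}

#' Assemble the hierarchical HMM
#'
#' One profile HMM per node with lineage-specific emissions: each column is
#' owned by the shallowest node on the lineage whose pattern includes it
#' (the root owns non-discriminating core columns; node-local insert
#' columns are owned where they first appear), and its emission
#' probabilities are estimated from all residues in that column of the
#' subtree rooted at the owner.  Node weights are proportional to the
#' down-weighted fraction of sequences assigned to each node.
#'
#' @param himsa A \code{HiMSA} with templates built.
#' @param insertPatterns Optional list (per node) of insert-region pattern
#'   additions from \code{\link{patternSearchInsertRegions}}.
#' @param config A \code{SamplerConfig}.
#' @return A \code{HiHMM}.
#' @export
assembleHiHMM <- function(himsa, insertPatterns = NULL,
                          config = SamplerConfig()) {
  hier <- himsa@hierarchy
  n <- nodeCount(hier)
  root <- rootNode(hier)
  rej <- rejectNode(hier)
  localPat <- nodeCoordinatePatterns(himsa)
  if (!is.null(insertPatterns)) {
    for (z in seq_along(insertPatterns)) {
      if (length(insertPatterns[[z]]))
        localPat[[z]] <- c(localPat[[z]], insertPatterns[[z]])
    }
  }
  prior <- defaultEmissionPrior(config@emissionPriorMass)
  emissions <- vector("list", n)
  transitions <- vector("list", n)
  ownership <- vector("list", n)
  for (z in setdiff(seq_len(n), rej)) {
    wZ <- numColumns(himsa@subAlignments[[z]])
    lineage <- rev(lineageNodes(hier, z)) # root first
    own <- integer(wZ)
    emis <- matrix(0, wZ, 20)
    maps <- lapply(lineage, function(a) mapColumnsToAncestor(himsa, z, a))
    names(maps) <- as.character(lineage)
    # per-ancestor counts cache
    ctsCache <- lapply(lineage, function(a)
      columnCounts(subsetSeqs(himsa@seqs, himsa@subMembers[[a]]),
                   himsa@subAlignments[[a]]))
    names(ctsCache) <- as.character(lineage)
    for (cc in seq_len(wZ)) {
      owner <- NA_integer_
      # shallowest patterning node possessing the column
      for (a in lineage) {
        ac <- maps[[as.character(a)]][cc]
        if (is.na(ac)) next
        if (as.character(ac) %in% names(localPat[[a]])) { owner <- a; break }
      }
      if (is.na(owner)) {
        for (a in lineage) {
          if (!is.na(maps[[as.character(a)]][cc])) { owner <- a; break }
        }
      }
      if (is.na(owner)) owner <- z
      own[cc] <- owner
      ac <- maps[[as.character(owner)]][cc]
      cts <- ctsCache[[as.character(owner)]][ac, ]
      post <- cts + prior@alpha[1, ]
      emis[cc, ] <- post / sum(post)
    }
    emissions[[z]] <- emis
    ownership[[z]] <- own
    transitions[[z]] <- transitionCounts(
      subsetSeqs(himsa@seqs, himsa@subMembers[[z]]),
      himsa@subAlignments[[z]])
  }
  wts <- himsa@seqs@weights
  nodeEff <- vapply(seq_len(n), function(z)
    sum(wts[hier@assignments == z]), numeric(1))
  nodeEff[rej] <- 0
  nw <- if (sum(nodeEff) > 0) nodeEff / sum(nodeEff) else nodeEff
  new("HiHMM", hierarchy = hier, emissions = emissions,
      transitions = transitions, ownership = ownership, nodeWeights = nw)
}

#' Build and refine the full hierarchical alignment
#'
#' Runs the hiMSA construction pipeline: top-down subgroup realignment
#' starting from the root's children, template construction, and pattern
#' search within subgroup-specific insert regions.
#'
#' @param seqs A \code{SequenceSet}.
#' @param aln The flat \code{AlignmentState}.
#' @param hierarchy A \code{Hierarchy}.
#' @param patterns A \code{PatternSet} (flat coordinates).
#' @param config A \code{SamplerConfig}.
#' @return List with elements \code{himsa} (a \code{HiMSA}),
#'   \code{insertPatterns}, and \code{hihmm} (a \code{HiHMM}).
#' @export
buildHiMSA <- function(seqs, aln, hierarchy, patterns,
                       config = SamplerConfig()) {
  himsa <- initHiMSA(seqs, aln, hierarchy, patterns)
  root <- rootNode(hierarchy)
  d <- nodeDepths(hierarchy@parent)
  order <- setdiff(order(d), c(root, rejectNode(hierarchy)))
  for (z in order) himsa <- refineSubgroupAlignments(himsa, z, config)
  himsa <- buildTemplates(himsa)
  insertPatterns <- replicate(nodeCount(hierarchy), list(), simplify = FALSE)
  for (z in order)
    insertPatterns[[z]] <- patternSearchInsertRegions(himsa, z, config)
  hihmm <- assembleHiHMM(himsa, insertPatterns, config)
  list(himsa = himsa, insertPatterns = insertPatterns, hihmm = hihmm)
}
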