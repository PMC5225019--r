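# Bayesian partitioning with pattern selection (BPPS): the hierarchy
# likelihood over contrast alignments, the residue-set catalog, node
# assignment priors, contamination mixing, and background compositions.
#
# Every node of the hierarchy except the reject node defines a contrast
# alignment: its foreground is the subtree rooted there, its background the
# rest of the parent's subtree (for the root: the standard-frequency model
# of random sequences).  Reject-node sequences participate in no contrast.

#' Catalog of allowed pattern residue sets
#'
#' Singletons plus biochemically sensible groupings (acidic DE, basic KR,
#' amide NQ, hydroxyl ST, small GA, aromatic FYW and its pairs, aliphatic
#' ILVM with its pairs and triples), with prior probability proportional to
#' \code{decay^(|set|-1)}, normalized over the catalog.
#'
#' @param decay Prior decay per extra residue, in (0, 1).
#' @return List with elements \code{sets} (list of character vectors) and
#'   \code{priors} (numeric, summing to 1).
#' @examples
#' cat20 <- allowedResidueSets()
#' length(cat20$sets)
#' @export
allowedResidueSets <- function(decay = 0.5) {
  if (decay <= 0 || decay >= 1) stop("decay must lie in (0, 1)")
  groups <- c(
    as.list(AA_ALPHABET20),
    list(c("D", "E"), c("K", "R"), c("N", "Q"), c("S", "T"), c("G", "A"),
         c("F", "Y"), c("F", "W"), c("Y", "W"),
         c("I", "L"), c("I", "V"), c("I", "M"),
         c("L", "V"), c("L", "M"), c("V", "M"),
         c("F", "Y", "W"),
         c("I", "L", "V"), c("I", "L", "M"), c("I", "V", "M"),
         c("L", "V", "M"),
         c("I", "L", "V", "M")))
  pri <- vapply(groups, function(g) decay^(length(g) - 1), numeric(1))
  list(sets = groups, priors = pri / sum(pri))
}

#' Node assignment priors
#'
#' Root 0.25, reject 0.70, and the remaining 0.05 split equally over the
#' other nodes.  With only root and reject present the two are renormalized
#' to sum to 1.
#'
#' @param hierarchy A \code{Hierarchy}.
#' @param rootPrior,rejectPrior Prior mass for root and reject.
#' @return Numeric vector of priors per node, summing to 1.
#' @examples
#' h <- Hierarchy(parent = c(0L, rep(1L, 5)), assignments = integer(0))
#' nodeAssignmentPriors(h)  # 5 interior nodes at 0.01 each
#' @export
nodeAssignmentPriors <- function(hierarchy, rootPrior = 0.25,
                                 rejectPrior = 0.70) {
  n <- nodeCount(hierarchy)
  root <- rootNode(hierarchy)
  rej <- rejectNode(hierarchy)
  pri <- numeric(n)
  pri[root] <- rootPrior
  pri[rej] <- rejectPrior
  others <- setdiff(seq_len(n), c(root, rej))
  if (length(others)) {
    pri[others] <- (1 - rootPrior - rejectPrior) / length(others)
  } else {
    pri <- pri / sum(pri)
  }
  pri
}

# Foreground emission distribution at a pattern column: mix the uniform
# distribution over the residue set with the background composition theta.
# "contamination": foreground = (1 - alpha) * set + alpha * theta (alpha is
# the fraction of background contamination among foreground sequences);
# "literal": the transposed reading.
#' @keywords internal
patternMixture <- function(set, theta, alpha, mixing = "contamination") {
  u <- numeric(20)
  u[match(set, AA_ALPHABET20)] <- 1 / length(set)
  if (mixing == "contamination") (1 - alpha) * u + alpha * theta
  else (1 - alpha) * theta + alpha * u
}

# Posterior-mean background composition from weighted counts.
#' @keywords internal
estimateTheta <- function(counts, background = standardBackground(),
                          mass = 2) {
  sweep(counts + matrix(background, nrow(counts), 20, byrow = TRUE) * mass,
        1, rowSums(counts) + mass, "/")
}

#' BPPS log-likelihood of an aligned, partitioned sequence set
#'
#' The sum over contrast alignments (one per non-reject node) of the
#' background log-composition terms for all participating sequences, plus,
#' at pattern columns only, the foreground log-ratio terms.  Column
#' positions are treated as statistically independent.  Natural log.
#'
#' @param seqs A \code{SequenceSet}.
#' @param aln The \code{AlignmentState}.
#' @param hierarchy A \code{Hierarchy} carrying sequence assignments.
#' @param patterns A \code{PatternSet}.
#' @param alphas Per-node contamination fractions in [0, 1].
#' @param thetas Optional list of per-node background composition matrices
#'   (columns x 20); estimated from the data when omitted.
#' @param background Standard background (root contrast background).
#' @param mixing \code{"contamination"} or \code{"literal"} (direction of
#'   the alpha mixture).
#' @return Log-likelihood (natural log).
#' @export
logLikelihoodBPPS <- function(seqs, aln, hierarchy, patterns, alphas,
                              thetas = NULL,
                              background = standardBackground(),
                              mixing = "contamination") {
  if (any(alphas < 0 | alphas > 1)) stop("alpha must lie in [0, 1]")
  n <- nodeCount(hierarchy)
  if (length(hierarchy@assignments) != length(seqs))
    stop("every sequence must be assigned to exactly one node")
  ri <- residueIndexMatrix(seqs, aln)
  wts <- seqs@weights
  rej <- rejectNode(hierarchy)
  if (is.null(thetas))
    thetas <- contrastThetas(ri, wts, hierarchy, background)
  total <- 0
  for (h in setdiff(seq_len(n), rej)) {
    part <- contrastPartition(hierarchy, h)
    fg <- which(hierarchy@assignments %in% part$fg)
    bg <- which(hierarchy@assignments %in% part$bg)
    lt <- log(pmax(thetas[[h]], 1e-300))
    for (i in c(fg, bg)) {
      ok <- which(!is.na(ri[i, ]))
      if (length(ok))
        total <- total + wts[i] * sum(lt[cbind(ok, ri[i, ok])])
    }
    pat <- patterns@patterns[[h]]
    if (length(pat)) {
      cols <- as.integer(names(pat))
      for (ci in seq_along(cols)) {
        j <- cols[ci]
        mix <- patternMixture(pat[[ci]], thetas[[h]][j, ], alphas[h], mixing)
        lr <- log(pmax(mix, 1e-300)) - lt[j, ]
        for (i in fg) {
          r <- ri[i, j]
          if (!is.na(r)) total <- total + wts[i] * lr[r]
        }
      }
    }
  }
  total
}

# Foreground/background node sets of a contrast.
#' @keywords internal
contrastPartition <- function(hierarchy, node) {
  rej <- rejectNode(hierarchy)
  fg <- setdiff(subtreeNodes(hierarchy, node), rej)
  if (node == rootNode(hierarchy)) {
    bg <- integer(0) # the standard-frequency model stands in
  } else {
    bg <- setdiff(subtreeNodes(hierarchy, hierarchy@parent[node]),
                  c(fg, rej))
  }
  list(fg = fg, bg = bg)
}

# Background composition matrices (columns x 20) for every contrast.
#' @keywords internal
contrastThetas <- function(ri, wts, hierarchy, background, mass = 2) {
  n <- nodeCount(hierarchy)
  w <- ncol(ri)
  rej <- rejectNode(hierarchy)
  out <- vector("list", n)
  for (h in setdiff(seq_len(n), rej)) {
    part <- contrastPartition(hierarchy, h)
    if (!length(part$bg)) {
      out[[h]] <- matrix(background, w, 20, byrow = TRUE)
    } else {
      bgSeqs <- which(hierarchy@assignments %in% part$bg)
      cts <- countsFromIndex(ri[bgSeqs, , drop = FALSE], wts[bgSeqs])
      out[[h]] <- estimateTheta(cts, background, mass)
    }
  }
  out
}

#' Build one node's contrast alignment
#'
#' Foreground: the node's subtree sequences; background: the rest of the
#' parent's subtree (for the root, the standard-frequency model of random
#' sequences).  The per-pattern-column divergence bar is
#' \code{log10(1 + lambda)} with lambda the foreground pattern log-ratio
#' term (nats) of that column.
#'
#' @param seqs A \code{SequenceSet}.
#' @param aln The \code{AlignmentState}.
#' @param hierarchy A \code{Hierarchy}.
#' @param node Node index (not the reject node).
#' @param patterns A \code{PatternSet}.
#' @param alphas Per-node contamination fractions.
#' @param background Standard background composition.
#' @param mixing Mixture direction.
#' @return A \code{ContrastAlignment}.
#' @export
buildContrastAlignment <- function(seqs, aln, hierarchy, node, patterns,
                                   alphas = NULL,
                                   background = standardBackground(),
                                   mixing = "contamination") {
  if (node == rejectNode(hierarchy)) stop("the reject node has no contrast")
  if (is.null(alphas)) alphas <- rep(0.1, nodeCount(hierarchy))
  ri <- residueIndexMatrix(seqs, aln)
  wts <- seqs@weights
  part <- contrastPartition(hierarchy, node)
  fg <- which(hierarchy@assignments %in% part$fg)
  bg <- which(hierarchy@assignments %in% part$bg)
  fgCts <- countsFromIndex(ri[fg, , drop = FALSE], wts[fg])
  if (length(bg)) {
    bgCts <- countsFromIndex(ri[bg, , drop = FALSE], wts[bg])
    theta <- estimateTheta(bgCts, background)
  } else {
    bgCts <- matrix(0, ncol(ri), 20)
    theta <- matrix(background, ncol(ri), 20, byrow = TRUE)
  }
  pat <- patterns@patterns[[node]]
  cols <- if (length(pat)) as.integer(names(pat)) else integer(0)
  div <- numeric(length(cols))
  for (ci in seq_along(cols)) {
    j <- cols[ci]
    mix <- patternMixture(pat[[ci]], theta[j, ], alphas[node], mixing)
    lr <- log(pmax(mix, 1e-300)) - log(pmax(theta[j, ], 1e-300))
    lam <- sum(fgCts[j, ] * lr)
    div[ci] <- log10(1 + max(0, lam))
  }
  ids <- seqIds(seqs)
  new("ContrastAlignment", node = as.integer(node),
      foreground = ids[fg], background = ids[bg],
      patternColumns = cols, patternSets = unname(pat),
      divergence = div, fgCounts = fgCts, bgCounts = bgCts)
}
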