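# MCMC over hierarchies: tree moves (add/delete/insert/move), Gibbs sweeps
# over sequence assignments and discriminating patterns, contamination
# updates, simulated annealing, and the MDL-penalized posterior that all of
# them target.
#
# Internally the sampler works on a plain-list state for speed; the S4
# classes are the public surface.

# ---- internal state --------------------------------------------------------

#' @keywords internal
bppsState <- function(seqs, aln, config,
                      hierarchy = NULL, patterns = NULL, alphas = NULL) {
  ri <- residueIndexMatrix(seqs, aln)
  K <- nrow(ri)
  if (is.null(hierarchy)) {
    parent <- c(0L, 1L)  # root + reject
    reject <- 2L
    assign <- rep(1L, K)
  } else {
    parent <- hierarchy@parent
    reject <- hierarchy@reject
    assign <- hierarchy@assignments
  }
  n <- length(parent)
  if (is.null(patterns))
    patterns <- replicate(n, list(), simplify = FALSE)
  else patterns <- patterns@patterns
  if (is.null(alphas)) alphas <- rep(0.1, n)
  catalog <- allowedResidueSets(config@setPriorDecay)
  byRes <- lapply(seq_len(20), function(r)
    which(vapply(catalog$sets, function(s) AA_ALPHABET20[r] %in% s,
                 logical(1))))
  list(ri = ri, wts = seqs@weights, K = K, w = ncol(ri),
       parent = parent, reject = reject, assign = assign,
       patterns = patterns, alpha = alphas, cfg = config,
       catalog = catalog, byRes = byRes,
       bg = standardBackground(), l2bg = log2(standardBackground()))
}

#' @keywords internal
stateHierarchy <- function(state, heightLimit = NULL) {
  new("Hierarchy", parent = state$parent,
      labels = as.character(seq_along(state$parent)),
      reject = state$reject, assignments = state$assign,
      heightLimit = as.integer(
        if (is.null(heightLimit)) state$cfg@heightLimit else heightLimit))
}

#' @keywords internal
statePatterns <- function(state) {
  PatternSet(state$patterns, state$cfg@maxPatterns)
}

# tree helpers on a parent vector
#' @keywords internal
subtreeP <- function(parent, node) {
  out <- node
  repeat {
    kids <- which(parent %in% out & !(seq_along(parent) %in% out))
    if (!length(kids)) break
    out <- c(out, kids)
  }
  out
}

#' @keywords internal
ancSelfP <- function(parent, node) {
  out <- node
  while (parent[node] != 0L) { node <- parent[node]; out <- c(out, node) }
  out
}

#' @keywords internal
statePriors <- function(state) {
  n <- length(state$parent)
  root <- which(state$parent == 0L)
  pri <- numeric(n)
  pri[root] <- state$cfg@rootPrior
  pri[state$reject] <- state$cfg@rejectPrior
  others <- setdiff(seq_len(n), c(root, state$reject))
  if (length(others)) pri[others] <- (1 - sum(pri)) / length(others)
  else pri <- pri / sum(pri)
  pri
}

# background composition per contrast (list over nodes; log2 matrices)
#' @keywords internal
stateThetas <- function(state) {
  h <- stateHierarchy(state, heightLimit = 99L)
  contrastThetas(state$ri, state$wts, h, state$bg,
                 mass = state$cfg@emissionPriorMass)
}

# weighted foreground counts of node's subtree: w x 20
#' @keywords internal
fgCountsState <- function(state, node) {
  fgNodes <- setdiff(subtreeP(state$parent, node), state$reject)
  idx <- which(state$assign %in% fgNodes)
  countsFromIndex(state$ri[idx, , drop = FALSE], state$wts[idx])
}

# effective (weighted) size of a node's contrast background; the root's
# background is the standard-frequency model and counts as unlimited
#' @keywords internal
bgEffectiveWeight <- function(state, node) {
  root <- which(state$parent == 0L)
  if (node == root) return(Inf)
  fgNodes <- setdiff(subtreeP(state$parent, node), state$reject)
  bgNodes <- setdiff(subtreeP(state$parent, state$parent[node]),
                     c(fgNodes, state$reject))
  sum(state$wts[state$assign %in% bgNodes])
}

# ---- pattern machinery -----------------------------------------------------

# log2 pattern column gain for a residue set at column j
#' @keywords internal
patternGainBits <- function(set, fgRow, thetaRow, alpha, mixing) {
  mix <- patternMixture(set, thetaRow, alpha, mixing)
  sum(fgRow * (log2(pmax(mix, 1e-300)) - log2(pmax(thetaRow, 1e-300))))
}

# total information a node contributes: pattern gain minus its pattern DL
#' @keywords internal
nodeNetBits <- function(state, node, thetas) {
  pat <- state$patterns[[node]]
  gain <- 0
  if (length(pat) && bgEffectiveWeight(state, node) < 2)
    return(-patternDLActualBits(state, node))
  if (length(pat)) {
    fgCts <- fgCountsState(state, node)
    th <- thetas[[node]]
    cols <- as.integer(names(pat))
    for (ci in seq_along(cols))
      gain <- gain + patternGainBits(pat[[ci]], fgCts[cols[ci], ],
                                     th[cols[ci], ], state$alpha[node],
                                     state$cfg@alphaMixing)
  }
  gain - patternDLActualBits(state, node)
}

# description length of a node's pattern under the column prior p and the
# residue-set catalog prior
#' @keywords internal
patternDLActualBits <- function(state, node) {
  if (node == state$reject) return(0)
  p <- state$cfg@patternPrior
  pat <- state$patterns[[node]]
  nSel <- length(pat)
  bits <- -(state$w - nSel) * log2(1 - p) - nSel * log2(p)
  if (nSel) {
    for (set in pat) {
      idx <- which(vapply(state$catalog$sets, function(s)
        setequal(s, set), logical(1)))
      pr <- if (length(idx)) state$catalog$priors[idx[1]]
            else min(state$catalog$priors)
      bits <- bits - log2(pr)
    }
  }
  bits
}

# Gibbs-sample the pattern of one node (NULL option per column, residue
# sets restricted to those containing the foreground consensus).
#' @keywords internal
samplePatternsState <- function(state, node, thetas, temperature = 1) {
  if (node == state$reject) return(state)
  # a contrast with (effectively) no background sequences carries no
  # discrimination: an absorbing child must not inherit the root's
  # privilege of scoring against the random-sequence model
  if (bgEffectiveWeight(state, node) < 2) {
    state$patterns[[node]] <- list()
    return(state)
  }
  fgCts <- fgCountsState(state, node)
  th <- thetas[[node]]
  p <- state$cfg@patternPrior
  newPat <- list()
  gains <- numeric(0)
  for (j in seq_len(state$w)) {
    if (sum(fgCts[j, ]) <= 0) next
    cons <- which.max(fgCts[j, ])
    cand <- state$byRes[[cons]]
    lw <- c(log2(1 - p),
            vapply(cand, function(ci)
              log2(p) + log2(state$catalog$priors[ci]) +
                patternGainBits(state$catalog$sets[[ci]], fgCts[j, ],
                                th[j, ], state$alpha[node],
                                state$cfg@alphaMixing), numeric(1)))
    pick <- sampleLog2(lw, temperature)
    if (pick > 1L) {
      ci <- cand[pick - 1L]
      newPat[[as.character(j)]] <- state$catalog$sets[[ci]]
      gains <- c(gains, lw[pick] - log2(p) - log2(state$catalog$priors[ci]))
    }
  }
  m <- state$cfg@maxPatterns
  if (length(newPat) > m) {
    keep <- order(gains, decreasing = TRUE)[seq_len(m)]
    newPat <- newPat[sort(keep)]
  }
  state$patterns[[node]] <- newPat
  state
}

# griddy Gibbs update of one node's contamination fraction (Beta(1,9) prior)
#' @keywords internal
updateAlphaState <- function(state, node, thetas) {
  pat <- state$patterns[[node]]
  if (!length(pat)) { state$alpha[node] <- 0.1; return(state) }
  fgCts <- fgCountsState(state, node)
  th <- thetas[[node]]
  cols <- as.integer(names(pat))
  grid <- seq(0.02, 0.6, length.out = 30)
  ll <- vapply(grid, function(a) {
    tot <- log2(dbeta(a, 1, 9))
    for (ci in seq_along(cols))
      tot <- tot + patternGainBits(pat[[ci]], fgCts[cols[ci], ],
                                   th[cols[ci], ], a, state$cfg@alphaMixing)
    tot
  }, numeric(1))
  state$alpha[node] <- grid[sampleLog2(ll)]
  state
}

# ---- assignment machinery --------------------------------------------------

# Per-sequence, per-node log2 score matrix: the likelihood-ratio form of
# the BPPS objective.  Placing sequence i at node z scores the sum, over
# the contrasts on z's lineage, of the foreground pattern log-ratio terms
# log2(theta^alpha / theta) at pattern columns (the background composition
# terms of the double sum telescope out of every between-node comparison
# and are omitted).  Reject placement scores 0: the pure background model.
#' @keywords internal
scoreMatrixState <- function(state, thetas) {
  n <- length(state$parent)
  K <- state$K
  nonRej <- setdiff(seq_len(n), state$reject)
  P <- matrix(0, K, n)
  for (h in nonRej) {
    th <- thetas[[h]]
    pat <- state$patterns[[h]]
    if (length(pat)) {
      ph <- numeric(K)
      cols <- as.integer(names(pat))
      for (ci in seq_along(cols)) {
        j <- cols[ci]
        mix <- patternMixture(pat[[ci]], th[j, ], state$alpha[h],
                              state$cfg@alphaMixing)
        lr <- log2(pmax(mix, 1e-300)) - log2(pmax(th[j, ], 1e-300))
        r <- state$ri[, j]
        ok <- !is.na(r)
        ph[ok] <- ph[ok] + lr[r[ok]]
      }
      P[, h] <- ph
    }
  }
  out <- matrix(0, K, n)
  for (z in nonRej) {
    anc <- ancSelfP(state$parent, z)
    s <- numeric(K)
    for (h in setdiff(anc, state$reject)) s <- s + P[, h]
    out[, z] <- s
  }
  out
}

#' @keywords internal
sampleAssignmentsState <- function(state, thetas, temperature = 1,
                                   subset = NULL, nodes = NULL) {
  sm <- scoreMatrixState(state, thetas)
  pri <- statePriors(state)
  lw <- sweep(sm, 2, log2(pri), "+")
  if (is.null(nodes)) nodes <- seq_along(state$parent)
  if (is.null(subset)) subset <- seq_len(state$K)
  for (i in subset) {
    li <- state$wts[i] * lw[i, nodes]
    state$assign[i] <- nodes[sampleLog2(li, temperature)]
  }
  state
}

# ---- MDL-penalized posterior ----------------------------------------------

#' @keywords internal
treeBitsFor <- function(n) {
  if (n <= 28) treeDLBits(n, exact = TRUE) else treeDLBits(n)
}

# the sampler's target, in bits (larger is better)
#' @keywords internal
penalizedBits <- function(state, thetas = NULL) {
  if (is.null(thetas)) thetas <- stateThetas(state)
  sm <- scoreMatrixState(state, thetas)
  pri <- statePriors(state)
  n <- length(state$parent)
  dataBits <- sum(state$wts * (sm[cbind(seq_len(state$K), state$assign)] +
                                 log2(pri[state$assign])))
  modelBits <- nodeCountDLBits(n, state$cfg@geometricFactor) + treeBitsFor(n) +
    sum(vapply(setdiff(seq_len(n), state$reject), function(z)
      patternDLActualBits(state, z), numeric(1)))
  dataBits - modelBits
}

# ---- tree moves ------------------------------------------------------------

#' @keywords internal
stateDepths <- function(state) nodeDepths(state$parent)

# delete node z: sequences and children go to its parent; indices > z shift
#' @keywords internal
deleteNodeState <- function(state, z) {
  root <- which(state$parent == 0L)
  if (z == root || z == state$reject) return(NULL)
  par <- state$parent[z]
  parent <- state$parent
  parent[parent == z] <- par
  state$assign[state$assign == z] <- par
  keep <- setdiff(seq_along(parent), z)
  remap <- integer(length(parent))
  remap[keep] <- seq_along(keep)
  pv <- parent[keep]
  newPar <- integer(length(pv))
  newPar[pv != 0L] <- remap[pv[pv != 0L]]
  state$parent <- newPar
  state$reject <- remap[state$reject]
  state$assign <- remap[state$assign]
  state$patterns <- state$patterns[keep]
  state$alpha <- state$alpha[keep]
  state
}

# add an empty child under node u (no seeding)
#' @keywords internal
addNodeState <- function(state, u) {
  state$parent <- c(state$parent, u)
  state$patterns <- c(state$patterns, list(list()))
  state$alpha <- c(state$alpha, 0.1)
  state
}

# add a leaf under u, seed it with the parent members most similar to a
# random seed sequence, then burn it in with restricted pattern/assignment
# sweeps
#' @keywords internal
addLeafState <- function(state, u, temperature = 1) {
  d <- stateDepths(state)
  if (d[u] + 1L > state$cfg@heightLimit) return(NULL)
  members <- which(state$assign == u)
  if (length(members) < 4L) return(NULL)
  state <- addNodeState(state, u)
  leaf <- length(state$parent)
  seed <- members[sample.int(length(members), 1L)]
  ident <- vapply(members, function(i) {
    ok <- !is.na(state$ri[i, ]) & !is.na(state$ri[seed, ])
    if (!any(ok)) return(0)
    mean(state$ri[i, ok] == state$ri[seed, ok])
  }, numeric(1))
  take <- members[ident >= stats::quantile(ident, 0.6)]
  if (length(take) < 2L) take <- c(seed, members[which.max(ident)])
  state$assign[take] <- leaf
  pool <- members
  burnTemp <- min(temperature, 0.5)
  n <- length(state$parent)
  pri <- statePriors(state)
  lpriDiff <- log2(pri[leaf]) - log2(pri[u])
  # Restricted burn-in: only the leaf's contrast changes while its members
  # shuffle between u and the leaf, and every other term of the two-way
  # conditional cancels, so each sweep needs just the leaf's background
  # composition, its pattern, and its pattern log-ratio vector.
  bgNodes <- setdiff(subtreeP(state$parent, u), c(leaf, state$reject))
  for (b in seq_len(state$cfg@burnInSweeps)) {
    bgSeqs <- which(state$assign %in% bgNodes)
    cts <- countsFromIndex(state$ri[bgSeqs, , drop = FALSE],
                           state$wts[bgSeqs])
    theta <- estimateTheta(cts, state$bg, state$cfg@emissionPriorMass)
    th <- vector("list", n)
    th[[leaf]] <- theta
    state <- samplePatternsState(state, leaf, th, burnTemp)
    state <- updateAlphaState(state, leaf, th)
    pat <- state$patterns[[leaf]]
    pl <- numeric(length(pool))
    if (length(pat)) {
      cols <- as.integer(names(pat))
      for (ci in seq_along(cols)) {
        j <- cols[ci]
        mix <- patternMixture(pat[[ci]], theta[j, ], state$alpha[leaf],
                              state$cfg@alphaMixing)
        lr <- log2(pmax(mix, 1e-300)) - log2(pmax(theta[j, ], 1e-300))
        r <- state$ri[pool, j]
        ok <- !is.na(r)
        pl[ok] <- pl[ok] + lr[r[ok]]
      }
    }
    dl <- state$wts[pool] * (pl + lpriDiff) / max(burnTemp, 1e-8)
    pLeaf <- 1 / (1 + 2^(-dl))
    state$assign[pool] <- ifelse(runif(length(pool)) < pLeaf, leaf, u)
  }
  state
}

# interpose a new node between z and its parent
#' @keywords internal
insertInternalState <- function(state, z) {
  root <- which(state$parent == 0L)
  if (z == root || z == state$reject) return(NULL)
  state <- addNodeState(state, state$parent[z])
  u <- length(state$parent)
  state$parent[z] <- u
  if (max(stateDepths(state)) > state$cfg@heightLimit) return(NULL)
  thetas <- stateThetas(state)
  state <- samplePatternsState(state, u, thetas)
  state
}

# reparent the subtree at z under u
#' @keywords internal
moveSubtreeState <- function(state, z, u) {
  root <- which(state$parent == 0L)
  if (z == root || z == state$reject || u == state$reject) return(NULL)
  if (u %in% subtreeP(state$parent, z)) return(NULL)
  if (u == state$parent[z]) return(NULL)
  state$parent[z] <- u
  if (max(stateDepths(state)) > state$cfg@heightLimit) return(NULL)
  state
}

# remove leaves below the sequence floor and nodes below the information
# floor, bottom-up
#' @keywords internal
pruneWeakNodes <- function(state) {
  repeat {
    n <- length(state$parent)
    root <- which(state$parent == 0L)
    thetas <- stateThetas(state)
    d <- stateDepths(state)
    victims <- integer(0)
    for (z in setdiff(order(d, decreasing = TRUE), c(root, state$reject))) {
      isLeaf <- !(z %in% state$parent)
      nSub <- sum(state$assign %in% setdiff(subtreeP(state$parent, z),
                                            state$reject))
      if (isLeaf && nSub < state$cfg@minLeafSequences) { victims <- z; break }
      if (nodeNetBits(state, z, thetas) < state$cfg@minNodeBits) {
        victims <- z; break
      }
    }
    if (!length(victims)) break
    state <- deleteNodeState(state, victims)
    if (length(state$parent) == n) break
  }
  state
}

# Bits saved by describing the sequences through the family HMM (column
# marginals + integrated path prior) instead of the null model (a single
# insert state coding every residue at the background composition).
# Negative for unrelated sequences: their apparent alignment is bought
# entirely with path bits.
#' @keywords internal
familySupportBits <- function(seqs, aln, prior, transPrior, background) {
  parts <- alignmentBitsParts(seqs, aln, prior, transPrior, background)
  s <- as.character(sequences(seqs))
  lens <- nchar(s)
  resBits <- 0
  for (k in seq_along(s)) {
    codes <- encodeResidues(s[k])
    codes <- codes[!is.na(codes)]
    resBits <- resBits - seqs@weights[k] * sum(log2(background)[codes])
  }
  tc0 <- list(mm = 0, mi = 0, md = 0, im = 0, ii = 0, dm = 0, dd = 0)
  for (k in seq_along(s))
    tc0 <- addPathCounts(tc0, integer(0), lens[k], seqs@weights[k])
  nullPath <- -logTransitionPrior(tc0, transPrior) / log(2)
  (resBits + nullPath) - (parts$dataBits + parts$pathBits)
}

# After fitting: the root family model is kept only if (a) coding the data
# through the HMM beats the null single-insert-state coding and (b) the
# root's pattern is worth its description; otherwise the selected model is
# the null hierarchy (reject node only).
#' @keywords internal
applyNullRule <- function(state, seqs, aln) {
  thetas <- stateThetas(state)
  root <- which(state$parent == 0L)
  prior <- defaultEmissionPrior(state$cfg@emissionPriorMass)
  support <- familySupportBits(seqs, aln, prior, state$cfg@transPrior,
                               state$bg)
  if (support < state$cfg@minNodeBits ||
      nodeNetBits(state, root, thetas) < state$cfg@minNodeBits) {
    while (length(state$parent) > 2L) {
      z <- setdiff(seq_along(state$parent),
                   c(root, state$reject))[1]
      state <- deleteNodeState(state, z)
      root <- which(state$parent == 0L)
    }
    state$assign[] <- state$reject
    state$patterns[[root]] <- list()
  }
  state
}

#' @keywords internal
acceptMH <- function(deltaBits, temperature) {
  is.finite(deltaBits) &&
    (deltaBits >= 0 || runif(1) < 2^(deltaBits / max(temperature, 1e-3)))
}

# ---- full BPPS fit ---------------------------------------------------------

# Fit the hierarchy by simulated annealing over tree moves with Gibbs
# sweeps inside; returns the best-visited state and the trace.
#' @keywords internal
bppsFit <- function(seqs, aln, config, initState = NULL) {
  state <- if (is.null(initState)) bppsState(seqs, aln, config) else initState
  thetas <- stateThetas(state)
  state <- samplePatternsState(state, which(state$parent == 0L), thetas)
  state <- updateAlphaState(state, which(state$parent == 0L), thetas)
  cur <- penalizedBits(state)
  best <- state
  bestBits <- cur
  trace <- data.frame(cycle = 0L, bits = cur, nodes = length(state$parent))
  stall <- 0L
  for (cycle in seq_len(config@maxCycles)) {
    temp <- max(config@t0 * config@cooling^cycle, 0.05)
    # structural moves
    cand <- NULL
    d <- stateDepths(state)
    eligible <- which(d < config@heightLimit &
                        tabulate(state$assign,
                                 length(state$parent)) >= 4L &
                        seq_along(state$parent) != state$reject)
    if (length(eligible)) {
      u <- eligible[sample.int(length(eligible), 1L)]
      cand <- addLeafState(state, u, temp)
      if (!is.null(cand)) {
        nb <- penalizedBits(cand)
        if (acceptMH(nb - cur, temp)) { state <- cand; cur <- nb }
      }
    }
    others <- setdiff(seq_along(state$parent),
                      c(which(state$parent == 0L), state$reject))
    if (length(others) && runif(1) < 0.35) {
      z <- others[sample.int(length(others), 1L)]
      cand <- deleteNodeState(state, z)
      if (!is.null(cand)) {
        nb <- penalizedBits(cand)
        if (acceptMH(nb - cur, temp)) { state <- cand; cur <- nb }
      }
    }
    others <- setdiff(seq_along(state$parent),
                      c(which(state$parent == 0L), state$reject))
    if (length(others) && runif(1) < 0.25) {
      z <- others[sample.int(length(others), 1L)]
      cand <- insertInternalState(state, z)
      if (!is.null(cand)) {
        nb <- penalizedBits(cand)
        if (acceptMH(nb - cur, temp)) { state <- cand; cur <- nb }
      }
    }
    others <- setdiff(seq_along(state$parent),
                      c(which(state$parent == 0L), state$reject))
    if (length(others) >= 2L && runif(1) < 0.25) {
      z <- others[sample.int(length(others), 1L)]
      targets <- setdiff(seq_along(state$parent),
                         c(subtreeP(state$parent, z), state$reject,
                           state$parent[z]))
      if (length(targets)) {
        u <- targets[sample.int(length(targets), 1L)]
        cand <- moveSubtreeState(state, z, u)
        if (!is.null(cand)) {
          nb <- penalizedBits(cand)
          if (acceptMH(nb - cur, temp)) { state <- cand; cur <- nb }
        }
      }
    }
    # within-state Gibbs sweeps
    thetas <- stateThetas(state)
    for (z in setdiff(seq_along(state$parent), state$reject)) {
      state <- samplePatternsState(state, z, thetas, temp)
      state <- updateAlphaState(state, z, thetas)
    }
    thetas <- stateThetas(state)
    state <- sampleAssignmentsState(state, thetas, temp)
    state <- pruneWeakNodes(state)
    cur <- penalizedBits(state)
    trace <- rbind(trace, data.frame(cycle = cycle, bits = cur,
                                     nodes = length(state$parent)))
    if (cur > bestBits + 0.1) {
      bestBits <- cur
      best <- state
      stall <- 0L
    } else stall <- stall + 1L
    if (stall >= config@stallCycles) break
  }
  best <- applyNullRule(best, seqs, aln)
  list(state = best, bits = penalizedBits(best), trace = trace)
}

# ---- public wrappers -------------------------------------------------------

#' Propose a structural move on a hierarchy
#'
#' Applies one of the Fig-style tree moves: \code{add_leaf} (attach an
#' empty child and seed it by burn-in sampling), \code{delete_node}
#' (sequences and children go to the parent), \code{insert_internal}
#' (interpose a node between a node and its parent), or
#' \code{move_subtree} (reparent a subtree).  Moves that would violate the
#' height limit or touch the reject node are signalled by \code{ok = FALSE}
#' rather than raised.
#'
#' @param seqs A \code{SequenceSet}.
#' @param aln An \code{AlignmentState}.
#' @param hierarchy A \code{Hierarchy}.
#' @param kind One of \code{"add_leaf"}, \code{"delete_node"},
#'   \code{"insert_internal"}, \code{"move_subtree"}.
#' @param node Target node of the move.
#' @param newParent New parent (for \code{move_subtree}).
#' @param patterns Current \code{PatternSet} (optional).
#' @param alphas Per-node contamination fractions (optional).
#' @param config A \code{SamplerConfig}.
#' @return List with elements \code{ok}, \code{hierarchy}, \code{patterns},
#'   \code{alphas}.
#' @export
proposeMove <- function(seqs, aln, hierarchy, kind, node,
                        newParent = NULL, patterns = NULL, alphas = NULL,
                        config = SamplerConfig()) {
  state <- bppsState(seqs, aln, config, hierarchy, patterns, alphas)
  cand <- switch(kind,
    add_leaf = addLeafState(state, node),
    delete_node = deleteNodeState(state, node),
    insert_internal = insertInternalState(state, node),
    move_subtree = {
      stopifnot(!is.null(newParent))
      moveSubtreeState(state, node, newParent)
    },
    stop("unknown move kind: ", kind))
  if (is.null(cand))
    return(list(ok = FALSE, hierarchy = hierarchy,
                patterns = statePatterns(state), alphas = state$alpha))
  list(ok = TRUE, hierarchy = stateHierarchy(cand),
       patterns = statePatterns(cand), alphas = cand$alpha)
}

#' Gibbs-sample sequence-to-node assignments
#'
#' Each sequence's node label is redrawn from its conditional posterior,
#' proportional to the node assignment prior times its contribution to the
#' BPPS likelihood; sequences fitting no node drift to the reject node.
#'
#' @inheritParams proposeMove
#' @param temperature Annealing temperature (1 = the posterior itself).
#' @return The updated \code{Hierarchy}.
#' @export
sampleSequenceAssignments <- function(seqs, aln, hierarchy, patterns = NULL,
                                      alphas = NULL,
                                      config = SamplerConfig(),
                                      temperature = 1) {
  state <- bppsState(seqs, aln, config, hierarchy, patterns, alphas)
  state <- sampleAssignmentsState(state, stateThetas(state), temperature)
  stateHierarchy(state, hierarchy@heightLimit)
}

#' Gibbs-sample one node's discriminating pattern
#'
#' Pattern columns and residue sets are redrawn proportional to their
#' foreground/background discrimination, the residue-set prior, and the
#' pattern column prior; at most \code{maxPatterns} columns are kept and
#' every set contains its column's foreground consensus residue.
#'
#' @inheritParams sampleSequenceAssignments
#' @param node Node whose pattern is resampled (not the reject node).
#' @return The updated \code{PatternSet}.
#' @export
samplePatterns <- function(seqs, aln, hierarchy, node, patterns = NULL,
                           alphas = NULL, config = SamplerConfig(),
                           temperature = 1) {
  if (node == rejectNode(hierarchy)) stop("the reject node carries no pattern")
  state <- bppsState(seqs, aln, config, hierarchy, patterns, alphas)
  state <- samplePatternsState(state, node, stateThetas(state), temperature)
  statePatterns(state)
}
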