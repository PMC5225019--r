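# Flat (non-hierarchical) MSA sampling: progressive initialization against
# a seed sequence, Gibbs sweeps over single-sequence paths, and MDL-gated
# architecture adjustment (match columns are added or removed only when the
# joint posterior, which prices path bits against BILD information,
# improves).

# Initialize an alignment: the sequence of median length becomes the
# template (its positions are the match columns); the remaining sequences
# are threaded progressively by Viterbi against the growing profile.
#' @keywords internal
initialAlignment <- function(seqs, prior, transPrior, background) {
  s <- as.character(sequences(seqs))
  K <- length(s)
  lens <- nchar(s)
  seed <- order(lens)[ceiling(K / 2)]
  w <- lens[seed]
  mm <- matrix(NA_integer_, K, w)
  rownames(mm) <- names(s)
  mm[seed, ] <- seq_len(w)
  counts <- countsFromIndex(matrix(encodeResidues(s[seed]), 1), seqs@weights[seed])
  tc <- addPathCounts(
    list(mm = numeric(w + 1), mi = numeric(w + 1), md = numeric(w + 1),
         im = numeric(w + 1), ii = numeric(w + 1), dm = numeric(w + 1),
         dd = numeric(w + 1)),
    mm[seed, ], lens[seed], seqs@weights[seed])
  for (k in setdiff(order(lens, decreasing = TRUE), seed)) {
    codes <- encodeResidues(s[k])
    row <- viterbiThread(codes, counts, tc, prior, transPrior, background)
    mm[k, ] <- row
    ok <- which(!is.na(row) & !is.na(codes[row]))
    if (length(ok)) {
      idx <- cbind(ok, codes[row[ok]])
      counts[idx] <- counts[idx] + seqs@weights[k]
    }
    tc <- addPathCounts(tc, row, lens[k], seqs@weights[k])
  }
  AlignmentState(mm)
}

# One Gibbs sweep over all sequences, maintaining counts incrementally.
#' @keywords internal
gibbsSweep <- function(seqs, aln, prior, transPrior, background) {
  mm <- matchMap(aln)
  K <- nrow(mm)
  s <- as.character(sequences(seqs))
  lens <- nchar(s)
  ri <- residueIndexMatrix(seqs, aln)
  counts <- countsFromIndex(ri, seqs@weights)
  tc <- transitionCounts(seqs, aln)
  for (k in seq_len(K)) {
    codes <- encodeResidues(s[k])
    # remove k
    ok <- which(!is.na(ri[k, ]))
    if (length(ok)) {
      idx <- cbind(ok, ri[k, ok])
      counts[idx] <- counts[idx] - seqs@weights[k]
    }
    tc <- addPathCounts(tc, mm[k, ], lens[k], -seqs@weights[k])
    newRow <- resampleCore(seqs, mm[k, ], k, counts, tc, prior, transPrior,
                           background)
    mm[k, ] <- newRow
    ri[k, ] <- NA_integer_
    okNew <- which(!is.na(newRow))
    if (length(okNew)) ri[k, okNew] <- codes[newRow[okNew]]
    ok <- which(!is.na(ri[k, ]))
    if (length(ok)) {
      idx <- cbind(ok, ri[k, ok])
      counts[idx] <- counts[idx] + seqs@weights[k]
    }
    tc <- addPathCounts(tc, newRow, lens[k], seqs@weights[k])
  }
  AlignmentState(mm)
}

# Remove match column j; residues aligned there become inserts.  Sequences
# whose path would become illegal (insert flanked by deletions) are
# re-threaded by Viterbi against the reduced profile.
#' @keywords internal
dropColumn <- function(seqs, aln, j, prior, transPrior, background) {
  mm <- matchMap(aln)[, -j, drop = FALSE]
  s <- as.character(sequences(seqs))
  bad <- integer(0)
  for (k in seq_len(nrow(mm))) {
    if (!legalRow(mm[k, ], nchar(s[k]))) bad <- c(bad, k)
  }
  if (length(bad)) {
    good <- setdiff(seq_len(nrow(mm)), bad)
    counts <- countsFromIndex(residueIndexMatrix(
      new("SequenceSet", seqs = seqs@seqs[good], weights = seqs@weights[good]),
      AlignmentState(mm[good, , drop = FALSE])), seqs@weights[good])
    tcg <- transitionCounts(
      new("SequenceSet", seqs = seqs@seqs[good], weights = seqs@weights[good]),
      AlignmentState(mm[good, , drop = FALSE]))
    for (k in bad) {
      codes <- encodeResidues(s[k])
      mm[k, ] <- viterbiThread(codes, counts, tcg, prior, transPrior, background)
    }
  }
  AlignmentState(mm)
}

# Is a match-map row a legal path? (strictly increasing positions; inserts
# only between two matched columns or at the free ends adjacent to matches)
#' @keywords internal
legalRow <- function(row, len) {
  w <- length(row)
  pos <- 0L
  prevMatched <- TRUE # Begin
  for (j in seq_len(w)) {
    if (!is.na(row[j])) {
      if (row[j] <= pos) return(FALSE)
      if (row[j] > pos + 1L && !prevMatched) return(FALSE)
      pos <- row[j]
      prevMatched <- TRUE
    } else prevMatched <- FALSE
  }
  if (len > pos && !prevMatched) return(FALSE)
  TRUE
}

# K x (w+1) logical: does sequence k carry >= 1 insert residue in the
# region after column j (block j, j = 0..w)?
#' @keywords internal
insertPresenceMatrix <- function(mm, lens) {
  K <- nrow(mm); w <- ncol(mm)
  out <- matrix(FALSE, K, w + 1L)
  for (k in seq_len(K)) {
    a <- mm[k, ]
    lo <- integer(w + 1L) # max matched position at or before block j
    cur <- 0L
    for (j in seq_len(w)) {
      if (!is.na(a[j])) cur <- a[j]
      lo[j + 1L] <- cur
    }
    hi <- integer(w + 1L) # min matched position after block j
    cur <- lens[k] + 1L
    for (j in w:1) {
      hi[j] <- if (!is.na(a[j])) a[j] else cur
      cur <- hi[j]
    }
    hi[w + 1L] <- lens[k] + 1L
    out[k, ] <- (hi - lo) > 1L
  }
  out
}

# Insert a new match column after column j (0 = before the first), taking
# for each sequence the first insert residue in that region (left
# justification); sequences with no insert there get a deletion.
#' @keywords internal
addColumnAfter <- function(seqs, aln, j) {
  mm <- matchMap(aln)
  s <- as.character(sequences(seqs))
  K <- nrow(mm)
  w <- ncol(mm)
  newCol <- rep(NA_integer_, K)
  for (k in seq_len(K)) {
    lo <- if (j >= 1) {
      prev <- mm[k, seq_len(j)]
      prev <- prev[!is.na(prev)]
      if (length(prev)) max(prev) else 0L
    } else 0L
    hi <- if (j < w) {
      nxt <- mm[k, (j + 1):w]
      nxt <- nxt[!is.na(nxt)]
      if (length(nxt)) min(nxt) else nchar(s[k]) + 1L
    } else nchar(s[k]) + 1L
    if (hi - lo > 1L) newCol[k] <- lo + 1L
  }
  mmNew <- cbind(mm[, seq_len(j), drop = FALSE], newCol,
                 if (j < w) mm[, (j + 1):w, drop = FALSE])
  colnames(mmNew) <- NULL
  # adding a column can strand a lone insert next to deletions; repair rows
  out <- AlignmentState(mmNew)
  bad <- which(!vapply(seq_len(K), function(k)
    legalRow(mmNew[k, ], nchar(s[k])), logical(1)))
  if (length(bad)) {
    for (k in bad) mmNew[k, ] <- NA_integer_ # re-threaded by caller's sweep
    out <- AlignmentState(mmNew)
  }
  out
}

#' MDL-gated architecture adjustment
#'
#' Scans the alignment for removable match columns (kept only if dropping
#' them lowers the joint posterior) and for insert regions consistent
#' enough to support new match columns (added only if the joint posterior
#' improves, i.e. the BILD information of the new column exceeds its path
#' cost).
#'
#' @param seqs A \code{SequenceSet}.
#' @param aln Current \code{AlignmentState}.
#' @param prior Emission \code{DirichletMixture}.
#' @param transPrior Named transition pseudocounts.
#' @param background Background composition.
#' @param minOccupancy Insert regions carried by at least this fraction of
#'   sequences are candidate columns.
#' @param maxDropOccupancy Only columns occupied by less than this fraction
#'   of sequences are candidates for removal.
#' @return An updated \code{AlignmentState}.
#' @export
adjustArchitecture <- function(seqs, aln, prior = defaultEmissionPrior(),
                               transPrior = SamplerConfig()@transPrior,
                               background = standardBackground(),
                               minOccupancy = 0.5,
                               maxDropOccupancy = 0.7) {
  best <- logJointAlignment(seqs, aln, prior, transPrior, background)
  # drop pass
  j <- 1L
  while (j <= ncol(matchMap(aln))) {
    occupied <- mean(!is.na(matchMap(aln)[, j]))
    if (occupied < maxDropOccupancy) { # well-occupied columns never improve
      cand <- dropColumn(seqs, aln, j, prior, transPrior, background)
      lj <- logJointAlignment(seqs, cand, prior, transPrior, background)
      if (lj > best) { aln <- cand; best <- lj; next }
    }
    j <- j + 1L
  }
  # add pass: look for populated insert regions
  repeat {
    mm <- matchMap(aln)
    w <- ncol(mm)
    s <- as.character(sequences(seqs))
    lens <- nchar(s)
    insertAt <- insertPresenceMatrix(mm, lens) # K x (w+1), blocks 0..w
    added <- FALSE
    for (j in 0:w) {
      if (mean(insertAt[, j + 1L]) < minOccupancy) next
      cand <- addColumnAfter(seqs, aln, j)
      # re-thread any rows that were invalidated
      blank <- which(apply(matchMap(cand), 1, function(r) all(is.na(r))))
      if (length(blank)) {
        good <- setdiff(seq_len(nrow(mm)), blank)
        counts <- countsFromIndex(residueIndexMatrix(
          new("SequenceSet", seqs = seqs@seqs[good],
              weights = seqs@weights[good]),
          AlignmentState(matchMap(cand)[good, , drop = FALSE])),
          seqs@weights[good])
        tcg <- transitionCounts(
          new("SequenceSet", seqs = seqs@seqs[good],
              weights = seqs@weights[good]),
          AlignmentState(matchMap(cand)[good, , drop = FALSE]))
        mc <- matchMap(cand)
        for (k in blank)
          mc[k, ] <- viterbiThread(encodeResidues(s[k]), counts, tcg, prior,
                                   transPrior, background)
        cand <- AlignmentState(mc)
      }
      lj <- logJointAlignment(seqs, cand, prior, transPrior, background)
      if (lj > best) { aln <- cand; best <- lj; added <- TRUE; break }
    }
    if (!added) break
  }
  aln
}

#' Sample a multiple sequence alignment
#'
#' Initializes an alignment progressively against a seed sequence, then
#' iterates Gibbs sweeps over single-sequence paths (each an exact draw
#' from its conditional posterior), with periodic MDL-gated architecture
#' adjustment.  Deterministic given the R RNG seed.
#'
#' @param seqs A \code{SequenceSet}.
#' @param sweeps Number of Gibbs sweeps.
#' @param prior Emission \code{DirichletMixture}.
#' @param transPrior Named transition pseudocounts.
#' @param background Background composition.
#' @param adjustAt Sweep indices after which architecture adjustment runs.
#' @return An \code{AlignmentState}.
#' @export
alignSequences <- function(seqs, sweeps = 8L,
                           prior = defaultEmissionPrior(),
                           transPrior = SamplerConfig()@transPrior,
                           background = standardBackground(),
                           adjustAt = c(3L, 6L)) {
  stopifnot(is(seqs, "SequenceSet"))
  if (length(seqs) == 0L) stop("empty sequence set")
  aln <- initialAlignment(seqs, prior, transPrior, background)
  if (length(seqs) == 1L) return(aln)
  for (sw in seq_len(sweeps)) {
    aln <- gibbsSweep(seqs, aln, prior, transPrior, background)
    if (sw %in% adjustAt)
      aln <- adjustArchitecture(seqs, aln, prior, transPrior, background)
  }
  aln
}
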