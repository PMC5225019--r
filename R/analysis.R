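# Post-hoc statistics and reporting: the Delta-BILD functional-specificity
# profile over major subgroups, and plain-text / minimal-RTF rendering of
# contrast alignments (consensus lines, frequency digits in integer
# tenths, pattern dots, semi-logarithmic divergence bars).

#' Delta-BILD score of one column for one major subgroup
#'
#' \code{BILD(subgroup) + BILD(superfamily minus subgroup) -
#' BILD(superfamily)}: positive when the subgroup's residue composition at
#' the column diverges from the rest of the superfamily.  Reject-node
#' sequences are excluded from the superfamily.
#'
#' @param seqs A \code{SequenceSet}.
#' @param aln The \code{AlignmentState}.
#' @param hierarchy A \code{Hierarchy}.
#' @param node A major subgroup (a non-reject child of the root).
#' @param j Column index.
#' @param prior Emission \code{DirichletMixture}.
#' @param null Background frequencies.
#' @return Score in bits (0 if the subgroup contributes no residues at j).
#' @export
deltaBild <- function(seqs, aln, hierarchy, node, j,
                      prior = defaultEmissionPrior(),
                      null = standardBackground()) {
  rej <- rejectNode(hierarchy)
  if (node == rej) stop("the reject node is not a subgroup")
  ri <- residueIndexMatrix(seqs, aln)
  wts <- seqs@weights
  inG <- hierarchy@assignments %in% setdiff(subtreeNodes(hierarchy, node), rej)
  inAll <- !(hierarchy@assignments %in% rej)
  ctsG <- countsFromIndex(ri[inG, , drop = FALSE], wts[inG])[j, ]
  ctsAll <- countsFromIndex(ri[inAll, , drop = FALSE], wts[inAll])[j, ]
  if (sum(ctsG) == 0) return(0)
  bildScore(ctsG, prior, null) + bildScore(ctsAll - ctsG, prior, null) -
    bildScore(ctsAll, prior, null)
}

#' Delta-BILD profile over all columns
#'
#' For each column, the average Delta-BILD score over the major subgroups
#' (subtrees directly attached to the root, excluding the reject node),
#' linearly normalized so the lowest score is 0 and the highest 100, with
#' columns more than two standard deviations above the mean flagged.
#' When every column scores identically the normalized profile is all
#' zeros and a warning is issued.
#'
#' @inheritParams deltaBild
#' @return A data frame with columns \code{column}, \code{raw} (bits),
#'   \code{normalized} (0-100), \code{flag}.
#' @export
deltaBildProfile <- function(seqs, aln, hierarchy,
                             prior = defaultEmissionPrior(),
                             null = standardBackground()) {
  root <- rootNode(hierarchy)
  majors <- setdiff(childNodes(hierarchy, root), rejectNode(hierarchy))
  if (length(majors) < 2L)
    stop("Delta-BILD profile needs at least two major subgroups")
  w <- numColumns(aln)
  raw <- vapply(seq_len(w), function(j)
    mean(vapply(majors, function(g)
      deltaBild(seqs, aln, hierarchy, g, j, prior, null), numeric(1))),
    numeric(1))
  rng <- range(raw)
  if (diff(rng) < 1e-12) {
    warning("degenerate Delta-BILD profile: all columns score identically")
    normalized <- rep(0, w)
  } else {
    normalized <- 100 * (raw - rng[1]) / diff(rng)
  }
  thr <- mean(normalized) + 2 * sd(normalized)
  data.frame(column = seq_len(w), raw = raw, normalized = normalized,
             flag = normalized > thr)
}

# frequency digit in integer tenths: '8' means 80-90%
#' @keywords internal
freqDigit <- function(f) min(9L, as.integer(floor(10 * f)))

#' Render a contrast alignment as text
#'
#' Produces the standard text notation: representative foreground rows
#' with their aligned residues, up to three consensus lines (residues
#' occurring most frequently and in at least 10 percent of the weighted
#' foreground), frequency digits in integer tenths directly below, dots
#' marking pattern positions, and semi-logarithmic divergence bars.
#'
#' @param ca A \code{ContrastAlignment}.
#' @param seqs The \code{SequenceSet} (for representative rows).
#' @param aln The \code{AlignmentState}.
#' @param representatives Ids (or number) of foreground sequences to show.
#' @param ownedColumns Optional integer subset of \code{ca}'s pattern
#'   columns to mark (lineage rendering marks only columns owned by this
#'   node).
#' @return Character vector of text lines.
#' @export
renderContrastAlignment <- function(ca, seqs, aln, representatives = 3L,
                                    ownedColumns = NULL) {
  w <- nrow(ca@fgCounts)
  fgTot <- rowSums(ca@fgCounts)
  eff <- max(fgTot)
  header <- sprintf("contrast node %d: fg=%d bg=%d wt_res_freqs=%.1f",
                    ca@node, length(ca@foreground), length(ca@background), eff)
  consChar <- matrix(" ", 3, w)
  consDigit <- matrix(" ", 3, w)
  for (j in seq_len(w)) {
    if (fgTot[j] <= 0) next
    f <- ca@fgCounts[j, ] / fgTot[j]
    ord <- order(f, decreasing = TRUE)
    shown <- ord[f[ord] >= 0.10][seq_len(3)]
    shown <- shown[!is.na(shown)]
    for (r in seq_along(shown)) {
      consChar[r, j] <- AA_ALPHABET20[shown[r]]
      consDigit[r, j] <- as.character(freqDigit(f[shown[r]]))
    }
  }
  marked <- if (is.null(ownedColumns)) ca@patternColumns
            else intersect(ca@patternColumns, ownedColumns)
  dots <- rep(" ", w)
  dots[marked] <- "."
  divLine <- rep(" ", w)
  for (ci in seq_along(ca@patternColumns)) {
    j <- ca@patternColumns[ci]
    divLine[j] <- as.character(min(9L, as.integer(floor(3 * ca@divergence[ci]))))
  }
  if (is.numeric(representatives) && length(representatives) == 1L) {
    representatives <- head(ca@foreground, representatives)
  }
  repIdx <- match(representatives, seqIds(seqs))
  repIdx <- repIdx[!is.na(repIdx)]
  mm <- matchMap(aln)
  s <- as.character(sequences(seqs))
  repLines <- vapply(repIdx, function(k) {
    chars <- strsplit(s[k], "")[[1]]
    row <- vapply(seq_len(w), function(j) {
      a <- mm[k, j]
      if (is.na(a)) "-" else chars[a]
    }, character(1))
    sprintf("%-12s %s", seqIds(seqs)[k], paste(row, collapse = ""))
  }, character(1))
  c(header,
    sprintf("%-12s %s", "divergence", paste(divLine, collapse = "")),
    sprintf("%-12s %s", "pattern", paste(dots, collapse = "")),
    repLines,
    vapply(1:3, function(r)
      sprintf("%-12s %s", paste0("consensus", r),
              paste(consChar[r, ], collapse = "")), character(1)),
    vapply(1:3, function(r)
      sprintf("%-12s %s", paste0("freq", r),
              paste(consDigit[r, ], collapse = "")), character(1)))
}

# wrap a rendered block in a minimal RTF dialect: monospace font, with
# frequency digits 5-6 in black, 7-9 in red, 0-4 in gray
#' @keywords internal
renderRTF <- function(lines) {
  esc <- function(x) gsub("([\\\\{}])", "\\\\\\1", x)
  colored <- vapply(lines, function(ln) {
    if (grepl("^freq", ln)) {
      chars <- strsplit(esc(ln), "")[[1]]
      paste(vapply(chars, function(ch) {
        if (ch %in% c("5", "6")) paste0("{\\cf1 ", ch, "}")
        else if (ch %in% c("7", "8", "9")) paste0("{\\cf2 ", ch, "}")
        else if (ch %in% c("0", "1", "2", "3", "4")) paste0("{\\cf3 ", ch, "}")
        else ch
      }, character(1)), collapse = "")
    } else esc(ln)
  }, character(1))
  c("{\\rtf1\\ansi{\\fonttbl{\\f0\\fmodern Courier;}}",
    "{\\colortbl;\\red0\\green0\\blue0;\\red255\\green0\\blue0;\\red128\\green128\\blue128;}",
    "\\f0\\fs18",
    paste0(colored, "\\line"),
    "}")
}

#' Render the hierarchical contrast alignments of one lineage
#'
#' One contrast-alignment block per node on the root-to-leaf path, in
#' root-first order; each pattern column is marked in the block of the
#' node that owns it (the shallowest node on the lineage whose pattern
#' includes it) and only there.
#'
#' @param seqs A \code{SequenceSet}.
#' @param aln The \code{AlignmentState}.
#' @param hierarchy A \code{Hierarchy}.
#' @param leaf Leaf node index.
#' @param patterns A \code{PatternSet}.
#' @param alphas Per-node contamination fractions (optional).
#' @param representatives Representatives per block.
#' @param format \code{"text"} or \code{"rtf"}.
#' @return Character vector: the concatenated blocks.
#' @export
renderLineage <- function(seqs, aln, hierarchy, leaf, patterns,
                          alphas = NULL, representatives = 3L,
                          format = c("text", "rtf")) {
  format <- match.arg(format)
  path <- rev(lineageNodes(hierarchy, leaf)) # root first
  claimed <- integer(0)
  out <- character(0)
  for (z in path) {
    ca <- buildContrastAlignment(seqs, aln, hierarchy, z, patterns, alphas)
    owned <- setdiff(ca@patternColumns, claimed)
    claimed <- union(claimed, owned)
    out <- c(out, renderContrastAlignment(ca, seqs, aln, representatives,
                                          ownedColumns = owned), "")
  }
  if (format == "rtf") renderRTF(out) else out
}
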