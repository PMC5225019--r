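# Sequence and alignment I/O, redundancy down-weighting, and the residue
# counting function h(.) feeding every likelihood in the package.
#
# Alignment files use the A2M dialect of aligned FASTA: uppercase = match
# column, lowercase = insert, '-' = deletion.  This encodes each sequence's
# HMM path directly.  Columns are 1-based in all user-facing output.

#' Read protein sequences from FASTA
#'
#' @param path Path to a FASTA file.
#' @return A \code{SequenceSet} with unit weights.  Non-standard letters are
#'   mapped to \code{X} (excluded from counts); order is preserved.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "ACDE"), f)
#' readProteinFasta(f)
#' @export
readProteinFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonEmpty <- which(nzchar(trimws(lines)))
  if (!length(nonEmpty))
    stop("FASTA format error at line 1: empty file")
  first <- nonEmpty[1]
  if (!startsWith(trimws(lines[first]), ">"))
    stop("FASTA format error at line ", first, ": expected '>' header")
  ss <- Biostrings::readAAStringSet(path)
  if (!length(ss)) stop("FASTA format error at line ", first, ": no sequences")
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate sequence id '", ids[duplicated(ids)][1], "'")
  if (any(Biostrings::width(ss) == 0L)) {
    bad <- ids[Biostrings::width(ss) == 0L][1]
    stop("FASTA format error: empty sequence '", bad, "'")
  }
  SequenceSet(setNames(as.character(ss), ids))
}

#' Write protein sequences to FASTA
#'
#' @param seqs A \code{SequenceSet}.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return Invisibly, \code{path}.
#' @export
writeProteinFasta <- function(seqs, path, width = 60L) {
  stopifnot(is(seqs, "SequenceSet"))
  con <- file(path, "w")
  on.exit(close(con))
  s <- as.character(sequences(seqs))
  for (i in seq_along(s)) {
    writeLines(paste0(">", names(s)[i]), con)
    body <- substring(s[i], seq(1, nchar(s[i]), width),
                      pmin(nchar(s[i]), seq(width, nchar(s[i]) + width - 1, width)))
    writeLines(body, con)
  }
  invisible(path)
}

#' Read an A2M alignment
#'
#' Uppercase letters are match states, lowercase letters inserts, '-' a
#' deletion; '.' padding is ignored.
#'
#' @param path Path to an aligned FASTA / A2M file.
#' @return List with elements \code{seqs} (a \code{SequenceSet}) and
#'   \code{alignment} (an \code{AlignmentState}).
#' @export
readA2M <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (!length(ss)) stop("A2M format error: no sequences")
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate sequence id '", ids[duplicated(ids)][1], "'")
  rows <- lapply(as.character(ss), function(s) {
    chars <- strsplit(gsub(".", "", s, fixed = TRUE), "")[[1]]
    isMatch <- chars == "-" | (chars == toupper(chars) & chars != "-")
    list(chars = chars, isMatch = isMatch)
  })
  w <- vapply(rows, function(r) sum(r$isMatch), integer(1))
  if (length(unique(w)) != 1L)
    stop("A2M format error: unequal numbers of match columns")
  w <- w[1]
  K <- length(rows)
  mm <- matrix(NA_integer_, K, w)
  res <- character(K)
  for (k in seq_len(K)) {
    r <- rows[[k]]
    pos <- 0L; col <- 0L
    for (i in seq_along(r$chars)) {
      ch <- r$chars[i]
      if (r$isMatch[i]) {
        col <- col + 1L
        if (ch != "-") { pos <- pos + 1L; mm[k, col] <- pos }
      } else pos <- pos + 1L
    }
    res[k] <- sanitizeResidues(gsub("-", "", paste(r$chars, collapse = ""),
                                    fixed = TRUE))
  }
  seqs <- SequenceSet(setNames(res, ids))
  rownames(mm) <- ids
  list(seqs = seqs, alignment = AlignmentState(mm))
}

#' Write an alignment in A2M format
#'
#' @param seqs A \code{SequenceSet}.
#' @param aln The matching \code{AlignmentState}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeA2M <- function(seqs, aln, path) {
  s <- as.character(sequences(seqs))
  mm <- matchMap(aln)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(nrow(mm))) {
    chars <- strsplit(s[k], "")[[1]]
    out <- character(0)
    pos <- 0L
    for (j in seq_len(ncol(mm))) {
      a <- mm[k, j]
      if (!is.na(a)) {
        if (a > pos + 1L) out <- c(out, tolower(chars[(pos + 1L):(a - 1L)]))
        out <- c(out, toupper(chars[a]))
        pos <- a
      } else out <- c(out, "-")
    }
    if (pos < length(chars)) out <- c(out, tolower(chars[(pos + 1L):length(chars)]))
    writeLines(c(paste0(">", names(s)[k]), paste(out, collapse = "")), con)
  }
  invisible(path)
}

# Integer residue codes at each match column: K x w matrix, NA for
# deletions and for X residues.
#' @keywords internal
residueIndexMatrix <- function(seqs, aln) {
  mm <- matchMap(aln)
  s <- as.character(sequences(seqs))
  K <- nrow(mm); w <- ncol(mm)
  out <- matrix(NA_integer_, K, w)
  for (k in seq_len(K)) {
    codes <- encodeResidues(s[k])
    a <- mm[k, ]
    ok <- !is.na(a)
    out[k, ok] <- codes[a[ok]]
  }
  out
}

#' Position-based redundancy down-weighting
#'
#' Each match column distributes weight 1/(t_j * n_{j,r}) to every sequence
#' carrying residue r there, where t_j is the number of distinct residue
#' types in the column and n_{j,r} the number of sequences carrying r; a
#' sequence's raw weight is the mean of its column shares.  Raw weights are
#' then rescaled to total the number of distinct sequences (and clamped to
#' at most 1), so a fully non-redundant set keeps weights near 1 while n
#' exact copies of one sequence each receive weight 1/n (effective size 1).
#' Identical sequences always share equal weight.
#'
#' @param seqs A \code{SequenceSet}.
#' @param aln The matching \code{AlignmentState}.
#' @return A \code{SequenceSet} with updated weights.
#' @examples
#' ss <- SequenceSet(c(a = "AC", b = "AC", c = "CD"))
#' aln <- AlignmentState(matrix(c(1L, 2L, 1L, 2L, 1L, 2L), 3, 2, byrow = TRUE))
#' seqWeights(computeSequenceWeights(ss, aln))
#' @export
computeSequenceWeights <- function(seqs, aln) {
  stopifnot(is(seqs, "SequenceSet"), is(aln, "AlignmentState"))
  if (ncol(matchMap(aln)) == 0L)
    stop("alignment has zero match columns; cannot weight")
  ri <- residueIndexMatrix(seqs, aln)
  K <- nrow(ri)
  share <- matrix(NA_real_, K, ncol(ri))
  for (j in seq_len(ncol(ri))) {
    col <- ri[, j]
    ok <- !is.na(col)
    if (!any(ok)) next
    tab <- tabulate(col[ok], nbins = 20L)
    tj <- sum(tab > 0)
    share[ok, j] <- 1 / (tj * tab[col[ok]])
  }
  raw <- apply(share, 1, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) 1 else mean(x)
  })
  nDistinct <- length(unique(as.character(sequences(seqs))))
  w <- raw * nDistinct / sum(raw)
  w <- pmin(1, pmax(w, 1e-8))
  new("SequenceSet", seqs = seqs@seqs, weights = as.numeric(w))
}

#' Weighted residue counts of one match column
#'
#' The counting function h(.): sequences with a deletion at the column and
#' \code{X} residues contribute nothing.
#'
#' @param seqs A \code{SequenceSet}.
#' @param aln The matching \code{AlignmentState}.
#' @param j Column index (1-based).
#' @return Named numeric vector of length 20 of weighted counts.
#' @examples
#' ss <- SequenceSet(c(a = "A", b = "A", c = "C"))
#' aln <- AlignmentState(matrix(1L, 3, 1))
#' countColumn(ss, aln, 1)
#' @export
countColumn <- function(seqs, aln, j) {
  w <- ncol(matchMap(aln))
  if (!is.numeric(j) || length(j) != 1L || j < 1 || j > w)
    stop("column index out of range: ", j)
  cc <- columnCounts(seqs, aln)
  setNames(cc[j, ], AA_ALPHABET20)
}

# All columns at once: w x 20 weighted count matrix.
#' @keywords internal
columnCounts <- function(seqs, aln, ri = NULL) {
  if (is.null(ri)) ri <- residueIndexMatrix(seqs, aln)
  countsFromIndex(ri, seqs@weights)
}

#' @keywords internal
countsFromIndex <- function(ri, weights) {
  w <- ncol(ri)
  out <- matrix(0, w, 20L)
  for (k in seq_len(nrow(ri))) {
    ok <- which(!is.na(ri[k, ]))
    if (length(ok)) {
      idx <- cbind(ok, ri[k, ok])
      out[idx] <- out[idx] + weights[k]
    }
  }
  out
}
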