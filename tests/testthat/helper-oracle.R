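# Independent brute-force oracle for the alignment joint posterior.
# Everything here is written from the model definition directly --
# explicit state chains, direct gamma-function products -- and never calls
# the package's own counting or scoring internals.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# All legal match-map rows for a sequence of length L against w columns.
# Legality: positions strictly increasing; insert residues may sit only
# between two matched columns or at an end adjacent to a matched column
# (no insert/delete adjacency).
oLegalRows <- function(L, w) {
  out <- list()
  recur <- function(row, pos) {
    j <- length(row) + 1L
    if (j > w) {
      if (oRowLegal(row, L)) out[[length(out) + 1L]] <<- row
      return(invisible())
    }
    recur(c(row, NA_integer_), pos)
    if (pos < L) for (p in (pos + 1L):L) recur(c(row, p), p)
  }
  recur(integer(0), 0L)
  out
}

oRowLegal <- function(row, L) {
  pos <- 0L
  prevM <- TRUE
  for (j in seq_along(row)) {
    if (!is.na(row[j])) {
      if (row[j] > pos + 1L && !prevM) return(FALSE)
      pos <- row[j]
      prevM <- TRUE
    } else prevM <- FALSE
  }
  if (L > pos && !prevM) return(FALSE)
  TRUE
}

# Explicit state chain of one row: list of c(type, block) with type in
# "m", "i", "d"; Begin is ("m", 0), End ("m", w+1) acts as a match.
oStateChain <- function(row, L) {
  w <- length(row)
  chain <- list(c("m", 0))
  pos <- 0L
  for (j in seq_len(w)) {
    if (!is.na(row[j])) {
      if (row[j] > pos + 1L)
        for (q in (pos + 1L):(row[j] - 1L)) chain[[length(chain) + 1L]] <- c("i", j - 1L)
      chain[[length(chain) + 1L]] <- c("m", j)
      pos <- row[j]
    } else chain[[length(chain) + 1L]] <- c("d", j)
  }
  if (L > pos) for (q in (pos + 1L):L) chain[[length(chain) + 1L]] <- c("i", w)
  chain[[length(chain) + 1L]] <- c("m", w + 1L)
  chain
}

# Direct unnormalized log joint of an alignment configuration:
# rows: K x w integer matrix (NA = deletion), seqsChars: residue strings.
oJointLog <- function(seqsChars, rows, priorVec, transPrior, bg) {
  K <- length(seqsChars)
  w <- ncol(rows)
  codes <- lapply(seqsChars, function(s) match(strsplit(s, "")[[1]], AA20))
  # column marginals
  colTerm <- 0
  for (j in seq_len(w)) {
    h <- numeric(20)
    for (k in seq_len(K)) {
      p <- rows[k, j]
      if (!is.na(p) && !is.na(codes[[k]][p])) h[codes[[k]][p]] <- h[codes[[k]][p]] + 1
    }
    colTerm <- colTerm + lgamma(sum(priorVec)) - lgamma(sum(h) + sum(priorVec)) +
      sum(lgamma(h + priorVec) - lgamma(priorVec))
  }
  # background product over unaligned residues
  bgTerm <- 0
  for (k in seq_len(K)) {
    aligned <- rows[k, ]
    aligned <- aligned[!is.na(aligned)]
    rest <- setdiff(seq_along(codes[[k]]), aligned)
    rest <- codes[[k]][rest]
    rest <- rest[!is.na(rest)]
    if (length(rest)) bgTerm <- bgTerm + sum(log(bg[rest]))
  }
  # transition blocks from explicit state chains
  N <- matrix(0, w + 1L, 7L,
              dimnames = list(NULL, c("mm", "mi", "md", "im", "ii", "dm", "dd")))
  for (k in seq_len(K)) {
    chain <- oStateChain(rows[k, ], length(codes[[k]]))
    for (t in seq_len(length(chain) - 1L)) {
      a <- chain[[t]]; b <- chain[[t + 1L]]
      pair <- paste0(a[1], b[1])
      if (pair == "dm" && as.integer(b[2]) == as.integer(a[2])) pair <- "di" # impossible
      if (!(pair %in% colnames(N))) return(-Inf)
      blk <- as.integer(a[2]) + 1L
      N[blk, pair] <- N[blk, pair] + 1
    }
  }
  nm <- transPrior[["mm"]] + transPrior[["mi"]] + transPrior[["md"]]
  ni <- transPrior[["im"]] + transPrior[["ii"]]
  nd <- transPrior[["dm"]] + transPrior[["dd"]]
  trTerm <- 0
  for (b in seq_len(w + 1L)) {
    trTerm <- trTerm +
      lgamma(N[b, "mm"] + transPrior[["mm"]]) + lgamma(N[b, "mi"] + transPrior[["mi"]]) +
      lgamma(N[b, "md"] + transPrior[["md"]]) + lgamma(nm) -
      lgamma(N[b, "mm"] + N[b, "mi"] + N[b, "md"] + nm) -
      lgamma(transPrior[["mm"]]) - lgamma(transPrior[["mi"]]) - lgamma(transPrior[["md"]]) +
      lgamma(N[b, "ii"] + transPrior[["ii"]]) + lgamma(N[b, "im"] + transPrior[["im"]]) +
      lgamma(ni) - lgamma(N[b, "ii"] + N[b, "im"] + ni) -
      lgamma(transPrior[["ii"]]) - lgamma(transPrior[["im"]]) +
      lgamma(N[b, "dd"] + transPrior[["dd"]]) + lgamma(N[b, "dm"] + transPrior[["dm"]]) +
      lgamma(nd) - lgamma(N[b, "dd"] + N[b, "dm"] + nd) -
      lgamma(transPrior[["dd"]]) - lgamma(transPrior[["dm"]])
  }
  unname(colTerm + bgTerm + trTerm)
}

# random background-composition sequences
randomBackgroundSeqs <- function(n, len, seed) {
  set.seed(seed)
  bg <- standardBackground()
  res <- vapply(seq_len(n), function(i)
    paste(sample(names(bg), len, replace = TRUE, prob = bg), collapse = ""), "")
  SequenceSet(setNames(res, sprintf("r%03d", seq_len(n))))
}
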