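# Hierarchy, pattern and weight exchange formats: Newick (node labels are
# node indices), TSV (sequence id -> node id; id -> weight), and JSON
# (node -> column -> residue set, plus contamination fractions).

#' @keywords internal
newickFromParent <- function(parent, labels = as.character(seq_along(parent))) {
  root <- which(parent == 0L)
  build <- function(z) {
    kids <- which(parent == z)
    if (!length(kids)) return(labels[z])
    paste0("(", paste(vapply(kids, build, character(1)), collapse = ","),
           ")", labels[z])
  }
  paste0(build(root), ";")
}

#' Export a hierarchy as Newick plus assignment TSV
#'
#' @param hierarchy A \code{Hierarchy}.
#' @param seqIds Sequence ids, in assignment order.
#' @param treePath Output Newick path.
#' @param assignPath Output TSV path (columns: id, node).
#' @return Invisibly, \code{treePath}.
#' @export
exportHierarchy <- function(hierarchy, seqIds, treePath, assignPath) {
  labels <- hierarchy@labels
  labels[hierarchy@reject] <- "reject" # keeps the reject identifiable
  writeLines(newickFromParent(hierarchy@parent, labels), treePath)
  df <- data.frame(id = seqIds, node = labels[hierarchy@assignments])
  write.table(df, assignPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(treePath)
}

#' Import a hierarchy from Newick plus assignment TSV
#'
#' The Newick node labels must be the node names used in the TSV; the
#' reject node is identified by the label \code{"reject"} or, failing
#' that, taken to be the last child of the root.
#'
#' @param treePath Newick path.
#' @param assignPath TSV path (columns: id, node).
#' @param seqIds Sequence ids the assignments must cover.
#' @param heightLimit Height limit of the returned \code{Hierarchy}.
#' @return A \code{Hierarchy}.
#' @export
importHierarchy <- function(treePath, assignPath, seqIds,
                            heightLimit = 5L) {
  tr <- ape::read.tree(treePath)
  if (is.null(tr)) stop("could not parse Newick file: ", treePath)
  nTips <- length(tr$tip.label)
  nAll <- nTips + tr$Nnode
  labs <- character(nAll)
  labs[seq_len(nTips)] <- tr$tip.label
  labs[(nTips + 1):nAll] <-
    if (!is.null(tr$node.label)) tr$node.label
    else as.character((nTips + 1):nAll)
  parent <- integer(nAll)
  for (e in seq_len(nrow(tr$edge)))
    parent[tr$edge[e, 2]] <- tr$edge[e, 1]
  root <- which(parent == 0L)
  rej <- which(labs == "reject")
  if (!length(rej)) {
    kids <- which(parent == root)
    rej <- kids[length(kids)]
  }
  df <- read.table(assignPath, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  ord <- match(seqIds, df$id)
  if (anyNA(ord)) stop("assignments missing for some sequences")
  assign <- match(as.character(df$node[ord]), labs)
  if (anyNA(assign)) stop("assignment refers to unknown node")
  new("Hierarchy", parent = parent, labels = labs,
      reject = as.integer(rej[1]), assignments = as.integer(assign),
      heightLimit = as.integer(heightLimit))
}

#' Write patterns (and contamination fractions) as JSON
#'
#' Patterns are stored per node label so they can be re-matched to a
#' hierarchy whose node numbering changed in Newick round-tripping.
#'
#' @param patterns A \code{PatternSet}.
#' @param alphas Per-node contamination fractions.
#' @param path Output path.
#' @param labels Node labels, one per pattern entry; defaults to node
#'   indices as characters.
#' @return Invisibly, \code{path}.
#' @export
writePatternsJSON <- function(patterns, alphas, path, labels = NULL) {
  if (is.null(labels)) labels <- as.character(seq_along(patterns@patterns))
  obj <- list(maxPatterns = patterns@maxPatterns,
              labels = labels,
              alphas = alphas,
              nodes = lapply(patterns@patterns, function(p)
                lapply(p, function(set) paste(set, collapse = ""))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read patterns from JSON
#'
#' @param path JSON path from \code{\link{writePatternsJSON}}.
#' @param orderLabels Optional node labels of the consuming hierarchy;
#'   the pattern entries are reordered to match.
#' @return List with elements \code{patterns} (a \code{PatternSet}),
#'   \code{alphas} and \code{labels}.
#' @export
readPatternsJSON <- function(path, orderLabels = NULL) {
  obj <- jsonlite::read_json(path)
  pats <- lapply(obj$nodes, function(p)
    lapply(p, function(s) strsplit(s, "")[[1]]))
  alphas <- as.numeric(unlist(obj$alphas))
  labels <- as.character(unlist(obj$labels))
  if (!is.null(orderLabels)) {
    ord <- match(orderLabels, labels)
    if (anyNA(ord)) stop("pattern file does not cover all hierarchy nodes")
    pats <- pats[ord]
    alphas <- alphas[ord]
    labels <- labels[ord]
  }
  list(patterns = PatternSet(pats, as.integer(obj$maxPatterns)),
       alphas = alphas, labels = labels)
}

#' Write per-sequence weights as TSV
#'
#' @param seqs A \code{SequenceSet}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeWeightsTSV <- function(seqs, path) {
  df <- data.frame(id = seqIds(seqs), weight = seqs@weights)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a description-length ledger as TSV
#'
#' @param ledger A \code{DLLedger}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeLedgerTSV <- function(ledger, path) {
  df <- data.frame(
    component = c("node_count", "tree", "patterns", "assignments",
                  "paths", "data", "total"),
    bits = c(ledger@nodeCountBits, ledger@treeBits, ledger@patternBits,
             ledger@assignmentBits, ledger@pathBits, ledger@dataBits,
             ledger@total))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
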