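# Generics and accessors.  Slot access from user code goes through these.

#' @rdname SequenceSet-class
#' @param object,x A \code{SequenceSet}.
#' @export
setGeneric("sequences", function(object) standardGeneric("sequences"))

#' @rdname SequenceSet-class
#' @export
setMethod("sequences", "SequenceSet", function(object) object@seqs)

#' @rdname SequenceSet-class
#' @export
setGeneric("seqWeights", function(object) standardGeneric("seqWeights"))

#' @rdname SequenceSet-class
#' @export
setMethod("seqWeights", "SequenceSet",
          function(object) setNames(object@weights, names(object@seqs)))

#' @rdname SequenceSet-class
#' @export
setGeneric("effectiveSize", function(object) standardGeneric("effectiveSize"))

#' @rdname SequenceSet-class
#' @export
setMethod("effectiveSize", "SequenceSet", function(object) sum(object@weights))

#' @rdname SequenceSet-class
#' @export
setGeneric("seqIds", function(object) standardGeneric("seqIds"))

#' @rdname SequenceSet-class
#' @export
setMethod("seqIds", "SequenceSet", function(object) names(object@seqs))

#' @rdname SequenceSet-class
#' @export
setMethod("length", "SequenceSet", function(x) length(x@seqs))

setMethod("show", "SequenceSet", function(object) {
  cat(sprintf("SequenceSet of %d sequences (effective size %.2f)\n",
              length(object@seqs), sum(object@weights)))
})

#' @rdname AlignmentState-class
#' @param object An \code{AlignmentState}.
#' @export
setGeneric("matchMap", function(object) standardGeneric("matchMap"))

#' @rdname AlignmentState-class
#' @export
setMethod("matchMap", "AlignmentState", function(object) object@matchMap)

#' @rdname AlignmentState-class
#' @export
setGeneric("numColumns", function(object) standardGeneric("numColumns"))

#' @rdname AlignmentState-class
#' @export
setMethod("numColumns", "AlignmentState", function(object) ncol(object@matchMap))

setMethod("show", "AlignmentState", function(object) {
  cat(sprintf("AlignmentState: %d sequences x %d match columns\n",
              nrow(object@matchMap), ncol(object@matchMap)))
})

#' @rdname Hierarchy-class
#' @param object A \code{Hierarchy}.
#' @export
setGeneric("parentMap", function(object) standardGeneric("parentMap"))

#' @rdname Hierarchy-class
#' @export
setMethod("parentMap", "Hierarchy", function(object) object@parent)

#' @rdname Hierarchy-class
#' @export
setGeneric("assignments", function(object) standardGeneric("assignments"))

#' @rdname Hierarchy-class
#' @export
setMethod("assignments", "Hierarchy", function(object) object@assignments)

#' @rdname Hierarchy-class
#' @export
setGeneric("rootNode", function(object) standardGeneric("rootNode"))

#' @rdname Hierarchy-class
#' @export
setMethod("rootNode", "Hierarchy", function(object) which(object@parent == 0L))

#' @rdname Hierarchy-class
#' @export
setGeneric("rejectNode", function(object) standardGeneric("rejectNode"))

#' @rdname Hierarchy-class
#' @export
setMethod("rejectNode", "Hierarchy", function(object) object@reject)

#' @rdname Hierarchy-class
#' @export
setGeneric("nodeCount", function(object) standardGeneric("nodeCount"))

#' @rdname Hierarchy-class
#' @export
setMethod("nodeCount", "Hierarchy", function(object) length(object@parent))

#' Nodes of the subtree rooted at a node
#' @param object A \code{Hierarchy}.
#' @param node Node index.
#' @return Integer vector of node indices (including \code{node}).
#' @export
setGeneric("subtreeNodes", function(object, node) standardGeneric("subtreeNodes"))

#' @rdname subtreeNodes
#' @export
setMethod("subtreeNodes", "Hierarchy", function(object, node) {
  p <- object@parent
  out <- node
  repeat {
    kids <- which(p %in% out & !(seq_along(p) %in% out))
    if (!length(kids)) break
    out <- c(out, kids)
  }
  sort(out)
})

#' Children of a node
#' @param object A \code{Hierarchy}.
#' @param node Node index.
#' @return Integer vector of child node indices.
#' @export
setGeneric("childNodes", function(object, node) standardGeneric("childNodes"))

#' @rdname childNodes
#' @export
setMethod("childNodes", "Hierarchy",
          function(object, node) which(object@parent == node))

#' Ancestors of a node (node first, root last)
#' @param object A \code{Hierarchy}.
#' @param node Node index.
#' @return Integer vector: the node and its ancestors up to the root.
#' @export
setGeneric("lineageNodes", function(object, node) standardGeneric("lineageNodes"))

#' @rdname lineageNodes
#' @export
setMethod("lineageNodes", "Hierarchy", function(object, node) {
  p <- object@parent
  out <- node
  while (p[node] != 0L) { node <- p[node]; out <- c(out, node) }
  out
})

setMethod("show", "Hierarchy", function(object) {
  d <- nodeDepths(object@parent)
  leaves <- sum(!(seq_along(object@parent) %in% object@parent) &
                seq_along(object@parent) != object@reject)
  cat(sprintf("Hierarchy: %d nodes (%d non-reject leaves), height %d, %d sequences\n",
              length(object@parent), leaves, max(d), length(object@assignments)))
})

setMethod("show", "DLLedger", function(object) {
  cat("Description length (bits):\n")
  cat(sprintf("  node count : %12.1f\n", object@nodeCountBits))
  cat(sprintf("  tree       : %12.1f\n", object@treeBits))
  cat(sprintf("  patterns   : %12.1f\n", object@patternBits))
  cat(sprintf("  assignments: %12.1f\n", object@assignmentBits))
  cat(sprintf("  paths      : %12.1f\n", object@pathBits))
  cat(sprintf("  data       : %12.1f\n", object@dataBits))
  cat(sprintf("  total      : %12.1f\n", object@total))
})

setMethod("show", "HiMSAFit", function(object) {
  cat("hiMSA fit\n")
  show(object@hierarchy)
  cat(sprintf("  alignment: %d columns; penalized posterior %.1f bits\n",
              ncol(object@alignment@matchMap),
              if (nrow(object@trace)) max(object@trace$bits) else NA_real_))
})

setMethod("show", "ContrastAlignment", function(object) {
  cat(sprintf("ContrastAlignment at node %d: %d foreground, %d background, %d pattern columns\n",
              object@node, length(object@foreground), length(object@background),
              length(object@patternColumns)))
})

setMethod("show", "HiHMM", function(object) {
  cat(sprintf("HiHMM over %d nodes; node weights: %s\n",
              length(object@emissions),
              paste(sprintf("%.2f", object@nodeWeights), collapse = " ")))
})
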