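# S4 classes for the hiMSA machinery.  SequenceSet wraps a Biostrings
# AAStringSet with redundancy down-weights; AlignmentState stores the
# match-column map (the per-sequence HMM path is fully determined by it,
# because insert and delete states may not interleave between two match
# states); Hierarchy stores the rooted subgroup tree plus sequence
# assignments and the reject node.

setClassUnion("listOrNULL", c("list", "NULL"))

#' SequenceSet: weighted protein sequences
#'
#' A set of protein sequences over the 20-letter amino-acid alphabet plus
#' \code{X} (unknown; excluded from all counts), each carrying a redundancy
#' down-weight in (0, 1].  The sum of weights is the effective number of
#' independent sequences used throughout the bit accounting.
#'
#' @slot seqs An \code{AAStringSet} holding the (unaligned) residues.
#' @slot weights Numeric vector of per-sequence weights in (0, 1].
#' @export
setClass("SequenceSet",
  slots = c(seqs = "ANY", weights = "numeric"))

setValidity("SequenceSet", function(object) {
  if (!is(object@seqs, "AAStringSet"))
    return("'seqs' must be an AAStringSet")
  n <- length(object@seqs)
  if (length(object@weights) != n)
    return("one weight per sequence required")
  if (n > 0) {
    if (any(object@weights <= 0 | object@weights > 1))
      return("weights must lie in (0, 1]")
    ids <- names(object@seqs)
    if (is.null(ids) || anyNA(ids) || any(ids == ""))
      return("every sequence needs a non-empty id")
    if (anyDuplicated(ids)) {
      dup <- ids[duplicated(ids)][1]
      return(sprintf("duplicate sequence id '%s'", dup))
    }
    if (any(Biostrings::width(object@seqs) == 0L))
      return("empty sequences are not allowed")
  }
  TRUE
})

#' Construct a SequenceSet
#'
#' @param x Named character vector of residue strings, or an
#'   \code{AAStringSet}.  Non-standard letters (B, Z, U, O, J) are mapped
#'   to \code{X} on input.
#' @param weights Per-sequence weights in (0, 1]; default 1.
#' @return A \code{SequenceSet}.
#' @examples
#' ss <- SequenceSet(c(s1 = "ACDE", s2 = "ACDF"))
#' effectiveSize(ss)
#' @export
SequenceSet <- function(x, weights = NULL) {
  if (is(x, "AAStringSet")) x <- setNames(as.character(x), names(x))
  stopifnot(is.character(x))
  if (length(x) == 0L)
    return(new("SequenceSet", seqs = Biostrings::AAStringSet(),
               weights = numeric(0)))
  if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
  clean <- vapply(x, sanitizeResidues, character(1))
  if (is.null(weights)) weights <- rep(1, length(x))
  new("SequenceSet",
      seqs = Biostrings::AAStringSet(setNames(clean, names(x))),
      weights = as.numeric(weights))
}

#' AlignmentState: match-column map of a multiple alignment
#'
#' Row k gives, for each of the w match columns, the (1-based) position of
#' sequence k aligned there, or \code{NA} for a deletion.  Residues not
#' covered by a match column sit in insert states; the profile HMM forbids
#' insert/delete adjacency, so the state path of every sequence is uniquely
#' determined by its row.
#'
#' @slot matchMap Integer matrix (sequences x columns), NA = deletion.
#' @export
setClass("AlignmentState",
  slots = c(matchMap = "matrix"))

setValidity("AlignmentState", function(object) {
  mm <- object@matchMap
  if (!is.numeric(mm[0]) && !is.integer(mm[0]))
    return("matchMap must be an integer matrix")
  if (nrow(mm) > 0 && ncol(mm) > 0) {
    for (k in seq_len(nrow(mm))) {
      v <- mm[k, ]
      vv <- v[!is.na(v)]
      if (length(vv) && (any(vv < 1) || any(diff(vv) <= 0)))
        return(sprintf("row %d: match positions must be strictly increasing", k))
    }
  }
  TRUE
})

#' Construct an AlignmentState
#' @param matchMap Integer matrix (sequences x columns), NA for deletions;
#'   rownames are sequence ids.
#' @return An \code{AlignmentState}.
#' @export
AlignmentState <- function(matchMap) {
  storage.mode(matchMap) <- "integer"
  new("AlignmentState", matchMap = matchMap)
}

#' DirichletMixture: emission prior over amino-acid compositions
#'
#' @slot weights Mixture weights, summing to 1.
#' @slot alpha Matrix (components x 20) of positive pseudocounts.
#' @export
setClass("DirichletMixture",
  slots = c(weights = "numeric", alpha = "matrix"))

setValidity("DirichletMixture", function(object) {
  if (ncol(object@alpha) != 20L) return("pseudocount vectors must have length 20")
  if (length(object@weights) != nrow(object@alpha))
    return("one weight per component required")
  if (abs(sum(object@weights) - 1) > 1e-8) return("weights must sum to 1")
  if (any(object@alpha <= 0)) return("pseudocounts must be positive")
  TRUE
})

#' Construct a DirichletMixture
#' @param weights Component weights (normalized internally).
#' @param alpha Matrix (components x 20) of positive pseudocounts, or a
#'   single length-20 vector.
#' @return A \code{DirichletMixture}.
#' @export
DirichletMixture <- function(weights, alpha) {
  if (is.null(dim(alpha))) alpha <- matrix(alpha, nrow = 1)
  new("DirichletMixture", weights = weights / sum(weights), alpha = alpha)
}

#' Default single-component emission prior
#'
#' A Dirichlet prior whose mean is the standard background composition,
#' with total pseudocount mass \code{mass} (default 2, a light prior that
#' lets ~2 observations dominate).
#'
#' @param mass Total pseudocount mass.
#' @return A \code{DirichletMixture} with one component.
#' @export
defaultEmissionPrior <- function(mass = 2) {
  DirichletMixture(1, mass * standardBackground())
}

#' Hierarchy: rooted subgroup tree with sequence assignments
#'
#' @slot parent Integer vector; parent index per node, 0 for the root.
#' @slot labels Character node labels.
#' @slot reject Index of the reject node (a child of the root holding
#'   unrelated/unalignable sequences; it carries no pattern).
#' @slot assignments Integer vector: node index per sequence.
#' @slot heightLimit Maximum tree height (root = height 1).
#' @export
setClass("Hierarchy",
  slots = c(parent = "integer", labels = "character", reject = "integer",
            assignments = "integer", heightLimit = "integer"))

setValidity("Hierarchy", function(object) {
  p <- object@parent
  n <- length(p)
  if (sum(p == 0L) != 1L) return("exactly one root required")
  root <- which(p == 0L)
  if (length(object@reject) != 1L || object@reject < 1L || object@reject > n)
    return("reject node index out of range")
  if (p[object@reject] != root) return("reject node must be a child of the root")
  if (length(object@labels) != n) return("one label per node required")
  if (anyNA(object@assignments) ||
      (length(object@assignments) && (min(object@assignments) < 1L ||
                                      max(object@assignments) > n)))
    return("every sequence must be assigned to exactly one node")
  d <- nodeDepths(p)
  if (max(d) > object@heightLimit)
    return(sprintf("tree height %d exceeds limit %d", max(d), object@heightLimit))
  TRUE
})

#' @keywords internal
nodeDepths <- function(parent) {
  n <- length(parent)
  d <- integer(n)
  for (i in seq_len(n)) {
    k <- i; depth <- 1L
    while (parent[k] != 0L) { k <- parent[k]; depth <- depth + 1L }
    d[i] <- depth
  }
  d
}

#' Construct a Hierarchy
#'
#' @param parent Integer parent vector (0 marks the root).
#' @param assignments Integer node index per sequence.
#' @param reject Index of the reject node; by default a reject node is
#'   appended as a child of the root.
#' @param labels Node labels; defaults to "1", "2", ...
#' @param heightLimit Maximum height (default 5).
#' @return A \code{Hierarchy}.
#' @examples
#' h <- Hierarchy(parent = c(0L, 1L), assignments = rep(1L, 3))
#' nodeCount(h)
#' @export
Hierarchy <- function(parent, assignments = integer(0), reject = NULL,
                      labels = NULL, heightLimit = 5L) {
  parent <- as.integer(parent)
  if (is.null(reject)) {
    root <- which(parent == 0L)
    parent <- c(parent, root)
    reject <- length(parent)
  }
  if (is.null(labels)) labels <- as.character(seq_along(parent))
  new("Hierarchy", parent = parent, labels = labels,
      reject = as.integer(reject), assignments = as.integer(assignments),
      heightLimit = as.integer(heightLimit))
}

#' PatternSet: discriminating columns and residue sets per node
#'
#' @slot patterns List, one element per node: a named list mapping column
#'   index (as character) to a character vector of residues.  The reject
#'   node's element is always empty.
#' @slot maxPatterns Per-node cap on the number of discriminating columns.
#' @export
setClass("PatternSet",
  slots = c(patterns = "list", maxPatterns = "integer"))

#' Construct a PatternSet
#' @param patterns List per node of named residue-set lists.
#' @param maxPatterns Cap m on discriminating columns per node (default 25).
#' @return A \code{PatternSet}.
#' @export
PatternSet <- function(patterns, maxPatterns = 25L) {
  new("PatternSet", patterns = patterns, maxPatterns = as.integer(maxPatterns))
}

#' DLLedger: itemized description length in bits
#'
#' @slot nodeCountBits,treeBits,patternBits,assignmentBits,pathBits,dataBits
#'   Component description lengths in bits.
#' @slot total Sum of the components.
#' @export
setClass("DLLedger",
  slots = c(nodeCountBits = "numeric", treeBits = "numeric",
            patternBits = "numeric", assignmentBits = "numeric",
            pathBits = "numeric", dataBits = "numeric", total = "numeric"))

setValidity("DLLedger", function(object) {
  comps <- object@nodeCountBits + object@treeBits + object@patternBits +
    object@assignmentBits + object@pathBits + object@dataBits
  if (abs(comps - object@total) > 1e-6 * max(1, abs(comps)))
    return("total must equal the sum of the components")
  TRUE
})

#' SamplerConfig: tunable parameters of the hiMSA sampler
#'
#' Defaults follow the method's standard settings: tree height limit 5,
#' at most 25 discriminating columns per node, at least 50 sequences per
#' leaf, at least 7 bits of information per node, node assignment priors
#' 0.25 (root) / 0.70 (reject) / 0.05 (rest), geometric node-count factor
#' 0.99, pattern prior 0.1, and a >= 95 percent identity purge for
#' subgroup realignment.
#'
#' @slot heightLimit Maximum hierarchy height.
#' @slot maxPatterns Cap on discriminating columns per node.
#' @slot minLeafSequences Minimum sequences per leaf node.
#' @slot minNodeBits Minimum information (bits) a node must contribute.
#' @slot rootPrior,rejectPrior Node-assignment prior mass for root/reject.
#' @slot geometricFactor Geometric prior factor x for the node count.
#' @slot patternPrior Prior probability p that a column is discriminating.
#' @slot setPriorDecay Decay rho of the residue-set size prior.
#' @slot purgeIdentity Identity threshold for the pre-realignment purge.
#' @slot msaSweeps Gibbs sweeps for flat MSA sampling.
#' @slot refineSweeps Gibbs sweeps per subgroup realignment.
#' @slot burnInSweeps Assignment/pattern mini-sweeps seeding a new leaf.
#' @slot stallCycles Stop after this many macro-cycles without >= 0.1 bit
#'   improvement.
#' @slot maxCycles Hard cap on macro-cycles.
#' @slot t0,cooling Initial temperature and geometric cooling factor of the
#'   simulated-annealing schedule.
#' @slot transPrior Named numeric: transition pseudocounts
#'   (mm, mi, md, im, ii, dm, dd).
#' @slot emissionPriorMass Total mass of the default emission Dirichlet.
#' @slot alphaMixing "contamination" (foreground = (1-alpha) pattern +
#'   alpha background) or "literal".
#' @export
setClass("SamplerConfig",
  slots = c(heightLimit = "integer", maxPatterns = "integer",
            minLeafSequences = "integer", minNodeBits = "numeric",
            rootPrior = "numeric", rejectPrior = "numeric",
            geometricFactor = "numeric", patternPrior = "numeric",
            setPriorDecay = "numeric", purgeIdentity = "numeric",
            msaSweeps = "integer", refineSweeps = "integer",
            burnInSweeps = "integer", stallCycles = "integer",
            maxCycles = "integer", t0 = "numeric", cooling = "numeric",
            transPrior = "numeric", emissionPriorMass = "numeric",
            alphaMixing = "character"))

setValidity("SamplerConfig", function(object) {
  if (object@geometricFactor <= 0 || object@geometricFactor >= 1)
    return("geometricFactor must lie in (0,1)")
  if (object@patternPrior <= 0 || object@patternPrior >= 1)
    return("patternPrior must lie in (0,1)")
  if (object@rootPrior + object@rejectPrior >= 1)
    return("root and reject priors must leave mass for other nodes")
  if (any(object@transPrior <= 0)) return("transition pseudocounts must be positive")
  need <- c("mm", "mi", "md", "im", "ii", "dm", "dd")
  if (!all(need %in% names(object@transPrior)))
    return("transPrior needs entries mm, mi, md, im, ii, dm, dd")
  if (object@t0 <= 0 || object@cooling <= 0 || object@cooling >= 1)
    return("annealing schedule: t0 > 0 and cooling in (0,1)")
  if (!object@alphaMixing %in% c("contamination", "literal"))
    return("alphaMixing must be 'contamination' or 'literal'")
  TRUE
})

#' Construct a SamplerConfig
#'
#' @param heightLimit,maxPatterns,minLeafSequences,minNodeBits,rootPrior,
#'   rejectPrior,geometricFactor,patternPrior,setPriorDecay,purgeIdentity,
#'   msaSweeps,refineSweeps,burnInSweeps,stallCycles,maxCycles,t0,cooling,
#'   transPrior,emissionPriorMass,alphaMixing See the class documentation.
#' @return A \code{SamplerConfig}.
#' @examples
#' cfg <- SamplerConfig()
#' cfg@minLeafSequences
#' @export
SamplerConfig <- function(heightLimit = 5L, maxPatterns = 25L,
                          minLeafSequences = 50L, minNodeBits = 7,
                          rootPrior = 0.25, rejectPrior = 0.70,
                          geometricFactor = 0.99, patternPrior = 0.1,
                          setPriorDecay = 0.5, purgeIdentity = 0.95,
                          msaSweeps = 8L, refineSweeps = 3L,
                          burnInSweeps = 20L, stallCycles = 20L,
                          maxCycles = 120L, t0 = 2, cooling = 0.95,
                          transPrior = c(mm = 8, mi = 0.5, md = 0.5,
                                         im = 1, ii = 1, dm = 1, dd = 1),
                          emissionPriorMass = 2,
                          alphaMixing = "contamination") {
  new("SamplerConfig", heightLimit = as.integer(heightLimit),
      maxPatterns = as.integer(maxPatterns),
      minLeafSequences = as.integer(minLeafSequences),
      minNodeBits = minNodeBits, rootPrior = rootPrior,
      rejectPrior = rejectPrior, geometricFactor = geometricFactor,
      patternPrior = patternPrior, setPriorDecay = setPriorDecay,
      purgeIdentity = purgeIdentity, msaSweeps = as.integer(msaSweeps),
      refineSweeps = as.integer(refineSweeps),
      burnInSweeps = as.integer(burnInSweeps),
      stallCycles = as.integer(stallCycles), maxCycles = as.integer(maxCycles),
      t0 = t0, cooling = cooling, transPrior = transPrior,
      emissionPriorMass = emissionPriorMass, alphaMixing = alphaMixing)
}

#' ContrastAlignment: one node's foreground/background view
#'
#' @slot node Node index.
#' @slot foreground,background Character vectors of sequence ids.
#' @slot patternColumns Integer column indices carrying the node's pattern.
#' @slot patternSets List of residue sets per pattern column.
#' @slot divergence Numeric per-pattern-column divergence (semi-log scale).
#' @slot fgCounts,bgCounts Weighted count matrices (columns x 20).
#' @export
setClass("ContrastAlignment",
  slots = c(node = "integer", foreground = "character",
            background = "character", patternColumns = "integer",
            patternSets = "list", divergence = "numeric",
            fgCounts = "matrix", bgCounts = "matrix"))

#' HiMSA: hierarchical multiple sequence alignment
#'
#' Per-node sub-alignments over each node's subtree sequences, templates
#' mapping child columns to parent columns, and per-lineage column
#' ownership.
#'
#' @slot hierarchy The \code{Hierarchy}.
#' @slot subAlignments List of \code{AlignmentState}, one per node.
#' @slot subMembers List of integer sequence indices per node (subtree).
#' @slot templates List per node: integer vector mapping that node's
#'   columns to its parent's columns (NA = node-local insert column).
#' @slot patterns A \code{PatternSet} in per-node column coordinates.
#' @slot seqs The underlying \code{SequenceSet}.
#' @export
setClass("HiMSA",
  slots = c(hierarchy = "Hierarchy", subAlignments = "list",
            subMembers = "list", templates = "list",
            patterns = "PatternSet", seqs = "SequenceSet"))

#' HiHMM: hierarchical interrelated hidden Markov models
#'
#' One profile HMM per node with lineage-specific emission tables (a
#' discriminating column owned by node N draws its emissions from the
#' subtree rooted at N) and node weights proportional to down-weighted
#' sequence fractions.
#'
#' @slot hierarchy The \code{Hierarchy}.
#' @slot emissions List per node: matrix (columns x 20) of emission
#'   probabilities.
#' @slot transitions List per node: transition count summaries.
#' @slot ownership List per node: integer vector giving, for each column
#'   of that node's HMM, the owning node on its lineage.
#' @slot nodeWeights Numeric per-node weights, summing to 1 over non-reject
#'   nodes.
#' @export
setClass("HiHMM",
  slots = c(hierarchy = "Hierarchy", emissions = "list",
            transitions = "list", ownership = "list",
            nodeWeights = "numeric"))

#' PlantedModel: specification of a synthetic hierarchy
#'
#' @slot nLeaves Number of leaves under the root.
#' @slot seqsPerLeaf Sequences emitted per leaf.
#' @slot coreLength Number of core (match) columns.
#' @slot leafPatternColumns Integer columns carrying leaf-discriminating
#'   patterns (shared specificity-determining positions).
#' @slot leafPatternResidues Character matrix (columns x leaves).
#' @slot rootPatternColumns Integer columns conserved across the family.
#' @slot rootPatternResidues Character vector, one per root column.
#' @slot strength Probability mass placed on a pattern residue.
#' @slot profile Matrix (columns x 20) of baseline emission probabilities.
#' @slot indelRate Per-position insertion/deletion probability.
#' @slot background Length-20 background composition.
#' @slot insertRegions List of per-leaf insert regions
#'   (list(position, length) or empty).
#' @slot seed Seed the model was built from.
#' @export
setClass("PlantedModel",
  slots = c(nLeaves = "integer", seqsPerLeaf = "integer",
            coreLength = "integer", leafPatternColumns = "integer",
            leafPatternResidues = "matrix", rootPatternColumns = "integer",
            rootPatternResidues = "character", strength = "numeric",
            profile = "matrix", indelRate = "numeric",
            background = "numeric", insertRegions = "list",
            seed = "integer"))

#' HiMSAFit: result of a full hiMSA sampling run
#'
#' @slot hierarchy Fitted \code{Hierarchy}.
#' @slot patterns Fitted \code{PatternSet} (flat-alignment coordinates).
#' @slot alignment Fitted \code{AlignmentState}.
#' @slot seqs Input \code{SequenceSet} with fitted weights.
#' @slot ledger \code{DLLedger} of the fitted model.
#' @slot trace Data frame: macro-cycle, penalized posterior (bits), nodes.
#' @slot alphas Per-node contamination fractions.
#' @slot himsa The hierarchical alignment (\code{HiMSA}) or NULL.
#' @slot hihmm The assembled \code{HiHMM} or NULL.
#' @slot config The \code{SamplerConfig} used.
#' @export
setClass("HiMSAFit",
  slots = c(hierarchy = "Hierarchy", patterns = "PatternSet",
            alignment = "AlignmentState", seqs = "SequenceSet",
            ledger = "DLLedger", trace = "data.frame", alphas = "numeric",
            himsa = "ANY", hihmm = "ANY", config = "SamplerConfig"))
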