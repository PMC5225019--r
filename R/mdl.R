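# Minimum-description-length accounting for hierarchical HMM model
# selection.  Each contribution to the total model description length is an
# exact, testable function; the sampler uses the itemized total as a
# posterior penalty, and model elements (nodes, patterns, match states) are
# admitted only when they pay for themselves in data bits.

#' Catalan number
#'
#' \code{C_n = (2n)! / ((n+1)! n!)}: the number of distinct rooted,
#' unlabeled (non-isomorphic ordered) trees on n nodes.
#'
#' @param n Positive integer.
#' @return The exact Catalan number (numeric; exact up to n = 30).
#' @examples
#' catalanNumber(3)  # 5
#' @export
catalanNumber <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("n must be a positive integer")
  exp(lgamma(2 * n + 1) - lgamma(n + 2) - lgamma(n + 1)) |> round()
}

#' Description length of a specific rooted tree, in bits
#'
#' Under a uniform prior over the \code{C_n} rooted unlabeled trees on n
#' nodes, using the asymptotic Catalan form: \code{2n - 1.5 log2(n) - 0.6}
#' bits.  With \code{exact = TRUE}, returns \code{log2(C_n)} instead.
#'
#' @param n Positive integer number of nodes.
#' @param exact Use the exact Catalan count (small n).
#' @return Bits.
#' @examples
#' treeDLBits(250)        # about 487.5
#' treeDLBits(1, exact = TRUE)  # 0
#' @export
treeDLBits <- function(n, exact = FALSE) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("n must be a positive integer")
  if (exact)
    (lgamma(2 * n + 1) - lgamma(n + 2) - lgamma(n + 1)) / log(2)
  else
    2 * n - 1.5 * log2(n) - 0.6
}

#' Description length of the node count under a geometric prior, in bits
#'
#' \code{-log2(1 - x) - (n - 1) log2(x)}: a slowly decaying geometric prior
#' with factor x near 1 renders the choice of n nearly irrelevant to the
#' total description length.
#'
#' @param n Positive integer number of nodes.
#' @param x Geometric factor in (0, 1); default 0.99.
#' @return Bits.
#' @examples
#' nodeCountDLBits(1, 0.99)    # about 6.6
#' nodeCountDLBits(250, 0.99)  # about 10.2
#' @export
nodeCountDLBits <- function(n, x = 0.99) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("n must be a positive integer")
  if (x <= 0 || x >= 1) stop("geometric factor must lie in (0, 1)")
  -log2(1 - x) - (n - 1) * log2(x)
}

#' Description length of a node's discriminating pattern, in bits
#'
#' \code{c * [-(1 - p) log2(1 - p) - p log2(p / t)]}: with prior
#' probability p that a column is discriminating and about t allowable,
#' equally probable residue sets per column, over c columns.
#'
#' @param c Number of columns (non-negative integer).
#' @param t Allowable residue sets per column (>= 1).
#' @param p Prior probability that a column is discriminating, in (0, 1).
#' @return Bits per node.
#' @examples
#' patternDLBits(200, 10, 0.1)  # about 160
#' @export
patternDLBits <- function(c, t, p) {
  if (c < 0 || c != round(c)) stop("c must be a non-negative integer")
  if (t < 1) stop("t must be >= 1")
  if (p <= 0 || p >= 1) stop("p must lie in (0, 1)")
  c * (-(1 - p) * log2(1 - p) - p * log2(p / t))
}

#' Description length of sequence-to-node assignments, in bits
#'
#' With all n nodes equally probable this is \code{log2(n)} bits per
#' effective (down-weighted) sequence.  Alternatively, supply the
#' non-uniform node priors and per-sequence node labels to get
#' \code{sum_i -log2(prior[node(i)])}.
#'
#' @param n Number of nodes.
#' @param sEff Effective number of sequences (sum of weights).
#' @param priors Optional node prior vector (summing to 1).
#' @param nodes Optional per-sequence node indices (used with
#'   \code{priors}; weights taken as 1 each unless \code{weights} given).
#' @param weights Optional per-sequence weights.
#' @return Bits.
#' @examples
#' assignmentDLBits(250, 25000)  # about 200,000
#' @export
assignmentDLBits <- function(n, sEff, priors = NULL, nodes = NULL,
                             weights = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (is.null(priors)) return(sEff * log2(n))
  stopifnot(!is.null(nodes))
  if (is.null(weights)) weights <- rep(1, length(nodes))
  sum(-weights * log2(priors[nodes]))
}

#' Itemized model description length
#'
#' Assembles a \code{DLLedger} from its components (all in bits).
#'
#' @param nodeCountBits,treeBits,patternBits,assignmentBits,pathBits,dataBits
#'   Component bits (default 0).
#' @return A \code{DLLedger}.
#' @examples
#' n <- 250
#' totalModelDL(nodeCountBits = nodeCountDLBits(n, 0.99),
#'              treeBits = treeDLBits(n),
#'              patternBits = n * patternDLBits(200, 10, 0.1),
#'              assignmentBits = assignmentDLBits(n, 25000))
#' @export
totalModelDL <- function(nodeCountBits = 0, treeBits = 0, patternBits = 0,
                         assignmentBits = 0, pathBits = 0, dataBits = 0) {
  new("DLLedger", nodeCountBits = nodeCountBits, treeBits = treeBits,
      patternBits = patternBits, assignmentBits = assignmentBits,
      pathBits = pathBits, dataBits = dataBits,
      total = nodeCountBits + treeBits + patternBits + assignmentBits +
        pathBits + dataBits)
}

#' MDL gain of adding a match column to the architecture, in bits
#'
#' The BILD score of the newly aligned residues minus the path description
#' cost of the extra state set.  A column is admissible iff the gain is
#' positive: extra states pay for themselves only through positive BILD
#' scores.
#'
#' @param counts Length-20 weighted counts of the candidate column.
#' @param prior Emission \code{DirichletMixture}.
#' @param null Background frequencies.
#' @param pathCostBits Non-negative path description cost in bits.
#' @return Gain in bits (column admissible iff > 0).
#' @export
architectureGainBits <- function(counts, prior = defaultEmissionPrior(),
                                 null = standardBackground(),
                                 pathCostBits = 0) {
  if (pathCostBits < 0) stop("path cost must be non-negative")
  bildScore(counts, prior, null) - pathCostBits
}
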