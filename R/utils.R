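# Shared low-level helpers: the residue alphabet, the standard background
# composition, and numerically safe log-space reductions.

AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Robinson & Robinson amino-acid frequencies, reordered to AA_ALPHABET20
# and renormalized.  Used as the "random protein" null everywhere.
.RR_FREQS <- c(
  A = 0.07805, C = 0.01925, D = 0.05364, E = 0.06295, F = 0.03856,
  G = 0.07377, H = 0.02199, I = 0.05142, K = 0.05744, L = 0.09019,
  M = 0.02243, N = 0.04487, P = 0.05203, Q = 0.04264, R = 0.05129,
  S = 0.07120, T = 0.05841, V = 0.06441, W = 0.01330, Y = 0.03216)

#' Standard amino-acid background frequencies
#'
#' The fixed background composition used as the null model for BILD scores,
#' for insert/unaligned residues, and as the root contrast background
#' (the "random sequences" background of the whole superfamily).
#'
#' @return Named numeric vector of length 20 (alphabetical one-letter order),
#'   summing to 1.
#' @examples
#' sum(standardBackground())
#' @export
standardBackground <- function() {
  f <- .RR_FREQS / sum(.RR_FREQS)
  names(f) <- AA_ALPHABET20
  f
}

#' @keywords internal
logSumExp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Encode residue characters to integer codes 1..20; non-standard letters
# (X and B, Z, U, O, J) map to NA and are excluded from all counts.
#' @keywords internal
encodeResidues <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  match(chars, AA_ALPHABET20)
}

#' @keywords internal
decodeResidues <- function(codes) {
  out <- rep("X", length(codes))
  ok <- !is.na(codes)
  out[ok] <- AA_ALPHABET20[codes[ok]]
  paste(out, collapse = "")
}

# Sanitize an input residue string: uppercase, map non-standard letters to X.
#' @keywords internal
sanitizeResidues <- function(x) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  bad <- !(chars %in% AA_ALPHABET20)
  chars[bad] <- "X"
  paste(chars, collapse = "")
}

# Draw one index from unnormalized log2 weights, optionally tempered.
#' @keywords internal
sampleLog2 <- function(logw, temperature = 1) {
  lw <- logw / max(temperature, 1e-8)
  lw <- lw - max(lw)
  p <- 2^lw
  sample.int(length(p), 1L, prob = p)
}

#' @keywords internal
bitsToNats <- function(x) x * log(2)

#' @keywords internal
natsToBits <- function(x) x / log(2)
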