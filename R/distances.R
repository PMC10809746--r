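#' Hamming distance between two equal-length nucleotide strings
#'
#' The number of positions at which `a` and `b` differ. Junction sequences are
#' stratified by length upstream of every distance computation, so unequal
#' lengths are a contract violation, not a fallback to alignment.
#'
#' @param a,b DNA strings over `A`, `C`, `G`, `T`, of equal length.
#' @return Non-negative integer count of mismatching positions.
#' @examples
#' hamming("ACGT", "ACGA")
#' normalized_hamming("AAAA", "AAAT")
#' @seealso [normalized_hamming()], [batch_distance()]
#' @export
hamming <- function(a, b) {
  if (length(a) != 1L || length(b) != 1L) {
    abort("`a` and `b` must be single strings.")
  }
  if (nchar(a) != nchar(b)) {
    abort(sprintf("sequence length mismatch: %d vs %d", nchar(a), nchar(b)))
  }
  sum(encode_sequences(a) != encode_sequences(b))
}

#' Normalized Hamming distance
#'
#' Hamming distance divided by the sequence length, giving a fraction in
#' `[0, 1]`. This is the scale on which the clonal cutoff (default 0.12) and
#' the partitioner's radius threshold are defined.
#'
#' @inheritParams hamming
#' @return Fraction of mismatching positions.
#' @export
normalized_hamming <- function(a, b) {
  if (nchar(a) == 0L) abort("sequences must be non-empty")
  hamming(a, b) / nchar(a)
}

# Integer-encode equal-length DNA strings as an n x L matrix (A=1, C=2, G=3,
# T=4). The encoding is internal; all public contracts are on strings.
encode_sequences <- function(x) {
  if (length(x) == 0L) return(matrix(integer(0), nrow = 0, ncol = 0))
  L <- unique(nchar(x))
  if (length(L) != 1L) abort("all sequences must share one length")
  bytes <- matrix(
    utf8ToInt(paste(x, collapse = "")),
    nrow = length(x), ncol = L, byrow = TRUE
  )
  key <- integer(128)
  key[utf8ToInt("A")] <- 1L; key[utf8ToInt("C")] <- 2L
  key[utf8ToInt("G")] <- 3L; key[utf8ToInt("T")] <- 4L
  enc <- matrix(key[bytes], nrow = length(x), ncol = L)
  if (any(enc == 0L)) abort("sequences may contain only A, C, G, T")
  enc
}

#' Normalized Hamming distances from sequences to a set of anchors
#'
#' Computes the n x k matrix whose `(i, j)` entry is the normalized Hamming
#' distance between sequence `i` and anchor `j`: the distance-vector embedding
#' on which the recursive partitioner operates.
#'
#' @param seqs Character vector of DNA strings, all the same length.
#' @param anchors Character vector of anchor DNA strings of that same length;
#'   at least one.
#' @return A numeric matrix with `length(seqs)` rows and `length(anchors)`
#'   columns, entries in `[0, 1]`.
#' @examples
#' batch_distance(c("AAAA", "AATT"), c("AAAA", "TTTT"))
#' @export
batch_distance <- function(seqs, anchors) {
  if (length(anchors) == 0L) abort("at least one anchor is required")
  es <- encode_sequences(seqs)
  ea <- encode_sequences(anchors)
  if (ncol(es) != ncol(ea)) abort("sequences and anchors must share one length")
  d <- cpp_hamming_matrix(es, ea) / ncol(es)
  dimnames(d) <- list(NULL, anchors)
  d
}

# Integer Hamming distance matrix between two encoded sets (internal).
hamming_matrix <- function(enc_a, enc_b = enc_a) {
  cpp_hamming_matrix(enc_a, enc_b)
}
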