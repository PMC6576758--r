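#' One-hot encode a DNA sequence
#'
#' Converts a DNA string over the alphabet A/C/G/T/N (case-insensitive) into
#' an L x 4 indicator matrix with columns ordered A, C, G, T.  An `N` base
#' carries no signal and is encoded as an all-zero row.
#'
#' @param seq A single DNA string.
#' @return An L x 4 numeric matrix with `colnames` `c("A","C","G","T")`.
#' @examples
#' encode_one_hot("ACGT")
#' @export
encode_one_hot <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  idx <- match(chars, c("A", "C", "G", "T", "N"))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop(sprintf("non-IUPAC character '%s' at position %d", chars[bad], bad))
  }
  L <- length(chars)
  m <- matrix(0, nrow = L, ncol = 4L, dimnames = list(NULL, DNA_BASES))
  hit <- idx <= 4L
  m[cbind(which(hit), idx[hit])] <- 1
  m
}

DNA_BASES <- c("A", "C", "G", "T")

#' Decode a one-hot matrix back to a DNA string
#'
#' Inverse of [encode_one_hot()]: all-zero rows decode to `N`.
#'
#' @param m An L x 4 one-hot matrix (columns A, C, G, T).
#' @return A DNA string of length `nrow(m)`.
#' @export
decode_one_hot <- function(m) {
  stopifnot(is.matrix(m), ncol(m) == 4L)
  hit <- max.col(m, ties.method = "first")
  hit[rowSums(m) == 0] <- 5L
  paste(c(DNA_BASES, "N")[hit], collapse = "")
}

#' Reverse-complement a one-hot matrix
#'
#' Rows are reversed and the base channels are swapped A<->T and C<->G, so
#' that `reverse_complement(encode_one_hot(s))` equals the encoding of the
#' reverse-complement of `s`.  The operation is an involution.
#'
#' @param m An L x 4 one-hot matrix (columns A, C, G, T).
#' @return The L x 4 one-hot matrix of the reverse-complement strand.
#' @export
reverse_complement <- function(m) {
  stopifnot(is.matrix(m), ncol(m) == 4L)
  out <- m[rev(seq_len(nrow(m))), c(4L, 3L, 2L, 1L), drop = FALSE]
  colnames(out) <- DNA_BASES
  out
}

#' Reverse-complement a DNA string
#' @param seq A DNA string over A/C/G/T/N.
#' @return The reverse-complement string.
#' @export
revcomp_seq <- function(seq) {
  chartr("ACGTNacgtn", "TGCANtgcan",
         paste(rev(strsplit(seq, "", fixed = TRUE)[[1]]), collapse = ""))
}

## Stack a character vector of equal-length sequences into a 3-d one-hot
## array with channel-fastest layout (4, L, N) used by the network engine.
encode_batch <- function(seqs) {
  L <- nchar(seqs[1])
  stopifnot(all(nchar(seqs) == L))
  n <- length(seqs)
  flat <- unlist(strsplit(toupper(paste(seqs, collapse = "")), "", fixed = TRUE),
                 use.names = FALSE)
  idx <- match(flat, c("A", "C", "G", "T", "N"))
  if (anyNA(idx)) stop("non-IUPAC character in batch")
  arr <- array(0, dim = c(4L, L, n))
  hit <- idx <= 4L
  pos <- seq_along(flat) - 1L              # 0-based position in concatenation
  arr[cbind(idx[hit], (pos[hit] %% L) + 1L, (pos[hit] %/% L) + 1L)] <- 1
  arr
}

## One fragment matrix (L x 4, row-per-position) -> engine layout (4, L, 1)
onehot_to_engine <- function(m) {
  array(t(m), dim = c(4L, nrow(m), 1L))
}

## Engine layout (4, L, n) -> list of L x 4 matrices
engine_to_onehot <- function(arr, i = 1L) {
  m <- t(arr[, , i])
  colnames(m) <- DNA_BASES
  m
}
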