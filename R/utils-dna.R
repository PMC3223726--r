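# Internal DNA helpers shared by the motif and scanning code.
#
# Sequences are plain upper-case character strings over A/C/G/T/N. Windows
# are represented as integer matrices (one row per window, one column per
# motif position, values 1..4 indexing A,C,G,T; NA for N) so that scoring,
# palindrome checks and Hamming distances are plain matrix operations.

DNA_BASES <- c("A", "C", "G", "T")

# complement of base index 1..4 (A<->T, C<->G)
COMP_IDX <- c(4L, 3L, 2L, 1L)

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' @noRd
random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

#' Is a DNA string its own reverse complement?
#' @noRd
is_palindromic <- function(x) {
  nchar(x) %% 2L == 0L && identical(revcomp(x), x)
}

# Encode a sequence into base indices (NA for anything not A/C/G/T).
#' @noRd
encode_dna <- function(sequence) {
  match(strsplit(toupper(sequence), "", fixed = TRUE)[[1]], DNA_BASES)
}

# All length-L windows of a sequence as an integer matrix plus 0-based
# offsets. Windows containing non-ACGT characters are dropped when
# drop_ambiguous is TRUE (the default everywhere: N-containing windows are
# skipped by all motif operations).
#' @noRd
window_matrix <- function(sequence, L, drop_ambiguous = TRUE) {
  idx <- encode_dna(sequence)
  n <- length(idx)
  if (n < L) {
    return(list(offsets = integer(0),
                mat = matrix(integer(0), nrow = 0, ncol = L)))
  }
  pos <- outer(seq_len(n - L + 1L), 0L:(L - 1L), "+")
  mat <- matrix(idx[pos], nrow = n - L + 1L, ncol = L)
  offsets <- 0L:(n - L)
  if (drop_ambiguous) {
    ok <- rowSums(is.na(mat)) == 0L
    mat <- mat[ok, , drop = FALSE]
    offsets <- offsets[ok]
  }
  list(offsets = offsets, mat = mat)
}

# Decode an index matrix row-wise back into strings.
#' @noRd
decode_windows <- function(mat) {
  if (nrow(mat) == 0L) return(character(0))
  apply(mat, 1L, function(r) paste(DNA_BASES[r], collapse = ""))
}

# Number of mismatched complementary pairs per window row: pair (j, L+1-j)
# matches when base[j] == complement(base[L+1-j]).
#' @noRd
mismatched_pairs <- function(mat) {
  L <- ncol(mat)
  half <- L %/% 2L
  mm <- integer(nrow(mat))
  for (j in seq_len(half)) {
    mm <- mm + as.integer(mat[, j] != COMP_IDX[mat[, L + 1L - j]])
  }
  mm
}

# PWM score of every window row: sum over positions of weights[base, pos].
#' @noRd
score_window_matrix <- function(mat, weights) {
  L <- ncol(mat)
  s <- numeric(nrow(mat))
  for (j in seq_len(L)) s <- s + weights[mat[, j], j]
  s
}

# Hamming distance of every window row to a reference index vector.
#' @noRd
hamming_to <- function(mat, ref) {
  L <- ncol(mat)
  d <- integer(nrow(mat))
  for (j in seq_len(L)) d <- d + as.integer(mat[, j] != ref[j])
  d
}

#' @noRd
check_scalar_int <- function(x, name, min = NULL) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x))
    stop(sprintf("'%s' must be a single integer", name), call. = FALSE)
  if (!is.null(min) && x < min)
    stop(sprintf("'%s' must be >= %s", name, min), call. = FALSE)
  invisible(as.integer(x))
}
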