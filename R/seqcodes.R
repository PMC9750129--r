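# Internal base encoding: 0 = N, 1 = A, 2 = C, 3 = G, 4 = T.
# Integer matrices (haplotypes/individuals x sites) are the working
# representation; character sequences are the interchange representation.

PQ_BASES <- c("A", "C", "G", "T")
# transition partner of A C G T (A<->G, C<->T)
PQ_TS_PARTNER <- c(3L, 4L, 1L, 2L)
# the two transversion partners of each base
PQ_TV1 <- c(2L, 1L, 2L, 1L)
PQ_TV2 <- c(4L, 3L, 4L, 3L)

#' Encode a nucleotide sequence as integers
#'
#' `A, C, G, T` map to `1:4`; `N` (and any IUPAC ambiguity code or gap,
#' which are treated as missing on ingest) maps to `0`.
#'
#' @param x A single string or a character vector of single bases.
#' @return Integer vector over `0:4`.
#' @keywords internal
#' @export
encode_bases <- function(x) {
  if (length(x) == 1 && nchar(x[1]) > 1) x <- strsplit(x, "")[[1]]
  m <- match(toupper(x), PQ_BASES)
  m[is.na(m)] <- 0L
  as.integer(m)
}

#' Decode an integer-coded sequence back to characters
#'
#' @param x Integer vector over `0:4`.
#' @param collapse If `TRUE` return a single string.
#' @return Character vector of bases (or one string).
#' @keywords internal
#' @export
decode_bases <- function(x, collapse = FALSE) {
  out <- c("N", PQ_BASES)[x + 1L]
  if (collapse) paste(out, collapse = "") else out
}

# character matrix (rows = sequences) -> integer matrix, preserving dimnames
encode_matrix <- function(m) {
  out <- matrix(match(toupper(m), PQ_BASES), nrow = nrow(m),
                dimnames = dimnames(m))
  out[is.na(out)] <- 0L
  storage.mode(out) <- "integer"
  out
}

decode_matrix <- function(m) {
  matrix(c("N", PQ_BASES)[m + 1L], nrow = nrow(m), dimnames = dimnames(m))
}

# named character vector of sequence strings -> integer matrix
strings_to_int <- function(seqs) {
  stopifnot(length(unique(nchar(seqs))) == 1)
  t(vapply(seqs, encode_bases, integer(nchar(seqs[[1]]))))
}
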