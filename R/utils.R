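# Low-level sequence and circular-coordinate helpers.
#
# Internal convention: 0-based half-open intervals; user-facing reports are
# 1-based inclusive (GenBank convention).

COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N", "-" = "-")

#' Reverse complement of a nucleotide string
#'
#' @param x a single character string over \{A,C,G,T,N\}.
#' @return the reverse-complemented string.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(x) {
  stopifnot(length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# vectorised over many strings (used by the IR seed finder)
revcomp_many <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# reverse complement of a character vector of single bases
revcomp_chars <- function(v) {
  unname(COMP[rev(v)])
}

comp_chars <- function(v) unname(COMP[v])

seq_to_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
chars_to_seq <- function(v) paste(v, collapse = "")

# position arithmetic on a circle of size n (0-based)
mod_pos <- function(p, n) ((p %% n) + n) %% n

# expand a circular 0-based half-open interval (start, len) into positions
circ_positions <- function(start, len, n) {
  mod_pos(seq.int(start, length.out = len), n)
}

# does circular arc a = (start,len) overlap arc b on a circle of size n?
circ_overlap <- function(a_start, a_len, b_start, b_len, n) {
  if (a_len == 0L || b_len == 0L) return(FALSE)
  # distance from a_start to b_start going forward
  d <- mod_pos(b_start - a_start, n)
  d < a_len || mod_pos(a_start - b_start, n) < b_len
}

# signed forward distance from position a to b on the circle
circ_fwd <- function(a, b, n) mod_pos(b - a, n)

# extract circular substring (0-based half-open, may wrap)
circ_substr <- function(seq, start, len) {
  n <- nchar(seq)
  start <- mod_pos(start, n)
  if (start + len <= n) {
    substr(seq, start + 1L, start + len)
  } else {
    paste0(substr(seq, start + 1L, n), substr(seq, 1L, start + len - n))
  }
}

is_base <- function(v) v == "A" | v == "C" | v == "G" | v == "T"

`%||%` <- function(a, b) if (is.null(a)) b else a
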