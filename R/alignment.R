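#' Alignment matrix with per-taxon coordinate maps
#'
#' Builds the package's alignment container from gapped sequences: a
#' character matrix (taxa x columns) over \{A,C,G,T,N,-\} plus, for each
#' taxon, a map from alignment column to 1-based ungapped sequence
#' coordinate (`NA` at gap columns). Removing the gaps from any row
#' reproduces the taxon's input sequence exactly.
#'
#' @param seqs named character vector of equal-length gapped sequences.
#' @return an object of class `alignment_matrix` with fields `taxa`, `ncol`,
#'   `mat`, `colmap`.
#' @export
alignment_matrix <- function(seqs) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("sequences must be named by taxon")
  }
  if (anyDuplicated(names(seqs))) stop("duplicate taxon names in alignment")
  w <- unique(nchar(seqs))
  if (length(w) != 1L) {
    stop("ragged alignment: sequence lengths ", paste(sort(nchar(seqs)), collapse = ", "))
  }
  seqs <- toupper(seqs)
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(mat) <- names(seqs)
  bad <- setdiff(unique(as.vector(mat)), c("A", "C", "G", "T", "N", "-"))
  if (length(bad)) stop("alignment contains characters outside {A,C,G,T,N,-}: ",
                        paste(bad, collapse = ""))
  if (any(rowSums(mat != "-") == 0L)) stop("all-gap row in alignment")
  colmap <- lapply(rownames(mat), function(tx) {
    gap <- mat[tx, ] == "-"
    m <- cumsum(!gap)
    m[gap] <- NA_integer_
    as.integer(m)
  })
  names(colmap) <- rownames(mat)
  structure(list(taxa = rownames(mat), ncol = ncol(mat),
                 mat = mat, colmap = colmap),
            class = "alignment_matrix")
}

#' Read an aligned FASTA file
#'
#' @param path aligned FASTA; all records must have equal length and use the
#'   alphabet \{A,C,G,T,N,-\}.
#' @return an [alignment_matrix()].
#' @export
read_alignment <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (!length(ss)) stop("no sequences in ", path)
  seqs <- setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  alignment_matrix(seqs)
}

#' Write an alignment to aligned FASTA
#'
#' @param aln an [alignment_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  seqs <- apply(aln$mat, 1L, paste, collapse = "")
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' @export
print.alignment_matrix <- function(x, ...) {
  cat(sprintf("<alignment_matrix> %d taxa x %s columns: %s\n",
              length(x$taxa), format(x$ncol, big.mark = ","),
              paste(head(x$taxa, 6L), collapse = ", ")))
  invisible(x)
}

# ungapped sequence of one row
aln_row_seq <- function(aln, taxon) {
  v <- aln$mat[taxon, ]
  paste(v[v != "-"], collapse = "")
}

# subset taxa, keeping column indexing intact
aln_subset <- function(aln, taxa) {
  missing <- setdiff(taxa, aln$taxa)
  if (length(missing)) stop("taxa not in alignment: ", paste(missing, collapse = ", "))
  out <- list(taxa = taxa, ncol = aln$ncol,
              mat = aln$mat[taxa, , drop = FALSE],
              colmap = aln$colmap[taxa])
  class(out) <- "alignment_matrix"
  out
}
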