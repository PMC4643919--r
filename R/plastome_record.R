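#' Annotated plastome record
#'
#' A `plastome_record` holds a circular (or linear) nucleotide sequence plus
#' an ordered list of annotated features. Coordinates are held internally as
#' 0-based half-open intervals; all printed reports use 1-based inclusive
#' coordinates.
#'
#' @param id record label (accession-like string).
#' @param sequence upper-case nucleotide string over \{A,C,G,T,N\}. Any other
#'   ambiguity character is rejected.
#' @param features list of [genome_feature()] objects.
#' @param circular logical; plastomes are circular molecules.
#' @return an object of class `plastome_record` with fields `id`, `length`,
#'   `sequence`, `circular`, `features`.
#' @export
plastome_record <- function(id, sequence, features = list(), circular = TRUE) {
  stopifnot(is.character(id), length(id) == 1L, is.character(sequence))
  sequence <- toupper(sequence)
  bad <- gsub("[ACGTN]", "", sequence)
  if (nzchar(bad)) {
    stop("sequence contains characters outside {A,C,G,T,N}: ",
         paste(unique(seq_to_chars(bad)), collapse = ""))
  }
  n <- nchar(sequence)
  for (f in features) {
    if (!inherits(f, "genome_feature")) stop("features must be genome_feature objects")
    if (any(f$exons < 0L) || any(f$exons > n)) {
      stop("feature '", f$name, "' has exon coordinates outside [0, ", n, ")")
    }
  }
  structure(
    list(id = id, length = n, sequence = sequence,
         circular = isTRUE(circular), features = features),
    class = "plastome_record"
  )
}

#' Annotated genome feature
#'
#' @param name gene symbol (e.g. `"ycf1"`, `"ndhF"`).
#' @param kind one of `"protein_coding"`, `"tRNA"`, `"rRNA"`, `"pseudogene"`.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column integer matrix of 0-based half-open exon intervals
#'   `(start, end)`, ordered and non-overlapping. More than one exon implies
#'   at least one intron.
#' @param is_duplicate flag for the second copy of an IR-resident gene.
#' @return an object of class `genome_feature`.
#' @export
genome_feature <- function(name, kind, strand, exons, is_duplicate = FALSE) {
  kind <- match.arg(kind, c("protein_coding", "tRNA", "rRNA", "pseudogene"))
  strand <- match.arg(strand, c("+", "-"))
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (any(exons[, 2L] <= exons[, 1L])) stop("empty or inverted exon interval in '", name, "'")
  if (nrow(exons) > 1L) {
    o <- order(exons[, 1L])
    exons <- exons[o, , drop = FALSE]
    if (any(exons[-1L, 1L] < exons[-nrow(exons), 2L])) {
      stop("overlapping exons in feature '", name, "'")
    }
  }
  structure(
    list(name = name, kind = kind, strand = strand, exons = exons,
         is_duplicate = isTRUE(is_duplicate)),
    class = "genome_feature"
  )
}

# full extent of a feature: (start of first exon, end of last exon)
feature_extent <- function(f) c(f$exons[1L, 1L], f$exons[nrow(f$exons), 2L])

feature_length <- function(f) sum(f$exons[, 2L] - f$exons[, 1L])

#' GC content of a record
#'
#' Fraction (G + C) / (A + C + G + T); `N` characters are ignored.
#'
#' @param record a [plastome_record()].
#' @return fraction in `[0, 1]`.
#' @export
gc_content <- function(record) {
  v <- seq_to_chars(record$sequence)
  tab <- table(factor(v, levels = c("A", "C", "G", "T")))
  denom <- sum(tab)
  if (denom == 0L) stop("no unambiguous bases in record")
  unname((tab[["G"]] + tab[["C"]]) / denom)
}

#' @export
print.plastome_record <- function(x, ...) {
  cat(sprintf("<plastome_record> %s: %s bp, %s, %d features\n",
              x$id, format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear", length(x$features)))
  invisible(x)
}

#' @export
print.genome_feature <- function(x, ...) {
  ivs <- apply(x$exons, 1L, function(e) sprintf("%d..%d", e[1L] + 1L, e[2L]))
  cat(sprintf("<feature> %s [%s, %s] %s%s\n", x$name, x$kind, x$strand,
              paste(ivs, collapse = ","),
              if (x$is_duplicate) " (IR duplicate)" else ""))
  invisible(x)
}

#' Gene inventory of an annotated plastome
#'
#' Counts annotated genes, splitting the total into unique genes and second
#' copies duplicated in the inverted repeats. A feature is counted as an IR
#' duplicate when it lies wholly or partly within IRa or IRb and a feature of
#' the same name lies in the other IR copy. Counting is by (name, locus):
#' distinct loci sharing a gene symbol (e.g. identical-sequence tRNA
#' isoacceptors) count separately.
#'
#' @param record annotated [plastome_record()].
#' @param structure a `quadripartite` object from [detect_inverted_repeats()].
#' @return a list of class `gene_inventory`: `total_genes`, `unique_genes`,
#'   `duplicated_in_IR`, and a per-kind breakdown `by_kind` (columns `total`,
#'   `duplicated`).
#' @export
gene_inventory <- function(record, structure) {
  feats <- record$features
  if (length(feats) == 0L) {
    warning("record has no annotated features; empty inventory")
    empty <- data.frame(kind = c("protein_coding", "tRNA", "rRNA", "pseudogene"),
                        total = 0L, duplicated = 0L)
    inv <- list(total_genes = 0L, unique_genes = 0L,
                duplicated_in_IR = 0L, by_kind = empty)
    class(inv) <- "gene_inventory"
    return(inv)
  }
  n <- record$length
  in_ir <- function(f, ir) {
    ext <- feature_extent(f)
    circ_overlap(ext[1L], ext[2L] - ext[1L], ir$start, ir$length, n)
  }
  ira_hit <- vapply(feats, in_ir, logical(1L), ir = structure$ira)
  irb_hit <- vapply(feats, in_ir, logical(1L), ir = structure$irb)
  names_v <- vapply(feats, `[[`, character(1L), "name")
  # duplicated: name present in both IR copies; the second copy is counted
  dup_names <- intersect(names_v[ira_hit], names_v[irb_hit])
  is_dup <- logical(length(feats))
  for (nm in dup_names) {
    idx <- which(names_v == nm & (ira_hit | irb_hit))
    if (length(idx) >= 2L) {
      # keep the first occurrence as the unique copy
      is_dup[idx[-1L]] <- TRUE
    }
  }
  kinds <- vapply(feats, `[[`, character(1L), "kind")
  by_kind <- do.call(rbind, lapply(c("protein_coding", "tRNA", "rRNA", "pseudogene"),
    function(k) data.frame(kind = k,
                           total = sum(kinds == k),
                           duplicated = sum(kinds == k & is_dup))))
  inv <- list(total_genes = length(feats),
              unique_genes = length(feats) - sum(is_dup),
              duplicated_in_IR = sum(is_dup),
              by_kind = by_kind)
  class(inv) <- "gene_inventory"
  inv
}

#' @export
print.gene_inventory <- function(x, ...) {
  cat(sprintf("<gene_inventory> %d genes: %d unique + %d duplicated in IR\n",
              x$total_genes, x$unique_genes, x$duplicated_in_IR))
  print(x$by_kind, row.names = FALSE)
  invisible(x)
}
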