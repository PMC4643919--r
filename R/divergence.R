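# Divergence profiling: p-distance, noncoding-region variability,
# sliding-window identity, parsimony-informative sites.

#' Uncorrected p-distance between two alignment rows
#'
#' Proportion of mismatching columns among columns where both taxa carry an
#' unambiguous base (pairwise deletion: columns with a gap or N in either
#' taxon are skipped).
#'
#' @param aln an [alignment_matrix()].
#' @param a,b taxon names.
#' @return fraction in `[0, 1]`.
#' @export
p_distance <- function(aln, a, b) {
  x <- aln$mat[a, ]; y <- aln$mat[b, ]
  ok <- is_base(x) & is_base(y)
  if (!any(ok)) stop("undefined p-distance: no compared columns between '",
                     a, "' and '", b, "'")
  mean(x[ok] != y[ok])
}

#' Pairwise p-distance summary over a set of taxa
#'
#' @param aln an [alignment_matrix()].
#' @param taxa taxa to compare (default all; at least 2).
#' @return list with `mean`, `min`, `max`, and the full symmetric `matrix`.
#' @export
overall_divergence <- function(aln, taxa = aln$taxa) {
  if (length(taxa) < 2L) stop("need at least two taxa")
  m <- matrix(0, length(taxa), length(taxa), dimnames = list(taxa, taxa))
  pairs <- combn(taxa, 2L)
  d <- apply(pairs, 2L, function(p) p_distance(aln, p[1L], p[2L]))
  for (i in seq_len(ncol(pairs))) {
    m[pairs[1L, i], pairs[2L, i]] <- m[pairs[2L, i], pairs[1L, i]] <- d[i]
  }
  list(mean = mean(d), min = min(d), max = max(d), matrix = m)
}

# logical vector over all columns: >= 2 distinct bases among `taxa`
substitution_site_mask <- function(aln, taxa) {
  sub <- aln$mat[taxa, , drop = FALSE]
  nstates <- Reduce(`+`, lapply(c("A", "C", "G", "T"), function(b)
    as.integer(colSums(sub == b) > 0L)))
  nstates >= 2L
}

# all maximal per-taxon gap runs: data.frame(taxon, start, end) (1-based cols)
gap_runs <- function(aln, taxa) {
  out <- lapply(taxa, function(tx) {
    r <- rle(aln$mat[tx, ] == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    if (!any(keep)) return(NULL)
    data.frame(taxon = tx, start = starts[keep], end = ends[keep])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(taxon = character(0), start = integer(0),
                               end = integer(0)) else out
}

#' Percent variability of noncoding regions
#'
#' For each region with aligned length above the threshold, counts
#' substitution sites (columns with at least two distinct bases among the
#' taxa, ignoring gaps and N at that column) and indel events (maximal gap
#' runs; a run shared identically by several taxa is one event, overlapping
#' runs of different extent are distinct events; a run is assigned to the
#' region containing its first column), and reports
#' `100 * (substitution sites + indel events) / aligned length`.
#'
#' @param aln an [alignment_matrix()].
#' @param regions data frame with columns `name`, `klass` (gene / intron /
#'   IGS), `start`, `end` (1-based inclusive alignment columns,
#'   non-overlapping).
#' @param taxa taxa to consider (default all).
#' @param min_aligned_length regions at or below this aligned length are
#'   dropped (default 200).
#' @return data frame with columns `name`, `klass`, `aligned_length`,
#'   `n_substitution_sites`, `n_indel_events`, `percent_variable`.
#' @export
region_variability <- function(aln, regions, taxa = aln$taxa,
                               min_aligned_length = 200L) {
  stopifnot(all(c("name", "start", "end") %in% names(regions)))
  if (!"klass" %in% names(regions)) regions$klass <- NA_character_
  o <- order(regions$start)
  regions <- regions[o, , drop = FALSE]
  if (any(regions$start < 1L) || any(regions$end > aln$ncol)) {
    stop("region interval outside alignment columns")
  }
  if (nrow(regions) > 1L &&
      any(regions$start[-1L] <= regions$end[-nrow(regions)])) {
    stop("overlapping regions on alignment columns")
  }
  sub_mask <- substitution_site_mask(aln, taxa)
  runs <- gap_runs(aln, taxa)
  runs <- unique(runs[, c("start", "end")])
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    s <- regions$start[i]; e <- regions$end[i]
    alen <- e - s + 1L
    if (alen <= min_aligned_length) return(NULL)
    nsub <- sum(sub_mask[s:e])
    nind <- sum(runs$start >= s & runs$start <= e)
    data.frame(name = regions$name[i], klass = regions$klass[i],
               aligned_length = alen,
               n_substitution_sites = nsub, n_indel_events = nind,
               percent_variable = 100 * (nsub + nind) / alen)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(name = character(0), klass = character(0),
                      aligned_length = integer(0),
                      n_substitution_sites = integer(0),
                      n_indel_events = integer(0),
                      percent_variable = numeric(0))
  }
  out
}

#' Sliding-window percent identity against a reference taxon
#'
#' mVISTA-style identity profile: for each window of alignment columns and
#' each non-reference taxon, `100 * matching columns / columns where either
#' taxon has a base`. Windows are indexed by the reference taxon's ungapped
#' coordinate at the window start.
#'
#' @param aln an [alignment_matrix()].
#' @param reference reference taxon name.
#' @param window window size in alignment columns (default 100).
#' @param step step in columns (default 25; must satisfy
#'   `window >= step >= 1`).
#' @return data frame with columns `taxon`, `col_start`, `col_end`,
#'   `ref_start` (reference coordinate), `identity` (percent; `NA` when no
#'   column in the window has a base in either taxon).
#' @export
sliding_identity <- function(aln, reference, window = 100L, step = 25L) {
  window <- as.integer(window); step <- as.integer(step)
  if (step < 1L || window < step) stop("need window >= step >= 1")
  if (window > aln$ncol) {
    warning("window larger than alignment; using a single truncated window")
    window <- aln$ncol
  }
  others <- setdiff(aln$taxa, reference)
  starts <- seq.int(1L, max(1L, aln$ncol - window + 1L), by = step)
  refv <- aln$mat[reference, ]
  ref_base <- is_base(refv)
  # reference coordinate at or after each column
  refcoord <- cumsum(ref_base)
  rows <- lapply(others, function(tx) {
    v <- aln$mat[tx, ]
    tx_base <- is_base(v)
    match_col <- ref_base & tx_base & refv == v
    cover_col <- ref_base | tx_base
    cm <- cumsum(match_col); cc <- cumsum(cover_col)
    ends <- pmin(starts + window - 1L, aln$ncol)
    nm <- cm[ends] - c(0, cm)[starts]
    nc <- cc[ends] - c(0, cc)[starts]
    data.frame(taxon = tx, col_start = starts, col_end = ends,
               ref_start = pmax(1L, refcoord[starts]),
               identity = ifelse(nc > 0L, 100 * nm / nc, NA_real_))
  })
  do.call(rbind, rows)
}

#' Count parsimony-informative sites
#'
#' A column is parsimony-informative when it shows at least two distinct
#' bases, each carried by at least two of the chosen taxa. Gaps and N are
#' not counted as states.
#'
#' @param aln an [alignment_matrix()].
#' @param taxa taxa subset (at least 4).
#' @return integer count.
#' @export
count_informative_sites <- function(aln, taxa = aln$taxa) {
  if (length(taxa) < 4L) stop("parsimony-informative sites need >= 4 taxa")
  sub <- aln$mat[taxa, , drop = FALSE]
  n_ge2 <- Reduce(`+`, lapply(c("A", "C", "G", "T"), function(b)
    as.integer(colSums(sub == b) >= 2L)))
  sum(n_ge2 >= 2L)
}
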