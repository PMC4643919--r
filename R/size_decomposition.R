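# Genome-size decomposition: partition an annotated plastome into genes,
# introns and intergenic spacers; attribute size differences between two
# genomes to matched elements and to large indels.

#' Partition an annotated genome into genes, introns and IGS
#'
#' One inverted-repeat copy is dropped first: the partition covers the
#' linearized LSC + IRb + SSC representation, so duplicated IR genes are
#' counted once. Within it, each feature contributes its exons as gene
#' elements (summed into one element per feature) and the gaps between
#' consecutive exons as intron elements; maximal intervals not covered by
#' any feature extent are intergenic spacers (IGS) named by their flanking
#' genes. Where gene extents overlap, overlap bases are assigned to the
#' earlier-starting gene and the later gene is truncated, so element lengths
#' are additive and tile the representation exactly.
#'
#' @param record annotated [plastome_record()].
#' @param structure `quadripartite` object from [detect_inverted_repeats()].
#' @return data frame of class `region_partition` with columns `name`,
#'   `klass` (`gene` / `intron` / `IGS`), `start`, `end` (0-based half-open
#'   in the rotated LSC+IRb+SSC representation), `length`; attribute
#'   `total_length` is the representation length.
#' @export
partition_genome <- function(record, structure) {
  n <- record$length
  rot <- structure$lsc$start
  M <- structure$lsc_length + structure$ir_length + structure$ssc_length
  shift <- function(p) mod_pos(p - rot, n)

  feats <- Filter(function(f) !f$is_duplicate, record$features)
  mapped <- list()
  for (f in feats) {
    ext <- feature_extent(f)
    s <- shift(ext[1L])
    glen <- circ_fwd(ext[1L], ext[2L], n)
    if (s >= M) next                      # wholly in the dropped IRa copy
    e <- min(s + glen, M)                 # clip at representation boundary
    ex <- t(apply(f$exons, 1L, function(iv) {
      c(shift(iv[1L]), shift(iv[1L]) + (iv[2L] - iv[1L]))
    }))
    ex <- ex[ex[, 1L] < M, , drop = FALSE]
    ex[, 2L] <- pmin(ex[, 2L], M)
    if (!nrow(ex)) next
    mapped[[length(mapped) + 1L]] <- list(name = f$name, start = s, end = e,
                                          exons = ex[order(ex[, 1L]), , drop = FALSE])
  }
  if (!length(mapped)) {
    warning("record has no usable annotation; partition is one IGS")
    out <- data.frame(name = "(unannotated)", klass = "IGS",
                      start = 0L, end = M, length = M)
    class(out) <- c("region_partition", "data.frame")
    attr(out, "total_length") <- M
    return(out)
  }
  mapped <- mapped[order(vapply(mapped, `[[`, numeric(1L), "start"))]

  rows <- list()
  covered_until <- 0L
  prev_gene <- "(start)"
  add <- function(name, klass, s, e) {
    if (e > s) rows[[length(rows) + 1L]] <<- data.frame(
      name = name, klass = klass, start = s, end = e, length = e - s)
  }
  for (g in mapped) {
    eff_s <- max(g$start, covered_until)
    if (eff_s >= g$end) next             # fully shadowed by an earlier gene
    add(paste0(prev_gene, "-", g$name), "IGS", covered_until, g$start)
    ex <- g$exons
    ex[, 1L] <- pmax(ex[, 1L], eff_s)
    ex <- ex[ex[, 2L] > ex[, 1L], , drop = FALSE]
    if (nrow(ex)) {
      for (i in seq_len(nrow(ex))) {
        add(g$name, "gene", ex[i, 1L], ex[i, 2L])
        if (i < nrow(ex)) {
          add(sprintf("%s.intron%d", g$name, i), "intron", ex[i, 2L], ex[i + 1L, 1L])
        }
      }
      # any truncated leading part of the extent not covered by clipped exons
      if (ex[1L, 1L] > eff_s) add(g$name, "gene", eff_s, ex[1L, 1L])
    } else {
      add(g$name, "gene", eff_s, g$end)
    }
    covered_until <- max(covered_until, g$end)
    prev_gene <- g$name
  }
  add(paste0(prev_gene, "-(end)"), "IGS", covered_until, M)
  out <- do.call(rbind, rows)
  # merge multi-exon gene pieces into one element per feature
  gene_rows <- out$klass == "gene"
  if (any(gene_rows)) {
    agg <- stats::aggregate(length ~ name, data = out[gene_rows, ], FUN = sum)
    starts <- stats::aggregate(start ~ name, data = out[gene_rows, ], FUN = min)
    ends <- stats::aggregate(end ~ name, data = out[gene_rows, ], FUN = max)
    merged <- merge(merge(agg, starts, by = "name"), ends, by = "name")
    merged$klass <- "gene"
    out <- rbind(out[!gene_rows, ],
                 merged[, c("name", "klass", "start", "end", "length")])
  }
  out <- out[order(out$start, out$end), ]
  rownames(out) <- NULL
  class(out) <- c("region_partition", "data.frame")
  attr(out, "total_length") <- M
  out
}

partition_key <- function(p) {
  ifelse(p$klass == "IGS",
         vapply(strsplit(p$name, "-", fixed = TRUE), function(v)
           paste(sort(v), collapse = "|"), character(1L)),
         p$name)
}

#' Compare two genome partitions element by element
#'
#' Matches elements of two [partition_genome()] results by name (IGS by
#' their flanking-gene pair, orientation-insensitive; rearranged
#' neighbourhoods therefore stay unmatched rather than being force-matched)
#' and reports per-element length differences.
#'
#' @param a,b `region_partition` objects (deltas are `a - b`).
#' @param large_threshold elements with `|delta|` strictly above this value
#'   are listed in `large` (default 100 bp).
#' @return list of class `size_comparison`: `matched` (data frame `name`,
#'   `klass`, `len_a`, `len_b`, `delta`), `unmatched_a`, `unmatched_b`,
#'   `by_klass` (per-class totals and deltas), `counts` (matched elements
#'   larger in a / larger in b / equal, overall and noncoding-only),
#'   `whole_delta` (total represented length difference), `large`.
#' @export
compare_partitions <- function(a, b, large_threshold = 100L) {
  ka <- partition_key(a); kb <- partition_key(b)
  da <- data.frame(key = ka, name = a$name, klass = a$klass, len_a = a$length)
  db <- data.frame(key = kb, name_b = b$name, klass_b = b$klass, len_b = b$length)
  if (anyDuplicated(da$key)) {
    da <- stats::aggregate(len_a ~ key + name + klass, data = da, FUN = sum)
  }
  if (anyDuplicated(db$key)) {
    db <- stats::aggregate(len_b ~ key + name_b + klass_b, data = db, FUN = sum)
  }
  m <- merge(da, db, by = "key")
  m <- m[m$klass == m$klass_b, ]
  matched <- data.frame(name = m$name, klass = m$klass,
                        len_a = m$len_a, len_b = m$len_b,
                        delta = m$len_a - m$len_b)
  matched <- matched[order(-abs(matched$delta)), ]
  rownames(matched) <- NULL
  unmatched_a <- a[!ka %in% m$key, c("name", "klass", "length")]
  unmatched_b <- b[!kb %in% m$key, c("name", "klass", "length")]
  by_klass <- do.call(rbind, lapply(c("gene", "intron", "IGS"), function(k) {
    data.frame(klass = k,
               total_a = sum(a$length[a$klass == k]),
               total_b = sum(b$length[b$klass == k]),
               delta = sum(a$length[a$klass == k]) - sum(b$length[b$klass == k]))
  }))
  noncoding <- matched$klass %in% c("intron", "IGS")
  counts <- data.frame(
    scope = c("all", "noncoding"),
    larger_in_a = c(sum(matched$delta > 0), sum(matched$delta > 0 & noncoding)),
    larger_in_b = c(sum(matched$delta < 0), sum(matched$delta < 0 & noncoding)),
    equal = c(sum(matched$delta == 0), sum(matched$delta == 0 & noncoding)))
  out <- list(matched = matched,
              unmatched_a = unmatched_a, unmatched_b = unmatched_b,
              by_klass = by_klass, counts = counts,
              whole_delta = attr(a, "total_length") - attr(b, "total_length"),
              large = matched[abs(matched$delta) > large_threshold, ])
  class(out) <- "size_comparison"
  out
}

#' @export
print.size_comparison <- function(x, ...) {
  cat(sprintf("<size_comparison> whole-representation delta %+d bp; %d matched elements (%d larger in a, %d in b, %d equal)\n",
              x$whole_delta, nrow(x$matched),
              x$counts$larger_in_a[1], x$counts$larger_in_b[1], x$counts$equal[1]))
  print(x$by_klass, row.names = FALSE)
  if (nrow(x$large)) {
    cat("  elements with |delta| above threshold:\n")
    print(x$large, row.names = FALSE)
  }
  invisible(x)
}

#' Region-level size deltas between two genomes
#'
#' Compares whole-genome and per-region (LSC, SSC, IR) sizes. Inputs can be
#' `quadripartite` objects or named numeric vectors with entries `size`,
#' `lsc`, `ssc`, `ir`.
#'
#' @param a,b `quadripartite` objects or named numeric vectors
#'   (deltas are `a - b`).
#' @return data frame with columns `region`, `a`, `b`, `delta`.
#' @export
region_size_deltas <- function(a, b) {
  as_vec <- function(x) {
    if (inherits(x, "quadripartite")) {
      c(size = x$genome_length, lsc = x$lsc_length,
        ssc = x$ssc_length, ir = x$ir_length)
    } else {
      stopifnot(all(c("size", "lsc", "ssc", "ir") %in% names(x)))
      x[c("size", "lsc", "ssc", "ir")]
    }
  }
  va <- as_vec(a); vb <- as_vec(b)
  data.frame(region = c("size", "lsc", "ssc", "ir"),
             a = unname(va), b = unname(vb), delta = unname(va - vb))
}

#' Large-indel accounting for a pairwise size difference
#'
#' Filters polarized indel events between two genomes to those strictly
#' longer than `min_len`, sums their signed contribution to the size of
#' genome `genome_a` (insertions carried by `genome_a` and deletions carried
#' by the other genome lengthen it), and expresses the sum as a fraction of
#' the observed total size difference.
#'
#' @param indels an `indel_events` object or its `events` data frame, from a
#'   two-genome (+ outgroup) alignment.
#' @param genome_a the taxon whose size excess is being explained.
#' @param total_delta observed size difference (`genome_a` minus the other;
#'   fraction is undefined when 0).
#' @param min_len length threshold in bases (default 100).
#' @return list with `n_large`, `summed_length`, `signed_sum`, `fraction`
#'   (`NA` when `total_delta == 0`).
#' @export
large_indel_accounting <- function(indels, genome_a, total_delta,
                                   min_len = 100L) {
  ev <- if (inherits(indels, "indel_events")) indels$events else indels
  big <- ev[ev$length > min_len, , drop = FALSE]
  carried_by_a <- vapply(strsplit(big$carriers, ",", fixed = TRUE),
                         function(v) genome_a %in% v, logical(1L))
  sign <- ifelse(big$polarity == "insertion", 1L, -1L) *
    ifelse(carried_by_a, 1L, -1L)
  signed_sum <- sum(sign * big$length)
  list(n_large = nrow(big),
       summed_length = sum(big$length),
       signed_sum = signed_sum,
       fraction = if (total_delta == 0) NA_real_ else signed_sum / total_delta)
}
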