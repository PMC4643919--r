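# Outgroup polarization of substitutions and indels, the 12-direction
# substitution spectrum, indel length spectrum and slipped-strand
# (homopolymer / tandem repeat) context classification.

PURINES <- c("A", "G")
DIRECTIONS <- {
  b <- c("A", "C", "G", "T")
  as.vector(outer(b, b, function(x, y) paste0(x, ">", y)))[as.vector(outer(b, b, "!="))]
}

ts_or_tv <- function(from, to) {
  ifelse((from %in% PURINES) == (to %in% PURINES), "transition", "transversion")
}

#' Polarize substitutions against an outgroup
#'
#' Scans alignment columns and emits one substitution event per column where
#' the direction is unambiguous: (i) no considered taxon carries a gap or N,
#' (ii) the ingroup shows exactly two states, and (iii) the outgroup state
#' equals one of them. The outgroup state is taken as ancestral; the ingroup
#' taxa bearing the other state are the carriers (a shared derived state is
#' one event, the parsimonious single-origin reading at shallow depth).
#' Columns failing a condition are tallied by skip reason.
#'
#' @param aln an [alignment_matrix()].
#' @param ingroup ingroup taxon names.
#' @param outgroup single outgroup taxon name (an error if absent).
#' @return list of class `substitution_events`: `events` (data frame with
#'   columns `column`, `ancestral`, `derived`, `carriers`, `n_carriers`,
#'   `klass`, `direction`), `skipped` (named counts: `gap_or_N`,
#'   `monomorphic`, `multiallelic`, `outgroup_mismatch`),
#'   `n_occurrences` (per-taxon occurrence tally, i.e. events weighted by
#'   carrier count).
#' @export
polarize_substitutions <- function(aln, ingroup, outgroup) {
  if (!outgroup %in% aln$taxa) stop("outgroup '", outgroup, "' not in alignment")
  if (length(outgroup) != 1L) stop("exactly one outgroup taxon required")
  sub <- aln$mat[c(ingroup, outgroup), , drop = FALSE]
  ing <- aln$mat[ingroup, , drop = FALSE]
  outv <- aln$mat[outgroup, ]
  ok <- colSums(!is_base(sub)) == 0L
  counts <- vapply(c("A", "C", "G", "T"), function(b) colSums(ing == b),
                   numeric(ncol(ing)))
  if (length(ingroup) == 1L) counts <- matrix(counts, nrow = aln$ncol)
  colnames(counts) <- c("A", "C", "G", "T")
  nstates <- rowSums(counts > 0L)
  two <- ok & nstates == 2L
  skipped <- c(gap_or_N = sum(!ok),
               monomorphic = sum(ok & nstates < 2L),
               multiallelic = sum(ok & nstates > 2L),
               outgroup_mismatch = 0L)
  rows <- list()
  for (col in which(two)) {
    states <- colnames(counts)[counts[col, ] > 0L]
    o <- outv[col]
    if (!o %in% states) {
      skipped[["outgroup_mismatch"]] <- skipped[["outgroup_mismatch"]] + 1L
      next
    }
    derived <- setdiff(states, o)
    carriers <- ingroup[ing[, col] == derived]
    rows[[length(rows) + 1L]] <- data.frame(
      column = col, ancestral = o, derived = derived,
      carriers = paste(carriers, collapse = ","),
      n_carriers = length(carriers),
      klass = ts_or_tv(o, derived),
      direction = paste0(o, ">", derived))
  }
  events <- if (length(rows)) do.call(rbind, rows) else
    data.frame(column = integer(0), ancestral = character(0),
               derived = character(0), carriers = character(0),
               n_carriers = integer(0), klass = character(0),
               direction = character(0))
  out <- list(events = events, skipped = skipped,
              n_occurrences = sum(events$n_carriers))
  class(out) <- "substitution_events"
  out
}

#' Directed substitution spectrum summary
#'
#' Tallies the 12 directed substitution types, transition and transversion
#' totals and their ratio, and flags directions whose counts fall outside
#' the central 99% binomial interval under a uniform 1/12 expectation
#' (descriptive, e.g. an excess of A>C).
#'
#' @param events a `substitution_events` object (or its `events` data frame).
#' @return list of class `spectrum_summary`: `directed` (data frame
#'   `direction`, `count`, `expected`, `status`), `n_transitions`,
#'   `n_transversions`, `ts_tv_ratio` (`NA` with a note when there are no
#'   transversions), `n_events`.
#' @export
substitution_spectrum <- function(events) {
  ev <- if (inherits(events, "substitution_events")) events$events else events
  counts <- table(factor(ev$direction, levels = DIRECTIONS))
  n <- nrow(ev)
  n_ts <- sum(ev$klass == "transition")
  n_tv <- sum(ev$klass == "transversion")
  expected <- n / 12
  status <- rep("typical", 12L)
  if (n > 0L) {
    lo <- qbinom(0.005, n, 1 / 12)
    hi <- qbinom(0.995, n, 1 / 12)
    status[counts > hi] <- "over"
    status[counts < lo] <- "under"
  }
  out <- list(
    directed = data.frame(direction = DIRECTIONS,
                          count = as.integer(counts),
                          expected = expected, status = status),
    n_transitions = n_ts, n_transversions = n_tv,
    ts_tv_ratio = if (n_tv > 0L) n_ts / n_tv else NA_real_,
    n_events = n)
  class(out) <- "spectrum_summary"
  out
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat(sprintf("<spectrum_summary> %d events: %d transitions, %d transversions (Ts/Tv = %s)\n",
              x$n_events, x$n_transitions, x$n_transversions,
              if (is.na(x$ts_tv_ratio)) "undefined (no transversions)"
              else sprintf("%.2f", x$ts_tv_ratio)))
  flagged <- x$directed[x$directed$status != "typical", ]
  if (nrow(flagged)) {
    cat("  directions outside the uniform 99% band:\n")
    for (i in seq_len(nrow(flagged))) {
      cat(sprintf("    %s: %d observed vs %.1f expected (%s)\n",
                  flagged$direction[i], flagged$count[i],
                  flagged$expected[i], flagged$status[i]))
    }
  }
  invisible(x)
}

#' Call and polarize indels against an outgroup
#'
#' Collects maximal gap runs per taxon and merges runs with identical
#' (interval, taxon-set) into one candidate event. An event is polarizable
#' when every considered taxon either carries exactly that maximal gap run
#' or has sequence across the whole interval. If the outgroup has sequence,
#' the gapped ingroup taxa suffered a deletion; if the outgroup is gapped
#' (along with the non-carrier ingroup), the taxa with sequence carry an
#' insertion. Anything else (partially overlapping runs, mixed gaps) is
#' excluded and tallied as unpolarizable. Events whose carriers would be the
#' entire ingroup are skipped too (tallied separately): like
#' ingroup-monomorphic substitution columns, they reflect change on the
#' outgroup lineage, not an indel among the ingroup genomes. Adjacent but
#' distinct gap runs separated by at least one base column are separate
#' events.
#'
#' @param aln an [alignment_matrix()].
#' @param ingroup ingroup taxon names.
#' @param outgroup single outgroup taxon name.
#' @return list of class `indel_events`: `events` (data frame with columns
#'   `col_start`, `col_end`, `length`, `polarity`, `carriers`, `n_carriers`,
#'   `seq`), `n_unpolarizable`, `n_ingroup_shared`.
#' @export
call_and_polarize_indels <- function(aln, ingroup, outgroup) {
  if (!outgroup %in% aln$taxa) stop("outgroup '", outgroup, "' not in alignment")
  taxa <- c(ingroup, outgroup)
  runs <- gap_runs(aln, taxa)
  n_unpol <- 0L
  n_shared <- 0L
  rows <- list()
  if (nrow(runs)) {
    key <- paste(runs$start, runs$end)
    for (kk in unique(key)) {
      grp <- runs[key == kk, ]
      s <- grp$start[1L]; e <- grp$end[1L]
      gapped <- grp$taxon
      others <- setdiff(taxa, gapped)
      cols <- s:e
      others_clean <- vapply(others, function(tx)
        all(aln$mat[tx, cols] != "-"), logical(1L))
      if (!all(others_clean) || length(others) == 0L) {
        n_unpol <- n_unpol + 1L
        next
      }
      if (!outgroup %in% gapped) {
        carriers <- gapped
        polarity <- "deletion"
        # report the deleted sequence from the closest relative with
        # sequence: a non-carrier ingroup taxon if there is one (the
        # outgroup may have accumulated its own changes at these columns)
        ing_src <- setdiff(others, outgroup)
        seqsrc <- if (length(ing_src)) ing_src[1L] else outgroup
      } else {
        carriers <- others
        if (!length(carriers) || !all(carriers %in% ingroup)) {
          n_unpol <- n_unpol + 1L
          next
        }
        polarity <- "insertion"
        seqsrc <- carriers[1L]
      }
      if (length(carriers) >= length(ingroup)) {
        # the whole ingroup shares the state: the event sits on the outgroup
        # lineage, not among the ingroup genomes
        n_shared <- n_shared + 1L
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        col_start = s, col_end = e, length = e - s + 1L,
        polarity = polarity,
        carriers = paste(carriers, collapse = ","),
        n_carriers = length(carriers),
        seq = paste(aln$mat[seqsrc, cols], collapse = ""))
    }
  }
  events <- if (length(rows)) do.call(rbind, rows) else
    data.frame(col_start = integer(0), col_end = integer(0),
               length = integer(0), polarity = character(0),
               carriers = character(0), n_carriers = integer(0),
               seq = character(0))
  events <- events[order(events$col_start), , drop = FALSE]
  rownames(events) <- NULL
  out <- list(events = events, n_unpolarizable = n_unpol,
              n_ingroup_shared = n_shared)
  class(out) <- "indel_events"
  out
}

#' Classify the repeat context of an indel
#'
#' Slipped-strand mispairing predicts that indels arise at repeats. An event
#' is `homopolymer` when the inserted/deleted sequence is a single repeated
#' base sitting inside a mononucleotide run of total length >=
#' `homopolymer_min` in the un-gapped neighbourhood; `tandem_repeat` when
#' the event sequence exactly equals the immediately adjacent upstream or
#' downstream flank of the same length; `none` otherwise. For 1-bp events
#' only the homopolymer test applies (a length-1 "tandem" is a 2-base
#' mononucleotide run, below the homopolymer threshold); for longer events
#' the tandem test is checked first.
#'
#' @param seq the inserted or deleted nucleotide string.
#' @param upstream un-gapped flanking sequence 5' of the event site.
#' @param downstream un-gapped flanking sequence 3' of the event site.
#' @param homopolymer_min minimum total mononucleotide run length
#'   (default 4).
#' @return one of `"homopolymer"`, `"tandem_repeat"`, `"none"`.
#' @export
classify_indel_context <- function(seq, upstream, downstream,
                                   homopolymer_min = 4L) {
  L <- nchar(seq)
  if (L < 1L) stop("empty indel sequence")
  if (nchar(upstream) < L && nchar(downstream) < L) {
    warning("flanks shorter than the event; context computed on available flank")
  }
  is_homo <- function() {
    v <- seq_to_chars(seq)
    if (length(unique(v)) != 1L) return(FALSE)
    b <- v[1L]
    up <- rev(seq_to_chars(upstream))
    dn <- seq_to_chars(downstream)
    run_up <- if (length(up)) match(FALSE, up == b, nomatch = length(up) + 1L) - 1L else 0L
    run_dn <- if (length(dn)) match(FALSE, dn == b, nomatch = length(dn) + 1L) - 1L else 0L
    run_up + L + run_dn >= homopolymer_min
  }
  is_tandem <- function() {
    up_ok <- nchar(upstream) >= L &&
      substr(upstream, nchar(upstream) - L + 1L, nchar(upstream)) == seq
    dn_ok <- nchar(downstream) >= L && substr(downstream, 1L, L) == seq
    up_ok || dn_ok
  }
  if (L == 1L) {
    # a length-1 "tandem" is just a 2-base mononucleotide run, below the
    # homopolymer threshold: only the homopolymer test applies
    if (is_homo()) return("homopolymer")
  } else {
    if (is_tandem()) return("tandem_repeat")
    if (is_homo()) return("homopolymer")
  }
  "none"
}

#' Repeat-context classification of called indel events
#'
#' Derives un-gapped flanks from the alignment and applies
#' [classify_indel_context()] to every event. Flanks represent the state of
#' the sequence the event happened in: for insertions they come from the
#' first carrier; for deletions, from the closest non-carrier ingroup taxon
#' (the outgroup is used only when no ingroup taxon retains the sequence,
#' since outgroup-lineage changes would corrupt the exact-match context
#' tests).
#'
#' @param aln the [alignment_matrix()] the events were called on.
#' @param indels an `indel_events` object from [call_and_polarize_indels()].
#' @param outgroup the outgroup taxon name.
#' @param ingroup ingroup taxa (default: all non-outgroup taxa).
#' @param homopolymer_min passed to [classify_indel_context()].
#' @param flank maximum flank length examined (default
#'   `max(event length, homopolymer_min)` per event).
#' @return the `indel_events` object with a `context` column added and a
#'   `n_repeat_associated` field.
#' @export
classify_indel_events <- function(aln, indels, outgroup,
                                  ingroup = setdiff(aln$taxa, outgroup),
                                  homopolymer_min = 4L, flank = NULL) {
  ev <- indels$events
  ctx <- character(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    carriers_i <- strsplit(ev$carriers[i], ",", fixed = TRUE)[[1]]
    src <- if (ev$polarity[i] == "deletion") {
      cand <- setdiff(ingroup, carriers_i)
      cand <- cand[apply(aln$mat[cand, ev$col_start[i]:ev$col_end[i],
                                 drop = FALSE] != "-", 1L, all)]
      if (length(cand)) cand[1L] else outgroup
    } else carriers_i[1L]
    row <- aln$mat[src, ]
    fl <- flank %||% max(ev$length[i], homopolymer_min)
    left <- row[seq_len(ev$col_start[i] - 1L)]
    left <- left[left != "-"]
    right <- row[seq.int(ev$col_end[i] + 1L, length.out = max(0L, aln$ncol - ev$col_end[i]))]
    right <- right[right != "-"]
    up <- paste(tail(left, fl), collapse = "")
    dn <- paste(head(right, fl), collapse = "")
    ctx[i] <- suppressWarnings(
      classify_indel_context(ev$seq[i], up, dn, homopolymer_min))
  }
  indels$events$context <- ctx
  indels$n_repeat_associated <- sum(ctx != "none")
  indels
}

#' Indel length spectrum
#'
#' @param indels an `indel_events` object or its `events` data frame.
#' @return list with per-polarity components `insertion` and `deletion`,
#'   each holding `n`, `lengths` (table), `frac_1bp`, `max`.
#' @export
indel_length_spectrum <- function(indels) {
  ev <- if (inherits(indels, "indel_events")) indels$events else indels
  per <- function(pol) {
    L <- ev$length[ev$polarity == pol]
    list(n = length(L),
         lengths = table(L),
         frac_1bp = if (length(L)) mean(L == 1L) else NA_real_,
         max = if (length(L)) max(L) else NA_integer_)
  }
  list(insertion = per("insertion"), deletion = per("deletion"))
}
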