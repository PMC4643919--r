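# Quadripartite structure detection.
#
# The inverted repeat is found as the longest pair of disjoint, exactly
# reverse-complementary repeats. Search is seed-and-extend on the doubled
# sequence (so repeats straddling the circular origin are found), with
# maximal extension by binary search on substring equality. The two IR
# copies of an assembled plastome are identical, so an exact-match search is
# sufficient; a mismatch-tolerant mode is deliberately not offered.

#' Detect the inverted repeat and partition the genome
#'
#' Finds the longest pair of disjoint, exactly reverse-complementary repeats
#' of at least `min_ir_length` bases and partitions the circle into LSC, SSC,
#' IRa and IRb. Single-copy regions are labelled by size (LSC is the longer
#' one); IRb is the IR copy immediately downstream of the LSC, matching the
#' usual JLB/JSB/JSA/JLA junction nomenclature. Ties between equal-length
#' candidate repeat pairs are broken by maximising the shorter single-copy
#' region, then by position, so detection is deterministic. The reported IR
#' length is the maximal exact-repeat length (which includes any duplicated
#' gene fragment at a junction).
#'
#' @param record a [plastome_record()] (sequence length must exceed
#'   `4 * min_ir_length`).
#' @param min_ir_length minimum repeat length in bases (default 1000;
#'   excludes small dispersed repeats while far below real ~25 kb IRs).
#' @return an object of class `quadripartite`: intervals `lsc`, `ssc`, `ira`,
#'   `irb` (each `list(start, length)`, 0-based circular start), plus
#'   `ir_length`, `lsc_length`, `ssc_length`, `genome_length`.
#' @export
detect_inverted_repeats <- function(record, min_ir_length = 1000L) {
  n <- record$length
  min_ir_length <- as.integer(min_ir_length)
  if (n <= 4L * min_ir_length) {
    stop("sequence length ", n, " too short for min_ir_length ", min_ir_length)
  }
  pair <- find_best_ir_pair(record$sequence, min_ir_length)
  if (is.null(pair)) {
    longest <- attr(find_best_ir_pair(record$sequence, 8L), "longest") %||% 0L
    stop("no quadripartite structure: no reverse-complementary repeat pair >= ",
         min_ir_length, " bp (longest found: ", longest, " bp)")
  }
  build_quadripartite(pair, n)
}

# returns list(a0, b0, len) of the winning pair, or NULL
find_best_ir_pair <- function(seq, min_ir_length) {
  n <- nchar(seq)
  k <- max(8L, min(32L, min_ir_length))
  D <- paste0(seq, seq)
  nD <- 2L * n
  all_starts <- seq_len(nD - k + 1L)
  all_kmers <- substring(D, all_starts, all_starts + k - 1L)

  seed_starts <- seq.int(1L, n, by = k)
  seed_kmers <- all_kmers[seed_starts]
  rc_seeds <- revcomp_many(seed_kmers)
  u <- unique(rc_seeds)
  hit_j <- which(all_kmers %in% u)
  if (!length(hit_j)) return(NULL)
  grp <- match(all_kmers[hit_j], u)
  seeds_by_u <- split(seed_starts, match(rc_seeds, u))
  js_by_u <- split(hit_j, grp)

  found <- list()   # each: list(Ai, Ae, Bi, Be) in D coordinates + normalized
  covered <- function(i, j) {
    for (p in found) {
      if (i >= p$Ai && i <= p$Ae - k && j >= p$Bi && j <= p$Be - k &&
          (i + j) == (p$Ai + p$Bi + (p$Ae - p$Ai) - k)) return(TRUE)
    }
    FALSE
  }
  check_right <- function(i, j, r) {
    j - r >= 1L && i + k - 1L + r <= nD &&
      substring(D, i, i + k - 1L + r) ==
        revcomp(substring(D, j - r, j + k - 1L))
  }
  check_left <- function(i, j, l) {
    i - l >= 1L && j + k - 1L + l <= nD &&
      substring(D, i - l, i + k - 1L) ==
        revcomp(substring(D, j, j + k - 1L + l))
  }
  bsearch <- function(cap, ok) {
    lo <- 0L; hi <- cap
    while (lo < hi) {
      mid <- as.integer(ceiling((lo + hi) / 2))
      if (ok(mid)) lo <- mid else hi <- mid - 1L
    }
    lo
  }

  best <- list(); longest <- 0L
  for (ui in names(seeds_by_u)) {
    js <- js_by_u[[ui]]
    if (is.null(js)) next
    for (i in seeds_by_u[[ui]]) {
      for (j in js) {
        if (covered(i, j)) next
        r <- bsearch(min(j - 1L, nD - i - k + 1L, n),
                     function(x) check_right(i, j, x))
        l <- bsearch(min(i - 1L, nD - j - k + 1L, n),
                     function(x) check_left(i, j, x))
        Ai <- i - l; Ae <- i + k + r
        Bi <- j - r; Be <- j + k + l
        len <- k + l + r
        found[[length(found) + 1L]] <- list(Ai = Ai, Ae = Ae, Bi = Bi, Be = Be)
        if (len > longest) longest <- len
        if (len < min_ir_length || 2L * len > n) next
        a0 <- mod_pos(Ai - 1L, n); b0 <- mod_pos(Bi - 1L, n)
        # canonical ordering of the two copies
        if (b0 < a0) { tmp <- a0; a0 <- b0; b0 <- tmp }
        if (a0 == b0) next                      # self-overlapping palindrome
        if (circ_overlap(a0, len, b0, len, n)) next
        key <- paste(a0, b0, len)
        if (!is.null(best[[key]])) next
        best[[key]] <- list(a0 = a0, b0 = b0, len = len)
      }
    }
  }
  if (!length(best)) {
    out <- NULL
    attr(out, "longest") <- longest
    return(out)
  }
  cand <- do.call(rbind, lapply(best, function(p) {
    g1 <- circ_fwd(p$a0 + p$len, p$b0, n)       # arc between copy1 end, copy2 start
    g2 <- n - 2L * p$len - g1
    data.frame(a0 = p$a0, b0 = p$b0, len = p$len,
               min_sc = min(g1, g2))
  }))
  o <- order(-cand$len, -cand$min_sc, cand$a0, cand$b0)
  cand <- cand[o[1L], ]
  list(a0 = cand$a0, b0 = cand$b0, len = cand$len)
}

build_quadripartite <- function(pair, n) {
  len <- pair$len
  s1 <- pair$a0; s2 <- pair$b0
  g1_start <- mod_pos(s1 + len, n); g1_len <- circ_fwd(s1 + len, s2, n)
  g2_start <- mod_pos(s2 + len, n); g2_len <- circ_fwd(s2 + len, s1, n)
  if (g1_len == 0L || g2_len == 0L) {
    stop("degenerate structure: IR copies are adjacent, no single-copy region")
  }
  if (g1_len >= g2_len) {
    lsc <- list(start = g1_start, length = g1_len)
    ssc <- list(start = g2_start, length = g2_len)
    irb <- list(start = s2, length = len)   # downstream of LSC
    ira <- list(start = s1, length = len)
  } else {
    lsc <- list(start = g2_start, length = g2_len)
    ssc <- list(start = g1_start, length = g1_len)
    irb <- list(start = s1, length = len)
    ira <- list(start = s2, length = len)
  }
  out <- list(lsc = lsc, ssc = ssc, ira = ira, irb = irb,
              ir_length = len, lsc_length = lsc$length,
              ssc_length = ssc$length, genome_length = n)
  class(out) <- "quadripartite"
  out
}

#' @export
print.quadripartite <- function(x, ...) {
  cat(sprintf("<quadripartite> genome %s bp: LSC %s + IRb %s + SSC %s + IRa %s\n",
              format(x$genome_length, big.mark = ","),
              format(x$lsc_length, big.mark = ","),
              format(x$ir_length, big.mark = ","),
              format(x$ssc_length, big.mark = ","),
              format(x$ir_length, big.mark = ",")))
  for (r in c("lsc", "irb", "ssc", "ira")) {
    iv <- x[[r]]
    cat(sprintf("  %-3s %9d..%d (1-based, circular)\n", toupper(r),
                iv$start + 1L, mod_pos(iv$start + iv$length - 1L,
                                       x$genome_length) + 1L))
  }
  invisible(x)
}

#' Extract the sequence of a structure region
#'
#' @param record a [plastome_record()].
#' @param structure a `quadripartite` object for the record.
#' @param region one of `"lsc"`, `"ssc"`, `"ira"`, `"irb"`.
#' @return the region sequence (wraps across the origin if needed).
#' @export
region_sequence <- function(record, structure, region) {
  region <- match.arg(region, c("lsc", "ssc", "ira", "irb"))
  iv <- structure[[region]]
  circ_substr(record$sequence, iv$start, iv$length)
}

# the four junction positions: boundary b means "between position b-1 and b"
junction_positions <- function(structure) {
  n <- structure$genome_length
  list(
    JLB = structure$irb$start,                                      # LSC | IRb
    JSB = mod_pos(structure$irb$start + structure$ir_length, n),    # IRb | SSC
    JSA = structure$ira$start,                                      # SSC | IRa
    JLA = mod_pos(structure$ira$start + structure$ir_length, n)     # IRa | LSC
  )
}

#' Junction gene overlap report
#'
#' For each of the four junctions (JLB = LSC/IRb, JSB = IRb/SSC,
#' JSA = SSC/IRa, JLA = IRa/LSC) the report names the annotated gene whose
#' extent crosses the junction and how many bases of it lie inside the
#' adjacent inverted repeat (e.g. a ycf1 gene crossing JSB with 36 bp
#' duplicated in the IR). Junctions with no spanning gene report the nearest
#' flanking gene and its distance instead.
#'
#' @param record annotated [plastome_record()].
#' @param structure `quadripartite` object from [detect_inverted_repeats()].
#' @return data frame of class `junction_report` with columns `junction`,
#'   `gene`, `ir_overlap` (bases of the spanning gene inside the IR, 0 if
#'   none), `distance` (to the nearest gene when no gene spans).
#' @export
junction_report <- function(record, structure) {
  n <- record$length
  jp <- junction_positions(structure)
  ir_of <- c(JLB = "irb", JSB = "irb", JSA = "ira", JLA = "ira")
  feats <- record$features
  rows <- lapply(names(jp), function(jn) {
    b <- jp[[jn]]
    ir <- structure[[ir_of[[jn]]]]
    if (!length(feats)) {
      return(data.frame(junction = jn, gene = NA_character_,
                        ir_overlap = NA_integer_, distance = NA_integer_))
    }
    spans <- NULL
    for (f in feats) {
      ext <- feature_extent(f)
      glen <- circ_fwd(ext[1L], ext[2L], n)
      if (glen == 0L) glen <- n
      # junction boundary b is crossed when b lies strictly inside the extent
      off <- circ_fwd(ext[1L], b, n)
      if (off > 0L && off < glen) { spans <- f; break }
    }
    if (!is.null(spans)) {
      ext <- feature_extent(spans)
      glen <- circ_fwd(ext[1L], ext[2L], n)
      pos <- circ_positions(ext[1L], glen, n)
      in_ir <- sum(circ_fwd(ir$start, pos, n) < ir$length)
      data.frame(junction = jn, gene = spans$name,
                 ir_overlap = as.integer(in_ir), distance = 0L)
    } else {
      d <- vapply(feats, function(f) {
        ext <- feature_extent(f)
        min(circ_fwd(ext[2L], b, n), circ_fwd(b, ext[1L], n))
      }, numeric(1L))
      i <- which.min(d)
      data.frame(junction = jn, gene = feats[[i]]$name,
                 ir_overlap = 0L, distance = as.integer(d[i]))
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("junction_report", "data.frame")
  out
}

#' Canonicalize SSC orientation against a reference genome
#'
#' The SSC can exist in two isomeric orientations in a plastome assembly;
#' the difference is a representation artifact, not a gene-order difference.
#' This compares the record's SSC against the reference SSC in both
#' orientations by shared k-mer count and, when the reverse complement
#' matches better, flips the SSC segment in place (feature coordinates and
#' strands inside the SSC are mirrored accordingly).
#'
#' @param record [plastome_record()] to canonicalize.
#' @param structure its `quadripartite` structure.
#' @param reference reference [plastome_record()].
#' @param reference_structure the reference's `quadripartite` structure
#'   (an error if missing).
#' @param k k-mer size for the orientation score (default 15).
#' @return the (possibly flipped) record, with attribute `ssc_flipped`.
#' @export
canonicalize_orientation <- function(record, structure, reference,
                                     reference_structure, k = 15L) {
  if (missing(reference_structure) || is.null(reference_structure)) {
    stop("reference record lacks a detected quadripartite structure")
  }
  ssc <- region_sequence(record, structure, "ssc")
  ref_ssc <- region_sequence(reference, reference_structure, "ssc")
  score <- function(a, b) {
    ka <- unique(substring(a, seq_len(nchar(a) - k + 1L),
                           seq_len(nchar(a) - k + 1L) + k - 1L))
    kb <- unique(substring(b, seq_len(nchar(b) - k + 1L),
                           seq_len(nchar(b) - k + 1L) + k - 1L))
    length(intersect(ka, kb))
  }
  fwd <- score(ssc, ref_ssc)
  rcs <- score(revcomp(ssc), ref_ssc)
  if (rcs <= fwd) {
    attr(record, "ssc_flipped") <- FALSE
    return(record)
  }
  record <- flip_ssc(record, structure)
  attr(record, "ssc_flipped") <- TRUE
  record
}

# reverse-complement the SSC segment of a record, mirroring contained features
flip_ssc <- function(record, structure) {
  n <- record$length
  s <- structure$ssc$start; L <- structure$ssc$length
  pos <- circ_positions(s, L, n)                 # 0-based positions of SSC
  v <- seq_to_chars(record$sequence)
  v[pos + 1L] <- revcomp_chars(v[pos + 1L])
  feats <- lapply(record$features, function(f) {
    ext <- feature_extent(f)
    off1 <- circ_fwd(s, ext[1L], n)
    off2 <- circ_fwd(s, ext[2L], n)
    inside <- off1 < L && off2 <= L && off2 >= off1
    if (!inside) {
      if (circ_overlap(ext[1L], max(1L, ext[2L] - ext[1L]), s, L, n) &&
          !(off1 < L && off2 <= L)) {
        warning("feature '", f$name, "' straddles the SSC boundary; ",
                "coordinates left unchanged by SSC flip")
      }
      return(f)
    }
    # mirror exon offsets within the SSC
    ex <- f$exons
    new <- t(apply(ex, 1L, function(e) {
      o1 <- circ_fwd(s, e[1L], n); o2 <- circ_fwd(s, e[2L], n)
      if (o2 == 0L) o2 <- L
      c(mod_pos(s + (L - o2), n), mod_pos(s + (L - o1) - 1L, n) + 1L)
    }))
    genome_feature(f$name, f$kind, if (f$strand == "+") "-" else "+",
                   new[rev(seq_len(nrow(new))), , drop = FALSE],
                   is_duplicate = f$is_duplicate)
  })
  plastome_record(record$id, chars_to_seq(v), feats, record$circular)
}
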