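# GenBank flat-file reader/writer.
#
# Scope: single-record nucleotide flat files with gene/CDS/tRNA/rRNA
# features, simple, complement() and join() locations. This covers deposited
# plastome records; anything fancier (remote references, fuzzy coordinates
# beyond </>) is rejected with the offending line number.

GB_KIND_TO_KEY <- c(protein_coding = "CDS", tRNA = "tRNA",
                    rRNA = "rRNA", pseudogene = "gene")

#' Read a GenBank flat file
#'
#' Parses a single-record GenBank nucleotide flat file into a
#' [plastome_record()]. `CDS`, `tRNA` and `rRNA` features are captured with
#' kinds `protein_coding`, `tRNA`, `rRNA`; `gene` features carrying `/pseudo`
#' become `pseudogene`. Bare `gene` features whose symbol is already covered
#' by a typed feature are dropped (they are the standard redundant gene/CDS
#' pairing); remaining bare `gene` features are kept as `protein_coding`.
#' Coordinates are converted from GenBank 1-based inclusive to internal
#' 0-based half-open; `join()` (multi-exon) locations are preserved, and
#' `complement()` sets the minus strand. The two segments of trans-spliced
#' rps12 appear as independent features; no intron is implied between them.
#'
#' @param path file path.
#' @return a [plastome_record()].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  loc_i <- grep("^LOCUS", lines)
  if (length(loc_i) != 1L) stop("expected exactly one LOCUS line in ", path)
  loc <- strsplit(trimws(lines[loc_i]), "[[:space:]]+")[[1]]
  id <- loc[2]
  circular <- any(grepl("circular", lines[loc_i], ignore.case = TRUE))

  feat_i <- grep("^FEATURES", lines)
  orig_i <- grep("^ORIGIN", lines)
  if (length(orig_i) != 1L) stop("no ORIGIN section (record without sequence) in ", path)

  # ---- sequence ----
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[end_i > orig_i][1] else length(lines) + 1L
  seq_lines <- lines[seq.int(orig_i + 1L, end_i - 1L)]
  sequence <- toupper(gsub("[0-9 [:space:]/]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) stop("record without sequence in ", path)

  # ---- features ----
  feats <- list()
  if (length(feat_i) == 1L) {
    fl <- seq.int(feat_i + 1L, orig_i - 1L)
    raw <- lines[fl]
    is_key <- grepl("^ {5}\\S", raw)
    starts <- which(is_key)
    for (si in seq_along(starts)) {
      a <- starts[si]
      b <- if (si < length(starts)) starts[si + 1L] - 1L else length(raw)
      block <- raw[a:b]
      key <- sub("^ {5}(\\S+).*$", "\\1", block[1])
      if (!key %in% c("gene", "CDS", "tRNA", "rRNA")) next
      # location may continue over lines until the first qualifier line
      body <- trimws(block)
      qual_start <- which(startsWith(body, "/"))[1]
      loc_lines <- if (is.na(qual_start)) body else body[seq_len(qual_start - 1L)]
      loc_lines[1] <- sub("^\\S+\\s+", "", loc_lines[1])
      locstr <- gsub("[[:space:]]", "", paste(loc_lines, collapse = ""))
      parsed <- tryCatch(parse_gb_location(locstr),
                         error = function(e) stop("malformed location at line ",
                                                  fl[a], " of ", path, ": ",
                                                  conditionMessage(e), call. = FALSE))
      quals <- if (is.na(qual_start)) character(0) else body[qual_start:length(body)]
      qtxt <- paste(quals, collapse = " ")
      name <- NA_character_
      m <- regmatches(qtxt, regexpr('/gene="[^"]*"', qtxt))
      if (length(m)) name <- sub('/gene="([^"]*)"', "\\1", m)
      if (is.na(name)) {
        m <- regmatches(qtxt, regexpr('/(product|locus_tag)="[^"]*"', qtxt))
        if (length(m)) name <- sub('.*="([^"]*)"', "\\1", m)
      }
      if (is.na(name)) name <- paste0(key, "_", si)
      pseudo <- grepl("/pseudo\\b", qtxt)
      kind <- switch(key, CDS = "protein_coding", tRNA = "tRNA", rRNA = "rRNA",
                     gene = if (pseudo) "pseudogene" else "protein_coding")
      feats[[length(feats) + 1L]] <- list(
        key = key, name = name, kind = kind, strand = parsed$strand,
        exons = parsed$exons)
    }
  }
  # drop redundant bare gene features covered by a typed feature of same name
  typed_names <- vapply(Filter(function(f) f$key != "gene", feats),
                        function(f) f$name, character(1L))
  feats <- Filter(function(f) !(f$key == "gene" && f$kind != "pseudogene" &&
                                  f$name %in% typed_names), feats)
  features <- lapply(feats, function(f)
    genome_feature(f$name, f$kind, f$strand, f$exons))
  plastome_record(id = id, sequence = sequence, features = features,
                  circular = circular)
}

# "complement(join(10..20,30..40))" -> strand/exons (0-based half-open)
parse_gb_location <- function(s) {
  strand <- "+"
  if (startsWith(s, "complement(")) {
    strand <- "-"
    s <- sub("^complement\\((.*)\\)$", "\\1", s)
  }
  if (startsWith(s, "join(")) {
    s <- sub("^join\\((.*)\\)$", "\\1", s)
  } else if (startsWith(s, "order(")) {
    s <- sub("^order\\((.*)\\)$", "\\1", s)
  }
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  if (!length(parts)) stop("empty location")
  exons <- t(vapply(parts, function(p) {
    p <- gsub("[<>]", "", p)
    if (grepl("^[0-9]+$", p)) {
      a <- as.integer(p); c(a - 1L, a)
    } else if (grepl("^[0-9]+\\.\\.[0-9]+$", p)) {
      ab <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
      if (ab[2] < ab[1]) stop("interval end before start: ", p)
      c(ab[1] - 1L, ab[2])
    } else stop("unsupported location element: ", p)
  }, integer(2L)))
  dimnames(exons) <- NULL
  list(strand = strand, exons = exons)
}

#' Write a GenBank flat file
#'
#' Writes a [plastome_record()] so that [read_genbank()] recovers the
#' sequence and every feature (name, kind, strand, exon coordinates)
#' losslessly.
#'
#' @param record a [plastome_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, path) {
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  topo <- if (record$circular) "circular" else "linear"
  cat(sprintf("LOCUS       %-16s %d bp    DNA     %s PLN %s\n",
              record$id, record$length, topo,
              format(Sys.Date(), "%d-%b-%Y")), file = con)
  cat(sprintf("DEFINITION  %s plastid genome record.\n", record$id), file = con)
  cat("FEATURES             Location/Qualifiers\n", file = con)
  cat(sprintf("     source          1..%d\n", record$length), file = con)
  for (f in record$features) {
    key <- GB_KIND_TO_KEY[[f$kind]]
    ivs <- apply(f$exons, 1L, function(e) sprintf("%d..%d", e[1L] + 1L, e[2L]))
    loc <- if (length(ivs) > 1L) sprintf("join(%s)", paste(ivs, collapse = ",")) else ivs
    if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
    cat(sprintf("     %-15s %s\n", key, loc), file = con)
    cat(sprintf('                     /gene="%s"\n', f$name), file = con)
    if (f$kind == "pseudogene") cat("                     /pseudo\n", file = con)
  }
  cat("ORIGIN\n", file = con)
  s <- tolower(record$sequence)
  starts <- seq(1L, nchar(s), by = 60L)
  for (st in starts) {
    chunk <- substr(s, st, min(st + 59L, nchar(s)))
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    cat(sprintf("%9d %s\n", st, paste(groups, collapse = " ")), file = con)
  }
  cat("//\n", file = con)
  invisible(path)
}

#' Read a FASTA record with a feature-table sidecar
#'
#' Alternative input route to [read_genbank()]: a plain FASTA sequence plus a
#' tab-separated annotation table with columns `name`, `kind`, `strand`,
#' `exons` (1-based inclusive intervals, `start..end` joined with `;`).
#'
#' @param fasta_path FASTA file with a single record.
#' @param features_path optional TSV feature table.
#' @param circular logical.
#' @return a [plastome_record()].
#' @export
read_fasta_record <- function(fasta_path, features_path = NULL, circular = TRUE) {
  ss <- Biostrings::readBStringSet(fasta_path)
  if (length(ss) != 1L) stop("expected a single FASTA record in ", fasta_path)
  features <- list()
  if (!is.null(features_path)) {
    tab <- read.delim(features_path, comment.char = "#",
                      stringsAsFactors = FALSE)
    features <- lapply(seq_len(nrow(tab)), function(i) {
      ivs <- strsplit(tab$exons[i], ";", fixed = TRUE)[[1]]
      exons <- t(vapply(ivs, function(p) {
        ab <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
        c(ab[1] - 1L, ab[2])
      }, integer(2L)))
      genome_feature(tab$name[i], tab$kind[i], tab$strand[i], exons)
    })
  }
  plastome_record(id = sub("\\s.*$", "", names(ss)[1]),
                  sequence = as.character(ss[[1]]),
                  features = features, circular = circular)
}

#' Write a record as FASTA plus feature-table sidecar
#'
#' @param record a [plastome_record()].
#' @param fasta_path output FASTA path.
#' @param features_path optional output TSV path for the annotation.
#' @return `fasta_path`, invisibly.
#' @export
write_fasta_record <- function(record, fasta_path, features_path = NULL) {
  ss <- Biostrings::DNAStringSet(setNames(record$sequence, record$id))
  Biostrings::writeXStringSet(ss, fasta_path, width = 70L)
  if (!is.null(features_path)) {
    rows <- lapply(record$features, function(f) {
      ivs <- apply(f$exons, 1L, function(e) sprintf("%d..%d", e[1L] + 1L, e[2L]))
      data.frame(name = f$name, kind = f$kind, strand = f$strand,
                 exons = paste(ivs, collapse = ";"))
    })
    tab <- if (length(rows)) do.call(rbind, rows) else
      data.frame(name = character(0), kind = character(0),
                 strand = character(0), exons = character(0))
    write.table(tab, features_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(fasta_path)
}
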