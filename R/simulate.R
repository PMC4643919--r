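# Plastome evolution simulator with ground truth.
#
# A synthetic root plastome (quadripartite, annotated, seeded with
# homopolymer runs and tandem repeats) is evolved along a rooted tree under
# a directional 12-cell substitution spectrum and a slipped-strand indel
# process. Homology is tracked exactly: every residue carries a sort key,
# insertions receive keys strictly between their neighbours', and the true
# multiple alignment is assembled from the keys without invoking an aligner.
# Per-branch event logs allow exact replay of every leaf from the root.

#' Simulation configuration
#'
#' Defaults emulate a shallow four-species plastome comparison: ~162 kb
#' quadripartite genomes, interspecific p-distance around 0.001-0.002, a
#' directional substitution spectrum with overall Ts/Tv = 0.5 (the ratio
#' expected when all changes are equally likely) plus an A>C excess and a
#' G:C transversion deficit, insertions outnumbering deletions 41:17, about
#' half of indels 1 bp long, and 52/58 of indels seeded at homopolymers or
#' tandem repeats.
#'
#' @param seed integer seed; identical (seed, config) gives byte-identical
#'   output.
#' @param lsc,ssc,ir region lengths in bases.
#' @param base_freq equilibrium base frequencies (named, sums to 1; default
#'   GC content 0.365).
#' @param genes_per_kb gene density in single-copy and IR regions.
#' @param intron_prob probability a protein-coding gene carries one intron.
#' @param trna_prob probability a gene is a tRNA (short) rather than
#'   protein-coding.
#' @param junction_overlap bases by which a planted ycf1-like gene crosses
#'   the IRb/SSC junction into the IR (default 36).
#' @param tree rooted newick string with branch lengths in expected
#'   substitutions per site, or an `ape::phylo` object.
#' @param spectrum 4x4 directional substitution rate matrix (rows = from,
#'   cols = to); the default encodes per-base Ts/Tv = 0.5 with rate(A>C) =
#'   2.5 and rate(G>C) = rate(C>G) = 0.4 against 1 for other transversions.
#'   It is normalized internally so branch lengths are expected
#'   substitutions per site at `base_freq`.
#' @param indel_sub_ratio expected indel events per substitution event
#'   (default 58/208).
#' @param insertion_fraction probability an indel is an insertion
#'   (default 41/58).
#' @param indel_len_p geometric length parameter; `P(length = 1)` equals
#'   this value (default 0.5).
#' @param max_indel_len truncation for the geometric length draw.
#' @param slip_fraction probability an indel is seeded at a homopolymer or
#'   tandem-repeat context (default 52/58).
#' @param homopolymer_every,tandem_every spacing (bases) of repeat seeds
#'   injected into the root sequence, so the slip process has realistic
#'   targets.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       lsc = 91000L, ssc = 20400L, ir = 25600L,
                       base_freq = c(A = 0.3175, C = 0.1825,
                                     G = 0.1825, T = 0.3175),
                       genes_per_kb = 0.7, intron_prob = 0.15,
                       trna_prob = 0.25,
                       junction_overlap = 36L,
                       tree = paste0("(((T_mand:0.0005,T_oliv:0.0005):0.0005,",
                                     "(T_pauc:0.0005,T_amur:0.0005):0.0005):0.01,",
                                     "OUT:0.015);"),
                       spectrum = NULL,
                       indel_sub_ratio = 58 / 208,
                       insertion_fraction = 41 / 58,
                       indel_len_p = 0.5,
                       max_indel_len = 80L,
                       slip_fraction = 52 / 58,
                       homopolymer_every = 250L,
                       tandem_every = 800L) {
  stopifnot(abs(sum(base_freq) - 1) < 1e-8,
            insertion_fraction >= 0, insertion_fraction <= 1,
            slip_fraction >= 0, slip_fraction <= 1,
            indel_sub_ratio >= 0)
  if (is.null(spectrum)) spectrum <- default_spectrum()
  stopifnot(is.matrix(spectrum), all(dim(spectrum) == 4L), all(spectrum >= 0))
  phy <- if (inherits(tree, "phylo")) tree else ape::read.tree(text = tree)
  if (any(phy$edge.length < 0)) stop("negative branch length in tree")
  # normalize so branch length == expected substitutions/site at base_freq
  rowrate <- rowSums(spectrum)
  mean_rate <- sum(base_freq[rownames(spectrum)] * rowrate)
  spectrum <- spectrum / mean_rate
  cfg <- list(seed = as.integer(seed), lsc = as.integer(lsc),
              ssc = as.integer(ssc), ir = as.integer(ir),
              base_freq = base_freq, genes_per_kb = genes_per_kb,
              intron_prob = intron_prob, trna_prob = trna_prob,
              junction_overlap = as.integer(junction_overlap),
              tree = phy, spectrum = spectrum,
              row_rate = rowSums(spectrum),
              indel_sub_ratio = indel_sub_ratio,
              insertion_fraction = insertion_fraction,
              indel_len_p = indel_len_p,
              max_indel_len = as.integer(max_indel_len),
              slip_fraction = slip_fraction,
              homopolymer_every = as.integer(homopolymer_every),
              tandem_every = as.integer(tandem_every))
  class(cfg) <- "sim_config"
  cfg
}

default_spectrum <- function() {
  b <- c("A", "C", "G", "T")
  m <- matrix(0, 4, 4, dimnames = list(b, b))
  # transversions
  m["A", "C"] <- 2.5; m["A", "T"] <- 1
  m["C", "A"] <- 1;   m["C", "G"] <- 0.4
  m["G", "C"] <- 0.4; m["G", "T"] <- 1
  m["T", "A"] <- 1;   m["T", "G"] <- 1
  # transitions: per-base rate = 0.5 * (sum of that base's transversions),
  # so conditional on an event P(transition) = 1/3 exactly (Ts/Tv = 0.5)
  m["A", "G"] <- 0.5 * (m["A", "C"] + m["A", "T"])
  m["C", "T"] <- 0.5 * (m["C", "A"] + m["C", "G"])
  m["G", "A"] <- 0.5 * (m["G", "C"] + m["G", "T"])
  m["T", "C"] <- 0.5 * (m["T", "A"] + m["T", "G"])
  m
}

# random sequence with injected homopolymer runs and tandem repeats
random_region <- function(len, cfg) {
  v <- sample(names(cfg$base_freq), len, replace = TRUE, prob = cfg$base_freq)
  if (cfg$homopolymer_every > 0L) {
    at <- seq.int(10L, len - 12L, by = cfg$homopolymer_every)
    for (p in at) {
      rl <- sample(4:8, 1L)
      v[p:(p + rl - 1L)] <- sample(names(cfg$base_freq), 1L, prob = cfg$base_freq)
    }
  }
  if (cfg$tandem_every > 0L) {
    at <- seq.int(60L, len - 40L, by = cfg$tandem_every)
    for (p in at) {
      mlen <- sample(2:5, 1L)
      ncopy <- sample(2:3, 1L)
      motif <- sample(names(cfg$base_freq), mlen, replace = TRUE,
                      prob = cfg$base_freq)
      v[p:(p + mlen * ncopy - 1L)] <- rep(motif, ncopy)
    }
  }
  v
}

# place non-overlapping genes along [0, len): returns list of features with
# 0-based coords relative to the region start
place_genes <- function(len, cfg, prefix, reserve_head = 0L, reserve_tail = 0L) {
  target <- round(cfg$genes_per_kb * len / 1000)
  feats <- list()
  pos <- reserve_head
  i <- 0L
  while (i < target) {
    gap <- sample(80:400, 1L)
    trna <- runif(1L) < cfg$trna_prob
    glen <- if (trna) sample(70:90, 1L) else sample(300:1200, 1L)
    if (pos + gap + glen > len - reserve_tail) break
    s <- pos + gap
    i <- i + 1L
    name <- sprintf("%s%02d", prefix, i)
    strand <- sample(c("+", "-"), 1L)
    if (!trna && runif(1L) < cfg$intron_prob && glen > 400L) {
      cut <- sample(150:(glen - 150L), 1L)
      intron <- sample(80:200, 1L)
      exons <- rbind(c(s, s + cut), c(s + cut + intron, s + glen + intron))
      glen <- glen + intron
    } else {
      exons <- rbind(c(s, s + glen))
    }
    feats[[length(feats) + 1L]] <- list(
      name = name, kind = if (trna) "tRNA" else "protein_coding",
      strand = strand, exons = exons)
    pos <- s + glen
  }
  feats
}

#' Simulate an annotated root plastome
#'
#' Builds a circular genome laid out LSC + IRb + SSC + IRa with
#' `IRa = revcomp(IRb)` exactly, gene annotations (IRb genes duplicated in
#' IRa), and one ycf1-like gene planted across the IRb/SSC junction with
#' `junction_overlap` bases inside the IR. Homopolymer runs and tandem
#' repeats are injected so the slipped-strand indel process has targets.
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_root`: `record` ([plastome_record()]),
#'   `structure` (true `quadripartite`), `state` (internal evolving state:
#'   residue characters, homology keys, region labels).
#' @export
simulate_root_plastome <- function(cfg) {
  set.seed(cfg$seed)
  ov <- cfg$junction_overlap
  if (cfg$ir <= ov + 200L || cfg$ssc <= 2000L || cfg$lsc <= 2000L) {
    stop("region lengths too small for the requested gene layout")
  }
  lsc_v <- random_region(cfg$lsc, cfg)
  irb_v <- random_region(cfg$ir, cfg)
  ssc_v <- random_region(cfg$ssc, cfg)
  # the planted IR must be the *maximal* exact repeat: make sure the bases
  # flanking the junctions cannot extend it by chance
  if (lsc_v[cfg$lsc] == COMP[[lsc_v[1L]]]) {
    lsc_v[1L] <- setdiff(c("A", "C", "G", "T"), COMP[[lsc_v[cfg$lsc]]])[1L]
  }
  if (ssc_v[1L] == COMP[[ssc_v[cfg$ssc]]]) {
    ssc_v[1L] <- setdiff(c("A", "C", "G", "T"), COMP[[ssc_v[cfg$ssc]]])[1L]
  }
  ira_v <- revcomp_chars(irb_v)
  chars <- c(lsc_v, irb_v, ssc_v, ira_v)
  n <- length(chars)
  region <- rep(c("LSC", "IRB", "SSC", "IRA"),
                times = c(cfg$lsc, cfg$ir, cfg$ssc, cfg$ir))

  jsb <- cfg$lsc + cfg$ir                  # 0-based position of first SSC base
  # ycf1-like junction gene: last `ov` bases of IRb + head of SSC
  jg_len <- min(1800L, cfg$ssc - 400L)
  jg <- list(name = "ycf1", kind = "protein_coding", strand = "-",
             exons = rbind(c(jsb - ov, jsb - ov + jg_len)))

  feats <- list()
  off <- function(fl, offset) lapply(fl, function(f) {
    f$exons <- f$exons + offset; f
  })
  feats <- c(feats,
             off(place_genes(cfg$lsc, cfg, "lscg"), 0L),
             off(place_genes(cfg$ir, cfg, "irg",
                             reserve_tail = ov + 60L), cfg$lsc),
             list(jg),
             off(place_genes(cfg$ssc, cfg, "sscg",
                             reserve_head = jg_len - ov + 60L), jsb))
  # duplicate IRb genes into IRa (mirrored coordinates, flipped strand)
  ira_start <- jsb + cfg$ssc
  dup <- lapply(Filter(function(f) startsWith(f$name, "irg"), feats), function(f) {
    ex <- f$exons - cfg$lsc               # offsets within IRb
    mir <- cbind(cfg$ir - ex[, 2L], cfg$ir - ex[, 1L]) + ira_start
    list(name = f$name, kind = f$kind,
         strand = if (f$strand == "+") "-" else "+",
         exons = mir[rev(seq_len(nrow(mir))), , drop = FALSE],
         is_duplicate = TRUE)
  })
  feats <- c(feats, dup)
  features <- lapply(feats, function(f)
    genome_feature(f$name, f$kind, f$strand, f$exons,
                   is_duplicate = isTRUE(f$is_duplicate)))
  record <- plastome_record("root", chars_to_seq(chars), features)
  truth <- build_quadripartite(list(a0 = ira_start, b0 = cfg$lsc, len = cfg$ir), n)
  out <- list(record = record, structure = truth,
              state = list(chars = chars, keys = as.numeric(seq_len(n)),
                           region = region))
  class(out) <- "sim_root"
  out
}

# ---- branch evolution ----------------------------------------------------

ir_pair_index <- function(region) {
  idxb <- which(region == "IRB")
  idxa <- rev(which(region == "IRA"))
  list(b = idxb, a = idxa)
}

# contiguous blocks of a region label
region_blocks <- function(region) {
  r <- rle(region)
  ends <- cumsum(r$lengths)
  data.frame(label = r$values, start = ends - r$lengths + 1L, end = ends)
}

sample_sc_interval <- function(region, L) {
  bl <- region_blocks(region)
  bl <- bl[bl$label %in% c("LSC", "SSC") & (bl$end - bl$start + 1L) >= L + 2L, ]
  if (!nrow(bl)) return(NULL)
  w <- bl$end - bl$start + 2L - L
  i <- sample.int(nrow(bl), 1L, prob = w)
  s <- bl$start[i] + sample.int(w[i], 1L) - 1L
  c(s, s + L - 1L)
}

homopolymer_runs <- function(chars, region, min_len) {
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= min_len &
    region[starts] %in% c("LSC", "SSC") & region[starts] == region[ends]
  data.frame(start = starts[keep], len = r$lengths[keep],
             base = r$values[keep])
}

# positions j such that chars[j..j+L-1] == chars[j+L..j+2L-1], all single-copy
tandem_pair_starts <- function(chars, region, L) {
  n <- length(chars)
  if (2L * L + 2L > n) return(integer(0))
  js <- seq_len(n - 2L * L)
  eq <- rep(TRUE, length(js))
  for (t in 0:(L - 1L)) eq <- eq & chars[js + t] == chars[js + L + t]
  js <- js[eq]
  sc <- region[js] %in% c("LSC", "SSC") & region[js] == region[js + 2L * L - 1L]
  js[sc]
}

splice_insert <- function(state, after, ins, label) {
  n <- length(state$chars)
  kprev <- if (after == 0L) 0 else state$keys[after]
  knext <- if (after == n) max(state$keys) + 1 else state$keys[after + 1L]
  newkeys <- kprev + sort(runif(length(ins))) * (knext - kprev)
  idx <- if (after == 0L) integer(0) else seq_len(after)
  rest <- if (after == n) integer(0) else (after + 1L):n
  state$chars <- c(state$chars[idx], ins, state$chars[rest])
  state$keys <- c(state$keys[idx], newkeys, state$keys[rest])
  state$region <- c(state$region[idx], rep(label, length(ins)), state$region[rest])
  state
}

splice_delete <- function(state, s, L) {
  drop <- s:(s + L - 1L)
  state$chars <- state$chars[-drop]
  state$keys <- state$keys[-drop]
  state$region <- state$region[-drop]
  state
}

evolve_branch <- function(state, brlen, cfg, branch) {
  events <- list()
  add_event <- function(type, pos, length, from = NA, to = NA,
                        polarity = NA, seq = NA, context = NA) {
    events[[length(events) + 1L]] <<- data.frame(
      branch = branch, type = type, pos = pos, length = length,
      from = from, to = to, polarity = polarity, seq = seq, context = context,
      stringsAsFactors = FALSE)
  }

  # --- substitutions (simultaneous; IRb changes mirrored into IRa) ---
  sub_logs <- NULL
  if (brlen > 0) {
    elig <- which(state$region != "IRA")
    bases <- state$chars[elig]
    mu <- brlen * cfg$row_rate[bases]
    hit <- elig[runif(length(elig)) < mu]
    if (length(hit)) {
      to <- character(length(hit))
      fb <- state$chars[hit]
      for (b in unique(fb)) {
        sel <- fb == b
        targets <- setdiff(colnames(cfg$spectrum), b)
        to[sel] <- sample(targets, sum(sel), replace = TRUE,
                          prob = cfg$spectrum[b, targets])
      }
      primary <- data.frame(branch = branch, type = "substitution",
                            pos = hit, length = 1L, from = fb, to = to,
                            polarity = NA_character_, seq = NA_character_,
                            context = NA_character_)
      state$chars[hit] <- to
      irb_hit <- which(state$region[hit] == "IRB")
      if (length(irb_hit)) {
        pairs <- ir_pair_index(state$region)
        q <- pairs$a[match(hit[irb_hit], pairs$b)]
        ct <- unname(COMP[to[irb_hit]])
        mirrored <- data.frame(branch = branch, type = "substitution",
                               pos = q, length = 1L,
                               from = state$chars[q], to = ct,
                               polarity = NA_character_, seq = NA_character_,
                               context = NA_character_)
        state$chars[q] <- ct
        sub_logs <- rbind(primary, mirrored)
      } else {
        sub_logs <- primary
      }
    }
  }

  # --- indels (sequential; single-copy regions only) ---
  n_sc <- sum(state$region %in% c("LSC", "SSC"))
  n_ind <- rpois(1L, cfg$indel_sub_ratio * brlen * n_sc)
  for (e in seq_len(n_ind)) {
    pol <- if (runif(1L) < cfg$insertion_fraction) "insertion" else "deletion"
    L <- min(rgeom(1L, cfg$indel_len_p) + 1L, cfg$max_indel_len)
    slip <- runif(1L) < cfg$slip_fraction
    done <- FALSE
    if (slip && L == 1L) {
      runs <- homopolymer_runs(state$chars, state$region,
                               if (pol == "insertion") 3L else 4L)
      if (nrow(runs)) {
        i <- sample.int(nrow(runs), 1L)
        b <- runs$base[i]; s <- runs$start[i]
        if (pol == "insertion") {
          add_event("indel", s, 1L, polarity = "insertion", seq = b,
                    context = "homopolymer")
          state <- splice_insert(state, s, b, state$region[s])
        } else {
          add_event("indel", s, 1L, polarity = "deletion", seq = b,
                    context = "homopolymer")
          state <- splice_delete(state, s, 1L)
        }
        done <- TRUE
      }
    } else if (slip) {
      if (pol == "insertion") {
        iv <- sample_sc_interval(state$region, L)
        if (!is.null(iv)) {
          motif <- state$chars[iv[1L]:iv[2L]]
          add_event("indel", iv[2L], L, polarity = "insertion",
                    seq = paste(motif, collapse = ""), context = "tandem_repeat")
          state <- splice_insert(state, iv[2L], motif, state$region[iv[1L]])
          done <- TRUE
        }
      } else {
        js <- tandem_pair_starts(state$chars, state$region, L)
        if (length(js)) {
          j <- js[sample.int(length(js), 1L)]
          add_event("indel", j + L, L, polarity = "deletion",
                    seq = paste(state$chars[(j + L):(j + 2L * L - 1L)],
                                collapse = ""),
                    context = "tandem_repeat")
          state <- splice_delete(state, j + L, L)
          done <- TRUE
        } else {
          # no adjacent duplicate of this length: fall back to a
          # homopolymer deletion (still slip-seeded)
          runs <- homopolymer_runs(state$chars, state$region, 4L)
          if (nrow(runs)) {
            i <- sample.int(nrow(runs), 1L)
            add_event("indel", runs$start[i], 1L, polarity = "deletion",
                      seq = runs$base[i], context = "homopolymer")
            state <- splice_delete(state, runs$start[i], 1L)
            done <- TRUE
          }
        }
      }
    }
    if (!done) {
      # context-free event at a uniform single-copy position
      iv <- sample_sc_interval(state$region, L)
      if (is.null(iv)) next
      if (pol == "insertion") {
        ins <- sample(names(cfg$base_freq), L, replace = TRUE,
                      prob = cfg$base_freq)
        add_event("indel", iv[1L] - 1L, L, polarity = "insertion",
                  seq = paste(ins, collapse = ""), context = "none")
        state <- splice_insert(state, iv[1L] - 1L, ins, state$region[iv[1L]])
      } else {
        add_event("indel", iv[1L], L, polarity = "deletion",
                  seq = paste(state$chars[iv[1L]:iv[2L]], collapse = ""),
                  context = "none")
        state <- splice_delete(state, iv[1L], L)
      }
    }
  }
  indel_log <- if (length(events)) do.call(rbind, events) else NULL
  log <- rbind(sub_logs, indel_log)
  if (is.null(log)) {
    log <- data.frame(branch = character(0), type = character(0),
                      pos = integer(0), length = integer(0),
                      from = character(0), to = character(0),
                      polarity = character(0), seq = character(0),
                      context = character(0))
  }
  list(state = state, log = log)
}

#' Evolve a root plastome along a tree
#'
#' Walks the rooted tree in preorder; on each branch, substitutions are
#' drawn per site from the directional spectrum (changes in IRb are mirrored
#' into IRa, emulating plastid IR copy correction) and indel events are
#' placed in the single-copy regions, at slipped-strand contexts with the
#' configured fraction. Homology keys give the true multiple alignment of
#' the leaves; per-branch logs allow exact replay.
#'
#' @param root a `sim_root` from [simulate_root_plastome()].
#' @param cfg the same [sim_config()].
#' @return list of class `synthetic_truth`: `alignment`
#'   ([alignment_matrix()] of all leaves), `column_keys`, `logs` (one data
#'   frame per branch, preorder, named by child node), `leaf_records`,
#'   `leaf_structures` (true region coordinates per leaf), `root`, `cfg`.
#' @export
evolve_along_tree <- function(root, cfg) {
  phy <- cfg$tree
  if (length(phy$tip.label) < 2L) stop("tree must have at least 2 leaves")
  phy <- stats::reorder(phy, "cladewise")      # preorder edge traversal
  ntip <- length(phy$tip.label)
  rootnode <- ntip + 1L
  states <- vector("list", ntip + phy$Nnode)
  states[[rootnode]] <- root$state
  logs <- list()
  node_name <- function(i) if (i <= ntip) phy$tip.label[i] else paste0("node", i)
  for (ei in seq_len(nrow(phy$edge))) {
    par <- phy$edge[ei, 1L]; chi <- phy$edge[ei, 2L]
    res <- evolve_branch(states[[par]], phy$edge.length[ei], cfg,
                         branch = node_name(chi))
    states[[chi]] <- res$state
    logs[[node_name(chi)]] <- res$log
  }
  # ---- assemble the true alignment over the leaves ----
  leaf_states <- states[seq_len(ntip)]
  names(leaf_states) <- phy$tip.label
  all_keys <- sort(unique(unlist(lapply(leaf_states, `[[`, "keys"))))
  seqs <- vapply(leaf_states, function(st) {
    row <- rep("-", length(all_keys))
    row[match(st$keys, all_keys)] <- st$chars
    paste(row, collapse = "")
  }, character(1L))
  aln <- alignment_matrix(seqs)
  leaf_records <- lapply(phy$tip.label, function(tx)
    leaf_record_from_state(tx, leaf_states[[tx]], root$record))
  names(leaf_records) <- phy$tip.label
  leaf_structures <- lapply(leaf_states, function(st) {
    bl <- region_blocks(st$region)
    irlen <- bl$end[bl$label == "IRB"] - bl$start[bl$label == "IRB"] + 1L
    build_quadripartite(list(a0 = bl$start[bl$label == "IRA"] - 1L,
                             b0 = bl$start[bl$label == "IRB"] - 1L,
                             len = irlen),
                        length(st$chars))
  })
  out <- list(alignment = aln, column_keys = all_keys, logs = logs,
              leaf_records = leaf_records, leaf_structures = leaf_structures,
              root = root, cfg = cfg)
  class(out) <- "synthetic_truth"
  out
}

# map root annotation onto a leaf through the homology keys
leaf_record_from_state <- function(id, st, root_record) {
  feats <- list()
  for (f in root_record$features) {
    ex <- f$exons
    new <- list()
    for (i in seq_len(nrow(ex))) {
      idx <- which(st$keys > ex[i, 1L] & st$keys <= ex[i, 2L])
      if (!length(idx)) next
      new[[length(new) + 1L]] <- c(min(idx) - 1L, max(idx))
    }
    if (!length(new)) next
    feats[[length(feats) + 1L]] <-
      genome_feature(f$name, f$kind, f$strand, do.call(rbind, new),
                     is_duplicate = f$is_duplicate)
  }
  plastome_record(id, chars_to_seq(st$chars), feats)
}

#' Replay a branch event log
#'
#' Applies a per-branch log from [evolve_along_tree()] to a character vector
#' of residues, in recorded order. Substitutions assert the expected
#' ancestral base; deletions assert the removed sequence.
#'
#' @param chars character vector of single residues (parent state).
#' @param log one branch's event data frame.
#' @return the child character vector.
#' @export
replay_branch <- function(chars, log) {
  for (i in seq_len(nrow(log))) {
    ev <- log[i, ]
    if (ev$type == "substitution") {
      if (chars[ev$pos] != ev$from) {
        stop("replay mismatch at position ", ev$pos, ": expected ", ev$from,
             ", found ", chars[ev$pos])
      }
      chars[ev$pos] <- ev$to
    } else if (ev$polarity == "insertion") {
      ins <- seq_to_chars(ev$seq)
      chars <- append(chars, ins, after = ev$pos)
    } else {
      drop <- ev$pos:(ev$pos + ev$length - 1L)
      if (paste(chars[drop], collapse = "") != ev$seq) {
        stop("replay mismatch: deletion at ", ev$pos, " does not match log")
      }
      chars <- chars[-drop]
    }
  }
  chars
}

#' Replay a leaf from the root through the logged events
#'
#' @param truth a `synthetic_truth` object.
#' @param leaf tip label.
#' @return the reconstructed leaf sequence (single string).
#' @export
replay_leaf <- function(truth, leaf) {
  phy <- stats::reorder(truth$cfg$tree, "cladewise")
  ntip <- length(phy$tip.label)
  target <- match(leaf, phy$tip.label)
  if (is.na(target)) stop("unknown leaf '", leaf, "'")
  # path root -> leaf
  path <- integer(0)
  node <- target
  repeat {
    ei <- which(phy$edge[, 2L] == node)
    if (!length(ei)) break
    path <- c(ei, path)
    node <- phy$edge[ei, 1L]
  }
  chars <- truth$root$state$chars
  node_name <- function(i) if (i <= ntip) phy$tip.label[i] else paste0("node", i)
  for (ei in path) {
    chars <- replay_branch(chars, truth$logs[[node_name(phy$edge[ei, 2L])]])
  }
  chars_to_seq(chars)
}

#' Run a full simulation (root + evolution) from one configuration
#'
#' Convenience wrapper: seeds the RNG, builds the root plastome and evolves
#' it along the configured tree. Identical configurations give byte-identical
#' results.
#'
#' @param cfg a [sim_config()].
#' @return a `synthetic_truth` object (see [evolve_along_tree()]).
#' @export
simulate_plastome_set <- function(cfg) {
  root <- simulate_root_plastome(cfg)
  evolve_along_tree(root, cfg)
}

#' Export a simulation as plain-text fixture files
#'
#' Writes, under `out_dir`: one GenBank file per leaf, the true alignment as
#' aligned FASTA, a region annotation TSV on alignment columns (from the
#' first leaf's partition), per-leaf structure TSV, and the truth event logs
#' as TSV. All files are consumable by the package's readers.
#'
#' @param truth a `synthetic_truth` object.
#' @param out_dir output directory (created if needed).
#' @param reference leaf used for the region annotation (default first tip).
#' @return named list of written paths, invisibly.
#' @export
export_fixture <- function(truth, out_dir,
                           reference = truth$alignment$taxa[1L]) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (tx in names(truth$leaf_records)) {
    p <- file.path(out_dir, paste0(tx, ".gb"))
    write_genbank(truth$leaf_records[[tx]], p)
    paths[[paste0("genbank_", tx)]] <- p
  }
  paths$alignment <- file.path(out_dir, "alignment.fasta")
  write_alignment(truth$alignment, paths$alignment)

  ref_rec <- truth$leaf_records[[reference]]
  ref_str <- truth$leaf_structures[[reference]]
  part <- partition_genome(ref_rec, ref_str)
  rot <- ref_str$lsc$start
  nref <- ref_rec$length
  cmap <- truth$alignment$colmap[[reference]]
  col_of <- match(seq_len(nref), cmap)      # genome position -> column
  reg <- data.frame(
    name = part$name, klass = part$klass,
    start = col_of[mod_pos(part$start + rot, nref) + 1L],
    end = col_of[mod_pos(part$end - 1L + rot, nref) + 1L])
  paths$regions <- file.path(out_dir, "regions.tsv")
  write.table(reg, paths$regions, sep = "\t", quote = FALSE, row.names = FALSE)

  strs <- do.call(rbind, lapply(names(truth$leaf_structures), function(tx) {
    s <- truth$leaf_structures[[tx]]
    data.frame(leaf = tx,
               region = c("LSC", "IRB", "SSC", "IRA"),
               start = c(s$lsc$start, s$irb$start, s$ssc$start, s$ira$start) + 1L,
               length = c(s$lsc_length, s$ir_length, s$ssc_length, s$ir_length))
  }))
  paths$structures <- file.path(out_dir, "structures.tsv")
  write.table(strs, paths$structures, sep = "\t", quote = FALSE,
              row.names = FALSE)

  log <- do.call(rbind, truth$logs)
  paths$events <- file.path(out_dir, "events.tsv")
  write.table(log, paths$events, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
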