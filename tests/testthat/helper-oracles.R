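# Independent brute-force oracles and small fixture builders used across the
# suite. The oracles re-state the rules from first principles and never call
# the implementation they check.

BASES <- c("A", "C", "G", "T")

# --- substitution polarization, one column at a time -----------------------
# ing: character vector of ingroup bases; out: outgroup base.
# Returns list(kind = "event"/"skip", reason/anc/derived/carriers)
brute_polarize_column <- function(ing, out) {
  col <- c(ing, out)
  if (any(!col %in% BASES)) return(list(kind = "skip", reason = "gap_or_N"))
  states <- unique(ing)
  if (length(states) < 2L) return(list(kind = "skip", reason = "monomorphic"))
  if (length(states) > 2L) return(list(kind = "skip", reason = "multiallelic"))
  if (!out %in% states) return(list(kind = "skip", reason = "outgroup_mismatch"))
  derived <- setdiff(states, out)
  list(kind = "event", anc = out, derived = derived,
       carriers = which(ing == derived))
}

# --- 3-taxon site pattern classification ----------------------------------
brute_site_pattern <- function(x, y, z) {
  if (any(!c(x, y, z) %in% BASES)) return("skipped")
  if (x == y && y == z) return("identical")
  if (x != y && x != z && y != z) return("divergent")
  if (y == z) return("uniq1")
  if (x == z) return("uniq2")
  "uniq_out"
}

# --- parsimony-informative column ------------------------------------------
brute_informative <- function(col) {
  col <- col[col %in% BASES]
  tab <- table(col)
  sum(tab >= 2L) >= 2L
}

# chi-square(1) upper tail via the normal distribution, independent of pchisq
chisq1_tail <- function(x) 2 * pnorm(-sqrt(x))

# --- small simulation configurations ---------------------------------------
small_cfg <- function(seed = 7L, ...) {
  sim_config(seed = seed, lsc = 9000L, ssc = 2400L, ir = 2600L,
             homopolymer_every = 150L, tandem_every = 500L, ...)
}

quartet_tree <- function(tip = 0.002, internal = 0.002,
                         stem = 0.02, out = 0.03) {
  sprintf("(((A:%g,B:%g):%g,(C:%g,D:%g):%g):%g,OUT:%g);",
          tip, tip, internal, tip, tip, internal, stem, out)
}

# alignment from a character matrix (rows = taxa)
aln_from_matrix <- function(m, taxa = rownames(m)) {
  seqs <- apply(m, 1L, paste, collapse = "")
  names(seqs) <- taxa
  alignment_matrix(seqs)
}

# --- lightweight 3-taxon sequence simulator for rate tests -----------------
# Star tree with per-lineage substitution probabilities (Jukes-Cantor-like):
# each site mutates independently with probability mu to a uniform other base.
simulate_star_triplet <- function(L, mu1, mu2, mu_out) {
  root <- sample(BASES, L, replace = TRUE)
  mutate <- function(v, mu) {
    hit <- runif(L) < mu
    v[hit] <- vapply(v[hit], function(b) sample(setdiff(BASES, b), 1L),
                     character(1L))
    v
  }
  rbind(ing1 = mutate(root, mu1), ing2 = mutate(root, mu2),
        out = mutate(root, mu_out))
}

# rotate a record's circular origin by `off` bases (features must not span
# the cut point)
rotate_record <- function(record, off) {
  n <- record$length
  seq2 <- paste0(substr(record$sequence, off + 1L, n),
                 substr(record$sequence, 1L, off))
  feats <- lapply(record$features, function(f) {
    ex <- (f$exons - off) %% n
    if (any(ex[, 2L] == 0L)) ex[ex[, 2L] == 0L, 2L] <- n
    if (any(ex[, 2L] <= ex[, 1L])) stop("rotation splits feature ", f$name)
    genome_feature(f$name, f$kind, f$strand, ex, is_duplicate = f$is_duplicate)
  })
  plastome_record(record$id, seq2, feats, record$circular)
}
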