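test_that("substitution polarization matches exhaustive brute-force over all 4^5 ungapped columns", {
  grid <- expand.grid(i1 = BASES, i2 = BASES, i3 = BASES, i4 = BASES,
                      out = BASES, stringsAsFactors = FALSE)
  m <- t(as.matrix(grid))
  rownames(m) <- c("i1", "i2", "i3", "i4", "out")
  aln <- aln_from_matrix(m)
  res <- polarize_substitutions(aln, c("i1", "i2", "i3", "i4"), "out")

  brute <- lapply(seq_len(ncol(m)), function(col)
    brute_polarize_column(m[1:4, col], m[5, col]))
  brute_events <- which(vapply(brute, `[[`, character(1), "kind") == "event")
  expect_equal(res$events$column, brute_events)
  for (k in seq_along(brute_events)) {
    b <- brute[[brute_events[k]]]
    expect_equal(res$events$ancestral[k], unname(b$anc))
    expect_equal(res$events$derived[k], unname(b$derived))
    expect_equal(res$events$carriers[k],
                 paste(c("i1", "i2", "i3", "i4")[b$carriers], collapse = ","))
  }
  reasons <- vapply(brute, function(b)
    if (b$kind == "skip") b$reason else "event", character(1))
  expect_equal(unname(res$skipped["monomorphic"]), sum(reasons == "monomorphic"))
  expect_equal(unname(res$skipped["multiallelic"]), sum(reasons == "multiallelic"))
  expect_equal(unname(res$skipped["outgroup_mismatch"]),
               sum(reasons == "outgroup_mismatch"))
  expect_equal(unname(res$skipped["gap_or_N"]), 0L)
  # conservation: events + skips = columns
  expect_equal(nrow(res$events) + sum(res$skipped), aln$ncol)
})

test_that("gap and N columns are excluded from polarization and tallied", {
  m <- rbind(i1 = c("A", "A", "-"), i2 = c("C", "A", "A"),
             i3 = c("C", "N", "A"), i4 = c("C", "A", "A"),
             out = c("A", "A", "A"))
  res <- polarize_substitutions(aln_from_matrix(m), paste0("i", 1:4), "out")
  expect_equal(nrow(res$events), 1L)
  expect_equal(res$events$direction, "A>C")
  expect_equal(res$events$n_carriers, 3L)
  expect_equal(unname(res$skipped["gap_or_N"]), 2L)
  expect_error(polarize_substitutions(aln_from_matrix(m), "i1", "nope"),
               "not in alignment")
})

test_that("the directed spectrum sums, collapses and flags correctly", {
  empty <- substitution_spectrum(data.frame(direction = character(0),
                                            klass = character(0)))
  expect_equal(empty$n_events, 0L)
  expect_true(all(empty$directed$count == 0L))
  expect_true(is.na(empty$ts_tv_ratio))

  # a directional event set: counts sum to total; pairwise collapse gives
  # the 6 undirected types
  set.seed(9)
  overloaded <- empty$directed$direction[12]
  dirs <- sample(empty$directed$direction, 240, TRUE,
                 prob = c(rep(1, 11), 6))
  ev <- data.frame(direction = dirs,
                   klass = ts_or_tv(substr(dirs, 1, 1), substr(dirs, 3, 3)))
  sp <- substitution_spectrum(ev)
  expect_equal(sum(sp$directed$count), 240L)
  expect_equal(sp$n_transitions + sp$n_transversions, 240L)
  undirected <- tapply(sp$directed$count,
                       vapply(strsplit(sp$directed$direction, ">"),
                              function(p) paste(sort(p), collapse = ":"),
                              character(1)), sum)
  expect_length(undirected, 6L)
  expect_equal(sum(undirected), 240L)
  # the overloaded direction is flagged as over-represented
  over <- sp$directed$direction[sp$directed$status == "over"]
  expect_true(overloaded %in% over)

  # transitions only -> undefined ratio
  ev2 <- data.frame(direction = "A>G", klass = "transition")
  expect_true(is.na(substitution_spectrum(ev2)$ts_tv_ratio))
})

test_that("indel calling polarizes simple patterns by the outgroup", {
  taxa <- c("i1", "i2", "i3", "i4", "out")
  base <- strrep("ACGTT", 4)
  # one taxon with a 3-column gap, everyone else with sequence -> deletion
  m <- do.call(rbind, rep(list(seq_to_chars(base)), 5))
  rownames(m) <- taxa
  m["i2", 8:10] <- "-"
  res <- call_and_polarize_indels(aln_from_matrix(m), taxa[1:4], "out")
  expect_equal(nrow(res$events), 1L)
  expect_equal(res$events$polarity, "deletion")
  expect_equal(res$events$carriers, "i2")
  expect_equal(res$events$length, 3L)
  expect_equal(res$events$seq, "GTT")

  # outgroup + three ingroup gapped, one ingroup with sequence -> insertion
  m2 <- do.call(rbind, rep(list(seq_to_chars(base)), 5))
  rownames(m2) <- taxa
  m2[c("i2", "i3", "i4", "out"), 6:7] <- "-"
  res2 <- call_and_polarize_indels(aln_from_matrix(m2), taxa[1:4], "out")
  expect_equal(res2$events$polarity, "insertion")
  expect_equal(res2$events$carriers, "i1")

  # partially overlapping runs are unpolarizable
  m3 <- do.call(rbind, rep(list(seq_to_chars(base)), 5))
  rownames(m3) <- taxa
  m3["i1", 6:9] <- "-"
  m3["i2", 8:11] <- "-"
  res3 <- call_and_polarize_indels(aln_from_matrix(m3), taxa[1:4], "out")
  expect_equal(nrow(res3$events), 0L)
  expect_equal(res3$n_unpolarizable, 2L)

  # a gap run shared by the whole ingroup reflects the outgroup lineage
  m4 <- do.call(rbind, rep(list(seq_to_chars(base)), 5))
  rownames(m4) <- taxa
  m4[taxa[1:4], 12:13] <- "-"
  res4 <- call_and_polarize_indels(aln_from_matrix(m4), taxa[1:4], "out")
  expect_equal(nrow(res4$events), 0L)
  expect_equal(res4$n_ingroup_shared, 1L)

  # no gaps at all -> empty call set
  m5 <- do.call(rbind, rep(list(seq_to_chars(base)), 5))
  rownames(m5) <- taxa
  res5 <- call_and_polarize_indels(aln_from_matrix(m5), taxa[1:4], "out")
  expect_equal(nrow(res5$events), 0L)
})

test_that("indel context classification follows the homopolymer and tandem definitions", {
  expect_equal(classify_indel_context("A", "CCAAA", "TGG"), "homopolymer")
  expect_equal(classify_indel_context("A", "CCC", "AAAG"), "homopolymer")
  expect_equal(classify_indel_context("A", "CC", "GG"), "none")
  expect_equal(classify_indel_context("ATG", "CCATG", "TTT"), "tandem_repeat")
  expect_equal(classify_indel_context("ATG", "CCCCC", "ATGTT"), "tandem_repeat")
  expect_equal(classify_indel_context("ATG", "CCCCC", "TTTTT"), "none")
  # precedence: a 1-bp event in a long run is homopolymer even though the
  # tandem test would also fire
  expect_equal(classify_indel_context("A", "GAAA", "AAAG"), "homopolymer")
  # multi-base single-base-composition event adjacent to its copy: tandem
  # is checked first for length > 1
  expect_equal(classify_indel_context("AA", "GGAA", "CC"), "tandem_repeat")
  # threshold: total run length must reach homopolymer_min
  expect_equal(classify_indel_context("A", "GA", "AG"), "none")
  expect_equal(classify_indel_context("A", "GA", "AG", homopolymer_min = 3),
               "homopolymer")
  expect_warning(classify_indel_context("ACGT", "AC", "G"), "flank")
})

test_that("called events on a single mutated branch match the simulator truth log", {
  cfg <- small_cfg(seed = 57L,
                   tree = "((A:0.0012,B:0.0):0.0,OUT:0.0);")
  truth <- simulate_plastome_set(cfg)
  log <- truth$logs[["A"]]
  aln <- truth$alignment

  subs <- polarize_substitutions(aln, c("A", "B"), "OUT")
  tr_subs <- log[log$type == "substitution", ]
  # every logged substitution is recovered with its direction (positions on
  # branch A; B and OUT retain the ancestral state)
  expect_equal(nrow(subs$events), nrow(tr_subs))
  expect_setequal(paste(subs$events$ancestral, subs$events$derived),
                  paste(tr_subs$from, tr_subs$to))
  expect_true(all(subs$events$carriers == "A"))

  ind <- call_and_polarize_indels(aln, c("A", "B"), "OUT")
  tr_ind <- log[log$type == "indel", ]
  expect_equal(nrow(ind$events), nrow(tr_ind))
  expect_true(all(ind$events$carriers == "A"))
  expect_setequal(paste(ind$events$polarity, ind$events$length, ind$events$seq),
                  paste(tr_ind$polarity, tr_ind$length, tr_ind$seq))

  # planted repeat contexts are recovered by the classifier
  ind <- classify_indel_events(aln, ind, "OUT")
  called <- ind$events[order(ind$events$col_start), ]
  planted_repeat <- sum(tr_ind$context != "none")
  expect_gte(ind$n_repeat_associated, planted_repeat)
})

test_that("indel length spectrum summarises per polarity", {
  ev <- data.frame(length = c(1L, 1L, 3L, 2L, 1L),
                   polarity = c("insertion", "insertion", "insertion",
                                "deletion", "deletion"))
  sp <- indel_length_spectrum(ev)
  expect_equal(sp$insertion$n, 3L)
  expect_equal(sp$insertion$frac_1bp, 2 / 3)
  expect_equal(sp$insertion$max, 3L)
  expect_equal(sp$deletion$frac_1bp, 1 / 2)
  expect_equal(sp$deletion$max, 2L)
  empty <- indel_length_spectrum(ev[0, ])
  expect_equal(empty$insertion$n, 0L)
  expect_true(is.na(empty$deletion$max))
})
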