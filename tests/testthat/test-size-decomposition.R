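toy_partition_record <- function() {
  # 10 kb toy with a planted 1 kb "IR" pair so detection works:
  # LSC 6000 + IR 1200 + SSC 1600 + IR' 1200
  set.seed(77)
  piece <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")
  lsc <- piece(6000); ir <- piece(1200); ssc <- piece(1600)
  feats <- list(
    genome_feature("gA", "protein_coding", "+", rbind(c(500L, 1400L))),
    genome_feature("gB", "protein_coding", "-",
                   rbind(c(2000L, 2600L), c(2850L, 3400L))),  # 250 bp intron
    genome_feature("gS", "tRNA", "+", rbind(c(7500L, 7580L))))
  rec <- plastome_record("toy", paste0(lsc, ir, ssc, revcomp(ir)), feats)
  st <- detect_inverted_repeats(rec, 1000L)
  list(rec = rec, st = st)
}

test_that("genome partition tiles the one-IR representation exactly", {
  toy <- toy_partition_record()
  part <- partition_genome(toy$rec, toy$st)
  M <- attr(part, "total_length")
  expect_equal(M, 6000L + 1200L + 1600L)
  expect_equal(sum(part$length), M)                 # conservation
  # single-exon elements have length == extent; multi-exon gene elements sum
  # their exons while the extent spans the intron
  single <- part$klass != "gene" | !part$name %in% "gB"
  expect_equal(part$length[single], (part$end - part$start)[single])

  genes <- part[part$klass == "gene", ]
  expect_setequal(genes$name, c("gA", "gB", "gS"))
  expect_equal(genes$length[genes$name == "gA"], 900L)
  expect_equal(genes$length[genes$name == "gB"], 600L + 550L)
  intr <- part[part$klass == "intron", ]
  expect_equal(intr$name, "gB.intron1")
  expect_equal(intr$length, 250L)                   # forced by exon gap
  # IGS are named by their flanking genes
  expect_true("gA-gB" %in% part$name[part$klass == "IGS"])
})

test_that("partition of simulated leaves conserves total length", {
  cfg <- small_cfg(seed = 61L, tree = quartet_tree())
  truth <- simulate_plastome_set(cfg)
  for (tx in c("A", "D")) {
    rec <- truth$leaf_records[[tx]]
    st <- detect_inverted_repeats(rec, 1000L)
    part <- partition_genome(rec, st)
    expect_equal(sum(part$length), attr(part, "total_length"))
    expect_equal(attr(part, "total_length"),
                 st$lsc_length + st$ir_length + st$ssc_length)
  }
})

test_that("partition comparison matches by name, is antisymmetric, and flags large deltas", {
  toy <- toy_partition_record()
  part <- partition_genome(toy$rec, toy$st)
  same <- compare_partitions(part, part)
  expect_true(all(same$matched$delta == 0L))
  expect_equal(same$whole_delta, 0L)
  expect_equal(nrow(same$large), 0L)
  # count decomposition holds by construction
  expect_equal(sum(same$counts[same$counts$scope == "all",
                               c("larger_in_a", "larger_in_b", "equal")]),
               nrow(same$matched))

  # lengthen one IGS by 150 bp in a modified copy
  rec2 <- toy$rec
  ins_at <- 1700L   # inside the gA-gB spacer
  seq2 <- paste0(substr(rec2$sequence, 1, ins_at),
                 strrep("ACGTT", 30),
                 substr(rec2$sequence, ins_at + 1, rec2$length))
  feats2 <- lapply(rec2$features, function(f) {
    ex <- f$exons
    ex[ex >= ins_at] <- ex[ex >= ins_at] + 150L
    genome_feature(f$name, f$kind, f$strand, ex)
  })
  rec2 <- plastome_record("toy2", seq2, feats2)
  st2 <- detect_inverted_repeats(rec2, 1000L)
  part2 <- partition_genome(rec2, st2)
  cmp <- compare_partitions(part2, part, large_threshold = 100L)
  expect_equal(cmp$whole_delta, 150L)
  expect_equal(nrow(cmp$large), 1L)
  expect_equal(cmp$large$delta, 150L)
  expect_true(grepl("gA", cmp$large$name) && grepl("gB", cmp$large$name))

  # antisymmetry
  cmp_rev <- compare_partitions(part, part2, large_threshold = 100L)
  expect_equal(cmp_rev$whole_delta, -cmp$whole_delta)
  m1 <- cmp$matched[order(cmp$matched$name), ]
  m2 <- cmp_rev$matched[order(cmp_rev$matched$name), ]
  expect_equal(m1$delta, -m2$delta)
})

test_that("region size deltas work on structures and named vectors", {
  toy <- toy_partition_record()
  d <- region_size_deltas(toy$st, toy$st)
  expect_true(all(d$delta == 0))
  d2 <- region_size_deltas(c(size = 162796, lsc = 91127, ssc = 20371, ir = 25649),
                           c(size = 160301, lsc = 88816, ssc = 20269, ir = 25608))
  expect_equal(d2$delta[d2$region == "size"], 2495)
  expect_equal(d2$delta[d2$region == "lsc"], 2311)
})

test_that("large-indel accounting sums signed lengths over the threshold", {
  ev <- data.frame(length = c(150L, 200L, 40L, 120L),
                   polarity = c("insertion", "insertion", "insertion", "deletion"),
                   carriers = c("A", "A", "A", "B"))
  acc <- large_indel_accounting(ev, "A", total_delta = 400L, min_len = 100L)
  expect_equal(acc$n_large, 3L)
  # +150 +200 (insertions in A) +120 (deletion in B lengthens A relatively)
  expect_equal(acc$signed_sum, 470L)
  acc2 <- large_indel_accounting(ev[1:2, ], "A", total_delta = 400L)
  expect_equal(acc2$fraction, 350 / 400)
  none <- large_indel_accounting(ev[3, , drop = FALSE], "A", total_delta = 400L)
  expect_equal(none$n_large, 0L)
  expect_equal(none$fraction, 0)
  undef <- large_indel_accounting(ev, "A", total_delta = 0L)
  expect_true(is.na(undef$fraction))
})
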