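test_that("p-distance follows the pairwise-deletion definition", {
  aln <- alignment_matrix(c(a = "AAAA", b = "AAAT"))
  expect_equal(p_distance(aln, "a", "b"), 0.25)
  expect_equal(p_distance(aln, "a", "a"), 0)

  # gap and N columns are excluded from the comparison
  expect_error(alignment_matrix(c(a = "AXCG", b = "ATCG")))  # bad alphabet
  aln2 <- alignment_matrix(c(a = "A-CGNT", b = "ATCGAA"))
  expect_equal(p_distance(aln2, "a", "b"), 1 / 4)  # cols 1,3,4,6 compared

  expect_error(p_distance(alignment_matrix(c(a = "N-A", b = "AN-")), "a", "b"),
               "undefined")
})

test_that("p-distance is symmetric, bounded, and zero iff compared columns agree", {
  set.seed(101)
  for (rep in 1:10) {
    m <- matrix(sample(c("A", "C", "G", "T", "N", "-"), 200, TRUE,
                       prob = c(rep(0.22, 4), 0.06, 0.06)),
                nrow = 2, dimnames = list(c("a", "b"), NULL))
    m[, 1] <- c("A", "A")   # guarantee a compared column
    aln <- aln_from_matrix(m)
    d1 <- p_distance(aln, "a", "b"); d2 <- p_distance(aln, "b", "a")
    expect_identical(d1, d2)
    expect_gte(d1, 0); expect_lte(d1, 1)
    ok <- is_base(m[1, ]) & is_base(m[2, ])
    expect_equal(d1 == 0, all(m[1, ok] == m[2, ok]))
  }
})

test_that("overall divergence summarises all pairs and matches simulation expectation", {
  aln <- alignment_matrix(c(a = "AAAA", b = "AAAT"))
  od <- overall_divergence(aln)
  expect_equal(od$mean, od$min)
  expect_equal(od$mean, od$max)
  expect_error(overall_divergence(aln, "a"), "two taxa")

  # substitution-only simulation: mean pairwise distance approximates the
  # mean tree-path length within 3 binomial SE
  cfg <- small_cfg(seed = 31L, indel_sub_ratio = 0,
                   tree = quartet_tree(tip = 0.004, internal = 0.004))
  truth <- simulate_plastome_set(cfg)
  od2 <- overall_divergence(truth$alignment, c("A", "B", "C", "D"))
  paths <- c(0.008, 0.016, 0.016, 0.016, 0.016, 0.008)   # 6 pair path lengths
  expectation <- mean(paths)
  n <- truth$alignment$ncol
  se <- sqrt(expectation * (1 - expectation) / n)
  expect_lt(abs(od2$mean - expectation), 3 * se + 1e-4)
})

test_that("region variability counts substitution sites and indel events per region", {
  # 300-column region: 6 substitution sites + one 3-column gap run -> 2.33%
  set.seed(5)
  base <- sample(c("A", "C", "G", "T"), 300, TRUE)
  m <- rbind(t1 = base, t2 = base, t3 = base)
  m[2, c(10, 50, 90, 130, 170, 210)] <- "A"
  m[1, c(10, 50, 90, 130, 170, 210)] <- "G"
  m[3, 240:242] <- "-"
  aln <- aln_from_matrix(m)
  regions <- data.frame(name = "r1", klass = "IGS", start = 1, end = 300)
  rv <- region_variability(aln, regions, min_aligned_length = 200)
  expect_equal(rv$n_substitution_sites, 6L)
  expect_equal(rv$n_indel_events, 1L)
  expect_equal(rv$percent_variable, 100 * 7 / 300)

  # identical region -> 0%; short regions are filtered; overlap errors
  m2 <- rbind(t1 = base, t2 = base)
  aln2 <- aln_from_matrix(m2)
  rv2 <- region_variability(aln2, regions, min_aligned_length = 200)
  expect_equal(rv2$percent_variable, 0)
  expect_equal(nrow(region_variability(aln2, regions,
                                       min_aligned_length = 300)), 0L)
  expect_error(region_variability(aln2, data.frame(
    name = c("a", "b"), klass = "IGS", start = c(1, 100), end = c(150, 300))),
    "overlapping")

  # identical gap run in several taxa is one event; different extents differ
  m3 <- rbind(t1 = base, t2 = base, t3 = base, t4 = base)
  m3[1, 20:25] <- "-"; m3[2, 20:25] <- "-"   # shared run: 1 event
  m3[3, 40:47] <- "-"; m3[4, 40:44] <- "-"   # overlapping, distinct: 2 events
  rv3 <- region_variability(aln_from_matrix(m3), regions,
                            min_aligned_length = 200)
  expect_equal(rv3$n_indel_events, 3L)
})

test_that("variability of concatenated disjoint regions is additive in counts", {
  cfg <- small_cfg(seed = 37L, tree = quartet_tree())
  truth <- simulate_plastome_set(cfg)
  aln <- truth$alignment
  regions <- data.frame(name = c("x", "y"), klass = "IGS",
                        start = c(1001, 3001), end = c(3000, 5000))
  merged <- data.frame(name = "xy", klass = "IGS", start = 1001, end = 5000)
  a <- region_variability(aln, regions, min_aligned_length = 100)
  b <- region_variability(aln, merged, min_aligned_length = 100)
  expect_equal(sum(a$n_substitution_sites), b$n_substitution_sites)
  expect_equal(sum(a$n_indel_events), b$n_indel_events)
})

test_that("sliding identity profiles match planted differences", {
  base <- strrep("ACGT", 50)
  aln <- alignment_matrix(c(ref = base, other = base))
  prof <- sliding_identity(aln, "ref", window = 100, step = 25)
  expect_true(all(prof$identity == 100))

  v <- seq_to_chars(base)
  v[31:40] <- ifelse(v[31:40] == "A", "C", "A")   # 10 mismatches in 31..40
  aln2 <- alignment_matrix(c(ref = base, other = paste(v, collapse = "")))
  prof2 <- sliding_identity(aln2, "ref", window = 100, step = 100)
  expect_equal(prof2$identity[1], 90)
  expect_equal(prof2$identity[2], 100)

  expect_warning(sliding_identity(aln2, "ref", window = 500, step = 25),
                 "truncated")
  expect_error(sliding_identity(aln2, "ref", window = 10, step = 20))

  # simulated quartet: profile mean approximates 100 * (1 - p-distance)
  cfg <- small_cfg(seed = 41L, indel_sub_ratio = 0, tree = quartet_tree())
  truth <- simulate_plastome_set(cfg)
  prof3 <- sliding_identity(truth$alignment, "A", window = 500, step = 500)
  pd <- p_distance(truth$alignment, "A", "B")
  mb <- mean(prof3$identity[prof3$taxon == "B"], na.rm = TRUE)
  expect_lt(abs(mb - 100 * (1 - pd)), 0.2)
})

test_that("parsimony-informative site counts match exhaustive enumeration", {
  # all 256 single-column patterns over 4 taxa
  grid <- expand.grid(a = BASES, b = BASES, c = BASES, d = BASES,
                      stringsAsFactors = FALSE)
  m <- t(as.matrix(grid))
  rownames(m) <- c("a", "b", "c", "d")
  aln <- aln_from_matrix(m)
  brute <- sum(apply(m, 2, brute_informative))
  expect_equal(count_informative_sites(aln), brute)

  # definitional cases
  expect_equal(count_informative_sites(
    alignment_matrix(c(a = "A", b = "A", c = "T", d = "T"))), 1L)
  expect_equal(count_informative_sites(
    alignment_matrix(c(a = "A", b = "A", c = "A", d = "T"))), 0L)
  expect_equal(count_informative_sites(
    alignment_matrix(c(a = "ACG", b = "ACG", c = "ACG", d = "ACG"))), 0L)
  expect_error(count_informative_sites(
    alignment_matrix(c(a = "A", b = "A", c = "T"))), "4 taxa")

  # gaps and N are not states
  expect_equal(count_informative_sites(
    alignment_matrix(c(a = "AA", b = "AA", c = "-A", d = "-A"))), 0L)
})
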