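test_that("a minimal hand-written GenBank file parses with strands, joins and coordinates", {
  txt <- c(
    "LOCUS       toy0001           60 bp    DNA     circular PLN 01-JAN-2000",
    "DEFINITION  toy record.",
    "FEATURES             Location/Qualifiers",
    "     source          1..60",
    "     CDS             5..16",
    '                     /gene="psbA"',
    "     tRNA            complement(join(20..25,31..36))",
    '                     /gene="trnH-GUG"',
    "ORIGIN",
    paste("        1", paste(rep("acgtacgtac", 6), collapse = " ")),
    "//")
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(txt, path)
  rec <- read_genbank(path)
  expect_equal(rec$id, "toy0001")
  expect_equal(rec$length, 60L)
  expect_true(rec$circular)
  expect_length(rec$features, 2L)
  f1 <- rec$features[[1]]
  expect_equal(f1$name, "psbA")
  expect_equal(f1$kind, "protein_coding")
  expect_equal(f1$strand, "+")
  expect_equal(unname(f1$exons), matrix(c(4L, 16L), 1L))
  f2 <- rec$features[[2]]
  expect_equal(f2$strand, "-")
  expect_equal(f2$kind, "tRNA")
  expect_equal(unname(f2$exons), rbind(c(19L, 25L), c(30L, 36L)))
})

test_that("malformed GenBank input fails with informative errors", {
  bad <- c(
    "LOCUS       bad               10 bp    DNA     linear PLN 01-JAN-2000",
    "FEATURES             Location/Qualifiers",
    "     CDS             5..x2",
    '                     /gene="g"',
    "ORIGIN",
    "        1 acgtacgtac",
    "//")
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(bad, path)
  expect_error(read_genbank(path), "line 3")

  noseq <- c(
    "LOCUS       bad               10 bp    DNA     linear PLN 01-JAN-2000",
    "FEATURES             Location/Qualifiers",
    "//")
  writeLines(noseq, path)
  expect_error(read_genbank(path), "without sequence|ORIGIN")
})

test_that("records round-trip through write_genbank and read_genbank losslessly", {
  cfg <- small_cfg(seed = 11L)
  root <- simulate_root_plastome(cfg)
  rec <- root$record
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(rec, path)
  back <- read_genbank(path)
  expect_equal(back$sequence, rec$sequence)
  expect_equal(back$length, rec$length)
  expect_length(back$features, length(rec$features))
  for (i in seq_along(rec$features)) {
    expect_equal(back$features[[i]]$name, rec$features[[i]]$name)
    expect_equal(back$features[[i]]$kind, rec$features[[i]]$kind)
    expect_equal(back$features[[i]]$strand, rec$features[[i]]$strand)
    expect_equal(back$features[[i]]$exons, rec$features[[i]]$exons)
  }
  # a record with no features still writes a valid, re-readable file
  bare <- plastome_record("bare", "ACGTACGTACGT", circular = FALSE)
  write_genbank(bare, path)
  back2 <- read_genbank(path)
  expect_equal(back2$sequence, bare$sequence)
  expect_length(back2$features, 0L)
})

test_that("FASTA with feature-table sidecar round-trips", {
  cfg <- small_cfg(seed = 3L)
  rec <- simulate_root_plastome(cfg)$record
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_fasta_record(rec, fa, tsv)
  back <- read_fasta_record(fa, tsv)
  expect_equal(back$sequence, rec$sequence)
  expect_length(back$features, length(rec$features))
  i <- length(rec$features)
  expect_equal(back$features[[i]]$exons, rec$features[[i]]$exons)
})

test_that("sequence validation rejects ambiguity characters other than N", {
  expect_error(plastome_record("x", "ACGTRY"), "outside")
  expect_silent(plastome_record("x", "ACGTN"))
})

test_that("alignment reader builds per-taxon coordinate maps and validates input", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">t1", "AC-GT", ">t2", "ACTGT"), fa)
  aln <- read_alignment(fa)
  expect_equal(aln$ncol, 5L)
  expect_equal(aln$colmap$t1, c(1L, 2L, NA, 3L, 4L))
  expect_equal(aln$colmap$t2, 1:5)
  expect_equal(aln_row_seq(aln, "t1"), "ACGT")

  writeLines(c(">t1", "ACGT", ">t2", "ACG"), fa)
  expect_error(read_alignment(fa), "ragged")
  writeLines(c(">t1", "ACGT", ">t1", "ACGT"), fa)
  expect_error(read_alignment(fa), "duplicate")

  # identical ungapped pair: identity column maps
  aln2 <- alignment_matrix(c(a = "ACGT", b = "ACGT"))
  expect_equal(aln2$colmap$a, aln2$colmap$b)

  # removing gaps from any row reproduces the input sequence
  cfg <- small_cfg(seed = 5L, tree = quartet_tree())
  truth <- simulate_plastome_set(cfg)
  for (tx in truth$alignment$taxa) {
    expect_identical(aln_row_seq(truth$alignment, tx),
                     truth$leaf_records[[tx]]$sequence)
  }
  # simulator truth: the column maps agree with the leaf sequences
  ref <- truth$alignment$taxa[1]
  cmap <- truth$alignment$colmap[[ref]]
  cols <- which(!is.na(cmap))[1:50]
  expect_equal(truth$alignment$mat[ref, cols],
               seq_to_chars(substr(truth$leaf_records[[ref]]$sequence, 1, 50)))
})

test_that("gene inventory counts IR duplicates and is rotation invariant", {
  cfg <- small_cfg(seed = 11L)
  root <- simulate_root_plastome(cfg)
  planted_dups <- sum(vapply(root$record$features, `[[`, logical(1),
                             "is_duplicate"))
  expect_gt(planted_dups, 0L)
  inv <- gene_inventory(root$record, root$structure)
  expect_equal(inv$duplicated_in_IR, planted_dups)
  expect_equal(inv$total_genes, inv$unique_genes + inv$duplicated_in_IR)

  rot <- rotate_record(root$record, 10L)
  st2 <- detect_inverted_repeats(rot, 1000L)
  inv2 <- gene_inventory(rot, st2)
  expect_equal(inv2$total_genes, inv$total_genes)
  expect_equal(inv2$unique_genes, inv$unique_genes)
  expect_equal(inv2$duplicated_in_IR, inv$duplicated_in_IR)

  # no IR-resident genes -> nothing duplicated
  toy <- plastome_record("t", strrep("ACGT", 2500),
                         list(genome_feature("g1", "protein_coding", "+",
                                             rbind(c(10L, 100L)))))
  fake <- build_quadripartite(list(a0 = 5000L, b0 = 7000L, len = 1000L), 10000L)
  expect_equal(gene_inventory(toy, fake)$duplicated_in_IR, 0L)
})

test_that("gc_content ignores N and matches hand computation", {
  expect_equal(gc_content(plastome_record("x", "GGCCAATTNN")), 0.5)
  expect_equal(gc_content(plastome_record("x", "GCGC")), 1)
})
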