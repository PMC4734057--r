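test_that("concatenation pads unsampled taxa with '?' and records partitions", {
  a <- alignment(c(sp1 = "AAA", sp2 = "CCC"), source_name = "locus1")
  b <- alignment(c(sp2 = "GG", sp3 = "TT"), source_name = "locus2")
  sm <- concatenate(list(a, b))
  expect_identical(sm$alignment$taxa, c("sp1", "sp2", "sp3"))
  expect_identical(sm$alignment$seqs, c("AAA??", "CCCGG", "???TT"))
  expect_identical(vapply(sm$partitions, `[[`, character(1), "name"),
                   c("locus1", "locus2"))
  expect_identical(sm$partitions[[1]]$sites, 1:3)
  expect_identical(sm$partitions[[2]]$sites, 4:5)
})

test_that("concatenating one alignment or identical taxon sets degenerates cleanly", {
  a <- alignment(c(t1 = "ACGT", t2 = "ACGA"), source_name = "only")
  sm <- concatenate(list(a))
  expect_identical(sm$alignment$seqs, a$seqs)
  expect_identical(sm$partitions[[1]]$sites, 1:4)

  b <- alignment(c(t1 = "GG", t2 = "TT"), source_name = "b")
  sm2 <- concatenate(list(a, b))
  expect_identical(sm2$alignment$seqs, c("ACGTGG", "ACGATT"))
  expect_false(any(grepl("?", sm2$alignment$seqs, fixed = TRUE)))
})

test_that("duplicate source names get numeric suffixes with a warning", {
  a <- alignment(c(t1 = "AA"), source_name = "locus")
  b <- alignment(c(t1 = "CC"), source_name = "locus")
  expect_message(sm <- concatenate(list(a, b)), "duplicate source")
  expect_identical(vapply(sm$partitions, `[[`, character(1), "name"),
                   c("locus_1", "locus_2"))
  expect_error(concatenate(list()), "no alignments")
})

test_that("concatenation conserves residues and tiles 1..L", {
  set.seed(17)
  for (rep in 1:15) {
    alns <- sim_alignment_set(n_loci = sample(2:6, 1), n_taxa = 6,
                              sites_range = c(5L, 40L))
    sm <- concatenate(alns)
    L <- n_sites(sm$alignment)
    expect_equal(L, sum(vapply(alns, n_sites, integer(1))))
    # partitions tile 1..L exactly, no gaps or overlaps
    tiled <- unlist(lapply(sm$partitions, `[[`, "sites"))
    expect_identical(tiled, seq_len(L))
    # every input residue lands at its partition-mapped coordinate
    for (i in seq_along(alns)) {
      sub <- split_alignment(sm$alignment, sm$partitions[i],
                             remove_empty = TRUE)[[1]]
      expect_identical(aln_as_map(sub), aln_as_map(alns[[i]]))
    }
    # fill cells are the (absent taxon, locus) slots; the rest are input cells
    n_union <- n_taxa(sm$alignment)
    n_fill <- sum(vapply(alns, function(a) {
      (n_union - n_taxa(a)) * n_sites(a)
    }, numeric(1)))
    in_cells <- sum(vapply(alns, function(a) n_taxa(a) * n_sites(a),
                           integer(1)))
    expect_equal(n_taxa(sm$alignment) * L - n_fill, in_cells)
    # cross-module: supermatrix undetermined = per-locus undetermined + fill
    su <- summarize_alignment(sm$alignment, "dna")$undetermined_count
    per_locus <- sum(vapply(alns, function(a) {
      summarize_alignment(a, "dna")$undetermined_count
    }, integer(1)))
    expect_equal(su, per_locus + n_fill)
  }
})

test_that("concatenation is associative in residue content", {
  set.seed(19)
  alns <- sim_alignment_set(n_loci = 3, n_taxa = 5)
  whole <- concatenate(alns)
  ab <- concatenate(alns[1:2])$alignment
  ab$source_name <- "ab"
  nested <- concatenate(list(ab, alns[[3]]))
  expect_identical(aln_as_map(nested$alignment), aln_as_map(whole$alignment))
})

test_that("partition files round-trip through the stated dialect", {
  p <- list(partition("p1", 1:3), partition("p2", 4:5))
  expect_identical(write_partition_file(p), "p1 = 1-3\np2 = 4-5\n")
  expect_identical(write_partition_file(list()), "")
  expect_identical(write_partition_file(list(partition("x", 1:10))),
                   "x = 1-10\n")
  back <- parse_partition_file(write_partition_file(p))
  expect_identical(lapply(back, unclass), lapply(p, unclass))
})

test_that("partition parsing handles strides, prefixes, commas and errors", {
  expect_identical(parse_partition_file("p1 = 1-3\np2 = 4-5")[[2]]$sites, 4:5)
  expect_identical(parse_partition_file("codon1 = 1-6\\3")[[1]]$sites,
                   c(1L, 4L))
  got <- parse_partition_file("DNA, gene1 = 1-100")
  expect_identical(got[[1]]$name, "gene1")
  expect_identical(got[[1]]$sites, 1:100)
  expect_identical(parse_partition_file("m = 1-3,7-8,12")[[1]]$sites,
                   c(1:3, 7:8, 12L))
  expect_error(parse_partition_file("p1 = 1-3\nbroken line"),
               "line 2")
  expect_error(parse_partition_file("p1 = 9-3"), "backwards")
  expect_message(parse_partition_file("p1 = 1-5\np2 = 4-8"), "overlap")
})

test_that("splitting extracts sites and can invert concatenation", {
  aln <- alignment(c(t1 = "ACGT"))
  piece <- split_alignment(aln, list(partition("px", c(1L, 4L))))[[1]]
  expect_identical(piece$seqs, "AT")
  expect_identical(piece$source_name, "px")

  whole <- split_alignment(aln, list(partition("all", 1:4)))[[1]]
  expect_identical(whole$seqs, aln$seqs)

  expect_error(split_alignment(aln, list(partition("far", 9L))),
               "'far'.*site 9")

  set.seed(29)
  alns <- sim_alignment_set(n_loci = 4, n_taxa = 7, occupancy = 0.6)
  sm <- concatenate(alns)
  pieces <- split_alignment(sm$alignment, sm$partitions, remove_empty = TRUE)
  expect_length(pieces, length(alns))
  for (i in seq_along(alns)) {
    expect_identical(aln_as_map(pieces[[i]]), aln_as_map(alns[[i]]))
  }
})

test_that("taxon removal preserves order and tolerates absent names", {
  aln <- alignment(c(t1 = "AA", t2 = "CC", t3 = "GG"))
  out <- remove_taxa(aln, "t2")
  expect_identical(out$taxa, c("t1", "t3"))
  expect_identical(remove_taxa(aln, character(0)), aln)
  expect_message(out2 <- remove_taxa(aln, "tX"), "not found")
  expect_identical(out2$taxa, aln$taxa)
  expect_error(remove_taxa(aln, c("t1", "t2", "t3")), "empty alignment")
})

test_that("replicates are seeded, sampled without replacement, RNG-clean", {
  set.seed(43)
  alns <- sim_alignment_set(n_loci = 4, n_taxa = 5)
  r1 <- make_replicates(alns, 2, 2, seed = 7)
  r2 <- make_replicates(alns, 2, 2, seed = 7)
  expect_identical(
    lapply(r1, function(s) write_alignment(s$alignment, "fasta")),
    lapply(r2, function(s) write_alignment(s$alignment, "fasta")))
  expect_length(r1, 2L)

  # k = all loci: every replicate holds each locus exactly once
  rall <- make_replicates(alns, 3, 4, seed = 1)
  locus_names <- vapply(alns, `[[`, character(1), "source_name")
  for (s in rall) {
    expect_setequal(vapply(s$partitions, `[[`, character(1), "name"),
                    locus_names)
  }

  expect_error(make_replicates(alns, 1, 5, seed = 1), "exceeds")

  # the caller's RNG stream is untouched
  set.seed(101); before <- .Random.seed
  invisible(make_replicates(alns, 1, 2, seed = 99))
  expect_identical(.Random.seed, before)
})
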