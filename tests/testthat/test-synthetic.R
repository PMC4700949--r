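# Synthetic post-WGD family generator: ground truth, determinism, and the
# effect of conversion events on paralog similarity.

test_that("scenario validation rejects bad windows, times and overlaps", {
  tr <- four_species_tree()
  expect_error(conversion_scenario(ape::unroot(tr)), "rooted")
  bad_win <- tibble::tibble(species = "gA", donor_track = 1L,
                            start_codon = 0L, end_codon = 10L,
                            time_fraction = 0.5)
  expect_error(conversion_scenario(tr, bad_win), "within")
  bad_time <- tibble::tibble(species = "gA", donor_track = 1L,
                             start_codon = 1L, end_codon = 10L,
                             time_fraction = 1.5)
  expect_error(conversion_scenario(tr, bad_time), "time_fraction")
  overlap <- tibble::tibble(species = c("gA", "gA"), donor_track = 1L,
                            start_codon = c(1L, 5L), end_codon = c(10L, 20L),
                            time_fraction = 0.5)
  expect_error(conversion_scenario(tr, overlap), "overlapping")
  expect_error(conversion_scenario(tr, n_codons = 0), "n_codons")
})

test_that("families carry both tracks, ground-truth orthology and losses", {
  sc <- default_scenario(seed = 71, losses = "speC_t2")
  fam <- generate_family(sc)
  expect_equal(length(fam$alignment$names), 11L) # 12 tips - 1 loss
  expect_false("speC_t2" %in% fam$alignment$names)
  expect_equal(sort(fam$orthology$gene_id), sort(fam$alignment$names))
  expect_true(all(fam$orthology$probability == 1))
  expect_false("speC_t2" %in% fam$doubled_tree$tip.label)

  # zero-length tree: everything identical to the root draw
  tr0 <- ape::read.tree(text = "((gA:0,gB:0):0,(gC:0,gD:0):0);")
  fam0 <- generate_family(conversion_scenario(tr0, n_codons = 30, seed = 72))
  expect_equal(length(unique(fam0$alignment$seqs)), 1L)
})

test_that("generation is deterministic under the scenario seed", {
  conv <- tibble::tibble(species = "speA", donor_track = 2L, start_codon = 10L,
                         end_codon = 80L, time_fraction = 0.4)
  f1 <- generate_family(default_scenario(conversions = conv, seed = 73))
  f2 <- generate_family(default_scenario(conversions = conv, seed = 73))
  expect_identical(f1$alignment$seqs, f2$alignment$seqs)
  f3 <- generate_family(default_scenario(conversions = conv, seed = 74))
  expect_false(identical(f1$alignment$seqs, f3$alignment$seqs))
})

test_that("conversion homogenizes the converted window and only it", {
  # long window, recent event: inside the window the paralogs are nearly
  # identical, outside they keep WGD-level divergence
  conv <- tibble::tibble(species = "speA", donor_track = 1L, start_codon = 1L,
                         end_codon = 75L, time_fraction = 0.05)
  fam <- generate_family(default_scenario(conversions = conv, seed = 75))
  codes <- fam$alignment$codes
  a1 <- codes[, match("speA_t1", fam$alignment$names)]
  a2 <- codes[, match("speA_t2", fam$alignment$names)]
  inside <- mean(a1[1:75] != a2[1:75])
  outside <- mean(a1[76:150] != a2[76:150])
  expect_lt(inside, outside)

  # paired seeds: conversion strictly reduces paralog nucleotide distance
  red <- vapply(1:25, function(s) {
    f_conv <- generate_family(default_scenario(conversions = tibble::tibble(
      species = "speA", donor_track = 1L, start_codon = 1L, end_codon = 150L,
      time_fraction = 0.3), seed = 200 + s))
    f_null <- generate_family(default_scenario(seed = 200 + s))
    d <- function(f) {
      i <- match(c("speA_t1", "speA_t2"), f$alignment$names)
      mean(f$alignment$codes[, i[1]] != f$alignment$codes[, i[2]])
    }
    d(f_conv) - d(f_null)
  }, numeric(1))
  expect_lt(mean(red), 0)
  expect_gt(mean(red <= 0), 0.9)
})

test_that("the converted-window genealogy places the pair as sisters", {
  conv <- tibble::tibble(species = "speA", donor_track = 1L, start_codon = 1L,
                         end_codon = 150L, time_fraction = 0.2)
  fam <- generate_family(default_scenario(conversions = conv, seed = 76))
  gt <- fam$gene_tree
  i1 <- match("speA_t1", gt$tip.label)
  i2 <- match("speA_t2", gt$tip.label)
  p1 <- gt$edge[match(i1, gt$edge[, 2]), 1]
  p2 <- gt$edge[match(i2, gt$edge[, 2]), 1]
  expect_equal(p1, p2)
})

test_that("null triplet generation hits the requested divergences", {
  # long sequences: realized pairwise differences reflect Ks/Ka inputs
  a <- generate_null_triplet(ka = c(0, 0, 0), ks = c(0, 0, 0),
                             n_codons = 50, seed = 77)
  expect_equal(length(unique(a$seqs)), 1L)
  b1 <- generate_null_triplet(ka = c(0.01, 0.02, 0.03), ks = c(0.1, 0.2, 0.3),
                              n_codons = 200, seed = 78)
  b2 <- generate_null_triplet(ka = c(0.01, 0.02, 0.03), ks = c(0.1, 0.2, 0.3),
                              n_codons = 200, seed = 79)
  expect_false(identical(b1$seqs, b2$seqs))
})

test_that("families round-trip through the plain-text writers", {
  fam <- generate_family(default_scenario(seed = 80))
  pref <- file.path(tempdir(), "fam_test")
  paths <- write_family(fam, pref)
  back <- read_codon_alignment(paths[["fasta"]])
  expect_identical(back$seqs, fam$alignment$seqs)
  tr <- ape::read.tree(paths[["spp"]])
  expect_equal(sort(tr$tip.label), sort(fam$species_tree$tip.label))
  orth <- read_orthology_table(paths[["orth"]])
  expect_equal(orth$gene_id, fam$orthology$gene_id)
})
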