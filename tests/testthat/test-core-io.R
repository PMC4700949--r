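# Alignment container, FASTA/TSV IO, p-distance, genetic-code tables.

test_that("codon alignments validate structure and round-trip through FASTA", {
  seqs <- c(s1 = "ATGAAAGTT", s2 = "ATGAGAGTT", s3 = "atgaaagtc")
  aln <- codon_alignment(seqs)
  expect_equal(aln$n_codons, 3L)
  expect_equal(length(aln$names), 3L)
  # lowercase normalized; U -> T
  expect_equal(codon_alignment(c(a = "AUGGUU", b = "ATGGTT"))$seqs,
               c("ATGGTT", "ATGGTT"))

  f <- tempfile(fileext = ".fasta")
  write_codon_alignment(aln, f)
  back <- read_codon_alignment(f)
  expect_equal(back$names, aln$names)
  expect_equal(back$seqs, aln$seqs)
  expect_identical(back$codes, aln$codes)

  expect_error(codon_alignment(c(a = "ATGAAA", b = "ATG")), "ragged")
  expect_error(codon_alignment(c(a = "ATGA")), "multiple of 3")
  expect_error(codon_alignment(c(a = "ATGTAAGTT")), "codon 2")
  expect_error(codon_alignment(c(a = "AT-GAA")), "codon boundaries")
  # whole-codon gaps and ambiguity codes become missing data
  aln2 <- codon_alignment(c(a = "ATG---GTT", b = "ATGAANGTT"))
  expect_true(is.na(aln2$codes[2, 1]))
  expect_true(is.na(aln2$codes[2, 2]))
})

test_that("p-distance follows its definition and excludes gapped columns", {
  expect_equal(p_distance("MKV", "MKV"), 0)
  expect_equal(p_distance("MKV", "MRV"), 1 / 3)
  expect_equal(p_distance("M-V", "MRV"), 0) # gap column dropped entirely
  expect_equal(p_distance("AKV", "AR-"), 1 / 2)
  # symmetry
  expect_equal(p_distance("AKVQ", "MRVQ"), p_distance("MRVQ", "AKVQ"))
  expect_error(p_distance("---", "MKV"), "no gap-free columns")
  expect_error(p_distance("MK", "MKV"), "different lengths")
})

test_that("translation handles gaps, stops and ambiguity", {
  expect_equal(translate_codons(c("ATG", "AAA", "---", "NNA")),
               c("M", "K", "-", "X"))
  aln <- codon_alignment(c(a = "ATGAAA---", b = "ATGAGAGTT"))
  tr <- translate_alignment(aln)
  expect_equal(unname(tr["a"]), "MK-")
  expect_equal(unname(tr["b"]), "MRV")
})

test_that("orthology tables validate tracks, probabilities and uniqueness", {
  df <- data.frame(species = c("s1", "s1", "s2", "s2"),
                   gene_id = c("g1", "g2", "g3", "g4"),
                   track = c(1, 2, 1, 2), probability = 1)
  tab <- validate_orthology_table(df)
  expect_equal(nrow(tab), 4L)

  f <- tempfile(fileext = ".tsv")
  write_orthology_table(tab, f)
  back <- read_orthology_table(f)
  expect_equal(back$gene_id, tab$gene_id)
  expect_equal(back$track, tab$track)

  df$probability[2] <- 0.97
  expect_equal(validate_orthology_table(df)$probability[2], 0.97)
  df$track[2] <- 3
  expect_error(validate_orthology_table(df), "track value '3'")
  df$track[2] <- 2
  df$probability[2] <- 1.4
  expect_error(validate_orthology_table(df), "\\[0, 1\\]")
  df$probability[2] <- 1
  df$track[2] <- 1 # duplicate (species, track)
  expect_error(validate_orthology_table(df), "duplicate")
})

test_that("the genetic-code tables have 61 symmetric sense-codon states", {
  cods <- sense_codons()
  expect_equal(length(cods), 61L)
  expect_false(any(c("TAA", "TAG", "TGA") %in% cods))
  nbr <- ohnoconv:::codon_tables()$neighbors
  # every single-nucleotide neighbor pair is classified symmetrically
  key <- paste(nbr$i, nbr$j)
  rev <- paste(nbr$j, nbr$i)
  m <- match(rev, key)
  expect_false(anyNA(m))
  expect_equal(nbr$is_syn, nbr$is_syn[m])
  expect_equal(nbr$is_ts, nbr$is_ts[m])
  # radical classification is symmetric too
  rad <- neighbor_is_radical(default_polarity_partition())
  expect_equal(rad, rad[m])
  # partition must cover the 20 amino acids exactly once
  bad <- default_polarity_partition()[-1]
  expect_error(ohnoconv:::validate_partition(bad), "exactly once")
})
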