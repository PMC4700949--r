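# Protein-identity candidate screen.

make_screen_fixture <- function(seqs) {
  aln <- codon_alignment(seqs)
  species_map <- stats::setNames(sub("_.*$", "", names(seqs)), names(seqs))
  list(aln = aln, species_map = species_map)
}

test_that("the candidate rule is a strict inequality on p-distances", {
  # spX paralogs identical; nearest relative spY differs by one residue
  fx <- make_screen_fixture(c(
    spX_g1 = "ATGAAAGTTCCA", spX_g2 = "ATGAAAGTTCCA",
    spY_g1 = "ATGAGAGTTCCA", spY_g2 = "ATGAGAGTTCCA"))
  nb <- c(spX = "spY", spY = "spX")
  rep <- screen_candidates(fx$aln, fx$species_map, nb)
  rx <- rep[rep$species == "spX", ]
  expect_equal(rx$dist_d1_d2, 0)
  expect_equal(rx$min_dist_to_relative, 0.25)
  expect_true(rx$is_candidate)
  # spY's paralogs identical to each other but also to... their own pair is 0,
  # min to relative 0.25 -> candidate as well (symmetric fixture)
  expect_true(rep$is_candidate[rep$species == "spY"])

  # paralogs farther apart than the relative -> not a candidate
  fx2 <- make_screen_fixture(c(
    spX_g1 = "ATGAAAGTTCCA", spX_g2 = "ATGCGAATTCCA",
    spY_g1 = "ATGAAAGTTCCA", spY_g2 = "ATGAAAGTTCCA"))
  rep2 <- screen_candidates(fx2$aln, fx2$species_map, nb)
  expect_false(rep2$is_candidate[rep2$species == "spX"])

  # exact tie -> not a candidate
  fx3 <- make_screen_fixture(c(
    spX_g1 = "ATGAAAGTTCCA", spX_g2 = "ATGAGAGTTCCA",
    spY_g1 = "ATGAAAGTTGGC", spY_g2 = "ATGAAAGTTGGC"))
  rep3 <- screen_candidates(fx3$aln, fx3$species_map, nb)
  rx3 <- rep3[rep3$species == "spX", ]
  expect_equal(rx3$dist_d1_d2, rx3$min_dist_to_relative)
  expect_false(rx3$is_candidate)
})

test_that("species without a relative homolog are skipped with a warning", {
  fx <- make_screen_fixture(c(
    spX_g1 = "ATGAAAGTTCCA", spX_g2 = "ATGAAAGTTCCA",
    spY_g1 = "ATGAGAGTTCCA", spY_g2 = "ATGAGAGTTCCA"))
  expect_warning(
    rep <- screen_candidates(fx$aln, fx$species_map,
                             c(spX = "spZ", spY = "spX")),
    "no homolog")
  expect_false("spX" %in% rep$species)
  # single-copy species produce no report row
  fx2 <- make_screen_fixture(c(
    spX_g1 = "ATGAAAGTTCCA", spX_g2 = "ATGAAAGTTCCA",
    spY_g1 = "ATGAGAGTTCCA"))
  rep2 <- screen_candidates(fx2$aln, fx2$species_map, c(spX = "spY"))
  expect_equal(rep2$species, "spX")
})

test_that("screen operating characteristics on simulated families", {
  set.seed(51)
  # tip-to-root depth 0.3 substitutions/codon and moderate purifying
  # selection, so amino-acid divergence is informative at 150 codons
  deep_scenario <- function(conv = NULL) {
    tr <- default_scenario()$species_tree
    tr$edge.length <- tr$edge.length * 2
    conversion_scenario(tr, conversions = conv,
                        model = codon_model(kappa = 2, omega = 0.2),
                        n_codons = 150)
  }
  nb <- nearest_relatives(default_scenario()$species_tree)
  n_rep <- 50
  # without conversion: false-candidate rate stays low
  false_flags <- 0
  tested <- 0
  for (r in seq_len(n_rep)) {
    fam <- generate_family(deep_scenario())
    scr <- screen_candidates(fam$alignment,
                             stats::setNames(fam$orthology$species,
                                             fam$orthology$gene_id), nb)
    false_flags <- false_flags + sum(scr$is_candidate)
    tested <- tested + nrow(scr)
  }
  expect_lt(false_flags / tested, 0.05)

  # with a recent full-gene conversion the converted species is flagged
  conv <- tibble::tibble(species = "speA", donor_track = 1L, start_codon = 1L,
                         end_codon = 150L, time_fraction = 0.05)
  hits <- vapply(seq_len(n_rep), function(r) {
    fam <- generate_family(deep_scenario(conv))
    scr <- screen_candidates(fam$alignment,
                             stats::setNames(fam$orthology$species,
                                             fam$orthology$gene_id), nb)
    scr$is_candidate[scr$species == "speA"]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
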