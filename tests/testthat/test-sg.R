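# Similarity-groups model: rate-matrix structure, the one-group limiting
# case, parameter recovery, the Rr = Rc LRT, FDR, and the binomial sign test.

test_that("the one-group partition collapses the SG model to plain MG/GY", {
  set.seed(91)
  tr <- four_species_tree()
  aln <- simulate_codon_alignment(tr, codon_model(kappa = 2, omega = 0.3), 400)
  one_group <- stats::setNames(rep("all", 20),
                               names(default_polarity_partition()))
  sg <- fit_sg(aln, tr, partition = one_group, restarts = 1)
  mg <- fit_codon_model(aln, tr, restarts = 1)
  expect_true(sg$one_group)
  expect_equal(sg$lnL, mg$lnL, tolerance = 1e-6)
  expect_equal(unname(sg$classes$Rc), mg$model$omega, tolerance = 1e-3)
})

test_that("SG fits recover the radical/conservative ratio", {
  set.seed(92)
  # the doubled post-WGD tree carries enough branch length for the
  # radical/conservative contrast to be informative at 2000 codons
  tr <- ohnoconv:::double_species_tree(default_scenario()$species_tree)
  ratios <- vapply(1:10, function(r) {
    aln <- simulate_sg_alignment(tr, Rc = 0.15, Rr = 0.30, n_codons = 2000)
    f <- fit_sg(aln, tr, restarts = 0)
    f$classes$ratio[1]
  }, numeric(1))
  expect_gte(mean(ratios >= 1.6 & ratios <= 2.4), 0.9)
})

test_that("purely synonymous variation floors both constraints", {
  set.seed(93)
  tr <- four_species_tree()
  tr$edge.length <- tr$edge.length * 3 # enough synonymous change to see
  aln <- simulate_sg_alignment(tr, Rc = 1e-8, Rr = 1e-8, n_codons = 400)
  # sanity: no amino-acid variation
  prot <- translate_alignment(aln)
  expect_equal(length(unique(prot)), 1L)
  f <- fit_sg(aln, tr, restarts = 0)
  expect_lt(f$classes$Rc[1], 1e-6)
  expect_lt(f$classes$Rr[1], 1e-6)
  expect_true(f$classes$ratio_undefined[1])
  expect_true(is.na(f$classes$ratio[1]))
})

test_that("branch classes isolate the converted clade and the LRT is nested", {
  set.seed(94)
  fam <- generate_family(default_scenario(conversions = tibble::tibble(
    species = "speA", donor_track = 1L, start_codon = 1L, end_codon = 150L,
    time_fraction = 0.2), seed = 95))
  gt <- expected_gene_tree(fam$species_tree, fam$orthology)
  gcs <- enumerate_gc_trees(gt, tibble::tibble(gene1 = "speA_t1",
                                               gene2 = "speA_t2"))
  best <- gcs$trees$tree[[1]]
  res <- sg_lrt(fam$alignment, best, converted_tips = c("speA_t1", "speA_t2"),
                restarts = 0)
  expect_setequal(res$class, c("background", "converted"))
  expect_true(all(res$lnL_constrained <= res$lnL_free + 1e-6))
  expect_true(all(res$P_raw >= 0 & res$P_raw <= 1))
  out <- sg_fdr(res)
  expect_true(all(out$P_fdr >= out$P_raw - 1e-12))
})

test_that("LRT type-I error is near nominal under Rr = Rc", {
  set.seed(96)
  tr <- three_species_tree()
  rej <- vapply(1:30, function(r) {
    aln <- simulate_sg_alignment(tr, Rc = 0.25, Rr = 0.25, n_codons = 400)
    res <- sg_lrt(aln, tr, test = "background", restarts = 0)
    res$P_raw < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.2) # generous desk-scale bound at n = 30
})

test_that("Benjamini-Hochberg behaves as hand-computed", {
  res <- tibble::tibble(P_raw = rep(0.04, 5))
  expect_equal(sg_fdr(res)$P_fdr, rep(0.04, 5))
  res2 <- tibble::tibble(P_raw = c(0.01, 0.02, 0.03, 0.04, 0.05))
  # hand BH: p_(i) * m / i, cumulative minimum from the largest rank
  expect_equal(sg_fdr(res2)$P_fdr, c(0.05, 0.05, 0.05, 0.05, 0.05))
  # monotone in the raw P values
  res3 <- tibble::tibble(P_raw = c(0.001, 0.2, 0.04, 0.9))
  adj <- sg_fdr(res3)$P_fdr
  expect_true(all(diff(adj[order(res3$P_raw)]) >= -1e-12))
})

test_that("the binomial sign test matches closed-form tail probabilities", {
  expect_equal(binomial_sign_test(5, 5, 0.5), 0.03125)
  expect_equal(binomial_sign_test(0, 5, 0.5), 1)
  expect_equal(binomial_sign_test(1, 1, 0.5), 0.5)
  expect_equal(binomial_sign_test(3, 10, 0.3),
               sum(stats::dbinom(3:10, 10, 0.3)), tolerance = 1e-12)
  expect_error(binomial_sign_test(6, 5), "k <= n")
})
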