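# The MG/GY codon engine: rate-matrix structure, pruning likelihood against
# an independent brute-force oracle, reversibility, fitting and simulation.

test_that("rate matrices have zero row sums, detailed balance, MG symmetry", {
  set.seed(41)
  for (r in 1:5) {
    mod <- random_codon_model()
    Q <- codon_rate_matrix(mod)
    expect_lt(max(abs(rowSums(Q))), 1e-12)
    # detailed balance pi_i q_ij = pi_j q_ji, checked against an
    # independently coded frequency product
    flux <- mod$pi * Q
    expect_lt(max(abs(flux - t(flux))), 1e-10)
    # unit expected rate after rescaling
    expect_equal(-sum(mod$pi * diag(Q)), 1, tolerance = 1e-12)
  }
  # kappa = 1, omega = 1, uniform frequencies: all allowed changes equal
  Q0 <- codon_rate_matrix(codon_model(kappa = 1, omega = 1))
  off <- Q0[row(Q0) != col(Q0)]
  expect_equal(length(unique(round(off[off > 0], 12))), 1L)
  # multi-nucleotide changes are forbidden
  nbr <- ohnoconv:::codon_tables()$neighbors
  allowed <- matrix(FALSE, 61, 61)
  allowed[cbind(nbr$i, nbr$j)] <- TRUE
  expect_true(all(Q0[!allowed & row(Q0) != col(Q0)] == 0))
})

test_that("pruning lnL equals brute-force ancestral enumeration", {
  set.seed(42)
  for (r in 1:12) {
    ntip <- sample(3:4, 1)
    tr <- random_small_tree(ntip)
    mod <- random_codon_model()
    aln <- simulate_codon_alignment(tr, mod, sample(5:20, 1))
    if (r %% 3 == 0) aln <- add_missing_codons(aln, 2)
    expect_equal(log_likelihood(aln, tr, mod), brute_force_lnl(aln, tr, mod),
                 tolerance = 1e-10)
  }
})

test_that("lnL is invariant to root placement (time reversibility)", {
  set.seed(43)
  for (r in 1:10) {
    tr <- random_small_tree(6)
    mod <- random_codon_model()
    aln <- simulate_codon_alignment(tr, mod, 40)
    l0 <- log_likelihood(aln, tr, mod)
    og <- sample(tr$tip.label, 1)
    rerooted <- ape::root(tr, outgroup = og, resolve.root = TRUE)
    expect_equal(log_likelihood(aln, rerooted, mod), l0, tolerance = 1e-6)
  }
})

test_that("degenerate trees give the closed-form likelihood", {
  mod <- codon_model(kappa = 2, omega = 0.2)
  tr <- ape::read.tree(text = "(A:0,B:0,C:0);")
  aln <- simulate_codon_alignment(tr, mod, 30, seed = 7)
  expect_equal(length(unique(aln$seqs)), 1L) # all tips identical
  expect_equal(log_likelihood(aln, tr, mod),
               sum(log(mod$pi[aln$codes[, 1]])), tolerance = 1e-10)
})

test_that("ML fitting recovers parameters and respects nesting", {
  set.seed(44)
  tr <- four_species_tree()
  truth <- codon_model(kappa = 2.5, omega = 0.2)
  aln <- simulate_codon_alignment(tr, truth, 2000)
  fit <- fit_codon_model(aln, tr, restarts = 1)
  expect_true(fit$converged)
  expect_lt(abs(fit$model$omega - 0.2), 0.05)
  expect_lt(abs(fit$model$kappa - 2.5), 0.6)
  # constrained fit (omega fixed away from the MLE) can never beat the free fit
  con <- fit_codon_model(aln, tr, model = codon_model(kappa = 2.5, omega = 0.5),
                         omega_free = FALSE, restarts = 1)
  expect_lte(con$lnL, fit$lnL + 1e-6)
  # refitting from the MLE reproduces the lnL
  refit <- fit_codon_model(aln, fit$tree, model = fit$model, restarts = 0)
  expect_equal(refit$lnL, fit$lnL, tolerance = 1e-4)
  # tidy/glance contracts
  td <- tidy(fit)
  expect_true(all(c("kappa", "omega") %in% td$term))
  expect_equal(nrow(glance(fit)), 1L)
})

test_that("identical sequences drive branch lengths to the lower bound", {
  aln <- codon_alignment(c(A = "ATGAAAGTTCCA", B = "ATGAAAGTTCCA",
                           C = "ATGAAAGTTCCA"))
  tr <- ape::read.tree(text = "(A:0.1,B:0.1,C:0.1);")
  fit <- fit_codon_model(aln, tr, restarts = 0)
  expect_true(all(fit$blens < 1e-6))
})

test_that("simulation is seed-reproducible and stationary on long branches", {
  mod <- codon_model(kappa = 2, omega = 0.3)
  tr <- ape::read.tree(text = "(A:50,B:0.1,C:0.1);")
  a1 <- simulate_codon_alignment(tr, mod, 200, seed = 5)
  a2 <- simulate_codon_alignment(tr, mod, 200, seed = 5)
  expect_identical(a1$seqs, a2$seqs)
  a3 <- simulate_codon_alignment(tr, mod, 200, seed = 6)
  expect_false(identical(a1$seqs, a3$seqs))

  # after t = 50 the tip distribution is the equilibrium distribution
  big <- simulate_codon_alignment(tr, mod, 50000, seed = 8)
  counts <- tabulate(big$codes[, match("A", big$names)], nbins = 61)
  p_hat <- counts / sum(counts)
  se <- sqrt(mod$pi * (1 - mod$pi) / 50000)
  expect_true(all(abs(p_hat - mod$pi) <= 3.5 * se + 1e-9))
})

test_that("branch lengths convert to Ka and Ks consistently", {
  mod <- codon_model(kappa = 2, omega = 1) # neutral: Ka = Ks
  kk <- kaks_from_lengths(mod, 0.3)
  expect_equal(kk$Ka, kk$Ks, tolerance = 1e-12)
  # under purifying selection Ka < Ks for the same branch length
  kk2 <- kaks_from_lengths(codon_model(kappa = 2, omega = 0.1), 0.3)
  expect_lt(kk2$Ka, kk2$Ks)
})
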