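# Shared test helpers: an independent brute-force likelihood oracle (explicit
# summation over ancestral states, no pruning) and small fixture builders.

# Transition matrix for the oracle, built from first principles with R's
# eigen() on the unsymmetrized generator (independent of the C++ path).
oracle_pmat <- function(Q, t) {
  e <- eigen(Q)
  P <- Re(e$vectors %*% diag(exp(e$values * t)) %*% solve(e$vectors))
  P[P < 0] <- 0
  P
}

# Column of P for an observed state, or ones for missing data.
oracle_col <- function(P, x) {
  if (is.na(x)) rep(1, nrow(P)) else P[, x]
}

# Brute-force lnL for unrooted 3-tip (star) and 4-tip trees by summation over
# all ancestral state combinations. `tree` must be one of the shapes below;
# tips are matched to alignment rows by label.
brute_force_lnl <- function(aln, tree, model) {
  Q <- codon_rate_matrix(model)
  pi <- model$pi
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  stopifnot(ntip %in% c(3L, 4L))
  codes <- aln$codes[, match(tree$tip.label, aln$names), drop = FALSE]
  nsite <- nrow(codes)
  edge <- tree$edge
  elen <- tree$edge.length
  P <- lapply(seq_len(nrow(edge)), function(k) oracle_pmat(Q, elen[k]))

  total <- 0
  if (ntip == 3L) {
    # single internal node u: L = sum_u pi_u * prod_b P_b[u, x_b]
    for (s in seq_len(nsite)) {
      acc <- pi
      for (k in seq_len(nrow(edge))) {
        acc <- acc * oracle_col(P[[k]], codes[s, edge[k, 2]])
      }
      total <- total + log(sum(acc))
    }
  } else {
    # two internal nodes u (root of the unrooted representation) and v
    internals <- sort(unique(edge[, 1]))
    u <- internals[1]
    v <- internals[2]
    for (s in seq_len(nsite)) {
      L <- 0
      for (su in 1:61) {
        term_u <- pi[su]
        inner_v <- rep(NA_real_, 61)
        for (sv in 1:61) {
          tv <- 1
          for (k in seq_len(nrow(edge))) {
            par <- edge[k, 1]; ch <- edge[k, 2]
            if (par == v && ch <= ntip) {
              tv <- tv * oracle_col(P[[k]], codes[s, ch])[sv]
            }
          }
          ku <- which(edge[, 1] == u & edge[, 2] == v)
          inner_v[sv] <- P[[ku]][su, sv] * tv
        }
        for (k in seq_len(nrow(edge))) {
          par <- edge[k, 1]; ch <- edge[k, 2]
          if (par == u && ch <= ntip) {
            term_u <- term_u * oracle_col(P[[k]], codes[s, ch])[su]
          }
        }
        L <- L + term_u * sum(inner_v)
      }
      total <- total + log(L)
    }
  }
  total
}

random_codon_model <- function() {
  fr <- matrix(stats::runif(12, 0.5, 1.5), 3, 4)
  fr <- fr / rowSums(fr)
  codon_model(kappa = stats::runif(1, 1, 4), omega = stats::runif(1, 0.05, 1),
              freqs_nt = fr)
}

random_small_tree <- function(ntip) {
  tr <- ape::rtree(ntip, br = NULL)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.02, 0.6)
  ape::unroot(tr)
}

# Inject whole-codon gaps / ambiguities into an alignment at random positions.
add_missing_codons <- function(aln, n_gap = 2) {
  seqs <- stats::setNames(aln$seqs, aln$names)
  for (i in seq_along(seqs)) {
    pos <- sample.int(aln$n_codons, n_gap)
    for (p in pos) {
      substr(seqs[i], 3 * p - 2, 3 * p) <- if (stats::runif(1) < 0.5) "---" else "NNN"
    }
  }
  codon_alignment(seqs)
}

# Small 4-species scenario used by several tests.
four_species_tree <- function() {
  ape::read.tree(text = "((gA:0.06,gB:0.06):0.05,(gC:0.07,gD:0.07):0.04);")
}

three_species_tree <- function() {
  ape::read.tree(text = "((gA:0.06,gB:0.06):0.05,gC:0.09);")
}
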