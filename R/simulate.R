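# Sequence simulation under the codon model: root state drawn from the
# equilibrium distribution, then evolved along each branch with the matrix
# exponential of Q*t.

# Sample child states given parent states and a transition matrix.
sim_child_states <- function(parent_states, P) {
  out <- integer(length(parent_states))
  for (s in unique(parent_states)) {
    idx <- which(parent_states == s)
    out[idx] <- sample.int(61L, length(idx), replace = TRUE, prob = P[s, ])
  }
  out
}

# Simulate codon states at every node of a tree; returns an (nnode x nsites)
# integer matrix of codon states. `eig` is the model eigendecomposition.
sim_states_on_tree <- function(tree, pi, eig, n_codons,
                               root_states = NULL, skip_tips = character(0)) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  states <- matrix(NA_integer_, nnode, n_codons)
  states[root, ] <- if (is.null(root_states)) {
    sample.int(61L, n_codons, replace = TRUE, prob = pi)
  } else root_states
  skip <- match(skip_tips, tree$tip.label)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]
    c <- tree$edge[k, 2]
    if (c %in% skip) next
    P <- transition_matrix(eig, tree$edge.length[k])
    states[c, ] <- sim_child_states(states[p, ], P)
  }
  states
}

transition_matrix <- function(eig, t) {
  P <- eig$left %*% (exp(as.numeric(eig$lam) * t) * eig$right)
  P[P < 0] <- 0
  P
}

states_to_seq <- function(states) {
  paste(codon_tables()$codons[states], collapse = "")
}

#' Simulate a codon alignment on a tree
#'
#' Draws the root codon from the model's equilibrium distribution and evolves
#' it along every branch under the matrix exponential of the rate matrix.
#'
#' @param tree ape `phylo` tree with branch lengths in expected substitutions
#'   per codon.
#' @param model A [codon_model()].
#' @param n_codons Alignment length in codons.
#' @param seed Optional integer seed (set before any draw, so equal seeds give
#'   identical alignments).
#' @return A [codon_alignment()] with one sequence per tip.
#' @export
simulate_codon_alignment <- function(tree, model, n_codons, seed = NULL) {
  stopifnot(inherits(model, "codon_model"), n_codons >= 1)
  if (!is.null(seed)) set.seed(seed)
  eig <- cpp_eig_rev(codon_rate_matrix(model), model$pi)
  tree2 <- ape::reorder.phylo(tree, "cladewise")
  states <- sim_states_on_tree(tree2, model$pi, eig, n_codons)
  ntip <- length(tree2$tip.label)
  seqs <- vapply(seq_len(ntip), function(i) states_to_seq(states[i, ]),
                 character(1))
  codon_alignment(stats::setNames(seqs, tree2$tip.label))
}
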