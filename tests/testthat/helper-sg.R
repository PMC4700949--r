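# SG-model simulation helpers shared across test files.

sg_sim_model <- function(Rc, Rr, kappa = 2,
                         partition = default_polarity_partition()) {
  # simulate under an SG generator by reusing the engine's building blocks
  parts <- ohnoconv:::mg_rate_parts(matrix(0.25, 3, 4), partition = partition)
  pi <- f3x4_frequencies(matrix(0.25, 3, 4))
  cube <- array(c(parts$syn_tv, parts$syn_ts, parts$con_tv, parts$con_ts,
                  parts$rad_tv, parts$rad_ts), dim = c(61, 61, 6))
  ohnoconv:::cpp_build_eig(cube, c(1, kappa, Rc, Rc * kappa, Rr, Rr * kappa),
                           pi, TRUE)
}

simulate_sg_alignment <- function(tree, Rc, Rr, n_codons, kappa = 2) {
  eig <- sg_sim_model(Rc, Rr, kappa)
  pi <- f3x4_frequencies(matrix(0.25, 3, 4))
  states <- ohnoconv:::sim_states_on_tree(tree, pi, eig, n_codons)
  ntip <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "cladewise")
  seqs <- vapply(seq_len(ntip), function(i)
    ohnoconv:::states_to_seq(states[i, ]), character(1))
  codon_alignment(stats::setNames(seqs, tr$tip.label))
}

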