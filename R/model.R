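# MG/GY-style codon model specification and rate-matrix construction.
# Rates for single-nucleotide codon changes are proportional to the target
# nucleotide's frequency at the changed position (Muse-Gaut style), with a
# kappa multiplier for transitions and an omega multiplier for nonsynonymous
# changes; equilibrium codon frequencies are the F3x4-style product of
# position-specific nucleotide frequencies renormalized over sense codons.

#' Specify an MG/GY codon substitution model
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio (>= 0).
#' @param freqs_nt 3 x 4 matrix of position-specific nucleotide frequencies
#'   (rows = codon positions, columns = A, C, G, T; each row sums to 1).
#'   Defaults to uniform frequencies.
#' @return An object of class `codon_model` with the implied equilibrium
#'   distribution over the 61 sense codons in `$pi`.
#' @export
codon_model <- function(kappa = 2, omega = 0.2, freqs_nt = NULL) {
  if (!is.numeric(kappa) || kappa <= 0) stop("kappa must be > 0")
  if (!is.numeric(omega) || omega < 0) stop("omega must be >= 0")
  freqs_nt <- validate_freqs_nt(freqs_nt)
  structure(
    list(kappa = kappa, omega = omega, freqs_nt = freqs_nt,
         pi = f3x4_frequencies(freqs_nt)),
    class = "codon_model"
  )
}

#' @export
print.codon_model <- function(x, ...) {
  cat("MG/GY codon model: kappa =", signif(x$kappa, 4),
      " omega =", signif(x$omega, 4), "\n")
  invisible(x)
}

validate_freqs_nt <- function(freqs_nt) {
  if (is.null(freqs_nt)) {
    freqs_nt <- matrix(0.25, 3, 4, dimnames = list(NULL, NUC))
  }
  if (!is.matrix(freqs_nt) || any(dim(freqs_nt) != c(3L, 4L))) {
    stop("freqs_nt must be a 3 x 4 matrix (positions x A,C,G,T)")
  }
  if (any(freqs_nt < 0) || any(abs(rowSums(freqs_nt) - 1) > 1e-8)) {
    stop("freqs_nt rows must be nonnegative and sum to 1")
  }
  # floor to keep every sense codon reachable (zero frequencies break the
  # reversible symmetrization)
  freqs_nt <- pmax(freqs_nt, 1e-6)
  freqs_nt <- freqs_nt / rowSums(freqs_nt)
  dimnames(freqs_nt) <- list(NULL, NUC)
  freqs_nt
}

#' F3x4 equilibrium codon frequencies
#'
#' @param freqs_nt 3 x 4 position-specific nucleotide frequency matrix.
#' @return Length-61 vector summing to 1, ordered as [sense_codons()].
#' @export
f3x4_frequencies <- function(freqs_nt) {
  freqs_nt <- validate_freqs_nt(freqs_nt)
  nt_idx <- codon_tables()$codon_nt
  pi <- freqs_nt[1, nt_idx[, 1]] * freqs_nt[2, nt_idx[, 2]] *
    freqs_nt[3, nt_idx[, 3]]
  unname(pi / sum(pi))
}

#' Empirical position-specific nucleotide frequencies
#'
#' Counts nucleotides at each codon position over all non-gap, non-ambiguous
#' codons of the alignment.
#'
#' @param aln A [codon_alignment()].
#' @return 3 x 4 frequency matrix suitable for [codon_model()].
#' @export
empirical_nt_freqs <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  tab <- codon_tables()
  counts <- matrix(1e-3, 3, 4, dimnames = list(NULL, NUC)) # pseudocount
  states <- aln$codes[!is.na(aln$codes)]
  for (pos in 1:3) {
    tb <- table(factor(tab$codon_nt[states, pos], levels = NUC))
    counts[pos, ] <- counts[pos, ] + as.numeric(tb)
  }
  counts / rowSums(counts)
}

# Off-diagonal rate-matrix building blocks. Each block is a 61 x 61 matrix
# with entry (i, j) = target-nucleotide frequency for the changed position,
# restricted to one change category; blocks are combined linearly with the
# kappa/omega (or Rc/Rr) multipliers. With `partition` supplied, the
# nonsynonymous blocks are split into conservative and radical parts.
mg_rate_parts <- function(freqs_nt, partition = NULL) {
  freqs_nt <- validate_freqs_nt(freqs_nt)
  nbr <- codon_tables()$neighbors
  base <- freqs_nt[cbind(nbr$pos, nbr$to_nt)]
  blk <- function(sel) {
    m <- matrix(0, 61, 61)
    m[cbind(nbr$i[sel], nbr$j[sel])] <- base[sel]
    m
  }
  if (is.null(partition)) {
    list(
      syn_tv = blk(nbr$is_syn & !nbr$is_ts),
      syn_ts = blk(nbr$is_syn & nbr$is_ts),
      non_tv = blk(!nbr$is_syn & !nbr$is_ts),
      non_ts = blk(!nbr$is_syn & nbr$is_ts)
    )
  } else {
    rad <- neighbor_is_radical(partition)
    list(
      syn_tv = blk(nbr$is_syn & !nbr$is_ts),
      syn_ts = blk(nbr$is_syn & nbr$is_ts),
      con_tv = blk(!nbr$is_syn & !nbr$is_ts & !rad),
      con_ts = blk(!nbr$is_syn & nbr$is_ts & !rad),
      rad_tv = blk(!nbr$is_syn & !nbr$is_ts & rad),
      rad_ts = blk(!nbr$is_syn & nbr$is_ts & rad)
    )
  }
}

# Assemble a scaled generator from blocks and multipliers. `mult` is a named
# vector of multipliers applied to the corresponding blocks.
assemble_q <- function(parts, mult, pi, scale = TRUE) {
  Q <- matrix(0, 61, 61)
  for (nm in names(parts)) Q <- Q + mult[[nm]] * parts[[nm]]
  diag(Q) <- -rowSums(Q)
  if (scale) {
    rate <- -sum(pi * diag(Q))
    if (rate <= 0) stop("degenerate rate matrix: zero total rate")
    Q <- Q / rate
    attr(Q, "rate_unscaled") <- rate
  }
  Q
}

#' Instantaneous rate matrix of a codon model
#'
#' Builds the 61 x 61 MG-style generator: zero for multi-nucleotide changes;
#' single-nucleotide changes get the target nucleotide's frequency at the
#' changed position, times `kappa` for transitions and `omega` for
#' nonsynonymous changes. Rows sum to zero and the matrix is rescaled so the
#' expected substitution rate at equilibrium is 1 per codon (branch lengths
#' are then expected substitutions per codon).
#'
#' @param model A [codon_model()].
#' @return 61 x 61 rate matrix (attribute `rate_unscaled` holds the
#'   pre-scaling equilibrium rate).
#' @export
codon_rate_matrix <- function(model) {
  stopifnot(inherits(model, "codon_model"))
  parts <- mg_rate_parts(model$freqs_nt)
  k <- model$kappa
  w <- model$omega
  assemble_q(parts,
             c(syn_tv = 1, syn_ts = k, non_tv = w, non_ts = w * k),
             model$pi)
}

# Per-codon synonymous/nonsynonymous flux of the *unit-multiplier* (neutral)
# MG matrix, and the implied site counts: N + S = 3 sites per codon split in
# proportion to neutral mutational flux.
neutral_site_composition <- function(kappa, freqs_nt) {
  parts <- mg_rate_parts(freqs_nt)
  pi <- f3x4_frequencies(freqs_nt)
  eS <- sum(pi * rowSums(parts$syn_tv + kappa * parts$syn_ts))
  eN <- sum(pi * rowSums(parts$non_tv + kappa * parts$non_ts))
  list(eS = eS, eN = eN, S = 3 * eS / (eS + eN), N = 3 * eN / (eS + eN))
}

#' Convert branch lengths to per-branch Ka and Ks
#'
#' For a branch of length `t` (expected substitutions per codon) evolved under
#' `model`, returns the implied nonsynonymous substitutions per nonsynonymous
#' site (Ka) and synonymous substitutions per synonymous site (Ks), with sites
#' counted from the neutral mutational flux of the model at equilibrium.
#'
#' @param model A [codon_model()].
#' @param t Numeric vector of branch lengths.
#' @return Tibble with columns `t`, `Ka`, `Ks`.
#' @export
kaks_from_lengths <- function(model, t) {
  comp <- neutral_site_composition(model$kappa, model$freqs_nt)
  rate <- comp$eS + model$omega * comp$eN # unscaled total rate
  syn_per_codon <- t * comp$eS / rate
  non_per_codon <- t * model$omega * comp$eN / rate
  tibble::tibble(t = t, Ka = non_per_codon / comp$N, Ks = syn_per_codon / comp$S)
}
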