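# Tree log-likelihood under the codon model: thin R wrapper over the C++
# pruning core. Trees are ape "phylo" objects with branch lengths in expected
# substitutions per codon.

# Validate and reorder a tree for the pruning core.
prepare_tree <- function(tree, aln = NULL) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  if (anyDuplicated(tree$tip.label) > 0L) stop("duplicate tip labels")
  if (!is.null(aln)) {
    miss <- setdiff(tree$tip.label, aln$names)
    if (length(miss) > 0L) {
      stop("tree tip(s) without sequence: ", paste(miss, collapse = ", "))
    }
  }
  tree <- ape::reorder.phylo(tree, "postorder")
  list(edge = matrix(as.integer(tree$edge), ncol = 2L),
       ntip = length(tree$tip.label),
       tip_labels = tree$tip.label,
       t = tree$edge.length,
       tree = tree)
}

eig_cube <- function(eigs) {
  C <- length(eigs)
  list(
    left = array(vapply(eigs, function(e) e$left, matrix(0, 61, 61)),
                 dim = c(61, 61, C)),
    right = array(vapply(eigs, function(e) e$right, matrix(0, 61, 61)),
                  dim = c(61, 61, C)),
    lam = vapply(eigs, function(e) as.numeric(e$lam), numeric(61))
  )
}

# Shared driver: patterns + per-edge class structure -> lnL (and gradient).
tree_lnl_core <- function(pat, pt, eigs, eclass, t, pi, grad = FALSE) {
  cubes <- eig_cube(eigs)
  lam <- cubes$lam
  if (is.null(dim(lam))) lam <- matrix(lam, ncol = length(eigs))
  cpp_tree_lnl(pt$edge, pt$ntip, pat$codes - 1L, pat$weights, pi,
               cubes$left, cubes$right, lam,
               as.integer(eclass), t, grad)
}

#' Log-likelihood of an alignment on a tree under a codon model
#'
#' Felsenstein pruning over codon site patterns; gap and ambiguous codons are
#' treated as missing data. The model is time-reversible, so the value does
#' not depend on root placement.
#'
#' @param aln A [codon_alignment()] containing (at least) every tree tip.
#' @param tree An ape `phylo` tree with branch lengths in expected
#'   substitutions per codon.
#' @param model A [codon_model()].
#' @return The log-likelihood (a scalar).
#' @export
log_likelihood <- function(aln, tree, model) {
  stopifnot(inherits(aln, "codon_alignment"), inherits(model, "codon_model"))
  pt <- prepare_tree(tree, aln)
  pat <- site_patterns(aln, pt$tip_labels)
  eig <- cpp_eig_rev(codon_rate_matrix(model), model$pi)
  res <- tree_lnl_core(pat, pt, list(eig), rep(1L, nrow(pt$edge)), pt$t,
                       model$pi, grad = FALSE)
  res$lnl
}
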