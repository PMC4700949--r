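# Species-tree versus gene-conversion-tree comparison. A "GC tree" is the
# species-tree topology with one putatively converted paralog pruned and
# regrafted as sister to its WGD partner; all GC trees for the candidate
# paralog pairs are fit under the codon model and the improvement of the best
# GC tree over the species tree is assessed by parametric bootstrap.

are_sisters <- function(tree, a, b) {
  ia <- match(a, tree$tip.label)
  ib <- match(b, tree$tip.label)
  pa <- tree$edge[match(ia, tree$edge[, 2]), 1]
  pb <- tree$edge[match(ib, tree$edge[, 2]), 1]
  pa == pb
}

# Prune `moved` and reattach it as sister to tip `target`, at the midpoint of
# target's branch; the moved tip's new branch length matches the attachment
# depth (starting values only - branch lengths are re-optimized in every fit).
regraft_sister <- function(tree, moved, target) {
  tr <- ape::drop.tip(tree, moved)
  at <- match(target, tr$tip.label)
  el <- tr$edge.length[match(at, tr$edge[, 2])]
  phytools::bind.tip(tr, moved, edge.length = el / 2, where = at,
                     position = el / 2)
}

same_topology <- function(t1, t2) {
  if (length(t1$tip.label) < 4L) {
    return(isTRUE(ape::all.equal.phylo(t1, t2, use.edge.length = FALSE)))
  }
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}

#' Enumerate gene-conversion trees for paralog pairs
#'
#' For every same-species WGD paralog pair, builds the two regrafted trees
#' (each paralog moved to be sister of the other). Pairs already sisters in
#' the species tree contribute no tree; duplicate topologies are removed.
#'
#' @param species_tree ape `phylo` containing all pair members as tips.
#' @param pairs Data frame with columns `gene1`, `gene2` (one row per paralog
#'   pair), or a list of length-2 character vectors.
#' @return An object of class `gc_tree_set`: list with `species_tree` and
#'   `trees`, a tibble with columns `id`, `moved_tip`, `target_tip`, `tree`
#'   (list column of `phylo`).
#' @export
enumerate_gc_trees <- function(species_tree, pairs) {
  if (is.data.frame(pairs)) {
    pairs <- purrr::map2(pairs$gene1, pairs$gene2, c)
  }
  rows <- list()
  kept <- list()
  for (pr in pairs) {
    miss <- setdiff(pr, species_tree$tip.label)
    if (length(miss) > 0L) {
      stop("paralog pair tip(s) missing from tree: ",
           paste(miss, collapse = ", "))
    }
    if (are_sisters(species_tree, pr[1], pr[2])) next
    for (dir in 1:2) {
      moved <- pr[dir]
      target <- pr[3 - dir]
      cand <- regraft_sister(species_tree, moved, target)
      if (any(vapply(kept, same_topology, logical(1), t2 = cand))) next
      kept[[length(kept) + 1L]] <- cand
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = paste0("gc_", length(rows) + 1L),
        moved_tip = moved, target_tip = target, tree = list(cand)
      )
    }
  }
  trees <- if (length(rows) > 0) dplyr::bind_rows(rows) else {
    tibble::tibble(id = character(0), moved_tip = character(0),
                   target_tip = character(0), tree = list())
  }
  structure(list(species_tree = species_tree, trees = trees),
            class = "gc_tree_set")
}

#' @export
print.gc_tree_set <- function(x, ...) {
  cat("gc_tree_set:", nrow(x$trees), "GC tree(s) on",
      length(x$species_tree$tip.label), "tips\n")
  invisible(x)
}

#' Fit the species tree and every GC tree to an alignment
#'
#' Branch lengths (and `kappa`, `omega`) are re-optimized independently for
#' each topology; the GC tree with the largest log-likelihood is retained as
#' the best.
#'
#' @param aln A [codon_alignment()] covering all tips.
#' @param gc_set A [enumerate_gc_trees()] result.
#' @param start Optional list with elements `model` and `tree` (a fitted
#'   species tree) used as warm starts.
#' @param restarts Optimizer restarts per topology.
#' @param factr Convergence tolerance factor (see [fit_codon_model()]).
#' @return Object of class `gc_tree_fits`: `fits` tibble (`id`, `lnL`,
#'   `kappa`, `omega`, `converged`; first row is the species tree),
#'   `best_gc` (id), `delta` (best GC lnL minus species lnL), plus the
#'   underlying `codon_fit` objects in `$fit_objects`.
#' @export
compare_gc_trees <- function(aln, gc_set, start = NULL, restarts = 1,
                             factr = 1e9) {
  stopifnot(inherits(gc_set, "gc_tree_set"))
  spp_tree <- if (!is.null(start$tree)) start$tree else gc_set$species_tree
  model <- start$model
  fit_spp <- fit_codon_model(aln, spp_tree, model = model,
                             restarts = restarts, factr = factr)
  fits <- list(species = fit_spp)
  for (k in seq_len(nrow(gc_set$trees))) {
    id <- gc_set$trees$id[k]
    gtr <- gc_set$trees$tree[[k]]
    if (!is.null(start$tree)) {
      gtr <- regraft_sister(start$tree, gc_set$trees$moved_tip[k],
                            gc_set$trees$target_tip[k])
    }
    fits[[id]] <- fit_codon_model(aln, gtr, model = model,
                                  restarts = restarts, factr = factr)
  }
  tab <- dplyr::bind_rows(purrr::imap(fits, function(f, id) {
    tibble::tibble(id = id, lnL = f$lnL, kappa = f$model$kappa,
                   omega = f$model$omega, converged = f$converged)
  }))
  gc_tab <- tab[tab$id != "species", ]
  best <- if (nrow(gc_tab) > 0) gc_tab$id[which.max(gc_tab$lnL)] else NA_character_
  delta <- if (nrow(gc_tab) > 0) max(gc_tab$lnL) - fit_spp$lnL else NA_real_
  structure(list(fits = tab, best_gc = best, delta = delta,
                 fit_objects = fits),
            class = "gc_tree_fits")
}

#' @export
print.gc_tree_fits <- function(x, ...) {
  cat("species tree lnL:", format(x$fits$lnL[x$fits$id == "species"],
                                  digits = 8), "\n")
  cat("best GC tree:", x$best_gc, " delta lnL:", format(x$delta, digits = 6),
      "\n")
  invisible(x)
}

#' Parametric bootstrap for the species-tree vs GC-tree comparison
#'
#' Fits the species tree to the data, simulates `n_reps` alignments of the
#' same length under the species-tree maximum-likelihood parameters, refits
#' the species tree and every GC tree to each replicate, and records the
#' per-replicate maximum improvement of a GC tree over the species tree. The
#' P value uses the `(k + 1) / (N + 1)` estimator, so "no exceedance in N
#' replicates" reports `1 / (N + 1)`.
#'
#' @inheritParams compare_gc_trees
#' @param n_reps Number of bootstrap replicates (the full analysis default is
#'   1000; scale down for exploratory runs).
#' @param seed Optional integer seed covering the whole bootstrap.
#' @param refit_params If `TRUE` (default), `kappa` and `omega` are
#'   re-estimated in every replicate fit; if `FALSE` they stay fixed at the
#'   generating maximum-likelihood estimates and only branch lengths are
#'   re-optimized.
#' @param max_redraw_frac Replicates whose fits fail are re-drawn, up to this
#'   fraction of `n_reps`.
#' @param replicate_factr Convergence tolerance factor for the replicate
#'   refits (looser than the data fit: the null statistic needs ~1e-4 lnL
#'   precision, not 1e-6).
#' @return Object of class `gc_bootstrap`: `observed_delta`, `null_deltas`,
#'   `n_reps`, `p_value`, `seed`, `observed` (the data's `gc_tree_fits`),
#'   `n_redraws`.
#' @export
parametric_bootstrap <- function(aln, gc_set, n_reps = 1000, seed = NULL,
                                 restarts = 1, refit_params = TRUE,
                                 max_redraw_frac = 0.05,
                                 replicate_factr = 1e11) {
  stopifnot(inherits(gc_set, "gc_tree_set"))
  if (!is.null(seed)) set.seed(seed)
  observed <- compare_gc_trees(aln, gc_set, restarts = restarts)
  fit_spp <- observed$fit_objects$species
  mle_model <- fit_spp$model
  mle_tree <- fit_spp$tree
  n_codons <- aln$n_codons

  # warm-start topologies: GC regrafts of the MLE species tree
  start <- list(model = mle_model, tree = mle_tree)
  null_deltas <- numeric(0)
  n_redraws <- 0L
  max_redraws <- ceiling(max_redraw_frac * n_reps)
  while (length(null_deltas) < n_reps) {
    rep_aln <- simulate_codon_alignment(mle_tree, mle_model, n_codons)
    res <- try({
      # mirror the observed computation: frequencies re-estimated from the
      # replicate itself, kappa/omega/branch lengths warm-started at the MLEs
      rep_start <- list(
        model = codon_model(kappa = mle_model$kappa, omega = mle_model$omega,
                            freqs_nt = empirical_nt_freqs(rep_aln)),
        tree = start$tree
      )
      cmp <- compare_gc_trees(rep_aln, gc_set, start = rep_start, restarts = 0,
                              factr = replicate_factr)
      if (!refit_params) {
        # refit with kappa/omega pinned at the generating values
        refit_one <- function(tr) {
          fit_codon_model(rep_aln, tr, model = mle_model, kappa_free = FALSE,
                          omega_free = FALSE, restarts = 0,
                          factr = replicate_factr)
        }
        f0 <- refit_one(mle_tree)
        gl <- vapply(seq_len(nrow(gc_set$trees)), function(k) {
          refit_one(regraft_sister(mle_tree, gc_set$trees$moved_tip[k],
                                   gc_set$trees$target_tip[k]))$lnL
        }, numeric(1))
        cmp$delta <- max(gl) - f0$lnL
      }
      cmp$delta
    }, silent = TRUE)
    if (inherits(res, "try-error") || !is.finite(res)) {
      n_redraws <- n_redraws + 1L
      if (n_redraws > max_redraws) {
        stop("too many failed bootstrap replicates (", n_redraws, ")")
      }
      next
    }
    null_deltas <- c(null_deltas, res)
  }
  p <- (sum(null_deltas >= observed$delta) + 1) / (n_reps + 1)
  structure(
    list(observed_delta = observed$delta, null_deltas = null_deltas,
         n_reps = n_reps, p_value = p, seed = seed, observed = observed,
         n_redraws = n_redraws),
    class = "gc_bootstrap"
  )
}

#' @export
print.gc_bootstrap <- function(x, ...) {
  cat("parametric bootstrap:", x$n_reps, "replicates\n")
  cat("observed delta lnL:", format(x$observed_delta, digits = 6),
      "  p =", format(x$p_value, digits = 4), "\n")
  invisible(x)
}

#' @rdname parametric_bootstrap
#' @param x A `gc_bootstrap`.
#' @param ... Unused.
#' @export
tidy.gc_bootstrap <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$null_deltas),
                 delta_lnL = x$null_deltas)
}

#' @rdname parametric_bootstrap
#' @export
glance.gc_bootstrap <- function(x, ...) {
  tibble::tibble(observed_delta = x$observed_delta, n_reps = x$n_reps,
                 p_value = x$p_value, n_redraws = x$n_redraws,
                 best_gc = x$observed$best_gc)
}

#' Serialize a bootstrap result to JSON
#'
#' @param x A `gc_bootstrap`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bootstrap_json <- function(x, path) {
  stopifnot(inherits(x, "gc_bootstrap"))
  jsonlite::write_json(
    list(observed_delta = x$observed_delta, null_deltas = x$null_deltas,
         n_replicates = x$n_reps, p_value = x$p_value, seed = x$seed,
         per_tree_lnL = as.list(stats::setNames(x$observed$fits$lnL,
                                                x$observed$fits$id)),
         n_redraws = x$n_redraws),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
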