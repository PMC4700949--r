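# Similarity-groups (SG) codon model: amino acids are partitioned into polar
# and nonpolar groups and the nonsynonymous multiplier splits into Rc for
# conservative (within-group) and Rr for radical (between-group) changes.
# Branches may be divided into classes (e.g. a converted clade vs the rest),
# each with its own (Rc, Rr); kappa and branch lengths are shared.

# Edge classes on the prepared (postorder) tree: the converted class is the
# two converted tip branches plus the branch above their most recent common
# ancestor (which exists as a distinct branch only when the tips are placed
# as sisters, i.e. on a GC topology).
sg_edge_classes <- function(pt, converted_tips) {
  E <- nrow(pt$edge)
  cls <- rep("background", E)
  if (is.null(converted_tips) || length(converted_tips) == 0L) return(cls)
  miss <- setdiff(converted_tips, pt$tip_labels)
  if (length(miss) > 0L) stop("converted tip(s) not in tree: ",
                              paste(miss, collapse = ", "))
  tipidx <- match(converted_tips, pt$tip_labels)
  cls[pt$edge[, 2] %in% tipidx] <- "converted"
  if (length(tipidx) >= 2L) {
    mrca <- ape::getMRCA(pt$tree, converted_tips)
    k <- match(mrca, pt$edge[, 2])
    if (!is.na(k)) cls[k] <- "converted"
  }
  cls
}

#' Fit the SG codon model
#'
#' Maximum-likelihood fit of branch lengths, `kappa`, and per-branch-class
#' `(Rc, Rr)` selective constraints. When the partition has a single group
#' there are no radical changes and `Rr` is tied to `Rc`, collapsing the model
#' to the plain MG/GY fit with `omega = Rc`.
#'
#' @param aln A [codon_alignment()].
#' @param tree ape `phylo` (unrooted internally).
#' @param converted_tips Optional character vector of tips forming the
#'   converted class (their terminal branches plus the branch above their
#'   most recent common ancestor); all other branches are `background`. With
#'   `NULL`, a single class covers the whole tree.
#' @param partition Amino-acid partition (see
#'   [default_polarity_partition()]).
#' @param constrain_classes Character vector of class names in which the null
#'   constraint `Rr = Rc` is imposed (default none).
#' @param restarts Optimizer restarts.
#' @return Object of class `sg_fit`: `classes` tibble (`class`, `Rc`, `Rr`,
#'   `ratio`, `ratio_undefined`), `kappa`, `lnL`, `blens`, `converged`,
#'   `n_evals`, `partition`.
#' @export
fit_sg <- function(aln, tree, converted_tips = NULL,
                   partition = default_polarity_partition(),
                   constrain_classes = character(0), restarts = 1) {
  stopifnot(inherits(aln, "codon_alignment"))
  partition <- validate_partition(partition)
  if (ape::is.rooted(tree) && length(tree$tip.label) > 2L) {
    tree <- ape::unroot(tree)
  }
  pt <- prepare_tree(tree, aln)
  pat <- site_patterns(aln, pt$tip_labels)
  cls <- sg_edge_classes(pt, converted_tips)
  class_names <- unique(c("background", "converted")[
    c("background", "converted") %in% cls])
  eclass <- match(cls, class_names)
  freqs_nt <- empirical_nt_freqs(aln)
  pi <- f3x4_frequencies(freqs_nt)
  parts <- mg_rate_parts(freqs_nt, partition = partition)
  one_group <- sum(parts$rad_tv) + sum(parts$rad_ts) == 0

  # rate-parameter layout: kappa, then per class Rc (and Rr unless tied)
  tied <- one_group | class_names %in% constrain_classes
  names(tied) <- class_names
  layout <- list(kappa = 1L)
  k <- 1L
  for (cn in class_names) {
    k <- k + 1L
    layout[[paste0("Rc_", cn)]] <- k
    if (!tied[[cn]]) {
      k <- k + 1L
      layout[[paste0("Rr_", cn)]] <- k
    }
  }
  rp0 <- numeric(k)
  rp0[1] <- 2
  for (cn in class_names) {
    rp0[layout[[paste0("Rc_", cn)]]] <- 0.2
    if (!tied[[cn]]) rp0[layout[[paste0("Rr_", cn)]]] <- 0.2
  }

  parts_cube <- array(c(parts$syn_tv, parts$syn_ts, parts$con_tv,
                        parts$con_ts, parts$rad_tv, parts$rad_ts),
                      dim = c(61, 61, 6))
  make_eigs <- function(rp) {
    kap <- rp[1]
    lapply(class_names, function(cn) {
      Rc <- rp[layout[[paste0("Rc_", cn)]]]
      Rr <- if (tied[[cn]]) Rc else rp[layout[[paste0("Rr_", cn)]]]
      cpp_build_eig(parts_cube,
                    c(1, kap, Rc, Rc * kap, Rr, Rr * kap), pi, TRUE)
    })
  }

  res <- optim_tree_lik(pat, pt, pi, make_eigs, rp0, eclass, t0 = pt$t,
                        restarts = restarts)
  rp <- res$rate_par
  floor_tol <- 1e-6
  classes <- dplyr::bind_rows(lapply(class_names, function(cn) {
    Rc <- rp[layout[[paste0("Rc_", cn)]]]
    Rr <- if (tied[[cn]]) Rc else rp[layout[[paste0("Rr_", cn)]]]
    undef <- Rc <= floor_tol
    tibble::tibble(class = cn, Rc = Rc, Rr = Rr,
                   ratio = if (undef) NA_real_ else Rr / Rc,
                   ratio_undefined = undef)
  }))
  child <- pt$edge[, 2]
  lab <- ifelse(child <= pt$ntip, pt$tip_labels[child], paste0("n", child))
  structure(
    list(classes = classes, kappa = rp[1], lnL = res$lnl,
         blens = stats::setNames(res$t, lab), converged = res$converged,
         n_evals = res$n_evals, partition = partition,
         constrained = class_names[tied & !one_group],
         one_group = one_group),
    class = "sg_fit"
  )
}

#' @export
print.sg_fit <- function(x, ...) {
  cat("SG model fit: lnL =", format(x$lnL, digits = 8),
      " kappa =", signif(x$kappa, 4), "\n")
  print(as.data.frame(x$classes), row.names = FALSE)
  invisible(x)
}

#' @rdname fit_sg
#' @param x An `sg_fit`.
#' @param ... Unused.
#' @export
tidy.sg_fit <- function(x, ...) {
  x$classes
}

#' @rdname fit_sg
#' @export
glance.sg_fit <- function(x, ...) {
  tibble::tibble(logLik = x$lnL, kappa = x$kappa,
                 n_classes = nrow(x$classes), converged = x$converged,
                 n_evals = x$n_evals)
}

#' Likelihood-ratio test of Rr = Rc per branch class
#'
#' Fits the free SG model and, for each tested class, a null model with
#' `Rr = Rc` imposed in that class; P values use chi-square with 1 degree of
#' freedom. Raw P values can be corrected across a family of tests with
#' [sg_fdr()].
#'
#' @inheritParams fit_sg
#' @param test Classes to test (default every class present).
#' @return Tibble with one row per tested class: `class`, `Rc`, `Rr`,
#'   `ratio`, `ratio_undefined`, `lnL_free`, `lnL_constrained`, `stat`,
#'   `P_raw`.
#' @export
sg_lrt <- function(aln, tree, converted_tips = NULL,
                   partition = default_polarity_partition(),
                   test = NULL, restarts = 1) {
  free <- fit_sg(aln, tree, converted_tips, partition, restarts = restarts)
  if (is.null(test)) test <- free$classes$class
  rows <- lapply(test, function(cn) {
    con <- fit_sg(aln, tree, converted_tips, partition,
                  constrain_classes = cn, restarts = restarts)
    stat <- max(0, 2 * (free$lnL - con$lnL))
    row <- free$classes[free$classes$class == cn, ]
    tibble::tibble(class = cn, Rc = row$Rc, Rr = row$Rr, ratio = row$ratio,
                   ratio_undefined = row$ratio_undefined,
                   lnL_free = free$lnL, lnL_constrained = con$lnL,
                   stat = stat,
                   P_raw = stats::pchisq(stat, df = 1, lower.tail = FALSE))
  })
  dplyr::bind_rows(rows)
}

#' Benjamini-Hochberg correction for a family of SG tests
#'
#' @param results Tibble with a `P_raw` column (rows = tests in the family).
#' @return The tibble with a `P_fdr` column appended.
#' @export
sg_fdr <- function(results) {
  stopifnot("P_raw" %in% names(results))
  results$P_fdr <- stats::p.adjust(results$P_raw, method = "BH")
  results
}

#' One-sided binomial sign test
#'
#' Upper-tail probability of observing at least `k` successes in `n` trials
#' under success probability `p0` (e.g. the chance that Rr exceeds Rc in at
#' least `k` of `n` independent gene families if exceedances were coin
#' flips).
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials.
#' @param p0 Null success probability.
#' @return One-sided P value.
#' @export
binomial_sign_test <- function(k, n, p0 = 0.5) {
  if (k < 0 || n < 1 || k > n) stop("need 0 <= k <= n with n >= 1")
  stats::binom.test(k, n, p = p0, alternative = "greater")$p.value
}
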