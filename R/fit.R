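# Maximum-likelihood fitting of codon models: branch lengths by L-BFGS-B with
# analytic gradients from the pruning core; rate parameters (kappa, omega, and
# the SG constraints) on the log scale with central-difference gradients.
# Parameters are bounded in [1e-8, 100]; convergence tolerance ~1e-6 in lnL.

PAR_LOWER <- log(1e-8)
PAR_UPPER <- log(100)

# Generic optimizer over (branch lengths, rate parameters) for a model family
# described by `make_eigs`, a function from the natural-scale rate-parameter
# vector to a list of per-class eigendecompositions.
optim_tree_lik <- function(pat, pt, pi, make_eigs, rate_par0, eclass,
                           t0, optimize_blens = TRUE, restarts = 0,
                           maxit = 500, factr = 1e9) {
  E <- nrow(pt$edge)
  nr <- length(rate_par0)
  if (!optimize_blens && nr == 0L) stop("no free parameters to optimize")

  cache <- new.env(parent = emptyenv())
  get_eigs <- function(rp) {
    key <- paste(signif(rp, 15), collapse = ",")
    if (!identical(cache$key, key)) {
      cache$key <- key
      cache$eigs <- make_eigs(rp)
    }
    cache$eigs
  }
  n_evals <- 0L

  split_par <- function(par) {
    if (optimize_blens) {
      list(t = exp(par[seq_len(E)]),
           rp = if (nr > 0) exp(par[E + seq_len(nr)]) else numeric(0))
    } else {
      list(t = t0, rp = exp(par))
    }
  }
  fn <- function(par) {
    sp <- split_par(par)
    n_evals <<- n_evals + 1L
    res <- tree_lnl_core(pat, pt, get_eigs(sp$rp), eclass, sp$t, pi,
                         grad = FALSE)
    -res$lnl
  }
  gr <- function(par) {
    sp <- split_par(par)
    g <- numeric(length(par))
    if (optimize_blens) {
      res <- tree_lnl_core(pat, pt, get_eigs(sp$rp), eclass, sp$t, pi,
                           grad = TRUE)
      n_evals <<- n_evals + 1L
      g[seq_len(E)] <- -res$grad * sp$t # chain rule for log-scale lengths
      off <- E
      f0 <- -res$lnl
    } else {
      off <- 0L
      f0 <- fn(par)
    }
    if (nr > 0) {
      # forward differences reusing the analytic-gradient evaluation
      h <- 1e-5
      for (k in seq_len(nr)) {
        pp <- par
        pp[off + k] <- pp[off + k] + h
        g[off + k] <- (fn(pp) - f0) / h
      }
    }
    g
  }

  par0 <- c(if (optimize_blens) log(pmin(pmax(t0, 1e-6), 90)),
            log(pmin(pmax(rate_par0, 1e-8), 90)))
  starts <- list(par0)
  if (restarts > 0) {
    for (r in seq_len(restarts)) {
      starts[[r + 1L]] <- pmin(pmax(par0 + stats::runif(length(par0), -0.7, 0.7),
                                    PAR_LOWER), PAR_UPPER)
    }
  }
  best <- NULL
  for (st in starts) {
    opt <- try(stats::optim(st, fn, gr, method = "L-BFGS-B",
                            lower = PAR_LOWER, upper = PAR_UPPER,
                            control = list(maxit = maxit, factr = factr)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("optimizer failed from every start")
  sp <- split_par(best$par)
  list(lnl = -best$value, t = sp$t, rate_par = sp$rp,
       converged = best$convergence == 0L, n_evals = n_evals)
}

#' Fit an MG/GY codon model by maximum likelihood
#'
#' Optimizes branch lengths and (optionally) `kappa` and `omega` on a fixed
#' topology. Branch lengths use analytic gradients; all parameters are bounded
#' in `[1e-8, 100]` on the natural scale.
#'
#' @param aln A [codon_alignment()].
#' @param tree ape `phylo` tree (rooted trees are unrooted internally; the
#'   likelihood is root-invariant). Existing branch lengths seed the search.
#' @param model Optional starting [codon_model()]; by default nucleotide
#'   frequencies are estimated empirically from the alignment and
#'   `kappa = 2`, `omega = 0.2` seed the search.
#' @param kappa_free,omega_free Whether to estimate `kappa` / `omega` (if
#'   `FALSE` they stay at the starting value).
#' @param optimize_blens Whether to optimize branch lengths.
#' @param restarts Number of random restarts around the starting point.
#' @param factr L-BFGS-B convergence tolerance factor (`factr * 1e-15`
#'   approximates the absolute lnL tolerance; the default corresponds to
#'   about 1e-6).
#' @return An object of class `codon_fit`: fields `lnL`, `model` (MLE),
#'   `tree` (with MLE branch lengths), `blens` (named by child node),
#'   `converged`, `n_evals`, `n_codons`.
#' @export
fit_codon_model <- function(aln, tree, model = NULL, kappa_free = TRUE,
                            omega_free = TRUE, optimize_blens = TRUE,
                            restarts = 3, factr = 1e9) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (is.null(model)) {
    model <- codon_model(kappa = 2, omega = 0.2,
                         freqs_nt = empirical_nt_freqs(aln))
  }
  if (ape::is.rooted(tree) && length(tree$tip.label) > 2L) {
    tree <- ape::unroot(tree)
  }
  pt <- prepare_tree(tree, aln)
  pat <- site_patterns(aln, pt$tip_labels)
  parts <- mg_rate_parts(model$freqs_nt)
  pi <- model$pi
  E <- nrow(pt$edge)

  free <- c(kappa = kappa_free, omega = omega_free)
  rp0 <- c(model$kappa, model$omega)[free]
  parts_cube <- array(c(parts$syn_tv, parts$syn_ts, parts$non_tv,
                        parts$non_ts), dim = c(61, 61, 4))
  make_eigs <- function(rp) {
    kw <- c(model$kappa, model$omega)
    kw[free] <- rp
    list(cpp_build_eig(parts_cube, c(1, kw[1], kw[2], kw[2] * kw[1]), pi,
                       TRUE))
  }

  res <- optim_tree_lik(pat, pt, pi, make_eigs, rp0, rep(1L, E),
                        t0 = pt$t, optimize_blens = optimize_blens,
                        restarts = restarts, factr = factr)
  kw <- c(model$kappa, model$omega)
  kw[free] <- res$rate_par
  mle <- codon_model(kappa = kw[1], omega = kw[2], freqs_nt = model$freqs_nt)
  fitted_tree <- pt$tree
  fitted_tree$edge.length <- res$t
  child <- pt$edge[, 2]
  lab <- ifelse(child <= pt$ntip, pt$tip_labels[child], paste0("n", child))
  structure(
    list(lnL = res$lnl, model = mle, tree = fitted_tree,
         blens = stats::setNames(res$t, lab), converged = res$converged,
         n_evals = res$n_evals, n_codons = aln$n_codons),
    class = "codon_fit"
  )
}

#' @export
print.codon_fit <- function(x, ...) {
  cat("codon model fit: lnL =", format(x$lnL, digits = 8),
      " kappa =", signif(x$model$kappa, 4),
      " omega =", signif(x$model$omega, 4),
      if (!x$converged) " [not converged]", "\n")
  invisible(x)
}

#' Tidy a codon model fit
#'
#' @param x A `codon_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter (`kappa`, `omega`, and one
#'   `t:<child>` branch length per edge).
#' @export
tidy.codon_fit <- function(x, ...) {
  tibble::tibble(
    term = c("kappa", "omega", paste0("t:", names(x$blens))),
    estimate = c(x$model$kappa, x$model$omega, unname(x$blens))
  )
}

#' One-row summary of a codon model fit
#'
#' @param x A `codon_fit`.
#' @param ... Unused.
#' @return One-row tibble: `logLik`, `kappa`, `omega`, `tree_length`,
#'   `n_codons`, `converged`, `n_evals`.
#' @export
glance.codon_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$lnL, kappa = x$model$kappa, omega = x$model$omega,
    tree_length = sum(x$blens), n_codons = x$n_codons,
    converged = x$converged, n_evals = x$n_evals
  )
}

#' Serialize a codon fit to JSON
#'
#' @param x A `codon_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(x, path) {
  stopifnot(inherits(x, "codon_fit"))
  jsonlite::write_json(
    list(lnL = x$lnL, kappa = x$model$kappa, omega = x$model$omega,
         branch_lengths = as.list(x$blens), converged = x$converged,
         n_evals = x$n_evals),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
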