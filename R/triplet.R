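# Triplet relative-rate test for gene conversion: the two WGD paralogs
# (D1, D2) and the ortholog O of D1 sit on an unrooted 3-branch star tree,
# each branch carrying its own nonsynonymous (Ka) and synonymous (Ks)
# divergence. Without conversion, D1 and O are separated from the star center
# by a recent speciation and should show equal divergence; conversion between
# D1 and D2 pulls D1's divergence below O's. The null model ties the chosen
# rate on the D1 branch to the O branch and the LRT uses chi-square(1).

triplet_prep <- function(aln, d1, d2, o) {
  labs <- c(d1, d2, o)
  if (anyDuplicated(labs) > 0L) stop("d1, d2 and o must name distinct sequences")
  sub <- subset_alignment(aln, labs)
  if (length(sub$names) != 3L) stop("triplet requires exactly 3 sequences")
  freqs_nt <- empirical_nt_freqs(sub)
  parts <- mg_rate_parts(freqs_nt)
  pat <- site_patterns(sub, labs)
  list(codes = pat$codes - 1L, w = pat$weights,
       pi = f3x4_frequencies(freqs_nt), parts = parts, labs = labs)
}

# Full-parameter vector layout: log kappa, then (log Ka, log Ks) for
# D1, D2, O. `tie` maps a reduced vector onto it for the constrained fits.
triplet_optim <- function(prep, constrain = "none", start = NULL,
                          restarts = 1) {
  expand <- switch(
    constrain,
    none = function(p) p,
    Ka = function(p) c(p[1:5], p[2], p[6]), # Ka(O) := Ka(D1)
    Ks = function(p) c(p[1:6], p[3]),       # Ks(O) := Ks(D1)
    stop("constrain must be 'none', 'Ka' or 'Ks'")
  )
  npar <- if (constrain == "none") 7L else 6L
  if (is.null(start)) {
    start <- c(log(2), rep(c(log(0.02), log(0.2)), 3))
  }
  start <- start[seq_len(npar)]
  last <- new.env(parent = emptyenv())
  nll <- function(p) {
    v <- cpp_triplet_nll(expand(p), prep$codes, prep$w, prep$pi,
                         prep$parts$syn_tv, prep$parts$syn_ts,
                         prep$parts$non_tv, prep$parts$non_ts)
    last$p <- p
    last$v <- v
    v
  }
  grf <- function(p) {
    f0 <- if (identical(p, last$p)) last$v else nll(p)
    h <- 1e-5
    vapply(seq_along(p), function(k) {
      pp <- p
      pp[k] <- pp[k] + h
      (nll(pp) - f0) / h
    }, numeric(1))
  }
  starts <- list(start)
  if (restarts > 0) {
    for (r in seq_len(restarts)) {
      starts[[r + 1L]] <- pmin(pmax(start + stats::runif(npar, -1, 1),
                                    PAR_LOWER), PAR_UPPER)
    }
  }
  best <- NULL
  for (st in starts) {
    opt <- try(stats::optim(st, nll, grf, method = "L-BFGS-B", lower = PAR_LOWER,
                            upper = PAR_UPPER,
                            control = list(maxit = 300, factr = 1e9)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("triplet optimizer failed from every start")
  full <- exp(expand(best$par))
  list(lnl = -best$value, kappa = full[1],
       ka = stats::setNames(full[c(2, 4, 6)], c("D1", "D2", "O")),
       ks = stats::setNames(full[c(3, 5, 7)], c("D1", "D2", "O")),
       converged = best$convergence == 0L,
       n_evals = best$counts[["function"]],
       par = best$par)
}

#' Branch-specific Ka/Ks estimates for a WGD triplet
#'
#' Fits the three-branch star tree for paralogs `d1`, `d2` and ortholog `o`,
#' with every branch carrying its own Ka (nonsynonymous substitutions per
#' nonsynonymous site) and Ks (synonymous substitutions per synonymous site);
#' sites are counted from the neutral mutational flux of the MG model at
#' equilibrium, and kappa is shared across branches.
#'
#' @param aln A [codon_alignment()] containing the three sequences.
#' @param d1,d2 Names of the two WGD paralogs.
#' @param o Name of the ortholog of `d1` in the nearest relative.
#' @param restarts Random optimizer restarts.
#' @return Tibble with columns `branch` (D1/D2/O), `gene_id`, `Ka`, `Ks`;
#'   attributes `lnL` and `kappa` carry the fit.
#' @export
estimate_triplet <- function(aln, d1, d2, o, restarts = 1) {
  prep <- triplet_prep(aln, d1, d2, o)
  fit <- triplet_optim(prep, "none", restarts = restarts)
  out <- tibble::tibble(branch = c("D1", "D2", "O"),
                        gene_id = prep$labs,
                        Ka = unname(fit$ka), Ks = unname(fit$ks))
  attr(out, "lnL") <- fit$lnl
  attr(out, "kappa") <- fit$kappa
  out
}

#' Triplet likelihood-ratio test for gene conversion
#'
#' Compares the free model (independent per-branch Ka and Ks) with null
#' models tying the chosen rate on the D1 branch to the O branch. P values
#' come from the upper tail of chi-square with 1 degree of freedom at
#' `2 * (lnL_free - lnL_constrained)`. With `alternative = "equal"` (the
#' default) the constraint is strict equality; `"one.sided"` treats the null
#' as Ka/Ks(D1) >= Ka/Ks(O), returning P = 1 when the free estimates satisfy
#' the null direction and halving the chi-square tail otherwise.
#'
#' @inheritParams estimate_triplet
#' @param rates Which rates to test (`"Ks"`, `"Ka"`, or both).
#' @param alternative `"equal"` or `"one.sided"`.
#' @return One-row tibble: gene ids, per-branch `Ka_*`/`Ks_*`, `kappa`,
#'   `lnL_free`, and per tested rate `lnL_constrained_*`, `stat_*`, `P_*`.
#' @export
triplet_test <- function(aln, d1, d2, o, rates = c("Ka", "Ks"),
                         alternative = c("equal", "one.sided"),
                         restarts = 1) {
  alternative <- match.arg(alternative)
  rates <- match.arg(rates, c("Ka", "Ks"), several.ok = TRUE)
  prep <- triplet_prep(aln, d1, d2, o)
  free <- triplet_optim(prep, "none", restarts = restarts)

  out <- tibble::tibble(
    d1 = d1, d2 = d2, o = o,
    Ka_d1 = free$ka[["D1"]], Ka_d2 = free$ka[["D2"]], Ka_o = free$ka[["O"]],
    Ks_d1 = free$ks[["D1"]], Ks_d2 = free$ks[["D2"]], Ks_o = free$ks[["O"]],
    kappa = free$kappa, lnL_free = free$lnl
  )
  for (rate in rates) {
    con <- triplet_optim(prep, rate, start = free$par[seq_len(6)],
                         restarts = 0)
    # guard optimizer failures: the null is nested, so lnL cannot exceed free
    lnl_free <- free$lnl
    if (con$lnl > lnl_free + 1e-6) {
      refit <- triplet_optim(prep, "none", start = c(con$par, con$par[6]),
                             restarts = restarts + 1)
      if (refit$lnl > lnl_free) {
        lnl_free <- refit$lnl
        out$lnL_free <- lnl_free
      }
    }
    stat <- max(0, 2 * (lnl_free - con$lnl))
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    if (alternative == "one.sided") {
      est <- if (rate == "Ka") free$ka else free$ks
      p <- if (est[["D1"]] >= est[["O"]]) 1 else p / 2
    }
    out[[paste0("lnL_constrained_", rate)]] <- con$lnl
    out[[paste0("stat_", rate)]] <- stat
    out[[paste0("P_", rate)]] <- p
  }
  out
}

#' Serialize a triplet test result to JSON
#'
#' @param x One-row tibble from [triplet_test()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_triplet_json <- function(x, path) {
  jsonlite::write_json(as.list(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
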