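# End-to-end orchestration over one gene family: candidate screen, triplet
# LRT for each candidate, species-tree vs GC-tree parametric bootstrap, and
# the SG radical/conservative fit on the best GC tree.

#' Expected gene-level species topology for a post-WGD family
#'
#' Duplicates the species tree at the root into tracks 1 and 2, renames each
#' tip to the gene occupying that (species, track) slot in the orthology
#' table, and drops slots with no surviving gene.
#'
#' @param species_tree Rooted species-level `phylo`.
#' @param orthology Orthology tibble (see [read_orthology_table()]).
#' @return ape `phylo` whose tips are gene ids.
#' @export
expected_gene_tree <- function(species_tree, orthology) {
  orthology <- validate_orthology_table(orthology)
  doubled <- double_species_tree(species_tree)
  slot <- paste0(orthology$species, "_t", orthology$track)
  hit <- match(doubled$tip.label, slot)
  lost <- doubled$tip.label[is.na(hit)]
  if (length(lost) > 0L) doubled <- ape::drop.tip(doubled, lost)
  doubled$tip.label <- orthology$gene_id[match(doubled$tip.label, slot)]
  doubled
}

#' Run the full gene-conversion detection pipeline on one family
#'
#' Stages run in order: (1) protein-identity screen; (2) triplet Ka/Ks LRT
#' for each screen candidate (D1 = the candidate paralog whose track has an
#' ortholog in the nearest relative, O = that ortholog); (3) enumeration of
#' GC trees for the candidate paralog pairs and the parametric bootstrap of
#' best-GC-tree improvement; (4) SG fit on the best GC tree with the
#' converted pair (plus their ancestral branch) as a separate branch class.
#' Stages 2-4 run only when at least one candidate was flagged, unless
#' `force_all = TRUE` (which treats every double-copy species as a
#' candidate).
#'
#' @param aln Family [codon_alignment()]; sequence names are gene ids.
#' @param species_tree Rooted species-level `phylo`.
#' @param orthology Orthology tibble mapping genes to (species, track).
#' @param neighbor_map Species -> nearest relative (named vector or data
#'   frame); defaults to [nearest_relatives()] on the species tree.
#' @param n_reps Bootstrap replicates.
#' @param seed Integer seed recorded in the result and set before any
#'   stochastic stage.
#' @param alpha Significance level used for flag columns.
#' @param partition SG amino-acid partition.
#' @param force_all Run downstream stages for all double-copy species.
#' @param run_sg Whether to run the SG stage.
#' @param restarts Optimizer restarts for all fits.
#' @return Object of class `conversion_report`: `report` (one tibble row per
#'   double-copy species), `screen`, `triplets`, `bootstrap`, `sg`, `seed`,
#'   `config`.
#' @export
run_conversion_pipeline <- function(aln, species_tree, orthology,
                                    neighbor_map = NULL, n_reps = 1000,
                                    seed = NULL, alpha = 0.05,
                                    partition = default_polarity_partition(),
                                    force_all = FALSE, run_sg = TRUE,
                                    restarts = 1) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (!(is.numeric(alpha) && alpha > 0 && alpha < 1)) {
    stop("alpha must lie in (0, 1)")
  }
  if (!is.null(seed)) set.seed(seed)
  orthology <- validate_orthology_table(orthology)
  if (is.null(neighbor_map)) neighbor_map <- nearest_relatives(species_tree)
  species_map <- stats::setNames(orthology$species, orthology$gene_id)

  scr <- screen_candidates(aln, species_map, neighbor_map)
  report <- scr
  cand <- if (force_all) scr else scr[scr$is_candidate, , drop = FALSE]

  triplets <- list()
  boot <- NULL
  sg <- NULL
  report$P_Ka <- NA_real_
  report$P_Ks <- NA_real_
  for (col in c("Ka_d1", "Ka_d2", "Ka_o", "Ks_d1", "Ks_d2", "Ks_o",
                "lnL_spp", "lnL_GC", "bootstrap_p")) {
    report[[col]] <- NA_real_
  }
  report$triplet_o <- NA_character_

  if (nrow(cand) > 0L) {
    for (r in seq_len(nrow(cand))) {
      sp <- cand$species[r]
      nb <- cand$neighbor[r]
      own <- orthology[orthology$species == sp, ]
      nbg <- orthology[orthology$species == nb, ]
      d1 <- d2 <- o <- NULL
      for (tr in own$track[order(own$track)]) {
        hit <- nbg$gene_id[nbg$track == tr]
        if (length(hit) == 1L) {
          d1 <- own$gene_id[own$track == tr]
          d2 <- own$gene_id[own$track != tr]
          o <- hit
          break
        }
      }
      if (is.null(d1)) {
        warning("species ", sp, ": no ortholog of either paralog in ", nb,
                "; triplet skipped")
        next
      }
      tt <- triplet_test(aln, d1, d2, o, restarts = restarts)
      triplets[[sp]] <- tt
      i <- match(sp, report$species)
      report[i, c("Ka_d1", "Ka_d2", "Ka_o")] <-
        as.list(tt[c("Ka_d1", "Ka_d2", "Ka_o")])
      report[i, c("Ks_d1", "Ks_d2", "Ks_o")] <-
        as.list(tt[c("Ks_d1", "Ks_d2", "Ks_o")])
      report$P_Ka[i] <- tt$P_Ka
      report$P_Ks[i] <- tt$P_Ks
      report$triplet_o[i] <- o
    }

    gene_tree <- expected_gene_tree(species_tree, orthology)
    pairs <- tibble::tibble(gene1 = cand$d1, gene2 = cand$d2)
    gc_set <- enumerate_gc_trees(gene_tree, pairs)
    if (nrow(gc_set$trees) > 0L) {
      boot <- parametric_bootstrap(aln, gc_set, n_reps = n_reps,
                                   restarts = restarts)
      lnl_spp <- boot$observed$fits$lnL[boot$observed$fits$id == "species"]
      best_row <- boot$observed$fits$id == boot$observed$best_gc
      report$lnL_spp[match(cand$species, report$species)] <- lnl_spp
      report$lnL_GC[match(cand$species, report$species)] <-
        boot$observed$fits$lnL[best_row]
      report$bootstrap_p[match(cand$species, report$species)] <- boot$p_value

      if (run_sg) {
        k <- match(boot$observed$best_gc, gc_set$trees$id)
        conv_tips <- c(gc_set$trees$moved_tip[k], gc_set$trees$target_tip[k])
        best_tree <- boot$observed$fit_objects[[boot$observed$best_gc]]$tree
        sg <- sg_lrt(aln, best_tree, converted_tips = conv_tips,
                     partition = partition, restarts = restarts)
        for (cn in sg$class) {
          i <- match(cand$species, report$species)
          row <- sg[sg$class == cn, ]
          report[[paste0("Rc_", cn)]] <- NA_real_
          report[[paste0("Rr_", cn)]] <- NA_real_
          report[[paste0("Rr_Rc_", cn)]] <- NA_real_
          report[[paste0("P_sg_", cn)]] <- NA_real_
          report[i, paste0("Rc_", cn)] <- row$Rc
          report[i, paste0("Rr_", cn)] <- row$Rr
          report[i, paste0("Rr_Rc_", cn)] <- row$ratio
          report[i, paste0("P_sg_", cn)] <- row$P_raw
        }
      }
    }
  }
  report$significant_Ks <- !is.na(report$P_Ks) & report$P_Ks < alpha
  report$significant_bootstrap <- !is.na(report$bootstrap_p) &
    report$bootstrap_p < alpha
  structure(
    list(report = report, screen = scr, triplets = triplets, bootstrap = boot,
         sg = sg, seed = seed,
         config = list(n_reps = n_reps, alpha = alpha, restarts = restarts,
                       force_all = force_all, run_sg = run_sg,
                       partition = partition)),
    class = "conversion_report"
  )
}

#' @export
print.conversion_report <- function(x, ...) {
  cat("gene-conversion pipeline report (seed ",
      if (is.null(x$seed)) "unset" else x$seed, "):\n", sep = "")
  print(as.data.frame(x$report[, c("species", "dist_d1_d2",
                                   "min_dist_to_relative", "is_candidate",
                                   "P_Ks", "bootstrap_p")]),
        row.names = FALSE)
  invisible(x)
}

#' Write a pipeline report as TSV
#'
#' @param x A `conversion_report` (or its `report` tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(x, path) {
  report <- if (inherits(x, "conversion_report")) x$report else x
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
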