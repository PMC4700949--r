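# Synthetic post-WGD gene families with known ground truth. A rooted species
# tree is duplicated at its root into two paralogous "tracks" per species,
# codon sequences evolve under the MG/GY model along the doubled tree, and
# optional gene-conversion events overwrite a contiguous codon window of one
# track with the other at a stated time before the present on the terminal
# branches.

#' Define a post-WGD conversion scenario
#'
#' @param species_tree Rooted ape `phylo` with branch lengths in expected
#'   substitutions per codon.
#' @param conversions Tibble/data frame with columns `species`,
#'   `donor_track` (1 or 2), `start_codon`, `end_codon` (1-based, inclusive),
#'   `time_fraction` (in `(0, 1]`, the fraction of the species' terminal
#'   branch length before the present at which the event occurs). May be
#'   `NULL` for no conversion. Overlapping windows on one species are
#'   rejected.
#' @param model A [codon_model()] (histone-like defaults: strong purifying
#'   selection).
#' @param n_codons Family length in codons.
#' @param losses Character vector of gene ids (`"<species>_t<track>"`) deleted
#'   from the family, mimicking post-WGD gene loss.
#' @param wgd_at_root If `TRUE` (default) the root carries the WGD and every
#'   species contributes up to two tracks.
#' @param seed Optional integer seed stored with the scenario.
#' @return An object of class `conversion_scenario`.
#' @export
conversion_scenario <- function(species_tree, conversions = NULL,
                                model = codon_model(kappa = 2, omega = 0.05),
                                n_codons = 150, losses = character(0),
                                wgd_at_root = TRUE, seed = NULL) {
  if (!inherits(species_tree, "phylo")) stop("species_tree must be a phylo")
  if (!ape::is.rooted(species_tree)) stop("species_tree must be rooted")
  if (n_codons < 1) stop("n_codons must be >= 1")
  if (!is.null(conversions) && nrow(conversions) > 0) {
    conversions <- tibble::as_tibble(conversions)
    need <- c("species", "donor_track", "start_codon", "end_codon",
              "time_fraction")
    if (!all(need %in% names(conversions))) {
      stop("conversions needs columns: ", paste(need, collapse = ", "))
    }
    if (!all(conversions$species %in% species_tree$tip.label)) {
      stop("conversion species not in the species tree")
    }
    if (!all(conversions$donor_track %in% c(1L, 2L))) {
      stop("donor_track must be 1 or 2")
    }
    with(conversions, {
      if (any(start_codon < 1 | end_codon > n_codons | start_codon > end_codon))
        stop("conversion windows must lie within [1, n_codons]")
      if (any(time_fraction <= 0 | time_fraction > 1))
        stop("time_fraction must lie in (0, 1]")
    })
    for (sp in unique(conversions$species)) {
      ev <- conversions[conversions$species == sp, ]
      if (nrow(ev) > 1L) {
        ord <- order(ev$start_codon)
        if (any(ev$end_codon[ord][-nrow(ev)] >= ev$start_codon[ord][-1])) {
          stop("overlapping conversion windows for species ", sp)
        }
      }
    }
  } else {
    conversions <- tibble::tibble(species = character(0),
                                  donor_track = integer(0),
                                  start_codon = integer(0),
                                  end_codon = integer(0),
                                  time_fraction = numeric(0))
  }
  structure(
    list(species_tree = species_tree, conversions = conversions,
         model = model, n_codons = as.integer(n_codons), losses = losses,
         wgd_at_root = isTRUE(wgd_at_root), seed = seed),
    class = "conversion_scenario"
  )
}

#' Bundled default scenario: six species, histone-like parameters
#'
#' Six post-WGD species in three cherries, tip-to-root depth about 0.15
#' expected substitutions per codon (so WGD paralogs diverge by roughly
#' Ks 0.1-0.5 across branches), `omega = 0.05`, `kappa = 2`, 150 codons.
#'
#' @param conversions Optional conversion events (see [conversion_scenario()]).
#' @param seed Integer seed.
#' @param ... Passed on to [conversion_scenario()].
#' @return A `conversion_scenario`.
#' @export
default_scenario <- function(conversions = NULL, seed = 101, ...) {
  tr <- ape::read.tree(text = paste0(
    "(((speA:0.05,speB:0.05):0.05,(speC:0.06,speD:0.06):0.04):0.05,",
    "(speE:0.08,speF:0.08):0.07);"))
  conversion_scenario(tr, conversions = conversions, seed = seed, ...)
}

# Double a rooted species tree at its root into two tracks.
double_species_tree <- function(species_tree) {
  t1 <- t2 <- species_tree
  t1$tip.label <- paste0(t1$tip.label, "_t1")
  t2$tip.label <- paste0(t2$tip.label, "_t2")
  nwk <- paste0("(", sub(";$", "", ape::write.tree(t1)), ":0,",
                sub(";$", "", ape::write.tree(t2)), ":0);")
  ape::read.tree(text = nwk)
}

evolve_states <- function(states, t, eig) {
  if (t <= 0) return(states)
  sim_child_states(states, transition_matrix(eig, t))
}

#' Generate a post-WGD gene family with known ground truth
#'
#' Duplicates the species tree at its root into tracks 1 and 2, simulates
#' codon sequences along the doubled tree, applies each conversion event by
#' overwriting the recipient track's codon window with the donor track's
#' states at the event time (both lineages then evolve independently to the
#' present), and removes lost genes.
#'
#' @param scenario A [conversion_scenario()].
#' @return A list of class `wgd_family`: `alignment` (a [codon_alignment()]
#'   with gene ids `"<species>_t<track>"`), `species_tree`, `gene_tree` (the
#'   doubled tree with each converted paralog regrafted as sister to its
#'   donor at the event time - the genealogy of the converted window),
#'   `orthology` (ground-truth table, probability 1), and `scenario`.
#' @export
generate_family <- function(scenario) {
  stopifnot(inherits(scenario, "conversion_scenario"))
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  model <- scenario$model
  n <- scenario$n_codons
  eig <- cpp_eig_rev(codon_rate_matrix(model), model$pi)
  gtree <- if (scenario$wgd_at_root) {
    double_species_tree(scenario$species_tree)
  } else {
    scenario$species_tree
  }
  conv <- scenario$conversions
  conv_tips <- c(paste0(conv$species, "_t1"), paste0(conv$species, "_t2"))
  gtree_cw <- ape::reorder.phylo(gtree, "cladewise")
  states <- sim_states_on_tree(gtree_cw, model$pi, eig, n,
                               skip_tips = conv_tips)
  tipmat <- states[seq_along(gtree_cw$tip.label), , drop = FALSE]
  rownames(tipmat) <- gtree_cw$tip.label

  for (sp in unique(conv$species)) {
    ev <- conv[conv$species == sp, ]
    ev <- ev[order(-ev$time_fraction), , drop = FALSE]
    tips <- paste0(sp, "_t", 1:2)
    ti <- match(tips, gtree_cw$tip.label)
    ek <- match(ti, gtree_cw$edge[, 2])
    tlen <- gtree_cw$edge.length[ek]
    if (abs(tlen[1] - tlen[2]) > 1e-12) {
      stop("track terminal branches differ in length for species ", sp)
    }
    cur <- list(states[gtree_cw$edge[ek[1], 1], ],
                states[gtree_cw$edge[ek[2], 1], ])
    pos <- 0
    for (r in seq_len(nrow(ev))) {
      d <- (1 - ev$time_fraction[r]) * tlen[1]
      cur <- lapply(cur, evolve_states, t = d - pos, eig = eig)
      win <- ev$start_codon[r]:ev$end_codon[r]
      donor <- ev$donor_track[r]
      cur[[3 - donor]][win] <- cur[[donor]][win]
      pos <- d
    }
    cur <- lapply(cur, evolve_states, t = tlen[1] - pos, eig = eig)
    tipmat[tips[1], ] <- cur[[1]]
    tipmat[tips[2], ] <- cur[[2]]
  }

  keep <- setdiff(rownames(tipmat), scenario$losses)
  seqs <- vapply(keep, function(tp) states_to_seq(tipmat[tp, ]), character(1))
  aln <- codon_alignment(stats::setNames(seqs, keep))

  # converted-window genealogy: regraft each recipient tip next to its donor
  eff <- gtree
  for (r in seq_len(nrow(conv))) {
    donor_tip <- paste0(conv$species[r], "_t", conv$donor_track[r])
    recip_tip <- paste0(conv$species[r], "_t", 3 - conv$donor_track[r])
    tf <- conv$time_fraction[r]
    ek <- match(match(recip_tip, eff$tip.label), eff$edge[, 2])
    tlen <- eff$edge.length[ek]
    eff <- ape::drop.tip(eff, recip_tip)
    at <- match(donor_tip, eff$tip.label)
    eff <- phytools::bind.tip(eff, recip_tip, edge.length = tf * tlen,
                              where = at, position = tf * tlen)
  }
  eff <- prune_lost(eff, scenario$losses)
  gtree_out <- prune_lost(gtree, scenario$losses)

  track <- as.integer(sub("^.*_t", "", keep))
  orth <- tibble::tibble(species = sub("_t[12]$", "", keep), gene_id = keep,
                         track = track, probability = 1)
  structure(
    list(alignment = aln, species_tree = scenario$species_tree,
         gene_tree = eff, doubled_tree = gtree_out,
         orthology = validate_orthology_table(orth), scenario = scenario),
    class = "wgd_family"
  )
}

prune_lost <- function(tree, losses) {
  drop <- intersect(losses, tree$tip.label)
  if (length(drop) > 0L) tree <- ape::drop.tip(tree, drop)
  tree
}

#' Simulate a null (or alternative) triplet alignment
#'
#' Star-tree simulation for (D1, D2, O) with specified per-branch Ka and Ks:
#' the root codon is drawn from the model's equilibrium distribution and each
#' tip evolves under its branch generator scaled to the requested divergences.
#'
#' @param ka,ks Length-3 numeric vectors of per-branch divergences, in the
#'   order D1, D2, O.
#' @param kappa Transition/transversion ratio.
#' @param freqs_nt Optional 3 x 4 nucleotide frequency matrix.
#' @param n_codons Alignment length.
#' @param seed Optional integer seed.
#' @param names Sequence names (default `c("D1", "D2", "O")`).
#' @return A [codon_alignment()] of three sequences.
#' @export
generate_null_triplet <- function(ka, ks, kappa = 2, freqs_nt = NULL,
                                  n_codons = 300, seed = NULL,
                                  names = c("D1", "D2", "O")) {
  stopifnot(length(ka) == 3L, length(ks) == 3L, all(ka >= 0), all(ks >= 0))
  if (!is.null(seed)) set.seed(seed)
  freqs_nt <- validate_freqs_nt(freqs_nt)
  parts <- mg_rate_parts(freqs_nt)
  pi <- f3x4_frequencies(freqs_nt)
  Qs <- parts$syn_tv + kappa * parts$syn_ts
  Qn <- parts$non_tv + kappa * parts$non_ts
  etot <- sum(pi * rowSums(Qs + Qn))
  root <- sample.int(61L, n_codons, replace = TRUE, prob = pi)
  seqs <- character(3)
  for (b in 1:3) {
    G <- (3 / etot) * (ka[b] * Qn + ks[b] * Qs)
    diag(G) <- -rowSums(G)
    eig <- cpp_eig_rev(G, pi)
    seqs[b] <- states_to_seq(evolve_states(root, 1, eig))
  }
  codon_alignment(stats::setNames(seqs, names))
}

#' Nearest relative of each species on a tree
#'
#' @param species_tree ape `phylo` with branch lengths.
#' @return Named character vector: for each tip, the tip with the smallest
#'   patristic distance (ties broken by tip order).
#' @export
nearest_relatives <- function(species_tree) {
  d <- ape::cophenetic.phylo(species_tree)
  diag(d) <- Inf
  nb <- colnames(d)[apply(d, 1L, which.min)]
  stats::setNames(nb, rownames(d))
}

#' Write a generated family to disk
#'
#' Writes `<prefix>.fasta` (alignment), `<prefix>_species.nwk`,
#' `<prefix>_gene.nwk` (converted-window genealogy) and `<prefix>_orthology.tsv`.
#'
#' @param family A `wgd_family` from [generate_family()].
#' @param prefix Output path prefix.
#' @return Invisibly, the vector of paths written.
#' @export
write_family <- function(family, prefix) {
  stopifnot(inherits(family, "wgd_family"))
  paths <- c(fasta = paste0(prefix, ".fasta"),
             spp = paste0(prefix, "_species.nwk"),
             gene = paste0(prefix, "_gene.nwk"),
             orth = paste0(prefix, "_orthology.tsv"))
  write_codon_alignment(family$alignment, paths[["fasta"]])
  ape::write.tree(family$species_tree, paths[["spp"]])
  ape::write.tree(family$gene_tree, paths[["gene"]])
  write_orthology_table(family$orthology, paths[["orth"]])
  invisible(paths)
}
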