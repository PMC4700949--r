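# Candidate screen: a WGD paralog pair is flagged when the two paralogs have
# higher protein identity to each other than either has to any homolog in the
# species' nearest relative (strict inequality; ties are not candidates).

#' Screen WGD paralog pairs for gene-conversion candidates
#'
#' Distances are amino-acid p-distances on the translated family alignment,
#' gap-free columns only. One report row is produced per species that retains
#' both paralogs; species whose nearest relative has no homolog in the family
#' are skipped with a warning.
#'
#' @param aln A [codon_alignment()] of one gene family.
#' @param species_map Mapping gene -> species: either a named character
#'   vector (`names` = gene ids) or a data frame with columns `gene_id`,
#'   `species`.
#' @param neighbor_map Mapping species -> nearest relative: named character
#'   vector or data frame with columns `species`, `neighbor`.
#' @return Tibble with one row per double-copy species: `species`, `d1`,
#'   `d2`, `dist_d1_d2`, `neighbor`, `min_dist_to_relative`, `is_candidate`
#'   (`dist_d1_d2 < min_dist_to_relative`, strict).
#' @export
screen_candidates <- function(aln, species_map, neighbor_map) {
  stopifnot(inherits(aln, "codon_alignment"))
  species_map <- as_named_map(species_map, c("gene_id", "species"))
  neighbor_map <- as_named_map(neighbor_map, c("species", "neighbor"))
  miss <- setdiff(aln$names, names(species_map))
  if (length(miss) > 0L) {
    stop("gene(s) without species assignment: ", paste(miss, collapse = ", "))
  }
  prot <- translate_alignment(aln)
  genes_by_species <- split(aln$names, unname(species_map[aln$names]))

  rows <- list()
  for (sp in names(genes_by_species)) {
    genes <- genes_by_species[[sp]]
    if (length(genes) != 2L) next
    if (!sp %in% names(neighbor_map)) {
      warning("no nearest relative defined for species ", sp, "; skipped")
      next
    }
    nb <- neighbor_map[[sp]]
    relatives <- genes_by_species[[nb]]
    if (is.null(relatives) || length(relatives) == 0L) {
      warning("species ", sp, ": nearest relative ", nb,
              " has no homolog in the family; skipped")
      next
    }
    d12 <- p_distance(prot[[genes[1]]], prot[[genes[2]]])
    dists <- vapply(genes, function(g) {
      min(vapply(relatives, function(r) p_distance(prot[[g]], prot[[r]]),
                 numeric(1)))
    }, numeric(1))
    dmin <- min(dists)
    rows[[sp]] <- tibble::tibble(
      species = sp, d1 = genes[1], d2 = genes[2], dist_d1_d2 = d12,
      neighbor = nb, min_dist_to_relative = dmin,
      is_candidate = d12 < dmin
    )
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(species = character(0), d1 = character(0),
                          d2 = character(0), dist_d1_d2 = numeric(0),
                          neighbor = character(0),
                          min_dist_to_relative = numeric(0),
                          is_candidate = logical(0)))
  }
  dplyr::bind_rows(rows)
}

as_named_map <- function(x, cols) {
  if (is.data.frame(x)) {
    if (!all(cols %in% names(x))) {
      stop("mapping data frame needs columns ", paste(cols, collapse = ", "))
    }
    stats::setNames(as.character(x[[cols[2]]]), as.character(x[[cols[1]]]))
  } else if (is.character(x) && !is.null(names(x))) {
    x
  } else {
    stop("mapping must be a named character vector or a data frame")
  }
}
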