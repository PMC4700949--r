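# Genetic-code machinery shared by the whole package: the 61 sense codons of
# the standard code, their translations, and the classification of every
# single-nucleotide codon change (synonymous vs nonsynonymous, transition vs
# transversion, radical vs conservative under a polarity partition).

.ohnoconv_cache <- new.env(parent = emptyenv())

NUC <- c("A", "C", "G", "T")

#' Sense codons of the standard genetic code
#'
#' Returns the 61 codons that encode amino acids under the standard nuclear
#' code, in the fixed alphabetical order used throughout the package (codon
#' state `i` in every rate matrix refers to `sense_codons()[i]`).
#'
#' @return Character vector of length 61.
#' @export
sense_codons <- function() {
  codon_tables()$codons
}

#' Translate codons to amino acids
#'
#' @param codons Character vector of codon strings (T or U, any case). Gap
#'   codons (`"---"`) and codons containing ambiguity characters translate to
#'   `"-"` and `"X"` respectively.
#' @return Character vector of one-letter amino-acid codes.
#' @export
translate_codons <- function(codons) {
  tab <- codon_tables()
  codons <- normalize_codons(codons)
  out <- rep("X", length(codons))
  out[codons == "---"] <- "-"
  hit <- match(codons, tab$codons)
  out[!is.na(hit)] <- tab$aa[hit[!is.na(hit)]]
  # stop codons translate to *
  out[codons %in% tab$stop_codons] <- "*"
  out
}

normalize_codons <- function(codons) {
  gsub("U", "T", toupper(codons), fixed = TRUE)
}

# Build (once) the codon tables: sense codons, translations, and the list of
# ordered single-nucleotide neighbor pairs with their change classification.
codon_tables <- function() {
  if (!is.null(.ohnoconv_cache$tables)) {
    return(.ohnoconv_cache$tables)
  }
  gc_map <- Biostrings::GENETIC_CODE
  all_codons <- names(gc_map)
  sense <- all_codons[gc_map != "*"]
  sense <- sort(sense)
  aa <- unname(gc_map[sense])
  stopifnot(length(sense) == 61L)

  idx <- seq_along(sense)
  mat <- do.call(rbind, strsplit(sense, ""))

  # all ordered pairs (i, j) of sense codons differing at exactly one position
  nb <- list()
  k <- 0L
  for (i in idx) {
    for (pos in 1:3) {
      for (nt in NUC) {
        if (nt == mat[i, pos]) next
        target <- mat[i, ]
        target[pos] <- nt
        j <- match(paste(target, collapse = ""), sense)
        if (is.na(j)) next # change creates a stop codon
        k <- k + 1L
        nb[[k]] <- c(i = i, j = j, pos = pos,
                     to_nt = match(nt, NUC), from_nt = match(mat[i, pos], NUC))
      }
    }
  }
  nb <- do.call(rbind, nb)
  purine <- c(TRUE, FALSE, TRUE, FALSE) # A, C, G, T
  is_ts <- purine[nb[, "from_nt"]] == purine[nb[, "to_nt"]]
  is_syn <- aa[nb[, "i"]] == aa[nb[, "j"]]

  .ohnoconv_cache$tables <- list(
    codons = sense,
    aa = aa,
    stop_codons = all_codons[gc_map == "*"],
    codon_nt = mat,
    neighbors = data.frame(
      i = nb[, "i"], j = nb[, "j"], pos = nb[, "pos"],
      to_nt = nb[, "to_nt"], is_ts = is_ts, is_syn = is_syn
    )
  )
  .ohnoconv_cache$tables
}

#' Default polarity partition of the 20 amino acids
#'
#' The similarity-groups (SG) model classifies each nonsynonymous change as
#' conservative (within-group) or radical (between-group) according to a
#' two-way partition of the amino acids into polar and nonpolar residues.
#' This default partition is a package choice and can be overridden wherever a
#' partition is accepted; the partition in force is recorded in SG outputs.
#'
#' @return Named character vector mapping each one-letter amino-acid code to
#'   `"polar"` or `"nonpolar"`.
#' @export
default_polarity_partition <- function() {
  polar <- c("R", "N", "D", "C", "Q", "E", "G", "H", "K", "S", "T", "Y")
  nonpolar <- c("A", "I", "L", "M", "F", "P", "W", "V")
  stats::setNames(
    c(rep("polar", length(polar)), rep("nonpolar", length(nonpolar))),
    c(polar, nonpolar)
  )
}

validate_partition <- function(partition) {
  aa20 <- sort(unique(codon_tables()$aa))
  if (!setequal(names(partition), aa20) ||
      anyDuplicated(names(partition)) > 0L) {
    stop("partition must assign each of the 20 amino acids exactly once")
  }
  if (length(unique(partition)) < 1L) stop("partition has no groups")
  partition
}

# TRUE for each neighbor pair that is a radical (between-group) nonsynonymous
# change under `partition`; NA for synonymous pairs.
neighbor_is_radical <- function(partition = default_polarity_partition()) {
  partition <- validate_partition(partition)
  tab <- codon_tables()
  nbr <- tab$neighbors
  rad <- partition[tab$aa[nbr$i]] != partition[tab$aa[nbr$j]]
  rad[nbr$is_syn] <- NA
  unname(rad)
}
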