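# The codon_alignment container: gap-aware, in-frame aligned coding sequences
# over the 61 sense codons. Gaps are whole-codon "---" units; ambiguous codons
# (any character outside ACGTU) are treated as missing data.

#' Construct a codon alignment
#'
#' @param seqs Named character vector of aligned nucleotide sequences (equal
#'   lengths, each a multiple of 3). `U` is read as `T`; case is ignored.
#' @param code Genetic-code identifier; only `"standard"` is supported.
#' @return An object of class `codon_alignment` with fields `names`, `seqs`
#'   (normalized sequence strings), `n_codons`, `code`, and `codes` (an
#'   `n_codons` x `n_seq` integer matrix of codon states 1..61, `NA` for gap
#'   or ambiguous codons).
#' @export
codon_alignment <- function(seqs, code = "standard") {
  if (code != "standard") stop("only the standard genetic code is supported")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("all sequences must be named")
  }
  if (anyDuplicated(names(seqs)) > 0L) stop("duplicate sequence names")
  seqs <- vapply(seqs, function(s) normalize_codons(s), character(1))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    bad <- names(seqs)[which(lens != lens[1])[1]]
    stop("ragged alignment: sequence '", bad, "' has length ", lens[[bad]],
         " but '", names(seqs)[1], "' has length ", lens[1])
  }
  if (lens[1] %% 3L != 0L) {
    stop("alignment length ", lens[1], " is not a multiple of 3")
  }
  n_codons <- unname(lens[1]) %/% 3L
  tab <- codon_tables()
  codes <- matrix(NA_integer_, nrow = n_codons, ncol = length(seqs),
                  dimnames = list(NULL, names(seqs)))
  for (k in seq_along(seqs)) {
    cods <- substring(seqs[k], 3L * seq_len(n_codons) - 2L,
                      3L * seq_len(n_codons))
    stop_hit <- which(cods %in% tab$stop_codons)
    if (length(stop_hit) > 0L) {
      stop("internal stop codon '", cods[stop_hit[1]], "' in sequence '",
           names(seqs)[k], "' at codon ", stop_hit[1])
    }
    part_gap <- grepl("-", cods) & cods != "---"
    if (any(part_gap)) {
      stop("gap not aligned to codon boundaries in sequence '",
           names(seqs)[k], "' at codon ", which(part_gap)[1])
    }
    codes[, k] <- match(cods, tab$codons)
  }
  structure(
    list(names = names(seqs), seqs = unname(seqs), n_codons = n_codons,
         code = code, codes = codes),
    class = "codon_alignment"
  )
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment: ", length(x$names), " sequences x ", x$n_codons,
      " codons (", x$code, " code)\n", sep = "")
  invisible(x)
}

#' Read an in-frame codon alignment from FASTA
#'
#' Reading is case-insensitive and `U` is treated as `T`. The alignment is
#' validated: equal sequence lengths, length a multiple of three, no internal
#' stop codons, gaps only as whole-codon `---` units.
#'
#' @param path Path to an aligned FASTA file.
#' @return A [codon_alignment()].
#' @export
read_codon_alignment <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  codon_alignment(stats::setNames(as.character(ss), names(ss)))
}

#' Write a codon alignment to FASTA
#'
#' @param aln A [codon_alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_codon_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "codon_alignment"))
  ss <- Biostrings::BStringSet(stats::setNames(aln$seqs, aln$names))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Translate a codon alignment
#'
#' @param aln A [codon_alignment()].
#' @return Named character vector of aligned amino-acid sequences (gap codons
#'   become `-`, ambiguous codons `X`).
#' @export
translate_alignment <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  n <- aln$n_codons
  out <- vapply(seq_along(aln$names), function(k) {
    cods <- substring(aln$seqs[k], 3L * seq_len(n) - 2L, 3L * seq_len(n))
    paste(translate_codons(cods), collapse = "")
  }, character(1))
  stats::setNames(out, aln$names)
}

#' Proportion of differing residues between two aligned sequences
#'
#' Columns where either sequence carries a gap (`-`) or an ambiguity (`X`) are
#' excluded from both numerator and denominator.
#'
#' @param a,b Equal-length aligned amino-acid strings.
#' @return Proportion in `[0, 1]`.
#' @export
p_distance <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  if (length(x) != length(y)) {
    stop("sequences have different lengths (", length(x), " vs ", length(y), ")")
  }
  keep <- !(x %in% c("-", "X")) & !(y %in% c("-", "X"))
  if (!any(keep)) stop("p-distance undefined: no gap-free columns")
  mean(x[keep] != y[keep])
}

# Subset an alignment to a set of sequence names (order preserved as given).
subset_alignment <- function(aln, keep) {
  stopifnot(inherits(aln, "codon_alignment"))
  miss <- setdiff(keep, aln$names)
  if (length(miss) > 0L) stop("sequences not in alignment: ",
                              paste(miss, collapse = ", "))
  idx <- match(keep, aln$names)
  codon_alignment(stats::setNames(aln$seqs[idx], keep), code = aln$code)
}

# Collapse alignment columns into unique site patterns for the sequences in
# `tips` (a character vector ordering the columns of the returned matrix).
# Returns list(codes = npat x ntip integer matrix with NA -> -1L, weights).
site_patterns <- function(aln, tips) {
  idx <- match(tips, aln$names)
  if (anyNA(idx)) stop("tree tip without sequence: ",
                       paste(tips[is.na(idx)], collapse = ", "))
  m <- aln$codes[, idx, drop = FALSE]
  m[is.na(m)] <- -1L
  key <- apply(m, 1L, paste, collapse = ",")
  first <- !duplicated(key)
  w <- as.numeric(table(factor(key, levels = key[first])))
  list(codes = m[first, , drop = FALSE], weights = w)
}
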