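# Orthology-assignment tables: the output of a synteny-based orthology
# inference (each post-WGD gene assigned to one of two duplicated tracks, with
# a posterior probability) is consumed here, never produced.

#' Read an orthology-assignment table
#'
#' Expects a UTF-8 TSV with header columns `species`, `gene_id`, `track`,
#' `probability`. `track` must be 1 or 2 and each `(species, track)` pair may
#' carry at most one gene; `probability` is the posterior probability of the
#' assignment and must lie in `[0, 1]`.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `species` (chr), `gene_id` (chr), `track`
#'   (int), `probability` (dbl).
#' @export
read_orthology_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_orthology_table(df)
}

#' Validate (and coerce) an orthology-assignment data frame
#'
#' @param df Data frame with columns `species`, `gene_id`, `track`,
#'   `probability`.
#' @return A validated tibble.
#' @export
validate_orthology_table <- function(df) {
  need <- c("species", "gene_id", "track", "probability")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) stop("orthology table missing column(s): ",
                              paste(miss, collapse = ", "))
  df <- tibble::as_tibble(df[need])
  if (!all(df$track %in% c(1L, 2L))) {
    bad <- df$track[!df$track %in% c(1L, 2L)][1]
    stop("unknown track value '", bad, "' (must be 1 or 2)")
  }
  df$track <- as.integer(df$track)
  if (any(!is.finite(df$probability)) ||
      any(df$probability < 0 | df$probability > 1)) {
    stop("orthology probabilities must lie in [0, 1]")
  }
  key <- paste(df$species, df$track)
  if (anyDuplicated(key) > 0L) {
    stop("duplicate (species, track) assignment: ", key[duplicated(key)][1])
  }
  df
}

#' Write an orthology-assignment table
#'
#' @param df Orthology tibble (see [read_orthology_table()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_orthology_table <- function(df, path) {
  df <- validate_orthology_table(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Same-species WGD paralog pairs (both tracks present) as a two-column matrix
# of gene ids, one row per species, track 1 first.
orthology_paralog_pairs <- function(df) {
  df <- validate_orthology_table(df)
  sp <- split(df, df$species)
  rows <- purrr::keep(sp, function(d) nrow(d) == 2L)
  out <- purrr::map(rows, function(d) {
    d <- d[order(d$track), ]
    tibble::tibble(species = d$species[1],
                   gene1 = d$gene_id[1], gene2 = d$gene_id[2])
  })
  dplyr::bind_rows(out)
}
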