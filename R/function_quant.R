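# Functional rollups: COG-level protein-intensity aggregation and
# taxon x pathway peptide-intensity aggregation.

#' Aggregate protein intensities by COG
#'
#' Per sample, the intensity of a COG is the sum of the (MaxLFQ-style)
#' intensities of all proteins annotated with that COG id; proteins without
#' an annotation contribute nowhere and their count is reported via
#' `message()`. When a protein group lists several accessions
#' (semicolon-separated), the leading accession decides the annotation.
#'
#' @param protein_quant tibble with a `protein_group` column plus one
#'   numeric intensity column per sample.
#' @param annotations tibble with `accession`, `cog_id` (one best hit per
#'   protein), optionally `cog_category`, `ec`.
#' @param samples sample columns (default: all numeric columns).
#' @return long tibble: `cog_id`, `sample`, `n_proteins`, `intensity`.
#' @export
aggregate_by_cog <- function(protein_quant, annotations, samples = NULL) {
  if (is.null(samples))
    samples <- names(protein_quant)[vapply(protein_quant, is.numeric,
                                           logical(1))]
  lead <- sub(";.*$", "", protein_quant$protein_group)
  cog <- annotations$cog_id[match(lead, annotations$accession)]
  n_un <- sum(is.na(cog))
  if (n_un > 0)
    message(n_un, " protein group(s) without COG annotation ignored")
  keep <- !is.na(cog)
  pq <- protein_quant[keep, , drop = FALSE]
  pq$cog_id <- cog[keep]
  rows <- lapply(split(pq, pq$cog_id), function(g) {
    tibble::tibble(cog_id = g$cog_id[1], sample = samples,
                   n_proteins = nrow(g),
                   intensity = unname(vapply(samples,
                                      function(s) sum(g[[s]], na.rm = TRUE),
                                      numeric(1))))
  })
  empty <- tibble::tibble(cog_id = character(), sample = character(),
                          n_proteins = integer(), intensity = numeric())
  dplyr::bind_rows(c(list(empty), unname(rows)))
}

#' Taxon-by-pathway functional profile from peptide intensities
#'
#' Per sample, the intensity of a (taxon, pathway) cell is the sum of the
#' intensities of peptides that are (i) specific to that taxon at the
#' chosen rank and (ii) carried by a protein group whose leading accession
#' is annotated with that pathway. A peptide whose protein maps to several
#' pathways contributes once to each (intensities are not split); peptides
#' not specific to any taxon at the rank contribute nowhere. A log2 view is
#' included for statistics.
#'
#' @param quant a `peptide_quant` table (with `protein_group`).
#' @param assignments tibble from [resolve_specificity()].
#' @param annotations tibble with `accession` and `kegg_pathways`
#'   (comma-separated pathway ids, or a list column).
#' @param rank taxonomic rank for specificity (default `"species"`).
#' @param samples sample columns (default: all in `quant`).
#' @return long tibble: `taxon`, `pathway`, `sample`, `n_peptides`,
#'   `intensity`, `log2_intensity`.
#' @export
taxon_function_profile <- function(quant, assignments, annotations,
                                   rank = "species",
                                   samples = quant_samples(quant)) {
  rank <- match.arg(rank, tax_ranks())
  spec <- .specific_map(assignments, rank)
  qt <- as.data.frame(quant)
  qt <- qt[qt$peptide %in% spec$peptide, , drop = FALSE]
  qt$taxon <- spec$taxon[match(qt$peptide, spec$peptide)]
  lead <- sub(";.*$", "", qt$protein_group)
  pw <- annotations$kegg_pathways[match(lead, annotations$accession)]
  if (!is.list(pw)) pw <- strsplit(ifelse(is.na(pw), "", pw), ",[ ]*")
  qt <- qt[lengths(pw) > 0, , drop = FALSE]
  pw <- pw[lengths(pw) > 0]
  expanded <- qt[rep(seq_len(nrow(qt)), lengths(pw)), , drop = FALSE]
  expanded$pathway <- unlist(pw)
  key <- paste(expanded$taxon, expanded$pathway, sep = "\r")
  rows <- lapply(split(expanded, key), function(g) {
    tibble::tibble(taxon = g$taxon[1], pathway = g$pathway[1],
                   sample = samples,
                   n_peptides = length(unique(g$peptide)),
                   intensity = unname(vapply(samples,
                                      function(s) sum(g[[s]], na.rm = TRUE),
                                      numeric(1))))
  })
  empty <- tibble::tibble(taxon = character(), pathway = character(),
                          sample = character(), n_peptides = integer(),
                          intensity = numeric())
  out <- dplyr::bind_rows(c(list(empty), unname(rows)))
  out$log2_intensity <- log2(out$intensity)
  out
}
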