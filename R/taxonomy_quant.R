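# Peptide-level taxonomic annotation (rank-wise consensus / LCA over
# 7-rank lineages), the 3-specific-peptide detection rule, taxon intensity
# quantification by summation of common peptides, and biomass fractions.

#' Resolve the taxonomic specificity of peptides
#'
#' For each peptide, the lineages of all matched taxids are compared rank
#' by rank from superkingdom downward. Blank (NA) rank names below
#' superkingdom are ignored: a blank neither contributes a name nor breaks
#' agreement. The consensus name at a rank is defined when exactly one
#' distinct non-blank name occurs there; walking deeper stops at the first
#' rank with conflicting names. The deepest rank with a consensus is the
#' peptide's specificity rank (the lowest common ancestor); a peptide is
#' species-specific iff all its matches share one species name.
#'
#' @param matches tibble with columns `peptide`, `taxid`: one row per
#'   (peptide, matched protein taxid).
#' @param lineages lineage table from [read_lineage_table()].
#' @return tibble with one row per peptide: `peptide`, `n_taxa`,
#'   `specificity_rank` (one of the 7 ranks or `"unranked"`), and the
#'   consensus name per rank column (NA where unresolved).
#' @export
resolve_specificity <- function(matches, lineages) {
  ranks <- tax_ranks()
  unknown <- setdiff(unique(matches$taxid), lineages$taxid)
  if (length(unknown))
    stop("taxid(s) absent from lineage table: ",
         paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
  joined <- dplyr::left_join(matches, lineages, by = "taxid")
  out <- lapply(split(joined, joined$peptide), function(g) {
    row <- list(peptide = g$peptide[1], n_taxa = length(unique(g$taxid)))
    spec <- "unranked"
    for (r in ranks) {
      names_r <- unique(g[[r]][!is.na(g[[r]])])
      if (length(names_r) == 1) {
        row[[r]] <- names_r
        spec <- r
      } else if (length(names_r) == 0) {
        row[[r]] <- NA_character_   # all blank: ignored, keep walking
      } else {
        row[[r]] <- NA_character_
        break
      }
    }
    for (r in setdiff(ranks, names(row))) row[[r]] <- NA_character_
    row$specificity_rank <- spec
    tibble::as_tibble(row[c("peptide", "n_taxa", ranks, "specificity_rank")])
  })
  dplyr::bind_rows(out)
}

#' Detect taxa by the minimum-specific-peptide rule
#'
#' A taxon is detected at rank `r` iff at least `min_specific` distinct
#' peptide sequences are specific to it at that rank (i.e. carry its name
#' as their rank-`r` consensus). The default cutoff of 3 is the workflow's
#' species-detection rule.
#'
#' @param assignments tibble from [resolve_specificity()].
#' @param rank one of the 7 canonical ranks.
#' @param min_specific minimum count of distinct specific peptides.
#' @return tibble `taxon`, `rank`, `n_specific_peptides`, sorted by
#'   descending peptide count then taxon name.
#' @export
detect_taxa <- function(assignments, rank = "species", min_specific = 3) {
  rank <- match.arg(rank, tax_ranks())
  pairs <- .specific_map(assignments, rank)
  cnt <- table(pairs$taxon)
  cnt <- cnt[cnt >= min_specific]
  counts <- tibble::tibble(taxon = names(cnt), rank = rank,
                           n_specific_peptides = as.integer(cnt))
  counts[order(-counts$n_specific_peptides, counts$taxon), ]
}

# Peptides specific to each taxon at a rank, as a peptide->taxon map.
.specific_map <- function(assignments, rank) {
  has <- assignments[!is.na(assignments[[rank]]), c("peptide", rank)]
  names(has) <- c("peptide", "taxon")
  dplyr::distinct(has)
}

#' Quantify taxa by summing common specific peptides
#'
#' The intensity of a taxon in a sample is the sum of the intensities of
#' its "common" specific peptides: peptides specific to the taxon at the
#' chosen rank and measured (present, non-NA) in every sample of the
#' comparison set, so that the per-sample sums are built from one shared
#' peptide basis. A detected taxon whose common-peptide set is empty is
#' reported with NA intensity and a warning. Summed intensities are also
#' provided log2-transformed for downstream statistics.
#'
#' @param assignments tibble from [resolve_specificity()].
#' @param quant a `peptide_quant` table.
#' @param rank taxonomic rank to quantify.
#' @param samples sample columns to use (default: all in `quant`).
#' @param taxa optional character vector restricting the taxa reported
#'   (e.g. the [detect_taxa()] survivors); default: all taxa with specific
#'   peptides.
#' @param common if `TRUE` (default) restrict to peptides present in every
#'   sample; if `FALSE`, sum whatever is present per sample.
#' @return long tibble: `taxon`, `rank`, `sample`, `n_peptides`,
#'   `intensity`, `log2_intensity`.
#' @export
quantify_taxon <- function(assignments, quant, rank = "species",
                           samples = quant_samples(quant), taxa = NULL,
                           common = TRUE) {
  rank <- match.arg(rank, tax_ranks())
  spec <- .specific_map(assignments, rank)
  if (!is.null(taxa)) spec <- spec[spec$taxon %in% taxa, , drop = FALSE]
  qt <- as.data.frame(quant)[, c("peptide", samples), drop = FALSE]
  qt <- qt[qt$peptide %in% spec$peptide, , drop = FALSE]
  if (common && nrow(qt)) {
    present <- stats::complete.cases(qt[, samples, drop = FALSE])
    qt <- qt[present, , drop = FALSE]
  }
  merged <- dplyr::inner_join(spec, qt, by = "peptide")
  rows <- lapply(split(merged, merged$taxon), function(g) {
    tibble::tibble(taxon = g$taxon[1], rank = rank, sample = samples,
                   n_peptides = length(unique(g$peptide)),
                   intensity = unname(vapply(samples,
                                      function(s) sum(g[[s]], na.rm = !common),
                                      numeric(1))))
  })
  empty <- tibble::tibble(taxon = character(), rank = character(),
                          sample = character(), n_peptides = integer(),
                          intensity = numeric())
  profile <- dplyr::bind_rows(c(list(empty), unname(rows)))
  wanted <- if (is.null(taxa)) unique(spec$taxon) else taxa
  absent <- setdiff(wanted, profile$taxon)
  if (length(absent)) {
    warning("no common quantified peptides for taxon/taxa: ",
            paste(absent, collapse = ", "), call. = FALSE)
    profile <- dplyr::bind_rows(profile, tibble::tibble(
      taxon = rep(absent, each = length(samples)), rank = rank,
      sample = rep(samples, length(absent)),
      n_peptides = 0L, intensity = NA_real_))
  }
  profile$log2_intensity <- log2(profile$intensity)
  profile <- profile[order(profile$taxon, match(profile$sample, samples)), ]
  tibble::as_tibble(profile)
}

#' Biomass fractions per sample
#'
#' Within each sample, a taxon's biomass fraction is 100 times its summed
#' intensity over the total across reported taxa, so fractions sum to 100
#' over taxa with non-missing intensity.
#'
#' @param profile long tibble from [quantify_taxon()].
#' @return `profile` with a `biomass_fraction` column (percent).
#' @export
biomass_fractions <- function(profile) {
  totals <- tapply(profile$intensity, profile$sample,
                   function(x) sum(x, na.rm = TRUE))
  profile$biomass_fraction <-
    100 * profile$intensity / as.numeric(totals[profile$sample])
  profile
}

#' Percent increase of a count over a baseline
#'
#' Coverage-gain arithmetic: `100 * additional / baseline` when `additional`
#' counts new items on top of the baseline, or
#' `100 * (new - baseline) / baseline` via `percent_increase(new - baseline,
#' baseline)`.
#'
#' @param additional items gained.
#' @param baseline baseline count (> 0).
#' @return percent gain.
#' @export
percent_increase <- function(additional, baseline) {
  stopifnot(baseline > 0)
  100 * additional / baseline
}
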