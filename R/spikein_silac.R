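# SILAC labeling efficiency, the three spike-in identification filters,
# and limit-of-detection cell-fraction arithmetic.

#' Describe a SILAC spike-in experiment
#'
#' @param labeled_species the heavy-labeled spiked species.
#' @param unlabeled_species the unlabeled exogenous spiked species.
#' @param cell_inputs numeric vector of spiked cell counts per level.
#' @param feces_mass_g fecal sample mass in grams (default 0.01 = 10 mg).
#' @param cells_per_gram assumed bacterial cell density of feces
#'   (default 1e12 cells/g, the genomic estimate for mouse feces).
#' @param replicate_samples sample ids of the spike-in replicates (per
#'   level: a named list `level -> sample ids`, or a flat vector).
#' @param control_samples sample ids of the non-spike control replicates.
#' @return a `spikein_design` list.
#' @export
spikein_design <- function(labeled_species, unlabeled_species,
                           cell_inputs = c(1e8, 1e7, 1e6, 1e5, 1e4),
                           feces_mass_g = 0.01, cells_per_gram = 1e12,
                           replicate_samples = NULL,
                           control_samples = character()) {
  stopifnot(feces_mass_g > 0, cells_per_gram > 0)
  structure(list(labeled_species = labeled_species,
                 unlabeled_species = unlabeled_species,
                 cell_inputs = cell_inputs, feces_mass_g = feces_mass_g,
                 cells_per_gram = cells_per_gram,
                 replicate_samples = replicate_samples,
                 control_samples = control_samples),
            class = "spikein_design")
}

#' Per-peptide SILAC labeling efficiency
#'
#' For each peptide, the most intense PSM per label channel is kept (heavy
#' and light resolved independently); a channel with no PSM at all is
#' assigned intensity 1 before applying
#' `efficiency = 100 * H / (H + L)`. Peptides with neither channel are
#' excluded with a warning. The cohort mean is the unweighted average over
#' peptides.
#'
#' @param measurements tibble of PSM-level intensities: columns `peptide`,
#'   `channel` (`"heavy"`/`"light"`), `intensity` (> 0).
#' @return list with `per_peptide` (tibble `peptide`, `intensity_heavy`,
#'   `intensity_light`, `efficiency`) and `mean_efficiency` (percent).
#' @export
labeling_efficiency <- function(measurements) {
  stopifnot(all(measurements$channel %in% c("heavy", "light")))
  if (any(measurements$intensity <= 0, na.rm = TRUE))
    stop("PSM intensities must be positive", call. = FALSE)
  best <- function(g, ch) {
    v <- g$intensity[g$channel == ch & !is.na(g$intensity)]
    if (length(v) == 0) NA_real_ else max(v)
  }
  rows <- lapply(split(measurements, measurements$peptide), function(g) {
    tibble::tibble(peptide = g$peptide[1],
                   intensity_heavy = best(g, "heavy"),
                   intensity_light = best(g, "light"))
  })
  pp <- dplyr::bind_rows(rows)
  none <- is.na(pp$intensity_heavy) & is.na(pp$intensity_light)
  if (any(none)) {
    warning(sum(none), " peptide(s) with no intensity in either channel excluded",
            call. = FALSE)
    pp <- pp[!none, , drop = FALSE]
  }
  h <- ifelse(is.na(pp$intensity_heavy), 1, pp$intensity_heavy)
  l <- ifelse(is.na(pp$intensity_light), 1, pp$intensity_light)
  pp$efficiency <- 100 * h / (h + l)
  list(per_peptide = pp, mean_efficiency = mean(pp$efficiency))
}

#' Apply the three spike-in identification filters
#'
#' Rows assigned to either spiked species are screened by three rules,
#' applied in order: (1) for the labeled species only heavy-labeled
#' peptides are kept, and heavy-labeled peptides assigned to the unlabeled
#' species are removed as false matches; (2) peptides assigned to both
#' spiked species, and rows whose protein group is shared between the two
#' species, are removed; (3) peptides assigned to either spiked species
#' that are also measured in any non-spike control sample are removed.
#' Each rule is a pure predicate, so the surviving set is order
#' independent; the per-rule removal counts reported are attributed in
#' rule order. Rows not assigned to a spiked species pass through
#' untouched.
#'
#' @param quant a `peptide_quant` table with `peptide`, `protein_group`,
#'   `label` columns; control samples must be among its sample columns.
#' @param assignments tibble mapping `peptide` to `species` (a peptide may
#'   map to several species over multiple rows).
#' @param design a [spikein_design()].
#' @return list with `table` (the filtered `peptide_quant`) and `removed`
#'   (tibble `rule`, `n_removed`).
#' @export
apply_spikein_filters <- function(quant, assignments, design) {
  spp <- c(design$labeled_species, design$unlabeled_species)
  species_of <- split(assignments$species, assignments$peptide)
  assigned_to <- function(peps, sp)
    vapply(species_of[peps], function(s) !is.null(s) && sp %in% s, logical(1),
           USE.NAMES = FALSE)
  qt <- quant
  to_lab <- assigned_to(qt$peptide, design$labeled_species)
  to_unl <- assigned_to(qt$peptide, design$unlabeled_species)
  spike_row <- to_lab | to_unl

  # rule 1: labeled species only via heavy channel; heavy + unlabeled
  # species is a false match
  r1 <- (to_lab & qt$label != "heavy") | (to_unl & qt$label == "heavy")

  # rule 2: co-assignment between the two spiked species, by peptide or by
  # shared protein group
  both <- to_lab & to_unl
  pg_lab <- unique(qt$protein_group[to_lab])
  pg_unl <- unique(qt$protein_group[to_unl])
  shared_pg <- intersect(pg_lab, pg_unl)
  r2 <- both | (spike_row & qt$protein_group %in% shared_pg)

  # rule 3: seen in any non-spike control
  ctrl <- intersect(design$control_samples, quant_samples(quant))
  in_ctrl <- if (length(ctrl) == 0) rep(FALSE, nrow(qt))
             else rowSums(!is.na(as.data.frame(qt)[, ctrl, drop = FALSE])) > 0
  r3 <- spike_row & in_ctrl

  removed <- tibble::tibble(
    rule = c("heavy_channel", "co_assignment", "control_presence"),
    n_removed = c(sum(r1), sum(r2 & !r1), sum(r3 & !r1 & !r2)))
  keep <- !(r1 | r2 | r3)
  list(table = qt[keep, , drop = FALSE], removed = removed)
}

#' Spiked cell input as a percent of community biomass
#'
#' `100 * n_cells / (feces_mass_g * cells_per_gram)`: the fraction of the
#' assumed bacterial cell population of the fecal sample represented by
#' the spiked cells. With the default density of 1e12 cells/g, 1e4 cells
#' in 10 mg of feces is 0.0001% — one cell in a million.
#'
#' @param n_cells spiked cell count (>= 0).
#' @param feces_mass_g fecal mass in grams.
#' @param cells_per_gram assumed cells per gram of feces.
#' @return percent of total cells.
#' @export
cell_fraction <- function(n_cells, feces_mass_g = 0.01,
                          cells_per_gram = 1e12) {
  stopifnot(all(n_cells >= 0), feces_mass_g > 0, cells_per_gram > 0)
  100 * n_cells / (feces_mass_g * cells_per_gram)
}

#' Summarise spike-in detection across input levels
#'
#' For each spiked species and cell-input level: the number of distinct
#' surviving peptides, distinct surviving protein groups, and (when a
#' biomass profile is supplied) the measured biomass fraction averaged
#' over that level's replicate samples.
#'
#' @param filtered_tables named list `level -> peptide_quant` of
#'   [apply_spikein_filters()] outputs (`$table`), names coercible to the
#'   cell-input numbers.
#' @param assignments tibble mapping `peptide` to `species`.
#' @param design a [spikein_design()].
#' @param profiles optional biomass profile from [biomass_fractions()]
#'   covering the replicate samples of each level.
#' @return tibble: `species`, `cell_input`, `n_peptides`,
#'   `n_protein_groups`, `biomass_fraction`.
#' @export
detection_summary <- function(filtered_tables, assignments, design,
                              profiles = NULL) {
  spp <- c(design$labeled_species, design$unlabeled_species)
  rows <- list()
  for (lvl in names(filtered_tables)) {
    qt <- filtered_tables[[lvl]]
    for (sp in spp) {
      peps <- unique(assignments$peptide[assignments$species == sp])
      sub <- qt[qt$peptide %in% peps, , drop = FALSE]
      frac <- NA_real_
      if (!is.null(profiles)) {
        reps <- design$replicate_samples[[lvl]]
        hit <- profiles$taxon == sp & profiles$sample %in% reps
        if (any(hit)) frac <- mean(profiles$biomass_fraction[hit], na.rm = TRUE)
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        species = sp, cell_input = as.numeric(lvl),
        n_peptides = length(unique(sub$peptide)),
        n_protein_groups = length(unique(sub$protein_group)),
        biomass_fraction = frac)
    }
  }
  dplyr::bind_rows(rows)
}
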