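# Orchestration: one function per stage plus run_pipeline() chaining
# filter -> build-db -> annotate -> quantify from a single YAML config.
# Re-running with identical inputs and seed reproduces byte-identical TSVs.

.default_config <- function() {
  list(
    seed = 1,
    filter = list(score_min = 65, charge_excluded = 1, length_min = 7,
                  central_fraction = 0.95, interval = "qnorm"),
    build_db = list(min_pident = 80),
    annotate = list(min_specific = 3, rank = "species"),
    quantify = list(rank = "species", common = TRUE),
    report = list(q_value_max = 0.01))
}

#' Read a pipeline configuration
#'
#' YAML with stage blocks (`filter`, `build_db`, `annotate`, `quantify`,
#' `report`), a `paths` block and a `seed`. Unknown keys are rejected;
#' missing ones take the workflow defaults (score 65, charge {1}, length
#' 7, central fraction 0.95, 80% identity, 3 specific peptides,
#' q <= 0.01).
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return nested configuration list.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- .default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  known <- c(names(cfg), "paths")
  unknown <- setdiff(names(user), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (k in names(user)) {
    if (is.list(user[[k]]) && k %in% names(cfg)) {
      bad <- setdiff(names(user[[k]]), names(cfg[[k]]))
      if (length(bad))
        stop("unknown config key(s) in '", k, "': ",
             paste(bad, collapse = ", "), call. = FALSE)
      cfg[[k]] <- utils::modifyList(cfg[[k]], user[[k]])
    } else cfg[[k]] <- user[[k]]
  }
  cfg
}

.manifest_entry <- function(stage, inputs, outputs, counts) {
  tibble::tibble(
    stage = stage,
    inputs = paste(names(inputs), vapply(unlist(inputs), function(p)
      if (file.exists(p)) unname(tools::md5sum(p)) else "-", character(1)),
      sep = ":", collapse = ";"),
    outputs = paste(unlist(outputs), collapse = ";"),
    counts = paste(names(counts), unlist(counts), sep = "=", collapse = ";"))
}

#' Run the pipeline end to end
#'
#' Chains the stages on file inputs named in `config$paths`: `psms` (de
#' novo PSM TSV) through the six-tier filter; `hits`/`lca`/`lineages`/
#' `subjects` through candidate selection, the identity floor and
#' database assembly; `report` (peptide quantification TSV) plus the
#' built peptide-taxid matches through annotation, detection and
#' quantification. Stages whose inputs are absent from `paths` are
#' skipped, so partial runs (e.g. filter only) are first-class. Every
#' stage writes its outputs under `out_dir` and appends a manifest row
#' (input md5s, counts).
#'
#' @param config list from [read_pipeline_config()] (its `paths` block
#'   names the inputs).
#' @param out_dir output directory, created if needed.
#' @return invisibly, the manifest tibble (also written to
#'   `out_dir/manifest.tsv`).
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- config$paths
  if (is.null(paths)) stop("config has no 'paths' block", call. = FALSE)
  for (p in unlist(paths))
    if (!file.exists(p)) stop("input path does not exist: ", p, call. = FALSE)
  set.seed(config$seed)
  manifest <- list()
  survivors <- NULL

  if (!is.null(paths$psms)) {
    psms <- read_denovo_psms(paths$psms)
    fc <- config$filter
    res <- run_filter_cascade(psms, filter_config(
      score_min = fc$score_min, charge_excluded = fc$charge_excluded,
      length_min = fc$length_min, central_fraction = fc$central_fraction,
      interval = fc$interval))
    survivors <- res$survivors
    out_surv <- file.path(out_dir, "survivors.tsv")
    out_rep <- file.path(out_dir, "tiers.tsv")
    write_denovo_psms(survivors, out_surv)
    write_tier_report(res$report, out_rep)
    for (i in seq_len(nrow(res$report)))
      message(sprintf("tier %-10s %6d -> %6d", res$report$tier[i],
                      res$report$n_in[i], res$report$n_out[i]))
    manifest$filter <- .manifest_entry("filter", paths["psms"],
      list(out_surv, out_rep),
      list(n_in = nrow(psms), n_out = nrow(survivors)))
  }

  if (!is.null(paths$hits)) {
    hits <- read_diamond_tabular(paths$hits)
    lca <- read_diamond_lca(paths$lca)
    lineages <- read_lineage_table(paths$lineages)
    subjects <- read_fasta(paths$subjects)
    if (!is.null(survivors))
      hits <- hits[hits$qseqid %in% survivors$peptide, , drop = FALSE]
    built <- build_protein_db(hits, lca, lineages, subjects,
                              min_pident = config$build_db$min_pident)
    out_db <- file.path(out_dir, "db.fasta")
    write_fasta(built$proteins, out_db)
    manifest$build_db <- .manifest_entry("build_db",
      paths[c("hits", "lca", "lineages", "subjects")], list(out_db),
      list(n_queries = length(unique(hits$qseqid)),
           n_kept = nrow(built$kept), n_proteins = nrow(built$proteins)))
  }

  if (!is.null(paths$report) && !is.null(paths$matches)) {
    quant <- read_peptide_report(paths$report,
                                 q_value_max = config$report$q_value_max)
    matches <- readr::read_tsv(paths$matches, show_col_types = FALSE,
                               progress = FALSE,
                               col_types = readr::cols(
                                 peptide = readr::col_character(),
                                 taxid = readr::col_integer()))
    lineages <- read_lineage_table(paths$lineages)
    assignments <- resolve_specificity(matches, lineages)
    rank <- config$annotate$rank
    detected <- detect_taxa(assignments, rank = rank,
                            min_specific = config$annotate$min_specific)
    profile <- quantify_taxon(assignments, quant, rank = rank,
                              taxa = detected$taxon,
                              common = config$quantify$common)
    profile <- biomass_fractions(profile)
    out_det <- file.path(out_dir, "detected_taxa.tsv")
    out_prof <- file.path(out_dir, "taxon_profile.tsv")
    readr::write_tsv(detected, out_det, progress = FALSE)
    readr::write_tsv(profile, out_prof, na = "", progress = FALSE)
    manifest$quantify <- .manifest_entry("quantify",
      paths[c("report", "matches", "lineages")], list(out_det, out_prof),
      list(n_peptides = nrow(quant), n_detected = nrow(detected)))
  }

  mtab <- dplyr::bind_rows(manifest)
  readr::write_tsv(mtab, file.path(out_dir, "manifest.tsv"),
                   progress = FALSE)
  invisible(mtab)
}
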