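# LCA-guided resolution of BLAST homology candidates and assembly of a
# non-redundant protein database with provenance and overlap accounting.

# Deepest non-blank rank of a lineage row (NULL if all ranks blank).
.deepest_rank <- function(lineage_row) {
  for (r in rev(tax_ranks()))
    if (!is.na(lineage_row[[r]])) return(r)
  NULL
}

.lineage_lookup <- function(lineages, taxid) {
  i <- match(taxid, lineages$taxid)
  if (is.na(i)) NULL else lineages[i, , drop = FALSE]
}

# Deterministic candidate ordering: bitscore desc, pident desc, evalue asc,
# accession lexicographic (C locale).
.order_hits <- function(hits) {
  order(-hits$bitscore, -hits$pident, hits$evalue, hits$sseqid,
        method = "radix")
}

#' Select one protein candidate per query, guided by the LCA assignment
#'
#' Resolution proceeds in three steps. Step A keeps candidates whose
#' subject taxid equals the consensus (LCA) taxid; a unique match is
#' returned immediately. Step B keeps candidates lying at or below the LCA
#' taxon: their lineage carries the LCA taxon's name at the LCA's own
#' (deepest non-blank) rank. Step C orders whatever set remains (Step-A
#' ties, Step-B survivors, or all hits when both steps are empty or the
#' query is LCA-unassigned) by bit score descending, percent identity
#' descending, e-value ascending, then subject accession, and returns the
#' first. Exactly one hit is always returned, and the choice is invariant
#' to the order of the input hits.
#'
#' @param hits tibble of BLAST hits for one query (columns `qseqid`,
#'   `sseqid`, `pident`, `evalue`, `bitscore`, `staxids`).
#' @param lca_taxid the query's LCA taxid; 0 or `NA` means unassigned.
#' @param lineages lineage table from [read_lineage_table()].
#' @return one-row tibble: the selected hit.
#' @export
select_candidate <- function(hits, lca_taxid, lineages) {
  if (is.null(hits) || nrow(hits) == 0)
    stop("select_candidate: empty hit list", call. = FALSE)
  if (length(unique(hits$qseqid)) > 1)
    stop("select_candidate: hits span multiple queries", call. = FALSE)
  pool <- hits
  if (!is.na(lca_taxid) && lca_taxid != 0) {
    exact <- hits[hits$staxids == lca_taxid, , drop = FALSE]
    if (nrow(exact) == 1) return(exact)
    if (nrow(exact) > 1) {
      pool <- exact
    } else {
      lca_lin <- .lineage_lookup(lineages, lca_taxid)
      if (!is.null(lca_lin)) {
        rank <- .deepest_rank(lca_lin)
        if (!is.null(rank)) {
          under <- vapply(hits$staxids, function(tx) {
            lin <- .lineage_lookup(lineages, tx)
            !is.null(lin) && !is.na(lin[[rank]]) &&
              lin[[rank]] == lca_lin[[rank]]
          }, logical(1))
          if (any(under)) pool <- hits[under, , drop = FALSE]
        }
      }
    }
  }
  pool[.order_hits(pool)[1], , drop = FALSE]
}

#' Resolve every query's hits to one candidate
#'
#' Vectorised driver over [select_candidate()].
#'
#' @param hits tibble from [read_diamond_tabular()].
#' @param lca tibble from [read_diamond_lca()].
#' @param lineages lineage table.
#' @return tibble with one selected hit per query, in first-appearance
#'   query order.
#' @export
select_candidates <- function(hits, lca, lineages) {
  if (nrow(hits) == 0) return(hits)
  queries <- unique(hits$qseqid)
  lca_of <- stats::setNames(lca$taxid, lca$qseqid)
  rows <- lapply(queries, function(q) {
    tx <- if (q %in% names(lca_of)) lca_of[[q]] else 0L
    select_candidate(hits[hits$qseqid == q, , drop = FALSE], tx, lineages)
  })
  dplyr::bind_rows(rows)
}

#' Apply the minimum percent-identity floor
#'
#' @param selected tibble of selected hits.
#' @param min_pident retain hits with `pident >= min_pident` (boundary
#'   inclusive; default 80).
#' @return filtered tibble.
#' @export
apply_identity_filter <- function(selected, min_pident = 80) {
  selected[selected$pident >= min_pident, , drop = FALSE]
}

#' Merge protein sources into a non-redundant database
#'
#' Records are deduplicated on the exact amino-acid sequence; the
#' first-seen accession/description survive and the provenance of every
#' duplicate is recorded on the survivor (comma-joined `source`). The
#' overlap report gives, for every pair of sources, the sequence-set
#' cardinalities |A|, |B|, |A intersect B| and |A union B|.
#'
#' @param ... one or more protein record tibbles (columns `accession`,
#'   `sequence`, optionally `description`, `source`). Unnamed arguments are
#'   labelled source1, source2, ...
#' @return list with `db` (deduplicated records) and `overlap` (pairwise
#'   tibble: `source_a`, `source_b`, `n_a`, `n_b`, `n_intersect`,
#'   `n_union`).
#' @export
merge_protein_dbs <- function(...) {
  sources <- list(...)
  if (length(sources) == 1 && is.list(sources[[1]]) &&
      !is.data.frame(sources[[1]]))
    sources <- sources[[1]]
  nm <- names(sources)
  if (is.null(nm)) nm <- rep("", length(sources))
  nm[nm == ""] <- paste0("source", which(nm == ""))
  names(sources) <- nm
  for (i in seq_along(sources)) {
    s <- sources[[i]]
    if (!"source" %in% names(s) || all(is.na(s$source)))
      s$source <- nm[i]
    if (!"description" %in% names(s)) s$description <- NA_character_
    sources[[i]] <- s[c("accession", "description", "sequence", "source")]
  }
  all_rec <- dplyr::bind_rows(sources)
  if (nrow(all_rec) == 0) {
    db <- tibble::as_tibble(all_rec)
  } else {
    prov <- vapply(split(all_rec$source, all_rec$sequence)[unique(all_rec$sequence)],
                   function(s) paste(unique(s), collapse = ","), character(1))
    db <- all_rec[!duplicated(all_rec$sequence), , drop = FALSE]
    db$source <- unname(prov[db$sequence])
  }
  seq_sets <- lapply(sources, function(s) unique(s$sequence))
  pairs <- if (length(sources) >= 2) utils::combn(nm, 2, simplify = FALSE)
           else list()
  overlap <- dplyr::bind_rows(lapply(pairs, function(p) {
    a <- seq_sets[[p[1]]]; b <- seq_sets[[p[2]]]
    tibble::tibble(source_a = p[1], source_b = p[2],
                   n_a = length(a), n_b = length(b),
                   n_intersect = length(intersect(a, b)),
                   n_union = length(union(a, b)))
  }))
  list(db = tibble::as_tibble(db), overlap = overlap)
}

#' Build a protein database from filtered de novo peptides
#'
#' End-to-end database assembly: resolve each query's top hits via
#' [select_candidate()], drop selections below the identity floor, and pull
#' the full-length subject sequences from the provided FASTA (sequence
#' retrieval is an input, never a network call).
#'
#' @param hits tibble from [read_diamond_tabular()].
#' @param lca tibble from [read_diamond_lca()].
#' @param lineages lineage table.
#' @param subject_seqs protein records (e.g. [read_fasta()]) covering the
#'   subject accessions.
#' @param min_pident identity floor in percent (default 80).
#' @param source provenance label stamped on the emitted records.
#' @return list with `proteins` (unique protein records for the surviving
#'   subjects), `selected` (per-query selected hits) and `kept` (selections
#'   passing the identity floor).
#' @export
build_protein_db <- function(hits, lca, lineages, subject_seqs,
                             min_pident = 80, source = "novomp") {
  selected <- select_candidates(hits, lca, lineages)
  kept <- apply_identity_filter(selected, min_pident)
  acc <- unique(kept$sseqid)
  missing <- setdiff(acc, subject_seqs$accession)
  if (length(missing))
    stop("subject sequence(s) absent from FASTA: ",
         paste(utils::head(missing, 3), collapse = ", "),
         if (length(missing) > 3) ", ...", call. = FALSE)
  proteins <- subject_seqs[match(acc, subject_seqs$accession), , drop = FALSE]
  proteins$source <- source
  list(proteins = tibble::as_tibble(proteins), selected = selected,
       kept = kept)
}
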