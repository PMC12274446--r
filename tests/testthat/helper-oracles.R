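# Independent brute-force oracles and tiny fixture builders shared across
# the test files. These deliberately re-derive results by the most direct
# route available (explicit loops, rule enumeration) and never call the
# package functions they are used to check.

# --- fixture builders -------------------------------------------------------

write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

toy_psm_lines <- function(rows) {
  header <- "spectrum_id\tpeptide\tscore\tcharge\tmass_error\trt_observed\trt_predicted\tccs_observed\tccs_predicted"
  c(header, rows)
}

toy_lineages <- function() {
  tibble::tibble(
    taxid = c(101L, 102L, 103L, 201L, 202L, 901L, 902L),
    superkingdom = "Bacteria",
    phylum = c(rep("p1", 5), "p1", "p1"),
    class = c(rep("c1", 5), "c1", "c1"),
    order = c(rep("o1", 5), "o1", "o1"),
    family = c("f1", "f1", "f1", "f2", "f2", "f1", "f2"),
    genus = c("gA", "gA", "gA", "gB", "gB", "gA", "gB"),
    species = c("sp_a1", "sp_a2", "sp_a3", "sp_b1", "sp_b2", NA, NA))
}

# --- brute-force oracle: one-pass cascade predicate evaluator ---------------

# Evaluates all six predicates in one pass given externally supplied
# distribution cutoffs (lo/hi per tier), without any sequential refitting.
brute_force_cascade <- function(psms, cutoffs, score_min = 65,
                                charge_excluded = 1, length_min = 7) {
  keep <- rep(TRUE, nrow(psms))
  keep <- keep & psms$score >= score_min
  keep <- keep & !(psms$charge %in% charge_excluded)
  keep <- keep & nchar(psms$peptide) >= length_min
  d <- list(mass_error = psms$mass_error,
            rt_shift = psms$rt_observed - psms$rt_predicted,
            ccs_shift = psms$ccs_observed - psms$ccs_predicted)
  for (tier in names(d))
    keep <- keep & d[[tier]] >= cutoffs[[tier]]["lo"] &
      d[[tier]] <= cutoffs[[tier]]["hi"]
  psms[keep, , drop = FALSE]
}

# Independent sequential re-implementation (explicit loop, no shared code
# with run_filter_cascade beyond stats::qnorm).
brute_force_sequential <- function(psms, fraction = 0.95) {
  cur <- psms[psms$score >= 65 & psms$charge != 1 &
                nchar(psms$peptide) >= 7, , drop = FALSE]
  z <- qnorm((1 + fraction) / 2)
  for (tier in c("mass_error", "rt_shift", "ccs_shift")) {
    d <- switch(tier,
                mass_error = cur$mass_error,
                rt_shift = cur$rt_observed - cur$rt_predicted,
                ccs_shift = cur$ccs_observed - cur$ccs_predicted)
    lo <- mean(d) - z * sd(d); hi <- mean(d) + z * sd(d)
    cur <- cur[d >= lo & d <= hi, , drop = FALSE]
  }
  cur
}

# --- brute-force oracle: LCA-guided candidate selection ---------------------

# Direct enumeration of the rule: Step A (exact taxid), Step B (lineage
# carries the LCA name at the LCA's deepest rank), Step C ordering.
brute_force_select <- function(hits, lca_taxid, lineages) {
  ranks <- c("superkingdom", "phylum", "class", "order", "family",
             "genus", "species")
  best_of <- function(pool) {
    key <- order(-pool$bitscore, -pool$pident, pool$evalue, pool$sseqid,
                 method = "radix")
    pool[key[1], , drop = FALSE]
  }
  if (!is.na(lca_taxid) && lca_taxid != 0) {
    exact <- hits[hits$staxids == lca_taxid, , drop = FALSE]
    if (nrow(exact) == 1) return(exact)
    if (nrow(exact) > 1) return(best_of(exact))
    li <- match(lca_taxid, lineages$taxid)
    if (!is.na(li)) {
      lca_rank <- NA
      for (r in ranks) if (!is.na(lineages[[r]][li])) lca_rank <- r
      if (!is.na(lca_rank)) {
        under <- logical(nrow(hits))
        for (j in seq_len(nrow(hits))) {
          hj <- match(hits$staxids[j], lineages$taxid)
          under[j] <- !is.na(hj) && !is.na(lineages[[lca_rank]][hj]) &&
            lineages[[lca_rank]][hj] == lineages[[lca_rank]][li]
        }
        if (any(under)) return(best_of(hits[under, , drop = FALSE]))
      }
    }
  }
  best_of(hits)
}

# --- brute-force oracle: rank-by-rank peptide specificity -------------------

brute_force_specificity <- function(taxids, lineages) {
  ranks <- c("superkingdom", "phylum", "class", "order", "family",
             "genus", "species")
  rows <- lineages[match(taxids, lineages$taxid), , drop = FALSE]
  res <- list(specificity_rank = "unranked")
  for (r in ranks) {
    nm <- unique(rows[[r]][!is.na(rows[[r]])])
    if (length(nm) > 1) { res[[r]] <- NA_character_; break }
    res[[r]] <- if (length(nm) == 1) nm else NA_character_
    if (length(nm) == 1) res$specificity_rank <- r
  }
  for (r in ranks) if (is.null(res[[r]])) res[[r]] <- NA_character_
  res
}

# Deterministic, pairwise-distinct amino-acid strings: the record index in
# base 20 over the amino-acid alphabet, fixed width -> uniqueness by
# construction, fast enough for the 158k-sequence union check.
make_unique_sequences <- function(n, width = 8) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  idx <- seq_len(n) - 1L
  chars <- matrix("", nrow = n, ncol = width)
  for (j in seq_len(width)) {
    chars[, j] <- aa[idx %% 20L + 1L]
    idx <- idx %/% 20L
  }
  paste0(do.call(paste0, as.data.frame(chars, stringsAsFactors = FALSE)),
         "K")
}

# Random hit sets for the selection fuzz suite.
random_hit_case <- function(lineages, max_hits = 5) {
  n <- sample.int(max_hits, 1)
  tibble::tibble(
    qseqid = "Q",
    sseqid = sprintf("ACC%02d", sample.int(50, n)),
    pident = round(runif(n, 40, 100), 1),
    evalue = signif(10^runif(n, -10, -2), 3),
    bitscore = sample(c(50, 80, 100, 120), n, replace = TRUE),
    staxids = sample(lineages$taxid, n, replace = TRUE))
}
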