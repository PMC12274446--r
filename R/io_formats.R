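# Readers and writers for every on-disk table the pipeline touches.
# Strict column contracts: a missing required column or a malformed numeric
# cell is an error, never a silent NA. TSV dialect: tab-separated, UTF-8,
# '.' decimal, no quoting, mandatory header (DIAMOND fmt6/fmt102 are the
# headerless exceptions, matching the tools that emit them).

#' Define a table schema
#'
#' A schema names the required and optional columns of a TSV input and their
#' semantic types, plus an optional rename map so real exports (DIA-NN,
#' DIAMOND wrappers) can be adapted without code changes.
#'
#' @param name identifier for the schema, used in error messages.
#' @param required named character vector: column name -> type, one of
#'   `"character"`, `"numeric"`, `"integer"`.
#' @param optional same shape as `required`; columns read when present.
#' @param rename named character vector mapping source-file column names to
#'   schema column names, applied before the contract is checked.
#' @return an object of class `novomp_schema`.
#' @export
table_schema <- function(name, required, optional = character(), rename = character()) {
  stopifnot(is.character(required), !is.null(names(required)))
  if (anyDuplicated(names(required)))
    stop("schema '", name, "': duplicate required columns", call. = FALSE)
  structure(list(name = name, required = required, optional = optional,
                 rename = rename),
            class = "novomp_schema")
}

# Strict numeric conversion: empty cells become NA (explicit absence);
# anything else non-numeric is an error naming the column and row.
.strict_numeric <- function(x, column, integer = FALSE) {
  x <- trimws(x)
  blank <- is.na(x) | x == "" | x == "NA"
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!blank & is.na(out))
  if (length(bad))
    stop("malformed numeric value '", x[bad[1]], "' in column '", column,
         "' (row ", bad[1], ")", call. = FALSE)
  if (integer) out <- as.integer(round(out))
  out
}

.read_tsv_raw <- function(source, col_names = TRUE) {
  readr::read_tsv(source, col_names = col_names,
                  col_types = readr::cols(.default = readr::col_character()),
                  quote = "", na = character(), progress = FALSE,
                  show_col_types = FALSE)
}

# Apply a schema to a raw character tibble: rename, check, convert.
.apply_schema <- function(raw, schema) {
  if (length(schema$rename)) {
    hit <- names(raw) %in% names(schema$rename)
    names(raw)[hit] <- unname(schema$rename[names(raw)[hit]])
  }
  missing <- setdiff(names(schema$required), names(raw))
  if (length(missing))
    stop("schema '", schema$name, "': required column(s) missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  keep <- c(names(schema$required),
            intersect(names(schema$optional), names(raw)))
  raw <- raw[keep]
  types <- c(schema$required, schema$optional)[keep]
  for (col in keep) {
    raw[[col]] <- switch(types[[col]],
      character = { x <- raw[[col]]; x[x == ""] <- NA_character_; x },
      numeric   = .strict_numeric(raw[[col]], col),
      integer   = .strict_numeric(raw[[col]], col, integer = TRUE),
      stop("unknown type '", types[[col]], "' in schema '", schema$name, "'"))
  }
  raw
}

#' Default schema for de novo PSM tables
#'
#' One row per peptide-spectrum match as exported by a de novo caller: the
#' stripped peptide, de novo score (0-100), precursor charge, precursor mass
#' error (ppm), and observed plus predicted retention time (min) and
#' collisional cross-section (A^2).
#'
#' @param rename optional column rename map, see [table_schema()].
#' @return a `novomp_schema`.
#' @export
denovo_psm_schema <- function(rename = character()) {
  table_schema(
    "denovo_psm",
    required = c(spectrum_id = "character", peptide = "character",
                 score = "numeric", charge = "integer", mass_error = "numeric"),
    optional = c(rt_observed = "numeric", rt_predicted = "numeric",
                 ccs_observed = "numeric", ccs_predicted = "numeric",
                 intensity = "numeric", modifications = "character"),
    rename = rename)
}

#' Read a de novo PSM table
#'
#' @param source path or connection to a TSV with header.
#' @param schema a [table_schema()]; defaults to [denovo_psm_schema()].
#' @return tibble of PSMs in file order.
#' @export
read_denovo_psms <- function(source, schema = denovo_psm_schema()) {
  psms <- .apply_schema(.read_tsv_raw(source), schema)
  bad <- which(is.na(psms$peptide) | !grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", psms$peptide))
  if (length(bad))
    stop("invalid peptide sequence at row ", bad[1], call. = FALSE)
  if (any(psms$charge < 1, na.rm = TRUE))
    stop("charge must be >= 1", call. = FALSE)
  psms
}

#' Write a de novo PSM table
#' @param psms tibble as returned by [read_denovo_psms()].
#' @param sink output path.
#' @export
write_denovo_psms <- function(psms, sink) {
  readr::write_tsv(psms, sink, progress = FALSE)
  invisible(sink)
}

.FMT6_DEFAULT <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                   "gapopen", "qstart", "qend", "sstart", "send",
                   "evalue", "bitscore", "staxids")

#' Read DIAMOND blastp tabular output (format 6)
#'
#' Headerless tab-separated hits, at most a handful per query (the pipeline
#' requests the top 5). The minimal column set consumed downstream is query
#' id, subject id, percent identity, e-value, bit score and subject taxid.
#'
#' @param source path or connection.
#' @param columns character vector naming the columns in file order; must
#'   contain `qseqid`, `sseqid`, `pident`, `evalue`, `bitscore`, `staxids`.
#' @return tibble with one row per hit, `rank_in_query` appended in file
#'   order within each query.
#' @export
read_diamond_tabular <- function(source, columns = .FMT6_DEFAULT) {
  need <- c("qseqid", "sseqid", "pident", "evalue", "bitscore", "staxids")
  missing <- setdiff(need, columns)
  if (length(missing))
    stop("format-6 column spec lacks: ", paste(missing, collapse = ", "),
         call. = FALSE)
  raw <- .read_tsv_raw(source, col_names = FALSE)
  if (nrow(raw) == 0) {
    out <- tibble::tibble(qseqid = character(), sseqid = character(),
                          pident = numeric(), evalue = numeric(),
                          bitscore = numeric(), staxids = integer(),
                          rank_in_query = integer())
    return(out)
  }
  if (ncol(raw) == length(need) && length(columns) != length(need))
    columns <- need   # minimal six-column profile, as written by simulate
  if (ncol(raw) < length(columns))
    stop("format-6 stream has ", ncol(raw), " columns, expected ",
         length(columns), call. = FALSE)
  names(raw)[seq_along(columns)] <- columns
  hits <- raw[need]
  for (col in c("pident", "evalue", "bitscore"))
    hits[[col]] <- tryCatch(.strict_numeric(hits[[col]], col),
                            error = function(e)
                              stop(conditionMessage(e), call. = FALSE))
  hits$staxids <- .strict_numeric(hits$staxids, "staxids", integer = TRUE)
  if (any(hits$pident < 0 | hits$pident > 100, na.rm = TRUE))
    stop("pident outside [0, 100]", call. = FALSE)
  hits$rank_in_query <- stats::ave(seq_len(nrow(hits)), hits$qseqid,
                                   FUN = seq_along)
  tibble::as_tibble(hits)
}

#' Read DIAMOND LCA output (format 102)
#'
#' Headerless three-column stream: query id, consensus taxid from the lowest
#' common ancestor of the query's hits, e-value. Taxid 0 encodes an
#' unassigned query.
#'
#' @param source path or connection.
#' @return tibble with columns `qseqid`, `taxid`, `evalue`; one row per query.
#' @export
read_diamond_lca <- function(source) {
  raw <- .read_tsv_raw(source, col_names = FALSE)
  if (nrow(raw) == 0)
    return(tibble::tibble(qseqid = character(), taxid = integer(),
                          evalue = numeric()))
  if (ncol(raw) < 3)
    stop("format-102 stream needs 3 columns (qseqid, taxid, evalue)",
         call. = FALSE)
  out <- tibble::tibble(
    qseqid = raw[[1]],
    taxid  = .strict_numeric(raw[[2]], "taxid", integer = TRUE),
    evalue = .strict_numeric(raw[[3]], "evalue"))
  dup <- out$qseqid[duplicated(out$qseqid)]
  if (length(dup))
    stop("duplicate query id in LCA output: ", dup[1], call. = FALSE)
  out
}

.RANKS <- c("superkingdom", "phylum", "class", "order", "family", "genus",
            "species")

#' Canonical taxonomic ranks, shallowest first
#' @return character vector of the 7 ranks.
#' @export
tax_ranks <- function() .RANKS

#' Read a taxonomic lineage table
#'
#' TSV with header: `taxid` plus the 7 canonical ranks (superkingdom through
#' species). Blank rank names are permitted below superkingdom and are
#' ignored by lowest-common-ancestor logic downstream.
#'
#' @param source path or connection.
#' @return tibble keyed by `taxid` with the 7 rank columns (blank -> `NA`).
#' @export
read_lineage_table <- function(source) {
  schema <- table_schema(
    "lineage", required = c(taxid = "integer",
                            stats::setNames(rep("character", 7), .RANKS)))
  lin <- .apply_schema(.read_tsv_raw(source), schema)
  if (anyDuplicated(lin$taxid))
    stop("duplicate taxid in lineage table", call. = FALSE)
  lin
}

#' Write a lineage table
#' @param lineages tibble as from [read_lineage_table()].
#' @param sink output path.
#' @export
write_lineage_table <- function(lineages, sink) {
  readr::write_tsv(lineages, sink, na = "", progress = FALSE)
  invisible(sink)
}

#' Read a protein FASTA
#'
#' Headers are split at the first whitespace into accession and description;
#' a `source=` tag in the description (written by [write_fasta()]) is parsed
#' back into the `source` column recording provenance (`db_search`,
#' `novomp`, `catalog`).
#'
#' @param source FASTA path.
#' @return tibble with columns `accession`, `description`, `sequence`,
#'   `source`.
#' @export
read_fasta <- function(source) {
  set <- Biostrings::readAAStringSet(source)
  headers <- names(set)
  accession <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), NA_character_)
  src <- rep(NA_character_, length(headers))
  tagged <- !is.na(description) & grepl("(^| )source=\\S+", description)
  src[tagged] <- sub(".*source=(\\S+).*", "\\1", description[tagged])
  description[tagged] <- trimws(sub("(^| )source=\\S+", "", description[tagged]))
  description[!is.na(description) & description == ""] <- NA_character_
  tibble::tibble(accession = accession, description = description,
                 sequence = as.character(set), source = src)
}

#' Write a protein FASTA
#'
#' The inverse of [read_fasta()]: provenance in `source` (possibly several
#' comma-joined tags after deduplication) is carried as a `source=` header
#' tag so that write-then-read is the identity on accession, description,
#' sequence and source.
#'
#' @param records tibble with `accession`, `sequence` and optionally
#'   `description`, `source`.
#' @param sink output path.
#' @param width line-wrapping width for sequences.
#' @export
write_fasta <- function(records, sink, width = 60) {
  if (nrow(records) == 0) {
    writeLines(character(), sink)
    return(invisible(sink))
  }
  desc <- if ("description" %in% names(records)) records$description
          else rep(NA_character_, nrow(records))
  src <- if ("source" %in% names(records)) records$source
         else rep(NA_character_, nrow(records))
  header <- records$accession
  has_desc <- !is.na(desc)
  header[has_desc] <- paste(header[has_desc], desc[has_desc])
  has_src <- !is.na(src)
  header[has_src] <- paste0(header[has_src], " source=", src[has_src])
  set <- Biostrings::AAStringSet(records$sequence)
  names(set) <- header
  Biostrings::writeXStringSet(set, sink, width = width)
  invisible(sink)
}

#' Default schema for DIA-style peptide quantification reports
#'
#' Long-format peptide report: stripped sequence, protein group, label
#' channel (`heavy`/`light`/`none`), precursor and protein-group q-values,
#' then one intensity column per sample. Every non-listed column is treated
#' as a sample intensity column.
#'
#' @param rename optional column rename map.
#' @return a `novomp_schema`.
#' @export
peptide_report_schema <- function(rename = character()) {
  table_schema(
    "peptide_report",
    required = c(peptide = "character", protein_group = "character",
                 label = "character", q_value = "numeric",
                 pg_q_value = "numeric"),
    rename = rename)
}

#' Read a peptide quantification report with q-value filtering
#'
#' Rows failing either the precursor or the protein-group q-value threshold
#' are dropped (the count is reported via `message()`). Intensities must be
#' positive when present; an empty cell is an explicitly absent measurement
#' (`NA`), never zero, because absence and zero differ downstream (labeling
#' efficiency, common-peptide summation).
#'
#' @param source path or connection to the TSV.
#' @param q_value_max retain rows with both q-values at or below this
#'   threshold (default 0.01).
#' @param schema a [table_schema()] for the metadata columns.
#' @return a `peptide_quant` tibble; attribute `samples` lists the sample
#'   columns.
#' @export
read_peptide_report <- function(source, q_value_max = 0.01,
                                schema = peptide_report_schema()) {
  raw <- .read_tsv_raw(source)
  meta <- .apply_schema(raw, schema)
  sample_cols <- setdiff(names(raw),
                         c(names(schema$required), names(schema$optional),
                           names(schema$rename)))
  for (col in sample_cols) {
    v <- .strict_numeric(raw[[col]], col)
    if (any(v < 0, na.rm = TRUE))
      stop("negative intensity in sample column '", col, "'", call. = FALSE)
    meta[[col]] <- v
  }
  keep <- meta$q_value <= q_value_max & meta$pg_q_value <= q_value_max
  keep[is.na(keep)] <- FALSE
  dropped <- sum(!keep)
  if (dropped > 0)
    message(dropped, " row(s) failed q-value <= ", q_value_max)
  out <- meta[keep, , drop = FALSE]
  peptide_quant(out, samples = sample_cols)
}

#' Construct a peptide quantification table
#'
#' @param table tibble with peptide metadata plus one numeric column per
#'   sample.
#' @param samples character vector naming the sample columns.
#' @return `table` with class `peptide_quant` and attribute `samples`.
#' @export
peptide_quant <- function(table, samples) {
  missing <- setdiff(samples, names(table))
  if (length(missing))
    stop("sample column(s) absent from table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  attr(table, "samples") <- samples
  class(table) <- unique(c("peptide_quant", class(table)))
  table
}

#' Sample columns of a peptide quantification table
#' @param quant a `peptide_quant` tibble.
#' @return character vector of sample column names.
#' @export
quant_samples <- function(quant) attr(quant, "samples")

#' Write a peptide quantification table
#' @param quant a `peptide_quant` tibble.
#' @param sink output path.
#' @export
write_peptide_report <- function(quant, sink) {
  readr::write_tsv(as.data.frame(quant), sink, na = "", progress = FALSE)
  invisible(sink)
}
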