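# Six-tier confidence filter for de novo PSMs. Tiers run strictly in
# order: score floor, charge exclusion, length floor, then three
# distribution tiers (precursor mass error, RT shift, CCS shift) whose
# cutoffs are refit on each tier's own surviving population.

.TIERS <- c("score", "charge", "length", "mass_error", "rt_shift", "ccs_shift")

#' Configuration for the de novo filter cascade
#'
#' Defaults are the workflow's published operating point: de novo score
#' floor 65, singly-charged PSMs excluded, minimum length 7 residues, and
#' each distribution tier retaining the central 95% of its input.
#'
#' @param score_min minimum de novo score retained (floor, inclusive).
#' @param charge_excluded integer charge states removed.
#' @param length_min minimum peptide length in residues (inclusive).
#' @param central_fraction central mass retained by each distribution tier,
#'   in (0, 1).
#' @param interval `"qnorm"` fits a normal (mean +/- z * sd);
#'   `"empirical"` uses sample quantiles instead, for sensitivity analysis.
#' @param tiers subset of tiers to run, in canonical order.
#' @return a `filter_config` list.
#' @export
filter_config <- function(score_min = 65, charge_excluded = 1L,
                          length_min = 7, central_fraction = 0.95,
                          interval = c("qnorm", "empirical"),
                          tiers = .TIERS) {
  interval <- match.arg(interval)
  stopifnot(central_fraction > 0, central_fraction < 1, length_min >= 1)
  tiers <- intersect(.TIERS, tiers)
  structure(list(score_min = score_min,
                 charge_excluded = as.integer(charge_excluded),
                 length_min = length_min,
                 central_fraction = central_fraction,
                 interval = interval, tiers = tiers),
            class = "filter_config")
}

#' Central interval of a distribution
#'
#' The cutoffs used by the distribution tiers: under the default normal fit
#' these are `mean(x) +/- qnorm((1 + fraction) / 2) * sd(x)` with the
#' sample (n-1) standard deviation; the empirical variant returns the
#' `(1 -/+ fraction)/2` sample quantiles.
#'
#' @param values numeric vector, at least 3 finite values with nonzero
#'   variance.
#' @param fraction central mass retained, in (0, 1).
#' @param method `"qnorm"` or `"empirical"`.
#' @param tier label used in error messages.
#' @return named numeric `c(lo, hi)` with `lo < hi`.
#' @export
central_interval <- function(values, fraction = 0.95,
                             method = c("qnorm", "empirical"),
                             tier = "distribution") {
  method <- match.arg(method)
  stopifnot(fraction > 0, fraction < 1)
  values <- values[is.finite(values)]
  if (length(values) < 3)
    stop("tier '", tier, "': need at least 3 finite values to fit cutoffs",
         call. = FALSE)
  if (stats::sd(values) == 0)
    stop("tier '", tier, "': zero variance, cutoffs undefined", call. = FALSE)
  if (method == "qnorm") {
    z <- stats::qnorm((1 + fraction) / 2)
    m <- mean(values)
    s <- stats::sd(values)
    c(lo = m - z * s, hi = m + z * s)
  } else {
    q <- stats::quantile(values, c((1 - fraction) / 2, (1 + fraction) / 2),
                         names = FALSE, type = 7)
    c(lo = q[1], hi = q[2])
  }
}

# Per-tier keep predicate. Distribution tiers receive precomputed cutoffs.
.tier_keep <- function(psms, tier, config, cutoffs = NULL) {
  delta <- switch(tier,
    score     = return(psms$score >= config$score_min),
    charge    = return(!(psms$charge %in% config$charge_excluded)),
    length    = return(nchar(psms$peptide) >= config$length_min),
    mass_error = psms$mass_error,
    rt_shift  = psms$rt_observed - psms$rt_predicted,
    ccs_shift = psms$ccs_observed - psms$ccs_predicted)
  delta >= cutoffs[["lo"]] & delta <= cutoffs[["hi"]]
}

.tier_delta_cols <- list(mass_error = "mass_error",
                         rt_shift = c("rt_observed", "rt_predicted"),
                         ccs_shift = c("ccs_observed", "ccs_predicted"))

#' Run the six-tier de novo PSM filter cascade
#'
#' Tiers are applied sequentially: (1) score >= `score_min`; (2) charge not
#' excluded; (3) length >= `length_min`; (4) precursor mass error within the
#' central interval of the remaining PSMs' mass-error distribution; (5)
#' observed - predicted retention time within the central interval of the
#' remaining deltas; (6) observed - predicted CCS likewise. Cutoff intervals
#' are closed (a value exactly at a cutoff is retained) and are refit on
#' each distribution tier's own input population, so tiers 4-6 are not
#' idempotent by design.
#'
#' @param psms tibble from [read_denovo_psms()].
#' @param config a [filter_config()].
#' @return list with `survivors` (the filtered tibble) and `report` (one
#'   row per tier: `tier`, `n_in`, `n_out`, `lo`, `hi`).
#' @export
run_filter_cascade <- function(psms, config = filter_config()) {
  # an enabled distribution tier needs its observed/predicted columns
  # complete over the whole input, checked before any tier runs
  for (tier in intersect(config$tiers, names(.tier_delta_cols))) {
    cols <- .tier_delta_cols[[tier]]
    if (!all(cols %in% names(psms)) || anyNA(psms[cols]))
      stop("tier '", tier, "' enabled but column(s) ",
           paste(cols, collapse = ", "), " absent or incomplete",
           call. = FALSE)
  }
  report <- tibble::tibble(tier = character(), n_in = integer(),
                           n_out = integer(), lo = numeric(), hi = numeric())
  current <- psms
  for (tier in config$tiers) {
    cutoffs <- c(lo = NA_real_, hi = NA_real_)
    if (tier %in% names(.tier_delta_cols) && nrow(current) == 0) {
      # nothing to fit on an empty cohort; the tier passes vacuously
      report <- dplyr::bind_rows(report, tibble::tibble(
        tier = tier, n_in = 0L, n_out = 0L, lo = NA_real_, hi = NA_real_))
      next
    }
    if (tier %in% names(.tier_delta_cols)) {
      cols <- .tier_delta_cols[[tier]]
      delta <- if (length(cols) == 2) current[[cols[1]]] - current[[cols[2]]]
               else current[[cols[1]]]
      cutoffs <- central_interval(delta, config$central_fraction,
                                  method = config$interval, tier = tier)
    }
    keep <- .tier_keep(current, tier, config, cutoffs)
    keep[is.na(keep)] <- FALSE
    report <- dplyr::bind_rows(report, tibble::tibble(
      tier = tier, n_in = nrow(current), n_out = sum(keep),
      lo = cutoffs[["lo"]], hi = cutoffs[["hi"]]))
    current <- current[keep, , drop = FALSE]
  }
  list(survivors = current, report = report)
}

#' Write a tier attrition report
#' @param report tibble from [run_filter_cascade()].
#' @param sink output path.
#' @export
write_tier_report <- function(report, sink) {
  readr::write_tsv(report, sink, na = "", progress = FALSE)
  invisible(sink)
}
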