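# Seeded generators for every input the pipeline consumes, with planted
# ground truth. These define the study conditions the test-suite runs
# under; defaults mirror the workflow's stated operating regime (tryptic
# peptides 7-30 residues, log-normal intensity noise at CV ~ 0.2, skewed
# log-normal community abundances).

.AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Deterministic unique tryptic-like peptide strings: random body over the
# 20-letter alphabet, K/R C-terminus, de-duplicated.
.random_peptides <- function(n, len_min = 7, len_max = 30) {
  out <- character(0)
  while (length(out) < n) {
    k <- n - length(out)
    lens <- sample(seq(len_min, len_max), k, replace = TRUE)
    body <- vapply(lens, function(l)
      paste(sample(.AA, l - 1, replace = TRUE), collapse = ""), character(1))
    pep <- paste0(body, sample(c("K", "R"), k, replace = TRUE))
    out <- unique(c(out, pep))
  }
  out[seq_len(n)]
}

#' Simulate a microbial community with log-normal abundances
#'
#' @param n_species number of species.
#' @param mu,sigma log-normal parameters of relative abundance
#'   (`sigma = 0` gives a uniform community).
#' @param seed RNG seed.
#' @return tibble `species`, `taxid`, `proportion` (sums to 1).
#' @export
simulate_community <- function(n_species, mu = 0, sigma = 1, seed = 1) {
  set.seed(seed)
  w <- stats::rlnorm(n_species, mu, sigma)
  tibble::tibble(
    species = sprintf("species_%03d", seq_len(n_species)),
    taxid = 1000L + seq_len(n_species),
    proportion = w / sum(w))
}

#' Simulate a taxonomy for a community
#'
#' Species are grouped into genera (consecutive blocks), genera into one
#' family/order/class/phylum chain per block, all under superkingdom
#' Bacteria. A fraction of species can have blank intermediate ranks to
#' exercise the blank-skipping LCA logic.
#'
#' @param community tibble from [simulate_community()].
#' @param species_per_genus genus block size.
#' @param blank_rate fraction of species with blank family/order ranks.
#' @param seed RNG seed.
#' @return lineage tibble (`taxid` + 7 rank columns) containing one row
#'   per species taxid and one per genus taxid (genus taxids start at
#'   9000).
#' @export
simulate_lineages <- function(community, species_per_genus = 2,
                              blank_rate = 0, seed = 1) {
  set.seed(seed)
  n <- nrow(community)
  g <- (seq_len(n) - 1) %/% species_per_genus + 1
  genus <- sprintf("genus_%03d", g)
  fam <- sprintf("family_%02d", (g - 1) %/% 2 + 1)
  ord <- sprintf("order_%02d", (g - 1) %/% 4 + 1)
  cls <- sprintf("class_%02d", (g - 1) %/% 8 + 1)
  phy <- sprintf("phylum_%02d", (g - 1) %/% 16 + 1)
  sp_rows <- tibble::tibble(
    taxid = community$taxid, superkingdom = "Bacteria", phylum = phy,
    class = cls, order = ord, family = fam, genus = genus,
    species = community$species)
  if (blank_rate > 0) {
    blank <- stats::runif(n) < blank_rate
    sp_rows$family[blank] <- NA_character_
    sp_rows$order[blank] <- NA_character_
  }
  gi <- !duplicated(g)
  genus_rows <- tibble::tibble(
    taxid = 9000L + g[gi], superkingdom = "Bacteria", phylum = phy[gi],
    class = cls[gi], order = ord[gi], family = fam[gi], genus = genus[gi],
    species = NA_character_)
  dplyr::bind_rows(sp_rows, genus_rows)
}

#' Simulate a de novo PSM cohort with planted outliers
#'
#' True PSMs carry normal errors in the three physicochemical dimensions
#' (precursor mass error in ppm, RT shift in minutes, CCS shift in A^2)
#' and confident de novo scores above the score floor
#' (65 + 35 x Beta(2, 2)); planted outliers sit at `outlier_k` standard
#' deviations (random sign) in every dimension and draw the same scores,
#' so that only the distribution tiers can remove them. Charge-1 and
#' short-peptide contaminants are added at the stated rates, with mediocre
#' scores (100 x Beta(4, 4)) typical of poor callouts.
#'
#' @param n_true number of well-behaved PSMs.
#' @param n_outlier number of planted distribution outliers.
#' @param sd_ppm,sd_rt,sd_ccs error standard deviations.
#' @param outlier_k offset of planted outliers in units of sd.
#' @param p_charge1,p_short,p_lowscore contamination rates applied to
#'   extra rows appended on top of `n_true` (each drawn independently).
#' @param seed RNG seed.
#' @return list with `psms` (tibble as read by [read_denovo_psms()]) and
#'   `truth` (tibble `spectrum_id`, `class` in
#'   `{"true", "outlier", "contaminant"}`).
#' @export
simulate_denovo_psms <- function(n_true = 1000, n_outlier = 200,
                                 sd_ppm = 3, sd_rt = 0.5, sd_ccs = 5,
                                 outlier_k = 10, p_charge1 = 0,
                                 p_short = 0, p_lowscore = 0, seed = 1) {
  set.seed(seed)
  n_c1 <- round(p_charge1 * n_true)
  n_sh <- round(p_short * n_true)
  n_lo <- round(p_lowscore * n_true)
  n <- n_true + n_outlier + n_c1 + n_sh + n_lo
  class <- c(rep("true", n_true), rep("outlier", n_outlier),
             rep("contaminant", n_c1 + n_sh + n_lo))
  peptide <- .random_peptides(n)
  short_idx <- n_true + n_outlier + n_c1 + seq_len(n_sh)
  if (n_sh > 0)
    peptide[short_idx] <- substr(peptide[short_idx], 1, 6)
  score <- 65 + 35 * stats::rbeta(n, 2, 2)
  lo_idx <- c(n_true + n_outlier + seq_len(n_c1), short_idx,
              n_true + n_outlier + n_c1 + n_sh + seq_len(n_lo))
  if (length(lo_idx))
    score[lo_idx] <- 100 * stats::rbeta(length(lo_idx), 4, 4)
  if (n_lo > 0)
    score[n_true + n_outlier + n_c1 + n_sh + seq_len(n_lo)] <-
      stats::runif(n_lo, 0, 64.9)
  charge <- sample(2:4, n, replace = TRUE)
  if (n_c1 > 0) charge[n_true + n_outlier + seq_len(n_c1)] <- 1L
  sgn <- function(k) sample(c(-1, 1), k, replace = TRUE)
  mass_error <- stats::rnorm(n, 0, sd_ppm)
  rt_pred <- stats::runif(n, 5, 60)
  ccs_pred <- stats::runif(n, 350, 800)
  rt_shift <- stats::rnorm(n, 0, sd_rt)
  ccs_shift <- stats::rnorm(n, 0, sd_ccs)
  out_idx <- n_true + seq_len(n_outlier)
  if (n_outlier > 0) {
    mass_error[out_idx] <- sgn(n_outlier) * outlier_k * sd_ppm
    rt_shift[out_idx] <- sgn(n_outlier) * outlier_k * sd_rt
    ccs_shift[out_idx] <- sgn(n_outlier) * outlier_k * sd_ccs
  }
  psms <- tibble::tibble(
    spectrum_id = sprintf("scan_%06d", seq_len(n)),
    peptide = peptide, score = score, charge = charge,
    mass_error = mass_error,
    rt_observed = rt_pred + rt_shift, rt_predicted = rt_pred,
    ccs_observed = ccs_pred + ccs_shift, ccs_predicted = ccs_pred,
    intensity = stats::rlnorm(n, 14, 1))
  list(psms = psms, truth = tibble::tibble(spectrum_id = psms$spectrum_id,
                                           class = class))
}

#' Simulate BLAST format-6 hits and format-102 LCA lines with truth
#'
#' Each query peptide gets exactly one planted correct subject (top bit
#' score, high identity) whose taxid is consistent with the emitted LCA
#' line, plus distractors with lower bit scores. Distractor taxids fall
#' inside the LCA clade (sister species of the same genus) at rate
#' `p_inside`, outside otherwise; the LCA line points at the species taxid
#' with probability `p_lca_species`, else at the genus taxid, and a
#' fraction `p_unassigned` of queries is emitted as unassigned (taxid 0).
#'
#' @param queries character vector of query peptides.
#' @param community,lineages tibbles from [simulate_community()] /
#'   [simulate_lineages()].
#' @param distractors_per_query distractor hits per query (total hits =
#'   distractors + 1, at most 5 by the format contract).
#' @param p_inside probability a distractor taxid lies inside the LCA
#'   clade.
#' @param p_lca_species probability the LCA line is species-level.
#' @param p_unassigned fraction of queries with taxid-0 LCA lines.
#' @param pident_correct,pident_distractor mean percent identity of the
#'   planted subject and of distractors.
#' @param seed RNG seed.
#' @return list with `hits`, `lca` (readable by the format-6/102
#'   readers after writing), `subjects` (protein records for every
#'   subject accession) and `truth` (tibble `qseqid`,
#'   `true_subject`, `true_taxid`).
#' @export
simulate_blast_results <- function(queries, community, lineages,
                                   distractors_per_query = 4,
                                   p_inside = 0.5, p_lca_species = 0.5,
                                   p_unassigned = 0.05,
                                   pident_correct = 95,
                                   pident_distractor = 70, seed = 1) {
  set.seed(seed)
  n <- length(queries)
  sp_idx <- sample(nrow(community), n, replace = TRUE)
  genus_block <- (sp_idx - 1) %/% 2 + 1   # matches simulate_lineages blocks
  hit_rows <- list(); lca_rows <- list(); truth_rows <- list()
  acc_count <- 0L
  for (i in seq_len(n)) {
    q <- queries[i]
    tx <- community$taxid[sp_idx[i]]
    acc_count <- acc_count + 1L
    correct_acc <- sprintf("SUBJ_%06d", acc_count)
    bit_correct <- stats::runif(1, 100, 150)
    rows <- tibble::tibble(
      qseqid = q, sseqid = correct_acc,
      pident = min(100, pident_correct + stats::rnorm(1, 0, 2)),
      evalue = 10^stats::runif(1, -12, -6), bitscore = bit_correct,
      staxids = tx)
    nd <- distractors_per_query
    if (nd > 0) {
      inside <- stats::runif(nd) < p_inside
      block_start <- ((sp_idx[i] - 1) %/% 2) * 2
      sister <- community$taxid[pmin(block_start +
                                       sample(1:2, nd, replace = TRUE),
                                     nrow(community))]
      in_block <- community$taxid[seq(block_start + 1,
                                      min(block_start + 2, nrow(community)))]
      out_pool <- setdiff(community$taxid, in_block)
      if (length(out_pool) == 0) out_pool <- community$taxid
      outsider <- out_pool[sample.int(length(out_pool), nd, replace = TRUE)]
      dtx <- ifelse(inside, sister, outsider)
      dacc <- sprintf("SUBJ_%06d", acc_count + seq_len(nd))
      acc_count <- acc_count + nd
      rows <- dplyr::bind_rows(rows, tibble::tibble(
        qseqid = q, sseqid = dacc,
        pident = pmin(100, pmax(20, pident_distractor +
                                  stats::rnorm(nd, 0, 8))),
        evalue = 10^stats::runif(nd, -6, -2),
        bitscore = stats::runif(nd, 40, bit_correct - 5), staxids = dtx))
    }
    hit_rows[[i]] <- rows
    lca_tx <- if (stats::runif(1) < p_unassigned) 0L
              else if (stats::runif(1) < p_lca_species) tx
              else 9000L + genus_block[i]
    lca_rows[[i]] <- tibble::tibble(qseqid = q, taxid = lca_tx,
                                    evalue = 1e-8)
    truth_rows[[i]] <- tibble::tibble(qseqid = q,
                                      true_subject = correct_acc,
                                      true_taxid = tx)
  }
  hits <- dplyr::bind_rows(hit_rows)
  hits$rank_in_query <- stats::ave(seq_len(nrow(hits)), hits$qseqid,
                                   FUN = seq_along)
  subj_acc <- unique(hits$sseqid)
  subjects <- tibble::tibble(
    accession = subj_acc, description = NA_character_,
    sequence = .random_peptides(length(subj_acc), 40, 60),
    source = NA_character_)
  list(hits = hits, lca = dplyr::bind_rows(lca_rows), subjects = subjects,
       truth = dplyr::bind_rows(truth_rows))
}

#' Simulate a peptide quantification experiment with planted fold changes
#'
#' Builds a peptide inventory (specific and shared peptides per species),
#' then per-sample intensities: species abundance x a fixed per-peptide
#' response x log-normal noise at the stated CV, times the per-species
#' condition fold change in condition-2 samples. Missing-at-random masking
#' is applied at `missing_rate`.
#'
#' @param community tibble from [simulate_community()].
#' @param peptides_per_species specific peptides per species; a single
#'   number or a vector (one per species).
#' @param shared_peptides number of peptides shared between random species
#'   pairs of the same genus.
#' @param n_samples samples per condition.
#' @param n_conditions 1 or 2.
#' @param cv coefficient of variation of multiplicative log-normal noise
#'   (0 = noise-free).
#' @param missing_rate missing-at-random masking rate.
#' @param fold_changes named numeric: species -> fold change applied in
#'   condition 2.
#' @param seed RNG seed.
#' @return list with `quant` (`peptide_quant`; label `"none"`), `matches`
#'   (tibble `peptide`, `taxid` for [resolve_specificity()]), `samples`
#'   (tibble `sample`, `condition`) and `truth` (community + inventory).
#' @export
simulate_quant_experiment <- function(community, peptides_per_species = 5,
                                      shared_peptides = 0, n_samples = 3,
                                      n_conditions = 1, cv = 0.2,
                                      missing_rate = 0,
                                      fold_changes = NULL, seed = 1) {
  set.seed(seed)
  n_sp <- nrow(community)
  pps <- rep(peptides_per_species, length.out = n_sp)
  n_pep <- sum(pps) + shared_peptides
  peps <- .random_peptides(n_pep)
  sp_of <- rep(seq_len(n_sp), pps)
  matches <- tibble::tibble(peptide = peps[seq_along(sp_of)],
                            taxid = community$taxid[sp_of])
  if (shared_peptides > 0) {
    shared <- peps[sum(pps) + seq_len(shared_peptides)]
    pair_base <- sample(seq_len(max(1, n_sp %/% 2)), shared_peptides,
                        replace = TRUE)
    a <- (pair_base - 1) * 2 + 1
    b <- pmin(a + 1, n_sp)
    matches <- dplyr::bind_rows(matches,
      tibble::tibble(peptide = rep(shared, 2),
                     taxid = community$taxid[c(a, b)]))
  }
  conds <- rep(seq_len(n_conditions), each = n_samples)
  samples <- sprintf("S%d_%d", conds, rep(seq_len(n_samples), n_conditions))
  response <- stats::rlnorm(n_pep, 0, 0.5)
  base <- 1e8
  sdlog <- sqrt(log(1 + cv^2))
  qt <- tibble::tibble(peptide = peps,
                       protein_group = sprintf("PG_%05d", seq_len(n_pep)),
                       label = "none")
  abund_of_pep <- c(community$proportion[sp_of],
                    if (shared_peptides > 0)
                      community$proportion[(rep(pair_base, 1) - 1) * 2 + 1]
                    else numeric(0))
  fc_of_pep <- rep(1, n_pep)
  if (!is.null(fold_changes)) {
    sp_name_of_pep <- c(community$species[sp_of],
                        rep(NA_character_, shared_peptides))
    hit <- !is.na(sp_name_of_pep) & sp_name_of_pep %in% names(fold_changes)
    fc_of_pep[hit] <- fold_changes[sp_name_of_pep[hit]]
  }
  for (j in seq_along(samples)) {
    mu <- base * abund_of_pep * response *
      (if (conds[j] == 2) fc_of_pep else 1)
    noise <- if (cv > 0) stats::rlnorm(n_pep, -sdlog^2 / 2, sdlog) else 1
    v <- mu * noise
    if (missing_rate > 0)
      v[stats::runif(n_pep) < missing_rate] <- NA_real_
    qt[[samples[j]]] <- v
  }
  list(quant = peptide_quant(qt, samples),
       matches = matches,
       samples = tibble::tibble(sample = samples, condition = conds),
       truth = list(community = community, peptides_per_species = pps,
                    matches = matches))
}

#' Simulate a SILAC spike-in titration with controls
#'
#' For each cell-input level, replicate samples contain the background
#' community plus the two spiked species, with labeled-species peptides
#' emitted in the heavy channel at `incorporation_rate` (light otherwise)
#' and spike intensities proportional to the spiked cell fraction.
#' Control samples contain background only. Planted rule violations
#' (light-channel labeled-species rows, co-assigned peptides,
#' control-contaminating peptides) can be added to exercise the
#' identification filters.
#'
#' @param design a [spikein_design()] (replicate/control sample ids are
#'   generated here and filled in on the returned design).
#' @param background community tibble for the endogenous species.
#' @param peptides_per_species specific peptides per species (background
#'   and spiked).
#' @param n_replicates replicates per level.
#' @param n_controls non-spike control replicates.
#' @param incorporation_rate heavy-channel emission probability for
#'   labeled-species peptides.
#' @param cv intensity noise CV.
#' @param n_violations planted violations of each filter rule.
#' @param seed RNG seed.
#' @return list with `quant_by_level` (named list of `peptide_quant`,
#'   one per cell input, controls included as samples), `assignments`
#'   (peptide -> species), `design` (completed), and `truth`.
#' @export
simulate_spikein <- function(design, background,
                             peptides_per_species = 8, n_replicates = 3,
                             n_controls = 3, incorporation_rate = 0.97,
                             cv = 0.1, n_violations = 0, seed = 1) {
  set.seed(seed)
  spp <- c(design$labeled_species, design$unlabeled_species)
  n_bg <- nrow(background)
  n_pep_sp <- peptides_per_species
  total_pep <- n_bg * n_pep_sp + 2 * n_pep_sp + 3 * n_violations
  peps <- .random_peptides(total_pep)
  bg_pep <- peps[seq_len(n_bg * n_pep_sp)]
  lab_pep <- peps[n_bg * n_pep_sp + seq_len(n_pep_sp)]
  unl_pep <- peps[n_bg * n_pep_sp + n_pep_sp + seq_len(n_pep_sp)]
  extra <- peps[n_bg * n_pep_sp + 2 * n_pep_sp + seq_len(3 * n_violations)]
  assignments <- dplyr::bind_rows(
    tibble::tibble(peptide = bg_pep,
                   species = rep(background$species, each = n_pep_sp)),
    tibble::tibble(peptide = lab_pep, species = design$labeled_species),
    tibble::tibble(peptide = unl_pep, species = design$unlabeled_species))
  viol_light <- viol_co <- viol_ctrl <- character(0)
  if (n_violations > 0) {
    viol_light <- extra[seq_len(n_violations)]
    viol_co <- extra[n_violations + seq_len(n_violations)]
    viol_ctrl <- extra[2 * n_violations + seq_len(n_violations)]
    assignments <- dplyr::bind_rows(assignments,
      tibble::tibble(peptide = viol_light, species = design$labeled_species),
      tibble::tibble(peptide = rep(viol_co, 2),
                     species = rep(spp, each = n_violations)),
      tibble::tibble(peptide = viol_ctrl,
                     species = sample(spp, n_violations, replace = TRUE)))
  }
  ctrl_samples <- sprintf("ctrl_%d", seq_len(n_controls))
  design$control_samples <- ctrl_samples
  design$replicate_samples <- list()
  sdlog <- sqrt(log(1 + cv^2))
  noise <- function(k) if (cv > 0) stats::rlnorm(k, -sdlog^2 / 2, sdlog)
                       else rep(1, k)
  mk_level <- function(n_cells, lvl_name) {
    reps <- sprintf("spk%s_%d", lvl_name, seq_len(n_replicates))
    frac <- cell_fraction(n_cells, design$feces_mass_g,
                          design$cells_per_gram) / 100
    all_pep <- c(bg_pep, lab_pep, unl_pep, viol_light, viol_co, viol_ctrl)
    label <- c(rep("none", length(bg_pep)),
               ifelse(stats::runif(length(lab_pep)) < incorporation_rate,
                      "heavy", "light"),
               rep("light", length(unl_pep)),
               rep("light", length(viol_light)),   # rule-1 violations
               rep("heavy", length(viol_co)),      # rule-2 co-assigned
               rep("heavy", length(viol_ctrl)))    # rule-3 in controls
    qt <- tibble::tibble(peptide = all_pep,
                         protein_group = paste0("PG_", all_pep),
                         label = label)
    bg_mu <- 1e9 * rep(background$proportion, each = n_pep_sp)
    spike_mu <- rep(1e9 * max(frac, 1e-12), length(all_pep) - length(bg_pep))
    mu <- c(bg_mu, spike_mu)
    for (s in reps) qt[[s]] <- mu * noise(length(mu))
    for (s in ctrl_samples) {
      v <- rep(NA_real_, length(all_pep))
      v[seq_along(bg_pep)] <- bg_mu * noise(length(bg_pep))
      if (length(viol_ctrl))
        v[match(viol_ctrl, all_pep)] <- 1e5 * noise(length(viol_ctrl))
      qt[[s]] <- v
    }
    list(quant = peptide_quant(qt, c(reps, ctrl_samples)), reps = reps)
  }
  quant_by_level <- list()
  for (n_cells in design$cell_inputs) {
    lvl <- format(n_cells, scientific = FALSE, trim = TRUE)
    made <- mk_level(n_cells, lvl)
    quant_by_level[[lvl]] <- made$quant
    design$replicate_samples[[lvl]] <- made$reps
  }
  list(quant_by_level = quant_by_level, assignments = assignments,
       design = design,
       truth = list(labeled_peptides = lab_pep, unlabeled_peptides = unl_pep,
                    violations = list(light = viol_light, co = viol_co,
                                      control = viol_ctrl)))
}
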