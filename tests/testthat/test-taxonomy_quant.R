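# Peptide specificity, the 3-specific-peptide rule, taxon quantification
# and biomass fractions.

make_quant <- function(df, samples) peptide_quant(tibble::as_tibble(df), samples)

test_that("specificity resolution: species, genus, blank-skipping", {
  lin <- toy_lineages()
  matches <- tibble::tibble(
    peptide = c("ONESPECK", rep("TWOSPECK", 2), rep("TWOGENUSK", 2)),
    taxid = c(101L, 101L, 102L, 101L, 201L))
  asg <- resolve_specificity(matches, lin)
  one <- asg[asg$peptide == "ONESPECK", ]
  expect_equal(one$specificity_rank, "species")
  expect_equal(one$species, "sp_a1")
  two <- asg[asg$peptide == "TWOSPECK", ]     # two species of one genus
  expect_equal(two$specificity_rank, "genus")
  expect_equal(two$genus, "gA")
  expect_true(is.na(two$species))
  cross <- asg[asg$peptide == "TWOGENUSK", ]  # gA vs gB agree only at order
  expect_equal(cross$specificity_rank, "order")

  # blanks below superkingdom are ignored, not treated as disagreement
  lin_blank <- lin
  lin_blank$family[lin_blank$taxid == 101L] <- NA
  asg2 <- resolve_specificity(tibble::tibble(peptide = "BLANKPEK",
                                             taxid = c(101L, 102L)),
                              lin_blank)
  expect_equal(asg2$specificity_rank, "genus")
  expect_equal(asg2$family, "f1")  # the one non-blank name carries

  expect_error(resolve_specificity(tibble::tibble(peptide = "X", taxid = 9L),
                                   lin), "absent")
})

test_that("specificity agrees with the rank-by-rank oracle on random sets", {
  comm <- simulate_community(24, seed = 31)
  lin <- simulate_lineages(comm, blank_rate = 0.3, seed = 31)
  set.seed(31)
  for (i in 1:100) {
    taxids <- sample(comm$taxid, sample(1:5, 1), replace = TRUE)
    asg <- resolve_specificity(tibble::tibble(peptide = "QQQQQQK",
                                              taxid = taxids), lin)
    want <- brute_force_specificity(unique(taxids), lin)
    expect_equal(asg$specificity_rank, want$specificity_rank)
    for (r in tax_ranks()) expect_equal(asg[[r]], want[[r]])
  }
})

test_that("detection needs >= min_specific distinct specific peptides", {
  lin <- toy_lineages()
  matches <- tibble::tibble(
    peptide = c("AAAAAAK", "AAAAAAR", "CCCCCCK",        # 3 specific to sp_a1
                "DDDDDDK", "DDDDDDR",                   # 2 specific to sp_b1
                rep("EEEEEEK", 2)),                     # genus-level only
    taxid = c(101L, 101L, 101L, 201L, 201L, 101L, 102L))
  asg <- resolve_specificity(matches, lin)
  det <- detect_taxa(asg, "species", min_specific = 3)
  expect_equal(det$taxon, "sp_a1")
  expect_equal(det$n_specific_peptides, 3L)
  # lowering the cutoff admits sp_b1; raising it never adds taxa (monotone)
  det1 <- detect_taxa(asg, "species", min_specific = 1)
  expect_setequal(det1$taxon, c("sp_a1", "sp_b1"))
  for (k in 1:4)
    expect_true(all(detect_taxa(asg, "species", k + 1)$taxon %in%
                      detect_taxa(asg, "species", k)$taxon))
  # the genus-level peptide counts toward genus detection
  detg <- detect_taxa(asg, "genus", min_specific = 4)
  expect_true("gA" %in% detg$taxon)
})

test_that("planted community: exactly the >=3-peptide species are detected", {
  comm <- simulate_community(20, seed = 41)
  # 12 species get 3-6 specific peptides, 8 get 0-2
  pps <- c(rep(c(3L, 4L, 6L), 4), rep(c(0L, 1L, 2L, 2L), 2))
  lin <- simulate_lineages(comm, seed = 41)
  sim <- simulate_quant_experiment(comm, peptides_per_species = pps,
                                   cv = 0, seed = 41)
  asg <- resolve_specificity(sim$matches, lin)
  det <- detect_taxa(asg, "species", 3)
  expect_setequal(det$taxon, comm$species[pps >= 3])
})

test_that("taxon intensity sums common peptides only", {
  lin <- toy_lineages()
  matches <- tibble::tibble(peptide = c("AK", "BK", "CK"), taxid = 101L)
  asg <- resolve_specificity(
    tibble::tibble(peptide = c("AAAAAAK", "BBBBBBK", "CCCCCCK"),
                   taxid = 101L), lin)
  qt <- make_quant(data.frame(
    peptide = c("AAAAAAK", "BBBBBBK", "CCCCCCK"),
    s1 = c(10, 20, 30), s2 = c(1, 2, NA), s3 = c(5, 5, 5)),
    c("s1", "s2", "s3"))
  prof <- quantify_taxon(asg, qt, "species")
  # CCCCCCK is absent in s2, so it is excluded from every sample's sum
  expect_equal(prof$intensity[prof$sample == "s1"], 30)
  expect_equal(prof$intensity[prof$sample == "s2"], 3)
  expect_equal(prof$intensity[prof$sample == "s3"], 10)
  expect_equal(prof$log2_intensity, log2(prof$intensity))
  # non-strict mode sums whatever is present
  prof2 <- quantify_taxon(asg, qt, "species", common = FALSE)
  expect_equal(prof2$intensity[prof2$sample == "s1"], 60)
  # detected taxon with no common quantified peptide -> NA + warning
  qt2 <- make_quant(data.frame(peptide = "AAAAAAK", s1 = NA_real_, s2 = 2),
                    c("s1", "s2"))
  expect_warning(p3 <- quantify_taxon(asg, qt2, "species"), "sp_a1")
  expect_true(all(is.na(p3$intensity)))
})

test_that("quantification is invariant to row and sample order", {
  comm <- simulate_community(8, seed = 51)
  lin <- simulate_lineages(comm, seed = 51)
  sim <- simulate_quant_experiment(comm, peptides_per_species = 4,
                                   n_samples = 3, cv = 0.2, seed = 51)
  asg <- resolve_specificity(sim$matches, lin)
  prof <- quantify_taxon(asg, sim$quant, "species")
  qt_shuf <- sim$quant[sample.int(nrow(sim$quant)), , drop = FALSE]
  attr(qt_shuf, "samples") <- attr(sim$quant, "samples")
  prof_shuf <- quantify_taxon(asg, qt_shuf, "species")
  expect_equal(prof, prof_shuf)
  rev_samples <- rev(quant_samples(sim$quant))
  prof_rev <- quantify_taxon(asg, sim$quant, "species",
                             samples = rev_samples)
  m1 <- prof[order(prof$taxon, prof$sample), c("taxon", "sample", "intensity")]
  m2 <- prof_rev[order(prof_rev$taxon, prof_rev$sample),
                 c("taxon", "sample", "intensity")]
  expect_equal(m1, m2)
})

test_that("biomass fractions sum to 100 and recover planted proportions", {
  # hand case: intensities {1, 1, 2} -> {25, 25, 50}
  prof <- tibble::tibble(taxon = c("a", "b", "c"), rank = "species",
                         sample = "s1", n_peptides = 1L,
                         intensity = c(1, 1, 2))
  bf <- biomass_fractions(prof)
  expect_equal(bf$biomass_fraction, c(25, 25, 50))
  # single taxon -> 100%
  expect_equal(biomass_fractions(prof[1, ])$biomass_fraction, 100)

  # noise-free generator: recovered fractions equal planted proportions
  comm <- simulate_community(12, seed = 61)
  lin <- simulate_lineages(comm, seed = 61)
  sim <- simulate_quant_experiment(comm, peptides_per_species = 3,
                                   cv = 0, seed = 61)
  asg <- resolve_specificity(sim$matches, lin)
  # equalize peptide responses so intensity is proportional to abundance:
  # instead, compare recovered fractions against truth computed from the
  # same per-peptide responses (exact on noise-free data)
  qt <- sim$quant
  prof <- biomass_fractions(quantify_taxon(asg, qt, "species"))
  s1 <- prof[prof$sample == quant_samples(qt)[1], ]
  truth_int <- vapply(split(qt[[quant_samples(qt)[1]]],
                            sim$matches$taxid[match(qt$peptide,
                                                    sim$matches$peptide)]),
                      sum, numeric(1))
  want <- 100 * truth_int / sum(truth_int)
  got <- s1$biomass_fraction[match(names(truth_int),
                                   comm$taxid[match(s1$taxon, comm$species)])]
  expect_equal(sum(s1$biomass_fraction), 100, tolerance = 1e-9)
  got_by_tax <- s1$biomass_fraction[match(comm$species, s1$taxon)]
  want_by_tax <- want[match(as.character(comm$taxid), names(truth_int))]
  expect_equal(unname(got_by_tax), unname(want_by_tax), tolerance = 1e-12)
})

test_that("planted 2-fold change is recovered as log2 ratio 1", {
  comm <- simulate_community(10, seed = 71)
  lin <- simulate_lineages(comm, seed = 71)
  fc <- setNames(rep(1, 10), comm$species)
  fc["species_003"] <- 2
  sim <- simulate_quant_experiment(comm, peptides_per_species = 6,
                                   n_samples = 4, n_conditions = 2,
                                   cv = 0.2, fold_changes = fc, seed = 71)
  asg <- resolve_specificity(sim$matches, lin)
  prof <- quantify_taxon(asg, sim$quant, "species")
  s <- sim$samples
  mean_l2 <- function(taxon, cond) {
    rows <- prof$taxon == taxon & prof$sample %in% s$sample[s$condition == cond]
    mean(prof$log2_intensity[rows])
  }
  ratio <- mean_l2("species_003", 2) - mean_l2("species_003", 1)
  expect_equal(ratio, 1, tolerance = 0.35)
  null_ratio <- mean_l2("species_001", 2) - mean_l2("species_001", 1)
  expect_equal(null_ratio, 0, tolerance = 0.35)
})

test_that("coverage arithmetic helper", {
  expect_equal(percent_increase(551, 223), 100 * 551 / 223)
  expect_equal(percent_increase(213 - 89, 89), 100 * 124 / 89)
})
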