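---
title: "Methods: de novo PSM filtering, LCA-guided database assembly and quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: de novo PSM filtering, LCA-guided database assembly and quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(novomp)
```

## The problem

De novo peptide sequencing reads a peptide directly off its fragmentation
spectrum, with no reference database. In metaproteomics this is the only
way to reach community members whose genomes are absent from the search
space, but raw de novo callouts are unreliable: the peptide landscape of
a fecal or environmental sample is enormous, and a wrong call poisons
everything downstream — the protein database, the taxonomy, the
quantification. `novomp` implements the post-acquisition computations
that make de novo callouts usable: a multi-tier confidence filter, an
LCA-guided protein-assignment procedure, database assembly with overlap
accounting, peptide-based taxonomic/functional quantification, and the
analytics of a SILAC spike-in limit-of-detection experiment.

## The six-tier confidence filter

`run_filter_cascade()` applies six predicates strictly in order. The
first three are fixed thresholds:

| tier | predicate | default | why |
|---|---|---|---|
| score | de novo score ≥ `score_min` | 65 | floor on caller confidence |
| charge | charge ∉ `charge_excluded` | {1} | singly charged precursors fragment poorly |
| length | length ≥ `length_min` | 7 residues | short peptides match ambiguously |

The last three are *distribution* tiers on, respectively, the precursor
mass error (ppm), the observed − predicted retention-time shift
(minutes), and the observed − predicted collisional-cross-section shift
(Å²). Each retains the central `central_fraction` (default 0.95) of its
own input population, with cutoffs

$$[\,\hat\mu - z\,\hat\sigma,\;\hat\mu + z\,\hat\sigma\,],
\qquad z = \Phi^{-1}\!\big(\tfrac{1+f}{2}\big),$$

where $\hat\mu,\hat\sigma$ are the sample mean and $(n-1)$ standard
deviation of the tier's input deltas. Three choices deserve comment:

- **Normal fit, not empirical quantiles.** The cutoffs are parametric
  normal quantiles (`mean ± 1.959964·sd` at 95%); an `interval =
  "empirical"` option switches to sample quantiles for sensitivity
  analysis. On clean normal data the two agree; under heavy tails the
  parametric interval is wider and more permissive.
- **Sequential refitting.** Cutoffs are refit on each tier's own input
  (the survivors of the previous tier), not once globally. A consequence,
  asserted as a documented property in the tests, is that tiers 4–6 are
  *not* idempotent: re-running the cascade on its own output refits
  narrower intervals and removes a further ~5% per tier. Tiers 1–3 are
  idempotent.
- **Closed intervals.** A delta exactly at a cutoff is retained.

Degenerate inputs: an empty cohort passes through the distribution tiers
vacuously (nothing to fit, nothing to cut); 1–2 values or zero variance
are an error naming the tier, since a normal fit is meaningless there. A
distribution tier whose observed/predicted columns are absent or
incomplete raises an error at cascade entry; disable the tier instead if
the predictions genuinely do not exist.

The per-tier attrition report (`tier`, `n_in`, `n_out`, `lo`, `hi`)
chains exactly: tier *k+1*'s input count is tier *k*'s surviving count.

## LCA-guided candidate selection and database assembly

Each query peptide arrives with up to five BLAST candidates (DIAMOND
format 6) and one consensus taxon from the lowest-common-ancestor
algorithm (format 102; taxid 0 = unassigned). `select_candidate()`
resolves them to exactly one protein:

- **Step A** — candidates whose subject taxid *equals* the LCA taxid; a
  unique match is returned immediately.
- **Step B** — otherwise, candidates lying *at or below* the LCA taxon.
  Lineage tables carry names, not taxid chains, so "below" is read as:
  the candidate's 7-rank lineage carries the LCA taxon's name at the
  LCA's own (deepest non-blank) rank.
- **Step C** — whatever set remains (Step-A ties, Step-B survivors, or
  all hits when both steps are empty or the query is unassigned) is
  ordered by bit score descending, percent identity descending, e-value
  ascending, then subject accession (C locale), and the first is
  returned.

The accession tie-break is ours: bit score, identity and e-value can all
tie, and a deterministic, permutation-invariant choice is worth more
than any pretence that the remaining ambiguity is resolvable. The whole
procedure is checked against an exhaustive rule enumerator on 10,000
random ≤5-hit cases.

Selections below the identity floor (default 80%, boundary inclusive)
are dropped. `merge_protein_dbs()` then deduplicates records on the
*exact amino-acid sequence* — the printed union arithmetic of the
source-database comparison is over unique sequences, not accessions —
keeping the first-seen accession and recording every source on the
survivor, and reports |A|, |B|, |A∩B|, |A∪B| per source pair.
Isoleucine/leucine are distinct by default (an I/L-equivalence collapse
can be applied upstream of the merge by the caller). Subject sequences
are an input FASTA, never a network fetch.

## Taxonomic annotation and quantification

`resolve_specificity()` compares the matched proteins' 7-rank lineages
rank by rank from superkingdom down. Blank rank names below superkingdom
are ignored: they neither contribute a name nor break agreement. The
deepest rank at which exactly one non-blank name occurs is the peptide's
specificity rank; walking stops at the first genuine conflict. A peptide
is species-specific iff all its matches share one species.

`detect_taxa()` applies the detection rule: a taxon is reported at rank
*r* when ≥ `min_specific` (default 3) distinct peptide sequences are
specific to it at that rank. Peptides are compared as stripped sequences;
modified forms of one sequence count once.

`quantify_taxon()` sums, per sample, the intensities of a taxon's
*common* specific peptides — present (non-absent) in every sample of the
comparison set. This is the strictest reading of "common", chosen so
that every per-sample sum is built from one shared peptide basis and
sums are comparable across samples; `common = FALSE` sums whatever is
present. Sums are also returned log2-transformed, with no pseudocount:
common peptides are positive by construction, and a detected taxon with
an empty common set is reported as absent (NA) with a warning rather
than as zero. `biomass_fractions()` normalises species intensities to
100% per sample.

Functional rollups (`aggregate_by_cog()`, `taxon_function_profile()`)
sum protein intensities per best-hit COG id and taxon-specific peptide
intensities per (taxon, KEGG pathway). When a protein group lists
several accessions, the leading accession decides the annotation. A
peptide whose protein maps to several pathways contributes its full
intensity to each — summation semantics, documented as potential
double-counting *across* pathways but never within one.

## SILAC spike-in analytics

`labeling_efficiency()` computes, per peptide,
$100\cdot H/(H+L)$ where $H$ and $L$ are the *most intense* PSM per
channel; a channel with no PSM at all is assigned intensity 1 before the
formula (so a fully heavy peptide reports just under 100%, never a
division by zero), and a peptide with neither channel is excluded with a
warning. The cohort mean is unweighted over peptides.

`apply_spikein_filters()` screens rows assigned to either spiked
species with three pure predicates: (1) only heavy-labeled peptides
count for the labeled species, and heavy peptides assigned to the
unlabeled species are false matches; (2) peptides co-assigned to both
spiked species, and rows whose protein group is shared between them, are
removed; (3) peptides of either species also measured in any non-spike
control are removed. Because each rule is a pure predicate the surviving
set is order-independent; the per-rule removal *counts* are attributed
in rule order (a heavy co-assigned peptide, for instance, is claimed by
rule 1) and documented as such.

`cell_fraction()` converts a spiked cell count to a biomass percentage,
$100\cdot n/(m\cdot d)$ with feces mass $m$ (default 0.01 g) and assumed
density $d$ (default $10^{12}$ cells/g of feces, the genomic estimate
for mouse feces): $10^4$ cells in 10 mg is 0.0001% — one cell in a
million.

## What the synthetic data emulate — and what they do not

The generators produce every input the pipeline reads, with planted
ground truth, deterministic under a seed:

- `simulate_community()`: log-normal relative abundances (σ = 1 by
  default), emulating the skew in which a handful of species carries
  half the community biomass.
- `simulate_denovo_psms()`: true PSMs with normal errors (3 ppm mass
  error, 0.5 min RT shift, 5 Å² CCS shift) and confident scores
  (65 + 35·Beta(2, 2)); planted outliers at ±10 sd in all three error
  dimensions; optional charge-1, short-peptide and sub-floor-score
  contaminants with mediocre scores (100·Beta(4, 4)).
- `simulate_blast_results()`: one planted correct subject per query,
  LCA-consistent, plus lower-scoring distractors inside/outside the LCA
  clade at stated rates.
- `simulate_quant_experiment()`: intensity = abundance × per-peptide
  response × log-normal noise at CV 0.2 (the workflow's observed
  precision regime), with per-species fold changes and
  missing-at-random masking.
- `simulate_spikein()`: titration levels with heavy-channel emission at
  a 97% incorporation rate, background-only controls, and optional
  planted violations of each identification filter.

These emulate the *statistical structure* the analysis assumes — not
instrument physics. No spectra are simulated; RT/CCS "predictions" are
the observed values minus a normal delta, not model outputs; missingness
is at random, whereas real DIA missingness is intensity-dependent; the
peptide inventory ignores shared tryptic homology between related
species except where explicitly planted. Passing tests therefore show
that the *computations* are correct under the stated model, not that the
workflow's biological numbers would reproduce on raw data.

## Problem sizes and numerical choices

The test suite runs the filter properties on a 10,000-PSM seeded cohort
(each distribution tier retains 95% ± 1%), the selection oracle on
10,000 random hit sets, parameter recovery on a 20-species community
(12 species planted above the 3-peptide cutoff), and the union
arithmetic on two synthetic sets of 73,168 and 98,189 sequences sharing
13,153 — sizes at which every check runs in seconds while exercising
the asymptotic behaviour that matters. Fraction recovery on noise-free
data is exact to 1e-9 relative; fold-change recovery under CV 0.2 noise
is asserted within ±0.35 log2 units (4 replicates × 6 peptides).

## Known limitations

- The LCA "belongs to" test is name-based over 7 canonical ranks; it
  cannot see structure between canonical ranks (subspecies, strain).
- Cross-source database deduplication beyond exact sequence identity
  (e.g. fragment-containment) is out of scope; published databases
  assembled with additional collapsing will be smaller than the plain
  union.
- `quantify_taxon()`'s strict common-peptide rule discards information
  when many samples are compared at once; use per-pair comparisons or
  `common = FALSE` when missingness is high.
- The spike-in detection summary reports raw surviving counts; it
  asserts no statistical detection threshold beyond them.
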