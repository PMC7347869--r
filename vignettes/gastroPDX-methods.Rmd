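---
title: "Molecular subtyping and clonal dynamics of gastric cancer PDX: methods"
author: "gastroPDX"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular subtyping and clonal dynamics of gastric cancer PDX: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gastroPDX)
```

## Scope

gastroPDX implements the analysis chain used to characterize a cohort of
gastric cancer patient-derived xenografts (PDX): qPCR-based molecular
subtyping in the ACRG and TCGA frameworks, the xenograft somatic-variant
hygiene chain, copy-number event summaries, passage-wise clonal-trajectory
analysis with droplet digital PCR (ddPCR) minor-clone quantification, and
cohort-level engraftment reporting. A fully seeded synthetic-cohort
generator produces every input the pipeline consumes, so the whole chain is
testable end to end without external data. Alignment, variant-caller and
segmentation internals are out of scope: the package consumes their output
tables.

## Molecular subtyping

MSI status follows the Bethesda pentaplex rule: a tumor is MSI-H when at
least two of the five microsatellite loci (BAT-26, BAT-25, D5S346, D17S250,
D2S123) show additional alleles against the matched normal, MSI-L with
exactly one, MSS with none; only MSI-H counts as "MSI" in the binary
classification. Xenografts have no matched normal, so MSI is inferred from
mismatch-repair deficiency: loss of homogeneous MLH1 staining or an MLH1
mutation.

Expression is quantified relative to 18S ribosomal RNA as
$E_g = 2^{\mathrm{Ct}_{18S} - \mathrm{Ct}_g}$ (arbitrary units, 40-cycle
assays; a missing Ct is the not-detected sentinel 0 and is excluded from
medians). Two two-gene scores normalize by cohort medians:

* TP53 activation: $E_{CDKN1A}/\tilde E_{CDKN1A} + E_{MDM2}/\tilde E_{MDM2}$,
  activated strictly above 2.5 units;
* proliferation: $E_{TOP2A}/\tilde E_{TOP2A} + E_{MKI67}/\tilde E_{MKI67}$,
  low below 1, intermediate on the closed interval [1, 4], high above 4.

The EBV burden is $2^{40-\mathrm{Ct}_{EBNA1}}/1000$; loads strictly above
1000 units are EBV-positive, and assays with no amplification are recorded
at the maximum Ct of 40.

The ACRG tree is: MSI first; then MSS/EMT when CDH1 expression is strictly
below 40 units; then the TP53 split; MSS samples lacking RNA stay
UNCLASSIFIED. The TCGA-style tree is MSI, then EBV, then GS/CIN by the
autosomal SCNA count (GS at $\le 15$, CIN above), with MSS_UNRESOLVED when
no copy-number assay exists.

Decisions where the source material was open:

* "above"/"below" wordings are implemented as strict inequalities, the
  intermediate proliferation band as a closed interval;
* score medians are computed once over the whole analyzed cohort (tumors
  and PDX pooled) — the population is configurable through
  `scoreContext()`;
* MSI takes precedence over EBV, as the subtypes are treated as disjoint
  and MSI is resolved first;
* the proliferation score is a descriptive annotation and does not enter
  the class assignment, which uses CDH1 and the TP53 score alone.

## The variant hygiene chain

Reads mapping strictly better to the mouse genome than to the human genome
are discarded as stroma (`deconvolveReads`); ties keep the human
assignment, because only reads mapping *better* to mouse are evidence of
mouse origin. The discarded fraction is the contamination estimate.

Caller tables are normalized to a shared key — multi-allelic records are
split and allele pairs parsimony-trimmed (shared suffix, then shared
prefix with position adjustment) — before the three-way consensus
intersection on (chrom, pos, ref, alt). Per-record fields come from a
configurable primary caller (default A), since the callers' values cannot
be reconciled generically.

Three record-wise filters follow, each a pure predicate so their order is
immaterial (a property the suite verifies by permutation):

* support: at least 3 variant-supporting reads and at least 5% allele
  fraction (both inclusive);
* polymorphism: drop on $\ge 3$ allele counts in HapMap/CGI-69/EVS+1000 or
  a dbSNP population MAF strictly above 5%;
* impact: keep high or moderate predicted protein impact; records without
  an annotation are dropped with a warning (the conservative reading).

Germline subtraction removes keys present in the matched or pooled normal
set. Mutation prevalence is count over capture size (Mb); the
hypermutation flag defaults to >21.1/Mb, the top of the
microsatellite-stable range, and is configurable because the original flag
had no printed numeric cutoff.

Spectra collapse SNVs to the pyrimidine strand into the six substitution
classes and, where a trinucleotide context is available, the standard 96
channels; SNVs without context count in the six classes only and are
tallied. Signature matching reports (a) nonnegative-least-squares
exposures (renormalized to sum 1) against a user-supplied 96-row signature
matrix and (b) the Spearman correlation of each normalized spectrum — and
of the cohort mean spectrum — against every signature column. Tests use
synthetic orthogonal signatures, for which NNLS has a closed form that
serves as the independent oracle; no signature download is required.

## Copy-number events

Per-gene absolute integer calls are classified as amplification at copy
number $\ge 8$ and homozygous deletion at exactly 0. The SCNA count is
their sum over autosomes; $\le 15$ is genomically stable, more is CIN.
Ploidy is the gene-span-length-weighted mean copy number over autosomes
(unweighted by flag); the estimator was not stated in the source material
and is treated as total-copy-number-derived, not allele-specific.

## Clonal trajectories, banding and ddPCR

A variant enters trajectory analysis only with $\ge 10\times$ coverage at
every stage (P0, P1–P3, established PDX); a call absent at a covered site
is allele fraction 0, distinct from "no coverage" which excludes the
variant. Three behaviours are distinguished, with precedence
selected_at_P1 > transient > stable:

* selected_at_P1 — AF gain of at least $\delta_{rise} = 0.25$ from P0 to
  P1 and post-P1 variation within $\delta_{stable} = 0.15$;
* transient — the presence indicator (AF $\ge$ 0.05, the calling floor)
  flips at least twice, or the variant disappears after detection;
* stable — total variation within $\delta_{stable}$; trajectories matching
  no rule (slow drift) also fall back to stable so the map is total.

No numeric thresholds were published for these classes; the defaults are
package decisions chosen so the narrated example trajectories (a rare
KRAS G13D clone fixed at P1; a G12D clone lost after P0; low-fraction
clones flickering across passages) classify as described, and all three
are configurable.

Allelic banding per chromosome window fits heterozygous-site AFs to the
candidate band sets {0, 1} (LOH), {0, 1/2, 1} (two alleles),
{0, 1/3, 2/3, 1} and {0, 1/4, 1/2, 3/4, 1} (copy gain) by mean absolute
deviation to the nearest band, tie-breaking toward fewer bands; the visual
"close to 0, 0.5, 1" criterion has no published tolerance, so the MAD
minimizer is the package's formalization. Stage clustering uses Jaccard
distance on presence/absence with average linkage (metric and linkage were
unstated; this pair is standard for binary profiles) and exports a newick
string.

ddPCR counts are converted to a mutant allele fraction with the
single-molecule Poisson occupancy correction
$\lambda = -\ln(1 - k/N)$ applied per channel when occupancy exceeds 10%.
Detection requires the estimate to exceed the negative-control estimate
(or a 5e-4 floor when no control is run) by three Poisson standard errors
of the background rate over the observed template count.

## The synthetic cohort generator

The generator's defaults are the study's stated operating conditions, and
they are fixed: subtype mixture 27% MSI, 13% MSS/EMT, 32% MSS/TP53−,
21% MSS/TP53+, 10% EBV (renormalized); engraftment probabilities MSI 0.56
and MSS 0.16; mutation rates uniform on 21.9–57.5/Mb (MSI) and
2.2–21.1/Mb (MSS) over a 51 Mb target; indel fractions 0.30 and 0.19;
mouse contamination uniform on 1.6–21%; mean depth 131× (passage series
use 150×, the round figure consistent with the upper on-target coverage
actually achieved); ploidy targets 2.29 (MSI) and 3.09 (MSS); CIN event
counts uniform on 42–258 and GS at most 15; the default passage scenario
is a 0.1% minor clone at P0 fixed from P1. Values the study did not state
were chosen once as field-typical (Ct noise 0.1 cycles; baseline
expression levels; a 5:1 CIN:GS split among MSS profiles mirroring the
10-vs-2 split among profiled models; Poisson droplet loading at 0.5
molecules/droplet) and are not tuned.

Every draw flows from the user's seed through named substreams, so one
stage's configuration cannot perturb another's draws and identical
seed+config is byte-identical. Caller outputs seed caller-specific false
positives (default 2%) but no shared false negatives: in a three-caller
consensus a variant is lost only if *some* caller misses it, and making
misses caller-independent would destroy the exact-recovery property the
generator is designed to provide; correlated caller error is therefore
deliberately not modeled.

What the generator does **not** emulate — so what passing tests cannot
show about real data: sequencing reads and alignment artifacts, correlated
caller errors, subclonal copy-number structure, focal-event positional
clustering, assay dropout patterns, and any joint distribution between
clinical covariates beyond the published marginals (the packaged
100-patient table reproduces each stratifier-by-engraftment margin; the
joint fill across fields is arbitrary).

## Problem sizes and numerics

The test suite runs 50 synthetic models for burden/indel recovery, 50
seeds × 1000 records for the filter-chain oracle, 200 passage replicates
at depth 150 for selection recovery, 10,000 random windows for the
banding oracle, and $10^5$–$10^6$ droplets for ddPCR recovery — sizes at
which the binomial/Poisson concentration bounds quoted in the tests hold
with margin. Integer copy numbers and counts are exact; score boundaries
are evaluated with strict/closed conventions as above; engraftment rates
round half away from zero to integers, the convention that reproduces
every printed rate cell.

## Known limitations

The subtype classifier is a threshold tree over qPCR scores, not a
transcriptome-wide classifier; samples near a score boundary are
legitimately unstable under Ct noise (the recovery guarantee is stated
for samples at least one score unit from every boundary). The trajectory
classes are marginal per-variant labels, not a subclonal tree
reconstruction. Published total variant counts implied additional
undocumented filtering; only the documented filters are implemented, so
those absolute counts are not reproduced.
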