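# gastroPDX

Molecular subtyping and clonal dynamics of gastric cancer patient-derived
xenografts (PDX).

When a resected gastric tumor is propagated in immunodeficient mice, three
questions decide whether the resulting model can stand in for the patient:
which molecular subtype the tumor belongs to (and whether that subtype
engrafts at all), whether the somatic variants called in the xenograft are
real (mouse stroma and caller disagreement both contaminate them), and
whether the clonal composition of the tumor survives passaging. gastroPDX
implements the full analysis chain for these questions:

* **Subtyping** — Bethesda pentaplex MSI calling (MLH1-loss surrogate for
  xenografts), EBV load `2^(40−Ct_EBNA1)/1000` with the 1000-unit cutoff,
  relative expression `2^(Ct_18S − Ct_gene)`, median-normalized TP53
  activation (`> 2.5` = activated) and proliferation scores, and the
  deterministic ACRG (MSI / MSS-EMT / MSS-TP53± via the CDH1 < 40 rule) and
  TCGA-style (MSI / EBV / GS / CIN via the SCNA ≤ 15 boundary) trees.
* **Variant hygiene** — mouse-read deconvolution (discard reads mapping
  strictly better to mm10), three-caller consensus on normalized keys,
  support ≥ 3 reads & AF ≥ 5%, polymorphism and impact filters, germline
  subtraction, mutation burden per Mb, 96-channel trinucleotide spectra
  and NNLS signature matching with Spearman reporting.
* **Copy number** — amplification (CN ≥ 8) and homozygous-deletion (CN = 0)
  events, autosomal SCNA counts, GS/CIN classification, length-weighted
  ploidy.
* **Clonal dynamics** — allele-fraction trajectories across P0→P1→P2→P3→PDX
  (≥ 10× coverage at every stage), classification into stable /
  selected-at-P1 / transient, allelic-banding detection (LOH, copy gain)
  by MAD band-set fitting, stage clustering, and ddPCR minor-clone
  quantification with Poisson occupancy correction.
* **Cohort reporting** — stratified engraftment rates, tumor–PDX subtype
  concordance, Fisher/chi-square association tests, targetable-alteration
  landscapes.
* **Synthetic cohorts** — a seeded generator producing every input above
  at the study's stated operating points, so the whole chain is testable
  offline.

## Worked example

```r
library(gastroPDX)

## simulate a 100-patient cohort and classify it back
sim   <- simulateCohort(100, seed = 1, ctSigma = 0.1)
calls <- subtypeCohort(sim$panels)
mean(calls$acrg == patients(sim$cohort)$acrg_true)
#> [1] 1

## somatic pipeline on one simulated hypermutated model
tv  <- simulateTruthVariants("MSI", seed = 3)
co  <- simulateCallerOutputs(tv$truth, seed = 4, nGermline = 50)
som <- somaticPipeline(co$A, co$B, co$C, co$normal)
mutationPrevalence(som, 51)$perMb
#> [1] 55.58824          # mutations per Mb: in the hypermutated MSI range
mutationSpectrum(som)$indelProportion
#> [1] 0.3181658         # ~30% indels, the MSI signature

## engraftment rates from the packaged 100-patient cohort table
engraftmentSummary(table1Cohort(), "msi_status")
#>   level  n pct n_engrafted success_rate is_unknown
#> 1   MSI 27  27          15           56      FALSE
#> 2   MSS 73  73          12           16      FALSE
associationTests(table1Cohort(), "msi_status", "engrafted")$p.value
#> [1] 0.0002327898      # MSI tumors engraft far more often

## the KRAS G12D -> G13D minor-clone swap across passages
ps <- simulatePassages(cloneSpecKrasSwap(), seed = 7)
subset(classifySeries(ps$series), grepl("KRAS", key))[, c("key", "class")]
#>                          key          class
#> 21 12:25398284:C>T_KRAS_G12D      transient
#> 23 12:25398281:C>T_KRAS_G13D selected_at_P1
```

The per-call numbers mean: the subtype trees recover every simulated label
at low Ct noise; the consensus-plus-filter chain returns exactly the
simulated somatic truth, whose burden and indel fraction land in the
microsatellite-instable range; the MSI engraftment rate is 56% against 16%
for MSS (Fisher p ≈ 2×10⁻⁴); and a 0.1% minor clone at P0 is correctly
reported as selected at first passage while the clone it replaced is lost.

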