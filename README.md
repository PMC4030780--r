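# triotriage

Variant triage for trio (proband–mother–father) exome studies of fetal
structural abnormalities.

When a fetus shows a structural anomaly on prenatal ultrasound and
karyotype/array testing is normal, exome sequencing of the affected fetus
and both parents can identify a genetic cause under several inheritance
models at once. `triotriage` implements that triage end to end:

* **Call merging** — per-individual call sets from three variant callers are
  normalized (left-aligned, parsimonious, biallelic) and unioned, with
  genotype disagreements resolved by majority vote (ties toward the less
  severe genotype, flagged for audit).
* **De novo screen** — high-sensitivity trio filtering (proband carries an
  alternate allele, both parents hom-ref with ≤1 stray alternate read,
  depth ≥10, GQ ≥20, MAF ≤1%), followed by orthogonal-validation
  bookkeeping, monozygotic-twin-aware independence collapse (an identical
  variant in MZ twins is one mutational event), and mosaicism flagging via
  an exact two-sided binomial test on allele balance (flag iff p < α and
  alternate fraction < 0.5).
* **Inherited screens** — rare (MAF < 1%) functional variants (essential
  splice site, stop gained, frameshift, non-synonymous, stop lost) under
  homozygous-recessive, compound-heterozygous (parental-transmission
  phasing: one confidently maternal plus one confidently paternal variant
  per gene; a validated de novo may stand in as a "second hit") and
  X-linked hemizygous models with configurable pseudoautosomal boundaries.
* **CNV filter** — external CNV calls kept iff confident, not matching a
  common-CNV catalog at 50% reciprocal overlap, overlapping a
  protein-coding gene, and consistent with a de novo / recessive / X-linked
  mode.
* **Evidence classifier** — a decision tree mapping curated per-gene
  evidence (known disease gene, previously reported identical variant,
  damaging variant class in a known domain, dosage-sensitive loss,
  model-organism support, functional plausibility/expression) plus
  HPO-style phenotype overlap (ancestor-closure score
  `|∩| / min(|A|,|B|)`) to **highly likely** / **possibly** / **unknown**
  causality, with a full rule trace per call.
* **Cohort statistics** — exact one-sided binomial test for synonymous
  depletion among independent de novo events
  (P = Σ<sub>i≤k</sub> C(n,i)p<sup>i</sup>(1−p)<sup>n−i</sup>, p = 0.29);
  recurrent-gene probability under a uniform-rate model
  (λ = n·L/30 Mb, P(≥2) = 1−(1+λ)e<sup>−λ</sup>) with the all-genes
  Bonferroni threshold 0.05/20,000 = 2.5×10⁻⁶; per-proband candidate-count
  summaries.
* **Synthetic cohort generator** — Hardy–Weinberg parents, Mendelian
  transmission, Poisson(1.1) de novo events (29% synonymous), injected
  recessive/X-linked configurations, MZ-twin genome sharing, depth and
  genotype noise, per-caller dropout — with a complete truth table, so every
  stage is testable without controlled data.

Inputs are standard dialects: VCF (v4.x, GT/AD/DP/GQ) per individual per
caller, 6-column PED with an `MZ:<id>` twin extension column, phenotype and
evidence TSVs, BED-like CNV and gene-model tables, OBO ontologies.

## Worked example

The package ships a 30-proband fixture cohort (26 trios, one MZ twin quad,
one sibling quad; 86 individuals) with its candidate-gene table, phenotype
sets and curated evidence records:

```r
library(triotriage)

fx <- fetal_cohort_fixture()
fx$cohort
#> trio_cohort: 86 individuals, 28 families, 30 probands, 1 MZ twin pair(s)

cl <- classify_candidates(fx$candidates, fx$evidence, fx$phenotypes, fx$ontology)
summarize_cohort(cl, fx$cohort)
#> cohort of 30 probands:
#>   highly_likely   3 (10%)
#>   possibly        5 (17%)
#>   unknown        22 (73%)

subset(cl, category != "unknown")[, c("proband_id", "gene", "mode", "category")]
#>     proband_id    gene         mode      category
#> 2           F1   PRKDC compound_het      possibly
#> 24          F5    DLC1 compound_het      possibly
#> 33          F6     NF1      de_novo      possibly
#> 34          F6 SMARCC2      de_novo      possibly
#> 38          F6    RERE compound_het      possibly
#> 67         F10   MACF1 compound_het      possibly
#> 75         F13   FRAS1 compound_het      possibly
#> 89         F14    OFD1  cnv_de_novo highly_likely
#> 137        F20  COL2A1      de_novo highly_likely
#> 162        F23   FGFR3      de_novo highly_likely
```

Three probands (10% of the cohort) get a highly-likely causal finding: a de
novo FGFR3 missense in a fetus with skeletal dysplasia (the identical
substitution previously reported causal), a de novo COL2A1
glycine-substitution in the triple-helical domain, and a de novo X
deletion removing most of the dosage-sensitive gene OFD1 — whose printed
breakpoints span `cnv_span(13770686, 13791294)` = 20,609 bp ≈ 21 kb. Five
more (17%) are possibly causal pending confirmation.

Cohort statistics on the de novo set (33 independent events, 3 synonymous):

```r
synonymous_enrichment_test(33, 3)       # exact lower tail at p = 0.29
#> 0.00586                               # significant synonymous depletion
recurrent_gene_probability(3600, 33)    # two hits in one 3.6 kb gene
#> $p_recurrent 7.82e-06   $bonferroni_threshold 2.5e-06
```

A synthetic cohort with known truth, end to end:

```r
sim <- simulate_cohort(sim_config(noiseless = TRUE, seed = 1))
trios <- sim_trios(sim)                       # merge callers, assemble trios
dn  <- screen_denovo(trios)                   # recovers sim$truth exactly
inh <- screen_inherited(trios, cohort = sim$cohort)
write_cohort_bundle(sim, "cohort_dir")        # PED + VCFs + TSV/BED bundle
```

`run_pipeline(analysis_config(...))` chains every stage over such a bundle
and writes the per-proband candidate table, classification report,
statistics JSON and a run log; `inst/cli/triotriage.R` exposes the stages
as shell subcommands (`simulate`, `merge`, `denovo`, `inherited`, `cnv`,
`classify`, `stats`, `run-all`).

## Not in scope

Read mapping, variant calling from reads and CNV detection from read depth
(calls are consumed as input); consequence annotation from transcripts;
haplotype phasing from reads; live queries to OMIM/DDG2P/model-organism
databases (evidence is a curated input table).
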