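---
title: "Trio exome variant triage: models, screens and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trio exome variant triage: models, screens and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triotriage)
```

## The problem

In a fetus with a structural abnormality seen on prenatal ultrasound and a
normal karyotype/array result, exome sequencing of the proband and both
parents can reveal a causal variant under several inheritance models at
once: a dominant de novo point mutation or indel, recessive biallelic
variants (homozygous or compound heterozygous), an X-linked hemizygous
variant in a male, or a copy-number variant. `triotriage` implements this
triage as a reusable, fully testable pipeline: it consumes per-individual
variant calls from several callers, pedigrees with monozygotic (MZ) twin
annotations, phenotype term sets, CNV calls and a curated gene-evidence
table, and emits per-proband candidate genes, three-way causality
classifications and cohort-level statistics.

Because the controlled sequence data such studies rest on cannot be
redistributed, the package pairs every screen with a synthetic cohort
generator (`simulate_cohort()`) that produces the same file dialects with a
complete truth table, so the whole pipeline is exercised end to end in the
test suite.

## Call merging and trio assembly

Each individual's call sets from three callers are merged by
`merge_caller_calls()`: the union of normalized sites, with records
identical on (chrom, pos, ref, alt) collapsed into one record carrying the
union of caller labels. The callers' genotype disagreements are resolved by
majority vote; a two-way tie resolves toward the **less severe** genotype
(het over hom-alt) and the record keeps a `discordant` flag so downstream
filters can treat such sites more sceptically. The tie direction is a
deliberate conservative choice: an inflated genotype (hom-alt where the
truth is het) would silently disable the compound-het screen for that gene,
while an understated one merely demands stronger evidence downstream.

Matching records across callers requires a canonical variant
representation; `normalize_variant()` trims shared leading/trailing bases
and left-aligns indels against the local reference context (idempotent, and
checked in the tests against a brute-force enumeration of all equivalent
representations of an edit). Multiallelic records are split per alternate
allele before merging, because every downstream rule is per-alternate.

Coordinates are 1-based inclusive throughout, matching HGVS-style
`g.<start>_<end>del` notation, and CNV spans are computed as
`end - start + 1` with half-up kb rounding (`cnv_span()`).

## The de novo screen

`screen_denovo()` is a transparent threshold rule, not a probabilistic
joint-genotype caller: a site is a candidate iff the proband carries an
alternate allele, both parents are called hom-ref with at most
`max_parent_alt_reads` (default 1) alternate-supporting reads, proband and
parental depths reach 10 reads, proband GQ reaches 20, and the population
allele frequency is at most 1%. A missing frequency passes the gate but is
flagged (`af_missing`), since absence from reference databases implies
rarity — while keeping the record auditable for probands from populations
the databases under-represent. The screen is deliberately tuned for
sensitivity; specificity is restored by `apply_validation()`, which
consumes an orthogonal validation table (capillary sequencing in the
motivating design) and drops refuted candidates. The candidate score is
`min(child GQ, parental GQ)` — the weakest link in the trio evidence.

Two bookkeeping operations follow. `collapse_independent()` counts an
identical variant observed in both members of an MZ twin pair as a single
mutational event (the representative is the lexicographically first twin
id, for determinism); identical variants in unrelated probands remain
independent. `flag_mosaic()` computes, per candidate, the exact two-sided
binomial probability of the observed alternate read count at expected
fraction 0.5, and flags suggestive mosaicism iff p < 0.01 **and** the
alternate fraction is below 0.5 — a germline het is balanced, a
post-zygotic event is depleted, and enrichment above 0.5 is reference bias
or CNV overlap, not mosaicism. The p-value is an explicit probability-mass
summation; the tests pin it to an independent enumeration oracle at 1e-12
and to `binom.test`.

## Inherited screens

"Functional" consequences are exactly the five classes: essential splice
site, stop gained, frameshift coding, non-synonymous, stop lost —
synonymous and everything else never pass. Rarity is strict (`MAF < 1%`).

* `screen_homozygous()`: proband hom-alt, both parents het. A hom-alt
  parent contradicts the unaffected-parent assumption and is excluded with
  a log record rather than silently dropped.
* `screen_compound_het()`: without read-backed phasing, parental origin is
  inferred purely from carriage — a proband het carried by exactly one
  parent is confidently assigned to that parent; carried by both, it is
  `ambiguous` and can never anchor a haplotype. A gene qualifies iff it
  carries at least one confidently maternal and one confidently paternal
  rare functional het (ambiguous variants are reported alongside).
  Optionally a **validated** de novo variant in the same gene may stand in
  for one side (a "second hit"), emitted with a `de_novo_second_hit` note.
  The screen's gene calls are checked against an exhaustive
  pair-enumeration oracle on 1,000 randomized small gene instances.
* `screen_hemizygous()`: male probands only, chrX outside the
  pseudoautosomal regions (GRCh37 PAR coordinates by default, configurable),
  mother het, father hemizygous-ref. Female X candidates are deliberately
  left to the homozygous/compound-het screens run on X, consistent with
  dosage logic.

## CNV filtering

CNV detection itself is out of scope; `filter_cnvs()` consumes an external
BED-like call table with per-trio carrier flags and keeps a call iff four
independent, commuting conditions hold: confidence at or above a cut
(default 10, set above the simulator's noise-score distribution — its
99th percentile is ≈9.7), no common-catalog interval reaching 50%
**reciprocal** overlap (both intervals must reach the fraction; the field's
convention), at least one protein-coding gene overlapped, and an
inheritance mode among de novo / recessive / X-linked
(`assign_cnv_mode()`). De novo takes precedence on X — a proband-only X
deletion is reported as de novo, which is also X-linked-consistent.

## Evidence classification

`classify_variant_gene()` maps curated per-gene evidence plus the proband's
phenotype to `highly_likely` / `possibly` / `unknown`:

* **highly_likely** requires all three of: a known human disease gene, a
  phenotype match (overlap score ≥ 0.5 against the known disorder's terms),
  and variant-level support — the identical variant previously reported
  pathogenic, or a damaging variant class within a known domain (the
  glycine-in-triple-helix archetype), or a mode-consistent loss of a
  dosage-sensitive gene (the CNV route).
* **possibly** requires any of: a known disease gene with at least partial
  phenotype overlap (score ≥ 0.2), a model-organism knockout/knockdown
  phenotype overlap, or functional plausibility together with relevant
  expression.
* everything else is **unknown**, including known disease genes whose
  disorder does not resemble the proband (a seizure/intellectual-disability
  gene in a fetus with multiple structural malformations).

Phenotype overlap is computed on ancestor closures in an HPO-style DAG:
`|closure(A) ∩ closure(B)| / min(|closure(A)|, |closure(B)|)`, root
excluded. The min-normalization makes a disease with a compact term set
comparable against a richly phenotyped proband. The 0.5 match cutoff and
the [0.2, 0.5) partial band replace what is otherwise expert judgment; both
are explicit, tunable (`classifier_cutoffs()`) and swept in monotonicity
tests. Every rule fires into a `rationale` trace so a classification is
auditable branch by branch. Multiple candidate genes in one proband all
retain independent classifications; the cohort summary takes each proband's
most severe category over all probands as denominator, with half-up integer
percentages.

The package ships a packaged fixture (`fetal_cohort_fixture()`) encoding a
30-proband cohort — 26 trios, one MZ twin quad, one sibling quad — with its
candidate-gene table, phenotype sets and evidence records. On it, the
classifier yields 3/30 probands highly likely (10%) and 5/30 possibly
(17%); these numbers are recomputed by `scripts/acceptance.R` and asserted
in the test suite. The fixture's ontology is a **synthetic** miniature
(HP:9xxxxxx ids) whose structure mirrors the higher-order phenotype
categories of fetal medicine; it is not the real Human Phenotype Ontology,
and real-data use should substitute a real OBO file (the reader handles
`is_a`-based DAGs generally).

## Cohort statistics

* `synonymous_enrichment_test()`: under neutrality, 29% of coding/splicing
  de novo events are synonymous. The test is the exact one-sided lower
  binomial tail of the observed synonymous count among **independent**
  events — one-sided because the scientific claim is depletion of
  synonymous (enrichment of functional) events. At the cohort scale of 33
  independent events with 3 synonymous it gives p = 0.0059 (the two-sided
  exact version gives 0.0066); either way a significant depletion at the
  conventional 0.01 level.
* `recurrent_gene_probability()`: the chance that two or more of n
  functional de novo events hit one gene of coding length L under a
  uniform-rate-per-bp model: lambda = n·L / 30 Mb and
  P(≥2) = 1 − (1+lambda)e^(−lambda), reported with the all-genes Bonferroni
  threshold 0.05 / 20,000 = 2.5e-6. The uniform model is deliberately
  transparent and oracle-checkable (tests compare it with 10^6-replicate
  Monte Carlo placement); gene-specific trinucleotide mutability would move
  individual answers and is declared out of scope.
* `candidate_count_summary()`: per-proband candidate counts as mean (two
  decimals) and range.

## The synthetic cohort generator

`simulate_cohort()` emulates, under one seed, the *structure* of a prenatal
trio cohort: 26 trios plus two quads (one MZ twin pair) by default — 30
probands; parental genotypes drawn under Hardy–Weinberg at each site's
population frequency and children by Mendelian transmission; X non-PAR
sites hemizygous in males, with a PAR1 boundary actually carrying genes so
the pseudoautosomal logic is exercised; de novo events at Poisson(1.1) per
proband genome, synonymous with probability 0.29; injected compound-het /
homozygous / hemizygous gene events at Poisson means 3 / 1 / 1 per proband
genome (hemizygous in males). The injected means are treated as Poisson
rates rather than fixed counts so per-proband candidate counts have
realistic spread; together with background-derived configurations they put
the per-proband inherited candidate-gene count at a mean near 5 with range
comfortably inside 0–15. MZ twins share a single genome — background
transmissions and injected events alike.

Observation noise is layered on separately: negative-binomial depth (mean
103, size 8), binomial allele-depth sampling with a 0.002 per-base error
rate, designated mosaic events (two per cohort at alternate fraction 0.2)
drawn at their mosaic fraction, a 0.002 genotype miscall rate, per-caller
dropout at 5% and per-caller genotype inflation at 1%. `noiseless = TRUE`
switches every channel off for truth-recovery testing. The exome-scale
depth and the noise rates are stated defaults, not fits; the allele
frequency spectrum (a 30/70 mixture of log-uniform rare and Beta(1.2, 4)
common) is a pragmatic choice, since no AF spectrum is derivable for the
background variation being emulated.

The truth table records every injected event **and** every candidate
configuration that arises from the Hardy–Weinberg background itself (a
rare functional het pair in trans, a homozygous or hemizygous draw): those
are genuine positives the screens must report, and recording them makes the
noiseless recovery comparison exact rather than probabilistic. Per-caller
VCFs are written with explicit hom-ref records at every cohort locus, so
"both parents hom-ref" is distinguishable from "no data" without joint
calling; a genuinely missing parental genotype is skipped and logged by the
screens, never silently treated as reference.

What the simulator does **not** model: read-level errors and mapping
artifacts, exome capture bias along genes, linkage between background
sites, population structure (every family is drawn from one AF spectrum),
mutation-rate heterogeneity across genes, and parental ages. Passing
recovery tests therefore demonstrates the correctness of the filtering
logic, not performance on real sequencing artifacts.

## Problem sizes in the test suite

The suite runs the generator at sizes chosen to keep properties sharp:
truth-recovery and calibration checks use the full default 30-proband
cohort; the Poisson-rate check uses 400 single-proband trios with all other
channels off; oracle comparisons use 1,000 randomized single-gene
instances; the Monte Carlo cross-check of the recurrence formula uses 10^6
replicates. The end-to-end pipeline tests use a 4-trio + 1-quad bundle
written to disk and re-read through the VCF/PED/TSV parsers.

## Known limitations

* Compound-het phasing is transmission-only; two variants both carried by
  both parents can never qualify, even when reads would phase them.
* The decision tree's thresholds encode one defensible reading of a
  manual curation workflow; they are exposed precisely so alternative trees
  can be configured, and the packaged evidence table is a curated input,
  not a product of literature mining.
* The recurrence model assumes uniform mutability per coding bp.
* The CNV screen trusts the upstream caller's confidence score and carrier
  assignments; it performs no read-depth inference of its own.
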