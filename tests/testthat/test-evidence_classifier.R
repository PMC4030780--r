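test_that("the OBO reader recovers terms, names and parents", {
  ont <- test_ontology()
  expect_s3_class(ont, "hpo_ontology")
  expect_true("HP:9010005" %in% ont$terms)
  expect_equal(ont$roots, "HP:9000001")
  expect_equal(ont$parents[["HP:9010005"]], "HP:9000060")
  # multi-parent DAG edges survive
  expect_setequal(ont$parents[["HP:9040001"]], c("HP:9000040", "HP:9000090"))
  expect_error(term_closure("HP:0000000", ont), "HP:0000000")
})

test_that("closures walk to the root but exclude it", {
  ont <- test_ontology()
  expect_setequal(term_closure("HP:9010005", ont),
                  c("HP:9010005", "HP:9000060", "HP:9000010"))
  # hepatic term lifts through the gastrointestinal chain
  expect_setequal(term_closure("HP:9140001", ont),
                  c("HP:9140001", "HP:9000140", "HP:9000070"))
  expect_false("HP:9000001" %in% term_closure("HP:9010005", ont))
})

test_that("phenotype overlap matches hand-enumerated closure ratios", {
  ont <- test_ontology()
  # identical non-empty sets
  expect_equal(phenotype_overlap("HP:9010005", "HP:9010005", ont)$score, 1)
  # branches sharing only the root
  ov <- phenotype_overlap("HP:9100001", "HP:9140001", ont)
  expect_equal(ov$score, 0)
  expect_false(ov$match)

  # toy 7-node DAG: root R; A,B under R; X,Y under A; Z under B; W under A+B
  toy <- tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: HP:0000001", "name: R",
               "[Term]", "id: HP:0000002", "name: A", "is_a: HP:0000001",
               "[Term]", "id: HP:0000003", "name: B", "is_a: HP:0000001",
               "[Term]", "id: HP:0000004", "name: X", "is_a: HP:0000002",
               "[Term]", "id: HP:0000005", "name: Y", "is_a: HP:0000002",
               "[Term]", "id: HP:0000006", "name: Z", "is_a: HP:0000003",
               "[Term]", "id: HP:0000007", "name: W", "is_a: HP:0000002",
               "is_a: HP:0000003"), toy)
  tont <- read_obo(toy)
  # closure(X) = {X, A} (2); closure(W) = {W, A, B} (3); shared = {A}
  expect_equal(phenotype_overlap("HP:0000004", "HP:0000007", tont)$score, 1 / 2)
  # closure(Z) = {Z, B}; vs W shared = {B} -> 1/2
  expect_equal(phenotype_overlap("HP:0000006", "HP:0000007", tont)$score, 1 / 2)
  # X vs Z share nothing below the root
  expect_equal(phenotype_overlap("HP:0000004", "HP:0000006", tont)$score, 0)
  # empty set: no match
  expect_equal(phenotype_overlap(character(0), "HP:0000004", tont)$score, 0)
})

test_that("the decision tree reproduces the three narrated archetypes", {
  fx <- fetal_cohort_fixture()
  ev <- function(g) fx$evidence[fx$evidence$gene == g, ]
  terms <- function(p) fx$phenotypes$hpo_terms[[match(p, fx$phenotypes$proband_id)]]

  # known gene + matching phenotype + identical variant previously causal
  hl <- classify_variant_gene(ev("FGFR3"), "de_novo", terms("F23"), fx$ontology)
  expect_equal(hl$category, "highly_likely")
  expect_true("identical_variant_reported_pathogenic" %in% hl$rationale)
  expect_true("phenotype_match" %in% hl$rationale)

  # known gene, phenotype mismatch: unknown despite the gene's disease status
  un <- classify_variant_gene(ev("GRIN2A"), "de_novo", terms("F2"), fx$ontology)
  expect_equal(un$category, "unknown")
  expect_equal(un$score, 0)

  # known gene, partial overlap, model-organism support: possibly
  po <- classify_variant_gene(ev("FRAS1"), "compound_het", terms("F13"),
                              fx$ontology)
  expect_equal(po$category, "possibly")
  expect_true(po$score >= 0.2 && po$score < 0.5)

  # dosage-sensitive loss branch needs a loss mode
  cn <- classify_variant_gene(ev("OFD1"), "cnv_de_novo", terms("F14"), fx$ontology)
  expect_equal(cn$category, "highly_likely")
  snv <- classify_variant_gene(ev("OFD1"), "de_novo", terms("F14"), fx$ontology)
  expect_false(snv$category == "highly_likely")
})

test_that("classification is deterministic and monotone in evidence", {
  fx <- fetal_cohort_fixture()
  terms <- fx$phenotypes$hpo_terms[[1]]
  sev <- c(unknown = 1, possibly = 2, highly_likely = 3)
  set.seed(53)
  for (i in 1:40) {
    ev <- as.list(setNames(runif(7) < 0.4, c(
      "known_human_disease_gene", "identical_variant_reported_pathogenic",
      "damaging_variant_class_in_known_domain", "dosage_sensitive_loss",
      "model_organism_phenotype_overlap", "functional_plausibility",
      "expression_relevant")))
    ev$gene <- "G"
    ev$disease_hpo <- list(if (ev$known_human_disease_gene) terms else character(0))
    mode <- sample(c("de_novo", "compound_het", "cnv_de_novo"), 1)
    base <- classify_variant_gene(ev, mode, terms, fx$ontology)
    rerun <- classify_variant_gene(ev, mode, terms, fx$ontology)
    expect_identical(rerun, base)  # determinism incl. the rationale trace
    for (fl in c("identical_variant_reported_pathogenic",
                 "damaging_variant_class_in_known_domain",
                 "model_organism_phenotype_overlap")) {
      if (!isTRUE(ev[[fl]])) {
        ev2 <- ev; ev2[[fl]] <- TRUE
        up <- classify_variant_gene(ev2, mode, terms, fx$ontology)
        expect_gte(sev[up$category], sev[base$category])
      }
    }
  }
})

test_that("cohort summary takes per-proband maxima over all probands", {
  co <- small_cohort(n_trios = 3)
  cl <- data.frame(
    proband_id = c("F1", "F1", "F1", "F2"),
    gene = c("A", "B", "C", "D"), mode = "de_novo",
    category = c("highly_likely", "possibly", "possibly", "possibly"),
    stringsAsFactors = FALSE)
  s <- summarize_cohort(cl, co)
  # F1 counted once, at its most severe category
  expect_equal(s$counts[["highly_likely"]], 1)
  expect_equal(s$counts[["possibly"]], 1)
  expect_equal(s$counts[["unknown"]], 1)  # F3 has no candidates
  expect_equal(s$per_proband$best_genes[s$per_proband$proband_id == "F1"], "A")
  expect_equal(sum(s$fractions), 1)

  empty <- cohort(data.frame(individual_id = c("M1", "P1", "F1"),
                             family_id = "FAM1",
                             father_id = c("0", "0", "P1"),
                             mother_id = c("0", "0", "M1"),
                             sex = c("female", "male", "male"),
                             affected = c(FALSE, FALSE, TRUE),
                             stringsAsFactors = FALSE))
  empty$probands <- character(0)
  expect_error(summarize_cohort(cl, empty), "no probands")
})

test_that("evidence tables validate their disease-term invariant", {
  f <- tempfile(fileext = ".tsv")
  hdr <- paste(c("gene", "known_human_disease_gene", "disease_hpo",
                 "identical_variant_reported_pathogenic",
                 "damaging_variant_class_in_known_domain",
                 "dosage_sensitive_loss", "model_organism_phenotype_overlap",
                 "functional_plausibility", "expression_relevant"),
               collapse = "\t")
  writeLines(c(hdr, "BAD\tFALSE\tHP:9010001\tFALSE\tFALSE\tFALSE\tFALSE\tFALSE\tFALSE"), f)
  expect_error(read_gene_evidence(f), "BAD")
})
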