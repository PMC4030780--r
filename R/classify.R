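#' Classifier cutoffs for phenotype matching
#'
#' The decision tree distinguishes a full phenotype match (overlap score at
#' or above `match_cutoff`) from a partial match (score in
#' `[partial_low, match_cutoff)`). The thresholds replace the expert
#' judgment of a manual curation step and are deliberately explicit and
#' tunable.
#'
#' @param match_cutoff Score at or above which phenotypes are considered
#'   matching (default 0.5).
#' @param partial_low Lower bound of the partial-match band (default 0.2).
#' @return A list of class `classifier_cutoffs`.
#' @export
classifier_cutoffs <- function(match_cutoff = 0.5, partial_low = 0.2) {
  stopifnot(partial_low >= 0, partial_low <= match_cutoff, match_cutoff <= 1)
  structure(list(match_cutoff = match_cutoff, partial_low = partial_low),
            class = "classifier_cutoffs")
}

.evidence_flags <- c("known_human_disease_gene",
                     "identical_variant_reported_pathogenic",
                     "damaging_variant_class_in_known_domain",
                     "dosage_sensitive_loss",
                     "model_organism_phenotype_overlap",
                     "functional_plausibility", "expression_relevant")

#' Read a gene-evidence table
#'
#' TSV with header: `gene`, the boolean evidence columns
#' (`known_human_disease_gene`, `identical_variant_reported_pathogenic`,
#' `damaging_variant_class_in_known_domain`, `dosage_sensitive_loss`,
#' `model_organism_phenotype_overlap`, `functional_plausibility`,
#' `expression_relevant`) and `disease_hpo` (semicolon-separated HPO terms
#' of the known disorder; must be empty when the gene is not a known human
#' disease gene).
#'
#' @param path Path to the TSV file.
#' @return Data frame with one row per gene; `disease_hpo` is a list-column.
#' @export
read_gene_evidence <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  miss <- setdiff(c("gene", "disease_hpo", .evidence_flags), names(x))
  if (length(miss) > 0) stop("evidence table lacks columns: ", paste(miss, collapse = ", "))
  for (fl in .evidence_flags) x[[fl]] <- toupper(x[[fl]]) %in% c("TRUE", "T", "1")
  terms <- lapply(x$disease_hpo, function(s) {
    tt <- strsplit(s, ";", fixed = TRUE)[[1]]
    tt[nzchar(tt) & tt != "."]
  })
  bad <- !x$known_human_disease_gene & vapply(terms, length, 0L) > 0
  if (any(bad)) {
    stop("disease_hpo must be empty for non-disease genes: ",
         paste(x$gene[bad], collapse = ", "))
  }
  x$disease_hpo <- I(terms)
  x
}

# all-false evidence used for genes with no curated record
.null_evidence <- function(gene) {
  ev <- as.list(setNames(rep(FALSE, length(.evidence_flags)), .evidence_flags))
  c(list(gene = gene, disease_hpo = list(character(0))), ev)
}

#' Classify one candidate gene with the evidence decision tree
#'
#' The tree maps curated per-gene evidence plus the proband's phenotype to
#' one of three causality categories:
#'
#' * `highly_likely` — the gene is a known human disease gene, the proband's
#'   phenotype matches the known disorder (overlap score at or above
#'   `match_cutoff`), and there is variant-level support: the identical
#'   variant previously reported pathogenic, or the variant falls in a
#'   particularly damaging class within a known domain, or the event is a
#'   mode-consistent loss (a CNV-style loss) of a dosage-sensitive known
#'   gene.
#' * `possibly` — not highly likely, but the gene is a known disease gene
#'   with at least partial phenotype overlap (score at or above
#'   `partial_low`), or a model-organism knockout/knockdown phenotype
#'   overlaps, or the gene is functionally plausible and relevantly
#'   expressed.
#' * `unknown` — everything else.
#'
#' @param evidence A single-row evidence record (one row of
#'   [read_gene_evidence()] output, or a list with the same fields).
#' @param mode Inheritance mode of the candidate: one of `de_novo`,
#'   `compound_het`, `homozygous`, `hemizygous`, `cnv_de_novo`,
#'   `cnv_recessive`, `cnv_x_linked`.
#' @param proband_terms Character vector of the proband's HPO terms.
#' @param ontology An `hpo_ontology`.
#' @param cutoffs A [classifier_cutoffs()].
#' @return List of class `gene_classification`: `category`, `score`
#'   (phenotype-overlap score, `NA` when not evaluable) and `rationale`
#'   (character vector naming each satisfied branch).
#' @export
classify_variant_gene <- function(evidence, mode, proband_terms, ontology,
                                  cutoffs = classifier_cutoffs()) {
  ev <- as.list(evidence)
  flag <- function(f) isTRUE(ev[[f]]) || identical(ev[[f]], "TRUE")
  disease_terms <- ev$disease_hpo
  if (is.list(disease_terms)) disease_terms <- disease_terms[[1]]
  score <- NA_real_
  matched <- FALSE
  partial <- FALSE
  rationale <- character(0)

  if (flag("known_human_disease_gene")) {
    rationale <- c(rationale, "known_human_disease_gene")
    if (length(disease_terms) > 0 && length(proband_terms) > 0) {
      ov <- phenotype_overlap(proband_terms, disease_terms, ontology,
                              cutoff = cutoffs$match_cutoff)
      score <- ov$score
      matched <- ov$match
      partial <- score >= cutoffs$partial_low
      if (matched) rationale <- c(rationale, "phenotype_match")
      else if (partial) rationale <- c(rationale, "phenotype_partial_match")
    }
  }

  loss_mode <- mode %in% c("cnv_de_novo", "cnv_recessive", "cnv_x_linked")
  variant_level <- FALSE
  if (flag("identical_variant_reported_pathogenic")) {
    variant_level <- TRUE
    rationale <- c(rationale, "identical_variant_reported_pathogenic")
  }
  if (flag("damaging_variant_class_in_known_domain")) {
    variant_level <- TRUE
    rationale <- c(rationale, "damaging_variant_class_in_known_domain")
  }
  if (flag("dosage_sensitive_loss") && loss_mode) {
    variant_level <- TRUE
    rationale <- c(rationale, "dosage_sensitive_loss_mode_consistent")
  }

  if (flag("known_human_disease_gene") && matched && variant_level) {
    return(structure(list(category = "highly_likely", score = score,
                          rationale = rationale),
                     class = "gene_classification"))
  }
  possibly <- FALSE
  if (flag("known_human_disease_gene") && partial) {
    possibly <- TRUE
    rationale <- c(rationale, "known_gene_with_phenotype_overlap")
  }
  if (flag("model_organism_phenotype_overlap")) {
    possibly <- TRUE
    rationale <- c(rationale, "model_organism_phenotype_overlap")
  }
  if (flag("functional_plausibility") && flag("expression_relevant")) {
    possibly <- TRUE
    rationale <- c(rationale, "functional_plausibility_with_relevant_expression")
  }
  structure(list(category = if (possibly) "possibly" else "unknown",
                 score = score, rationale = rationale),
            class = "gene_classification")
}

#' @export
print.gene_classification <- function(x, ...) {
  cat(sprintf("%s (score %s): %s\n", x$category,
              ifelse(is.na(x$score), "-", format(round(x$score, 3))),
              if (length(x$rationale)) paste(x$rationale, collapse = " + ")
              else "no supporting evidence"))
  invisible(x)
}

#' Classify a table of candidate proband-gene records
#'
#' Runs [classify_variant_gene()] on every row. Genes without a curated
#' evidence record receive an all-false record (category `unknown`).
#' Multiple candidate genes in one proband are all retained with independent
#' classifications.
#'
#' @param candidates Data frame with columns `proband_id`, `gene`, `mode`.
#' @param evidence Evidence table from [read_gene_evidence()].
#' @param phenotypes Phenotype table from [read_phenotypes()].
#' @param ontology An `hpo_ontology`.
#' @param cutoffs A [classifier_cutoffs()].
#' @return The candidates with added columns `category`, `phenotype_score`,
#'   `rationale` (rule-path trace, `+`-joined).
#' @export
classify_candidates <- function(candidates, evidence, phenotypes, ontology,
                                cutoffs = classifier_cutoffs()) {
  n <- nrow(candidates)
  category <- character(n); score <- numeric(n); rationale <- character(n)
  for (i in seq_len(n)) {
    g <- candidates$gene[i]
    ei <- match(g, evidence$gene)
    ev <- if (is.na(ei)) .null_evidence(g) else as.list(evidence[ei, , drop = FALSE])
    pi <- match(candidates$proband_id[i], phenotypes$proband_id)
    terms <- if (is.na(pi)) character(0) else phenotypes$hpo_terms[[pi]]
    cl <- classify_variant_gene(ev, candidates$mode[i], terms, ontology, cutoffs)
    category[i] <- cl$category
    score[i] <- ifelse(is.na(cl$score), NA_real_, cl$score)
    rationale[i] <- paste(cl$rationale, collapse = "+")
  }
  out <- candidates
  out$category <- category
  out$phenotype_score <- score
  out$rationale <- rationale
  out
}

.category_severity <- c(unknown = 1, possibly = 2, highly_likely = 3)

#' Summarize classifications over a cohort
#'
#' Each proband's category is the most severe among its candidate-gene
#' classifications (`highly_likely` > `possibly` > `unknown`); probands with
#' no candidates count as `unknown`. Fractions are over all analyzed
#' probands; percentages are rounded half-up to the nearest integer.
#'
#' @param classified Output of [classify_candidates()].
#' @param cohort A [cohort()]; every proband is included in the denominator.
#' @return List of class `cohort_summary`: `per_proband` (data frame
#'   `proband_id`, `category`, `best_genes`), `counts`, `fractions` and
#'   `percent` (named by category).
#' @export
summarize_cohort <- function(classified, cohort) {
  pro <- probands(cohort)
  if (length(pro) == 0) stop("cohort has no probands: denominator undefined")
  cats <- c("highly_likely", "possibly", "unknown")
  per <- data.frame(proband_id = pro, category = "unknown",
                    best_genes = "", stringsAsFactors = FALSE)
  for (i in seq_along(pro)) {
    rows <- classified[classified$proband_id == pro[i], , drop = FALSE]
    if (nrow(rows) == 0) next
    best <- max(.category_severity[rows$category])
    per$category[i] <- names(.category_severity)[match(best, .category_severity)]
    per$best_genes[i] <- paste(sort(unique(
      rows$gene[.category_severity[rows$category] == best])), collapse = ";")
  }
  counts <- vapply(cats, function(cc) sum(per$category == cc), 0L)
  fractions <- counts / length(pro)
  structure(list(per_proband = per, counts = counts, fractions = fractions,
                 percent = round_half_up(100 * fractions),
                 n_probands = length(pro)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("cohort of %d probands:\n", x$n_probands))
  for (cc in names(x$counts)) {
    cat(sprintf("  %-14s %2d (%d%%)\n", cc, x$counts[[cc]], x$percent[[cc]]))
  }
  invisible(x)
}

#' Write a classification report
#'
#' @param classified Output of [classify_candidates()].
#' @param summary Output of [summarize_cohort()].
#' @param path Output TSV path for the per-candidate report; the per-proband
#'   summary goes to `paste0(path, ".summary.tsv")`.
#' @return Invisibly, the paths written.
#' @export
write_classification_report <- function(classified, summary, path) {
  write.table(classified, path, sep = "\t", quote = FALSE, row.names = FALSE)
  spath <- paste0(path, ".summary.tsv")
  write.table(summary$per_proband, spath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(report = path, summary = spath))
}
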