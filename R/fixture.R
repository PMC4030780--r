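#' Packaged 30-proband prenatal cohort fixture
#'
#' A fixture encoding a 30-proband fetal structural-abnormality trio cohort:
#' pedigree (26 trios and two quads, one monozygotic twin pair), per-proband
#' phenotype terms against the packaged synthetic ontology, the per-proband
#' candidate-gene table (de novo / compound-het / homozygous / hemizygous /
#' CNV columns) and the curated per-gene evidence table feeding the
#' decision-tree classifier. Used by the worked examples, the acceptance
#' checks and as a template for the expected input dialects.
#'
#' @return List with `cohort`, `phenotypes`, `candidates` (long data frame
#'   `proband_id`, `gene`, `mode`), `evidence` and `ontology`.
#' @export
fetal_cohort_fixture <- function() {
  ext <- function(f) system.file("extdata", f, package = "triotriage")
  wide <- read.delim(ext("fetal_candidates.tsv"), stringsAsFactors = FALSE,
                     colClasses = "character")
  long <- list()
  for (i in seq_len(nrow(wide))) {
    for (col in c("de_novo", "compound_het", "homozygous", "hemizygous")) {
      genes <- strsplit(wide[[col]][i], ";", fixed = TRUE)[[1]]
      genes <- genes[nzchar(genes) & genes != "."]
      if (length(genes) > 0) {
        long[[length(long) + 1]] <- data.frame(
          proband_id = wide$proband_id[i], gene = genes, mode = col,
          stringsAsFactors = FALSE)
      }
    }
    genes <- strsplit(wide$cnv[i], ";", fixed = TRUE)[[1]]
    genes <- genes[nzchar(genes) & genes != "."]
    if (length(genes) > 0) {
      long[[length(long) + 1]] <- data.frame(
        proband_id = wide$proband_id[i], gene = genes,
        mode = wide$cnv_mode[i], stringsAsFactors = FALSE)
    }
  }
  list(cohort = read_pedigree(ext("fetal_cohort.ped")),
       phenotypes = read_phenotypes(ext("fetal_phenotypes.tsv")),
       candidates = do.call(rbind, long),
       evidence = read_gene_evidence(ext("fetal_gene_evidence.tsv")),
       ontology = read_obo(ext("hpo_synthetic_subset.obo")))
}
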