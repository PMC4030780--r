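#' Analysis configuration for the end-to-end pipeline
#'
#' Collects every input path and tunable in one serializable object. All
#' paths are resolved and checked at construction; the configuration
#' round-trips through YAML.
#'
#' @param paths Named list of input paths: `pedigree`, `phenotypes`,
#'   `calls_dir` (directory of `<individual>.<caller>.vcf` files),
#'   `ontology`, and optionally `cnv_calls`, `cnv_common`, `gene_model`,
#'   `evidence`, `validation`.
#' @param thresholds A [screen_thresholds()].
#' @param stats A [stats_config()].
#' @param cutoffs A [classifier_cutoffs()].
#' @param cnv_min_confidence,cnv_reciprocal_overlap CNV filter parameters.
#' @param mosaic_alpha Significance level for mosaic flagging.
#' @param par PAR boundaries.
#' @param seed Seed for any stochastic step (the pipeline itself is
#'   deterministic; the seed is recorded for provenance).
#' @param log_level `"info"` or `"quiet"`.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(paths, thresholds = screen_thresholds(),
                            stats = stats_config(),
                            cutoffs = classifier_cutoffs(),
                            cnv_min_confidence = 10,
                            cnv_reciprocal_overlap = 0.5,
                            mosaic_alpha = 0.01,
                            par = par_boundaries_grch37(),
                            seed = 1L, log_level = "info") {
  required <- c("pedigree", "phenotypes", "calls_dir", "ontology")
  miss <- setdiff(required, names(paths))
  if (length(miss) > 0) stop("config lacks paths: ", paste(miss, collapse = ", "))
  for (p in unlist(paths)) {
    if (!is.null(p) && !file.exists(p)) stop("input does not exist: ", p)
  }
  structure(list(paths = paths, thresholds = thresholds, stats = stats,
                 cutoffs = cutoffs, cnv_min_confidence = cnv_min_confidence,
                 cnv_reciprocal_overlap = cnv_reciprocal_overlap,
                 mosaic_alpha = mosaic_alpha, par = par,
                 seed = as.integer(seed), log_level = log_level),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#' @param path YAML file with the fields of [analysis_config()].
#' @param base_dir Directory against which relative paths resolve (defaults
#'   to the YAML file's directory).
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path, base_dir = dirname(path)) {
  y <- yaml::read_yaml(path)
  paths <- lapply(y$paths, function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base_dir, p)
  })
  analysis_config(
    paths = paths,
    thresholds = do.call(screen_thresholds, y$thresholds %||% list()),
    stats = do.call(stats_config, y$stats %||% list()),
    cutoffs = do.call(classifier_cutoffs, y$cutoffs %||% list()),
    cnv_min_confidence = y$cnv_min_confidence %||% 10,
    cnv_reciprocal_overlap = y$cnv_reciprocal_overlap %||% 0.5,
    mosaic_alpha = y$mosaic_alpha %||% 0.01,
    seed = y$seed %||% 1L,
    log_level = y$log_level %||% "info")
}

.plog <- function(config, ..., log = NULL) {
  msg <- paste0("[triotriage] ", ...)
  if (identical(config$log_level, "info")) message(msg)
  if (!is.null(log)) cat(msg, "\n", file = log, append = TRUE)
  invisible(msg)
}

#' Load and merge per-caller call sets for a cohort
#'
#' Expects `calls_dir` to contain one VCF per individual per caller named
#' `<individual>.<caller>.vcf`; callers missing for an individual are
#' tolerated.
#'
#' @param calls_dir Directory of VCFs.
#' @param cohort A [cohort()].
#' @return Named list of unified call sets, one per individual.
#' @export
load_merged_callsets <- function(calls_dir, cohort) {
  out <- list()
  for (id in cohort$members$individual_id) {
    files <- list.files(calls_dir, pattern = paste0("^", id, "\\..*\\.vcf$"),
                        full.names = TRUE)
    if (length(files) == 0) stop("no call files for individual ", id)
    css <- lapply(files, function(f) {
      caller <- sub("\\.vcf$", "", sub(paste0("^", id, "\\."), "", basename(f)))
      read_caller_vcf(f, caller = caller, individual_id = id)
    })
    out[[id]] <- merge_caller_calls(css)
  }
  out
}

#' Run the full triage pipeline
#'
#' Stages: read pedigree and phenotypes; load and merge per-caller call
#' sets; assemble trios; de novo screen (+ optional validation, twin
#' collapse, mosaic flagging); inherited screens; CNV filter (if CNV inputs
#' given); decision-tree classification of all candidate genes; cohort
#' summary and statistics. Deterministic given the configuration.
#'
#' @param config An [analysis_config()].
#' @param out_dir Output directory for the report bundle (`NULL`: no files
#'   written, results only returned).
#' @return List of class `triage_result`: `cohort`, `trios`, `denovo`,
#'   `inherited`, `inherited_genes`, `cnv`, `candidates` (unified
#'   proband-gene-mode table), `classified`, `summary`, `stats`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  set.seed(config$seed)
  log <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    log <- file.path(out_dir, "run.log")
    cat("triotriage run\n", file = log)
    yaml::write_yaml(.serializable_config(config),
                     file.path(out_dir, "config_resolved.yaml"))
  }
  p <- config$paths
  .plog(config, "reading pedigree: ", p$pedigree, log = log)
  cohort <- read_pedigree(p$pedigree)
  phen <- read_phenotypes(p$phenotypes)
  ontology <- read_obo(p$ontology)

  .plog(config, "merging caller call sets from ", p$calls_dir, log = log)
  merged <- load_merged_callsets(p$calls_dir, cohort)
  trios <- build_trio_genotypes(merged, cohort)

  .plog(config, "de novo screen over ", nrow(trios), " trio-site records", log = log)
  dn <- screen_denovo(trios, config$thresholds)
  if (!is.null(p$validation)) {
    statuses <- read.delim(p$validation, stringsAsFactors = FALSE,
                           colClasses = c(chrom = "character",
                                          ref = "character", alt = "character"))
    dn <- apply_validation(dn, statuses)
  }
  dn <- collapse_independent(dn, cohort)
  dn <- flag_mosaic(dn, config$mosaic_alpha)

  .plog(config, "inherited screens", log = log)
  dn_for_pairing <- if (!is.null(p$validation)) validated_denovos(dn) else NULL
  inh <- screen_inherited(trios, config$thresholds, cohort,
                          validated_denovo = dn_for_pairing, par = config$par)
  inh_genes <- inherited_candidate_genes(inh)

  cnv_kept <- NULL
  cnv_modes <- NULL
  if (!is.null(p$cnv_calls)) {
    .plog(config, "CNV filter", log = log)
    calls <- read_cnv_table(p$cnv_calls)
    catalog <- if (!is.null(p$cnv_common)) read_interval_table(p$cnv_common)
    else data.frame(chrom = character(0), start = integer(0), end = integer(0))
    gm <- read_interval_table(p$gene_model)
    cnv_kept <- filter_cnvs(calls, catalog, gm, cohort,
                            min_confidence = config$cnv_min_confidence,
                            reciprocal_overlap = config$cnv_reciprocal_overlap)
  }

  # unified proband-gene-mode candidate table for classification
  cand <- list()
  dn_final <- if (!is.null(p$validation)) validated_denovos(dn) else dn
  if (nrow(dn_final) > 0) {
    cand[[length(cand) + 1]] <- data.frame(
      proband_id = dn_final$proband_id, gene = dn_final$gene,
      mode = "de_novo", stringsAsFactors = FALSE)
  }
  if (nrow(inh_genes) > 0) {
    cand[[length(cand) + 1]] <- inh_genes[, c("proband_id", "gene", "mode")]
  }
  if (!is.null(cnv_kept) && nrow(cnv_kept) > 0) {
    for (i in seq_len(nrow(cnv_kept))) {
      genes <- strsplit(cnv_kept$genes[i], ";", fixed = TRUE)[[1]]
      cand[[length(cand) + 1]] <- data.frame(
        proband_id = cnv_kept$proband_id[i], gene = genes,
        mode = paste0("cnv_", cnv_kept$mode[i]), stringsAsFactors = FALSE)
    }
  }
  candidates <- if (length(cand) > 0) unique(do.call(rbind, cand)) else
    data.frame(proband_id = character(0), gene = character(0),
               mode = character(0), stringsAsFactors = FALSE)
  rownames(candidates) <- NULL

  evidence <- if (!is.null(p$evidence)) read_gene_evidence(p$evidence) else
    read_gene_evidence(system.file("extdata", "fetal_gene_evidence.tsv",
                                   package = "triotriage"))[0, ]
  .plog(config, "classifying ", nrow(candidates), " candidate gene records", log = log)
  classified <- classify_candidates(candidates, evidence, phen, ontology,
                                    config$cutoffs)
  summary <- summarize_cohort(classified, cohort)

  # cohort statistics over the final de novo set
  dn_ind <- dn_final[!is.na(dn_final$independent) & dn_final$independent, ,
                     drop = FALSE]
  n_ind <- nrow(dn_ind)
  n_syn <- sum(dn_ind$consequence == "synonymous")
  stats_out <- list(
    n_denovo = nrow(dn_final),
    n_independent = n_ind,
    n_synonymous_independent = n_syn,
    synonymous_p = if (n_ind > 0)
      synonymous_enrichment_test(n_ind, n_syn, config$stats) else NA_real_,
    denovo_counts = candidate_count_summary(
      vapply(probands(cohort),
             function(pr) sum(dn_final$proband_id == pr), 0L)),
    inherited_gene_counts = candidate_count_summary(
      vapply(probands(cohort),
             function(pr) length(unique(inh_genes$gene[inh_genes$proband_id == pr])), 0L))
  )

  result <- structure(list(cohort = cohort, trios = trios, denovo = dn,
                           inherited = inh, inherited_genes = inh_genes,
                           cnv = cnv_kept, candidates = candidates,
                           classified = classified, summary = summary,
                           stats = stats_out),
                      class = "triage_result")
  if (!is.null(out_dir)) {
    write_denovo_candidates(dn, file.path(out_dir, "denovo_candidates.tsv"),
                            file.path(out_dir, "denovo_candidates.vcf"))
    write.table(inh, file.path(out_dir, "inherited_candidates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(.table1_layout(result),
                file.path(out_dir, "candidate_genes_by_proband.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(cnv_kept)) {
      write.table(cnv_kept, file.path(out_dir, "cnv_kept.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_classification_report(classified, summary,
                                file.path(out_dir, "classification.tsv"))
    writeLines(jsonlite::toJSON(stats_out, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
               file.path(out_dir, "statistics.json"))
    .plog(config, "reports written to ", out_dir, log = log)
  }
  result
}

# per-proband candidate table in the five-column cohort-table layout
.table1_layout <- function(result) {
  pro <- probands(result$cohort)
  modes <- c("de_novo", "compound_het", "homozygous", "hemizygous")
  out <- data.frame(proband_id = pro, stringsAsFactors = FALSE)
  cc <- result$candidates
  for (m in modes) {
    out[[m]] <- vapply(pro, function(pr) {
      g <- sort(unique(cc$gene[cc$proband_id == pr & cc$mode == m]))
      if (length(g) == 0) "." else paste(g, collapse = ";")
    }, "")
  }
  out$cnv <- vapply(pro, function(pr) {
    g <- sort(unique(cc$gene[cc$proband_id == pr & startsWith(cc$mode, "cnv")]))
    if (length(g) == 0) "." else paste(g, collapse = ";")
  }, "")
  out
}

.serializable_config <- function(config) {
  x <- unclass(config)
  x$thresholds <- unclass(x$thresholds)
  x$stats <- unclass(x$stats)
  x$cutoffs <- unclass(x$cutoffs)
  x$par <- lapply(x$par, as.integer)
  x
}

#' @export
print.triage_result <- function(x, ...) {
  cat("triotriage result\n")
  cat(sprintf("  de novo candidates: %d (%d independent)\n",
              nrow(x$denovo), n_independent(x$denovo)))
  cat(sprintf("  inherited candidate genes: %d\n", nrow(x$inherited_genes)))
  if (!is.null(x$cnv)) cat(sprintf("  CNV calls kept: %d\n", nrow(x$cnv)))
  print(x$summary)
  invisible(x)
}
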