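# shared builders and independent oracles used across test files

# one row of a trio genotype table with sensible defaults; allele depths are
# derived from the genotypes unless given explicitly
trio_row <- function(proband_id = "F1", family_id = "FAM1", chrom = "1",
                     pos = 1000L, ref = "A", alt = "G", gene = "G1",
                     consequence = "non_synonymous", population_af = 0.001,
                     gt_p = "het", gt_m = "hom_ref", gt_f = "hom_ref",
                     dp = 60L, gq = 99L,
                     ad_alt_p = NULL, ad_alt_m = NULL, ad_alt_f = NULL) {
  frac <- function(gt) c(hom_ref = 0, het = 0.5, hom_alt = 1, hemi_ref = 0,
                         hemi_alt = 1, missing = 0)[gt]
  ad <- function(gt, ad_alt) {
    if (is.null(ad_alt)) ad_alt <- as.integer(round(dp * frac(gt)))
    c(ref = dp - ad_alt, alt = ad_alt)
  }
  p <- ad(gt_p, ad_alt_p); m <- ad(gt_m, ad_alt_m); f <- ad(gt_f, ad_alt_f)
  data.frame(family_id = family_id, proband_id = proband_id, chrom = chrom,
             pos = as.integer(pos), ref = ref, alt = alt, gene = gene,
             consequence = consequence, population_af = population_af,
             gt_p = gt_p, ad_ref_p = p[["ref"]], ad_alt_p = p[["alt"]],
             dp_p = dp, gq_p = gq,
             gt_m = gt_m, ad_ref_m = m[["ref"]], ad_alt_m = m[["alt"]],
             dp_m = dp, gq_m = gq,
             gt_f = gt_f, ad_ref_f = f[["ref"]], ad_alt_f = f[["alt"]],
             dp_f = dp, gq_f = gq, stringsAsFactors = FALSE)
}

# minimal cohort: n single-proband trios, optionally one MZ twin quad
small_cohort <- function(n_trios = 2, twins = FALSE,
                         sexes = rep("male", n_trios + 2 * twins)) {
  rows <- list()
  k <- 0
  add <- function(fam, kids, kid_sex, mz) {
    rows[[length(rows) + 1]] <<- data.frame(
      individual_id = c(paste0("M", fam), paste0("P", fam)),
      family_id = paste0("FAM", fam), father_id = "0", mother_id = "0",
      sex = c("female", "male"), affected = FALSE,
      mz_twin_of = NA_character_, stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <<- data.frame(
      individual_id = kids, family_id = paste0("FAM", fam),
      father_id = paste0("P", fam), mother_id = paste0("M", fam),
      sex = kid_sex, affected = TRUE,
      mz_twin_of = if (mz) rev(kids) else NA_character_,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_trios)) {
    k <- k + 1
    add(i, paste0("F", i), sexes[k], FALSE)
  }
  if (twins) {
    add(n_trios + 1, c("T1", "T2"), rep(sexes[k + 1], 2), TRUE)
  }
  cohort(do.call(rbind, rows))
}

# exhaustive pair-enumeration oracle for compound-het gene candidacy,
# independent of the screen's implementation
oracle_comphet_genes <- function(trios, max_af = 0.01) {
  origin_of <- function(gm, gf) {
    m <- gm %in% c("het", "hom_alt")
    f <- gf %in% c("het", "hom_alt", "hemi_alt")
    if (m && f) "ambiguous" else if (m) "maternal" else if (f) "paternal" else "none"
  }
  out <- list()
  for (key in unique(paste(trios$proband_id, trios$gene, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    g <- trios[trios$proband_id == parts[1] & trios$gene == parts[2], , drop = FALSE]
    rare <- is.na(g$population_af) | g$population_af < max_af
    g <- g[g$gt_p == "het" & rare &
             g$consequence %in% functional_consequences() &
             g$gt_m != "missing" & g$gt_f != "missing", , drop = FALSE]
    n <- nrow(g)
    if (n < 2) next
    found <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        oi <- origin_of(g$gt_m[i], g$gt_f[i])
        oj <- origin_of(g$gt_m[j], g$gt_f[j])
        if ((oi == "maternal" && oj == "paternal") ||
            (oi == "paternal" && oj == "maternal")) found <- TRUE
      }
    }
    if (found) {
      out[[length(out) + 1]] <- data.frame(proband_id = parts[1],
                                           gene = parts[2],
                                           stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(proband_id = character(0), gene = character(0)))
  }
  do.call(rbind, out)
}

# random small gene instance for oracle comparisons: one proband, one gene,
# up to 6 variants with random genotypes, frequencies and consequences
random_gene_instance <- function(gene = "G1", proband = "F1") {
  n <- sample(1:6, 1)
  rows <- lapply(seq_len(n), function(i) {
    trio_row(proband_id = proband, gene = gene, pos = 1000L + 10L * i,
             gt_p = sample(c("het", "hom_ref", "hom_alt"), 1,
                           prob = c(0.7, 0.2, 0.1)),
             gt_m = sample(c("hom_ref", "het"), 1),
             gt_f = sample(c("hom_ref", "het"), 1),
             population_af = sample(c(0.001, 0.005, 0.02, NA), 1,
                                    prob = c(0.4, 0.3, 0.2, 0.1)),
             consequence = sample(consequence_classes(), 1,
                                  prob = c(rep(0.16, 5), 0.1, 0.1)))
  })
  do.call(rbind, rows)
}

fixture_path <- function(f) system.file("extdata", f, package = "triotriage")
test_ontology <- function() read_obo(fixture_path("hpo_synthetic_subset.obo"))
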