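#' Quality and rarity thresholds for the trio screens
#'
#' The de novo screen is a transparent threshold rule: rare, high-quality
#' sites where the proband carries an alternate allele both parents lack.
#' Defaults echo conventional trio practice (10-read depth, GQ 20, at most
#' one stray parental alt read, 1% frequency ceiling); all are configurable.
#'
#' @param min_child_depth,min_parent_depth Minimum read depth in the proband
#'   and in each parent.
#' @param min_child_gq Minimum proband genotype quality.
#' @param max_parent_alt_reads Maximum alternate-supporting reads tolerated
#'   in a hom-ref parent.
#' @param max_af Population allele-frequency ceiling (the de novo screen uses
#'   `<=`, the inherited screens use strict `<` per the "<1%" rule).
#' @param restrict_to_coding Keep only sites whose consequence class is a
#'   coding/splicing class (everything but `other`).
#' @return A list of class `screen_thresholds`.
#' @export
screen_thresholds <- function(min_child_depth = 10, min_parent_depth = 10,
                              min_child_gq = 20, max_parent_alt_reads = 1,
                              max_af = 0.01, restrict_to_coding = TRUE) {
  stopifnot(min_child_depth >= 0, min_parent_depth >= 0, min_child_gq >= 0,
            max_parent_alt_reads >= 0, max_af >= 0, max_af <= 1)
  structure(list(min_child_depth = min_child_depth,
                 min_parent_depth = min_parent_depth,
                 min_child_gq = min_child_gq,
                 max_parent_alt_reads = max_parent_alt_reads,
                 max_af = max_af, restrict_to_coding = restrict_to_coding),
            class = "screen_thresholds")
}

.alt_gts <- c("het", "hom_alt", "hemi_alt")
.ref_gts <- c("hom_ref", "hemi_ref")

# AF gate: missing frequency is treated as rare (absent from reference
# databases implies rarity) but flagged for auditability
.af_pass <- function(af, max_af, strict = FALSE) {
  known <- !is.na(af)
  pass <- !known | (if (strict) af < max_af else af <= max_af)
  list(pass = pass, af_missing = !known)
}

#' Screen trios for candidate de novo variants
#'
#' A site is a candidate iff the proband carries at least one alternate
#' allele, both parents are called hom-ref (or hemi-ref) with at most
#' `max_parent_alt_reads` alternate-supporting reads, depth and genotype
#' quality thresholds are met, the population allele frequency is at or
#' below `max_af` (missing frequency passes but is flagged), and the
#' consequence is in coding/splicing scope. Designed for high sensitivity;
#' specificity is recovered downstream by [apply_validation()].
#'
#' Sites with a missing parental genotype are skipped, not silently dropped:
#' they are returned in the `skipped` attribute with a reason.
#'
#' @param trios Trio genotype table from [build_trio_genotypes()].
#' @param thresholds A [screen_thresholds()].
#' @return Data frame of candidates (class `denovo_candidates`): the trio
#'   columns plus `score` (min of child and parental GQ), `af_missing`,
#'   `validation_status` (`"candidate"`), `independent`, `mosaic_flag`,
#'   `mosaic_p`. Attribute `skipped` holds the skipped-site log.
#' @export
screen_denovo <- function(trios, thresholds = screen_thresholds()) {
  t <- trios
  missing_parent <- t$gt_m == "missing" | t$gt_f == "missing"
  relevant <- t$gt_p %in% .alt_gts
  skipped <- t[missing_parent & relevant,
               c("proband_id", "chrom", "pos", "ref", "alt"), drop = FALSE]
  if (nrow(skipped) > 0) {
    skipped$reason <- ifelse(
      t$gt_m[missing_parent & relevant] == "missing" &
        t$gt_f[missing_parent & relevant] == "missing",
      "both parental genotypes missing",
      ifelse(t$gt_m[missing_parent & relevant] == "missing",
             "maternal genotype missing", "paternal genotype missing"))
    message("screen_denovo: skipped ", nrow(skipped),
            " site(s) with missing parental genotypes")
  }
  af <- .af_pass(t$population_af, thresholds$max_af, strict = FALSE)
  keep <- relevant & !missing_parent &
    t$gt_m %in% "hom_ref" & t$gt_f %in% .ref_gts &
    t$ad_alt_m <= thresholds$max_parent_alt_reads &
    t$ad_alt_f <= thresholds$max_parent_alt_reads &
    t$dp_p >= thresholds$min_child_depth &
    t$dp_m >= thresholds$min_parent_depth &
    t$dp_f >= thresholds$min_parent_depth &
    t$gq_p >= thresholds$min_child_gq &
    af$pass
  if (thresholds$restrict_to_coding) keep <- keep & t$consequence != "other"
  out <- t[keep, , drop = FALSE]
  out$score <- pmin(out$gq_p, out$gq_m, out$gq_f)
  out$af_missing <- af$af_missing[keep]
  out$validation_status <- rep("candidate", nrow(out))
  out$independent <- rep(NA, nrow(out))
  out$mosaic_flag <- rep(NA, nrow(out))
  out$mosaic_p <- rep(NA_real_, nrow(out))
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("denovo_candidates", class(out))
  out
}

#' Apply external validation results to de novo candidates
#'
#' The high-sensitivity screen is followed by orthogonal validation
#' (capillary sequencing in the motivating design). Candidates marked
#' `refuted` are excluded from the returned set; `validated` candidates are
#' so labelled; candidates with no status remain `candidate`.
#'
#' @param candidates A `denovo_candidates` data frame.
#' @param statuses Data frame keyed by `proband_id`, `chrom`, `pos`, `ref`,
#'   `alt` with a `status` column in `candidate` / `validated` / `refuted`.
#' @return The candidates with `validation_status` updated and refuted rows
#'   removed. Statuses for unknown candidates trigger a warning and are
#'   ignored.
#' @export
apply_validation <- function(candidates, statuses) {
  if (nrow(statuses) > 0 &&
      !all(statuses$status %in% c("candidate", "validated", "refuted"))) {
    stop("validation status must be candidate/validated/refuted")
  }
  ck <- paste(candidates$proband_id, candidates$chrom, candidates$pos,
              candidates$ref, candidates$alt, sep = "\r")
  sk <- paste(statuses$proband_id, statuses$chrom, statuses$pos,
              statuses$ref, statuses$alt, sep = "\r")
  unknown <- !(sk %in% ck)
  if (any(unknown)) {
    warning(sum(unknown), " validation status(es) for unknown candidates ignored")
  }
  i <- match(ck, sk)
  st <- ifelse(is.na(i), "candidate", statuses$status[i])
  candidates$validation_status <- st
  out <- candidates[st != "refuted", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Subset de novo candidates to validated events
#' @param candidates A `denovo_candidates` data frame.
#' @return The validated rows.
#' @export
validated_denovos <- function(candidates) {
  candidates[candidates$validation_status == "validated", , drop = FALSE]
}

#' Collapse monozygotic-twin-shared de novo events into independent events
#'
#' Identical (chrom, pos, ref, alt) candidates observed in both members of a
#' monozygotic twin pair arose from a single mutational event and are counted
#' once: one twin's record keeps `independent = TRUE` (the lexicographically
#' first proband id, for determinism), the other is flagged `FALSE`.
#' Identical variants in unrelated probands remain separate independent
#' events.
#'
#' @param candidates A `denovo_candidates` data frame.
#' @param cohort A [cohort()] with the MZ twin links.
#' @return The candidates with the `independent` flag set.
#' @export
collapse_independent <- function(candidates, cohort) {
  candidates$independent <- TRUE
  tw <- mz_twin_pairs(cohort)
  for (r in seq_len(nrow(tw))) {
    a <- tw$twin1[r]; b <- tw$twin2[r]
    ka <- candidates$proband_id == a
    kb <- candidates$proband_id == b
    va <- paste(candidates$chrom, candidates$pos, candidates$ref,
                candidates$alt, sep = "\r")
    shared <- intersect(va[ka], va[kb])
    # representative: the twin with the smaller id keeps the event
    rep_twin <- min(a, b)
    dupe <- va %in% shared & candidates$proband_id %in% c(a, b) &
      candidates$proband_id != rep_twin
    candidates$independent[dupe] <- FALSE
  }
  candidates
}

#' Count independent de novo events
#' @param candidates Candidates after [collapse_independent()].
#' @return Number of rows flagged independent.
#' @export
n_independent <- function(candidates) sum(candidates$independent, na.rm = TRUE)

# exact two-sided binomial probability by pmf summation (p0 = expected
# alt fraction); the sum of all outcome probabilities not exceeding the
# observed outcome's probability
exact_binom_two_sided <- function(k, n, p0 = 0.5) {
  if (n == 0) return(NA_real_)
  d <- dbinom(0:n, n, p0)
  sum(d[d <= d[k + 1] * (1 + 1e-7)])
}

#' Flag candidate mosaic de novo events from allele balance
#'
#' A germline heterozygous event is expected at alternate-allele fraction
#' 0.5; post-zygotic (mosaic) events present in only a fraction of cells show
#' depleted alternate fractions. `mosaic_p` is the two-sided exact binomial
#' probability of the observed alternate count at expected fraction 0.5 given
#' `ad_ref + ad_alt` trials; the flag is set iff `mosaic_p < alpha` AND the
#' alternate fraction is below 0.5 (skews above 0.5 are not mosaicism).
#' Candidates with zero informative reads get `mosaic_p = NA` and an
#' unevaluable flag.
#'
#' @param candidates A `denovo_candidates` data frame.
#' @param alpha Significance level (default 0.01).
#' @return The candidates with `mosaic_p` and `mosaic_flag` filled in.
#' @export
flag_mosaic <- function(candidates, alpha = 0.01) {
  n <- candidates$ad_ref_p + candidates$ad_alt_p
  k <- candidates$ad_alt_p
  p <- vapply(seq_along(n), function(i) {
    if (n[i] == 0) NA_real_ else exact_binom_two_sided(k[i], n[i], 0.5)
  }, 0)
  frac <- ifelse(n > 0, k / n, NA_real_)
  candidates$mosaic_p <- p
  candidates$mosaic_flag <- !is.na(p) & p < alpha & frac < 0.5
  candidates$mosaic_flag[n == 0] <- NA
  candidates
}

#' Write de novo candidates as a TSV and an annotated VCF
#'
#' The VCF carries INFO flags `DENOVO`, `INDEPENDENT` and `MOSAIC`.
#'
#' @param candidates A `denovo_candidates` data frame.
#' @param tsv_path,vcf_path Output paths (`NULL` to skip either).
#' @return Invisibly, the paths written.
#' @export
write_denovo_candidates <- function(candidates, tsv_path = NULL, vcf_path = NULL) {
  if (!is.null(tsv_path)) {
    write.table(as.data.frame(candidates), tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(vcf_path)) {
    hdr <- c(
      "##fileformat=VCFv4.2",
      "##source=triotriage_denovo",
      "##INFO=<ID=DENOVO,Number=0,Type=Flag,Description=\"De novo candidate\">",
      "##INFO=<ID=INDEPENDENT,Number=0,Type=Flag,Description=\"Independent event after MZ-twin collapse\">",
      "##INFO=<ID=MOSAIC,Number=0,Type=Flag,Description=\"Suggestive mosaicism (depleted alt fraction)\">",
      "##INFO=<ID=PROBAND,Number=1,Type=String,Description=\"Proband id\">",
      "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
      paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            sep = "\t")
    )
    info <- paste0("DENOVO;PROBAND=", candidates$proband_id,
                   ";GENE=", candidates$gene,
                   ifelse(!is.na(candidates$independent) & candidates$independent,
                          ";INDEPENDENT", ""),
                   ifelse(!is.na(candidates$mosaic_flag) & candidates$mosaic_flag,
                          ";MOSAIC", ""))
    body <- paste(candidates$chrom, candidates$pos, ".", candidates$ref,
                  candidates$alt, ".", "PASS", info, sep = "\t")
    writeLines(c(hdr, body), vcf_path)
  }
  invisible(list(tsv = tsv_path, vcf = vcf_path))
}
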