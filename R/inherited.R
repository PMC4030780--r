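#' Screen for homozygous-recessive candidate genes
#'
#' A variant is a homozygous candidate iff the proband is hom-alt, both
#' parents are het carriers, the population frequency is strictly below
#' `max_af` (the "<1%" rarity rule; missing frequency passes but is
#' flagged), and the consequence class is functional
#' ([functional_consequences()]). Sites where a parent is hom-alt are
#' excluded (inconsistent with the unaffected-parent assumption) and logged
#' in the `excluded` attribute.
#'
#' @param trios Trio genotype table from [build_trio_genotypes()].
#' @param thresholds A [screen_thresholds()].
#' @return Data frame of candidate variants: `proband_id`, `gene`,
#'   `mode = "homozygous"`, site columns, `parental_origin = "both"`,
#'   `af_missing`.
#' @export
screen_homozygous <- function(trios, thresholds = screen_thresholds()) {
  t <- trios
  af <- .af_pass(t$population_af, thresholds$max_af, strict = TRUE)
  functional <- t$consequence %in% functional_consequences()
  parent_hom <- (t$gt_m == "hom_alt" | t$gt_f %in% c("hom_alt", "hemi_alt")) &
    t$gt_p == "hom_alt" & af$pass & functional
  if (any(parent_hom)) {
    message("screen_homozygous: excluded ", sum(parent_hom),
            " site(s) with a homozygous parent")
  }
  keep <- t$gt_p == "hom_alt" & t$gt_m == "het" & t$gt_f == "het" &
    af$pass & functional
  out <- data.frame(proband_id = t$proband_id[keep], gene = t$gene[keep],
                    mode = rep("homozygous", sum(keep)),
                    chrom = t$chrom[keep], pos = t$pos[keep],
                    ref = t$ref[keep], alt = t$alt[keep],
                    consequence = t$consequence[keep],
                    population_af = t$population_af[keep],
                    parental_origin = rep("both", sum(keep)),
                    af_missing = af$af_missing[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- t[parent_hom, c("proband_id", "chrom", "pos",
                                           "ref", "alt"), drop = FALSE]
  out
}

# parental origin of a proband het variant inferred from carriage:
# the unique carrying parent anchors the origin; both carrying -> ambiguous;
# neither -> apparent de novo (not inherited)
.het_origin <- function(gt_m, gt_f) {
  m <- gt_m %in% c("het", "hom_alt")
  f <- gt_f %in% c("het", "hom_alt", "hemi_alt")
  ifelse(m & f, "ambiguous",
         ifelse(m, "maternal", ifelse(f, "paternal", "none")))
}

#' Screen for compound-heterozygous candidate genes
#'
#' Without read-backed phasing, parental origin is inferred solely from
#' parental carriage: a proband het variant carried by exactly one parent is
#' confidently assigned to that parent; variants carried by both parents are
#' `ambiguous` and cannot anchor either haplotype. A gene is a candidate iff
#' it holds at least two distinct rare functional het variants in the
#' proband with at least one confidently maternal and one confidently
#' paternal among them (ambiguous variants are reported alongside but never
#' anchor). Optionally, a validated de novo variant in the same gene may
#' stand in for one side ("second hit" pairing); such candidates carry a
#' `mixed_origin_note`.
#'
#' @param trios Trio genotype table.
#' @param thresholds A [screen_thresholds()].
#' @param validated_denovo Optional `denovo_candidates` rows (validated) to
#'   allow de novo / inherited pairing.
#' @return Data frame of candidate variants: `proband_id`, `gene`,
#'   `mode = "compound_het"`, site columns, `parental_origin`
#'   (`maternal` / `paternal` / `ambiguous` / `de_novo`) and
#'   `mixed_origin_note`.
#' @export
screen_compound_het <- function(trios, thresholds = screen_thresholds(),
                                validated_denovo = NULL) {
  t <- trios
  af <- .af_pass(t$population_af, thresholds$max_af, strict = TRUE)
  functional <- t$consequence %in% functional_consequences()
  het <- t$gt_p == "het" & af$pass & functional &
    t$gt_m != "missing" & t$gt_f != "missing"
  tt <- t[het, , drop = FALSE]
  if (nrow(tt) == 0 && is.null(validated_denovo)) {
    return(.empty_comphet())
  }
  tt$parental_origin <- .het_origin(tt$gt_m, tt$gt_f)
  tt <- tt[tt$parental_origin != "none", , drop = FALSE]

  dn <- NULL
  if (!is.null(validated_denovo) && nrow(validated_denovo) > 0) {
    dn <- validated_denovo[validated_denovo$consequence %in%
                             functional_consequences(), , drop = FALSE]
  }

  out <- list()
  for (grp in split(seq_len(nrow(tt)), paste(tt$proband_id, tt$gene, sep = "\r"))) {
    g <- tt[grp, , drop = FALSE]
    pid <- g$proband_id[1]; gene <- g$gene[1]
    has_mat <- any(g$parental_origin == "maternal")
    has_pat <- any(g$parental_origin == "paternal")
    dn_g <- if (is.null(dn)) NULL else
      dn[dn$proband_id == pid & dn$gene == gene, , drop = FALSE]
    has_dn <- !is.null(dn_g) && nrow(dn_g) > 0
    classic <- has_mat && has_pat
    second_hit <- has_dn && (has_mat || has_pat)
    if (!classic && !second_hit) next
    note <- if (!classic && second_hit) "de_novo_second_hit" else ""
    rows <- data.frame(proband_id = pid, gene = gene, mode = "compound_het",
                       chrom = g$chrom, pos = g$pos, ref = g$ref, alt = g$alt,
                       consequence = g$consequence,
                       population_af = g$population_af,
                       parental_origin = g$parental_origin,
                       af_missing = is.na(g$population_af),
                       mixed_origin_note = note, stringsAsFactors = FALSE)
    if (second_hit && !classic) {
      rows <- rbind(rows, data.frame(
        proband_id = pid, gene = gene, mode = "compound_het",
        chrom = dn_g$chrom, pos = dn_g$pos, ref = dn_g$ref, alt = dn_g$alt,
        consequence = dn_g$consequence, population_af = dn_g$population_af,
        parental_origin = "de_novo", af_missing = is.na(dn_g$population_af),
        mixed_origin_note = note, stringsAsFactors = FALSE))
    }
    out[[length(out) + 1]] <- rows
  }
  if (length(out) == 0) return(.empty_comphet())
  res <- do.call(rbind, out)
  res <- res[order(res$proband_id, res$gene, res$chrom, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.empty_comphet <- function() {
  data.frame(proband_id = character(0), gene = character(0),
             mode = character(0), chrom = character(0), pos = integer(0),
             ref = character(0), alt = character(0),
             consequence = character(0), population_af = numeric(0),
             parental_origin = character(0), af_missing = logical(0),
             mixed_origin_note = character(0), stringsAsFactors = FALSE)
}

#' Screen for X-linked hemizygous candidate genes
#'
#' A variant is a hemizygous candidate iff the proband is male and
#' hemizygous-alt at a chrX non-PAR site, the mother is a het carrier, the
#' father is hemizygous-ref, the frequency is strictly below `max_af` and
#' the consequence is functional. Female probands are not screened here (the
#' homozygous / compound-het screens applied to chrX cover them) and are
#' logged.
#'
#' @param trios Trio genotype table.
#' @param thresholds A [screen_thresholds()].
#' @param cohort A [cohort()] (for proband sex).
#' @param par PAR boundaries, see [par_boundaries_grch37()].
#' @return Data frame of candidate variants with `mode = "hemizygous"` and
#'   `parental_origin = "maternal"`.
#' @export
screen_hemizygous <- function(trios, thresholds = screen_thresholds(),
                              cohort, par = par_boundaries_grch37()) {
  t <- trios
  sex <- member_sex(cohort, t$proband_id)
  xnp <- is_x_nonpar(t$chrom, t$pos, par)
  female_x <- xnp & sex == "female" & t$gt_p %in% c("het", "hom_alt")
  if (any(female_x)) {
    message("screen_hemizygous: ", sum(female_x),
            " female chrX site(s) not screened here (handled by the ",
            "recessive screens on X)")
  }
  af <- .af_pass(t$population_af, thresholds$max_af, strict = TRUE)
  keep <- sex == "male" & xnp & t$gt_p == "hemi_alt" & t$gt_m == "het" &
    t$gt_f == "hemi_ref" & af$pass &
    t$consequence %in% functional_consequences()
  out <- data.frame(proband_id = t$proband_id[keep], gene = t$gene[keep],
                    mode = rep("hemizygous", sum(keep)),
                    chrom = t$chrom[keep], pos = t$pos[keep],
                    ref = t$ref[keep], alt = t$alt[keep],
                    consequence = t$consequence[keep],
                    population_af = t$population_af[keep],
                    parental_origin = rep("maternal", sum(keep)),
                    af_missing = af$af_missing[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Run all three inherited screens
#'
#' @param trios Trio genotype table.
#' @param thresholds A [screen_thresholds()].
#' @param cohort A [cohort()].
#' @param validated_denovo Optional validated de novo candidates for
#'   second-hit compound-het pairing.
#' @param par PAR boundaries.
#' @return Data frame of all inherited candidate variants (columns as in the
#'   individual screens; `mixed_origin_note` is empty for non-compound-het
#'   modes).
#' @export
screen_inherited <- function(trios, thresholds = screen_thresholds(), cohort,
                             validated_denovo = NULL,
                             par = par_boundaries_grch37()) {
  hom <- screen_homozygous(trios, thresholds)
  ch <- screen_compound_het(trios, thresholds, validated_denovo)
  hemi <- screen_hemizygous(trios, thresholds, cohort, par)
  hom$mixed_origin_note <- if (nrow(hom)) "" else character(0)
  hemi$mixed_origin_note <- if (nrow(hemi)) "" else character(0)
  out <- rbind(hom[, names(ch)], ch, hemi[, names(ch)])
  out <- out[order(out$proband_id, out$mode, out$gene, out$chrom, out$pos), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Candidate genes per proband and inheritance mode
#'
#' Collapses per-variant screen output to one row per (proband, gene, mode),
#' the unit the cohort bookkeeping counts.
#'
#' @param inherited Output of [screen_inherited()] (or one of the screens).
#' @return Data frame `proband_id`, `gene`, `mode`, `n_variants`.
#' @export
inherited_candidate_genes <- function(inherited) {
  if (nrow(inherited) == 0) {
    return(data.frame(proband_id = character(0), gene = character(0),
                      mode = character(0), n_variants = integer(0)))
  }
  key <- paste(inherited$proband_id, inherited$gene, inherited$mode, sep = "\r")
  agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
  parts <- strsplit(agg$key, "\r", fixed = TRUE)
  out <- data.frame(proband_id = vapply(parts, `[`, "", 1),
                    gene = vapply(parts, `[`, "", 2),
                    mode = vapply(parts, `[`, "", 3),
                    n_variants = agg$Freq, stringsAsFactors = FALSE)
  out[order(out$proband_id, out$mode, out$gene), , drop = FALSE]
}
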