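#' Normalize a variant to its left-aligned, parsimonious representation
#'
#' Matching variant records across callers and individuals requires a
#' canonical representation: common trailing/leading bases are trimmed and
#' indels are shifted as far left as the reference context allows (the usual
#' vt/bcftools normalization convention, 1-based inclusive coordinates).
#' The operation is idempotent.
#'
#' @param pos 1-based position of the variant.
#' @param ref Reference allele string.
#' @param alt Alternate allele string (single alternate; split multiallelics
#'   first, see [split_multiallelic()]).
#' @param context Local reference sequence covering the locus (a single
#'   character string).
#' @param context_start 1-based position of the first base of `context`.
#' @return List with elements `pos`, `ref`, `alt`.
#' @export
normalize_variant <- function(pos, ref, alt, context, context_start = 1L) {
  if (ref == alt) stop("ref and alt alleles are identical")
  ctx_at <- function(p) {
    i <- p - context_start + 1L
    if (i < 1L || i > nchar(context)) {
      stop("reference context does not cover position ", p)
    }
    substr(context, i, i)
  }
  # check ref against context
  for (k in seq_len(nchar(ref))) {
    if (ctx_at(pos + k - 1L) != substr(ref, k, k)) {
      stop(sprintf("ref allele '%s' inconsistent with reference context at %d", ref, pos))
    }
  }
  repeat {
    changed <- FALSE
    # trim shared rightmost base; re-extend left if an allele empties
    while (nchar(ref) > 0 && nchar(alt) > 0 &&
           substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
      ref <- substr(ref, 1L, nchar(ref) - 1L)
      alt <- substr(alt, 1L, nchar(alt) - 1L)
      changed <- TRUE
      if (nchar(ref) == 0 || nchar(alt) == 0) {
        b <- ctx_at(pos - 1L)
        ref <- paste0(b, ref)
        alt <- paste0(b, alt)
        pos <- pos - 1L
      }
    }
    # trim shared leftmost base while both alleles keep >= 1 base
    while (nchar(ref) >= 2 && nchar(alt) >= 2 &&
           substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
      ref <- substr(ref, 2L, nchar(ref))
      alt <- substr(alt, 2L, nchar(alt))
      pos <- pos + 1L
      changed <- TRUE
    }
    if (!changed) break
  }
  list(pos = as.integer(pos), ref = ref, alt = alt)
}

# empty call-set skeleton shared by parsers and the simulator
callset_columns <- function() {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), gene = character(0), consequence = character(0),
             population_af = numeric(0), individual_id = character(0),
             gt = character(0), ad_ref = integer(0), ad_alt = integer(0),
             depth = integer(0), gq = integer(0), callers = character(0),
             discordant = logical(0), stringsAsFactors = FALSE)
}

gt_from_string <- function(gt) {
  out <- rep("missing", length(gt))
  gt <- gsub("|", "/", gt, fixed = TRUE)
  out[gt %in% c("0/0")] <- "hom_ref"
  out[gt %in% c("0/1", "1/0")] <- "het"
  out[gt %in% c("1/1")] <- "hom_alt"
  out[gt == "0"] <- "hemi_ref"
  out[gt == "1"] <- "hemi_alt"
  out
}

gt_to_string <- function(gt) {
  c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
    hemi_ref = "0", hemi_alt = "1", missing = "./.")[gt]
}

#' Split multiallelic VCF-style records into biallelic records
#'
#' All downstream screens operate per alternate allele. Genotypes are recoded
#' per alternate: two copies of the alternate give `hom_alt`, one copy gives
#' `het` (or `hemi_alt` for haploid calls), none gives `hom_ref`.
#'
#' @param chrom,pos,ref,alt Parallel vectors; `alt` may contain
#'   comma-separated alternates.
#' @param gt_raw Raw VCF GT strings (e.g. `"1/2"`).
#' @param ad Raw VCF AD strings (`ref,alt1,alt2,...`), or `NA`.
#' @return Data frame with one row per (record, alternate): columns `row`
#'   (input record index), `alt_index`, `alt`, `gt`, `ad_ref`, `ad_alt`.
#' @export
split_multiallelic <- function(chrom, pos, ref, alt, gt_raw, ad) {
  out <- vector("list", length(alt))
  for (i in seq_along(alt)) {
    alts <- strsplit(alt[i], ",", fixed = TRUE)[[1]]
    adv <- if (is.na(ad[i])) rep(NA_integer_, length(alts) + 1L) else
      suppressWarnings(as.integer(strsplit(ad[i], ",", fixed = TRUE)[[1]]))
    g <- gsub("|", "/", gt_raw[i], fixed = TRUE)
    alleles <- strsplit(g, "/", fixed = TRUE)[[1]]
    haploid <- length(alleles) == 1L
    rows <- lapply(seq_along(alts), function(k) {
      n_alt <- sum(alleles == as.character(k))
      gt <- if (any(alleles == ".")) "missing"
      else if (haploid) c("hemi_ref", "hemi_alt")[n_alt + 1L]
      else if (n_alt == 2L) "hom_alt"
      else if (n_alt == 1L) "het"
      else "hom_ref"
      data.frame(row = i, alt_index = k, alt = alts[k], gt = gt,
                 ad_ref = adv[1L], ad_alt = adv[k + 1L],
                 stringsAsFactors = FALSE)
    })
    out[[i]] <- do.call(rbind, rows)
  }
  do.call(rbind, out)
}

#' Read a per-individual, per-caller VCF into a call-set table
#'
#' Honors FORMAT fields GT, AD, DP, GQ (missing AD/GQ tolerated: depths fall
#' back to DP with unknown allele split, quality to 0) and the INFO fields
#' `GENE`, `CSQ` (consequence class) and `AF` (population allele frequency;
#' `.` or absent means unknown-presumed-rare). Multiallelic records are split
#' into biallelic records.
#'
#' @param path Path to an uncompressed VCF (v4.x) with a single sample column.
#' @param caller Caller label to record; defaults to the file's
#'   `##source=` header value or `"unknown"`.
#' @param individual_id Expected sample name; defaults to the VCF sample.
#' @return A call-set data frame (one row per site and alternate allele).
#' @export
read_caller_vcf <- function(path, caller = NULL, individual_id = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (is.null(caller)) {
    src <- grep("^##source=", v@meta, value = TRUE)
    caller <- if (length(src) > 0) sub("^##source=", "", src[1]) else "unknown"
  }
  sample <- colnames(v@gt)[2]
  if (is.null(individual_id)) individual_id <- sample
  if (!identical(sample, individual_id)) {
    stop("VCF sample '", sample, "' does not match expected individual '",
         individual_id, "'")
  }
  if (nrow(v@fix) == 0) {
    out <- callset_columns()
    return(out)
  }
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) {  # single-record VCFs drop to a named vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  info_field <- function(key) {
    x <- vcfR::extract.info(v, element = key)
    if (is.null(x)) rep(NA_character_, nrow(fix)) else x
  }
  gene <- info_field("GENE")
  csq <- info_field("CSQ")
  af_chr <- info_field("AF")
  af <- suppressWarnings(as.numeric(ifelse(af_chr %in% c(".", ""), NA, af_chr)))
  gt_raw <- vcfR::extract.gt(v, element = "GT")[, 1]
  ad_raw <- tryCatch(vcfR::extract.gt(v, element = "AD")[, 1],
                     error = function(e) rep(NA_character_, nrow(fix)))
  dp_raw <- tryCatch(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)[, 1],
                     error = function(e) rep(NA_real_, nrow(fix)))
  gq_raw <- tryCatch(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE)[, 1],
                     error = function(e) rep(NA_real_, nrow(fix)))

  sp <- split_multiallelic(fix[, "CHROM"], as.integer(fix[, "POS"]),
                           fix[, "REF"], fix[, "ALT"], gt_raw, ad_raw)
  i <- sp$row
  dp <- as.integer(dp_raw[i])
  ad_ref <- sp$ad_ref
  ad_alt <- sp$ad_alt
  # degrade gracefully when AD is absent: keep DP, leave allele split unknown
  ad_ref[is.na(ad_ref)] <- 0L
  ad_alt[is.na(ad_alt)] <- 0L
  dp[is.na(dp)] <- ad_ref[is.na(dp)] + ad_alt[is.na(dp)]
  gq <- as.integer(gq_raw[i])
  gq[is.na(gq)] <- 0L

  data.frame(chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
             ref = fix[i, "REF"], alt = sp$alt,
             gene = gene[i], consequence = csq[i], population_af = af[i],
             individual_id = individual_id,
             gt = sp$gt, ad_ref = ad_ref, ad_alt = ad_alt,
             depth = dp, gq = gq,
             callers = caller, discordant = FALSE,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a call-set table as a single-sample VCF
#'
#' @param callset A call-set data frame for one individual.
#' @param path Output path.
#' @param source_label Value for the `##source=` header line (the caller).
#' @return Invisibly, `path`.
#' @export
write_callset_vcf <- function(callset, path, source_label = "triotriage") {
  stopifnot(length(unique(callset$individual_id)) <= 1)
  ind <- if (nrow(callset) > 0) callset$individual_id[1] else "sample"
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=", source_label),
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Predicted protein consequence class\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Population allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", ind, sep = "\t")
  )
  if (nrow(callset) > 0) {
    cs <- callset[order(callset$chrom, callset$pos, callset$ref, callset$alt), ]
    info <- sprintf("GENE=%s;CSQ=%s;AF=%s", cs$gene, cs$consequence,
                    ifelse(is.na(cs$population_af), ".",
                           format(cs$population_af, scientific = FALSE, trim = TRUE)))
    smp <- sprintf("%s:%d,%d:%d:%d", gt_to_string(cs$gt),
                   cs$ad_ref, cs$ad_alt, cs$depth, cs$gq)
    body <- paste(cs$chrom, cs$pos, ".", cs$ref, cs$alt, ".", "PASS",
                  info, "GT:AD:DP:GQ", smp, sep = "\t")
  } else body <- character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write / read a call-set table as TSV
#' @param callset A call-set data frame.
#' @param path File path.
#' @return `write_callset_tsv` returns `path` invisibly; `read_callset_tsv`
#'   returns the call-set data frame.
#' @export
write_callset_tsv <- function(callset, path) {
  write.table(callset, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_callset_tsv
#' @export
read_callset_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(chrom = "character", individual_id = "character",
                            ref = "character", alt = "character"))
}

# severity ranking for the tie rule: ties resolve toward the less severe call
.gt_severity <- c(missing = 0, hom_ref = 1, hemi_ref = 1, het = 2,
                  hemi_alt = 3, hom_alt = 4)

#' Merge per-caller call sets for one individual
#'
#' Takes the union of sites across callers. Records identical on
#' (chrom, pos, ref, alt) collapse into one record whose `callers` field is
#' the union of caller labels. Genotype disagreements are resolved by
#' majority vote; two-way ties resolve toward the less severe genotype
#' (e.g. het over hom_alt) and the record is flagged `discordant` for
#' downstream quality filtering. Depth/quality fields are taken from the
#' caller record supporting the winning genotype with the highest depth.
#'
#' @param callsets List of call-set data frames, one per caller, all for the
#'   same individual and already normalized (see [normalize_variant()]).
#' @return A unified call-set data frame.
#' @export
merge_caller_calls <- function(callsets) {
  callsets <- callsets[vapply(callsets, nrow, 0L) > 0]
  if (length(callsets) == 0) return(callset_columns())
  all <- do.call(rbind, callsets)
  inds <- unique(all$individual_id)
  if (length(inds) > 1) {
    stop("call sets belong to different individuals: ", paste(inds, collapse = ", "))
  }
  kf <- factor(paste(all$chrom, all$pos, all$ref, all$alt, sep = "\r"))
  gts <- c("hom_ref", "hemi_ref", "het", "hemi_alt", "hom_alt")  # severity asc
  tab <- unclass(table(kf, factor(all$gt, levels = gts)))
  any_call <- rowSums(tab) > 0
  win <- gts[max.col(tab, ties.method = "first")]  # tie -> least severe
  win[!any_call] <- "missing"
  discord <- rowSums(tab > 0) > 1
  # representative record: supports the winning genotype, highest depth
  ki <- as.integer(kf)
  pref <- all$gt == win[ki]
  ord <- order(ki, !pref, -all$depth)
  out <- all[ord[!duplicated(ki[ord])], , drop = FALSE]  # one row per level
  out$gt <- win
  out$discordant <- discord
  out$callers <- vapply(split(all$callers, kf), function(x) {
    paste(sort(unique(unlist(strsplit(x, ";", fixed = TRUE)))), collapse = ";")
  }, "")
  out <- out[order(out$chrom, out$pos, out$ref, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble per-trio genotype records from unified per-individual call sets
#'
#' Joins the proband's, mother's and father's unified call sets on
#' (chrom, pos, ref, alt) into one wide table per trio, the unit all screens
#' consume. An individual lacking any record at a site is coded `missing`
#' there (the screens then skip and log such sites); call sets written by the
#' simulator carry explicit hom-ref records at all cohort loci, so `missing`
#' genuinely means "not assayed".
#'
#' @param callsets Named list of unified call-set data frames, one per
#'   individual (names are individual ids), as from [merge_caller_calls()].
#' @param cohort A [cohort()] object.
#' @return Data frame with one row per (proband, site): site columns plus
#'   `gt_p`, `ad_ref_p`, `ad_alt_p`, `dp_p`, `gq_p` for the proband and the
#'   analogous `_m` / `_f` columns for mother and father.
#' @export
build_trio_genotypes <- function(callsets, cohort) {
  out <- list()
  for (pid in probands(cohort)) {
    par <- trio_parents(cohort, pid)
    cs_p <- callsets[[pid]]
    cs_m <- callsets[[par$mother]]
    cs_f <- callsets[[par$father]]
    if (is.null(cs_p)) next
    if (is.null(cs_m)) cs_m <- callset_columns()
    if (is.null(cs_f)) cs_f <- callset_columns()

    keyify <- function(cs) paste(cs$chrom, cs$pos, cs$ref, cs$alt, sep = "\r")
    keys <- unique(c(keyify(cs_p), keyify(cs_m), keyify(cs_f)))
    pick <- function(cs, keys) {
      i <- match(keys, keyify(cs))
      data.frame(gt = ifelse(is.na(i), "missing", cs$gt[i]),
                 ad_ref = ifelse(is.na(i), 0L, cs$ad_ref[i]),
                 ad_alt = ifelse(is.na(i), 0L, cs$ad_alt[i]),
                 dp = ifelse(is.na(i), 0L, cs$depth[i]),
                 gq = ifelse(is.na(i), 0L, cs$gq[i]),
                 stringsAsFactors = FALSE)
    }
    # site annotation from whichever member carries the record
    site_from <- function(keys) {
      for_one <- function(cs) match(keys, keyify(cs))
      ip <- for_one(cs_p); im <- for_one(cs_m); if_ <- for_one(cs_f)
      src <- ifelse(!is.na(ip), "p", ifelse(!is.na(im), "m", "f"))
      idx <- ifelse(!is.na(ip), ip, ifelse(!is.na(im), im, if_))
      take <- function(col) {
        v <- vector(mode = class(cs_p[[col]]), length = length(keys))
        for (s in c("p", "m", "f")) {
          cs <- switch(s, p = cs_p, m = cs_m, f = cs_f)
          sel <- src == s
          v[sel] <- cs[[col]][idx[sel]]
        }
        v
      }
      data.frame(chrom = take("chrom"), pos = take("pos"), ref = take("ref"),
                 alt = take("alt"), gene = take("gene"),
                 consequence = take("consequence"),
                 population_af = take("population_af"),
                 stringsAsFactors = FALSE)
    }
    site <- site_from(keys)
    p <- pick(cs_p, keys); m <- pick(cs_m, keys); f <- pick(cs_f, keys)
    fam <- cohort$members$family_id[match(pid, cohort$members$individual_id)]
    out[[pid]] <- data.frame(
      family_id = fam, proband_id = pid, site,
      gt_p = p$gt, ad_ref_p = p$ad_ref, ad_alt_p = p$ad_alt, dp_p = p$dp, gq_p = p$gq,
      gt_m = m$gt, ad_ref_m = m$ad_ref, ad_alt_m = m$ad_alt, dp_m = m$dp, gq_m = m$gq,
      gt_f = f$gt, ad_ref_f = f$ad_ref, ad_alt_f = f$ad_alt, dp_f = f$dp, gq_f = f$gq,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(NULL)
  rownames(res) <- NULL
  res[order(res$proband_id, res$chrom, res$pos, res$ref, res$alt), , drop = FALSE]
}
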