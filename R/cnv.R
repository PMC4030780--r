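#' Read a CNV call table
#'
#' BED-like TSV with header: `call_id`, `family_id`, `proband_id`, `chrom`,
#' `start`, `end` (1-based inclusive), `cnv_type` (`deletion` /
#' `duplication`), `confidence`, and per-trio-member carrier booleans
#' `proband_carrier`, `mother_carrier`, `father_carrier` (NA allowed for
#' unknown parental status).
#'
#' @param path Path to the TSV file.
#' @return Data frame of CNV calls.
#' @export
read_cnv_table <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(chrom = "character"))
  required <- c("chrom", "start", "end", "cnv_type", "confidence",
                "proband_id", "proband_carrier", "mother_carrier",
                "father_carrier")
  miss <- setdiff(required, names(x))
  if (length(miss) > 0) stop("CNV table lacks columns: ", paste(miss, collapse = ", "))
  x
}

#' Read a BED-like interval table (common-CNV catalog or gene model)
#'
#' Expects a header with at least `chrom`, `start`, `end`; gene models add
#' `gene` and `biotype`.
#'
#' @param path Path to the TSV file.
#' @return Data frame of intervals.
#' @export
read_interval_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, colClasses = c(chrom = "character"))
}

.cnv_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
}

#' Genes overlapped by each CNV call
#'
#' @param calls CNV call data frame.
#' @param gene_model Gene model data frame (`chrom`, `start`, `end`, `gene`,
#'   `biotype`).
#' @param protein_coding_only Restrict to protein-coding genes.
#' @return Character vector (length `nrow(calls)`) of semicolon-joined gene
#'   symbols, `""` where none overlap.
#' @export
cnv_overlapping_genes <- function(calls, gene_model, protein_coding_only = TRUE) {
  gm <- gene_model
  if (protein_coding_only && !is.null(gm$biotype)) {
    gm <- gm[gm$biotype == "protein_coding", , drop = FALSE]
  }
  if (nrow(calls) == 0) return(character(0))
  if (nrow(gm) == 0) return(rep("", nrow(calls)))
  # the two range sets may legitimately name disjoint chromosomes
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(.cnv_granges(calls), .cnv_granges(gm)))
  out <- rep("", nrow(calls))
  if (length(hits) > 0) {
    by_call <- split(gm$gene[S4Vectors::subjectHits(hits)],
                     S4Vectors::queryHits(hits))
    for (q in names(by_call)) {
      out[as.integer(q)] <- paste(sort(unique(by_call[[q]])), collapse = ";")
    }
  }
  out
}

# does any catalog interval reach the reciprocal-overlap fraction with a call?
.common_overlap <- function(calls, catalog, fraction) {
  if (nrow(calls) == 0 || nrow(catalog) == 0) return(rep(FALSE, nrow(calls)))
  q <- .cnv_granges(calls); s <- .cnv_granges(catalog)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(q, s))
  out <- rep(FALSE, nrow(calls))
  if (length(hits) == 0) return(out)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(IRanges::ranges(q)[qh],
                                           IRanges::ranges(s)[sh]))
  recip <- ov / IRanges::width(IRanges::ranges(q)[qh]) >= fraction &
    ov / IRanges::width(IRanges::ranges(s)[sh]) >= fraction
  out[unique(qh[recip])] <- TRUE
  out
}

#' Assign a mode of inheritance to CNV calls
#'
#' Using per-trio carrier status: `de_novo` iff the proband carries the CNV
#' and neither parent does; `x_linked` iff the call is on chrX in a male
#' proband inheriting from a carrier mother (de novo events on X are
#' reported as `de_novo`, which is also X-linked-consistent); `recessive`
#' iff a biallelic-loss configuration (a deletion carried by the proband and
#' both parents); anything else — including dominant-inconsistent carriage
#' from an unaffected parent — is `other`. Missing parental carrier status
#' yields `other` and is logged.
#'
#' @param calls CNV call data frame (see [read_cnv_table()]).
#' @param cohort A [cohort()] (for proband sex).
#' @return Character vector of modes, one per call.
#' @export
assign_cnv_mode <- function(calls, cohort) {
  if (nrow(calls) == 0) return(character(0))
  sex <- member_sex(cohort, calls$proband_id)
  p <- calls$proband_carrier; m <- calls$mother_carrier; f <- calls$father_carrier
  unknown <- is.na(m) | is.na(f) | is.na(p)
  if (any(unknown)) {
    message("assign_cnv_mode: ", sum(unknown),
            " call(s) with missing carrier status assigned mode 'other'")
  }
  on_x <- calls$chrom %in% c("X", "chrX")
  mode <- rep("other", nrow(calls))
  ok <- !unknown
  mode[ok & p & !m & !f] <- "de_novo"
  mode[ok & p & m & !f & on_x & sex == "male"] <- "x_linked"
  mode[ok & p & m & f & calls$cnv_type == "deletion"] <- "recessive"
  mode
}

#' Filter CNV calls by confidence, common overlap, gene overlap and mode
#'
#' Keeps a call iff (i) `confidence >= min_confidence`; (ii) no common-CNV
#' catalog interval reaches `reciprocal_overlap` with it; (iii) it overlaps
#' at least one protein-coding gene; and (iv) its inheritance mode (see
#' [assign_cnv_mode()]) is `de_novo`, `recessive` or `x_linked`. The four
#' conditions are independent and commute.
#'
#' @param calls CNV call data frame.
#' @param common_catalog Interval data frame of common CNVs.
#' @param gene_model Gene model data frame.
#' @param cohort A [cohort()].
#' @param min_confidence Minimum confidence score (default 10, calibrated to
#'   sit above the simulator's noise-score distribution).
#' @param reciprocal_overlap Reciprocal-overlap fraction for a common-CNV
#'   match (default 0.5, the field's convention).
#' @return The kept calls with added columns `genes` (semicolon-joined) and
#'   `mode`.
#' @export
filter_cnvs <- function(calls, common_catalog, gene_model, cohort,
                        min_confidence = 10, reciprocal_overlap = 0.5) {
  if (nrow(calls) > 0) {
    bad <- which(is.na(calls$start) | is.na(calls$end) |
                   calls$start > calls$end | calls$start < 1)
    if (length(bad) > 0) stop("malformed CNV interval at record ", bad[1])
  }
  genes <- cnv_overlapping_genes(calls, gene_model, protein_coding_only = TRUE)
  common <- .common_overlap(calls, common_catalog, reciprocal_overlap)
  mode <- assign_cnv_mode(calls, cohort)
  keep <- calls$confidence >= min_confidence & !common & genes != "" &
    mode %in% c("de_novo", "recessive", "x_linked")
  out <- calls[keep, , drop = FALSE]
  out$genes <- genes[keep]
  out$mode <- mode[keep]
  rownames(out) <- NULL
  out
}

#' Span of a CNV call
#'
#' 1-based inclusive arithmetic: `bp = end - start + 1`; `kb` is `bp / 1000`
#' rounded half-up to the nearest integer.
#'
#' @param start,end 1-based inclusive interval bounds (vectors allowed).
#' @return List with numeric vectors `bp` and `kb`.
#' @export
cnv_span <- function(start, end) {
  if (any(end < start)) stop("end < start in CNV interval")
  bp <- end - start + 1
  list(bp = bp, kb = round_half_up(bp / 1000))
}
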