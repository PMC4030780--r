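test_that("pedigree parsing handles trios, quads and twin links", {
  ped <- tempfile(fileext = ".ped")
  writeLines(c("FAM1\tF1\tP1\tM1\t1\t2\t.",
               "FAM1\tM1\t0\t0\t2\t1\t.",
               "FAM1\tP1\t0\t0\t1\t1\t."), ped)
  co <- read_pedigree(ped)
  expect_equal(nrow(co$members), 3)
  expect_equal(probands(co), "F1")
  expect_equal(co$members$role[co$members$individual_id == "M1"], "mother")

  # quad: two affected siblings sharing parents
  writeLines(c("FAM1\tF1\tP1\tM1\t2\t2\t.",
               "FAM1\tF2\tP1\tM1\t2\t2\t.",
               "FAM1\tM1\t0\t0\t2\t1\t.",
               "FAM1\tP1\t0\t0\t1\t1\t."), ped)
  quad <- read_pedigree(ped)
  expect_equal(length(probands(quad)), 2)
  expect_equal(nrow(quad$members), 4)

  # twin links are symmetric and surface as one pair
  writeLines(c("FAM1\tF1\tP1\tM1\t1\t2\tMZ:F2",
               "FAM1\tF2\tP1\tM1\t1\t2\tMZ:F1",
               "FAM1\tM1\t0\t0\t2\t1\t.",
               "FAM1\tP1\t0\t0\t1\t1\t."), ped)
  tw <- mz_twin_pairs(read_pedigree(ped))
  expect_equal(nrow(tw), 1)
  expect_setequal(c(tw$twin1, tw$twin2), c("F1", "F2"))
})

test_that("pedigree structural errors are caught and name the family", {
  ped <- tempfile(fileext = ".ped")
  writeLines(c("FAM9\tF1\tPX\tM1\t1\t2\t.",
               "FAM9\tM1\t0\t0\t2\t1\t."), ped)
  expect_error(read_pedigree(ped), "FAM9.*father 'PX'")

  writeLines(c("FAM1\tF1\tP1\tM1\t1\t2\t.",
               "FAM1\tF1\tP1\tM1\t1\t2\t.",
               "FAM1\tM1\t0\t0\t2\t1\t.",
               "FAM1\tP1\t0\t0\t1\t1\t."), ped)
  expect_error(read_pedigree(ped), "duplicate")

  # asymmetric twin link
  writeLines(c("FAM1\tF1\tP1\tM1\t1\t2\tMZ:F2",
               "FAM1\tF2\tP1\tM1\t1\t2\t.",
               "FAM1\tM1\t0\t0\t2\t1\t.",
               "FAM1\tP1\t0\t0\t1\t1\t."), ped)
  expect_error(read_pedigree(ped), "symmetric")
})

test_that("pedigree and phenotype tables round-trip through write/read", {
  co <- small_cohort(n_trios = 2, twins = TRUE)
  ped <- tempfile(fileext = ".ped")
  write_pedigree(co, ped)
  co2 <- read_pedigree(ped)
  expect_equal(co2$members, co$members)
  expect_equal(probands(co2), probands(co))

  ph <- data.frame(proband_id = c("F1", "F2"),
                   source = c("ultrasound", "postmortem"),
                   hpo_terms = I(list(c("HP:9010001", "HP:9020001"),
                                      "HP:9030001")),
                   stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".tsv")
  write_phenotypes(ph, f)
  ph2 <- read_phenotypes(f)
  expect_equal(ph2$proband_id, ph$proband_id)
  expect_equal(as.list(ph2$hpo_terms), as.list(ph$hpo_terms),
               ignore_attr = TRUE)
})

test_that("phenotype parsing validates and deduplicates terms", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("proband_id\thpo_terms\tsource",
               "F23\tHP:0002652;HP:0001166\tultrasound"), f)
  ph <- read_phenotypes(f)
  expect_length(ph$hpo_terms[[1]], 2)

  writeLines(c("proband_id\thpo_terms\tsource",
               "F1\tHP:9010001;HP:9010001;HP:9010002\tultrasound"), f)
  expect_length(read_phenotypes(f)$hpo_terms[[1]], 2)

  writeLines(c("proband_id\thpo_terms\tsource",
               "F1\tHP:9010001\tultrasound",
               "F2\tHP:12\tultrasound"), f)
  expect_error(read_phenotypes(f), "line 3.*HP:12")
})

test_that("terms grouped by higher-order category tally multi-system probands", {
  # a proband with many distinct skeletal anomalies tallies >= 8 under the
  # skeletal category when terms are lifted through the ontology
  ont <- test_ontology()
  terms <- c("HP:9010001", "HP:9010002", "HP:9010003", "HP:9010004",
             "HP:9010005", "HP:9010006", "HP:9010007", "HP:9010008")
  in_skeletal <- vapply(terms, function(t) "HP:9000010" %in% term_closure(t, ont),
                        TRUE)
  expect_gte(sum(in_skeletal), 8)
})

test_that("caller merge unions callers and resolves discordance by majority", {
  mk <- function(caller, gt = "het", pos = 100L) {
    data.frame(chrom = "1", pos = pos, ref = "A", alt = "G", gene = "G1",
               consequence = "non_synonymous", population_af = 0.001,
               individual_id = "F1", gt = gt, ad_ref = 30L, ad_alt = 30L,
               depth = 60L, gq = 99L, callers = caller, discordant = FALSE,
               stringsAsFactors = FALSE)
  }
  # identical call from all three callers collapses to one record
  m <- merge_caller_calls(list(mk("samtools_like"), mk("gatk_like"), mk("dindel_like")))
  expect_equal(nrow(m), 1)
  expect_equal(m$callers, "dindel_like;gatk_like;samtools_like")
  expect_false(m$discordant)

  # disjoint single-call sets union to three records with one caller each
  m2 <- merge_caller_calls(list(mk("samtools_like", pos = 1L),
                                mk("gatk_like", pos = 2L),
                                mk("dindel_like", pos = 3L)))
  expect_equal(nrow(m2), 3)
  expect_setequal(m2$callers, c("samtools_like", "gatk_like", "dindel_like"))

  # het by two callers, hom_alt by one: majority keeps het, flags discordance
  m3 <- merge_caller_calls(list(mk("samtools_like"), mk("gatk_like"),
                                mk("dindel_like", gt = "hom_alt")))
  expect_equal(m3$gt, "het")
  expect_true(m3$discordant)

  # two-way tie resolves toward the less severe genotype
  m4 <- merge_caller_calls(list(mk("samtools_like"), mk("gatk_like", gt = "hom_alt")))
  expect_equal(m4$gt, "het")
  expect_true(m4$discordant)

  expect_error(merge_caller_calls(list(mk("a"), {
    x <- mk("b"); x$individual_id <- "F2"; x
  })), "different individuals")
})

test_that("caller merge is order-independent and bounded in size", {
  set.seed(41)
  mk_set <- function(caller, n) {
    data.frame(chrom = "1", pos = sample(1:30, n), ref = "A", alt = "G",
               gene = "G1", consequence = "non_synonymous",
               population_af = 0.001, individual_id = "F1",
               gt = sample(c("het", "hom_alt", "hom_ref"), n, replace = TRUE),
               ad_ref = 30L, ad_alt = 30L, depth = sample(40:80, n),
               gq = 99L, callers = caller, discordant = FALSE,
               stringsAsFactors = FALSE)
  }
  for (rep in 1:10) {
    sets <- list(mk_set("samtools_like", sample(5:15, 1)),
                 mk_set("gatk_like", sample(5:15, 1)),
                 mk_set("dindel_like", sample(5:15, 1)))
    m <- merge_caller_calls(sets)
    expect_lte(nrow(m), sum(vapply(sets, nrow, 0L)))
    expect_gte(nrow(m), max(vapply(sets, nrow, 0L)))
    for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
      expect_identical(merge_caller_calls(sets[perm]), m)
    }
  }
})

test_that("variant normalization left-aligns, trims and is idempotent", {
  ctx <- "GGGCAAAAACTT"  # positions 1..12; A-run at 5..9

  # SNV already minimal
  expect_equal(normalize_variant(3, "G", "T", ctx),
               list(pos = 3L, ref = "G", alt = "T"))
  # right-shifted single-A deletion left-aligns to the run anchor
  expect_equal(normalize_variant(8, "AA", "A", ctx),
               list(pos = 4L, ref = "CA", alt = "C"))
  # padded representation trims to parsimony
  expect_equal(normalize_variant(4, "CAA", "CA", ctx),
               list(pos = 4L, ref = "CA", alt = "C"))
  # idempotence
  n1 <- normalize_variant(8, "AA", "A", ctx)
  expect_equal(normalize_variant(n1$pos, n1$ref, n1$alt, ctx), n1)
  # ref inconsistent with context
  expect_error(normalize_variant(3, "T", "A", ctx), "inconsistent")
})

test_that("all representations of the same edit normalize identically", {
  # brute force: every (pos, ref, alt) pair that produces the same edited
  # sequence must normalize to the same record
  ctx <- "GGGCAAAAACTT"
  apply_edit <- function(pos, ref, alt) {
    paste0(substr(ctx, 1, pos - 1), alt,
           substr(ctx, pos + nchar(ref), nchar(ctx)))
  }
  target <- apply_edit(4, "CA", "C")  # delete one A from the run
  reprs <- list()
  for (pos in 1:12) {
    for (len_r in 1:4) {
      if (pos + len_r - 1 > 12) next
      ref <- substr(ctx, pos, pos + len_r - 1)
      for (len_a in 0:4) {
        if (len_a == 0 && pos == 1) next  # needs left anchor
        alts <- if (len_a == 0) "" else
          apply(expand.grid(rep(list(c("A", "C", "G", "T")), len_a)), 1, paste,
                collapse = "")
        for (alt in alts) {
          if (alt == ref) next
          if (identical(apply_edit(pos, ref, alt), target) && nzchar(alt)) {
            reprs[[length(reprs) + 1]] <- list(pos = pos, ref = ref, alt = alt)
          }
        }
      }
    }
  }
  expect_gt(length(reprs), 3)
  norm <- lapply(reprs, function(r) normalize_variant(r$pos, r$ref, r$alt, ctx))
  expect_true(all(vapply(norm, identical, TRUE, norm[[1]])))
})

test_that("multiallelic records split into per-alternate biallelic records", {
  sp <- split_multiallelic("1", 100L, "A", "G,T", "1/2", "10,20,30")
  expect_equal(nrow(sp), 2)
  expect_equal(sp$gt, c("het", "het"))
  expect_equal(sp$ad_alt, c(20L, 30L))
  sp2 <- split_multiallelic("1", 100L, "A", "G,T", "2/2", "5,0,55")
  expect_equal(sp2$gt, c("hom_ref", "hom_alt"))
})

test_that("VCF write/read round-trips a call set", {
  cs <- data.frame(chrom = c("1", "X"), pos = c(100L, 200L),
                   ref = c("A", "T"), alt = c("G", "C"),
                   gene = c("G1", "G2"),
                   consequence = c("non_synonymous", "synonymous"),
                   population_af = c(0.001, NA),
                   individual_id = "F1",
                   gt = c("het", "hemi_alt"), ad_ref = c(30L, 0L),
                   ad_alt = c(28L, 44L), depth = c(58L, 44L),
                   gq = c(99L, 80L), callers = "gatk_like",
                   discordant = FALSE, stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".vcf")
  write_callset_vcf(cs, f, source_label = "gatk_like")
  back <- read_caller_vcf(f)
  expect_equal(back$gt, cs$gt)
  expect_equal(back$ad_alt, cs$ad_alt)
  expect_equal(back$gq, cs$gq)
  expect_equal(back$callers, rep("gatk_like", 2))
  expect_true(is.na(back$population_af[2]))
  expect_equal(back$population_af[1], 0.001, tolerance = 1e-6)

  # single-record and record-free VCFs parse too
  write_callset_vcf(cs[1, ], f)
  one <- read_caller_vcf(f)
  expect_equal(nrow(one), 1)
  expect_equal(one$gt, "het")
  write_callset_vcf(cs[0, ], f)
  expect_equal(nrow(read_caller_vcf(f)), 0)
})
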