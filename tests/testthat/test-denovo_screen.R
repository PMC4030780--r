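test_that("the de novo screen follows its definitional rules", {
  # proband hom-ref: nothing to call
  expect_equal(nrow(screen_denovo(trio_row(gt_p = "hom_ref"))), 0)
  # inherited het (mother het): not de novo
  expect_equal(nrow(screen_denovo(trio_row(gt_m = "het"))), 0)
  # clean trio: candidate
  cand <- screen_denovo(trio_row())
  expect_equal(nrow(cand), 1)
  expect_equal(cand$validation_status, "candidate")
  expect_equal(cand$score, 99)
  # hemizygous de novo in a male X also qualifies
  expect_equal(nrow(screen_denovo(
    trio_row(chrom = "X", gt_p = "hemi_alt", gt_f = "hemi_ref"))), 1)
})

test_that("quality, parental-support and frequency gates apply", {
  th <- screen_thresholds()
  expect_equal(nrow(screen_denovo(trio_row(dp = 5), th)), 0)
  expect_equal(nrow(screen_denovo(trio_row(gq = 10), th)), 0)
  expect_equal(nrow(screen_denovo(trio_row(ad_alt_m = 3), th)), 0)
  expect_equal(nrow(screen_denovo(trio_row(population_af = 0.05), th)), 0)
  expect_equal(nrow(screen_denovo(trio_row(consequence = "other"), th)), 0)
  # synonymous is in coding scope for the de novo screen
  expect_equal(nrow(screen_denovo(trio_row(consequence = "synonymous"), th)), 1)
  # missing frequency passes but is flagged
  cand <- screen_denovo(trio_row(population_af = NA), th)
  expect_equal(nrow(cand), 1)
  expect_true(cand$af_missing)
})

test_that("sites with missing parental genotypes are skipped and logged", {
  trios <- rbind(trio_row(pos = 1L), trio_row(pos = 2L, gt_m = "missing"))
  expect_message(cand <- screen_denovo(trios), "skipped 1")
  expect_equal(nrow(cand), 1)
  sk <- attr(cand, "skipped")
  expect_equal(sk$pos, 2L)
  expect_match(sk$reason, "maternal")
})

test_that("no candidate ever carries a parental alternate call", {
  sim <- simulate_cohort(sim_config(n_trios = 8, n_quads = 0, n_sites = 80,
                                    seed = 13))
  trios <- suppressMessages(sim_trios(sim))
  cand <- suppressMessages(screen_denovo(trios))
  expect_false(any(cand$gt_m %in% c("het", "hom_alt", "hemi_alt")))
  expect_false(any(cand$gt_f %in% c("het", "hom_alt", "hemi_alt")))
})

test_that("relaxing thresholds never shrinks the candidate set", {
  sim <- simulate_cohort(sim_config(n_trios = 6, n_quads = 0, n_sites = 60,
                                    seed = 17))
  trios <- suppressMessages(sim_trios(sim))
  key <- function(x) paste(x$proband_id, x$chrom, x$pos, x$ref, x$alt)
  base <- screen_thresholds()
  strict <- suppressMessages(screen_denovo(trios, base))
  relaxations <- list(
    screen_thresholds(min_child_depth = 0),
    screen_thresholds(min_parent_depth = 0),
    screen_thresholds(min_child_gq = 0),
    screen_thresholds(max_parent_alt_reads = 5),
    screen_thresholds(max_af = 0.2),
    screen_thresholds(restrict_to_coding = FALSE)
  )
  for (th in relaxations) {
    relaxed <- suppressMessages(screen_denovo(trios, th))
    expect_true(all(key(strict) %in% key(relaxed)))
  }
})

test_that("validation statuses gate the downstream de novo set", {
  trios <- do.call(rbind, lapply(1:4, function(i) trio_row(pos = i * 10L)))
  cand <- screen_denovo(trios)
  expect_equal(nrow(cand), 4)

  # empty status table: everything stays a candidate
  empty <- data.frame(proband_id = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), status = character(0))
  expect_equal(apply_validation(cand, empty)$validation_status,
               rep("candidate", 4))

  st <- data.frame(proband_id = "F1", chrom = "1", pos = c(10L, 20L, 30L),
                   ref = "A", alt = "G",
                   status = c("validated", "refuted", "validated"),
                   stringsAsFactors = FALSE)
  out <- apply_validation(cand, st)
  expect_equal(nrow(out), 3)  # refuted excluded
  expect_equal(nrow(validated_denovos(out)), 2)

  # all refuted -> empty validated set
  st$status <- "refuted"
  expect_equal(nrow(apply_validation(cand, st)), 1)  # only the unknown pos=40
  # status for an unknown candidate warns and is ignored
  st2 <- data.frame(proband_id = "F9", chrom = "1", pos = 999L, ref = "A",
                    alt = "G", status = "validated", stringsAsFactors = FALSE)
  expect_warning(apply_validation(cand, st2), "unknown")
})

test_that("the screen-then-validate funnel removes exactly the false calls", {
  # noisy cohort: the high-sensitivity screen over-calls; truth-driven
  # validation must cut the set back to the true de novo events it found
  sim <- simulate_cohort(sim_config(n_trios = 10, n_quads = 0, n_sites = 100,
                                    genotype_error = 0.01, seed = 19))
  trios <- suppressMessages(sim_trios(sim))
  cand <- suppressMessages(screen_denovo(trios))
  tk <- with(sim$truth[sim$truth$class %in% c("de_novo", "mosaic_de_novo"), ],
             paste(proband_id, chrom, pos, ref, alt))
  ck <- paste(cand$proband_id, cand$chrom, cand$pos, cand$ref, cand$alt)
  expect_gt(nrow(cand), sum(ck %in% tk))  # over-calling happened
  val <- apply_validation(cand, truth_validation_table(cand, sim$truth))
  vk <- with(validated_denovos(val), paste(proband_id, chrom, pos, ref, alt))
  expect_setequal(vk, intersect(ck, tk))
})

test_that("twin-aware collapse counts MZ-shared events once", {
  co <- small_cohort(n_trios = 2, twins = TRUE)
  # identical variant in both twins + private events elsewhere
  cand <- rbind(trio_row(proband_id = "T1", family_id = "FAM3", pos = 500L),
                trio_row(proband_id = "T2", family_id = "FAM3", pos = 500L),
                trio_row(proband_id = "F1", pos = 600L),
                trio_row(proband_id = "F2", pos = 700L))
  cand <- screen_denovo(cand)
  out <- collapse_independent(cand, co)
  expect_equal(n_independent(out), 3)
  # the twin with the smaller id keeps the event
  expect_true(out$independent[out$proband_id == "T1"])
  expect_false(out$independent[out$proband_id == "T2"])

  # without twins the collapse is the identity
  co2 <- small_cohort(n_trios = 2)
  cand2 <- screen_denovo(rbind(trio_row(proband_id = "F1"),
                               trio_row(proband_id = "F2")))
  expect_equal(n_independent(collapse_independent(cand2, co2)), 2)

  # the same variant in unrelated probands stays two independent events
  cand3 <- screen_denovo(rbind(trio_row(proband_id = "F1", pos = 500L),
                               trio_row(proband_id = "F2", pos = 500L)))
  expect_equal(n_independent(collapse_independent(cand3, co2)), 2)
})

test_that("mosaic flagging matches the exact binomial and its direction rule", {
  # balanced depths: no flag
  b <- flag_mosaic(screen_denovo(trio_row(dp = 60L, ad_alt_p = 30L)))
  expect_false(b$mosaic_flag)
  # strongly depleted alt fraction: flagged, p from the exact two-sided tail
  lo <- flag_mosaic(screen_denovo(trio_row(dp = 60L, ad_alt_p = 6L)), alpha = 0.01)
  d <- dbinom(0:60, 60, 0.5)
  oracle <- sum(d[d <= d[7] * (1 + 1e-7)])
  expect_equal(lo$mosaic_p, oracle, tolerance = 1e-12)
  expect_true(lo$mosaic_flag)
  # skew above 0.5 is not mosaicism however small the p-value
  hi <- flag_mosaic(screen_denovo(trio_row(dp = 60L, ad_alt_p = 54L)), alpha = 0.01)
  expect_lt(hi$mosaic_p, 0.01)
  expect_false(hi$mosaic_flag)
  # zero informative reads: not evaluable
  z <- trio_row(); z <- screen_denovo(z)
  z$ad_ref_p <- 0L; z$ad_alt_p <- 0L
  expect_true(is.na(flag_mosaic(z)$mosaic_flag))
})

test_that("simulated mosaic events surface through the flag", {
  sim <- simulate_cohort(sim_config(n_trios = 20, n_quads = 0, n_sites = 0,
                                    de_novo_rate_per_proband = 2,
                                    n_comphet_genes_per_proband = 0,
                                    n_homozygous_per_proband = 0,
                                    n_hemizygous_per_male_proband = 0,
                                    n_mosaic_events = 2, mosaic_fraction = 0.15,
                                    noiseless = TRUE, seed = 23))
  trios <- suppressMessages(sim_trios(sim))
  cand <- flag_mosaic(suppressMessages(screen_denovo(trios)), alpha = 0.01)
  mk <- with(sim$truth[sim$truth$class == "mosaic_de_novo", ],
             paste(proband_id, chrom, pos))
  ck <- paste(cand$proband_id, cand$chrom, cand$pos)
  expect_length(mk, 2)
  expect_true(all(cand$mosaic_flag[ck %in% mk]))
  expect_false(any(cand$mosaic_flag[!ck %in% mk]))
})
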