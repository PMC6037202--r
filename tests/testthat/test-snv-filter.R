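test_that("variant allele fraction matches the reported read ratios", {
  expect_equal(round_half_up(100 * variant_allele_fraction(7, 22), 0), 32)
  expect_equal(round_half_up(100 * variant_allele_fraction(9, 29), 0), 31)
  expect_equal(variant_allele_fraction(10, 20), 0.5)
  expect_warning(v <- variant_allele_fraction(0, 0), "zero depth")
  expect_true(is.na(v))
  expect_error(variant_allele_fraction(5, 3), "exceeds")
})

test_that("quality gate boundaries are inclusive and every failure is named", {
  ## all thresholds exactly attained -> pass
  q <- quality_filter(make_variant(gq = 30, dp = 10, alt_depth = 5))
  expect_equal(q$outcome, "pass")
  ## the 32%-fails / 33%-passes VAF boundary, as rational arithmetic
  q <- quality_filter(make_variant(gq = 60, dp = 22, alt_depth = 7))
  expect_equal(q$outcome, "fail")
  expect_equal(q$reason_codes, "low_vaf")
  q <- quality_filter(make_variant(dp = 100, alt_depth = 33))
  expect_equal(q$outcome, "pass")
  q <- quality_filter(make_variant(dp = 100, alt_depth = 32))
  expect_equal(q$outcome, "fail")
  ## two-read site fails depth
  q <- quality_filter(make_variant(dp = 2, alt_depth = 2))
  expect_match(q$reason_codes, "low_dp")
  ## compound failure lists every criterion
  q <- quality_filter(make_variant(gq = 29, dp = 9, alt_depth = 1,
                                   filter_status = "LowQual"))
  expect_setequal(strsplit(q$reason_codes, ";")[[1]],
                  c("low_gq", "low_dp", "low_vaf", "non_pass_filter"))
  ## missing quality fields fail explicitly
  q <- quality_filter(make_variant(gq = NA_real_))
  expect_match(q$reason_codes, "missing_quality_field")
})

test_that("frequency gate is strict above 0.01 and treats absent as zero", {
  f <- frequency_filter(make_variant(af_exac = 0.02))
  expect_equal(f$outcome, "fail")
  expect_equal(f$reason_codes, "af_exac_above_threshold")
  expect_equal(frequency_filter(make_variant(af_exac = 0.01))$outcome,
               "pass")
  expect_equal(frequency_filter(make_variant(af_1kg = 0.010001))$outcome,
               "fail")
  ## absent-as-zero: same verdict as explicit zero
  both <- rbind(make_variant(af_exac = NA, af_1kg = NA),
                make_variant(af_exac = 0, af_1kg = 0))
  expect_equal(frequency_filter(both)$outcome, c("pass", "pass"))
  expect_error(frequency_filter(make_variant(af_exac = -0.1)), "negative")
})

test_that("retention fires on any of the four evidence routes", {
  r <- retention_rules(make_variant(so_consequence = "stop_gained"))
  expect_equal(r$outcome, "retained")
  expect_equal(r$reason_codes, "truncating_consequence")
  r <- retention_rules(make_variant(so_consequence = "missense_variant",
                                    truncation_fraction = NA,
                                    cadd_phred = 35))
  expect_equal(r$reason_codes, "cadd_above_threshold")
  expect_true(r$cadd_only)
  r <- retention_rules(make_variant(so_consequence = "missense_variant",
                                    truncation_fraction = NA,
                                    cadd_phred = 20))
  expect_equal(r$outcome, "fail")
  expect_equal(r$reason_codes, "no_retention_criterion")
  r <- retention_rules(make_variant(so_consequence = "missense_variant",
                                    truncation_fraction = NA,
                                    clinvar_assertion = "pathogenic",
                                    clinvar_stars = 2,
                                    clinvar_submission_count = 3))
  expect_equal(r$reason_codes, "clinvar_pathogenic")
  ## one-star pathogenic assertions carry no weight
  r <- retention_rules(make_variant(so_consequence = "missense_variant",
                                    truncation_fraction = NA,
                                    clinvar_assertion = "pathogenic",
                                    clinvar_stars = 1,
                                    clinvar_submission_count = 1))
  expect_equal(r$outcome, "fail")
  ## CADD boundary: attaining the threshold qualifies
  expect_equal(retention_rules(make_variant(
    so_consequence = "missense_variant", truncation_fraction = NA,
    cadd_phred = 34))$outcome, "retained")
  expect_equal(retention_rules(make_variant(
    so_consequence = "missense_variant", truncation_fraction = NA,
    cadd_phred = 33.99))$outcome, "fail")
  ## unknown SO terms are logged and treated as non-truncating
  expect_message(
    r <- retention_rules(make_variant(so_consequence = "weird_term",
                                      truncation_fraction = NA)),
    "non-truncating")
  expect_equal(r$outcome, "fail")
})

test_that("the CADD threshold is the median of pathogenic scores", {
  expect_equal(derive_cadd_threshold(c(30, 34, 40)), 34)
  expect_equal(derive_cadd_threshold(c(30, 38)), 34)
  expect_error(derive_cadd_threshold(numeric(0)), "default")
  withr::with_seed(11, {
    scores <- runif(101, 20, 50)
    expect_equal(derive_cadd_threshold(scores), oracle_median(scores))
    scores <- runif(100, 20, 50)
    expect_equal(derive_cadd_threshold(scores), oracle_median(scores))
  })
})

test_that("non-coding lookup requires an exact position-allele match", {
  panel <- test_panel()
  hit <- make_variant(contig = "chr1", position = 1500L, ref = "G",
                      alt = "A", so_consequence = "intron_variant",
                      truncation_fraction = NA)
  expect_true(noncoding_lookup(hit, panel))
  miss <- hit; miss$alt <- "C"
  expect_false(noncoding_lookup(miss, panel))
  empty_panel <- test_panel(); empty_panel$noncoding <-
    empty_panel$noncoding[0, ]
  expect_false(noncoding_lookup(hit, empty_panel))
})

test_that("each exclusion criterion fires on its construction", {
  panel <- test_panel()
  cases <- list(
    list(v = make_variant(gene_symbol = "TSG1",
                          clinvar_assertion = "benign", clinvar_stars = 2,
                          clinvar_submission_count = 3),
         code = "truncating_with_benign_clinvar"),
    list(v = make_variant(gene_symbol = "ONC1", contig = "chr2"),
         code = "truncating_in_proto_oncogene"),
    list(v = make_variant(truncation_fraction = 0.03),
         code = "minimal_truncation"),
    list(v = make_variant(gene_symbol = "REC1", contig = "chr3"),
         code = "recessive_without_second_variant"),
    list(v = make_variant(so_consequence = "missense_variant",
                          truncation_fraction = NA, hgmd_dm = TRUE,
                          clinvar_assertion = "uncertain",
                          clinvar_stars = 2,
                          clinvar_submission_count = 2),
         code = "insilico_refuted_by_clinvar"))
  for (case in cases) {
    e <- exclusion_rules(case$v, panel)
    expect_equal(e$outcome, "excluded")
    expect_match(e$reason_codes, case$code)
  }
  ## boundary: 5% of transcript is not "minimal"
  e <- exclusion_rules(make_variant(truncation_fraction = 0.05), panel)
  expect_equal(e$outcome, "retained_for_assessment")
  e <- exclusion_rules(make_variant(truncation_fraction = 0.049), panel)
  expect_equal(e$outcome, "excluded")
  ## criterion 5 via one star + multiple submissions, no P/LP assertion
  e <- exclusion_rules(make_variant(so_consequence = "missense_variant",
                                    truncation_fraction = NA,
                                    cadd_phred = 40,
                                    clinvar_assertion = "uncertain",
                                    clinvar_stars = 1,
                                    clinvar_submission_count = 2), panel)
  expect_equal(e$outcome, "excluded")
  ## ...but a single submission is not enough
  e <- exclusion_rules(make_variant(so_consequence = "missense_variant",
                                    truncation_fraction = NA,
                                    cadd_phred = 40,
                                    clinvar_assertion = "uncertain",
                                    clinvar_stars = 1,
                                    clinvar_submission_count = 1), panel)
  expect_equal(e$outcome, "retained_for_assessment")
})

test_that("recessive genes admit homozygous or biallelic configurations", {
  panel <- test_panel()
  ## homozygote counts as two filtered variants
  hom <- make_variant(gene_symbol = "REC1", contig = "chr3",
                      zygosity = "hom", alt_depth = 29)
  expect_equal(exclusion_rules(hom, panel)$outcome,
               "retained_for_assessment")
  ## two heterozygous hits in the same gene are presumed compound het
  pair <- rbind(
    make_variant(gene_symbol = "REC1", contig = "chr3", position = 1100L),
    make_variant(gene_symbol = "REC1", contig = "chr3", position = 3100L,
                 ref = "C", alt = "G"))
  expect_equal(exclusion_rules(pair, panel)$outcome,
               rep("retained_for_assessment", 2))
  ## a second hit in a different individual does not rescue
  pair$individual_id <- c("P1", "P2")
  expect_equal(exclusion_rules(pair, panel)$outcome, rep("excluded", 2))
})

test_that("missing truncation fraction disables criterion 3 with a note", {
  panel <- test_panel()
  expect_message(
    e <- exclusion_rules(make_variant(truncation_fraction = NA), panel),
    "not applied")
  expect_equal(e$outcome, "retained_for_assessment")
})

test_that("the pipeline conserves counts, dedups, and quarantines", {
  panel <- test_panel()
  good <- make_variant()
  dup <- good
  bad <- make_variant(position = 3100L, alt_depth = 50)  # alt > dp
  fail_q <- make_variant(position = 5100L, gq = 10)
  suppressWarnings(
    res <- run_snv_pipeline(rbind(good, dup, bad, fail_q), panel))
  a <- res$audit
  expect_equal(a$n_input, 4)
  expect_equal(a$n_duplicates, 1)
  expect_equal(a$n_quarantined, 1)
  expect_equal(a$n_retained_for_assessment, 1)
  expect_equal(a$n_fail_quality, 1)
  expect_equal(a$n_input,
               a$n_quarantined + a$n_duplicates + a$n_fail_quality +
                 a$n_fail_frequency + a$n_not_retained + a$n_excluded +
                 a$n_retained_for_assessment)
  expect_warning(run_snv_pipeline(rbind(good, dup), panel), "duplicate")
  expect_warning(run_snv_pipeline(bad, panel), "quarantined")
})

test_that("the empty pipeline yields an empty, zeroed audit", {
  res <- run_snv_pipeline(make_variant()[0, ], test_panel())
  expect_equal(nrow(res$retained), 0)
  expect_equal(res$audit$n_input, 0)
  expect_equal(res$audit$n_retained_for_assessment, 0)
})

test_that("dispositions are invariant to input order", {
  sim <- simulate_cohort_inputs(sim_config(seed = 5, n_probands = 60))
  r1 <- run_snv_pipeline(sim$snv$variants, sim$panel)
  shuffled <- sim$snv$variants[rev(seq_len(nrow(sim$snv$variants))), ]
  r2 <- run_snv_pipeline(shuffled, sim$panel)
  expect_identical(retained_keys(r1), retained_keys(r2))
  d1 <- r1$dispositions[order(r1$dispositions$individual_id,
                              r1$dispositions$contig,
                              r1$dispositions$position), ]
  d2 <- r2$dispositions[order(r2$dispositions$individual_id,
                              r2$dispositions$contig,
                              r2$dispositions$position), ]
  rownames(d1) <- rownames(d2) <- NULL
  expect_identical(d1, d2)
})

test_that("the cascade equals a naive single-pass predicate oracle", {
  for (seed in c(3, 9)) {
    sim <- simulate_cohort_inputs(sim_config(seed = seed, n_probands = 120))
    res <- run_snv_pipeline(sim$snv$variants, sim$panel)
    expect_identical(retained_keys(res),
                     oracle_retained_keys(sim$snv$variants, sim$panel))
  }
})

test_that("annotated variants round-trip through VCF", {
  sim <- simulate_cohort_inputs(sim_config(seed = 13, n_probands = 30))
  v <- sim$snv$variants
  ind <- names(sort(table(v$individual_id), decreasing = TRUE))[1]
  mine <- v[v$individual_id == ind, ]
  d <- withr::local_tempdir()
  path <- file.path(d, "sample.vcf")
  write_annotated_vcf(mine, path)
  back <- read_annotated_vcf(path)
  ord <- function(d) {
    d <- d[order(d$contig, d$position, d$alt), ]
    rownames(d) <- NULL
    d
  }
  mine <- ord(mine); back <- ord(back)
  expect_equal(back$position, mine$position)
  expect_equal(back$gene_symbol, mine$gene_symbol)
  expect_equal(back$gq, mine$gq)
  expect_equal(back$alt_depth, mine$alt_depth)
  expect_equal(back$zygosity, mine$zygosity)
  expect_equal(back$cadd_phred, mine$cadd_phred, tolerance = 1e-6)
  expect_equal(back$hgmd_dm, mine$hgmd_dm)
  ## the triage verdict is unchanged by the round trip
  r1 <- run_snv_pipeline(mine, sim$panel)
  r2 <- run_snv_pipeline(back, sim$panel)
  expect_identical(retained_keys(r1), retained_keys(r2))
})
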