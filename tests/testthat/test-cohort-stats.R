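test_that("combination enumeration pairs distinct categories only", {
  expect_equal(nrow(enumerate_combinations(c("breast", "colorectal"))), 1)
  expect_equal(nrow(enumerate_combinations(c("breast", "ovary",
                                             "endometrium"))), 3)
  expect_equal(nrow(enumerate_combinations(c("breast", "breast"))), 0)
  expect_equal(nrow(enumerate_combinations(character())), 0)
  ## order-normalized
  p <- enumerate_combinations(c("ovary", "breast"))
  expect_equal(p$cat_a, "breast")
  expect_equal(p$cat_b, "ovary")
})

test_that("cohort combination totals satisfy the C(k,2) identity", {
  sim <- generate_cohort(sim_config(seed = 31, n_probands = 150))
  combos <- cohort_combinations(sim$tumors)
  expected <- sum(vapply(split(sim$tumors$tumor_category,
                               sim$tumors$individual_id), function(cats) {
    k <- length(unique(cats))
    choose(k, 2)
  }, numeric(1)))
  expect_equal(nrow(combos), expected)
})

test_that("the frequency-of-frequency breakdown reproduces known shares", {
  ## 206 types once, 53 twice, 68 three-or-more (out of 327 types)
  types <- c(sprintf("a%03d+b%03d", 1:206, 1:206),
             rep(sprintf("c%02d+d%02d", 1:53, 1:53), 2),
             rep(sprintf("e%02d+f%02d", 1:68, 1:68), 3))
  dist <- combination_distribution(data.frame(combination = types))
  expect_equal(dist$n_types, 327)
  fof <- setNames(dist$frequency_of$pct_of_types,
                  dist$frequency_of$times_observed)
  expect_equal(unname(fof["once"]), 63.0)
  expect_equal(unname(fof["twice"]), 16.2)
  expect_equal(unname(fof["three_plus"]), 20.8)
  ## single individual with one pair: one type at 100%
  single <- combination_distribution(data.frame(combination = "x+y"))
  expect_equal(single$n_types, 1)
  expect_equal(single$type_counts$pct_of_combinations, 100)
})

test_that("uncorrected Pearson chi-squared matches the brute-force formula", {
  brute <- function(m) {
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    sum((m - e)^2 / e)
  }
  tables <- list(matrix(c(52, 298, 388, 8694), 2),
                 matrix(c(41, 298, 399, 8694), 2),
                 matrix(c(27, 40, 109, 264), 2),
                 matrix(c(10, 10, 90, 90), 2))
  withr::with_seed(4, {
    for (i in 1:20) tables <- c(tables, list(matrix(sample(1:500, 4), 2)))
  })
  for (m in tables) {
    res <- pearson_chi2(m)
    expect_equal(res$statistic, brute(m), tolerance = 1e-10)
    expect_equal(res$df, 1)
    ## invariant under row and column swaps
    expect_equal(pearson_chi2(m[2:1, ])$statistic, res$statistic)
    expect_equal(pearson_chi2(m[, 2:1])$statistic, res$statistic)
  }
  expect_equal(pearson_chi2(matrix(c(10, 10, 90, 90), 2))$statistic, 0)
  expect_error(pearson_chi2(matrix(c(0, 0, 5, 5), 2)), "margin")
  expect_error(pearson_chi2(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("registry comparison flags enriched types and only tested ones", {
  mk <- function(prefix, n_a, n_b, pair_a = c("breast", "colorectal"),
                 pair_b = c("breast", "lung")) {
    n <- n_a + n_b
    data.frame(
      individual_id = rep(sprintf("%s%04d", prefix, seq_len(n)), each = 2),
      tumor_category = c(rep(pair_a, n_a), rep(pair_b, n_b)),
      age_at_diagnosis = 45,
      stringsAsFactors = FALSE)
  }
  mpt <- mk("M", 40, 60)
  reg <- mk("R", 8, 92)
  res <- registry_comparison(mpt, reg)
  enriched <- res$tests[res$tests$combination == "breast+colorectal", ]
  expect_true(enriched$significant)
  ## identical cohorts flag nothing
  res0 <- registry_comparison(mk("M", 40, 60), mk("R", 40, 60))
  expect_false(any(res0$tests$significant))
  ## a type below the 1% share is not tested
  mpt_rare <- rbind(mk("M", 99, 0),
                    mk("X", 1, 0, pair_a = c("ovary", "thyroid")))
  res_rare <- registry_comparison(mpt_rare, reg)
  expect_false("ovary+thyroid" %in% res_rare$tests$combination)
})

test_that("registry restriction drops non-malignant and late diagnoses", {
  mpt <- data.frame(
    individual_id = rep(c("A", "B", "C"), each = 2),
    tumor_category = c("breast", "colorectal",      # kept
                       "breast", "pheochromocytoma", # pheo dropped
                       "breast", "colorectal"),     # B's ages disqualify
    age_at_diagnosis = c(45, 50, 40, 41, 45, 61),
    stringsAsFactors = FALSE)
  reg <- data.frame(
    individual_id = rep(sprintf("R%02d", 1:50), each = 2),
    tumor_category = rep(c("breast", "colorectal"), 50),
    age_at_diagnosis = 45, stringsAsFactors = FALSE)
  ## suppress the small-expected-count caveat from the tiny fixture
  res <- suppressWarnings(registry_comparison(mpt, reg))
  ## only A's pair survives restriction on the MPT side
  expect_equal(res$n_mpt_combinations, 1)
  ## CNS tumors are kept despite not being coded malignant
  mpt$tumor_category[4] <- "cns"
  res <- suppressWarnings(registry_comparison(mpt, reg))
  expect_equal(res$n_mpt_combinations, 2)
})

test_that("sex adjustment interpolates between per-sex frequencies", {
  ## identical frequencies are invariant under any target split
  ref <- list(n_male = 1000, n_female = 1000, carriers_male = 50,
              carriers_female = 50)
  for (t in c(0.2, 0.5, 0.77)) {
    expect_equal(sex_adjusted_frequency(ref, t), 0.05)
  }
  ## hand-computed: f_m 0.10, f_f 0.02, n_f 1000, target 50% -> 0.06
  ref <- list(n_male = 2000, n_female = 1000, carriers_male = 200,
              carriers_female = 20)
  expect_equal(sex_adjusted_frequency(ref, 0.5), 0.06)
  ## bounded by the per-sex frequencies
  withr::with_seed(6, {
    for (i in 1:50) {
      ref <- list(n_male = sample(500:5000, 1),
                  n_female = sample(500:5000, 1))
      ref$carriers_male <- rbinom(1, ref$n_male, runif(1, 0.01, 0.2))
      ref$carriers_female <- rbinom(1, ref$n_female, runif(1, 0.01, 0.2))
      t <- runif(1, 0.05, 0.95)
      f <- sex_adjusted_frequency(ref, t)
      f_m <- ref$carriers_male / ref$n_male
      f_f <- ref$carriers_female / ref$n_female
      expect_gte(f, min(f_m, f_f))
      expect_lte(f, max(f_m, f_f))
    }
  })
  ## the 77%-female target shrinks males to n_f * 23/77
  ref <- list(n_male = 8592, n_female = 6929, carriers_male = 284,
              carriers_female = 229)
  n_male_adj <- 6929 * 0.23 / 0.77
  expect_equal(n_male_adj, 2069.65, tolerance = 1e-4)
  f <- sex_adjusted_frequency(ref, 0.77)
  expect_equal(f, (284 / 8592 * n_male_adj + 229 / 6929 * 6929) /
                 (n_male_adj + 6929))
  expect_error(sex_adjusted_frequency(ref, 1), "target_prop_female")
  expect_error(sex_adjusted_frequency(list(n_male = 0, n_female = 10,
                                           carriers_male = 0,
                                           carriers_female = 1), 0.5),
               "both sexes")
})

test_that("yield projection reproduces the printed combined rates", {
  expect_equal(pct(yield_projection(0.207, 0.152), 1), 32.8)
  expect_equal(pct(yield_projection(0.207, 0.086), 1), 27.5)
  expect_equal(yield_projection(0, 0.3), 0.3)
  expect_equal(yield_projection(1, 0.3), 1)
  ## monotone and bounded
  withr::with_seed(2, {
    p <- runif(50); q <- runif(50)
    y <- yield_projection(p, q)
    expect_true(all(y >= 0 & y <= 1))
    expect_true(all(yield_projection(p, pmin(q + 0.1, 1)) >= y))
    expect_true(all(yield_projection(pmin(p + 0.1, 1), q) >= y))
  })
})

test_that("detection rates carry exact fractions with reported rounding", {
  r <- detection_rates(67, 440)
  expect_equal(r$percent, 15.2)
  expect_equal(r$rate, 67 / 440)
  expect_equal(detection_rates(61, 440)$percent, 13.9)
  expect_equal(detection_rates(0, 440)$percent, 0)
  expect_equal(detection_rates(281, 1143)$percent, 24.6)
  expect_error(detection_rates(1, 0), "zero")
})

test_that("coverage summary equals a naive loop", {
  expect_equal(coverage_summary(rep(35, 100)),
               list(mean_depth = 35, fraction_at_threshold = 1))
  expect_equal(coverage_summary(c(5, 15)),
               list(mean_depth = 10, fraction_at_threshold = 0.5))
  withr::with_seed(9, {
    depths <- rpois(5000, 30)
    s <- coverage_summary(depths, threshold = 10)
    total <- 0; hit <- 0
    for (d in depths) {
      total <- total + d
      if (d >= 10) hit <- hit + 1
    }
    expect_equal(s$mean_depth, total / length(depths))
    expect_equal(s$fraction_at_threshold, hit / length(depths))
  })
  expect_error(coverage_summary(numeric(0)), "empty")
})
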