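## Cohort-level statistics: discordant tumor-combination enumeration and
## distribution, registry comparison by uncorrected Pearson chi-squared
## tests, sex-adjusted reference-population burden comparison,
## diagnostic-yield projection, detection rates, and coverage summaries.

#' Enumerate discordant tumor combinations for one individual
#'
#' All unordered pairs over the individual's distinct tumor categories;
#' same-category repeats (e.g. bilateral breast cancer) contribute no
#' pair. An individual with k distinct categories yields C(k, 2) pairs.
#'
#' @param tumor_categories character vector of tumor-category labels.
#' @return data.frame with order-normalized columns `cat_a` < `cat_b`
#'   (zero rows when fewer than two distinct categories).
#' @export
enumerate_combinations <- function(tumor_categories) {
  cats <- sort(unique(tumor_categories))
  if (length(cats) < 2) {
    return(data.frame(cat_a = character(), cat_b = character(),
                      stringsAsFactors = FALSE))
  }
  pairs <- utils::combn(cats, 2)
  data.frame(cat_a = pairs[1, ], cat_b = pairs[2, ],
             stringsAsFactors = FALSE)
}

#' Enumerate combinations across a cohort
#'
#' @param cohort phenotype table (one row per tumor, with `individual_id`
#'   and `tumor_category`).
#' @return data.frame with `individual_id`, `cat_a`, `cat_b`, and a
#'   normalized `combination` label (`"cat_a+cat_b"`).
#' @export
cohort_combinations <- function(cohort) {
  by_ind <- split(cohort$tumor_category, cohort$individual_id)
  pieces <- lapply(names(by_ind), function(ind) {
    p <- enumerate_combinations(by_ind[[ind]])
    if (nrow(p)) p$individual_id <- ind
    p
  })
  out <- do.call(rbind, pieces[vapply(pieces, nrow, integer(1)) > 0])
  if (is.null(out)) {
    out <- data.frame(cat_a = character(), cat_b = character(),
                      individual_id = character(), stringsAsFactors = FALSE)
  }
  out$combination <- paste(out$cat_a, out$cat_b, sep = "+")
  out[c("individual_id", "cat_a", "cat_b", "combination")]
}

#' Distribution of combination types
#'
#' @param combinations data.frame from [cohort_combinations()] (or any
#'   table with a `combination` column, one row per observed combination).
#' @return list with `type_counts` (data.frame: combination, count,
#'   pct_of_combinations), `n_combinations`, `n_types`, and `frequency_of`
#'   (data.frame with counts and percentages of types occurring once,
#'   twice, and three or more times).
#' @export
combination_distribution <- function(combinations) {
  counts <- sort(table(combinations$combination), decreasing = TRUE)
  n_comb <- sum(counts)
  n_types <- length(counts)
  type_counts <- data.frame(
    combination = names(counts),
    count = as.integer(counts),
    pct_of_combinations = pct(as.integer(counts), n_comb),
    stringsAsFactors = FALSE)
  bins <- c(once = sum(counts == 1), twice = sum(counts == 2),
            three_plus = sum(counts >= 3))
  frequency_of <- data.frame(
    times_observed = names(bins),
    n_types = as.integer(bins),
    pct_of_types = if (n_types) pct(as.integer(bins), n_types) else
      rep(NA_real_, 3),
    stringsAsFactors = FALSE)
  list(type_counts = type_counts, n_combinations = n_comb,
       n_types = n_types, frequency_of = frequency_of)
}

#' Uncorrected Pearson chi-squared test on a 2x2 table
#'
#' No Yates continuity correction: the statistic is
#' `N (ad - bc)^2 / [(a+b)(c+d)(a+c)(b+d)]` with one degree of freedom and
#' an upper-tail p-value.
#'
#' @param table 2x2 numeric matrix of counts (non-negative; both margins
#'   positive).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
pearson_chi2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("need a 2x2 table")
  if (any(table < 0)) stop("cell counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero margin in contingency table")
  }
  ct <- stats::chisq.test(table, correct = FALSE)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' Compare MPT combination frequencies with a registry cohort
#'
#' Both cohorts are first restricted to the registry's inclusion criteria:
#' only malignant (or CNS) tumor categories, diagnosed strictly before
#' `age_limit`. For every combination type representing more than
#' `min_share` of the restricted MPT combinations, a 2x2 uncorrected
#' chi-squared test of type-count versus all other combinations is run
#' between the cohorts.
#'
#' @param mpt_cohort,registry_cohort phenotype tables (one row per tumor:
#'   `individual_id`, `tumor_category`, `age_at_diagnosis`).
#' @param vocabulary tumor vocabulary with `malignant` and `cns` flags
#'   (default [tumor_vocabulary()]).
#' @param age_limit diagnoses at or beyond this age are dropped (strict
#'   `<`; default 60).
#' @param min_share minimum share of MPT combinations for a type to be
#'   tested (strict `>`; default 0.01).
#' @param alpha significance flag threshold (default 0.05).
#' @return list with `tests` (data.frame: combination, counts, statistic,
#'   p_value, significant) and the restricted combination totals.
#' @export
registry_comparison <- function(mpt_cohort, registry_cohort,
                                vocabulary = tumor_vocabulary(),
                                age_limit = 60, min_share = 0.01,
                                alpha = 0.05) {
  restrict <- function(cohort) {
    stop_if_missing_cols(cohort, c("individual_id", "tumor_category",
                                   "age_at_diagnosis"), "cohort table")
    unknown <- setdiff(unique(cohort$tumor_category), vocabulary$category)
    if (length(unknown)) {
      stop("unknown tumor categories: ", paste(unknown, collapse = ", "))
    }
    keep_cat <- vocabulary$category[vocabulary$malignant | vocabulary$cns]
    cohort[cohort$tumor_category %in% keep_cat &
             cohort$age_at_diagnosis < age_limit, , drop = FALSE]
  }
  mpt <- cohort_combinations(restrict(mpt_cohort))
  reg <- cohort_combinations(restrict(registry_cohort))
  if (!nrow(mpt) || !nrow(reg)) {
    stop("a cohort has no qualifying combinations after restriction")
  }
  n_mpt <- nrow(mpt); n_reg <- nrow(reg)
  counts_mpt <- table(mpt$combination)
  tested <- names(counts_mpt)[counts_mpt / n_mpt > min_share]
  tests <- do.call(rbind, lapply(tested, function(type) {
    a <- sum(mpt$combination == type)
    b <- sum(reg$combination == type)
    tab <- matrix(c(a, n_mpt - a, b, n_reg - b), nrow = 2, byrow = TRUE)
    if (any(colSums(tab) == 0)) {
      ## degenerate: the type is all (or none) of both cohorts' burden —
      ## no contrast to test
      res <- list(statistic = NA_real_, p_value = NA_real_)
      sig <- FALSE
    } else {
      res <- pearson_chi2(tab)
      sig <- res$p_value < alpha
    }
    data.frame(combination = type, mpt_count = a, registry_count = b,
               mpt_share = a / n_mpt, registry_share = b / n_reg,
               statistic = res$statistic, p_value = res$p_value,
               significant = sig, stringsAsFactors = FALSE)
  }))
  if (is.null(tests)) {
    tests <- data.frame(combination = character(), mpt_count = integer(),
                        registry_count = integer(), mpt_share = numeric(),
                        registry_share = numeric(), statistic = numeric(),
                        p_value = numeric(), significant = logical(),
                        stringsAsFactors = FALSE)
  }
  tests <- tests[order(tests$p_value), , drop = FALSE]
  rownames(tests) <- NULL
  list(tests = tests, n_mpt_combinations = n_mpt,
       n_registry_combinations = n_reg)
}

#' Sex-adjusted reference-population carrier frequency
#'
#' Re-weights per-sex carrier frequencies of a reference population to a
#' target sex distribution: the female count is kept fixed and the male
#' count is shrunk to `n_female * (1 - target_prop_female) /
#' target_prop_female` (not rounded); the adjusted frequency is the
#' carrier-count-weighted mean over the re-balanced population.
#'
#' @param ref list or data.frame with `n_male`, `n_female`,
#'   `carriers_male`, `carriers_female`.
#' @param target_prop_female target proportion of females, in (0, 1).
#' @return adjusted carrier frequency (fraction).
#' @export
sex_adjusted_frequency <- function(ref, target_prop_female) {
  if (target_prop_female <= 0 || target_prop_female >= 1) {
    stop("target_prop_female must be in (0, 1)")
  }
  if (ref$n_male <= 0 || ref$n_female <= 0) {
    stop("both sexes must be represented in the reference population")
  }
  if (ref$carriers_male > ref$n_male || ref$carriers_female > ref$n_female) {
    stop("carrier counts cannot exceed population counts")
  }
  f_m <- ref$carriers_male / ref$n_male
  f_f <- ref$carriers_female / ref$n_female
  n_male_adj <- ref$n_female * (1 - target_prop_female) / target_prop_female
  (f_m * n_male_adj + f_f * ref$n_female) / (n_male_adj + ref$n_female)
}

#' Diagnostic-yield projection
#'
#' Combines a prior detection rate (routine targeted testing) with an
#' incremental rate applying to the remainder:
#' `prior + (1 - prior) * incremental`.
#'
#' @param prior_rate,incremental_rate rates in \[0, 1\].
#' @return combined rate in \[0, 1\].
#' @export
yield_projection <- function(prior_rate, incremental_rate) {
  if (any(prior_rate < 0 | prior_rate > 1 |
            incremental_rate < 0 | incremental_rate > 1)) {
    stop("rates must be in [0, 1]")
  }
  prior_rate + (1 - prior_rate) * incremental_rate
}

#' Detection rate with reporting-style rounding
#'
#' @param numerator,denominator counts.
#' @return list with `numerator`, `denominator`, `rate` (exact fraction)
#'   and `percent` (one decimal, half-up).
#' @export
detection_rates <- function(numerator, denominator) {
  if (denominator == 0) stop("zero denominator")
  list(numerator = numerator, denominator = denominator,
       rate = numerator / denominator,
       percent = pct(numerator, denominator))
}

#' Coverage summary
#'
#' @param depths numeric vector of per-base read depths over the regions
#'   of interest.
#' @param threshold depth threshold for the covered fraction (inclusive
#'   `>=`; default 10).
#' @return list with `mean_depth` and `fraction_at_threshold`.
#' @export
coverage_summary <- function(depths, threshold = 10) {
  if (!length(depths)) stop("empty region set")
  list(mean_depth = mean(depths),
       fraction_at_threshold = mean(depths >= threshold))
}
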