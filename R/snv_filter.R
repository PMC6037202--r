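## SNV/indel triage cascade. Every variant receives exactly one terminal
## disposition (quality fail, frequency fail, no retention criterion,
## excluded by a refutation criterion, or retained for ACMG assessment),
## with reason codes at every step so the whole run is auditable.

#' Default truncating Sequence Ontology terms
#'
#' SO consequence terms treated as protein-truncating by the retention and
#' exclusion rules. Ships as configuration because different annotation
#' pipelines emit slightly different term sets.
#'
#' @return character vector of SO terms.
#' @export
truncating_so_terms <- function() {
  c("stop_gained", "frameshift_variant", "splice_acceptor_variant",
    "splice_donor_variant", "start_lost", "transcript_ablation")
}

#' SNV cascade configuration
#'
#' @param min_gq minimum Phred genotype quality (default 30).
#' @param min_dp minimum read depth (default 10).
#' @param vaf_num,vaf_den variant-allele-fraction threshold as an exact
#'   rational `vaf_num / vaf_den` (default 33/100); the comparison
#'   `alt_depth * vaf_den >= vaf_num * dp` avoids float rounding at the
#'   32%-fails / 33%-passes boundary.
#' @param max_af maximum population allele frequency (strictly above fails;
#'   default 0.01).
#' @param cadd_threshold Phred-scaled CADD retention threshold (default 34,
#'   the median score of variants deemed pathogenic through the database
#'   routes; see [derive_cadd_threshold()]). Attaining the threshold
#'   qualifies (`>=`).
#' @param min_clinvar_stars review level required for ClinVar evidence to
#'   carry weight (default 2).
#' @param truncating_terms SO terms treated as truncating.
#' @return named list of settings.
#' @export
snv_config <- function(min_gq = 30, min_dp = 10, vaf_num = 33L,
                       vaf_den = 100L, max_af = 0.01, cadd_threshold = 34,
                       min_clinvar_stars = 2,
                       truncating_terms = truncating_so_terms()) {
  list(min_gq = min_gq, min_dp = min_dp, vaf_num = as.integer(vaf_num),
       vaf_den = as.integer(vaf_den), max_af = max_af,
       cadd_threshold = cadd_threshold,
       min_clinvar_stars = min_clinvar_stars,
       truncating_terms = truncating_terms)
}

#' Variant allele fraction
#'
#' @param alt_depth reads supporting the alternate allele.
#' @param dp total read depth.
#' @return `alt_depth / dp`; `NA` (with a warning) where `dp` is zero —
#'   such records are routed to a quality failure by [quality_filter()].
#' @export
variant_allele_fraction <- function(alt_depth, dp) {
  if (any(!is.na(alt_depth) & !is.na(dp) & alt_depth > dp)) {
    stop("alt_depth exceeds dp")
  }
  out <- ifelse(!is.na(dp) & dp == 0, NA_real_, alt_depth / dp)
  if (any(!is.na(dp) & dp == 0)) {
    warning("VAF undefined at zero depth; returning NA")
  }
  out
}

## assemble a disposition data.frame from a logical pass vector and a
## character matrix of reason codes (NA where not triggered)
disposition <- function(stage, pass, reason_mat,
                        outcome_pass = "pass", outcome_fail = "fail") {
  reasons <- apply(reason_mat, 1, function(r) paste(r[!is.na(r)],
                                                    collapse = ";"))
  data.frame(stage = stage,
             outcome = ifelse(pass, outcome_pass, outcome_fail),
             reason_codes = reasons, stringsAsFactors = FALSE)
}

#' Genotype-quality gate
#'
#' Pass requires GQ >= 30, DP >= 10, VAF >= 33% (rational comparison) and
#' caller filter PASS; every failed criterion is named in the reason codes.
#' Missing GQ/DP fails with `missing_quality_field`.
#'
#' @param variants annotated-variant data.frame (see [read_annotated_vcf()]
#'   for the column contract).
#' @param config [snv_config()].
#' @return data.frame with `stage`, `outcome` (pass/fail), `reason_codes`.
#' @export
quality_filter <- function(variants, config = snv_config()) {
  n <- nrow(variants)
  gq <- variants$gq
  dp <- variants$dp
  ad <- variants$alt_depth
  missing_q <- is.na(gq) | is.na(dp) | is.na(ad)
  ## rational VAF: alt/dp >= num/den  <=>  alt*den >= num*dp
  vaf_ok <- !missing_q & dp > 0 & (ad * config$vaf_den >= config$vaf_num * dp)
  reason <- cbind(
    ifelse(missing_q, "missing_quality_field", NA),
    ifelse(!missing_q & gq < config$min_gq, "low_gq", NA),
    ifelse(!missing_q & dp < config$min_dp, "low_dp", NA),
    ifelse(!missing_q & !vaf_ok, "low_vaf", NA),
    ifelse(is.na(variants$filter_status) | variants$filter_status != "PASS",
           "non_pass_filter", NA))
  pass <- rowSums(!is.na(reason)) == 0
  disposition(rep("quality", n), pass, reason)
}

#' Population-frequency gate
#'
#' Fails a variant whose maximum allele frequency in either reference
#' resource is strictly above the threshold (default 0.01). An absent
#' frequency means the variant was not observed and is treated as 0.
#'
#' @inheritParams quality_filter
#' @return disposition data.frame.
#' @export
frequency_filter <- function(variants, config = snv_config()) {
  af1 <- variants$af_exac
  af2 <- variants$af_1kg
  if (any(af1 < 0, na.rm = TRUE) || any(af2 < 0, na.rm = TRUE)) {
    stop("negative population allele frequency")
  }
  af1 <- ifelse(is.na(af1), 0, af1)
  af2 <- ifelse(is.na(af2), 0, af2)
  reason <- cbind(ifelse(af1 > config$max_af, "af_exac_above_threshold", NA),
                  ifelse(af2 > config$max_af, "af_1kg_above_threshold", NA))
  disposition(rep("frequency", nrow(variants)),
              rowSums(!is.na(reason)) == 0, reason)
}

clinvar_plp <- function(variants, config) {
  !is.na(variants$clinvar_assertion) &
    variants$clinvar_assertion %in% c("pathogenic", "likely_pathogenic") &
    !is.na(variants$clinvar_stars) &
    variants$clinvar_stars >= config$min_clinvar_stars
}

## benign/uncertain side; "conflicting" counts as uncertain because a
## conflicted assertion cannot support pathogenicity
clinvar_benign_uncertain <- function(variants) {
  !is.na(variants$clinvar_assertion) &
    variants$clinvar_assertion %in% c("benign", "likely_benign",
                                      "uncertain", "conflicting")
}

#' Retention rules
#'
#' A quality- and frequency-passing variant is retained for review if at
#' least one of four criteria holds: (a) truncating SO consequence;
#' (b) ClinVar pathogenic/likely-pathogenic at two or more review stars;
#' (c) HGMD disease-mutation status; (d) CADD Phred score at or above the
#' threshold. Criterion (d) is logically a second filtering pass (in-silico
#' rescue of variants absent from databases); retention is evaluated so
#' that the two-pass and single-pass retained sets are identical, and
#' [run_snv_pipeline()] asserts this.
#'
#' @inheritParams quality_filter
#' @param cadd_threshold override for the configured CADD threshold.
#' @return data.frame with `stage`, `outcome` (retained/fail),
#'   `reason_codes` listing every satisfied criterion, and a helper column
#'   `cadd_only` flagging variants retained solely through the in-silico
#'   route (used by exclusion criterion 5).
#' @export
retention_rules <- function(variants, config = snv_config(),
                            cadd_threshold = NULL) {
  thr <- cadd_threshold %||% config$cadd_threshold
  so <- variants$so_consequence
  known_terms <- c(config$truncating_terms, non_truncating_so_terms())
  unknown <- setdiff(unique(so[!is.na(so)]), known_terms)
  if (length(unknown)) {
    message("treating unknown SO term(s) as non-truncating: ",
            paste(unknown, collapse = ", "))
  }
  trunc <- !is.na(so) & so %in% config$truncating_terms
  plp <- clinvar_plp(variants, config)
  dm <- !is.na(variants$hgmd_dm) & variants$hgmd_dm
  cadd <- !is.na(variants$cadd_phred) & variants$cadd_phred >= thr
  reason <- cbind(ifelse(trunc, "truncating_consequence", NA),
                  ifelse(plp, "clinvar_pathogenic", NA),
                  ifelse(dm, "hgmd_dm", NA),
                  ifelse(cadd, "cadd_above_threshold", NA))
  out <- disposition(rep("retention", nrow(variants)),
                     rowSums(!is.na(reason)) > 0, reason,
                     outcome_pass = "retained")
  out$reason_codes[out$outcome == "fail"] <- "no_retention_criterion"
  out$cadd_only <- cadd & !(trunc | plp | dm)
  out
}

## SO terms commonly seen but not truncating; anything outside both sets
## is reported as unknown (and treated as non-truncating)
non_truncating_so_terms <- function() {
  c("missense_variant", "synonymous_variant", "inframe_insertion",
    "inframe_deletion", "splice_region_variant", "intron_variant",
    "5_prime_UTR_variant", "3_prime_UTR_variant", "upstream_gene_variant",
    "downstream_gene_variant", "non_coding_transcript_exon_variant",
    "stop_retained_variant", "protein_altering_variant")
}

#' Derive the CADD retention threshold
#'
#' The in-silico retention threshold is the median Phred-scaled CADD score
#' of variants deemed pathogenic through the other retention routes
#' (even-length inputs: midpoint of the two central values).
#'
#' @param pathogenic_scores numeric vector of CADD scores.
#' @return the median.
#' @export
derive_cadd_threshold <- function(pathogenic_scores) {
  scores <- pathogenic_scores[!is.na(pathogenic_scores)]
  if (!length(scores)) {
    stop("no pathogenic CADD scores supplied; fall back to the configured ",
         "default threshold")
  }
  stats::median(scores)
}

#' Non-coding positional lookup
#'
#' Variants in non-coding space are not retained by consequence; instead a
#' short curated list of known pathogenic non-coding positions is searched
#' by exact (contig, position, ref, alt) match.
#'
#' @inheritParams quality_filter
#' @param panel `cpg_panel` whose `noncoding` table holds the positions.
#' @return logical vector, `TRUE` where the variant matches a listed
#'   position and allele exactly.
#' @export
noncoding_lookup <- function(variants, panel) {
  if (!nrow(panel$noncoding)) return(rep(FALSE, nrow(variants)))
  key <- function(d) paste(d$contig, d$position, d$ref, d$alt, sep = "\r")
  key(variants) %in% key(panel$noncoding)
}

#' Exclusion (pathogenicity-refutation) criteria
#'
#' A retained variant is excluded if any of five criteria refutes its
#' putative pathogenicity:
#' 1. truncating, but ClinVar asserts benign/uncertain at >= 2 stars;
#' 2. truncating in a proto-oncogene (risk alleles there are
#'    gain-of-function, so truncation is not expected to raise risk);
#' 3. truncating but removing < 5% of the canonical transcript;
#' 4. in a recessive-only gene without a second filtered variant in the
#'    same gene in the same individual (homozygous counts as two; two
#'    distinct heterozygous hits are presumed compound-heterozygous);
#' 5. retained solely through HGMD-DM or CADD, with ClinVar
#'    benign/uncertain at >= 2 stars, or at 1 star with multiple
#'    submissions and no pathogenic assertion.
#'
#' @param variants retained variants (rows must carry `gene_symbol`,
#'   `zygosity`, `individual_id` and the annotation columns).
#' @param panel a `cpg_panel`; every `gene_symbol` must be in it.
#' @param retention retention disposition for the same rows (provides the
#'   `cadd_only` flag and reason codes); defaults to recomputing.
#' @param config [snv_config()].
#' @return data.frame with `stage`, `outcome` (excluded /
#'   retained_for_assessment) and `reason_codes` naming the triggering
#'   criteria.
#' @export
exclusion_rules <- function(variants, panel,
                            retention = retention_rules(variants, config),
                            config = snv_config()) {
  idx <- match(variants$gene_symbol, panel$genes$symbol)
  if (anyNA(idx)) {
    stop("variant gene symbol(s) absent from panel: ",
         paste(unique(variants$gene_symbol[is.na(idx)]), collapse = ", "))
  }
  proto <- panel$genes$proto_oncogene[idx]
  recessive <- panel$genes$recessive_only[idx]

  so <- variants$so_consequence
  trunc <- !is.na(so) & so %in% config$truncating_terms
  ben_unc <- clinvar_benign_uncertain(variants)
  stars <- variants$clinvar_stars
  subs <- variants$clinvar_submission_count
  tf <- variants$truncation_fraction

  c1 <- trunc & ben_unc & !is.na(stars) & stars >= config$min_clinvar_stars
  c2 <- trunc & proto
  ## missing truncation fraction -> criterion 3 not applied
  c3 <- trunc & !is.na(tf) & tf < 0.05
  if (any(trunc & is.na(tf))) {
    message(sum(trunc & is.na(tf)),
            " truncating variant(s) lack a truncation fraction; ",
            "minimal-truncation criterion not applied to them")
  }

  ## criterion 4: count filtered variants per individual x gene across the
  ## retained set itself; homozygous counts as two
  weight <- ifelse(!is.na(variants$zygosity) & variants$zygosity == "hom",
                   2L, 1L)
  key <- paste(variants$individual_id, variants$gene_symbol, sep = "\r")
  hits <- as.vector(tapply(weight, key, sum)[key])
  c4 <- recessive & hits < 2

  solely_insilico <- retention$cadd_only |
    vapply(split_codes(retention$reason_codes), function(r) {
      length(r) > 0 &&
        all(r %in% c("hgmd_dm", "cadd_above_threshold"))
    }, logical(1))
  refuted <- (ben_unc & !is.na(stars) & stars >= config$min_clinvar_stars) |
    (ben_unc & !is.na(stars) & stars == 1 & !is.na(subs) & subs >= 2)
  c5 <- solely_insilico & refuted

  reason <- cbind(
    ifelse(c1, "truncating_with_benign_clinvar", NA),
    ifelse(c2, "truncating_in_proto_oncogene", NA),
    ifelse(c3, "minimal_truncation", NA),
    ifelse(c4, "recessive_without_second_variant", NA),
    ifelse(c5, "insilico_refuted_by_clinvar", NA))
  out <- disposition(rep("exclusion", nrow(variants)),
                     rowSums(!is.na(reason)) == 0, reason,
                     outcome_pass = "retained_for_assessment",
                     outcome_fail = "excluded")
  out$stage[out$outcome == "retained_for_assessment"] <-
    "retained_for_assessment"
  out
}

## columns that uniquely identify a called genotype
variant_key_cols <- c("individual_id", "contig", "position", "ref", "alt")

variant_key <- function(variants) {
  do.call(paste, c(variants[variant_key_cols], sep = "\r"))
}

#' Run the full SNV/indel triage cascade
#'
#' Orchestrates deduplication, the quality gate, the frequency gate, the
#' retention rules (with the in-silico CADD route as a second pass), the
#' non-coding positional lookup and the exclusion criteria. Every input
#' variant receives exactly one terminal disposition and the per-stage
#' audit counts conserve the input count exactly.
#'
#' @param variants annotated-variant data.frame.
#' @param panel a `cpg_panel`.
#' @param config [snv_config()].
#' @return an object of class `snv_triage`: list with `retained`
#'   (variants retained for ACMG assessment, sorted by contig, position,
#'   alt, individual; with retention reason codes), `dispositions`
#'   (terminal disposition for every deduplicated input row), `audit`
#'   (named per-stage counts), and `quarantine` (malformed rows set aside
#'   with a warning, never silently dropped).
#' @export
run_snv_pipeline <- function(variants, panel, config = snv_config()) {
  required <- c(variant_key_cols, "gene_symbol", "so_consequence", "gq",
                "dp", "alt_depth", "filter_status", "af_exac", "af_1kg",
                "clinvar_assertion", "clinvar_stars",
                "clinvar_submission_count", "hgmd_dm", "cadd_phred",
                "truncation_fraction", "zygosity")
  stop_if_missing_cols(variants, required, "variant table")
  n_input <- nrow(variants)

  ## quarantine malformed records
  bad <- is.na(variants$contig) | is.na(variants$position) |
    is.na(variants$ref) | is.na(variants$alt) |
    is.na(variants$individual_id) |
    (!is.na(variants$alt_depth) & !is.na(variants$dp) &
       variants$alt_depth > variants$dp) |
    (!is.na(variants$af_exac) & variants$af_exac < 0) |
    (!is.na(variants$af_1kg) & variants$af_1kg < 0) |
    (!is.na(variants$truncation_fraction) &
       (variants$truncation_fraction < 0 | variants$truncation_fraction > 1))
  quarantine <- variants[bad, , drop = FALSE]
  if (nrow(quarantine)) {
    warning(nrow(quarantine), " malformed record(s) quarantined")
  }
  variants <- variants[!bad, , drop = FALSE]

  ## deduplicate on (individual, contig, pos, ref, alt)
  dup <- duplicated(variant_key(variants))
  if (any(dup)) {
    warning(sum(dup), " duplicate record(s) removed")
  }
  variants <- variants[!dup, , drop = FALSE]
  n <- nrow(variants)

  dispo <- data.frame(variants[variant_key_cols],
                      gene_symbol = variants$gene_symbol,
                      stage = rep(NA_character_, n),
                      outcome = rep(NA_character_, n),
                      reason_codes = rep(NA_character_, n),
                      stringsAsFactors = FALSE)

  if (n == 0) {
    empty_audit <- audit_counts(n_input, nrow(quarantine), sum(dup), dispo)
    return(structure(list(retained = variants, dispositions = dispo,
                          audit = empty_audit, quarantine = quarantine),
                     class = "snv_triage"))
  }

  q <- quality_filter(variants, config)
  qfail <- q$outcome == "fail"
  dispo[qfail, c("stage", "outcome", "reason_codes")] <-
    q[qfail, c("stage", "outcome", "reason_codes")]

  f <- frequency_filter(variants, config)
  ffail <- !qfail & f$outcome == "fail"
  dispo[ffail, c("stage", "outcome", "reason_codes")] <-
    f[ffail, c("stage", "outcome", "reason_codes")]

  open <- !qfail & !ffail

  ret <- retention_rules(variants, config)
  nc <- noncoding_lookup(variants, panel)
  ## two-pass structure: database/consequence routes first, then the
  ## in-silico (CADD-only) second pass; assert equivalence to single-pass
  first_pass <- open & ret$outcome == "retained" & !ret$cadd_only
  second_pass <- open & ret$outcome == "retained" & ret$cadd_only
  retained_flag <- (first_pass | second_pass | (open & nc))
  stopifnot(identical(retained_flag,
                      open & (ret$outcome == "retained" | nc)))

  ret$reason_codes[nc & ret$outcome != "retained"] <- ""
  ret$reason_codes[nc] <- ifelse(
    ret$reason_codes[nc] == "", "noncoding_pathogenic_position",
    paste(ret$reason_codes[nc], "noncoding_pathogenic_position", sep = ";"))

  not_ret <- open & !retained_flag
  dispo$stage[not_ret] <- "retention"
  dispo$outcome[not_ret] <- "fail"
  dispo$reason_codes[not_ret] <- "no_retention_criterion"

  retained <- variants[retained_flag, , drop = FALSE]
  ret_ret <- ret[retained_flag, , drop = FALSE]
  if (nrow(retained)) {
    exc <- exclusion_rules(retained, panel, retention = ret_ret,
                           config = config)
    dispo[retained_flag, c("stage", "outcome", "reason_codes")] <-
      exc[, c("stage", "outcome", "reason_codes")]
    keep <- exc$outcome == "retained_for_assessment"
    retained <- retained[keep, , drop = FALSE]
    retained$retention_reasons <- ret_ret$reason_codes[keep]
  } else {
    retained$retention_reasons <- character(0)
  }

  ord <- order(retained$contig, retained$position, retained$alt,
               retained$individual_id)
  retained <- retained[ord, , drop = FALSE]
  rownames(retained) <- NULL

  audit <- audit_counts(n_input, nrow(quarantine), sum(dup), dispo)
  stopifnot(!anyNA(dispo$outcome))
  structure(list(retained = retained, dispositions = dispo, audit = audit,
                 quarantine = quarantine),
            class = "snv_triage")
}

audit_counts <- function(n_input, n_quarantined, n_duplicates, dispo) {
  counts <- list(
    n_input = n_input,
    n_quarantined = n_quarantined,
    n_duplicates = n_duplicates,
    n_fail_quality = sum(dispo$stage == "quality" &
                           dispo$outcome == "fail", na.rm = TRUE),
    n_fail_frequency = sum(dispo$stage == "frequency" &
                             dispo$outcome == "fail", na.rm = TRUE),
    n_not_retained = sum(dispo$stage == "retention" &
                           dispo$outcome == "fail", na.rm = TRUE),
    n_excluded = sum(dispo$outcome == "excluded", na.rm = TRUE),
    n_retained_for_assessment = sum(
      dispo$outcome == "retained_for_assessment", na.rm = TRUE))
  ## conservation: input = quarantined + duplicates + every terminal outcome
  stopifnot(n_input == n_quarantined + n_duplicates +
              counts$n_fail_quality + counts$n_fail_frequency +
              counts$n_not_retained + counts$n_excluded +
              counts$n_retained_for_assessment)
  counts
}

#' @export
print.snv_triage <- function(x, ...) {
  a <- x$audit
  cat("SNV triage:", a$n_input, "input;",
      a$n_retained_for_assessment, "retained for assessment\n")
  cat(sprintf(
    "  quarantined %d | duplicates %d | quality fail %d | frequency fail %d | not retained %d | excluded %d\n",
    a$n_quarantined, a$n_duplicates, a$n_fail_quality, a$n_fail_frequency,
    a$n_not_retained, a$n_excluded))
  invisible(x)
}
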