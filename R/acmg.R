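## ACMG/AMP evidence combination. Evidence codes arrive as input (curator
## judgment is not automated); this module applies the published combining
## rules to produce the five-tier classification, plus cohort-level
## tallies. A clearly-labelled heuristic pre-populator can seed a handful
## of codes from the variant annotations.

#' Valid ACMG evidence codes
#'
#' @return character vector of the recognized code identifiers.
#' @export
acmg_codes <- function() {
  c("PVS1",
    paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5),
    "BA1", paste0("BS", 1:4), paste0("BP", 1:7))
}

acmg_strength <- function(codes) {
  sub("^(PVS|PS|PM|PP|BA|BS|BP)[0-9]+$", "\\1", codes)
}

#' Combine ACMG evidence codes into a five-tier classification
#'
#' Applies the published combining table. Pathogenic: PVS1 with (>=1 PS,
#' >=2 PM, 1 PM + 1 PP, or >=2 PP); >=2 PS; or 1 PS with (>=3 PM,
#' 2 PM + >=2 PP, or 1 PM + >=4 PP). Likely pathogenic: PVS1 + 1 PM;
#' 1 PS + 1-2 PM; 1 PS + >=2 PP; >=3 PM; 2 PM + >=2 PP; or 1 PM + >=4 PP.
#' Benign: BA1 or >=2 BS. Likely benign: 1 BS + 1 BP or >=2 BP.
#' Everything else — including any case where both a pathogenic-side and a
#' benign-side rule fire (conflicting evidence) — is uncertain.
#'
#' @param codes character vector of evidence codes (each at most once);
#'   duplicates are collapsed, unknown codes are rejected.
#' @return one of `"pathogenic"`, `"likely_pathogenic"`, `"uncertain"`,
#'   `"likely_benign"`, `"benign"`.
#' @export
combine_acmg <- function(codes) {
  codes <- unique(codes[!is.na(codes) & nzchar(codes)])
  bad <- setdiff(codes, acmg_codes())
  if (length(bad)) {
    stop("unknown ACMG evidence code(s): ", paste(bad, collapse = ", "),
         "; valid codes are ", paste(acmg_codes(), collapse = ", "))
  }
  s <- acmg_strength(codes)
  pvs <- sum(s == "PVS"); ps <- sum(s == "PS"); pm <- sum(s == "PM")
  pp <- sum(s == "PP"); ba <- sum(s == "BA"); bs <- sum(s == "BS")
  bp <- sum(s == "BP")

  pathogenic <-
    (pvs >= 1 && (ps >= 1 || pm >= 2 || (pm == 1 && pp >= 1) || pp >= 2)) ||
    ps >= 2 ||
    (ps == 1 && (pm >= 3 || (pm == 2 && pp >= 2) || (pm == 1 && pp >= 4)))
  likely_pathogenic <-
    (pvs >= 1 && pm == 1) ||
    (ps == 1 && pm >= 1 && pm <= 2) ||
    (ps == 1 && pp >= 2) ||
    pm >= 3 ||
    (pm == 2 && pp >= 2) ||
    (pm == 1 && pp >= 4)
  benign <- ba >= 1 || bs >= 2
  likely_benign <- (bs == 1 && bp >= 1) || bp >= 2

  path_side <- pathogenic || likely_pathogenic
  benign_side <- benign || likely_benign
  if (path_side && benign_side) return("uncertain")
  if (pathogenic) return("pathogenic")
  if (likely_pathogenic) return("likely_pathogenic")
  if (benign) return("benign")
  if (likely_benign) return("likely_benign")
  "uncertain"
}

#' Classify a table of variants from evidence-code strings
#'
#' @param evidence data.frame with `variant_id` and `codes`
#'   (semicolon-separated evidence identifiers; empty for no evidence).
#' @return the input with an added `tier` column.
#' @export
classify_evidence <- function(evidence) {
  stop_if_missing_cols(evidence, c("variant_id", "codes"), "evidence table")
  evidence$tier <- vapply(split_codes(evidence$codes), combine_acmg,
                          character(1))
  evidence
}

#' Heuristic evidence pre-populator
#'
#' Seeds a small set of codes from variant annotations: PVS1 for a
#' truncating consequence in a gene where loss of function is the disease
#' mechanism (not a proto-oncogene), PM2 for absence from the reference
#' populations, PP3 for a CADD score at or above the retention threshold.
#' A convenience starting point for curation, not a substitute for it.
#'
#' @param variants annotated-variant data.frame.
#' @param panel a `cpg_panel`.
#' @param config [snv_config()].
#' @return data.frame with `variant_id` (contig:pos:ref:alt) and `codes`.
#' @export
suggest_evidence <- function(variants, panel, config = snv_config()) {
  idx <- match(variants$gene_symbol, panel$genes$symbol)
  proto <- panel$genes$proto_oncogene[idx]
  trunc <- !is.na(variants$so_consequence) &
    variants$so_consequence %in% config$truncating_terms
  absent <- (is.na(variants$af_exac) | variants$af_exac == 0) &
    (is.na(variants$af_1kg) | variants$af_1kg == 0)
  cadd_hi <- !is.na(variants$cadd_phred) &
    variants$cadd_phred >= config$cadd_threshold
  codes <- mapply(function(a, b, c3) {
    paste(c(if (a) "PVS1", if (b) "PM2", if (c3) "PP3"), collapse = ";")
  }, trunc & !is.na(proto) & !proto, absent, cadd_hi)
  data.frame(
    variant_id = paste(variants$contig, variants$position, variants$ref,
                       variants$alt, sep = ":"),
    codes = unname(codes), stringsAsFactors = FALSE)
}

#' Tally cohort classifications
#'
#' Counts unique variants and occurrences per tier and per gene, and the
#' family-deduplicated proband-level pathogenic/likely-pathogenic
#' detection indicator (when a variant occurs in two members of the same
#' family, the family contributes once to the detection rate).
#'
#' @param classified data.frame with one row per variant occurrence:
#'   `variant_id`, `tier`, `individual_id`, `family_id`, and optionally
#'   `gene_symbol`.
#' @return list with `unique_by_tier`, `occurrences_by_tier`,
#'   `n_unique_variants`, `n_occurrences`, `by_gene` (occurrence counts),
#'   `families_with_plp` (character vector), `n_families_with_plp`.
#' @export
tally_classifications <- function(classified) {
  tiers <- c("pathogenic", "likely_pathogenic", "uncertain",
             "likely_benign", "benign")
  if (!nrow(classified)) {
    z <- setNames(integer(length(tiers)), tiers)
    return(list(unique_by_tier = z, occurrences_by_tier = z,
                n_unique_variants = 0L, n_occurrences = 0L,
                by_gene = integer(0), families_with_plp = character(0),
                n_families_with_plp = 0L))
  }
  stop_if_missing_cols(classified, c("variant_id", "tier", "individual_id",
                                     "family_id"), "classified table")
  uni <- classified[!duplicated(classified$variant_id), , drop = FALSE]
  unique_by_tier <- setNames(
    vapply(tiers, function(t) sum(uni$tier == t), integer(1)), tiers)
  occurrences_by_tier <- setNames(
    vapply(tiers, function(t) sum(classified$tier == t), integer(1)), tiers)
  by_gene <- if (!is.null(classified$gene_symbol)) {
    sort(table(classified$gene_symbol), decreasing = TRUE)
  } else integer(0)
  plp <- classified$tier %in% c("pathogenic", "likely_pathogenic")
  fams <- unique(classified$family_id[plp])
  list(unique_by_tier = unique_by_tier,
       occurrences_by_tier = occurrences_by_tier,
       n_unique_variants = nrow(uni),
       n_occurrences = nrow(classified),
       by_gene = by_gene,
       families_with_plp = fams,
       n_families_with_plp = length(fams))
}
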