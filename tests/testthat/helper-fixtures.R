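## Fixture builders and independent oracles. Oracles deliberately use a
## different formulation than the implementation they check (explicit
## loops, sort-and-index, rule-pattern matching) so agreement is evidence,
## not tautology.

make_variant <- function(individual_id = "P1", contig = "chr1",
                         position = 1100L, ref = "A", alt = "T",
                         gene_symbol = "TSG1",
                         so_consequence = "stop_gained", gq = 60, dp = 30,
                         alt_depth = 15, filter_status = "PASS",
                         af_exac = NA_real_, af_1kg = NA_real_,
                         clinvar_assertion = NA_character_,
                         clinvar_stars = NA_real_,
                         clinvar_submission_count = NA_real_,
                         hgmd_dm = FALSE, cadd_phred = NA_real_,
                         truncation_fraction = 0.5, zygosity = "het") {
  data.frame(individual_id = individual_id, contig = contig,
             position = position, ref = ref, alt = alt,
             gene_symbol = gene_symbol, so_consequence = so_consequence,
             gq = gq, dp = dp, alt_depth = alt_depth,
             filter_status = filter_status, af_exac = af_exac,
             af_1kg = af_1kg, clinvar_assertion = clinvar_assertion,
             clinvar_stars = clinvar_stars,
             clinvar_submission_count = clinvar_submission_count,
             hgmd_dm = hgmd_dm, cadd_phred = cadd_phred,
             truncation_fraction = truncation_fraction,
             zygosity = zygosity, stringsAsFactors = FALSE)
}

## three-gene panel: one ordinary TSG, one proto-oncogene, one
## recessive-only gene; one known pathogenic intronic position in TSG1
test_panel <- function() {
  genes <- data.frame(
    symbol = c("TSG1", "ONC1", "REC1"),
    proto_oncogene = c(0, 1, 0),
    recessive_only = c(0, 0, 1),
    characteristic_tumors = c("breast;ovary", "", "colorectal"),
    stringsAsFactors = FALSE)
  exons <- GenomicRanges::GRanges(
    rep(c("chr1", "chr2", "chr3"), each = 3),
    IRanges::IRanges(rep(c(1000L, 3000L, 5000L), 3), width = 200L),
    symbol = rep(c("TSG1", "ONC1", "REC1"), each = 3))
  noncoding <- data.frame(contig = "chr1", position = 1500L, ref = "G",
                          alt = "A", stringsAsFactors = FALSE)
  cpg_panel(genes, exons = exons, noncoding = noncoding)
}

## ---- ACMG oracle: explicit rule-pattern matching -----------------------
## Each pattern is a vector of minimum counts per strength class; a tier's
## rule fires when any of its patterns is met. Pathogenic takes priority
## over likely pathogenic, any pathogenic-side + benign-side co-firing is
## uncertain.
oracle_acmg <- function(codes) {
  cnt <- c(PVS = sum(grepl("^PVS", codes)), PS = sum(grepl("^PS", codes)),
           PM = sum(grepl("^PM", codes)), PP = sum(grepl("^PP", codes)),
           BA = sum(grepl("^BA", codes)), BS = sum(grepl("^BS", codes)),
           BP = sum(grepl("^BP", codes)))
  meets <- function(patterns) {
    any(vapply(patterns, function(p) all(cnt[names(p)] >= p), logical(1)))
  }
  path <- meets(list(
    c(PVS = 1, PS = 1), c(PVS = 1, PM = 2), c(PVS = 1, PM = 1, PP = 1),
    c(PVS = 1, PP = 2), c(PS = 2), c(PS = 1, PM = 3),
    c(PS = 1, PM = 2, PP = 2), c(PS = 1, PM = 1, PP = 4)))
  lp <- meets(list(
    c(PVS = 1, PM = 1), c(PS = 1, PM = 1), c(PS = 1, PP = 2),
    c(PM = 3), c(PM = 2, PP = 2), c(PM = 1, PP = 4)))
  ben <- meets(list(c(BA = 1), c(BS = 2)))
  lb <- meets(list(c(BS = 1, BP = 1), c(BP = 2)))
  if ((path || lp) && (ben || lb)) return("uncertain")
  if (path) return("pathogenic")
  if (lp) return("likely_pathogenic")
  if (ben) return("benign")
  if (lb) return("likely_benign")
  "uncertain"
}

## ---- median oracle: sort and index ------------------------------------
oracle_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

## ---- single-pass cascade oracle ---------------------------------------
## Naive per-row reapplication of every predicate, structured nothing like
## the pipeline: one flat loop, no staging, set semantics for dedup.
oracle_retained_keys <- function(variants, panel, cadd_threshold = 34) {
  key <- paste(variants$individual_id, variants$contig, variants$position,
               variants$ref, variants$alt, sep = "|")
  variants <- variants[!duplicated(key), , drop = FALSE]
  key <- key[!duplicated(key)]
  trunc_terms <- truncating_so_terms()
  gene <- function(sym) panel$genes[panel$genes$symbol == sym, ]
  nckey <- paste(panel$noncoding$contig, panel$noncoding$position,
                 panel$noncoding$ref, panel$noncoding$alt)

  survives_gates <- logical(nrow(variants))
  retained <- logical(nrow(variants))
  reasons_insilico_only <- logical(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    q <- !is.na(v$gq) && !is.na(v$dp) && !is.na(v$alt_depth) &&
      v$gq >= 30 && v$dp >= 10 && v$dp > 0 &&
      (v$alt_depth / v$dp) * 100 >= 33 - 1e-12 &&
      !is.na(v$filter_status) && v$filter_status == "PASS"
    af1 <- if (is.na(v$af_exac)) 0 else v$af_exac
    af2 <- if (is.na(v$af_1kg)) 0 else v$af_1kg
    f <- af1 <= 0.01 && af2 <= 0.01
    tr <- !is.na(v$so_consequence) && v$so_consequence %in% trunc_terms
    plp <- !is.na(v$clinvar_assertion) &&
      v$clinvar_assertion %in% c("pathogenic", "likely_pathogenic") &&
      !is.na(v$clinvar_stars) && v$clinvar_stars >= 2
    dm <- isTRUE(v$hgmd_dm)
    ca <- !is.na(v$cadd_phred) && v$cadd_phred >= cadd_threshold
    nc <- paste(v$contig, v$position, v$ref, v$alt) %in% nckey
    survives_gates[i] <- q && f
    retained[i] <- q && f && (tr || plp || dm || ca || nc)
    reasons_insilico_only[i] <- (dm || ca) && !tr && !plp && !nc
  }

  ## exclusion criteria on the retained set
  keep <- logical(nrow(variants))
  for (i in which(retained)) {
    v <- variants[i, ]
    g <- gene(v$gene_symbol)
    tr <- !is.na(v$so_consequence) &&
      v$so_consequence %in% trunc_terms
    bu <- !is.na(v$clinvar_assertion) &&
      v$clinvar_assertion %in% c("benign", "likely_benign", "uncertain",
                                 "conflicting")
    st <- v$clinvar_stars
    c1 <- tr && bu && !is.na(st) && st >= 2
    c2 <- tr && g$proto_oncogene
    c3 <- tr && !is.na(v$truncation_fraction) &&
      v$truncation_fraction < 0.05
    same_gene <- which(retained &
                         variants$individual_id == v$individual_id &
                         variants$gene_symbol == v$gene_symbol)
    n_hits <- sum(ifelse(variants$zygosity[same_gene] == "hom", 2, 1))
    c4 <- g$recessive_only && n_hits < 2
    c5 <- reasons_insilico_only[i] && bu && !is.na(st) &&
      (st >= 2 || (st == 1 && !is.na(v$clinvar_submission_count) &&
                     v$clinvar_submission_count >= 2))
    keep[i] <- !(c1 || c2 || c3 || c4 || c5)
  }
  sort(key[keep])
}

retained_keys <- function(triage) {
  r <- triage$retained
  sort(paste(r$individual_id, r$contig, r$position, r$ref, r$alt,
             sep = "|"))
}
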