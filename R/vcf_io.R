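## VCF 4.2 I/O for annotated small variants. Annotations travel as INFO
## key=value pairs (keys configurable to match the local annotation
## pipeline); genotype quality fields come from the FORMAT column of the
## single sample in each file. Reading uses vcfR; writing emits VCF text.

#' Default INFO-key mapping
#'
#' Maps annotated-variant columns to the VCF INFO keys that carry them.
#'
#' @return named character vector (column -> INFO key).
#' @export
vcf_info_keys <- function() {
  c(gene_symbol = "GENE", so_consequence = "CSQ_SO", af_exac = "AF_EXAC",
    af_1kg = "AF_1KG", clinvar_assertion = "CLNSIG",
    clinvar_stars = "CLNREVSTAT", clinvar_submission_count = "CLNSUBS",
    hgmd_dm = "HGMD_DM", cadd_phred = "CADD_PHRED",
    truncation_fraction = "TRUNC_FRAC")
}

#' Read an annotated single-sample VCF
#'
#' @param path VCF path (plain text or bgzipped).
#' @param info_keys column -> INFO key mapping, see [vcf_info_keys()].
#' @param individual_id identifier for the sample; defaults to the VCF
#'   sample column name.
#' @return annotated-variant data.frame with the columns
#'   [run_snv_pipeline()] expects.
#' @export
read_annotated_vcf <- function(path, info_keys = vcf_info_keys(),
                               individual_id = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  n <- nrow(fix)
  sample_name <- colnames(vcf@gt)[2]
  get_info <- function(key, as = "character") {
    v <- vcfR::extract.info(vcf, element = key, as.numeric = as == "numeric")
    if (is.null(v)) v <- rep(NA, n)
    v
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")[, 1]
  gq <- as.numeric(vcfR::extract.gt(vcf, element = "GQ")[, 1])
  dp <- as.integer(vcfR::extract.gt(vcf, element = "DP")[, 1])
  ad <- vcfR::extract.gt(vcf, element = "AD")[, 1]
  alt_depth <- as.integer(vapply(strsplit(ad, ","), function(x) {
    if (length(x) >= 2) x[2] else NA_character_
  }, character(1)))
  data.frame(
    individual_id = individual_id %||% sample_name,
    contig = fix$CHROM,
    position = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    gene_symbol = get_info(info_keys[["gene_symbol"]]),
    so_consequence = get_info(info_keys[["so_consequence"]]),
    gq = gq, dp = dp, alt_depth = alt_depth,
    filter_status = fix$FILTER,
    af_exac = get_info(info_keys[["af_exac"]], "numeric"),
    af_1kg = get_info(info_keys[["af_1kg"]], "numeric"),
    clinvar_assertion = get_info(info_keys[["clinvar_assertion"]]),
    clinvar_stars = get_info(info_keys[["clinvar_stars"]], "numeric"),
    clinvar_submission_count = get_info(
      info_keys[["clinvar_submission_count"]], "numeric"),
    hgmd_dm = !is.na(get_info(info_keys[["hgmd_dm"]])) &
      get_info(info_keys[["hgmd_dm"]]) == "1",
    cadd_phred = get_info(info_keys[["cadd_phred"]], "numeric"),
    truncation_fraction = get_info(info_keys[["truncation_fraction"]],
                                   "numeric"),
    zygosity = ifelse(gt %in% c("1/1", "1|1"), "hom", "het"),
    stringsAsFactors = FALSE)
}

#' Write annotated variants for one individual as VCF 4.2
#'
#' @param variants annotated-variant data.frame (single individual).
#' @param path output path.
#' @param info_keys column -> INFO key mapping.
#' @return invisibly, `path`.
#' @export
write_annotated_vcf <- function(variants, path,
                                info_keys = vcf_info_keys()) {
  if (length(unique(variants$individual_id)) > 1) {
    stop("write_annotated_vcf writes one individual per file")
  }
  sample_name <- if (nrow(variants)) variants$individual_id[1] else "SAMPLE"
  contigs <- unique(variants$contig)
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", contigs),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"%s\">",
            unname(info_keys), names(info_keys)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_name), collapse = "\t"))
  fmt_info <- function(i) {
    parts <- character(0)
    for (col in names(info_keys)) {
      v <- variants[[col]][i]
      if (is.na(v) || identical(v, "")) next
      if (is.logical(v)) v <- as.integer(v)
      parts <- c(parts, paste0(info_keys[[col]], "=", v))
    }
    if (!length(parts)) "." else paste(parts, collapse = ";")
  }
  records <- vapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    gt <- if (!is.na(v$zygosity) && v$zygosity == "hom") "1/1" else "0/1"
    ad <- paste(v$dp - v$alt_depth, v$alt_depth, sep = ",")
    paste(v$contig, v$position, ".", v$ref, v$alt, ".",
          v$filter_status, fmt_info(i), "GT:GQ:DP:AD",
          paste(gt, v$gq, v$dp, ad, sep = ":"), sep = "\t")
  }, character(1))
  writeLines(c(header, records), path)
  invisible(path)
}

#' Read / write an SV call table (BEDPE-like TSV)
#'
#' Columns: `caller` (canvas/manta), `sv_type` (deletion, duplication,
#' inversion, translocation, copy_gain, copy_loss), `contig_a`, `start_a`,
#' `contig_b`, `end_b` (second breakend; same contig unless translocation),
#' `quality` (GQ for manta, QUAL for canvas), `cohort_frequency`,
#' `zygosity`, `individual_id`. Coordinates are 1-based inclusive.
#'
#' @param path TSV path.
#' @return data.frame of SV calls.
#' @export
read_sv_table <- function(path) {
  sv <- read.table(path, header = TRUE, sep = "\t", quote = "",
                   stringsAsFactors = FALSE)
  stop_if_missing_cols(sv, c("caller", "sv_type", "contig_a", "start_a",
                             "contig_b", "end_b", "quality",
                             "cohort_frequency", "zygosity",
                             "individual_id"), "SV table")
  sv
}

#' @rdname read_sv_table
#' @param svs SV call data.frame.
#' @export
write_sv_table <- function(svs, path) {
  write.table(svs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a CNV map (BED)
#'
#' Common copy-number variation regions, used to exclude SV calls fully
#' contained in a known polymorphic region.
#'
#' @param path BED path (0-based half-open on disk).
#' @return `GRanges` (1-based internally).
#' @export
read_cnv_map <- function(path) {
  rtracklayer::import(path, format = "BED")
}
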