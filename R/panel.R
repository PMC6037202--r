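## Gene panel: the set of cancer-predisposition genes (CPGs) against which
## variants are triaged, with the per-gene flags the filtering rules need
## (proto-oncogene: truncation does not raise risk; recessive-only: one
## heterozygous hit is insufficient), the characteristic-tumor categories
## used for genotype-phenotype concordance, exon intervals, and the short
## list of known pathogenic non-coding positions searched by position.

#' Construct a CPG panel
#'
#' @param genes data.frame with columns `symbol`, `proto_oncogene` (logical
#'   or 0/1), `recessive_only` (logical or 0/1), and `characteristic_tumors`
#'   (semicolon-separated string or list of character vectors; may be
#'   empty).
#' @param exons `GRanges` of exon intervals with a `symbol` metadata column,
#'   or `NULL` for a panel without coordinates (SNV triage does not need
#'   them; SV triage does).
#' @param noncoding data.frame of known pathogenic non-coding positions
#'   with columns `contig`, `position`, `ref`, `alt`, or `NULL`.
#' @return object of class `cpg_panel`.
#' @export
cpg_panel <- function(genes, exons = NULL, noncoding = NULL) {
  stop_if_missing_cols(genes, c("symbol", "proto_oncogene", "recessive_only"),
                       "panel gene table")
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (anyDuplicated(genes$symbol)) {
    stop("panel gene symbols must be unique: ",
         paste(unique(genes$symbol[duplicated(genes$symbol)]), collapse = ", "))
  }
  genes$proto_oncogene <- as.logical(as.integer(genes$proto_oncogene))
  genes$recessive_only <- as.logical(as.integer(genes$recessive_only))
  ct <- genes$characteristic_tumors %||% rep("", nrow(genes))
  if (!is.list(ct)) ct <- split_codes(as.character(ct))
  genes$characteristic_tumors <- I(lapply(ct, function(x) x[nzchar(x)]))

  if (is.null(exons)) exons <- GenomicRanges::GRanges()
  if (!methods::is(exons, "GRanges")) {
    stop("exons must be a GRanges (or NULL)")
  }
  if (length(exons)) {
    if (is.null(exons$symbol)) stop("exon GRanges needs a 'symbol' column")
    unknown <- setdiff(unique(exons$symbol), genes$symbol)
    if (length(unknown)) {
      stop("exons reference symbols absent from the panel: ",
           paste(unknown, collapse = ", "))
    }
    ncontig <- vapply(
      split(as.character(GenomicRanges::seqnames(exons)), exons$symbol),
      function(x) length(unique(x)), integer(1))
    if (any(ncontig > 1)) {
      stop("exons of a single gene must lie on one contig: ",
           paste(names(ncontig)[ncontig > 1], collapse = ", "))
    }
  }

  if (!is.null(noncoding)) {
    stop_if_missing_cols(noncoding, c("contig", "position", "ref", "alt"),
                         "noncoding position table")
    noncoding <- as.data.frame(noncoding, stringsAsFactors = FALSE)
  } else {
    noncoding <- data.frame(contig = character(), position = integer(),
                            ref = character(), alt = character(),
                            stringsAsFactors = FALSE)
  }

  structure(list(genes = genes, exons = exons, noncoding = noncoding),
            class = "cpg_panel")
}

#' @export
print.cpg_panel <- function(x, ...) {
  cat(sprintf(
    "CPG panel: %d genes (%d proto-oncogene, %d recessive-only), %d exons, %d non-coding positions\n",
    nrow(x$genes), sum(x$genes$proto_oncogene), sum(x$genes$recessive_only),
    length(x$exons), nrow(x$noncoding)))
  invisible(x)
}

#' Default 83-gene CPG panel
#'
#' The adult cancer-predisposition gene panel used for the MPT triage
#' cascade, with proto-oncogene and recessive-only flags. The
#' characteristic-tumor map is a best-effort reconstruction from the
#' published gene-tumor associations and ships as an editable configuration
#' table (`inst/extdata/cpg_panel_default.tsv`); it carries no exon
#' coordinates (supply a BED file, or use [generate_panel()] for synthetic
#' work).
#'
#' @return a `cpg_panel`.
#' @export
default_panel <- function() {
  path <- system.file("extdata", "cpg_panel_default.tsv", package = "mptriage")
  genes <- read.table(path, header = TRUE, sep = "\t", quote = "",
                      colClasses = "character")
  cpg_panel(genes)
}

#' Tumor-category vocabulary
#'
#' Controlled vocabulary of tumor-category labels with per-category
#' `malignant` and `cns` flags (used when restricting cohorts for registry
#' comparison). A reconstruction shipped as configuration; edit or replace
#' to match local coding practice.
#'
#' @param path optional TSV with columns `category`, `malignant`, `cns`.
#' @return data.frame with logical `malignant` and `cns` columns.
#' @export
tumor_vocabulary <- function(path = NULL) {
  path <- path %||% system.file("extdata", "tumor_vocabulary.tsv",
                                package = "mptriage")
  voc <- read.table(path, header = TRUE, sep = "\t", quote = "",
                    colClasses = c("character", "integer", "integer"))
  voc$malignant <- as.logical(voc$malignant)
  voc$cns <- as.logical(voc$cns)
  voc
}

## gene transcribed spans (range of each gene's exons) as GRanges
gene_spans <- function(panel) {
  if (!length(panel$exons)) {
    return(GenomicRanges::GRanges())
  }
  ex <- panel$exons
  sym <- ex$symbol
  start <- tapply(GenomicRanges::start(ex), sym, min)
  end <- tapply(GenomicRanges::end(ex), sym, max)
  contig <- tapply(as.character(GenomicRanges::seqnames(ex)), sym,
                   function(x) x[1])
  spans <- GenomicRanges::GRanges(
    unname(contig),
    IRanges::IRanges(unname(start), unname(end)))
  spans$symbol <- names(start)
  spans
}

## ---- on-disk representation -------------------------------------------

#' Read a CPG panel from disk
#'
#' @param gene_tsv TSV with columns `symbol`, `proto_oncogene` (0/1),
#'   `recessive_only` (0/1), `characteristic_tumors` (semicolon-separated).
#' @param exon_bed optional BED file (0-based half-open) of exon intervals;
#'   the BED name column holds the gene symbol.
#' @param noncoding_tsv optional TSV with columns `contig`, `position`,
#'   `ref`, `alt` (1-based positions).
#' @return a `cpg_panel`.
#' @export
read_panel <- function(gene_tsv, exon_bed = NULL, noncoding_tsv = NULL) {
  genes <- read.table(gene_tsv, header = TRUE, sep = "\t", quote = "",
                      colClasses = "character")
  exons <- NULL
  if (!is.null(exon_bed)) {
    exons <- rtracklayer::import(exon_bed, format = "BED")
    exons$symbol <- exons$name
    exons$name <- NULL
    if (!is.null(exons$score)) exons$score <- NULL
  }
  noncoding <- NULL
  if (!is.null(noncoding_tsv)) {
    noncoding <- read.table(noncoding_tsv, header = TRUE, sep = "\t",
                            quote = "", stringsAsFactors = FALSE)
  }
  cpg_panel(genes, exons = exons, noncoding = noncoding)
}

#' Write a CPG panel to disk
#'
#' Inverse of [read_panel()]; a written panel re-reads bit-identically
#' (the files produced by a write/read/write cycle are byte-equal).
#'
#' @param panel a `cpg_panel`.
#' @param gene_tsv,exon_bed,noncoding_tsv output paths; `exon_bed` /
#'   `noncoding_tsv` may be `NULL` to skip.
#' @return invisibly, the paths written.
#' @export
write_panel <- function(panel, gene_tsv, exon_bed = NULL,
                        noncoding_tsv = NULL) {
  genes <- panel$genes
  out <- data.frame(
    symbol = genes$symbol,
    proto_oncogene = as.integer(genes$proto_oncogene),
    recessive_only = as.integer(genes$recessive_only),
    characteristic_tumors = join_codes(genes$characteristic_tumors),
    stringsAsFactors = FALSE)
  write.table(out, gene_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- gene_tsv
  if (!is.null(exon_bed)) {
    ex <- panel$exons
    bed <- data.frame(
      contig = as.character(GenomicRanges::seqnames(ex)),
      start = GenomicRanges::start(ex) - 1L,   # BED is 0-based half-open
      end = GenomicRanges::end(ex),
      name = ex$symbol, stringsAsFactors = FALSE)
    bed <- bed[order(bed$contig, bed$start, bed$end, bed$name), ]
    write.table(bed, exon_bed, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    paths <- c(paths, exon_bed)
  }
  if (!is.null(noncoding_tsv)) {
    write.table(panel$noncoding, noncoding_tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, noncoding_tsv)
  }
  invisible(paths)
}
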