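## Cohort phenotypes: one row per primary-tumor diagnosis. Tumour records
## arrive pre-adjudicated (deciding whether two lesions are separate
## primaries is upstream clinical work); this module only applies the
## multiple-primary-tumor (MPT) eligibility rule and annotates
## genotype-phenotype concordance.

#' MPT eligibility
#'
#' An individual qualifies as having multiple primary tumors when they have
#' at least two primaries by age 60 or at least three by age 70 ("by" is
#' inclusive of the boundary year).
#'
#' @param ages numeric vector of ages at diagnosis (years), one per
#'   adjudicated primary tumor.
#' @return logical flag.
#' @export
mpt_eligible <- function(ages) {
  if (length(ages) == 0) return(FALSE)
  if (anyNA(ages) || any(ages < 0) || any(ages > 120)) {
    stop("ages at diagnosis must be in [0, 120] and non-missing")
  }
  sum(ages <= 60) >= 2 || sum(ages <= 70) >= 3
}

#' Characteristic-tumor concordance
#'
#' Has this individual been diagnosed with a tumor type characteristically
#' associated with pathogenic variants in the gene? Duplicate diagnoses and
#' ordering are irrelevant; the answer is the non-emptiness of the
#' intersection between the individual's tumor categories and the gene's
#' characteristic set.
#'
#' @param tumor_categories character vector of the individual's tumor
#'   category labels (possibly empty).
#' @param gene one-row slice of a panel gene table, a gene symbol plus
#'   `panel`, or a character vector of characteristic categories.
#' @param panel optional `cpg_panel` used to resolve a gene symbol.
#' @param vocabulary optional controlled vocabulary (data.frame with a
#'   `category` column); when supplied, unknown tumor labels are rejected
#'   with the list of valid labels.
#' @return logical flag.
#' @export
characteristic_tumor <- function(tumor_categories, gene, panel = NULL,
                                 vocabulary = NULL) {
  if (!is.null(vocabulary)) {
    unknown <- setdiff(tumor_categories, vocabulary$category)
    if (length(unknown)) {
      stop("unknown tumor categories: ", paste(unknown, collapse = ", "),
           "; valid labels are: ", paste(vocabulary$category, collapse = ", "))
    }
  }
  chars <- gene
  if (is.character(gene) && length(gene) == 1 && !is.null(panel)) {
    i <- match(gene, panel$genes$symbol)
    if (is.na(i)) stop("gene ", gene, " is not in the panel")
    chars <- panel$genes$characteristic_tumors[[i]]
  } else if (is.data.frame(gene)) {
    chars <- gene$characteristic_tumors[[1]]
  }
  length(intersect(unique(tumor_categories), chars)) > 0
}

#' Read / write a cohort phenotype table
#'
#' One row per tumor: `individual_id`, `family_id`, `sex` (male/female),
#' `tumor_category`, `age_at_diagnosis`. Individuals with no tumors
#' (unaffected relatives) may appear with an empty `tumor_category`.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_cohort <- function(path) {
  ph <- read.table(path, header = TRUE, sep = "\t", quote = "",
                   stringsAsFactors = FALSE)
  stop_if_missing_cols(ph, c("individual_id", "family_id", "sex",
                             "tumor_category", "age_at_diagnosis"),
                       "cohort phenotype table")
  bad_sex <- setdiff(unique(ph$sex), c("male", "female"))
  if (length(bad_sex)) stop("sex must be male/female; got: ",
                            paste(bad_sex, collapse = ", "))
  ph
}

#' @rdname read_cohort
#' @param cohort phenotype data.frame as returned by [read_cohort()].
#' @export
write_cohort <- function(cohort, path) {
  write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Annotate retained variants with phenotype concordance
#'
#' For each (individual, gene) pair in a retained-variant table, record
#' whether the individual has had a tumor characteristic of that gene.
#'
#' @param variants data.frame with `individual_id` and `gene_symbol`.
#' @param cohort phenotype table (one row per tumor).
#' @param panel a `cpg_panel`.
#' @param vocabulary optional controlled vocabulary for label validation.
#' @return `variants` with an added logical `characteristic_tumor` column.
#' @export
annotate_concordance <- function(variants, cohort, panel, vocabulary = NULL) {
  tumors_by_ind <- split(cohort$tumor_category, cohort$individual_id)
  variants$characteristic_tumor <- mapply(function(ind, gene) {
    characteristic_tumor(tumors_by_ind[[ind]] %||% character(), gene,
                         panel = panel, vocabulary = vocabulary)
  }, variants$individual_id, variants$gene_symbol, USE.NAMES = FALSE)
  variants
}
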