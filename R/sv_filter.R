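## Structural-variant prioritization. Calls from a copy-number caller
## ("canvas") and a breakend caller ("manta") are merged, gated on quality,
## cohort frequency and exon/gene overlap, assigned one of three
## pathogenicity categories per intersected panel gene, and finally
## screened against a common copy-number-variation map.
##
## Coordinate conventions: SV tables are 1-based inclusive (VCF-style);
## interval arithmetic is done on GRanges; BED I/O is 0-based half-open on
## disk (handled by the I/O layer).

SPAN_SV_TYPES <- c("deletion", "duplication", "copy_gain", "copy_loss")
BREAKEND_SV_TYPES <- c("inversion", "translocation")

## put two GRanges on a shared seqlevel set so overlap operations do not
## warn about disjoint contig universes
shared_levels <- function(a, b) {
  lv <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  list(a = a, b = b)
}

overlaps_any <- function(a, b, ...) {
  h <- shared_levels(a, b)
  IRanges::overlapsAny(h$a, h$b, ...)
}

find_overlaps <- function(a, b, ...) {
  h <- shared_levels(a, b)
  GenomicRanges::findOverlaps(h$a, h$b, ...)
}

sv_validate <- function(svs) {
  stop_if_missing_cols(svs, c("caller", "sv_type", "contig_a", "start_a",
                              "contig_b", "end_b", "quality",
                              "cohort_frequency", "zygosity",
                              "individual_id"), "SV table")
  bad_type <- setdiff(unique(svs$sv_type),
                      c(SPAN_SV_TYPES, BREAKEND_SV_TYPES))
  if (length(bad_type)) {
    stop("unknown sv_type: ", paste(bad_type, collapse = ", "))
  }
  tra <- svs$sv_type == "translocation"
  if (any(tra & (is.na(svs$contig_b) | is.na(svs$end_b)))) {
    stop("translocation with missing second breakend")
  }
  intra <- !tra
  if (any(intra & svs$contig_a != svs$contig_b)) {
    stop("non-translocation SV with breakends on different contigs")
  }
  if (any(intra & svs$start_a >= svs$end_b)) {
    stop("intra-contig SV must have start < end")
  }
  if (any(svs$cohort_frequency < 0 | svs$cohort_frequency > 1)) {
    stop("cohort_frequency must be in [0, 1]")
  }
  invisible(svs)
}

## GRanges of the spanned interval for intra-contig calls (zero-width
## placeholder for translocations, which have no single span)
sv_span <- function(svs) {
  intra <- svs$sv_type != "translocation"
  GenomicRanges::GRanges(
    seqnames = ifelse(intra, svs$contig_a, "."),
    ranges = IRanges::IRanges(
      start = ifelse(intra, svs$start_a, 1L),
      end = ifelse(intra, svs$end_b, 0L)))
}

sv_breakends <- function(svs) {
  GenomicRanges::GRanges(
    seqnames = c(svs$contig_a, svs$contig_b),
    ranges = IRanges::IRanges(start = c(svs$start_a, svs$end_b), width = 1L),
    call = rep(seq_len(nrow(svs)), 2))
}

#' Merge duplicate SV calls from different callers
#'
#' Two same-type intra-contig calls are the same event when they overlap
#' reciprocally by at least `reciprocal`; translocations match when both
#' breakend pairs agree within `breakend_tol` bases. The higher-quality
#' record of each group is kept.
#'
#' @param svs SV call data.frame.
#' @param reciprocal reciprocal-overlap fraction (default 0.5).
#' @param breakend_tol translocation breakend tolerance in bp (default
#'   1000).
#' @return merged SV data.frame with an added `n_callers` column.
#' @export
merge_sv_calls <- function(svs, reciprocal = 0.5, breakend_tol = 1000) {
  sv_validate(svs)
  if (!nrow(svs)) {
    svs$n_callers <- integer(0)
    return(svs)
  }
  n <- nrow(svs)
  group <- seq_len(n)
  intra <- which(svs$sv_type != "translocation")
  if (length(intra) > 1) {
    gr <- sv_span(svs[intra, , drop = FALSE])
    hits <- GenomicRanges::findOverlaps(gr, gr)
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    keep <- q < s &
      svs$sv_type[intra[q]] == svs$sv_type[intra[s]] &
      svs$individual_id[intra[q]] == svs$individual_id[intra[s]]
    q <- q[keep]; s <- s[keep]
    if (length(q)) {
      ov <- IRanges::width(IRanges::pintersect(IRanges::ranges(gr)[q],
                                               IRanges::ranges(gr)[s]))
      rec <- ov >= reciprocal * IRanges::width(gr)[q] &
        ov >= reciprocal * IRanges::width(gr)[s]
      for (k in which(rec)) {
        a <- intra[q[k]]; b <- intra[s[k]]
        group[group == group[b]] <- group[a]
      }
    }
  }
  tra <- which(svs$sv_type == "translocation")
  if (length(tra) > 1) {
    for (i in seq_along(tra)[-1]) {
      for (j in seq_len(i - 1)) {
        a <- tra[j]; b <- tra[i]
        if (svs$individual_id[a] == svs$individual_id[b] &&
            svs$contig_a[a] == svs$contig_a[b] &&
            svs$contig_b[a] == svs$contig_b[b] &&
            abs(svs$start_a[a] - svs$start_a[b]) <= breakend_tol &&
            abs(svs$end_b[a] - svs$end_b[b]) <= breakend_tol) {
          group[group == group[b]] <- group[a]
        }
      }
    }
  }
  picked <- vapply(split(seq_len(n), group), function(idx) {
    idx[which.max(svs$quality[idx])]
  }, integer(1))
  out <- svs[sort(picked), , drop = FALSE]
  out$n_callers <- as.vector(table(group)[as.character(group[sort(picked)])])
  rownames(out) <- NULL
  out
}

#' SV prefilter
#'
#' Pass requires quality >= `min_quality`, cohort frequency strictly below
#' `max_frequency`, and contact with the panel: span-type SVs (deletion,
#' duplication, copy gain/loss) must intersect at least one panel exon;
#' breakend-type SVs (inversion, translocation) qualify when a breakend
#' falls within a panel gene's transcribed span (intronic breakpoints are
#' retained — an intron-disrupting inversion is a reportable event).
#'
#' @param svs SV call data.frame.
#' @param panel a `cpg_panel` with exon intervals.
#' @param min_quality quality gate (default 30, inclusive).
#' @param max_frequency cohort-frequency gate (default 0.01, strict).
#' @return disposition data.frame (`stage`, `outcome`, `reason_codes`).
#' @export
sv_prefilter <- function(svs, panel, min_quality = 30,
                         max_frequency = 0.01) {
  sv_validate(svs)
  n <- nrow(svs)
  spans <- gene_spans(panel)
  span_hit <- rep(FALSE, n)
  breakend_hit <- rep(FALSE, n)
  if (n && length(panel$exons)) {
    is_span <- svs$sv_type %in% SPAN_SV_TYPES
    if (any(is_span)) {
      gr <- sv_span(svs[is_span, , drop = FALSE])
      span_hit[is_span] <- overlaps_any(gr, panel$exons)
    }
    if (any(!is_span)) {
      be <- sv_breakends(svs[!is_span, , drop = FALSE])
      hit_calls <- unique(be$call[overlaps_any(be, spans)])
      breakend_hit[which(!is_span)[hit_calls]] <- TRUE
    }
  }
  affects <- span_hit | breakend_hit
  reason <- cbind(
    ifelse(svs$quality < min_quality, "low_quality", NA),
    ifelse(svs$cohort_frequency >= max_frequency, "common_in_cohort", NA),
    ifelse(!affects, "no_panel_exon_contact", NA))
  disposition(rep("sv_prefilter", n), rowSums(!is.na(reason)) == 0, reason)
}

#' Categorize a prefiltered SV against the panel
#'
#' Assigns one assessment per (SV, intersected panel gene):
#' `tsg_copy_loss` for a deletion/copy-loss covering at least one exon of a
#' non-proto-oncogene; `oncogene_copy_gain` for a duplication/copy-gain of
#' a proto-oncogene's coding region; `breakpoint_disruption` for any SV
#' type with a breakend strictly inside the gene's transcribed span;
#' `none` otherwise. For recessive-only genes the category is `none`
#' unless the call is homozygous or a second qualifying hit (SV or
#' retained SNV) exists in the same gene and individual.
#'
#' @param svs prefiltered SV call data.frame (with an `sv_id` column, else
#'   row numbers are used).
#' @param panel a `cpg_panel` with exon intervals.
#' @param other_hits optional data.frame of other qualifying hits with
#'   columns `individual_id`, `gene_symbol` (e.g. retained SNVs), used for
#'   the compound-heterozygosity test in recessive-only genes.
#' @return data.frame with one row per (SV, gene): `sv_id`, `gene_symbol`,
#'   `category`.
#' @export
sv_categorize <- function(svs, panel, other_hits = NULL) {
  sv_validate(svs)
  if (is.null(svs$sv_id)) svs$sv_id <- as.character(seq_len(nrow(svs)))
  spans <- gene_spans(panel)
  out <- data.frame(sv_id = character(), gene_symbol = character(),
                    category = character(), stringsAsFactors = FALSE)
  if (!nrow(svs) || !length(spans)) return(out)

  ## candidate (sv, gene) pairs: span overlap with gene span, or breakend
  ## within gene span
  span_gr <- sv_span(svs)
  cand <- find_overlaps(span_gr, spans)
  pairs <- unique(data.frame(i = S4Vectors::queryHits(cand),
                             g = S4Vectors::subjectHits(cand)))
  be <- sv_breakends(svs)
  bh <- find_overlaps(be, spans)
  pairs <- unique(rbind(pairs,
                        data.frame(i = be$call[S4Vectors::queryHits(bh)],
                                   g = S4Vectors::subjectHits(bh))))
  pairs <- pairs[order(pairs$i, pairs$g), , drop = FALSE]
  if (!nrow(pairs)) return(out)

  gidx <- match(spans$symbol, panel$genes$symbol)
  proto <- panel$genes$proto_oncogene[gidx]
  recessive <- panel$genes$recessive_only[gidx]

  category <- character(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; g <- pairs$g[k]
    sym <- spans$symbol[g]
    type <- svs$sv_type[i]
    exons_g <- panel$exons[panel$exons$symbol == sym]
    covers_exon <- type %in% SPAN_SV_TYPES &&
      overlaps_any(span_gr[i], exons_g)
    ## strictly inside the transcribed span (not at its ends)
    span_start <- GenomicRanges::start(spans)[g]
    span_end <- GenomicRanges::end(spans)[g]
    contig_g <- as.character(GenomicRanges::seqnames(spans))[g]
    inside <- function(contig, pos) {
      contig == contig_g && pos > span_start && pos < span_end
    }
    breakend_in <- inside(svs$contig_a[i], svs$start_a[i]) ||
      inside(svs$contig_b[i], svs$end_b[i])

    cat_k <- "none"
    if (type %in% c("deletion", "copy_loss") && !proto[g] && covers_exon) {
      cat_k <- "tsg_copy_loss"
    } else if (type %in% c("duplication", "copy_gain") && proto[g] &&
               covers_exon) {
      cat_k <- "oncogene_copy_gain"
    } else if (breakend_in) {
      cat_k <- "breakpoint_disruption"
    }

    if (cat_k != "none" && recessive[g]) {
      hom <- !is.na(svs$zygosity[i]) && svs$zygosity[i] == "hom"
      second <- FALSE
      ## another qualifying SV of this individual touching the same gene
      others <- setdiff(which(pairs$g == g &
                                svs$individual_id[pairs$i] ==
                                  svs$individual_id[i]), k)
      second <- length(unique(pairs$i[others])) > 0
      if (!second && !is.null(other_hits)) {
        second <- any(other_hits$individual_id == svs$individual_id[i] &
                        other_hits$gene_symbol == sym)
      }
      if (!hom && !second) cat_k <- "none"
    }
    category[k] <- cat_k
  }
  data.frame(sv_id = svs$sv_id[pairs$i],
             gene_symbol = spans$symbol[pairs$g],
             category = category, stringsAsFactors = FALSE)
}

#' CNV-map exclusion
#'
#' An SV is excluded when its spanned interval is fully contained within a
#' region of a common copy-number-variation map (containment, not mere
#' overlap: overlap-based exclusion would discard whole-gene deletions
#' whenever any small common CNV lies inside the gene). Translocations
#' have no span and are never excluded by the map.
#'
#' @param svs SV call data.frame.
#' @param cnv_map `GRanges` of common-CNV regions (see [read_cnv_map()]).
#' @return logical vector, `TRUE` where excluded.
#' @export
cnv_map_exclude <- function(svs, cnv_map) {
  sv_validate(svs)
  out <- rep(FALSE, nrow(svs))
  if (is.null(cnv_map) || !length(cnv_map) || !nrow(svs)) return(out)
  intra <- svs$sv_type != "translocation"
  if (any(intra)) {
    gr <- sv_span(svs[intra, , drop = FALSE])
    out[intra] <- overlaps_any(gr, cnv_map, type = "within")
  }
  out
}

#' Run the full SV prioritization pipeline
#'
#' Caller-merge, prefilter, per-gene categorization, and CNV-map
#' exclusion, with a per-stage audit.
#'
#' @param svs SV call data.frame.
#' @param panel a `cpg_panel` with exon intervals.
#' @param cnv_map optional `GRanges` CNV map.
#' @param other_hits optional qualifying-hit table for recessive genes
#'   (see [sv_categorize()]).
#' @param min_quality,max_frequency,reciprocal gates passed through.
#' @return object of class `sv_triage`: list with `prioritized` (one row
#'   per SV x gene with category != none and not CNV-map excluded, joined
#'   to the call fields), `assessments` (all SV x gene assessments,
#'   including CNV-map flags), `dispositions` (per merged call), `audit`.
#' @export
run_sv_pipeline <- function(svs, panel, cnv_map = NULL, other_hits = NULL,
                            min_quality = 30, max_frequency = 0.01,
                            reciprocal = 0.5) {
  n_input <- nrow(svs)
  merged <- merge_sv_calls(svs, reciprocal = reciprocal)
  if (is.null(merged$sv_id)) merged$sv_id <- as.character(seq_len(nrow(merged)))
  pre <- sv_prefilter(merged, panel, min_quality = min_quality,
                      max_frequency = max_frequency)
  dispo <- cbind(merged[c("sv_id", "individual_id", "caller", "sv_type")],
                 pre)
  passed <- merged[pre$outcome == "pass", , drop = FALSE]

  assess <- sv_categorize(passed, panel, other_hits = other_hits)
  if (nrow(assess)) {
    excl <- cnv_map_exclude(passed, cnv_map)
    assess$excluded_by_cnv_map <-
      excl[match(assess$sv_id, passed$sv_id)]
  } else {
    assess$excluded_by_cnv_map <- logical(0)
  }
  hit <- assess[assess$category != "none" & !assess$excluded_by_cnv_map, ,
                drop = FALSE]
  prioritized <- merge(hit, passed, by = "sv_id", sort = FALSE)
  prioritized <- prioritized[order(prioritized$contig_a,
                                   prioritized$start_a,
                                   prioritized$gene_symbol), , drop = FALSE]
  rownames(prioritized) <- NULL

  audit <- list(
    n_input = n_input,
    n_merged = nrow(merged),
    n_prefilter_fail = sum(pre$outcome == "fail"),
    n_prefilter_pass = sum(pre$outcome == "pass"),
    n_category_none = length(setdiff(passed$sv_id,
                                     assess$sv_id[assess$category != "none"])),
    n_cnv_map_excluded = length(unique(
      assess$sv_id[assess$category != "none" & assess$excluded_by_cnv_map])),
    n_prioritized_calls = length(unique(prioritized$sv_id)))
  stopifnot(audit$n_merged ==
              audit$n_prefilter_fail + audit$n_prefilter_pass)
  structure(list(prioritized = prioritized, assessments = assess,
                 dispositions = dispo, audit = audit),
            class = "sv_triage")
}

#' @export
print.sv_triage <- function(x, ...) {
  a <- x$audit
  cat("SV triage:", a$n_input, "calls ->", a$n_merged, "merged;",
      a$n_prioritized_calls, "prioritized\n")
  invisible(x)
}
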