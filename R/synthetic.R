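## Seeded synthetic-data generator. Emulates every input the triage
## pipeline consumes — gene panel on a miniature genome, cohort
## phenotypes, annotated small variants, SV calls, a CNV map, reference
## population counts, registry data — with planted truth tables so tests
## never re-derive intent from the generated data. All randomness is
## drawn under withr::with_seed from offsets of one configured seed, so a
## given configuration is fully deterministic and leaves the caller's RNG
## state untouched.

#' Default tumor-category frequencies
#'
#' Category weights for cohort simulation, anchored to the shares of the
#' most frequent tumor types in a referral-based MPT series (breast 24.6%,
#' colorectal 9.9%, kidney 7.3%, ...); the remainder is spread over the
#' rarer categories and a catch-all.
#'
#' @return named numeric vector summing to 1.
#' @export
default_tumor_frequencies <- function() {
  f <- c(breast = 0.246, colorectal = 0.099, kidney = 0.073, nmsc = 0.059,
         ovary = 0.051, endometrium = 0.040, hem_lymphoid = 0.040,
         melanoma = 0.035, thyroid = 0.030, lung = 0.025, cns = 0.025,
         soft_tissue_sarcoma = 0.020, pheochromocytoma = 0.020,
         pancreas = 0.020, prostate = 0.020, gastric = 0.015,
         pituitary_adenoma = 0.015, bladder = 0.015, cervix = 0.015)
  c(f, other = 1 - sum(f))
}

#' Simulation configuration
#'
#' @param seed integer seed; every generator draws from deterministic
#'   offsets of it.
#' @param n_probands cohort size (default 440, the reference MPT series).
#' @param sex_prop_female probability a proband is female (default 0.77).
#' @param tumor_category_freqs named category weights (sum to 1).
#' @param tumors_per_individual named probabilities over tumor counts
#'   (names are the counts).
#' @param planted_plp_rate per-proband probability of one planted
#'   qualifying variant (default 0.152, the observed P/LP proband rate).
#' @param background_per_proband background variants per proband, each
#'   constructed to fail exactly one named gate (default 5).
#' @param n_sv_decoys SV decoy calls (default 50).
#' @param recessive_biallelic_count carriers whose planted hit is realized
#'   as a biallelic pair (or homozygote) in a recessive-only gene.
#' @param concordance_probability chance a planted carrier also receives a
#'   tumor characteristic of the planted gene (default 0.567).
#' @param refpop reference-population sizes and per-sex carrier
#'   frequencies (defaults mirror a gnomAD-like genome set: 55.3% male,
#'   6,929 females, qualifying-variant frequency 3.3% in both sexes).
#' @param n_genes panel size on the miniature genome (default 20).
#' @return named list of settings (class `sim_config`).
#' @export
sim_config <- function(seed = 1, n_probands = 440,
                       sex_prop_female = 0.77,
                       tumor_category_freqs = default_tumor_frequencies(),
                       tumors_per_individual = c("2" = 0.6, "3" = 0.3,
                                                 "4" = 0.1),
                       planted_plp_rate = 0.152,
                       background_per_proband = 5,
                       n_sv_decoys = 50,
                       recessive_biallelic_count = 2,
                       concordance_probability = 0.567,
                       refpop = list(n_male = 8592, n_female = 6929,
                                     f_male = 0.033, f_female = 0.033),
                       n_genes = 20) {
  stopifnot(abs(sum(tumor_category_freqs) - 1) < 1e-9,
            abs(sum(tumors_per_individual) - 1) < 1e-9,
            planted_plp_rate >= 0, planted_plp_rate <= 1,
            sex_prop_female >= 0, sex_prop_female <= 1)
  structure(list(seed = seed, n_probands = n_probands,
                 sex_prop_female = sex_prop_female,
                 tumor_category_freqs = tumor_category_freqs,
                 tumors_per_individual = tumors_per_individual,
                 planted_plp_rate = planted_plp_rate,
                 background_per_proband = background_per_proband,
                 n_sv_decoys = n_sv_decoys,
                 recessive_biallelic_count = recessive_biallelic_count,
                 concordance_probability = concordance_probability,
                 refpop = refpop, n_genes = n_genes),
            class = "sim_config")
}

## ---- miniature genome / panel -----------------------------------------

#' Generate a synthetic gene panel on a miniature genome
#'
#' `n_genes` kilobase-scale genes with 3-8 exons spread over four contigs;
#' two proto-oncogenes, two recessive-only genes, characteristic-tumor
#' categories drawn from the vocabulary, and three known pathogenic
#' non-coding (intronic) positions.
#'
#' @param config [sim_config()].
#' @return a `cpg_panel` (the non-coding table carries an extra
#'   `gene_symbol` column).
#' @export
generate_panel <- function(config = sim_config()) {
  withr::with_seed(config$seed + 101L, {
    n <- config$n_genes
    stopifnot(n >= 8)
    voc <- tumor_vocabulary()
    symbols <- sprintf("GENE%02d", seq_len(n))
    contigs <- paste0("chr", rep_len(1:4, n))
    pos_in_contig <- as.integer(stats::ave(seq_len(n), contigs,
                                           FUN = seq_along))
    gene_start <- 100000L + (pos_in_contig - 1L) * 50000L

    exon_list <- lapply(seq_len(n), function(i) {
      n_ex <- sample(3:8, 1)
      widths <- sample(100:300, n_ex, replace = TRUE)
      gaps <- sample(500:2000, n_ex, replace = TRUE)
      starts <- gene_start[i] + cumsum(c(0L, head(widths + gaps, -1)))
      data.frame(contig = contigs[i], start = starts,
                 end = starts + widths - 1L, symbol = symbols[i],
                 stringsAsFactors = FALSE)
    })
    exons_df <- do.call(rbind, exon_list)
    exons <- GenomicRanges::GRanges(
      exons_df$contig,
      IRanges::IRanges(exons_df$start, exons_df$end),
      symbol = exons_df$symbol)

    proto <- rep(FALSE, n); proto[c(5, 15)] <- TRUE
    recessive <- rep(FALSE, n); recessive[c(8, 18)] <- TRUE
    chars <- vapply(seq_len(n), function(i) {
      paste(sample(voc$category, sample(1:2, 1)), collapse = ";")
    }, character(1))
    genes <- data.frame(symbol = symbols, proto_oncogene = proto,
                        recessive_only = recessive,
                        characteristic_tumors = chars,
                        stringsAsFactors = FALSE)

    ## three known pathogenic intronic positions in dominant TSGs
    nc_genes <- which(!proto & !recessive)[1:3]
    noncoding <- do.call(rbind, lapply(nc_genes, function(i) {
      ex <- exon_list[[i]]
      pos <- ex$end[1] + sample(50:400, 1)  # first intron
      ref <- sample(c("A", "C", "G", "T"), 1)
      data.frame(contig = contigs[i], position = pos, ref = ref,
                 alt = sample(setdiff(c("A", "C", "G", "T"), ref), 1),
                 gene_symbol = symbols[i], stringsAsFactors = FALSE)
    }))
    cpg_panel(genes, exons = exons, noncoding = noncoding)
  })
}

## ---- cohort ------------------------------------------------------------

#' Generate a synthetic MPT cohort
#'
#' Sex by Bernoulli(`sex_prop_female`); tumor counts and categories from
#' the configured distributions; ages drawn so that every proband
#' satisfies [mpt_eligible()] (two-tumor probands by 60, three-or-more by
#' 70). One proband per family.
#'
#' @param config [sim_config()].
#' @return list with `individuals` (individual_id, family_id, sex) and
#'   `tumors` (one row per tumor, [read_cohort()] layout).
#' @export
generate_cohort <- function(config = sim_config()) {
  withr::with_seed(config$seed + 202L, {
    n <- config$n_probands
    freqs <- config$tumor_category_freqs
    if (!length(freqs)) stop("no tumor categories configured")
    ids <- sprintf("P%05d", seq_len(n))
    fams <- sprintf("F%05d", seq_len(n))
    sex <- ifelse(runif(n) < config$sex_prop_female, "female", "male")
    individuals <- data.frame(individual_id = ids, family_id = fams,
                              sex = sex, stringsAsFactors = FALSE)
    if (n == 0) {
      tumors <- data.frame(individual_id = character(),
                           family_id = character(), sex = character(),
                           tumor_category = character(),
                           age_at_diagnosis = numeric(),
                           stringsAsFactors = FALSE)
      return(list(individuals = individuals, tumors = tumors))
    }
    k <- as.integer(sample(names(config$tumors_per_individual), n,
                           replace = TRUE,
                           prob = config$tumors_per_individual))
    rows <- rep(seq_len(n), k)
    cats <- sample(names(freqs), sum(k), replace = TRUE, prob = freqs)
    ages <- integer(sum(k))
    two <- k[rows] == 2
    ages[two] <- sample(25:60, sum(two), replace = TRUE)
    ages[!two] <- sample(25:70, sum(!two), replace = TRUE)
    tumors <- data.frame(individual_id = ids[rows], family_id = fams[rows],
                         sex = sex[rows], tumor_category = cats,
                         age_at_diagnosis = ages, stringsAsFactors = FALSE)
    list(individuals = individuals, tumors = tumors)
  })
}

## ---- small variants ----------------------------------------------------

random_bases <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

## alt depth: rejection-sample binomial reads until the VAF gate is met
## (het centered on 0.5, hom near 1.0 — the diploid expectation behind
## the 33% gate)
draw_alt_depth <- function(dp, hom) {
  alt <- integer(length(dp))
  todo <- seq_along(dp)
  while (length(todo)) {
    alt[todo] <- rbinom(length(todo), dp[todo],
                        ifelse(hom[todo], 0.98, 0.5))
    ok <- alt[todo] * 100L >= 33L * dp[todo]
    todo <- todo[!ok]
  }
  alt
}

blank_variants <- function(n) {
  data.frame(
    individual_id = character(n), contig = character(n),
    position = integer(n), ref = character(n), alt = character(n),
    gene_symbol = character(n), so_consequence = character(n),
    gq = integer(n), dp = integer(n), alt_depth = integer(n),
    filter_status = rep("PASS", n),
    af_exac = rep(NA_real_, n), af_1kg = rep(NA_real_, n),
    clinvar_assertion = rep(NA_character_, n),
    clinvar_stars = rep(NA_real_, n),
    clinvar_submission_count = rep(NA_real_, n),
    hgmd_dm = rep(FALSE, n), cadd_phred = rep(NA_real_, n),
    truncation_fraction = rep(NA_real_, n),
    zygosity = rep("het", n), stringsAsFactors = FALSE)
}

#' Generate annotated variants with a planted truth table
#'
#' Plants one qualifying variant per sampled carrier (route mixture over
#' truncating / ClinVar / HGMD / CADD / non-coding evidence, all gates
#' satisfied), realizes a configured number of carriers as biallelic hits
#' in recessive-only genes, adds per-proband background variants each
#' constructed to fail exactly one named gate, and one decoy per
#' exclusion criterion. The truth table records the intended class and
#' terminal disposition of every variant.
#'
#' @param config [sim_config()].
#' @param cohort from [generate_cohort()].
#' @param panel from [generate_panel()] (exon coordinates required).
#' @return list with `variants` (annotated-variant data.frame, shuffled)
#'   and `truth` (variant key columns plus `class`, `subclass`,
#'   `expected_outcome`, `expected_stage`).
#' @export
generate_variants <- function(config, cohort, panel) {
  genes <- panel$genes
  if (!any(genes$recessive_only) || !any(genes$proto_oncogene)) {
    stop("panel must contain a recessive-only and a proto-oncogene gene ",
         "when exclusion decoys are requested")
  }
  exdf <- data.frame(
    contig = as.character(GenomicRanges::seqnames(panel$exons)),
    start = GenomicRanges::start(panel$exons),
    end = GenomicRanges::end(panel$exons),
    symbol = panel$exons$symbol, stringsAsFactors = FALSE)
  if (!nrow(exdf)) stop("panel has no exon coordinates")
  dominant <- genes$symbol[!genes$recessive_only & !genes$proto_oncogene]
  recessive <- genes$symbol[genes$recessive_only]
  proto <- genes$symbol[genes$proto_oncogene]

  pick_pos <- function(gene_syms) {
    vapply(gene_syms, function(g) {
      ex <- exdf[exdf$symbol == g, , drop = FALSE]
      i <- sample(nrow(ex), 1)
      as.integer(sample(ex$start[i]:ex$end[i], 1))
    }, integer(1), USE.NAMES = FALSE)
  }
  gene_contig <- function(gene_syms) {
    exdf$contig[match(gene_syms, exdf$symbol)]
  }

  withr::with_seed(config$seed + 303L, {
    inds <- cohort$individuals$individual_id
    n <- length(inds)
    carriers <- inds[runif(n) < config$planted_plp_rate]
    n_bi <- min(config$recessive_biallelic_count, length(carriers))
    bi_carriers <- carriers[seq_len(n_bi)]
    mono_carriers <- setdiff(carriers, bi_carriers)

    pieces <- list()
    truth <- list()
    add <- function(v, class, subclass, outcome, stage) {
      pieces[[length(pieces) + 1]] <<- v
      t <- v[c("individual_id", "contig", "position", "ref", "alt",
               "gene_symbol")]
      t$class <- class; t$subclass <- subclass
      t$expected_outcome <- outcome; t$expected_stage <- stage
      truth[[length(truth) + 1]] <<- t
    }

    ## ---- planted qualifying variants (monoallelic carriers)
    if (length(mono_carriers)) {
      m <- length(mono_carriers)
      routes <- sample(c("truncating", "clinvar", "hgmd", "cadd",
                         "noncoding"), m, replace = TRUE,
                       prob = c(0.45, 0.2, 0.15, 0.15, 0.05))
      v <- blank_variants(m)
      v$individual_id <- mono_carriers
      v$gq <- sample(30:99, m, replace = TRUE)
      v$dp <- sample(10:60, m, replace = TRUE)
      v$alt_depth <- draw_alt_depth(v$dp, rep(FALSE, m))
      v$af_exac <- ifelse(runif(m) < 0.5, NA, runif(m, 0, 0.005))
      v$af_1kg <- ifelse(runif(m) < 0.5, NA, runif(m, 0, 0.005))

      tr <- routes == "truncating"
      v$gene_symbol[tr] <- sample(dominant, sum(tr), replace = TRUE)
      v$so_consequence[tr] <- sample(truncating_so_terms()[1:4], sum(tr),
                                     replace = TRUE)
      v$truncation_fraction[tr] <- runif(sum(tr), 0.06, 0.95)

      cl <- routes == "clinvar"
      v$gene_symbol[cl] <- sample(c(dominant, proto), sum(cl),
                                  replace = TRUE)
      v$so_consequence[cl] <- "missense_variant"
      v$clinvar_assertion[cl] <- sample(c("pathogenic",
                                          "likely_pathogenic"),
                                        sum(cl), replace = TRUE)
      v$clinvar_stars[cl] <- sample(2:4, sum(cl), replace = TRUE)
      v$clinvar_submission_count[cl] <- sample(3:10, sum(cl),
                                               replace = TRUE)

      hg <- routes == "hgmd"
      v$gene_symbol[hg] <- sample(c(dominant, proto), sum(hg),
                                  replace = TRUE)
      v$so_consequence[hg] <- "missense_variant"
      v$hgmd_dm[hg] <- TRUE

      ca <- routes == "cadd"
      v$gene_symbol[ca] <- sample(c(dominant, proto), sum(ca),
                                  replace = TRUE)
      v$so_consequence[ca] <- "missense_variant"
      v$cadd_phred[ca] <- runif(sum(ca), 34, 55)

      nc <- routes == "noncoding"
      if (any(nc)) {
        pick <- sample(nrow(panel$noncoding), sum(nc), replace = TRUE)
        v$gene_symbol[nc] <- panel$noncoding$gene_symbol[pick]
        v$so_consequence[nc] <- "intron_variant"
        v$contig[nc] <- panel$noncoding$contig[pick]
        v$position[nc] <- panel$noncoding$position[pick]
        v$ref[nc] <- panel$noncoding$ref[pick]
        v$alt[nc] <- panel$noncoding$alt[pick]
      }
      coding <- !nc
      v$contig[coding] <- gene_contig(v$gene_symbol[coding])
      v$position[coding] <- pick_pos(v$gene_symbol[coding])
      v$ref[coding] <- random_bases(sum(coding))
      v$alt[coding] <- vapply(v$ref[coding], function(r) {
        sample(setdiff(c("A", "C", "G", "T"), r), 1)
      }, character(1), USE.NAMES = FALSE)
      fs <- v$so_consequence == "frameshift_variant"
      v$alt[fs] <- paste0(v$ref[fs], random_bases(sum(fs)))
      add(v, "qualifying", routes, "retained_for_assessment",
          "retained_for_assessment")
    }

    ## ---- biallelic carriers in recessive-only genes
    for (i in seq_along(bi_carriers)) {
      ind <- bi_carriers[i]
      g <- sample(recessive, 1)
      if (i %% 2 == 1) {  # homozygote: one variant, hom counts as two
        v <- blank_variants(1)
        v$individual_id <- ind; v$gene_symbol <- g
        v$contig <- gene_contig(g); v$position <- pick_pos(g)
        v$ref <- random_bases(1)
        v$alt <- sample(setdiff(c("A", "C", "G", "T"), v$ref), 1)
        v$so_consequence <- "stop_gained"
        v$truncation_fraction <- runif(1, 0.06, 0.95)
        v$gq <- sample(30:99, 1); v$dp <- sample(10:60, 1)
        v$zygosity <- "hom"
        v$alt_depth <- draw_alt_depth(v$dp, TRUE)
        add(v, "qualifying", "recessive_hom", "retained_for_assessment",
            "retained_for_assessment")
      } else {            # presumed compound heterozygote: two variants
        v <- blank_variants(2)
        v$individual_id <- ind; v$gene_symbol <- g
        v$contig <- gene_contig(c(g, g)); v$position <- pick_pos(c(g, g))
        while (v$position[2] == v$position[1]) v$position[2] <- pick_pos(g)
        v$ref <- random_bases(2)
        v$alt <- vapply(v$ref, function(r) {
          sample(setdiff(c("A", "C", "G", "T"), r), 1)
        }, character(1), USE.NAMES = FALSE)
        v$so_consequence <- c("stop_gained", "frameshift_variant")
        v$alt[2] <- paste0(v$ref[2], random_bases(1))
        v$truncation_fraction <- runif(2, 0.06, 0.95)
        v$gq <- sample(30:99, 2, replace = TRUE)
        v$dp <- sample(10:60, 2, replace = TRUE)
        v$alt_depth <- draw_alt_depth(v$dp, c(FALSE, FALSE))
        add(v, "qualifying", "recessive_comphet",
            "retained_for_assessment", "retained_for_assessment")
      }
    }

    ## ---- background variants: each fails exactly one named gate
    if (config$background_per_proband > 0 && n > 0) {
      classes <- c("low_gq", "low_dp", "low_vaf", "non_pass",
                   "af_exac_high", "af_1kg_high", "no_retention")
      b <- n * config$background_per_proband
      cls <- rep_len(classes, b)
      v <- blank_variants(b)
      v$individual_id <- rep(inds, each = config$background_per_proband)
      v$gene_symbol <- sample(dominant, b, replace = TRUE)
      v$contig <- gene_contig(v$gene_symbol)
      v$position <- pick_pos(v$gene_symbol)
      v$ref <- random_bases(b)
      v$alt <- vapply(v$ref, function(r) {
        sample(setdiff(c("A", "C", "G", "T"), r), 1)
      }, character(1), USE.NAMES = FALSE)
      ## qualifying-like retention evidence (truncating) so the broken
      ## gate is the only reason for failure
      v$so_consequence <- "stop_gained"
      v$truncation_fraction <- runif(b, 0.06, 0.95)
      v$gq <- sample(30:99, b, replace = TRUE)
      v$dp <- sample(10:60, b, replace = TRUE)
      v$alt_depth <- draw_alt_depth(v$dp, rep(FALSE, b))

      i <- cls == "low_gq"
      v$gq[i] <- sample(0:29, sum(i), replace = TRUE)
      i <- cls == "low_dp"
      v$dp[i] <- sample(3:9, sum(i), replace = TRUE)
      v$alt_depth[i] <- v$dp[i]
      i <- cls == "low_vaf"
      v$dp[i] <- sample(30:60, sum(i), replace = TRUE)
      v$alt_depth[i] <- floor(0.2 * v$dp[i])
      i <- cls == "non_pass"
      v$filter_status[i] <- "LowQual"
      i <- cls == "af_exac_high"
      v$af_exac[i] <- runif(sum(i), 0.011, 0.5)
      i <- cls == "af_1kg_high"
      v$af_1kg[i] <- runif(sum(i), 0.011, 0.5)
      i <- cls == "no_retention"
      v$so_consequence[i] <- "missense_variant"
      v$truncation_fraction[i] <- NA_real_
      v$cadd_phred[i] <- runif(sum(i), 5, 33)

      stage <- ifelse(cls %in% c("low_gq", "low_dp", "low_vaf",
                                 "non_pass"), "quality",
                      ifelse(cls %in% c("af_exac_high", "af_1kg_high"),
                             "frequency", "retention"))
      add(v, "background", cls, "fail", stage)
    }

    ## ---- exclusion decoys, one per refutation criterion
    pool <- setdiff(inds, carriers)
    if (length(pool) < 5) stop("cohort too small for exclusion decoys")
    who <- sample(pool, 5)
    v <- blank_variants(5)
    v$individual_id <- who
    v$gene_symbol <- c(sample(dominant, 1), sample(proto, 1),
                       sample(dominant, 1), sample(recessive, 1),
                       sample(dominant, 1))
    v$so_consequence <- c("stop_gained", "stop_gained", "stop_gained",
                          "missense_variant", "missense_variant")
    v$truncation_fraction <- c(runif(1, 0.06, 0.95), runif(1, 0.06, 0.95),
                               runif(1, 0.005, 0.049), NA, NA)
    v$clinvar_assertion <- c("benign", NA, NA, "pathogenic", "uncertain")
    v$clinvar_stars <- c(2, NA, NA, 3, 2)
    v$clinvar_submission_count <- c(4, NA, NA, 5, 3)
    v$hgmd_dm <- c(FALSE, FALSE, FALSE, FALSE, TRUE)
    v$contig <- gene_contig(v$gene_symbol)
    v$position <- pick_pos(v$gene_symbol)
    v$ref <- random_bases(5)
    v$alt <- vapply(v$ref, function(r) {
      sample(setdiff(c("A", "C", "G", "T"), r), 1)
    }, character(1), USE.NAMES = FALSE)
    v$gq <- sample(30:99, 5, replace = TRUE)
    v$dp <- sample(10:60, 5, replace = TRUE)
    v$alt_depth <- draw_alt_depth(v$dp, rep(FALSE, 5))
    add(v, "exclusion_decoy",
        c("truncating_with_benign_clinvar",
          "truncating_in_proto_oncogene", "minimal_truncation",
          "recessive_without_second_variant",
          "insilico_refuted_by_clinvar"),
        "excluded", "exclusion")

    variants <- do.call(rbind, pieces)
    truth <- do.call(rbind, truth)

    ## de-collide: unique (individual, contig, position) keys
    key <- paste(variants$individual_id, variants$contig,
                 variants$position)
    while (any(d <- duplicated(key))) {
      variants$position[d] <- pick_pos(variants$gene_symbol[d])
      truth$position[d] <- variants$position[d]
      key <- paste(variants$individual_id, variants$contig,
                   variants$position)
    }

    ord <- sample(nrow(variants))
    variants <- variants[ord, , drop = FALSE]
    truth <- truth[ord, , drop = FALSE]
    rownames(variants) <- rownames(truth) <- NULL
    list(variants = variants, truth = truth)
  })
}

## ---- structural variants ----------------------------------------------

#' Generate SV calls with a planted truth table
#'
#' Plants six prioritizable archetypes (single-exon deletion reported by
#' both callers, full-gene deletion, exon-flanking inversion,
#' intron-breakpoint inversion, proto-oncogene exon duplication, and a
#' translocation with a breakend in a first exon) plus decoys failing the
#' quality, frequency or exon gates or contained in the CNV map.
#'
#' @param config [sim_config()].
#' @param cohort from [generate_cohort()].
#' @param panel from [generate_panel()].
#' @return list with `svs` (call table), `truth` (per event: event_id,
#'   class, expected gene/category), and `cnv_map` (`GRanges`).
#' @export
generate_svs <- function(config, cohort, panel) {
  genes <- panel$genes
  if (!any(genes$proto_oncogene)) stop("panel needs a proto-oncogene")
  exdf <- data.frame(
    contig = as.character(GenomicRanges::seqnames(panel$exons)),
    start = GenomicRanges::start(panel$exons),
    end = GenomicRanges::end(panel$exons),
    symbol = panel$exons$symbol, stringsAsFactors = FALSE)
  gene_ex <- function(g) exdf[exdf$symbol == g, , drop = FALSE]
  dominant <- genes$symbol[!genes$recessive_only & !genes$proto_oncogene]
  proto <- genes$symbol[genes$proto_oncogene]
  if (length(dominant) < 6) stop("panel too small for SV archetypes")

  withr::with_seed(config$seed + 404L, {
    inds <- cohort$individuals$individual_id
    if (length(inds) < 7) stop("cohort too small for SV archetypes")
    gsel <- sample(dominant, 6)  # 5 archetype genes + 1 CNV-map gene
    who <- sample(inds, 7)
    svs <- list(); truth <- list()
    add_sv <- function(caller, type, ca, sa, cb, eb, q, fr, ind, event,
                       class, gene = NA, category = NA) {
      svs[[length(svs) + 1]] <<- data.frame(
        sv_id = sprintf("SV%03d", length(svs) + 1), caller = caller,
        sv_type = type, contig_a = ca, start_a = as.integer(sa),
        contig_b = cb, end_b = as.integer(eb), quality = q,
        cohort_frequency = fr, zygosity = "het", individual_id = ind,
        stringsAsFactors = FALSE)
      truth[[length(truth) + 1]] <<- data.frame(
        event_id = event, class = class, gene_symbol = gene,
        expected_category = category, stringsAsFactors = FALSE)
    }
    rare <- function() runif(1, 0, 0.005)

    ## 1: deletion of exon 2, reported by both callers (merged downstream)
    e <- gene_ex(gsel[1])
    add_sv("canvas", "deletion", e$contig[1], e$start[2] - 60,
           e$contig[1], e$end[2] + 60, sample(40:90, 1), rare(), who[1],
           "EV1", "planted", gsel[1], "tsg_copy_loss")
    add_sv("manta", "deletion", e$contig[1], e$start[2] - 35,
           e$contig[1], e$end[2] + 85, sample(40:90, 1), rare(), who[1],
           "EV1", "planted_duplicate_caller", gsel[1], "tsg_copy_loss")
    ## 2: full-gene deletion
    e <- gene_ex(gsel[2])
    add_sv("canvas", "copy_loss", e$contig[1], min(e$start) - 1500,
           e$contig[1], max(e$end) + 1500, sample(40:90, 1), rare(),
           who[2], "EV2", "planted", gsel[2], "tsg_copy_loss")
    ## 3: inversion with breakends flanking an exon (introns 1 and 2)
    e <- gene_ex(gsel[3])
    add_sv("manta", "inversion", e$contig[1], e$end[1] + 40,
           e$contig[1], e$start[3] - 40, sample(40:90, 1), rare(),
           who[3], "EV3", "planted", gsel[3], "breakpoint_disruption")
    ## 4: inversion with both breakends intronic
    e <- gene_ex(gsel[4])
    add_sv("manta", "inversion", e$contig[1], e$end[1] + 25,
           e$contig[1], e$end[2] + 25, sample(40:90, 1), rare(), who[4],
           "EV4", "planted", gsel[4], "breakpoint_disruption")
    ## 5: duplication of a proto-oncogene exon
    pg <- sample(proto, 1)
    e <- gene_ex(pg)
    add_sv("canvas", "duplication", e$contig[1], e$start[2] - 120,
           e$contig[1], e$end[2] + 120, sample(40:90, 1), rare(), who[5],
           "EV5", "planted", pg, "oncogene_copy_gain")
    ## 6: translocation with a breakend inside exon 1
    e <- gene_ex(gsel[5])
    other_contig <- setdiff(paste0("chr", 1:4), e$contig[1])[1]
    add_sv("manta", "translocation", e$contig[1],
           e$start[1] + floor((e$end[1] - e$start[1]) / 2),
           other_contig, 20000, sample(40:90, 1), rare(), who[6],
           "EV6", "planted", gsel[5], "breakpoint_disruption")

    ## CNV map: contains the sixth selected gene (decoy target) plus two
    ## intergenic regions
    cnv_e <- gene_ex(gsel[6])
    cnv_map <- GenomicRanges::GRanges(
      c(cnv_e$contig[1], "chr1", "chr2"),
      IRanges::IRanges(
        start = c(min(cnv_e$start) - 5000, 2000, 4000),
        end = c(max(cnv_e$end) + 5000, 9000, 9000)))

    ## decoys
    classes <- c("low_quality", "common_in_cohort", "non_exonic_span",
                 "non_exonic_breakend", "cnv_map_contained")
    for (i in seq_len(config$n_sv_decoys)) {
      cls <- classes[(i - 1) %% length(classes) + 1]
      ind <- sample(inds, 1)
      ev <- sprintf("DECOY%03d", i)
      if (cls == "low_quality") {
        g <- sample(dominant, 1); e <- gene_ex(g)
        add_sv("canvas", "deletion", e$contig[1], e$start[1] - 50,
               e$contig[1], e$end[1] + 50, sample(5:29, 1), rare(), ind,
               ev, cls)
      } else if (cls == "common_in_cohort") {
        g <- sample(dominant, 1); e <- gene_ex(g)
        add_sv("canvas", "deletion", e$contig[1], e$start[1] - 50,
               e$contig[1], e$end[1] + 50, sample(40:90, 1),
               runif(1, 0.01, 0.2), ind, ev, cls)
      } else if (cls == "non_exonic_span") {
        ctg <- sample(paste0("chr", 1:4), 1)
        s <- sample(30000:60000, 1)
        add_sv("canvas", "deletion", ctg, s, ctg, s + sample(500:3000, 1),
               sample(40:90, 1), rare(), ind, ev, cls)
      } else if (cls == "non_exonic_breakend") {
        ctg <- sample(paste0("chr", 1:4), 1)
        s <- sample(30000:60000, 1)
        add_sv("manta", "inversion", ctg, s, ctg, s + sample(500:3000, 1),
               sample(40:90, 1), rare(), ind, ev, cls)
      } else {  # qualifying call fully inside a CNV-map region
        add_sv("canvas", "deletion", cnv_e$contig[1],
               min(cnv_e$start) - 200, cnv_e$contig[1],
               max(cnv_e$end) + 200, sample(40:90, 1), rare(), ind, ev,
               cls, gsel[6], "tsg_copy_loss")
      }
    }
    svs <- do.call(rbind, svs)
    truth <- cbind(sv_id = svs$sv_id, do.call(rbind, truth))
    rownames(svs) <- rownames(truth) <- NULL
    list(svs = svs, truth = truth, cnv_map = cnv_map)
  })
}

## ---- reference population & registry ----------------------------------

#' Generate reference-population carrier counts
#'
#' Carrier counts drawn Binomial(n_sex, f_sex) per sex.
#'
#' @param config [sim_config()].
#' @return list with `n_male`, `n_female`, `carriers_male`,
#'   `carriers_female`.
#' @export
generate_reference_population <- function(config = sim_config()) {
  rp <- config$refpop
  if (rp$n_male <= 0 || rp$n_female <= 0) {
    stop("reference population needs individuals of both sexes")
  }
  withr::with_seed(config$seed + 505L, {
    list(n_male = rp$n_male, n_female = rp$n_female,
         carriers_male = rbinom(1, rp$n_male, rp$f_male),
         carriers_female = rbinom(1, rp$n_female, rp$f_female))
  })
}

#' Generate a registry-style comparison cohort
#'
#' Individuals with two malignant (or CNS) tumor diagnoses before age 60,
#' with category weights flatter than the referral-enriched MPT series.
#'
#' @param config [sim_config()].
#' @param n_individuals registry cohort size (default 471).
#' @return phenotype table (one row per tumor).
#' @export
generate_registry <- function(config = sim_config(), n_individuals = 471) {
  withr::with_seed(config$seed + 606L, {
    w <- c(breast = 0.15, colorectal = 0.15, nmsc = 0.12, lung = 0.12,
           melanoma = 0.08, hem_lymphoid = 0.08, kidney = 0.05,
           endometrium = 0.05, ovary = 0.03, thyroid = 0.03, other = 0.14)
    n <- n_individuals
    cats <- replicate(n, sample(names(w), 2, replace = FALSE, prob = w))
    data.frame(
      individual_id = rep(sprintf("R%05d", seq_len(n)), each = 2),
      tumor_category = as.vector(cats),
      age_at_diagnosis = sample(25:59, 2 * n, replace = TRUE),
      stringsAsFactors = FALSE)
  })
}

## ---- orchestration -----------------------------------------------------

#' Generate every synthetic input in one call
#'
#' @param config [sim_config()].
#' @return list with `config`, `panel`, `cohort`, `snv` (variants +
#'   truth), `sv` (calls + truth + cnv_map), `refpop`, `registry`.
#' @export
simulate_cohort_inputs <- function(config = sim_config()) {
  panel <- generate_panel(config)
  cohort <- generate_cohort(config)
  snv <- generate_variants(config, cohort, panel)
  sv <- generate_svs(config, cohort, panel)
  list(config = config, panel = panel, cohort = cohort, snv = snv,
       sv = sv, refpop = generate_reference_population(config),
       registry = generate_registry(config))
}

#' Write a simulation to disk
#'
#' Panel TSV + exon BED + non-coding TSV, cohort phenotypes, variants
#' (TSV, optionally per-individual VCFs), SV calls, CNV map BED, truth
#' tables, reference-population counts, registry table, and a JSON echo
#' of the resolved configuration.
#'
#' @param sim from [simulate_cohort_inputs()].
#' @param dir output directory (created if needed).
#' @param write_vcf also write one VCF per individual (default FALSE; the
#'   TSV is the primary representation).
#' @return invisibly, the directory.
#' @export
write_simulation <- function(sim, dir, write_vcf = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  write_panel(sim$panel, p("panel_genes.tsv"), p("panel_exons.bed"),
              p("panel_noncoding.tsv"))
  write_cohort(sim$cohort$tumors, p("cohort_phenotypes.tsv"))
  write.table(sim$snv$variants, p("variants.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$snv$truth, p("variants_truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_sv_table(sim$sv$svs, p("sv_calls.tsv"))
  write.table(sim$sv$truth, p("sv_truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cm <- sim$sv$cnv_map
  write.table(
    data.frame(as.character(GenomicRanges::seqnames(cm)),
               GenomicRanges::start(cm) - 1L, GenomicRanges::end(cm)),
    p("cnv_map.bed"), sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  write.table(as.data.frame(sim$refpop), p("reference_population.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$registry, p("registry_phenotypes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(sim$config), p("config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (write_vcf) {
    vdir <- p("vcf")
    dir.create(vdir, showWarnings = FALSE)
    for (ind in unique(sim$snv$variants$individual_id)) {
      write_annotated_vcf(
        sim$snv$variants[sim$snv$variants$individual_id == ind, ,
                         drop = FALSE],
        file.path(vdir, paste0(ind, ".vcf")))
    }
  }
  invisible(dir)
}

#' Score a triage run against a truth table
#'
#' Sensitivity: fraction of variants planted to survive the cascade that
#' were retained for assessment. Specificity: fraction of variants
#' planted to fail or be excluded that were not retained.
#'
#' @param triage an `snv_triage` from [run_snv_pipeline()].
#' @param truth truth table from [generate_variants()].
#' @return list with `sensitivity`, `specificity`, and the counts behind
#'   them.
#' @export
evaluate_against_truth <- function(triage, truth) {
  key <- function(d) paste(d$individual_id, d$contig, d$position, d$ref,
                           d$alt, sep = "\r")
  retained <- key(triage$retained)
  pos <- truth$expected_outcome == "retained_for_assessment"
  tp <- sum(key(truth[pos, ]) %in% retained)
  fn <- sum(pos) - tp
  fp <- sum(key(truth[!pos, ]) %in% retained)
  tn <- sum(!pos) - fp
  list(sensitivity = if (sum(pos)) tp / sum(pos) else NA_real_,
       specificity = if (sum(!pos)) tn / sum(!pos) else NA_real_,
       tp = tp, fn = fn, fp = fp, tn = tn)
}
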