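# mptriage

Germline variant triage for cohorts of individuals with **multiple
primary tumors (MPTs)** — at least two primary tumors by age 60 or at
least three by 70. Such individuals are strongly enriched for germline
variants in **cancer-predisposition genes (CPGs)**, and genome-wide
sequencing of an MPT cohort produces far more candidate calls than any
curation team can review. `mptriage` is for the analyst sitting between
the variant caller and the curator: it reduces annotated calls to a
short, fully audited list, applies the ACMG five-tier evidence
combination, and computes the cohort-level statistics used to interpret
the result.

## What it implements

**Small-variant cascade** (`run_snv_pipeline`) — every annotated
SNV/indel gets exactly one terminal disposition with named reason codes:

1. quality gate: GQ ≥ 30, DP ≥ 10, VAF ≥ 33% (exact rational comparison
   `alt·100 ≥ 33·dp`), caller filter `PASS`;
2. population-frequency gate: fail if allele frequency > 0.01 in either
   reference resource (absent = 0);
3. retention: truncating SO consequence, ClinVar P/LP at ≥ 2 stars,
   HGMD DM status, or CADD ≥ 34 (the threshold is the median CADD of
   variants deemed pathogenic via the other routes,
   `derive_cadd_threshold`);
4. non-coding positional lookup against a curated list of known
   pathogenic non-coding positions;
5. five refutation criteria (ClinVar-refuted truncation; truncation in a
   proto-oncogene; truncation of < 5% of the transcript; single hit in a
   recessive-only gene; in-silico-only retention refuted by ClinVar).

**SV prioritization** (`run_sv_pipeline`) — caller merge at ≥ 50%
reciprocal overlap, quality ≥ 30 / cohort frequency < 1% / exon-contact
prefilter, three-category assessment per intersected panel gene
(TSG copy loss, oncogene copy gain, breakpoint disruption), and
exclusion of calls fully contained in a common-CNV map.

**ACMG combination** (`combine_acmg`) — the published combining table
over PVS/PS/PM/PP/BA/BS/BP codes into
pathogenic / likely pathogenic / uncertain / likely benign / benign,
with conflicting evidence collapsing to uncertain.

**Cohort statistics** (`cohort_stats` functions) — discordant
tumor-combination enumeration (C(k,2) over distinct categories) and
distribution; uncorrected Pearson χ² on 2×2 tables
(χ² = N(ad−bc)²/[(a+b)(c+d)(a+c)(b+d)], no Yates correction); registry
comparison restricted to malignant/CNS diagnoses before 60;
sex-adjusted reference-population carrier frequency; diagnostic-yield
projection `p + (1−p)q`; detection rates and coverage summaries.

**Synthetic data** (`simulate_cohort_inputs`) — a seeded generator for
every input (panel on a miniature genome, phenotypes, annotated
variants, SV calls, CNV map, reference population, registry) with
planted truth tables: qualifying variants satisfy every gate by
construction, each background variant fails exactly one named gate, and
one decoy per exclusion criterion is planted.

## Worked example

```r
library(mptriage)

cfg <- sim_config(seed = 1, n_probands = 200)   # 77% female, 15.2% planted carriers
sim <- simulate_cohort_inputs(cfg)

res <- run_snv_pipeline(sim$snv$variants, sim$panel)
res
#> SNV triage: 1039 input; 34 retained for assessment
#>   quarantined 0 | duplicates 0 | quality fail 572 | frequency fail 286 | not retained 142 | excluded 5

evaluate_against_truth(res, sim$snv$truth)[c("sensitivity", "specificity")]
#> $sensitivity
#> [1] 1
#> $specificity
#> [1] 1

run_sv_pipeline(sim$sv$svs, sim$panel, cnv_map = sim$sv$cnv_map)
#> SV triage: 57 calls -> 56 merged; 6 prioritized
```

The audit line reads: of 1,039 annotated input variants, 572 failed the
quality gate, 286 the frequency gate, 142 met no retention criterion,
5 were excluded by a refutation criterion (one per planted decoy class),
and 34 — exactly the planted qualifying set — survived for ACMG
assessment. The six prioritized SVs are the six planted archetypes
(exon deletion reported by both callers and merged, full-gene deletion,
two inversions, a proto-oncogene duplication, and a translocation with
an exonic breakend).

Classification and the headline contingency test:

```r
combine_acmg(c("PVS1", "PM2"))
#> [1] "likely_pathogenic"

pearson_chi2(matrix(c(52, 388, 298, 8694), 2, byrow = TRUE))$statistic
#> [1] 84.90289

detection_rates(67, 440)$percent
#> [1] 15.2
```

A thin CLI over the same functions ships in `exec/mptriage`
(subcommands `simulate`, `filter-snv`, `filter-sv`, `classify`,
`stats`).

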