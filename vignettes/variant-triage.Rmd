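---
title: "Germline CPG variant triage for multiple-primary-tumor cohorts"
author: "mptriage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Germline CPG variant triage for multiple-primary-tumor cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mptriage)
```

## The problem

Individuals who develop multiple primary tumors (MPTs) — at least two
primaries by age 60 or at least three by 70 — are strongly enriched for
germline variants in cancer-predisposition genes (CPGs). When such a
cohort is sequenced genome-wide, the analytic task is to reduce millions
of calls to a short list worth curator review, without losing the rare
pathogenic variants that motivated sequencing in the first place.
`mptriage` implements that reduction as an explicit, auditable cascade,
together with the cohort-level statistics used to interpret the result,
and a seeded synthetic-data generator that makes the whole pipeline
testable without access to protected patient data.

## The small-variant cascade

Every annotated SNV/indel receives exactly one terminal disposition, and
stage counts conserve the input count exactly. The stages are:

1. **Quality gate.** Genotype quality GQ ≥ 30, read depth DP ≥ 10,
   variant allele fraction VAF ≥ 33%, and caller filter `PASS`. The VAF
   comparison is done in exact rational arithmetic
   (`alt_depth × 100 ≥ 33 × dp`), because the interesting failures sit
   right at the boundary: 7/22 reads is 31.8%, reported as 32%, and must
   fail; 33/100 must pass. Missing GQ/DP is itself a quality failure
   (`missing_quality_field`), never a silent pass.
2. **Population-frequency gate.** Fail if the maximum allele frequency in
   either reference resource (ExAC-style or 1000-Genomes-style, carried
   as annotations) is *strictly above* 0.01. An absent frequency means
   the variant was never observed and is treated as 0 — rare pathogenic
   variants are routinely absent from reference panels, and failing on
   missingness would gut sensitivity.
3. **Retention rules.** A surviving variant is retained for review if at
   least one of four routes fires: (a) a truncating Sequence Ontology
   consequence (configurable set; default `stop_gained`,
   `frameshift_variant`, splice donor/acceptor, `start_lost`,
   `transcript_ablation`); (b) ClinVar pathogenic/likely-pathogenic at
   ≥ 2 review stars (multiple submitters, no conflicts); (c) HGMD
   disease-mutation status; (d) Phred-scaled CADD score ≥ 34. Route (d)
   is logically a second pass — an in-silico rescue of variants absent
   from databases — and the threshold 34 is the median CADD score of
   variants deemed pathogenic through the other routes
   (`derive_cadd_threshold()`); the shipped default is that median.
   "Exceeding the threshold" is implemented as ≥ 34, so a score equal to
   the defining median qualifies; the pipeline asserts that two-pass and
   single-pass evaluation retain identical sets.
4. **Non-coding positional lookup.** Deep intronic or regulatory variants
   never carry a retaining consequence, so a short curated list of known
   pathogenic non-coding positions is searched by exact
   (contig, position, ref, alt) match. The list is user configuration:
   the published curation reduced to only three genome-wide positions,
   and their identities are not printed, so no default list ships.
5. **Exclusion (refutation) criteria.** A retained variant is excluded
   when any of five criteria refutes pathogenicity: (1) truncating but
   ClinVar-benign/uncertain at ≥ 2 stars; (2) truncating in a
   proto-oncogene, whose risk alleles are gain-of-function; (3)
   truncating but removing < 5% of the canonical transcript (LOFTEE-style
   annotation); (4) in a recessive-only gene without a second filtered
   variant in the same gene and individual — a homozygote counts as two,
   and two heterozygous hits are *presumed* compound-heterozygous since
   phase is unknown; (5) retained solely through HGMD/CADD while ClinVar
   refutes at ≥ 2 stars, or at 1 star with multiple submissions and no
   pathogenic assertion. ClinVar "conflicting" is treated as uncertain
   throughout: a conflicted assertion cannot support retention, and can
   support refutation.

Dispositions carry ordered reason codes naming every criterion that
fired, so an audit can reconstruct each decision. Malformed records are
quarantined with a warning, never dropped silently; duplicate genotype
records (same individual, contig, position, ref, alt) are deduplicated
with a warning.

## Structural-variant prioritization

SV calls arrive from a copy-number caller ("canvas") and a breakend
caller ("manta"). Same-type calls for the same event are merged at ≥ 50%
reciprocal overlap (translocations: both breakends within 1 kb), keeping
the higher-quality record — published results report the same deletion
with slightly different coordinates from each caller, which is what this
rule absorbs. The prefilter requires quality ≥ 30, cohort frequency
strictly below 1%, and contact with the panel. "Affects at least one
exon" is deliberately type-dependent: span-type SVs
(deletion/duplication/copy-number events) must intersect a coding exon,
while breakend-type SVs (inversions, translocations) qualify when a
breakend falls anywhere in a gene's transcribed span — published
prioritized SVs include an inversion with both breakpoints intronic, so
intronic breakends must survive.

Surviving calls are assessed once per intersected panel gene into three
categories: copy-number **loss** of a tumor-suppressor gene's coding
region, copy-number **gain** of a proto-oncogene, or **breakpoint
disruption** (any type with a breakend strictly inside the gene span).
Recessive-only genes yield no category unless the call is homozygous or
a second qualifying hit exists. Finally, calls fully **contained** in a
common copy-number-variation map region are excluded. Containment rather
than any-overlap is a deliberate choice: overlap-based exclusion would
discard every whole-gene deletion whenever a small common CNV lies
inside the gene. Both the merge rule and the containment semantics are
configurable, since the underlying publications do not state them.

## ACMG evidence combination

Evidence codes (PVS1, PS1–4, PM1–6, PP1–5, BA1, BS1–4, BP1–7) arrive as
input — assigning them is curator judgment, not automation — and
`combine_acmg()` applies the published combining table to produce the
five-tier classification. Any co-firing of a pathogenic-side and a
benign-side rule yields *uncertain*, per the guideline's conflict
advice. A clearly-labelled heuristic pre-populator
(`suggest_evidence()`) can seed PVS1/PM2/PP3 from annotations as a
curation starting point; it is off the critical path and can be ignored.
Cohort tallies deduplicate families: a variant occurring in two members
of one family contributes once to proband-level detection rates.

## Cohort statistics

* `enumerate_combinations()` — all unordered pairs over an individual's
  *distinct* tumor categories (bilateral/metachronous same-site tumors
  contribute no pair); an individual with k distinct categories
  contributes C(k, 2) combinations.
* `pearson_chi2()` — the uncorrected Pearson χ² on a 2×2 table. The
  Yates continuity correction is explicitly disabled: the uncorrected
  statistic reproduces the published values (84.903, 43.642, 3.2628)
  exactly, the corrected one does not.
* `registry_comparison()` — restricts both cohorts to malignant (or CNS)
  tumors diagnosed strictly before 60, then tests each combination type
  representing > 1% of MPT combinations against the registry.
* `sex_adjusted_frequency()` — reference-population carrier burden
  re-weighted to a target sex split: the female count stays fixed, the
  male count is shrunk to `n_female (1 − p) / p` (kept fractional, not
  rounded), and per-sex frequencies are averaged with those weights.
  Computed from first principles; note that published intermediate male
  counts differ slightly from this arithmetic (6,929 × 23/77 ≈ 2,070),
  so the function documents its formula rather than forcing any printed
  intermediate.
* `yield_projection()` — combines a prior detection rate with an
  incremental rate on the remainder: `p + (1 − p) q`.
* Percentages are reported at one decimal with half-up rounding next to
  exact fractions, matching clinical reporting conventions.

## What the synthetic generator emulates

`sim_config()` fixes the study conditions: 440 probands by default, 77%
female, tumor categories weighted by the shares observed in a
referral-based MPT series (breast 24.6%, colorectal 9.9%, ...), every
proband MPT-eligible by construction, a planted qualifying-variant rate
of 15.2% per proband, five background variants per proband, fifty SV
decoys, two recessive biallelic carriers, and a gnomAD-like reference
population (55.3% male; 6,929 females; 3.3% qualifying-variant frequency
in both sexes). Genes live on a miniature four-contig genome with
kilobase-scale genes, so no reference download is needed.

Planted variants satisfy every gate by construction (VAF resampled from
Binomial(dp, 0.5) until ≥ 33% for heterozygotes, near 1 for
homozygotes); each background variant is constructed to fail *exactly
one* named gate; one decoy per exclusion criterion is planted; truth
tables are first-class outputs so tests compare against intent, not
re-derivation. This is what the perfect sensitivity/specificity results
on synthetic data do and do not mean: they verify that the implemented
predicates match their specifications on inputs that exercise every
branch and boundary, not that the cascade would achieve those operating
characteristics on real sequencing data, whose error modes (caller false
negatives, annotation disagreement, alignment artifacts around indels)
the generator deliberately does not model. A known example of the gap:
real callers miss true events outright (a multi-exon deletion known to
the referring clinician was never called), and no filter downstream of
calling can recover that.

## Numerical and design choices

* Boundary semantics are inclusive where the rules say "at least" (GQ 30,
  DP 10, VAF 33%, CADD 34, quality 30) and strict where they say
  "above"/"less than" (allele frequency 0.01, cohort frequency 1%,
  truncation fraction 5%).
* Coordinates: variant tables and SV tables are 1-based inclusive
  (VCF convention); BED files are 0-based half-open on disk; interval
  arithmetic runs on `GenomicRanges`.
* Determinism: all generation runs under `withr::with_seed` on offsets
  of one configured seed; two runs with the same configuration are
  byte-identical on disk, and the caller's RNG state is untouched.
* Degenerate inputs: zero-depth sites route to a quality failure rather
  than a division error; empty cohorts yield empty, zeroed audits;
  registry tests on degenerate tables (a type comprising all
  combinations of both cohorts) return NA statistics instead of erroring.
* Problem sizes in the shipped tests: synthetic cohorts of 25–1,000
  probands (about 5,200 variants and 57 SV calls at n = 1,000), five
  seeds for the recovery checks, and the full cross-product of ACMG
  evidence sets up to size four (12,950 sets). These sizes exercise
  every code path while keeping the default suite fast.

## Known limitations

* The characteristic-tumor map and the tumor-category vocabulary are
  best-effort reconstructions shipped as editable configuration; local
  deployments should replace them with curated tables.
* Evidence-code assignment, variant calling, annotation (VEP/CADD/
  LOFTEE), and live database queries are out of scope by design; the
  pipeline consumes annotations, it does not produce them.
* The recessive compound-heterozygosity rule cannot see phase; two
  variants in *cis* would be wrongly presumed biallelic (flagged as
  presumptive in the audit trail).
* SV support covers the BEDPE-like tabular interchange format; breakend
  VCF (`SVTYPE`/`MATEID`) parsing is not implemented.
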