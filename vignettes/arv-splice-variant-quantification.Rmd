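---
title: "Quantifying AR splice variants from junction reads and droplet digital PCR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying AR splice variants from junction reads and droplet digital PCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ARVquant)
```

## The problem

Androgen receptor (AR) splice variants drive resistance to AR-directed
therapy in metastatic castration-resistant prostate cancer (mCRPC). The
two clinically most relevant variants, AR-V7 and AR-v567es, lack the
ligand-binding domain and remain constitutively active. Measuring them
in circulating tumor cells (CTCs) -- down to single cells -- requires
assays that are transcript-specific despite extensive sequence sharing
between variants (AR-V7 and AR-V9 are nearly identical over their 3'
cryptic exons).

The discriminating feature of each transcript is a unique exon--exon
splice junction:

| Transcript | Junction |
|---|---|
| AR-FL (full length) | exon 7 → exon 8 |
| AR-V7 | exon 3 → cryptic exon 3 (CE3) |
| AR-v567es | exon 4 → exon 8 (exons 5--7 skipped) |

ARVquant quantifies these transcripts through two independent readouts
that both key on those junctions: (i) counting spliced RNA-Seq
alignments whose skip bridges a junction exactly, and (ii) absolute
quantification by droplet digital PCR (ddPCR) with junction-spanning
assays, followed by cohort-level statistics.

## Junction counting from spliced alignments

A spliced alignment supports a transcript when its CIGAR contains an `N`
(skip) operation whose skipped reference interval is exactly
`[donor_end + 1, acceptor_start - 1]` for that transcript's signature,
with at least `min_overhang` aligned (`M/=/X`) bases immediately
flanking the skip on each side. Design choices:

* **Exact boundary matching** (`tolerance = 0` by default): the
  specificity argument is exact exon-boundary identity; a slack flag
  exists for noisy aligners but is off by default.
* **`min_overhang = 6`**: small enough to keep single-junction reads
  from short reads, large enough to suppress 1--2-base spurious anchors.
* **Positivity threshold of 1 spanning read**: positivity is a
  presence/absence call; stricter thresholds are configurable.
* Insertions in the read do not break an anchor (the reference stays
  contiguous); deletions, clips and further skips do.
* Duplicate alignments are **not** collapsed; with PCR duplicates in
  the input, spanning counts are inflated accordingly (a documented
  limitation, not a bug).
* Secondary/supplementary alignments are dropped at parse time so one
  fragment cannot be counted twice; mapping-quality filtering is off by
  default (`min_mapq = 0`).

Signature uniqueness is a precondition: if two transcripts share a
junction, `count_junction_reads()` refuses to run rather than produce
ambiguous counts. `validate_signatures()` reports such collisions.

The shipped coordinates (`build_toy_ar_model()`) are a deliberately
synthetic single-contig system (contig `chrT_AR`, 100-bp exons), because
genomic coordinates are not part of the package's contract; real hg38
junction coordinates are supplied through `load_model()`.

```{r}
model <- build_toy_ar_model()
sim <- simulate_spliced_reads(model,
                              c("AR-FL" = 12, "AR-V7" = 7, "AR-v567es" = 3),
                              n_background = 30, seed = 6)
count_junction_reads(parse_sam(sim$sam), model, min_overhang = 6)
```

## ddPCR quantification model

Template molecules partition into droplets approximately Poisson. With
`n_pos` of `n_total` droplets fluorescent, the mean occupancy is

$$\hat\lambda = -\ln\!\left(1 - \frac{n_{pos}}{n_{total}}\right),$$

and the concentration in copies/µL of reaction is
$\hat\lambda \cdot 1000 / v$ with $v$ the droplet volume in nL.
Parameters that matter:

* **Droplet volume 0.85 nL** (QX200 nominal); configurable.
* **Reaction volume 22 µL** (one-step RT-ddPCR loading 11 µL of sample
  RNA); `copies_per_sample = conc \cdot 22 / f` with `f` the fraction of
  the sample loaded. Optional divisors (`normalizer`) support per-CTC or
  per-ng reporting, since different experiments normalise differently;
  the default applies none.
* **Amplitude thresholding**: a fixed threshold, or `"auto"` -- the
  exact two-class 1-D partition minimising within-class variance, with
  the cut at the midpoint of the class means. This is a documented
  stand-in for the instrument's unpublished per-well rule, not a claim
  to reproduce it.
* **QC**: `NTC` wells tolerate at most 2 positive droplets (a common
  rain allowance); positive-control wells must have ≥ 1 positive
  droplet; wells under 10,000 accepted droplets are flagged
  `LOW_DROPLETS`; fully positive wells are `SATURATED` (no finite
  estimate). Samples on a failed plate are flagged unreliable but still
  reported.
* **Repeatability**: `replicate_cv()` uses the *sample* standard
  deviation (n − 1) over the mean, reported in percent, for both
  intra-assay (repeatability) and inter-assay (reproducibility) sets.

```{r}
sim <- simulate_droplets(lambda_true = 0.3, n_droplets = 15000, seed = 11)
cls <- classify_droplets(sim$droplets$amplitude, "auto")
poisson_concentration(cls$n_pos, cls$n_total)
```

## Cohort statistics

* **Positivity** (`call_positive()`): copies above 0 by default -- any
  detected signal counts, the convention of a detection heatmap where
  white means not detected. A background-subtraction threshold is
  available because leukocyte fractions can carry a trace of AR-FL
  (a few copies/sample).
* **Summaries** (`summarize_cohort()`): medians, means and ranges are
  computed over *all* subjects including zeros (ranges that start at 0
  imply this convention); prevalence is reported as an integer percent
  but stored at full precision. Missing measurements count as not
  detected.
* **Fisher exact test** (`fisher_exact_two_tailed()`): implemented by
  full enumeration over the hypergeometric support, two-sided by the
  point-probability rule (sum every table whose probability ≤ the
  observed one, relative tie tolerance 1e−12 -- tables on opposite
  tails can be equal up to floating point). This is the dominant
  convention of common analysis software; it is stated explicitly
  because two-sided Fisher conventions differ.
* **Mann--Whitney** (`mann_whitney()`): midrank U; exact enumeration of
  all group assignments when $n_x + n_y \le 12$ (cheap below, standard
  approximation above), otherwise the normal approximation with tie
  correction and a 0.5 continuity correction; always two-sided. Group
  comparisons of expression are done on `log2_transform()`ed counts
  (offset 1, mapping zero counts to zero).
* **EpCAM fractions** (`compare_epcam_fractions()`): per-transcript
  prevalence in EpCAM-positive vs EpCAM-negative CTC pools with a
  Fisher p per transcript, quantifying how much EpCAM-based capture
  under-samples variant-expressing cells.

```{r}
# AR-v567es in single CTCs: 6/53 (CRPC) vs 10/17 (NEPC)
fisher_exact_two_tailed(rbind(c(6, 47), c(10, 7)))$p_value
```

## What the synthetic generators emulate

`simulate_droplets()` draws per-droplet template counts
Poisson(λ), then amplitudes from two Gaussian modes (defaults
1000/8000, σ 300); optional "rain" re-draws a fraction of droplets
uniformly between the modes. `simulate_spliced_reads()` emits
`aMkNbM` records whose skip length equals the signature's intron
exactly, with anchors drawn from a configurable range, plus unspliced
background reads; base sequences are a fixed pattern because counting
never inspects them. `simulate_cohort()` makes each subject positive
per transcript with configured prevalence (defaults 90% / 66% / 52%
over 29 subjects, the composition of an mCRPC CTC cohort) and draws
positive expression log-normally (meanlog `log(15)`, `log(2.5)`,
`log(0.4)`; sdlog 1.2), chosen once to mirror the observed medians
(≈ 8.5 / 1.3 / 0.14 copies/sample) and heavy-tailed ranges.

What they deliberately do **not** model: sequencing or alignment
error, soft-clipped or multi-junction reads, amplitude drift and plate
effects, channel crosstalk, or correlated expression between
transcripts within a patient. Passing tests therefore demonstrate
correctness of the counting and estimation machinery under the stated
statistical model, not robustness to every artefact of real data.

A known property of the rain model: re-drawing a random droplet
uniformly between the modes flips it across the midpoint threshold
with probability ≈ 1/2, biasing the positive fraction toward 0.5 by
about $r\,(0.5 - p)$ for rain fraction $r$. At low occupancy this
exceeds Monte-Carlo error, so estimator-recovery checks either use
rain-free wells or compare against the analytically shifted
expectation.

The shipped `inst/extdata/synthetic_cohort_table1.csv` is a
**synthetic** 29-subject cohort constructed so its per-transcript
marginals (positivity 26/19/15, medians, means, ranges, 13
triple-positive and 2 all-negative subjects) match the published
summary table of an mCRPC CTC cohort; it stands in for per-patient
source data that cannot be redistributed, and exercises
`summarize_cohort()` end to end.

## Numerical choices and degenerate inputs

* `auto` thresholding is exact (sorted-scan minimisation), hence
  deterministic; constant amplitude vectors classify everything
  negative.
* Saturated wells (`n_pos = n_total`) return `Inf` rather than an
  arbitrary cap; callers must handle the flag.
* CV of an all-zero replicate set is undefined and flagged, not 0.
* Fisher enumeration works in log-binomial space; support sums are
  verified to 1 within 1e−10 in the tests.
* Empty cohorts, empty samples, zero droplets and negative counts are
  rejected with named errors rather than propagated as NaN.

## Scale of the validation suite

The test and acceptance suites run entirely on synthetic data at desk
scale: 15,000-droplet wells over 100 seeds per occupancy for estimator
recovery, 20 × 5-well replicate sets for the CV bound, 1,000 random
spliced reads for oracle equivalence against a base-projection
implementation, exhaustive Fisher enumeration for small tables plus
hundreds of random tables with margins ≤ 30, and 500 simulated
29-subject cohorts for prevalence recovery and confidence-interval
coverage. These sizes were chosen to make sampling error small relative
to the tested tolerances while keeping the suite fast.

## Limitations

* Junction counting consumes SAM text; BAM inputs should be converted
  (e.g. `samtools view`) upstream.
* No deduplication, no strand-awareness beyond coordinate
  normalisation, no novel-junction discovery, no isoform quantification
  beyond the three signatures.
* The auto threshold is not the instrument's algorithm; wells with
  heavy rain deserve manual thresholds.
* Cohort tools report raw p-values only (no multiplicity correction)
  and no survival or outcome modelling.
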