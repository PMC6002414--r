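---
title: "Detecting, quantifying and dating interspecies introgression with introscan"
author: "introscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting, quantifying and dating interspecies introgression with introscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introscan)
```

## The problem

When a domesticated species expands into the range of a wild relative —
cattle meeting banteng in southern China, or yak on the Tibetan plateau —
hybridisation can leave tracts of the wild species' genome segregating in
the domestic population.  Such adaptive introgression is detectable from
whole-genome resequencing panels long after the event.  `introscan`
implements a complete desk-scale analysis of this situation: given a joint
biallelic SNP callset and a mapping of samples to panels, it

1. identifies **donor-diagnostic alleles**: alleles carried by the donor
   species panel and absent from every "exclusion" panel (populations
   related to the recipient but not involved in the admixture);
2. scans the recipient in **sliding windows**, averaging the
   diagnostic-allele frequency per window, and calls **introgressed
   segments** per haplotype with a deterministic run-length caller;
3. summarises the **introgressed genome fraction** per genome and the
   intervals shared by multiple haplotypes;
4. tests the admixture hypothesis with from-scratch **f3** and
   **ABBA-BABA D** statistics, with weighted block-jackknife standard
   errors;
5. confirms tract origin with a **neighbour-joining tree** of phased
   haplotypes over the introgressed intervals;
6. **dates the pulse** with a net-divergence molecular clock, and
   interprets cross-coalescence-rate curves from sequential coalescent
   methods via their threshold crossing times.

A synthetic-data generator with exact tract truth underpins the test suite:
every statistical claim the package makes about itself is demonstrated on
data whose answer is known.

## Diagnostic alleles and the window scan

A site is donor-diagnostic when at least `min_donor_carriers` donor samples
carry an allele whose observed frequency in every exclusion panel is at
most `max_exclusion_freq` (default 0: strict absence).  Two choices here
deserve comment.

* The diagnostic allele may be REF or ALT.  Reference assemblies are
  usually built from one of the exclusion lineages, so donor-specific
  variation is mostly ALT — but a donor fixed for the reference base at a
  site where all exclusion panels are fixed ALT is equally diagnostic, and
  the finder records which allele it used.
* Absence is evaluated on observed allele copies only.  A site is
  ineligible when the donor or an exclusion panel exceeds the
  `max_missing_per_panel` missingness bound or has no observed copies; no
  imputation is performed anywhere in the package.

The window scan tiles contigs (5 kb windows by default; terminal partial
windows are kept and length-normalised rather than dropped, which avoids a
systematic telomeric undercall) and, per window, averages the
diagnostic-allele frequency in the recipient target.  In haplotype mode —
the default for phased callsets — each recipient haplotype is scanned
separately and the per-site value is the 0/1 carriage indicator, so the
window mean is the fraction of diagnostic sites the haplotype carries.

## Segment calling

The caller is a deterministic threshold/run-length/merge procedure: a
window qualifies at `mean_freq >= 0.5` (a haplotype either carries the
donor tract or it does not; 0.5 splits noise symmetrically) with at least
`min_support_sites = 2` informative sites; runs with at least
`min_consecutive_windows = 2` qualifying windows, bridging up to
`max_merge_gap_windows = 1` failing or empty windows, become half-open
segments.  All four knobs are exposed in the pipeline configuration.  This
density caller deliberately replaces local-ancestry HMMs: the
diagnostic-allele density itself is the ancestry indicator, the procedure
has no tuned emission model, and its behaviour is fully checkable against
a brute-force oracle (which the test suite does on random instances).

Per-genome fractions divide the summed segment bp of a genome's two
haplotypes by twice the callable length (sample mode: segment bp over
callable length).  Both normalisations are available because published
per-genome percentages do not always state which was used; the group
summary reports mean and standard error (sd/\(\sqrt{n}\), \(n-1\)
denominator).

## f3 and D

For target \(C\) and sources \(A, B\), the f3 statistic is the mean over
sites of \((\hat c - \hat a)(\hat c - \hat b)\), optionally minus the
finite-sample correction \(\hat c(1-\hat c)/(n_C - 1)\) that removes the
bias of the squared sample frequency; significantly negative values
indicate admixture.  The outgroup-f3 variant uses the outgroup as target
and no correction — it is a shared-drift ranking device, not a test.

The D statistic follows the (( P1, P2 ), P3, O) topology with per-site
ABBA/BABA terms symmetrised over the arbitrary choice of counted allele.
The symmetrised numerator and denominator reduce to
\((p_2 - p_1)(p_3 - p_O)\) and
\((p_1 + p_2 - 2p_1p_2)(p_3 + p_O - 2p_3p_O)\); this makes the statistic
exactly invariant under global allele relabeling (a property the test
suite asserts), while coinciding term-by-term with raw ABBA/BABA counts
whenever the outgroup polarises the site.

Standard errors come from a weighted delete-one-block jackknife over
physical blocks (5 Mb by default; physical rather than equal-site blocks
are robust to SNP-density variation).  The implementation follows the
weighted jackknife variance formula with block site counts as weights; the
two-block closed form and a naive leave-one-out transcription serve as
oracles in the tests, and on 1,000 iid blocks the jackknife SE matches the
analytic SE within 10%.  Sites where a required panel has no observed
copies are skipped per statistic, not globally, which maximises usable
sites and matches the per-statistic site counts standard tools report.

## Haplotype confirmation and dating

`hap_distances()` computes p-distances — mismatches per callable bp, with
pairwise-complete handling of missing sites — between phased haplotypes
over an interval set, and `nj_tree()`/`hap_tree()` build the
neighbour-joining tree with optional bootstrap support from resampling
variant sites.  p-distance is appropriate here because the haplotypes
compared are conspecific or nearly so; at these divergences multiple-hit
corrections are negligible relative to the sampling noise of short
intervals.

Dating converts the net tract–donor divergence to time through
\(d_{net} = 2\mu t\): `clock_date(d_net = 1.26e-5)` with
\(\mu = 1.26\times10^{-8}\) per generation and 6 years per generation
gives 500 generations = 3,000 years.  The default ancestral-polymorphism
correction subtracts the **full** within-donor diversity from the
tract–donor distance.  The reasoning: introgressed tract lineages entered
the recipient from the donor gene pool, so a tract lineage and a sampled
donor lineage coalesce no more recently than the pulse; their expected
divergence is \(2\mu t_{adm}\) *plus* the donor's stationary coalescent
diversity, which the modern within-donor \(\pi\) estimates directly.  The
classical \(d_a\) correction (half the within-donor plus half the
within-tract diversity) is also available, but note that post-pulse
private mutations enter the cross distance once and the tract diversity
twice, so \(d_a\) cancels much of the very signal being dated — it is the
right correction for a *population split*, not for a pulse out of a
sampled donor.  Confidence intervals come from a bp-weighted bootstrap
over segments.

When dating *called* segments rather than known tracts, the pipeline
first erodes each segment by one window width (`date_trim_bp`).
Window-quantised calls overhang the true tract boundary by up to a window,
and because the non-tract recipient background is diverged from the donor
at the species level, even a fraction of a percent of contaminating bp
inflates the net divergence several-fold; edge erosion removes it at a
negligible cost in signal.

Cross-coalescence-rate curves (e.g. from sequential Markovian coalescent
software) are interpreted by `ccr_crossing()`: scanning from the present
into the past, the first crossing of a threshold (0.5 by convention;
0.25/0.75 bracket a range) is located by linear interpolation between the
bracketing estimates, and the first raw grid point past the threshold is
reported alongside, since the piecewise-constant output of such software
makes "the first time point at or beyond" the natural raw reading.

## The synthetic-data generator

`simulate_introgression()` produces phased diploid panels for five
populations — outgroup, donor, a taurine-like exclusion panel, and a pair
of sister recipient-side populations (the second exclusion panel doubles
as the unadmixed sister and as P1/source A in the statistics) — under a
layered approximation of the coalescent:

* **branch substitutions**: Poisson(\(\mu \ell L\)) fixed differences per
  population-tree branch;
* **stationary within-population polymorphism**: segregating sites with
  latent frequencies \(p \sim \mathrm{Beta}(0.5, 0.5)\) (U-shaped, like a
  neutral frequency spectrum), haplotypes sampled Bernoulli(\(p\)); site
  counts are calibrated so the expected heterozygosity matches the
  configured per-bp \(\pi\);
* **shared ancestral polymorphism**: the same construction applied to
  internal ancestors, with per-descendant-population frequencies drifted
  apart through a Beta concentration parameter — this is the source of
  incomplete lineage sorting, and hence of ABBA/BABA noise under the null;
* **the pulse**: per recipient haplotype, donor tracts placed by an
  alternating exponential renewal process (mean tract `L_mean`, gap mean
  chosen so the stationary tract fraction is `f`); tract alleles are drawn
  Bernoulli at the donor population frequencies, then each tract receives
  Poisson(\(2\mu t_{adm}\,\mathrm{bp}\)) private mutations — the factor 2
  accounts for divergence accruing on both the tract lineage and the donor
  lineage it will later be compared with.  Drawing founder alleles at the
  donor's latent frequencies (rather than copying a sampled donor
  haplotype) keeps the dating estimator free of a \(-\pi_D/2n_D\)
  self-comparison bias.

Default parameters describe the cattle-like desk scenario: one 10-Mb
contig; \(\mu = 1.26\times10^{-8}\); splits at 5e5 (outgroup), 2.5e5
(donor), 5e4 (taurine/indicine), 7.5e3 (sister indicine) generations; a
pulse of `f = 0.03` at 500 generations with 200-kb mean tracts (the tract
scale expected for a pulse of that age at ~1 cM/Mb); panels of 2–10
diploids; per-population diversities of 0.6–1.2 × 10⁻³/bp.  These values
were fixed once, from the history the analysis targets, and the whole
suite runs against them.

What the generator does **not** emulate: linkage disequilibrium outside
tracts (sites are exchangeable given their layer), recombination within
tracts (each tract has a single founder draw per site instead of a mosaic
of donor lineages), sequencing or genotyping error, and recurrent
mutation (infinite sites; duplicate positions are dropped).  Passing tests
therefore demonstrate correctness of the *machinery* and calibration under
an idealised but structurally faithful null and alternative — not
robustness to base-calling artefacts or LD pruning choices, which are
upstream of this package's inputs.

## Numerical and design choices worth knowing

* Coordinates are converted to 0-based half-open at VCF ingest; every
  downstream interval, window and BED row uses that convention.
* Multi-allelic and non-SNP records are dropped, not split; duplicated
  positions keep the first record.
* Missing genotypes never enter frequency denominators; a mean over zero
  informative sites is reported `NA`, never silently dropped or zeroed.
* Windows with no diagnostic site remain in the scan output with
  `n_sites = 0`, so callers can distinguish "no evidence" from "evidence
  against".
* The segment caller's gap bridging counts *consecutive* non-qualifying
  windows; a bridged gap never starts or ends a segment.
* Jackknife SE of 0 (all blocks identical) reports Z as signed infinity
  with a warning rather than NA, so downstream thresholding fails loudly.
* NJ branch lengths are clamped at 0 with a message; tie behaviour is
  whatever the underlying agglomeration gives, which is deterministic for
  a fixed input matrix.
* Pipeline reruns with the same configuration are bit-identical; the
  manifest hash covers the configuration (minus the output location) and
  the MD5 of every output file.

## Problem sizes used in the validation suite

The shipped tests validate each operation against brute-force oracles on
hundreds of random small instances, and the statistical behaviour on the
default 10-Mb scenario: 50 null replicates for calibration of D and f3,
20 replicates each for signal detection, tract recovery and dating
recovery.  These sizes give stable rates while keeping a full run in
minutes on a single core.

## Known limitations

* The dating estimator is noisy at desk scale: with ~5 Mb of aggregate
  tract sequence and donor diversity ~10³ times the per-generation
  mutation input, the sampling noise of \(d_{cross} - d_{within}\) is a
  substantial fraction of the 500-generation signal, so individual
  replicate estimates scatter around the truth by roughly a factor of two
  even though they are unbiased; genome-scale data (hundreds of Mb)
  shrinks this proportionally.  The bootstrap CI reported by
  `date_segments()` makes this uncertainty visible.
* Unphased callsets restrict haplotype-mode scanning, tree building and
  dating to homozygous sites; sample-mode scanning is provided but has
  lower resolution for low-frequency tracts.
* The shared-interval filter counts carriers per bp; it does not test
  identity by descent between the carriers.
* `panel_partition()` defines presence as at least one observed copy of
  the alt allele, so its Venn cells depend on which lineage the reference
  assembly represents, exactly as published SNP-sharing Venn diagrams do.
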