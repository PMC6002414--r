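# introscan

Detection, quantification and dating of interspecies introgression from
whole-genome SNP data.

When a domestic population hybridises with a wild relative — cattle with
banteng in southern China, taurine cattle with yak on the Tibetan plateau —
tracts of the donor species' genome keep segregating in the recipient and
can be recognised long after the event.  `introscan` is an R package for
population geneticists who have a joint multi-species VCF and want the
complete downstream analysis of that situation at a desk scale:

* **donor-diagnostic alleles** — alleles carried by the donor panel and
  absent (frequency ≤ a configurable bound, default 0) from every
  exclusion panel;
* **sliding-window scans** of the diagnostic-allele frequency in the
  recipient (5-kb windows by default), per haplotype or per sample;
* **introgressed-segment calling** with a deterministic
  threshold/run-length/merge caller, interval sharing across haplotypes,
  and per-genome **introgressed fraction** (mean ± SE);
* **f3 and ABBA-BABA D statistics** written from first principles, with
  weighted block-jackknife standard errors and Z-scores
  (`f3(C; A, B) = mean (c−a)(c−b)` with optional target-heterozygosity
  bias correction; `D = Σ(ABBA−BABA) / Σ(ABBA+BABA)` symmetrised over
  allele labeling, i.e. numerator `(p2−p1)(p3−pO)`);
* **NJ haplotype trees** (p-distance, bootstrap support) to confirm that
  recipient tract haplotypes cluster with the donor;
* **molecular-clock dating** of the pulse from net tract–donor divergence
  (`d_net = 2 μ t`, default μ = 1.26e-8/generation, 6 years/generation)
  with bootstrap CIs, and **cross-coalescence-rate curve** interpretation
  (threshold crossings at 0.25/0.5/0.75 by linear interpolation);
* a **synthetic-data generator** with exact tract truth (structured
  panels, shared ancestral polymorphism, an exponential-tract admixture
  pulse) and per-bp precision/recall scoring, used throughout the test
  suite so every statistical claim is validated against known answers.

## Worked example

Simulate the default cattle-like scenario (10-Mb contig, donor split 2.5e5
generations ago, a 3% admixture pulse 500 generations ago into 10 recipient
diploids) and run the full analysis:

```r
library(introscan)

sim <- simulate_introgression(sim_params(seed = 42))
gm  <- sim$genotypes                     # 389,487 sites x 28 samples
pan <- sim$panels

das <- find_diagnostic_alleles(gm, pan)  # 80,040 donor-diagnostic sites
ws  <- window_scan(gm, das, pan$recipient, make_windows(gm$contig_lengths),
                   mode = "haplotype")
seg <- call_segments(ws)                 # 34 segments across 20 haplotypes

genome_fraction(seg, callable_mask(contig_lengths = gm$contig_lengths),
                pan$recipient)$mean      # 0.0394 (truth: 0.0396)

d_stat(gm, pan, "exclusion_2", "recipient", "donor", "outgroup",
       block_size_bp = 5e5)
#> estimate 0.289261  SE 0.0481  Z 6.01  (20 blocks)

f3_stat(gm, pan, "recipient", "exclusion_2", "donor", block_size_bp = 5e5)
#> estimate 0.0382942  SE 0.00275  Z 13.95  (20 blocks)

date_segments(gm, seg, pan$donor, trim_bp = 5000, n_boot = 200)
#> admixture date: 477 generations = 2863 years (d_net 1.2e-05, ancestral correction)
#>   95% CI: 0 - 5067 years

evaluate_calls(seg, sim$truth)[c("precision", "recall")]
#> $precision 0.997   $recall 0.993
```

Reading the numbers: the positive D (Z ≫ 3) rejects treeness in the
direction of donor→recipient gene flow; the segment caller recovers the
planted tracts almost exactly per bp; the diploid-normalised introgressed
fraction matches the realized truth; and the clock dates the pulse at its
simulated age (500 generations) within the bootstrap uncertainty.  On a
null simulation (`f = 0`) the same D statistic is calibrated: |Z| < 3.

The same functions run on real data via `read_vcf()`, `read_panels()` (a
TSV of `sample_id`, `role` with roles `donor`, `recipient`,
`exclusion_1..k`, `outgroup`) and `run_pipeline()`, which orchestrates
every stage, writes TSV/BED/JSON/newick outputs plus a manifest whose hash
makes reruns verifiable, and can be driven from the shell with
`Rscript inst/scripts/introscan.R --config run.yaml`.

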