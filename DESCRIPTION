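Package: introscan
Title: Detection, Quantification and Dating of Interspecies Introgression
    from Donor-Diagnostic Alleles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting adaptive introgression between closely
    related species in whole-genome resequencing data: discovery of
    donor-diagnostic alleles against exclusion panels, sliding-window
    diagnostic-allele scans with run-length segment calling of introgressed
    tracts, genome-fraction summaries, windowed nucleotide diversity, f3 and
    ABBA-BABA D statistics with weighted block-jackknife standard errors,
    neighbour-joining haplotype confirmation, net-divergence molecular-clock
    dating of admixture pulses, cross-coalescence-curve interpretation, and a
    coalescent-flavoured synthetic-data generator with known tract truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    vcfR,
    ape,
    IRanges,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
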