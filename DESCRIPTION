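Package: REMIscreen
Title: Genotyping and Screening Toolkit for REMI-Based Strain Engineering in Komagataella phaffii
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: In-silico counterparts of the computational steps used when
    engineering secretion-enhanced Komagataella phaffii (Pichia pastoris)
    strains from a restriction enzyme-mediated integration (REMI)
    genome-disruption library: a pileup-based differential "plausible SNP"
    caller that contrasts a mutant isolate against its parental host, a
    restriction-digestion / plasmid-rescue simulator that recovers the
    genomic locus flanking a random plasmid insertion, quantitative screen
    metrics (relative secretion titer, hit calling, productivity, specific
    growth rate, Welch's t-test, serial-transfer generation arithmetic),
    a LAST tabular alignment reader with best-score selection, and a
    synthetic-data module that generates genomes, constraint-satisfying
    plasmids, planted variants and error-bearing reads with full ground
    truth so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
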