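Package: seedbulge
Title: CG-Seed microRNAs and Their Non-Canonical Bulge Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for microRNAs carrying a CG dinucleotide in
    their seed region and the non-canonical "bulge" target sites they can
    recognise. Provides seed extraction and CG-dimer classification,
    canonical seed-site and CG-bulge-site search in 3'UTRs with random-bulge
    controls, conservation-rate scoring across multi-species alignments,
    MAF-binned CpG mutation-rate profiles from population variants,
    miRNA-target expression-correlation tests with resampled random-gene
    nulls, transfection shift tests, simplified nearest-neighbor duplex
    minimum-free-energy scoring, CLASH chimeric-read classification with
    shuffle and scramble nulls, and synthetic-data generators with planted
    ground truth that make the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
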