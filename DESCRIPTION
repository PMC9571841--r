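Package: emsmap
Title: Bulked-Segregant Mapping of EMS-Induced Mutations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.invalid",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for mapping-by-sequencing of
    chemically induced mutations in an interspecific F2 bulk-segregant
    design. Simulates F2 recombination under the Haldane map function,
    EMS-spectrum background mutations and pooled sequencing counts at
    interspecific SNP markers; computes pooled non-reference
    allele-frequency profiles; localizes the candidate region where the
    mutant pool's allele frequency falls to zero; filters and annotates
    candidate homozygous mutations (frameshift, nonsense, missense, CAPS
    feasibility); and provides the segregation chi-square, inheritance-mode
    classification, screening-rate and LD50 statistics used to frame a
    mutagenesis program.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings,
    vcfR,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
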