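Package: teunmask
Title: Transposon Insertions that Unmask Recessive Insecticide Resistance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for the discovery of intragenic
    DNA-transposon insertions that silence one allele of an insecticide target
    gene and thereby unmask recessive resistance mutations carried on the
    homologous chromosome. Provides a diploid locus and paired-end read
    simulator with analytic truth alignments; detection of heterozygous
    insertion breakpoints from soft-clipped alignments; targeted reconstruction
    of the inserted sequence by iterative seed extension; terminal
    inverted-repeat and truncation annotation of the reconstructed element;
    reading-frame and premature-termination-codon impact analysis with a
    nonsense-mediated-decay flag; allele-specific expression quantification at
    heterozygous variant sites; a Mendelian cross model over
    susceptible/resistant/silenced haplotypes including a homozygous-lethal
    silenced allele; in-silico PCR genotyping; and probit dose-response
    analysis (LC50, Fieller confidence intervals, resistance ratios,
    likelihood-ratio equality tests) plus delta-delta-Ct expression analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
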