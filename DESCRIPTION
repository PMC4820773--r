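Package: mipkit
Title: Design and Validation of Molecular Inversion Probe Panels for
    Non-Model Organisms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for building targeted-resequencing panels of Molecular
    Inversion Probes (MIPs) from transcriptome assemblies of organisms
    without a sequenced genome. Identifies exon boundaries in transcripts by
    local alignment to ortholog gene models, designs 70-nt probes whose
    arms are chosen by nearest-neighbor melting temperature, and checks
    probe geometry by in-silico capture. Downstream analytics quantify
    per-probe capture performance as the fraction of mapped reads (FMR),
    select probes for concentration rebalancing, and validate markers as
    single-copy Mendelian loci using an exact multinomial segregation test
    and exact Hardy-Weinberg tests for heterozygote excess (collapsed
    paralogs) and deficit (null alleles). Includes a simulator that
    generates references, probe panels, read counts and family and
    population genotypes with the statistical structure the analyses
    assume, plus replicate concordance (non-reference discrepancy rate),
    nucleotide diversity and panel cost models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    vcfR,
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
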