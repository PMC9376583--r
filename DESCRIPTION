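Package: lnpscreen
Title: Analysis of DNA-Barcoded Lipid Nanoparticle Delivery Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and analysis toolkit for pooled in vivo screens of
    DNA-barcoded lipid nanoparticles (LNPs). Covers error-tolerant barcode set
    design and 91-nt scaffold assembly, combinatorial formulation library
    enumeration with dynamic-light-scattering quality control, injected-pool
    dose accounting, ground-truthed simulation of amplicon sequencing reads
    (staggered nested-PCR primers, per-molecule UMIs, PCR amplification bias,
    substitution errors), mismatch-tolerant barcode counting from FASTQ,
    input-normalized delivery quantification with negative-control checks, and
    component-level fold enrichment over the top and bottom deciles of ranked
    LNPs with bootstrap resampling intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
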