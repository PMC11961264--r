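Package: potkit
Title: Primer Design, In-Silico Validation and Spot Photometry for PCR-Based
    Protein Tagging in Trypanosomatids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools supporting PCR-only tagging (pPOT) workflows in
    trypanosomatids: design of long tagging primers (homology arm plus
    universal plasmid annealing sequence) for N-terminal, C-terminal,
    signal-peptide-replacement and GPI-anchor/CTD-replacement tagging;
    in-silico amplification, locus integration and fusion reading-frame
    verification; codon-usage tables and codon-frequency recoding of tag
    genes; protein molecular weight and isoelectric point; and quantification
    of fluorescent-spot brightness with median local-background subtraction
    together with photobleaching half-life estimation from time-lapse stacks,
    including a synthetic image generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    tiff,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
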