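Package: venomest
Title: Simulation, Assembly and Annotation of Venom-Gland EST Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for single-pass venom-gland expressed
    sequence tag (EST) libraries. Provides a synthetic EST generator with
    full ground truth (toxin-class mixture, truncated-normal length model,
    vector/polyA decorations, quality decay, planted SNPs, indels,
    microsatellites, transposable elements and inverted repeats), read
    cleaning (vector screening, quality and polyA/polyT trimming, slippage
    flagging), overlap clustering and quality-weighted consensus assembly,
    similarity-based toxin annotation with Karlin-Altschul E-value
    statistics, SNP/indel calling from contig layouts with plate-of-origin
    artifact controls, microsatellite detection, transposable-element and
    chimeric-transcript classification, and long inverted-repeat discovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
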