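Package: frdemux
Title: Fragment-Ratio Demultiplexing and Quality Control for Multiplexed
    Droplet scATAC-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Demultiplexes Tn5-sample-barcode-multiplexed droplet single-cell
    ATAC-seq experiments afflicted by sample-barcode hopping. Builds the cell
    barcode by sample fragment count matrix, computes per-barcode fragment
    ratios, assigns barcodes to samples at a configurable threshold and splits
    fragment files into clean per-sample outputs. Also provides the ATAC
    quality-control metrics used to compare experimental conditions (FRIP, TSS
    enrichment, nucleosome signal, mitochondrial fraction, fragment-length
    distributions), peak-set comparison utilities (overlap fractions, upset
    intersection counts, fraction-of-cells-with-signal correlation) and a
    synthetic fragment simulator with known ground truth so the whole pipeline
    can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    BiocGenerics,
    S4Vectors,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    tools,
    graphics
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
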