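Package: oriscan
Title: Prediction and Analysis of Bacterial Replication Origins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts bacterial replication origins (oriC) and termini from
    complete or draft genomes. Every intergenic sequence is scored on three
    lines of evidence: distance to the minimum of the cumulative GC disparity
    (Z-curve method), flanking replication-initiator indicator genes (dnaA by
    default), and DnaA-box content weighted by mismatch count. Ties are
    screened with oriC functional elements (DnaA-trios, Dam/GATC sites).
    Includes degenerate IUPAC motif scanning with mismatches, annotation of
    ATP-DnaA boxes, CtrA binding sites and AT-rich unwinding elements,
    dif-site or GC-disparity terminus prediction, replichore partitioning
    with leading/lagging strand-bias statistics, a synthetic-genome
    simulator with planted origin architecture for benchmarking, and a
    command-line interface producing JSON/TSV/BED reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
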