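Package: circbalance
Title: Analysis of RNA-Binding-Protein Control of Exonic circRNA Biogenesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: A pipeline for studying how an RNA-binding protein that occupies
    intronic sites suppresses exonic circRNA biogenesis. Provides strand-aware
    gene models with exon/intron structure read from GTF, backsplice-junction
    (BSJ) count quantification with fold-change classification of wild-type
    versus knockout libraries, nascent-RNA circRNA fractions, CLIP-style
    binding-site filtering and genomic-feature annotation, flanking-intron
    enrichment statistics for circularized versus non-backsplicing exons,
    per-gene circRNA:mRNA ratio-shift classification, and a fully
    deterministic synthetic-study generator (genome, annotation, peaks and
    negative-binomial count tables with planted effects) so that every stage
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
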