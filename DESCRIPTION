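Package: ppigsea
Title: Interaction-Partner-Weighted Pathway Enrichment for GWAS Summary
    Statistics and Seed-Gene Molecular Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pathway-level association testing of genome-wide association
    summary statistics around a seed gene and its protein-protein
    interaction partners (I-Genes). SNP p-values are collapsed to genes by
    a first-order-statistic (FOSCO) gene-size correction, pathways are
    curated into seed-gene-containing and I-Gene-enriched collections,
    and enrichment is assessed with self-contained (SumStat) and
    competitive (GSEA enrichment score) statistics under a gene-label
    permutation null, with optional doubling of I-Gene weights and
    Benjamini-Hochberg adjustment. A companion molecular-evolution arm
    computes pairwise alignment identities, Nei-Gojobori (1986) dN/dS
    from codon alignments, and neighbor-joining trees. A synthetic-data
    module generates summary statistics, annotations, interaction tables
    and gene-set catalogues with known ground truth for calibration and
    power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse,
    withr,
    seqinr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'geneset-curation.R'
    'enrichment.R'
    'formats-io.R'
    'gene-scoring.R'
    'methods-accessors.R'
    'molecular-evolution.R'
    'synthetic-data.R'
    'pipeline.R'
    'ppigsea-package.R'
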