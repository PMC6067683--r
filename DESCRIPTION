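Package: placodelim
Title: Multilevel Comparative Genomics for Cryptic Species Delimitation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for delimiting cryptic animal species from pairs of
    annotated genomes and multilocus marker data, following a multilevel
    comparative-genomics workflow: Markov clustering of all-vs-all protein
    similarity into ortholog/co-ortholog duplication categories; codon-aware
    back-alignment with Nei-Gojobori-style dN/dS counting and codon
    saturation partitioning (dN1/dN2/dN3); microsynteny block detection with
    a bounded skip rule and per-gene collinear/inverted/translocated calls;
    haploweb construction from phased alleles and conspecificity-matrix
    scoring with UPGMA (JC69) ordering; screening of grouped alignments for
    diagnostic nucleotide positions; between-group p-distance profiles
    across nested taxonomic ranks; and small assembly/variant summaries
    (N50, SNP-density heterozygosity, exonic/intronic/intergenic SNP
    partitioning). A synthetic-data module generates genome pairs, codon
    alignments, phased-allele datasets and grouped alignments with planted
    ground truth so every analysis stage is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    vcfR,
    igraph,
    ape,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
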