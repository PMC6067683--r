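# Small assembly and variant summaries: N50, SNP-density heterozygosity,
# SNP partitioning into exonic/intronic/intergenic fractions, and variant
# set comparison.

#' N50 of a set of contig lengths
#'
#' The smallest length L such that contigs of length >= L sum to at least
#' half of the assembly.
#'
#' @param lengths Positive contig lengths (bp).
#' @return N50 in bp.
#' @export
n50 <- function(lengths) {
  if (!length(lengths)) stop("empty length list")
  if (any(lengths <= 0)) stop("contig lengths must be positive")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Assembly summary statistics
#'
#' @param lengths Positive contig lengths (bp).
#' @return A list with `n_contigs`, `total_bp`, `n50_bp`, `largest_bp`.
#' @export
assembly_stats <- function(lengths) {
  list(n_contigs = length(lengths), total_bp = sum(lengths),
       n50_bp = n50(lengths), largest_bp = max(lengths))
}

#' Heterozygosity as SNP density
#'
#' This is the SNP-count sense of heterozygosity (variants per kilobase and
#' as a percentage of the genome), not expected heterozygosity from
#' genotype frequencies.
#'
#' @param n_snps Number of SNPs.
#' @param genome_bp Genome size in bp (> 0).
#' @return A list with `snps_per_kb` and `percent`.
#' @export
heterozygosity <- function(n_snps, genome_bp) {
  stopifnot(genome_bp > 0)
  list(snps_per_kb = 1000 * n_snps / genome_bp,
       percent = 100 * n_snps / genome_bp)
}

#' Partition SNPs into exonic, intronic and intergenic fractions
#'
#' A SNP is exonic if it lies inside any exon interval, intronic if inside a
#' gene span but no exon, intergenic otherwise. Intervals are 1-based
#' inclusive, so SNPs exactly on exon boundaries are exonic. SNPs on
#' contigs absent from the annotation are counted intergenic with a
#' warning.
#'
#' @param variants Data frame with columns `contig`, `pos` (e.g. from
#'   [read_variants()]).
#' @param genes A `"genome_annotation"` (gene spans).
#' @param exons Data frame with columns `contig`, `start`, `end` (e.g. from
#'   [read_gff3_exons()]).
#' @return A list of class `"variant_partition"` with integer `counts`
#'   (named `exonic`, `intronic`, `intergenic`) and `labels`, the
#'   per-variant classification.
#' @export
partition_variants <- function(variants, genes, exons) {
  genes <- as.data.frame(genes)
  in_any <- function(contig, pos, ivs) {
    sel <- ivs$contig == contig & ivs$start <= pos & ivs$end >= pos
    any(sel)
  }
  known <- unique(genes$contig)
  labels <- character(nrow(variants))
  warned <- FALSE
  for (i in seq_len(nrow(variants))) {
    ct <- variants$contig[i]
    pos <- variants$pos[i]
    if (!ct %in% known) {
      if (!warned) {
        warning("SNP on contig absent from annotation (counted intergenic): ",
                ct)
        warned <- TRUE
      }
      labels[i] <- "intergenic"
    } else if (in_any(ct, pos, exons)) {
      labels[i] <- "exonic"
    } else if (in_any(ct, pos, genes)) {
      labels[i] <- "intronic"
    } else {
      labels[i] <- "intergenic"
    }
  }
  counts <- c(exonic = sum(labels == "exonic"),
              intronic = sum(labels == "intronic"),
              intergenic = sum(labels == "intergenic"))
  structure(list(counts = counts, labels = labels),
            class = "variant_partition")
}

#' Compare two variant sets
#'
#' Variants are keyed by `(contig, pos, alt)`; exact set operations.
#'
#' @param set_a,set_b Data frames with columns `contig`, `pos`, `alt`.
#' @return A list with `shared`, `unique_a`, `unique_b` counts and the
#'   corresponding key vectors.
#' @export
compare_variant_sets <- function(set_a, set_b) {
  key <- function(v) paste(v$contig, v$pos, v$alt, sep = ":")
  ka <- unique(key(set_a))
  kb <- unique(key(set_b))
  list(shared = length(intersect(ka, kb)),
       unique_a = length(setdiff(ka, kb)),
       unique_b = length(setdiff(kb, ka)),
       shared_keys = intersect(ka, kb),
       unique_a_keys = setdiff(ka, kb),
       unique_b_keys = setdiff(kb, ka))
}
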