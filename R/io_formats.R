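# Readers and writers for the standard formats consumed by the analysis
# modules: FASTA, GFF3 gene models, 12-column tabular similarity searches
# (BLAST outfmt 6) and a SNP subset of VCF.

#' Read a FASTA file into a validated sequence set
#'
#' Sequences are upper-cased, `.` gap characters are normalised to `-`, and
#' every record is checked against the declared alphabet. Record ids are the
#' first whitespace-delimited token of each header; the remainder is kept as
#' the description.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"nt"` (IUPAC nucleotide codes plus gap) or `"aa"`.
#' @return A named character vector of class `"seq_set"` with attributes
#'   `alphabet` and `descriptions`.
#' @export
read_fasta <- function(path, alphabet = c("nt", "aa")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot parse FASTA file '", path,
                                           "': ", conditionMessage(e)))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  full <- names(set)
  ids <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id: ", ids[duplicated(ids)][1])
  }
  seqs <- gsub(".", "-", toupper(as.character(set)), fixed = TRUE)
  names(seqs) <- ids
  .validate_alphabet(seqs, alphabet)
  structure(seqs, descriptions = stats::setNames(desc, ids),
            alphabet = alphabet, class = "seq_set")
}

.validate_alphabet <- function(seqs, alphabet) {
  allowed <- if (alphabet == "nt") .NT_ALPHABET else .AA_ALPHABET
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[[i]])) stop("empty sequence for record: ", names(seqs)[i])
    ch <- .chars(seqs[[i]])
    bad <- which(!ch %in% allowed)
    if (length(bad)) {
      stop(sprintf("illegal %s character '%s' in record '%s' at position %d",
                   alphabet, ch[bad[1]], names(seqs)[i], bad[1]))
    }
  }
  invisible(seqs)
}

#' Write a sequence set to FASTA
#'
#' Round-trips with [read_fasta()]: ids and sequences are preserved exactly.
#'
#' @param seqs Named character vector (or `"seq_set"`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  desc <- attr(seqs, "descriptions")
  headers <- names(seqs)
  if (!is.null(desc)) {
    has <- nzchar(desc[headers]) & !is.na(desc[headers])
    headers[has] <- paste(headers[has], desc[headers][has])
  }
  set <- Biostrings::BStringSet(as.character(seqs))
  names(set) <- headers
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a multiple sequence alignment from FASTA
#'
#' @inheritParams read_fasta
#' @return A `"seq_set"` that is also of class `"msa"`: at least two rows of
#'   equal length. Gap-only columns are permitted and flagged in the
#'   `gap_only_columns` attribute.
#' @export
read_alignment <- function(path, alphabet = c("nt", "aa")) {
  as_alignment(read_fasta(path, alphabet))
}

#' Validate a sequence set as an alignment
#'
#' @param seqs A named character vector of aligned rows (gap `-`).
#' @param alphabet Declared alphabet; taken from `seqs` when available.
#' @return The input with class `c("msa", "seq_set")`.
#' @export
as_alignment <- function(seqs, alphabet = attr(seqs, "alphabet")) {
  if (is.null(alphabet)) alphabet <- "nt"
  stopifnot(!is.null(names(seqs)))
  if (length(seqs) < 2L) stop("an alignment needs at least 2 rows")
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    stop("alignment rows have unequal lengths: ",
         paste(unique(widths), collapse = ", "))
  }
  mat <- do.call(rbind, strsplit(as.character(seqs), "", fixed = TRUE))
  gap_only <- which(apply(mat == "-", 2, all))
  structure(as.character(seqs) |> stats::setNames(names(seqs)),
            alphabet = alphabet, gap_only_columns = gap_only,
            class = c("msa", "seq_set"))
}

#' Read gene models from a GFF3 file
#'
#' One record is kept per gene. When several transcripts (mRNA features)
#' share a parent gene, only the longest span is retained, so downstream
#' gene-order analyses see a single model per locus. Either `gene` features
#' or `mRNA` features (grouped by `Parent`) are accepted.
#'
#' @param path Path to a GFF3 file.
#' @param species Species label attached to the annotation.
#' @param feature `"auto"` uses `gene` rows when present, else `mRNA`.
#' @return A `"genome_annotation"`: a data frame with columns `gene_id`,
#'   `contig`, `start`, `end`, `strand`, sorted per contig by
#'   `(start, gene_id)`, with attribute `species`.
#' @export
read_gff3_genes <- function(path, species,
                            feature = c("auto", "gene", "mRNA")) {
  feature <- match.arg(feature)
  if (!file.exists(path)) stop("file not found: ", path)
  gff <- as.data.frame(rtracklayer::readGFF(path))
  # map feature rows back to file line numbers for error reporting
  raw <- readLines(path, warn = FALSE)
  feat_lines <- which(!grepl("^#", raw) & nzchar(trimws(raw)))
  fasta_start <- grep("^##FASTA", raw)
  if (length(fasta_start)) feat_lines <- feat_lines[feat_lines < fasta_start[1]]
  gff$.line <- feat_lines[seq_len(nrow(gff))]

  use_gene <- switch(feature,
                     gene = TRUE,
                     mRNA = FALSE,
                     auto = any(gff$type == "gene"))
  rows <- gff[gff$type == (if (use_gene) "gene" else "mRNA"), , drop = FALSE]
  if (nrow(rows) == 0L) stop("no ", if (use_gene) "gene" else "mRNA",
                             " features found in ", path)
  if (is.null(rows$ID)) rows$ID <- rep(NA_character_, nrow(rows))
  missing_id <- is.na(rows$ID) | !nzchar(as.character(rows$ID))
  if (any(missing_id)) {
    stop("missing ID attribute at line ", rows$.line[which(missing_id)[1]])
  }
  bad_span <- rows$end < rows$start
  if (any(bad_span)) {
    stop("end < start at line ", rows$.line[which(bad_span)[1]])
  }
  if (!use_gene) {
    # group transcripts by parent gene where available
    parent <- vapply(seq_len(nrow(rows)), function(i) {
      p <- rows$Parent[[i]]
      if (length(p) && nzchar(p[1])) as.character(p[1]) else as.character(rows$ID[i])
    }, character(1))
    rows$gene_id <- parent
  } else {
    rows$gene_id <- as.character(rows$ID)
  }
  strand <- as.character(rows$strand)
  if (any(!strand %in% c("+", "-"))) {
    i <- which(!strand %in% c("+", "-"))[1]
    stop("feature without strand at line ", rows$.line[i],
         " (strand is required for rearrangement classification)")
  }
  ann <- data.frame(gene_id = rows$gene_id,
                    contig = as.character(rows$seqid),
                    start = as.integer(rows$start),
                    end = as.integer(rows$end),
                    strand = strand,
                    stringsAsFactors = FALSE)
  # longest span per gene
  ann <- ann[order(ann$gene_id, -(ann$end - ann$start)), , drop = FALSE]
  ann <- ann[!duplicated(ann$gene_id), , drop = FALSE]
  as_genome_annotation(ann, species)
}

#' Construct a genome annotation from a gene table
#'
#' @param genes Data frame with columns `gene_id`, `contig`, `start`, `end`,
#'   `strand` (1-based inclusive coordinates).
#' @param species Species label.
#' @return A `"genome_annotation"` sorted per contig by `(start, gene_id)`.
#' @export
as_genome_annotation <- function(genes, species) {
  req <- c("gene_id", "contig", "start", "end", "strand")
  stopifnot(all(req %in% names(genes)))
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id: ", genes$gene_id[duplicated(genes$gene_id)][1])
  }
  if (any(genes$start < 1L)) stop("gene start < 1")
  if (any(genes$end < genes$start)) stop("gene end < start")
  genes <- genes[order(genes$contig, genes$start, genes$gene_id), req,
                 drop = FALSE]
  rownames(genes) <- NULL
  structure(genes, species = species,
            class = c("genome_annotation", "data.frame"))
}

#' Read exon features from a GFF3 file
#'
#' Used by [partition_variants()] to separate exonic from intronic SNPs.
#'
#' @param path Path to a GFF3 file with `exon` features.
#' @return Data frame with columns `contig`, `start`, `end`, `parent`.
#' @export
read_gff3_exons <- function(path) {
  gff <- as.data.frame(rtracklayer::readGFF(path))
  ex <- gff[gff$type == "exon", , drop = FALSE]
  parent <- vapply(seq_len(nrow(ex)), function(i) {
    p <- ex$Parent[[i]]
    if (length(p)) as.character(p[1]) else NA_character_
  }, character(1))
  data.frame(contig = as.character(ex$seqid), start = as.integer(ex$start),
             end = as.integer(ex$end), parent = parent,
             stringsAsFactors = FALSE)
}

#' Read a 12-column tabular similarity table (BLAST outfmt 6)
#'
#' @param path Path to a tab-separated file with the standard columns
#'   `qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#'   evalue bitscore`.
#' @return Data frame with those columns plus a logical `self_hit` flag.
#' @export
read_similarity_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(raw) & !grepl("^#", raw)]
  if (!length(raw)) {
    return(.empty_similarity())
  }
  fields <- strsplit(raw, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    stop("malformed similarity row ", which(nf != 12L)[1],
         ": expected 12 columns, found ", nf[nf != 12L][1])
  }
  mat <- do.call(rbind, fields)
  num <- function(col, name) {
    x <- suppressWarnings(as.numeric(mat[, col]))
    if (anyNA(x)) stop("non-numeric ", name, " in similarity row ",
                       which(is.na(x))[1])
    x
  }
  out <- data.frame(
    qseqid = mat[, 1], sseqid = mat[, 2],
    pident = num(3, "pident"), length = as.integer(num(4, "length")),
    mismatch = as.integer(num(5, "mismatch")),
    gapopen = as.integer(num(6, "gapopen")),
    qstart = as.integer(num(7, "qstart")), qend = as.integer(num(8, "qend")),
    sstart = as.integer(num(9, "sstart")), send = as.integer(num(10, "send")),
    evalue = num(11, "evalue"), bitscore = num(12, "bitscore"),
    stringsAsFactors = FALSE)
  if (any(out$evalue < 0)) stop("negative evalue in similarity row ",
                                which(out$evalue < 0)[1])
  if (any(out$bitscore < 0)) stop("negative bitscore in similarity row ",
                                  which(out$bitscore < 0)[1])
  out$self_hit <- out$qseqid == out$sseqid
  out
}

.empty_similarity <- function() {
  data.frame(qseqid = character(), sseqid = character(), pident = numeric(),
             length = integer(), mismatch = integer(), gapopen = integer(),
             qstart = integer(), qend = integer(), sstart = integer(),
             send = integer(), evalue = numeric(), bitscore = numeric(),
             self_hit = logical(), stringsAsFactors = FALSE)
}

#' Write a similarity table in 12-column tabular format
#'
#' @param edges Data frame as returned by [read_similarity_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_similarity_table <- function(edges, path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  utils::write.table(edges[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read biallelic SNPs from a VCF file
#'
#' Only `CHROM`/`POS`/`REF`/`ALT`/`QUAL` are consumed. Indels, multi-allelic
#' rows and rows failing a populated `FILTER` column are dropped; the number
#' of dropped rows is reported via `message()` and stored in the `n_dropped`
#' attribute.
#'
#' @param path Path to a VCF (v4.x) file with a header.
#' @return Data frame with columns `contig`, `pos`, `ref`, `alt`, `qual`.
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  if (!any(grepl("^#CHROM\\t", raw))) {
    stop("missing VCF header (#CHROM line) in ", path)
  }
  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    out <- data.frame(contig = character(), pos = integer(),
                      ref = character(), alt = character(), qual = numeric(),
                      stringsAsFactors = FALSE)
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  pos <- suppressWarnings(as.numeric(fix$POS))
  if (anyNA(pos) || any(pos != round(pos))) {
    stop("non-integer POS in VCF row ", which(is.na(pos) | pos != round(pos))[1])
  }
  vars <- data.frame(contig = fix$CHROM, pos = as.integer(pos),
                     ref = fix$REF, alt = fix$ALT,
                     qual = suppressWarnings(as.numeric(fix$QUAL)),
                     filter = fix$FILTER,
                     stringsAsFactors = FALSE)
  out <- filter_snps(vars)
  n_dropped <- nrow(vars) - nrow(out)
  if (n_dropped > 0L) {
    message("read_variants: dropped ", n_dropped,
            " non-SNP, multi-allelic or filtered rows")
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Restrict a variant table to biallelic SNPs
#'
#' Idempotent: filtering an already filtered table changes nothing.
#'
#' @param vars Data frame with columns `contig`, `pos`, `ref`, `alt` and
#'   optionally `qual` and `filter`.
#' @return The SNP subset with columns `contig`, `pos`, `ref`, `alt`, `qual`.
#' @export
filter_snps <- function(vars) {
  if (is.null(vars$qual)) vars$qual <- NA_real_
  keep <- !is.na(vars$ref) & !is.na(vars$alt) &
    nchar(vars$ref) == 1L & nchar(vars$alt) == 1L &
    !grepl(",", vars$alt, fixed = TRUE) &
    vars$ref != vars$alt & vars$pos >= 1L
  if (!is.null(vars$filter)) {
    keep <- keep & (is.na(vars$filter) | vars$filter %in% c("PASS", "."))
  }
  out <- vars[keep, c("contig", "pos", "ref", "alt", "qual"), drop = FALSE]
  rownames(out) <- NULL
  out
}
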