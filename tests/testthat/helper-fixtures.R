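# Small plain-text fixture builders (written to tempfiles at test time).

write_tmp_fasta <- function(records, widths = NULL) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  lines <- character(0)
  for (id in names(records)) {
    lines <- c(lines, paste0(">", id))
    seq <- records[[id]]
    if (is.null(widths)) {
      lines <- c(lines, seq)
    } else {
      lines <- c(lines, substring(seq, seq(1, nchar(seq), widths),
                                  pmin(nchar(seq),
                                       seq(widths, nchar(seq) + widths - 1,
                                           widths))))
    }
  }
  writeLines(lines, path)
  path
}

gff_line <- function(contig, type, start, end, strand, attrs,
                     source = "test") {
  paste(contig, source, type, start, end, ".", strand, ".", attrs,
        sep = "\t")
}

write_tmp_gff3 <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gff3",
                                .local_envir = parent.frame())
  writeLines(c("##gff-version 3", lines), path)
  path
}

write_tmp_vcf <- function(rows, header = TRUE) {
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  head <- if (header) {
    c("##fileformat=VCFv4.2",
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  } else character(0)
  writeLines(c(head, rows), path)
  path
}

vcf_row <- function(contig, pos, ref, alt, qual = 50, filter = "PASS") {
  paste(contig, pos, ".", ref, alt, qual, filter, ".", sep = "\t")
}

write_tmp_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

blast_row <- function(q, s, pident = 95, len = 100, evalue = 1e-50,
                      bitscore = 200) {
  paste(q, s, pident, len, 2, 0, 1, len, 1, len,
        format(evalue, scientific = TRUE), bitscore, sep = "\t")
}
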