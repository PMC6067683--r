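# Internal helpers shared across modules.

.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# IUPAC nucleotide codes -> set of compatible bases
.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.NT_ALPHABET <- c(names(.IUPAC), "-")
.AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                  "N", "P", "Q", "R", "S", "T", "V", "W", "Y",
                  "B", "J", "O", "U", "X", "Z", "*", "-")

# base -> IUPAC code for an unordered pair of bases (heterozygote consensus)
.IUPAC_PAIR <- c(
  "AG" = "R", "CT" = "Y", "CG" = "S", "AT" = "W",
  "GT" = "K", "AC" = "M"
)

.stop_codons <- c("TAA", "TAG", "TGA")

# translate a single codon under the standard nuclear code; "*" for stops
.translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

# split a CDS string into codons (length must be a multiple of 3)
.codons <- function(seq) {
  n <- nchar(seq)
  stopifnot(n %% 3L == 0L)
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

# Derive an independent per-component seed from the user's global seed so
# adding a simulator never perturbs existing random streams. Kept well below
# .Machine$integer.max for 32-bit safety.
.derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 1021L + as.integer(offset)
}

# deterministic sample() under a derived seed, without touching the caller's
# RNG state
.with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random CDS of n_codons sense codons (no stops)
.random_cds <- function(n_codons) {
  sense <- setdiff(names(Biostrings::GENETIC_CODE), .stop_codons)
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

.translate_cds <- function(cds) {
  paste(vapply(.codons(cds), .translate_codon, character(1)), collapse = "")
}

# all k! orderings of 1..k (k <= 3 here)
.orderings <- function(k) {
  if (k == 1L) return(list(1L))
  if (k == 2L) return(list(c(1L, 2L), c(2L, 1L)))
  perms <- list()
  for (i in 1:3) for (j in setdiff(1:3, i)) {
    perms[[length(perms) + 1L]] <- c(i, j, setdiff(1:3, c(i, j)))
  }
  perms
}
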