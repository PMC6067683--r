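# Codon-aware divergence: back-alignment of CDS onto protein alignments,
# p-distances with pairwise deletion, and counting-based dN/dS in the
# Nei-Gojobori (1986) style with codon-class partitioning.
#
# Counting conventions (all exposed in the docs): potential synonymous sites
# per codon are the per-position fractions of synonymous single-base changes
# among changes that do not create a stop codon, averaged over the two rows;
# observed substitutions in multi-hit codons are averaged over all
# substitution orderings, excluding orderings that pass through stop codons
# (orderings are weighted equally when every one passes through a stop).
# No multiple-hit correction is applied: distances are raw p-distances.

#' Back-align two CDS onto a pairwise protein alignment
#'
#' Each protein residue is replaced by its codon and each protein gap by
#' `---`, producing a codon alignment whose gaps sit on codon boundaries. A
#' terminal stop codon on either CDS is stripped before re-gapping.
#'
#' @param protein_alignment Named character vector of exactly 2 aligned
#'   protein rows (gap `-`), in the same order as the two CDS.
#' @param cds_a,cds_b Ungapped CDS strings (or length-1 named vectors) that
#'   translate to the two protein rows under the standard code.
#' @return A `"codon_alignment"`: list with `rows` (2 aligned CDS strings)
#'   and `length`.
#' @section Errors: a CDS whose length or translation does not match its
#'   protein row raises an error of class `"regap_error"`, so pipelines can
#'   report and skip ambiguous pairs.
#' @export
backalign_cds <- function(protein_alignment, cds_a, cds_b) {
  prot <- as.character(protein_alignment)
  if (length(prot) != 2L) stop("protein_alignment must have exactly 2 rows")
  if (nchar(prot[1]) != nchar(prot[2])) {
    stop("protein alignment rows have unequal length")
  }
  rows <- c(.regap_one(prot[1], as.character(cds_a)[1], 1L),
            .regap_one(prot[2], as.character(cds_b)[1], 2L))
  names(rows) <- names(protein_alignment)
  structure(list(rows = rows, length = nchar(rows[1])),
            class = "codon_alignment")
}

.regap_error <- function(which_row, msg) {
  stop(structure(class = c("regap_error", "error", "condition"),
                 list(message = sprintf("ambiguous regap (row %d): %s",
                                        which_row, msg),
                      call = sys.call(-1))))
}

.regap_one <- function(prot_row, cds, which_row) {
  res <- .chars(prot_row)
  plain <- res[res != "-"]
  cds <- toupper(gsub("-", "", cds))
  n_res <- length(plain)
  if (nchar(cds) == 3L * (n_res + 1L) &&
      substring(cds, nchar(cds) - 2L) %in% .stop_codons) {
    cds <- substring(cds, 1L, nchar(cds) - 3L)  # strip terminal stop
  }
  if (nchar(cds) != 3L * n_res) {
    .regap_error(which_row, sprintf(
      "CDS length %d does not match 3 x %d ungapped residues",
      nchar(cds), n_res))
  }
  codons <- .codons(cds)
  aa <- vapply(codons, function(cd) {
    if (grepl("[^ACGT]", cd)) "X" else .translate_codon(cd)
  }, character(1))
  mismatch <- which(aa != plain & aa != "X" & plain != "X")
  if (length(mismatch)) {
    .regap_error(which_row, sprintf(
      "translation mismatch at residue %d (%s vs %s)",
      mismatch[1], aa[mismatch[1]], plain[mismatch[1]]))
  }
  out <- character(length(res))
  out[res == "-"] <- "---"
  out[res != "-"] <- codons
  paste(out, collapse = "")
}

#' Pairwise p-distance between two aligned rows
#'
#' Pairwise deletion: columns with a gap in either row are excluded; the
#' distance is `100 * mismatches / comparable columns`.
#'
#' @param row_a,row_b Aligned sequence strings of equal length.
#' @return Percent distance in `[0, 100]`; `NA` (with a warning) when no
#'   column is comparable.
#' @export
pairwise_p_distance <- function(row_a, row_b) {
  a <- .chars(toupper(as.character(row_a)[1]))
  b <- .chars(toupper(as.character(row_b)[1]))
  if (length(a) != length(b)) stop("rows have unequal length")
  comparable <- a != "-" & b != "-"
  n <- sum(comparable)
  if (n == 0L) {
    warning("no comparable columns; distance undefined")
    return(NA_real_)
  }
  100 * sum(a[comparable] != b[comparable]) / n
}

# ---- Nei-Gojobori style counting -------------------------------------------

# potential synonymous sites of one codon: per position, fraction of
# synonymous changes among the single-base changes that do not create a stop
.ng_syn_sites <- function(codon) {
  aa <- .translate_codon(codon)
  bases <- c("A", "C", "G", "T")
  s <- 0
  cc <- .chars(codon)
  for (pos in 1:3) {
    n_syn <- 0L
    n_ok <- 0L
    for (alt in setdiff(bases, cc[pos])) {
      mut <- cc
      mut[pos] <- alt
      mut_codon <- paste(mut, collapse = "")
      if (mut_codon %in% .stop_codons) next
      n_ok <- n_ok + 1L
      if (.translate_codon(mut_codon) == aa) n_syn <- n_syn + 1L
    }
    if (n_ok > 0L) s <- s + n_syn / n_ok
  }
  s
}

# observed synonymous/nonsynonymous substitutions between two codons,
# averaged over substitution orderings (stop-passing orderings excluded
# unless all pass through stops, in which case all are weighted equally)
.ng_observed <- function(c1, c2) {
  d <- which(.chars(c1) != .chars(c2))
  k <- length(d)
  if (k == 0L) return(c(sd = 0, nd = 0))
  paths <- .orderings(k)
  tallies <- matrix(NA_real_, nrow = length(paths), ncol = 2)
  through_stop <- logical(length(paths))
  for (p in seq_along(paths)) {
    cur <- .chars(c1)
    tgt <- .chars(c2)
    sd <- 0L; nd <- 0L
    for (step in paths[[p]]) {
      pos <- d[step]
      nxt <- cur
      nxt[pos] <- tgt[pos]
      from <- paste(cur, collapse = "")
      to <- paste(nxt, collapse = "")
      if (to %in% .stop_codons && to != c2) through_stop[p] <- TRUE
      aa_from <- if (from %in% .stop_codons) "*" else .translate_codon(from)
      aa_to <- if (to %in% .stop_codons) "*" else .translate_codon(to)
      if (identical(aa_from, aa_to)) sd <- sd + 1L else nd <- nd + 1L
      cur <- nxt
    }
    tallies[p, ] <- c(sd, nd)
  }
  use <- if (all(through_stop)) rep(TRUE, length(paths)) else !through_stop
  c(sd = mean(tallies[use, 1]), nd = mean(tallies[use, 2]))
}

# per-codon-pair statistics, memoised (there are at most 61 x 61 pairs)
.ng_pair_env <- new.env(parent = emptyenv())

.ng_pair <- function(c1, c2) {
  key <- paste0(c1, c2)
  hit <- .ng_pair_env[[key]]
  if (!is.null(hit)) return(hit)
  s_sites <- (.ng_syn_sites(c1) + .ng_syn_sites(c2)) / 2
  obs <- .ng_observed(c1, c2)
  ndiff <- sum(.chars(c1) != .chars(c2))
  aa_same <- identical(.translate_codon(c1), .translate_codon(c2))
  res <- list(S = s_sites, N = 3 - s_sites, Sd = obs[["sd"]], Nd = obs[["nd"]],
              ndiff = ndiff, aa_same = aa_same)
  assign(key, res, envir = .ng_pair_env)
  res
}

#' Codon-level substitution statistics for a pairwise codon alignment
#'
#' Codons containing gaps or ambiguity codes in either row are excluded from
#' all counts. Remaining codon pairs are partitioned into unchanged,
#' synonymous (same amino acid, at least one base change) and dN1/dN2/dN3
#' classes (amino acid changed; 1, 2 or 3 differing bases) -- the
#' codon-saturation diagnostic. Potential sites (`S`, `N`) and observed
#' substitutions (`Sd`, `Nd`) follow unweighted Nei-Gojobori counting; see
#' the package vignette for the exact conventions.
#'
#' @param codon_alignment A `"codon_alignment"` from [backalign_cds()], or a
#'   list/vector of two aligned CDS strings whose length is a multiple of 3.
#' @return A list of class `"codon_pair_stats"` with elements
#'   `n_codons_compared`, `unchanged`, `synonymous`, `dn1`, `dn2`, `dn3`,
#'   `S`, `N`, `Sd`, `Nd`, `pS`, `pN` and `omega` (`NA` when `Sd = 0`).
#' @export
codon_pair_stats <- function(codon_alignment) {
  rows <- if (inherits(codon_alignment, "codon_alignment")) {
    codon_alignment$rows
  } else {
    as.character(codon_alignment)
  }
  stopifnot(length(rows) == 2L)
  if (nchar(rows[1]) != nchar(rows[2])) stop("rows have unequal length")
  if (nchar(rows[1]) %% 3L != 0L) stop("alignment length is not a multiple of 3")
  cod1 <- .codons(toupper(rows[1]))
  cod2 <- .codons(toupper(rows[2]))
  counts <- c(unchanged = 0L, synonymous = 0L, dn1 = 0L, dn2 = 0L, dn3 = 0L)
  S <- N <- Sd <- Nd <- 0
  n_used <- 0L
  for (i in seq_along(cod1)) {
    c1 <- cod1[i]; c2 <- cod2[i]
    if (grepl("[^ACGT]", c1) || grepl("[^ACGT]", c2)) next  # gap/ambiguity
    if (c1 %in% .stop_codons || c2 %in% .stop_codons) {
      stop("internal stop codon at codon index ", i)
    }
    p <- .ng_pair(c1, c2)
    n_used <- n_used + 1L
    S <- S + p$S; N <- N + p$N; Sd <- Sd + p$Sd; Nd <- Nd + p$Nd
    cls <- if (p$ndiff == 0L) "unchanged"
    else if (p$aa_same) "synonymous"
    else c("dn1", "dn2", "dn3")[p$ndiff]
    counts[cls] <- counts[cls] + 1L
  }
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  omega <- if (!is.na(pS) && Sd > 0) pN / pS else NA_real_
  structure(list(n_codons_compared = n_used,
                 unchanged = counts[["unchanged"]],
                 synonymous = counts[["synonymous"]],
                 dn1 = counts[["dn1"]], dn2 = counts[["dn2"]],
                 dn3 = counts[["dn3"]],
                 S = S, N = N, Sd = Sd, Nd = Nd,
                 pS = pS, pN = pN, omega = omega),
            class = "codon_pair_stats")
}

#' @export
print.codon_pair_stats <- function(x, ...) {
  cat(sprintf(
    "codon pair stats: %d codons (%d unchanged, %d syn, %d/%d/%d dN1/2/3)\n",
    x$n_codons_compared, x$unchanged, x$synonymous, x$dn1, x$dn2, x$dn3))
  cat(sprintf("  S=%.3f N=%.3f Sd=%.3f Nd=%.3f pS=%.4f pN=%.4f omega=%s\n",
              x$S, x$N, x$Sd, x$Nd, x$pS, x$pN,
              ifelse(is.na(x$omega), "undefined", sprintf("%.4f", x$omega))))
  invisible(x)
}

#' Summarise selection over a set of ortholog pairs
#'
#' Thresholds follow the usual reading of dN/dS: `omega < 0.5` strong
#' purifying selection, `omega > 1` positive selection. Pairs with undefined
#' omega (`Sd = 0`) are counted separately and excluded from the threshold
#' bins.
#'
#' @param stats List of `"codon_pair_stats"`, optionally named by ortholog.
#' @param distances Optional data frame with columns `ortholog_id`,
#'   `protein_distance`, `cds_distance` (percent), used to compute the
#'   fraction of orthologs whose protein distance exceeds the CDS distance.
#' @return A list of class `"selection_summary"`: counts `n_total`,
#'   `n_purifying`, `n_positive`, `n_omega_undefined`,
#'   `frac_protein_gt_cds` (or `NA`), and `table`, a per-ortholog data frame
#'   sorted by increasing omega (undefined last).
#' @export
summarize_selection <- function(stats, distances = NULL) {
  if (!length(stats)) stop("empty ortholog set")
  ids <- names(stats)
  if (is.null(ids)) ids <- as.character(seq_along(stats))
  tab <- data.frame(
    ortholog_id = ids,
    omega = vapply(stats, function(s) s$omega, numeric(1)),
    pN = vapply(stats, function(s) s$pN, numeric(1)),
    pS = vapply(stats, function(s) s$pS, numeric(1)),
    Sd = vapply(stats, function(s) s$Sd, numeric(1)),
    Nd = vapply(stats, function(s) s$Nd, numeric(1)),
    stringsAsFactors = FALSE)
  if (!is.null(distances)) {
    tab <- merge(tab, distances, by = "ortholog_id", all.x = TRUE,
                 sort = FALSE)
  }
  tab <- tab[order(tab$omega, na.last = TRUE), , drop = FALSE]
  rownames(tab) <- NULL
  defined <- !is.na(tab$omega)
  frac_gt <- NA_real_
  if (!is.null(distances)) {
    ok <- !is.na(tab$protein_distance) & !is.na(tab$cds_distance)
    if (any(ok)) {
      frac_gt <- mean(tab$protein_distance[ok] > tab$cds_distance[ok])
    }
  }
  structure(list(n_total = nrow(tab),
                 n_purifying = sum(defined & tab$omega < 0.5),
                 n_positive = sum(defined & tab$omega > 1),
                 n_omega_undefined = sum(!defined),
                 frac_protein_gt_cds = frac_gt,
                 table = tab),
            class = "selection_summary")
}

#' @export
print.selection_summary <- function(x, ...) {
  cat(sprintf(
    "selection summary: %d orthologs; %d purifying (omega < 0.5), %d positive (omega > 1), %d undefined\n",
    x$n_total, x$n_purifying, x$n_positive, x$n_omega_undefined))
  if (!is.na(x$frac_protein_gt_cds)) {
    cat(sprintf("  fraction with protein distance > CDS distance: %.3f\n",
                x$frac_protein_gt_cds))
  }
  invisible(x)
}

#' Join allelic (within-species) and interspecific distances per ortholog
#'
#' @param allelic,interspecific Data frames with columns `ortholog_id`,
#'   `protein_distance`, `cds_distance` (percent).
#' @return Data frame joined on shared ortholog ids with columns
#'   `allelic_protein`, `allelic_cds`, `inter_protein`, `inter_cds` and
#'   `diff_protein` (`inter - allelic`), sorted by increasing `diff_protein`.
#' @export
compare_intra_inter <- function(allelic, interspecific) {
  shared <- intersect(allelic$ortholog_id, interspecific$ortholog_id)
  if (!length(shared)) stop("no shared ortholog ids between the two sets")
  a <- allelic[match(shared, allelic$ortholog_id), , drop = FALSE]
  b <- interspecific[match(shared, interspecific$ortholog_id), , drop = FALSE]
  out <- data.frame(ortholog_id = shared,
                    allelic_protein = a$protein_distance,
                    allelic_cds = a$cds_distance,
                    inter_protein = b$protein_distance,
                    inter_cds = b$cds_distance,
                    stringsAsFactors = FALSE)
  out$diff_protein <- out$inter_protein - out$allelic_protein
  out <- out[order(out$diff_protein), , drop = FALSE]
  rownames(out) <- NULL
  out
}
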