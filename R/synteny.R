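# Microsynteny: reciprocal-best-hit ortholog mapping, syntenic block
# chaining with a bounded skip rule, per-gene rearrangement labels, and
# size-weighted collinearity summaries.

#' Strict reciprocal best hits between two gene sets
#'
#' A pair `(a, b)` is kept iff `b` is `a`'s best hit and `a` is `b`'s best
#' hit. Best hits are ranked by descending bitscore, ties broken by lower
#' evalue, then lexicographically by subject id, so the map is
#' deterministic.
#'
#' @param edges_ab,edges_ba Directed similarity tables (A queries vs B
#'   subjects and vice versa), as from [read_similarity_table()].
#' @return Data frame with columns `gene_a`, `gene_b`; possibly empty.
#' @export
reciprocal_best_hits <- function(edges_ab, edges_ba) {
  best <- function(e) {
    e <- e[e$qseqid != e$sseqid, , drop = FALSE]
    if (!nrow(e)) return(stats::setNames(character(0), character(0)))
    e <- e[order(e$qseqid, -e$bitscore, e$evalue, e$sseqid), , drop = FALSE]
    e <- e[!duplicated(e$qseqid), , drop = FALSE]
    stats::setNames(e$sseqid, e$qseqid)
  }
  ab <- best(edges_ab)
  ba <- best(edges_ba)
  keep <- names(ab)[!is.na(ba[ab]) & ba[ab] == names(ab)]
  out <- data.frame(gene_a = keep, gene_b = unname(ab[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# per-contig gene ranks for an annotation (order by start, ties by gene_id)
.gene_positions <- function(annotation) {
  ann <- as.data.frame(annotation)
  ann <- ann[order(ann$contig, ann$start, ann$gene_id), , drop = FALSE]
  pos <- stats::ave(seq_len(nrow(ann)), ann$contig, FUN = seq_along)
  data.frame(gene_id = ann$gene_id, contig = ann$contig, position = pos,
             start = ann$start, end = ann$end, strand = ann$strand,
             stringsAsFactors = FALSE)
}

# longest valid chain among anchors (ia strictly increasing; ib strictly
# monotonic with the given sign; gaps on both genomes <= max_skip). Returns
# the lexicographically smallest (by A-position sequence) chain of maximal
# length, as anchor row indices, or NULL.
.best_chain <- function(ia, ib, direction, max_skip) {
  n <- length(ia)
  if (n == 0L) return(NULL)
  ord <- order(ia)
  ia <- ia[ord]; ib <- ib[ord]
  ok_step <- function(i, j) {
    (ia[j] - ia[i] - 1L) <= max_skip &&
      sign(ib[j] - ib[i]) == direction &&
      (abs(ib[j] - ib[i]) - 1L) <= max_skip
  }
  # L[i]: longest chain starting at anchor i
  L <- rep(1L, n)
  for (i in rev(seq_len(n))) {
    for (j in seq_len(n)) {
      if (j > i && ok_step(i, j) && L[j] + 1L > L[i]) L[i] <- L[j] + 1L
    }
  }
  maxlen <- max(L)
  # greedy reconstruction of the lexicographically smallest maximal chain
  chain <- integer(0)
  cur <- which(L == maxlen)[1]
  chain <- cur
  remaining <- maxlen - 1L
  while (remaining > 0L) {
    nxt <- NA_integer_
    for (j in seq_len(n)) {
      if (j > cur && ok_step(cur, j) && L[j] >= remaining) {
        nxt <- j
        break
      }
    }
    chain <- c(chain, nxt)
    cur <- nxt
    remaining <- remaining - 1L
  }
  ord[chain]
}

#' Detect syntenic blocks between two gene orders
#'
#' Blocks are maximal chains of one-to-one ortholog pairs that are strictly
#' increasing (orientation `same`) or decreasing (`inverted`) in the second
#' genome's gene order, allowing at most `max_skip` intervening genes on
#' either genome between consecutive pairs. Chains shorter than
#' `min_block_size` are discarded. Each ortholog pair belongs to at most one
#' block: blocks are extracted greedily, longest chain first, ties broken by
#' leftmost start on genome A (then `same` before `inverted`).
#'
#' @param annotation_a,annotation_b `"genome_annotation"` objects.
#' @param ortholog_map Data frame with columns `gene_a`, `gene_b`
#'   (one-to-one), e.g. from [reciprocal_best_hits()].
#' @param max_skip Maximum intervening genes allowed between consecutive
#'   pairs on each genome (default 1).
#' @param min_block_size Minimum ortholog pairs per block (default 3).
#' @return A list of class `"synteny_blocks"`: `blocks` (data frame
#'   `block_id`, `contig_a`, `contig_b`, `orientation`, `n_genes`, `skips`)
#'   and `pairs` (data frame `block_id`, `gene_a`, `gene_b`, `pos_a`,
#'   `pos_b`), plus the position tables used.
#' @export
detect_syntenic_blocks <- function(annotation_a, annotation_b, ortholog_map,
                                   max_skip = 1, min_block_size = 3) {
  if (anyDuplicated(ortholog_map$gene_a) || anyDuplicated(ortholog_map$gene_b)) {
    stop("ortholog_map is not one-to-one")
  }
  pos_a <- .gene_positions(annotation_a)
  pos_b <- .gene_positions(annotation_b)
  if (anyDuplicated(pos_a[c("contig", "position")]) ||
      anyDuplicated(pos_b[c("contig", "position")])) {
    stop("duplicate gene positions")
  }
  m <- ortholog_map
  ia <- match(m$gene_a, pos_a$gene_id)
  ib <- match(m$gene_b, pos_b$gene_id)
  keep <- !is.na(ia) & !is.na(ib)
  anchors <- data.frame(gene_a = m$gene_a[keep], gene_b = m$gene_b[keep],
                        contig_a = pos_a$contig[ia[keep]],
                        contig_b = pos_b$contig[ib[keep]],
                        pos_a = pos_a$position[ia[keep]],
                        pos_b = pos_b$position[ib[keep]],
                        stringsAsFactors = FALSE)
  blocks <- list()
  pairs <- list()
  active <- rep(TRUE, nrow(anchors))
  block_id <- 0L
  repeat {
    # best candidate chain over all contig pairs and orientations
    best <- NULL
    av <- anchors[active, , drop = FALSE]
    if (!nrow(av)) break
    for (cp in unique(paste(av$contig_a, av$contig_b, sep = "\r"))) {
      sel <- which(active &
                     paste(anchors$contig_a, anchors$contig_b, sep = "\r") == cp)
      for (direction in c(1L, -1L)) {
        ch <- .best_chain(anchors$pos_a[sel], anchors$pos_b[sel],
                          direction, max_skip)
        if (is.null(ch) || length(ch) < min_block_size) next
        cand <- list(rows = sel[ch], direction = direction,
                     len = length(ch), start_a = anchors$pos_a[sel[ch][1]],
                     contig_a = anchors$contig_a[sel[1]])
        if (is.null(best) ||
            cand$len > best$len ||
            (cand$len == best$len &&
             .chain_before(cand, best))) {
          best <- cand
        }
      }
    }
    if (is.null(best)) break
    block_id <- block_id + 1L
    rows <- best$rows
    pa <- anchors$pos_a[rows]
    pb <- anchors$pos_b[rows]
    skips <- sum(abs(diff(pa)) - 1L) + sum(abs(diff(pb)) - 1L)
    blocks[[block_id]] <- data.frame(
      block_id = block_id,
      contig_a = anchors$contig_a[rows[1]],
      contig_b = anchors$contig_b[rows[1]],
      orientation = if (best$direction == 1L) "same" else "inverted",
      n_genes = length(rows), skips = skips, stringsAsFactors = FALSE)
    pairs[[block_id]] <- data.frame(
      block_id = block_id, gene_a = anchors$gene_a[rows],
      gene_b = anchors$gene_b[rows], pos_a = pa, pos_b = pb,
      contig_a = anchors$contig_a[rows], contig_b = anchors$contig_b[rows],
      stringsAsFactors = FALSE)
    active[rows] <- FALSE
  }
  structure(list(
    blocks = if (length(blocks)) do.call(rbind, blocks) else
      data.frame(block_id = integer(), contig_a = character(),
                 contig_b = character(), orientation = character(),
                 n_genes = integer(), skips = integer()),
    pairs = if (length(pairs)) do.call(rbind, pairs) else
      data.frame(block_id = integer(), gene_a = character(),
                 gene_b = character(), pos_a = integer(), pos_b = integer(),
                 contig_a = character(), contig_b = character()),
    positions_a = pos_a, positions_b = pos_b,
    max_skip = max_skip, min_block_size = min_block_size),
    class = "synteny_blocks")
}

# tie order between equal-length candidate chains: leftmost start on A,
# then contig name, then orientation same (1) before inverted (-1)
.chain_before <- function(cand, best) {
  if (cand$contig_a != best$contig_a) return(cand$contig_a < best$contig_a)
  if (cand$start_a != best$start_a) return(cand$start_a < best$start_a)
  cand$direction > best$direction
}

#' Classify mapped genes as collinear, inverted, translocated or unplaced
#'
#' For each genome-A contig, the genome-B contig carrying most of its
#' block-assigned genes is its dominant partner, and within that contig
#' pairing the orientation covering most genes is dominant. Genes in
#' dominant-orientation blocks on the dominant partner are collinear; genes
#' in opposite-orientation blocks there are inverted; mapped genes outside
#' any block, or in blocks on a non-dominant partner contig, are
#' translocated; unmapped genes are unplaced.
#'
#' @param blocks A `"synteny_blocks"` object.
#' @param annotation_a Genome-A annotation (defines the gene universe).
#' @param ortholog_map The one-to-one map used for block detection.
#' @return A named character vector over all genome-A genes with values in
#'   `collinear`, `inverted`, `translocated`, `unplaced`.
#' @export
classify_gene_rearrangements <- function(blocks, annotation_a, ortholog_map) {
  genes <- as.data.frame(annotation_a)$gene_id
  labels <- stats::setNames(rep("unplaced", length(genes)), genes)
  mapped <- ortholog_map$gene_a[ortholog_map$gene_a %in% genes]
  labels[mapped] <- "translocated"
  p <- blocks$pairs
  if (nrow(p)) {
    # dominant partner contig per contig_a
    tab <- stats::aggregate(n <- rep(1L, nrow(p)),
                            by = list(contig_a = p$contig_a,
                                      contig_b = p$contig_b), FUN = sum)
    names(tab)[3] <- "n"
    tab <- tab[order(tab$contig_a, -tab$n, tab$contig_b), , drop = FALSE]
    dominant_partner <- stats::setNames(tab$contig_b[!duplicated(tab$contig_a)],
                                        tab$contig_a[!duplicated(tab$contig_a)])
    # dominant orientation per (contig_a, contig_b) pairing
    bo <- merge(p, blocks$blocks[c("block_id", "orientation")], by = "block_id")
    otab <- stats::aggregate(rep(1L, nrow(bo)),
                             by = list(contig_a = bo$contig_a,
                                       contig_b = bo$contig_b,
                                       orientation = bo$orientation),
                             FUN = sum)
    names(otab)[4] <- "n"
    otab <- otab[order(otab$contig_a, otab$contig_b, -otab$n,
                       otab$orientation), , drop = FALSE]
    key <- paste(otab$contig_a, otab$contig_b, sep = "\r")
    dominant_orient <- stats::setNames(otab$orientation[!duplicated(key)],
                                       key[!duplicated(key)])
    for (i in seq_len(nrow(bo))) {
      ga <- bo$gene_a[i]
      if (bo$contig_b[i] != dominant_partner[[bo$contig_a[i]]]) next
      k <- paste(bo$contig_a[i], bo$contig_b[i], sep = "\r")
      labels[ga] <- if (bo$orientation[i] == dominant_orient[[k]])
        "collinear" else "inverted"
    }
  }
  labels
}

#' Per-contig and size-weighted collinearity summary
#'
#' Per genome-A contig, the collinear fraction is `collinear / mapped` genes
#' on that contig (percent). The weighted mean uses each contig's evaluated
#' span -- the base-pair extent from the first to the last mapped gene -- as
#' its size weight. Contigs with no mapped genes are excluded with a
#' message.
#'
#' @param calls Labels from [classify_gene_rearrangements()].
#' @param blocks The `"synteny_blocks"` object.
#' @param annotation_a Genome-A annotation.
#' @param ortholog_map The one-to-one ortholog map.
#' @return A list of class `"collinearity_report"`: `per_contig` (data
#'   frame `contig`, `n_mapped`, `n_collinear`, `fraction`, `weight`),
#'   `weighted_mean`, `block_size_mean`, `block_size_sd`, `n_blocks`.
#' @export
collinearity_summary <- function(calls, blocks, annotation_a, ortholog_map) {
  ann <- as.data.frame(annotation_a)
  mapped <- ann$gene_id %in% ortholog_map$gene_a
  contigs <- unique(ann$contig)
  rows <- lapply(contigs, function(ct) {
    sel <- ann$contig == ct & mapped
    n_mapped <- sum(sel)
    if (n_mapped == 0L) return(NULL)
    span <- max(ann$end[sel]) - min(ann$start[sel]) + 1
    n_col <- sum(calls[ann$gene_id[sel]] == "collinear")
    data.frame(contig = ct, n_mapped = n_mapped, n_collinear = n_col,
               fraction = 100 * n_col / n_mapped, span = span,
               stringsAsFactors = FALSE)
  })
  dropped <- contigs[vapply(rows, is.null, logical(1))]
  if (length(dropped)) {
    message("collinearity_summary: excluded contigs with no mapped genes: ",
            paste(dropped, collapse = ", "))
  }
  per <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(per) || nrow(per) == 0L) stop("no contig has mapped genes")
  per$weight <- per$span / sum(per$span)
  sizes <- blocks$blocks$n_genes
  structure(list(per_contig = per,
                 weighted_mean = sum(per$fraction * per$weight),
                 block_size_mean = if (length(sizes)) mean(sizes) else NA_real_,
                 block_size_sd = if (length(sizes) > 1) stats::sd(sizes) else NA_real_,
                 n_blocks = length(sizes)),
            class = "collinearity_report")
}

#' @export
print.collinearity_report <- function(x, ...) {
  cat(sprintf(
    "collinearity: weighted mean %.1f%% over %d contigs; %d blocks (size %.1f +/- %.1f genes)\n",
    x$weighted_mean, nrow(x$per_contig), x$n_blocks,
    x$block_size_mean, ifelse(is.na(x$block_size_sd), 0, x$block_size_sd)))
  invisible(x)
}
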