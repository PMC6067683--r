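# Independent oracles used by the test suite. These re-derive expected
# values by brute force (full enumeration, direct scans) and are kept
# independent of the package's implementation paths.

# ---- Nei-Gojobori-style codon counting, by full pathway enumeration --------

oracle_codon_pair <- function(c1, c2) {
  GC <- Biostrings::GENETIC_CODE
  stop_set <- names(GC)[GC == "*"]
  aa_of <- function(cod) if (cod %in% stop_set) "*" else GC[[cod]]
  syn_sites <- function(cod) {
    cc <- strsplit(cod, "")[[1]]
    s <- 0
    for (pos in 1:3) {
      syn <- 0L; ok <- 0L
      for (b in setdiff(c("A", "C", "G", "T"), cc[pos])) {
        m <- cc
        m[pos] <- b
        mc <- paste(m, collapse = "")
        if (mc %in% stop_set) next
        ok <- ok + 1L
        if (GC[[mc]] == GC[[cod]]) syn <- syn + 1L
      }
      if (ok > 0L) s <- s + syn / ok
    }
    s
  }
  leaves <- list()
  walk <- function(cur, sd, nd, hit_stop) {
    d <- which(strsplit(cur, "")[[1]] != strsplit(c2, "")[[1]])
    if (!length(d)) {
      leaves[[length(leaves) + 1L]] <<- c(sd = sd, nd = nd,
                                          stop = as.numeric(hit_stop))
      return(invisible(NULL))
    }
    for (pos in d) {
      m <- strsplit(cur, "")[[1]]
      m[pos] <- strsplit(c2, "")[[1]][pos]
      nxt <- paste(m, collapse = "")
      step_syn <- aa_of(cur) == aa_of(nxt)
      walk(nxt, sd + as.numeric(step_syn), nd + as.numeric(!step_syn),
           hit_stop || (nxt %in% stop_set && nxt != c2))
    }
  }
  walk(c1, 0, 0, FALSE)
  L <- do.call(rbind, leaves)
  use <- if (all(L[, "stop"] == 1)) rep(TRUE, nrow(L)) else L[, "stop"] == 0
  S <- (syn_sites(c1) + syn_sites(c2)) / 2
  list(S = S, N = 3 - S, Sd = mean(L[use, "sd"]), Nd = mean(L[use, "nd"]))
}

random_sense_codon <- function(n = 1) {
  sense <- setdiff(names(Biostrings::GENETIC_CODE),
                   names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == "*"])
  sample(sense, n, replace = TRUE)
}

# ---- syntenic block detection, by exhaustive chain enumeration --------------

# all valid chains (as index vectors into the anchor table) for one
# orientation, given A/B positions of anchors on a single contig pair
oracle_all_chains <- function(pos_a, pos_b, direction, max_skip) {
  ord <- order(pos_a)
  ia <- pos_a[ord]
  ib <- pos_b[ord]
  res <- list()
  grow <- function(chain) {
    res[[length(res) + 1L]] <<- ord[chain]
    last <- chain[length(chain)]
    for (j in seq_along(ia)) {
      if (j <= last) next
      if ((ia[j] - ia[last] - 1L) <= max_skip &&
          sign(ib[j] - ib[last]) == direction &&
          (abs(ib[j] - ib[last]) - 1L) <= max_skip) {
        grow(c(chain, j))
      }
    }
  }
  for (s in seq_along(ia)) grow(s)
  res
}

lex_less <- function(a, b) {
  k <- min(length(a), length(b))
  for (i in seq_len(k)) if (a[i] != b[i]) return(a[i] < b[i])
  length(a) < length(b)
}

# greedy extraction over exhaustively enumerated chains, mirroring the
# documented selection rule: longest first, ties by leftmost A position,
# then orientation "same", then lexicographically smallest A positions
oracle_blocks <- function(pos_a, pos_b, max_skip, min_block_size) {
  active <- seq_along(pos_a)
  blocks <- list()
  repeat {
    cands <- list()
    for (direction in c(1L, -1L)) {
      chains <- oracle_all_chains(pos_a[active], pos_b[active], direction,
                                  max_skip)
      for (ch in chains) {
        idx <- active[ch]
        if (length(idx) >= min_block_size) {
          cands[[length(cands) + 1L]] <- list(rows = idx, dir = direction)
        }
      }
    }
    if (!length(cands)) break
    lens <- vapply(cands, function(cd) length(cd$rows), integer(1))
    cands <- cands[lens == max(lens)]
    starts <- vapply(cands, function(cd) pos_a[cd$rows[1]], numeric(1))
    cands <- cands[starts == min(starts)]
    dirs <- vapply(cands, function(cd) cd$dir, integer(1))
    if (any(dirs == 1L)) cands <- cands[dirs == 1L]
    pick <- cands[[1]]
    for (cd in cands[-1]) {
      if (lex_less(pos_a[cd$rows], pos_a[pick$rows])) pick <- cd
    }
    blocks[[length(blocks) + 1L]] <- list(
      rows = pick$rows,
      orientation = if (pick$dir == 1L) "same" else "inverted")
    active <- setdiff(active, pick$rows)
  }
  blocks
}

# random single-contig synteny instance with n genes and a partial
# one-to-one map; returns annotations plus the map
random_synteny_instance <- function(n) {
  genes <- sprintf("g%02d", seq_len(n))
  n_mapped <- sample(2:n, 1)
  mapped <- sort(sample(genes, n_mapped))
  ann_a <- as_genome_annotation(data.frame(
    gene_id = paste0(genes, "_A"), contig = "cA",
    start = seq_len(n) * 100L, end = seq_len(n) * 100L + 50L,
    strand = "+"), "A")
  perm <- sample(seq_len(n))
  ann_b <- as_genome_annotation(data.frame(
    gene_id = paste0(genes[perm], "_B"), contig = "cB",
    start = seq_len(n) * 100L, end = seq_len(n) * 100L + 50L,
    strand = "+"), "B")
  list(ann_a = ann_a, ann_b = ann_b,
       map = data.frame(gene_a = paste0(mapped, "_A"),
                        gene_b = paste0(mapped, "_B"),
                        stringsAsFactors = FALSE))
}

# per-contig gene ranks, recomputed directly for oracle use
.gene_positions_for_test <- function(ann) {
  df <- as.data.frame(ann)
  df <- df[order(df$contig, df$start, df$gene_id), ]
  stats::setNames(stats::ave(seq_len(nrow(df)), df$contig, FUN = seq_along),
                  df$gene_id)
}

# ---- misc direct oracles ----------------------------------------------------

# largest candidate length whose >=L tail covers half the assembly (the
# descending scan's first hit), checked against every candidate length
oracle_n50 <- function(lengths) {
  total <- sum(lengths)
  for (L in sort(unique(lengths), decreasing = TRUE)) {
    if (sum(lengths[lengths >= L]) >= total / 2) return(L)
  }
  NA
}

oracle_partition <- function(variants, genes, exons) {
  out <- character(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    ct <- variants$contig[i]; p <- variants$pos[i]
    inside <- function(df) any(df$contig == ct & df$start <= p & df$end >= p)
    out[i] <- if (inside(exons)) "exonic"
    else if (inside(genes)) "intronic"
    else "intergenic"
  }
  out
}
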