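# Haplowebs: allele-sharing graphs per marker, fields for recombination
# (FFRs), the isolate-by-isolate conspecificity matrix, and UPGMA (JC69)
# ordering of isolates.

#' Read a phased-allele table from marker FASTA files
#'
#' Sequence ids follow the `isolate|marker|allele` convention (allele tag
#' arbitrary, e.g. `a1`/`a2`).
#'
#' @param paths Character vector of multi-FASTA files (one or more markers).
#' @return An `"allele_table"`: data frame with columns `isolate`, `marker`,
#'   `seq`, at most two rows per (isolate, marker).
#' @export
read_allele_table <- function(paths) {
  rows <- lapply(paths, function(p) {
    seqs <- read_fasta(p, "nt")
    parts <- strsplit(names(seqs), "|", fixed = TRUE)
    bad <- lengths(parts) < 2L
    if (any(bad)) stop("allele id not in isolate|marker|allele form: ",
                       names(seqs)[bad][1])
    data.frame(isolate = vapply(parts, `[`, "", 1),
               marker = vapply(parts, `[`, "", 2),
               seq = as.character(seqs), stringsAsFactors = FALSE)
  })
  as_allele_table(do.call(rbind, rows))
}

#' Validate an allele table
#'
#' @param tab Data frame with columns `isolate`, `marker`, `seq`. A
#'   homozygote may be stored once or twice.
#' @return The table with class `"allele_table"`.
#' @export
as_allele_table <- function(tab) {
  stopifnot(all(c("isolate", "marker", "seq") %in% names(tab)))
  cell <- paste(tab$isolate, tab$marker, sep = "\r")
  n_alleles <- table(cell)
  if (any(n_alleles > 2L)) {
    bad <- names(n_alleles)[n_alleles > 2L][1]
    stop("more than 2 alleles for isolate/marker: ",
         gsub("\r", " / ", bad, fixed = TRUE))
  }
  rownames(tab) <- NULL
  structure(tab, class = c("allele_table", "data.frame"))
}

# normalise an allele sequence for identity comparison
.norm_allele <- function(seq) gsub("-", "", toupper(seq), fixed = TRUE)

#' Build a haploweb for one marker
#'
#' Nodes are the distinct allele sequences (exact string identity after
#' upper-casing and de-gapping); an edge joins the two alleles of each
#' heterozygous isolate. Fields for recombination (FFRs) are the connected
#' components; isolates in the same FFR are co-assignable to one species at
#' this marker. Haplotype and FFR ids are derived from sorted sequences, so
#' they are stable under input order.
#'
#' @param allele_table An `"allele_table"`.
#' @param marker Marker id to build the web for.
#' @return A list of class `"haploweb"`: `marker`, `haplotypes` (data frame
#'   `hap_id`, `seq`, `ffr`), `edges` (data frame `hap1`, `hap2`,
#'   `isolate`), `isolate_ffr` (named integer; NA for isolates without data
#'   at this marker).
#' @export
build_haploweb <- function(allele_table, marker) {
  tab <- allele_table[allele_table$marker == marker, , drop = FALSE]
  if (!nrow(tab)) stop("no isolate has data for marker ", marker)
  tab$seq <- vapply(tab$seq, .norm_allele, character(1), USE.NAMES = FALSE)
  haps <- sort(unique(tab$seq))
  hap_id <- stats::setNames(seq_along(haps), haps)
  # one edge per heterozygous isolate
  edges <- list()
  iso_haps <- split(tab$seq, tab$isolate)
  for (iso in names(iso_haps)) {
    hs <- unique(iso_haps[[iso]])
    if (length(hs) > 2L) stop("more than 2 alleles for isolate ", iso)
    if (length(hs) == 2L) {
      edges[[length(edges) + 1L]] <- data.frame(
        hap1 = hap_id[[hs[1]]], hap2 = hap_id[[hs[2]]], isolate = iso,
        stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(hap1 = integer(), hap2 = integer(), isolate = character())
  g <- igraph::make_empty_graph(n = length(haps), directed = FALSE)
  if (nrow(edges)) {
    g <- igraph::add_edges(g, rbind(edges$hap1, edges$hap2))
  }
  comp <- igraph::components(g)$membership
  # FFR id = smallest hap id in the component (stable under input order)
  ffr_of_comp <- tapply(seq_along(comp), comp, min)
  ffr <- as.integer(ffr_of_comp[as.character(comp)])
  isolate_ffr <- vapply(iso_haps, function(hs) ffr[hap_id[[hs[1]]]],
                        integer(1))
  structure(list(marker = marker,
                 haplotypes = data.frame(hap_id = seq_along(haps), seq = haps,
                                         ffr = ffr, stringsAsFactors = FALSE),
                 edges = edges,
                 isolate_ffr = isolate_ffr),
            class = "haploweb")
}

#' Conspecificity matrix across markers
#'
#' For each pair of isolates, the score is the number of markers at which
#' both have data and share a field for recombination, minus the number of
#' markers at which both have data and do not. Markers missing in either
#' isolate contribute 0, so `|score| <=` markers evaluated for the pair.
#' Isolates with no data at any marker are excluded with a message.
#'
#' @param haplowebs List of `"haploweb"` objects (one per marker).
#' @return A list of class `"conspecificity_matrix"`: `scores` (symmetric
#'   integer matrix; the diagonal holds the number of markers sequenced for
#'   the isolate), `markers_evaluated` (pairwise counts), `markers`.
#' @export
conspecificity_matrix <- function(haplowebs) {
  if (!length(haplowebs)) stop("at least one marker is required")
  isolates <- sort(unique(unlist(lapply(haplowebs, function(h)
    names(h$isolate_ffr)))))
  n <- length(isolates)
  scores <- matrix(0L, n, n, dimnames = list(isolates, isolates))
  evaluated <- matrix(0L, n, n, dimnames = list(isolates, isolates))
  for (h in haplowebs) {
    ffr <- h$isolate_ffr[isolates]
    names(ffr) <- isolates
    has <- !is.na(ffr)
    for (i in seq_len(n)) {
      if (!has[i]) next
      scores[i, i] <- scores[i, i] + 1L
      for (j in seq_len(n)) {
        if (j <= i || !has[j]) next
        evaluated[i, j] <- evaluated[i, j] + 1L
        evaluated[j, i] <- evaluated[i, j]
        delta <- if (ffr[i] == ffr[j]) 1L else -1L
        scores[i, j] <- scores[i, j] + delta
        scores[j, i] <- scores[i, j]
      }
    }
  }
  none <- isolates[diag(scores) == 0L]
  if (length(none)) {
    message("conspecificity_matrix: excluding isolates with no data: ",
            paste(none, collapse = ", "))
    keep <- setdiff(isolates, none)
    scores <- scores[keep, keep, drop = FALSE]
    evaluated <- evaluated[keep, keep, drop = FALSE]
  }
  structure(list(scores = scores, markers_evaluated = evaluated,
                 markers = vapply(haplowebs, function(h) h$marker, "")),
            class = "conspecificity_matrix")
}

#' @export
print.conspecificity_matrix <- function(x, ...) {
  cat("conspecificity matrix over", length(x$markers), "markers and",
      nrow(x$scores), "isolates\n")
  print(x$scores)
  invisible(x)
}

# IUPAC consensus of two equal-length allele strings (het sites -> ambiguity)
.consensus_alleles <- function(seqs) {
  if (length(seqs) == 1L) return(toupper(seqs))
  a <- .chars(toupper(seqs[1]))
  b <- .chars(toupper(seqs[2]))
  if (length(a) != length(b)) {
    stop("alleles of one isolate have unequal aligned lengths")
  }
  out <- a
  het <- which(a != b)
  for (i in het) {
    pair <- sort(c(a[i], b[i]))
    if (any(pair == "-")) {
      out[i] <- "-"
    } else {
      key <- paste(pair, collapse = "")
      out[i] <- if (!is.na(.IUPAC_PAIR[key])) .IUPAC_PAIR[[key]] else "N"
    }
  }
  paste(out, collapse = "")
}

#' UPGMA ordering of isolates from concatenated marker consensi
#'
#' Per isolate and marker, the consensus of its (at most two) alleles is
#' taken with IUPAC ambiguity codes at heterozygous sites; markers are
#' concatenated (missing markers padded with `N`); columns containing any
#' gap are removed; pairwise distances are JC69 transforms
#' `d = -(3/4) log(1 - 4p/3)` of p-distances in which a site mismatches iff
#' the IUPAC state sets of the two isolates are disjoint. UPGMA
#' agglomeration uses average linkage with deterministic tie-breaking
#' (the pair whose lexicographically smallest member label sorts first).
#'
#' @param allele_table An `"allele_table"` whose alleles are aligned within
#'   each marker (equal lengths).
#' @return A list of class `"upgma_order"`: `order` (leaf labels in
#'   dendrogram order), `tree` (an `ape::phylo`), `newick` (string),
#'   `distances` (the JC69 matrix).
#' @export
upgma_order <- function(allele_table) {
  isolates <- sort(unique(allele_table$isolate))
  markers <- sort(unique(allele_table$marker))
  # per-marker aligned length
  concat <- stats::setNames(rep("", length(isolates)), isolates)
  for (mk in markers) {
    sub <- allele_table[allele_table$marker == mk, , drop = FALSE]
    len <- unique(nchar(sub$seq))
    if (length(len) != 1L) {
      stop("alleles of marker ", mk, " are not aligned (unequal lengths)")
    }
    for (iso in isolates) {
      seqs <- sub$seq[sub$isolate == iso]
      piece <- if (length(seqs)) .consensus_alleles(unique(seqs)) else
        strrep("N", len)
      concat[iso] <- paste0(concat[iso], piece)
    }
  }
  mat <- do.call(rbind, strsplit(unname(concat), "", fixed = TRUE))
  rownames(mat) <- isolates
  gap_cols <- apply(mat == "-", 2, any)
  mat <- mat[, !gap_cols, drop = FALSE]
  if (ncol(mat) == 0L) stop("no ungapped columns left after indel removal")
  n <- length(isolates)
  d <- matrix(0, n, n, dimnames = list(isolates, isolates))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      p <- .iupac_p_distance(mat[i, ], mat[j, ])
      if (is.na(p)) stop("no comparable sites between ", isolates[i],
                         " and ", isolates[j])
      if (p >= 0.75) {
        stop("JC69 distance undefined (p >= 0.75) for pair ", isolates[i],
             " / ", isolates[j])
      }
      d[i, j] <- d[j, i] <- -0.75 * log(1 - 4 * p / 3)
    }
  }
  res <- .upgma(d)
  structure(list(order = res$order, tree = res$tree,
                 newick = ape::write.tree(res$tree), distances = d),
            class = "upgma_order")
}

# p-distance over IUPAC states: mismatch iff state sets are disjoint
.iupac_p_distance <- function(a, b) {
  n <- length(a)
  mism <- 0L
  used <- 0L
  for (i in seq_len(n)) {
    sa <- .IUPAC[[a[i]]]
    sb <- .IUPAC[[b[i]]]
    if (is.null(sa) || is.null(sb)) next
    used <- used + 1L
    if (!length(intersect(sa, sb))) mism <- mism + 1L
  }
  if (used == 0L) return(NA_real_)
  mism / used
}

# deterministic average-linkage UPGMA on a distance matrix
.upgma <- function(d) {
  labels <- rownames(d)
  n <- length(labels)
  if (n == 1L) stop("UPGMA needs at least 2 isolates")
  active <- as.list(seq_len(n))              # member row indices per cluster
  cl_label <- labels                         # smallest member label
  cl_newick <- labels
  cl_height <- rep(0, n)
  cl_size <- rep(1L, n)
  alive <- rep(TRUE, n)
  dist_between <- function(mi, mj) mean(d[mi, mj])
  repeat {
    live <- which(alive)
    if (length(live) == 1L) break
    # pick minimal-distance pair, ties by sorted label pair
    best <- NULL
    for (ii in seq_along(live)) {
      for (jj in seq_along(live)) {
        if (jj <= ii) next
        i <- live[ii]; j <- live[jj]
        dij <- dist_between(active[[i]], active[[j]])
        lab <- sort(c(cl_label[i], cl_label[j]))
        if (is.null(best) || dij < best$d - 1e-12 ||
            (abs(dij - best$d) <= 1e-12 &&
             (lab[1] < best$lab[1] ||
              (lab[1] == best$lab[1] && lab[2] < best$lab[2])))) {
          best <- list(i = i, j = j, d = dij, lab = lab)
        }
      }
    }
    i <- best$i; j <- best$j
    h <- best$d / 2
    # order children: lexicographically smaller label first
    first <- if (cl_label[i] <= cl_label[j]) i else j
    second <- if (first == i) j else i
    bl <- function(k) h - cl_height[k]
    nk <- sprintf("(%s:%.10g,%s:%.10g)", cl_newick[first], bl(first),
                  cl_newick[second], bl(second))
    # merge into slot i
    active[[i]] <- c(active[[first]], active[[second]])
    cl_label[i] <- min(cl_label[first], cl_label[second])
    cl_newick[i] <- nk
    cl_height[i] <- h
    cl_size[i] <- cl_size[first] + cl_size[second]
    alive[j] <- FALSE
  }
  root <- which(alive)
  newick <- paste0(cl_newick[root], ";")
  tree <- ape::read.tree(text = newick)
  # leaf order as written in the newick string (dendrogram order)
  list(order = tree$tip.label, tree = tree, newick = newick)
}
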