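# Ortholog clustering: build an undirected similarity graph from all-vs-all
# search results, partition it with Markov clustering (MCL), and assign
# duplication categories to the resulting cross-species clusters.

#' Build a similarity graph from all-vs-all search edges
#'
#' Rows with `evalue` above the cutoff and self-hits are dropped; reciprocal
#' rows are merged into one undirected edge whose weight is the maximum
#' bitscore of the two directions. Bitscore (rather than `-log10` evalue) is
#' used as the weight to avoid infinite weights at evalue 0. Every gene in
#' `species_map` becomes a node, so genes without surviving hits stay in the
#' graph as isolated nodes.
#'
#' @param edges Data frame as returned by [read_similarity_table()] (needs
#'   columns `qseqid`, `sseqid`, `evalue`, `bitscore`).
#' @param species_map Named character vector `gene_id -> species label`.
#' @param evalue_cutoff Maximum evalue retained (default `1e-3`).
#' @return A list of class `"similarity_graph"` with `nodes` (data frame
#'   `id`, `species`) and `edges` (data frame `from`, `to`, `weight`).
#' @export
build_similarity_graph <- function(edges, species_map, evalue_cutoff = 1e-3) {
  stopifnot(evalue_cutoff > 0)
  ids <- unique(c(edges$qseqid, edges$sseqid))
  unknown <- setdiff(ids, names(species_map))
  if (length(unknown)) stop("gene id not in species_map: ", unknown[1])
  keep <- edges$evalue <= evalue_cutoff & edges$qseqid != edges$sseqid
  e <- edges[keep, c("qseqid", "sseqid", "bitscore"), drop = FALSE]
  if (nrow(e)) {
    a <- pmin(e$qseqid, e$sseqid)
    b <- pmax(e$qseqid, e$sseqid)
    key <- paste(a, b, sep = "\r")
    w <- tapply(e$bitscore, key, max)
    parts <- strsplit(names(w), "\r", fixed = TRUE)
    und <- data.frame(from = vapply(parts, `[`, "", 1),
                      to = vapply(parts, `[`, "", 2),
                      weight = as.numeric(w), stringsAsFactors = FALSE)
    und <- und[order(und$from, und$to), , drop = FALSE]
    rownames(und) <- NULL
  } else {
    und <- data.frame(from = character(), to = character(),
                      weight = numeric(), stringsAsFactors = FALSE)
  }
  if (any(und$weight <= 0)) stop("non-positive edge weight after merging")
  nodes <- data.frame(id = names(species_map),
                      species = as.character(species_map),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = und), class = "similarity_graph")
}

#' Markov clustering (MCL) of a similarity graph
#'
#' Canonical dense MCL: the weighted adjacency matrix is augmented with
#' self-loops (per node, the maximum incident edge weight; 1 for isolated
#' nodes), column-normalised to a stochastic matrix, then expansion (matrix
#' squaring) and inflation (entrywise power followed by column
#' renormalisation) alternate, pruning entries below `prune_threshold`,
#' until the largest entrywise change falls below `convergence_eps` or
#' `max_iter` is reached (the latter emits a warning and returns the current
#' clustering). Clusters are the weak components of the support of the
#' limiting matrix, so they are always subsets of connected components of
#' the input graph, and the procedure is deterministic and invariant under
#' node relabelling.
#'
#' @param graph A `"similarity_graph"`.
#' @param inflation Inflation exponent, must be `> 1` (default 2).
#' @param max_iter Maximum expansion/inflation iterations.
#' @param prune_threshold Entries below this are zeroed each iteration.
#' @param convergence_eps Convergence tolerance on the max entry change.
#' @return A list of class `"ortholog_clusters"` with `clusters` (list of
#'   character vectors of gene ids) and `membership` (named integer vector).
#' @export
mcl_cluster <- function(graph, inflation = 2, max_iter = 100,
                        prune_threshold = 1e-5, convergence_eps = 1e-8) {
  if (inflation <= 1) stop("inflation must be > 1")
  nodes <- sort(graph$nodes$id)
  n <- length(nodes)
  if (n == 0L) stop("empty graph")
  M <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(graph$edges)) {
    i <- match(graph$edges$from, nodes)
    j <- match(graph$edges$to, nodes)
    M[cbind(i, j)] <- graph$edges$weight
    M[cbind(j, i)] <- graph$edges$weight
  }
  loop <- apply(M, 1, max)
  loop[loop == 0] <- 1
  diag(M) <- loop
  normalize <- function(m) sweep(m, 2, colSums(m), "/")
  M <- normalize(M)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    prev <- M
    M <- M %*% M                 # expansion
    M <- normalize(M^inflation)  # inflation
    M[M < prune_threshold] <- 0  # pruning
    cs <- colSums(M)
    if (any(cs == 0)) {          # resurrect fully pruned columns
      idx <- which(cs == 0)
      M[cbind(idx, idx)] <- 1
      cs[idx] <- 1
    }
    M <- sweep(M, 2, cs, "/")
    if (max(abs(M - prev)) < convergence_eps) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("MCL did not converge in ", max_iter,
            " iterations; returning current clustering")
  }
  support <- (M > 0) | (t(M) > 0)
  g <- igraph::graph_from_adjacency_matrix(support, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  # stable cluster ids: order by smallest member id
  split_ids <- split(nodes, comp[nodes])
  split_ids <- split_ids[order(vapply(split_ids, min, character(1)))]
  clusters <- lapply(unname(split_ids), sort)
  membership <- integer(n)
  names(membership) <- nodes
  for (k in seq_along(clusters)) membership[clusters[[k]]] <- k
  structure(list(clusters = clusters, membership = membership),
            class = "ortholog_clusters")
}

#' Assign duplication categories to cross-species clusters
#'
#' For a cluster with `a` genes from the first species and `b` from the
#' second: `(1,1)` makes both genes one-to-one; `(1,>1)` makes the singleton
#' species' gene one-to-many and the other species' genes many-to-one;
#' `(>1,>1)` is many-to-many; clusters confined to one species are
#' many-to-zero. A gene that ends up alone in its cluster with no incident
#' edge in the similarity graph is binned as no-hit (no reciprocal hit at
#' all); a singleton that had edges (split off by clustering) is
#' many-to-zero.
#'
#' @param clusters An `"ortholog_clusters"` object.
#' @param species_map Named character vector `gene_id -> species` with
#'   exactly two species labels overall.
#' @param graph Optional `"similarity_graph"` used to distinguish no-hit
#'   singletons from many-to-zero singletons; without it every singleton is
#'   no-hit.
#' @return A list of class `"category_assignment"` with `genes` (data frame
#'   `gene_id`, `species`, `cluster`, `category`) and `clusters` (data frame
#'   `cluster`, `count_A`, `count_B`); species A/B are the two labels in
#'   sorted order.
#' @export
categorize_orthologs <- function(clusters, species_map, graph = NULL) {
  sp <- sort(unique(as.character(species_map)))
  if (length(sp) != 2L) {
    stop("exactly two species are required, found ", length(sp))
  }
  has_edge <- character(0)
  if (!is.null(graph) && nrow(graph$edges)) {
    has_edge <- unique(c(graph$edges$from, graph$edges$to))
  }
  genes <- list()
  ctab <- data.frame(cluster = seq_along(clusters$clusters),
                     count_A = 0L, count_B = 0L)
  for (k in seq_along(clusters$clusters)) {
    members <- clusters$clusters[[k]]
    spk <- species_map[members]
    if (anyNA(spk)) stop("gene id not in species_map: ",
                         members[is.na(spk)][1])
    a <- sum(spk == sp[1]); b <- sum(spk == sp[2])
    ctab$count_A[k] <- a; ctab$count_B[k] <- b
    cat_for <- function(own, other, gene) {
      if (own >= 1 && other == 0) {
        if (own + other >= 2 || gene %in% has_edge) "many-to-zero" else "no-hit"
      } else if (own == 1 && other == 1) "one-to-one"
      else if (own == 1 && other > 1) "one-to-many"
      else if (own > 1 && other == 1) "many-to-one"
      else "many-to-many"
    }
    categ <- vapply(seq_along(members), function(i) {
      own_is_a <- spk[i] == sp[1]
      cat_for(if (own_is_a) a else b, if (own_is_a) b else a, members[i])
    }, character(1))
    genes[[k]] <- data.frame(gene_id = members, species = as.character(spk),
                             cluster = k, category = categ,
                             stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes)
  rownames(genes) <- NULL
  structure(list(genes = genes, clusters = ctab, species = sp),
            class = "category_assignment")
}

#' Tabulate category counts per species
#'
#' @param assignment A `"category_assignment"`.
#' @return Data frame with one row per (species, category) and a `count`
#'   column; categories sum to the species' total gene count.
#' @export
category_summary <- function(assignment) {
  levels <- c("one-to-one", "one-to-many", "many-to-one", "many-to-many",
              "many-to-zero", "no-hit")
  g <- assignment$genes
  out <- expand.grid(species = assignment$species, category = levels,
                     stringsAsFactors = FALSE)
  out$count <- mapply(function(s, cat) sum(g$species == s & g$category == cat),
                      out$species, out$category)
  out[order(out$species, match(out$category, levels)), , drop = FALSE]
}
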