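# Diagnostic-site screening of grouped alignments (molecular synapomorphies)
# and between-group p-distance profiles across nested taxonomic ranks.

#' Assemble a grouped alignment
#'
#' @param alignment An `"msa"` (see [as_alignment()]).
#' @param groups Named character vector `seq_id -> group label` covering
#'   every row.
#' @param region Optional integer `c(start, end)` column interval (1-based,
#'   inclusive); defaults to the full alignment.
#' @param mask Optional integer vector of columns eligible for diagnostics
#'   (e.g. rRNA stem regions); defaults to all columns. Masks are inputs:
#'   inferring secondary structure is out of scope.
#' @return A list of class `"grouped_alignment"`.
#' @export
grouped_alignment <- function(alignment, groups, region = NULL, mask = NULL) {
  alignment <- as_alignment(alignment)
  width <- nchar(alignment[[1]])
  missing <- setdiff(names(alignment), names(groups))
  if (length(missing)) stop("sequence without group label: ", missing[1])
  if (is.null(region)) region <- c(1L, width)
  if (region[1] < 1L || region[2] > width || region[1] > region[2]) {
    stop("region [", region[1], ", ", region[2],
         "] outside alignment of width ", width)
  }
  if (is.null(mask)) mask <- seq_len(width)
  structure(list(alignment = alignment,
                 groups = groups[names(alignment)],
                 region = as.integer(region),
                 mask = sort(unique(as.integer(mask)))),
            class = "grouped_alignment")
}

#' Screen for diagnostic nucleotide positions
#'
#' A column (within the region/mask intersection) is diagnostic for the
#' focal group when all focal sequences carry one unambiguous non-gap state
#' that no non-focal sequence carries. In `strict` mode the whole column
#' must additionally be free of gaps and ambiguity codes; `relaxed` mode
#' tolerates gaps/ambiguities in non-focal sequences (useful when the
#' comparison pool lumps heterogeneous clades), still requiring clean focal
#' states.
#'
#' @param ga A `"grouped_alignment"`.
#' @param focal_group Group label to diagnose.
#' @param mode `"strict"` (default) or `"relaxed"`.
#' @return Data frame with columns `column` (1-based alignment position),
#'   `state_focal`, `states_other` (comma-collapsed), sorted ascending.
#' @export
find_diagnostic_sites <- function(ga, focal_group, mode = c("strict", "relaxed")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ga, "grouped_alignment"))
  if (!focal_group %in% ga$groups) stop("focal group absent: ", focal_group)
  mat <- do.call(rbind, strsplit(as.character(ga$alignment), "", fixed = TRUE))
  focal <- ga$groups == focal_group
  cols <- intersect(seq(ga$region[1], ga$region[2]), ga$mask)
  plain <- c("A", "C", "G", "T")
  hits <- list()
  for (col in cols) {
    v <- toupper(mat[, col])
    vf <- v[focal]
    vo <- v[!focal]
    if (any(!vf %in% plain)) next                  # gap/ambiguity in focal
    if (length(unique(vf)) != 1L) next             # focal not fixed
    state <- vf[1]
    if (state %in% vo) next                        # state present elsewhere
    if (mode == "strict" && any(!vo %in% plain)) next
    hits[[length(hits) + 1L]] <- data.frame(
      column = col, state_focal = state,
      states_other = paste(sort(unique(vo)), collapse = ","),
      stringsAsFactors = FALSE)
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(column = integer(), state_focal = character(),
               states_other = character(), stringsAsFactors = FALSE)
  out[order(out$column), , drop = FALSE]
}

#' Mean between-group p-distance
#'
#' Mean of [pairwise_p_distance()] (pairwise deletion) over all cross pairs
#' of the two groups. Pairs with no comparable columns are skipped with a
#' message; if all pairs are skipped an error is raised.
#'
#' @param alignment An `"msa"` (or named character vector of aligned rows).
#' @param group_a,group_b Character vectors of sequence ids.
#' @return Mean percent distance.
#' @export
between_group_mean_distance <- function(alignment, group_a, group_b) {
  seqs <- as.character(alignment)
  names(seqs) <- names(alignment)
  missing <- setdiff(c(group_a, group_b), names(seqs))
  if (length(missing)) stop("sequence not in alignment: ", missing[1])
  if (!length(group_a) || !length(group_b)) {
    stop("both groups need at least one sequence")
  }
  vals <- c()
  skipped <- 0L
  for (x in group_a) {
    for (y in group_b) {
      d <- suppressWarnings(pairwise_p_distance(seqs[[x]], seqs[[y]]))
      if (is.na(d)) skipped <- skipped + 1L else vals <- c(vals, d)
    }
  }
  if (skipped > 0L) {
    message("between_group_mean_distance: skipped ", skipped,
            " pairs with no comparable columns")
  }
  if (!length(vals)) stop("all cross pairs lack comparable columns")
  mean(vals)
}

#' Between-group distance profile across nested taxonomic ranks
#'
#' For each parent taxon with at least two child groups, the between-group
#' mean distance of every child pair is computed; per rank
#' (orders-within-classes, families-within-orders, genera-within-families)
#' the grand mean and SD over those pair means are reported. Rank levels
#' with no qualifying parent are omitted with a message.
#'
#' @param alignment An `"msa"` of all sequences (one marker).
#' @param taxonomy Data frame with columns `seq_id`, `class`, `order`,
#'   `family`, `genus`.
#' @param marker Label attached to the profile rows.
#' @return A list of class `"rank_distance_profile"`: `pair_means` (data
#'   frame `rank`, `parent`, `group1`, `group2`, `mean_distance`, `marker`)
#'   and `summary` (data frame `rank`, `n`, `grand_mean`, `sd`).
#' @export
rank_distance_profile <- function(alignment, taxonomy, marker = "marker") {
  req <- c("seq_id", "class", "order", "family", "genus")
  stopifnot(all(req %in% names(taxonomy)))
  missing <- setdiff(taxonomy$seq_id, names(alignment))
  if (length(missing)) stop("taxonomy row without sequence: ", missing[1])
  ranks <- list(
    `orders-within-classes` = c(parent = "class", child = "order"),
    `families-within-orders` = c(parent = "order", child = "family"),
    `genera-within-families` = c(parent = "family", child = "genus"))
  rows <- list()
  for (rk in names(ranks)) {
    parent_col <- ranks[[rk]][["parent"]]
    child_col <- ranks[[rk]][["child"]]
    for (parent in sort(unique(taxonomy[[parent_col]]))) {
      sub <- taxonomy[taxonomy[[parent_col]] == parent, , drop = FALSE]
      children <- sort(unique(sub[[child_col]]))
      if (length(children) < 2L) next
      for (pair in utils::combn(children, 2, simplify = FALSE)) {
        ga <- sub$seq_id[sub[[child_col]] == pair[1]]
        gb <- sub$seq_id[sub[[child_col]] == pair[2]]
        rows[[length(rows) + 1L]] <- data.frame(
          rank = rk, parent = parent, group1 = pair[1], group2 = pair[2],
          mean_distance = between_group_mean_distance(alignment, ga, gb),
          marker = marker, stringsAsFactors = FALSE)
      }
    }
  }
  pair_means <- if (length(rows)) do.call(rbind, rows) else
    data.frame(rank = character(), parent = character(), group1 = character(),
               group2 = character(), mean_distance = numeric(),
               marker = character(), stringsAsFactors = FALSE)
  present <- unique(pair_means$rank)
  omitted <- setdiff(names(ranks), present)
  if (length(omitted)) {
    message("rank_distance_profile: no qualifying parent for: ",
            paste(omitted, collapse = ", "))
  }
  summ <- do.call(rbind, lapply(present, function(rk) {
    v <- pair_means$mean_distance[pair_means$rank == rk]
    data.frame(rank = rk, n = length(v), grand_mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (is.null(summ)) {
    summ <- data.frame(rank = character(), n = integer(),
                       grand_mean = numeric(), sd = numeric())
  }
  structure(list(pair_means = pair_means, summary = summ, marker = marker),
            class = "rank_distance_profile")
}

#' Place a candidate species pair on the rank-distance ladder
#'
#' The candidate distance is compared to each rank's distribution of
#' between-group means via a z-score; the suggested rank is the one with
#' the smallest |z|, ties resolved toward the lower (more finely split)
#' rank. Ranks whose SD is zero (or undefined) are compared by absolute
#' difference and flagged. This placement is a formalisation of the
#' qualitative "comparable to distances between X within Y" reading of a
#' rank profile.
#'
#' @param candidate_distance Percent distance of the candidate pair.
#' @param profile A `"rank_distance_profile"`.
#' @return A list of class `"rank_placement"`: `per_rank` (data frame
#'   `rank`, `n`, `grand_mean`, `sd`, `z`, `flagged`) and `suggested_rank`.
#' @export
place_candidate_pair <- function(candidate_distance, profile) {
  summ <- profile$summary[profile$summary$n >= 2, , drop = FALSE]
  if (!nrow(summ)) stop("profile has no rank with >= 2 group means")
  # rank order from lower (finer) to higher
  ladder <- c("genera-within-families", "families-within-orders",
              "orders-within-classes")
  summ$flagged <- is.na(summ$sd) | summ$sd == 0
  summ$z <- ifelse(summ$flagged,
                   candidate_distance - summ$grand_mean,
                   (candidate_distance - summ$grand_mean) / summ$sd)
  summ <- summ[order(match(summ$rank, ladder)), , drop = FALSE]
  best <- which.min(abs(summ$z))  # which.min takes the first = lowest rank
  structure(list(per_rank = summ, candidate_distance = candidate_distance,
                 suggested_rank = summ$rank[best]),
            class = "rank_placement")
}

#' @export
print.rank_placement <- function(x, ...) {
  cat(sprintf("candidate distance %.2f%% -> suggested rank: %s\n",
              x$candidate_distance, x$suggested_rank))
  print(x$per_rank, row.names = FALSE)
  invisible(x)
}
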