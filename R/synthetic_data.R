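# Synthetic-data generators with planted ground truth. Every generator is
# deterministic given its seed; independent per-component streams are
# derived from the one user seed so adding a generator never perturbs the
# others. The generators emulate the statistical structure the analysis
# stages assume (diverged gene sets with planted duplication categories and
# rearrangements, codon pairs evolved at a target dN/dS, multi-marker
# phased-allele datasets with planted species boundaries, alignments with
# planted diagnostic columns); they deliberately do not model indel
# evolution, intron structure or recombination within markers.

# ---- codon-level evolution helpers -----------------------------------------

# propose-and-filter substitution process on a CDS: single-base proposals,
# stop-creating proposals rejected outright, synonymous proposals accepted,
# nonsynonymous proposals accepted with probability min(1, omega)
.evolve_cds <- function(cds, n_events, omega) {
  bases <- c("A", "C", "G", "T")
  chars <- .chars(cds)
  acc_syn <- 0L
  acc_nonsyn <- 0L
  rej_stop <- 0L
  rej_omega <- 0L
  for (e in seq_len(n_events)) {
    pos <- sample.int(length(chars), 1L)
    alt <- sample(setdiff(bases, chars[pos]), 1L)
    ci <- (pos - 1L) %/% 3L
    old_codon <- paste(chars[(ci * 3L + 1L):(ci * 3L + 3L)], collapse = "")
    new <- chars
    new[pos] <- alt
    new_codon <- paste(new[(ci * 3L + 1L):(ci * 3L + 3L)], collapse = "")
    if (new_codon %in% .stop_codons) {
      rej_stop <- rej_stop + 1L
      next
    }
    if (.translate_codon(old_codon) == .translate_codon(new_codon)) {
      chars <- new
      acc_syn <- acc_syn + 1L
    } else if (stats::runif(1) < min(1, omega)) {
      chars <- new
      acc_nonsyn <- acc_nonsyn + 1L
    } else {
      rej_omega <- rej_omega + 1L
    }
  }
  list(seq = paste(chars, collapse = ""), accepted_syn = acc_syn,
       accepted_nonsyn = acc_nonsyn, rejected_stop = rej_stop,
       rejected_omega = rej_omega)
}

# per-site substitutions at a fixed rate, skipping stop-creating changes;
# used to diverge duplicated gene copies
.mutate_copy <- function(cds, rate) {
  bases <- c("A", "C", "G", "T")
  chars <- .chars(cds)
  hit <- which(stats::runif(length(chars)) < rate)
  for (pos in hit) {
    alt <- sample(setdiff(bases, chars[pos]), 1L)
    ci <- (pos - 1L) %/% 3L
    new <- chars
    new[pos] <- alt
    codon <- paste(new[(ci * 3L + 1L):(ci * 3L + 3L)], collapse = "")
    if (codon %in% .stop_codons) next
    chars <- new
  }
  paste(chars, collapse = "")
}

.nt_identity <- function(a, b) {
  ca <- .chars(a); cb <- .chars(b)
  100 * sum(ca == cb) / length(ca)
}

# ---- genome pair ------------------------------------------------------------

#' Simulate a pair of diverged, rearranged genomes with planted truth
#'
#' Genome B starts as a diverged copy of genome A (each gene's CDS evolved
#' under the propose-and-filter codon process) and is then transformed by
#' the requested events in order: inversions, translocations, duplications,
#' losses. Event windows are placed with a 3-gene buffer between events and
#' contig ends so that, at the default synteny settings (`max_skip = 1`,
#' `min_block_size = 3`), every planted label is recoverable exactly.
#' Translocations move a window to a different contig (so `n_contigs >= 2`
#' is required when translocations are requested). Duplicated copies are
#' mutated at a small per-site rate so similarity ranks self > paralog >
#' ortholog. A within-family all-vs-all similarity table is emitted in
#' 12-column tabular form.
#'
#' @param n_genes Number of ancestral genes (>= 10).
#' @param n_contigs Number of contigs per genome (default 2).
#' @param n_inversions,n_translocations Planted event counts.
#' @param duplication_spec Named list/vector of counts per category among
#'   `one-to-many`, `many-to-one`, `many-to-many`, `many-to-zero`.
#' @param loss_rate Fraction of eligible genome-B orthologs deleted.
#' @param seed Integer seed; identical seeds give identical output.
#' @param n_codons_per_gene Gene length in codons (default 100).
#' @param ortholog_events_per_gene Substitution proposals per gene on the
#'   A-to-B branch (default 20, i.e. 0.2 proposals/codon).
#' @param ortholog_omega Target dN/dS on the A-to-B branch (default 0.3).
#' @param copy_mut_rate Per-site mutation rate for duplicated copies
#'   (default 0.02).
#' @return A list of class `"sim_genome_pair"` with `annotation_a`,
#'   `annotation_b`, `cds_a`, `cds_b`, `prot_a`, `prot_b`, `similarity`,
#'   `species_map` and `truth` (`orthologs`, `categories`,
#'   `rearrangement`, `events`).
#' @export
simulate_genome_pair <- function(n_genes, n_contigs = 2, n_inversions = 0,
                                 n_translocations = 0,
                                 duplication_spec = list(), loss_rate = 0,
                                 seed = 1, n_codons_per_gene = 100,
                                 ortholog_events_per_gene = 20,
                                 ortholog_omega = 0.3,
                                 copy_mut_rate = 0.02) {
  stopifnot(n_genes >= 10, n_contigs >= 1, n_inversions >= 0,
            n_translocations >= 0, loss_rate >= 0, loss_rate < 1)
  if (n_translocations > 0 && n_contigs < 2) {
    stop("translocations require n_contigs >= 2")
  }
  dup_ok <- c("one-to-many", "many-to-one", "many-to-many", "many-to-zero")
  if (length(duplication_spec) &&
      !all(names(duplication_spec) %in% dup_ok)) {
    stop("unknown duplication category: ",
         setdiff(names(duplication_spec), dup_ok)[1])
  }
  .with_seed(.derive_seed(seed, 101L), {
    genes <- sprintf("g%04d", seq_len(n_genes))
    id_a <- stats::setNames(paste0(genes, "_A"), genes)
    id_b <- stats::setNames(paste0(genes, "_B"), genes)
    # contiguous contig blocks
    cut <- floor(seq(0, n_genes, length.out = n_contigs + 1))
    contig_of <- rep(seq_len(n_contigs), diff(cut))
    order_a <- split(genes, contig_of)
    names(order_a) <- sprintf("ctgA_%d", seq_len(n_contigs))
    strand_a <- stats::setNames(sample(c("+", "-"), n_genes, replace = TRUE),
                                genes)
    # sequences
    cds_anc <- stats::setNames(
      vapply(genes, function(g) .random_cds(n_codons_per_gene), ""), genes)
    evolved <- lapply(cds_anc, .evolve_cds, n_events = ortholog_events_per_gene,
                      omega = ortholog_omega)
    cds_b_orth <- stats::setNames(vapply(evolved, `[[`, "", "seq"), genes)

    # --- event window placement on A indices, with 3-gene buffers ---
    buffer <- 3L
    occupied <- lapply(order_a, function(x) rep(FALSE, length(x)))
    pick_window <- function(len) {
      for (try in seq_len(2000L)) {
        ctg <- sample(names(order_a), 1L)
        sz <- length(order_a[[ctg]])
        if (sz < len + 2L * buffer) next
        start <- sample.int(sz - len + 1L, 1L)
        lo <- max(1L, start - buffer)
        hi <- min(sz, start + len - 1L + buffer)
        if (start - 1L < buffer || sz - (start + len - 1L) < buffer) next
        if (any(occupied[[ctg]][lo:hi])) next
        occupied[[ctg]][start:(start + len - 1L)] <<- TRUE
        return(list(contig = ctg, start = start, len = len))
      }
      stop("requested events exceed genome size: cannot place a ", len,
           "-gene window with ", buffer, "-gene buffers")
    }
    # inversion windows use 4-6 genes: a 3-gene inversion leaves its middle
    # gene at an unchanged position, which a same-orientation chain can
    # absorb through the 1-gene skip allowance
    inv_windows <- lapply(seq_len(n_inversions), function(k)
      pick_window(sample(4:6, 1L)))
    tra_windows <- lapply(seq_len(n_translocations), function(k)
      pick_window(sample(3:5, 1L)))

    # --- genome B order: start identical, apply events ---
    order_b <- order_a
    names(order_b) <- sprintf("ctgB_%d", seq_len(n_contigs))
    strand_b <- strand_a
    truth_rearr <- stats::setNames(rep("collinear", n_genes), genes)
    events <- list()
    b_ctg_of_a_ctg <- stats::setNames(names(order_b), names(order_a))

    for (w in inv_windows) {
      bc <- b_ctg_of_a_ctg[[w$contig]]
      run <- order_a[[w$contig]][w$start:(w$start + w$len - 1L)]
      idx <- match(run, order_b[[bc]])
      order_b[[bc]][idx] <- rev(run)
      strand_b[run] <- ifelse(strand_b[run] == "+", "-", "+")
      truth_rearr[run] <- "inverted"
      events[[length(events) + 1L]] <- list(type = "inversion", genes = run)
    }
    # event genes (any window) are ineligible as translocation insertion
    # neighbours so collinear fragments keep >= 3 clean genes
    event_genes <- unlist(lapply(c(inv_windows, tra_windows), function(w)
      order_a[[w$contig]][w$start:(w$start + w$len - 1L)]))
    for (w in tra_windows) {
      src <- b_ctg_of_a_ctg[[w$contig]]
      run <- order_a[[w$contig]][w$start:(w$start + w$len - 1L)]
      order_b[[src]] <- setdiff(order_b[[src]], run)
      dst_choices <- setdiff(names(order_b), src)
      placed <- FALSE
      for (try in seq_len(2000L)) {
        dst <- sample(dst_choices, 1L)
        cur <- order_b[[dst]]
        if (length(cur) < 2L * buffer) next
        slot <- sample(seq(buffer + 1L, length(cur) - buffer + 1L), 1L)
        neigh <- cur[max(1L, slot - buffer):min(length(cur), slot + buffer - 1L)]
        if (any(neigh %in% event_genes)) next
        order_b[[dst]] <- append(cur, run, after = slot - 1L)
        placed <- TRUE
        break
      }
      if (!placed) stop("requested events exceed genome size: no insertion ",
                        "slot for a translocated window")
      truth_rearr[run] <- "translocated"
      events[[length(events) + 1L]] <- list(type = "translocation",
                                            genes = run)
    }

    # --- duplications ---
    used <- unique(event_genes)
    cds_a_extra <- character(0)
    cds_b_extra <- character(0)
    truth_cat <- stats::setNames(rep("one-to-one", 0L), character(0))
    pick_plain_gene <- function() {
      cand <- setdiff(genes, used)
      if (!length(cand)) stop("requested events exceed genome size: no ",
                              "unused gene left for duplication planting")
      g <- sample(cand, 1L)
      used <<- c(used, g)
      g
    }
    dup_families <- list()  # gene -> extra member ids
    b_lost <- character(0)
    for (cat in names(duplication_spec)) {
      for (k in seq_len(as.integer(duplication_spec[[cat]]))) {
        g <- pick_plain_gene()
        if (cat %in% c("one-to-many", "many-to-many")) {
          cid <- paste0(g, "_Bdup")
          cds_b_extra[cid] <- .mutate_copy(cds_b_orth[[g]], copy_mut_rate)
          ctg <- sample(names(order_b), 1L)
          order_b[[ctg]] <- c(order_b[[ctg]], paste0(g, "|dupB"))
          dup_families[[g]] <- c(dup_families[[g]], cid)
        }
        if (cat %in% c("many-to-one", "many-to-many", "many-to-zero")) {
          cid <- paste0(g, "_Adup")
          cds_a_extra[cid] <- .mutate_copy(cds_anc[[g]], copy_mut_rate)
          ctg <- sample(names(order_a), 1L)
          order_a[[ctg]] <- c(order_a[[ctg]], paste0(g, "|dupA"))
          dup_families[[g]] <- c(dup_families[[g]], cid)
        }
        if (cat == "many-to-zero") {
          bc <- names(order_b)[vapply(order_b, function(x) g %in% x,
                                      logical(1))]
          order_b[[bc]] <- setdiff(order_b[[bc]], g)
          b_lost <- c(b_lost, g)
        }
        # per-gene truth categories
        switch(cat,
          `one-to-many` = {
            truth_cat[id_a[[g]]] <- "one-to-many"
            truth_cat[id_b[[g]]] <- "many-to-one"
            truth_cat[paste0(g, "_Bdup")] <- "many-to-one"
          },
          `many-to-one` = {
            truth_cat[id_a[[g]]] <- "many-to-one"
            truth_cat[paste0(g, "_Adup")] <- "many-to-one"
            truth_cat[id_b[[g]]] <- "one-to-many"
          },
          `many-to-many` = {
            truth_cat[c(id_a[[g]], paste0(g, "_Adup"),
                        id_b[[g]], paste0(g, "_Bdup"))] <- "many-to-many"
          },
          `many-to-zero` = {
            truth_cat[c(id_a[[g]], paste0(g, "_Adup"))] <- "many-to-zero"
          })
        events[[length(events) + 1L]] <- list(type = "duplication",
                                              category = cat, genes = g)
      }
    }

    # --- losses ---
    loss_cand <- setdiff(genes, used)
    n_loss <- floor(loss_rate * length(loss_cand))
    lost <- if (n_loss > 0L) sample(loss_cand, n_loss) else character(0)
    for (g in lost) {
      bc <- names(order_b)[vapply(order_b, function(x) g %in% x, logical(1))]
      order_b[[bc]] <- setdiff(order_b[[bc]], g)
      truth_cat[id_a[[g]]] <- "no-hit"
      truth_rearr[g] <- "unplaced"
      events[[length(events) + 1L]] <- list(type = "loss", genes = g)
    }
    b_lost <- c(b_lost, lost)

    # --- final gene tables ---
    # order lists currently hold ancestral gene names plus "g|dupA/B" tags
    final_ids <- function(order_list, suffix) {
      lapply(order_list, function(v) {
        vapply(v, function(g) {
          if (grepl("|dupA", g, fixed = TRUE)) {
            paste0(sub("|dupA", "", g, fixed = TRUE), "_Adup")
          } else if (grepl("|dupB", g, fixed = TRUE)) {
            paste0(sub("|dupB", "", g, fixed = TRUE), "_Bdup")
          } else {
            paste0(g, suffix)
          }
        }, "")
      })
    }
    ids_a <- final_ids(order_a, "_A")
    ids_b <- final_ids(order_b, "_B")
    build_ann <- function(ids_per_ctg, strands, species) {
      rows <- list()
      for (ctg in names(ids_per_ctg)) {
        v <- ids_per_ctg[[ctg]]
        if (!length(v)) next
        start <- (seq_along(v) - 1L) * 1500L + 1L
        rows[[ctg]] <- data.frame(
          gene_id = v, contig = ctg, start = start,
          end = start + 3L * n_codons_per_gene - 1L,
          strand = strands[v], stringsAsFactors = FALSE)
      }
      as_genome_annotation(do.call(rbind, rows), species)
    }
    # strands for final ids
    strands_a <- stats::setNames(strand_a[genes], id_a[genes])
    strands_b <- stats::setNames(strand_b[genes], id_b[genes])
    extra_ids <- c(names(cds_a_extra), names(cds_b_extra))
    strands_all <- c(strands_a, strands_b,
                     stats::setNames(rep("+", length(extra_ids)), extra_ids))
    annotation_a <- build_ann(ids_a, strands_all, "A")
    annotation_b <- build_ann(ids_b, strands_all, "B")

    cds_a <- c(stats::setNames(cds_anc[genes], id_a[genes]), cds_a_extra)
    cds_b_named <- stats::setNames(cds_b_orth[genes], id_b[genes])
    cds_b_named <- cds_b_named[!names(cds_b_named) %in% id_b[b_lost]]
    cds_b <- c(cds_b_named, cds_b_extra)
    prot <- function(x) {
      structure(vapply(x, .translate_cds, ""), alphabet = "aa",
                class = "seq_set")
    }
    seqset <- function(x) structure(x, alphabet = "nt", class = "seq_set")

    # --- within-family similarity table ---
    sim_rows <- list()
    for (g in genes) {
      fam <- c(id_a[[g]],
               if (!g %in% b_lost) id_b[[g]],
               dup_families[[g]])
      seqs <- c(cds_a, cds_b)[fam]
      for (q in fam) {
        for (s in fam) {
          pid <- if (q == s) 100 else .nt_identity(seqs[[q]], seqs[[s]])
          len <- nchar(seqs[[q]])
          sim_rows[[length(sim_rows) + 1L]] <- data.frame(
            qseqid = q, sseqid = s, pident = round(pid, 2), length = len,
            mismatch = as.integer(round((100 - pid) / 100 * len)),
            gapopen = 0L, qstart = 1L, qend = len, sstart = 1L, send = len,
            evalue = signif(10^(-(pid / 5 + 3)), 3),
            bitscore = round(2 * pid * len / 100, 1),
            stringsAsFactors = FALSE)
        }
      }
    }
    similarity <- do.call(rbind, sim_rows)
    similarity$self_hit <- similarity$qseqid == similarity$sseqid

    all_ids <- c(names(cds_a), names(cds_b))
    species_map <- stats::setNames(
      ifelse(all_ids %in% names(cds_a), "A", "B"), all_ids)
    surviving <- setdiff(genes, b_lost)
    truth_orthologs <- data.frame(gene_a = unname(id_a[surviving]),
                                  gene_b = unname(id_b[surviving]),
                                  stringsAsFactors = FALSE)
    # fill default one-to-one truth for unplanted genes
    for (g in surviving) {
      if (!id_a[[g]] %in% names(truth_cat)) truth_cat[id_a[[g]]] <- "one-to-one"
      if (!id_b[[g]] %in% names(truth_cat)) truth_cat[id_b[[g]]] <- "one-to-one"
    }
    truth_rearr_a <- stats::setNames(truth_rearr[genes], id_a[genes])
    if (length(extra_ids)) {
      truth_rearr_a <- c(truth_rearr_a, stats::setNames(
        rep("unplaced", sum(grepl("_Adup$", extra_ids))),
        extra_ids[grepl("_Adup$", extra_ids)]))
    }
    structure(list(annotation_a = annotation_a, annotation_b = annotation_b,
                   cds_a = seqset(cds_a), cds_b = seqset(cds_b),
                   prot_a = prot(cds_a), prot_b = prot(cds_b),
                   similarity = similarity, species_map = species_map,
                   truth = list(orthologs = truth_orthologs,
                                categories = truth_cat,
                                rearrangement = truth_rearr_a,
                                events = events)),
              class = "sim_genome_pair")
  })
}

# ---- codon ortholog pairs ---------------------------------------------------

#' Simulate codon-aligned ortholog pairs at a target dN/dS
#'
#' Each pair descends from a random stop-free ancestor; `n_events`
#' single-base proposals are split at random over the two lineages.
#' Proposals creating stop codons are rejected (and still consume an
#' event, keeping event counts interpretable); synonymous proposals are
#' accepted; nonsynonymous proposals are accepted with probability
#' `min(1, omega)`. Accepted event counts per pair are recorded as ground
#' truth.
#'
#' @param n_pairs Number of ortholog pairs (default 200).
#' @param n_codons Codons per sequence (>= 10; default 300).
#' @param omega Target dN/dS (>= 0; default 0.3).
#' @param n_events Substitution proposals per pair (default 60).
#' @param seed Integer seed.
#' @return A list of class `"sim_codon_set"`: `pairs` (list of
#'   `c(cds_a, cds_b)`), `truth` (data frame `pair`, `accepted_syn`,
#'   `accepted_nonsyn`, `rejected_stop`, `rejected_omega`), `omega`,
#'   `n_events`.
#' @export
simulate_codon_orthologs <- function(n_pairs = 200, n_codons = 300,
                                     omega = 0.3, n_events = 60, seed = 1) {
  if (omega < 0) stop("omega must be >= 0")
  stopifnot(n_codons >= 10, n_events >= 0, n_pairs >= 1)
  .with_seed(.derive_seed(seed, 202L), {
    pairs <- vector("list", n_pairs)
    truth <- data.frame(pair = seq_len(n_pairs), accepted_syn = 0L,
                        accepted_nonsyn = 0L, rejected_stop = 0L,
                        rejected_omega = 0L)
    for (p in seq_len(n_pairs)) {
      anc <- .random_cds(n_codons)
      split_ab <- sample(c(TRUE, FALSE), n_events, replace = TRUE)
      ev_a <- .evolve_cds(anc, sum(split_ab), omega)
      ev_b <- .evolve_cds(anc, sum(!split_ab), omega)
      pairs[[p]] <- c(cds_a = ev_a$seq, cds_b = ev_b$seq)
      truth$accepted_syn[p] <- ev_a$accepted_syn + ev_b$accepted_syn
      truth$accepted_nonsyn[p] <- ev_a$accepted_nonsyn + ev_b$accepted_nonsyn
      truth$rejected_stop[p] <- ev_a$rejected_stop + ev_b$rejected_stop
      truth$rejected_omega[p] <- ev_a$rejected_omega + ev_b$rejected_omega
    }
    structure(list(pairs = pairs, truth = truth, omega = omega,
                   n_events = n_events),
              class = "sim_codon_set")
  })
}

# ---- phased-allele datasets -------------------------------------------------

#' Simulate a multi-marker phased-allele dataset with planted species
#'
#' Per species and marker, alleles form a chain: each heterozygous isolate
#' bridges the current allele and a freshly mutated one, so the species'
#' allele pool is always a single connected haploweb component. Species
#' allele pools descend from a common marker ancestor diverged at
#' `species_divergence` substitutions per site (markers are homologous, so
#' between-species distances stay in a realistic range), and are verified
#' disjoint. Missing entries are drawn independently at `missing_rate`.
#'
#' @param n_species Number of species (>= 1).
#' @param isolates_per_species Isolates per species.
#' @param n_markers Number of markers (>= 1).
#' @param heterozygosity_rate Probability an isolate is heterozygous at a
#'   marker.
#' @param missing_rate Probability an (isolate, marker) cell is missing.
#' @param seed Integer seed.
#' @param marker_length Marker length in bp (default 300).
#' @param species_divergence Per-site substitution rate between each
#'   species' marker base and the shared marker ancestor (default 0.08).
#' @return A list of class `"sim_allele_set"`: `allele_table` (an
#'   `"allele_table"`), `truth_species` (named vector), `markers`,
#'   `missing` (data frame of missing cells).
#' @export
simulate_allele_dataset <- function(n_species = 2, isolates_per_species = 4,
                                    n_markers = 3, heterozygosity_rate = 0.5,
                                    missing_rate = 0, seed = 1,
                                    marker_length = 300,
                                    species_divergence = 0.08) {
  stopifnot(n_species >= 1, n_markers >= 1, isolates_per_species >= 1,
            heterozygosity_rate >= 0, heterozygosity_rate <= 1,
            missing_rate >= 0, missing_rate < 1)
  if (isolates_per_species < 2 && heterozygosity_rate > 0) {
    warning("heterozygosity_rate > 0 with a single isolate per species: ",
            "no allele sharing is possible")
  }
  .with_seed(.derive_seed(seed, 303L), {
    markers <- sprintf("mk%02d", seq_len(n_markers))
    ancestors <- stats::setNames(
      vapply(markers, function(mk) .random_dna(marker_length), ""), markers)
    n_sub <- max(1L, round(species_divergence * marker_length))
    rows <- list()
    truth_species <- character(0)
    missing_cells <- list()
    for (sp in seq_len(n_species)) {
      isolates <- sprintf("sp%d_iso%d", sp, seq_len(isolates_per_species))
      truth_species[isolates] <- sprintf("sp%d", sp)
      for (mk in markers) {
        cur <- .mutate_copy_nt(ancestors[[mk]], n_sub)
        for (iso in isolates) {
          het <- stats::runif(1) < heterozygosity_rate
          if (het) {
            nxt <- .mutate_copy_nt(cur, 2L)
            alleles <- c(cur, nxt)
            cur <- nxt
          } else {
            alleles <- c(cur, cur)
          }
          if (stats::runif(1) < missing_rate) {
            missing_cells[[length(missing_cells) + 1L]] <-
              data.frame(isolate = iso, marker = mk, stringsAsFactors = FALSE)
            next
          }
          rows[[length(rows) + 1L]] <- data.frame(
            isolate = iso, marker = mk, seq = alleles,
            stringsAsFactors = FALSE)
        }
      }
    }
    tab <- as_allele_table(do.call(rbind, rows))
    # planted species pools must be disjoint: astronomically unlikely to
    # collide for random 300-bp sequences, but verify
    key <- paste(tab$marker, tab$seq, sep = "\r")
    sp_of <- truth_species[tab$isolate]
    if (any(vapply(split(sp_of, key), function(x) length(unique(x)) > 1,
                   logical(1)))) {
      stop("allele collision between species; use a longer marker_length")
    }
    structure(list(allele_table = tab, truth_species = truth_species,
                   markers = markers,
                   missing = if (length(missing_cells))
                     do.call(rbind, missing_cells) else
                       data.frame(isolate = character(), marker = character())),
              class = "sim_allele_set")
  })
}

# substitute exactly n random sites of a DNA string
.mutate_copy_nt <- function(seq, n_subs) {
  bases <- c("A", "C", "G", "T")
  chars <- .chars(seq)
  pos <- sample.int(length(chars), n_subs)
  for (p in pos) chars[p] <- sample(setdiff(bases, chars[p]), 1L)
  paste(chars, collapse = "")
}

# ---- diagnostic alignments --------------------------------------------------

#' Simulate a grouped alignment with planted diagnostic columns
#'
#' All sequences share one random backbone; at each of `n_diagnostic`
#' columns (chosen inside the region/mask intersection) the focal group --
#' the first group of `groups_spec` -- receives one state and all other
#' groups a different state, making the column fully diagnostic. Noise
#' substitutions are then applied outside the planted columns; noise draws
#' that would fix a new group-distinguishing state inside the region/mask
#' intersection are rejected and resampled, so the planted sites remain the
#' only diagnostic columns there.
#'
#' @param groups_spec Named integer vector `group -> number of sequences`;
#'   the first entry is the focal group.
#' @param length Alignment length in columns (default 2551, a full-length
#'   16S-scale alignment).
#' @param n_diagnostic Number of planted diagnostic columns.
#' @param region Integer `c(start, end)` (1-based, inclusive); default the
#'   whole alignment.
#' @param stem_mask Columns eligible for diagnostics (default: all columns
#'   in `region`).
#' @param noise_rate Per-sequence per-column substitution probability.
#' @param seed Integer seed.
#' @return A list of class `"sim_diag_alignment"`: `grouped` (a
#'   `"grouped_alignment"`), `truth_sites` (sorted planted columns),
#'   `region`, `stem_mask`.
#' @export
simulate_diagnostic_alignment <- function(groups_spec, length = 2551,
                                          n_diagnostic = 4, region = NULL,
                                          stem_mask = NULL, noise_rate = 0,
                                          seed = 1) {
  stopifnot(length >= 1, n_diagnostic >= 0, !is.null(names(groups_spec)),
            all(groups_spec >= 1))
  if (is.null(region)) region <- c(1L, length)
  if (region[1] < 1L || region[2] > length || region[1] > region[2]) {
    stop("region outside alignment")
  }
  if (is.null(stem_mask)) stem_mask <- seq(region[1], region[2])
  eligible <- intersect(seq(region[1], region[2]), stem_mask)
  if (n_diagnostic > base::length(eligible)) {
    stop("n_diagnostic exceeds the region/mask intersection (",
         base::length(eligible), " columns)")
  }
  .with_seed(.derive_seed(seed, 404L), {
    bases <- c("A", "C", "G", "T")
    group_of <- rep(names(groups_spec), times = groups_spec)
    seq_ids <- sprintf("%s_s%d", group_of, stats::ave(
      seq_along(group_of), group_of, FUN = seq_along))
    n_seq <- base::length(seq_ids)
    backbone <- sample(bases, length, replace = TRUE)
    mat <- matrix(rep(backbone, each = n_seq), nrow = n_seq)
    truth_sites <- sort(sample(eligible, n_diagnostic))
    focal <- group_of == names(groups_spec)[1]
    for (col in truth_sites) {
      st <- sample(bases, 2L)
      mat[focal, col] <- st[1]
      mat[!focal, col] <- st[2]
    }
    # noise outside planted columns; resample any column that becomes
    # diagnostic for some group inside the region/mask intersection
    is_diag_col <- function(v) {
      for (grp in unique(group_of)) {
        vf <- v[group_of == grp]
        vo <- v[group_of != grp]
        if (base::length(unique(vf)) == 1L && !vf[1] %in% vo) return(TRUE)
      }
      FALSE
    }
    if (noise_rate > 0) {
      for (col in setdiff(seq_len(length), truth_sites)) {
        guard <- col %in% eligible
        for (try in seq_len(100L)) {
          v <- mat[, col]
          hit <- which(stats::runif(n_seq) < noise_rate)
          for (i in hit) v[i] <- sample(setdiff(bases, v[i]), 1L)
          if (!guard || !is_diag_col(v)) {
            mat[, col] <- v
            break
          }
          # else: rejected, resample this column's noise
        }
      }
    }
    seqs <- stats::setNames(apply(mat, 1, paste, collapse = ""), seq_ids)
    ga <- grouped_alignment(as_alignment(structure(seqs, alphabet = "nt")),
                            stats::setNames(group_of, seq_ids),
                            region = region, mask = stem_mask)
    structure(list(grouped = ga, truth_sites = truth_sites, region = region,
                   stem_mask = stem_mask,
                   groups = stats::setNames(group_of, seq_ids)),
              class = "sim_diag_alignment")
  })
}
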