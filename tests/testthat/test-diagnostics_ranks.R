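mk_ga <- function(seqs, groups, region = NULL, mask = NULL) {
  grouped_alignment(as_alignment(structure(seqs, alphabet = "nt")),
                    groups, region = region, mask = mask)
}

test_that("diagnostic screening requires fixation in focal and absence elsewhere", {
  seqs <- c(f1 = "ATTA", f2 = "ATTA", o1 = "AATA", o2 = "AATA")
  groups <- stats::setNames(c("foc", "foc", "oth", "oth"), names(seqs))
  ga <- mk_ga(seqs, groups)
  hits <- find_diagnostic_sites(ga, "foc")
  expect_equal(hits$column, 2L)
  expect_equal(hits$state_focal, "T")
  expect_equal(hits$states_other, "A")
  # a gap in a focal sequence disqualifies the column
  seqs2 <- c(f1 = "AT", f2 = "A-", o1 = "AA", o2 = "AA")
  ga2 <- mk_ga(seqs2, groups |> stats::setNames(names(seqs2)))
  expect_equal(nrow(find_diagnostic_sites(ga2, "foc")), 0)
  # strict mode rejects columns with non-focal ambiguity; relaxed keeps them
  seqs3 <- c(f1 = "AT", f2 = "AT", o1 = "AN", o2 = "AA")
  ga3 <- mk_ga(seqs3, groups |> stats::setNames(names(seqs3)))
  expect_equal(nrow(find_diagnostic_sites(ga3, "foc", mode = "strict")), 0)
  expect_equal(find_diagnostic_sites(ga3, "foc", mode = "relaxed")$column, 2L)
  # columns outside region/mask are never reported
  ga4 <- mk_ga(seqs, groups, region = c(1, 1))
  expect_equal(nrow(find_diagnostic_sites(ga4, "foc")), 0)
  expect_error(find_diagnostic_sites(ga, "absent"), "absent")
  expect_error(mk_ga(seqs, groups, region = c(0, 9)), "outside alignment")
})

test_that("planted diagnostic columns are recovered exactly and only those", {
  sim <- simulate_diagnostic_alignment(c(focal = 3, other = 6), length = 300,
                                       n_diagnostic = 4, region = c(40, 260),
                                       stem_mask = seq(40, 260, by = 2),
                                       noise_rate = 0, seed = 8)
  hits <- find_diagnostic_sites(sim$grouped, "focal")
  expect_equal(hits$column, sim$truth_sites)
  # zero planted sites, zero noise: nothing found
  sim0 <- simulate_diagnostic_alignment(c(a = 3, b = 3), length = 120,
                                        n_diagnostic = 0, noise_rate = 0,
                                        seed = 8)
  expect_equal(nrow(find_diagnostic_sites(sim0$grouped, "a")), 0)
  # under noise, recovery is still exact inside the guarded region
  simn <- simulate_diagnostic_alignment(c(focal = 4, other = 8), length = 500,
                                        n_diagnostic = 14, noise_rate = 0.02,
                                        seed = 13)
  expect_equal(find_diagnostic_sites(simn$grouped, "focal")$column,
               simn$truth_sites)
})

test_that("between-group mean distance equals the brute-force double loop", {
  # worked example: {AAAA} vs {AAAT, AATT} -> mean(25, 50)
  aln <- structure(c(x = "AAAA", y = "AAAT", z = "AATT"), alphabet = "nt")
  expect_equal(between_group_mean_distance(aln, "x", c("y", "z")), 37.5)
  expect_equal(between_group_mean_distance(aln, "x", "x"), 0)
  # symmetry and equality with a direct double loop on random groups
  withr::local_seed(21)
  seqs <- vapply(1:10, function(i)
    paste(sample(c("A", "C", "G", "T", "-"), 60, TRUE,
                 prob = c(.23, .23, .23, .23, .08)), collapse = ""), "")
  names(seqs) <- sprintf("s%02d", 1:10)
  ga <- names(seqs)[1:5]
  gb <- names(seqs)[6:10]
  got <- between_group_mean_distance(seqs, ga, gb)
  acc <- c()
  for (x in ga) for (y in gb) {
    a <- strsplit(seqs[[x]], "")[[1]]
    b <- strsplit(seqs[[y]], "")[[1]]
    ok <- a != "-" & b != "-"
    acc <- c(acc, 100 * sum(a[ok] != b[ok]) / sum(ok))
  }
  expect_equal(got, mean(acc))
  expect_equal(got, between_group_mean_distance(seqs, gb, ga))
})

# hierarchical alignment generator: divergence proportional to rank height
rank_sim <- function(seed = 31, site_n = 600) {
  withr::with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    mutate_n <- function(s, n) {
      ch <- strsplit(s, "")[[1]]
      pos <- sample(length(ch), n)
      for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1)
      paste(ch, collapse = "")
    }
    root <- paste(sample(bases, site_n, TRUE), collapse = "")
    taxa <- list()
    seqs <- c()
    for (cl in c("c1", "c2")) {
      cl_seq <- mutate_n(root, 120)
      for (or in paste0(cl, c("_o1", "_o2"))) {
        or_seq <- mutate_n(cl_seq, 60)
        for (fa in paste0(or, c("_f1", "_f2"))) {
          fa_seq <- mutate_n(or_seq, 30)
          for (ge in paste0(fa, c("_g1", "_g2"))) {
            ge_seq <- mutate_n(fa_seq, 10)
            for (s in 1:2) {
              id <- paste0(ge, "_s", s)
              seqs[id] <- mutate_n(ge_seq, 2)
              taxa[[id]] <- data.frame(seq_id = id, class = cl, order = or,
                                       family = fa, genus = ge)
            }
          }
        }
      }
    }
    list(aln = seqs, tax = do.call(rbind, taxa))
  })
}

test_that("rank profiles aggregate child-pair means and grow with rank height", {
  sim <- rank_sim()
  prof <- rank_distance_profile(sim$aln, sim$tax, marker = "sim")
  s <- prof$summary
  expect_setequal(s$rank, c("orders-within-classes", "families-within-orders",
                            "genera-within-families"))
  gm <- stats::setNames(s$grand_mean, s$rank)
  expect_true(gm["genera-within-families"] < gm["families-within-orders"])
  expect_true(gm["families-within-orders"] < gm["orders-within-classes"])
  # combinatorics: 2 classes x 1 order-pair, 4 orders x 1 family-pair, etc.
  pm <- prof$pair_means
  expect_equal(sum(pm$rank == "orders-within-classes"), 2)
  expect_equal(sum(pm$rank == "families-within-orders"), 4)
  expect_equal(sum(pm$rank == "genera-within-families"), 8)
  # single family with two genera: exactly one genus-level entry
  tax1 <- data.frame(seq_id = c("p", "q"), class = "c", order = "o",
                     family = "f", genus = c("g1", "g2"))
  aln1 <- c(p = "AAAA", q = "AAAT")
  suppressMessages(prof1 <- rank_distance_profile(aln1, tax1))
  expect_equal(nrow(prof1$pair_means), 1)
  expect_equal(prof1$pair_means$rank, "genera-within-families")
})

test_that("candidate placement picks the rank with the smallest |z|", {
  sim <- rank_sim()
  prof <- rank_distance_profile(sim$aln, sim$tax)
  gm <- stats::setNames(prof$summary$grand_mean, prof$summary$rank)
  # candidate equal to a rank mean: that rank suggested with z = 0
  pl <- place_candidate_pair(gm[["genera-within-families"]], prof)
  expect_equal(pl$suggested_rank, "genera-within-families")
  expect_equal(min(abs(pl$per_rank$z)), 0)
  # candidate planted at genus level in the simulation scale
  genus_scale <- mean(prof$pair_means$mean_distance[
    prof$pair_means$rank == "genera-within-families"])
  pl2 <- place_candidate_pair(genus_scale * 1.02, prof)
  expect_equal(pl2$suggested_rank, "genera-within-families")
  # SD = 0 ranks are flagged and compared by absolute difference
  prof0 <- structure(list(summary = data.frame(
    rank = c("genera-within-families", "families-within-orders"),
    n = c(3L, 3L), grand_mean = c(5, 10), sd = c(0, 2))),
    class = "rank_distance_profile")
  pl3 <- place_candidate_pair(5.5, prof0)
  expect_true(pl3$per_rank$flagged[pl3$per_rank$rank == "genera-within-families"])
  expect_equal(pl3$suggested_rank, "genera-within-families")
})

test_that("identical sequences yield the zero/empty element everywhere", {
  seqs <- c(a1 = "ACGT", a2 = "ACGT", b1 = "ACGT", b2 = "ACGT")
  groups <- stats::setNames(c("A", "A", "B", "B"), names(seqs))
  ga <- mk_ga(seqs, groups)
  expect_equal(nrow(find_diagnostic_sites(ga, "A")), 0)
  expect_equal(between_group_mean_distance(seqs, c("a1", "a2"),
                                           c("b1", "b2")), 0)
})
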