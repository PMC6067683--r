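test_that("simulators are deterministic given the seed", {
  a <- simulate_genome_pair(30, n_contigs = 2, n_inversions = 1, seed = 5)
  b <- simulate_genome_pair(30, n_contigs = 2, n_inversions = 1, seed = 5)
  expect_identical(a, b)
  c1 <- simulate_codon_orthologs(5, 30, 0.3, 10, seed = 4)
  c2 <- simulate_codon_orthologs(5, 30, 0.3, 10, seed = 4)
  expect_identical(c1, c2)
  d1 <- simulate_allele_dataset(2, 3, 2, 0.5, 0.2, seed = 6)
  d2 <- simulate_allele_dataset(2, 3, 2, 0.5, 0.2, seed = 6)
  expect_identical(d1, d2)
  e1 <- simulate_diagnostic_alignment(c(x = 2, y = 3), 100, 3, seed = 7)
  e2 <- simulate_diagnostic_alignment(c(x = 2, y = 3), 100, 3, seed = 7)
  expect_identical(e1, e2)
  # different seeds diverge
  expect_false(identical(a, simulate_genome_pair(30, n_contigs = 2,
                                                 n_inversions = 1, seed = 6)))
})

test_that("zero-event genome pairs are identical in order with empty truth", {
  sp <- simulate_genome_pair(20, n_contigs = 1, seed = 1)
  expect_length(sp$truth$events, 0)
  ga <- as.data.frame(sp$annotation_a)$gene_id
  gb <- as.data.frame(sp$annotation_b)$gene_id
  expect_equal(sub("_A$", "", ga), sub("_B$", "", gb))
  expect_true(all(sp$truth$rearrangement == "collinear"))
})

test_that("a single inversion reverses one segment and flips its strands", {
  sp <- simulate_genome_pair(20, n_contigs = 1, n_inversions = 1, seed = 1)
  ev <- sp$truth$events
  expect_length(ev, 1)
  expect_equal(ev[[1]]$type, "inversion")
  run <- ev[[1]]$genes
  a <- as.data.frame(sp$annotation_a)
  b <- as.data.frame(sp$annotation_b)
  rownames(a) <- a$gene_id
  rownames(b) <- b$gene_id
  ob <- sub("_B$", "", b$gene_id)
  expect_equal(ob[ob %in% run], rev(run))  # reversed order in B
  expect_true(all(a[paste0(run, "_A"), "strand"] !=
                    b[paste0(run, "_B"), "strand"]))
})

test_that("duplication planting emits exactly the requested category labels", {
  sp <- simulate_genome_pair(50, n_contigs = 2, n_inversions = 2,
                             n_translocations = 1,
                             duplication_spec = list(`one-to-many` = 3),
                             loss_rate = 0.05, seed = 7)
  expect_equal(sum(sp$truth$categories == "one-to-many"), 3)
  # each planted gene has one A copy and two B copies in the gene tables
  planted <- names(sp$truth$categories)[sp$truth$categories == "one-to-many"]
  for (g in planted) {
    core <- sub("_A$", "", g)
    expect_equal(sum(grepl(core, names(sp$cds_b), fixed = TRUE)), 2)
  }
  # losses recorded as events and as no-hit truth
  n_loss <- sum(vapply(sp$truth$events, function(e) e$type == "loss",
                       logical(1)))
  expect_equal(sum(sp$truth$categories == "no-hit"), n_loss)
  expect_error(simulate_genome_pair(10, 1, n_translocations = 1),
               "n_contigs >= 2")
  expect_error(simulate_genome_pair(12, 1, n_inversions = 5, seed = 1),
               "exceed genome size")
})

test_that("similarity ranking is self > paralog > ortholog", {
  sp <- simulate_genome_pair(30, n_contigs = 2,
                             duplication_spec = list(`one-to-many` = 2),
                             seed = 9)
  sim <- sp$similarity
  planted <- sub("_A$", "",
                 names(sp$truth$categories)[sp$truth$categories == "one-to-many"])
  for (core in planted) {
    b_orig <- paste0(core, "_B")
    rows <- sim[sim$qseqid == b_orig, ]
    self <- rows$bitscore[rows$sseqid == b_orig]
    par <- rows$bitscore[rows$sseqid == paste0(core, "_Bdup")]
    orth <- rows$bitscore[rows$sseqid == paste0(core, "_A")]
    expect_gt(self, par)
    expect_gt(par, orth)
  }
})

test_that("codon simulator honours omega in its accepted-event log", {
  s0 <- simulate_codon_orthologs(20, 50, omega = 0, n_events = 30, seed = 2)
  expect_true(all(s0$truth$accepted_nonsyn == 0))
  # n_events = 0: identical pairs, unchanged fraction 1
  sid <- simulate_codon_orthologs(5, 50, omega = 0.3, n_events = 0, seed = 2)
  for (p in sid$pairs) {
    expect_equal(p[["cds_a"]], p[["cds_b"]])
    st <- codon_pair_stats(p)
    expect_equal(st$unchanged, st$n_codons_compared)
  }
  expect_error(simulate_codon_orthologs(5, 50, omega = -1), "omega")
  # event-log oracle: omega recomputed from accepted events tracks the target
  sim <- simulate_codon_orthologs(60, 200, omega = 0.3, n_events = 40,
                                  seed = 3)
  with(sim$truth, {
    # acceptance-corrected ratio of rates: nonsyn accepted / nonsyn proposed
    # over syn accepted / syn proposed
    nonsyn_prop <- accepted_nonsyn + rejected_omega
    expect_equal(sum(accepted_nonsyn) / sum(nonsyn_prop), 0.3,
                 tolerance = 0.15)
  })
})

test_that("allele simulator keeps species pools connected and disjoint", {
  sim <- simulate_allele_dataset(1, 4, 3, 0.5, 0, seed = 1)
  webs <- lapply(sim$markers, build_haploweb, allele_table = sim$allele_table)
  cm <- conspecificity_matrix(webs)
  off <- !diag(TRUE, nrow(cm$scores))
  expect_true(all(cm$scores[off] == 3L))
  sim2 <- simulate_allele_dataset(2, 3, 3, 0.5, 0, seed = 2)
  webs2 <- lapply(sim2$markers, build_haploweb,
                  allele_table = sim2$allele_table)
  cm2 <- conspecificity_matrix(webs2)
  iso <- rownames(cm2$scores)
  between <- outer(sim2$truth_species[iso], sim2$truth_species[iso], "!=")
  expect_true(all(cm2$scores[between] == -3L))
  # missing data bounds |score| by markers evaluated for the pair
  sim3 <- simulate_allele_dataset(2, 3, 3, 0.5, 0.3, seed = 2)
  webs3 <- lapply(sim3$markers, build_haploweb,
                  allele_table = sim3$allele_table)
  cm3 <- suppressMessages(conspecificity_matrix(webs3))
  expect_true(all(cm3$markers_evaluated <= 3))
  off3 <- !diag(TRUE, nrow(cm3$scores))
  expect_true(all(abs(cm3$scores[off3]) <= cm3$markers_evaluated[off3]))
  expect_warning(simulate_allele_dataset(1, 1, 2, 0.5, 0, seed = 1),
                 "single isolate")
})

test_that("diagnostic alignment plants exactly the requested columns", {
  sim <- simulate_diagnostic_alignment(c(f = 3, o = 5), length = 200,
                                       n_diagnostic = 5, region = c(20, 180),
                                       stem_mask = seq(20, 180, 3),
                                       noise_rate = 0, seed = 4)
  expect_length(sim$truth_sites, 5)
  eligible <- intersect(20:180, seq(20, 180, 3))
  expect_true(all(sim$truth_sites %in% eligible))
  got <- find_diagnostic_sites(sim$grouped, "f")
  expect_equal(got$column, sim$truth_sites)
  expect_error(simulate_diagnostic_alignment(c(f = 2, o = 2), length = 50,
                                             n_diagnostic = 60),
               "exceeds the region/mask")
  expect_error(simulate_diagnostic_alignment(c(f = 2, o = 2), length = 50,
                                             region = c(10, 60)),
               "outside alignment")
})

test_that("recovery degrades at most gently, never improves, with noise", {
  rec <- vapply(c(0, 0.05, 0.25), function(nr) {
    sim <- simulate_diagnostic_alignment(c(f = 4, o = 8), length = 300,
                                         n_diagnostic = 6,
                                         noise_rate = nr, seed = 10)
    hits <- find_diagnostic_sites(sim$grouped, "f")
    length(intersect(hits$column, sim$truth_sites)) / 6
  }, numeric(1))
  expect_equal(rec[1], 1)
  expect_true(all(diff(rec) <= 0))
})

test_that("simulator output round-trips through the io readers", {
  sp <- simulate_genome_pair(20, n_contigs = 1, seed = 12)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(sp$cds_a, fa)
  expect_equal(c(read_fasta(fa, "nt")), c(unclass(sp$cds_a)),
               ignore_attr = TRUE)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_similarity_table(sp$similarity, tsv)
  back <- read_similarity_table(tsv)
  expect_equal(back$qseqid, sp$similarity$qseqid)
  expect_equal(back$bitscore, sp$similarity$bitscore)
  # phased-allele FASTA with the isolate|marker|allele id convention
  sim <- simulate_allele_dataset(1, 3, 1, 0.5, 0, seed = 3)
  tab <- sim$allele_table
  ids <- paste(tab$isolate, tab$marker,
               paste0("a", stats::ave(seq_len(nrow(tab)),
                                      paste(tab$isolate, tab$marker),
                                      FUN = seq_along)), sep = "|")
  af <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(stats::setNames(tab$seq, ids), af)
  tab2 <- read_allele_table(af)
  expect_equal(tab2$isolate, tab$isolate)
  expect_equal(tab2$seq, tab$seq)
})
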