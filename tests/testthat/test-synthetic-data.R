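test_that("clone tree simulation respects the schedule and degenerate rates", {
  expect_error(simulate_clone_tree(mutations_per_day = 0), "must be > 0")
  expect_error(simulate_clone_tree(n_cells = 5, seed = 1), "does not match")

  # near-zero rate: no mutations, all cells genotypically identical
  tr0 <- simulate_clone_tree(mutations_per_day = 1e-9, seed = 1)
  expect_equal(nrow(tr0$mutations), 0)
  expect_equal(sum(tr0$tree_mutations$edge.length), 0)

  tr <- simulate_clone_tree(seed = 7)
  expect_s3_class(tr$tree_days, "phylo")
  expect_equal(length(tr$clone_of_cell), 16)
  expect_equal(length(unique(tr$clone_of_cell)), 8)  # 7 derived + parental
  # culture time = sampled day of the cell's clone
  expect_equal(unname(tr$culture_time[c("P_1", "C7_2")]), c(7, 63))
})

test_that("cells of one clone share all mutations above their divergence", {
  tr <- simulate_clone_tree(seed = 11)
  G <- tr$genotypes
  paths <- clonescope:::edges_on_root_paths(tr$tree_days)
  tips <- tr$tree_days$tip.label
  for (clone in paste0("C", 1:7)) {
    pair <- tips[tr$clone_of_cell[tips] == clone]
    shared_edges <- intersect(paths[[match(pair[1], tips)]],
                              paths[[match(pair[2], tips)]])
    on_shared <- tr$mutations$edge %in% shared_edges
    expect_true(all(G[pair[1], on_shared] == 1L))
    expect_equal(G[pair[1], on_shared], G[pair[2], on_shared])
  }
})

test_that("per-branch mutation counts are Poisson with mean rate x duration", {
  # rate 2/day on 10-day branches: mean count 20, checked within 3 SE
  sched <- data.frame(clone = c("P", "C1"), founded_day = c(0, 0),
                      sampled_day = c(10, 10), n_cells = c(1, 1))
  n_rep <- 1500
  counts <- unlist(lapply(seq_len(n_rep), function(i) {
    tr <- simulate_clone_tree(n_cells = 2, n_clones = 1,
                              mutations_per_day = 2,
                              sampling_schedule = sched, seed = i)
    tr$tree_mutations$edge.length
  }))
  se <- sqrt(20 / length(counts))
  expect_lt(abs(mean(counts) - 20), 3 * se)
})

test_that("WGA read counts reproduce the dropout and imbalance model", {
  G <- matrix(1L, 2, 5, dimnames = list(c("a", "b"), paste0("m", 1:5)))
  expect_error(simulate_wga_readcounts(G[0, , drop = FALSE]), "empty")

  snps <- simulate_het_snps(4000, 1e7, seed = 1)
  # no dropout, near-zero dispersion: both alleles near 0.5 BAF
  clean <- wga_profile(ado_rate = 0, amp_error_rate = 0,
                       imbalance_dispersion = 1e-4, mean_depth = 40)
  rc <- simulate_wga_readcounts(G, clean, snps, seed = 2)
  germ <- rc[rc$site_type == "germline_het", ]
  baf <- germ$alt_depth / (germ$ref_depth + germ$alt_depth)
  expect_true(all(germ$ref_depth > 0 & germ$alt_depth > 0))
  expect_lt(mean(abs(baf - 0.5)), 0.1)

  # realized locus-level ADO converges to the profile value
  rc2 <- simulate_wga_readcounts(G[1, , drop = FALSE],
                                 wga_profile(ado_rate = 0.057,
                                             amp_error_rate = 0),
                                 simulate_het_snps(20000, 1e8, seed = 3),
                                 seed = 4)
  est <- estimate_ado(rc2)
  se <- sqrt(0.057 * (1 - 0.057) / est$n_sites)
  expect_lt(abs(est$ado_rate - 0.057), 3 * se)
})

test_that("MDA-like amplification gives visibly wider BAF spread than PTA", {
  G <- matrix(1L, 1, 1, dimnames = list("a", "m1"))
  snps <- simulate_het_snps(8000, 1e8, seed = 5)
  baf_of <- function(profile, seed) {
    rc <- simulate_wga_readcounts(G, profile, snps, seed = seed)
    g <- rc[rc$site_type == "germline_het", ]
    tot <- g$ref_depth + g$alt_depth
    (g$alt_depth / tot)[tot > 0]
  }
  v_pta <- var(baf_of(pta_profile(), 6))
  v_mda <- var(baf_of(mda_profile(), 7))
  expect_gt(v_mda, v_pta)
})

test_that("CNV injection creates hemizygous BAF shifts only inside the event", {
  sim <- two_clone_cnv_sim(seed = 101)
  rc <- sim$rc
  germ <- rc[rc$site_type == "germline_het", ]
  inside <- germ$pos >= sim$del[1] & germ$pos < sim$del[2]
  carrier <- germ$cell %in% sim$carriers
  baf <- germ$alt_depth / (germ$ref_depth + germ$alt_depth)

  # carriers inside the deletion: BAF collapses to ~0 or ~1
  b_in <- baf[inside & carrier]
  expect_gt(mean(b_in < 0.05 | b_in > 0.95, na.rm = TRUE), 0.95)

  # outside the interval the BAF distribution is unchanged
  # (carrier vs non-carrier two-sample test non-significant)
  set.seed(1)
  b_car <- sample(baf[!inside & carrier & !is.na(baf)], 1000)
  b_non <- sample(baf[!inside & !carrier & !is.na(baf)], 1000)
  expect_gt(suppressWarnings(ks.test(b_car, b_non)$p.value), 0.01)

  # interval with no het sites: warning and no-op
  expect_warning(
    rc2 <- inject_cnv(rc, carrier_cells = sim$carriers,
                      event = list(chrom = "99", start = 0, end = 100)),
    "no-op")
  expect_identical(rc2$ref_depth, rc$ref_depth)
})

test_that("UMI families copy molecules faithfully and track the true VAF", {
  expect_error(simulate_umi_families(0.1, 10, per_read_error = -1), ">= 0")

  ufs0 <- simulate_umi_families(0.3, 200, per_read_error = 0, seed = 1)
  same <- vapply(ufs0$families, function(f)
    all(apply(f$reads, 2, function(col) length(unique(col)) == 1)), TRUE)
  expect_true(all(same))

  ufs <- simulate_umi_families(0.005, 1e5, per_read_error = 0.001, seed = 2)
  frac <- true_alt_fraction(ufs)
  se <- sqrt(0.005 * 0.995 / 1e5)
  expect_lt(abs(frac - 0.005), 3 * se)

  # fixed family size 2 cannot pass minmem 3
  ufs2 <- simulate_umi_families(0.1, 50, reads_per_family = 2, seed = 3)
  cons <- call_consensus_set(ufs2)
  expect_true(all(cons$status == "rejected"))
  expect_true(all(cons$reason == "minmem"))
})

test_that("phenotypes evolve by Brownian motion with tip noise", {
  tr <- simulate_clone_tree(seed = 21)$tree_days
  # bm_rate 0, noise 0: every cell keeps the root value exactly
  X0 <- simulate_phenotypes(tr, 3, bm_rate = 0, noise_sd = 0,
                            root_value = 2, seed = 1)
  expect_true(all(X0 == 2))
  # trait covariance ~ bm_rate * shared path length (many markers)
  V <- ape::vcv(tr)
  X <- simulate_phenotypes(tr, 3000, bm_rate = 2, noise_sd = 0, seed = 2)
  emp <- cov(t(X))
  expect_lt(max(abs(emp - 2 * V)) / max(2 * V), 0.15)
})

test_that("identical seeds give byte-identical simulator output", {
  expect_identical(simulate_clone_tree(seed = 5), simulate_clone_tree(seed = 5))
  G <- simulate_clone_tree(seed = 5)
  snps <- simulate_het_snps(500, 1e7, seed = 6)
  expect_identical(simulate_wga_readcounts(G, pta_profile(), snps, seed = 7),
                   simulate_wga_readcounts(G, pta_profile(), snps, seed = 7))
  expect_identical(simulate_umi_families(0.1, 100, seed = 8),
                   simulate_umi_families(0.1, 100, seed = 8))
  expect_identical(simulate_phenotypes(G$tree_days, 4, seed = 9),
                   simulate_phenotypes(G$tree_days, 4, seed = 9))
})

test_that("truth genotypes carry no homoplasy", {
  tr <- simulate_clone_tree(seed = 31)
  cls <- phylogeny_filter(tr$genotypes, tr$tree_days)
  expect_false(any(cls$homoplasic))
})
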