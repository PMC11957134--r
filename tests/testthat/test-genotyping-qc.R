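test_that("ADO estimator counts single-allele het sites", {
  ref <- c(rep(10, 94), rep(0, 3), rep(12, 3))
  alt <- c(rep(8, 94), rep(15, 3), rep(0, 3))
  est <- estimate_ado(depth_table(ref, alt))
  expect_equal(est$ado_rate, 0.06)
  expect_equal(estimate_ado(depth_table(rep(5, 50), rep(5, 50)))$ado_rate, 0)
  # nothing passes min_depth: undefined and flagged
  low <- estimate_ado(depth_table(rep(1, 10), rep(1, 10)), min_depth = 5)
  expect_true(is.na(low$ado_rate))
  expect_equal(low$flag, "no_qualifying_sites")
})

test_that("germline recall counts surviving variant alleles", {
  d <- depth_table(rep(10, 100), c(rep(6, 84), rep(0, 16)))
  expect_equal(estimate_recall_germline(d)$recall, 0.84)
  expect_error(estimate_recall_germline(d[0, ]), "empty")

  # no dropout, no filters: recall 1
  G <- matrix(1L, 1, 1, dimnames = list("a", "m1"))
  rc <- simulate_wga_readcounts(
    G, wga_profile(ado_rate = 0, amp_error_rate = 0,
                   imbalance_dispersion = 1e-4, mean_depth = 40),
    simulate_het_snps(2000, 1e7, seed = 1), seed = 2)
  expect_equal(estimate_recall_germline(rc)$recall, 1)
  # a filter pipeline can only lower recall
  expect_lte(estimate_recall_germline(rc, filter_pipeline = function(d)
    d$alt_depth >= 10)$recall, 1)
})

test_that("linked-read precision scores two-haplotype consistency", {
  mk <- function(id, combos) do.call(rbind, lapply(seq_len(nrow(combos)),
    function(i) data.frame(candidate = id, het_allele = combos[i, 1],
                           ssnv_allele = combos[i, 2])))
  # clean two-haplotype candidate: (A, alt) x4 and (B, ref) x4
  good <- mk("v1", cbind(rep(c("A", "B"), each = 4),
                         rep(c("alt", "ref"), each = 4)))
  # artifact: alt on both haplotypes with >= 2 reads each
  bad <- mk("v2", cbind(rep(c("A", "A", "B", "B"), 2),
                        rep(c("alt", "ref"), 4)))
  est <- estimate_precision_linked(rbind(good, bad))
  expect_equal(est$precision, 0.5)
  expect_equal(est$n_assessable, 2L)

  all_good <- estimate_precision_linked(good)
  expect_equal(all_good$precision, 1)
  # a lone third-haplotype read does not overturn a candidate
  noisy <- rbind(good, data.frame(candidate = "v1", het_allele = "B",
                                  ssnv_allele = "alt"))
  expect_equal(estimate_precision_linked(noisy)$precision, 1)
  # nothing assessable: flagged
  tiny <- estimate_precision_linked(good[1:2, ], min_spanning = 4)
  expect_true(is.na(tiny$precision))
  expect_equal(tiny$flag, "no_assessable_candidates")
})

test_that("precision estimator is consistent on generative mixtures", {
  for (reads in c(12, 30)) {
    lr <- simulate_linked_reads(n_candidates = 400, true_fraction = 0.9,
                                reads_per_candidate = reads, seed = reads)
    est <- estimate_precision_linked(lr$read_pairs)
    expect_lt(abs(est$precision - 0.9), if (reads == 12) 0.06 else 0.03)
  }
})

test_that("false heterozygous calls concentrate at low BAF", {
  region <- list(chrom = "1", start = 0, end = 1e7)
  clean <- depth_table(rep(30, 100), rep(0, 100))
  expect_equal(estimate_false_het(clean, region)$false_het_rate, 0)

  d <- depth_table(c(rep(30, 2997), rep(27, 3)), c(rep(0, 2997), rep(3, 3)))
  fh <- estimate_false_het(d, region)
  expect_equal(fh$false_het_rate, 0.001)
  expect_error(estimate_false_het(clean, list(chrom = "9", start = 0,
                                              end = 10)), "no sites")

  # amplification-error simulation: hom-ref sites, error reads only
  G <- matrix(0L, 1, 4000, dimnames = list("a", paste0("m", 1:4000)))
  rc <- simulate_wga_readcounts(
    G, wga_profile(ado_rate = 0, amp_error_rate = 0.01, mean_depth = 30),
    het_snps = NULL, seed = 3)
  fh2 <- estimate_false_het(rc, list(chrom = "1", start = 0, end = 1e7))
  expect_gt(fh2$n_false_het, 0)
  expect_lt(median(fh2$baf), 0.2)
})

test_that("clonal calling requires concordance and clean normals", {
  G <- rbind(c1 = c(1L, 1L, 0L, 1L), c2 = c(1L, 0L, 1L, 1L),
             c3 = c(0L, 0L, 0L, 1L))
  colnames(G) <- paste0("v", 1:4)
  expect_error(call_clonal_mutations(G[1, , drop = FALSE]), "at least 2")
  expect_equal(call_clonal_mutations(G), c("v1", "v4"))
  expect_equal(call_clonal_mutations(G, bulk_germline = "v1"), "v4")
  normals <- rbind(n1 = c(0L, 0L, 0L, 1L))
  colnames(normals) <- colnames(G)
  expect_equal(call_clonal_mutations(G, normal_cell_calls = normals), "v1")
})

test_that("min_concordant extremes reduce to intersection and union", {
  set.seed(99)
  for (i in 1:10) {
    n <- sample(2:5, 1)
    G <- matrix(rbinom(n * 8, 1, 0.4), n, 8,
                dimnames = list(paste0("c", 1:n), paste0("v", 1:8)))
    inter <- colnames(G)[colSums(G) == n]
    uni <- colnames(G)[colSums(G) > 0]
    expect_equal(call_clonal_mutations(G, min_concordant = n), inter)
    expect_equal(call_clonal_mutations(G, min_concordant = 1), uni)
  }
})

test_that("hard filters parse, round-trip and apply with strict bounds", {
  expr <- paste("QD < 2.0 || FS > 60.0 || MQ < 40.0 ||",
                "HaplotypeScore > 13.0 || MQRankSum < -12.5 ||",
                "ReadPosRankSum < -8.0")
  f <- parse_hard_filters(expr)
  expect_equal(nrow(f), 6)
  expect_equal(format_hard_filters(f), expr)
  expect_error(parse_hard_filters("QD << 2.0"), "clause 1")

  rec <- data.frame(QD = c(1.9, 2.0, 30), FS = c(10, 10, 10),
                    MQ = c(60, 60, 60), HaplotypeScore = 1,
                    MQRankSum = 0, ReadPosRankSum = 0)
  kept <- apply_hard_filters(rec, f)
  expect_equal(kept$QD, c(2.0, 30))       # boundary QD = 2.0 survives <
  expect_equal(attr(kept, "n_removed"), 1L)
  # missing metric: clause skipped and logged
  kept2 <- apply_hard_filters(rec[, c("QD", "FS")], f)
  expect_true("MQ" %in% attr(kept2, "skipped_metrics"))
})

test_that("burden correction subtracts the normal-cell baseline", {
  b <- estimate_burden(c(t1 = 1.2 * 2800), 0.2 * 2800)
  expect_equal(b$per_mb, 1.0)
  expect_equal(estimate_burden(c(t1 = 560), 560)$corrected, 0)
  expect_warning(estimate_burden(c(t1 = 100), 200), "over-correction")

  # generative scale check: 3553 true + 200 artifact vs 200 artifact
  set.seed(4)
  tumors <- rpois(20, 3553) + rpois(20, 200)
  normals <- rpois(3, 200)
  est <- estimate_burden(tumors, normals)
  se <- sqrt(3753 / 20 + var(normals) / 3)
  expect_lt(abs(mean(est$corrected) - 3553), 4 * se + 3 * sqrt(200 / 3))
})
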