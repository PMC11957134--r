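test_that("window values are mean mirrored BAFs with QC flags", {
  # two SNPs in one 5-kb window, balanced: window value 0.5
  d <- depth_table(c(15, 15), c(15, 15), pos = c(1000, 2000))
  bwm <- window_mirrored_baf(d, min_snps_per_window = 2, min_cells = 1)
  expect_equal(unname(bwm$values[1, 1]), 0.5)
  expect_true(bwm$qc_pass[1, 1])

  # hemizygous window: BAFs {1, 0} -> mirrored {1, 1} -> 1
  d2 <- depth_table(c(0, 30), c(30, 0), pos = c(1000, 2000))
  bwm2 <- window_mirrored_baf(d2, min_snps_per_window = 2, min_cells = 1)
  expect_equal(unname(bwm2$values[1, 1]), 1)

  # below min_snps_per_window: qc_fail; zero covered SNPs: undefined
  d3 <- depth_table(15, 15, pos = 1000)
  bwm3 <- window_mirrored_baf(d3, min_snps_per_window = 2, min_cells = 1)
  expect_false(bwm3$qc_pass[1, 1])
  expect_true(all(is.na(bwm3$values[bwm3$n_snps == 0])))

  # mirrored BAF always within [0.5, 1]
  sim <- two_clone_cnv_sim(seed = 301)
  bwm4 <- window_mirrored_baf(sim$rc)
  expect_true(all(bwm4$values >= 0.5 & bwm4$values <= 1, na.rm = TRUE))
})

test_that("carrier cells show near-1 mirrored BAF across the deleted windows", {
  sim <- two_clone_cnv_sim(seed = 311)
  bwm <- window_mirrored_baf(sim$rc)
  region <- colnames(bwm$values)[bwm$windows$start >= sim$del[1] &
                                   bwm$windows$start < sim$del[2]]
  expect_gte(length(region), 55)
  vals <- bwm$values[sim$carriers, region]
  ok <- bwm$qc_pass[sim$carriers, region]
  expect_gt(mean(vals[ok] > 0.9), 0.99)
})

test_that("threshold calls are monotone and degenerate thresholds behave", {
  sim <- two_clone_cnv_sim(seed = 321)
  bwm <- window_mirrored_baf(sim$rc)
  expect_error(call_cnv_threshold(bwm, 0.4))
  calls_05 <- call_cnv_threshold(bwm, 0.5)
  qc_eligible <- bwm$qc_pass & matrix(bwm$eligible, nrow(bwm$qc_pass),
                                      ncol(bwm$qc_pass), byrow = TRUE)
  expect_equal(calls_05, qc_eligible)

  counts <- vapply(seq(0.5, 1, by = 0.05), function(th)
    sum(call_cnv_threshold(bwm, th)), 0)
  expect_true(all(diff(counts) <= 0))

  # noise-free balanced data at threshold 1: zero calls
  d <- depth_table(rep(15, 8), rep(15, 8), pos = seq(500, 4500, length.out = 8))
  clean <- window_mirrored_baf(d, min_cells = 1)
  expect_equal(sum(call_cnv_threshold(clean, 1)), 0)
})

test_that("ROC behaves at the extremes and rejects one-class truth", {
  sim <- two_clone_cnv_sim(seed = 331)
  bwm <- window_mirrored_baf(sim$rc)
  region <- colnames(bwm$values)[bwm$windows$start >= sim$del[1] &
                                   bwm$windows$start < sim$del[2]]
  roc <- roc_evaluate(bwm, sim$carriers, region_windows = region,
                      n_bootstrap = 20, seed = 1)
  expect_gte(roc$auc, 0.99)                 # perfectly separated classes
  expect_true(all(diff(roc$roc$fpr) <= 0))  # sweep is monotone
  expect_error(roc_evaluate(bwm, rownames(bwm$values)), "single class")
})

test_that("AUC is invariant to monotone transforms of window values", {
  sim <- two_clone_cnv_sim(seed = 341)
  bwm <- window_mirrored_baf(sim$rc)
  region <- colnames(bwm$values)[bwm$windows$start >= sim$del[1] &
                                   bwm$windows$start < sim$del[2]]
  dense <- seq(0.5, 1, by = 0.001)
  a1 <- roc_evaluate(bwm, sim$carriers, region, thresholds = dense,
                     n_bootstrap = 2, seed = 1)$auc
  bwm2 <- bwm
  bwm2$values <- 0.5 + ((bwm$values - 0.5) * 2)^2 / 2  # monotone on [0.5,1]
  a2 <- roc_evaluate(bwm2, sim$carriers, region, thresholds = dense,
                     n_bootstrap = 2, seed = 1)$auc
  expect_lt(abs(a1 - a2), 0.005)
})

test_that("wider windows improve the AUC on fixed noisy data", {
  sim <- two_clone_cnv_sim(seed = 351, profile = mda_profile())
  auc_at <- function(w) {
    bwm <- window_mirrored_baf(sim$rc, w = w)
    region <- colnames(bwm$values)[bwm$windows$start >= sim$del[1] &
                                     bwm$windows$start < sim$del[2]]
    roc_evaluate(bwm, sim$carriers, region, n_bootstrap = 2, seed = 1)$auc
  }
  expect_gte(auc_at(25000) + 0.005, auc_at(5000))
})
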