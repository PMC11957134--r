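test_that("the 96 categories follow the canonical pyrimidine convention", {
  ctx <- sbs96_contexts()
  expect_length(unique(ctx), 96)
  expect_equal(ctx[1], "A[C>A]A")
  expect_equal(ctx[96], "T[T>G]T")
  expect_true(all(substr(ctx, 3, 3) %in% c("C", "T")))
})

test_that("context counting reverse-complements purine references", {
  v <- data.frame(ref = "C", alt = "T", context = "ACA")
  M <- sbs96_matrix(v)
  expect_equal(unname(M["A[C>T]A", 1]), 1L)

  # G>A at T_T is the same event read from the other strand
  v2 <- data.frame(ref = "G", alt = "A", context = "TGT")
  M2 <- sbs96_matrix(v2)
  expect_equal(unname(M2["A[C>T]A", 1]), 1L)

  # conservation: column sums equal retained variant counts
  tr <- simulate_clone_tree(seed = 1)
  muts <- tr$mutations
  muts$sample <- rep(c("x", "y"), length.out = nrow(muts))
  M3 <- sbs96_matrix(muts)
  expect_equal(unname(colSums(M3)),
               as.vector(table(muts$sample)[colnames(M3)]))

  # ambiguous contexts are skipped with a message
  vN <- data.frame(ref = c("C", "C"), alt = c("T", "A"),
                   context = c("ANA", "ACA"))
  expect_message(MN <- sbs96_matrix(vN), "skipped")
  expect_equal(sum(MN), 1L)
})

test_that("NNLS fitting recovers exact mixtures and pure signatures", {
  P <- example_signature_catalog()
  mix <- 0.7 * P[, 1] + 0.3 * P[, 3]
  fit <- fit_signatures(cbind(s1 = mix), P)
  expect_lt(max(abs(fit$exposures[c(1, 3), 1] - c(0.7, 0.3))), 1e-6)
  expect_equal(unname(fit$cosine["s1"]), 1, tolerance = 1e-9)

  pure <- fit_signatures(cbind(s1 = P[, 2] * 500), P)
  expect_equal(unname(pure$exposures[2, 1]), 1, tolerance = 1e-9)

  zero <- fit_signatures(cbind(s1 = rep(0, 96)), P)
  expect_equal(zero$flags[["s1"]], "zero_counts")
  expect_true(all(zero$exposures == 0))
  expect_equal(cosine_similarity(P[, 1], P[, 1]), 1)
})

test_that("single-signature data is recovered at k = 1 and runs are reproducible", {
  P <- example_signature_catalog()
  set.seed(1)
  V <- matrix(rpois(96 * 6, as.vector(P[, 3] %o% runif(6, 2000, 6000))),
              96, 6)
  expect_warning(ex0 <- extract_de_novo(V[, 1:1, drop = FALSE], 1,
                                        n_restarts = 2, seed = 2), "overfit")
  ex <- extract_de_novo(V, 1, n_restarts = 3, seed = 2)
  expect_gte(cosine_similarity(ex$signatures[, 1], P[, 3]), 0.99)
  expect_identical(extract_de_novo(V, 2, n_restarts = 2, seed = 5),
                   extract_de_novo(V, 2, n_restarts = 2, seed = 5))
})

test_that("early/late contrast flags only genuine enrichment", {
  tr <- simulate_clone_tree(seed = 3)
  muts <- tr$mutations
  half <- seq_len(nrow(muts)) <= nrow(muts) / 2
  # identical class compositions: nothing significant
  same <- early_late_contrast(muts[half, ], muts[!half, ])
  expect_equal(sum(same$tests$significant), 0)

  # APOBEC-only early class: TpC C>T / C>G categories enriched
  ctx <- sbs96_contexts()
  apo_idx <- which(substr(ctx, 1, 1) == "T" &
                     substr(ctx, 3, 5) %in% c("C>T", "C>G"))
  apo_prob <- setNames(rep(0, 96), ctx)
  apo_prob[apo_idx] <- 1 / length(apo_idx)
  early <- simulate_clone_tree(seed = 4,
                               context_distribution = apo_prob)$mutations
  late <- muts
  con <- early_late_contrast(early, late)
  sig_apo <- con$tests$significant[apo_idx]
  expect_gt(mean(sig_apo), 0.5)
  enriched <- con$tests$shared_frac[apo_idx] > con$tests$private_frac[apo_idx]
  expect_true(all(enriched[con$tests$significant[apo_idx]]))

  # one variant per class: underpowered flag
  tiny <- early_late_contrast(muts[1, , drop = FALSE],
                              muts[2, , drop = FALSE])
  expect_equal(tiny$flag, "underpowered")
  expect_error(early_late_contrast(muts[0, ], muts), "non-empty")
})
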