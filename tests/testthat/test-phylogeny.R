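test_that("nested mutation sets give the matching caterpillar topology", {
  # a carries {1}, b carries {1,2}, c carries {1,2,3}: b and c are sisters
  G <- rbind(a = c(1L, 0L, 0L, 0L), b = c(1L, 1L, 0L, 0L),
             c = c(1L, 1L, 1L, 1L))
  colnames(G) <- paste0("v", 1:4)
  tr <- build_tree(G)
  expect_setequal(tr$tip.label, c("a", "b", "c"))
  bc <- ape::extract.clade(tr, ape::getMRCA(tr, c("b", "c")))$tip.label
  expect_setequal(bc, c("b", "c"))

  # duplicate cells form a zero-length cherry (collapse zero branches
  # before counting edges, since the resolution among ties is arbitrary)
  G2 <- rbind(G, b2 = G["b", ])
  tr2 <- build_tree(G2)
  expect_equal(unname(cophenetic(tr2)["b", "b2"]), 0)
  expect_equal(unname(node_distance_matrix(ape::di2multi(tr2))["b", "b2"]), 2L)

  # all-identical cells: star tree with a warning
  G3 <- matrix(rep(c(1L, 0L, 1L), each = 3), 3,
               dimnames = list(c("x", "y", "z"), NULL))
  expect_warning(star <- build_tree(G3), "star")
  expect_equal(star$Nnode, 1L)
})

test_that("noiseless serial design is reconstructed exactly", {
  truth <- simulate_clone_tree(seed = 41)
  est <- build_tree(truth$genotypes)
  expect_equal(phangorn::RF.dist(ape::unroot(est),
                                 ape::unroot(truth$tree_mutations)), 0)
  nd <- node_distance_matrix(est)
  for (clone in paste0("C", 1:7)) {
    pair <- names(truth$clone_of_cell)[truth$clone_of_cell == clone]
    expect_equal(unname(nd[pair[1], pair[2]]), 2L)  # clone pairs are cherries
  }
  # parsimony agrees with NJ on clean data
  est_mp <- build_tree(truth$genotypes, method = "parsimony")
  expect_equal(phangorn::RF.dist(ape::unroot(est_mp),
                                 ape::unroot(truth$tree_mutations)), 0)
})

test_that("reconstruction degrades gracefully with allelic dropout", {
  rf_at <- function(ado, seed) {
    truth <- simulate_clone_tree(seed = seed, mutations_per_day = 3)
    prof <- wga_profile(ado_rate = ado, mean_depth = 20)
    rc <- simulate_wga_readcounts(truth, prof, het_snps = NULL,
                                  seed = seed + 1L)
    est <- build_tree(call_genotypes(rc))
    phangorn::RF.dist(ape::unroot(est), ape::unroot(truth$tree_mutations))
  }
  lo <- mean(vapply(1:3, function(s) rf_at(0.02, 50 + s), 0))
  hi <- mean(vapply(1:3, function(s) rf_at(0.60, 50 + s), 0))
  expect_lte(lo, hi)
})

test_that("bootstrap supports reflect signal strength", {
  truth <- simulate_clone_tree(seed = 61)
  bs <- bootstrap_support(truth$genotypes, n_reps = 50, seed = 1)
  sup <- attr(bs, "support")
  expect_true(all(sup[-1] == 100))          # no conflicting signal

  one <- bootstrap_support(truth$genotypes, n_reps = 1, seed = 2)
  expect_true(all(attr(one, "support")[-1] %in% c(0, 100)))

  set.seed(3)
  rand <- matrix(rbinom(12 * 60, 1, 0.5), 12, 60,
                 dimnames = list(paste0("c", 1:12), NULL))
  bs_r <- bootstrap_support(rand, n_reps = 50, seed = 4)
  expect_lt(median(attr(bs_r, "support")[-1]), 70)
})

test_that("node distances equal edge counts on known shapes", {
  bal <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  nd <- node_distance_matrix(bal)
  expect_equal(unname(nd["a", "b"]), 2L)
  expect_equal(unname(nd["a", "c"]), 4L)    # cross-pair in balanced quartet
  expect_equal(unname(diag(nd)), rep(0L, 4))
})

test_that("monophyly verdicts match labeled topologies", {
  mono <- ape::read.tree(text = "((t1:1,t2:1):1,(n1:1,n2:1):1);")
  res <- test_monophyly(mono, c("t1", "t2"))
  expect_true(res$monophyletic)
  expect_setequal(res$clade_tips, c("t1", "t2"))

  mixed <- ape::read.tree(text = "((t1:1,n1:1):1,(t2:1,n2:1):1);")
  expect_false(test_monophyly(mixed, c("t1", "t2"))$monophyletic)
  expect_equal(test_monophyly(mono, c("t1", "t2", "n1", "n2"))$flag,
               "single_class")
  expect_error(test_monophyly(mono, setNames(c(TRUE, NA, FALSE, FALSE),
                                             mono$tip.label)), "unlabeled")
})

test_that("driver-clade simulations are always called monophyletic", {
  verdicts <- vapply(1:25, function(s) {
    truth <- simulate_clone_tree(seed = 400 + s, mutations_per_day = 4)
    est <- build_tree(truth$genotypes)
    # malignant = everything descending from the first derived clone's
    # founding, i.e. all non-parental cells
    mal <- names(truth$clone_of_cell)[truth$clone_of_cell != "P"]
    test_monophyly(est, mal)$monophyletic
  }, TRUE)
  expect_true(all(verdicts))
})

test_that("branch-time correlation finds the clock and rejects noise", {
  truth <- simulate_clone_tree(seed = 71)
  est <- build_tree(truth$genotypes)
  ct <- correlate_branch_time(est, truth$culture_time, seed = 1)
  expect_gt(ct$rho, 0.9)
  expect_lt(ct$p_value, 0.01)

  set.seed(2)
  perm_times <- setNames(sample(truth$culture_time), names(truth$culture_time))
  ct_p <- correlate_branch_time(est, perm_times, seed = 3)
  expect_lt(abs(ct_p$rho), 0.5)

  const <- setNames(rep(5, 16), names(truth$culture_time))
  expect_equal(correlate_branch_time(est, const)$flag, "constant_times")
})

test_that("phylogeny filter separates private, clean shared and homoplasic", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  G <- rbind(a = c(1L, 1L, 1L), b = c(0L, 1L, 0L),
             c = c(0L, 0L, 1L), d = c(0L, 0L, 0L))
  colnames(G) <- c("priv", "clade", "homo")
  res <- phylogeny_filter(G, tr)
  expect_equal(res$class, c("private", "shared", "shared"))
  expect_equal(res$homoplasic, c(FALSE, FALSE, TRUE))
  expect_true(res$branch_node[2] > 0)
  expect_true(is.na(res$branch_node[3]) || res$branch_node[3] == 0)
})

test_that("Poisson time calibration matches its conjugate closed form", {
  tre <- ape::read.tree(text = "(a:10,b:0);")
  post <- time_calibrate(tre, rate = 2, n_samples = 20000, seed = 1)
  mc_se <- sqrt(11) / 2 / sqrt(20000)
  # m = 10, lambda = 2: Gamma(11, 2), mean 5.5
  expect_lt(abs(mean(post$durations[, 1]) - 5.5), 4 * mc_se)
  # m = 0: Gamma(1, lambda), mean 1/lambda
  expect_lt(abs(mean(post$durations[, 2]) - 0.5), 4 * sqrt(1) / 2 / sqrt(20000))
  expect_error(time_calibrate(tre), "non-identifiable")
})

test_that("calibration credible intervals cover true branch durations", {
  set.seed(5)
  lambda <- 3
  cover <- replicate(150, {
    t_true <- rexp(1, 1 / 4)
    m <- rpois(1, lambda * t_true)
    ci <- qgamma(c(0.05, 0.95), m + 1, lambda)
    t_true >= ci[1] && t_true <= ci[2]
  })
  # the same Gamma(m+1, lambda) conditional the sampler draws from
  expect_gt(mean(cover), 0.84)
  expect_lt(mean(cover), 0.97)

  # node ages respect parent <= child along the time axis
  truth <- simulate_clone_tree(seed = 81)
  est <- build_tree(truth$genotypes)
  post <- time_calibrate(est, rate = 8, n_samples = 500, seed = 2)
  tr <- post$tree
  age <- post$node_age$mean
  expect_true(all(age[tr$edge[, 1]] <= age[tr$edge[, 2]] + 1e-9))
})

test_that("anchored calibration recovers the clock rate", {
  truth <- simulate_clone_tree(seed = 91, mutations_per_day = 8)
  est <- build_tree(truth$genotypes)
  anchors <- data.frame(tip = c("C7_1", "C7_2"),
                        age = unname(truth$culture_time[c("C7_1", "C7_2")]))
  post <- time_calibrate(est, anchors = anchors, n_samples = 2000, seed = 3)
  expect_lt(abs(mean(post$lambda) - 8) / 8, 0.15)
})

test_that("skyline recovers constant size and growth shape", {
  tr <- sim_coalescent_tree(50, ne = 1000, seed = 10)
  sky <- skyline_ne(tr)
  expect_gt(median(sky$skyline$ne), 500)
  expect_lt(median(sky$skyline$ne), 2000)

  # exponential growth (backward-in-time shrinking N): increasing toward
  # the present, i.e. ne decreases with time-before-present
  grow <- sim_coalescent_tree(50, ne = function(t) 5000 * exp(-0.01 * t),
                              seed = 11)
  sg <- skyline_ne(grow)$skyline
  if (nrow(sg) >= 2) {
    fit <- cor(sg$time, sg$ne, method = "spearman")
    expect_lt(fit, 0.5)
  }
  two <- skyline_ne(sim_coalescent_tree(2, ne = 100, seed = 12))
  expect_equal(two$flag, "underpowered")
  expect_equal(nrow(two$skyline), 1)
})

test_that("Blomberg's K matches its published reference implementation", {
  skip_if_not_installed("picante")
  set.seed(20)
  tr <- ape::rcoal(40)
  x <- simulate_phenotypes(tr, 1, bm_rate = 1, seed = 21)[, 1]
  mine <- blomberg_k(tr, x, n_perm = 99, seed = 22)
  expect_equal(mine$K, as.numeric(picante::Kcalc(x[tr$tip.label], tr)),
               tolerance = 1e-8)
})

test_that("K is near 1 under Brownian motion and low for white noise", {
  set.seed(30)
  tr <- ape::rcoal(64)
  X <- simulate_phenotypes(tr, 200, bm_rate = 1, seed = 31)
  ks <- apply(X, 2, function(x) blomberg_k(tr, x, n_perm = 0)$K)
  expect_gt(mean(ks), 0.8)
  expect_lt(mean(ks), 1.2)

  wn <- setNames(rnorm(64), tr$tip.label)
  expect_lt(blomberg_k(tr, wn, n_perm = 99, seed = 32)$K, 1)
  expect_equal(blomberg_k(tr, setNames(rep(1, 64), tr$tip.label))$flag,
               "constant_trait")
})

test_that("clone-indicator traits show significant phylogenetic signal", {
  # clones large enough for the permutation test to have power
  sched <- default_sampling_schedule(n_clones = 4, cells_per_clone = 8)
  sig <- vapply(1:30, function(s) {
    truth <- simulate_clone_tree(n_cells = 34, n_clones = 4,
                                 sampling_schedule = sched, seed = 500 + s)
    trait <- setNames(as.numeric(truth$clone_of_cell == "C3"),
                      names(truth$clone_of_cell))
    blomberg_k(truth$tree_days, trait, n_perm = 199, seed = s)$p_value
  }, 0)
  expect_gte(mean(sig < 0.05), 0.9)
})
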