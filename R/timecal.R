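#' Poisson-branch time calibration of a mutation-scaled phylogeny
#'
#' Models each branch's mutation count as `m ~ Poisson(lambda * t)` with a
#' shared clock rate `lambda` (mutations per year) and per-branch duration
#' `t` in years.  Under a flat prior on durations, `t | lambda, m` is
#' conjugate `Gamma(m + 1, lambda)`, so a branch with zero mutations still
#' has positive expected duration `1/lambda`.  The rate is identified
#' either by fixing it, by a proper Gamma prior, or by anchor tips of
#' known age: for an anchor tip with root-to-tip count `M` and age `A`,
#' `M ~ Poisson(lambda * A)` gives `lambda | anchors ~
#' Gamma(a0 + sum M, b0 + sum A)` (anchor paths are treated as
#' independent, which is exact when anchors share only the root, as for
#' premalignant cells each descending from a distinct stem cell).  Anchor
#' ages may be intervals (e.g. a stem-cell origin in the first year of
#' life), sampled uniformly per draw.
#'
#' @param tree rooted `phylo` with branch lengths in mutation counts
#'   (rounded to integers internally).
#' @param rate fixed clock rate (mutations/year), or NULL.
#' @param rate_prior c(shape, rate) of a proper Gamma prior on lambda used
#'   when no anchors are given, or NULL.
#' @param anchors data.frame with `tip` and either `age` or
#'   `age_min`/`age_max` (years from root to that tip).
#' @param a0,b0 Gamma hyperprior on lambda when anchors are used.
#' @param n_samples posterior draws (default 2000).
#' @param seed integer seed.
#' @return object of class `time_tree_posterior`: list with `tree`,
#'   `m` (per-edge counts), `lambda` (draws), `durations` (draws x edges,
#'   years), `node_age` (summary data.frame, years from root),
#'   `mean_tree` (`phylo` with edge lengths = posterior mean years).
#' @export
time_calibrate <- function(tree, rate = NULL, rate_prior = NULL,
                           anchors = NULL, a0 = 1, b0 = 1e-6,
                           n_samples = 2000L, seed = NULL) {
  tree <- ape::reorder.phylo(tree, "cladewise")  # parents precede children
  m <- round(tree$edge.length)
  if (any(m < 0)) stop("negative branch lengths")
  n_edge <- length(m)
  if (is.null(rate) && is.null(anchors) && is.null(rate_prior))
    stop("non-identifiable: supply a fixed rate, a proper rate_prior, ",
         "or anchor tips of known age")

  with_seed(seed, {
    if (!is.null(rate)) {
      stopifnot(rate > 0)
      lambda <- rep(rate, n_samples)
    } else if (!is.null(anchors)) {
      stopifnot("tip" %in% names(anchors),
                all(anchors$tip %in% tree$tip.label))
      depth_m <- ape::node.depth.edgelength(
        `[[<-`(tree, "edge.length", as.numeric(m)))
      M <- depth_m[match(anchors$tip, tree$tip.label)]
      age_draw <- function() {
        if ("age" %in% names(anchors)) return(anchors$age)
        runif(nrow(anchors), anchors$age_min, anchors$age_max)
      }
      lambda <- vapply(seq_len(n_samples), function(s) {
        A <- age_draw()
        rgamma(1, a0 + sum(M), b0 + sum(A))
      }, 0)
    } else {
      stopifnot(length(rate_prior) == 2, all(rate_prior > 0))
      lambda <- rgamma(n_samples, rate_prior[1], rate_prior[2])
    }

    durations <- matrix(rgamma(n_samples * n_edge,
                               shape = rep(m + 1, each = n_samples),
                               rate = rep(lambda, times = n_edge)),
                        nrow = n_samples)

    # node ages (years from root) per draw: cumulative durations root->node
    n_tip <- length(tree$tip.label)
    n_node <- max(tree$edge)
    ages <- matrix(0, n_samples, n_node)
    for (e in seq_len(n_edge)) {
      par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
      ages[, child] <- ages[, par] + durations[, e]
    }
    node_age <- data.frame(
      node = seq_len(n_node),
      is_tip = seq_len(n_node) <= n_tip,
      label = c(tree$tip.label, rep(NA, n_node - n_tip)),
      mean = colMeans(ages),
      lo90 = apply(ages, 2, quantile, 0.05),
      hi90 = apply(ages, 2, quantile, 0.95),
      stringsAsFactors = FALSE
    )
    mean_tree <- tree
    mean_tree$edge.length <- colMeans(durations)

    structure(list(tree = tree, m = m, lambda = lambda,
                   durations = durations, node_age = node_age,
                   mean_tree = mean_tree),
              class = "time_tree_posterior")
  })
}

#' @export
print.time_tree_posterior <- function(x, ...) {
  cat("time_tree_posterior:", ncol(x$durations), "branches,",
      nrow(x$durations), "draws; lambda mean",
      signif(mean(x$lambda), 4), "mutations/year\n")
  invisible(x)
}

#' Extract posterior time-tree samples
#' @param posterior a `time_tree_posterior`.
#' @param k number of trees (default 100, evenly spaced draws).
#' @return list of `phylo` with edge lengths in years.
#' @export
time_tree_samples <- function(posterior, k = 100L) {
  idx <- unique(round(seq(1, nrow(posterior$durations), length.out = k)))
  lapply(idx, function(i) {
    tr <- posterior$tree
    tr$edge.length <- posterior$durations[i, ]
    tr
  })
}

#' Force a time tree to be ultrametric by adjusting terminal branches
#'
#' Terminal branch durations are extended (or shrunk, never below zero)
#' so every tip sits at the maximum root-to-tip depth — appropriate when
#' all cells were sampled at the same real time and depth differences
#' reflect duration-estimate noise.
#'
#' @param tree `phylo` with branch lengths in time units.
#' @return ultrametric `phylo`.
#' @export
make_ultrametric <- function(tree) {
  n_tip <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  target <- max(depth[seq_len(n_tip)])
  term <- match(seq_len(n_tip), tree$edge[, 2])
  adj <- target - depth[seq_len(n_tip)]
  tree$edge.length[term] <- pmax(tree$edge.length[term] + adj, 0)
  tree
}

#' Generalized-skyline effective population size through time
#'
#' Classic generalized skyline on the coalescent intervals of an
#' ultrametric time tree: within an interval with `k` lineages and pooled
#' length `dt` containing one coalescent event the estimate is
#' `k (k - 1) dt / 2`; adjacent small intervals are pooled with the
#' epsilon smoothing parameter, selected by small-sample AIC over a grid
#' when not supplied.  A credible band can be formed by applying the
#' estimator across posterior time-tree samples.
#'
#' @param time_tree ultrametric `phylo` in time units (polytomies are
#'   resolved with zero-length branches; non-ultrametric input is aligned
#'   with [make_ultrametric()] and noted).
#' @param epsilon pooling parameter; NULL selects it by AICc.
#' @param posterior_trees optional list of `phylo` (e.g.
#'   [time_tree_samples()]) for an uncertainty band.
#' @param probs band quantiles (default 2.5% and 97.5%).
#' @return list with `skyline` (data.frame `time` before present, `ne`),
#'   `epsilon`, `flag`, and when posterior trees are given `band`
#'   (data.frame `time`, `lo`, `med`, `hi`).
#' @export
skyline_ne <- function(time_tree, epsilon = NULL, posterior_trees = NULL,
                       probs = c(0.025, 0.975)) {
  prep <- function(tr) {
    if (!ape::is.binary(tr)) tr <- ape::multi2di(tr)
    if (!ape::is.ultrametric(tr, tol = 1e-6)) tr <- make_ultrametric(tr)
    tr
  }
  tr <- prep(time_tree)
  flag <- if (length(tr$tip.label) < 5) "underpowered" else NA_character_
  if (length(tr$tip.label) == 2) {
    # single coalescent interval: N-hat = k(k-1) dt / 2 with k = 2
    dt <- max(ape::node.depth.edgelength(tr))
    return(list(skyline = data.frame(time = dt, ne = dt),
                epsilon = 0, flag = "underpowered"))
  }
  ci <- ape::coalescent.intervals(tr)

  pick_eps <- function(ci) {
    cand <- unique(c(0, quantile(ci$interval.length,
                                 c(.1, .25, .5, .75, .9, 1)) ,
                     sum(ci$interval.length)))
    cand <- sort(unique(pmax(cand, 0)))
    aicc <- vapply(cand, function(eps) {
      sk <- tryCatch(ape::skyline(ci, epsilon = eps), error = function(e) NULL)
      if (is.null(sk)) return(Inf)
      K <- sk$parameter.count
      n <- ci$interval.count
      if (n - K - 1 <= 0) return(Inf)
      -2 * sk$logL + 2 * K + 2 * K * (K + 1) / (n - K - 1)
    }, 0)
    cand[which.min(aicc)]
  }
  if (is.null(epsilon)) epsilon <- pick_eps(ci)
  sk <- ape::skyline(ci, epsilon = epsilon)
  skyline_df <- data.frame(time = sk$time, ne = sk$population.size)

  out <- list(skyline = skyline_df, epsilon = epsilon, flag = flag)
  if (!is.null(posterior_trees)) {
    grid <- seq(0, max(skyline_df$time), length.out = 50)
    step_at <- function(df, t) {
      idx <- findInterval(t, c(0, df$time), rightmost.closed = TRUE)
      df$ne[pmin(pmax(idx, 1), nrow(df))]
    }
    mats <- vapply(posterior_trees, function(ptr) {
      ptr <- prep(ptr)
      pci <- ape::coalescent.intervals(ptr)
      psk <- ape::skyline(pci, epsilon = epsilon)
      step_at(data.frame(time = psk$time, ne = psk$population.size), grid)
    }, numeric(length(grid)))
    out$band <- data.frame(
      time = grid,
      lo = apply(mats, 1, quantile, probs[1]),
      med = apply(mats, 1, median),
      hi = apply(mats, 1, quantile, probs[2])
    )
  }
  out
}
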