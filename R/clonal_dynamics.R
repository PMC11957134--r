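#' Wright-Fisher forward simulation of a selected clone
#'
#' A clone seeded as a single cell at generation `t0` evolves by binomial
#' resampling with selection: given frequency `p`, the next generation's
#' expected frequency is `p (1 + s) / (1 + p s)` and the realized count is
#' Binomial(N, p').  Extinction simply ends the trajectory at zero.
#'
#' @param generations_total number of generations simulated.
#' @param N population size per generation: scalar or vector of length
#'   `generations_total` (integer >= 1).
#' @param s selection coefficient (>= -1).
#' @param t0 onset generation (1-based, <= generations_total).
#' @param p0 initial clone frequency at onset; default a single cell,
#'   `1 / N(t0)`.
#' @param seed integer seed.
#' @return numeric vector of clone frequencies per generation (length
#'   `generations_total`), zero before onset.
#' @export
wf_simulate <- function(generations_total, N = 1000L, s = 0, t0 = 1L,
                        p0 = NULL, seed = NULL) {
  stopifnot(generations_total >= 1, s >= -1, t0 >= 1,
            t0 <= generations_total, all(N >= 1))
  N <- as.integer(if (length(N) == 1) rep(N, generations_total) else N)
  stopifnot(length(N) == generations_total)
  if (!is.null(p0)) stopifnot(p0 >= 0, p0 <= 1)
  with_seed(seed, {
    freq <- numeric(generations_total)
    p <- p0 %||% (1 / N[t0])
    freq[t0] <- p
    if (t0 < generations_total) {
      for (g in (t0 + 1L):generations_total) {
        if (p <= 0) break
        if (p >= 1) { freq[g] <- 1; p <- 1; next }
        p_sel <- p * (1 + s) / (1 + p * s)
        p <- rbinom(1, N[g], p_sel) / N[g]
        freq[g] <- p
      }
    }
    freq
  })
}

#' Simulate a coalescent tree under an arbitrary population-size history
#'
#' Discrete-generation Kingman coalescent run backwards in time: with `k`
#' active lineages and haploid size `N(t)` at `t` generations before
#' sampling, a coalescence occurs with probability `choose(k, 2) / N(t)`
#' per generation (at most one per generation; valid for `k^2 << N`).
#'
#' @param n_tips number of sampled lineages.
#' @param ne haploid effective size: scalar, vector indexed by generation
#'   before present, or function(t) -> N.
#' @param gen_time years (or any time unit) per generation; branch
#'   lengths are reported in this unit.
#' @param max_generations safety cap; remaining lineages are forced to
#'   coalesce there.
#' @param seed integer seed.
#' @return ultrametric `phylo`.
#' @export
sim_coalescent_tree <- function(n_tips, ne = 1000, gen_time = 1,
                                max_generations = 1e6, seed = NULL) {
  stopifnot(n_tips >= 2)
  ne_at <- if (is.function(ne)) ne
  else if (length(ne) == 1) function(t) ne
  else function(t) ne[min(length(ne), max(1L, ceiling(t)))]

  with_seed(seed, {
    labels <- paste0("t", seq_len(n_tips))
    nodes <- as.list(labels)
    heights <- numeric(n_tips)
    t <- 0
    while (length(nodes) > 1) {
      k <- length(nodes)
      rate <- k * (k - 1) / 2 / max(ne_at(t), 1)
      t <- t + max(1, rgeom(1, min(rate, 0.99)) + 1)
      if (t >= max_generations) t <- max_generations
      pair <- sample(k, 2)
      h <- t * gen_time
      merged <- sprintf("(%s:%g,%s:%g)",
                        nodes[[pair[1]]], h - heights[pair[1]],
                        nodes[[pair[2]]], h - heights[pair[2]])
      nodes[[pair[1]]] <- merged
      heights[pair[1]] <- h
      nodes <- nodes[-pair[2]]
      heights <- heights[-pair[2]]
      if (t >= max_generations && length(nodes) > 1) {
        # force the remainder together at the cap
        while (length(nodes) > 1) {
          merged <- sprintf("(%s:%g,%s:%g)", nodes[[1]], h - heights[1],
                            nodes[[2]], h - heights[2])
          nodes[[1]] <- merged; heights[1] <- h
          nodes <- nodes[-2]; heights <- heights[-2]
        }
      }
    }
    ape::read.tree(text = paste0(nodes[[1]], ";"))
  })
}

#' Phylogeny-derived summary statistics for one clone
#'
#' Returns the summaries used for clone-dynamics inference: the clone's
#' tip fraction at each timepoint, the age of the clone's most recent
#' common ancestor (time before sampling), and the mean pairwise
#' coalescent time within the clone.
#'
#' @param time_tree ultrametric-in-time `phylo` (tip-to-root depths equal).
#' @param clone_tips character vector of the clone's tip labels.
#' @param timepoint_of optional named vector tip -> timepoint label; NULL
#'   treats all tips as one timepoint.
#' @return named numeric vector: `frac_<timepoint>`, `mrca_age`,
#'   `mean_pair_coal`; singleton clones get `mrca_age = 0` and NA pair
#'   time with attribute `flag = "singleton"`.
#' @export
tree_summaries <- function(time_tree, clone_tips, timepoint_of = NULL) {
  tips <- time_tree$tip.label
  if (!all(clone_tips %in% tips)) stop("clone tips absent from tree")
  if (length(clone_tips) == 0) stop("clone has no tips")
  tp <- timepoint_of %||% setNames(rep("s1", length(tips)), tips)
  fracs <- vapply(split(tips, tp[tips]), function(g)
    mean(g %in% clone_tips), 0)
  names(fracs) <- paste0("frac_", names(fracs))

  if (length(clone_tips) == 1) {
    out <- c(fracs, mrca_age = 0, mean_pair_coal = NA_real_)
    attr(out, "flag") <- "singleton"
    return(out)
  }
  depth <- ape::node.depth.edgelength(time_tree)
  total <- max(depth[seq_along(tips)])
  mrca <- ape::getMRCA(time_tree, clone_tips)
  mrca_age <- total - depth[mrca]
  D <- cophenetic(time_tree)[clone_tips, clone_tips]
  mean_pair <- mean(D[upper.tri(D)]) / 2  # patristic distance = 2x coal time
  c(fracs, mrca_age = mrca_age, mean_pair_coal = mean_pair)
}

#' Forward-then-backward simulation of clone summaries
#'
#' The generative model behind [abc_infer()]: a Wright-Fisher trajectory
#' for the clone ([wf_simulate()]), binomial sampling of how many of the
#' `n_tips` sampled cells fall in the clone, and a backward coalescent of
#' those cells inside the clone (size `freq(t) * N(t)`), forced to the
#' clone's founding at `t0`.  Times are reported in generations before
#' sampling scaled by `gen_time`.
#'
#' @param t0 onset generation.
#' @param s selection coefficient.
#' @param model list with `generations_total`, `N`, `n_tips`, `gen_time`.
#' @return named vector `frac_s1`, `mrca_age`, `mean_pair_coal` (zeros
#'   when the clone is extinct or unsampled).
#' @export
abc_simulate_summaries <- function(t0, s, model) {
  gt <- model$generations_total
  freq <- wf_simulate(gt, N = model$N, s = s, t0 = round(t0))
  n_tips <- model$n_tips
  k <- rbinom(1, n_tips, freq[gt])
  if (k < 1) return(c(frac_s1 = 0, mrca_age = 0, mean_pair_coal = 0))
  if (k == 1) return(c(frac_s1 = 1 / n_tips, mrca_age = 0, mean_pair_coal = 0))

  N <- as.integer(if (length(model$N) == 1) rep(model$N, gt) else model$N)
  back <- gt:round(t0)                    # generation index, present -> onset
  clone_n <- pmax(freq[back] * N[back], 1)
  lineages <- k
  coal_gen <- numeric(0)                  # generations before present
  for (i in seq_along(back)) {
    if (lineages <= 1) break
    pr <- min(lineages * (lineages - 1) / 2 / clone_n[i], 1)
    if (runif(1) < pr) {
      coal_gen <- c(coal_gen, i)
      lineages <- lineages - 1
    }
  }
  if (lineages > 1) {                     # force coalescence at founding
    coal_gen <- c(coal_gen, rep(length(back), lineages - 1))
    lineages <- 1
  }
  # pairwise coalescent times from the merge sequence (random joins)
  sizes <- rep(1, k)
  pair_sum <- 0
  for (g in coal_gen) {
    pick <- sample(length(sizes), 2)
    pair_sum <- pair_sum + sizes[pick[1]] * sizes[pick[2]] * g
    sizes[pick[1]] <- sizes[pick[1]] + sizes[pick[2]]
    sizes <- sizes[-pick[2]]
  }
  gen_time <- model$gen_time %||% 1
  c(frac_s1 = k / n_tips,
    mrca_age = max(coal_gen) * gen_time,
    mean_pair_coal = pair_sum / choose(k, 2) * gen_time)
}

#' Rejection-ABC inference of clone onset time and selection
#'
#' Draws `(t0, s)` from uniform priors, simulates summaries with
#' [abc_simulate_summaries()], and keeps the draws whose Euclidean
#' distance to the observed summaries (each summary standardized by its
#' median absolute deviation across simulations) falls inside the
#' `tolerance_quantile` of distances.
#'
#' @param observed_summaries named vector as from [tree_summaries()] /
#'   [abc_simulate_summaries()] (`frac_s1`, `mrca_age`, `mean_pair_coal`).
#' @param priors list with `t0 = c(min, max)` (generations) and
#'   `s = c(min, max)`.
#' @param model list passed to [abc_simulate_summaries()].
#' @param n_sims prior draws (>= 1000 recommended).
#' @param tolerance_quantile accepted fraction (default 0.1).
#' @param seed integer seed.
#' @return object of class `clone_trajectory_posterior`: list with
#'   `accepted` (data.frame t0, s, distance), `tolerance`, `n_sims`,
#'   `priors`, `acceptance_fraction`.
#' @export
abc_infer <- function(observed_summaries, priors, model,
                      n_sims = 2000L, tolerance_quantile = 0.1,
                      seed = NULL) {
  stopifnot(all(c("t0", "s") %in% names(priors)), n_sims >= 1)
  with_seed(seed, {
    t0_draw <- runif(n_sims, priors$t0[1], priors$t0[2])
    s_draw <- runif(n_sims, priors$s[1], priors$s[2])
    sims <- t(vapply(seq_len(n_sims), function(i)
      abc_simulate_summaries(t0_draw[i], s_draw[i], model),
      numeric(length(observed_summaries))))

    scale <- apply(sims, 2, function(x) {
      s <- stats::mad(x)
      if (s == 0) s <- sd(x)
      if (is.na(s) || s == 0) s <- 1
      s
    })
    obs <- as.numeric(observed_summaries[colnames(sims) %||%
                                           names(observed_summaries)])
    d <- sqrt(colSums((t(sims) / scale - obs / scale)^2))
    tol <- quantile(d, tolerance_quantile)
    keep <- d <= tol
    if (!any(keep))
      stop("zero acceptances: increase tolerance_quantile or n_sims")
    structure(list(
      accepted = data.frame(t0 = t0_draw[keep], s = s_draw[keep],
                            distance = d[keep]),
      tolerance = unname(tol), n_sims = n_sims, priors = priors,
      acceptance_fraction = mean(keep)
    ), class = "clone_trajectory_posterior")
  })
}

#' @export
print.clone_trajectory_posterior <- function(x, ...) {
  cat("clone_trajectory_posterior:", nrow(x$accepted), "accepted of",
      x$n_sims, "draws (tolerance", signif(x$tolerance, 3), ")\n")
  cat("  t0: mean", signif(mean(x$accepted$t0), 4),
      " s: mean", signif(mean(x$accepted$s), 4), "\n")
  invisible(x)
}
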