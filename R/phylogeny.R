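#' Pairwise genotype distances with pairwise deletion of missing entries
#'
#' For two cells, only sites genotyped in both (co-covered) are compared.
#' `"count"` scales the number of discordant mutations up to the full site
#' set (`mismatches * n_sites / n_cocovered`), an additive tree metric on
#' noiseless data with branch lengths in expected mutation counts;
#' `"jaccard"` is `1 - shared/union` over co-covered sites.
#'
#' @param genotypes cells x sites matrix with entries 0, 1, NA.
#' @param type "count" (default) or "jaccard".
#' @return dist-convertible symmetric matrix.
#' @export
genotype_distance <- function(genotypes, type = c("count", "jaccard")) {
  type <- match.arg(type)
  G <- genotypes
  obs <- !is.na(G)
  X <- G; X[!obs] <- 0L
  X <- matrix(as.numeric(X), nrow(G), dimnames = dimnames(G))
  O <- matrix(as.numeric(obs), nrow(G), dimnames = dimnames(G))
  shared <- X %*% t(X)
  cocov <- O %*% t(O)
  ones_vs_obs <- X %*% t(O)
  union <- ones_vs_obs + t(ones_vs_obs) - shared
  if (type == "jaccard") {
    D <- 1 - shared / union
    D[union == 0] <- 0
  } else {
    D <- (union - shared) * ncol(G) / cocov
    D[cocov == 0] <- NA
  }
  diag(D) <- 0
  D
}

#' Reconstruct a rooted cell phylogeny from a genotype matrix
#'
#' Default method: neighbor-joining on the pairwise mutation-sharing
#' distance (see [genotype_distance()]), with branch lengths refit by
#' non-negative least squares so they read as expected mutation counts,
#' rooted on an outgroup (a supplied normal cell, or an all-reference
#' pseudo-cell appended internally and removed after rooting).  A
#' maximum-parsimony alternative is available.
#'
#' @param genotypes cells x sites 0/1/NA matrix (>= 3 cells).
#' @param method "nj" (default) or "parsimony".
#' @param outgroup name of a row to root on, or NULL to use an appended
#'   all-reference pseudo-cell.
#' @return rooted `phylo` with branch lengths in expected mutation counts.
#'   All-identical cells yield a star tree with a warning.
#' @export
build_tree <- function(genotypes, method = c("nj", "parsimony"),
                       outgroup = NULL) {
  method <- match.arg(method)
  G <- genotypes
  stopifnot(nrow(G) >= 3)
  if (is.null(rownames(G))) rownames(G) <- paste0("cell", seq_len(nrow(G)))
  og <- outgroup
  if (is.null(og)) {
    og <- ".outgroup"
    G <- rbind(G, matrix(0L, 1, ncol(G), dimnames = list(og, colnames(G))))
  } else stopifnot(og %in% rownames(G))

  D_in <- genotype_distance(genotypes, "count")
  if (!anyNA(D_in) && max(D_in) == 0) {
    warning("all cells genotypically identical: returning a star tree")
    nwk <- paste0("(", paste(paste0(rownames(genotypes) %||%
                                      paste0("cell", seq_len(nrow(genotypes))),
                                    ":0"), collapse = ","), ");")
    return(ape::read.tree(text = nwk))
  }
  if (method == "nj") {
    D <- genotype_distance(G, "count")
    if (anyNA(D)) stop("some cell pairs share no co-covered sites")
    tree <- ape::nj(as.dist(D))
    tree <- phangorn::nnls.tree(as.dist(D), tree, method = "unrooted")
  } else {
    chr <- matrix(as.character(G), nrow(G), dimnames = dimnames(G))
    chr[is.na(chr)] <- "?"
    dat <- phangorn::phyDat(chr, type = "USER", levels = c("0", "1"),
                            ambiguity = "?")
    start <- ape::nj(as.dist(genotype_distance(G, "count")))
    tree <- phangorn::optim.parsimony(start, dat, trace = 0)
    tree <- phangorn::acctran(tree, dat)
  }
  tree <- ape::root(tree, outgroup = og, resolve.root = TRUE)
  if (is.null(outgroup)) tree <- ape::drop.tip(tree, og)
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Site-resampling bootstrap support for a cell phylogeny
#'
#' Variant sites are resampled with replacement `n_reps` times, the tree
#' is rebuilt on each replicate, and each internal split of the
#' point-estimate tree receives the percentage of replicate trees that
#' contain it.
#'
#' @param genotypes cells x sites 0/1/NA matrix (>= 10 sites).
#' @param n_reps bootstrap replicates (default 100).
#' @param method tree method passed to [build_tree()].
#' @param outgroup passed to [build_tree()].
#' @param seed integer seed.
#' @return the point-estimate tree with `node.label` set to integer
#'   bootstrap percentages (root NA), plus attribute `support`.
#' @export
bootstrap_support <- function(genotypes, n_reps = 100L,
                              method = "nj", outgroup = NULL, seed = NULL) {
  stopifnot(ncol(genotypes) >= 10)
  point <- build_tree(genotypes, method = method, outgroup = outgroup)
  reps <- with_seed(seed, {
    lapply(seq_len(n_reps), function(i) {
      idx <- sample.int(ncol(genotypes), replace = TRUE)
      build_tree(genotypes[, idx, drop = FALSE], method = method,
                 outgroup = outgroup)
    })
  })
  counts <- ape::prop.clades(point, part = ape::prop.part(reps),
                             rooted = FALSE)
  counts[is.na(counts)] <- 0L
  # near-trivial splits can match several pooled partitions; cap at n_reps
  support <- pmin(round(100 * counts / n_reps), 100L)
  support[1] <- NA  # root split is not a statement about the data
  point$node.label <- as.character(support)
  attr(point, "support") <- support
  point
}

#' Pairwise topological node distances between tips
#'
#' The distance between two tips is the number of edges on the path
#' connecting them (cherry mates are at distance 2).
#'
#' @param tree a `phylo` (binary or multifurcating).
#' @return tips x tips integer matrix.
#' @export
node_distance_matrix <- function(tree) {
  unit <- tree
  unit$edge.length <- rep(1, nrow(tree$edge))
  D <- cophenetic(unit)
  storage.mode(D) <- "integer"
  D[tree$tip.label, tree$tip.label]
}

#' Test whether malignant cells form a monophyletic clade
#'
#' Finds the smallest clade containing every malignant tip; the tumor is
#' monophyletic iff that clade contains no non-malignant tip.
#'
#' @param tree rooted `phylo`.
#' @param malignant_labels named logical vector over all tips (TRUE =
#'   malignant), or a character vector of malignant tip names.
#' @return list with `monophyletic`, `clade_node`, `clade_tips`,
#'   `support` (bootstrap label of the clade node if present), and `flag`
#'   ("single_class" when only one label is present, in which case the
#'   verdict is trivially TRUE).
#' @export
test_monophyly <- function(tree, malignant_labels) {
  tips <- tree$tip.label
  if (is.character(malignant_labels)) {
    mal <- tips %in% malignant_labels
  } else {
    if (is.null(names(malignant_labels)) ||
        !all(tips %in% names(malignant_labels)))
      stop("malignant_labels must name every tip")
    mal <- as.logical(malignant_labels[tips])
  }
  if (anyNA(mal)) stop("unlabeled tips")
  if (all(mal) || !any(mal))
    return(list(monophyletic = TRUE, clade_node = NA_integer_,
                clade_tips = tips[mal], support = NA,
                flag = "single_class"))
  mal_tips <- tips[mal]
  if (length(mal_tips) == 1)
    return(list(monophyletic = TRUE, clade_node = NA_integer_,
                clade_tips = mal_tips, support = NA, flag = "single_tip"))
  node <- ape::getMRCA(tree, mal_tips)
  clade_tips <- ape::extract.clade(tree, node)$tip.label
  support <- NA
  if (!is.null(tree$node.label)) {
    lab <- tree$node.label[node - length(tips)]
    support <- suppressWarnings(as.numeric(lab))
  }
  list(monophyletic = all(clade_tips %in% mal_tips),
       clade_node = node, clade_tips = clade_tips, support = support,
       flag = NA_character_)
}

#' Correlation between root-to-tip branch length and culture time
#'
#' Spearman correlation of each cell's root-to-tip path length (in
#' mutations) against its days in culture, with a permutation p-value
#' from shuffling times across tips.
#'
#' @param tree rooted `phylo` with branch lengths in mutation counts.
#' @param culture_times named numeric vector of days per tip.
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @return list with `rho`, `p_value`, `root_to_tip`, `flag`
#'   ("constant_times" or "underpowered" when applicable).
#' @export
correlate_branch_time <- function(tree, culture_times, n_perm = 999L,
                                  seed = NULL) {
  tips <- tree$tip.label
  if (!all(tips %in% names(culture_times)))
    stop("culture_times must cover all tips")
  times <- as.numeric(culture_times[tips])
  depth <- ape::node.depth.edgelength(tree)[seq_along(tips)]
  names(depth) <- tips
  if (sd(times) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, root_to_tip = depth,
                flag = "constant_times"))
  rho <- cor(depth, times, method = "spearman")
  flag <- if (length(tips) < 3) "underpowered" else NA_character_
  p <- with_seed(seed, {
    perm <- replicate(n_perm,
                      cor(depth, sample(times), method = "spearman"))
    (1 + sum(abs(perm) >= abs(rho))) / (n_perm + 1)
  })
  list(rho = rho, p_value = p, root_to_tip = depth, flag = flag)
}

#' Blomberg's K phylogenetic signal with permutation test
#'
#' K compares the observed ratio of tip variance to phylogenetically
#' corrected variance against its Brownian-motion expectation on the same
#' tree: K near 1 matches BM heritability, K below 1 indicates weaker
#' phylogenetic signal.  Significance comes from permuting trait values
#' across tips.
#'
#' @param tree `phylo` with positive branch lengths.
#' @param trait named numeric vector over tips; variance must be > 0.
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @return list with `K`, `p_value`, `n_perm`, `flag`.
#' @export
blomberg_k <- function(tree, trait, n_perm = 999L, seed = NULL) {
  tips <- tree$tip.label
  if (!is.null(names(trait))) trait <- trait[tips]
  if (length(trait) != length(tips)) stop("trait must cover all tips")
  if (var(trait) == 0)
    return(list(K = NA_real_, p_value = NA_real_, n_perm = n_perm,
                flag = "constant_trait"))
  C <- ape::vcv(tree)
  invC <- solve(C)
  n <- length(tips)
  denom_exp <- (sum(diag(C)) - n / sum(invC)) / (n - 1)
  k_of <- function(x) {
    a <- sum(invC %*% x) / sum(invC)
    d <- x - a
    mse0 <- sum(d^2) / (n - 1)
    mse <- drop(t(d) %*% invC %*% d) / (n - 1)
    (mse0 / mse) / denom_exp
  }
  K <- k_of(trait)
  p <- if (n_perm < 1) NA_real_ else with_seed(seed, {
    perm <- replicate(n_perm, k_of(sample(trait)))
    (1 + sum(perm >= K)) / (n_perm + 1)
  })
  list(K = K, p_value = p, n_perm = n_perm, flag = NA_character_)
}

#' Classify variants as shared or private and flag homoplasy
#'
#' Variants carried by two or more cells are "shared" (expected to include
#' almost no single-cell WGA artifacts, since those would have to recur
#' independently across amplification reactions); single-cell variants are
#' "private".  A shared variant whose carrier set is not a clade on the
#' tree cannot sit on a single branch and is flagged homoplasic.
#'
#' @param genotypes cells x sites 0/1/NA matrix.
#' @param tree `phylo` over the same cells.
#' @return data.frame with `site_id`, `n_carriers`, `class`
#'   ("private"/"shared"/"absent"), `homoplasic`, `branch_node` (MRCA node
#'   of the carrier clade for clean shared variants, NA otherwise).
#' @export
phylogeny_filter <- function(genotypes, tree) {
  stopifnot(all(rownames(genotypes) %in% tree$tip.label))
  sites <- colnames(genotypes) %||% paste0("s", seq_len(ncol(genotypes)))
  carrier_key <- apply(genotypes == 1L & !is.na(genotypes), 2, function(v)
    paste0("k|", paste(rownames(genotypes)[v], collapse = "|")))
  uniq <- !duplicated(carrier_key)
  lookup <- new.env(parent = emptyenv())
  for (key in carrier_key[uniq]) {
    carriers <- strsplit(key, "|", fixed = TRUE)[[1]][-1]
    nc <- length(carriers)
    if (nc == 0) {
      assign(key, list("absent", FALSE, NA_integer_), lookup)
    } else if (nc == 1) {
      assign(key, list("private", FALSE, NA_integer_), lookup)
    } else {
      node <- ape::getMRCA(tree, carriers)
      clade <- ape::extract.clade(tree, node)$tip.label
      clade <- intersect(clade, rownames(genotypes))
      clean <- setequal(clade, carriers)
      assign(key, list("shared", !clean,
                       if (clean) node else NA_integer_), lookup)
    }
  }
  res <- lapply(carrier_key, get, envir = lookup)
  data.frame(
    site_id = sites,
    n_carriers = colSums(genotypes == 1L, na.rm = TRUE),
    class = vapply(res, `[[`, "", 1),
    homoplasic = vapply(res, `[[`, TRUE, 2),
    branch_node = vapply(res, `[[`, 0L, 3),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
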