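#' Hierarchical clustering of mutation frequencies across treatments
#'
#' Clusters both mutations (rows) and treatment conditions (columns) of a
#' VAF matrix by agglomerative clustering, by default on correlation
#' distance (1 - Pearson r) with average linkage; replicate columns of
#' the same drug/dose merge first when replicate noise is smaller than
#' drug effects.  Missing VAFs are treated as below the detection limit
#' (imputed as 0).
#'
#' @param matrix mutations x conditions numeric VAF matrix in \[0, 1\]
#'   (>= 2 rows and columns).
#' @param distance "correlation" (default) or "euclidean".
#' @param linkage passed to [hclust()] (default "average").
#' @param k_rows,k_cols optional flat cluster counts ([cutree()]).
#' @return list with `row_hclust`, `col_hclust`, `row_clusters`,
#'   `col_clusters`, `flag` ("degenerate" for a constant matrix;
#'   zero-variance rows/columns get distance 1 to everything under
#'   correlation distance, with a warning).
#' @export
cluster_vaf_matrix <- function(matrix, distance = c("correlation", "euclidean"),
                               linkage = "average", k_rows = NULL,
                               k_cols = NULL) {
  distance <- match.arg(distance)
  M <- as.matrix(matrix)
  stopifnot(nrow(M) >= 2, ncol(M) >= 2)
  M[is.na(M)] <- 0
  if (any(M < 0 | M > 1)) stop("VAFs must lie in [0, 1]")
  flag <- NA_character_
  if (sd(M) == 0) {
    flag <- "degenerate"
    warning("constant VAF matrix: clustering is degenerate")
  }
  dfun <- function(X) {
    if (distance == "euclidean") return(dist(X))
    cc <- suppressWarnings(cor(t(X)))
    bad <- apply(X, 1, sd) == 0
    if (any(bad) && is.na(flag))
      warning(sum(bad), " zero-variance row(s): correlation distance set to 1")
    cc[is.na(cc)] <- 0
    diag(cc) <- 1
    as.dist(1 - cc)
  }
  rh <- hclust(dfun(M), method = linkage)
  ch <- hclust(dfun(t(M)), method = linkage)
  list(
    row_hclust = rh, col_hclust = ch,
    row_clusters = if (!is.null(k_rows)) cutree(rh, k = k_rows),
    col_clusters = if (!is.null(k_cols)) cutree(ch, k = k_cols),
    flag = flag
  )
}

#' Detect clones emerging under treatment
#'
#' A post-treatment clone is emergent iff none of its defining features
#' (variants or CNVs) was detected in the pre-treatment sample above the
#' detection limit.  For emergent clones, the undetected pre-treatment
#' frequency is bounded by the rule of three: with 0 carriers among `n`
#' sampled cells the 95% upper bound is `3 / n`.
#'
#' @param pre_calls data.frame with `feature` and `vaf` (pre-treatment
#'   frequency; features absent from the table count as undetected).
#' @param post_clones named list: clone id -> character vector of
#'   defining feature ids (variants and/or CNV ids).
#' @param detection_limit VAF below which a feature counts as undetected
#'   (default 0.005, the sensitivity of error-corrected sequencing).
#' @param pre_cell_count cells sampled pre-treatment, for the
#'   rule-of-three bound (NA bound when missing).
#' @param post_fraction optional named numeric: clone -> post-treatment
#'   cell fraction, copied into the report.
#' @return data.frame with one row per clone: `clone`, `n_features`,
#'   `n_detected_pre`, `emergent`, `pre_freq_upper_bound`,
#'   `post_fraction`.
#' @export
detect_emergent_clones <- function(pre_calls, post_clones,
                                   detection_limit = 0.005,
                                   pre_cell_count = NULL,
                                   post_fraction = NULL) {
  stopifnot(is.list(post_clones), length(post_clones) >= 1)
  pre_vaf <- setNames(pre_calls$vaf, pre_calls$feature)
  rows <- lapply(names(post_clones), function(cl) {
    feats <- post_clones[[cl]]
    if (length(feats) == 0)
      stop("clone '", cl, "' has no defining features")
    vafs <- pre_vaf[feats]
    vafs[is.na(vafs)] <- 0
    detected <- vafs >= detection_limit
    emergent <- !any(detected)
    data.frame(
      clone = cl, n_features = length(feats),
      n_detected_pre = sum(detected), emergent = emergent,
      pre_freq_upper_bound = if (emergent && !is.null(pre_cell_count))
        3 / pre_cell_count else NA_real_,
      post_fraction = if (!is.null(post_fraction))
        unname(post_fraction[cl]) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# planted-structure treatment VAF matrix used by the pipeline demo:
# blocks of mutations responding oppositely to dose, with replicate noise
simulate_treatment_vaf <- function(n_mutations = 40, drugs = c("drugA", "drugB"),
                                   doses = 1:3, replicates = 3,
                                   effect = 0.08, noise_sd = 0.01,
                                   seed = NULL) {
  with_seed(seed, {
    conds <- expand.grid(drug = drugs, dose = doses, rep = seq_len(replicates),
                         stringsAsFactors = FALSE)
    cond_names <- with(conds, paste0(drug, "_d", dose, "_r", rep))
    block <- rep(c(1, 2), length.out = n_mutations)
    base <- runif(n_mutations, 0.05, 0.2)
    M <- sapply(seq_len(nrow(conds)), function(j) {
      dir <- ifelse(block == 1, 1, -1) *
        ifelse(conds$drug[j] == drugs[1], 1, -1)
      pmin(pmax(base + dir * effect * conds$dose[j] +
                  rnorm(n_mutations, sd = noise_sd), 0), 1)
    })
    dimnames(M) <- list(paste0("mut", seq_len(n_mutations)), cond_names)
    attr(M, "block") <- block
    attr(M, "conditions") <- conds
    M
  })
}
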