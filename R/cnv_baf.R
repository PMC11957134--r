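#' Windowed mirrored-BAF matrix from het-SNP allele depths
#'
#' Per SNP with sufficient depth, BAF = alt / (alt + ref) and mirrored
#' BAF = max(BAF, 1 - BAF); each (cell, window) value is the mean mirrored
#' BAF over qualifying SNPs in the half-open genomic window.  Windows with
#' fewer than `min_snps_per_window` qualifying SNPs in a cell are flagged
#' `qc_fail` there; a window is analysis-eligible iff it passes QC in at
#' least `min_cells` cells.
#'
#' @param allele_depths data.frame with `cell`, `chrom`, `pos`,
#'   `ref_depth`, `alt_depth` at heterozygous germline SNPs (rows with a
#'   `site_type` column are restricted to "germline_het").
#' @param w window width in bp (default 5000); windows are 0-based
#'   half-open `[k*w, (k+1)*w)`.
#' @param min_snps_per_window minimum qualifying SNPs per (cell, window).
#' @param min_depth minimum total depth for a SNP to qualify.
#' @param min_cells minimum QC-passing cells for an eligible window.
#' @return object of class `baf_window_matrix`: list with `values`
#'   (cells x windows, NA where undefined), `qc_pass`, `n_snps`,
#'   `windows` (data.frame `chrom`, `start`, `end`), `eligible` (logical
#'   per window), and the thresholds used.
#' @export
window_mirrored_baf <- function(allele_depths, w = 5000L,
                                min_snps_per_window = 3L, min_depth = 8L,
                                min_cells = 5L) {
  stopifnot(w > 0)
  d <- allele_depths
  if ("site_type" %in% names(d)) d <- d[d$site_type == "germline_het", , drop = FALSE]
  if (nrow(d) == 0) stop("no het SNP depths supplied")
  if (any(d$ref_depth < 0 | d$alt_depth < 0)) stop("negative depths")
  tot <- d$ref_depth + d$alt_depth
  d <- d[tot >= min_depth, , drop = FALSE]
  tot <- d$ref_depth + d$alt_depth

  win_idx <- (d$pos - 1L) %/% as.integer(w)   # 1-based pos -> 0-based window
  win_key <- paste(d$chrom, win_idx, sep = ":")
  baf <- d$alt_depth / tot
  mbaf <- pmax(baf, 1 - baf)

  cells <- sort(unique(allele_depths$cell))
  wins <- unique(data.frame(chrom = d$chrom, idx = win_idx, key = win_key,
                            stringsAsFactors = FALSE))
  wins <- wins[order(wins$chrom, wins$idx), , drop = FALSE]

  ci <- match(d$cell, cells)
  wi <- match(win_key, wins$key)
  grp <- (wi - 1L) * length(cells) + ci
  sums <- tapply(mbaf, grp, sum)
  ns <- tapply(mbaf, grp, length)
  values <- matrix(NA_real_, length(cells), nrow(wins),
                   dimnames = list(cells, wins$key))
  n_snps <- matrix(0L, length(cells), nrow(wins),
                   dimnames = list(cells, wins$key))
  idx <- as.integer(names(sums))
  values[idx] <- sums / ns
  n_snps[idx] <- ns

  qc <- n_snps >= min_snps_per_window & !is.na(values)
  eligible <- colSums(qc) >= min_cells

  structure(list(
    values = values, qc_pass = qc, n_snps = n_snps,
    windows = data.frame(chrom = wins$chrom, start = wins$idx * w,
                         end = (wins$idx + 1L) * w, stringsAsFactors = FALSE),
    eligible = eligible, w = w, min_snps_per_window = min_snps_per_window,
    min_depth = min_depth, min_cells = min_cells
  ), class = "baf_window_matrix")
}

#' @export
print.baf_window_matrix <- function(x, ...) {
  cat("baf_window_matrix:", nrow(x$values), "cells x", ncol(x$values),
      "windows (", x$w, "bp );", sum(x$eligible), "eligible windows\n")
  invisible(x)
}

#' Threshold-based allelic-imbalance calls per (cell, window)
#'
#' @param matrix a `baf_window_matrix`.
#' @param threshold mirrored-BAF threshold in \[0.5, 1\]; a window is
#'   called imbalanced in a cell iff its value is >= the threshold, it
#'   passes QC in that cell, and the window is analysis-eligible.
#' @return logical cells x windows matrix of imbalance calls.
#' @export
call_cnv_threshold <- function(matrix, threshold) {
  stopifnot(inherits(matrix, "baf_window_matrix"),
            threshold >= 0.5, threshold <= 1)
  calls <- !is.na(matrix$values) & matrix$values >= threshold & matrix$qc_pass
  calls[, !matrix$eligible] <- FALSE
  calls
}

#' ROC evaluation of the mirrored-BAF CNV caller against clone truth
#'
#' Sweeps fixed BAF thresholds, scoring each qc-passing (cell, window)
#' pair against truth: pairs in carrier cells within the event region are
#' positives, pairs in non-carrier cells are negatives.  TPR and FPR at a
#' threshold are the called fractions of each class; AUC is the trapezoid
#' integral over the sweep.  Uncertainty comes from bootstrap resampling
#' of cells with replacement.
#'
#' @param matrix a `baf_window_matrix`.
#' @param carrier_cells character vector of deletion-carrying cells.
#' @param region_windows window keys (columns of `matrix$values`) covered
#'   by the true event; default all eligible windows.
#' @param thresholds mirrored-BAF sweep (default 0.5 to 1 by 0.005).
#' @param n_bootstrap bootstrap resamples of cells (default 100).
#' @param seed integer seed for the bootstrap.
#' @return list with `roc` (data.frame threshold, tpr, fpr, and bootstrap
#'   mean +/- 2 sd bands), `auc`, `auc_sd`, `auc_band`.
#' @export
roc_evaluate <- function(matrix, carrier_cells, region_windows = NULL,
                         thresholds = seq(0.5, 1, by = 0.005),
                         n_bootstrap = 100L, seed = NULL) {
  stopifnot(inherits(matrix, "baf_window_matrix"))
  cells <- rownames(matrix$values)
  carrier <- cells %in% carrier_cells
  if (all(carrier) || !any(carrier))
    stop("truth labels contain a single class")
  wins <- region_windows %||% colnames(matrix$values)[matrix$eligible]
  wins <- intersect(wins, colnames(matrix$values)[matrix$eligible])
  if (length(wins) == 0) stop("no eligible windows in the evaluation region")

  vals <- matrix$values[, wins, drop = FALSE]
  ok <- matrix$qc_pass[, wins, drop = FALSE]

  curve_for <- function(cell_idx) {
    v <- vals[cell_idx, , drop = FALSE]
    o <- ok[cell_idx, , drop = FALSE]
    pos <- carrier[cell_idx]
    pv <- v[pos, , drop = FALSE][o[pos, , drop = FALSE]]
    nv <- v[!pos, , drop = FALSE][o[!pos, , drop = FALSE]]
    tpr <- vapply(thresholds, function(th) mean(pv >= th), 0)
    fpr <- vapply(thresholds, function(th) mean(nv >= th), 0)
    cbind(tpr = tpr, fpr = fpr)
  }
  trap_auc <- function(tpr, fpr) {
    o <- order(fpr, tpr)
    x <- c(0, fpr[o], 1); y <- c(0, tpr[o], 1)
    sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  }

  point <- curve_for(seq_along(cells))
  auc <- trap_auc(point[, "tpr"], point[, "fpr"])

  boot <- with_seed(seed, {
    replicate(n_bootstrap, {
      idx <- sample(seq_along(cells), replace = TRUE)
      while (all(carrier[idx]) || !any(carrier[idx]))
        idx <- sample(seq_along(cells), replace = TRUE)
      cv <- curve_for(idx)
      c(cv[, "tpr"], cv[, "fpr"], trap_auc(cv[, "tpr"], cv[, "fpr"]))
    })
  })
  nt <- length(thresholds)
  tpr_b <- boot[seq_len(nt), , drop = FALSE]
  fpr_b <- boot[nt + seq_len(nt), , drop = FALSE]
  auc_b <- boot[2 * nt + 1, ]

  roc <- data.frame(
    threshold = thresholds,
    tpr = point[, "tpr"], fpr = point[, "fpr"],
    tpr_mean = rowMeans(tpr_b), tpr_sd = apply(tpr_b, 1, sd),
    fpr_mean = rowMeans(fpr_b), fpr_sd = apply(fpr_b, 1, sd)
  )
  roc$tpr_lo <- roc$tpr_mean - 2 * roc$tpr_sd
  roc$tpr_hi <- roc$tpr_mean + 2 * roc$tpr_sd
  list(roc = roc, auc = auc, auc_sd = sd(auc_b),
       auc_band = c(mean(auc_b) - 2 * sd(auc_b), mean(auc_b) + 2 * sd(auc_b)))
}
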