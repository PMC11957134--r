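#' The 96 canonical single-base-substitution categories
#'
#' Pyrimidine-centered trinucleotide contexts in the standard catalogue
#' order: substitutions C>A, C>G, C>T, T>A, T>C, T>G, each with 5' and 3'
#' flanks cycling A, C, G, T (flank order 3' fastest).
#'
#' @return character vector of 96 labels like "A\[C>A\]A".
#' @export
sbs96_contexts <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s)
    unlist(lapply(bases, function(five)
      paste0(five, "[", s, "]", bases)))))
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(x, ""), function(ch)
           paste(rev(ch), collapse = ""), ""))
}

#' Build an SBS96 context-count matrix from variants
#'
#' Each single-nucleotide variant is classified by its substitution and
#' trinucleotide context; purine-reference variants are
#' reverse-complemented to the pyrimidine-centered convention.  Variants
#' with ambiguous context (containing N) or whose context middle base
#' disagrees with the reference are skipped with a message.
#'
#' @param variants data.frame with `ref`, `alt`, `context` (3-base string
#'   centered on the variant) and optionally `sample`.
#' @return object of class `sbs96_matrix`: 96 x samples integer matrix
#'   with rownames [sbs96_contexts()]; column sums equal the per-sample
#'   retained SNV counts.
#' @export
sbs96_matrix <- function(variants) {
  stopifnot(all(c("ref", "alt", "context") %in% names(variants)))
  v <- variants
  v$sample <- if ("sample" %in% names(v)) as.character(v$sample) else "all"

  ok <- nchar(v$context) == 3 & !grepl("N", v$context) &
    v$ref %in% c("A", "C", "G", "T") & v$alt %in% c("A", "C", "G", "T") &
    substr(v$context, 2, 2) == v$ref & v$ref != v$alt
  if (any(!ok)) message(sum(!ok), " variant(s) with unusable context skipped")
  v <- v[ok, , drop = FALSE]

  purine <- v$ref %in% c("A", "G")
  ctx <- v$context; ref <- v$ref; alt <- v$alt
  ctx[purine] <- revcomp(ctx[purine])
  ref[purine] <- chartr("ACGT", "TGCA", ref[purine])
  alt[purine] <- chartr("ACGT", "TGCA", alt[purine])
  cat96 <- paste0(substr(ctx, 1, 1), "[", ref, ">", alt, "]",
                  substr(ctx, 3, 3))

  samples <- sort(unique(v$sample))
  M <- matrix(0L, 96, length(samples),
              dimnames = list(sbs96_contexts(), samples))
  tab <- table(factor(cat96, levels = sbs96_contexts()), v$sample)
  M[, colnames(tab)] <- tab
  structure(M, class = c("sbs96_matrix", class(M)))
}

#' Synthetic reference signature catalogue
#'
#' A small built-in catalogue of synthetic SBS96 signatures shaped like
#' well-known mutational processes, for fitting and simulation when no
#' external catalogue TSV is supplied.  These are constructed profiles,
#' not the published catalogue: "clocklike_flat" spreads mass broadly
#' (SBS5-like), "cpg_deamination" concentrates C>T at NpCpG contexts
#' (SBS1-like), "apobec_tpc" concentrates C>T and C>G at TpC contexts
#' (SBS2/SBS13-like), "mmr_ct" favors C>T at all contexts, and
#' "t_clock" favors T>C changes.
#'
#' @return 96 x 5 column-normalized numeric matrix.
#' @export
example_signature_catalog <- function() {
  ctx <- sbs96_contexts()
  five <- substr(ctx, 1, 1)
  sub <- substr(ctx, 3, 5)
  three <- substr(ctx, 7, 7)

  flat <- rep(1, 96)
  cpg <- ifelse(sub == "C>T" & three == "G", 12, 0.2)
  apobec <- ifelse(five == "T" & sub %in% c("C>T", "C>G"), 10, 0.1)
  mmr <- ifelse(sub == "C>T", 4, 0.3)
  tclock <- ifelse(sub == "T>C", 5, 0.25)

  P <- cbind(clocklike_flat = flat, cpg_deamination = cpg,
             apobec_tpc = apobec, mmr_ct = mmr, t_clock = tclock)
  rownames(P) <- ctx
  sweep(P, 2, colSums(P), "/")
}

#' Fit reference signatures to SBS96 counts by non-negative least squares
#'
#' Each sample's 96-category count vector is decomposed over the
#' reference signatures with NNLS; the reconstruction quality is reported
#' as the cosine similarity between observed and fitted profiles.
#'
#' @param matrix 96 x samples count matrix ([sbs96_matrix()]).
#' @param reference_signatures 96 x k matrix with columns summing to 1.
#' @param normalize return exposures as per-sample fractions.
#' @return list with `exposures` (k x samples), `cosine` (per sample,
#'   NA + flag for zero-count samples), `residual` (Frobenius norm per
#'   sample), `flags`.
#' @export
fit_signatures <- function(matrix, reference_signatures, normalize = TRUE) {
  P <- as.matrix(reference_signatures)
  stopifnot(nrow(matrix) == 96, nrow(P) == 96)
  if (any(abs(colSums(P) - 1) > 1e-6))
    stop("reference signature columns must sum to 1")
  M <- as.matrix(matrix)
  k <- ncol(P)
  expo <- matrix(0, k, ncol(M), dimnames = list(colnames(P), colnames(M)))
  cosine <- residual <- setNames(rep(NA_real_, ncol(M)), colnames(M))
  flags <- setNames(rep(NA_character_, ncol(M)), colnames(M))
  for (j in seq_len(ncol(M))) {
    m <- M[, j]
    if (sum(m) == 0) { flags[j] <- "zero_counts"; expo[, j] <- 0; next }
    fit <- pracma::lsqnonneg(P, m)
    expo[, j] <- fit$x
    fitted <- P %*% fit$x
    cosine[j] <- cosine_similarity(m, fitted)
    residual[j] <- sqrt(sum((m - fitted)^2))
  }
  if (normalize) {
    tot <- colSums(expo)
    tot[tot == 0] <- 1
    expo <- sweep(expo, 2, tot, "/")
  }
  list(exposures = expo, cosine = cosine, residual = residual, flags = flags)
}

# one KL-NMF run with multiplicative updates; objective is non-increasing
kl_nmf_once <- function(V, k, max_iter, tol) {
  eps <- 1e-10
  n <- nrow(V); s <- ncol(V)
  W <- matrix(runif(n * k, 0.1, 1), n, k)
  H <- matrix(runif(k * s, 0.1, 1), k, s)
  kl <- function(WH) sum(ifelse(V > 0, V * log((V + eps) / (WH + eps)), 0) -
                           V + WH)
  obj <- Inf
  for (it in seq_len(max_iter)) {
    WH <- W %*% H
    W <- W * ((V / (WH + eps)) %*% t(H)) /
      (matrix(rowSums(H), n, k, byrow = TRUE) + eps)
    WH <- W %*% H
    H <- H * (t(W) %*% (V / (WH + eps))) /
      (matrix(colSums(W), k, s) + eps)
    new_obj <- kl(W %*% H)
    if (is.finite(obj) && abs(obj - new_obj) < tol * (abs(obj) + eps)) {
      obj <- new_obj
      break
    }
    obj <- new_obj
  }
  list(W = W, H = H, kl = obj)
}

#' De novo signature extraction by KL-divergence NMF
#'
#' Factorizes the 96 x samples count matrix as `V ~ W H` with
#' non-negative factors, minimizing the generalized Kullback-Leibler
#' divergence (the Poisson-appropriate objective) with multiplicative
#' updates; the best of `n_restarts` random restarts is kept.  Extracted
#' signatures (columns of W) are L1-normalized and each is matched to its
#' nearest reference signature by cosine similarity.
#'
#' @param matrix 96 x samples count matrix.
#' @param k number of signatures (must be < number of categories; a
#'   warning is issued when k >= samples).
#' @param n_restarts random restarts (default 10).
#' @param max_iter,tol update iterations and relative convergence
#'   tolerance per run.
#' @param reference optional 96 x r catalogue for nearest-reference
#'   matching (default [example_signature_catalog()]).
#' @param seed integer seed; fixed seed gives identical output.
#' @return list with `signatures` (96 x k, columns sum to 1), `exposures`
#'   (k x samples), `kl` (best objective), `matched_reference`
#'   (data.frame signature, reference, cosine).
#' @export
extract_de_novo <- function(matrix, k, n_restarts = 10L, max_iter = 500L,
                            tol = 1e-6, reference = example_signature_catalog(),
                            seed = NULL) {
  V <- as.matrix(matrix)
  stopifnot(nrow(V) == 96, k >= 1, k < 96)
  if (k >= ncol(V)) warning("k >= number of samples: extraction may overfit")
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      run <- kl_nmf_once(V, k, max_iter, tol)
      if (is.null(best) || run$kl < best$kl) best <- run
    }
  })
  scale <- colSums(best$W)
  W <- sweep(best$W, 2, scale, "/")
  H <- best$H * scale
  colnames(W) <- paste0("SBS96-", LETTERS[seq_len(k)])
  rownames(W) <- rownames(V) %||% sbs96_contexts()
  rownames(H) <- colnames(W)
  colnames(H) <- colnames(V)

  match_df <- do.call(rbind, lapply(seq_len(k), function(j) {
    cs <- apply(reference, 2, cosine_similarity, y = W[, j])
    data.frame(signature = colnames(W)[j],
               reference = names(which.max(cs)),
               cosine = max(cs), stringsAsFactors = FALSE)
  }))
  list(signatures = W, exposures = H, kl = best$kl,
       matched_reference = match_df)
}

#' Match extracted signatures to truth by best assignment
#'
#' Enumerates assignments (for small k) to maximize total cosine
#' similarity between extracted and true signature sets.
#'
#' @param extracted 96 x k matrix.
#' @param truth 96 x k matrix.
#' @return data.frame with `extracted`, `truth`, `cosine` for the optimal
#'   assignment.
#' @export
match_signatures <- function(extracted, truth) {
  k <- ncol(extracted)
  stopifnot(ncol(truth) == k, k <= 8)
  S <- outer(seq_len(k), seq_len(k),
             Vectorize(function(i, j)
               cosine_similarity(extracted[, i], truth[, j])))
  perms <- permutations_of(k)
  scores <- vapply(perms, function(p) sum(S[cbind(seq_len(k), p)]), 0)
  best <- perms[[which.max(scores)]]
  data.frame(
    extracted = colnames(extracted) %||% paste0("E", seq_len(k)),
    truth = (colnames(truth) %||% paste0("T", seq_len(k)))[best],
    cosine = S[cbind(seq_len(k), best)],
    stringsAsFactors = FALSE
  )
}

permutations_of <- function(k) {
  if (k == 1) return(list(1L))
  sub <- permutations_of(k - 1)
  out <- list()
  for (p in sub) for (pos in 0:(k - 1))
    out[[length(out) + 1L]] <- append(p, k, after = pos)
  out
}

#' Contrast mutational contexts of early (shared) vs late (private) SNVs
#'
#' Builds separate SBS96 matrices for variants shared across cells and
#' variants private to single cells, then tests each of the 96 categories
#' for a difference in proportions between the two classes, with
#' Benjamini-Hochberg correction.
#'
#' @param shared_variants,private_variants data.frames as for
#'   [sbs96_matrix()]; both must be non-empty.
#' @param fdr significance threshold on adjusted p-values (default 0.05).
#' @param min_class_size below this many variants per class the test is
#'   flagged underpowered.
#' @return list with `shared_matrix`, `private_matrix`, `tests`
#'   (data.frame category, shared count/fraction, private count/fraction,
#'   p, fdr, significant), `flag`.
#' @export
early_late_contrast <- function(shared_variants, private_variants,
                                fdr = 0.05, min_class_size = 20L) {
  if (nrow(shared_variants) == 0 || nrow(private_variants) == 0)
    stop("both variant classes must be non-empty")
  Ms <- rowSums(sbs96_matrix(shared_variants))
  Mp <- rowSums(sbs96_matrix(private_variants))
  ns <- sum(Ms); np <- sum(Mp)
  flag <- if (min(ns, np) < min_class_size) "underpowered" else NA_character_

  p <- vapply(seq_len(96), function(i) {
    if (Ms[i] + Mp[i] == 0) return(NA_real_)
    suppressWarnings(
      prop.test(c(Ms[i], Mp[i]), c(ns, np))$p.value)
  }, 0)
  adj <- p.adjust(p, method = "BH")
  tests <- data.frame(
    category = sbs96_contexts(),
    shared = as.integer(Ms), shared_frac = Ms / ns,
    private = as.integer(Mp), private_frac = Mp / np,
    p = p, fdr = adj,
    significant = !is.na(adj) & adj < fdr,
    stringsAsFactors = FALSE
  )
  list(shared_matrix = Ms, private_matrix = Mp, tests = tests, flag = flag)
}
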