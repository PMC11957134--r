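#' Consensus-calling parameters for UMI read families
#'
#' @param minmem minimum family size; smaller families are rejected.
#' @param base_cutoff fraction of reads that must agree for a base to be
#'   emitted at a position (ties at exactly the cutoff are emitted);
#'   must exceed 0.5 so at most one base can qualify.
#' @param n_cutoff minimum fraction of non-'N' positions a consensus must
#'   retain; consensi with an N fraction above `1 - n_cutoff` are discarded.
#' @return object of class `consensus_params`.
#' @export
consensus_params <- function(minmem = 3L, base_cutoff = 0.8, n_cutoff = 0.7) {
  stopifnot(minmem >= 1, base_cutoff > 0.5, base_cutoff <= 1,
            n_cutoff > 0, n_cutoff <= 1)
  structure(list(minmem = as.integer(minmem), base_cutoff = base_cutoff,
                 n_cutoff = n_cutoff), class = "consensus_params")
}

#' Call the consensus sequence of one UMI family
#'
#' Families smaller than `minmem` are rejected.  At each position the base
#' carried by at least `base_cutoff` of the reads is emitted; positions
#' with no such majority become 'N'.  If the resulting consensus has an N
#' fraction above `1 - n_cutoff` it is discarded.
#'
#' @param family a list with a `reads` character matrix (reads x positions,
#'   single characters), or the matrix itself.
#' @param params a [consensus_params()].
#' @return list with `status` ("ok" or "rejected"), `reason` (NA, "empty",
#'   "minmem" or "n_fraction"), and `consensus` (string or NA).
#' @export
call_consensus <- function(family, params = consensus_params()) {
  reads <- if (is.matrix(family)) family else family$reads
  if (is.null(reads) || nrow(reads) == 0)
    return(list(status = "rejected", reason = "empty", consensus = NA_character_))
  n <- nrow(reads)
  if (n < params$minmem)
    return(list(status = "rejected", reason = "minmem", consensus = NA_character_))
  cons <- apply(reads, 2, function(col) {
    tab <- table(col)
    top <- which.max(tab)
    if (tab[top] / n >= params$base_cutoff) names(tab)[top] else "N"
  })
  n_frac <- mean(cons == "N")
  if (n_frac > 1 - params$n_cutoff)
    return(list(status = "rejected", reason = "n_fraction",
                consensus = NA_character_))
  list(status = "ok", reason = NA_character_,
       consensus = paste(cons, collapse = ""))
}

#' Call consensus sequences for a whole UMI family set
#'
#' @param ufs a `umi_family_set` (see [simulate_umi_families()]).
#' @param params a [consensus_params()].
#' @return data.frame with `umi`, `family_size`, `status`, `reason`,
#'   `consensus`.
#' @export
call_consensus_set <- function(ufs, params = consensus_params()) {
  res <- lapply(ufs$families, function(f) {
    cc <- call_consensus(f, params)
    data.frame(umi = f$umi, family_size = nrow(f$reads),
               status = cc$status, reason = cc$reason,
               consensus = cc$consensus, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Somatic-variant filter parameters for tumor/normal comparison
#'
#' @param p_threshold Fisher's-exact-test p-value below which a site is a
#'   somatic candidate.
#' @param max_normal_alt_reads exclusive upper bound on variant-supporting
#'   reads in the normal sample (a site with this many or more is rejected).
#' @param max_strand_fraction maximum fraction of tumor variant reads
#'   allowed on a single strand.
#' @return object of class `somatic_filter_params`.
#' @export
somatic_filter_params <- function(p_threshold = 1e-4,
                                  max_normal_alt_reads = 5L,
                                  max_strand_fraction = 0.9) {
  stopifnot(p_threshold > 0, p_threshold < 1,
            max_normal_alt_reads >= 1,
            max_strand_fraction > 0, max_strand_fraction <= 1)
  structure(list(p_threshold = p_threshold,
                 max_normal_alt_reads = as.integer(max_normal_alt_reads),
                 max_strand_fraction = max_strand_fraction),
            class = "somatic_filter_params")
}

#' Tumor/normal somatic variant test on pileup tallies
#'
#' Compares tumor and normal allele counts position by position with a
#' one-sided Fisher's exact test (tumor enriched for the variant allele).
#' A variant is reported as somatic iff the p-value is below
#' `p_threshold`, the normal sample has fewer than `max_normal_alt_reads`
#' variant-supporting reads, and no more than `max_strand_fraction` of the
#' tumor variant reads sit on one strand.
#'
#' @param tumor_pileup data.frame with `chrom`, `pos`, `ref`, `alt`,
#'   `ref_depth`, `alt_depth` and optionally `alt_fwd`, `alt_rev` strand
#'   tallies of the variant reads.
#' @param normal_pileup data.frame with the same positions and columns
#'   `ref_depth`, `alt_depth`.
#' @param params a [somatic_filter_params()].
#' @return data.frame of all shared positions with `p_value`,
#'   `strand_fraction`, `normal_alt`, per-filter logical flags and the
#'   final `somatic` verdict; zero-depth sites are skipped (dropped with a
#'   message).
#' @export
call_somatic <- function(tumor_pileup, normal_pileup,
                         params = somatic_filter_params()) {
  key <- function(d) paste(d$chrom, d$pos, sep = ":")
  shared <- intersect(key(tumor_pileup), key(normal_pileup))
  if (length(shared) == 0) stop("pileups share no positions")
  tu <- tumor_pileup[match(shared, key(tumor_pileup)), , drop = FALSE]
  no <- normal_pileup[match(shared, key(normal_pileup)), , drop = FALSE]

  t_tot <- tu$ref_depth + tu$alt_depth
  n_tot <- no$ref_depth + no$alt_depth
  zero <- t_tot == 0 | n_tot == 0
  if (any(zero)) {
    message(sum(zero), " zero-depth site(s) skipped")
    tu <- tu[!zero, , drop = FALSE]
    no <- no[!zero, , drop = FALSE]
  }
  if (nrow(tu) == 0) stop("no testable sites after depth filtering")

  p <- vapply(seq_len(nrow(tu)), function(i) {
    m <- matrix(c(tu$alt_depth[i], tu$ref_depth[i],
                  no$alt_depth[i], no$ref_depth[i]), nrow = 2)
    fisher.test(m, alternative = "greater")$p.value
  }, 0)

  if (all(c("alt_fwd", "alt_rev") %in% names(tu))) {
    tot_alt <- tu$alt_fwd + tu$alt_rev
    strand_frac <- ifelse(tot_alt > 0,
                          pmax(tu$alt_fwd, tu$alt_rev) / tot_alt, 0)
  } else {
    strand_frac <- rep(NA_real_, nrow(tu))
  }

  pass_p <- p < params$p_threshold
  pass_normal <- no$alt_depth < params$max_normal_alt_reads
  pass_strand <- is.na(strand_frac) | strand_frac <= params$max_strand_fraction

  out <- data.frame(
    chrom = tu$chrom, pos = tu$pos,
    ref = tu$ref %||% NA_character_, alt = tu$alt %||% NA_character_,
    tumor_ref = tu$ref_depth, tumor_alt = tu$alt_depth,
    normal_ref = no$ref_depth, normal_alt = no$alt_depth,
    p_value = p, strand_fraction = strand_frac,
    pass_p = pass_p, pass_normal = pass_normal, pass_strand = pass_strand,
    somatic = pass_p & pass_normal & pass_strand,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
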