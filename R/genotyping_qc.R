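#' Call ternary genotypes from per-cell allele depths
#'
#' A site is callable when its total depth reaches `min_depth`; the
#' variant allele is called present when supported by at least `min_alt`
#' reads.  Uncallable sites are NA (missing), so downstream distances use
#' pairwise deletion rather than assuming reference.
#'
#' @param readcounts data.frame with `cell`, `site_id`, `ref_depth`,
#'   `alt_depth` (e.g. from [simulate_wga_readcounts()]); rows with
#'   `site_type` other than "somatic" are ignored when present.
#' @param min_depth minimum total depth for a callable site.
#' @param min_alt minimum variant-supporting reads to call the variant.
#' @return cells x sites integer matrix with entries 0, 1 or NA.
#' @export
call_genotypes <- function(readcounts, min_depth = 5L, min_alt = 2L) {
  rc <- readcounts
  if ("site_type" %in% names(rc)) rc <- rc[rc$site_type == "somatic", , drop = FALSE]
  if (nrow(rc) == 0) stop("no somatic sites in readcounts")
  cells <- unique(rc$cell)
  sites <- unique(rc$site_id)
  tot <- rc$ref_depth + rc$alt_depth
  gt <- ifelse(tot < min_depth, NA_integer_,
               ifelse(rc$alt_depth >= min_alt, 1L, 0L))
  G <- matrix(NA_integer_, length(cells), length(sites),
              dimnames = list(cells, sites))
  G[cbind(match(rc$cell, cells), match(rc$site_id, sites))] <- gt
  G
}

#' Estimate the allelic dropout rate of one cell
#'
#' ADO is defined at locus level: among heterozygous germline sites with
#' total depth of at least `min_depth`, the fraction at which exactly one
#' allele has supporting reads.
#'
#' @param cell_allele_depths data.frame with `ref_depth`, `alt_depth` at
#'   known het sites for one cell (rows with `site_type` are restricted to
#'   "germline_het" when the column is present).
#' @param min_depth minimum total depth for a site to qualify.
#' @return list with `ado_rate` (NA and `flag = "no_qualifying_sites"` when
#'   undefined), `n_sites`, `n_single_allele`.
#' @export
estimate_ado <- function(cell_allele_depths, min_depth = 5L) {
  d <- cell_allele_depths
  if ("site_type" %in% names(d)) d <- d[d$site_type == "germline_het", , drop = FALSE]
  tot <- d$ref_depth + d$alt_depth
  keep <- tot >= min_depth
  d <- d[keep, , drop = FALSE]
  if (nrow(d) == 0)
    return(list(ado_rate = NA_real_, n_sites = 0L, n_single_allele = 0L,
                flag = "no_qualifying_sites"))
  single <- xor(d$ref_depth == 0, d$alt_depth == 0)
  list(ado_rate = mean(single), n_sites = nrow(d),
       n_single_allele = sum(single), flag = NA_character_)
}

#' Estimate germline recall for one cell
#'
#' The fraction of heterozygous germline sites at which the variant allele
#' survives the calling/filtering pipeline, a per-cell proxy for somatic
#' recall since germline het sites are known true positives.
#'
#' @param cell_allele_depths depths at known het germline sites for one
#'   cell (as in [estimate_ado()]).
#' @param min_depth minimum total depth for a site to be assessable.
#' @param min_alt minimum variant reads to count the variant as recovered.
#' @param filter_pipeline optional function(data.frame) -> logical keep
#'   vector applied before scoring (the same hard filters used for somatic
#'   calls); filtered sites count as missed.
#' @return list with `recall`, `n_sites`, `n_recovered`.
#' @export
estimate_recall_germline <- function(cell_allele_depths, min_depth = 1L,
                                     min_alt = 1L, filter_pipeline = NULL) {
  d <- cell_allele_depths
  if ("site_type" %in% names(d)) d <- d[d$site_type == "germline_het", , drop = FALSE]
  if (nrow(d) == 0) stop("empty het site list")
  assess <- d$ref_depth + d$alt_depth >= min_depth
  d <- d[assess, , drop = FALSE]
  if (nrow(d) == 0) stop("no het sites pass min_depth")
  recovered <- d$alt_depth >= min_alt
  if (!is.null(filter_pipeline)) recovered <- recovered & filter_pipeline(d)
  list(recall = mean(recovered), n_sites = nrow(d), n_recovered = sum(recovered))
}

#' Linked-read precision of somatic candidate calls
#'
#' Reads spanning a candidate somatic SNV and a nearby heterozygous
#' germline SNP should support only two haplotypes: variant reads should
#' co-occur with a single germline allele.  A (germline allele, somatic
#' allele) combination is counted as real only when supported by at least
#' `min_reads_per_combo` reads, guarding against lone sequencing errors.
#' A candidate is "supported" iff, among counted combinations, no germline
#' allele carries both somatic alleles (i.e. the combinations are
#' consistent with exactly two haplotypes).
#'
#' @param phased_read_pairs data.frame with one row per spanning read:
#'   `candidate` (sSNV id), `het_allele` ("A"/"B" or base), `ssnv_allele`
#'   ("ref"/"alt" or base).
#' @param min_spanning minimum spanning reads for a candidate to be
#'   assessable.
#' @param min_reads_per_combo reads needed for a combination to count.
#' @return list with `precision` (NA + flag when nothing assessable),
#'   `n_assessable`, `n_supported`, and per-candidate data.frame `detail`.
#' @export
estimate_precision_linked <- function(phased_read_pairs, min_spanning = 4L,
                                      min_reads_per_combo = 2L) {
  stopifnot(all(c("candidate", "het_allele", "ssnv_allele") %in%
                  names(phased_read_pairs)))
  split_rows <- split(phased_read_pairs, phased_read_pairs$candidate)
  detail <- do.call(rbind, lapply(names(split_rows), function(id) {
    d <- split_rows[[id]]
    if (nrow(d) < min_spanning)
      return(data.frame(candidate = id, assessable = FALSE,
                        supported = NA, stringsAsFactors = FALSE))
    tab <- table(d$het_allele, d$ssnv_allele)
    tab[tab < min_reads_per_combo] <- 0L
    # supported iff each germline allele carries at most one somatic allele
    per_het <- rowSums(tab > 0)
    data.frame(candidate = id, assessable = TRUE,
               supported = all(per_het <= 1), stringsAsFactors = FALSE)
  }))
  assessable <- detail$assessable
  if (!any(assessable))
    return(list(precision = NA_real_, n_assessable = 0L, n_supported = 0L,
                flag = "no_assessable_candidates", detail = detail))
  supp <- detail$supported[assessable]
  list(precision = mean(supp), n_assessable = sum(assessable),
       n_supported = sum(supp), flag = NA_character_, detail = detail)
}

#' False heterozygous call rate in a hemizygous/homozygous region
#'
#' In a region known to carry a single haplotype no heterozygous call
#' should occur; the rate of het calls there estimates the false positive
#' rate, and the BAF distribution of those calls shows where artifacts
#' concentrate.
#'
#' @param cell_calls data.frame with `chrom`, `pos`, `ref_depth`,
#'   `alt_depth` for one cell.
#' @param hemizygous_region list or one-row data.frame with `chrom`,
#'   `start`, `end` (0-based half-open).
#' @param min_depth minimum depth for a site to be assessed.
#' @param min_alt variant reads needed to call a (false) het.
#' @return list with `false_het_rate`, `n_sites`, `n_false_het`, and
#'   `baf` (numeric vector of BAFs of the false het calls).
#' @export
estimate_false_het <- function(cell_calls, hemizygous_region,
                               min_depth = 5L, min_alt = 2L) {
  r <- as.list(hemizygous_region)
  d <- cell_calls[cell_calls$chrom == r$chrom &
                    cell_calls$pos >= r$start & cell_calls$pos < r$end, ,
                  drop = FALSE]
  if (nrow(d) == 0) stop("region contains no sites in cell_calls")
  tot <- d$ref_depth + d$alt_depth
  d <- d[tot >= min_depth, , drop = FALSE]
  tot <- d$ref_depth + d$alt_depth
  het <- d$alt_depth >= min_alt & d$ref_depth >= min_alt
  baf <- d$alt_depth[het] / tot[het]
  list(false_het_rate = if (nrow(d)) mean(het) else NA_real_,
       n_sites = nrow(d), n_false_het = sum(het), baf = baf)
}

#' Clone-level concordant mutation calling
#'
#' A variant is retained for a clone iff it is called (value 1) in at
#' least `min_concordant` of the clone's cells, is absent from the bulk
#' germline SNP list, and is absent from every normal single cell.
#'
#' @param clone_calls cells x sites 0/1/NA matrix for the clone's cells.
#' @param min_concordant minimum concordant cells (default 2).
#' @param bulk_germline character vector of site ids (or positions) known
#'   germline from bulk sequencing.
#' @param normal_cell_calls optional cells x sites matrix for normal cells;
#'   any site called in any normal cell is removed.
#' @return character vector of retained site ids.
#' @export
call_clonal_mutations <- function(clone_calls, min_concordant = 2L,
                                  bulk_germline = character(0),
                                  normal_cell_calls = NULL) {
  if (is.null(dim(clone_calls)) || nrow(clone_calls) < 2)
    stop("clonal calling needs at least 2 cells in the clone")
  counts <- colSums(clone_calls == 1L, na.rm = TRUE)
  keep <- names(counts)[counts >= min_concordant]
  keep <- setdiff(keep, bulk_germline)
  if (!is.null(normal_cell_calls)) {
    normal_hits <- colnames(normal_cell_calls)[
      colSums(normal_cell_calls == 1L, na.rm = TRUE) > 0]
    keep <- setdiff(keep, normal_hits)
  }
  keep
}

#' Per-cell mutation-burden estimate with normal-cell baseline subtraction
#'
#' The background rate from amplification artifacts, somatic mosaicism in
#' normal cells and miscalls is removed by subtracting the mean call rate
#' of the normal cells from each tumor cell's rate.
#'
#' @param cell_call_rates named numeric vector of raw per-cell mutation
#'   counts (tumor cells).
#' @param normal_cell_call_rates numeric vector of raw counts in normal
#'   cells (>= 1 value).
#' @param callable_mb callable genome size in megabases used for the
#'   per-Mb rate (default 2800).
#' @return data.frame with `cell`, `raw`, `corrected`, `per_mb`; negative
#'   corrected burdens are kept as-is with a warning.
#' @export
estimate_burden <- function(cell_call_rates, normal_cell_call_rates,
                            callable_mb = 2800) {
  if (length(normal_cell_call_rates) < 1)
    stop("at least one normal cell is required")
  baseline <- mean(normal_cell_call_rates)
  corrected <- cell_call_rates - baseline
  if (any(corrected < 0))
    warning("negative corrected burden for ",
            sum(corrected < 0), " cell(s): possible over-correction")
  data.frame(
    cell = names(cell_call_rates) %||% seq_along(cell_call_rates),
    raw = as.numeric(cell_call_rates),
    corrected = as.numeric(corrected),
    per_mb = as.numeric(corrected) / callable_mb,
    stringsAsFactors = FALSE
  )
}
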