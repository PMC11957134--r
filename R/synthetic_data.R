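#' Default sampling schedule for a serial clone-expansion experiment
#'
#' Describes an in vitro evolutionary design in which single cells are
#' sequentially isolated from an expanding parental culture, each founding a
#' clone that is expanded and then sampled.  The parental line ("P") is
#' sampled early; derived clones are founded at regular intervals and
#' sampled after a fixed expansion period, so sampled cells span a wide
#' range of total culture times.
#'
#' @param n_clones number of derived clones (default 7).
#' @param cells_per_clone cells sampled per derived clone (default 2).
#' @param parental_cells cells sampled from the parental line (default 2).
#' @param founding_interval days between successive clone foundings.
#' @param expansion_days days each derived clone is expanded before sampling.
#' @return data.frame with columns `clone`, `founded_day`, `sampled_day`,
#'   `n_cells`.  Row one is the parental line founded at day 0.
#' @export
default_sampling_schedule <- function(n_clones = 7, cells_per_clone = 2,
                                      parental_cells = 2,
                                      founding_interval = 7,
                                      expansion_days = 14) {
  stopifnot(n_clones >= 1, cells_per_clone >= 1, parental_cells >= 1)
  founded <- founding_interval * seq_len(n_clones)
  data.frame(
    clone = c("P", paste0("C", seq_len(n_clones))),
    founded_day = c(0, founded),
    sampled_day = c(founding_interval, founded + expansion_days),
    n_cells = c(parental_cells, rep(cells_per_clone, n_clones)),
    stringsAsFactors = FALSE
  )
}

#' Simulate a clone tree with Poisson mutation accumulation
#'
#' Builds the cell-level truth for a serial expansion experiment: derived
#' clones branch off the parental lineage at their founding day, cells
#' within a clone diverge at the clone's founding, and every branch
#' accumulates mutations as a Poisson count with mean
#' `mutations_per_day * branch duration`.  A cell's truth genotype is the
#' union of mutations on its root-to-tip path, so branch lengths (and
#' root-to-tip mutation counts) are proportional to culture time in
#' expectation.
#'
#' @param n_cells total cells; must equal `sum(sampling_schedule$n_cells)`.
#' @param n_clones number of derived clones; must match the schedule.
#' @param mutations_per_day mutation accumulation rate (> 0), mutations per
#'   day along a lineage.
#' @param sampling_schedule data.frame as returned by
#'   [default_sampling_schedule()].
#' @param genome_size genome length (bp) over which mutation positions are
#'   placed uniformly.
#' @param context_distribution optional probability vector over the 96
#'   trinucleotide substitution categories (names as [sbs96_contexts()])
#'   from which each mutation's base change is drawn; default uniform.
#' @param clone_split_fraction fraction of a clone's expansion period at
#'   which its sampled cells diverge from each other (cells drawn from an
#'   expanded clone coalesce close to its founding; default 0.2).
#' @param seed integer seed; identical seeds give identical output.
#' @return object of class `clone_truth`: a list with
#'   \describe{
#'     \item{tree_days}{rooted `phylo`, edge lengths in days}
#'     \item{tree_mutations}{same topology, edge lengths = realized
#'       per-branch mutation counts}
#'     \item{clone_of_cell}{named character vector cell -> clone}
#'     \item{culture_time}{named numeric vector, days of culture per cell}
#'     \item{mutations}{data.frame: id, edge, chrom, pos, ref, alt, context,
#'       category}
#'     \item{genotypes}{cells x mutations 0/1 truth matrix}
#'     \item{cnv_events}{data.frame of injected copy-number events
#'       (initially empty)}
#'   }
#' @export
simulate_clone_tree <- function(n_cells = 16, n_clones = 7,
                                mutations_per_day = 8,
                                sampling_schedule = default_sampling_schedule(n_clones),
                                genome_size = 1e8,
                                context_distribution = NULL,
                                clone_split_fraction = 0.2,
                                seed = NULL) {
  if (!is.numeric(mutations_per_day) || mutations_per_day <= 0)
    stop("`mutations_per_day` must be > 0")
  sched <- sampling_schedule
  stopifnot(all(c("clone", "founded_day", "sampled_day", "n_cells") %in% names(sched)))
  if (any(sched$sampled_day < sched$founded_day))
    stop("sampled_day must be >= founded_day for every clone")
  if (sum(sched$n_cells) != n_cells)
    stop("n_cells (", n_cells, ") does not match the schedule total (",
         sum(sched$n_cells), ")")
  derived <- sched[sched$clone != "P", , drop = FALSE]
  if (nrow(derived) != n_clones)
    stop("n_clones does not match the number of derived clones in the schedule")
  if (n_clones > n_cells) stop("n_clones must be <= n_cells")

  derived <- derived[order(derived$founded_day), , drop = FALSE]
  parental <- sched[sched$clone == "P", , drop = FALSE]

  tip_of <- function(clone, i) paste0(clone, "_", i)
  # Lineage of one clone hanging off the backbone node at its founding
  # day: a founder stem down to the within-clone divergence (placed
  # `clone_split_fraction` into the expansion, since cells sampled from
  # an expanded clone coalesce close to its founding), then the cells.
  clone_group <- function(row) {
    span <- row$sampled_day - row$founded_day
    if (row$n_cells == 1)
      return(list(str = tip_of(row$clone, 1), stem = span))
    d <- clone_split_fraction * span
    tips <- paste0(tip_of(row$clone, seq_len(row$n_cells)), ":", span - d)
    list(str = paste0("(", paste(tips, collapse = ","), ")"), stem = d)
  }
  # Backbone recursion: subtree rooted at the backbone node at clone j's
  # founding day (for the last clone, at its within-clone divergence).
  backbone <- function(j) {
    row <- derived[j, ]
    cg <- clone_group(row)
    if (j == nrow(derived))
      return(list(str = cg$str, attach = row$founded_day + cg$stem))
    inner <- backbone(j + 1)
    list(str = paste0("(", cg$str, ":", cg$stem, ",", inner$str, ":",
                      inner$attach - row$founded_day, ")"),
         attach = row$founded_day)
  }
  bb <- backbone(1)
  p_tips <- if (nrow(parental) == 1)
    paste0(tip_of(parental$clone, seq_len(parental$n_cells)), ":",
           parental$sampled_day - parental$founded_day)
  else character(0)
  nwk <- paste0("(", paste(c(p_tips, paste0(bb$str, ":", bb$attach)),
                           collapse = ","), ");")
  tree <- ape::read.tree(text = nwk)

  clone_of_cell <- sub("_[0-9]+$", "", tree$tip.label)
  names(clone_of_cell) <- tree$tip.label
  culture_time <- sched$sampled_day[match(clone_of_cell, sched$clone)]
  names(culture_time) <- tree$tip.label

  with_seed(seed, {
    durations <- tree$edge.length
    m_per_edge <- rpois(length(durations), mutations_per_day * durations)
    n_mut <- sum(m_per_edge)
    edge_of_mut <- rep(seq_along(durations), m_per_edge)

    contexts <- sbs96_contexts()
    probs <- context_distribution %||% rep(1 / 96, 96)
    if (!is.null(names(probs))) probs <- probs[contexts]
    stopifnot(length(probs) == 96, all(probs >= 0))
    cat_idx <- if (n_mut > 0)
      sample.int(96, n_mut, replace = TRUE, prob = probs) else integer(0)
    cat_names <- contexts[cat_idx]
    ref <- substr(cat_names, 3, 3)
    alt <- substr(cat_names, 5, 5)
    context <- paste0(substr(cat_names, 1, 1), ref, substr(cat_names, 7, 7))
    pos <- if (n_mut > 0) sort(sample.int(genome_size, n_mut)) else integer(0)

    mutations <- data.frame(
      id = if (n_mut > 0) paste0("m", seq_len(n_mut)) else character(0),
      edge = edge_of_mut,
      chrom = rep("1", n_mut),
      pos = pos, ref = ref, alt = alt, context = context,
      category = cat_names,
      stringsAsFactors = FALSE
    )

    # genotype = union of mutations on the root-to-tip path
    tip_edges <- edges_on_root_paths(tree)
    G <- matrix(0L, nrow = length(tree$tip.label), ncol = n_mut,
                dimnames = list(tree$tip.label, mutations$id))
    for (i in seq_along(tree$tip.label)) {
      on_path <- edge_of_mut %in% tip_edges[[i]]
      G[i, on_path] <- 1L
    }

    tree_mut <- tree
    tree_mut$edge.length <- as.numeric(m_per_edge)

    structure(list(
      tree_days = tree,
      tree_mutations = tree_mut,
      clone_of_cell = clone_of_cell,
      culture_time = culture_time,
      schedule = sched,
      mutations = mutations,
      genotypes = G,
      cnv_events = data.frame(clone = character(0), chrom = character(0),
                              start = integer(0), end = integer(0),
                              lost_haplotype = character(0))
    ), class = "clone_truth")
  })
}

# list, per tip index, of edge indices on the root-to-tip path
edges_on_root_paths <- function(tree) {
  n_tip <- length(tree$tip.label)
  parent_edge <- integer(max(tree$edge))
  parent_edge[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  root <- n_tip + 1L
  lapply(seq_len(n_tip), function(tip) {
    path <- integer(0)
    node <- tip
    while (node != root) {
      e <- parent_edge[node]
      path <- c(path, e)
      node <- tree$edge[e, 1]
    }
    path
  })
}

#' @export
print.clone_truth <- function(x, ...) {
  cat("clone_truth:", length(x$clone_of_cell), "cells,",
      length(unique(x$clone_of_cell)), "clones,",
      nrow(x$mutations), "mutations,",
      nrow(x$cnv_events), "CNV events\n")
  invisible(x)
}

#' Whole-genome-amplification noise profile
#'
#' Bundles the parameters of the single-cell WGA read-count model: the
#' locus-level allelic dropout rate, the per-read amplification/sequencing
#' error rate, the Beta overdispersion of the allelic balance at covered
#' heterozygous sites, and the mean total depth per site.
#'
#' @param ado_rate locus-level allelic dropout probability in \[0, 1\]: the
#'   expected fraction of covered heterozygous sites at which exactly one
#'   allele is observed.
#' @param amp_error_rate per-read probability that the read reports the
#'   opposite allele, in \[0, 1\].
#' @param imbalance_dispersion Beta overdispersion (> 0) of the allelic
#'   balance; the ref-allele fraction at a biallelic site is drawn from
#'   Beta(a, a) with `a = 0.5 / imbalance_dispersion`, so values near 0 give
#'   balanced amplification and values near 1 give the U-shaped imbalance
#'   typical of displacement amplification.
#' @param mean_depth mean total reads per site (> 0).
#' @return object of class `wga_profile`.
#' @export
wga_profile <- function(ado_rate, amp_error_rate = 0.002,
                        imbalance_dispersion = 0.05, mean_depth = 30) {
  stopifnot(ado_rate >= 0, ado_rate <= 1,
            amp_error_rate >= 0, amp_error_rate <= 1,
            imbalance_dispersion > 0, mean_depth > 0)
  structure(list(ado_rate = ado_rate, amp_error_rate = amp_error_rate,
                 imbalance_dispersion = imbalance_dispersion,
                 mean_depth = mean_depth),
            class = "wga_profile")
}

#' PTA-like amplification profile (low dropout, mild imbalance)
#' @param mean_depth mean total reads per site.
#' @return `wga_profile` with `ado_rate = 0.057`.
#' @export
pta_profile <- function(mean_depth = 30) {
  wga_profile(ado_rate = 0.057, amp_error_rate = 0.002,
              imbalance_dispersion = 0.05, mean_depth = mean_depth)
}

#' MDA-like amplification profile (high dropout, strong imbalance)
#' @param mean_depth mean total reads per site.
#' @return `wga_profile` with `ado_rate = 0.164`.
#' @export
mda_profile <- function(mean_depth = 30) {
  wga_profile(ado_rate = 0.164, amp_error_rate = 0.005,
              imbalance_dispersion = 0.5, mean_depth = mean_depth)
}

#' Simulate a germline heterozygous SNP panel
#'
#' @param n_snps number of het SNPs.
#' @param genome_size genome length in bp (positions uniform, unique).
#' @param chrom chromosome label.
#' @param seed integer seed.
#' @return data.frame with `chrom`, `pos` (sorted, 1-based).
#' @export
simulate_het_snps <- function(n_snps, genome_size = 1e8, chrom = "1",
                              seed = NULL) {
  stopifnot(n_snps >= 1, n_snps <= genome_size)
  with_seed(seed, {
    data.frame(chrom = chrom, pos = sort(sample.int(genome_size, n_snps)),
               stringsAsFactors = FALSE)
  })
}

#' Simulate WGA-distorted allele depths
#'
#' Generates per-cell, per-site ref/alt read counts at germline
#' heterozygous SNPs and at somatic variant sites, under the WGA model: at
#' a heterozygous site each allele drops out independently (per-allele drop
#' probability `q = ado / (2 - ado)`, so the fraction of covered sites
#' showing exactly one allele converges to `ado_rate`); surviving alleles
#' split a Poisson total depth with Beta-Binomial imbalance; and each read
#' reports the opposite allele with probability `amp_error_rate`.
#'
#' @param truth_genotypes a `clone_truth` object, or a cells x sites 0/1
#'   matrix of somatic truth genotypes (1 = heterozygous variant).
#' @param profile a [wga_profile()].
#' @param het_snps data.frame of germline het SNPs (`chrom`, `pos`), or
#'   NULL to simulate somatic sites only.
#' @param seed integer seed.
#' @return data.frame with columns `cell`, `chrom`, `pos`, `site_id`,
#'   `site_type` ("germline_het" or "somatic"), `true_gt` (0 hom-ref,
#'   1 het), `ref_depth`, `alt_depth`.
#' @export
simulate_wga_readcounts <- function(truth_genotypes, profile = pta_profile(),
                                    het_snps = NULL, seed = NULL) {
  stopifnot(inherits(profile, "wga_profile"))
  if (inherits(truth_genotypes, "clone_truth")) {
    G <- truth_genotypes$genotypes
    som_sites <- truth_genotypes$mutations[, c("chrom", "pos")]
    som_ids <- truth_genotypes$mutations$id
  } else {
    G <- truth_genotypes
    if (is.null(G) || nrow(G) == 0)
      stop("empty genotype matrix")
    som_ids <- colnames(G) %||% (if (ncol(G) > 0) paste0("m", seq_len(ncol(G))) else character(0))
    som_sites <- data.frame(chrom = rep("1", ncol(G)), pos = seq_len(ncol(G)))
  }
  if (nrow(G) == 0) stop("empty genotype matrix")
  cells <- rownames(G) %||% paste0("cell", seq_len(nrow(G)))

  blocks <- list()
  if (!is.null(het_snps) && nrow(het_snps) > 0) {
    n <- nrow(het_snps)
    blocks$germ <- data.frame(
      cell = rep(cells, each = n),
      chrom = rep(het_snps$chrom, times = length(cells)),
      pos = rep(het_snps$pos, times = length(cells)),
      site_id = rep(paste0("snp", seq_len(n)), times = length(cells)),
      site_type = "germline_het",
      true_gt = 1L,
      stringsAsFactors = FALSE
    )
  }
  if (ncol(G) > 0) {
    n <- ncol(G)
    blocks$som <- data.frame(
      cell = rep(cells, each = n),
      chrom = rep(som_sites$chrom, times = length(cells)),
      pos = rep(som_sites$pos, times = length(cells)),
      site_id = rep(som_ids, times = length(cells)),
      site_type = "somatic",
      true_gt = as.integer(t(G)),
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, blocks)
  if (is.null(tab) || nrow(tab) == 0) stop("no sites to simulate")
  rownames(tab) <- NULL

  with_seed(seed, {
    n <- nrow(tab)
    depth <- rpois(n, profile$mean_depth)
    q <- profile$ado_rate / (2 - profile$ado_rate)  # per-allele drop prob
    a <- 0.5 / profile$imbalance_dispersion

    het <- tab$true_gt == 1L
    drop_ref <- het & (runif(n) < q)
    drop_alt <- het & (runif(n) < q)

    p_ref <- rbeta(n, a, a)           # ref fraction when both alleles survive
    p_ref[!het | drop_ref] <- 0
    p_ref[het & drop_alt & !drop_ref] <- 1
    p_ref[het & drop_ref & drop_alt] <- NA  # both dropped: no template
    p_ref[!het] <- 1                  # hom ref

    eff_depth <- depth
    eff_depth[het & drop_ref & drop_alt] <- 0L
    ref <- rbinom(n, eff_depth, ifelse(is.na(p_ref), 0, p_ref))
    alt <- eff_depth - ref

    e <- profile$amp_error_rate
    flip_to_alt <- rbinom(n, ref, e)
    flip_to_ref <- rbinom(n, alt, e)
    tab$ref_depth <- ref - flip_to_alt + flip_to_ref
    tab$alt_depth <- alt - flip_to_ref + flip_to_alt
    tab
  })
}

#' Inject a hemizygous-deletion CNV into simulated allele depths
#'
#' In carrier cells, every germline het SNP inside the half-open interval
#' \[start, end) has the lost haplotype's allele depth replaced by
#' amplification-error background only: all real reads move to the kept
#' allele and the lost allele retains only error reads.  Phase (which
#' allele sits on the lost haplotype) is drawn once per SNP.
#'
#' @param readcounts output of [simulate_wga_readcounts()].
#' @param carrier_cells character vector of carrier cell names, or a
#'   `clone_truth` plus `clone` to resolve them.
#' @param event list or one-row data.frame with `chrom`, `start`, `end`
#'   (0-based half-open) and optionally `clone`.
#' @param truth optional `clone_truth` used to resolve `event$clone` into
#'   carrier cells.
#' @param amp_error_rate background error rate used for the lost allele.
#' @param seed integer seed (phase and background draws).
#' @return modified readcounts; the event is appended to
#'   `attr(, "cnv_events")`.
#' @export
inject_cnv <- function(readcounts, carrier_cells = NULL, event,
                       truth = NULL, amp_error_rate = 0.002, seed = NULL) {
  ev <- as.list(event)
  stopifnot(!is.null(ev$chrom), !is.null(ev$start), !is.null(ev$end),
            ev$end > ev$start)
  if (is.null(carrier_cells)) {
    if (is.null(truth) || is.null(ev$clone))
      stop("provide carrier_cells, or truth plus event$clone")
    carrier_cells <- names(truth$clone_of_cell)[truth$clone_of_cell == ev$clone]
  }
  in_region <- readcounts$site_type == "germline_het" &
    readcounts$chrom == ev$chrom &
    readcounts$pos >= ev$start & readcounts$pos < ev$end
  if (!any(in_region)) {
    warning("CNV interval overlaps no het sites; no-op")
    return(readcounts)
  }
  target <- in_region & readcounts$cell %in% carrier_cells

  with_seed(seed, {
    # per-SNP phase: TRUE = ref allele lies on the lost haplotype
    snps <- unique(readcounts$pos[in_region])
    lost_is_ref <- setNames(runif(length(snps)) < 0.5, snps)
    idx <- which(target)
    lose_ref <- lost_is_ref[as.character(readcounts$pos[idx])]
    total <- readcounts$ref_depth[idx] + readcounts$alt_depth[idx]
    bg <- rbinom(length(idx), total, amp_error_rate)
    kept <- total - bg
    readcounts$ref_depth[idx] <- ifelse(lose_ref, bg, kept)
    readcounts$alt_depth[idx] <- ifelse(lose_ref, kept, bg)
    attr(readcounts, "cnv_events") <- rbind(
      attr(readcounts, "cnv_events"),
      data.frame(chrom = ev$chrom, start = ev$start, end = ev$end,
                 clone = ev$clone %||% NA_character_,
                 lost_haplotype = ev$lost_haplotype %||% "A",
                 stringsAsFactors = FALSE))
    readcounts
  })
}

#' Simulate UMI read families with polymerase/sequencing error
#'
#' Each original molecule is assigned the variant allele with probability
#' `true_vaf`; a family of reads copies the molecule's sequence with
#' independent per-base errors (an error substitutes a uniformly chosen
#' different base).  Family sizes are drawn from `reads_per_family`
#' (default truncated negative binomial, minimum 1).
#'
#' @param true_vaf variant allele fraction in \[0, 1\].
#' @param n_molecules number of original molecules (> 0).
#' @param reads_per_family function(n) returning n integer family sizes
#'   (>= 1), or a fixed integer.
#' @param per_read_error per-base error probability per read (>= 0).
#' @param seq_length length of the simulated molecule sequence; the variant
#'   base sits at the middle position.
#' @param seed integer seed.
#' @return object of class `umi_family_set`: list with `families` (each a
#'   list `umi`, `reads` character matrix reads x positions, `true_allele`),
#'   `ref_seq`, `alt_seq`, `focal_pos`, `true_vaf`.
#' @export
simulate_umi_families <- function(true_vaf, n_molecules,
                                  reads_per_family = NULL,
                                  per_read_error = 0.001,
                                  seq_length = 1, seed = NULL) {
  stopifnot(true_vaf >= 0, true_vaf <= 1, n_molecules > 0)
  if (per_read_error < 0) stop("per_read_error must be >= 0")
  if (is.null(reads_per_family)) {
    reads_per_family <- function(n) {
      sizes <- rnbinom(n, size = 2, mu = 4)
      while (any(sizes < 1)) {
        redo <- sizes < 1
        sizes[redo] <- rnbinom(sum(redo), size = 2, mu = 4)
      }
      sizes
    }
  } else if (is.numeric(reads_per_family)) {
    k <- as.integer(reads_per_family)
    stopifnot(k >= 1)
    reads_per_family <- function(n) rep(k, n)
  }
  bases <- c("A", "C", "G", "T")

  with_seed(seed, {
    ref_seq <- sample(bases, seq_length, replace = TRUE)
    focal <- (seq_length + 1L) %/% 2L
    alt_seq <- ref_seq
    alt_seq[focal] <- sample(setdiff(bases, ref_seq[focal]), 1)

    is_alt <- runif(n_molecules) < true_vaf
    sizes <- reads_per_family(n_molecules)
    families <- vector("list", n_molecules)
    for (i in seq_len(n_molecules)) {
      mol <- if (is_alt[i]) alt_seq else ref_seq
      nr <- sizes[i]
      reads <- matrix(rep(mol, each = nr), nrow = nr)
      if (per_read_error > 0) {
        err <- which(matrix(runif(nr * seq_length) < per_read_error, nrow = nr))
        if (length(err)) {
          cur <- reads[err]
          reads[err] <- vapply(cur, function(b) sample(setdiff(bases, b), 1), "")
        }
      }
      families[[i]] <- list(umi = sprintf("UMI%06d", i), reads = reads,
                            true_allele = if (is_alt[i]) "alt" else "ref")
    }
    structure(list(families = families,
                   ref_seq = paste(ref_seq, collapse = ""),
                   alt_seq = paste(alt_seq, collapse = ""),
                   focal_pos = focal, true_vaf = true_vaf),
              class = "umi_family_set")
  })
}

#' @export
print.umi_family_set <- function(x, ...) {
  sizes <- vapply(x$families, function(f) nrow(f$reads), 0L)
  cat("umi_family_set:", length(x$families), "families, mean size",
      round(mean(sizes), 2), "- true VAF", x$true_vaf, "\n")
  invisible(x)
}

#' Fraction of molecules carrying the variant allele (truth accessor)
#' @param ufs a `umi_family_set`.
#' @return numeric fraction.
#' @export
true_alt_fraction <- function(ufs) {
  mean(vapply(ufs$families, function(f) f$true_allele == "alt", TRUE))
}

#' Simulate reads co-spanning a candidate somatic SNV and a het SNP
#'
#' Generates the linked-read evidence used to estimate somatic-call
#' precision.  A true somatic variant arose on one germline haplotype, so
#' its variant reads all carry the same het-SNP allele; a WGA artifact
#' arises independently during amplification and its variant reads appear
#' on both haplotypes.  Each candidate receives `reads_per_candidate`
#' spanning reads split evenly between haplotypes; sequencing errors flip
#' the somatic allele on a read with probability `seq_error`.
#'
#' @param n_candidates number of candidate somatic SNVs.
#' @param true_fraction exact fraction of candidates that are true
#'   variants (the rest are artifacts).
#' @param reads_per_candidate spanning reads per candidate.
#' @param artifact_vaf fraction of reads showing the artifact allele
#'   (drawn per read on either haplotype).
#' @param seq_error per-read probability of flipping the somatic allele.
#' @param seed integer seed.
#' @return list with `read_pairs` (data.frame `candidate`, `het_allele`,
#'   `ssnv_allele`) and `truth` (data.frame `candidate`, `is_true`).
#' @export
simulate_linked_reads <- function(n_candidates = 200, true_fraction = 0.92,
                                  reads_per_candidate = 20,
                                  artifact_vaf = 0.4, seq_error = 0.005,
                                  seed = NULL) {
  stopifnot(true_fraction >= 0, true_fraction <= 1, reads_per_candidate >= 2)
  n_true <- round(true_fraction * n_candidates)
  with_seed(seed, {
    rows <- lapply(seq_len(n_candidates), function(i) {
      is_true <- i <= n_true
      hap <- sample(rep(c("A", "B"), length.out = reads_per_candidate))
      if (is_true) {
        mut_hap <- sample(c("A", "B"), 1)
        allele <- ifelse(hap == mut_hap, "alt", "ref")
      } else {
        allele <- ifelse(runif(reads_per_candidate) < artifact_vaf,
                         "alt", "ref")
      }
      flip <- runif(reads_per_candidate) < seq_error
      allele[flip] <- ifelse(allele[flip] == "alt", "ref", "alt")
      data.frame(candidate = sprintf("cand%04d", i), het_allele = hap,
                 ssnv_allele = allele, stringsAsFactors = FALSE)
    })
    list(read_pairs = do.call(rbind, rows),
         truth = data.frame(candidate = sprintf("cand%04d", seq_len(n_candidates)),
                            is_true = seq_len(n_candidates) <= n_true,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate heritable surface-marker phenotypes on a cell tree
#'
#' Marker values evolve by Brownian motion along branches (variance
#' accumulating at `bm_rate` per unit branch length) with i.i.d. Gaussian
#' measurement noise added at the tips.  With `noise_sd = 0` the trait
#' covariance between two cells equals `bm_rate` times their shared
#' root-to-tip path length.
#'
#' @param cell_tree rooted `phylo` with non-negative branch lengths.
#' @param n_markers number of independent markers.
#' @param bm_rate Brownian-motion variance rate (>= 0).
#' @param noise_sd tip measurement noise standard deviation (>= 0).
#' @param root_value trait value at the root.
#' @param marker_names optional column names.
#' @param seed integer seed.
#' @return cells x markers numeric matrix.
#' @export
simulate_phenotypes <- function(cell_tree, n_markers = 6, bm_rate = 1,
                                noise_sd = 0, root_value = 0,
                                marker_names = NULL, seed = NULL) {
  stopifnot(inherits(cell_tree, "phylo"), n_markers >= 1,
            bm_rate >= 0, noise_sd >= 0)
  if (any(cell_tree$edge.length < 0)) stop("tree has negative branch lengths")
  n <- length(cell_tree$tip.label)
  V <- ape::vcv(cell_tree)

  with_seed(seed, {
    X <- matrix(root_value, nrow = n, ncol = n_markers,
                dimnames = list(rownames(V),
                                marker_names %||% paste0("marker", seq_len(n_markers))))
    if (bm_rate > 0) {
      # BM tip values ~ MVN(root, bm_rate * V); V is PSD, use eigen root
      eg <- eigen(V, symmetric = TRUE)
      lam <- pmax(eg$values, 0)
      L <- eg$vectors %*% diag(sqrt(lam), n)
      Z <- matrix(rnorm(n * n_markers), nrow = n)
      X <- X + sqrt(bm_rate) * (L %*% Z)
    }
    if (noise_sd > 0)
      X <- X + matrix(rnorm(n * n_markers, sd = noise_sd), nrow = n)
    X
  })
}
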