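#' Default end-to-end pipeline configuration
#'
#' Every stage parameter of [run_pipeline()] with its default.  The
#' simulated study mirrors a serial clone-expansion experiment: 16 cells
#' in 7 derived clones plus a parental pair, PTA-like amplification at
#' 30x, a hemizygous deletion spanning 60 five-kb windows in clone C1,
#' and clone-structured phenotypes.  A single top-level seed fans out to
#' per-stage child seeds so disabling one stage does not perturb the
#' random stream of another.
#'
#' @return nested list of stage parameters.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    stages = c("simulate", "qc", "clonal", "cnv", "tree", "timecal",
               "skyline", "abc", "signatures", "treatment", "emergent"),
    simulate = list(
      n_cells = 16L, n_clones = 7L, mutations_per_day = 8,
      n_het_snps = 8000L, genome_size = 1e7, profile = "pta",
      cnv = list(clone = "C1", chrom = "1", start = 2e6, end = 2.3e6),
      phenotype_markers = 4L, bm_rate = 1, noise_sd = 0.2
    ),
    qc = list(min_depth = 5L),
    clonal = list(min_concordant = 2L),
    cnv = list(window = 5000L, min_snps_per_window = 3L, min_depth = 8L,
               min_cells = 5L, n_bootstrap = 25L),
    tree = list(method = "nj", n_bootstrap = 25L),
    timecal = list(n_samples = 1000L),
    skyline = list(),
    abc = list(n_sims = 300L, tolerance_quantile = 0.1,
               generations_total = 120L, N = 500L,
               priors = list(t0 = c(1, 100), s = c(0, 0.5))),
    signatures = list(k = 2L, n_restarts = 4L),
    treatment = list(k_rows = 2L),
    emergent = list(detection_limit = 0.005, pre_cell_count = 60L)
  )
}

#' Run the synthetic-to-report analysis pipeline
#'
#' Executes the toggled stages in dependency order — simulate, per-cell
#' QC, clonal calling, BAF-window CNV with ROC, phylogeny with bootstrap
#' and branch-time correlation, Poisson time calibration, skyline,
#' Wright-Fisher ABC, SBS96 signatures, treatment clustering and
#' emergent-clone detection — writing versioned plain-text outputs and a
#' log into `outdir`.  A stage failure halts its downstream dependents
#' while retaining partial outputs; reruns with the same config and seed
#' give byte-identical outputs.
#'
#' @param config nested list as from [default_config()] (partial configs
#'   are merged over the defaults).
#' @param outdir output directory (created if needed).
#' @param seed optional override of `config$seed`.
#' @return invisibly, a summary list with per-stage status ("ok",
#'   "failed", "skipped", "disabled") and key results; also written as
#'   `summary.json`.
#' @export
run_pipeline <- function(config = default_config(), outdir, seed = NULL) {
  cfg <- utils::modifyList(default_config(), config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "run.log")
  logf <- function(...) cat(..., "\n", file = log_path,
                            append = TRUE, sep = "")
  unlink(log_path)
  yaml::write_yaml(cfg, file.path(outdir, "config.yaml"))

  deps <- list(
    simulate = character(0),
    qc = "simulate", clonal = "simulate", cnv = "simulate",
    tree = "simulate", timecal = "tree", skyline = "timecal",
    abc = "timecal", signatures = c("simulate", "tree"),
    treatment = character(0), emergent = "simulate"
  )
  status <- setNames(rep("disabled", length(deps)), names(deps))
  status[cfg$stages] <- "pending"
  env <- new.env(parent = emptyenv())
  summary <- list(seed = cfg$seed)

  run_stage <- function(name, fun) {
    if (status[[name]] != "pending") return(invisible(NULL))
    failed_dep <- deps[[name]][status[deps[[name]]] != "ok"]
    if (length(failed_dep)) {
      status[[name]] <<- "skipped"
      logf("SKIP ", name, " (dependency not ok: ",
           paste(failed_dep, collapse = ", "), ")")
      return(invisible(NULL))
    }
    res <- tryCatch({
      out <- fun()
      status[[name]] <<- "ok"
      logf("OK   ", name)
      out
    }, error = function(e) {
      status[[name]] <<- "failed"
      logf("FAIL ", name, ": ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) summary[[name]] <<- res
    invisible(NULL)
  }

  run_stage("simulate", function() {
    p <- cfg$simulate
    truth <- simulate_clone_tree(
      n_cells = p$n_cells, n_clones = p$n_clones,
      mutations_per_day = p$mutations_per_day,
      sampling_schedule = default_sampling_schedule(p$n_clones),
      genome_size = p$genome_size,
      seed = stage_seed(cfg$seed, "simulate"))
    profile <- switch(p$profile, pta = pta_profile(), mda = mda_profile(),
                      stop("unknown profile: ", p$profile))
    snps <- simulate_het_snps(p$n_het_snps, p$genome_size,
                              seed = stage_seed(cfg$seed, "simulate") + 1L)
    rc <- simulate_wga_readcounts(truth, profile, snps,
                                  seed = stage_seed(cfg$seed, "simulate") + 2L)
    rc <- inject_cnv(rc, event = p$cnv, truth = truth,
                     amp_error_rate = profile$amp_error_rate,
                     seed = stage_seed(cfg$seed, "simulate") + 3L)
    pheno <- simulate_phenotypes(truth$tree_days, p$phenotype_markers,
                                 bm_rate = p$bm_rate, noise_sd = p$noise_sd,
                                 seed = stage_seed(cfg$seed, "phenotypes"))
    env$truth <- truth; env$rc <- rc; env$profile <- profile
    env$pheno <- pheno; env$snps <- snps

    write_vcf(cbind(truth$mutations[, c("chrom", "pos", "ref", "alt")],
                    id = truth$mutations$id), file.path(outdir, "truth.vcf"))
    ape::write.tree(truth$tree_mutations, file.path(outdir, "truth_tree.nwk"))
    write_tsv_file(rc, file.path(outdir, "allele_depths.tsv"))
    write_bed(data.frame(chrom = p$cnv$chrom, start = p$cnv$start,
                         end = p$cnv$end, name = p$cnv$clone),
              file.path(outdir, "cnv_truth.bed"))
    write_tsv_file(data.frame(cell = rownames(pheno), pheno),
                   file.path(outdir, "phenotypes.tsv"))
    list(n_cells = p$n_cells, n_mutations = nrow(truth$mutations),
         n_het_snps = nrow(snps))
  })

  run_stage("qc", function() {
    rc <- env$rc
    per_cell <- lapply(split(rc, rc$cell), function(d) {
      ado <- estimate_ado(d, min_depth = cfg$qc$min_depth)
      rec <- estimate_recall_germline(d)
      data.frame(cell = d$cell[1], ado_rate = ado$ado_rate,
                 ado_sites = ado$n_sites, recall = rec$recall,
                 stringsAsFactors = FALSE)
    })
    qc <- do.call(rbind, per_cell)
    write_tsv_file(qc, file.path(outdir, "qc_report.tsv"))
    list(mean_ado = mean(qc$ado_rate), mean_recall = mean(qc$recall))
  })

  run_stage("clonal", function() {
    G <- call_genotypes(env$rc)
    env$G <- G
    clones <- split(names(env$truth$clone_of_cell), env$truth$clone_of_cell)
    clonal <- lapply(clones[lengths(clones) >= 2], function(cells)
      call_clonal_mutations(G[cells, , drop = FALSE],
                            min_concordant = cfg$clonal$min_concordant))
    df <- do.call(rbind, lapply(names(clonal), function(cl)
      if (length(clonal[[cl]]))
        data.frame(clone = cl, site_id = clonal[[cl]],
                   stringsAsFactors = FALSE)))
    write_tsv_file(df %||% data.frame(clone = character(0),
                                      site_id = character(0)),
                   file.path(outdir, "clonal_mutations.tsv"))
    list(n_clonal = nrow(df %||% data.frame()))
  })

  run_stage("cnv", function() {
    p <- cfg$cnv
    bwm <- window_mirrored_baf(env$rc, w = p$window,
                               min_snps_per_window = p$min_snps_per_window,
                               min_depth = p$min_depth,
                               min_cells = p$min_cells)
    ev <- cfg$simulate$cnv
    carriers <- names(env$truth$clone_of_cell)[
      env$truth$clone_of_cell == ev$clone]
    keys <- colnames(bwm$values)
    starts <- bwm$windows$start
    region <- keys[bwm$windows$chrom == ev$chrom &
                     starts >= ev$start & starts < ev$end]
    roc <- roc_evaluate(bwm, carriers, region_windows = region,
                        n_bootstrap = p$n_bootstrap,
                        seed = stage_seed(cfg$seed, "cnv"))
    write_tsv_file(roc$roc, file.path(outdir, "cnv_roc.tsv"))
    jsonlite::write_json(list(auc = roc$auc, auc_sd = roc$auc_sd),
                         file.path(outdir, "cnv_auc.json"),
                         auto_unbox = TRUE, digits = NA)
    list(auc = roc$auc)
  })

  run_stage("tree", function() {
    G <- env$G %||% call_genotypes(env$rc)
    env$G <- G
    tr <- bootstrap_support(G, n_reps = cfg$tree$n_bootstrap,
                            method = cfg$tree$method,
                            seed = stage_seed(cfg$seed, "tree"))
    env$tree <- tr
    ape::write.tree(tr, file.path(outdir, "tree.nwk"))
    ct <- correlate_branch_time(tr, env$truth$culture_time,
                                seed = stage_seed(cfg$seed, "tree") + 1L)
    rf <- phangorn::RF.dist(ape::unroot(tr),
                            ape::unroot(env$truth$tree_mutations))
    mono <- test_monophyly(tr, names(env$truth$clone_of_cell)[
      env$truth$clone_of_cell != "P"])
    list(rho_branch_time = ct$rho, rho_p = ct$p_value,
         rf_to_truth = rf, tumor_monophyletic = mono$monophyletic)
  })

  run_stage("timecal", function() {
    post <- time_calibrate(env$tree, rate = cfg$simulate$mutations_per_day,
                           n_samples = cfg$timecal$n_samples,
                           seed = stage_seed(cfg$seed, "timecal"))
    env$timecal <- post
    write_tsv_file(post$node_age, file.path(outdir, "node_ages.tsv"))
    list(lambda_mean = mean(post$lambda),
         max_tip_age_days = max(post$node_age$mean[post$node_age$is_tip]))
  })

  run_stage("skyline", function() {
    sky <- skyline_ne(make_ultrametric(env$timecal$mean_tree),
                      posterior_trees = lapply(
                        time_tree_samples(env$timecal, 25), make_ultrametric))
    write_tsv_file(sky$skyline, file.path(outdir, "skyline.tsv"))
    list(epsilon = sky$epsilon, n_epochs = nrow(sky$skyline))
  })

  run_stage("abc", function() {
    p <- cfg$abc
    ult <- make_ultrametric(env$timecal$mean_tree)
    clone_tips <- names(env$truth$clone_of_cell)[
      env$truth$clone_of_cell == "C1"]
    obs <- tree_summaries(ult, clone_tips)
    model <- list(generations_total = p$generations_total, N = p$N,
                  n_tips = length(ult$tip.label), gen_time = 1)
    post <- with_seed(stage_seed(cfg$seed, "abc"),
                      abc_infer(obs, priors = p$priors, model = model,
                                n_sims = p$n_sims,
                                tolerance_quantile = p$tolerance_quantile))
    write_tsv_file(post$accepted, file.path(outdir, "abc_posterior.tsv"))
    jsonlite::write_json(
      list(t0_mean = mean(post$accepted$t0), s_mean = mean(post$accepted$s),
           acceptance = post$acceptance_fraction),
      file.path(outdir, "abc_summary.json"), auto_unbox = TRUE, digits = NA)
    list(t0_mean = mean(post$accepted$t0), s_mean = mean(post$accepted$s))
  })

  run_stage("signatures", function() {
    muts <- env$truth$mutations
    muts$sample <- "truth"
    M <- sbs96_matrix(muts)
    fit <- fit_signatures(M, example_signature_catalog())
    write_tsv_file(data.frame(category = rownames(M), M),
                   file.path(outdir, "sbs96_counts.tsv"))
    write_tsv_file(data.frame(signature = rownames(fit$exposures),
                              fit$exposures),
                   file.path(outdir, "signature_exposures.tsv"))
    cls <- phylogeny_filter(env$G, env$tree)
    shared_ids <- cls$site_id[cls$class == "shared"]
    private_ids <- cls$site_id[cls$class == "private"]
    contrast <- if (length(shared_ids) && length(private_ids))
      early_late_contrast(muts[muts$id %in% shared_ids, ],
                          muts[muts$id %in% private_ids, ])
    list(fit_cosine = unname(fit$cosine["truth"]),
         n_shared = length(shared_ids), n_private = length(private_ids),
         n_enriched = if (!is.null(contrast)) sum(contrast$tests$significant)
         else NA_integer_)
  })

  run_stage("treatment", function() {
    M <- simulate_treatment_vaf(seed = stage_seed(cfg$seed, "treatment"))
    cl <- cluster_vaf_matrix(M, k_rows = cfg$treatment$k_rows)
    write_tsv_file(data.frame(mutation = rownames(M), M),
                   file.path(outdir, "treatment_vaf.tsv"))
    write_tsv_file(data.frame(mutation = names(cl$row_clusters),
                              cluster = cl$row_clusters),
                   file.path(outdir, "treatment_clusters.tsv"))
    list(n_row_clusters = length(unique(cl$row_clusters)))
  })

  run_stage("emergent", function() {
    # pre-treatment detection table: derived clones present at their tip
    # fraction, except the CNV clone which is absent pre-treatment
    truth <- env$truth
    clones <- setdiff(unique(truth$clone_of_cell), "P")
    frac <- table(truth$clone_of_cell)[clones] /
      length(truth$clone_of_cell)
    post_clones <- lapply(setNames(clones, clones), function(cl)
      paste0("marker_", cl))
    pre <- data.frame(
      feature = unlist(post_clones),
      vaf = ifelse(clones == cfg$simulate$cnv$clone, 0, as.numeric(frac) / 2))
    rep <- detect_emergent_clones(pre, post_clones,
                                  detection_limit = cfg$emergent$detection_limit,
                                  pre_cell_count = cfg$emergent$pre_cell_count,
                                  post_fraction = setNames(as.numeric(frac),
                                                           clones))
    jsonlite::write_json(rep, file.path(outdir, "emergent_clones.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    list(n_emergent = sum(rep$emergent))
  })

  summary$status <- as.list(status)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(summary)
}
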