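# Small fixtures shared across test files; everything is generated in
# code so the suite carries no data files.

# two-clone design used by the CNV tests: 8 carrier + 8 non-carrier cells
two_clone_cnv_sim <- function(seed, n_snps = 4000, genome = 5e6,
                              del_start = 2e6, del_end = 2.3e6,
                              profile = pta_profile()) {
  sched <- data.frame(clone = c("P", "C1"), founded_day = c(0, 7),
                      sampled_day = c(21, 21), n_cells = c(8, 8))
  truth <- simulate_clone_tree(n_cells = 16, n_clones = 1,
                               mutations_per_day = 2,
                               sampling_schedule = sched, seed = seed)
  snps <- simulate_het_snps(n_snps, genome, seed = seed + 1L)
  rc <- simulate_wga_readcounts(truth, profile, snps, seed = seed + 2L)
  carriers <- names(truth$clone_of_cell)[truth$clone_of_cell == "C1"]
  rc <- inject_cnv(rc, carrier_cells = carriers,
                   event = list(chrom = "1", start = del_start,
                                end = del_end),
                   amp_error_rate = profile$amp_error_rate,
                   seed = seed + 3L)
  list(truth = truth, rc = rc, carriers = carriers,
       del = c(del_start, del_end))
}

# the serial-expansion design: 16 cells / 7 clones + parental pair
serial_design_sim <- function(seed, profile = pta_profile(),
                              mutations_per_day = 8, n_snps = 2000) {
  truth <- simulate_clone_tree(seed = seed,
                               mutations_per_day = mutations_per_day)
  snps <- simulate_het_snps(n_snps, 1e8, seed = seed + 1L)
  rc <- simulate_wga_readcounts(truth, profile, snps, seed = seed + 2L)
  list(truth = truth, rc = rc, genotypes = call_genotypes(rc))
}

# depth table for one cell from explicit ref/alt vectors
depth_table <- function(ref, alt, pos = seq_along(ref), chrom = "1",
                        cell = "c1", site_type = "germline_het") {
  data.frame(cell = cell, chrom = chrom, pos = pos,
             site_id = paste0("s", seq_along(ref)), site_type = site_type,
             true_gt = 1L, ref_depth = ref, alt_depth = alt,
             stringsAsFactors = FALSE)
}
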