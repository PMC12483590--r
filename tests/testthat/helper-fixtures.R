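# shared fixture builders: everything is generated in code at test time

# small hand-built matrix: 4 features x 6 samples (3 lines x 2 reps)
tiny_matrix <- function(values = NULL, scale = "raw") {
  meta <- data.frame(
    sample = c("A_r1", "A_r2", "B_r1", "B_r2", "C_r1", "C_r2"),
    cell_line = rep(c("A", "B", "C"), each = 2),
    replicate = rep(c("r1", "r2"), 3),
    lineage = rep(c("g1", "g1", "g2"), each = 2),
    stringsAsFactors = FALSE)
  if (is.null(values)) {
    set.seed(42)
    values <- matrix(2^rnorm(24, 10, 1), 4, 6,
                     dimnames = list(paste0("P", 1:4), meta$sample))
  }
  abundance_matrix(values, meta, scale)
}

# quick preprocessing chain used across tests
preprocess <- function(m, min_frac = 0.05) {
  log2p1_median_normalize(impute_global_min(
    filter_low_detection(m, min_frac)))
}

fast_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_lines = 10, n_reps_per_line = 3, n_proteins = 200,
         n_phosphosites = 400, n_lineages = 2, n_markers_per_lineage = 5),
    list(...))
  do.call(sim_config, args)
}
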