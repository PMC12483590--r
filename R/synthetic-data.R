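#' Simulation configuration for the synthetic cell-line panel
#'
#' Parameterizes every synthetic input layer: a panel of `n_lines` cell
#' lines in `n_lineages` lineages measured in `n_reps_per_line` replicates.
#' Log2-scale variance components: `base_sd` (between-feature dynamic
#' range around `base_mean`), `lineage_effect_sd` (per-feature lineage
#' shifts), `line_sd` (between-line biological variation) and `noise_sd`
#' (replicate/technical noise). Lineage markers are up-shifted by
#' `marker_fold` (linear). Missingness is abundance-dependent (logistic in
#' log intensity) with overall rate `dropout_rate`. One global `seed` fans
#' out to per-table child seeds so adding one generator never perturbs
#' another's random stream.
#'
#' When `n_lines = 54` and `n_lineages = 7` the default lineage sizes are
#' 7/8/8/5/5/5/16, the composition of a typical pan-cancer panel; otherwise
#' lines are split near-equally (always configurable via `lineage_sizes`).
#'
#' @param n_lines,n_reps_per_line,n_proteins,n_phosphosites,n_lineages
#'   panel dimensions (all >= 1).
#' @param n_markers_per_lineage planted marker proteins per lineage.
#' @param marker_fold linear fold shift of markers in their lineage (> 1).
#' @param kinase_effect log2 shift applied to substrate sites of planted
#'   active kinases.
#' @param noise_sd,line_sd,lineage_effect_sd,base_sd log2-scale SDs.
#' @param base_mean log2-scale mean intensity.
#' @param dropout_rate overall missing-value probability in \[0, 1\].
#' @param rppa_noise_sd log2-scale SD of RPPA measurement noise; the
#'   default is calibrated so the default panel yields a median per-protein
#'   MS~RPPA Spearman correlation near 0.6.
#' @param cis_corr target Spearman correlation of planted cis CNA effects,
#'   in \[-1, 1\].
#' @param loc_below_frac fraction of phosphosites with localization
#'   probability below 0.75.
#' @param lineage_sizes optional integer vector of lines per lineage
#'   (length `n_lineages`, summing to `n_lines`).
#' @param seed integer; identical configs (incl. seed) give bit-identical
#'   outputs.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_lines = 20, n_reps_per_line = 3,
                       n_proteins = 1000, n_phosphosites = 1500,
                       n_lineages = 4, n_markers_per_lineage = 10,
                       marker_fold = 4, kinase_effect = 1.5,
                       noise_sd = 0.2, line_sd = 0.8,
                       lineage_effect_sd = 0.8, base_mean = 20,
                       base_sd = 2, dropout_rate = 0.1,
                       rppa_noise_sd = 1.2, cis_corr = 0.6,
                       loc_below_frac = 0.1, lineage_sizes = NULL,
                       seed = 1) {
  cfg <- list(n_lines = n_lines, n_reps_per_line = n_reps_per_line,
              n_proteins = n_proteins, n_phosphosites = n_phosphosites,
              n_lineages = n_lineages,
              n_markers_per_lineage = n_markers_per_lineage,
              marker_fold = marker_fold, kinase_effect = kinase_effect,
              noise_sd = noise_sd, line_sd = line_sd,
              lineage_effect_sd = lineage_effect_sd,
              base_mean = base_mean, base_sd = base_sd,
              dropout_rate = dropout_rate, rppa_noise_sd = rppa_noise_sd,
              cis_corr = cis_corr, loc_below_frac = loc_below_frac,
              seed = seed)
  counts <- c("n_lines", "n_reps_per_line", "n_proteins",
              "n_phosphosites", "n_lineages")
  for (nm in counts) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1 || v < 1 || v != round(v))
      stop("`", nm, "` must be a positive integer count")
  }
  for (nm in c("dropout_rate", "loc_below_frac")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop("`", nm, "` must be a probability in [0, 1]")
  }
  if (marker_fold <= 1) stop("`marker_fold` must be a linear fold > 1")
  if (abs(cis_corr) > 1) stop("`cis_corr` must lie in [-1, 1]")
  for (nm in c("noise_sd", "line_sd", "lineage_effect_sd", "base_sd",
               "rppa_noise_sd"))
    if (cfg[[nm]] < 0) stop("`", nm, "` must be >= 0")
  if (n_lineages > n_lines) stop("more lineages than lines")
  if (n_markers_per_lineage * n_lineages > n_proteins)
    stop("more planted markers than proteins")
  if (is.null(lineage_sizes)) {
    if (n_lines == 54 && n_lineages == 7) {
      lineage_sizes <- c(7L, 8L, 8L, 5L, 5L, 5L, 16L)
    } else {
      lineage_sizes <- diff(round(seq(0, n_lines,
                                      length.out = n_lineages + 1)))
    }
  }
  if (length(lineage_sizes) != n_lineages ||
      sum(lineage_sizes) != n_lines || any(lineage_sizes < 1))
    stop("`lineage_sizes` must have length n_lineages, entries >= 1, ",
         "and sum to n_lines")
  cfg$lineage_sizes <- as.integer(lineage_sizes)
  if (!is.numeric(seed) || length(seed) != 1 || seed != round(seed))
    stop("`seed` must be an integer")
  structure(cfg, class = "sim_config")
}

# deterministic child seed per table; keeps streams independent
child_seed <- function(config, k) {
  (abs(config$seed) %% 1000000L) * 1009L + k * 7919L
}

sim_panel_meta <- function(config) {
  lines <- sprintf("L%02d", seq_len(config$n_lines))
  lineage <- rep(sprintf("lineage%d", seq_len(config$n_lineages)),
                 times = config$lineage_sizes)
  reps <- seq_len(config$n_reps_per_line)
  data.frame(
    sample = paste0(rep(lines, each = length(reps)), "_r", reps),
    cell_line = rep(lines, each = length(reps)),
    replicate = paste0("r", reps),
    lineage = rep(lineage, each = length(reps)),
    stringsAsFactors = FALSE)
}

# logistic abundance-dependent missingness with overall rate `rate`:
# p_ij = plogis(a - z_ij) with z the standardized log2 intensity and `a`
# solved so mean(p) = rate (left-censoring: low intensity -> more missing)
dropout_probs <- function(log2_vals, rate) {
  if (rate == 0) return(matrix(0, nrow(log2_vals), ncol(log2_vals)))
  if (rate == 1) return(matrix(1, nrow(log2_vals), ncol(log2_vals)))
  z <- (log2_vals - mean(log2_vals)) / max(stats::sd(log2_vals), 1e-12)
  f <- function(a) mean(stats::plogis(a - z)) - rate
  a <- stats::uniroot(f, c(-50, 50))$root
  matrix(stats::plogis(a - z), nrow(log2_vals), ncol(log2_vals))
}

sim_log2_layer <- function(config, feature_ids, lineage_effects) {
  meta <- sim_panel_meta(config)
  lines <- unique(meta$cell_line)
  lineage_of_line <- meta$lineage[match(lines, meta$cell_line)]
  n_feat <- length(feature_ids)
  lineage_labels <- sprintf("lineage%d", seq_len(config$n_lineages))
  base <- stats::rnorm(n_feat, config$base_mean, config$base_sd)
  line_means <- base +
    lineage_effects[, match(lineage_of_line, lineage_labels),
                    drop = FALSE] +
    matrix(stats::rnorm(n_feat * length(lines), 0, config$line_sd),
           n_feat, length(lines))
  reps <- line_means[, match(meta$cell_line, lines), drop = FALSE] +
    matrix(stats::rnorm(n_feat * nrow(meta), 0, config$noise_sd),
           n_feat, nrow(meta))
  dimnames(reps) <- list(feature_ids, meta$sample)
  reps
}

apply_dropout <- function(log2_vals, config) {
  p <- dropout_probs(log2_vals, config$dropout_rate)
  miss <- matrix(stats::runif(length(log2_vals)) < p,
                 nrow(log2_vals), ncol(log2_vals))
  lin <- 2^log2_vals
  lin[miss] <- NA
  lin
}

#' Simulate a label-free proteome intensity matrix with planted markers
#'
#' Log-normal base intensities; each lineage receives
#' `n_markers_per_lineage` marker proteins up-shifted by `marker_fold`
#' (linear) in its lines; features get per-lineage shifts
#' (`lineage_effect_sd`), per-line biological variation (`line_sd`) and
#' replicate noise (`noise_sd`); missingness is abundance-dependent with
#' overall rate `dropout_rate`.
#'
#' @param config a [sim_config()].
#' @return list with `matrix` (raw-scale `AbundanceMatrix`, linear
#'   intensities with `NA` for missing) and `truth` (list with
#'   `marker_assignments` protein->lineage, `lineage_of_line`, and the
#'   noise-free per-line log2 means `line_means`).
#' @export
simulate_proteome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config, 1L))
  prot <- sprintf("P%04d", seq_len(config$n_proteins))
  lineages <- sprintf("lineage%d", seq_len(config$n_lineages))
  lineage_effects <- matrix(
    stats::rnorm(config$n_proteins * config$n_lineages, 0,
                 config$lineage_effect_sd),
    config$n_proteins, config$n_lineages, dimnames = list(prot, lineages))
  marker_idx <- matrix(
    sample(config$n_proteins,
           config$n_markers_per_lineage * config$n_lineages),
    ncol = config$n_lineages)
  for (l in seq_len(config$n_lineages)) {
    idx <- marker_idx[, l]
    lineage_effects[idx, ] <- 0       # markers carry only their own shift
    lineage_effects[idx, l] <- log2(config$marker_fold)
  }
  marker_assignments <- stats::setNames(
    rep(lineages, each = config$n_markers_per_lineage),
    prot[as.vector(marker_idx)])
  log2v <- sim_log2_layer(config, prot, lineage_effects)
  lin <- apply_dropout(log2v, config)
  meta <- sim_panel_meta(config)
  list(matrix = abundance_matrix(lin, meta, "raw"),
       truth = list(marker_assignments = marker_assignments,
                    lineage_of_line = stats::setNames(
                      meta$lineage[match(unique(meta$cell_line),
                                         meta$cell_line)],
                      unique(meta$cell_line)),
                    log2_noise_free = log2v))
}

#' Generate a synthetic kinase-substrate map
#'
#' @param config a [sim_config()].
#' @param n_kinases number of kinases.
#' @param n_substrates_per_kinase substrate sites per kinase.
#' @return data.frame `kinase`, `protein`, `site` with no duplicate
#'   substrate entries per kinase; substrate proteins live in the same
#'   accession namespace as [simulate_proteome()].
#' @export
make_kinase_substrate_map <- function(config, n_kinases = 20,
                                      n_substrates_per_kinase = 10) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config, 2L))
  n <- n_kinases * n_substrates_per_kinase
  # unique (protein, position) pairs drawn without replacement
  pool <- sample(config$n_proteins * 500L, n)
  protein <- sprintf("P%04d", (pool - 1L) %% config$n_proteins + 1L)
  position <- (pool - 1L) %/% config$n_proteins + 1L
  residue <- sample(c("S", "T", "Y"), n, replace = TRUE,
                    prob = c(0.75, 0.2, 0.05))
  data.frame(kinase = rep(sprintf("KIN%02d", seq_len(n_kinases)),
                          each = n_substrates_per_kinase),
             protein = protein,
             site = paste0(residue, position),
             stringsAsFactors = FALSE)
}

#' Simulate a phosphosite intensity matrix with planted kinase activity
#'
#' Substrate sites of each planted (kinase, cell line) pair are shifted by
#' `effect` log2 units in that line on top of the shared variance
#' components; localization probabilities are drawn with a fraction
#' `loc_below_frac` at or below 0.75.
#'
#' @param config a [sim_config()].
#' @param ks_map kinase-substrate map (see [make_kinase_substrate_map()]).
#' @param active_kinases data.frame with columns `kinase`, `cell_line`,
#'   `effect`; defaults to the map's first kinase active in the first line
#'   with effect `config$kinase_effect`. Kinases absent from the map are
#'   an error.
#' @return list with `matrix` (raw-scale site x sample `AbundanceMatrix`,
#'   site IDs `protein:site`), `sites` (data.frame `site_id`, `protein`,
#'   `residue`, `position`, `localization_prob`) and `truth` (list with
#'   `active_kinases` and `substrate_sites`).
#' @export
simulate_phospho <- function(config, ks_map, active_kinases = NULL) {
  stopifnot(inherits(config, "sim_config"))
  ks_map <- as_kinase_substrate_map(ks_map)
  set.seed(child_seed(config, 3L))
  meta <- sim_panel_meta(config)
  lines <- unique(meta$cell_line)
  if (is.null(active_kinases)) {
    active_kinases <- data.frame(kinase = ks_map$kinase[1],
                                 cell_line = lines[1],
                                 effect = config$kinase_effect,
                                 stringsAsFactors = FALSE)
  }
  unknown <- setdiff(active_kinases$kinase, ks_map$kinase)
  if (length(unknown))
    stop("active kinase(s) absent from map: ",
         paste(unknown, collapse = ", "))
  if (!all(active_kinases$cell_line %in% lines))
    stop("active kinase cell line not in the panel")

  sub_ids <- unique(ks_map$site_id)
  n_bg <- config$n_phosphosites - length(sub_ids)
  if (n_bg < 0)
    stop("n_phosphosites smaller than the number of substrate sites")
  pool <- sample(config$n_proteins * 500L, n_bg)
  bg_prot <- sprintf("P%04d", (pool - 1L) %% config$n_proteins + 1L)
  bg_pos <- (pool - 1L) %/% config$n_proteins + 1L
  bg_res <- sample(c("S", "T", "Y"), n_bg, replace = TRUE,
                   prob = c(0.75, 0.2, 0.05))
  bg_ids <- paste0(bg_prot, ":", bg_res, bg_pos)
  bg_ids <- setdiff(bg_ids, sub_ids)
  site_ids <- c(sub_ids, bg_ids)
  n_sites <- length(site_ids)

  lineage_effects <- matrix(
    stats::rnorm(n_sites * config$n_lineages, 0,
                 config$lineage_effect_sd),
    n_sites, config$n_lineages)
  log2v <- sim_log2_layer(config, site_ids, lineage_effects)
  # plant kinase-driven shifts (applied to every replicate of the line)
  for (i in seq_len(nrow(active_kinases))) {
    subs <- ks_map$site_id[ks_map$kinase == active_kinases$kinase[i]]
    cols <- meta$sample[meta$cell_line == active_kinases$cell_line[i]]
    log2v[subs, cols] <- log2v[subs, cols] + active_kinases$effect[i]
  }
  lin <- apply_dropout(log2v, config)

  below <- stats::runif(n_sites) < config$loc_below_frac
  loc <- ifelse(below, stats::runif(n_sites, 0, 0.75),
                stats::runif(n_sites, 0.7501, 1))
  parts <- strsplit(site_ids, ":", fixed = TRUE)
  site_lab <- vapply(parts, `[[`, "", 2L)
  sites <- data.frame(
    site_id = site_ids,
    protein = vapply(parts, `[[`, "", 1L),
    residue = substr(site_lab, 1, 1),
    position = as.integer(substring(site_lab, 2)),
    localization_prob = loc,
    stringsAsFactors = FALSE)
  list(matrix = abundance_matrix(lin, meta, "raw"),
       sites = sites,
       truth = list(active_kinases = active_kinases,
                    substrate_sites = stats::setNames(
                      lapply(unique(ks_map$kinase), function(k)
                        ks_map$site_id[ks_map$kinase == k]),
                      unique(ks_map$kinase))))
}

# one random composition per class that classify_glycan() maps back to it
random_composition <- function(class) {
  comp <- switch(class,
    sialylated = c(HexNAc = sample(3:5, 1), Hex = sample(4:6, 1),
                   Fuc = sample(0:1, 1), NeuAc = sample(1:2, 1)),
    fucosylated = c(HexNAc = sample(3:5, 1), Hex = sample(3:5, 1),
                    Fuc = sample(1:2, 1)),
    high_mannose = c(HexNAc = 2, Hex = sample(5:9, 1)),
    other = c(HexNAc = 2, Hex = sample(3:4, 1)))
  glycan_to_string(comp)
}

#' Simulate a glycopeptide PSM table from known site-glycan counts
#'
#' First draws ground-truth spectral counts per (protein, site,
#' composition, sample) key, then emits exactly that many PSM rows per
#' key, randomizing peptide sequence/length, missed cleavages (0-2) and
#' charge (2-4). Glycan compositions are drawn from a class mixture whose
#' default reflects the composition of a typical IMAC-co-enriched
#' glycoproteome (roughly half sialylated, a quarter each fucosylated and
#' high-mannose).
#'
#' @param config a [sim_config()].
#' @param n_keys number of distinct site-specific glycans.
#' @param mean_count Poisson mean of per-(key, sample) spectral counts;
#'   every key is guaranteed at least one PSM overall.
#' @param class_mix named probabilities over
#'   sialylated/fucosylated/high_mannose/other.
#' @return list with `psms` (data.frame: `spectrum_id`, `protein`, `site`,
#'   `residue`, `peptide`, `charge`, `missed_cleavages`, `composition`,
#'   `sample`, `replicate`, `cell_line`) and `truth` (list with `keys`
#'   data.frame incl. drawn class per key, `counts` long data.frame of
#'   nonzero true counts, and `class_tally`).
#' @export
simulate_glyco_psms <- function(config, n_keys = 300, mean_count = 2,
                                class_mix = c(sialylated = 0.4972,
                                              fucosylated = 0.2516,
                                              high_mannose = 0.2511,
                                              other = 0.0001)) {
  stopifnot(inherits(config, "sim_config"))
  if (any(class_mix < 0) || sum(class_mix) <= 0)
    stop("invalid class mixture")
  class_mix <- class_mix[glycan_classes] / sum(class_mix[glycan_classes])
  set.seed(child_seed(config, 4L))
  meta <- sim_panel_meta(config)
  samples <- meta$sample

  cls <- sample(glycan_classes, n_keys, replace = TRUE, prob = class_mix)
  pool <- sample(config$n_proteins * 900L, n_keys)
  keys <- data.frame(
    protein = sprintf("P%04d", (pool - 1L) %% config$n_proteins + 1L),
    site = (pool - 1L) %/% config$n_proteins + 1L,
    composition = vapply(cls, random_composition, ""),
    class = cls, stringsAsFactors = FALSE)
  # duplicate (protein, site, composition) keys collapse under counting;
  # nudge sites until all keys are unique
  kstr <- function(k) paste(k$protein, k$site, k$composition)
  while (anyDuplicated(kstr(keys))) {
    d <- which(duplicated(kstr(keys)))
    keys$site[d] <- keys$site[d] + sample(500L, length(d), replace = TRUE)
  }

  counts <- matrix(stats::rpois(n_keys * length(samples), mean_count),
                   n_keys, length(samples),
                   dimnames = list(NULL, samples))
  empty <- rowSums(counts) == 0
  if (any(empty))
    counts[cbind(which(empty),
                 sample(length(samples), sum(empty), replace = TRUE))] <- 1L

  long <- which(counts > 0, arr.ind = TRUE)
  key_i <- rep(long[, 1], counts[long])
  smp_i <- rep(long[, 2], counts[long])
  n_psm <- length(key_i)
  pep_len <- sample(8:25, n_psm, replace = TRUE)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "P",
          "Q", "R", "S", "T", "V", "W", "Y")
  peptide <- vapply(pep_len, function(l)
    paste0(paste(sample(aa, l - 1, replace = TRUE), collapse = ""), "N"),
    "")
  psms <- data.frame(
    spectrum_id = sprintf("spec%06d", seq_len(n_psm)),
    protein = keys$protein[key_i],
    site = keys$site[key_i],
    residue = "N",
    peptide = peptide,
    charge = sample(2:4, n_psm, replace = TRUE),
    missed_cleavages = sample(0:2, n_psm, replace = TRUE),
    composition = keys$composition[key_i],
    sample = samples[smp_i],
    replicate = meta$replicate[smp_i],
    cell_line = meta$cell_line[smp_i],
    stringsAsFactors = FALSE)
  psms <- psms[sample(n_psm), , drop = FALSE]  # shuffle row order
  rownames(psms) <- NULL

  truth_counts <- data.frame(
    protein = keys$protein[long[, 1]], site = keys$site[long[, 1]],
    composition = keys$composition[long[, 1]],
    sample = samples[long[, 2]], count = counts[long],
    stringsAsFactors = FALSE)
  list(psms = psms,
       truth = list(keys = keys, counts = truth_counts,
                    class_tally = base::table(
                      factor(keys$class, levels = glycan_classes))))
}

#' Generate a synthetic RPPA antibody panel against the MS namespace
#'
#' @param config a [sim_config()].
#' @param ms raw-scale MS `AbundanceMatrix` providing the accession
#'   namespace.
#' @param n_total number of total-protein antibodies.
#' @param n_phospho number of phosphosite-specific antibodies.
#' @param n_ms_absent how many total-protein targets are deliberately
#'   absent from MS (invented accessions), emulating antibody targets the
#'   MS platform misses.
#' @return RPPA panel data.frame (see [as_rppa_panel()]); representative
#'   accessions are unique.
#' @export
make_rppa_panel <- function(config, ms, n_total = 231, n_phospho = 74,
                            n_ms_absent = 19) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config, 5L))
  feats <- rownames(ms$values)
  if (n_total - n_ms_absent > length(feats))
    stop("panel larger than the MS feature space")
  present <- sample(feats, n_total - n_ms_absent)
  absent <- sprintf("ABX%03d", seq_len(n_ms_absent))
  targets <- c(present, absent)
  phospho_targets <- sample(present, min(n_phospho, length(present)))
  panel <- data.frame(
    antibody = c(sprintf("ab_total_%03d", seq_len(n_total)),
                 sprintf("ab_phos_%03d", seq_along(phospho_targets))),
    targets = c(targets, phospho_targets),
    representative = c(targets, phospho_targets),
    is_phospho = c(rep(FALSE, n_total),
                   rep(TRUE, length(phospho_targets))),
    site_label = c(rep(NA_character_, n_total),
                   if (length(phospho_targets))
                     paste0("S", sample(50:900, length(phospho_targets)))
                   else character(0)),
    stringsAsFactors = FALSE)
  as_rppa_panel(panel)
}

#' Simulate RPPA measurements coupled to an MS proteome
#'
#' Each antibody's value is an affine transform (antibody-specific
#' positive slope and offset) of the target's MS log2 intensity plus
#' Gaussian noise of SD `rppa_noise_sd`. MS-absent targets get independent
#' values. RPPA has no missing values; MS-missing cells are backed by the
#' target's observed mean, emulating the antibody still binding protein
#' the MS run dropped.
#'
#' @param ms raw-scale MS `AbundanceMatrix`.
#' @param panel RPPA panel ([make_rppa_panel()]).
#' @param config a [sim_config()].
#' @return `AbundanceMatrix` (scale `"log2p1"`) keyed by representative
#'   accession for total-protein antibodies and by
#'   `representative:site_label` for phospho antibodies.
#' @export
simulate_rppa <- function(ms, panel, config) {
  stopifnot(inherits(config, "sim_config"))
  panel <- as_rppa_panel(panel)
  set.seed(child_seed(config, 6L))
  log2ms <- log2(ms$values + 1)
  rmu <- rowMeans(log2ms, na.rm = TRUE)
  for (i in seq_len(nrow(log2ms)))
    log2ms[i, is.na(log2ms[i, ])] <- rmu[i]
  n_s <- ncol(log2ms)
  rows <- matrix(NA_real_, nrow(panel), n_s)
  ids <- character(nrow(panel))
  for (i in seq_len(nrow(panel))) {
    tgt <- panel$representative[i]
    slope <- stats::runif(1, 0.7, 1.3)
    offset <- stats::rnorm(1, 0, 1)
    base <- if (tgt %in% rownames(log2ms)) {
      slope * (log2ms[tgt, ] - mean(log2ms[tgt, ])) + offset
    } else {
      stats::rnorm(n_s, offset, 1)
    }
    rows[i, ] <- base + stats::rnorm(n_s, 0, config$rppa_noise_sd)
    ids[i] <- if (panel$is_phospho[i])
      paste0(tgt, ":", panel$site_label[i]) else tgt
  }
  dimnames(rows) <- list(ids, colnames(ms$values))
  abundance_matrix(rows, ms$meta, "log2p1")
}

#' Simulate a copy-number matrix with planted cis effects
#'
#' Cis genes receive copy-number values whose ranks correlate with the
#' gene's protein abundance across lines at target Spearman `cis_corr`
#' (internally converted to a latent Pearson correlation via
#' `2*sin(pi*rho/6)`); other genes are independent. Latent values map to
#' `log2(CN ratio + 1)` monotonically with the diploid state (CN ratio 1)
#' at 1. Chromosome arms are assigned round-robin; an optional trans
#' hotspot arm carries genes correlated with non-cis features.
#'
#' @param config a [sim_config()].
#' @param proteome result of [simulate_proteome()] (the list, or the
#'   raw `AbundanceMatrix` itself).
#' @param n_cis number of planted cis genes.
#' @param hotspot_arm optional arm label (e.g. `"chr5p"`) for a planted
#'   trans hotspot.
#' @param n_hotspot_genes genes on the hotspot arm (each tied to one
#'   non-cis feature).
#' @param hotspot_corr target Spearman of hotspot trans effects.
#' @return list with `cna` (`CNAMatrix` over the proteome's genes) and
#'   `truth` (list with `cis_genes` and `hotspot` pair table).
#' @export
simulate_cna <- function(config, proteome, n_cis = 50,
                         hotspot_arm = NULL, n_hotspot_genes = 0,
                         hotspot_corr = 0.8) {
  stopifnot(inherits(config, "sim_config"))
  m <- if (is_abundance_matrix(proteome)) proteome else proteome$matrix
  set.seed(child_seed(config, 7L))
  # line-level log2 abundance (generator-internal collapse)
  log2v <- log2(m$values + 1)
  lines <- unique(m$meta$cell_line)
  prot_line <- vapply(lines, function(cl)
    rowMeans(log2v[, m$meta$sample[m$meta$cell_line == cl], drop = FALSE],
             na.rm = TRUE), numeric(nrow(log2v)))
  prot_line[is.nan(prot_line)] <- config$base_mean
  genes <- rownames(m$values)
  n_g <- length(genes)
  n_l <- length(lines)
  if (n_cis + n_hotspot_genes > n_g) stop("more planted genes than genes")

  rho_p <- function(rho_s) 2 * sin(pi * rho_s / 6)
  latent <- matrix(stats::rnorm(n_g * n_l), n_g, n_l,
                   dimnames = list(genes, lines))
  cis_genes <- sample(genes, n_cis)
  for (gn in cis_genes) {
    x <- prot_line[gn, ]
    xs <- (x - mean(x)) / max(stats::sd(x), 1e-12)
    r <- rho_p(config$cis_corr)
    latent[gn, ] <- r * xs + sqrt(max(0, 1 - r^2)) * latent[gn, ]
  }
  arms <- paste0("chr", rep(1:22, each = 2), c("p", "q"))
  arm <- stats::setNames(rep(arms, length.out = n_g), genes)
  hotspot <- NULL
  if (!is.null(hotspot_arm) && n_hotspot_genes > 0) {
    hot_genes <- sample(setdiff(genes, cis_genes), n_hotspot_genes)
    tgt_pool <- setdiff(genes, c(cis_genes, hot_genes))
    tgt <- sample(tgt_pool, n_hotspot_genes)
    r <- rho_p(hotspot_corr)
    for (i in seq_len(n_hotspot_genes)) {
      x <- prot_line[tgt[i], ]
      xs <- (x - mean(x)) / max(stats::sd(x), 1e-12)
      latent[hot_genes[i], ] <- r * xs +
        sqrt(max(0, 1 - r^2)) * stats::rnorm(n_l)
    }
    arm[setdiff(genes, hot_genes)] <- rep(
      setdiff(arms, hotspot_arm), length.out = n_g - n_hotspot_genes)
    arm[hot_genes] <- hotspot_arm
    hotspot <- data.frame(gene = hot_genes, feature = tgt,
                          arm = hotspot_arm, stringsAsFactors = FALSE)
  }
  values <- log2(2^(0.5 * latent) + 1)
  cna <- cna_matrix(values, arm)
  list(cna = cna,
       truth = list(cis_genes = cis_genes, hotspot = hotspot))
}
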