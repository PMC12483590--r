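#' Read a typed table with schema validation
#'
#' Delimiter is auto-detected (tab or comma). The schema names the
#' required columns; violations raise an error naming the column.
#'
#' @param path file path.
#' @param schema one of `"psm"`, `"ks_map"`, `"panel"`, `"cna"`,
#'   `"replicate_map"`, or a character vector of required column names.
#' @return data.frame with validated columns.
#' @export
read_table <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path)
  schemas <- list(
    psm = c("protein", "site", "peptide", "charge", "missed_cleavages",
            "composition", "sample"),
    ks_map = c("kinase", "protein", "site"),
    panel = c("antibody", "targets", "representative", "is_phospho"),
    cna = c("gene", "arm"),
    replicate_map = c("sample", "cell_line"))
  req <- if (is.character(schema) && length(schema) == 1 &&
             schema %in% names(schemas)) schemas[[schema]] else schema
  first <- readLines(path, n = 1)
  sep <- if (lengths(regmatches(first, gregexpr("\t", first))) > 0)
    "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "\"", comment.char = "")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("missing required column(s) in ", basename(path), ": ",
         paste(missing_cols, collapse = ", "))
  message(sprintf("read %s: %d rows x %d columns", basename(path),
                  nrow(df), ncol(df)))
  df
}

#' Write / read an AbundanceMatrix as TSV
#'
#' The layout is a feature x sample value grid preceded by three
#' metadata header rows (`#cell_line`, `#replicate`, `#lineage`) so the
#' sample annotation travels with the matrix. The scale tag is stored in
#' the first header line.
#'
#' @param m `AbundanceMatrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_abundance_matrix <- function(m, path) {
  stopifnot(is_abundance_matrix(m))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#scale\t", m$scale,
                    strrep("\t", ncol(m$values) - 1)), con)
  hdr <- function(tag, vals)
    paste(c(tag, vals), collapse = "\t")
  writeLines(hdr("#cell_line", m$meta$cell_line), con)
  writeLines(hdr("#replicate", m$meta$replicate), con)
  writeLines(hdr("#lineage", m$meta$lineage), con)
  writeLines(hdr("feature", colnames(m$values)), con)
  utils::write.table(m$values, con, sep = "\t", quote = FALSE,
                     col.names = FALSE, row.names = TRUE, na = "NA")
  invisible(path)
}

#' @rdname write_abundance_matrix
#' @export
read_abundance_matrix <- function(path) {
  lines <- readLines(path, n = 5)
  if (!startsWith(lines[1], "#scale"))
    stop("not an AbundanceMatrix TSV (missing #scale header)")
  scale <- strsplit(lines[1], "\t")[[1]][2]
  split_hdr <- function(l) strsplit(l, "\t")[[1]][-1]
  cl <- split_hdr(lines[2]); rp <- split_hdr(lines[3])
  lg <- split_hdr(lines[4]); smp <- split_hdr(lines[5])
  df <- utils::read.table(path, header = FALSE, sep = "\t", skip = 5,
                          stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  dimnames(v) <- list(df[[1]], smp)
  meta <- data.frame(sample = smp, cell_line = cl, replicate = rp,
                     lineage = lg, stringsAsFactors = FALSE)
  abundance_matrix(v, meta, scale)
}

#' Write a CNAMatrix as CSV (gene, arm, then one column per line)
#'
#' @param cna `CNAMatrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cna_matrix <- function(cna, path) {
  df <- data.frame(gene = rownames(cna$values),
                   arm = unname(cna$arm),
                   cna$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cna_matrix
#' @export
read_cna_matrix <- function(path) {
  df <- read_table(path, "cna")
  v <- as.matrix(df[, setdiff(names(df), c("gene", "arm")), drop = FALSE])
  rownames(v) <- df$gene
  cna_matrix(v, stats::setNames(df$arm, df$gene))
}

# rolling polynomial hash over a deparsed object; manifest provenance only
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full synthetic multi-layer pipeline
#'
#' Generates every input layer from one [sim_config()], then executes the
#' stages in dependency order: proteome/phosphoproteome preprocessing
#' (detection filter, global-minimum imputation, log2(x+1) median
#' normalization, replicate collapse), differential expression and marker
#' scoring, glycan spectral counting with the replicate-consistency
#' filter, KSEA and the kinase-driver screen, MS-RPPA coverage and
#' concordance, and CNA-proteome correlation. All result tables plus a
#' JSON manifest (config, config hash, seed, per-stage row counts) are
#' written under `out_dir`. A rerun with the same config reproduces the
#' outputs exactly.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param thresholds named list overriding analysis thresholds:
#'   `detection_frac` (0.05), `localization` (0.75), `fold` (1.5),
#'   `floor_frac` (0.5), `min_substrates` (5), `fdr` (0.05),
#'   `de_fc` (2), `cna_r` (0.5).
#' @return invisibly, a list of all stage results plus the manifest.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = tempdir(),
                         thresholds = list()) {
  stopifnot(inherits(config, "sim_config"))
  th <- utils::modifyList(
    list(detection_frac = 0.05, localization = 0.75, fold = 1.5,
         floor_frac = 0.5, min_substrates = 5, fdr = 0.05, de_fc = 2,
         cna_r = 0.5), thresholds)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    stages[[name]] <<- res
    res
  }

  sim <- run_stage("simulate", {
    prot <- simulate_proteome(config)
    ks <- make_kinase_substrate_map(config)
    phos <- simulate_phospho(config, ks)
    gly <- simulate_glyco_psms(config)
    panel <- make_rppa_panel(
      config, prot$matrix,
      n_total = min(231L, max(10L, config$n_proteins %/% 4)),
      n_phospho = min(74L, max(3L, config$n_proteins %/% 12)),
      n_ms_absent = min(19L, max(1L, config$n_proteins %/% 50)))
    rppa <- simulate_rppa(prot$matrix, panel, config)
    cna <- simulate_cna(config, prot)
    list(proteome = prot, ks_map = ks, phospho = phos, glyco = gly,
         panel = panel, rppa = rppa, cna = cna)
  })

  prep <- run_stage("prep", {
    pp <- function(m) {
      m <- filter_low_detection(m, th$detection_frac)
      m <- impute_global_min(m)
      log2p1_median_normalize(m)
    }
    prot_log <- pp(sim$proteome$matrix)
    keep_sites <- filter_localization(
      sim$phospho$sites, th$localization)$site_id
    phos_raw <- sim$phospho$matrix[
      rownames(sim$phospho$matrix$values) %in% keep_sites, ]
    phos_prot_raw <- sum_phospho_by_protein(phos_raw)
    phospho_log <- pp(phos_raw)
    list(protein_log = prot_log,
         protein_collapsed = collapse_replicates(prot_log),
         phospho_log = phospho_log,
         phospho_collapsed = collapse_replicates(phospho_log),
         phospho_protein_log = pp(phos_prot_raw))
  })

  de <- run_stage("differential", {
    groups <- stats::setNames(prep$protein_collapsed$meta$lineage,
                              prep$protein_collapsed$meta$sample)
    list(de = wilcoxon_de(prep$protein_collapsed, groups,
                          fc_cutoff = th$de_fc, exact = FALSE),
         markers = cosine_marker_score(prep$protein_collapsed, groups))
  })

  gly <- run_stage("glyco", {
    tab <- aggregate_site_glycans(sim$glyco$psms)
    kept <- consistency_filter(
      tab, sim$proteome$matrix$meta[, c("sample", "cell_line")])
    list(table = tab, consistent = kept,
         fractions = class_fractions(tab))
  })

  kin <- run_stage("kinase", {
    list(ksea = ksea_all_lines(prep$phospho_collapsed, sim$ks_map,
                               min_substrates = th$min_substrates,
                               fdr_cutoff = th$fdr),
         drivers = screen_driver_kinases(prep$protein_log,
                                         prep$phospho_protein_log,
                                         fold = th$fold,
                                         floor_frac = th$floor_frac),
         site_corr = phospho_protein_correlation(
           prep$phospho_collapsed, prep$protein_collapsed))
  })

  rppa <- run_stage("rppa", {
    norm <- rppa_normalize(sim$rppa)
    cov <- detection_coverage(sim$panel, sim$proteome$matrix)
    rppa_coll <- collapse_replicates(norm)
    corr <- per_protein_correlation(prep$protein_collapsed, rppa_coll)
    lineages <- prep$protein_collapsed$meta$lineage
    lines <- prep$protein_collapsed$meta$cell_line
    two <- utils::head(unique(lineages), 2)
    fcc <- foldchange_concordance(prep$protein_collapsed, rppa_coll,
                                  lines[lineages == two[1]],
                                  lines[lineages == two[2]])
    groups <- stats::setNames(prep$protein_log$meta$cell_line,
                              prep$protein_log$meta$sample)
    list(normalized = norm, coverage = cov, correlation = corr,
         fc_concordance = fcc,
         intra_inter = intra_inter_correlation(prep$protein_log, groups))
  })

  cna <- run_stage("cna", {
    corr <- cna_feature_correlation(sim$cna$cna, prep$protein_collapsed,
                                    trans = "subset")
    list(correlation = corr,
         summary = cis_trans_summary(corr, th$cna_r))
  })

  # persist outputs
  write_abundance_matrix(prep$protein_collapsed,
                         file.path(out_dir, "protein_collapsed.tsv"))
  write_abundance_matrix(prep$phospho_collapsed,
                         file.path(out_dir, "phospho_collapsed.tsv"))
  utils::write.table(sim$glyco$psms, file.path(out_dir, "glyco_psms.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(gly$consistent,
                     file.path(out_dir, "site_glycans_consistent.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(de$de, file.path(out_dir, "differential.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(kin$ksea, file.path(out_dir, "ksea.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(kin$drivers, file.path(out_dir, "driver_hits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cna$correlation,
                     file.path(out_dir, "cna_correlation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_cna_matrix(sim$cna$cna, file.path(out_dir, "cna_matrix.csv"))

  manifest <- list(
    package = "proteopanel",
    version = as.character(utils::packageVersion("proteopanel")),
    seed = config$seed,
    config = unclass(config),
    config_hash = config_hash(unclass(config)),
    thresholds = th,
    stage_rows = list(
      proteome_features = nrow(sim$proteome$matrix$values),
      proteome_after_prep = nrow(prep$protein_collapsed$values),
      phosphosites_after_localization =
        nrow(prep$phospho_collapsed$values),
      glyco_psms = nrow(sim$glyco$psms),
      site_glycans = nrow(gly$table),
      site_glycans_consistent = nrow(gly$consistent),
      ksea_tests = nrow(kin$ksea),
      driver_hits = nrow(kin$drivers),
      rppa_antibodies = nrow(sim$rppa$values),
      cna_pairs = nrow(cna$correlation)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(stages, list(manifest = manifest)))
}
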