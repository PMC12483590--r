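#' Filter phosphosites by localization probability
#'
#' Keeps class-I sites: localization probability strictly greater than the
#' cutoff (default 0.75). Sites with a missing probability are dropped with
#' a warning by default.
#'
#' @param sites data.frame of phosphosite records with a
#'   `localization_prob` column in \[0, 1\].
#' @param cutoff strict lower bound (default 0.75).
#' @param missing how to treat `NA` probabilities: `"drop"` (default, with
#'   warning) or `"keep"`.
#' @return the filtered data.frame.
#' @export
filter_localization <- function(sites, cutoff = 0.75,
                                missing = c("drop", "keep")) {
  missing <- match.arg(missing)
  if (!"localization_prob" %in% names(sites))
    stop("`sites` must have a localization_prob column")
  p <- sites$localization_prob
  if (any(p[!is.na(p)] < 0 | p[!is.na(p)] > 1))
    stop("localization probabilities must lie in [0, 1]")
  if (anyNA(p)) {
    if (missing == "drop") {
      warning(sum(is.na(p)), " sites with missing localization ",
              "probability dropped")
      keep <- !is.na(p) & p > cutoff
    } else {
      keep <- is.na(p) | p > cutoff
    }
  } else {
    keep <- p > cutoff
  }
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Validate/normalize a kinase-substrate map
#'
#' @param ks_map data.frame with columns `kinase`, `protein`, `site`
#'   (site label such as "S473"). Duplicate (kinase, substrate) entries
#'   are an error.
#' @return the map with an added `site_id` column (`protein:site`).
#' @export
as_kinase_substrate_map <- function(ks_map) {
  req <- c("kinase", "protein", "site")
  if (!is.data.frame(ks_map) || !all(req %in% names(ks_map)))
    stop("kinase-substrate map needs columns: ",
         paste(req, collapse = ", "))
  if (nrow(ks_map) == 0) stop("kinase-substrate map is empty")
  ks_map$site_id <- paste(ks_map$protein, ks_map$site, sep = ":")
  if (anyDuplicated(paste(ks_map$kinase, ks_map$site_id)))
    stop("duplicate substrate entries per kinase in map")
  ks_map
}

#' Kinase-substrate enrichment analysis (KSEA) for one cell line
#'
#' For each kinase with matched substrate sites among the measured
#' phosphosites, the Z-score contrasts the mean log2 fold change of its
#' substrates with the mean over all measured sites:
#' \deqn{z = (\bar{s} - \bar{p})\sqrt{m} / \sigma_p}
#' where \eqn{\bar{s}} is the substrate mean, \eqn{\bar{p}} and
#' \eqn{\sigma_p} the mean and SD of all site fold changes in the line, and
#' m the number of matched substrates. Two-sided normal p-values are BH
#' adjusted across kinases within the line; a kinase is flagged active when
#' FDR < `fdr_cutoff` and it has more than `min_substrates` substrates.
#'
#' @param site_fc named numeric vector: per-phosphosite log2 fold change
#'   for one cell line; names are site IDs (`protein:site`).
#' @param ks_map kinase-substrate map (see [as_kinase_substrate_map()]).
#' @param min_substrates a kinase must have strictly more than this many
#'   matched substrates to be flagged (default 5, i.e. m >= 6).
#' @param fdr_cutoff BH FDR cutoff for the active flag (default 0.05).
#' @return data.frame with `kinase`, `m`, `mean_s`, `z`, `p`, `fdr`,
#'   `active`; kinases with zero matched substrates are omitted.
#' @export
ksea <- function(site_fc, ks_map, min_substrates = 5, fdr_cutoff = 0.05) {
  if (length(site_fc) == 0) stop("`site_fc` is empty")
  ks_map <- as_kinase_substrate_map(ks_map)
  mean_p <- mean(site_fc)
  sd_p <- stats::sd(site_fc)
  if (is.na(sd_p) || sd_p == 0)
    stop("population SD of site fold changes is zero; Z-scores undefined")
  matched <- ks_map[ks_map$site_id %in% names(site_fc), ]
  if (nrow(matched) == 0) {
    return(data.frame(kinase = character(), m = integer(),
                      mean_s = numeric(), z = numeric(), p = numeric(),
                      fdr = numeric(), active = logical()))
  }
  by_kin <- split(matched$site_id, matched$kinase)
  m <- lengths(by_kin)
  mean_s <- vapply(by_kin, function(s) mean(site_fc[s]), numeric(1))
  z <- (mean_s - mean_p) * sqrt(m) / sd_p
  p <- 2 * stats::pnorm(-abs(z))
  fdr <- stats::p.adjust(p, method = "BH")
  out <- data.frame(kinase = names(by_kin), m = as.integer(m),
                    mean_s = unname(mean_s), z = unname(z),
                    p = unname(p), fdr = unname(fdr),
                    stringsAsFactors = FALSE)
  out$active <- out$fdr < fdr_cutoff & out$m > min_substrates
  rownames(out) <- NULL
  out
}

#' Per-line site fold changes and KSEA across all cell lines
#'
#' Site fold change for a line is its collapsed log2 value minus the mean
#' over all other lines (one-vs-rest), the same contrast used for protein
#' fold changes. KSEA is then run per line with BH adjustment within each
#' line.
#'
#' @param phospho_m collapsed log2-scale phosphosite `AbundanceMatrix`
#'   (rownames are site IDs `protein:site`).
#' @param ks_map kinase-substrate map.
#' @param ... passed to [ksea()].
#' @return data.frame of per-(kinase, cell line) KSEA results with a
#'   `cell_line` column.
#' @export
ksea_all_lines <- function(phospho_m, ks_map, ...) {
  stopifnot_scale(phospho_m, "collapsed", "ksea_all_lines")
  lines <- colnames(phospho_m$values)
  if (length(lines) < 2) stop("need at least 2 cell lines")
  res <- lapply(lines, function(cl) {
    fc <- phospho_m$values[, cl] -
      rowMeans(phospho_m$values[, setdiff(lines, cl), drop = FALSE])
    r <- ksea(fc, ks_map, ...)
    if (nrow(r)) r$cell_line <- cl
    r
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Sum phosphosite intensities per protein
#'
#' Site-level phosphorylation of a protein is summarized as the sum of all
#' its identified phosphosite intensities per sample, on the linear scale.
#'
#' @param phospho_m raw (linear) scale phosphosite `AbundanceMatrix` with
#'   site IDs `protein:site` as rownames; `NA`s are treated as undetected
#'   (0) in the sum, and proteins with no observed site in a sample are
#'   `NA`.
#' @return raw-scale `AbundanceMatrix` keyed by protein.
#' @export
sum_phospho_by_protein <- function(phospho_m) {
  stopifnot_scale(phospho_m, "raw", "sum_phospho_by_protein")
  prot <- sub(":.*$", "", rownames(phospho_m$values))
  v <- phospho_m$values
  obs <- !is.na(v)
  v0 <- ifelse(obs, v, 0)
  sums <- rowsum(v0, prot)
  nobs <- rowsum(obs + 0, prot)
  sums[nobs == 0] <- NA
  abundance_matrix(sums, phospho_m$meta, "raw")
}

#' Screen for candidate kinase drivers
#'
#' A kinase/protein is a driver hit for a cell line when that line is the
#' top line by linear mean at BOTH the total-protein and the summed-
#' phosphorylation level with its mean at least `fold` times every other
#' line's mean, and the replicate floor holds: the lowest replicate in the
#' top line still exceeds `floor_frac` of the highest replicate observed in
#' any other line, again at both levels.
#'
#' @param protein_m,phospho_m log2-scale (`log2p1`) replicate-level
#'   `AbundanceMatrix` objects sharing cell lines; `phospho_m` must already
#'   be protein-keyed (see [sum_phospho_by_protein()], then preprocess).
#'   Fold comparisons are made on the linear scale (`2^v - 1`).
#' @param fold minimum linear fold of the top line over every other line
#'   (default 1.5).
#' @param floor_frac replicate floor fraction (default 0.5).
#' @param floor_within if `TRUE`, the floor compares the top line's lowest
#'   replicate to `floor_frac` of the top line's own highest replicate
#'   (the alternative reading of the rule); default `FALSE` compares
#'   against the highest replicate in the other lines.
#' @return data.frame of hits: `feature`, `cell_line`, `protein_fold`,
#'   `phospho_fold` (linear ratios vs the best other line), `runner_up`,
#'   `replicate_floor_ok` (always `TRUE` for emitted hits).
#' @export
screen_driver_kinases <- function(protein_m, phospho_m, fold = 1.5,
                                  floor_frac = 0.5, floor_within = FALSE) {
  stopifnot_scale(protein_m, "log2p1", "screen_driver_kinases")
  stopifnot_scale(phospho_m, "log2p1", "screen_driver_kinases")
  shared_lines <- intersect(unique(protein_m$meta$cell_line),
                            unique(phospho_m$meta$cell_line))
  if (length(shared_lines) < 2)
    stop("matrices must share at least 2 cell lines")
  feats <- intersect(rownames(protein_m$values), rownames(phospho_m$values))
  skipped <- setdiff(union(rownames(protein_m$values),
                           rownames(phospho_m$values)), feats)
  if (length(skipped))
    message(length(skipped), " features absent from one level skipped")

  level_stats <- function(m) {
    lin <- 2^m$values - 1
    lin[lin < 0] <- 0
    cl <- m$meta$cell_line
    keep <- cl %in% shared_lines
    lin <- lin[feats, keep, drop = FALSE]
    cl <- cl[keep]
    means <- t(rowsum(t(lin), cl) / as.vector(base::table(cl)))
    # per-line replicate min/max
    mins <- matrix(vapply(shared_lines, function(l)
      apply(lin[, cl == l, drop = FALSE], 1, min),
      numeric(length(feats))), nrow = length(feats))
    maxs <- matrix(vapply(shared_lines, function(l)
      apply(lin[, cl == l, drop = FALSE], 1, max),
      numeric(length(feats))), nrow = length(feats))
    dimnames(mins) <- dimnames(maxs) <- list(feats, shared_lines)
    list(means = means[, shared_lines, drop = FALSE], mins = mins,
         maxs = maxs)
  }
  ps <- level_stats(protein_m)
  hs <- level_stats(phospho_m)

  hits <- lapply(feats, function(f) {
    pm <- ps$means[f, ]; hm <- hs$means[f, ]
    top <- names(pm)[which.max(pm)]
    if (names(hm)[which.max(hm)] != top) return(NULL)
    others <- setdiff(shared_lines, top)
    p_fold <- pm[top] / max(pm[others])
    h_fold <- hm[top] / max(hm[others])
    if (!is.finite(p_fold) || !is.finite(h_fold)) return(NULL)
    if (p_fold < fold || h_fold < fold) return(NULL)
    floor_ref_p <- if (floor_within) ps$maxs[f, top] else
      max(ps$maxs[f, others])
    floor_ref_h <- if (floor_within) hs$maxs[f, top] else
      max(hs$maxs[f, others])
    ok <- ps$mins[f, top] > floor_frac * floor_ref_p &&
      hs$mins[f, top] > floor_frac * floor_ref_h
    if (!ok) return(NULL)
    data.frame(feature = f, cell_line = top,
               protein_fold = unname(p_fold),
               phospho_fold = unname(h_fold),
               runner_up = names(pm[others])[which.max(pm[others])],
               replicate_floor_ok = TRUE,
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits))
    hits <- data.frame(feature = character(), cell_line = character(),
                       protein_fold = numeric(), phospho_fold = numeric(),
                       runner_up = character(),
                       replicate_floor_ok = logical())
  rownames(hits) <- NULL
  hits
}

#' Correlate site phosphorylation with parent protein abundance
#'
#' Spearman correlation between each phosphosite and its parent protein
#' across cell lines, binned as strong (r > 0.6), moderate (0.4 < r <= 0.6),
#' weak (0.2 < r <= 0.4) and none (r <= 0.2). Ties get average ranks.
#'
#' @param phospho_m collapsed phosphosite `AbundanceMatrix` (site IDs
#'   `protein:site`).
#' @param protein_m collapsed protein `AbundanceMatrix`.
#' @param min_shared minimum shared non-missing lines per pair (default 5).
#' @return data.frame `site`, `protein`, `n`, `r`, `bin`; pairs with too
#'   few shared observations are excluded and their count attached as
#'   attribute `"n_excluded"`.
#' @export
phospho_protein_correlation <- function(phospho_m, protein_m,
                                        min_shared = 5) {
  stopifnot_scale(phospho_m, "collapsed", "phospho_protein_correlation")
  stopifnot_scale(protein_m, "collapsed", "phospho_protein_correlation")
  lines <- intersect(colnames(phospho_m$values), colnames(protein_m$values))
  if (length(lines) < min_shared) stop("too few shared cell lines")
  prot_of_site <- sub(":.*$", "", rownames(phospho_m$values))
  usable <- prot_of_site %in% rownames(protein_m$values)
  n_excluded <- 0L
  rows <- lapply(which(usable), function(i) {
    s <- phospho_m$values[i, lines]
    p <- protein_m$values[prot_of_site[i], lines]
    ok <- !is.na(s) & !is.na(p)
    if (sum(ok) < min_shared) {
      n_excluded <<- n_excluded + 1L
      return(NULL)
    }
    r <- stats::cor(s[ok], p[ok], method = "spearman")
    data.frame(site = rownames(phospho_m$values)[i],
               protein = prot_of_site[i], n = sum(ok), r = r,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(site = character(), protein = character(),
                      n = integer(), r = numeric())
  out$bin <- correlation_bin(out$r)
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded + sum(!usable)
  out
}

correlation_bin <- function(r) {
  ifelse(is.na(r), NA_character_,
         ifelse(r > 0.6, "strong",
                ifelse(r > 0.4, "moderate",
                       ifelse(r > 0.2, "weak", "none"))))
}

#' Adjust phosphosite levels by parent protein abundance
#'
#' Subtracts the parent protein's log2 value from each site's log2 value
#' per cell line, removing the protein-expression component so residual
#' variation reflects kinase/phosphatase regulation. Sites whose parent
#' protein is absent from the protein matrix are dropped with a message.
#'
#' @param phospho_m,protein_m log-scale matrices sharing cell-line columns
#'   (typically collapsed).
#' @return `AbundanceMatrix` of protein-adjusted site values on the
#'   phospho matrix's scale tag.
#' @export
adjust_phospho_by_protein <- function(phospho_m, protein_m) {
  stopifnot_scale(phospho_m, c("log2p1", "lognorm", "collapsed"),
                  "adjust_phospho_by_protein")
  stopifnot_scale(protein_m, c("log2p1", "lognorm", "collapsed"),
                  "adjust_phospho_by_protein")
  cols <- intersect(colnames(phospho_m$values), colnames(protein_m$values))
  if (length(cols) == 0) stop("no shared columns")
  prot_of_site <- sub(":.*$", "", rownames(phospho_m$values))
  keep <- prot_of_site %in% rownames(protein_m$values)
  if (any(!keep))
    message(sum(!keep), " sites without a measured parent protein dropped")
  v <- phospho_m$values[keep, cols, drop = FALSE] -
    protein_m$values[prot_of_site[keep], cols, drop = FALSE]
  rownames(v) <- rownames(phospho_m$values)[keep]
  meta <- phospho_m$meta[match(cols, phospho_m$meta$sample), ]
  abundance_matrix(v, meta, phospho_m$scale)
}
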