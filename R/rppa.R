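#' Median-center an RPPA log2 matrix
#'
#' Loading normalization for reverse-phase protein arrays: each antibody
#' column is median-subtracted, then each sample row is median-subtracted.
#' The input is an antibody x sample matrix of log2 values, so here
#' "column" means antibody (matrix row = antibody feature); the operation
#' subtracts per-antibody medians across samples first, then per-sample
#' medians across antibodies. Optionally the normalized log2 values are
#' antilogged (2^x) to produce a linear dataset.
#'
#' @param raw_log2 `AbundanceMatrix` of log2 RPPA values (antibodies in
#'   rows, samples in columns), scale tag `"log2p1"`.
#' @param linearize if `TRUE`, return `2^value` on the raw scale tag.
#' @return normalized `AbundanceMatrix`.
#' @export
rppa_normalize <- function(raw_log2, linearize = FALSE) {
  stopifnot_scale(raw_log2, "log2p1", "rppa_normalize")
  v <- raw_log2$values
  if (any(rowSums(!is.na(v)) == 0) || any(colSums(!is.na(v)) == 0))
    stop("all-missing antibody row or sample column")
  ab_med <- apply(v, 1, stats::median, na.rm = TRUE)
  v <- v - ab_med
  smp_med <- apply(v, 2, stats::median, na.rm = TRUE)
  v <- sweep(v, 2, smp_med)
  if (linearize) {
    return(abundance_matrix(2^v, raw_log2$meta, "raw"))
  }
  abundance_matrix(v, raw_log2$meta, "log2p1")
}

#' Validate an RPPA antibody panel
#'
#' @param panel data.frame with columns `antibody`, `targets` (";"-joined
#'   accessions), `representative`, `is_phospho` (logical), and optionally
#'   `site_label`.
#' @return the validated panel.
#' @export
as_rppa_panel <- function(panel) {
  req <- c("antibody", "targets", "representative", "is_phospho")
  if (!is.data.frame(panel) || !all(req %in% names(panel)))
    stop("panel needs columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(panel$antibody)) stop("duplicate antibody IDs in panel")
  tg <- strsplit(panel$targets, ";", fixed = TRUE)
  ok <- mapply(function(t, r) r %in% t, tg, panel$representative)
  if (!all(ok))
    stop("representative accession not among targets for: ",
         paste(panel$antibody[!ok], collapse = ", "))
  panel
}

#' Map RPPA antibodies to MS features via representative accessions
#'
#' @param panel RPPA panel (see [as_rppa_panel()]).
#' @param ms `AbundanceMatrix` of MS features.
#' @return data.frame with one row per antibody: `antibody`,
#'   `representative`, `is_phospho`, `ms_feature` (`NA` when the
#'   representative accession is absent from the MS matrix).
#' @export
map_panel <- function(panel, ms) {
  panel <- as_rppa_panel(panel)
  feat <- rownames(ms$values)
  data.frame(antibody = panel$antibody,
             representative = panel$representative,
             is_phospho = panel$is_phospho,
             ms_feature = ifelse(panel$representative %in% feat,
                                 panel$representative, NA_character_),
             stringsAsFactors = FALSE)
}

#' Classify RPPA targets by MS detection coverage
#'
#' Each non-phospho antibody target is classified by the fraction of MS
#' samples in which it is detected (non-missing and positive):
#' `ms_majority` when detected in strictly more than 50% of samples,
#' `ms_minority` when detected in some but at most 50%, and `ms_absent`
#' when never detected by MS.
#'
#' @param panel RPPA panel.
#' @param ms raw-scale MS `AbundanceMatrix`.
#' @param majority_frac detection-fraction boundary (default 0.5, strict).
#' @return list with `per_antibody` (data.frame `antibody`,
#'   `ms_feature`, `detection_frac`, `class`) and `summary` (counts and
#'   fractions per class; classes partition the non-phospho panel).
#' @export
detection_coverage <- function(panel, ms, majority_frac = 0.5) {
  mapping <- map_panel(panel, ms)
  mapping <- mapping[!mapping$is_phospho, , drop = FALSE]
  det <- rowMeans(!is.na(ms$values) & ms$values > 0)
  frac <- ifelse(is.na(mapping$ms_feature), 0,
                 det[mapping$ms_feature])
  cls <- ifelse(frac > majority_frac, "ms_majority",
                ifelse(frac > 0, "ms_minority", "ms_absent"))
  per <- data.frame(antibody = mapping$antibody,
                    ms_feature = mapping$ms_feature,
                    detection_frac = unname(frac), class = cls,
                    stringsAsFactors = FALSE)
  counts <- base::table(factor(cls, levels = c("ms_majority", "ms_minority",
                                               "ms_absent")))
  list(per_antibody = per,
       summary = data.frame(class = names(counts),
                            n = as.integer(counts),
                            fraction = as.integer(counts) / nrow(per),
                            stringsAsFactors = FALSE))
}

#' Per-protein Spearman correlation between MS and RPPA across cell lines
#'
#' @param ms_collapsed,rppa_collapsed collapsed `AbundanceMatrix` objects
#'   with shared protein rownames and cell-line columns.
#' @param min_shared minimum shared non-missing lines per protein
#'   (default 5).
#' @return list with `per_protein` (data.frame `protein`, `n`, `r`),
#'   `median_r`, `fraction_positive`, `n_excluded`.
#' @export
per_protein_correlation <- function(ms_collapsed, rppa_collapsed,
                                    min_shared = 5) {
  stopifnot_scale(ms_collapsed, "collapsed", "per_protein_correlation")
  stopifnot_scale(rppa_collapsed, "collapsed", "per_protein_correlation")
  prots <- intersect(rownames(ms_collapsed$values),
                     rownames(rppa_collapsed$values))
  lines <- intersect(colnames(ms_collapsed$values),
                     colnames(rppa_collapsed$values))
  n_excluded <- 0L
  rows <- lapply(prots, function(p) {
    x <- ms_collapsed$values[p, lines]
    y <- rppa_collapsed$values[p, lines]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < min_shared) {
      n_excluded <<- n_excluded + 1L
      return(NULL)
    }
    data.frame(protein = p, n = sum(ok),
               r = stats::cor(x[ok], y[ok], method = "spearman"),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  if (is.null(per))
    per <- data.frame(protein = character(), n = integer(), r = numeric())
  rownames(per) <- NULL
  list(per_protein = per,
       median_r = stats::median(per$r),
       fraction_positive = mean(per$r > 0),
       n_excluded = n_excluded)
}

#' Fold-change concordance between MS and RPPA
#'
#' Per-protein log2 fold change between two cell-line groups, computed
#' identically on both platforms as the difference of group means of
#' log-scale values, then the Spearman correlation of the two fold-change
#' vectors across proteins.
#'
#' @param ms,rppa collapsed log-scale `AbundanceMatrix` objects.
#' @param group_a,group_b disjoint non-empty cell-line sets present on
#'   both platforms.
#' @return list with `fc` (data.frame `protein`, `fc_ms`, `fc_rppa`),
#'   `spearman`, `n_excluded` (proteins missing a group on a platform).
#' @export
foldchange_concordance <- function(ms, rppa, group_a, group_b) {
  stopifnot_scale(ms, "collapsed", "foldchange_concordance")
  stopifnot_scale(rppa, "collapsed", "foldchange_concordance")
  if (length(intersect(group_a, group_b)))
    stop("groups must be disjoint")
  if (!length(group_a) || !length(group_b)) stop("empty group")
  prots <- intersect(rownames(ms$values), rownames(rppa$values))
  gfc <- function(v, p) {
    a <- v[p, intersect(group_a, colnames(v)), drop = FALSE]
    b <- v[p, intersect(group_b, colnames(v)), drop = FALSE]
    if (ncol(a) == 0 || ncol(b) == 0) return(NA_real_)
    ma <- rowMeans(a); mb <- rowMeans(b)
    ma - mb
  }
  fc_ms <- gfc(ms$values, prots)
  fc_rppa <- gfc(rppa$values, prots)
  ok <- !is.na(fc_ms) & !is.na(fc_rppa)
  fc <- data.frame(protein = prots[ok], fc_ms = unname(fc_ms[ok]),
                   fc_rppa = unname(fc_rppa[ok]),
                   stringsAsFactors = FALSE)
  list(fc = fc,
       spearman = if (nrow(fc) >= 3)
         stats::cor(fc$fc_ms, fc$fc_rppa, method = "spearman")
       else NA_real_,
       n_excluded = sum(!ok))
}

#' Within- versus between-group sample correlations
#'
#' Mean pairwise Spearman correlation of sample columns within groups
#' (intra) and across groups (inter), a reproducibility summary for one
#' data layer. Singleton groups contribute no intra pairs.
#'
#' @param m `AbundanceMatrix` on any scale.
#' @param groups named character vector mapping each sample to a group.
#' @return list with `intra`, `inter` (mean correlations), and `pairs`
#'   (data.frame of all pairwise correlations with a `type` column).
#' @export
intra_inter_correlation <- function(m, groups) {
  cols <- colnames(m$values)
  if (!all(cols %in% names(groups)))
    stop("`groups` must label every sample")
  g <- groups[cols]
  if (length(unique(g)) < 2) stop("need at least 2 groups")
  cm <- stats::cor(m$values, method = "spearman",
                   use = "pairwise.complete.obs")
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  pairs <- data.frame(sample1 = cols[idx[, 1]], sample2 = cols[idx[, 2]],
                      r = cm[idx],
                      type = ifelse(g[idx[, 1]] == g[idx[, 2]],
                                    "intra", "inter"),
                      stringsAsFactors = FALSE)
  list(intra = mean(pairs$r[pairs$type == "intra"]),
       inter = mean(pairs$r[pairs$type == "inter"]),
       pairs = pairs)
}
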