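#' Drop features detected in too few samples
#'
#' Detection means a non-missing, strictly positive raw intensity. Features
#' detected in fewer than `min_frac` of samples are removed; the default 5%
#' is deliberately lenient to accommodate lineage-restricted proteins in a
#' diverse cell-line panel.
#'
#' @param m raw-scale `AbundanceMatrix`.
#' @param min_frac minimum detection fraction in (0, 1].
#' @return filtered `AbundanceMatrix`; dropped feature IDs are attached as
#'   attribute `"dropped"`.
#' @export
filter_low_detection <- function(m, min_frac = 0.05) {
  stopifnot_scale(m, "raw", "filter_low_detection")
  if (!is.numeric(min_frac) || length(min_frac) != 1 ||
      min_frac <= 0 || min_frac > 1)
    stop("`min_frac` must be in (0, 1]")
  det <- rowMeans(!is.na(m$values) & m$values > 0)
  keep <- det >= min_frac
  out <- abundance_matrix(m$values[keep, , drop = FALSE], m$meta, "raw")
  attr(out, "dropped") <- rownames(m$values)[!keep]
  out
}

#' Impute missing intensities with the global observed minimum
#'
#' Every missing cell is set to the single smallest observed intensity in
#' the whole matrix, reflecting the left-censored nature of MS missingness
#' (undetected low-abundance peptides). No observed cell changes.
#'
#' @param m raw-scale `AbundanceMatrix`.
#' @return imputed `AbundanceMatrix` (raw scale, no `NA`s).
#' @export
impute_global_min <- function(m) {
  stopifnot_scale(m, "raw", "impute_global_min")
  if (all(is.na(m$values))) stop("cannot impute an all-missing matrix")
  gmin <- min(m$values, na.rm = TRUE)
  v <- m$values
  v[is.na(v)] <- gmin
  abundance_matrix(v, m$meta, "raw")
}

#' log2(x+1) transform with sample-wise median adjustment
#'
#' Intensities are log2(x+1)-transformed, then each sample column is
#' shifted so its median equals the grand median of the column medians.
#' The post-condition (all column medians equal) holds exactly.
#'
#' @param m raw-scale, imputed `AbundanceMatrix`.
#' @return `AbundanceMatrix` with scale tag `"log2p1"`.
#' @export
log2p1_median_normalize <- function(m) {
  stopifnot_scale(m, "raw", "log2p1_median_normalize")
  if (anyNA(m$values))
    stop("impute before normalizing (missing values present)")
  if (any(m$values < 0)) stop("negative intensities")
  v <- log2(m$values + 1)
  med <- apply(v, 2, stats::median)
  target <- stats::median(med)
  v <- sweep(v, 2, med - target)
  abundance_matrix(v, m$meta, "log2p1")
}

#' Library-size log normalization
#'
#' Per sample: value <- ln(1 + scale_factor * x / column_sum), the
#' "LogNormalize" scheme used by single-cell toolkits, here applied to
#' LFQ intensity columns. Scale-invariant within a column.
#'
#' @param m raw-scale, imputed `AbundanceMatrix`.
#' @param scale_factor pseudo library size (default 1e4).
#' @return `AbundanceMatrix` with scale tag `"lognorm"`.
#' @export
lognormalize <- function(m, scale_factor = 1e4) {
  stopifnot_scale(m, "raw", "lognormalize")
  if (anyNA(m$values))
    stop("impute before normalizing (missing values present)")
  cs <- colSums(m$values)
  if (any(cs == 0)) stop("zero column sum; cannot lognormalize")
  v <- log1p(sweep(m$values, 2, cs / scale_factor, "/"))
  abundance_matrix(v, m$meta, "lognorm")
}

#' Average replicate columns into one column per cell line
#'
#' @param m log-scale (`log2p1` or `lognorm`) `AbundanceMatrix` with
#'   replicate metadata.
#' @return `AbundanceMatrix` with scale tag `"collapsed"`, one column per
#'   cell line (arithmetic mean of its replicates on the log scale); the
#'   metadata keeps one row per line with `replicate = "mean"`.
#' @export
collapse_replicates <- function(m) {
  stopifnot_scale(m, c("log2p1", "lognorm"), "collapse_replicates")
  lines <- unique(m$meta$cell_line)
  v <- vapply(lines, function(cl) {
    cols <- m$meta$sample[m$meta$cell_line == cl]
    if (length(cols) == 0) stop("cell line with zero replicates: ", cl)
    rowMeans(m$values[, cols, drop = FALSE])
  }, numeric(nrow(m$values)))
  dimnames(v) <- list(rownames(m$values), lines)
  meta <- data.frame(
    sample = lines, cell_line = lines, replicate = "mean",
    lineage = m$meta$lineage[match(lines, m$meta$cell_line)],
    stringsAsFactors = FALSE)
  abundance_matrix(v, meta, "collapsed")
}

#' Per-feature coefficient of variation across one line's replicates
#'
#' CV = sample SD / mean over the replicates of `line`, on the raw (linear)
#' intensity scale. Features with any missing replicate in that line are
#' excluded. Used to assess technical reproducibility (e.g. the fraction of
#' proteins with CV below 20%).
#'
#' @param m raw-scale `AbundanceMatrix`.
#' @param line cell-line ID with at least two replicates.
#' @param threshold CV threshold for the summary fraction (default 0.2).
#' @return list with `cv` (named per-feature vector), `fraction_below`,
#'   `threshold`, and `n_excluded` (features with missing replicates).
#' @export
compute_cv <- function(m, line, threshold = 0.2) {
  stopifnot_scale(m, "raw", "compute_cv")
  cols <- m$meta$sample[m$meta$cell_line == line]
  if (length(cols) < 2) stop("line '", line, "' has fewer than 2 replicates")
  v <- m$values[, cols, drop = FALSE]
  complete <- rowSums(is.na(v)) == 0
  v <- v[complete, , drop = FALSE]
  mu <- rowMeans(v)
  sdv <- apply(v, 1, stats::sd)
  cv <- sdv / mu
  list(cv = cv,
       fraction_below = mean(cv < threshold),
       threshold = threshold,
       n_excluded = sum(!complete))
}

#' Log2 fold change of a cell-line group versus all other lines
#'
#' FC = mean over the group's columns minus mean over the complement, on
#' the collapsed log2 scale (a difference of log2 means).
#'
#' @param m collapsed `AbundanceMatrix`.
#' @param group character vector of cell-line IDs; must be a non-empty
#'   proper subset of the matrix's lines.
#' @return named numeric vector of per-feature log2 fold changes.
#' @export
group_fold_change <- function(m, group) {
  stopifnot_scale(m, "collapsed", "group_fold_change")
  lines <- colnames(m$values)
  group <- unique(group)
  if (!all(group %in% lines)) stop("unknown cell line in `group`")
  rest <- setdiff(lines, group)
  if (length(group) == 0) stop("`group` is empty")
  if (length(rest) == 0) stop("`group` leaves an empty complement")
  rowMeans(m$values[, group, drop = FALSE]) -
    rowMeans(m$values[, rest, drop = FALSE])
}

#' One-vs-rest Wilcoxon rank-sum differential expression
#'
#' For each feature and each group, a two-sided Wilcoxon rank-sum test of
#' the group's samples against all others, with Bonferroni adjustment over
#' the total feature count. A feature is called significant for a group
#' when |log2 FC| > `fc_cutoff` and the adjusted p-value is below `alpha`.
#' Constant features get p = 1 by convention.
#'
#' @param m log-scale `AbundanceMatrix` (columns are the test units;
#'   typically a collapsed matrix, so lines are units).
#' @param groups named character vector mapping every sample/column to a
#'   group label (e.g. lineage).
#' @param fc_cutoff absolute log2 FC cutoff (default 2).
#' @param alpha adjusted p-value cutoff (default 0.05).
#' @param exact passed to [stats::wilcox.test()]; `NULL` lets it choose,
#'   `FALSE` forces the normal approximation (appropriate for dozens of
#'   samples per test and much faster in simulations).
#' @return data.frame with columns `feature`, `group`, `log2_fc`, `p`,
#'   `p_adj`, `significant`.
#' @export
wilcoxon_de <- function(m, groups, fc_cutoff = 2, alpha = 0.05,
                        exact = NULL) {
  stopifnot_scale(m, c("log2p1", "lognorm", "collapsed"), "wilcoxon_de")
  cols <- colnames(m$values)
  if (!all(cols %in% names(groups)))
    stop("`groups` must label every column of the matrix")
  g <- groups[cols]
  labs <- unique(g)
  if (length(labs) < 2) stop("need at least 2 groups")
  if (any(base::table(g) < 2)) stop("every group needs >= 2 samples")
  n_feat <- nrow(m$values)
  one_group <- function(lab) {
    in_g <- g == lab
    x <- m$values[, in_g, drop = FALSE]
    y <- m$values[, !in_g, drop = FALSE]
    fc <- rowMeans(x) - rowMeans(y)
    p <- vapply(seq_len(n_feat), function(i) {
      xi <- x[i, ]; yi <- y[i, ]
      if (stats::sd(c(xi, yi)) == 0) return(1)
      stats::wilcox.test(xi, yi, exact = exact)$p.value
    }, numeric(1))
    data.frame(feature = rownames(m$values), group = lab,
               log2_fc = fc, p = p, stringsAsFactors = FALSE)
  }
  if (length(labs) == 2) {
    # two-sided one-vs-rest tests for two groups mirror each other
    first <- one_group(labs[1])
    second <- first
    second$group <- labs[2]
    second$log2_fc <- -first$log2_fc
    res <- list(first, second)
  } else {
    res <- lapply(labs, one_group)
  }
  out <- do.call(rbind, res)
  out$p_adj <- pmin(1, out$p * n_feat)
  out$significant <- abs(out$log2_fc) > fc_cutoff & out$p_adj < alpha
  rownames(out) <- NULL
  out
}

#' Cosine marker score (COSG-style) for one-vs-rest marker detection
#'
#' For each feature, the cosine similarity \eqn{\lambda_k} between its
#' linear-intensity vector across cell lines and each group's indicator
#' vector is computed; the score for (feature, group k) is
#' \deqn{s_k = \lambda_k \cdot \frac{\lambda_k^2}{\mu \sum_j \lambda_j^2 +
#'   (1-\mu)\lambda_k^2}}
#' so similarity to the other groups is penalized with weight `mu`. A
#' feature expressed only in the target group (equal values inside, zero
#' outside) scores exactly 1 for any `mu`. Scores are computed on the
#' back-transformed linear scale (`2^v - 1` for a log2(x+1)-derived
#' collapsed matrix): the cosine geometry assumes non-negative vectors in
#' which group-restricted expression dominates the norm, as in the sparse
#' expression data the scheme was designed for.
#'
#' @param m collapsed `AbundanceMatrix` (log2p1-derived).
#' @param groups named character vector mapping each cell line to a group
#'   (default: the lineage metadata).
#' @param mu penalty weight >= 0 (default 1).
#' @param threshold marker flag threshold on the score (default 0.5).
#' @return data.frame with `feature`, `group`, `score`, `marker`.
#'   Features with no signal in any line (zero norm) score 0 for every
#'   group.
#' @export
cosine_marker_score <- function(m, groups = NULL, mu = 1, threshold = 0.5) {
  stopifnot_scale(m, "collapsed", "cosine_marker_score")
  lines <- colnames(m$values)
  if (is.null(groups)) {
    groups <- stats::setNames(m$meta$lineage, m$meta$sample)
  }
  if (!all(lines %in% names(groups)))
    stop("`groups` must label every cell line")
  g <- groups[lines]
  labs <- sort(unique(g))
  if (length(labs) < 2) stop("need at least 2 groups")
  v <- 2^m$values - 1                  # back to linear intensities
  v[v < 0] <- 0
  zero_norm <- rowSums(v^2) == 0       # no signal anywhere -> score 0
  v_norm <- sqrt(rowSums(v^2))
  v_norm[v_norm == 0] <- 1
  ind <- vapply(labs, function(lab) as.numeric(g == lab),
                numeric(length(lines)))
  ind <- sweep(ind, 2, sqrt(colSums(ind^2)), "/")
  lam <- (v %*% ind) / v_norm          # features x groups cosine matrix
  lam2 <- lam^2
  denom <- mu * rowSums(lam2) + (1 - mu) * lam2
  denom[denom == 0] <- 1
  score <- lam * lam2 / denom
  score[zero_norm, ] <- 0
  out <- data.frame(
    feature = rep(rownames(v), times = length(labs)),
    group = rep(labs, each = nrow(v)),
    score = as.vector(score),
    stringsAsFactors = FALSE)
  out$marker <- out$score > threshold
  out
}
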