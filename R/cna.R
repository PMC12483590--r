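#' Correlate copy number with proteomic/phosphoproteomic features
#'
#' Spearman correlations between gene copy-number values (log2(CN ratio+1))
#' and feature abundances across shared cell lines. Cis pairs (feature's
#' own gene) are always computed; trans pairs are computed for a
#' configurable gene/feature subset since the full cross-product grows as
#' genes x features. Protein features should be normalized and phosphosite
#' features protein-adjusted (see [adjust_phospho_by_protein()]) before
#' calling.
#'
#' @param cna `CNAMatrix`.
#' @param features collapsed `AbundanceMatrix`.
#' @param feature_gene_map named character vector mapping feature IDs to
#'   gene symbols; defaults to identity on the feature rownames (with
#'   `protein:site` IDs truncated to the protein).
#' @param trans `"none"`, `"subset"` (default) or `"full"`: whether to add
#'   trans pairs, and for `"subset"` restrict to the `max_trans_genes` /
#'   `max_trans_features` highest-variance genes and features.
#' @param max_trans_genes,max_trans_features subset sizes (default 100).
#' @param min_shared minimum shared cell lines per pair (default 5).
#' @return data.frame `gene`, `feature`, `arm`, `n`, `r`, `cis`.
#' @export
cna_feature_correlation <- function(cna, features, feature_gene_map = NULL,
                                    trans = c("subset", "none", "full"),
                                    max_trans_genes = 100,
                                    max_trans_features = 100,
                                    min_shared = 5) {
  trans <- match.arg(trans)
  if (!inherits(cna, "CNAMatrix")) stop("`cna` must be a CNAMatrix")
  stopifnot_scale(features, c("collapsed", "log2p1", "lognorm"),
                  "cna_feature_correlation")
  feat_ids <- rownames(features$values)
  if (is.null(feature_gene_map))
    feature_gene_map <- stats::setNames(sub(":.*$", "", feat_ids), feat_ids)
  if (!all(feat_ids %in% names(feature_gene_map)))
    stop("feature_gene_map must cover every feature")
  lines <- intersect(colnames(cna$values), colnames(features$values))
  if (length(lines) < min_shared) stop("fewer than ", min_shared,
                                       " shared cell lines")
  genes <- rownames(cna$values)
  if (any(is.na(cna$arm)))
    warning("genes without arm annotation enter trans summaries only")

  pairs <- data.frame(gene = character(), feature = character(),
                      stringsAsFactors = FALSE)
  cis_genes <- feature_gene_map[feat_ids]
  cis_idx <- cis_genes %in% genes
  pairs <- rbind(pairs, data.frame(gene = unname(cis_genes[cis_idx]),
                                   feature = feat_ids[cis_idx],
                                   stringsAsFactors = FALSE))
  if (trans != "none") {
    tg <- genes
    tf <- feat_ids
    if (trans == "subset") {
      gv <- apply(cna$values[, lines, drop = FALSE], 1, stats::var)
      fv <- apply(features$values[, lines, drop = FALSE], 1, stats::var)
      tg <- names(sort(gv, decreasing = TRUE))[
        seq_len(min(max_trans_genes, length(gv)))]
      tf <- names(sort(fv, decreasing = TRUE))[
        seq_len(min(max_trans_features, length(fv)))]
    }
    tp <- expand.grid(gene = tg, feature = tf, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
    tp <- tp[feature_gene_map[tp$feature] != tp$gene, , drop = FALSE]
    pairs <- rbind(pairs, tp)
  }
  pairs <- unique(pairs)

  # rank-transform once, then Pearson on ranks = Spearman (complete lines)
  gmat <- cna$values[, lines, drop = FALSE]
  fmat <- features$values[, lines, drop = FALSE]
  r <- numeric(nrow(pairs))
  n <- integer(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    x <- gmat[pairs$gene[k], ]
    y <- fmat[pairs$feature[k], ]
    ok <- !is.na(x) & !is.na(y)
    n[k] <- sum(ok)
    r[k] <- if (n[k] >= min_shared)
      stats::cor(x[ok], y[ok], method = "spearman") else NA_real_
  }
  out <- data.frame(gene = pairs$gene, feature = pairs$feature,
                    arm = unname(cna$arm[pairs$gene]), n = n, r = r,
                    cis = feature_gene_map[pairs$feature] == pairs$gene,
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$r), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-arm cis/trans association summary
#'
#' Counts, per chromosome arm, the (gene, feature) correlations whose
#' absolute Spearman r passes a threshold, split into cis and trans.
#'
#' @param corr data.frame from [cna_feature_correlation()].
#' @param r_threshold absolute-correlation threshold (default 0.5); the
#'   hotspot usage is visual, so no specific threshold is canonical.
#' @return data.frame `arm`, `cis_n`, `trans_n`, `cis_fraction`,
#'   `trans_fraction` (fractions of all passing cis/trans pairs on that
#'   arm); counts sum to the number of passing pairs.
#' @export
cis_trans_summary <- function(corr, r_threshold = 0.5) {
  pass <- corr[abs(corr$r) >= r_threshold, , drop = FALSE]
  arms <- sort(unique(corr$arm))
  cis_n <- vapply(arms, function(a)
    sum(pass$arm == a & pass$cis), integer(1))
  trans_n <- vapply(arms, function(a)
    sum(pass$arm == a & !pass$cis), integer(1))
  data.frame(arm = arms, cis_n = cis_n, trans_n = trans_n,
             cis_fraction = if (sum(cis_n)) cis_n / sum(cis_n) else 0,
             trans_fraction = if (sum(trans_n)) trans_n / sum(trans_n)
             else 0,
             row.names = NULL, stringsAsFactors = FALSE)
}
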