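#' Feature-by-sample abundance matrix with sample metadata
#'
#' The shared container for proteome, phosphoproteome and RPPA layers: a
#' numeric feature x sample matrix (missing values as `NA`) together with a
#' sample metadata table mapping each column to a cell line, replicate and
#' lineage, and a scale tag recording where the matrix sits in the
#' preprocessing pipeline.
#'
#' The scale tag enforces pipeline order: `"raw"` (linear intensities, may
#' contain `NA`/zero), `"log2p1"` (log2(x+1) median-normalized), `"lognorm"`
#' (library-size log normalization) and `"collapsed"` (log-scale, one column
#' per cell line). Operations check the tag and fail loudly when called out
#' of order.
#'
#' @param values numeric matrix, features in rows (rownames required),
#'   samples in columns (colnames required). Raw-scale values must be
#'   non-negative where observed.
#' @param meta data.frame with columns `sample`, `cell_line`, `replicate`,
#'   `lineage`; one row per column of `values`, matched by `sample`.
#' @param scale one of `"raw"`, `"log2p1"`, `"lognorm"`, `"collapsed"`.
#' @return An object of class `AbundanceMatrix`: a list with elements
#'   `values`, `meta`, `scale`.
#' @export
abundance_matrix <- function(values, meta, scale = "raw") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have rownames (features) and colnames (samples)")
  scale <- match.arg(scale, c("raw", "log2p1", "lognorm", "collapsed"))
  req <- c("sample", "cell_line", "replicate", "lineage")
  if (!is.data.frame(meta) || !all(req %in% names(meta)))
    stop("`meta` must be a data.frame with columns: ",
         paste(req, collapse = ", "))
  if (!setequal(meta$sample, colnames(values)) ||
      nrow(meta) != ncol(values))
    stop("`meta$sample` must match the columns of `values` exactly")
  meta <- meta[match(colnames(values), meta$sample), req, drop = FALSE]
  rownames(meta) <- NULL
  if (scale == "raw") {
    obs <- values[!is.na(values)]
    if (length(obs) && any(obs < 0))
      stop("raw-scale intensities must be non-negative")
  }
  structure(list(values = values, meta = meta, scale = scale),
            class = "AbundanceMatrix")
}

#' @export
print.AbundanceMatrix <- function(x, ...) {
  cat(sprintf(
    "AbundanceMatrix: %d features x %d samples [scale: %s]\n",
    nrow(x$values), ncol(x$values), x$scale))
  cat(sprintf("  cell lines: %d; lineages: %d; missing: %.1f%%\n",
              length(unique(x$meta$cell_line)),
              length(unique(x$meta$lineage)),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.AbundanceMatrix <- function(x) dim(x$values)

is_abundance_matrix <- function(x) inherits(x, "AbundanceMatrix")

stopifnot_scale <- function(m, allowed, op) {
  if (!is_abundance_matrix(m))
    stop(op, "() expects an AbundanceMatrix")
  if (!m$scale %in% allowed)
    stop(op, "() requires scale ", paste(allowed, collapse = "/"),
         " but got '", m$scale, "' - pipeline stages called out of order")
  invisible(TRUE)
}

#' Subset an AbundanceMatrix
#'
#' @param x AbundanceMatrix
#' @param i feature index (rows)
#' @param j sample index (columns)
#' @param ... unused
#' @return AbundanceMatrix restricted to the selected features/samples.
#' @export
`[.AbundanceMatrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  v <- x$values[i, j, drop = FALSE]
  abundance_matrix(v, x$meta[match(colnames(v), x$meta$sample), ],
                   scale = x$scale)
}

#' Copy-number matrix with chromosome-arm annotation
#'
#' Gene x cell-line copy-number values on the log2(CN ratio + 1) scale, where
#' a diploid gene (CN ratio 1) maps to 1, plus a chromosome-arm label per
#' gene used for cis/trans hotspot summaries.
#'
#' @param values numeric gene x line matrix (rownames = genes); values must
#'   be non-negative (log2(CN ratio + 1) with CN ratio >= 0).
#' @param arm named character vector of arm labels (e.g. "chr5p"), one per
#'   gene in `values`.
#' @return Object of class `CNAMatrix`, a list with `values` and `arm`.
#' @export
cna_matrix <- function(values, arm) {
  if (!is.matrix(values) || is.null(rownames(values)))
    stop("`values` must be a matrix with gene rownames")
  if (any(values[!is.na(values)] < 0))
    stop("log2(CN ratio + 1) values must be non-negative")
  if (is.null(names(arm)) || !all(rownames(values) %in% names(arm)))
    stop("`arm` must be named and cover every gene")
  structure(list(values = values, arm = arm[rownames(values)]),
            class = "CNAMatrix")
}

#' @export
print.CNAMatrix <- function(x, ...) {
  cat(sprintf("CNAMatrix: %d genes x %d lines, %d chromosome arms\n",
              nrow(x$values), ncol(x$values), length(unique(x$arm))))
  invisible(x)
}
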