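#' Parse a Byonic-style glycan composition string
#'
#' Glycan compositions are reported as concatenated `Token(count)` pairs,
#' e.g. `"HexNAc(4)Hex(5)NeuAc(2)"`, over the monosaccharide tokens HexNAc
#' (N-acetylhexosamine), Hex (hexose), Fuc (fucose), NeuAc (sialic acid) and
#' an open set of rarer residues.
#'
#' @param text composition string.
#' @return named integer vector of monosaccharide counts (class
#'   `glycan_composition`), in canonical token order.
#' @export
#' @examples
#' parse_glycan_composition("HexNAc(4)Hex(5)NeuAc(2)")
parse_glycan_composition <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text) ||
      !nzchar(text))
    stop("composition must be a single non-empty string")
  m <- gregexpr("([A-Za-z0-9_]+)\\(([^)]*)\\)", text, perl = TRUE)[[1]]
  if (m[1] == -1)
    stop("malformed glycan composition: '", text, "'")
  parts <- regmatches(text, gregexpr("([A-Za-z0-9_]+)\\(([^)]*)\\)",
                                     text, perl = TRUE))[[1]]
  if (sum(nchar(parts)) != nchar(text))
    stop("malformed glycan composition: '", text,
         "' contains text outside Token(count) pairs")
  tokens <- sub("\\(.*$", "", parts)
  counts_chr <- sub("^.*\\(", "", sub("\\)$", "", parts))
  bad <- !grepl("^[0-9]+$", counts_chr)
  if (any(bad))
    stop("malformed glycan composition: non-integer count for token '",
         tokens[which(bad)[1]], "'")
  counts <- as.integer(counts_chr)
  if (anyDuplicated(tokens)) {
    counts <- tapply(counts, tokens, sum)
    tokens <- names(counts)
    counts <- as.integer(counts)
  }
  names(counts) <- tokens
  comp <- counts[counts > 0]
  if (length(comp) == 0 || sum(comp) < 1)
    stop("glycan composition must contain at least one residue")
  structure(comp[order_glycan_tokens(names(comp))],
            class = "glycan_composition")
}

# canonical token order: HexNAc, Hex, Fuc, NeuAc, then others alphabetically
order_glycan_tokens <- function(tokens) {
  core <- c("HexNAc", "Hex", "Fuc", "NeuAc")
  rank <- match(tokens, core)
  rank[is.na(rank)] <- length(core) + 1L
  order(rank, tokens)
}

#' Canonical string form of a glycan composition
#'
#' @param comp named integer vector as returned by
#'   [parse_glycan_composition()].
#' @return canonical composition string; `parse_glycan_composition()`
#'   round-trips it.
#' @export
glycan_to_string <- function(comp) {
  comp <- comp[comp > 0]
  comp <- comp[order_glycan_tokens(names(comp))]
  paste0(names(comp), "(", as.integer(comp), ")", collapse = "")
}

#' Classify a glycan composition
#'
#' Mutually exclusive priority classes: `sialylated` if the composition
#' contains any NeuAc; otherwise `fucosylated` if it contains any Fuc;
#' otherwise `high_mannose` if it has exactly the chitobiose core
#' (HexNAc = 2) with five or more hexoses; otherwise `other`. Sialylation
#' takes priority over fucosylation so the three named classes partition
#' the glycans.
#'
#' @param comp parsed composition (named integer vector) or a composition
#'   string.
#' @return one of `"sialylated"`, `"fucosylated"`, `"high_mannose"`,
#'   `"other"`.
#' @export
classify_glycan <- function(comp) {
  if (is.character(comp)) comp <- parse_glycan_composition(comp)
  cnt <- function(tok) if (tok %in% names(comp)) unname(comp[[tok]]) else 0L
  if (cnt("NeuAc") >= 1) return("sialylated")
  if (cnt("Fuc") >= 1) return("fucosylated")
  if (cnt("HexNAc") == 2 && cnt("Hex") >= 5) return("high_mannose")
  "other"
}

glycan_classes <- c("sialylated", "fucosylated", "high_mannose", "other")

check_psm_table <- function(psms) {
  req <- c("protein", "site", "composition", "sample")
  if (!is.data.frame(psms) || !all(req %in% names(psms)))
    stop("PSM table must contain columns: ", paste(req, collapse = ", "))
  if (nrow(psms) && "spectrum_id" %in% names(psms) &&
      anyDuplicated(psms$spectrum_id))
    stop("duplicate spectrum identifiers in PSM table: ",
         "spectral counting would double-count")
  invisible(TRUE)
}

#' Aggregate glycopeptide PSMs into site-specific glycan spectral counts
#'
#' A site-specific glycan is a particular glycan composition at a specific
#' glycosylation site of a protein. Its abundance in a sample is the number
#' of peptide-spectrum matches carrying that composition at that site,
#' pooled over peptide sequence, missed cleavages and charge state.
#'
#' @param psms data.frame with columns `protein`, `site`, `composition`
#'   (canonical composition string), `sample`; extra columns (peptide,
#'   charge, missed_cleavages, spectrum_id, ...) are ignored except that
#'   duplicated `spectrum_id`s raise an error.
#' @return a `site_glycan_table`: data.frame with columns `protein`, `site`,
#'   `composition`, `class`, then one integer count column per sample.
#'   Keys with zero PSMs are absent; column sums equal the number of input
#'   PSMs per sample.
#' @export
aggregate_site_glycans <- function(psms) {
  check_psm_table(psms)
  samples <- sort(unique(as.character(psms$sample)))
  if (nrow(psms) == 0) {
    out <- data.frame(protein = character(), site = integer(),
                      composition = character(), class = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("site_glycan_table", class(out))
    attr(out, "samples") <- character()
    return(out)
  }
  key <- paste(psms$protein, psms$site, psms$composition, sep = "\r")
  tab <- table(key, factor(as.character(psms$sample), levels = samples))
  keys <- rownames(tab)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(
    protein = vapply(parts, `[[`, "", 1L),
    site = as.integer(vapply(parts, `[[`, "", 2L)),
    composition = vapply(parts, `[[`, "", 3L),
    stringsAsFactors = FALSE)
  out$class <- vapply(out$composition, classify_glycan, "")
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = list(NULL, samples))
  out <- cbind(out, as.data.frame(counts, stringsAsFactors = FALSE))
  ord <- order(out$protein, out$site, out$composition)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("site_glycan_table", class(out))
  attr(out, "samples") <- samples
  out
}

sgt_samples <- function(table) {
  s <- attr(table, "samples")
  if (is.null(s))
    s <- setdiff(names(table),
                 c("protein", "site", "composition", "class",
                   "n_consistent_lines"))
  s
}

#' Replicate-consistency filter for site-specific glycans
#'
#' A site-specific glycan is consistently detected in a cell line when it
#' has nonzero spectral counts in strictly more than half of that line's
#' replicates. The filter keeps rows consistently detected in at least one
#' cell line and annotates each kept row with the number of lines in which
#' it is consistent.
#'
#' @param table `site_glycan_table` from [aggregate_site_glycans()].
#' @param replicate_map data.frame with columns `sample`, `cell_line`
#'   covering every count column of `table`.
#' @return the filtered table with an extra `n_consistent_lines` column.
#' @export
consistency_filter <- function(table, replicate_map) {
  samples <- sgt_samples(table)
  if (!all(samples %in% replicate_map$sample))
    stop("replicate_map must cover every sample column of the table")
  rm <- replicate_map[match(samples, replicate_map$sample), ]
  lines <- split(samples, rm$cell_line)
  if (any(lengths(lines) == 0))
    stop("cell line with zero replicates")
  counts <- as.matrix(table[, samples, drop = FALSE])
  n_consistent <- rep(0L, nrow(table))
  for (line_samples in lines) {
    n_rep <- length(line_samples)
    det <- rowSums(counts[, line_samples, drop = FALSE] > 0)
    n_consistent <- n_consistent + as.integer(det > n_rep / 2)
  }
  keep <- n_consistent >= 1L
  out <- table[keep, , drop = FALSE]
  out$n_consistent_lines <- n_consistent[keep]
  rownames(out) <- NULL
  attr(out, "samples") <- samples
  out
}

#' Class fractions of distinct site-specific glycans
#'
#' Fractions of unique (protein, site, composition) keys falling in each
#' glycan class; the enumerated unit is the distinct site-specific glycan,
#' not its spectral count.
#'
#' @param table `site_glycan_table`.
#' @return named numeric vector over `sialylated`, `fucosylated`,
#'   `high_mannose`, `other`; sums to 1.
#' @export
class_fractions <- function(table) {
  if (nrow(table) == 0) stop("class_fractions() needs a non-empty table")
  cls <- factor(table$class, levels = glycan_classes)
  tab <- base::table(cls)
  frac <- as.vector(tab) / nrow(table)
  names(frac) <- glycan_classes
  frac
}
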