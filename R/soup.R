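#' Read a droplet count matrix triplet (MatrixMarket + barcodes + features)
#'
#' Reads the standard droplet-matrix directory layout: `matrix.mtx`
#' (genes x barcodes, MatrixMarket), `barcodes.tsv` (one barcode per line)
#' and `features.tsv` (gene id in the first column).
#'
#' @param dir directory containing the three files.
#' @return sparse `dgCMatrix`, genes in rows, barcodes in columns.
#' @export
read_droplet_matrix <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  barcodes <- readr::read_tsv(file.path(dir, "barcodes.tsv"),
                              col_names = FALSE, show_col_types = FALSE)[[1]]
  features <- readr::read_tsv(file.path(dir, "features.tsv"),
                              col_names = FALSE, show_col_types = FALSE)[[1]]
  if (nrow(m) != length(features) || ncol(m) != length(barcodes)) {
    stop("matrix dimensions do not match features/barcodes files")
  }
  dimnames(m) <- list(features, barcodes)
  m
}

#' Write a droplet count matrix triplet
#'
#' @param counts sparse or dense genes x barcodes matrix with dimnames.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_droplet_matrix <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(methods::as(counts, "dMatrix"), "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  invisible(dir)
}

#' Discard fake droplets with very few UMIs
#'
#' Removes barcodes whose total UMI count is strictly below `min_umi`
#' (droplets this shallow are likely artifacts of sequencing errors rather
#' than real emulsion droplets, empty or not).
#'
#' @param counts genes x barcodes count matrix.
#' @param min_umi minimum total UMI count to keep a barcode (strict `<`
#'   removal; the default keeps barcodes with 5 or more UMIs).
#' @return the matrix restricted to retained barcodes.
#' @export
filter_fake_droplets <- function(counts, min_umi = 5) {
  totals <- Matrix::colSums(counts)
  keep <- totals >= min_umi
  if (!any(keep)) warning("all barcodes fall below the UMI threshold")
  counts[, keep, drop = FALSE]
}

#' Should a sample contribute to ambient-soup estimation?
#'
#' A sample is treated as ambient-noisy — and therefore informative about
#' the soup — when its 'fraction of reads in cells' quality metric is
#' strictly below the threshold (default 70%, following the standard
#' guidance for interpreting that metric).
#'
#' @param fraction_reads_in_cells per-sample fraction in \eqn{[0, 1]}.
#' @param threshold gate value (default 0.70).
#' @return logical: `TRUE` when the sample passes the gate (is noisy).
#' @export
sample_noisiness_gate <- function(fraction_reads_in_cells, threshold = 0.70) {
  if (any(fraction_reads_in_cells < 0 | fraction_reads_in_cells > 1)) {
    stop("fraction_reads_in_cells must lie in [0, 1]")
  }
  fraction_reads_in_cells < threshold
}

#' Per-gene soup probability
#'
#' For every gene g computes
#' \deqn{P_g = E_g^{empty} / (E_g^{empty} + E_g^{cells}),}
#' where \eqn{E_g^{empty}} is the gene's total UMI count over empty droplets
#' and \eqn{E_g^{cells}} its total over droplets called as cells/nuclei.
#' Genes observed in neither class are marked undefined and never labelled.
#'
#' @param counts pooled genes x barcodes count matrix (fake droplets already
#'   removed, see [filter_fake_droplets()]).
#' @param cell_flag logical vector over barcodes: `TRUE` for cells/nuclei,
#'   `FALSE` for empty droplets.
#' @return tibble, one row per gene: `gene`, `e_empty`, `e_cells`, `soup_p`
#'   (`NA` when undefined).
#' @export
soup_probability <- function(counts, cell_flag) {
  if (length(cell_flag) != ncol(counts)) {
    stop("cell_flag must have one entry per barcode")
  }
  if (!any(!cell_flag)) stop("no empty droplets present")
  e_empty <- unname(as.numeric(Matrix::rowSums(counts[, !cell_flag, drop = FALSE])))
  e_cells <- unname(as.numeric(Matrix::rowSums(counts[, cell_flag, drop = FALSE])))
  tot <- e_empty + e_cells
  tibble::tibble(
    gene = rownames(counts),
    e_empty = e_empty,
    e_cells = e_cells,
    soup_p = ifelse(tot > 0, e_empty / tot, NA_real_)
  )
}

#' Soup statistics from a raw/filtered droplet matrix pair
#'
#' Convenience wrapper implementing the full empty-droplet bookkeeping:
#' fake droplets (< `min_umi` UMIs) are discarded from the raw matrix,
#' barcodes present in the raw but absent from the filtered (cell-called)
#' matrix are treated as empty droplets, and [soup_probability()] is
#' computed over the result.
#'
#' @param raw genes x barcodes raw count matrix (all droplets).
#' @param filtered genes x barcodes matrix restricted to called
#'   cells/nuclei, or a character vector of cell barcodes.
#' @param min_umi fake-droplet threshold passed to [filter_fake_droplets()].
#' @return tibble as in [soup_probability()].
#' @export
soup_stats <- function(raw, filtered, min_umi = 5) {
  cells <- if (is.character(filtered)) filtered else colnames(filtered)
  raw <- filter_fake_droplets(raw, min_umi = min_umi)
  soup_probability(raw, colnames(raw) %in% cells)
}

#' Label ambient-noisy genes by soup-probability quantile
#'
#' Flags a gene as noisy when its soup probability strictly exceeds the
#' empirical `quantile` (linear interpolation between order statistics) of
#' the soup-probability distribution over defined genes. With the default
#' 0.5 this is a strict-median rule: at most half of the defined genes are
#' flagged, and when all probabilities are equal none are. A precomputed
#' `threshold` may be supplied instead, e.g. to label one droplet class
#' (cells) with a threshold derived from another (nuclei).
#'
#' @param stats tibble from [soup_probability()] / [soup_stats()].
#' @param quantile quantile of the defined soup probabilities (default 0.5).
#' @param threshold optional explicit cutoff overriding the quantile.
#' @return `stats` with columns `noisy` (logical; `FALSE` for undefined
#'   genes) and the `threshold` used as an attribute.
#' @export
label_noisy_genes <- function(stats, quantile = 0.5, threshold = NULL) {
  defined <- !is.na(stats$soup_p)
  if (!any(defined)) stop("no gene has a defined soup probability")
  if (is.null(threshold)) {
    threshold <- stats::quantile(stats$soup_p[defined], probs = quantile,
                                 type = 7, names = FALSE)
  }
  out <- dplyr::mutate(stats, noisy = !is.na(.data$soup_p) & .data$soup_p > threshold)
  attr(out, "threshold") <- threshold
  out
}
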