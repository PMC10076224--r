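#' Read a per-spot cell-state density table
#'
#' Reads the TSV/CSV table a spot-deconvolution tool emits: one row per
#' capture spot with columns `spot_id`, `x`, `y`, one column per cell state
#' (estimated cells of that state in the spot) and optionally `region`
#' and/or `sample`.
#'
#' @param path file path; `.csv` is comma-separated, anything else
#'   tab-separated.
#' @return validated tibble.
#' @export
read_density_table <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  required <- c("spot_id", "x", "y")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$spot_id)) stop("duplicate spot_ids")
  if (!all(is.finite(df$x)) || !all(is.finite(df$y))) stop("non-finite coordinates")
  state_cols <- setdiff(names(df), c(required, "region", "sample"))
  if (length(state_cols) == 0) stop("no state density columns found")
  for (s in state_cols) {
    if (!is.numeric(df[[s]])) stop("state column '", s, "' is not numeric")
    if (any(df[[s]] < 0, na.rm = TRUE)) stop("negative densities in column '", s, "'")
  }
  df
}

#' @rdname read_density_table
#' @param data density tibble.
#' @param path output path.
#' @export
write_density_table <- function(data, path) {
  readr::write_tsv(data, path)
  invisible(path)
}

#' Write a trajectory tree as edge-list TSV (and DOT)
#'
#' The TSV has columns `state_a`, `state_b`, `weight` (weights at 6
#' significant digits). A Graphviz DOT rendering is written next to it
#' unless `dot = FALSE`.
#'
#' @param tree `storder_tree`.
#' @param path output TSV path.
#' @param dot DOT output path, or `TRUE` (same path with `.dot`), or
#'   `FALSE` to skip.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path, dot = TRUE) {
  stopifnot(inherits(tree, "storder_tree"))
  edges <- dplyr::mutate(tree$edges, weight = signif(.data$weight, 6))
  readr::write_tsv(edges, path)
  if (!isFALSE(dot)) {
    dot_path <- if (isTRUE(dot)) sub("\\.[^.]*$", ".dot", path) else dot
    lines <- c("graph trajectory {",
               sprintf('  "%s" -- "%s" [label="%.4g"];',
                       edges$state_a, edges$state_b, edges$weight),
               "}")
    writeLines(lines, dot_path)
  }
  invisible(path)
}

#' Read a trajectory tree from its edge-list TSV
#'
#' @param path TSV written by [write_tree()].
#' @return `storder_tree`.
#' @export
read_tree <- function(path) {
  edges <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("state_a", "state_b", "weight") %in% names(edges)))
  states <- sort(unique(c(edges$state_a, edges$state_b)))
  structure(list(states = states,
                 edges = edges[, c("state_a", "state_b", "weight")],
                 total_weight = sum(edges$weight),
                 weakly_connected = any(edges$weight == 0)),
            class = "storder_tree")
}
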