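#' Cluster-level expression connectivity from a cell neighbour graph
#'
#' Aggregates an undirected cell-cell neighbour graph (typically a k-NN graph
#' built in expression space) to the cluster level: for each unordered pair of
#' cell states the observed number of inter-state edges is divided by its
#' expectation under random edge placement given the state sizes,
#' \deqn{\hat e_{ij} = 2 m \, n_i n_j / (n (n - 1)),}
#' where \eqn{m} is the total edge count and \eqn{n} the total cell count.
#' Ratios are clipped to \eqn{[0, 1]} and the diagonal is forced to zero,
#' giving a PAGA-style connectivity matrix commensurate with the spatial
#' correlation matrix it is later fused with (see [combine_connectivity()]).
#'
#' Edges are treated as unweighted and undirected; duplicate pairs, reversed
#' duplicates and self-loops are removed before counting. States with zero
#' cells cannot arise (labels define the states), but labels mapping to no
#' edges are retained as zero rows.
#'
#' @param edges data frame with two columns of cell identifiers, one row per
#'   undirected edge.
#' @param labels data frame with columns `cell` and `state` (any names; first
#'   column is taken as the cell id, second as the state), covering every cell
#'   that appears in `edges`.
#' @return A symmetric states-by-states numeric matrix with entries in
#'   \eqn{[0, 1]}, zero diagonal and `dimnames` set to the state names
#'   (sorted), of class `storder_connectivity`.
#' @examples
#' edges <- data.frame(from = c("a", "c", "a", "b"), to = c("b", "d", "c", "d"))
#' labels <- data.frame(cell = letters[1:4], state = c("s1", "s1", "s2", "s2"))
#' connectivity_matrix(edges, labels)
#' @export
connectivity_matrix <- function(edges, labels) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 2,
            is.data.frame(labels), ncol(labels) >= 2)
  cell <- as.character(labels[[1]])
  state <- as.character(labels[[2]])
  if (anyDuplicated(cell)) stop("duplicate cell ids in labels")
  lab <- stats::setNames(state, cell)

  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  missing <- setdiff(unique(c(a, b)), cell)
  if (length(missing) > 0) {
    stop("unlabeled cells in edge list: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  # canonical undirected representation: drop self-loops and duplicates
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  dup <- duplicated(paste(lo, hi, sep = "\r"))
  lo <- lo[!dup]; hi <- hi[!dup]
  if (length(lo) == 0) stop("graph has no edges after removing self-loops/duplicates")

  states <- sort(unique(state))
  k <- length(states)
  if (k < 2) {
    warning("only one state present; returning 1x1 zero matrix")
    m0 <- matrix(0, 1, 1, dimnames = list(states, states))
    return(structure(m0, class = c("storder_connectivity", "matrix", "array")))
  }

  n <- length(cell)
  m <- length(lo)
  n_per <- table(factor(state, levels = states))

  sa <- lab[lo]; sb <- lab[hi]
  inter <- sa != sb
  P <- matrix(0, k, k, dimnames = list(states, states))
  if (any(inter)) {
    cnt <- table(factor(pmin(sa, sb)[inter], levels = states),
                 factor(pmax(sa, sb)[inter], levels = states))
    e_obs <- matrix(cnt, k, k) + t(matrix(cnt, k, k))
    e_exp <- 2 * m * outer(as.numeric(n_per), as.numeric(n_per)) / (n * (n - 1))
    P <- pmin(e_obs / e_exp, 1)
    dimnames(P) <- list(states, states)
  }
  diag(P) <- 0
  structure(P, class = c("storder_connectivity", "matrix", "array"))
}

#' Validate a state-by-state connectivity/correlation matrix
#'
#' Checks squareness, matching dimnames, symmetry (within `tol`, then
#' symmetrised by averaging), the \eqn{[0, 1]} range and zero diagonal.
#' Used by the readers and by [combine_connectivity()].
#'
#' @param m numeric matrix with identical row and column names.
#' @param states optional character vector: subset/reorder to these states.
#' @param tol maximum tolerated asymmetry before erroring.
#' @return the validated (possibly permuted) matrix.
#' @keywords internal
validate_state_matrix <- function(m, states = NULL, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("matrix must be square")
  if (is.null(rownames(m)) || is.null(colnames(m)) ||
      !identical(rownames(m), colnames(m))) {
    stop("row and column names must be present and identical")
  }
  if (max(abs(m - t(m))) >= tol) stop("matrix asymmetric beyond tolerance ", tol)
  m <- (m + t(m)) / 2
  if (any(m < 0)) stop("negative entries in connectivity matrix")
  if (any(m > 1 + 1e-12)) stop("entries above 1 in connectivity matrix")
  if (any(abs(diag(m)) > 1e-12)) stop("diagonal must be zero")
  diag(m) <- 0
  if (!is.null(states)) {
    unknown <- setdiff(states, rownames(m))
    if (length(unknown) > 0) stop("unknown state name(s): ", paste(unknown, collapse = ", "))
    m <- m[states, states, drop = FALSE]
  }
  m
}

#' Read a precomputed connectivity or spatial-correlation matrix
#'
#' Reads a TSV/CSV square matrix whose header row and first (index) column
#' carry matching state names, validates it with [validate_state_matrix()]
#' and optionally subsets/reorders it.
#'
#' @param path file path; delimiter inferred from the extension
#'   (`.csv` uses comma, otherwise tab).
#' @param states optional character vector of states to keep, in order.
#' @return validated symmetric matrix.
#' @export
read_connectivity <- function(path, states = NULL) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  validate_state_matrix(m, states = states)
}

#' Write a state matrix as TSV (header row + index column)
#'
#' @param m symmetric state matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_connectivity <- function(m, path) {
  df <- tibble::as_tibble(unclass(m), .name_repair = "minimal")
  df <- tibble::add_column(df, state = rownames(m), .before = 1)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @export
tidy.storder_connectivity <- function(x, ...) {
  state_matrix_tidy(x)
}

# long-tibble view of any symmetric state matrix (upper triangle)
state_matrix_tidy <- function(m) {
  states <- rownames(m)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(
    state_a = states[idx[, 1]],
    state_b = states[idx[, 2]],
    value = m[idx]
  )
}
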