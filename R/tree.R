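#' Fuse expression connectivity and spatial correlation
#'
#' Elementwise weighted combination
#' \deqn{W = \beta(\alpha P + (1 - \alpha) S) + (1 - \beta)\, P \odot S}
#' of the expression connectivity matrix \eqn{P} and the spatial correlation
#' matrix \eqn{S}. \eqn{\alpha} weights \eqn{P} versus \eqn{S} in the additive
#' term; \eqn{\beta} weights the additive versus the multiplicative
#' (elementwise product) term. When both inputs live in \eqn{[0, 1]} the
#' result does too.
#'
#' @param P,S symmetric state matrices with identical state names/order.
#' @param alpha,beta weights in \eqn{[0, 1]}.
#' @return symmetric combined-weight matrix with attributes `alpha`, `beta`.
#' @export
combine_connectivity <- function(P, S, alpha, beta) {
  P <- unclass(P); S <- unclass(S)
  if (!identical(dimnames(P), dimnames(S)) || !identical(dim(P), dim(S))) {
    stop("P and S must share states and order")
  }
  if (alpha < 0 || alpha > 1 || beta < 0 || beta > 1) {
    stop("alpha and beta must lie in [0, 1]")
  }
  W <- beta * (alpha * P + (1 - alpha) * S) + (1 - beta) * P * S
  diag(W) <- 0
  attr(W, "alpha") <- alpha
  attr(W, "beta") <- beta
  W
}

# Kruskal on a complete graph given by upper-triangle edge arrays.
# Maximum-weight spanning tree; ties broken by lexicographic (state_a,
# state_b) pair order. Edges of weight 0 are used only if positive-weight
# edges leave the graph disconnected (`weak` flags that).
kruskal_max <- function(ia, ib, w, k) {
  ord <- order(-w, ia, ib)
  parent <- seq_len(k)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  chosen <- integer(0)
  weak <- FALSE
  for (e in ord) {
    if (length(chosen) == k - 1L) break
    ra <- find(ia[e]); rb <- find(ib[e])
    if (ra != rb) {
      parent[ra] <- rb
      chosen <- c(chosen, e)
      if (w[e] == 0) weak <- TRUE
    }
  }
  list(edges = sort(chosen), weak = weak, complete = length(chosen) == k - 1L)
}

#' Maximum-weight spanning tree of combined state weights
#'
#' Reconstructs the candidate trajectory tree as the spanning tree maximising
#' total edge weight (Kruskal on descending weights, deterministic
#' lexicographic tie-break). Zero-weight edges are admitted only when needed
#' for connectivity, in which case the tree is flagged weakly connected.
#'
#' @param weights symmetric state weight matrix (e.g. from
#'   [combine_connectivity()]).
#' @return `storder_tree`: list with `states`, `edges` (tibble `state_a`,
#'   `state_b`, `weight`), `total_weight`, `weakly_connected`.
#' @export
max_spanning_tree <- function(weights) {
  weights <- unclass(weights)
  states <- rownames(weights)
  k <- length(states)
  if (k < 2) stop("need at least 2 states")
  idx <- which(upper.tri(weights), arr.ind = TRUE)
  ia <- idx[, 1]; ib <- idx[, 2]; w <- weights[idx]
  res <- kruskal_max(ia, ib, w, k)
  edges <- tibble::tibble(
    state_a = states[ia[res$edges]],
    state_b = states[ib[res$edges]],
    weight = w[res$edges]
  )
  structure(list(states = states, edges = edges,
                 total_weight = sum(edges$weight),
                 weakly_connected = res$weak),
            class = "storder_tree")
}

#' @export
print.storder_tree <- function(x, ...) {
  cat("Trajectory tree over", length(x$states), "states, total weight",
      sprintf("%.4f", x$total_weight),
      if (x$weakly_connected) "[weakly connected]" else "", "\n")
  print(x$edges, n = nrow(x$edges))
  invisible(x)
}

#' @export
tidy.storder_tree <- function(x, ...) x$edges

tree_degrees <- function(tree) {
  tab <- table(factor(c(tree$edges$state_a, tree$edges$state_b),
                      levels = tree$states))
  stats::setNames(as.integer(tab), tree$states)
}

#' Check a trajectory tree against topology assumptions
#'
#' A candidate tree is topology-valid when it is a connected spanning tree
#' with exactly `n_branch_points` branching nodes (degree >= 3), the root
#' state is a leaf (degree 1, relaxable via `root_must_be_leaf`), every
#' required end state is a leaf, and no other state is a leaf — i.e. the
#' degree-1 node set equals \{root\} union the required leaves. This mirrors
#' the topology screen used for invasion trajectories: one branching point,
#' no cycles, a fixed origin population and fixed terminal populations.
#'
#' @param tree `storder_tree`.
#' @param root name of the origin state.
#' @param leaves character vector of required terminal states.
#' @param n_branch_points required number of degree->=3 nodes (default 1).
#' @param root_must_be_leaf if `FALSE`, the root's degree is not checked.
#' @return list: `valid`, `branch_states` (degree >= 3 nodes),
#'   `n_branch_ge3`, `n_branch_eq3`, `degrees`, `failures` (character vector
#'   naming each violated criterion; empty when valid).
#' @export
check_topology <- function(tree, root, leaves, n_branch_points = 1,
                           root_must_be_leaf = TRUE) {
  stopifnot(inherits(tree, "storder_tree"))
  unknown <- setdiff(c(root, leaves), tree$states)
  if (length(unknown) > 0) stop("unknown state(s): ", paste(unknown, collapse = ", "))
  if (root %in% leaves) stop("root must not be a required leaf")
  deg <- tree_degrees(tree)
  failures <- character(0)
  connected <- nrow(tree$edges) == length(tree$states) - 1 &&
    !tree$weakly_connected
  if (!connected) failures <- c(failures, "not connected")
  branch_states <- names(deg)[deg >= 3]
  if (length(branch_states) != n_branch_points) {
    failures <- c(failures, sprintf("expected %d branching point(s), found %d",
                                    n_branch_points, length(branch_states)))
  }
  if (root_must_be_leaf && deg[[root]] != 1) {
    failures <- c(failures, "root is not a leaf")
  }
  bad_leaves <- leaves[deg[leaves] != 1]
  if (length(bad_leaves) > 0) {
    failures <- c(failures, paste("required end state not a leaf:",
                                  paste(bad_leaves, collapse = ", ")))
  }
  deg1 <- names(deg)[deg == 1]
  expected1 <- if (root_must_be_leaf) c(root, leaves) else leaves
  extra <- setdiff(deg1, c(root, leaves))
  if (length(extra) > 0) {
    failures <- c(failures, paste("unexpected leaf state(s):",
                                  paste(extra, collapse = ", ")))
  }
  if (!setequal(deg1, union(expected1, intersect(deg1, root)))) {
    # covered by the specific checks above; kept for the exact set rule
    if (!setequal(deg1, c(root, leaves)) && root_must_be_leaf) {
      failures <- unique(c(failures, "leaf set differs from {root} + end states"))
    }
  }
  list(valid = length(failures) == 0,
       branch_states = branch_states,
       n_branch_ge3 = length(branch_states),
       n_branch_eq3 = sum(deg == 3),
       degrees = deg,
       failures = failures)
}

#' Grid scan over the fusion weights (alpha, beta)
#'
#' Enumerates \eqn{(\alpha, \beta)} over the inclusive \eqn{[0, 1]^2} grid at
#' the given step (0.01 gives 101 values per axis, 10,201 pairs), and for
#' each cell fuses P and S ([combine_connectivity()]), reconstructs the
#' maximum spanning tree and checks it against the topology assumptions.
#' Summarises how many cells pass the screen and which branching state each
#' valid tree proposes; the consensus branch state is the mode over valid
#' trees (all modal states are reported on ties).
#'
#' @inheritParams combine_connectivity
#' @inheritParams check_topology
#' @param step grid increment; must divide 1 within 1e-12.
#' @return `storder_scan`: `records` tibble (one row per grid cell: `alpha`,
#'   `beta`, `valid`, `branch_state`, `n_branch`, `tree_id`), `trees` lookup
#'   (tibble `tree_id` -> edge list string), `n_pairs`, `n_valid`,
#'   `branch_freq` tibble, `consensus_branch`.
#' @export
grid_scan <- function(P, S, root, leaves, step = 0.01, n_branch_points = 1,
                      root_must_be_leaf = TRUE) {
  P <- validate_state_matrix(unclass(P))
  S <- validate_state_matrix(unclass(S), states = rownames(P))
  nsteps <- 1 / step
  if (abs(nsteps - round(nsteps)) > 1e-12) stop("step must divide 1")
  vals <- seq(0, 1, length.out = round(nsteps) + 1)
  states <- rownames(P)
  k <- length(states)
  idx <- which(upper.tri(P), arr.ind = TRUE)
  ia <- idx[, 1]; ib <- idx[, 2]
  p <- P[idx]; s <- S[idx]; ps <- p * s

  grid <- tidyr::expand_grid(alpha = vals, beta = vals)
  n_cell <- nrow(grid)
  valid <- logical(n_cell)
  branch <- character(n_cell)
  nbranch <- integer(n_cell)
  tree_id <- character(n_cell)
  root_i <- match(root, states)
  leaf_i <- match(leaves, states)

  for (g in seq_len(n_cell)) {
    a <- grid$alpha[g]; b <- grid$beta[g]
    w <- b * (a * p + (1 - a) * s) + (1 - b) * ps
    res <- kruskal_max(ia, ib, w, k)
    tree_id[g] <- paste(res$edges, collapse = ",")
    deg <- tabulate(c(ia[res$edges], ib[res$edges]), nbins = k)
    br <- which(deg >= 3)
    nbranch[g] <- length(br)
    branch[g] <- if (length(br) > 0) paste(states[br], collapse = "+") else NA_character_
    ok <- res$complete && !res$weak &&
      length(br) == n_branch_points &&
      all(deg[leaf_i] == 1) &&
      setequal(which(deg == 1), c(root_i, leaf_i))
    if (root_must_be_leaf) ok <- ok && deg[root_i] == 1
    valid[g] <- ok
  }

  records <- tibble::tibble(alpha = grid$alpha, beta = grid$beta,
                            valid = valid, branch_state = branch,
                            n_branch = nbranch, tree_id = tree_id)
  trees <- dplyr::distinct(records["tree_id"])
  trees$edges <- purrr::map_chr(trees$tree_id, function(id) {
    e <- as.integer(strsplit(id, ",")[[1]])
    paste(states[ia[e]], states[ib[e]], sep = "-", collapse = ";")
  })
  bf <- dplyr::count(dplyr::filter(records, valid), .data$branch_state,
                     sort = TRUE, name = "n_valid_trees")
  consensus <- if (nrow(bf) > 0) {
    bf$branch_state[bf$n_valid_trees == max(bf$n_valid_trees)]
  } else character(0)
  structure(list(records = records, trees = trees,
                 n_pairs = n_cell, n_valid = sum(valid),
                 branch_freq = bf, consensus_branch = consensus,
                 step = step, root = root, leaves = leaves),
            class = "storder_scan")
}

#' @export
print.storder_scan <- function(x, ...) {
  cat("Weight-grid scan:", x$n_pairs, "(alpha,beta) pairs,",
      x$n_valid, "topology-valid trees\n")
  if (nrow(x$branch_freq) > 0) {
    cat("Consensus branching state:", paste(x$consensus_branch, collapse = " / "), "\n")
    print(x$branch_freq)
  }
  invisible(x)
}

#' @export
tidy.storder_scan <- function(x, ...) x$records

#' @export
glance.storder_scan <- function(x, ...) {
  tibble::tibble(n_pairs = x$n_pairs, n_valid = x$n_valid,
                 valid_fraction = x$n_valid / x$n_pairs,
                 consensus_branch = paste(x$consensus_branch, collapse = "/"),
                 n_distinct_trees = nrow(x$trees))
}

#' @rdname grid_scan
#' @param object `storder_scan` object.
#' @export
autoplot.storder_scan <- function(object, ...) {
  df <- object$records
  df$branch_state[!df$valid] <- NA_character_
  ggplot2::ggplot(df, ggplot2::aes(.data$alpha, .data$beta,
                                   fill = .data$branch_state)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_discrete(na.value = "grey85") +
    ggplot2::labs(x = expression(alpha), y = expression(beta),
                  fill = "branch state",
                  title = "Topology-valid region of the (alpha, beta) grid") +
    ggplot2::theme_minimal()
}

#' @rdname max_spanning_tree
#' @param object `storder_tree` object.
#' @export
autoplot.storder_tree <- function(object, ...) {
  # simple layered layout: BFS depths from the first leaf
  deg <- tree_degrees(object)
  start <- names(deg)[deg == 1][1]
  adj <- split(c(object$edges$state_b, object$edges$state_a),
               c(object$edges$state_a, object$edges$state_b))
  depth <- stats::setNames(rep(NA_integer_, length(object$states)), object$states)
  depth[start] <- 0L
  frontier <- start
  while (length(frontier) > 0) {
    nxt <- character(0)
    for (v in frontier) {
      for (u in adj[[v]]) if (is.na(depth[u])) {
        depth[u] <- depth[v] + 1L
        nxt <- c(nxt, u)
      }
    }
    frontier <- nxt
  }
  ord <- stats::ave(seq_along(depth), depth, FUN = seq_along)
  pos <- tibble::tibble(state = names(depth), x = as.numeric(depth), y = ord)
  seg <- dplyr::left_join(object$edges, pos, by = c(state_a = "state"))
  seg <- dplyr::left_join(seg, pos, by = c(state_b = "state"),
                          suffix = c("", "end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       linewidth = .data$weight),
                          colour = "grey50") +
    ggplot2::geom_label(data = pos,
                        ggplot2::aes(.data$x, .data$y, label = .data$state)) +
    ggplot2::scale_linewidth(range = c(0.3, 2)) +
    ggplot2::theme_void()
}
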