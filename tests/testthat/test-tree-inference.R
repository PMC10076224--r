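test_that("fusion formula reduces to its exact limits", {
  set.seed(61)
  P <- random_state_matrix(5)
  S <- random_state_matrix(5)
  expect_equal(unclass(combine_connectivity(P, S, 1, 1)), P, ignore_attr = TRUE)
  expect_equal(unclass(combine_connectivity(P, S, 0, 1)), S, ignore_attr = TRUE)
  expect_equal(unclass(combine_connectivity(P, S, 0.3, 0)), P * S,
               ignore_attr = TRUE)
  W <- combine_connectivity(P, S, 0.4, 0.5)
  expect_equal(unclass(W), t(unclass(W)), ignore_attr = TRUE)
  expect_true(all(W >= 0 & W <= 1))
  expect_error(combine_connectivity(P, S, 1.2, 0.5), "\\[0, 1\\]")
  expect_error(combine_connectivity(P, S[c(2, 1, 3:5), c(2, 1, 3:5)], 0.5, 0.5),
               "share states")
})

test_that("maximum spanning tree picks the heaviest acyclic edge set", {
  W <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  W["a", "b"] <- W["b", "a"] <- 0.9
  W["b", "c"] <- W["c", "b"] <- 0.8
  W["a", "c"] <- W["c", "a"] <- 0.1
  tree <- max_spanning_tree(W)
  expect_equal(nrow(tree$edges), 2)
  expect_setequal(paste(tree$edges$state_a, tree$edges$state_b),
                  c("a b", "b c"))
  expect_equal(tree$total_weight, 1.7)

  two <- matrix(c(0, .4, .4, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  t2 <- max_spanning_tree(two)
  expect_equal(nrow(t2$edges), 1)
  expect_equal(t2$edges$weight, 0.4)
})

test_that("tree weight matches brute-force enumeration of all labeled trees", {
  set.seed(62)
  for (i in 1:30) {
    W <- random_state_matrix(5)
    tree <- max_spanning_tree(W)
    expect_equal(tree$total_weight, brute_force_mst_weight(W))
  }
})

test_that("tree agrees with an independent graph library", {
  skip_if_not_installed("igraph")
  set.seed(63)
  for (i in 1:10) {
    W <- random_state_matrix(6)
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                             weighted = TRUE)
    mst <- igraph::mst(g, weights = -igraph::E(g)$weight)
    expect_equal(max_spanning_tree(W)$total_weight,
                 sum(igraph::E(mst)$weight))
  }
})

test_that("tree is invariant to state reordering", {
  set.seed(64)
  W <- random_state_matrix(6)
  perm <- sample(6)
  t1 <- max_spanning_tree(W)
  t2 <- max_spanning_tree(W[perm, perm])
  canon <- function(tr) {
    e <- tr$edges
    sorted <- paste(pmin(e$state_a, e$state_b), pmax(e$state_a, e$state_b))
    sort(sorted)
  }
  expect_equal(canon(t1), canon(t2))
})

test_that("zero-weight edges are used only as a last resort", {
  W <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  W["a", "b"] <- W["b", "a"] <- 0.5
  W["c", "d"] <- W["d", "c"] <- 0.5
  tree <- max_spanning_tree(W)
  expect_true(tree$weakly_connected)
  expect_equal(nrow(tree$edges), 3)
})

test_that("topology screen enforces root, end points and branch count", {
  path <- read_tree_from_edges(tibble::tibble(
    state_a = c("a", "b"), state_b = c("b", "c"), weight = 1))
  rep1 <- check_topology(path, root = "a", leaves = "c")
  expect_false(rep1$valid)
  expect_match(rep1$failures, "branching", all = FALSE)

  star <- read_tree_from_edges(tibble::tibble(
    state_a = c("r", "x", "v", "v"), state_b = c("x", "v", "y", "z"),
    weight = 1))
  rep2 <- check_topology(star, root = "r", leaves = c("y", "z"))
  expect_true(rep2$valid)
  expect_equal(rep2$branch_states, "v")

  # two degree-3 nodes
  big <- read_tree_from_edges(tibble::tibble(
    state_a = c("r", "u", "u", "u", "w", "w"),
    state_b = c("u", "p", "q", "w", "s", "t"), weight = 1))
  rep3 <- check_topology(big, root = "r", leaves = c("p", "q", "s", "t"),
                         n_branch_points = 1)
  expect_false(rep3$valid)
  expect_equal(rep3$n_branch_ge3, 2)

  expect_error(check_topology(star, root = "missing", leaves = "y"), "unknown")
  expect_error(check_topology(star, root = "y", leaves = "y"), "root")
})

test_that("grid scan enumerates the full inclusive grid", {
  set.seed(65)
  P <- random_state_matrix(6)
  S <- random_state_matrix(6)
  scan <- grid_scan(P, S, root = "s1", leaves = c("s5", "s6"), step = 0.25)
  expect_equal(scan$n_pairs, 25L)
  expect_equal(sort(unique(scan$records$alpha)), seq(0, 1, 0.25))
  expect_lte(scan$n_valid, scan$n_pairs)
  expect_error(grid_scan(P, S, "s1", c("s5", "s6"), step = 0.3), "divide")
})

test_that("identical P and S give the same tree at every grid cell", {
  # x -> beta x + (1 - beta) x^2 is strictly increasing on [0, 1], so edge
  # ranking (hence the MST) cannot depend on (alpha, beta)
  set.seed(66)
  P <- random_state_matrix(6)
  scan <- grid_scan(P, P, root = "s1", leaves = c("s5", "s6"), step = 0.1)
  expect_equal(length(unique(scan$records$tree_id)), 1L)
})

test_that("reported branch states really have degree >= 3", {
  set.seed(67)
  P <- random_state_matrix(5)
  S <- random_state_matrix(5)
  scan <- grid_scan(P, S, root = "s1", leaves = c("s4", "s5"), step = 0.2)
  with_branch <- dplyr::filter(scan$records, !is.na(branch_state),
                               !grepl("\\+", branch_state))
  for (g in seq_len(nrow(with_branch))) {
    W <- combine_connectivity(P, S, with_branch$alpha[g], with_branch$beta[g])
    tr <- max_spanning_tree(W)
    deg <- table(c(tr$edges$state_a, tr$edges$state_b))
    expect_gte(deg[[with_branch$branch_state[g]]], 3)
  }
})
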