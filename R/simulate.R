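# run code under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Hexagonally packed spot lattice
#'
#' Regular triangular lattice emulating the centres of spatial capture spots:
#' `nx` spots per row, `ny` rows, odd rows offset by half a spacing, rows
#' `spacing * sqrt(3)/2` apart, so every nearest-neighbour distance equals
#' `spacing`.
#'
#' @param nx,ny lattice dimensions (>= 1).
#' @param spacing nearest-neighbour distance (> 0).
#' @return tibble with `spot_id`, `x`, `y`.
#' @export
make_hex_lattice <- function(nx, ny, spacing = 1) {
  stopifnot(nx >= 1, ny >= 1, spacing > 0)
  g <- tidyr::expand_grid(row = seq_len(ny) - 1L, col = seq_len(nx) - 1L)
  tibble::tibble(
    spot_id = sprintf("spot_%04d", seq_len(nrow(g))),
    x = g$col * spacing + (g$row %% 2) * spacing / 2,
    y = g$row * spacing * sqrt(3) / 2
  )
}

#' Draw density fields from the pairwise spatial covariance model
#'
#' Exact multivariate-normal draw of the stacked vector \eqn{(Y_i, Y_j)}
#' under the model of [pair_gp_loglik()]: covariance
#' \eqn{\Sigma_1 \otimes K(X, l) + \mathrm{diag}(\sigma^2_i, \sigma^2_j)
#' \otimes I}, via a dense Cholesky factor of the full \eqn{2n \times 2n}
#' covariance (the reference construction, independent of the fast
#' likelihood path).
#'
#' @param coords spot coordinates (matrix or tibble with `x`, `y`).
#' @param between between-state covariance, named vector
#'   `c(s11 = , s12 = , s22 = )`; must be positive semidefinite.
#' @param noise_i,noise_j positive noise variances.
#' @param length_scale kernel length scale.
#' @param seed RNG seed.
#' @param n_rep number of replicate draws.
#' @return list with matrices `y_i`, `y_j` (`n` rows, `n_rep` columns;
#'   dropped to vectors when `n_rep = 1`).
#' @export
simulate_pair_densities <- function(coords, between, noise_i, noise_j,
                                    length_scale, seed, n_rep = 1) {
  if (is.data.frame(coords)) coords <- as.matrix(coords[, c("x", "y")])
  s11 <- between[["s11"]]; s12 <- between[["s12"]]; s22 <- between[["s22"]]
  if (s11 < 0 || s22 < 0 || s11 * s22 - s12^2 < -1e-12) {
    stop("between-state covariance must be positive semidefinite")
  }
  stopifnot(noise_i > 0, noise_j > 0, length_scale > 0)
  n <- nrow(coords)
  K <- sq_exp_kernel(coords, length_scale)
  cov <- rbind(cbind(s11 * K + noise_i * diag(n), s12 * K),
               cbind(s12 * K, s22 * K + noise_j * diag(n)))
  L <- t(chol(cov + 1e-10 * diag(2 * n)))
  z <- with_seed(seed, matrix(stats::rnorm(2 * n * n_rep), 2 * n, n_rep))
  draws <- L %*% z
  y_i <- draws[seq_len(n), , drop = n_rep > 1]
  y_j <- draws[n + seq_len(n), , drop = n_rep > 1]
  list(y_i = y_i, y_j = y_j)
}

# equally spaced points along a polyline given as a 2-column matrix
polyline_points <- function(vertices, n) {
  seg <- diff(vertices)
  len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(len))
  t_out <- seq(0, cum[length(cum)], length.out = n)
  out <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    k <- findInterval(t_out[i], cum, rightmost.closed = TRUE)
    frac <- if (len[k] > 0) (t_out[i] - cum[k]) / len[k] else 0
    out[i, ] <- vertices[k, ] + frac * seg[k, ]
  }
  out
}

#' Planted trajectory landscape on a hex lattice
#'
#' Generates a spots-by-states density table with unambiguous ground truth:
#' each state's density is a Gaussian bump (peak 1) centred on its position
#' along a chain or Y-shaped path laid over the lattice, plus iid Gaussian
#' noise, clipped at 0. Consecutive states' bump centres sit
#' `2 * bump_width * (1 - overlap)` apart, so neighbouring states share
#' territory while distant states do not. Alongside the densities the
#' planted trajectory tree and a planted expression-connectivity matrix
#' (high for consecutive states, low otherwise) are returned, giving an
#' end-to-end fixture for the full fusion + tree pipeline.
#'
#' @param layout `"y"` (default; root, two internal states, a branching
#'   state and two leaf arms) or `"chain"`.
#' @param n_states number of states (6 for `"y"`; any >= 2 for `"chain"`).
#' @param nx,ny,spacing lattice, see [make_hex_lattice()].
#' @param bump_width spatial standard deviation of each state's bump, in
#'   coordinate units.
#' @param overlap fraction of bump width shared between consecutive states
#'   (0 = centres two widths apart, 1 = coincident).
#' @param noise_sd standard deviation of additive noise (bump peak is 1).
#' @param p_consecutive,p_other planted connectivity values for
#'   tree-adjacent and non-adjacent state pairs.
#' @param seed RNG seed.
#' @return list: `densities` (tibble `spot_id`, `x`, `y`, one column per
#'   state), `tree` (planted `storder_tree`), `P` (planted connectivity
#'   matrix), `branch_state` (`NA` for chains), `clip_fraction`.
#' @export
simulate_trajectory_landscape <- function(layout = c("y", "chain"),
                                          n_states = 6,
                                          nx = 24, ny = 16, spacing = 1,
                                          bump_width = 2.2, overlap = 0.5,
                                          noise_sd = 0.06,
                                          p_consecutive = 0.8, p_other = 0.05,
                                          seed = 1) {
  layout <- match.arg(layout)
  stopifnot(bump_width > 0, overlap >= 0, overlap < 1, noise_sd >= 0)
  lattice <- make_hex_lattice(nx, ny, spacing)
  width <- max(lattice$x) - min(lattice$x)
  height <- max(lattice$y) - min(lattice$y)
  mid <- min(lattice$y) + height / 2
  step_len <- 2 * bump_width * (1 - overlap)

  if (layout == "y") {
    if (n_states < 4) stop("a Y layout needs at least 4 states")
    n_arm <- max(1, (n_states - 2) %/% 3)
    n_stem <- n_states - 2 * n_arm      # includes root..branch
    x0 <- min(lattice$x) + 0.12 * width
    stem_end <- x0 + (n_stem - 1) * step_len
    ang <- 55 * pi / 180
    centres <- rbind(
      cbind(seq(x0, stem_end, length.out = n_stem), rep(mid, n_stem)),
      cbind(stem_end + seq_len(n_arm) * step_len * cos(ang),
            mid + seq_len(n_arm) * step_len * sin(ang)),
      cbind(stem_end + seq_len(n_arm) * step_len * cos(ang),
            mid - seq_len(n_arm) * step_len * sin(ang))
    )
    states <- c(sprintf("stem%d", seq_len(n_stem)),
                sprintf("armA%d", seq_len(n_arm)),
                sprintf("armB%d", seq_len(n_arm)))
    states[1] <- "root"
    branch_state <- sprintf("stem%d", n_stem)
    parent <- c(NA, states[seq_len(n_stem - 1)],            # stem chain
                branch_state, if (n_arm > 1) states[n_stem + seq_len(n_arm - 1)],
                branch_state, if (n_arm > 1) states[n_stem + n_arm + seq_len(n_arm - 1)])
    edges <- tibble::tibble(state_a = parent[-1], state_b = states[-1])
  } else {
    if (n_states < 2) stop("a chain needs at least 2 states")
    x0 <- min(lattice$x) + 0.1 * width
    centres <- cbind(seq(x0, x0 + (n_states - 1) * step_len,
                         length.out = n_states), rep(mid, n_states))
    states <- c("root", sprintf("state%d", seq_len(n_states - 1)))
    branch_state <- NA_character_
    edges <- tibble::tibble(state_a = states[-n_states], state_b = states[-1])
  }
  if (max(centres[, 1]) > max(lattice$x) || max(abs(centres[, 2] - mid)) > height / 2) {
    stop("state layout extends beyond the lattice; enlarge it or shrink bump_width")
  }

  dens <- with_seed(seed, {
    vapply(seq_along(states), function(k) {
      d2 <- (lattice$x - centres[k, 1])^2 + (lattice$y - centres[k, 2])^2
      pmax(exp(-d2 / (2 * bump_width^2)) +
             stats::rnorm(nrow(lattice), sd = noise_sd), 0)
    }, numeric(nrow(lattice)))
  })
  clip_fraction <- mean(dens == 0)
  colnames(dens) <- states
  densities <- dplyr::bind_cols(lattice, tibble::as_tibble(dens))

  k <- length(states)
  P <- matrix(p_other, k, k, dimnames = list(states, states))
  jit <- with_seed(seed + 1L, stats::runif(nrow(edges), -0.02, 0.02))
  for (e in seq_len(nrow(edges))) {
    v <- min(1, p_consecutive + jit[e])
    P[edges$state_a[e], edges$state_b[e]] <- v
    P[edges$state_b[e], edges$state_a[e]] <- v
  }
  diag(P) <- 0

  tree <- structure(list(
    states = states,
    edges = dplyr::mutate(edges, weight = P[cbind(state_a, state_b)]),
    total_weight = sum(P[cbind(edges$state_a, edges$state_b)]),
    weakly_connected = FALSE
  ), class = "storder_tree")

  list(densities = densities, tree = tree, P = P,
       branch_state = branch_state, clip_fraction = clip_fraction)
}

#' Ambient-contaminated droplet matrix pair
#'
#' Simulates a raw/filtered count-matrix pair with planted ambient structure:
#' cells draw Poisson counts from log-normal gene rates; empty droplets are
#' shallow and draw from the same rates except for a designated ambient gene
#' subset whose rate is multiplied by `enrichment`; fake droplets (total
#' UMIs below the usual threshold) are appended to the raw matrix. The
#' filtered matrix contains the cell barcodes only.
#'
#' @param n_genes,n_cells,n_empty,n_fake matrix dimensions.
#' @param ambient_gene_fraction fraction of genes given ambient enrichment.
#' @param enrichment rate multiplier (>= 1) for ambient genes in empty
#'   droplets.
#' @param cell_depth,empty_depth expected total UMIs per cell / empty
#'   droplet.
#' @param seed RNG seed.
#' @return list: `raw`, `filtered` (sparse genes x barcodes matrices),
#'   `ambient_genes` (character vector of planted noisy genes).
#' @export
simulate_droplet_matrix <- function(n_genes = 200, n_cells = 300,
                                    n_empty = 1500, n_fake = 150,
                                    ambient_gene_fraction = 0.5,
                                    enrichment = 10,
                                    cell_depth = 1000, empty_depth = 20,
                                    seed = 1) {
  stopifnot(n_genes > 0, n_cells > 0, n_empty > 0, enrichment >= 1,
            ambient_gene_fraction >= 0, ambient_gene_fraction <= 1)
  genes <- sprintf("gene_%04d", seq_len(n_genes))
  with_seed(seed, {
    base <- stats::rlnorm(n_genes, sdlog = 1)
    base <- base / sum(base)
    n_amb <- round(ambient_gene_fraction * n_genes)
    ambient_genes <- sample(genes, n_amb)
    amb_rate <- base * ifelse(genes %in% ambient_genes, enrichment, 1)
    amb_rate <- amb_rate / sum(amb_rate)

    cells <- matrix(stats::rpois(n_genes * n_cells, base * cell_depth),
                    n_genes, n_cells)
    empty <- matrix(stats::rpois(n_genes * n_empty, amb_rate * empty_depth),
                    n_genes, n_empty)
    # fake droplets: sub-threshold totals (truncated Poisson on 0..4) split
    # multinomially over the ambient gene profile
    fake_tot <- sample(0:4, n_fake, replace = TRUE, prob = stats::dpois(0:4, 2))
    fake <- vapply(fake_tot, function(t) {
      drop(stats::rmultinom(1, t, amb_rate))
    }, integer(n_genes))
    raw <- cbind(cells, empty, fake)
    colnames(raw) <- c(sprintf("CELL_%04d", seq_len(n_cells)),
                       sprintf("EMPTY_%04d", seq_len(n_empty)),
                       sprintf("FAKE_%04d", seq_len(n_fake)))
    rownames(raw) <- genes
    raw <- methods::as(Matrix::Matrix(raw, sparse = TRUE), "CsparseMatrix")
    list(raw = raw,
         filtered = raw[, seq_len(n_cells), drop = FALSE],
         ambient_genes = sort(ambient_genes))
  })
}
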