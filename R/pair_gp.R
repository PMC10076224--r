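#' Squared-exponential spatial kernel
#'
#' \deqn{K_{mn} = \exp(-\|x_m - x_n\|^2 / (2 l^2))}
#' over 2-D spot coordinates. The kernel has unit diagonal and entries in
#' \eqn{(0, 1]}; `l` (the length scale) controls how quickly spatial
#' correlation of a density field decays with distance, in coordinate units.
#'
#' @param coords numeric matrix (or data frame) with one row per spot and two
#'   coordinate columns.
#' @param length_scale positive length scale \eqn{l}.
#' @return symmetric n-by-n kernel matrix.
#' @examples
#' x <- cbind(c(0, 1), c(0, 0))
#' sq_exp_kernel(x, length_scale = 1)[1, 2]  # exp(-1/2)
#' @export
sq_exp_kernel <- function(coords, length_scale) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2, nrow(coords) >= 1, all(is.finite(coords)))
  if (!is.numeric(length_scale) || length(length_scale) != 1 || length_scale <= 0) {
    stop("length_scale must be a positive scalar")
  }
  d2 <- unname(as.matrix(stats::dist(coords)))^2
  exp(-d2 / (2 * length_scale^2))
}

# between-state covariance from the lower-triangular Cholesky factors
# A = [[a1, 0], [a2, a3]],  Sigma1 = A %*% t(A)
between_cov <- function(a1, a2, a3) {
  c(s11 = a1^2, s12 = a1 * a2, s22 = a2^2 + a3^2)
}

# Log-likelihood in the eigenbasis of K. For cov = Sigma1 (x) K + D (x) I
# with K = U L U', rotating each field by U' decouples the 2n problem into n
# independent 2x2 Gaussians with covariance Sigma1 * lambda_m + D.
pair_loglik_eigen <- function(lambda, zi, zj, s11, s12, s22, d1, d2) {
  m11 <- s11 * lambda + d1
  m22 <- s22 * lambda + d2
  m12 <- s12 * lambda
  det2 <- m11 * m22 - m12^2
  if (any(det2 <= 0)) return(-Inf)
  quad <- (m22 * zi^2 - 2 * m12 * zi * zj + m11 * zj^2) / det2
  -0.5 * (sum(log(det2)) + sum(quad) + 2 * length(lambda) * log(2 * pi))
}

#' Exact log-likelihood of the pairwise spatial covariance model
#'
#' Evaluates the log density of the stacked vector \eqn{(Y_i, Y_j)} under the
#' zero-mean multivariate normal with covariance
#' \deqn{A A^\top \otimes K(X, l) + \mathrm{diag}(\sigma^2_i, \sigma^2_j) \otimes I,}
#' where \eqn{A = [[a_1, 0], [a_2, a_3]]} is the Cholesky factor of the
#' between-state covariance and \eqn{K} the squared-exponential kernel over
#' the spot coordinates. The evaluation eigendecomposes \eqn{K} once and
#' solves an independent 2-by-2 system per eigen-coordinate, which is
#' mathematically identical to (and much cheaper than) factorising the dense
#' \eqn{2n \times 2n} covariance.
#'
#' @param y_i,y_j numeric density vectors for the two states (centered by the
#'   caller; the model has zero mean).
#' @param coords spot coordinates, one row per spot.
#' @param params named list or vector with `a1`, `a2`, `a3`,
#'   `noise_i`, `noise_j` (positive noise variances) and `length_scale`.
#' @param jitter nugget added to the diagonal of \eqn{K} for numerical
#'   stability.
#' @return log-likelihood (scalar).
#' @export
pair_gp_loglik <- function(y_i, y_j, coords, params, jitter = 1e-6) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (length(y_i) != n || length(y_j) != n) stop("y_i, y_j and coords must share length")
  p <- as.list(params)
  if (p$noise_i <= 0 || p$noise_j <= 0) stop("noise variances must be positive")
  K <- sq_exp_kernel(coords, p$length_scale)
  diag(K) <- diag(K) + jitter
  eg <- eigen(K, symmetric = TRUE)
  zi <- drop(crossprod(eg$vectors, y_i))
  zj <- drop(crossprod(eg$vectors, y_j))
  s <- between_cov(p$a1, p$a2, p$a3)
  ll <- pair_loglik_eigen(eg$values, zi, zj, s["s11"], s["s12"], s["s22"],
                          p$noise_i, p$noise_j)
  if (!is.finite(ll)) stop("covariance numerically singular; increase jitter")
  ll
}

# Inner ML problem at fixed length scale: maximize over
# (a1, a2, a3, log d1, log d2) given the rotated data. Returns the optim fit.
fit_inner <- function(lambda, zi, zj, start) {
  nll <- function(p) {
    s <- between_cov(p[1], p[2], p[3])
    ll <- pair_loglik_eigen(lambda, zi, zj, s[1], s[2], s[3], exp(p[4]), exp(p[5]))
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  stats::optim(start, nll, method = "BFGS",
               control = list(maxit = 300, reltol = 1e-10))
}

# Median nearest-neighbour distance: the default length-scale initializer
# (the distance between centres of neighbouring capture spots).
median_nn_distance <- function(coords) {
  d <- as.matrix(stats::dist(as.matrix(coords)))
  diag(d) <- Inf
  stats::median(apply(d, 1, min))
}

#' Fit the pairwise Gaussian-process spatial covariance model
#'
#' Maximum-likelihood fit of the model in [pair_gp_loglik()] to the density
#' fields of two cell states. Densities are mean-centered per state before
#' fitting. The length scale is profiled: an outer golden-section search over
#' \eqn{\log l} (bracketed around the median nearest-neighbour spot distance)
#' wraps an inner BFGS over \eqn{(a_1, a_2, a_3, \log\sigma^2_i,
#' \log\sigma^2_j)}, with the kernel eigendecomposition computed once per
#' candidate \eqn{l} and inner solutions warm-started. The between-state
#' covariance is kept positive semidefinite by construction
#' (\eqn{\Sigma = A A^\top}).
#'
#' The spatial-correlation score is the normalised between-state
#' cross-covariance \eqn{\max(0, \sigma_{12} / \sqrt{\sigma_{11}\sigma_{22}})}.
#'
#' @param data density table: a data frame with columns `x`, `y` and one
#'   column per state (see [read_density_table()]).
#' @param state_i,state_j names of the two state columns to fit.
#' @param length_scale_init optional initial length scale; defaults to the
#'   median nearest-neighbour spot distance.
#' @param bracket_factor the outer search covers
#'   `length_scale_init / bracket_factor` to `length_scale_init * bracket_factor`.
#' @param jitter nugget added to the kernel diagonal.
#' @return `storder_pair_fit` object: parameter estimates, between-state
#'   covariance, log-likelihood, score, convergence flag, spot count. Has
#'   [generics::tidy()] and [generics::glance()] methods.
#' @export
fit_pair_gp <- function(data, state_i, state_j,
                        length_scale_init = NULL, bracket_factor = 8,
                        jitter = 1e-6) {
  stopifnot(all(c("x", "y", state_i, state_j) %in% names(data)))
  coords <- as.matrix(data[, c("x", "y")])
  ok <- is.finite(coords[, 1]) & is.finite(coords[, 2])
  coords <- coords[ok, , drop = FALSE]
  n <- nrow(coords)
  if (n < 10) stop("need at least 10 spots with finite coordinates")
  yi <- as.numeric(data[[state_i]])[ok]
  yj <- as.numeric(data[[state_j]])[ok]

  blank <- function(flag) {
    structure(list(
      state_i = state_i, state_j = state_j,
      params = c(a1 = 0, a2 = 0, a3 = 0, noise_i = NA_real_,
                 noise_j = NA_real_, length_scale = NA_real_),
      between = c(s11 = 0, s12 = 0, s22 = 0),
      loglik = NA_real_, converged = FALSE, degenerate = TRUE,
      flag = flag, n_spots = n, score = 0
    ), class = "storder_pair_fit")
  }
  if (stats::var(yi) == 0 || stats::var(yj) == 0) {
    return(blank("constant or all-zero density field"))
  }
  yi <- yi - mean(yi)
  yj <- yj - mean(yj)

  l0 <- if (is.null(length_scale_init)) median_nn_distance(coords) else length_scale_init
  vi <- stats::var(yi); vj <- stats::var(yj)
  r0 <- stats::cor(yi, yj)
  start0 <- c(sqrt(vi / 2),
              r0 * sqrt(vj / 2),
              sqrt(max(vj / 2 * (1 - r0^2), vj / 20)),
              log(vi / 2), log(vj / 2))

  env <- new.env()
  env$best <- NULL

  # profile value at one length scale; inner BFGS tried from the default
  # data-driven start and from the best solution found so far, so a
  # degenerate inner optimum at one l cannot poison the whole profile
  neg_profile <- function(logl) {
    K <- sq_exp_kernel(coords, exp(logl))
    diag(K) <- diag(K) + jitter
    eg <- eigen(K, symmetric = TRUE)
    zi <- drop(crossprod(eg$vectors, yi))
    zj <- drop(crossprod(eg$vectors, yj))
    starts <- list(start0)
    if (!is.null(env$best)) starts <- c(starts, list(env$best$par))
    fits <- lapply(starts, function(s) fit_inner(eg$values, zi, zj, s))
    fit <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
    if (is.null(env$best) || fit$value < env$best$value) {
      env$best <- list(value = fit$value, par = fit$par, logl = logl,
                       convergence = fit$convergence)
    }
    fit$value
  }

  # coarse grid over log l, then golden-section refinement in the
  # bracketing interval around the grid optimum
  interval <- log(l0) + c(-1, 1) * log(bracket_factor)
  grid <- seq(interval[1], interval[2], length.out = 9)
  vals <- vapply(grid, neg_profile, numeric(1))
  k_best <- which.min(vals)
  lo <- grid[max(1, k_best - 1)]
  hi <- grid[min(length(grid), k_best + 1)]
  stats::optimize(neg_profile, interval = c(lo, hi), tol = 5e-3)
  best <- env$best

  p <- best$par
  s <- between_cov(p[1], p[2], p[3])
  score <- if (s["s11"] * s["s22"] > 0) {
    max(0, s[["s12"]] / sqrt(s[["s11"]] * s[["s22"]]))
  } else 0
  structure(list(
    state_i = state_i, state_j = state_j,
    params = c(a1 = p[[1]], a2 = p[[2]], a3 = p[[3]],
               noise_i = exp(p[[4]]), noise_j = exp(p[[5]]),
               length_scale = exp(best$logl)),
    between = c(s11 = s[["s11"]], s12 = s[["s12"]], s22 = s[["s22"]]),
    loglik = -best$value,
    converged = best$convergence == 0,
    degenerate = FALSE, flag = NA_character_,
    n_spots = n, score = score
  ), class = "storder_pair_fit")
}

#' @export
print.storder_pair_fit <- function(x, ...) {
  cat("Pairwise spatial GP fit:", x$state_i, "~", x$state_j, "\n")
  cat(sprintf("  score %.3f | loglik %.2f | l = %.3g | n = %d spots%s\n",
              x$score, x$loglik, x$params[["length_scale"]], x$n_spots,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' @export
tidy.storder_pair_fit <- function(x, ...) {
  tibble::tibble(
    term = c(names(x$params), names(x$between)),
    estimate = c(unname(x$params), unname(x$between))
  )
}

#' @export
glance.storder_pair_fit <- function(x, ...) {
  tibble::tibble(
    state_i = x$state_i, state_j = x$state_j, score = x$score,
    logLik = x$loglik, length_scale = x$params[["length_scale"]],
    converged = x$converged, degenerate = x$degenerate, n_spots = x$n_spots
  )
}

#' Spatial correlation matrix over all state pairs
#'
#' Runs [fit_pair_gp()] independently for every unordered pair of states and
#' assembles the symmetric spatial correlation matrix S (scores clipped below
#' at 0 by construction, zero diagonal). Degenerate pairs (a state with
#' constant/all-zero density) get score 0 and a flag instead of an error.
#'
#' @param data density table (`x`, `y`, one column per state, optional
#'   `region` column).
#' @param states character vector of state columns; defaults to every column
#'   other than `spot_id`, `x`, `y`, `region`.
#' @param region optional character vector: keep only spots whose `region`
#'   value is in this set before fitting.
#' @param ... passed to [fit_pair_gp()].
#' @return `storder_spatial` object with elements `S` (matrix) and `fits`
#'   (one-row-per-pair tibble of diagnostics). `tidy()` returns the long
#'   pairwise view; `autoplot()` draws the matrix.
#' @export
spatial_correlation <- function(data, states = NULL, region = NULL, ...) {
  if (!is.null(region)) {
    if (!"region" %in% names(data)) stop("no 'region' column in data")
    data <- data[data$region %in% region, , drop = FALSE]
  }
  if (is.null(states)) {
    states <- setdiff(names(data), c("spot_id", "x", "y", "region"))
  }
  if (length(states) < 2) stop("need at least 2 states")
  pairs <- utils::combn(states, 2)
  fits <- purrr::map(seq_len(ncol(pairs)), function(k) {
    fit_pair_gp(data, pairs[1, k], pairs[2, k], ...)
  })
  S <- matrix(0, length(states), length(states), dimnames = list(states, states))
  for (f in fits) {
    S[f$state_i, f$state_j] <- f$score
    S[f$state_j, f$state_i] <- f$score
  }
  structure(list(S = S, fits = purrr::map_dfr(fits, glance),
                 pair_fits = fits),
            class = "storder_spatial")
}

#' @export
print.storder_spatial <- function(x, ...) {
  cat("Spatial correlation matrix,", nrow(x$S), "states,",
      nrow(x$fits), "pairwise GP fits\n")
  print(round(x$S, 3))
  invisible(x)
}

#' @export
tidy.storder_spatial <- function(x, ...) {
  dplyr::rename(state_matrix_tidy(x$S), score = "value")
}

#' @export
glance.storder_spatial <- function(x, ...) {
  tibble::tibble(
    n_states = nrow(x$S), n_pairs = nrow(x$fits),
    n_converged = sum(x$fits$converged), n_degenerate = sum(x$fits$degenerate),
    median_length_scale = stats::median(x$fits$length_scale, na.rm = TRUE)
  )
}

#' @rdname spatial_correlation
#' @param object `storder_spatial` object.
#' @export
autoplot.storder_spatial <- function(object, ...) {
  df <- tidyr::expand_grid(
    state_a = factor(rownames(object$S), levels = rownames(object$S)),
    state_b = factor(colnames(object$S), levels = colnames(object$S))
  )
  df$score <- as.vector(t(object$S))
  ggplot2::ggplot(df, ggplot2::aes(.data$state_b, .data$state_a, fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "S") +
    ggplot2::theme_minimal()
}

#' Offset per-sample coordinates so capture areas never overlap
#'
#' For density tables pooled across several capture areas, shifts each
#' sample's coordinates along x by a multiple of the global coordinate span,
#' so a joint fit treats spots from different samples as spatially distant
#' (kernel correlation effectively zero across samples).
#'
#' @param data density table with a `sample` column.
#' @param gap multiple of the global x-span inserted between samples.
#' @return the table with shifted `x`.
#' @export
offset_sample_coords <- function(data, gap = 3) {
  stopifnot("sample" %in% names(data))
  span <- diff(range(data$x)) + diff(range(data$y))
  ids <- unique(data$sample)
  shift <- stats::setNames(gap * span * (seq_along(ids) - 1), ids)
  data$x <- data$x + shift[as.character(data$sample)]
  data
}
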