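test_that("squared-exponential kernel has its closed-form values", {
  set.seed(21)
  x <- matrix(runif(20, 0, 5), 10, 2)
  K <- sq_exp_kernel(x, length_scale = 1.3)
  expect_equal(diag(K), rep(1, 10))
  expect_equal(K, t(K))
  expect_true(all(K > 0 & K <= 1))
  two <- rbind(c(0, 0), c(1.3, 0))
  expect_equal(sq_exp_kernel(two, 1.3)[1, 2], exp(-1 / 2))
  expect_error(sq_exp_kernel(two, -1), "positive")
})

test_that("eigendecomposition likelihood equals the dense-covariance oracle", {
  set.seed(22)
  for (i in 1:50) {
    n <- sample(5:50, 1)
    coords <- matrix(runif(2 * n, 0, 5), n, 2)
    p <- random_gp_params()
    y_i <- rnorm(n); y_j <- rnorm(n)
    fast <- pair_gp_loglik(y_i, y_j, coords, p)
    dense <- dense_pair_loglik(y_i, y_j, coords, p)
    expect_lt(abs(fast - dense) / abs(dense), 1e-6)
  }
})

test_that("zero cross term decouples into two independent GPs", {
  set.seed(23)
  n <- 30
  coords <- matrix(runif(2 * n, 0, 4), n, 2)
  p <- random_gp_params(); p$a2 <- 0
  y_i <- rnorm(n); y_j <- rnorm(n)
  joint <- pair_gp_loglik(y_i, y_j, coords, p)
  sep <- dense_single_loglik(y_i, coords, p$a1^2, p$noise_i, p$length_scale) +
    dense_single_loglik(y_j, coords, p$a3^2, p$noise_j, p$length_scale)
  expect_equal(joint, sep, tolerance = 1e-8)
})

test_that("vanishing length scale reduces to iid bivariate normals", {
  set.seed(24)
  n <- 25
  coords <- matrix(runif(2 * n, 0, 4), n, 2)
  spacing <- min(dist(coords))
  p <- random_gp_params()
  p$length_scale <- 1e-6 * spacing
  y_i <- rnorm(n); y_j <- rnorm(n)
  # closed form: per spot, (y_i, y_j) ~ N(0, A A' + diag(noise) + jitter I)
  A <- matrix(c(p$a1, p$a2, 0, p$a3), 2, 2)
  S <- A %*% t(A) * (1 + 1e-6) + diag(c(p$noise_i, p$noise_j))
  Sinv <- solve(S)
  q <- Sinv[1, 1] * y_i^2 + 2 * Sinv[1, 2] * y_i * y_j + Sinv[2, 2] * y_j^2
  iid <- sum(-log(2 * pi) - 0.5 * log(det(S)) - 0.5 * q)
  expect_equal(pair_gp_loglik(y_i, y_j, coords, p), iid, tolerance = 1e-6)
})

test_that("a field fitted against itself scores near one", {
  lat <- make_hex_lattice(12, 12)
  sim <- simulate_pair_densities(lat, c(s11 = 1, s12 = 0, s22 = 1),
                                 0.05, 0.05, 2, seed = 31)
  d <- dplyr::bind_cols(lat, tibble::tibble(A = sim$y_i,
                                            B = sim$y_i + rnorm(144, sd = 0.02)))
  fit <- fit_pair_gp(d, "A", "B")
  expect_gte(fit$score, 0.95)
})

test_that("independent white-noise fields score near zero", {
  lat <- make_hex_lattice(12, 12)
  scores <- sapply(1:10, function(s) {
    d <- with(lat, dplyr::bind_cols(
      lat, tibble::tibble(A = with_seed(400 + s, rnorm(nrow(lat))),
                          B = with_seed(500 + s, rnorm(nrow(lat))))))
    fit_pair_gp(d, "A", "B")$score
  })
  expect_lte(median(scores), 0.15)
})

test_that("score is invariant to rescaling and to state order", {
  lat <- make_hex_lattice(12, 12)
  sim <- simulate_pair_densities(lat, c(s11 = 1, s12 = 0.7, s22 = 1),
                                 0.3, 0.3, 2, seed = 32)
  d <- dplyr::bind_cols(lat, tibble::tibble(A = sim$y_i, B = sim$y_j))
  f0 <- fit_pair_gp(d, "A", "B")
  d2 <- dplyr::mutate(d, A = 7.3 * A, B = 7.3 * B)
  f_scaled <- fit_pair_gp(d2, "A", "B")
  expect_lt(abs(f0$score - f_scaled$score), 1e-3)
  f_swap <- fit_pair_gp(d, "B", "A")
  expect_lt(abs(f0$score - f_swap$score), 1e-3)
})

test_that("fitted between-state covariance is positive semidefinite", {
  lat <- make_hex_lattice(10, 10)
  for (s in 1:3) {
    sim <- simulate_pair_densities(lat, c(s11 = 1, s12 = 0.5, s22 = 0.6),
                                   0.2, 0.4, 1.5, seed = 40 + s)
    d <- dplyr::bind_cols(lat, tibble::tibble(A = sim$y_i, B = sim$y_j))
    f <- fit_pair_gp(d, "A", "B")
    S1 <- matrix(c(f$between["s11"], f$between["s12"],
                   f$between["s12"], f$between["s22"]), 2, 2)
    expect_gte(min(eigen(S1, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  }
})

test_that("degenerate density fields are flagged, not fatal", {
  lat <- make_hex_lattice(10, 10)
  d <- dplyr::bind_cols(lat, tibble::tibble(A = 0, B = rnorm(nrow(lat))^2))
  f <- fit_pair_gp(d, "A", "B")
  expect_true(f$degenerate)
  expect_equal(f$score, 0)
  expect_false(f$converged)
  d$C <- rnorm(nrow(lat))^2
  sc <- spatial_correlation(d)
  expect_equal(unname(sc$S["A", ]), c(0, 0, 0))
  expect_equal(sum(sc$fits$degenerate), 2)
})

test_that("planted shared field separates correlated from independent states", {
  lat <- make_hex_lattice(14, 14)
  sim <- simulate_pair_densities(lat, c(s11 = 1, s12 = 0.85, s22 = 1),
                                 0.2, 0.2, 2, seed = 51)
  ind <- simulate_pair_densities(lat, c(s11 = 1, s12 = 0, s22 = 1),
                                 0.2, 0.2, 2, seed = 52)
  d <- dplyr::bind_cols(lat, tibble::tibble(s1 = sim$y_i, s2 = sim$y_j,
                                            s3 = ind$y_i))
  sc <- spatial_correlation(d, states = c("s1", "s2", "s3"))
  expect_equal(sc$S, t(sc$S))
  expect_gt(sc$S["s1", "s2"], sc$S["s1", "s3"])
  expect_gt(sc$S["s1", "s2"], sc$S["s2", "s3"])
  expect_s3_class(tidy(sc), "tbl_df")
  expect_equal(nrow(glance(sc)), 1)
})

test_that("region masks restrict the spots used for fitting", {
  lat <- make_hex_lattice(10, 14)
  lat$region <- ifelse(lat$y > median(lat$y), "decidua", "placenta")
  sim <- simulate_pair_densities(lat, c(s11 = 1, s12 = 0.8, s22 = 1),
                                 0.2, 0.2, 2, seed = 60)
  d <- dplyr::bind_cols(lat, tibble::tibble(A = sim$y_i, B = sim$y_j))
  sc <- spatial_correlation(d, states = c("A", "B"), region = "decidua")
  expect_equal(unique(sc$fits$n_spots), sum(lat$region == "decidua"))
  expect_error(spatial_correlation(d[, -4], states = c("A", "B"),
                                   region = "decidua"), "region")
})
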