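# B-spline numerics: basis evaluation, adaptive grids, coefficient refits.

test_that("grid_spec validates its invariants", {
  g <- uniform_grid(5, 3, -1, 1)
  expect_s3_class(g, "grid_spec")
  expect_length(g$knots, 5 + 2 * 3 + 1)
  expect_equal(n_bases(g), 8)
  expect_equal(g$domain_lo, -1)
  expect_equal(g$domain_hi, 1)
  expect_error(grid_spec(1:5, G = 5, kappa = 3), "length")
  expect_error(grid_spec(rev(seq_len(12)), G = 5, kappa = 3), "non-decreasing")
  expect_error(uniform_grid(5, 3, epsilon = 1.5), "epsilon")
  expect_error(grid_spec(seq_len(12), G = 0, kappa = 3), "positive")
})

test_that("order-0 basis is the half-open cell indicator", {
  # knots ..., 0, 1, ... at unit spacing: uniform_grid(5, 2, -2, 3)
  g <- uniform_grid(5, 2, -2, 3)
  j0 <- which(g$knots == 0)
  expect_equal(bspline_basis0(0.5, g, j0), 1)   # t_j <= x < t_{j+1}
  expect_equal(bspline_basis0(1.0, g, j0), 0)   # half-open right boundary
  expect_equal(bspline_basis0(-2, g, j0), 0)    # outside support
  expect_equal(bspline_basis0(c(0, 0.99, 1), g, j0), c(1, 1, 0))
  expect_error(bspline_basis0(0.5, g, 0), "out of range")
  expect_error(bspline_basis0(0.5, g, length(g$knots)), "out of range")
})

test_that("order-1 hat function peaks at its middle knot", {
  g <- uniform_grid(5, 2, -2, 3)          # integer knots
  j0 <- which(g$knots == 0)               # B over knots {0, 1, 2}
  expect_equal(bspline_basis(1, g, j0, 1), 1)
  expect_equal(bspline_basis(0.5, g, j0, 1), 0.5)
  expect_equal(bspline_basis(c(0, 2, 3), g, j0, 1), c(0, 0, 0))
})

test_that("recursion rejects orders above kappa and bad indices", {
  g <- uniform_grid(4, 2)
  expect_error(bspline_basis(0, g, 1, 3), "kappa")
  expect_error(bspline_basis(0, g, 100, 2), "out of range")
})

test_that("repeated knots are handled by the 0/0 -> 0 convention", {
  kn <- c(0, 0, 0, 1, 2, 3, 3, 3)         # G = 3, kappa = 2
  g <- grid_spec(kn, G = 3, kappa = 2)
  xs <- seq(-0.5, 3.5, by = 0.1)
  for (j in seq_len(n_bases(g))) {
    v <- bspline_basis(xs, g, j, 2)
    expect_true(all(is.finite(v)))
    expect_true(all(v >= 0))
  }
})

test_that("recursive evaluation matches the DP oracle on random draws", {
  set.seed(101)
  for (rep in 1:100) {
    g <- random_grid()
    k <- sample(0:g$kappa, 1L)
    j <- sample(length(g$knots) - k - 1L, 1L)
    x <- runif(1L, g$knots[1L] - 0.5, g$knots[length(g$knots)] + 0.5)
    expect_equal(bspline_basis(x, g, j, k),
                 oracle_bspline(x, g$knots, j, k), tolerance = 1e-12)
  }
})

test_that("basis functions are non-negative with local support", {
  set.seed(7)
  for (rep in 1:20) {
    g <- random_grid()
    k <- g$kappa
    j <- sample(n_bases(g), 1L)
    xs <- seq(g$knots[1L] - 1, g$knots[length(g$knots)] + 1, length.out = 200L)
    v <- bspline_basis(xs, g, j, k)
    expect_true(all(v >= 0))
    outside <- xs < g$knots[j] | xs >= g$knots[j + k + 1L]
    expect_true(all(v[outside] == 0))
  }
})

test_that("partition of unity holds strictly inside the domain", {
  set.seed(11)
  for (rep in 1:10) {
    G <- sample(3:8, 1L); kap <- sample(1:4, 1L)
    lo <- runif(1L, -2, 0); hi <- lo + runif(1L, 1, 3)
    g <- uniform_grid(G, kap, lo, hi)
    xs <- seq(lo + 1e-9, hi - 1e-9, length.out = 100L)
    total <- rowSums(bspline_design(xs, g))
    expect_true(all(abs(total - 1) <= 1e-9))
  }
})

test_that("the batched design matrix agrees with scalar recursion", {
  set.seed(21)
  g <- random_grid(G = 6, kappa = 3)
  xs <- runif(25L, g$domain_lo - 1, g$domain_hi + 1)
  D <- bspline_design(xs, g)
  expect_equal(dim(D), c(25L, n_bases(g)))
  for (j in seq_len(n_bases(g))) {
    expect_equal(D[, j], bspline_basis(xs, g, j, g$kappa), tolerance = 1e-12)
  }
})

test_that("evaluate_spline is linear in the coefficients", {
  set.seed(31)
  g <- uniform_grid(5, 3, -1, 1)
  K <- n_bases(g)
  xs <- runif(40L, -1.5, 1.5)
  # all-zero coefficients give zero everywhere
  p0 <- edge_params(0, 1, rep(0, K), g)
  expect_equal(evaluate_spline(xs, p0), rep(0, length(xs)))
  # one-hot coefficients reproduce a single basis (scaled)
  for (j in c(1L, K %/% 2L, K)) {
    ch <- rep(0, K); ch[j] <- 2
    pj <- edge_params(0, 1, ch, g)
    expect_equal(evaluate_spline(xs, pj), 2 * bspline_basis(xs, g, j, g$kappa),
                 tolerance = 1e-12)
  }
  # far outside the extended knot range every basis vanishes
  pr <- random_edge(g)
  expect_equal(evaluate_spline(c(-50, 50), pr), c(0, 0))
  expect_error(edge_params(1, 1, rep(0, K - 1L), g), "length")
  expect_error(edge_params(1, NaN, rep(0, K), g), "finite")
})

test_that("update_grid reproduces the uniform grid at epsilon = 1", {
  s <- c(-1, runif(50L, -1, 1), 1)
  g <- update_grid(s, G = 5, kappa = 3, epsilon = 1)
  interior <- g$knots[(3 + 1):(3 + 5 + 1)]
  expect_equal(interior, c(-1, -0.6, -0.2, 0.2, 0.6, 1))
  expect_equal(g$epsilon, 1)
})

test_that("update_grid reproduces the order-statistic grid at epsilon = 0", {
  set.seed(41)
  s <- rnorm(37L)
  G <- 4L
  g <- update_grid(s, G = G, kappa = 2, epsilon = 0)
  srt <- sort(s)
  idx <- floor(1 + (0:G) * (length(s) - 1) / G + 0.5)
  expect_equal(g$knots[(2 + 1):(2 + G + 1)], srt[idx])
})

test_that("blended interior knots are convex combinations", {
  set.seed(51)
  s <- rexp(60L)
  G <- 6L
  gq <- update_grid(s, G, 3, epsilon = 0)
  gu <- update_grid(s, G, 3, epsilon = 1)
  for (eps in c(0.25, 0.5, 0.9)) {
    gb <- update_grid(s, G, 3, epsilon = eps)
    ii <- (3 + 1):(3 + G + 1)
    expect_equal(gb$knots[ii], eps * gu$knots[ii] + (1 - eps) * gq$knots[ii],
                 tolerance = 1e-12)
    expect_true(all(gb$knots[ii] >= pmin(gu$knots[ii], gq$knots[ii]) - 1e-12))
    expect_true(all(gb$knots[ii] <= pmax(gu$knots[ii], gq$knots[ii]) + 1e-12))
  }
})

test_that("update_grid is permutation-invariant and rejects bad input", {
  set.seed(61)
  s <- rnorm(30L)
  g1 <- update_grid(s, 5, 3, 0.1)
  g2 <- update_grid(sample(s), 5, 3, 0.1)
  expect_identical(g1$knots, g2$knots)
  expect_error(update_grid(rep(2, 10L), 5, 3), "degenerate")
  expect_error(update_grid(numeric(0), 5, 3), "non-empty")
  expect_error(update_grid(c(1, NA), 5, 3), "finite")
  expect_error(update_grid(s, 5, 3, epsilon = -0.1), "epsilon")
})

test_that("refitting onto the same grid is the identity", {
  set.seed(71)
  g <- uniform_grid(5, 3, 0, 2)
  p <- random_edge(g)
  s <- runif(100L, 0, 2)
  p2 <- refit_coefficients(p, g, s)
  expect_equal(p2$coeffs, p$coeffs, tolerance = 1e-10)
  expect_identical(p2$w_b, p$w_b)
  expect_identical(p2$w_s, p$w_s)
  # zero spline refits to zero
  pz <- edge_params(1, 1, rep(0, n_bases(g)), g)
  gnew <- update_grid(s, 5, 3, 0.5)
  expect_equal(refit_coefficients(pz, gnew, s)$coeffs, rep(0, n_bases(g)))
})

test_that("refit residual matches the normal-equations solution", {
  set.seed(81)
  for (rep in 1:10) {
    g <- uniform_grid(5, 3, -1, 1)
    p <- random_edge(g)
    s <- runif(80L, -1.2, 1.2)
    gnew <- update_grid(s, 5, 3, 0.3)
    pref <- refit_coefficients(p, gnew, s)
    y <- evaluate_spline(s, p)
    B <- bspline_design(s, gnew)
    cne <- solve(crossprod(B) + 1e-12 * diag(ncol(B)), crossprod(B, y))
    r_pkg <- sqrt(mean((bspline_design(s, gnew) %*% pref$coeffs - y)^2))
    r_ne <- sqrt(mean((B %*% cne - y)^2))
    expect_equal(r_pkg, r_ne, tolerance = 1e-8)
  }
})

test_that("rank-deficient refits warn and stay finite", {
  g <- uniform_grid(5, 3, -1, 1)
  p <- random_edge(g)
  s <- rep(c(-0.5, 0.5), each = 4L)   # 2 distinct values << K
  gnew <- uniform_grid(5, 3, -0.5, 0.5)
  expect_warning(p2 <- refit_coefficients(p, gnew, s), "rank-deficient")
  expect_true(all(is.finite(p2$coeffs)))
})
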