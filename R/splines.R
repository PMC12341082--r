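# B-spline numerics: basis evaluation (recursive and batched dynamic
# programming), adaptive grid construction, and least-squares coefficient
# refitting.  These are the atoms of every KAN edge activation.

#' Grid specification for a B-spline edge activation
#'
#' A grid is an ordered knot vector together with the parameters that
#' generated it.  The interior knots (`G + 1` of them) span
#' `[domain_lo, domain_hi]`; `kappa` extra knots are appended on each side
#' at constant spacing `(domain_hi - domain_lo) / G` so that every basis
#' function of order `kappa` has a full knot support.  A grid of size `G`
#' and order `kappa` carries `K = G + kappa` basis functions.
#'
#' @param knots numeric, non-decreasing, of length `G + 2 * kappa + 1`.
#' @param G positive integer grid size (number of interior cells).
#' @param kappa positive integer spline order.
#' @param epsilon blend weight in `[0, 1]` between the uniform grid
#'   (`epsilon = 1`) and the pure quantile grid (`epsilon = 0`); stored so
#'   the grid can be regenerated from new samples with the same policy.
#' @return an object of class `grid_spec`.
#' @seealso [update_grid()], [bspline_basis()]
#' @export
grid_spec <- function(knots, G, kappa, epsilon = 0.02) {
  G <- as.integer(G)
  kappa <- as.integer(kappa)
  if (length(G) != 1L || is.na(G) || G < 1L) stop("G must be a positive integer")
  if (length(kappa) != 1L || is.na(kappa) || kappa < 1L) {
    stop("kappa must be a positive integer")
  }
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0 || epsilon > 1) {
    stop("epsilon must lie in [0, 1]")
  }
  knots <- as.numeric(knots)
  want <- G + 2L * kappa + 1L
  if (length(knots) != want) {
    stop(sprintf("knot vector must have length G + 2*kappa + 1 = %d, got %d",
                 want, length(knots)))
  }
  if (anyNA(knots) || any(!is.finite(knots))) stop("knots must be finite")
  if (is.unsorted(knots)) stop("knots must be non-decreasing")
  structure(
    list(knots = knots, G = G, kappa = kappa, epsilon = as.numeric(epsilon),
         domain_lo = knots[kappa + 1L], domain_hi = knots[kappa + G + 1L]),
    class = "grid_spec"
  )
}

#' Number of basis functions carried by a grid
#'
#' `K = G + kappa`: the count of order-`kappa` B-splines with full knot
#' support on a grid of size `G` extended by `kappa` knots per side.
#'
#' @param grid a [grid_spec()].
#' @return integer.
#' @export
n_bases <- function(grid) grid$G + grid$kappa

#' Uniform grid over an interval
#'
#' Convenience constructor for the initial, data-independent grid: `G + 1`
#' equally spaced interior knots over `[lo, hi]` plus the `kappa`-knot
#' extensions.  This is the state of every edge before the first
#' data-driven [update_grid()].
#'
#' @inheritParams grid_spec
#' @param lo,hi interval endpoints, `lo < hi`.
#' @return a `grid_spec`.
#' @export
uniform_grid <- function(G = 5L, kappa = 3L, lo = -1, hi = 1, epsilon = 0.02) {
  if (!(lo < hi)) stop("need lo < hi")
  G <- as.integer(G); kappa <- as.integer(kappa)
  h <- (hi - lo) / G
  knots <- seq(lo - kappa * h, hi + kappa * h, length.out = G + 2L * kappa + 1L)
  grid_spec(knots, G, kappa, epsilon)
}

#' Trainable parameters of one edge activation
#'
#' One KAN edge carries phi(x) = w_b * silu(x) + w_s * spline(x), where
#' spline(x) = sum_k coeffs[k] * B_k(x) over the grid's basis functions.
#'
#' @param w_b,w_s real scalars: basis (SiLU) and spline weights.
#' @param coeffs numeric of length [n_bases()] of `grid`.
#' @param grid a [grid_spec()].
#' @return an object of class `edge_params`.
#' @export
edge_params <- function(w_b, w_s, coeffs, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  coeffs <- as.numeric(coeffs)
  if (length(coeffs) != n_bases(grid)) {
    stop(sprintf("coeffs must have length K = G + kappa = %d, got %d",
                 n_bases(grid), length(coeffs)))
  }
  if (!all(is.finite(c(w_b, w_s, coeffs)))) {
    stop("edge parameters must be finite")
  }
  structure(list(w_b = as.numeric(w_b), w_s = as.numeric(w_s),
                 coeffs = coeffs, grid = grid),
            class = "edge_params")
}

#' Zeroth-order B-spline basis function
#'
#' Indicator of the half-open knot cell: 1 if `t_j <= x < t_{j+1}`, else 0.
#' `j` is a 1-based index into the knot vector (the signed textbook index
#' running from `-kappa` maps to `j_R = j_signed + kappa + 1`).
#'
#' @param x numeric vector of evaluation points.
#' @param grid a [grid_spec()].
#' @param j 1-based knot index; `j + 1` must also be a valid index.
#' @return numeric vector of 0/1 values.
#' @export
bspline_basis0 <- function(x, grid, j) {
  t <- grid$knots
  j <- as.integer(j)
  if (length(j) != 1L || is.na(j) || j < 1L || j + 1L > length(t)) {
    stop(sprintf("knot index j = %s out of range [1, %d]",
                 as.character(j), length(t) - 1L))
  }
  as.numeric(t[j] <= x & x < t[j + 1L])
}

#' B-spline basis function of order k (Cox-de Boor recursion)
#'
#' Evaluates `B_{j,k}(x)` by the literal two-term recursion.  Any term
#' whose knot-span denominator is zero (repeated knots) contributes zero,
#' the standard Cox-de Boor convention, so the result is always finite.
#'
#' @inheritParams bspline_basis0
#' @param k spline order, `0 <= k <= grid$kappa`.
#' @return numeric vector, `B_{j,k}` at each `x`.
#' @export
bspline_basis <- function(x, grid, j, k) {
  k <- as.integer(k)
  if (k < 0L || k > grid$kappa) {
    stop(sprintf("order k = %d outside [0, kappa = %d]", k, grid$kappa))
  }
  t <- grid$knots
  j <- as.integer(j)
  if (j < 1L || j + k + 1L > length(t)) {
    stop(sprintf("knot indices %d..%d out of range for %d knots",
                 j, j + k + 1L, length(t)))
  }
  rec <- function(j, k) {
    if (k == 0L) return(as.numeric(t[j] <= x & x < t[j + 1L]))
    d1 <- t[j + k] - t[j]
    d2 <- t[j + k + 1L] - t[j + 1L]
    a <- if (d1 > 0) (x - t[j]) / d1 * rec(j, k - 1L) else 0
    b <- if (d2 > 0) (t[j + k + 1L] - x) / d2 * rec(j + 1L, k - 1L) else 0
    a + b
  }
  rec(j, k)
}

# Batched design evaluation by dynamic programming, in transposed layout.
#
# Xt: p x n matrix of inputs (one ROW per input node, so that length-p
# vectors broadcast down columns by R's native recycling -- no rep()
# allocations); Tm: nk x p matrix of knots (one knot vector per column).
# Returns list(Bt [, dBt]): Bt is a list of K = nk - kappa - 1 matrices
# (p x n), one per order-kappa basis function; dBt their derivatives.
bsd_core_t <- function(Xt, Tm, kappa, deriv = FALSE) {
  p <- nrow(Xt); nk <- nrow(Tm)
  kappa <- as.integer(kappa)
  nb0 <- nk - 1L
  B <- vector("list", nb0)
  for (j in seq_len(nb0)) {
    B[[j]] <- (Xt >= Tm[j, ] & Xt < Tm[j + 1L, ]) * 1
  }
  Bprev <- NULL
  for (k in seq_len(kappa)) {
    if (deriv && k == kappa) Bprev <- B
    nb <- nk - 1L - k
    Bk <- vector("list", nb)
    for (j in seq_len(nb)) {
      d1 <- Tm[j + k, ] - Tm[j, ]
      d2 <- Tm[j + k + 1L, ] - Tm[j + 1L, ]
      r1 <- ifelse(d1 > 0, 1 / d1, 0)
      r2 <- ifelse(d2 > 0, 1 / d2, 0)
      Bk[[j]] <- (Xt - Tm[j, ]) * r1 * B[[j]] +
        (Tm[j + k + 1L, ] - Xt) * r2 * B[[j + 1L]]
    }
    B <- Bk
  }
  out <- list(Bt = B)
  if (deriv) {
    K <- nk - kappa - 1L
    dB <- vector("list", K)
    k <- kappa
    for (j in seq_len(K)) {
      d1 <- Tm[j + k, ] - Tm[j, ]
      d2 <- Tm[j + k + 1L, ] - Tm[j + 1L, ]
      dB[[j]] <- Bprev[[j]] * ifelse(d1 > 0, k / d1, 0) -
        Bprev[[j + 1L]] * ifelse(d2 > 0, k / d2, 0)
    }
    out$dBt <- dB
  }
  out
}

# Convenience wrapper in the (n, K, p) array layout used by callers that
# index per input node.
bsd_core <- function(X, Tm, kappa, deriv = FALSE) {
  n <- nrow(X); p <- ncol(X)
  res <- bsd_core_t(t(X), Tm, kappa, deriv = deriv)
  K <- length(res$Bt)
  arr <- array(0, c(n, K, p))
  for (j in seq_len(K)) arr[, j, ] <- t(res$Bt[[j]])
  out <- list(B = arr)
  if (deriv) {
    dar <- array(0, c(n, K, p))
    for (j in seq_len(K)) dar[, j, ] <- t(res$dBt[[j]])
    out$dB <- dar
  }
  out
}

#' B-spline design matrix
#'
#' All `K = G + kappa` order-`kappa` basis functions of a grid evaluated at
#' a vector of points, computed bottom-up (dynamic programming over the
#' Cox-de Boor table) rather than by recursion.
#'
#' @param x numeric vector.
#' @param grid a [grid_spec()].
#' @return numeric matrix, `length(x)` rows by `K` columns.
#' @export
bspline_design <- function(x, grid) {
  res <- bsd_core(matrix(as.numeric(x), ncol = 1L),
                  matrix(grid$knots, ncol = 1L), grid$kappa)
  matrix(res$B, length(x), n_bases(grid))
}

#' Evaluate the spline part of an edge activation
#'
#' `spline(x) = sum_k coeffs[k] B_k(x)`; linear in the coefficients.
#' Points outside the extended knot range receive zero from every basis.
#'
#' @param x numeric vector.
#' @param params an [edge_params()].
#' @return numeric vector.
#' @export
evaluate_spline <- function(x, params) {
  stopifnot(inherits(params, "edge_params"))
  as.vector(bspline_design(x, params$grid) %*% params$coeffs)
}

# Interior knots from a sample: epsilon-blend of the uniform grid over
# [min, max] and G + 1 evenly spaced order statistics of the sorted sample
# (indices rounded half-up, no interpolation).
blend_interior_knots <- function(samples, G, epsilon) {
  s <- sort(samples)
  n <- length(s)
  if (s[1L] == s[n]) {
    stop("degenerate sample range: all values identical; a constant input carries no information for an adaptive grid")
  }
  idx <- pmin(n, pmax(1L, as.integer(floor(1 + (0:G) * (n - 1) / G + 0.5))))
  qg <- s[idx]
  ug <- seq(s[1L], s[n], length.out = G + 1L)
  epsilon * ug + (1 - epsilon) * qg
}

#' Adaptive grid from data
#'
#' Builds a new grid whose interior knots are the weighted average
#' `epsilon * uniform + (1 - epsilon) * quantile` of a uniform grid over
#' `[min(samples), max(samples)]` and the quantile grid formed by `G + 1`
#' evenly spaced order statistics of the sorted samples.  `kappa` extra
#' knots are appended on each side at the constant uniform spacing
#' `(max - min) / G`.
#'
#' @param samples non-empty finite numeric vector (the edge's inputs).
#' @param G grid size.
#' @param kappa spline order.
#' @param epsilon blend weight in `[0, 1]`.
#' @return a [grid_spec()].
#' @export
update_grid <- function(samples, G, kappa, epsilon = 0.02) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L || anyNA(samples) || any(!is.finite(samples))) {
    stop("samples must be non-empty and finite")
  }
  if (epsilon < 0 || epsilon > 1) stop("epsilon must lie in [0, 1]")
  G <- as.integer(G); kappa <- as.integer(kappa)
  interior <- blend_interior_knots(samples, G, epsilon)
  h <- (max(samples) - min(samples)) / G
  knots <- c(interior[1L] - h * (kappa:1), interior,
             interior[G + 1L] + h * seq_len(kappa))
  grid_spec(knots, G, kappa, epsilon)
}

# Minimum-norm least squares via SVD; warns on rank deficiency.
ls_minnorm <- function(A, Y, tol = 1e-10, warn = TRUE) {
  Y <- as.matrix(Y)
  s <- svd(A)
  dmax <- max(s$d, 0)
  pos <- if (dmax > 0) s$d > tol * dmax else rep(FALSE, length(s$d))
  if (warn && sum(pos) < ncol(A)) {
    warning(sprintf("rank-deficient design (rank %d < %d columns); minimum-norm least-squares solution used",
                    sum(pos), ncol(A)))
  }
  dinv <- ifelse(pos, 1 / s$d, 0)
  s$v %*% (dinv * (t(s$u) %*% Y))
}

#' Refit spline coefficients after a grid change
#'
#' After the grid moves, coefficients are recalculated by least squares so
#' that the new spline reproduces the old spline's output on the update
#' batch: the returned coefficients minimize
#' `sum_i (spline_new(x_i) - spline_old(x_i))^2`.  `w_b` and `w_s` are
#' untouched.  A rank-deficient design (fewer distinct samples than basis
#' functions) is solved by minimum-norm least squares with a warning.
#'
#' @param old_params the edge's current [edge_params()].
#' @param new_grid the freshly computed [grid_spec()] (same `G`, `kappa`).
#' @param samples the batch used to build `new_grid`.
#' @return an [edge_params()] carrying `new_grid` and the refitted coeffs.
#' @export
refit_coefficients <- function(old_params, new_grid, samples) {
  stopifnot(inherits(old_params, "edge_params"), inherits(new_grid, "grid_spec"))
  if (n_bases(new_grid) != n_bases(old_params$grid)) {
    stop("new grid must carry the same number of basis functions")
  }
  y <- evaluate_spline(samples, old_params)
  B <- bspline_design(samples, new_grid)
  cnew <- as.vector(ls_minnorm(B, y))
  edge_params(old_params$w_b, old_params$w_s, cnew, new_grid)
}
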