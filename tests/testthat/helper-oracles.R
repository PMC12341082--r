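# Independent oracles and small fixture builders shared across tests.

# Table-filling (dynamic-programming) Cox-de Boor oracle for a single
# scalar x: builds the full triangle of basis values bottom-up, no
# recursion, independent of the package's evaluation path.
oracle_bspline <- function(x, knots, j, k) {
  nb <- length(knots) - 1L
  N <- vapply(seq_len(nb), function(jj) {
    as.numeric(knots[jj] <= x && x < knots[jj + 1L])
  }, numeric(1L))
  if (k >= 1L) {
    for (kk in seq_len(k)) {
      nb <- length(knots) - 1L - kk
      Nn <- numeric(nb)
      for (jj in seq_len(nb)) {
        d1 <- knots[jj + kk] - knots[jj]
        d2 <- knots[jj + kk + 1L] - knots[jj + 1L]
        a <- if (d1 > 0) (x - knots[jj]) / d1 * N[jj] else 0
        b <- if (d2 > 0) (knots[jj + kk + 1L] - x) / d2 * N[jj + 1L] else 0
        Nn[jj] <- a + b
      }
      N <- Nn
    }
  }
  N[j]
}

# Random non-degenerate grid_spec.
random_grid <- function(G = sample(3:8, 1L), kappa = sample(1:4, 1L),
                        lo = runif(1L, -3, 0), span = runif(1L, 0.5, 4)) {
  uniform_grid(G, kappa, lo = lo, hi = lo + span,
               epsilon = runif(1L, 0, 1))
}

# Random edge parameters on a random grid.
random_edge <- function(grid = random_grid()) {
  edge_params(rnorm(1L), rnorm(1L), rnorm(n_bases(grid), sd = 0.5), grid)
}

# Small random KAN model for forward/invariance tests.
random_model <- function(dims, task = "coordinates", n_classes = NULL,
                         use_relu = TRUE, seed = 1L, jitter = TRUE) {
  m <- init_model(dims, task = task, n_classes = n_classes,
                  use_relu = use_relu, seed = seed, G = 4L, kappa = 2L)
  if (jitter) {
    # break the symmetric init so tests see generic parameter values
    set.seed(seed + 1000L)
    for (l in seq_along(m$layers)) {
      la <- m$layers[[l]]
      m$layers[[l]]$Wb <- la$Wb + matrix(rnorm(length(la$Wb), sd = 0.2),
                                         nrow(la$Wb))
      m$layers[[l]]$Ws <- la$Ws + matrix(rnorm(length(la$Ws), sd = 0.2),
                                         nrow(la$Ws))
      m$layers[[l]]$C <- la$C + array(rnorm(length(la$C), sd = 0.3),
                                      dim(la$C))
    }
  }
  m
}

# Tiny layered fixture for pipeline tests (fast).
tiny_layered <- function(seed = 1L, n = 240L, m = 40L, k = 8L, layers = 4L) {
  simulate_layered_tissue(sim_config(
    n_spots = n, n_genes = m, n_informative = k, task = "layered",
    n_layers = layers, effect_size = 1.2, library_size_mean = 1500,
    seed = seed))
}

fast_pipeline_config <- function(...) {
  args <- utils::modifyList(list(epochs = 6L, batch_size = 64L,
                                 grid_update_epochs = c(1L, 3L)),
                            list(...))
  do.call(pipeline_config, args)
}
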