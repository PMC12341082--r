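# Seeded generators of spatial-transcriptomics-like fixtures with planted
# ground truth.  Counts are negative binomial with log-link means: a small
# planted subset of genes carries layer-specific (layered task) or smooth
# spatial (gradient task) signal; all remaining genes share one global
# mean and are pure noise.

#' Simulation configuration
#'
#' @param n_spots number of spots (objects).
#' @param n_genes total number of genes.
#' @param n_informative number of planted signal genes
#'   (`<= n_genes`).
#' @param task `"layered"` (ordinal bands) or `"gradient"` (continuous
#'   coordinates).
#' @param n_layers number of ordinal layers (layered task), `>= 2`.
#' @param effect_size log-scale amplitude of the planted mean shifts.  The
#'   default 1 (about an e-fold swing) is a strong, clearly detectable
#'   layer effect.
#' @param graded_effects if `TRUE`, the planted amplitudes decay linearly
#'   from `effect_size` down to `0.15 * effect_size` across the
#'   informative genes.  This emulates real filtered expression matrices,
#'   where many genes carry spatial signal of widely varying strength and
#'   information is partly redundant; with the default `FALSE` every
#'   informative gene has the same amplitude and all remaining genes are
#'   pure noise.
#' @param library_size_mean expected total counts per spot.
#' @param dispersion negative-binomial dispersion (`1/size`); 0 gives
#'   Poisson counts.
#' @param seed integer; the generator is fully reproducible from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_spots = 2000L, n_genes = 200L, n_informative = 20L,
                       task = c("layered", "gradient"), n_layers = 7L,
                       effect_size = 1.0, graded_effects = FALSE,
                       library_size_mean = 2000,
                       dispersion = 0.25, seed = 1L) {
  task <- match.arg(task)
  n_spots <- as.integer(n_spots); n_genes <- as.integer(n_genes)
  n_informative <- as.integer(n_informative); n_layers <- as.integer(n_layers)
  if (n_informative > n_genes) stop("n_informative must be <= n_genes")
  if (n_informative < 0L || n_spots < 1L || n_genes < 1L) stop("invalid config")
  if (task == "layered" && n_layers < 2L) stop("n_layers must be >= 2")
  if (dispersion < 0) stop("dispersion must be >= 0")
  structure(list(n_spots = n_spots, n_genes = n_genes,
                 n_informative = n_informative, task = task,
                 n_layers = n_layers, effect_size = effect_size,
                 graded_effects = isTRUE(graded_effects),
                 library_size_mean = library_size_mean,
                 dispersion = dispersion, seed = as.integer(seed)),
            class = "sim_config")
}

# NB draws with Poisson limit at dispersion 0.
draw_counts <- function(mu, dispersion) {
  n <- length(mu)
  if (dispersion > 0) stats::rnbinom(n, mu = mu, size = 1 / dispersion)
  else stats::rpois(n, lambda = mu)
}

sim_gene_names <- function(m) sprintf("g%04d", seq_len(m))

# Per-informative-gene amplitudes: constant, or linearly graded to 15%.
sim_amplitudes <- function(cfg) {
  if (cfg$n_informative == 0L) return(numeric(0))
  if (cfg$graded_effects) {
    cfg$effect_size * seq(1, 0.15, length.out = cfg$n_informative)
  } else {
    rep(cfg$effect_size, cfg$n_informative)
  }
}

#' Simulate a layered tissue (ordinal ground truth)
#'
#' Spots sit on a jittered square grid partitioned into `n_layers`
#' horizontal bands (the ordinal labels).  Each informative gene receives
#' a smooth layer-dependent log-mean profile of amplitude `effect_size`:
#' half are monotone in layer (random direction), half unimodal with a
#' random peak layer, so adjacent layers share signal and top-2 accuracy
#' is meaningful.  Non-informative genes share one global mean.  Counts
#' are negative binomial with per-spot lognormal size factors.
#'
#' @param cfg a [sim_config()] with `task = "layered"`.
#' @return list with `counts` (n x m integer matrix, dimnames set),
#'   `coords` (n x 2), `labels` (0-based integer layers), `layer_levels`,
#'   and `informative` (the planted gene names).
#' @export
simulate_layered_tissue <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$task != "layered") stop("cfg$task must be 'layered'")
  set.seed(cfg$seed)
  n <- cfg$n_spots; m <- cfg$n_genes; L <- cfg$n_layers
  side <- ceiling(sqrt(n))
  gx <- (seq_len(n) - 1L) %% side
  gy <- (seq_len(n) - 1L) %/% side
  coords <- cbind(x = gx + stats::runif(n, -0.3, 0.3),
                  y = gy + stats::runif(n, -0.3, 0.3))
  ymax <- max(gy) + 1L
  labels <- pmin(L - 1L, as.integer(floor(gy / ymax * L)))

  genes <- sim_gene_names(m)
  info_idx <- sort(sample.int(m, cfg$n_informative))
  amp <- sim_amplitudes(cfg)
  # layer-profile matrix: L x m of log-mean shifts, zero for noise genes
  delta <- matrix(0, L, m)
  ell <- seq_len(L) - 1L
  for (r in seq_along(info_idx)) {
    gidx <- info_idx[r]
    if (r %% 2L == 1L) {                       # monotone in layer
      s <- sample(c(-1, 1), 1L)
      delta[, gidx] <- s * amp[r] * (2 * ell / (L - 1) - 1)
    } else {                                   # unimodal bump
      peak <- sample(ell, 1L)
      prof <- exp(-(ell - peak)^2 / 2)
      delta[, gidx] <- amp[r] * (prof - mean(prof))
    }
  }
  mu0 <- cfg$library_size_mean / m
  sf <- exp(stats::rnorm(n, 0, 0.2))
  sf <- sf / mean(sf)
  mu <- mu0 * exp(delta[labels + 1L, , drop = FALSE]) * sf
  counts <- matrix(draw_counts(mu, cfg$dispersion), n, m,
                   dimnames = list(sprintf("spot%05d", seq_len(n)), genes))
  list(counts = counts, coords = coords, labels = labels,
       layer_levels = 0:(L - 1L), informative = genes[info_idx],
       amplitudes = stats::setNames(amp, genes[info_idx]))
}

#' Simulate a gradient tissue (continuous coordinates)
#'
#' Spots uniform on a `[0, 100]^2` rectangle.  Each informative gene's
#' log-mean is a distinct smooth spatial function assigned
#' deterministically from the seed: alternating linear gradients of random
#' direction and radial bumps of random center, with amplitude
#' `effect_size`.  Noise genes share one global mean.
#'
#' @param cfg a [sim_config()] with `task = "gradient"`.
#' @return list with `counts`, `coords`, `informative`, and
#'   `log_mean_shift` (the noiseless n x n_informative signal matrix, for
#'   oracle checks).
#' @export
simulate_gradient_tissue <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$task != "gradient") stop("cfg$task must be 'gradient'")
  set.seed(cfg$seed)
  n <- cfg$n_spots; m <- cfg$n_genes
  coords <- cbind(x = stats::runif(n, 0, 100), y = stats::runif(n, 0, 100))
  u <- 2 * coords[, 1L] / 100 - 1
  v <- 2 * coords[, 2L] / 100 - 1
  genes <- sim_gene_names(m)
  info_idx <- sort(sample.int(m, cfg$n_informative))
  amp <- sim_amplitudes(cfg)
  delta <- matrix(0, n, m)
  for (r in seq_along(info_idx)) {
    gidx <- info_idx[r]
    if (r %% 2L == 1L) {                       # linear gradient
      th <- stats::runif(1L, 0, 2 * pi)
      delta[, gidx] <- amp[r] * (cos(th) * u + sin(th) * v) / sqrt(2)
    } else {                                   # radial bump
      cx <- stats::runif(1L, 20, 80); cy <- stats::runif(1L, 20, 80)
      d2 <- (coords[, 1L] - cx)^2 + (coords[, 2L] - cy)^2
      prof <- exp(-d2 / (2 * 25^2))
      delta[, gidx] <- amp[r] * (2 * prof - 1)
    }
  }
  mu0 <- cfg$library_size_mean / m
  sf <- exp(stats::rnorm(n, 0, 0.2))
  sf <- sf / mean(sf)
  mu <- mu0 * exp(delta) * sf
  counts <- matrix(draw_counts(mu, cfg$dispersion), n, m,
                   dimnames = list(sprintf("cell%05d", seq_len(n)), genes))
  list(counts = counts, coords = coords, informative = genes[info_idx],
       amplitudes = stats::setNames(amp, genes[info_idx]),
       log_mean_shift = delta[, info_idx, drop = FALSE])
}

#' Split a simulated dataset into reference and query parts
#'
#' Disjoint random row split; coordinates and labels are retained on both
#' sides so query predictions can be evaluated.
#'
#' @param sim output of [simulate_layered_tissue()] or
#'   [simulate_gradient_tissue()] (any list with a `counts` matrix and
#'   optional row-aligned `coords` / `labels`).
#' @param fraction fraction of rows assigned to the reference part,
#'   strictly between 0 and 1.
#' @param seed integer seed for the split.
#' @return list with `reference` and `query`, each shaped like `sim`.
#' @export
split_query <- function(sim, fraction, seed = 1L) {
  if (!is.list(sim) || is.null(sim$counts)) stop("sim must carry a counts matrix")
  n <- nrow(sim$counts)
  if (!(fraction > 0 && fraction < 1)) stop("fraction must lie strictly in (0, 1)")
  n_ref <- as.integer(round(fraction * n))
  if (n_ref < 1L || n_ref > n - 1L) stop("degenerate split: both parts must be non-empty")
  set.seed(seed)
  ref_idx <- sort(sample.int(n, n_ref))
  take <- function(idx) {
    out <- sim
    out$counts <- sim$counts[idx, , drop = FALSE]
    if (!is.null(sim$coords)) out$coords <- sim$coords[idx, , drop = FALSE]
    if (!is.null(sim$labels)) out$labels <- sim$labels[idx]
    if (!is.null(sim$log_mean_shift)) {
      out$log_mean_shift <- sim$log_mean_shift[idx, , drop = FALSE]
    }
    out
  }
  list(reference = take(ref_idx), query = take(setdiff(seq_len(n), ref_idx)))
}
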