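# Synthetic replicate pairs with known embedded time-scale structure, so
# the whole detection chain is testable without any external download.

#' Simulation configuration
#'
#' Describes a synthetic replicate pair with three gene classes:
#' \describe{
#'   \item{sync}{the same smooth pattern at the same position in both
#'     replicates -- processes on the synchronized (measured) time scale.}
#'   \item{shifted}{the pattern displaced by `s0` grid steps in replicate 1
#'     relative to replicate 2 -- a process on a separate time scale.}
#'   \item{noise}{i.i.d. Gaussian series with no reproducible structure.}
#' }
#' Independent Gaussian noise of SD `noise_sd` is added to every
#' measurement. The default pattern is a sinusoid with a period of
#' `period` grid steps and a random phase per gene, emulating an
#' oscillatory process (such as the cell cycle) sampled roughly ten points
#' per cycle; `"gaussian_bump"` (a single peak of width `bump_width`
#' traversing the series -- note its flat tails carry no rank information,
#' which weakens shift recovery under noise) and `"ramp"` (strictly
#' monotone) are alternatives.
#'
#' @param M_sync,M_shifted,M_noise non-negative gene counts per class.
#' @param N number of time points (at least 3).
#' @param s0 true shift of the shifted class, in grid steps;
#'   `|s0| <= floor(N/2)`.
#' @param pattern `"sine"`, `"gaussian_bump"` or `"ramp"`.
#' @param amplitude pattern amplitude (expression units).
#' @param noise_sd SD of the additive measurement noise, same units.
#' @param period sine period in grid steps.
#' @param bump_width Gaussian-bump SD in grid steps; default `N/8`.
#' @param wrap logical; wrap the shifted pattern around the series edges
#'   (periodic, cell-cycle-like) instead of letting it exit the window.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(M_sync = 0L, M_shifted = 0L, M_noise = 0L,
                       N = 20L, s0 = 2L,
                       pattern = c("sine", "gaussian_bump", "ramp"),
                       amplitude = 1, noise_sd = 0.25,
                       period = 10, bump_width = NULL,
                       wrap = FALSE, seed = 1L) {
  pattern <- match.arg(pattern)
  counts <- c(M_sync, M_shifted, M_noise)
  if (!is_whole(counts) || any(counts < 0)) {
    stop2("gene counts must be non-negative integers")
  }
  if (!is_whole(N) || N < 3) stop2("N must be an integer >= 3")
  if (!is_whole(s0) || abs(s0) > floor(N / 2)) {
    stop2("s0 must be an integer with |s0| <= floor(N/2)")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) stop2("noise_sd must be >= 0")
  if (!is.numeric(amplitude) || amplitude <= 0) stop2("amplitude must be > 0")
  if (is.null(bump_width)) bump_width <- N / 8
  structure(list(M_sync = as.integer(M_sync),
                 M_shifted = as.integer(M_shifted),
                 M_noise = as.integer(M_noise),
                 N = as.integer(N), s0 = as.integer(s0), pattern = pattern,
                 amplitude = amplitude, noise_sd = noise_sd,
                 period = period, bump_width = bump_width,
                 wrap = isTRUE(wrap), seed = as.integer(seed)),
            class = "sim_config")
}

# Draw one smooth template; returns a function of (possibly fractional)
# grid position.
draw_pattern <- function(config) {
  A <- config$amplitude
  N <- config$N
  switch(config$pattern,
    sine = {
      phase <- stats::runif(1, 0, 2 * pi)
      function(x) A * sin(2 * pi * x / config$period + phase)
    },
    gaussian_bump = {
      center <- stats::runif(1, 0.3 * N, 0.7 * N)
      w <- config$bump_width
      function(x) A * exp(-(x - center)^2 / (2 * w^2))
    },
    ramp = {
      sgn <- sample(c(-1, 1), 1)
      function(x) sgn * A * (x - 1) / (N - 1)
    })
}

#' Generate a synthetic replicate pair with known shifts
#'
#' See [sim_config()] for the data model. Replicate 2 carries each pattern
#' at its nominal position; replicate 1 carries it displaced by `s0` steps
#' for the shifted class (replicate 1 lagging for positive `s0`, matching
#' the sign convention of [gamma_at_shift()]).
#'
#' @param config a [sim_config()].
#' @return List with `pair` (a [replicate_pair()]) and `truth` (data frame
#'   `gene_id`, `class`, `true_shift`; `true_shift` is `NA` for noise
#'   genes).
#' @export
generate_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  N <- config$N
  t_grid <- seq_len(N)
  ids <- c(sprintf("sync_%05d", seq_len(config$M_sync)),
           sprintf("shift_%05d", seq_len(config$M_shifted)),
           sprintf("noise_%05d", seq_len(config$M_noise)))
  classes <- rep(c("sync", "shifted", "noise"),
                 c(config$M_sync, config$M_shifted, config$M_noise))
  M <- length(ids)
  out <- with_seed(config$seed, {
    v1 <- matrix(0, M, N)
    v2 <- matrix(0, M, N)
    eval_at <- function(f, x) {
      if (config$wrap) f((x - 1) %% N + 1) else f(x)
    }
    for (i in seq_len(M)) {
      if (classes[i] == "noise") {
        v1[i, ] <- stats::rnorm(N, 0, config$amplitude)
        v2[i, ] <- stats::rnorm(N, 0, config$amplitude)
      } else {
        f <- draw_pattern(config)
        shift <- if (classes[i] == "shifted") config$s0 else 0L
        v2[i, ] <- eval_at(f, t_grid)
        v1[i, ] <- eval_at(f, t_grid - shift)
      }
      if (config$noise_sd > 0) {
        v1[i, ] <- v1[i, ] + stats::rnorm(N, 0, config$noise_sd)
        v2[i, ] <- v2[i, ] + stats::rnorm(N, 0, config$noise_sd)
      }
    }
    list(v1 = v1, v2 = v2)
  })
  rownames(out$v1) <- rownames(out$v2) <- ids
  truth <- data.frame(
    gene_id = ids, class = classes,
    true_shift = ifelse(classes == "shifted", config$s0,
                        ifelse(classes == "sync", 0L, NA_integer_)))
  list(pair = replicate_pair(expr_matrix(out$v1, t_grid, ids),
                             expr_matrix(out$v2, t_grid, ids)),
       truth = truth)
}

#' Generate cell-type profiles around cluster templates
#'
#' Fixture generator for co-expression module recovery: `n_clusters`
#' Gaussian template profiles over `n_conditions` conditions, each
#' replicated `genes_per_cluster` times with additive noise.
#'
#' @param n_clusters number of templates.
#' @param genes_per_cluster genes drawn around each template.
#' @param n_conditions number of conditions (at least 3).
#' @param noise_sd additive noise SD (the templates have SD `amplitude`).
#' @param amplitude template SD.
#' @param seed integer seed.
#' @return List with `profiles` (matrix, gene rownames) and `truth`
#'   (data frame `gene_id`, `cluster`).
#' @export
generate_celltype_profiles <- function(n_clusters = 3L,
                                       genes_per_cluster = 10L,
                                       n_conditions = 8L,
                                       noise_sd = 0.1, amplitude = 1,
                                       seed = 1L) {
  if (!is_whole(n_clusters) || n_clusters < 1) {
    stop2("n_clusters must be a positive integer")
  }
  if (!is_whole(genes_per_cluster) || genes_per_cluster < 1) {
    stop2("genes_per_cluster must be a positive integer")
  }
  if (!is_whole(n_conditions) || n_conditions < 3) {
    stop2("need at least 3 conditions")
  }
  res <- with_seed(seed, {
    templates <- matrix(stats::rnorm(n_clusters * n_conditions, 0, amplitude),
                        n_clusters, n_conditions)
    profiles <- matrix(0, n_clusters * genes_per_cluster, n_conditions)
    for (c_i in seq_len(n_clusters)) {
      for (g in seq_len(genes_per_cluster)) {
        row <- (c_i - 1) * genes_per_cluster + g
        profiles[row, ] <- templates[c_i, ] +
          stats::rnorm(n_conditions, 0, noise_sd)
      }
    }
    profiles
  })
  ids <- sprintf("c%02d_g%03d", rep(seq_len(n_clusters),
                                    each = genes_per_cluster),
                 rep(seq_len(genes_per_cluster), n_clusters))
  rownames(res) <- ids
  list(profiles = res,
       truth = data.frame(gene_id = ids,
                          cluster = rep(seq_len(n_clusters),
                                        each = genes_per_cluster)))
}
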