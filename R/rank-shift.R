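#' Rank-transform one expression series
#'
#' Converts a series of N expression values to a rank permutation with the
#' descending convention: rank 1 is the highest value, rank N the lowest,
#' so `(0.3, 0.5, 0.6, 0.2)` becomes `(3, 2, 1, 4)`. Exact ties -- rare in
#' high-resolution data -- are broken uniformly at random under `tie_seed`
#' so results are reproducible.
#'
#' @param values numeric vector, length >= 2, all finite.
#' @param tie_seed integer seed used only when ties are present.
#' @return Integer vector: a permutation of `1:length(values)`.
#' @export
rank_transform <- function(values, tie_seed = 1L) {
  if (!is.numeric(values) || length(values) < 2) {
    stop2("values must be a numeric vector of length >= 2")
  }
  if (any(!is.finite(values))) stop2("values must all be finite")
  if (anyDuplicated(values)) {
    r <- with_seed(tie_seed, rank(-values, ties.method = "random"))
  } else {
    r <- rank(-values)
  }
  as.integer(r)
}

#' Rank-transform every row of an expression matrix
#'
#' Row-wise [rank_transform()] under a single RNG stream seeded once with
#' `tie_seed`, so the whole matrix is deterministic given the seed. The
#' number of tied values per row is recorded in the `"n_ties"` attribute
#' (an audit trail for the stochastic tie-break), and rows that are
#' entirely constant are flagged in `"degenerate"`.
#'
#' @param values numeric matrix (genes x time points) with rownames.
#' @param tie_seed integer seed for tie-breaking.
#' @return Integer matrix of row permutations with attributes `n_ties` and
#'   `degenerate`.
#' @export
rank_matrix <- function(values, tie_seed = 1L) {
  values <- as.matrix(values)
  if (ncol(values) < 2) stop2("need at least 2 time points")
  if (any(!is.finite(values))) stop2("values must all be finite")
  perms <- with_seed(tie_seed, {
    t(apply(values, 1, function(v) rank(-v, ties.method = "random")))
  })
  storage.mode(perms) <- "integer"
  rownames(perms) <- rownames(values)
  n_ties <- apply(values, 1, function(v) sum(duplicated(v)))
  attr(perms, "n_ties") <- n_ties
  attr(perms, "degenerate") <- apply(values, 1, function(v) {
    length(unique(v)) == 1
  })
  perms
}

check_permutation <- function(p, arg) {
  if (!is_whole(p) || !identical(sort(as.integer(p)), seq_len(length(p)))) {
    stop2(arg, " must be a permutation of 1..N")
  }
}

#' Shifted rank similarity statistic
#'
#' The similarity of two rank profiles at an integer shift `s` is the sum of
#' absolute rank differences over the overlap window of width
#' `W = N - |s|`, divided by N:
#' \deqn{\gamma(s) = \frac{1}{N} \sum_{j=1}^{N-s} |\pi^1_{j+s} - \pi^2_j|,
#'   \quad s \ge 0,}
#' and symmetrically with the roles of the profiles exchanged for `s < 0`.
#' Smaller values mean greater similarity; `gamma = 0` is a perfect rank
#' match over the window. Positive `s` means replicate 1's pattern occurs
#' later than replicate 2's.
#'
#' @param pi1,pi2 integer permutations of `1:N` (see [rank_transform()]).
#' @param s integer shift with `|s| <= N - 2`.
#' @return The statistic, a non-negative number.
#' @export
gamma_at_shift <- function(pi1, pi2, s) {
  check_permutation(pi1, "pi1")
  check_permutation(pi2, "pi2")
  n <- length(pi1)
  if (length(pi2) != n) stop2("pi1 and pi2 must have equal length")
  if (!is_whole(s) || length(s) != 1) stop2("s must be a single integer")
  if (abs(s) > n - 2) {
    stop2(sprintf("|s| = %d leaves an overlap window below 2 (N = %d)",
                  abs(s), n))
  }
  s <- as.integer(s)
  if (s >= 0) {
    sum(abs(pi1[(1 + s):n] - pi2[1:(n - s)])) / n
  } else {
    a <- -s
    sum(abs(pi1[1:(n - a)] - pi2[(1 + a):n])) / n
  }
}

#' Gaussian null parameters for one overlap window
#'
#' Under uniformly random permutations (the null for i.i.d. data) each
#' normalized rank behaves like a continuous Uniform(0,1) variable, and the
#' absolute difference of two independent uniforms has mean 1/3 and
#' variance 1/18. Summed over the `W = N - |s|` pairs of the overlap
#' window, on the scale where [gamma_at_shift()] divides rank differences
#' by N, the statistic is approximately Gaussian with
#' \deqn{\mu = W/3, \qquad \sigma = \sqrt{W/18}.}
#' The width-dependence of both moments is why the most significant shift
#' need not be the one with the smallest statistic.
#'
#' @param N series length.
#' @param s integer shift; the window `W = N - |s|` must be at least 2.
#' @return An object of class `null_params`: list with `N`, `s`, `W`,
#'   `mu`, `sigma`.
#' @export
null_params <- function(N, s) {
  if (!is_whole(N) || length(N) != 1 || N < 2) stop2("N must be an integer >= 2")
  if (!is_whole(s) || length(s) != 1) stop2("s must be a single integer")
  W <- as.integer(N) - abs(as.integer(s))
  if (W < 2) {
    stop2(sprintf("overlap window W = %d is degenerate (need W >= 2)", W))
  }
  structure(list(N = as.integer(N), s = as.integer(s), W = W,
                 mu = W / 3, sigma = sqrt(W / 18)),
            class = "null_params")
}

#' @export
print.null_params <- function(x, ...) {
  cat(sprintf("null_params: N = %d, s = %+d, W = %d, mu = %.4f, sigma = %.4f\n",
              x$N, x$s, x$W, x$mu, x$sigma))
  invisible(x)
}

#' One-sided p-value for a shifted similarity statistic
#'
#' Lower-tail Gaussian probability `P(Gamma <= gamma)` under the null of
#' [null_params()]. Only the similarity direction is of interest, i.e. the
#' caller should treat the value as a significance measure only when
#' `gamma < mu`. Because the Gaussian extends below 0 while the statistic
#' cannot, this p-value is an upper bound on the exact permutation p-value
#' in the significant tail (conservative).
#'
#' @param gamma statistic from [gamma_at_shift()] (vectorized).
#' @param params a [null_params()] object.
#' @return p-value(s) in (0, 1).
#' @export
shift_pvalue <- function(gamma, params) {
  stopifnot(inherits(params, "null_params"))
  stats::pnorm(gamma, mean = params$mu, sd = params$sigma)
}

#' Scan all shifts for one gene
#'
#' Evaluates [gamma_at_shift()] and its p-value for every integer shift in
#' `-s_max..+s_max`. The p-value is recorded at every shift; rows with
#' `gamma >= mu` are never significant but are kept for completeness.
#'
#' @param pi1,pi2 rank permutations of the gene's two replicate series.
#' @param s_max maximal |shift| to scan; must leave a window of at least 2,
#'   and shifts beyond `floor(N/2)` cover less than half the series and are
#'   best avoided.
#' @param gene_id optional identifier stored with the scan.
#' @return A data frame of class `shift_scan` with columns `shift`, `W`,
#'   `gamma`, `mu`, `p`.
#' @export
scan_shifts <- function(pi1, pi2, s_max, gene_id = NULL) {
  n <- length(pi1)
  if (!is_whole(s_max) || length(s_max) != 1 || s_max < 1) {
    stop2("s_max must be a positive integer")
  }
  if (s_max > n - 2) stop2("s_max must be <= N - 2")
  shifts <- seq.int(-s_max, s_max)
  rows <- lapply(shifts, function(s) {
    np <- null_params(n, s)
    g <- gamma_at_shift(pi1, pi2, s)
    data.frame(shift = s, W = np$W, gamma = g, mu = np$mu,
               p = shift_pvalue(g, np))
  })
  out <- do.call(rbind, rows)
  attr(out, "gene_id") <- gene_id
  class(out) <- c("shift_scan", "data.frame")
  out
}

#' Most-significant-shift classification of one gene
#'
#' Among scanned shifts where the statistic indicates similarity
#' (`gamma < mu`), picks the shift with the smallest p-value. Exact p-value
#' ties are broken toward the smaller |shift|, then the positive sign.
#' The gene is significant when that best p-value is at or below `alpha`.
#'
#' @param scan a [scan_shifts()] result.
#' @param alpha significance threshold on the raw p-value.
#' @return A one-row data frame: `gene_id`, `best_shift` (NA when no shift
#'   shows similarity), `best_p`, `significant`.
#' @export
classify_gene <- function(scan, alpha = 0.001) {
  stopifnot(inherits(scan, "shift_scan") || is.data.frame(scan))
  if (!nrow(scan)) stop2("scan is empty")
  gene_id <- attr(scan, "gene_id")
  if (is.null(gene_id)) gene_id <- NA_character_
  el <- scan[scan$gamma < scan$mu, , drop = FALSE]
  if (!nrow(el)) {
    return(data.frame(gene_id = gene_id, best_shift = NA_integer_,
                      best_p = NA_real_, significant = FALSE))
  }
  o <- order(el$p, abs(el$shift), -el$shift)
  best <- el[o[1], ]
  data.frame(gene_id = gene_id, best_shift = as.integer(best$shift),
             best_p = best$p, significant = best$p <= alpha)
}
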