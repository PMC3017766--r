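#' Classify every gene of a replicate pair by its most significant shift
#'
#' The full detection pipeline on aligned replicates: rank-transform both
#' matrices (one seeded RNG stream, so results are deterministic given
#' `tie_seed`), evaluate the shifted similarity statistic and its one-sided
#' Gaussian p-value at every shift in `-s_max..+s_max`, and record for each
#' gene the shift with the smallest p-value among those showing similarity
#' (`gamma < mu`). No multiple-testing correction is applied to the
#' significance call, matching the raw-threshold usage the method was
#' designed around; a Benjamini-Hochberg adjusted column (`best_p_bh`,
#' computed across genes) is emitted for users who want it.
#'
#' Genes whose series is constant in either replicate are flagged
#' `degenerate` and never called significant: their ranks are pure
#' tie-breaking noise.
#'
#' @param pair a [replicate_pair()].
#' @param s_max maximal |shift| in grid steps; at most `N - 2`, and
#'   typically at most `floor(N/2)` so the overlap window always covers at
#'   least half the series.
#' @param alpha raw p-value threshold for the significance call.
#' @param tie_seed seed for random tie-breaking in the rank transform.
#' @return An object of class `shift_result`: list with
#'   \describe{
#'     \item{table}{data frame: `gene_id`, `best_shift`, `best_p`,
#'       `significant`, `degenerate`, `best_p_bh`, then the p-value at each
#'       scanned shift (`p_s-2`, ..., `p_s+2` style columns).}
#'     \item{gamma, p}{M x (2 s_max + 1) matrices of statistics/p-values.}
#'     \item{shifts, alpha, s_max, tie_seed, n_ties}{run metadata.}
#'   }
#' @export
classify_all <- function(pair, s_max, alpha = 0.001, tie_seed = 1L) {
  stopifnot(inherits(pair, "replicate_pair"))
  X1 <- pair$rep1$values
  X2 <- pair$rep2$values
  N <- ncol(X1)
  M <- nrow(X1)
  if (!is_whole(s_max) || s_max < 1 || s_max > N - 2) {
    stop2("s_max must be an integer in 1..(N-2)")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop2("alpha must lie in (0, 1)")
  }
  shifts <- seq.int(-s_max, s_max)
  S <- length(shifts)

  if (M == 0) {
    tab <- data.frame(gene_id = character(0), best_shift = integer(0),
                      best_p = numeric(0), significant = logical(0),
                      degenerate = logical(0), best_p_bh = numeric(0))
    for (s in shifts) tab[[sprintf("p_s%+d", s)]] <- numeric(0)
    return(structure(list(table = tab,
                          gamma = matrix(0, 0, S), p = matrix(0, 0, S),
                          shifts = shifts, N = N, alpha = alpha,
                          s_max = s_max, tie_seed = tie_seed,
                          n_ties = integer(0)),
                     class = "shift_result"))
  }

  # replicates ranked under derived seeds so their tie-breaks are independent
  R1 <- rank_matrix(X1, tie_seed = tie_seed)
  R2 <- rank_matrix(X2, tie_seed = tie_seed + 1L)
  degenerate <- attr(R1, "degenerate") | attr(R2, "degenerate")
  n_ties <- attr(R1, "n_ties") + attr(R2, "n_ties")

  G <- matrix(NA_real_, M, S)
  P <- matrix(NA_real_, M, S)
  mu_s <- (N - abs(shifts)) / 3
  sd_s <- sqrt((N - abs(shifts)) / 18)
  for (k in seq_len(S)) {
    s <- shifts[k]
    if (s >= 0) {
      D <- abs(R1[, (1 + s):N, drop = FALSE] - R2[, 1:(N - s), drop = FALSE])
    } else {
      a <- -s
      D <- abs(R1[, 1:(N - a), drop = FALSE] - R2[, (1 + a):N, drop = FALSE])
    }
    G[, k] <- rowSums(D) / N
    P[, k] <- stats::pnorm(G[, k], mu_s[k], sd_s[k])
  }

  # best shift: min p among similar (gamma < mu), ties toward small |s|,
  # then positive sign (column preference order encodes the tie-break)
  eligible <- sweep(G, 2, mu_s, "<")
  Psel <- ifelse(eligible, P, Inf)
  pref <- order(abs(shifts), -shifts)
  Pp <- Psel[, pref, drop = FALSE]
  idx <- max.col(-Pp, ties.method = "first")
  best_p <- Pp[cbind(seq_len(M), idx)]
  best_shift <- shifts[pref][idx]
  none <- !is.finite(best_p)
  best_shift[none] <- NA_integer_
  best_p[none] <- NA_real_
  significant <- !none & !degenerate & best_p <= alpha

  tab <- data.frame(gene_id = rownames(X1),
                    best_shift = as.integer(best_shift),
                    best_p = best_p,
                    significant = significant,
                    degenerate = degenerate,
                    best_p_bh = stats::p.adjust(best_p, method = "BH"),
                    row.names = NULL)
  for (k in seq_len(S)) tab[[sprintf("p_s%+d", shifts[k])]] <- P[, k]

  structure(list(table = tab, gamma = G, p = P, shifts = shifts, N = N,
                 alpha = alpha, s_max = s_max, tie_seed = tie_seed,
                 n_ties = n_ties),
            class = "shift_result")
}

#' @export
print.shift_result <- function(x, ...) {
  n <- nrow(x$table)
  ns <- sum(x$table$significant)
  cat(sprintf("shift_result: %d genes scanned at shifts %+d..%+d, alpha = %g\n",
              n, min(x$shifts), max(x$shifts), x$alpha))
  cat(sprintf("  significant: %d (%.1f%%); degenerate rows: %d\n",
              ns, if (n) 100 * ns / n else 0, sum(x$table$degenerate)))
  invisible(x)
}

#' Shift-class histogram
#'
#' Tabulates, per scanned shift, how many genes are significant at that
#' shift (p <= alpha and gamma < mu there) and how many have it as their
#' most significant shift; genes significant nowhere are counted under
#' `not_significant`.
#'
#' @param result a [classify_all()] result.
#' @return Data frame with columns `class`, `n_significant_at`,
#'   `n_most_significant`.
#' @export
shift_histogram <- function(result) {
  stopifnot(inherits(result, "shift_result"))
  shifts <- result$shifts
  deg <- result$table$degenerate
  mu_s <- (result$N - abs(shifts)) / 3
  eligible <- sweep(result$gamma, 2, mu_s, "<")
  sig_at <- colSums(eligible & result$p <= result$alpha & !deg)
  most <- vapply(shifts, function(s) {
    sum(result$table$significant & result$table$best_shift == s, na.rm = TRUE)
  }, integer(1))
  data.frame(class = c("not_significant", sprintf("%+d", shifts)),
             n_significant_at = c(NA_integer_, as.integer(sig_at)),
             n_most_significant = c(sum(!result$table$significant), most))
}
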