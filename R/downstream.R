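# Post-classification chain: co-expression modules on auxiliary expression,
# gene-set enrichment, shift-magnitude filtering, multi-replicate
# combination.

#' Hierarchical co-expression clustering cut at a correlation threshold
#'
#' Agglomerative clustering of genes on auxiliary profiles (e.g. cell-type
#' or condition expression) with distance `1 - Pearson r`, cutting the tree
#' at distance `1 - r_threshold` so that modules group genes correlated
#' above the threshold. Singleton clusters are allowed.
#'
#' @param profiles numeric matrix, genes in rows (rownames required),
#'   conditions in columns (at least 3).
#' @param r_threshold Pearson correlation cut value, default 0.75.
#' @param linkage agglomeration method: `"average"` (default),
#'   `"complete"` or `"single"`.
#' @return An object of class `cluster_set`: list with `clusters` (named
#'   list of gene-id vectors), `assignments` (named integer vector),
#'   `threshold`, `linkage`.
#' @export
cluster_genes <- function(profiles, r_threshold = 0.75,
                          linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2) stop2("need at least 2 genes")
  if (ncol(profiles) < 3) stop2("need at least 3 conditions")
  if (is.null(rownames(profiles))) stop2("profiles must have gene rownames")
  if (!is.numeric(r_threshold) || r_threshold <= -1 || r_threshold >= 1) {
    stop2("r_threshold must lie in (-1, 1)")
  }
  v <- apply(profiles, 1, stats::var)
  if (any(v == 0)) {
    stop2("zero-variance profiles for: ",
          paste(rownames(profiles)[v == 0], collapse = ", "))
  }
  d <- stats::as.dist(1 - stats::cor(t(profiles)))
  hc <- stats::hclust(d, method = linkage)
  cut <- stats::cutree(hc, h = 1 - r_threshold)
  structure(list(clusters = split(names(cut), cut),
                 assignments = cut,
                 threshold = r_threshold,
                 linkage = linkage),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat(sprintf(
    "cluster_set: %d clusters over %d genes (r > %.2f, %s linkage)\n",
    length(sizes), sum(sizes), x$threshold, x$linkage))
  cat("  sizes:", paste(sort(sizes, decreasing = TRUE), collapse = " "), "\n")
  invisible(x)
}

#' Drop small clusters
#'
#' Retains clusters with strictly more than `min_size` members (the
#' "greater than 10 members" rule at the default).
#'
#' @param clusters a [cluster_genes()] result.
#' @param min_size strict lower size bound, default 10.
#' @return A `cluster_set` containing only the retained clusters.
#' @export
filter_clusters <- function(clusters, min_size = 10L) {
  stopifnot(inherits(clusters, "cluster_set"))
  if (!is_whole(min_size) || min_size < 0) {
    stop2("min_size must be a non-negative integer")
  }
  keep <- lengths(clusters$clusters) > min_size
  out <- clusters
  out$clusters <- clusters$clusters[keep]
  out$assignments <- clusters$assignments[
    as.character(clusters$assignments) %in% names(out$clusters)]
  out
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail probability `P(X >= k)` of drawing `k` or more members of a
#' gene set of size `K` when sampling `n` cluster genes without replacement
#' from a universe of `U` genes. Sets are intersected with the universe
#' before testing.
#'
#' @param genes character vector, the cluster to test; must be contained in
#'   `universe`.
#' @param sets named list of gene-id vectors (see [read_gmt()]).
#' @param universe character vector of all genes eligible for membership.
#' @return Data frame, one row per set: `set`, `k`, `n`, `K`, `U`, `p`,
#'   ordered by `p`.
#' @export
hypergeom_enrich <- function(genes, sets, universe) {
  genes <- unique(as.character(genes))
  universe <- unique(as.character(universe))
  missing <- setdiff(genes, universe)
  if (length(missing)) {
    stop2("cluster genes absent from universe: ",
          paste(utils::head(missing, 5), collapse = ", "))
  }
  if (!length(sets)) {
    return(data.frame(set = character(0), k = integer(0), n = integer(0),
                      K = integer(0), U = integer(0), p = numeric(0)))
  }
  U <- length(universe)
  n <- length(genes)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(unique(as.character(sets[[nm]])), universe)
    K <- length(members)
    k <- length(intersect(genes, members))
    p <- stats::phyper(k - 1, K, U - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, n = n, K = K, U = U, p = p)
  })
  out <- do.call(rbind, rows)
  out[order(out$p, out$set), , drop = FALSE]
}

#' Select genes shifted beyond a magnitude threshold
#'
#' Keeps significant genes whose most significant shift is strictly greater
#' than `+min_abs_shift` or strictly less than `-min_abs_shift`. The
#' default `min_abs_shift = 2` reproduces the "beyond two sections" rule;
#' `min_abs_shift = 0` keeps every significant non-zero shift.
#'
#' @param classifications the `table` of a [classify_all()] result (or the
#'   result itself).
#' @param min_abs_shift non-negative integer threshold.
#' @return The filtered classification table.
#' @export
filter_by_shift <- function(classifications, min_abs_shift = 2L) {
  if (inherits(classifications, "shift_result")) {
    classifications <- classifications$table
  }
  if (!is_whole(min_abs_shift) || min_abs_shift < 0) {
    stop2("min_abs_shift must be a non-negative integer")
  }
  if (!nrow(classifications)) return(classifications)
  keep <- classifications$significant &
    !is.na(classifications$best_shift) &
    abs(classifications$best_shift) > min_abs_shift
  classifications[keep, , drop = FALSE]
}

#' Combine independent p-values with Fisher's method
#'
#' `X^2 = -2 sum(log p)` referred to a chi-square distribution with `2k`
#' degrees of freedom. Used to combine the per-replicate-pair shift
#' p-values when three or more replicates are available (choose `m - 1`
#' independent pairs among `m` replicates); a single p-value is returned
#' unchanged.
#'
#' @param pvals numeric vector of p-values in (0, 1]; zeros must be floored
#'   by the caller first.
#' @return The combined p-value.
#' @export
fisher_combine <- function(pvals) {
  if (!is.numeric(pvals) || !length(pvals)) {
    stop2("pvals must be a non-empty numeric vector")
  }
  if (any(is.na(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    stop2("all p-values must lie in (0, 1]; floor zeros before combining")
  }
  x2 <- -2 * sum(log(pvals))
  stats::pchisq(x2, df = 2 * length(pvals), lower.tail = FALSE)
}
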