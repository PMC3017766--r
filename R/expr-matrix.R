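#' Expression matrix container
#'
#' A minimal container for one replicate of an expression time course: an
#' M x N numeric matrix of expression values, the N strictly increasing
#' sampling times (minutes, or section indices treated as times 1..N), and
#' M unique gene identifiers.
#'
#' @param values numeric matrix, genes in rows, time points in columns.
#' @param times numeric vector of sampling times, strictly increasing, one
#'   per column.
#' @param gene_ids character vector of unique gene identifiers, one per row.
#'   Defaults to `rownames(values)`.
#'
#' @return An object of class `expr_matrix`: a list with elements
#'   `gene_ids`, `times` and `values` (the matrix carries the ids as
#'   rownames).
#' @export
expr_matrix <- function(values, times, gene_ids = rownames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) {
    stop2("gene_ids are required (or set rownames on `values`)")
  }
  gene_ids <- as.character(gene_ids)
  if (nrow(values) != length(gene_ids)) {
    stop2("length(gene_ids) must equal nrow(values)")
  }
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup)) {
    stop2("duplicate gene ids: ", paste(dup, collapse = ", "))
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop2("expression values must be finite and non-missing")
  }
  times <- as.numeric(times)
  if (length(times) != ncol(values)) {
    stop2("length(times) must equal ncol(values)")
  }
  if (length(times) < 3) {
    stop2("at least 3 time points are required")
  }
  if (any(diff(times) <= 0)) {
    stop2("times must be strictly increasing")
  }
  rownames(values) <- gene_ids
  colnames(values) <- NULL
  structure(list(gene_ids = gene_ids, times = times, values = values),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d time points (t = %s .. %s)\n",
              nrow(x$values), length(x$times),
              format(min(x$times)), format(max(x$times))))
  invisible(x)
}

#' Read a delimited expression matrix
#'
#' Expects one header row whose fields past the id column label the time
#' points, then one row per gene with the identifier in `id_column`. When
#' all time labels parse as numbers they are used as sampling times,
#' otherwise columns are indexed 1..N.
#'
#' @param path file to read.
#' @param id_column column (index) holding gene identifiers. Default 1.
#' @param delimiter field separator; tab by default, use "," for CSV.
#'
#' @return An [expr_matrix()].
#' @export
read_expression_matrix <- function(path, id_column = 1L, delimiter = "\t") {
  if (!file.exists(path)) stop2("file not found: ", path)
  raw <- utils::read.table(path, sep = delimiter, header = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE)
  if (nrow(raw) < 2) stop2("expected a header row and at least one gene row")
  header <- as.character(raw[1, ])
  body <- raw[-1, , drop = FALSE]
  data_cols <- setdiff(seq_len(ncol(raw)), id_column)
  gene_ids <- as.character(body[[id_column]])
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup)) {
    stop2("duplicate gene ids: ", paste(dup, collapse = ", "))
  }
  vals <- matrix(NA_real_, nrow(body), length(data_cols))
  for (j in seq_along(data_cols)) {
    col <- body[[data_cols[j]]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num))
    if (length(bad)) {
      stop2(sprintf("non-numeric value '%s' at row %d, column %d",
                    col[bad[1]], bad[1] + 1L, data_cols[j]))
    }
    vals[, j] <- num
  }
  labels <- header[data_cols]
  times <- suppressWarnings(as.numeric(labels))
  if (anyNA(times)) times <- seq_along(data_cols)
  expr_matrix(vals, times, gene_ids)
}

#' Write an expression matrix as delimited text
#'
#' Layout mirrors [read_expression_matrix()]: a header of time labels, one
#' row per gene. Values are written with enough digits to round-trip.
#'
#' @param x an [expr_matrix()].
#' @param path output file.
#' @param delimiter field separator.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, delimiter = "\t") {
  stopifnot(inherits(x, "expr_matrix"))
  header <- paste(c("gene", sprintf("%.15g", x$times)), collapse = delimiter)
  rows <- vapply(seq_along(x$gene_ids), function(i) {
    paste(c(x$gene_ids[i], sprintf("%.15g", x$values[i, ])),
          collapse = delimiter)
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Resample a time course by linear interpolation
#'
#' Fits simple linear splines through each gene's series and evaluates them
#' at `new_times`. No extrapolation: the new grid must lie inside the
#' observed time range.
#'
#' @param x an [expr_matrix()].
#' @param new_times strictly increasing times inside `range(x$times)`.
#' @return An [expr_matrix()] on the new grid.
#' @export
resample_linear <- function(x, new_times) {
  stopifnot(inherits(x, "expr_matrix"))
  new_times <- as.numeric(new_times)
  if (min(new_times) < min(x$times) || max(new_times) > max(x$times)) {
    stop2(sprintf(
      "no extrapolation: requested [%g, %g] outside observed [%g, %g]",
      min(new_times), max(new_times), min(x$times), max(x$times)))
  }
  out <- t(apply(x$values, 1, function(v) {
    stats::approx(x$times, v, xout = new_times, method = "linear")$y
  }))
  if (length(new_times) == 1) out <- matrix(out, ncol = 1)
  expr_matrix(out, new_times, x$gene_ids)
}

#' Replicate pair container
#'
#' Two replicates on a common time grid with identical gene lists, the
#' directly comparable form required by the shift statistic.
#'
#' @param rep1,rep2 [expr_matrix()] objects with element-wise equal
#'   `gene_ids` and `times`.
#' @return An object of class `replicate_pair`.
#' @export
replicate_pair <- function(rep1, rep2) {
  stopifnot(inherits(rep1, "expr_matrix"), inherits(rep2, "expr_matrix"))
  if (!identical(rep1$gene_ids, rep2$gene_ids)) {
    stop2("replicates must have identical gene ids in identical order")
  }
  if (length(rep1$times) != length(rep2$times) ||
      any(rep1$times != rep2$times)) {
    stop2("replicates must share one time grid")
  }
  structure(list(rep1 = rep1, rep2 = rep2), class = "replicate_pair")
}

#' @export
print.replicate_pair <- function(x, ...) {
  cat(sprintf("replicate_pair: %d genes x %d common time points\n",
              length(x$rep1$gene_ids), length(x$rep1$times)))
  invisible(x)
}

#' Align two replicates onto a common grid
#'
#' Optionally drops leading samples (e.g. the first of 13 root sections so
#' both series span 12 comparable sections), resamples both replicates to a
#' shared grid, and intersects the gene lists.
#'
#' @param rep1,rep2 [expr_matrix()] objects.
#' @param drop_leading integer vector of length 2: leading samples to drop
#'   from each replicate before alignment.
#' @param grid numeric vector of target times, or `"auto"` to use the
#'   coarser replicate's grid restricted to the overlap of both time ranges.
#' @return A [replicate_pair()].
#' @export
align_replicates <- function(rep1, rep2, drop_leading = c(0L, 0L),
                             grid = "auto") {
  stopifnot(inherits(rep1, "expr_matrix"), inherits(rep2, "expr_matrix"))
  drop_leading <- rep_len(as.integer(drop_leading), 2)
  drop1 <- function(x, k) {
    if (k <= 0) return(x)
    expr_matrix(x$values[, -seq_len(k), drop = FALSE], x$times[-seq_len(k)],
                x$gene_ids)
  }
  rep1 <- drop1(rep1, drop_leading[1])
  rep2 <- drop1(rep2, drop_leading[2])
  lo <- max(min(rep1$times), min(rep2$times))
  hi <- min(max(rep1$times), max(rep2$times))
  if (identical(grid, "auto")) {
    coarser <- if (stats::median(diff(rep1$times)) >=
                   stats::median(diff(rep2$times))) rep1 else rep2
    grid <- coarser$times[coarser$times >= lo & coarser$times <= hi]
  }
  grid <- as.numeric(grid)
  if (min(grid) < lo || max(grid) > hi) {
    stop2("grid extends outside the overlap of the replicates' time ranges")
  }
  common <- intersect(rep1$gene_ids, rep2$gene_ids)
  if (!length(common)) stop2("replicates share no gene ids")
  sub <- function(x) {
    expr_matrix(x$values[match(common, x$gene_ids), , drop = FALSE],
                x$times, common)
  }
  replicate_pair(resample_linear(sub(rep1), grid),
                 resample_linear(sub(rep2), grid))
}

#' Read gene sets in GMT format
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name`, `description`, then member identifiers.
#'
#' @param path GMT file.
#' @return Named list mapping set name to a character vector of members.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop2(sprintf("malformed GMT line %d: expected at least 3 fields", i))
    }
    sets[[fields[1]]] <- unique(fields[-(1:2)])
  }
  sets
}
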