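# Small programmatic fixtures shared across test files.

write_tsv_matrix <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

toy_matrix <- function(M = 3, N = 4, times = seq_len(N), seed = 1) {
  vals <- shiftscan:::with_seed(seed, matrix(stats::rnorm(M * N), M, N))
  expr_matrix(vals, times, sprintf("g%d", seq_len(M)))
}

# Reference statistic computed the slow, obvious way (independent oracle).
gamma_brute <- function(pi1, pi2, s) {
  n <- length(pi1)
  tot <- 0
  for (j in seq_len(n)) {
    jj <- j + s
    if (jj >= 1 && jj <= n) tot <- tot + abs(pi1[jj] - pi2[j])
  }
  tot / n
}
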