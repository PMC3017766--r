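test_that("rank transform uses the descending convention", {
  expect_identical(rank_transform(c(0.3, 0.5, 0.6, 0.2)), c(3L, 2L, 1L, 4L))
  expect_identical(rank_transform(c(5, 4, 3, 2, 1)), 1:5)
  expect_error(rank_transform(c(1, NA, 3)), "finite")
  expect_error(rank_transform(3), "length >= 2")
})

test_that("exact ties are broken uniformly at random over seeds", {
  hits <- vapply(1:4000, function(seed) {
    rank_transform(c(1.0, 1.0), tie_seed = seed)[1] == 1L
  }, logical(1))
  expect_gt(mean(hits), 0.45)
  expect_lt(mean(hits), 0.55)
  # and deterministically given one seed
  expect_identical(rank_transform(c(1, 1, 2), tie_seed = 7),
                   rank_transform(c(1, 1, 2), tie_seed = 7))
})

test_that("the shifted similarity statistic matches hand values and the brute oracle", {
  expect_equal(gamma_at_shift(c(3, 1, 2, 4), c(3, 1, 2, 4), 0), 0)
  expect_equal(gamma_at_shift(c(1, 2, 3, 4), c(4, 3, 2, 1), 0), 2)
  expect_equal(gamma_at_shift(c(5, 1, 2, 3, 4), c(1, 2, 3, 4, 5), 1), 0)

  set.seed(31)
  for (rep_i in 1:25) {
    n <- sample(5:12, 1)
    p1 <- sample(n)
    p2 <- sample(n)
    s <- sample(seq(-(n - 2), n - 2), 1)
    expect_equal(gamma_at_shift(p1, p2, s), gamma_brute(p1, p2, s))
    # symmetry: swapping profiles flips the shift sign
    expect_equal(gamma_at_shift(p1, p2, s), gamma_at_shift(p2, p1, -s))
    # normalization bound: per-pair rank difference is at most N - 1
    expect_lte(gamma_at_shift(p1, p2, s), (n - abs(s)) * (n - 1) / n)
  }

  expect_error(gamma_at_shift(1:4, 1:5, 0), "equal length")
  expect_error(gamma_at_shift(1:4, 1:4, 3), "overlap")
  expect_error(gamma_at_shift(c(1, 1, 2, 3), 1:4, 0), "permutation")
})

test_that("null moments follow the uniform-difference closed form", {
  np <- null_params(28, 0)
  expect_equal(np$W, 28L)
  expect_equal(np$mu, 28 / 3)
  expect_equal(np$sigma, sqrt(28 / 18))
  np6 <- null_params(28, -6)
  expect_equal(np6$W, 22L)
  expect_equal(np6$mu, 22 / 3, tolerance = 1e-12)
  expect_equal(np6$sigma, sqrt(22 / 18), tolerance = 1e-12)
  expect_error(null_params(4, 3), "degenerate")
})

test_that("p-values are one-sided lower-tail Gaussian probabilities", {
  np <- null_params(10, 2)
  expect_equal(shift_pvalue(np$mu, np), 0.5)
  expect_equal(shift_pvalue(np$mu - 1.959964 * np$sigma, np), 0.025,
               tolerance = 1e-6)
  np4 <- null_params(6, 2) # W = 4
  expect_equal(shift_pvalue(0, np4), pnorm(-(4 / 3) / sqrt(4 / 18)),
               tolerance = 1e-12)
  expect_equal(shift_pvalue(0, np4), 2.34e-3, tolerance = 1e-2)
  # a perfect match is more significant the wider the window
  p_at_zero <- vapply(4:15, function(W) {
    shift_pvalue(0, null_params(20, 20 - W))
  }, numeric(1))
  expect_true(all(diff(p_at_zero) < 0))
})

test_that("scanning shifts records every shift and finds the best one", {
  pi0 <- 1:10
  sc <- scan_shifts(pi0, pi0, s_max = 2, gene_id = "g")
  expect_equal(nrow(sc), 5L)
  expect_equal(sc$gamma[sc$shift == 0], 0)
  expect_equal(sc$gamma[sc$shift == 1], 0.9)
  expect_equal(sc$gamma[sc$shift == -1], 0.9)
  expect_equal(sc$shift[which.min(sc$p)], 0)

  cls <- classify_gene(sc, alpha = 0.001)
  expect_equal(cls$best_shift, 0L)
  expect_true(cls$significant)
})

test_that("classification applies the stated tie-break and similarity rules", {
  mk_scan <- function(shift, gamma, mu, p) {
    out <- data.frame(shift = shift, W = 10 - abs(shift), gamma = gamma,
                      mu = mu, p = p)
    class(out) <- c("shift_scan", "data.frame")
    out
  }
  # direct argmin
  sc <- mk_scan(c(-1, 0, 1), c(1, 1, 1), c(3, 3.3, 3), c(0.2, 5e-4, 0.3))
  expect_equal(classify_gene(sc, 0.001)$best_shift, 0L)
  expect_true(classify_gene(sc, 0.001)$significant)
  # no similarity anywhere
  sc2 <- mk_scan(c(-1, 0, 1), c(4, 4, 4), c(3, 3.3, 3), c(0.9, 0.8, 0.9))
  expect_true(is.na(classify_gene(sc2)$best_shift))
  expect_false(classify_gene(sc2)$significant)
  # exact p tie at -1 and +1 resolves to +1
  sc3 <- mk_scan(c(-1, 0, 1), c(1, 5, 1), c(3, 3.3, 3), c(0.01, 0.9, 0.01))
  expect_equal(classify_gene(sc3)$best_shift, 1L)
})

test_that("identical replicates classify at shift zero; empty input gives empty table", {
  m <- toy_matrix(M = 20, N = 15, seed = 9)
  pair <- replicate_pair(m, m)
  res <- classify_all(pair, s_max = 4)
  expect_true(all(res$table$best_shift == 0L))
  expect_true(all(res$table$gene_id == m$gene_ids))

  empty_pair <- pair
  empty_pair$rep1$values <- m$values[0, , drop = FALSE]
  empty_pair$rep1$gene_ids <- character(0)
  empty_pair$rep2$values <- m$values[0, , drop = FALSE]
  empty_pair$rep2$gene_ids <- character(0)
  res0 <- classify_all(empty_pair, s_max = 4)
  expect_equal(nrow(res0$table), 0L)
})

test_that("classify_all is deterministic given the tie seed and matches scan_shifts", {
  sim <- generate_pair(sim_config(M_shifted = 8, M_noise = 8, N = 16,
                                  s0 = 2, seed = 21))
  r1 <- classify_all(sim$pair, s_max = 5, tie_seed = 3)
  r2 <- classify_all(sim$pair, s_max = 5, tie_seed = 3)
  expect_identical(r1$table, r2$table)

  # per-gene agreement with the scalar path (no ties in this fixture)
  i <- 5
  sc <- scan_shifts(rank_transform(sim$pair$rep1$values[i, ]),
                    rank_transform(sim$pair$rep2$values[i, ]), s_max = 5)
  expect_equal(unname(r1$gamma[i, ]), sc$gamma)
  expect_equal(unname(r1$p[i, ]), sc$p)
})

test_that("constant rows are flagged degenerate and never significant", {
  vals <- rbind(rep(1, 12), sin(1:12))
  rownames(vals) <- c("flat", "wave")
  m <- expr_matrix(vals, 1:12, c("flat", "wave"))
  res <- classify_all(replicate_pair(m, m), s_max = 3)
  expect_true(res$table$degenerate[1])
  expect_false(res$table$significant[1])
  expect_false(res$table$degenerate[2])
})

test_that("shift histogram matches the classification table", {
  sim <- generate_pair(sim_config(M_shifted = 30, M_noise = 10, N = 20,
                                  s0 = 2, noise_sd = 0.1, seed = 2))
  res <- classify_all(sim$pair, s_max = 6)
  h <- shift_histogram(res)
  expect_equal(nrow(h), 14L)
  expect_equal(sum(h$n_most_significant), nrow(res$table))
  expect_equal(h$n_most_significant[h$class == "+2"],
               sum(res$table$significant & res$table$best_shift == 2))
})
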