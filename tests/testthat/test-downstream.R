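test_that("correlation clustering groups identical and splits anti-correlated rows", {
  base <- c(1, 3, 2, 5, 4, 6)
  prof <- rbind(a = base, b = base + 10, c = -base)
  cs <- cluster_genes(prof, r_threshold = 0.75)
  asg <- cs$assignments
  expect_equal(asg[["a"]], asg[["b"]]) # r = 1 (affine copies)
  expect_false(asg[["a"]] == asg[["c"]]) # r = -1, distance 2 > 0.25

  expect_error(cluster_genes(rbind(a = rep(1, 4), b = 1:4)), "zero-variance")
  expect_error(cluster_genes(prof[, 1:2]), "3 conditions")
})

test_that("clustering recovers planted templates and ignores affine rescaling", {
  ct <- generate_celltype_profiles(n_clusters = 3, genes_per_cluster = 10,
                                   n_conditions = 8, noise_sd = 0.1,
                                   seed = 11)
  cs <- cluster_genes(ct$profiles, r_threshold = 0.75)
  # same partition as the truth: one-to-one between labels
  tab <- table(ct$truth$cluster, cs$assignments[ct$truth$gene_id])
  expect_equal(sum(tab > 0), 3L)
  expect_true(all(rowSums(tab > 0) == 1))

  scaled <- ct$profiles * rep(runif(30, 0.5, 3), 8) + rep(rnorm(30), 8)
  cs2 <- cluster_genes(scaled, r_threshold = 0.75)
  expect_identical(cs$assignments, cs2$assignments)
})

test_that("cluster size filtering is strictly greater-than", {
  cs <- structure(list(clusters = list(`1` = sprintf("a%d", 1:11),
                                       `2` = sprintf("b%d", 1:10),
                                       `3` = sprintf("c%d", 1:3)),
                       assignments = c(rep(1L, 11), rep(2L, 10), rep(3L, 3)),
                       threshold = 0.75, linkage = "average"),
                  class = "cluster_set")
  names(cs$assignments) <- unlist(cs$clusters)
  kept <- filter_clusters(cs, min_size = 10)
  expect_equal(names(kept$clusters), "1")
  expect_equal(length(filter_clusters(cs, min_size = 0)$clusters), 3L)
  empty <- cs
  empty$clusters <- list()
  empty$assignments <- integer(0)
  expect_equal(length(filter_clusters(empty)$clusters), 0L)
})

test_that("hypergeometric enrichment matches combinatorics", {
  universe <- sprintf("g%d", 1:20)
  res <- hypergeom_enrich(sprintf("g%d", 1:5),
                          list(hit = sprintf("g%d", 1:5),
                               all = universe,
                               none = sprintf("g%d", 6:10)),
                          universe)
  expect_equal(res$p[res$set == "hit"], 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$p[res$set == "all"], 1) # set is the whole universe
  expect_equal(res$p[res$set == "none"], 1) # zero overlap
  expect_error(hypergeom_enrich(c("g1", "zz"), list(s = "g1"), universe),
               "absent from universe")

  # p decreases as the overlap grows at fixed (U, K, n)
  ps <- vapply(1:5, function(k) {
    hypergeom_enrich(c(sprintf("g%d", seq_len(k)),
                       sprintf("x%d", seq_len(5 - k))),
                     list(s = sprintf("g%d", 1:5)),
                     c(universe, sprintf("x%d", 1:5)))$p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("shift-magnitude filter keeps only |shift| beyond the threshold", {
  tab <- data.frame(gene_id = letters[1:5],
                    best_shift = c(3L, 2L, 0L, -3L, NA),
                    best_p = c(1e-4, 1e-4, 1e-4, 1e-4, NA),
                    significant = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(filter_by_shift(tab, 2)$gene_id, c("a", "d"))
  expect_equal(filter_by_shift(tab, 0)$gene_id, c("a", "b", "d"))
  expect_equal(nrow(filter_by_shift(tab[0, ], 2)), 0L)
})

test_that("Fisher combination matches closed forms and accumulates evidence", {
  expect_equal(fisher_combine(0.5), 0.5, tolerance = 1e-12)
  x2 <- -2 * 2 * log(0.1)
  expect_equal(fisher_combine(c(0.1, 0.1)), (1 + x2 / 2) * exp(-x2 / 2),
               tolerance = 1e-12)
  expect_equal(fisher_combine(c(0.1, 0.1)), 0.05605, tolerance = 1e-4)
  expect_equal(fisher_combine(c(1, 1, 1)), 1)
  expect_error(fisher_combine(c(0.5, 0)), "floor")

  # repeated small p concentrates evidence (not true for p near 1, where
  # the chi-square combination is above the common value)
  for (p in c(0.001, 0.01, 0.05, 0.1)) {
    expect_lt(fisher_combine(rep(p, 3)), p)
  }
  expect_gt(fisher_combine(rep(0.6, 3)), 0.6)
})

test_that("Fisher combination of uniform p-values is uniform", {
  set.seed(19)
  comb <- replicate(10000, fisher_combine(runif(3)))
  ks <- max(abs(sort(comb) - (1:10000) / 10000))
  expect_lt(ks, 0.02)
})
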