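# fixed worked example: tree ((a,b)@2, c)@6
.abc_tree <- function() {
  m <- matrix(c(0, 2, 6, 2, 0, 8, 6, 8, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  agglomerate(m, "single")
}

test_that("alpha, beta and gamma reproduce the worked three-leaf example", {
  t <- .abc_tree()
  expect_equal(max_jaccard_alpha(t, c("a", "c")), 2 / 3)
  expect_equal(beta_dispersion(t, c("a", "c")), 2 / 3)
  expect_equal(gamma_dispersion(t, c("a", "c")), 0)
  # a group that appears as a cluster scores perfectly on all three
  for (g in list(c("a", "b"), c("a", "b", "c"))) {
    expect_equal(max_jaccard_alpha(t, g), 1)
    expect_equal(beta_dispersion(t, g), 1)
    expect_equal(gamma_dispersion(t, g), 1)
  }
  # singletons are clusters themselves; gamma = 1 by convention
  expect_equal(max_jaccard_alpha(t, "a"), 1)
  expect_equal(gamma_dispersion(t, "a"), 1)
  expect_equal(gamma_dispersion(t, c("a", "b", "c")), 1)
})

test_that("members absent from the dendrogram are dropped; empty groups error", {
  t <- .abc_tree()
  expect_warning(a <- max_jaccard_alpha(t, c("a", "c", "zz")),
                 "dropping 1 member")
  expect_equal(a, 2 / 3)
  expect_error(suppressWarnings(beta_dispersion(t, "zz")),
               "no group member")
})

test_that("alpha matches an independent brute-force over all node leaf sets", {
  set.seed(55)
  for (rep in 1:15) {
    t <- agglomerate(rand_distmat(12), "upgma")
    clusters <- enumerate_clusters_recursive(t)
    for (k in c(1, 3, 6)) {
      g <- sample(t$labels, k)
      expect_equal(max_jaccard_alpha(t, g), naive_alpha(clusters, g))
    }
  }
})

test_that("scores are invariant under relabeling and child-order swaps", {
  set.seed(77)
  m <- rand_distmat(10)
  t <- agglomerate(m, "upgma")
  g <- sample(t$labels, 4)
  base <- c(max_jaccard_alpha(t, g), beta_dispersion(t, g),
            gamma_dispersion(t, g))
  # relabel families
  map <- setNames(paste0("X", seq_along(t$labels)), t$labels)
  t2 <- t; t2$labels <- unname(map[t$labels])
  expect_equal(c(max_jaccard_alpha(t2, unname(map[g])),
                 beta_dispersion(t2, unname(map[g])),
                 gamma_dispersion(t2, unname(map[g]))), base)
  # swap children of every merge
  t3 <- t; t3$merge <- t$merge[, 2:1]
  expect_equal(c(max_jaccard_alpha(t3, g), beta_dispersion(t3, g),
                 gamma_dispersion(t3, g)), base)
})

test_that("beta never improves when a far outlier joins a tight group", {
  # 9 tightly clustered members plus one distant outlier in a 100-leaf tree
  set.seed(91)
  n <- 100
  labs <- sprintf("F%03d", 1:n)
  # 10-member tight block, 90 loosely related others, blocks far apart
  m <- matrix(10, n, n, dimnames = list(labs, labs))
  m[1:10, 1:10] <- 1
  m[1:10, 11:100] <- m[11:100, 1:10] <- 50
  m <- m + matrix(stats::runif(n * n, 0, 0.01), n, n)  # break ties
  m <- (m + t(m)) / 2; diag(m) <- 0
  t <- agglomerate(m, "upgma")
  tight <- labs[1:9]
  expect_equal(beta_dispersion(t, tight), 9 / 10, tolerance = 1e-6)
  with_outlier <- c(tight, labs[95])
  expect_equal(beta_dispersion(t, with_outlier), 10 / 100, tolerance = 1e-6)
  expect_lte(beta_dispersion(t, with_outlier), beta_dispersion(t, tight))
  # alpha is always at least the Jaccard score of the enclosing cluster
  expect_gte(max_jaccard_alpha(t, with_outlier), 10 / 100)
})

test_that("clan_report ranks groups by descending beta deterministically", {
  t <- .abc_tree()
  rep1 <- clan_report(t, list(CLA = c("a", "b"), CLB = c("a", "c")))
  expect_identical(rep1$group, c("CLA", "CLB"))
  expect_equal(rep1$alpha, c(1, 2 / 3))
  expect_equal(rep1$beta, c(1, 2 / 3))
  expect_equal(rep1$gamma, c(1, 0))
  expect_equal(rep1$best_cluster_size, c(2L, 3L))
  expect_equal(rep1$enclosing_cluster_size, c(2L, 3L))

  p <- withr::local_tempfile(fileext = ".tsv")
  write_clan_report(rep1, p)
  back <- utils::read.delim(p)
  expect_identical(back$group, rep1$group)
  expect_equal(back$beta, rep1$beta)
})
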