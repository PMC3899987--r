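test_that("the three linkage recursions reproduce hand-computed merge heights", {
  m <- matrix(c(0, 2, 6, 2, 0, 8, 6, 8, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  expect_equal(agglomerate(m, "single")$height, c(2, 6))
  expect_equal(agglomerate(m, "complete")$height, c(2, 8))
  expect_equal(agglomerate(m, "upgma")$height, c(2, 7))

  # two points: one merge at their distance, identical for all methods
  m2 <- matrix(c(0, 5, 5, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  for (meth in c("upgma", "single", "complete"))
    expect_equal(agglomerate(m2, meth)$height, 5)

  # constant matrix: every merge at the constant, whatever the method
  mc <- matrix(3, 4, 4); diag(mc) <- 0
  dimnames(mc) <- list(letters[1:4], letters[1:4])
  for (meth in c("upgma", "single", "complete"))
    expect_equal(agglomerate(mc, meth)$height, c(3, 3, 3))

  expect_error(agglomerate(m2[1, 1, drop = FALSE]), "at least 2")
  mna <- m; mna[1, 2] <- mna[2, 1] <- NA
  expect_error(agglomerate(mna), "NA")
})

test_that("Lance-Williams updates match the naive from-definition agglomeration", {
  set.seed(31)
  for (meth in c("upgma", "single", "complete")) {
    for (rep in 1:50) {
      m <- rand_distmat(10)
      got <- agglomerate(m, meth)
      ref <- naive_agglomerate(m, meth)
      expect_equal(got$height, ref$height, tolerance = 1e-12)
      expect_identical(unname(got$merge), unname(ref$merge))
    }
  }
})

test_that("merge heights are monotone along every root-to-leaf path", {
  set.seed(17)
  for (meth in c("upgma", "single", "complete")) {
    for (rep in 1:20) {
      t <- agglomerate(rand_distmat(12), meth)
      for (s in seq_along(t$height)) {
        for (k in t$merge[s, ]) {
          if (k > 0L) expect_lte(t$height[k], t$height[s] + 1e-12)
        }
      }
    }
  }
})

test_that("single-linkage merge heights equal the sorted MST edge weights", {
  set.seed(23)
  for (rep in 1:20) {
    m <- rand_distmat(12)
    expect_equal(sort(agglomerate(m, "single")$height),
                 mst_edge_weights(m), tolerance = 1e-12)
  }
})

test_that("cophenetic distances are an ultrametric", {
  set.seed(41)
  for (meth in c("upgma", "single", "complete")) {
    t <- agglomerate(rand_distmat(15), meth)
    coph <- as.matrix(stats::cophenetic(as.hclust(t)))
    for (i in 1:100) {
      tri <- sample(rownames(coph), 3)
      expect_lte(coph[tri[1], tri[2]],
                 max(coph[tri[1], tri[3]], coph[tri[2], tri[3]]) + 1e-12)
    }
  }
})

test_that("all_clusters enumerates the 2n-1 subtree leaf sets with heights", {
  m2 <- matrix(c(0, 5, 5, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  cl <- all_clusters(agglomerate(m2, "upgma"))
  expect_length(cl, 3L)
  expect_identical(cl[[1]]$members, "x")
  expect_equal(cl[[3]]$height, 5)
  expect_setequal(cl[[3]]$members, c("x", "y"))

  m <- matrix(c(0, 2, 6, 2, 0, 8, 6, 8, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  cl <- all_clusters(agglomerate(m, "single"))
  sets <- lapply(cl, function(x) sort(x$members))
  has_set <- function(s) any(vapply(sets, identical, logical(1), s))
  expect_true(has_set(c("a", "b")))
  expect_true(has_set(c("a", "b", "c")))

  set.seed(3)
  t10 <- agglomerate(rand_distmat(10), "upgma")
  expect_length(all_clusters(t10), 19L)
})

test_that("Newick export encodes height differences and survives a round trip", {
  m2 <- matrix(c(0, 5, 5, 0), 2, 2,
               dimnames = list(c("RFa", "RFb"), c("RFa", "RFb")))
  nwk <- to_newick(agglomerate(m2, "upgma"))
  expect_match(nwk, "^\\(RFa:5,RFb:5\\)\\[&height=5\\];$")

  m <- matrix(c(0, 2, 6, 2, 0, 8, 6, 8, 0), 3, 3,
              dimnames = list(c("RFa", "RFb", "RFc"), c("RFa", "RFb", "RFc")))
  t <- agglomerate(m, "single")
  nwk <- to_newick(t)
  expect_match(nwk, "RFc:6")
  expect_match(nwk, "\\):4")      # 6 - 2 between root and the (a,b) node

  # round trip recovers the same leaf-set / height pairs
  set.seed(13)
  t2 <- agglomerate(rand_distmat(8, values = c(1.5, 2.25, 4, 7)), "upgma")
  back <- read_newick(to_newick(t2))
  key <- function(t) sort(vapply(all_clusters(t), function(cl)
    paste0(paste(sort(cl$members), collapse = ","), "@",
           format(round(cl$height, 9))), character(1)))
  expect_identical(key(back), key(t2))

  # labels with metacharacters are quoted and survive
  t3 <- new_dendrogram(matrix(c(-1L, -2L), 1), 3, c("fam (odd)", "plain"))
  expect_match(to_newick(t3), "'fam \\(odd\\)'")
  expect_setequal(read_newick(to_newick(t3))$labels, c("fam (odd)", "plain"))
})

test_that("dendrograms convert to hclust and expose a display leaf order", {
  set.seed(8)
  m <- rand_distmat(9)
  t <- agglomerate(m, "complete")
  hc <- as.hclust(t)
  expect_s3_class(hc, "hclust")
  expect_equal(hc$height, t$height)
  expect_setequal(leaf_order(t), t$labels)
})
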