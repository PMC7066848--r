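test_that("per-subtype normalisation is column-wise min-max", {
  m <- cbind(a = c(0, 5, 10), b = c(4, 4, 4), c = c(0, 0.5, 1))
  rownames(m) <- c("x", "y", "z")
  n <- normalize_per_subtype(m)
  expect_equal(n[, "a"], c(x = 0, y = 0.5, z = 1))
  expect_equal(n[, "b"], c(x = 0, y = 0, z = 0))     # constant column zeroed
  expect_equal(n[, "c"], m[, "c"])                   # idempotent on [0,1]
  expect_equal(normalize_per_subtype(n), n)

  # every non-constant column spans exactly [0, 1]
  set.seed(8)
  r <- matrix(rpois(60, 7), 15, 4, dimnames = list(sprintf("g%02d", 1:15), NULL))
  nr <- normalize_per_subtype(r)
  for (j in 1:4) {
    if (max(r[, j]) > min(r[, j])) {
      expect_equal(range(nr[, j]), c(0, 1))
    } else expect_true(all(nr[, j] == 0))
  }

  # z-score alternative
  z <- normalize_per_subtype(r, method = "zscore")
  expect_equal(colMeans(z), rep(0, 4), tolerance = 1e-12)
})

test_that("chebyshev is the maximum coordinate difference and a metric", {
  expect_equal(chebyshev(c(0, 0), c(3, 4)), 4)
  expect_equal(chebyshev(1:5, 1:5), 0)
  expect_equal(chebyshev(c(1, 0, 0.5), c(0, 1, 0.5)), 1)
  expect_error(chebyshev(1:2, 1:3), "length")

  set.seed(12)
  for (i in 1:200) {
    u <- runif(4); v <- runif(4); w <- runif(4)
    expect_equal(chebyshev(u, v), chebyshev(v, u))
    expect_equal(chebyshev(u, u), 0)
    expect_lte(chebyshev(u, w), chebyshev(u, v) + chebyshev(v, w) + 1e-12)
  }
})

test_that("three-row agglomeration merges the close pair first", {
  m <- rbind(A = c(0, 0), B = c(0.1, 0), C = c(1, 1))
  dn <- complete_linkage(m)
  expect_equal(dn$height, c(0.1, 1.0))
  expect_equal(dn$members[[1]], c("A", "B"))
  expect_equal(dn$members[[2]], c("A", "B", "C"))
  expect_equal(leaf_order(dn), c("A", "B", "C"))
})

test_that("identical rows merge at height zero in label order", {
  m <- matrix(0.5, 4, 3, dimnames = list(c("d", "b", "a", "c"), NULL))
  dn <- complete_linkage(m)
  expect_true(all(dn$height == 0))
  expect_equal(leaf_order(dn), c("a", "b", "c", "d"))
  expect_error(complete_linkage(m[1, , drop = FALSE]), "2 rows")
})

test_that("merge sequence and heights match the naive agglomerator", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    m <- matrix(runif(n * 4), n, 4,
                dimnames = list(sample(sprintf("g%d", 1:n)), NULL))
    # half the cases get adversarial ties from a coarse value grid
    if (rep %% 2 == 0) m[] <- round(m * 4) / 4
    dn <- complete_linkage(m)
    ora <- oracle_agglomerate(m)
    expect_equal(dn$height, ora$heights, tolerance = 1e-12)
    expect_identical(dn$members, ora$members)
  }
})

test_that("heights agree with stats::hclust on tie-free matrices", {
  set.seed(33)
  for (rep in 1:5) {
    m <- matrix(runif(28), 7, 4, dimnames = list(letters[1:7], NULL))
    dn <- complete_linkage(m)
    h <- stats::hclust(stats::dist(m, method = "maximum"),
                       method = "complete")
    expect_equal(dn$height, h$height, tolerance = 1e-12)
  }
})

test_that("merge heights never decrease along the agglomeration", {
  set.seed(44)
  for (rep in 1:10) {
    m <- matrix(sample(0:3, 32, replace = TRUE) / 3, 8, 4,
                dimnames = list(letters[1:8], NULL))
    dn <- complete_linkage(m)
    expect_true(all(diff(dn$height) >= -1e-12))
  }
})

test_that("row permutation yields identical heights and clusters", {
  set.seed(55)
  m <- matrix(runif(24), 6, 4, dimnames = list(letters[1:6], NULL))
  dn1 <- complete_linkage(m)
  perm <- sample(6)
  dn2 <- complete_linkage(m[perm, , drop = FALSE])
  expect_equal(dn1$height, dn2$height, tolerance = 1e-12)
  expect_identical(dn1$members, dn2$members)
  expect_identical(leaf_order(dn1), leaf_order(dn2))
})

test_that("leaf order puts the smallest-label child left deterministically", {
  m <- rbind(b = c(0, 0), a = c(0.05, 0), d = c(1, 1), c = c(0.95, 1))
  dn <- complete_linkage(m)
  lo <- leaf_order(dn)
  expect_equal(lo[1:2], c("a", "b"))
  expect_equal(sort(lo[3:4]), c("c", "d"))
  expect_equal(dn$labels[dn$order], lo)
})

test_that("monophyly detection and hclust coercion are consistent", {
  m <- rbind(A = c(0, 0), B = c(0.1, 0), C = c(1, 1), D = c(0.9, 1))
  dn <- complete_linkage(m)
  expect_true(is_monophyletic(dn, c("A", "B")))
  expect_true(is_monophyletic(dn, c("C", "D")))
  expect_false(is_monophyletic(dn, c("A", "C")))
  expect_true(is_monophyletic(dn, "A"))
  hc <- as.hclust(dn)
  expect_s3_class(hc, "hclust")
  ct <- stats::cutree(hc, 2)
  expect_equal(unname(ct["A"]), unname(ct["B"]))
  expect_equal(unname(ct["C"]), unname(ct["D"]))
  expect_false(ct[["A"]] == ct[["C"]])
})

test_that("newick export is a valid ultrametric tree", {
  skip_if_not_installed("ape")
  m <- rbind(A = c(0, 0), B = c(0.1, 0), C = c(1, 1), D = c(0.9, 1))
  dn <- complete_linkage(m)
  tr <- ape::read.tree(text = dendro_to_newick(dn))
  expect_setequal(tr$tip.label, rownames(m))
  depths <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)]
  expect_equal(max(depths) - min(depths), 0, tolerance = 1e-9)
  expect_equal(max(depths), max(dn$height), tolerance = 1e-9)
})
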