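test_that("fingerprint dissimilarity matches the brute-force double loop", {
  set.seed(101)
  v <- matrix(sample(1:16), 4, 4)   # distinct integer entries
  W <- pairwise_dissimilarity(connectivity_matrix(v, symmetric = FALSE))
  for (i in 1:4) for (j in 1:4) {
    a <- setdiff(1:4, c(i, j))
    want <- sqrt(sum((v[i, a] - v[j, a])^2) + sum((v[a, i] - v[a, j])^2))
    expect_equal(W[i, j], want, tolerance = 1e-10)
  }
  # symmetric D: the row and column sums coincide, W = sqrt(2) * row part
  vs <- v + t(v)
  Ws <- pairwise_dissimilarity(connectivity_matrix(vs, symmetric = TRUE))
  i <- 1; j <- 3; a <- c(2, 4)
  expect_equal(Ws[i, j], sqrt(2 * sum((vs[i, a] - vs[j, a])^2)),
               tolerance = 1e-10)
  # identical fingerprints => zero dissimilarity
  v2 <- matrix(1:5, 5, 5)           # rows distinct, columns constant
  v2[1, ] <- v2[2, ]; v2[, 1] <- v2[, 2]
  W2 <- pairwise_dissimilarity(connectivity_matrix(v2, symmetric = FALSE))
  expect_equal(W2[1, 2], 0, tolerance = 1e-10)
})

test_that("edge thresholding recovers separated blocks and hits extremes", {
  g <- grid_graph(1, 6)
  # three well-separated blocks along a path
  z_true <- c(1, 1, 2, 2, 3, 3)
  set.seed(102)
  ds <- sample_connectivity(z_true, sigma = 0)
  W <- pairwise_dissimilarity(ds$D)
  expect_equal(nmi(local_similarity(W, g, 3), z_true), 1)
  expect_equal(local_similarity(W, g, 6)$k, 6L)      # below min edge weight
  expect_equal(local_similarity(W, g, 1)$k, 1L)      # above max
})

test_that("normalized cut bisects at a weak bridge and returns exactly k", {
  # two 2x3 grid halves joined by one bridge of dissimilar elements
  g <- grid_graph(2, 6)
  z_true <- rep(rep(1:2, each = 3), 2)
  set.seed(103)
  ds <- sample_connectivity(z_true, sigma = 0.05)
  W <- pairwise_dissimilarity(ds$D)
  set.seed(1)
  p <- normalized_cut(W, g, 2)
  expect_equal(p$k, 2L)
  expect_equal(nmi(p, z_true), 1)
  expect_true(assert_contiguous(p, g))
  # always exactly k clusters
  set.seed(2)
  for (k in c(3, 5, 8)) {
    pk <- normalized_cut(W, g, k)
    expect_equal(pk$k, k)
    expect_true(assert_contiguous(pk, g))
  }
})

test_that("region growing recovers noiseless blocks and survives constant input", {
  g <- grid_graph(1, 9)
  z_true <- rep(1:3, each = 3)
  set.seed(104)
  ds <- sample_connectivity(z_true, sigma = 0)
  W <- pairwise_dissimilarity(ds$D)
  expect_equal(nmi(region_growing(W, g, 3), z_true), 1)
  # all-equal dissimilarity: still k connected clusters
  W0 <- matrix(1, 9, 9); diag(W0) <- 0
  p <- region_growing(W0, g, 4)
  expect_equal(p$k, 4L)
  expect_true(assert_contiguous(p, g))
})

test_that("constrained Ward reproduces the brute-force merge sequence", {
  # Euclidean-realizable toy: 5 points on a line, path adjacency
  x <- c(0, 0.9, 3.1, 3.2, 7)
  W <- as.matrix(dist(x))
  g <- grid_graph(1, 5)
  tree <- ward_tree(W, g)
  oracle <- naive_constrained_ward(W, g, 1)
  # same sequence of merge costs implies the same hierarchy: compare the
  # partitions at every level
  for (k in 4:1) {
    want <- naive_constrained_ward(W, g, k)$labels
    expect_equal(cut_ward_tree(tree, k), parcellation(want)$labels)
  }
  expect_equal(ward_parcellation(W, g, 5)$labels, 1:5)  # K = N singletons
})

test_that("constrained Ward output is contiguous on random data", {
  set.seed(105)
  g <- grid_graph(5, 5)
  v <- matrix(rnorm(625), 25); v[lower.tri(v)] <- t(v)[lower.tri(v)]
  diag(v) <- 0
  W <- pairwise_dissimilarity(connectivity_matrix(v, symmetric = TRUE))
  for (k in c(2, 5, 12)) {
    p <- ward_parcellation(W, g, k)
    expect_equal(p$k, k)
    expect_true(assert_contiguous(p, g))
  }
})

test_that("random merging yields contiguous parcellations with the right k", {
  g <- grid_graph(4, 4)
  set.seed(106)
  expect_equal(random_parcellation(g, 16)$k, 16L)
  expect_equal(random_parcellation(g, 1)$k, 1L)
  for (rep in 1:20) {
    p <- random_parcellation(g, 5)
    expect_equal(p$k, 5L)
    expect_true(assert_contiguous(p, g))
  }
})

test_that("random-clustering NMI forms a null envelope well below recovery", {
  set.seed(107)
  gt <- grid_truth("nonuniform5")
  draws <- vapply(1:100, function(i)
    nmi(random_parcellation(gt$graph, 5), gt$truth), numeric(1))
  expect_lt(mean(draws) + 2 * sd(draws), 0.9)
  expect_gt(sd(draws), 0)
})

test_that("all methods recover the noiseless equal-size layout; random does not", {
  set.seed(108)
  gt <- grid_truth("squares9")
  ds <- sample_connectivity(gt$truth, sigma = 0)
  W <- pairwise_dissimilarity(ds$D)
  expect_equal(nmi(ward_parcellation(W, gt$graph, 9), gt$truth), 1)
  expect_equal(nmi(local_similarity(W, gt$graph, 9), gt$truth), 1)
  expect_equal(nmi(region_growing(W, gt$graph, 9), gt$truth), 1)
  set.seed(5)
  expect_equal(nmi(normalized_cut(W, gt$graph, 9), gt$truth), 1)
  set.seed(6)
  expect_lt(nmi(random_parcellation(gt$graph, 9), gt$truth), 1)
})

test_that("the method dispatcher honours the shared interface", {
  set.seed(109)
  gt <- grid_truth("squares9")
  ds <- sample_connectivity(gt$truth, sigma = 0.3)
  for (m in c("ward", "local", "grow")) {
    p <- baseline_parcellation(ds$D, gt$graph, 9, method = m)
    expect_equal(p$k, 9L)
    expect_true(assert_contiguous(p, gt$graph))
  }
})
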