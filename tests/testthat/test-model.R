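test_that("dd-CRP prior gives the analytic per-element link probabilities", {
  # centre of a 3x3 grid has 4 neighbours; alpha = 10 => self 10/14, each 1/14
  g <- grid_graph(3, 3)
  h <- hyperparams(0.01, alpha = 10)
  base <- rep(5L, 9)  # placeholder: build states differing only in link 5
  links_self <- seq_len(9)
  lp_self <- log_ddcrp_prior(links_self, g, h)
  links_nb <- links_self; links_nb[5] <- 2L
  lp_nb <- log_ddcrp_prior(links_nb, g, h)
  expect_equal(exp(lp_self - lp_nb), 10, tolerance = 1e-12)
  # absolute value of the element-5 factor: alpha/(alpha + degree)
  # total prior factorizes, so compare against the direct product
  direct <- sum(log(10) - log(10 + lengths(g$neighbors)))
  expect_equal(lp_self, direct, tolerance = 1e-12)
})

test_that("links outside the neighbour relation have probability zero", {
  g <- path4()
  h <- hyperparams(0.01, alpha = 1)
  expect_identical(log_ddcrp_prior(c(3, 2, 3, 4), g, h), -Inf)
  h0 <- hyperparams(0.01, alpha = 0)
  expect_identical(log_ddcrp_prior(c(1, 1, 2, 3), g, h0), -Inf)  # self @ a=0
})

test_that("dd-CRP prior is normalized over all valid link states", {
  for (g in list(grid_graph(1, 3), grid_graph(2, 2), grid_graph(1, 4))) {
    for (alpha in c(0.5, 1, 10)) {
      h <- hyperparams(0.01, alpha = alpha)
      states <- enumerate_link_states(g)
      tot <- sum(apply(states, 1, function(s)
        exp(log_ddcrp_prior(as.integer(s), g, h))))
      expect_equal(tot, 1, tolerance = 1e-12)
    }
  }
})

test_that("block statistics match the brute-force oracle", {
  # worked example: one parcel, symmetric 3x3 with upper triangle {1, 2, 4}
  v <- matrix(0, 3, 3)
  v[upper.tri(v)] <- c(1, 2, 4)
  v <- v + t(v)
  st <- block_stats(connectivity_matrix(v, symmetric = TRUE), rep(1, 3))
  expect_equal(st$L[1, 1], 3)
  expect_equal(st$mean[1, 1], 7 / 3)
  expect_equal(st$ss[1, 1], 14 / 3)

  # singleton parcels, asymmetric: every cross block has L = 1, ss = 0
  set.seed(5)
  va <- matrix(rnorm(16), 4)
  sta <- block_stats(connectivity_matrix(va, symmetric = FALSE), 1:4)
  expect_true(all(sta$L[row(sta$L) != col(sta$L)] == 1))
  expect_true(all(sta$ss == 0))

  # random partitions, both symmetry modes, against the naive loop oracle
  for (symmetric in c(TRUE, FALSE)) {
    for (rep in 1:5) {
      n <- 7
      v <- matrix(rnorm(n * n), n)
      if (symmetric) v[lower.tri(v)] <- t(v)[lower.tri(v)]
      diag(v) <- 0
      z <- parcellation(sample(1:3, n, replace = TRUE))$labels
      D <- connectivity_matrix(v, symmetric = symmetric)
      st <- block_stats(D, z)
      oracle <- naive_block_stats(v, z, symmetric)
      for (key in names(oracle)) {
        mn <- as.integer(strsplit(key, " ")[[1]])
        expect_equal(st$L[mn[1], mn[2]], oracle[[key]]$L)
        expect_equal(st$mean[mn[1], mn[2]], oracle[[key]]$mean,
                     tolerance = 1e-10)
        expect_equal(st$ss[mn[1], mn[2]], oracle[[key]]$ss,
                     tolerance = 1e-10)
      }
      # the blocks partition the included entries
      keep <- if (symmetric) upper.tri(st$L, diag = TRUE) else
        matrix(TRUE, nrow(st$L), ncol(st$L))
      expect_equal(sum(st$L[keep]),
                   if (symmetric) n * (n - 1) / 2 else n * (n - 1))
    }
  }
})

test_that("closed-form block marginal matches 2-D quadrature", {
  expect_identical(log_marginal_block(0, 0, 0, hyperparams(1)), 0)
  set.seed(21)
  for (rep in 1:20) {
    L <- sample(1:5, 1)
    x <- round(rnorm(L, sd = 1.5), 2)
    mu0 <- runif(1, -1, 1); kappa0 <- runif(1, 0.01, 2)
    s0 <- runif(1, 0.1, 2); nu0 <- runif(1, 0.5, 3)
    h <- hyperparams(s0, mu0 = mu0, kappa0 = kappa0, nu0 = nu0)
    got <- log_marginal_block(L, mean(x), sum((x - mean(x))^2), h)
    want <- quad_log_marginal(x, mu0, kappa0, s0, nu0)
    expect_equal(got, want, tolerance = 1e-7)  # >= 6 significant digits
  }
  # worked case from the quadrature oracle: data {-1, 0, 1}
  h <- hyperparams(1, mu0 = 0, kappa0 = 1e-4, nu0 = 1)
  got <- log_marginal_block(3, 0, 2, h)
  want <- quad_log_marginal(c(-1, 0, 1), 0, 1e-4, 1, 1)
  expect_equal(got, want, tolerance = 1e-7)
})

test_that("marginal decreases as the block mean moves from the prior mean", {
  h <- hyperparams(0.5, mu0 = 0, kappa0 = 5, nu0 = 1)
  vals <- log_marginal_block(4, c(0, 0.5, 1, 2), 1.3, h)
  expect_true(all(diff(vals) < 0))
})

test_that("merging block statistics equals direct computation on pooled data", {
  # worked example: {1, 2} pooled with {4}
  m <- merge_block_stats(2, 1.5, 0.5, 1, 4, 0)
  expect_equal(m$L, 3)
  expect_equal(m$mean, 7 / 3, tolerance = 1e-12)
  expect_equal(m$ss, 14 / 3, tolerance = 1e-12)
  # empty-block identity
  m0 <- merge_block_stats(0, 0, 0, 5, 2.2, 3.3)
  expect_equal(m0, list(L = 5, mean = 2.2, ss = 3.3))

  set.seed(8)
  for (rep in 1:50) {
    x1 <- rnorm(sample(0:6, 1)); x2 <- rnorm(sample(1:6, 1))
    st <- function(x) if (!length(x)) c(0, 0, 0) else
      c(length(x), mean(x), sum((x - mean(x))^2))
    a <- st(x1); b <- st(x2); ab <- st(c(x1, x2))
    m <- merge_block_stats(a[1], a[2], a[3], b[1], b[2], b[3])
    expect_equal(c(m$L, m$mean, m$ss), ab, tolerance = 1e-10)
    # commutativity
    m2 <- merge_block_stats(b[1], b[2], b[3], a[1], a[2], a[3])
    expect_equal(m, m2, tolerance = 1e-10)
    # associativity
    x3 <- rnorm(sample(1:6, 1)); cst <- st(x3)
    left <- merge_block_stats(m$L, m$mean, m$ss, cst[1], cst[2], cst[3])
    mbc <- merge_block_stats(b[1], b[2], b[3], cst[1], cst[2], cst[3])
    right <- merge_block_stats(a[1], a[2], a[3], mbc$L, mbc$mean, mbc$ss)
    expect_equal(left, right, tolerance = 1e-10)
  }
})

test_that("partition score is a sum of block marginals, invariant to relabeling", {
  set.seed(10)
  v <- matrix(rnorm(36), 6); diag(v) <- 0
  D <- connectivity_matrix(v, symmetric = FALSE)
  h <- hyperparams(0.3)
  z <- c(1, 1, 2, 2, 3, 3)
  st <- block_stats(D, z)
  expect_equal(log_model(D, z, h),
               sum(log_marginal_block(st$L, st$mean, st$ss, h)))
  zperm <- c(3, 3, 1, 1, 2, 2)
  expect_equal(log_model(D, zperm, h), log_model(D, z, h), tolerance = 1e-10)
})

test_that("exhaustive scoring ranks the generating split highest at low noise", {
  # 6-element path, two parcels of three; sigma = 0.01
  g <- grid_graph(1, 6)
  z_true <- c(1, 1, 1, 2, 2, 2)
  set.seed(14)
  ds <- sample_connectivity(z_true, sigma = 0.01)
  h <- hyperparams(0.01)
  # all contiguous 2-parcellations of a path: 5 cut positions
  scores <- vapply(1:5, function(cut)
    log_model(ds$D, rep(1:2, c(cut, 6 - cut)), h), numeric(1))
  expect_equal(which.max(scores), 3L)
})

test_that("pooling parcels through merged statistics reproduces the merged score", {
  set.seed(17)
  for (symmetric in c(TRUE, FALSE)) {
    n <- 9
    v <- matrix(rnorm(n * n), n)
    if (symmetric) v[lower.tri(v)] <- t(v)[lower.tri(v)]
    diag(v) <- 0
    D <- connectivity_matrix(v, symmetric = symmetric)
    h <- hyperparams(0.7)
    for (rep in 1:20) {
      z <- parcellation(sample(1:4, n, replace = TRUE))$labels
      if (max(z) < 2) next
      ab <- sample(max(z), 2)
      zm <- z; zm[zm == ab[2]] <- ab[1]
      # merged-score identity: sum over pooled blocks == score of merged z
      st <- block_stats(D, z)
      stm <- block_stats(D, zm)
      expect_equal(sum_pooled_score(st, ab[1], ab[2], h, symmetric),
                   log_model(D, zm, h), tolerance = 1e-8)
    }
  }
})
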