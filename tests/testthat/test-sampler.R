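# direct access to sampler internals for oracle checks
mk_state <- function(links, graph, hyper, D) {
  dat <- ddparcel:::.sampler_data(D)
  list(state = ddparcel:::.state_init(links, graph, hyper, dat), dat = dat)
}

test_that("link removal reproduces the from-scratch induced partition", {
  set.seed(31)
  g <- grid_graph(4, 5)
  h <- hyperparams(0.5)
  v <- matrix(rnorm(g$n^2), g$n)
  v[lower.tri(v)] <- t(v)[lower.tri(v)]; diag(v) <- 0
  D <- connectivity_matrix(v, symmetric = TRUE)
  for (rep in 1:100) {
    links <- random_valid_links(g)
    i <- sample.int(g$n, 1)
    s <- mk_state(links, g, h, D)
    out <- ddparcel:::.split_on_removal(s$state, i, g, h, s$dat)
    links2 <- links; links2[i] <- i
    want <- connected_components(links2, g)
    expect_equal(parcellation(out$z)$labels, want$labels)
    # refreshed caches agree with a full recomputation
    fresh <- ddparcel:::.state_init(links2, g, h, s$dat)
    perm <- match(parcellation(fresh$z)$labels, parcellation(out$z)$labels)
    expect_equal(sort(as.vector(out$L)), sort(as.vector(fresh$L)))
    expect_equal(ddparcel:::.state_log_marginal(out, s$dat),
                 ddparcel:::.state_log_marginal(fresh, s$dat),
                 tolerance = 1e-8)
  }
  # removing a self-link leaves the partition unchanged
  links <- random_valid_links(g)
  i <- which(links == seq_len(g$n))[1]
  if (!is.na(i)) {
    s <- mk_state(links, g, h, D)
    out <- ddparcel:::.split_on_removal(s$state, i, g, h, s$dat)
    expect_equal(out$z, s$state$z)
  }
  # removing the middle link of a 3-chain splits the parcel
  g3 <- grid_graph(1, 3)
  v3 <- matrix(rnorm(9), 3); diag(v3) <- 0
  s3 <- mk_state(c(2, 3, 3), g3, hyperparams(1),
                 connectivity_matrix(v3, symmetric = FALSE))
  out3 <- ddparcel:::.split_on_removal(s3$state, 2L, g3, hyperparams(1), s3$dat)
  expect_equal(out3$K, s3$state$K + 1L)
})

test_that("Gibbs candidate probabilities match full model recomputation", {
  g <- path4()
  h <- hyperparams(0.2, alpha = 3)
  for (symmetric in c(FALSE, TRUE)) {
    D <- fixed_D4(symmetric)
    set.seed(55)
    for (rep in 1:20) {
      links <- random_valid_links(g)
      i <- sample.int(4, 1)
      s <- mk_state(links, g, h, D)
      cd <- ddparcel:::.candidates(s$state, i, g, h, s$dat)
      # oracle: score every candidate by full prior + likelihood recompute
      full <- vapply(cd$candidates, function(v) {
        l2 <- links; l2[i] <- v
        log_ddcrp_prior(l2, g, h) +
          log_model(D, connected_components(l2, g), h)
      }, numeric(1))
      # compare normalized log-probabilities
      lw <- cd$lw - max(cd$lw)
      fw <- full - max(full)
      expect_equal(lw - log(sum(exp(lw))), fw - log(sum(exp(fw))),
                   tolerance = 1e-8)
    }
  }
})

test_that("overwhelming alpha forces self-links", {
  g <- grid_graph(2, 3)
  h <- hyperparams(0.5, alpha = 1e100)  # log alpha dwarfs any likelihood ratio here
  set.seed(3)
  v <- matrix(rnorm(36), 6); diag(v) <- 0
  s <- mk_state(random_valid_links(g), g, h, connectivity_matrix(v, FALSE))
  st <- s$state
  set.seed(4)
  for (i in 1:6) st <- ddparcel:::.gibbs_step(st, i, g, h, s$dat)
  expect_equal(st$links, 1:6)
  expect_equal(st$K, 6L)
})

test_that("initialization reproduces the requested structure", {
  set.seed(61)
  gt <- grid_truth("squares9")
  ds <- sample_connectivity(gt$truth, sigma = 0.2)
  Dn <- normalize_matrix(ds$D)
  h <- hyperparams(0.01)
  # fixed-K ward init: induced labels equal the constrained-Ward labels
  st <- sampler_init(Dn, gt$graph, h, init = "ward-k", k_init = 9)
  W <- pairwise_dissimilarity(Dn)
  zw <- ward_parcellation(W, gt$graph, 9)
  expect_equal(connected_components(st$links, gt$graph)$labels, zw$labels)
  # K = N: all self-links realize the all-singleton parcellation
  stN <- sampler_init(Dn, gt$graph, h, init = "ward-k", k_init = gt$graph$n)
  expect_equal(stN$links, seq_len(gt$graph$n))
  # random init is valid and contiguous
  str <- sampler_init(Dn, gt$graph, h, init = "random")
  expect_true(assert_contiguous(parcellation(str$z), gt$graph))
  # disconnected graph is rejected
  g2 <- spatial_graph(rbind(c(1, 2), c(3, 4)), 4)
  expect_error(sampler_init(fixed_D4(), g2, h), "connected")
})

test_that("spanning-tree construction is uniform over the 2x3 grid trees", {
  # the 2x3 grid has 15 spanning trees; 200 draws should see every one
  g <- grid_graph(2, 3)
  set.seed(71)
  seen <- character(0)
  for (rep in 1:200) {
    links <- links_from_labels(rep(1, 6), g)
    edges <- t(apply(cbind(seq_len(6), links), 1, sort))
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    key <- paste(sort(paste(edges[, 1], edges[, 2])), collapse = ";")
    expect_equal(connected_components(links, g)$k, 1L)
    seen <- union(seen, key)
  }
  expect_equal(length(seen), 15L)
})

test_that("the sampler is reproducible, monotone in MAP and drift-free", {
  set.seed(81)
  gt <- grid_truth("squares9")
  ds <- sample_connectivity(gt$truth, sigma = 0.8)
  Dn <- normalize_matrix(ds$D)
  h <- hyperparams(0.01)
  set.seed(5)
  st0 <- sampler_init(Dn, gt$graph, h)
  lp0 <- ddparcel:::.state_log_posterior(st0, gt$graph, h,
                                         ddparcel:::.sampler_data(Dn))
  set.seed(6)
  r1 <- run_sampler(Dn, gt$graph, h, passes = 3, state = st0,
                    record_trace = TRUE, check_each_pass = TRUE)
  expect_gte(r1$map$log_posterior, lp0)
  expect_lt(r1$max_drift, 1e-6)
  set.seed(6)
  r2 <- run_sampler(Dn, gt$graph, h, passes = 3, state = st0)
  expect_equal(r1$map$labels$labels, r2$map$labels$labels)
  expect_equal(r1$map$log_posterior, r2$map$log_posterior)
  # trace bookkeeping
  expect_equal(nrow(r1$trace), 3 * gt$graph$n)
  expect_true(all(diff(cummax(r1$trace$log_posterior)) >= 0))
  # every visited state is contiguous: final state check as proxy plus MAP
  expect_true(assert_contiguous(r1$map$labels, gt$graph))
  expect_true(assert_contiguous(parcellation(r1$final$z), gt$graph))
})

test_that("gibbs chain frequencies match the exhaustive posterior (4-path)", {
  g <- path4()
  h <- hyperparams(0.5, alpha = 2)
  set.seed(91)
  v <- matrix(rnorm(16, sd = 0.3), 4); diag(v) <- 0
  D <- connectivity_matrix(v, symmetric = FALSE)
  # exhaustive posterior over all valid link states
  states <- enumerate_link_states(g)
  lp <- apply(states, 1, function(s) {
    s <- as.integer(s)
    log_ddcrp_prior(s, g, h) + log_model(D, connected_components(s, g), h)
  })
  post <- exp(lp - max(lp)); post <- post / sum(post)
  keys <- apply(states, 1, paste, collapse = ",")
  # random-scan Gibbs chain
  s <- mk_state(random_valid_links(g), g, h, D)
  st <- s$state
  n_steps <- 2e5
  counts <- integer(length(keys)); names(counts) <- keys
  set.seed(92)
  is <- sample.int(4, n_steps, replace = TRUE)
  for (t in seq_len(n_steps)) {
    st <- ddparcel:::.gibbs_step(st, is[t], g, h, s$dat)
    k <- paste(st$links, collapse = ",")
    counts[k] <- counts[k] + 1L
  }
  freq <- counts / n_steps
  se <- sqrt(post * (1 - post) / n_steps)
  # single-site Gibbs is autocorrelated; allow for that in the error bars
  ess_deflation <- 5
  expect_true(all(abs(freq - post) <= 3 * sqrt(ess_deflation) * se + 1e-4))
})
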