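# Independent reference implementations used as oracles.  These are written
# for clarity (loops, quadrature, exhaustive enumeration) and deliberately
# share no code with the package internals they check.

# brute-force block sufficient statistics by explicit loops over the
# included entries (diagonal excluded; upper triangle only when symmetric,
# blocks then keyed by the unordered parcel pair)
naive_block_stats <- function(vals, z, symmetric) {
  n <- nrow(vals)
  data <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (symmetric && j < i) next
    key <- if (symmetric) paste(min(z[i], z[j]), max(z[i], z[j]))
           else paste(z[i], z[j])
    data[[key]] <- c(data[[key]], vals[i, j])
  }
  lapply(data, function(xs)
    list(L = length(xs), mean = mean(xs), ss = sum((xs - mean(xs))^2)))
}

# 2-D quadrature of the Normal x NIchi2 integral (marginal likelihood)
quad_log_marginal <- function(x, mu0, kappa0, sigma0_sq, nu0) {
  L <- length(x)
  if (L == 0) return(0)
  f_inner <- function(s2) vapply(s2, function(v) {
    g <- function(A) {
      ll <- vapply(A, function(a) sum(dnorm(x, a, sqrt(v), log = TRUE)),
                   numeric(1))
      exp(ll) * dnorm(A, mu0, sqrt(v / kappa0))
    }
    dens_s2 <- ((nu0 / 2)^(nu0 / 2) / gamma(nu0 / 2)) * sigma0_sq^(nu0 / 2) *
      v^(-(nu0 / 2 + 1)) * exp(-nu0 * sigma0_sq / (2 * v))
    integrate(g, -Inf, Inf, rel.tol = 1e-10)$value * dens_s2
  }, numeric(1))
  log(integrate(f_inner, 0, Inf, rel.tol = 1e-10)$value)
}

# exhaustive enumeration of all valid link states of a small graph
enumerate_link_states <- function(graph) {
  cand <- lapply(seq_len(graph$n), function(i) c(i, graph$neighbors[[i]]))
  as.matrix(expand.grid(cand))
}

# draw one uniformly random *valid* link state (each link uniform over its
# candidate set; support of the dd-CRP prior)
random_valid_links <- function(graph) {
  vapply(seq_len(graph$n), function(i) {
    cand <- c(i, graph$neighbors[[i]])
    cand[sample.int(length(cand), 1L)]
  }, integer(1))
}

# Ward merge cost between two groups from squared pairwise Euclidean
# distances (identity: mean cross d^2 minus within-scatter terms)
ward_group_cost <- function(W2, A, B) {
  nA <- length(A); nB <- length(B)
  VA <- sum(W2[A, A]) / (2 * nA^2)
  VB <- sum(W2[B, B]) / (2 * nB^2)
  between <- sum(W2[A, B]) / (nA * nB) - VA - VB
  2 * nA * nB / (nA + nB) * between
}

# brute-force spatially constrained Ward: recompute every candidate merge
# cost from scratch at each step
naive_constrained_ward <- function(W, graph, k) {
  W2 <- W^2
  z <- seq_len(graph$n)
  merge_log <- list()
  while (max(z) > k) {
    labs <- sort(unique(z))
    best <- c(Inf, 0, 0)
    for (ai in seq_along(labs)) for (bi in seq_len(ai - 1L)) {
      A <- which(z == labs[ai]); B <- which(z == labs[bi])
      adjacent <- any(apply(graph$edges, 1, function(e)
        (z[e[1]] == labs[ai] & z[e[2]] == labs[bi]) |
        (z[e[2]] == labs[ai] & z[e[1]] == labs[bi])))
      if (!adjacent) next
      cost <- ward_group_cost(W2, A, B)
      if (cost < best[1]) best <- c(cost, labs[bi], labs[ai])
    }
    merge_log[[length(merge_log) + 1L]] <- best
    z[z == best[3]] <- best[2]
    z <- match(z, sort(unique(z)))
  }
  list(labels = z, merges = merge_log)
}

# total partition score after merging parcels a and b, built only from the
# exported primitives (block_stats output + merge_block_stats +
# log_marginal_block); checks the pooled-update identity
sum_pooled_score <- function(st, a, b, h, symmetric) {
  K <- nrow(st$L)
  q <- setdiff(seq_len(K), c(a, b))
  lm <- function(L, m, s) sum(log_marginal_block(L, m, s, h))
  total <- 0
  if (symmetric) {
    if (length(q) > 1) {
      keep <- upper.tri(st$L, diag = TRUE)[q, q]
      total <- total + lm(st$L[q, q][keep], st$mean[q, q][keep],
                          st$ss[q, q][keep])
    } else if (length(q) == 1) {
      total <- total + lm(st$L[q, q], st$mean[q, q], st$ss[q, q])
    }
    if (length(q)) {
      mg <- merge_block_stats(st$L[q, a], st$mean[q, a], st$ss[q, a],
                              st$L[q, b], st$mean[q, b], st$ss[q, b])
      total <- total + lm(mg$L, mg$mean, mg$ss)
    }
    w <- merge_block_stats(st$L[a, a], st$mean[a, a], st$ss[a, a],
                           st$L[b, b], st$mean[b, b], st$ss[b, b])
    w <- merge_block_stats(w$L, w$mean, w$ss,
                           st$L[a, b], st$mean[a, b], st$ss[a, b])
    total + lm(w$L, w$mean, w$ss)
  } else {
    if (length(q)) {
      total <- total + lm(st$L[q, q], st$mean[q, q], st$ss[q, q])
      r <- merge_block_stats(st$L[a, q], st$mean[a, q], st$ss[a, q],
                             st$L[b, q], st$mean[b, q], st$ss[b, q])
      cl <- merge_block_stats(st$L[q, a], st$mean[q, a], st$ss[q, a],
                              st$L[q, b], st$mean[q, b], st$ss[q, b])
      total <- total + lm(r$L, r$mean, r$ss) + lm(cl$L, cl$mean, cl$ss)
    }
    w <- merge_block_stats(st$L[a, a], st$mean[a, a], st$ss[a, a],
                           st$L[b, b], st$mean[b, b], st$ss[b, b])
    w <- merge_block_stats(w$L, w$mean, w$ss,
                           st$L[a, b], st$mean[a, b], st$ss[a, b])
    w <- merge_block_stats(w$L, w$mean, w$ss,
                           st$L[b, a], st$mean[b, a], st$ss[b, a])
    total + lm(w$L, w$mean, w$ss)
  }
}

# contingency-table NMI from first principles (natural logs)
naive_nmi <- function(a, b) {
  N <- length(a)
  ta <- table(a); tb <- table(b)
  I <- 0
  for (h in names(ta)) for (l in names(tb)) {
    nhl <- sum(a == h & b == l)
    if (nhl > 0) I <- I + nhl * log(N * nhl / (ta[[h]] * tb[[l]]))
  }
  Ha <- -sum(ta * log(ta / N)); Hb <- -sum(tb * log(tb / N))
  I / sqrt(Ha * Hb)
}

# small fixture: 4-element path graph and a fixed asymmetric matrix
path4 <- function() grid_graph(1, 4)

fixed_D4 <- function(symmetric = FALSE) {
  set.seed(99)
  v <- matrix(rnorm(16), 4, 4)
  if (symmetric) {
    v[lower.tri(v)] <- t(v)[lower.tri(v)]
  }
  diag(v) <- 0
  connectivity_matrix(v, symmetric = symmetric, diagonal_defined = FALSE)
}
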