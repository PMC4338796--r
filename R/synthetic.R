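# Synthetic benchmarks: ground-truth layouts on an 18 x 18 grid, the
# block-Normal connectivity sampler, and a three-spiral geometry.

#' Ground-truth grid layouts
#'
#' Three fixed parcellations of an 18 x 18 4-neighbour grid, used as
#' recovery benchmarks:
#' * `"squares9"` -- a 3 x 3 arrangement of 6 x 6 squares (K = 9, all
#'   parcels equal size 36);
#' * `"stripes6"` -- horizontal stripes of heights 6, 4, 3, 2, 2, 1
#'   (K = 6, sizes 108, 72, 54, 36, 36, 18; the two smallest stripes are
#'   adjacent);
#' * `"nonuniform5"` -- one large L-shaped region plus four rectangles of
#'   sizes 96, 48, 24 and 12 (K = 5, sizes 144, 96, 48, 24, 12).
#'
#' The layouts are versioned constants of this package: benchmark results
#' are reproducible against them.
#'
#' @param layout one of `"squares9"`, `"nonuniform5"`, `"stripes6"`.
#' @return List with `graph` (a [grid_graph()]) and `truth`
#'   (a [parcellation()]).
#' @examples
#' gt <- grid_truth("squares9")
#' table(gt$truth$labels)
#' @export
grid_truth <- function(layout = c("squares9", "nonuniform5", "stripes6")) {
  layout <- match.arg(layout)
  n <- 18L
  g <- grid_graph(n, n)
  r <- rep(seq_len(n), each = n)   # row of element (row-major layout)
  c <- rep(seq_len(n), times = n)
  z <- switch(layout,
    squares9 = 3L * ((r - 1L) %/% 6L) + (c - 1L) %/% 6L + 1L,
    stripes6 = {
      heights <- c(6L, 4L, 3L, 2L, 2L, 1L)
      findInterval(r, cumsum(c(0L, heights)) + 1L)
    },
    nonuniform5 = {
      z <- integer(n * n)
      z[c <= 6L | r >= 16L] <- 1L                      # L-shape, 144
      z[z == 0L & r <= 8L] <- 2L                       # 96
      z[z == 0L & r <= 12L] <- 3L                      # 48
      z[z == 0L & c <= 14L] <- 4L                      # 24 (rows 13-15)
      z[z == 0L] <- 5L                                 # 12
      z
    })
  list(graph = g, truth = parcellation(z))
}

#' Sample a block-Normal connectivity matrix
#'
#' Generative model for synthetic benchmarks: a `K x K` matrix of block
#' means `A` with i.i.d. standard normal entries (symmetrized when a
#' symmetric matrix is requested), and each included connectivity entry
#' drawn independently `D_ij ~ Normal(A[z_i, z_j], sigma^2)`.  At
#' `sigma = 0` every block of `D` is constant.  Uses the current R random
#' stream; call `set.seed()` for reproducibility.
#'
#' @param truth a [parcellation()] or label vector.
#' @param sigma noise standard deviation (>= 0).
#' @param symmetric generate a symmetric matrix (the default, matching
#'   correlation-type data); set `FALSE` for a fully asymmetric one.
#' @return List with `D` (a [connectivity_matrix()], diagonal excluded),
#'   `A` (block means), `truth`, `sigma`.
#' @export
sample_connectivity <- function(truth, sigma, symmetric = TRUE) {
  stopifnot(sigma >= 0)
  z <- as_parcellation(truth)$labels
  K <- max(z)
  n <- length(z)
  A <- matrix(stats::rnorm(K * K), K, K)
  if (symmetric) A[lower.tri(A)] <- t(A)[lower.tri(A)]
  M <- A[cbind(rep(z, times = n), rep(z, each = n))]
  dim(M) <- c(n, n)
  if (symmetric) {
    up <- upper.tri(M)
    vals <- matrix(0, n, n)
    vals[up] <- M[up] + stats::rnorm(sum(up), 0, sigma)
    vals <- vals + t(vals)
  } else {
    vals <- M + matrix(stats::rnorm(n * n, 0, sigma), n, n)
  }
  diag(vals) <- 0
  list(D = connectivity_matrix(vals, symmetric = symmetric,
                               diagonal_defined = FALSE),
       A = A, truth = as_parcellation(truth), sigma = sigma)
}

#' Three-spiral ground truth
#'
#' Three interleaved Archimedean spiral arms of `n_per_arm` points each
#' (radius `r = r0 + b * theta`, arms offset by 120 degrees).  Elements are
#' adjacent if consecutive along an arm or nearest cross-spiral neighbours
#' (each point is linked to its nearest point on each of the other two
#' arms).  Ground truth is arm membership (K = 3).
#'
#' @param n_per_arm points per arm (>= 3).
#' @param turns number of full turns each arm makes (geometry constant).
#' @param r0,b spiral radius offset and growth rate (geometry constants).
#' @return List with `graph` (a [spatial_graph()] carrying a `coords`
#'   attribute), `truth` (a [parcellation()]).
#' @export
spiral_truth <- function(n_per_arm, turns = 1.5, r0 = 0.5, b = 1) {
  stopifnot(n_per_arm >= 3)
  theta <- seq(0, turns * 2 * pi, length.out = n_per_arm)
  coords <- NULL
  for (arm in 0:2) {
    phi <- theta + arm * 2 * pi / 3
    r <- r0 + b * theta
    coords <- rbind(coords, cbind(r * cos(phi), r * sin(phi)))
  }
  n <- 3L * n_per_arm
  z <- rep(1:3, each = n_per_arm)
  within <- NULL
  for (arm in 0:2) {
    o <- arm * n_per_arm
    within <- rbind(within, cbind(o + seq_len(n_per_arm - 1L),
                                  o + seq_len(n_per_arm - 1L) + 1L))
  }
  cross <- NULL
  for (i in seq_len(n)) {
    for (arm in setdiff(1:3, z[i])) {
      idx <- which(z == arm)
      d2 <- rowSums((coords[idx, , drop = FALSE] -
                       matrix(coords[i, ], length(idx), 2, byrow = TRUE))^2)
      cross <- rbind(cross, c(i, idx[which.min(d2)]))
    }
  }
  g <- spatial_graph(rbind(within, cross), n = n)
  attr(g, "coords") <- coords
  list(graph = g, truth = parcellation(z))
}

#' Noise sweep over layouts, noise levels and methods
#'
#' For each (layout, sigma, replicate): generate a synthetic dataset, fit
#' the dd-CRP model, then run each baseline at the number of clusters the
#' model inferred, and score every method's NMI with the ground truth.
#'
#' @param layouts character vector of [grid_truth()] layout names.
#' @param sigmas numeric vector of noise levels.
#' @param n_reps replicates per condition.
#' @param methods character vector from `"model"`, `"ward"`, `"local"`,
#'   `"ncut"`, `"grow"`, `"random"`.
#' @param sigma0_sq,passes model settings passed to [parcellate()].
#' @param seed integer seed for the whole sweep.
#' @return A tidy data.frame with one row per
#'   (layout, sigma, replicate, method): columns `layout`, `sigma`, `rep`,
#'   `method`, `k`, `nmi`.
#' @export
noise_sweep <- function(layouts, sigmas, n_reps,
                        methods = c("model", "ward"),
                        sigma0_sq = 0.01, passes = 30, seed = 1) {
  stopifnot(all(methods %in% c("model", "ward", "local", "ncut", "grow",
                               "random")))
  out <- list()
  set.seed(seed)
  for (layout in layouts) {
    gt <- grid_truth(layout)
    for (sigma in sigmas) {
      for (rep_i in seq_len(n_reps)) {
        ds <- sample_connectivity(gt$truth, sigma)
        Dn <- normalize_matrix(ds$D)
        fit <- parcellate(Dn, gt$graph, sigma0_sq = sigma0_sq,
                          passes = passes, normalize = FALSE)
        k_hat <- fit$k
        W <- NULL
        for (method in methods) {
          p <- if (method == "model") fit$parcellation
          else if (method == "random") random_parcellation(gt$graph, k_hat)
          else {
            if (is.null(W)) W <- pairwise_dissimilarity(Dn)
            switch(method,
                   ward = ward_parcellation(W, gt$graph, k_hat),
                   local = suppressWarnings(
                     local_similarity(W, gt$graph, k_hat)),
                   ncut = normalized_cut(W, gt$graph, k_hat),
                   grow = region_growing(W, gt$graph, k_hat))
          }
          out[[length(out) + 1L]] <- data.frame(
            layout = layout, sigma = sigma, rep = rep_i, method = method,
            k = p$k, nmi = nmi(p, gt$truth))
        }
      }
    }
  }
  do.call(rbind, out)
}
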