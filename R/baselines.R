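# Spatially constrained comparison methods.  All operate on the
# connectivity-fingerprint dissimilarity W (pairwise_dissimilarity) and a
# spatial graph, and return exactly K contiguous parcels (local similarity
# warns when K is unattainable by thresholding alone and repairs by merging).

# dissimilarities along the graph edges
edge_weights <- function(W, graph) {
  W[graph$edges]
}

# merge the smallest clusters into their most similar spatial neighbour
# cluster until exactly k remain (repair used by several methods)
.repair_to_k <- function(z, W, graph, k) {
  z <- as_parcellation(z)$labels
  while (max(z) > k) {
    sizes <- tabulate(z, max(z))
    small <- which.min(sizes)
    e <- graph$edges
    touch <- z[e[, 1L]] == small | z[e[, 2L]] == small
    nb_lab <- setdiff(unique(c(z[e[touch, 1L]], z[e[touch, 2L]])), small)
    if (!length(nb_lab)) stop("cannot repair: isolated cluster")
    # most similar neighbour cluster by mean squared fingerprint distance
    msd <- vapply(nb_lab, function(l)
      mean(W[z == small, z == l, drop = FALSE]^2), numeric(1))
    tgt <- nb_lab[which.min(msd)]
    z[z == small] <- tgt
    z <- match(z, sort(unique(z)))
  }
  parcellation(z)
}

#' Local-similarity (edge-thresholding) parcellation
#'
#' Removes all spatial edges whose fingerprint dissimilarity exceeds a
#' threshold and takes connected components; the threshold is searched over
#' the sorted edge dissimilarities for the smallest value giving at least
#' `k` components (equivalent to spatially constrained single linkage).  If
#' no threshold hits `k` exactly, the nearest achievable solution is
#' repaired by merging the smallest adjacent components, with a warning.
#'
#' @param W dissimilarity matrix from [pairwise_dissimilarity()].
#' @param graph a connected [spatial_graph()].
#' @param k target number of clusters.
#' @return A [parcellation()].
#' @export
local_similarity <- function(W, graph, k) {
  stopifnot(k >= 1, k <= graph$n)
  ew <- edge_weights(W, graph)
  thr <- c(-Inf, sort(unique(ew)), Inf)   # -Inf keeps all edges out (k = N)
  # number of components is non-increasing in the threshold: binary search
  ncomp_at <- function(t) {
    keep <- ew <= t
    max(comp_of_edges(graph$n, graph$edges[keep, , drop = FALSE]))
  }
  lo <- 1L; hi <- length(thr)       # ncomp(thr[hi]) <= k <= ncomp(thr[lo])
  if (ncomp_at(thr[hi]) > k) {
    z <- comp_of_edges(graph$n, graph$edges)
    warning("graph has more than k components")
    return(parcellation(z))
  }
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (ncomp_at(thr[mid]) >= k) lo <- mid else hi <- mid
  }
  t_star <- if (ncomp_at(thr[lo]) >= k) thr[lo] else thr[hi]
  z <- comp_of_edges(graph$n,
                     graph$edges[ew <= t_star, , drop = FALSE])
  if (max(z) != k) {
    warning("exact k unattainable by thresholding; merging ",
            max(z) - k, " smallest components")
    return(.repair_to_k(z, W, graph, k))
  }
  parcellation(z)
}

#' Normalized-cut parcellation
#'
#' Builds the neighbour similarity graph `S = 1/W` on spatial edges (capped
#' at `1e12` where `W = 0`), embeds the elements with the `k` leading
#' eigenvectors of the symmetric normalized affinity, discretizes by
#' k-means on the row-normalized embedding, then splits any spatially
#' disconnected cluster and repairs the count back to `k` by merging the
#' smallest adjacent clusters.
#'
#' @inheritParams local_similarity
#' @param nstart k-means restarts for the discretization (the embedding is
#'   exact; restarts only harden the discretization against bad local
#'   optima, and are cheap at these problem sizes).
#' @return A [parcellation()].
#' @export
normalized_cut <- function(W, graph, k, nstart = 50) {
  stopifnot(k >= 1, k <= graph$n)
  if (k == 1) return(parcellation(rep(1L, graph$n)))
  n <- graph$n
  S <- matrix(0, n, n)
  ew <- edge_weights(W, graph)
  sim <- ifelse(ew > 0, 1 / ew, 1e12)
  sim <- pmin(sim, 1e12)
  S[graph$edges] <- sim
  S[graph$edges[, 2:1, drop = FALSE]] <- sim
  dg <- rowSums(S)
  dg[dg <= 0] <- 1e-12
  Dm <- 1 / sqrt(dg)
  Ls <- t(S * Dm) * Dm            # D^{-1/2} S D^{-1/2}
  eg <- eigen(Ls, symmetric = TRUE)
  U <- eg$vectors[, seq_len(k), drop = FALSE]
  rn <- sqrt(rowSums(U^2)); rn[rn == 0] <- 1
  U <- U / rn
  km <- stats::kmeans(U, centers = k, nstart = nstart, iter.max = 100)
  z <- km$cluster
  # split disconnected clusters into their spatial components
  e <- graph$edges
  same <- z[e[, 1L]] == z[e[, 2L]]
  z <- comp_of_edges(n, e[same, , drop = FALSE])
  .repair_to_k(z, W, graph, k)
}

#' Region-growing parcellation
#'
#' Seeds are elements whose worst (largest) neighbour dissimilarity is no
#' larger than that of any of their neighbours (local minima of the
#' worst-neighbour statistic; ties broken by index).  Regions grow by
#' repeatedly attaching the unassigned element with the smallest
#' dissimilarity to an adjacent region's seed; the grown regions are then
#' merged down to `k` by spatially constrained Ward linkage.
#'
#' @inheritParams local_similarity
#' @return A [parcellation()].
#' @export
region_growing <- function(W, graph, k) {
  stopifnot(k >= 1, k <= graph$n)
  n <- graph$n
  worst <- vapply(seq_len(n), function(i) {
    nb <- graph$neighbors[[i]]
    if (!length(nb)) 0 else max(W[i, nb])
  }, numeric(1))
  is_seed <- vapply(seq_len(n), function(i) {
    nb <- graph$neighbors[[i]]
    all(worst[i] < worst[nb] | (worst[i] == worst[nb] & i < nb))
  }, logical(1))
  seeds <- which(is_seed)
  if (!length(seeds)) seeds <- which.min(worst)
  if (length(seeds) < k) {
    # degenerate seed statistic (e.g. constant W): supplement with the
    # next-most-stable elements so k regions are reachable
    extra <- order(worst, seq_len(n))
    seeds <- sort(c(seeds, setdiff(extra, seeds))[seq_len(k)])
  }
  z <- integer(n)
  z[seeds] <- seq_along(seeds)
  # frontier: (element, region, dissimilarity to that region's seed)
  repeat {
    un <- which(z == 0L)
    if (!length(un)) break
    best <- c(Inf, 0L, 0L)
    for (i in un) {
      nb <- graph$neighbors[[i]]
      nb <- nb[z[nb] != 0L]
      if (!length(nb)) next
      dd <- W[i, seeds[z[nb]]]
      j <- which.min(dd)
      if (dd[j] < best[1]) best <- c(dd[j], i, z[nb[j]])
    }
    if (best[2] == 0L) stop("graph is not connected")
    z[best[2]] <- best[3]
  }
  if (length(seeds) < k)
    stop("fewer grown regions (", length(seeds), ") than k = ", k)
  if (length(seeds) == k) return(parcellation(z))
  tree <- ward_tree(W, graph, init_labels = z)
  parcellation(cut_ward_tree(tree, k))
}

#' Spatially constrained Ward parcellation
#'
#' Agglomerative Ward linkage over the full fingerprint dissimilarity,
#' merging only spatially adjacent clusters; deterministic given `W`.
#'
#' @inheritParams local_similarity
#' @return A [parcellation()].
#' @export
ward_parcellation <- function(W, graph, k) {
  stopifnot(k >= 1, k <= graph$n)
  parcellation(cut_ward_tree(ward_tree(W, graph), k))
}

#' Random contiguous parcellation
#'
#' Starting from singletons, repeatedly picks a cluster uniformly at random
#' and merges it with a uniformly chosen neighbouring cluster until `k`
#' remain; contiguous by construction.  Uses the current R random stream.
#'
#' @param graph a connected [spatial_graph()].
#' @param k target number of clusters.
#' @return A [parcellation()].
#' @export
random_parcellation <- function(graph, k) {
  stopifnot(k >= 1, k <= graph$n)
  n <- graph$n
  z <- seq_len(n)
  nclust <- n
  while (nclust > k) {
    labs <- unique(z)
    a <- labs[sample.int(length(labs), 1L)]
    mem <- which(z == a)
    nb_lab <- unique(z[unlist(graph$neighbors[mem], use.names = FALSE)])
    nb_lab <- setdiff(nb_lab, a)
    if (!length(nb_lab)) next
    b <- if (length(nb_lab) == 1L) nb_lab else
      nb_lab[sample.int(length(nb_lab), 1L)]
    z[z == b] <- a
    nclust <- nclust - 1L
  }
  parcellation(z)
}

#' Run a named baseline method
#'
#' Dispatcher over the five comparison methods, sharing one interface.
#'
#' @param D a [connectivity_matrix()] or plain matrix.
#' @param graph a connected [spatial_graph()].
#' @param k target number of clusters.
#' @param method one of `"local"`, `"ncut"`, `"grow"`, `"ward"`, `"random"`.
#' @return A [parcellation()].
#' @export
baseline_parcellation <- function(D, graph, k,
                                  method = c("ward", "local", "ncut",
                                             "grow", "random")) {
  method <- match.arg(method)
  if (method == "random") return(random_parcellation(graph, k))
  W <- pairwise_dissimilarity(D)
  switch(method,
         local = local_similarity(W, graph, k),
         ncut = normalized_cut(W, graph, k),
         grow = region_growing(W, graph, k),
         ward = ward_parcellation(W, graph, k))
}
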