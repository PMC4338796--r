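#' Connectivity-fingerprint dissimilarity
#'
#' Distance between the connectivity patterns of elements `i` and `j`:
#' \deqn{W_{ij} = \sqrt{\sum_{a \ne i,j} (D_{ia} - D_{ja})^2 +
#'                      \sum_{a \ne i,j} (D_{ai} - D_{aj})^2}}
#' i.e. the Euclidean distance between rows plus columns of `D`, excluding
#' the entries involving `i` and `j` themselves.
#'
#' @param D a [connectivity_matrix()] or plain matrix (N >= 3).
#' @return An `N x N` symmetric nonnegative matrix with zero diagonal.
#' @export
pairwise_dissimilarity <- function(D) {
  D <- as_connectivity(D)
  V <- D$values
  n <- nrow(V)
  stopifnot(n >= 3L)
  sq_dist <- function(X) {        # full squared Euclidean row distances
    s <- rowSums(X^2)
    d <- outer(s, s, "+") - 2 * tcrossprod(X)
    pmax(d, 0)
  }
  dr <- sq_dist(V)                # sum over all a of (D[i,a] - D[j,a])^2
  dc <- sq_dist(t(V))
  # remove the a = i and a = j terms from each sum
  Vt <- t(V)
  A <- matrix(diag(V), n, n)      # A[i,j] = D[i,i]
  dr <- dr - (A - Vt)^2 - (V - t(A))^2
  dc <- dc - (A - V)^2 - (Vt - t(A))^2
  W <- sqrt(pmax(dr + dc, 0))
  diag(W) <- 0
  W
}

#' Spatially constrained Ward linkage tree
#'
#' Agglomerative clustering by Ward's variance-minimizing rule, with merges
#' restricted to spatially adjacent clusters.  Cluster distances follow the
#' Lance-Williams recurrence on squared dissimilarities (exact Ward when `W`
#' is Euclidean); distances are maintained between all cluster pairs, and
#' only the choice of the next merge is restricted to adjacent pairs.
#'
#' @param W `N x N` symmetric dissimilarity matrix between elements (e.g.
#'   from [pairwise_dissimilarity()]).
#' @param graph a connected [spatial_graph()].
#' @param init_labels optional starting partition (contiguous label vector);
#'   default is all-singleton.  Initial inter-cluster distances are derived
#'   from `W^2` by the Ward group formula.
#' @return Object of class `ward_tree`: list with `merges` (`(m-1) x 2`
#'   matrix of merged cluster node ids per step), `m` (initial cluster
#'   count) and `init_labels`.  Cut it with [cut_ward_tree()].
#' @export
ward_tree <- function(W, graph, init_labels = NULL) {
  n <- graph$n
  stopifnot(nrow(W) == n, ncol(W) == n)
  if (is.null(init_labels)) init_labels <- seq_len(n)
  z0 <- as_parcellation(init_labels)$labels
  m <- max(z0)
  sizes <- as.numeric(tabulate(z0, m))
  if (m == n) {
    d <- W^2
  } else {
    # Ward distance between groups from squared dissimilarities:
    # d(A,B) = 2 nA nB / (nA + nB) * ||xbar_A - xbar_B||^2 with
    # ||xbar_A - xbar_B||^2 = mean_{AB} W^2 - V_A - V_B,
    # V_A = sum_{a,a' in A} W^2 / (2 nA^2)
    Z <- matrix(0, n, m); Z[cbind(seq_len(n), z0)] <- 1
    S <- crossprod(Z, W^2) %*% Z
    nn <- outer(sizes, sizes)
    meanAB <- S / nn
    V <- diag(S) / (2 * sizes^2)
    between <- pmax(meanAB - outer(V, V, "+"), 0)
    d <- 2 * nn / outer(sizes, sizes, "+") * between
  }
  diag(d) <- Inf
  adj <- matrix(FALSE, m, m)
  ecl <- cbind(z0[graph$edges[, 1L]], z0[graph$edges[, 2L]])
  ecl <- ecl[ecl[, 1L] != ecl[, 2L], , drop = FALSE]
  adj[ecl] <- TRUE
  adj[ecl[, 2:1, drop = FALSE]] <- TRUE
  active <- rep(TRUE, m)
  merges <- matrix(0L, max(m - 1L, 0L), 2L)
  for (step in seq_len(m - 1L)) {
    dm <- d
    dm[!adj] <- Inf
    idx <- arrayInd(which.min(dm), dim(dm))
    a <- min(idx); b <- max(idx)
    if (!is.finite(dm[a, b])) stop("graph is not connected")
    merges[step, ] <- c(a, b)
    keep <- active; keep[c(a, b)] <- FALSE
    kk <- which(keep)
    if (length(kk)) {
      nc <- sizes[kk]
      newd <- ((sizes[a] + nc) * d[a, kk] + (sizes[b] + nc) * d[b, kk] -
                 nc * d[a, b]) / (sizes[a] + sizes[b] + nc)
      d[a, kk] <- newd; d[kk, a] <- newd
      adj_ab <- adj[a, kk] | adj[b, kk]
      adj[a, kk] <- adj_ab; adj[kk, a] <- adj_ab
    }
    sizes[a] <- sizes[a] + sizes[b]
    active[b] <- FALSE
    d[b, ] <- Inf; d[, b] <- Inf
    adj[b, ] <- FALSE; adj[, b] <- FALSE
  }
  structure(list(merges = merges, m = m, init_labels = z0),
            class = "ward_tree")
}

#' Cut a constrained Ward tree at K clusters
#'
#' Replays the first `m - k` merges of the recorded agglomeration and maps
#' the result back to elements.
#'
#' @param tree a [ward_tree()].
#' @param k desired number of clusters (`1 <= k <= tree$m`).
#' @return Canonical label vector over elements.
#' @export
cut_ward_tree <- function(tree, k) {
  stopifnot(k >= 1, k <= tree$m)
  edges <- tree$merges[seq_len(tree$m - k), , drop = FALSE]
  comp <- comp_of_edges(tree$m, edges)
  parcellation(comp[tree$init_labels])$labels
}
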