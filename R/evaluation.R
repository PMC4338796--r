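#' Normalized mutual information between two parcellations
#'
#' Mutual information of the two labelings normalized by the geometric mean
#' of their entropies (natural logarithms; the ratio is base-invariant):
#' \deqn{\mathrm{NMI}(z, z') = \frac{\sum_{h,l} n_{hl}
#'   \log\left(N n_{hl} / (n_h n'_l)\right)}
#'   {\sqrt{\left(\sum_h n_h \log(n_h/N)\right)
#'          \left(\sum_l n'_l \log(n'_l/N)\right)}}}
#' Ranges over \[0, 1\], with 1 for identical partitions up to relabelling;
#' empty contingency cells contribute 0.  A labelling with a single cluster
#' has zero entropy, leaving the measure undefined: this raises an error
#' rather than silently returning 0.
#'
#' @param z,z_gt parcellations ([parcellation()] or label vectors) of equal
#'   length, each with at least 2 clusters.
#' @return NMI in \[0, 1\].
#' @examples
#' nmi(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1
#' @export
nmi <- function(z, z_gt) {
  a <- as_parcellation(z)$labels
  b <- as_parcellation(z_gt)$labels
  stopifnot(length(a) == length(b))
  if (max(a) < 2L || max(b) < 2L)
    stop("NMI is undefined when a labeling has a single cluster")
  N <- length(a)
  tab <- table(a, b)
  nh <- rowSums(tab)
  nl <- colSums(tab)
  nz <- tab > 0
  I <- sum(tab[nz] * log(N * tab[nz] /
                           (outer(nh, nl)[nz])))
  H1 <- sum(nh * log(nh / N))
  H2 <- sum(nl * log(nl / N))
  val <- I / sqrt(H1 * H2)
  min(max(val, 0), 1)
}

#' Fraction of connectivity variance explained by a parcellation
#'
#' Replaces every included entry of `D` by its parcel-pair block mean and
#' reports `1 - SS_residual / SS_total` over the included entries (diagonal
#' excluded; upper triangle only for symmetric input).  Equals 0 for a
#' single parcel and 1 when `D` is exactly piecewise constant over the
#' blocks.
#'
#' @param D a [connectivity_matrix()] or plain matrix.
#' @param z a [parcellation()] or label vector.
#' @return Variance explained, at most 1.
#' @export
variance_explained <- function(D, z) {
  D <- as_connectivity(D)
  z <- as_parcellation(z)$labels
  mask <- included_mask(D)
  x <- D$values[mask]
  sst <- sum((x - mean(x))^2)
  if (sst < .Machine$double.eps) stop("constant matrix: zero total variance")
  st <- block_stats(D, z)
  ssr <- sum(st$ss[if (st$symmetric) upper.tri(st$ss, diag = TRUE)
                   else TRUE])
  1 - ssr / sst
}

#' Compare parcellation methods on one dataset
#'
#' Runs the model and/or baselines and scores each result; baselines use
#' the number of clusters inferred by the model (or an explicit `k`).
#'
#' @param D a [connectivity_matrix()]; normalized internally for the model.
#' @param graph a connected [spatial_graph()].
#' @param truth optional ground-truth [parcellation()] for NMI.
#' @param methods character vector from `"model"`, `"ward"`, `"local"`,
#'   `"ncut"`, `"grow"`, `"random"`.
#' @param k cluster count for baselines; default: the model's inferred k
#'   (requires `"model"` among `methods`).
#' @param seeds integer vector; each method is run once per seed
#'   (deterministic methods repeat identically).
#' @param sigma0_sq,passes model settings.
#' @return data.frame with columns `method`, `seed`, `k`, `nmi` (NA without
#'   truth), `variance_explained`.
#' @export
compare_methods <- function(D, graph, truth = NULL,
                            methods = c("model", "ward"), k = NULL,
                            seeds = 1L, sigma0_sq = 0.01, passes = 30) {
  D <- as_connectivity(D)
  Dn <- normalize_matrix(D)
  W <- NULL
  rows <- list()
  for (seed in seeds) {
    fit <- NULL
    if ("model" %in% methods) {
      set.seed(seed)
      fit <- parcellate(Dn, graph, sigma0_sq = sigma0_sq, passes = passes,
                        normalize = FALSE)
    }
    k_run <- if (!is.null(k)) k else if (!is.null(fit)) fit$k else
      stop("supply k or include 'model' in methods")
    for (method in methods) {
      p <- if (method == "model") fit$parcellation
      else if (method == "random") {
        set.seed(seed + 1e6)
        random_parcellation(graph, k_run)
      } else {
        if (is.null(W)) W <- pairwise_dissimilarity(Dn)
        switch(method,
               ward = ward_parcellation(W, graph, k_run),
               local = suppressWarnings(local_similarity(W, graph, k_run)),
               ncut = {
                 set.seed(seed)
                 normalized_cut(W, graph, k_run)
               },
               grow = region_growing(W, graph, k_run))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        method = method, seed = seed, k = p$k,
        nmi = if (is.null(truth)) NA_real_ else nmi(p, truth),
        variance_explained = variance_explained(Dn, p))
    }
  }
  do.call(rbind, rows)
}
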