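#' Fit a spatially contiguous connectivity parcellation
#'
#' Divides the elements of a spatial map into contiguous parcels with
#' homogeneous connectivity.  The prior over partitions is a
#' distance-dependent Chinese restaurant process in which each element
#' links to itself (weight `alpha`) or to a spatial neighbour (weight 1);
#' parcels are the connected components of the link graph, so every
#' reachable partition is contiguous and the number of parcels is learned
#' from the data.  Given a partition, the connectivities between each pair
#' of parcels are modelled as i.i.d. Normal with a conjugate
#' Normal-Inverse-chi-squared prior on the block mean and variance, which
#' integrates out in closed form.  Collapsed Gibbs sampling over the links
#' explores the posterior; the maximum a posteriori state visited is
#' reported.
#'
#' The input matrix is standardized to zero mean and unit variance over its
#' included entries (see [normalize_matrix()]) unless `normalize = FALSE`.
#' The one hyperparameter that materially shapes the solution is
#' `sigma0_sq`, the prior expected within-block variance of the
#' standardized connectivities: smaller values demand tighter blocks and so
#' yield more, smaller parcels.
#'
#' @param D an `N x N` connectivity matrix ([connectivity_matrix()] or
#'   plain matrix; symmetric or asymmetric).
#' @param graph a connected [spatial_graph()] over the same `N` elements.
#' @param sigma0_sq prior expected block variance; e.g. 0.01 for low-noise
#'   standardized data, larger for noisier data.
#' @param passes number of Gibbs sweeps through all elements.
#' @param alpha,mu0,kappa0,nu0 remaining prior hyperparameters, see
#'   [hyperparams()].
#' @param init initialization: `"ward-auto"` (constrained Ward at the
#'   model-preferred cluster count; default), `"ward-k"` (fixed `k_init`),
#'   or `"random"`.
#' @param k_init initial cluster count for `init = "ward-k"`.
#' @param normalize standardize `D` before fitting (default `TRUE`).
#' @param record_trace keep a per-step trace of (k, log posterior).
#' @param seed optional integer; if given, sets the random stream so the
#'   fit is exactly reproducible.
#' @return An object of class `ddparcel_fit` with components
#'   `parcellation` (MAP [parcellation()]), `labels`, `k`, `links`,
#'   `log_posterior`, `hyper`, `trace` (or `NULL`), `D` (the standardized
#'   matrix), `graph`, and `call`.  Methods: [print.ddparcel_fit()],
#'   [summary.ddparcel_fit()], [coef.ddparcel_fit()] (block connectivity
#'   means), [fitted.ddparcel_fit()] (block-mean reconstruction),
#'   [residuals.ddparcel_fit()], [plot.ddparcel_fit()].
#' @examples
#' gt <- grid_truth("squares9")
#' set.seed(1)
#' ds <- sample_connectivity(gt$truth, sigma = 0.2)
#' fit <- parcellate(ds$D, gt$graph, sigma0_sq = 0.01, passes = 3, seed = 1)
#' fit$k
#' nmi(fit$parcellation, gt$truth)
#' @export
parcellate <- function(D, graph, sigma0_sq, passes = 30,
                       alpha = 10, mu0 = 0, kappa0 = 1e-4, nu0 = 1,
                       init = c("ward-auto", "ward-k", "random"),
                       k_init = NULL, normalize = TRUE,
                       record_trace = FALSE, seed = NULL) {
  init <- match.arg(init)
  if (!is.null(seed)) set.seed(seed)
  D <- as_connectivity(D)
  if (normalize) D <- normalize_matrix(D)
  hyper <- hyperparams(sigma0_sq = sigma0_sq, alpha = alpha, mu0 = mu0,
                       kappa0 = kappa0, nu0 = nu0)
  res <- run_sampler(D, graph, hyper, passes = passes, init = init,
                     k_init = k_init, record_trace = record_trace)
  structure(list(parcellation = res$map$labels,
                 labels = res$map$labels$labels,
                 k = res$map$labels$k,
                 links = res$map$links,
                 log_posterior = res$map$log_posterior,
                 hyper = hyper, passes = passes, init = init,
                 trace = res$trace, D = D, graph = graph,
                 call = match.call()),
            class = "ddparcel_fit")
}

#' @export
print.ddparcel_fit <- function(x, ...) {
  cat("Spatially contiguous connectivity parcellation (dd-CRP)\n")
  cat(sprintf("  %d elements -> %d parcels; MAP log posterior %.2f\n",
              length(x$labels), x$k, x$log_posterior))
  cat(sprintf("  sigma0_sq = %g, alpha = %g, %d passes, init = %s\n",
              x$hyper$sigma0_sq, x$hyper$alpha, x$passes, x$init))
  invisible(x)
}

#' @describeIn parcellate parcel sizes, block-mean range and fit summary.
#' @param object,x a `ddparcel_fit`.
#' @param ... unused.
#' @export
summary.ddparcel_fit <- function(object, ...) {
  sizes <- tabulate(object$labels, object$k)
  ve <- variance_explained(object$D, object$parcellation)
  out <- list(k = object$k, sizes = sizes,
              log_posterior = object$log_posterior,
              variance_explained = ve,
              block_means = coef(object))
  class(out) <- "summary.ddparcel_fit"
  out
}

#' @export
print.summary.ddparcel_fit <- function(x, ...) {
  cat(sprintf("%d parcels; sizes: %s\n", x$k,
              paste(x$sizes, collapse = " ")))
  cat(sprintf("MAP log posterior: %.2f\n", x$log_posterior))
  cat(sprintf("variance explained by block means: %.4f\n",
              x$variance_explained))
  invisible(x)
}

#' @describeIn parcellate posterior-mean connectivity between parcels
#'   (`k x k` matrix; the model's block strength estimates
#'   \eqn{(\kappa_0\mu_0 + L\bar d)/(\kappa_0 + L)}).
#' @export
coef.ddparcel_fit <- function(object, ...) {
  st <- block_stats(object$D, object$parcellation)
  h <- object$hyper
  mu <- (h$kappa0 * h$mu0 + st$L * st$mean) / (h$kappa0 + st$L)
  if (st$symmetric) mu[lower.tri(mu)] <- t(mu)[lower.tri(mu)]
  mu
}

#' @describeIn parcellate block-mean reconstruction of the standardized
#'   connectivity matrix (excluded diagonal set to `NA`).
#' @export
fitted.ddparcel_fit <- function(object, ...) {
  A <- coef(object)
  z <- object$labels
  out <- A[cbind(rep(z, times = length(z)), rep(z, each = length(z)))]
  dim(out) <- c(length(z), length(z))
  if (!object$D$diagonal_defined) diag(out) <- NA_real_
  out
}

#' @describeIn parcellate residual connectivity `D - fitted`.
#' @export
residuals.ddparcel_fit <- function(object, ...) {
  object$D$values - fitted(object)
}

#' @describeIn parcellate plots the parcellation: as a labelled image when
#'   the graph is a grid, as the sampling trace when `which = "trace"`, and
#'   as parcel sizes otherwise.
#' @param which `"map"`, `"trace"` or `"sizes"`.
#' @export
plot.ddparcel_fit <- function(x, which = c("map", "trace", "sizes"), ...) {
  which <- match.arg(which)
  if (which == "trace") {
    if (is.null(x$trace)) stop("fit was run without record_trace = TRUE")
    graphics::plot(x$trace$step, x$trace$log_posterior, type = "l",
                   xlab = "Gibbs step", ylab = "log posterior", ...)
    return(invisible(x))
  }
  gd <- attr(x$graph, "grid_dim")
  if (which == "map" && !is.null(gd)) {
    m <- matrix(x$labels, gd[1], gd[2], byrow = TRUE)
    graphics::image(seq_len(gd[2]), seq_len(gd[1]), t(m)[, rev(seq_len(gd[1]))],
                    col = grDevices::hcl.colors(x$k, "Spectral"),
                    xlab = "", ylab = "", axes = FALSE, ...)
    graphics::box()
  } else {
    graphics::barplot(sort(tabulate(x$labels, x$k), decreasing = TRUE),
                      xlab = "parcel (sorted)", ylab = "size", ...)
  }
  invisible(x)
}
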