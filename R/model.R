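#' Model hyperparameters
#'
#' The generative model draws a mean/variance pair for every parcel-pair
#' block from a Normal-Inverse-chi-squared prior
#' `(A, sigma^2) ~ NIchi2(mu0, kappa0, sigma0_sq, nu0)` and the observed
#' connectivities in the block i.i.d. Normal around it; `alpha` is the
#' self-link concentration of the dd-CRP prior over neighbour links.
#'
#' In practice the only critical setting is `sigma0_sq`, the prior expected
#' within-block variance: smaller values favour more, smaller parcels.  The
#' remaining defaults (`alpha = 10`, `mu0 = 0`, `kappa0 = 1e-4`, `nu0 = 1`)
#' are weakly informative and can be used unchanged for standardized input.
#'
#' @param sigma0_sq prior expected block variance (> 0); no default -- choose
#'   per dataset (e.g. 0.01 for low-noise standardized matrices).
#' @param alpha dd-CRP self-link concentration (>= 0).
#' @param mu0 prior block mean.
#' @param kappa0 prior precision on the mean (> 0).
#' @param nu0 prior degrees of freedom on the variance (> 0).
#' @return Object of class `ddparcel_hyper`.
#' @examples
#' hyperparams(sigma0_sq = 0.01)
#' @export
hyperparams <- function(sigma0_sq, alpha = 10, mu0 = 0, kappa0 = 1e-4,
                        nu0 = 1) {
  stopifnot(sigma0_sq > 0, kappa0 > 0, nu0 > 0, alpha >= 0)
  structure(list(alpha = alpha, mu0 = mu0, kappa0 = kappa0,
                 sigma0_sq = sigma0_sq, nu0 = nu0),
            class = "ddparcel_hyper")
}

#' @export
print.ddparcel_hyper <- function(x, ...) {
  cat(sprintf(
    "hyperparameters: alpha=%g mu0=%g kappa0=%g sigma0_sq=%g nu0=%g\n",
    x$alpha, x$mu0, x$kappa0, x$sigma0_sq, x$nu0))
  invisible(x)
}

#' Log prior of a link state under the dd-CRP
#'
#' Each element links independently to itself (weight `alpha`) or to one of
#' its spatial neighbours (weight 1); weights are normalized per element.
#' Links to non-neighbours have probability zero (`-Inf`), as does a
#' self-link when `alpha = 0`.
#'
#' @param links a [link_state()] or integer vector.
#' @param graph a [spatial_graph()].
#' @param hyper a [hyperparams()] object (only `alpha` is used).
#' @return Log prior probability (scalar).
#' @export
log_ddcrp_prior <- function(links, graph, hyper) {
  if (inherits(links, "link_state")) links <- links$links
  stopifnot(length(links) == graph$n)
  lw <- numeric(graph$n)
  for (i in seq_len(graph$n)) {
    if (links[i] == i) {
      lw[i] <- if (hyper$alpha > 0) log(hyper$alpha) else -Inf
    } else if (links[i] %in% graph$neighbors[[i]]) {
      lw[i] <- 0
    } else {
      lw[i] <- -Inf
    }
  }
  sum(lw) - sum(log(hyper$alpha + degree(graph)))
}

#' Block sufficient statistics of a parcellation
#'
#' For every parcel pair the count `L`, mean `dbar` and sum of squared
#' deviations `s` of the connectivities between the two parcels -- the
#' sufficient statistics of the Normal likelihood with NIchi2 prior.
#' Diagonal entries of `D` are excluded; for symmetric `D` each unordered
#' element pair is counted once, so blocks are indexed by unordered parcel
#' pairs (`m <= n`) and a within-parcel block of size `p` has
#' `L = p * (p - 1) / 2` (`p * (p - 1)` in the asymmetric case, where blocks
#' are ordered pairs).
#'
#' @param D a [connectivity_matrix()] or plain matrix.
#' @param z a [parcellation()] or label vector.
#' @return A list with `K x K` matrices `L`, `mean`, `ss` and the flag
#'   `symmetric`.  For symmetric input only entries with `m <= n` are
#'   meaningful; the lower triangle mirrors them.
#' @export
block_stats <- function(D, z) {
  D <- as_connectivity(D)
  z <- as_parcellation(z)$labels
  n <- nrow(D$values)
  stopifnot(length(z) == n)
  K <- max(z)
  Z <- matrix(0, n, K); Z[cbind(seq_len(n), z)] <- 1
  V <- D$values
  dvals <- diag(V)
  diag(V) <- 0
  V2 <- V * V
  S1 <- crossprod(Z, V) %*% Z    # ordered block sums, diagonal excluded
  S2 <- crossprod(Z, V2) %*% Z
  sizes <- tabulate(z, K)
  L <- outer(sizes, sizes)
  if (D$symmetric) {
    # unordered blocks: cross sums equal the ordered sums; within sums halve
    diag(S1) <- diag(S1) / 2
    diag(S2) <- diag(S2) / 2
    diag(L) <- sizes * (sizes - 1) / 2
  } else {
    diag(L) <- sizes * (sizes - 1)
  }
  if (D$diagonal_defined) {
    dsum  <- rowsum(dvals, z)[, 1L]
    dsum2 <- rowsum(dvals^2, z)[, 1L]
    diag(S1) <- diag(S1) + dsum
    diag(S2) <- diag(S2) + dsum2
    diag(L) <- diag(L) + sizes
  }
  mean <- ifelse(L > 0, S1 / pmax(L, 1), 0)
  ss <- pmax(S2 - L * mean^2, 0)
  list(L = L, mean = mean, ss = ss, symmetric = D$symmetric)
}

#' Log marginal likelihood of one block
#'
#' Closed-form marginal of `L` Normal observations with NIchi2 prior on
#' their mean and variance, computed entirely in the log domain:
#' \deqn{\log p = \log\Gamma(\nu_{mn}/2) - \log\Gamma(\nu_0/2)
#'   + \tfrac12\log(\kappa_0/\kappa_{mn})
#'   + \tfrac{\nu_0}{2}\log(\nu_0\sigma_0^2)
#'   - \tfrac{\nu_{mn}}{2}\log(\nu_{mn}\sigma_{mn}^2)
#'   - \tfrac{L}{2}\log\pi}
#' with \eqn{\kappa_{mn} = \kappa_0 + L}, \eqn{\nu_{mn} = \nu_0 + L} and
#' \eqn{\nu_{mn}\sigma_{mn}^2 = \nu_0\sigma_0^2 + s +
#' \frac{L\kappa_0}{\kappa_0 + L}(\mu_0 - \bar d)^2}.  An empty block
#' (`L = 0`) contributes 0.  All arguments are vectorized.
#'
#' @param L block count(s).
#' @param dbar block mean(s).
#' @param ss block sum(s) of squared deviations.
#' @param hyper a [hyperparams()] object.
#' @return Log marginal likelihood, same length as the inputs.
#' @export
log_marginal_block <- function(L, dbar, ss, hyper) {
  nu_n  <- hyper$nu0 + L
  kap_n <- hyper$kappa0 + L
  nssq  <- hyper$nu0 * hyper$sigma0_sq + ss +
    L * hyper$kappa0 / kap_n * (hyper$mu0 - dbar)^2
  out <- lgamma(nu_n / 2) - lgamma(hyper$nu0 / 2) +
    0.5 * (log(hyper$kappa0) - log(kap_n)) +
    (hyper$nu0 / 2) * log(hyper$nu0 * hyper$sigma0_sq) -
    (nu_n / 2) * log(nssq) - (L / 2) * log(pi)
  out[L == 0] <- 0
  out
}

#' Merge block sufficient statistics
#'
#' Pools two blocks' `(L, dbar, s)` statistics without touching the data:
#' counts add, means combine count-weighted, and
#' \deqn{s = s_1 + s_2 + \frac{L_1 L_2}{L_1 + L_2}(\bar d_1 - \bar d_2)^2.}
#' Vectorized; merging with an empty block returns the other unchanged.
#'
#' @param L1,dbar1,ss1 statistics of the first block(s).
#' @param L2,dbar2,ss2 statistics of the second block(s).
#' @return List with components `L`, `mean`, `ss`.
#' @export
merge_block_stats <- function(L1, dbar1, ss1, L2, dbar2, ss2) {
  L <- L1 + L2
  safeL <- pmax(L, 1)
  mean <- (L1 * dbar1 + L2 * dbar2) / safeL
  ss <- ss1 + ss2 + ifelse(L > 0, L1 * L2 / safeL * (dbar1 - dbar2)^2, 0)
  list(L = L, mean = ifelse(L > 0, mean, 0), ss = ss)
}

# sum of log marginals over the valid blocks of a stats object
sum_log_marginal <- function(st, hyper) {
  if (st$symmetric) {
    keep <- upper.tri(st$L, diag = TRUE)
    sum(log_marginal_block(st$L[keep], st$mean[keep], st$ss[keep], hyper))
  } else {
    sum(log_marginal_block(st$L, st$mean, st$ss, hyper))
  }
}

#' Log marginal likelihood of a parcellation
#'
#' Sum of [log_marginal_block()] over all parcel-pair blocks of
#' [block_stats()]: the collapsed likelihood `p(D | z)` with block means and
#' variances integrated out.
#'
#' @inheritParams block_stats
#' @param hyper a [hyperparams()] object.
#' @return Log likelihood (scalar).
#' @export
log_model <- function(D, z, hyper) {
  sum_log_marginal(block_stats(D, z), hyper)
}
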