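# Collapsed Gibbs sampling over dd-CRP neighbour links.
#
# The sampler state caches, for the current partition z(c): parcel sizes and
# member lists, the block sufficient statistics (L, mean, ss) and per-block
# log marginals, and the link part of the log prior.  One Gibbs step removes
# link c_i (possibly splitting i's parcel), scores every candidate in
# {i} U neighbors(i) -- merge candidates through pooled block statistics,
# never by full recomputation -- and resamples c_i.

# immutable per-run data: D with zeroed diagonal, its square, symmetry flag
.sampler_data <- function(D) {
  D <- as_connectivity(D)
  V <- D$values
  diag(V) <- 0
  list(V = V, V2 = V * V, symmetric = D$symmetric, n = nrow(V),
       D = connectivity_matrix(D$values, symmetric = D$symmetric,
                               diagonal_defined = FALSE))
}

# build a full sampler state from links (stats computed from scratch)
.state_init <- function(links, graph, hyper, dat) {
  p <- connected_components(links, graph)
  st <- block_stats(dat$D, p)
  z <- p$labels
  K <- p$k
  LM <- matrix(log_marginal_block(st$L, st$mean, st$ss, hyper), K, K)
  list(links = as.integer(links), z = z, K = K,
       sizes = tabulate(z, K),
       members = split(seq_along(z), z),
       L = st$L, M = st$mean, S = st$ss, LM = LM,
       n_self = sum(links == seq_along(links)))
}

.state_log_prior <- function(state, graph, hyper) {
  lw <- if (hyper$alpha > 0) state$n_self * log(hyper$alpha)
        else if (state$n_self > 0) -Inf else 0
  lw - sum(log(hyper$alpha + degree(graph)))
}

.state_log_marginal <- function(state, dat) {
  if (dat$symmetric) sum(state$LM[upper.tri(state$LM, diag = TRUE)])
  else sum(state$LM)
}

.state_log_posterior <- function(state, graph, hyper, dat) {
  .state_log_prior(state, graph, hyper) + .state_log_marginal(state, dat)
}

# recompute all block stats touching label `a` from the data (both
# orientations); writes row/col a of L, M, S, LM
.refresh_label <- function(state, a, hyper, dat) {
  X <- state$members[[a]]
  z <- state$z
  K <- state$K
  sz <- state$sizes
  cs  <- colSums(dat$V[X, , drop = FALSE])
  cs2 <- colSums(dat$V2[X, , drop = FALSE])
  # ordered sums over (X, parcel q), grouped via the cached member lists
  sum_row  <- vapply(state$members, function(ix) sum(cs[ix]), numeric(1))
  sum2_row <- vapply(state$members, function(ix) sum(cs2[ix]), numeric(1))
  p <- length(X)
  if (dat$symmetric) {
    Lr <- p * sz
    Lr[a] <- p * (p - 1) / 2
    sum_row[a] <- sum_row[a] / 2
    sum2_row[a] <- sum2_row[a] / 2
    mr <- ifelse(Lr > 0, sum_row / pmax(Lr, 1), 0)
    sr <- pmax(sum2_row - Lr * mr^2, 0)
    lm <- log_marginal_block(Lr, mr, sr, hyper)
    state$L[a, ] <- Lr; state$L[, a] <- Lr
    state$M[a, ] <- mr; state$M[, a] <- mr
    state$S[a, ] <- sr; state$S[, a] <- sr
    state$LM[a, ] <- lm; state$LM[, a] <- lm
  } else {
    rs  <- rowSums(dat$V[, X, drop = FALSE])
    rs2 <- rowSums(dat$V2[, X, drop = FALSE])
    sum_col  <- vapply(state$members, function(ix) sum(rs[ix]), numeric(1))
    sum2_col <- vapply(state$members, function(ix) sum(rs2[ix]), numeric(1))
    Lr <- p * sz; Lr[a] <- p * (p - 1)
    Lc <- p * sz; Lc[a] <- p * (p - 1)
    mr <- ifelse(Lr > 0, sum_row / pmax(Lr, 1), 0)
    sr <- pmax(sum2_row - Lr * mr^2, 0)
    mc <- ifelse(Lc > 0, sum_col / pmax(Lc, 1), 0)
    sc <- pmax(sum2_col - Lc * mc^2, 0)
    state$L[a, ] <- Lr; state$M[a, ] <- mr; state$S[a, ] <- sr
    state$LM[a, ] <- log_marginal_block(Lr, mr, sr, hyper)
    state$L[, a] <- Lc; state$M[, a] <- mc; state$S[, a] <- sc
    state$LM[, a] <- log_marginal_block(Lc, mc, sc, hyper)
    # the (a, a) entry was written twice with the same value
  }
  state
}

# grow cached matrices by one row/column (new empty label)
.grow_state <- function(state) {
  K <- state$K + 1L
  grow <- function(m) {
    out <- matrix(0, K, K)
    out[seq_len(K - 1L), seq_len(K - 1L)] <- m
    out
  }
  state$L <- grow(state$L); state$M <- grow(state$M)
  state$S <- grow(state$S); state$LM <- grow(state$LM)
  state$sizes <- c(state$sizes, 0L)
  state$members <- c(state$members, list(integer(0)))
  state$K <- K
  state
}

#' Remove one link and update the induced partition
#'
#' Sets `links[i]` to a self-link.  If that disconnects element `i`'s parcel
#' in the undirected link graph, the parcel splits into its two components
#' (the component containing `i` receives a new label `K + 1`) and the block
#' statistics touching the split parcel are refreshed; all other blocks are
#' untouched.
#'
#' @param state a sampler state as built by [sampler_init()].
#' @param i element index.
#' @param graph,hyper,dat run context (graph, [hyperparams()], internal data).
#' @return The updated state.
#' @keywords internal
.split_on_removal <- function(state, i, graph, hyper, dat) {
  old <- state$links[i]
  if (old == i) return(state)
  state$links[i] <- i
  state$n_self <- state$n_self + 1L
  a <- state$z[i]
  mem <- state$members[[a]]
  nonself <- mem[state$links[mem] != mem]
  comp <- comp_of_edges(length(mem),
                        cbind(match(nonself, mem),
                              match(state$links[nonself], mem)))
  if (max(comp) == 1L) return(state)
  in_i <- comp == comp[match(i, mem)]
  part_i <- mem[in_i]
  state <- .grow_state(state)
  b <- state$K
  state$z[part_i] <- b
  state$members[[b]] <- part_i
  state$members[[a]] <- mem[!in_i]
  state$sizes[b] <- length(part_i)
  state$sizes[a] <- length(mem) - length(part_i)
  state <- .refresh_label(state, a, hyper, dat)
  state <- .refresh_label(state, b, hyper, dat)
  state
}

# log-likelihood gain of merging parcels a and b, via pooled block stats
# (Eq.-ratio structure: only blocks touching a or b change).
# Returns list(delta, within = pooled (a,a/b,b/a,b[,b,a]) stats).
.merge_delta <- function(state, a, b, hyper, dat) {
  K <- state$K
  q <- setdiff(seq_len(K), c(a, b))
  delta <- 0
  if (dat$symmetric) {
    if (length(q)) {
      m1 <- merge_block_stats(state$L[q, a], state$M[q, a], state$S[q, a],
                              state$L[q, b], state$M[q, b], state$S[q, b])
      delta <- sum(log_marginal_block(m1$L, m1$mean, m1$ss, hyper)) -
        sum(state$LM[q, a]) - sum(state$LM[q, b])
    }
    w <- merge_block_stats(state$L[a, a], state$M[a, a], state$S[a, a],
                           state$L[b, b], state$M[b, b], state$S[b, b])
    w <- merge_block_stats(w$L, w$mean, w$ss,
                           state$L[a, b], state$M[a, b], state$S[a, b])
    delta <- delta + log_marginal_block(w$L, w$mean, w$ss, hyper) -
      (state$LM[a, a] + state$LM[b, b] + state$LM[a, b])
    list(delta = delta, cross = if (length(q)) m1 else NULL, within = w, q = q)
  } else {
    cr <- cc <- NULL
    if (length(q)) {
      cr <- merge_block_stats(state$L[a, q], state$M[a, q], state$S[a, q],
                              state$L[b, q], state$M[b, q], state$S[b, q])
      cc <- merge_block_stats(state$L[q, a], state$M[q, a], state$S[q, a],
                              state$L[q, b], state$M[q, b], state$S[q, b])
      delta <- sum(log_marginal_block(cr$L, cr$mean, cr$ss, hyper)) +
        sum(log_marginal_block(cc$L, cc$mean, cc$ss, hyper)) -
        sum(state$LM[a, q]) - sum(state$LM[b, q]) -
        sum(state$LM[q, a]) - sum(state$LM[q, b])
    }
    w <- merge_block_stats(state$L[a, a], state$M[a, a], state$S[a, a],
                           state$L[b, b], state$M[b, b], state$S[b, b])
    w <- merge_block_stats(w$L, w$mean, w$ss,
                           state$L[a, b], state$M[a, b], state$S[a, b])
    w <- merge_block_stats(w$L, w$mean, w$ss,
                           state$L[b, a], state$M[b, a], state$S[b, a])
    delta <- delta + log_marginal_block(w$L, w$mean, w$ss, hyper) -
      (state$LM[a, a] + state$LM[b, b] + state$LM[a, b] + state$LM[b, a])
    list(delta = delta, cross_row = cr, cross_col = cc, within = w, q = q)
  }
}

# apply an accepted merge of parcel a into parcel b using the stats already
# pooled by .merge_delta; then relocate label K into slot a
.apply_merge <- function(state, a, b, mg, dat) {
  K <- state$K
  q <- mg$q
  if (dat$symmetric) {
    if (length(q)) {
      state$L[q, b] <- mg$cross$L;   state$L[b, q] <- mg$cross$L
      state$M[q, b] <- mg$cross$mean; state$M[b, q] <- mg$cross$mean
      state$S[q, b] <- mg$cross$ss;  state$S[b, q] <- mg$cross$ss
      lm <- log_marginal_block(mg$cross$L, mg$cross$mean, mg$cross$ss,
                               attr(mg, "hyper"))
      state$LM[q, b] <- lm; state$LM[b, q] <- lm
    }
    state$L[b, b] <- mg$within$L
    state$M[b, b] <- mg$within$mean
    state$S[b, b] <- mg$within$ss
    state$LM[b, b] <- attr(mg, "lm_within")
  } else {
    if (length(q)) {
      state$L[b, q] <- mg$cross_row$L
      state$M[b, q] <- mg$cross_row$mean
      state$S[b, q] <- mg$cross_row$ss
      state$LM[b, q] <- log_marginal_block(mg$cross_row$L, mg$cross_row$mean,
                                           mg$cross_row$ss, attr(mg, "hyper"))
      state$L[q, b] <- mg$cross_col$L
      state$M[q, b] <- mg$cross_col$mean
      state$S[q, b] <- mg$cross_col$ss
      state$LM[q, b] <- log_marginal_block(mg$cross_col$L, mg$cross_col$mean,
                                           mg$cross_col$ss, attr(mg, "hyper"))
    }
    state$L[b, b] <- mg$within$L
    state$M[b, b] <- mg$within$mean
    state$S[b, b] <- mg$within$ss
    state$LM[b, b] <- attr(mg, "lm_within")
  }
  state$z[state$members[[a]]] <- b
  state$members[[b]] <- c(state$members[[b]], state$members[[a]])
  state$sizes[b] <- state$sizes[b] + state$sizes[a]
  # relocate last label K into the vacated slot a
  if (a != K) {
    state$z[state$members[[K]]] <- a
    state$members[[a]] <- state$members[[K]]
    state$sizes[a] <- state$sizes[K]
    for (nm in c("L", "M", "S", "LM")) {
      m <- state[[nm]]
      m[a, ] <- m[K, ]; m[, a] <- m[, K]
      m[a, a] <- m[K, K]
      state[[nm]] <- m[-K, -K, drop = FALSE]
    }
  } else {
    for (nm in c("L", "M", "S", "LM"))
      state[[nm]] <- state[[nm]][-K, -K, drop = FALSE]
  }
  state$members[[K]] <- NULL
  state$sizes <- state$sizes[-K]
  state$K <- K - 1L
  state
}

#' One collapsed Gibbs update of a single link
#'
#' Removes `links[i]`, then resamples it over `{i} U neighbors(i)` with
#' probability proportional to the dd-CRP weight (`alpha` for self, 1
#' otherwise) times the marginal likelihood of the induced partition;
#' candidates that merge two parcels are scored through pooled block
#' statistics.  Uses the current R random number stream.
#'
#' @param state sampler state (see [sampler_init()]).
#' @param i element index to update.
#' @param graph a [spatial_graph()].
#' @param hyper a [hyperparams()] object.
#' @param dat internal data object from `ddparcel:::.sampler_data`.
#' @return The updated state.
#' @keywords internal
.gibbs_step <- function(state, i, graph, hyper, dat) {
  cd <- .candidates(state, i, graph, hyper, dat)
  state <- cd$state
  a <- state$z[i]
  nb <- cd$neighbors
  w <- exp(cd$lw - max(cd$lw))
  pick <- sample.int(length(w), 1L, prob = w)
  if (pick == 1L) return(state)   # keep the self-link set during removal
  j <- nb[pick - 1L]
  state$links[i] <- j
  state$n_self <- state$n_self - 1L
  b <- state$z[j]
  if (b != a) {
    mg <- cd$merges[[match(b, cd$targets)]]
    state <- .apply_merge(state, a, b, mg, dat)
  }
  state
}

# candidate set and log-weights for resampling link c_i: removes the current
# link (split configuration), then scores the self-link (log alpha) and each
# neighbour (0 for non-merging, the pooled-statistics likelihood ratio for
# merging candidates).  Shared by the sampler and the oracle tests.
.candidates <- function(state, i, graph, hyper, dat) {
  state <- .split_on_removal(state, i, graph, hyper, dat)
  a <- state$z[i]
  nb <- graph$neighbors[[i]]
  tgt <- state$z[nb]
  utgt <- unique(tgt[tgt != a])
  deltas <- numeric(length(utgt))
  merges <- vector("list", length(utgt))
  for (k in seq_along(utgt)) {
    mg <- .merge_delta(state, a, utgt[k], hyper, dat)
    attr(mg, "hyper") <- hyper
    attr(mg, "lm_within") <- log_marginal_block(mg$within$L, mg$within$mean,
                                                mg$within$ss, hyper)
    deltas[k] <- mg$delta
    merges[[k]] <- mg
  }
  lw_self <- if (hyper$alpha > 0) log(hyper$alpha) else -Inf
  lw_nb <- ifelse(tgt == a, 0, deltas[match(tgt, utgt)])
  list(state = state, neighbors = nb, candidates = c(i, nb),
       lw = c(lw_self, lw_nb), targets = utgt, merges = merges)
}

#' Initialize the sampler state
#'
#' Default (`"ward-auto"`): run spatially constrained Ward linkage on the
#' pairwise connectivity-fingerprint dissimilarity, score each candidate
#' number of clusters K under the model (collapsed likelihood plus the
#' dd-CRP prior, which for one spanning tree per parcel contributes
#' `K * log(alpha)` up to a constant), take the best K, and draw one uniform
#' random spanning tree per Ward cluster (Wilson's algorithm) oriented so
#' the induced labels reproduce the Ward labels.  `"ward-k"` fixes K;
#' `"random"` draws every link uniformly from its candidate set.
#'
#' @param D normalized [connectivity_matrix()].
#' @param graph a [spatial_graph()]; must be connected.
#' @param hyper a [hyperparams()] object.
#' @param init one of `"ward-auto"`, `"ward-k"`, `"random"`.
#' @param k_init cluster count for `"ward-k"`.
#' @return A sampler state list (links, labels `z`, cached block statistics).
#' @export
sampler_init <- function(D, graph, hyper, init = c("ward-auto", "ward-k",
                                                   "random"), k_init = NULL) {
  init <- match.arg(init)
  if (!is_connected_graph(graph))
    stop("spatial graph must be connected")
  dat <- .sampler_data(D)
  stopifnot(dat$n == graph$n)
  if (init == "random") {
    links <- vapply(seq_len(graph$n), function(i) {
      cand <- c(i, graph$neighbors[[i]])
      cand[sample.int(length(cand), 1L)]
    }, integer(1))
    return(.state_init(links, graph, hyper, dat))
  }
  wd <- ward_tree(pairwise_dissimilarity(dat$D), graph)
  if (init == "ward-k") {
    stopifnot(!is.null(k_init), k_init >= 1, k_init <= graph$n)
    z <- cut_ward_tree(wd, k_init)
  } else {
    n <- graph$n
    ks <- unique(pmin(2^(1:ceiling(log2(n))), n))
    score <- function(k) log_model(dat$D, cut_ward_tree(wd, k), hyper) +
      k * log(hyper$alpha)
    sc <- vapply(ks, score, numeric(1))
    k0 <- ks[which.max(sc)]
    ks2 <- setdiff(unique(pmax(1, round(k0 * c(0.75, 0.875, 1.125, 1.25)))), ks)
    ks2 <- ks2[ks2 >= 1 & ks2 <= n]
    if (length(ks2)) {
      sc2 <- vapply(ks2, score, numeric(1))
      ks <- c(ks, ks2); sc <- c(sc, sc2)
    }
    z <- cut_ward_tree(wd, ks[which.max(sc)])
  }
  links <- links_from_labels(z, graph)
  .state_init(links, graph, hyper, dat)
}

#' Links realizing a given contiguous labelling
#'
#' Draws, for every parcel, a uniform random spanning tree of the parcel's
#' induced subgraph (Wilson's loop-erased random-walk algorithm) and orients
#' it toward a root self-link, so that the connected components of the
#' result reproduce `z` exactly.
#'
#' @param z label vector (each parcel must induce a connected subgraph).
#' @param graph a [spatial_graph()].
#' @return Integer link vector.
#' @export
links_from_labels <- function(z, graph) {
  z <- as_parcellation(z)$labels
  links <- integer(graph$n)
  for (lab in seq_len(max(z))) {
    mem <- which(z == lab)
    tree <- wilson_spanning_tree(mem, graph)
    links[mem] <- tree
  }
  links
}

# uniform spanning tree of the subgraph induced on `mem`; returns parent
# links (root links to itself), as global indices
wilson_spanning_tree <- function(mem, graph) {
  p <- length(mem)
  if (p == 1L) return(stats::setNames(mem, NULL))
  local <- integer(max(mem)); local[mem] <- seq_len(p)
  nb <- lapply(mem, function(v) {
    x <- graph$neighbors[[v]]
    x[x %in% mem]
  })
  in_tree <- logical(p)
  parent <- integer(p)
  root <- sample.int(p, 1L)
  in_tree[root] <- TRUE
  parent[root] <- root
  for (start in sample.int(p)) {
    if (in_tree[start]) next
    # loop-erased random walk recorded via next-pointers
    nxt <- integer(p)
    u <- start
    while (!in_tree[u]) {
      nbu <- nb[[u]]
      v <- local[nbu[sample.int(length(nbu), 1L)]]
      nxt[u] <- v
      u <- v
    }
    u <- start
    while (!in_tree[u]) {
      in_tree[u] <- TRUE
      parent[u] <- nxt[u]
      u <- nxt[u]
    }
  }
  if (any(!in_tree)) stop("parcel subgraph is not connected")
  mem[parent]
}

#' Run the collapsed Gibbs sampler
#'
#' Sweeps the elements in a fresh uniform random order each pass, updating
#' every link by [one collapsed Gibbs draw][sampler_init], and tracks the
#' maximum a posteriori state over the whole trajectory.
#'
#' @param D normalized [connectivity_matrix()] (use [normalize_matrix()]).
#' @param graph a connected [spatial_graph()].
#' @param hyper a [hyperparams()] object.
#' @param passes number of full sweeps (>= 1).
#' @param init,k_init initialization mode, see [sampler_init()].
#' @param state optional pre-built initial state (overrides `init`).
#' @param record_trace if `TRUE`, keep a per-step data.frame of
#'   (step, k, log posterior).
#' @param check_each_pass if `TRUE`, verify the incrementally maintained
#'   score against a from-scratch recomputation after every pass (drift
#'   guard; used by the test suite).
#' @return A list with `map` (links, labels, k, log_posterior of the best
#'   visited state), `final` (last state), `trace` (or `NULL`) and
#'   `max_drift` (largest bookkeeping drift seen, when checked).
#' @export
run_sampler <- function(D, graph, hyper, passes = 30,
                        init = "ward-auto", k_init = NULL, state = NULL,
                        record_trace = FALSE, check_each_pass = FALSE) {
  stopifnot(passes >= 1)
  dat <- .sampler_data(D)
  if (is.null(state))
    state <- sampler_init(dat$D, graph, hyper, init = init, k_init = k_init)
  lp <- .state_log_posterior(state, graph, hyper, dat)
  best <- list(links = state$links, labels = state$z, k = state$K,
               log_posterior = lp)
  n_steps <- passes * graph$n
  trace <- if (record_trace)
    list(step = integer(n_steps), k = integer(n_steps),
         log_posterior = numeric(n_steps))
  max_drift <- 0
  step <- 0L
  for (pass in seq_len(passes)) {
    for (i in sample.int(graph$n)) {
      step <- step + 1L
      state <- .gibbs_step(state, i, graph, hyper, dat)
      lp <- .state_log_posterior(state, graph, hyper, dat)
      if (lp > best$log_posterior)
        best <- list(links = state$links, labels = state$z, k = state$K,
                     log_posterior = lp)
      if (record_trace) {
        trace$step[step] <- step
        trace$k[step] <- state$K
        trace$log_posterior[step] <- lp
      }
    }
    if (check_each_pass) {
      fresh <- .state_init(state$links, graph, hyper, dat)
      drift <- abs(.state_log_posterior(state, graph, hyper, dat) -
                   .state_log_posterior(fresh, graph, hyper, dat))
      max_drift <- max(max_drift, drift)
    }
  }
  best$labels <- parcellation(best$labels)
  list(map = best, final = state,
       trace = if (record_trace) as.data.frame(trace),
       max_drift = max_drift)
}
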