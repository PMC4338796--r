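# Preprocessing for origin-destination flow matrices (e.g. migration
# between counties): merging of small units within their administrative
# group, and normalization of raw mover counts against the flow expected
# from population alone.

#' Origin-destination flow table
#'
#' @param units data.frame with columns `id` (unique unit ids, integers),
#'   `population` (> 0) and `group` (administrative group, e.g. state).
#' @param movers data.frame with columns `origin`, `dest`, `count`
#'   (annual movers, >= 0); pairs not listed are zero.  Self-flows are
#'   ignored.
#' @param graph a [spatial_graph()] over the units, in the row order of
#'   `units` (element `i` of the graph is `units$id[i]`).
#' @return Object of class `flow_table`.
#' @export
flow_table <- function(units, movers, graph) {
  stopifnot(all(c("id", "population", "group") %in% names(units)),
            all(c("origin", "dest", "count") %in% names(movers)),
            all(units$population > 0), all(movers$count >= 0),
            !anyDuplicated(units$id), graph$n == nrow(units))
  movers <- movers[movers$origin != movers$dest, , drop = FALSE]
  stopifnot(all(movers$origin %in% units$id),
            all(movers$dest %in% units$id))
  structure(list(units = units, movers = movers, graph = graph),
            class = "flow_table")
}

#' @export
print.flow_table <- function(x, ...) {
  cat("flow_table:", nrow(x$units), "units,", length(unique(x$units$group)),
      "groups,", sum(x$movers$count), "movers\n")
  invisible(x)
}

#' Merge small units into neighbours within their group
#'
#' Repeatedly takes the lowest-population unit below `min_pop` (ties by
#' unit id) and merges it with its lowest-population spatial neighbour in
#' the same group; populations and flows are summed, adjacency is the
#' union, and flows internal to a merged unit drop onto the ignored
#' diagonal.  Deterministic.
#'
#' @param t a [flow_table()].
#' @param min_pop population threshold.
#' @return A [flow_table()] in which every unit has population
#'   `>= min_pop`.  The surviving unit of each merge keeps the absorbing
#'   neighbour's id.
#' @export
merge_small_units <- function(t, min_pop) {
  units <- t$units
  n <- nrow(units)
  # adjacency as id sets
  nb <- lapply(seq_len(n), function(i) units$id[t$graph$neighbors[[i]]])
  names(nb) <- as.character(units$id)
  pop <- stats::setNames(units$population, units$id)
  grp <- stats::setNames(units$group, units$id)
  mv <- t$movers
  repeat {
    below <- names(pop)[pop < min_pop]
    if (!length(below)) break
    u <- below[order(pop[below], as.integer(below))][1L]
    cand <- nb[[u]][grp[as.character(nb[[u]])] == grp[u]]
    cand <- as.character(cand)
    if (!length(cand))
      stop("unit ", u, " is below min_pop but has no within-group neighbor")
    v <- cand[order(pop[cand], as.integer(cand))][1L]
    # absorb u into v
    pop[v] <- pop[v] + pop[u]
    pop <- pop[names(pop) != u]
    grp <- grp[names(grp) != u]
    uid <- as.integer(u); vid <- as.integer(v)
    mv$origin[mv$origin == uid] <- vid
    mv$dest[mv$dest == uid] <- vid
    nbu <- setdiff(union(nb[[u]], nb[[v]]), c(uid, vid))
    nb[[v]] <- nbu
    nb[[u]] <- NULL
    for (w in as.character(nbu)) {
      nb[[w]] <- setdiff(union(nb[[w]], vid), uid)
    }
  }
  mv <- mv[mv$origin != mv$dest, , drop = FALSE]
  mv <- stats::aggregate(count ~ origin + dest, data = mv, FUN = sum)
  ids <- as.integer(names(pop))
  ord <- order(ids)
  ids <- ids[ord]
  units2 <- data.frame(id = ids, population = as.numeric(pop[as.character(ids)]),
                       group = grp[as.character(ids)], row.names = NULL)
  idx <- stats::setNames(seq_along(ids), ids)
  edges <- do.call(rbind, lapply(as.character(ids), function(u)
    if (length(nb[[u]])) cbind(idx[u], idx[as.character(nb[[u]])]) else NULL))
  g2 <- spatial_graph(edges, n = length(ids))
  flow_table(units2, mv, g2)
}

#' Chance-normalize a flow table
#'
#' Converts raw mover counts into flows relative to the count expected if
#' movers chose origin and destination purely in proportion to population:
#' \deqn{D_{ab} = \frac{M_{ab}}{(\sum M) \; P_a P_b / (\sum P)^2}}
#' Values above 1 are above-chance flows.  The result is a nonnegative,
#' asymmetric [connectivity_matrix()] (diagonal ignored), in unit order of
#' the table.
#'
#' @param t a [flow_table()].
#' @return A [connectivity_matrix()].
#' @export
normalize_flows <- function(t) {
  n <- nrow(t$units)
  P <- t$units$population
  M <- matrix(0, n, n)
  oi <- match(t$movers$origin, t$units$id)
  di <- match(t$movers$dest, t$units$id)
  M[cbind(oi, di)] <- t$movers$count
  total <- sum(M)
  if (total <= 0) stop("total movers must be positive")
  chance <- total * outer(P, P) / sum(P)^2
  D <- M / chance
  diag(D) <- 0
  connectivity_matrix(D, symmetric = FALSE, diagonal_defined = FALSE)
}

#' Simulate a synthetic flow table with planted communities
#'
#' Synthetic stand-in for census-style migration data: units on a planar
#' grid with contiguous administrative groups (vertical bands) and
#' contiguous planted communities (random contiguous merges).  Mover counts
#' are Poisson with rate equal to the population-chance rate times a
#' community multiplier: `effect` within a community and 1 across; at
#' `effect = 1` the normalized flows are chance-level on average.
#'
#' @param n_units number of units (an `r x c` grid with `r = floor(sqrt)`).
#' @param n_groups number of administrative groups.
#' @param k_communities number of planted communities.
#' @param effect within-community rate multiplier (>= 1).
#' @param movers_per_unit expected total movers divided by `n_units`
#'   (controls sparsity).
#' @return List with `table` (a [flow_table()]) and `truth`
#'   (a [parcellation()] of the units into communities).  Uses the current
#'   R random stream.
#' @export
simulate_flow_table <- function(n_units, n_groups = 4, k_communities = 5,
                                effect = 20, movers_per_unit = 200) {
  stopifnot(k_communities <= n_units, effect >= 1)
  r <- max(1L, floor(sqrt(n_units)))
  while (n_units %% r != 0L) r <- r - 1L
  cc <- n_units %/% r
  graph <- grid_graph(r, cc)
  col_of <- rep(seq_len(cc), times = r)
  group <- cut(col_of, breaks = n_groups, labels = FALSE)
  truth <- balanced_contiguous_partition(graph, k_communities)
  pop <- round(stats::rlnorm(n_units, log(2e4), 0.4))
  total <- movers_per_unit * n_units
  chance <- total * outer(pop, pop) / sum(pop)^2
  mult <- 1 + (effect - 1) * outer(truth$labels, truth$labels, "==")
  M <- matrix(stats::rpois(n_units^2, chance * mult), n_units, n_units)
  diag(M) <- 0
  nz <- which(M > 0, arr.ind = TRUE)
  movers <- data.frame(origin = nz[, 1L], dest = nz[, 2L],
                       count = M[nz])
  units <- data.frame(id = seq_len(n_units), population = pop,
                      group = group)
  list(table = flow_table(units, movers, graph), truth = truth)
}

# planted-partition truth: grow k contiguous regions of comparable size by
# multi-source expansion from random seeds (smallest region claims a random
# unassigned neighbour each round)
balanced_contiguous_partition <- function(graph, k) {
  n <- graph$n
  z <- integer(n)
  z[sample.int(n, k)] <- seq_len(k)
  sizes <- rep(1L, k)
  while (any(z == 0L)) {
    for (lab in order(sizes)) {
      frontier <- unique(unlist(graph$neighbors[which(z == lab)],
                                use.names = FALSE))
      frontier <- frontier[z[frontier] == 0L]
      if (length(frontier)) {
        pick <- frontier[sample.int(length(frontier), 1L)]
        z[pick] <- lab
        sizes[lab] <- sizes[lab] + 1L
        break
      }
    }
  }
  parcellation(z)
}

#' Alignment of a parcellation with administrative borders
#'
#' NMI between a parcellation and the group (e.g. state) labelling, and a
#' Monte-Carlo null envelope from random contiguous parcellations with the
#' same number of clusters.
#'
#' @param p a [parcellation()] or label vector.
#' @param groups group labels of the same length.
#' @return `border_alignment()` returns the NMI (scalar).
#' @export
border_alignment <- function(p, groups) {
  nmi(p, groups)
}

#' @rdname border_alignment
#' @param graph a connected [spatial_graph()].
#' @param k number of clusters for the null parcellations.
#' @param n_draws Monte-Carlo replicates.
#' @return `border_alignment_null()` returns a list with `mean`, `lower`,
#'   `upper` (2.5% and 97.5% quantiles) and the vector of draws.
#' @export
border_alignment_null <- function(graph, k, groups, n_draws = 100) {
  draws <- vapply(seq_len(n_draws), function(i)
    nmi(random_parcellation(graph, k), groups), numeric(1))
  list(mean = mean(draws),
       lower = stats::quantile(draws, 0.025, names = FALSE),
       upper = stats::quantile(draws, 0.975, names = FALSE),
       draws = draws)
}
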