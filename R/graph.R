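#' Spatial adjacency graph
#'
#' A `spatial_graph` records the neighbour relation over the `n` elements of a
#' spatial map (grid cells, cortical vertices, counties, ...).  Parcels are
#' required to be connected in this graph.  Elements are indexed `1..n`, also
#' in all file formats read and written by this package.
#'
#' @param edges two-column integer matrix (or data.frame) of undirected edges;
#'   each row one unordered pair of element ids in `1..n`.  Duplicate rows and
#'   reversed duplicates are collapsed; self-edges are an error.
#' @param n number of elements.
#' @return An object of class `spatial_graph` with components `n` (element
#'   count), `edges` (canonical two-column matrix with `edges[,1] < edges[,2]`)
#'   and `neighbors` (list of integer vectors, the adjacency list).
#' @examples
#' g <- spatial_graph(rbind(c(1, 2), c(2, 3)), n = 3)
#' g$neighbors[[2]]
#' @export
spatial_graph <- function(edges, n) {
  n <- as.integer(n)
  stopifnot(length(n) == 1L, n >= 1L)
  edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(integer(0), 0L, 2L)
  }
  stopifnot(ncol(edges) == 2L)
  storage.mode(edges) <- "integer"
  if (any(edges < 1L | edges > n))
    stop("edge endpoint outside [1, n]")
  if (any(edges[, 1L] == edges[, 2L]))
    stop("self-edges are not allowed")
  a <- pmin(edges[, 1L], edges[, 2L])
  b <- pmax(edges[, 1L], edges[, 2L])
  keep <- !duplicated(a * (n + 1) + b)
  edges <- cbind(a[keep], b[keep])
  nb <- vector("list", n)
  tab <- split(c(edges[, 2L], edges[, 1L]), c(edges[, 1L], edges[, 2L]))
  for (nm in names(tab)) nb[[as.integer(nm)]] <- sort(unique(tab[[nm]]))
  for (i in seq_len(n)) if (is.null(nb[[i]])) nb[[i]] <- integer(0)
  structure(list(n = n, edges = edges, neighbors = nb),
            class = "spatial_graph")
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat("spatial_graph:", x$n, "elements,", nrow(x$edges), "edges\n")
  if (!is.null(attr(x, "grid_dim")))
    cat("  4-neighbor grid", attr(x, "grid_dim")[1], "x", attr(x, "grid_dim")[2], "\n")
  invisible(x)
}

#' Rectangular 4-neighbour grid graph
#'
#' Elements are laid out row-major: element `(r, c)` has index
#' `(r - 1) * ncol + c`.
#'
#' @param nrow,ncol grid dimensions.
#' @return A [spatial_graph()] with a `grid_dim` attribute used by plotting.
#' @examples
#' g <- grid_graph(18, 18)
#' @export
grid_graph <- function(nrow, ncol) {
  nrow <- as.integer(nrow); ncol <- as.integer(ncol)
  idx <- function(r, c) (r - 1L) * ncol + c
  r <- rep(seq_len(nrow), each = ncol)
  c <- rep(seq_len(ncol), times = nrow)
  right <- cbind(idx(r, c), idx(r, c + 1L))[c < ncol, , drop = FALSE]
  down  <- cbind(idx(r, c), idx(r + 1L, c))[r < nrow, , drop = FALSE]
  g <- spatial_graph(rbind(right, down), n = nrow * ncol)
  attr(g, "grid_dim") <- c(nrow, ncol)
  g
}

#' @rdname spatial_graph
#' @param graph object to test.
#' @export
is_spatial_graph <- function(graph) inherits(graph, "spatial_graph")

degree <- function(graph) lengths(graph$neighbors)

#' Connected components of a spatial graph
#'
#' @param graph a [spatial_graph()].
#' @param edges optional two-column matrix restricting the edge set (defaults
#'   to all edges of `graph`).
#' @return Integer vector of component labels in `1..n_components`, each
#'   component labelled by its smallest member index rank.
#' @keywords internal
graph_components <- function(graph, edges = graph$edges) {
  comp_of_edges(graph$n, edges)
}

# union-find over 1..n given an edge matrix; labels canonicalized so that
# components are numbered by order of their smallest member.  Union always
# attaches the larger root under the smaller, so each final root is its
# component's minimum member.
comp_of_edges <- function(n, edges) {
  parent <- seq_len(n)
  if (nrow(edges)) {
    e1 <- edges[, 1L]; e2 <- edges[, 2L]
    for (k in seq_along(e1)) {
      x <- e1[k]
      while (parent[x] != x) { parent[x] <- parent[parent[x]]; x <- parent[x] }
      y <- e2[k]
      while (parent[y] != y) { parent[y] <- parent[parent[y]]; y <- parent[y] }
      if (x != y) parent[max(x, y)] <- min(x, y)
    }
  }
  roots <- integer(n)
  for (i in seq_len(n)) {
    x <- i
    while (parent[x] != x) { parent[x] <- parent[parent[x]]; x <- parent[x] }
    roots[i] <- x
  }
  match(roots, sort(unique(roots)))
}

is_connected_graph <- function(graph) {
  graph$n <= 1L || max(graph_components(graph)) == 1L
}

#' Read and write edge lists
#'
#' Edge lists are two-column tab-separated files of element ids (1-based,
#' no header).
#'
#' @param path file path.
#' @param n element count; defaults to the largest id present.
#' @return `read_edges()` returns a [spatial_graph()].
#' @export
read_edges <- function(path, n = NULL) {
  e <- utils::read.table(path, sep = "\t", header = FALSE,
                         colClasses = "integer")
  if (is.null(n)) n <- max(e)
  spatial_graph(as.matrix(e), n = n)
}

#' @rdname read_edges
#' @param graph a [spatial_graph()] to write.
#' @export
write_edges <- function(graph, path) {
  utils::write.table(graph$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
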