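#' Parcellation (partition of the spatial map)
#'
#' A parcellation assigns each of the `n` elements a label in `1..k`; every
#' parcel is nonempty, and parcellations produced by this package are
#' connected in the spatial graph.  Labels are canonicalized so parcels are
#' numbered by the rank of their smallest member index, which makes
#' serialized output deterministic.
#'
#' @param labels integer vector of cluster labels (any values; recoded).
#' @return An object of class `parcellation` with components `labels`
#'   (canonical labels) and `k`.
#' @examples
#' p <- parcellation(c(7, 7, 2, 2))
#' p$labels  # 1 1 2 2
#' @export
parcellation <- function(labels) {
  labels <- as.integer(labels)
  if (anyNA(labels)) stop("labels must be non-missing")
  # number parcels in order of first appearance == by smallest member index
  labels <- match(labels, unique(labels))
  structure(list(labels = labels, k = max(labels)), class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat("parcellation:", length(x$labels), "elements,", x$k, "parcels; sizes:",
      paste(tabulate(x$labels, x$k), collapse = " "), "\n")
  invisible(x)
}

as_parcellation <- function(z) {
  if (inherits(z, "parcellation")) z else parcellation(z)
}

#' Neighbour-link state of the dd-CRP
#'
#' Each element `i` carries one link `links[i]`, either to itself or to a
#' spatial neighbour.  The induced parcellation is the set of connected
#' components of the undirected link graph, so every reachable partition is
#' spatially contiguous by construction.
#'
#' @param links integer vector; `links[i]` in `{i} U neighbors(i)`.
#' @param graph a [spatial_graph()]; if given, links are validated.
#' @return An object of class `link_state`.
#' @export
link_state <- function(links, graph = NULL) {
  links <- as.integer(links)
  if (!is.null(graph)) {
    stopifnot(length(links) == graph$n)
    for (i in seq_along(links)) {
      if (links[i] != i && !(links[i] %in% graph$neighbors[[i]]))
        stop("invalid link: ", i, " -> ", links[i], " is not a neighbor pair")
    }
  }
  structure(list(links = links), class = "link_state")
}

#' Parcellation induced by a link state
#'
#' Computes the undirected connected components of the link graph whose
#' edges are `{i, links[i]}` for every non-self link.
#'
#' @param links a [link_state()] or plain integer vector.
#' @param graph a [spatial_graph()] used to validate the links.
#' @return A [parcellation()].
#' @examples
#' g <- grid_graph(1, 4)
#' connected_components(c(1, 1, 4, 3), g)$labels  # 1 1 2 2
#' @export
connected_components <- function(links, graph) {
  if (inherits(links, "link_state")) links <- links$links
  links <- link_state(links, graph)$links
  nonself <- which(links != seq_along(links))
  edges <- cbind(nonself, links[nonself])
  parcellation(comp_of_edges(graph$n, edges))
}

#' Check spatial contiguity of a parcellation
#'
#' `TRUE` iff every parcel's induced subgraph of `graph` is connected.
#'
#' @param p a [parcellation()] or label vector.
#' @param graph a [spatial_graph()].
#' @return Logical scalar.
#' @export
assert_contiguous <- function(p, graph) {
  z <- as_parcellation(p)$labels
  stopifnot(length(z) == graph$n)
  e <- graph$edges
  same <- z[e[, 1L]] == z[e[, 2L]]
  comp <- comp_of_edges(graph$n, e[same, , drop = FALSE])
  # contiguous iff the within-parcel components refine to exactly the parcels
  all(tapply(comp, z, function(v) length(unique(v))) == 1L)
}

#' Read and write parcellation labels
#'
#' Two-column tab-separated text: `element_id<TAB>label`, 1-based, no header.
#'
#' @param path file path.
#' @return `read_labels()` returns a [parcellation()].
#' @export
read_labels <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE)
  parcellation(tab[order(tab[, 1L]), 2L])
}

#' @rdname read_labels
#' @param p parcellation (or label vector) to write.
#' @export
write_labels <- function(p, path) {
  z <- as_parcellation(p)$labels
  utils::write.table(cbind(seq_along(z), z), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
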