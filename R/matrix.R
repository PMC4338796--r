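#' Connectivity matrix container
#'
#' Wraps an `N x N` numeric matrix of pairwise connectivities `D` together
#' with its symmetry flag and the diagonal convention.  Self-connectivity
#' `D[i, i]` is excluded from normalization, from all block statistics and
#' from variance explained (`diagonal_defined = FALSE`, the default): for a
#' correlation matrix the diagonal is identically 1 and carries no
#' information.  When `symmetric = TRUE` only the upper-triangle entries
#' (`i < j`) count as observations, so each measured connectivity enters the
#' likelihood exactly once.
#'
#' @param values square numeric matrix.
#' @param symmetric logical; if `NULL`, detected from `values`.
#' @param diagonal_defined logical; whether diagonal entries are data.
#' @return An object of class `connectivity_matrix` with components `values`,
#'   `symmetric`, `diagonal_defined`.
#' @examples
#' D <- connectivity_matrix(matrix(c(0, 1, 1, 0), 2))
#' D$symmetric
#' @export
connectivity_matrix <- function(values, symmetric = NULL,
                                diagonal_defined = FALSE) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("connectivity matrix must be square")
  storage.mode(values) <- "double"
  if (is.null(symmetric)) symmetric <- isSymmetric(unname(values))
  if (symmetric && !isTRUE(all.equal(values, t(values), tolerance = 1e-8,
                                     check.attributes = FALSE)))
    stop("symmetric = TRUE but values are not symmetric")
  structure(list(values = unname(values), symmetric = isTRUE(symmetric),
                 diagonal_defined = isTRUE(diagonal_defined)),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("connectivity_matrix:", nrow(x$values), "x", ncol(x$values),
      if (x$symmetric) "(symmetric)" else "(asymmetric)",
      if (x$diagonal_defined) "diagonal included" else "diagonal excluded",
      "\n")
  invisible(x)
}

as_connectivity <- function(D, symmetric = NULL, diagonal_defined = FALSE) {
  if (inherits(D, "connectivity_matrix")) D
  else connectivity_matrix(D, symmetric, diagonal_defined)
}

# logical index of included entries (vectorized over the full matrix)
included_mask <- function(D) {
  n <- nrow(D$values)
  m <- matrix(TRUE, n, n)
  if (!D$diagonal_defined) diag(m) <- FALSE
  if (D$symmetric) m[lower.tri(m)] <- FALSE
  m
}

#' Standardize a connectivity matrix
#'
#' Rescales the included entries of `D` (see [connectivity_matrix()] for the
#' diagonal and symmetry conventions) to sample mean 0 and sample variance 1.
#' Hyperparameters of the parcellation model are comparable across datasets
#' of the same size only after this normalization.
#'
#' @param D a [connectivity_matrix()] or plain matrix.
#' @return A `connectivity_matrix` with standardized entries; excluded
#'   diagonal entries are set to 0.  Symmetry is preserved.
#' @examples
#' D <- connectivity_matrix(matrix(c(0, 1, 3, 0), 2), symmetric = FALSE)
#' normalize_matrix(D)$values
#' @export
normalize_matrix <- function(D) {
  D <- as_connectivity(D)
  mask <- included_mask(D)
  x <- D$values[mask]
  if (length(x) < 2L) stop("need at least two included entries")
  v <- mean((x - mean(x))^2)      # population variance
  if (v < .Machine$double.eps) stop("constant matrix: zero variance")
  vals <- (D$values - mean(x)) / sqrt(v)
  if (D$symmetric) vals[lower.tri(vals)] <- t(vals)[lower.tri(vals)]
  if (!D$diagonal_defined) diag(vals) <- 0
  connectivity_matrix(vals, symmetric = D$symmetric,
                      diagonal_defined = D$diagonal_defined)
}

#' Read and write connectivity matrices
#'
#' Matrices are stored as dense delimited text (tab or comma); a JSON sidecar
#' `<path>.json` records the symmetry flag and diagonal convention so that a
#' round trip restores the container exactly.
#'
#' @param path file path of the matrix body.
#' @param sep field separator.
#' @return `read_matrix()` returns a [connectivity_matrix()].
#' @export
read_matrix <- function(path, sep = "\t") {
  vals <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    connectivity_matrix(vals, symmetric = isTRUE(meta$symmetric),
                        diagonal_defined = isTRUE(meta$diagonal_defined))
  } else {
    connectivity_matrix(vals)
  }
}

#' @rdname read_matrix
#' @param D matrix to write.
#' @export
write_matrix <- function(D, path, sep = "\t") {
  D <- as_connectivity(D)
  utils::write.table(D$values, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(symmetric = D$symmetric,
                            diagonal_defined = D$diagonal_defined),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
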