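#' Graph operators for a Markov signalling model
#'
#' From the adjacency induced by the chosen variant, builds the degree
#' matrix `D` (row sums of A), the Laplacian (Kirchhoff) matrix `L = D - A`,
#' its Moore-Penrose pseudoinverse, and the row-stochastic transition matrix
#' `M = D^-1 A` of the random walk a signal is assumed to take.
#'
#' The pseudoinverse is computed by full symmetric eigendecomposition with
#' eigenvalues below `1e-10 * max(eigenvalue)` treated as the null space;
#' for a connected graph exactly one eigenvalue is dropped.
#'
#' @param connectome a [structural_connectome()].
#' @param variant which adjacency to operate on: `"density"` (raw tract
#'   counts, the default), `"binary"` (1 where a tract exists),
#'   `"length"` (mean tract lengths as weights) or `"inverse_length"`
#'   (1/length on the tract support).
#' @return object of class `graph_operators`: list with `adjacency`,
#'   `degree` (vector of `D_ii`), `laplacian`, `laplacian_pinv`,
#'   `transition`, `variant`, `region_labels`, and the originating
#'   `connectome`.
#' @export
build_operators <- function(connectome,
                            variant = c("density", "binary", "length",
                                        "inverse_length")) {
  stopifnot(inherits(connectome, "structural_connectome"))
  variant <- match.arg(variant)
  W <- connectome$weights
  A <- switch(variant,
    density = W,
    binary = (W > 0) * 1,
    length = {
      if (is.null(connectome$lengths))
        stop("variant 'length' requires a lengths matrix", call. = FALSE)
      connectome$lengths
    },
    inverse_length = {
      if (is.null(connectome$lengths))
        stop("variant 'inverse_length' requires a lengths matrix",
             call. = FALSE)
      out <- W * 0
      sup <- connectome$lengths > 0
      out[sup] <- 1 / connectome$lengths[sup]
      out
    })
  dimnames(A) <- dimnames(W)

  comp <- graph_components(A)
  if (max(comp) > 1) {
    sizes <- table(comp)
    stop("graph is disconnected (", length(sizes), " components of sizes ",
         paste(sizes, collapse = ", "),
         "); commute time is undefined across components", call. = FALSE)
  }

  d <- rowSums(A)
  if (any(d <= 0))
    stop("zero-degree region(s): ",
         paste(connectome$region_labels[d <= 0], collapse = ", "),
         call. = FALSE)
  L <- diag(d) - A
  eig <- eigen(L, symmetric = TRUE)
  keep <- eig$values > 1e-10 * max(eig$values)
  V <- eig$vectors[, keep, drop = FALSE]
  Lp <- V %*% (t(V) / eig$values[keep])
  Lp <- (Lp + t(Lp)) / 2
  M <- A / d
  dimnames(L) <- dimnames(Lp) <- dimnames(M) <- dimnames(A)

  structure(
    list(adjacency = A, degree = d, laplacian = L, laplacian_pinv = Lp,
         transition = M, variant = variant,
         region_labels = connectome$region_labels, connectome = connectome),
    class = "graph_operators")
}

#' @export
print.graph_operators <- function(x, ...) {
  cat("graph_operators:", length(x$degree), "regions, variant =",
      x$variant, "\n")
  invisible(x)
}

# Connected-component labels of the graph induced by nonzero entries.
graph_components <- function(A) {
  g <- igraph::graph_from_adjacency_matrix(A > 0, mode = "undirected",
                                           diag = FALSE)
  igraph::components(g)$membership
}

is_connected_adjacency <- function(A) max(graph_components(A)) == 1
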