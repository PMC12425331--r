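#' Pairwise metric container
#'
#' An N x N region-by-region metric matrix with a tag identifying the
#' metric. Hitting time and raw search information are asymmetric; all
#' other tags are symmetric with zero diagonal where the metric is a
#' distance-like quantity.
#'
#' @param values N x N numeric matrix.
#' @param metric_tag one of `"commute_time"`, `"hitting_time"`,
#'   `"mfpt_commute"`, `"communicability"`, `"search_information"`,
#'   `"connectivity"`, `"resistance"`.
#' @param symmetric logical; whether `values` is symmetric.
#' @param meta optional list of computation settings recorded with the
#'   output (conventions, normalizations).
#' @return object of class `pairwise_metric`.
#' @export
pairwise_metric <- function(values, metric_tag, symmetric, meta = list()) {
  tags <- c("commute_time", "hitting_time", "mfpt_commute", "communicability",
            "search_information", "connectivity", "resistance")
  if (!metric_tag %in% tags)
    stop("unknown metric_tag: ", metric_tag, call. = FALSE)
  structure(list(values = values, metric_tag = metric_tag,
                 symmetric = symmetric, meta = meta),
            class = "pairwise_metric")
}

#' @export
print.pairwise_metric <- function(x, ...) {
  cat("pairwise_metric [", x$metric_tag, "]: ", nrow(x$values), " x ",
      ncol(x$values), if (x$symmetric) ", symmetric" else ", asymmetric",
      "\n", sep = "")
  invisible(x)
}

#' Hitting time of the structural random walk
#'
#' Expected number of steps for a random walker following the transition
#' matrix `M = D^-1 A` to first reach region `j` from region `i`, computed
#' in closed form from the Laplacian pseudoinverse `G`:
#' `H[i, j] = sum_k (G[i, k] - G[i, j] - G[j, k] + G[j, j]) * D[k, k]`.
#' Asymmetric; `H[i, i] = 0`.
#'
#' @param ops a [build_operators()] result.
#' @return `pairwise_metric` tagged `hitting_time`.
#' @export
hitting_time <- function(ops) {
  G <- ops$laplacian_pinv
  d <- ops$degree
  S <- sum(d)
  gd <- as.vector(G %*% d)
  g <- diag(G)
  n <- length(d)
  # H_ij = (G d)_i - (G d)_j + S * (G_jj - G_ij)
  H <- outer(gd, rep(1, n)) - outer(rep(1, n), gd) +
    S * (outer(rep(1, n), g) - G)
  diag(H) <- 0
  dimnames(H) <- dimnames(G)
  pairwise_metric(H, "hitting_time", symmetric = FALSE)
}

#' Commute time between brain regions
#'
#' Expected number of random-walk steps to go from region `i` to `j` and
#' back, `C = H + t(H)`, evaluated directly from the Laplacian
#' pseudoinverse: `C[i, j] = (G[i, i] + G[j, j] - 2 G[i, j]) * sum(D)`.
#' Symmetric with zero diagonal; strictly positive off-diagonal for a
#' connected graph.
#'
#' @inheritParams hitting_time
#' @return `pairwise_metric` tagged `commute_time`.
#' @export
commute_time <- function(ops) {
  G <- ops$laplacian_pinv
  S <- sum(ops$degree)
  g <- diag(G)
  C <- S * (outer(g, g, `+`) - 2 * G)
  diag(C) <- 0
  dimnames(C) <- dimnames(G)
  pairwise_metric(C, "commute_time", symmetric = TRUE)
}

#' Resistance distance
#'
#' Effective electrical resistance between regions when each tract is a
#' conductor: `Omega[i, j] = G[i, i] + G[j, j] - 2 G[i, j]`. Proportional
#' to commute time via `C = Omega * sum(D)`, an identity used as a
#' cross-check throughout the test-suite.
#'
#' @inheritParams hitting_time
#' @return `pairwise_metric` tagged `resistance`.
#' @export
resistance_distance <- function(ops) {
  G <- ops$laplacian_pinv
  g <- diag(G)
  R <- outer(g, g, `+`) - 2 * G
  diag(R) <- 0
  dimnames(R) <- dimnames(G)
  pairwise_metric(R, "resistance", symmetric = TRUE)
}

#' Commute time via mean first passage times
#'
#' Mean first passage times of the chain `M` from its fundamental matrix
#' `Z = (I - M + 1 pi')^-1` with stationary distribution
#' `pi_i = D_ii / sum(D)`: `mfpt[i, j] = (Z[j, j] - Z[i, j]) / pi_j`.
#' The commute variant is `mfpt + t(mfpt)` (symmetric, zero diagonal).
#'
#' @inheritParams hitting_time
#' @return `pairwise_metric` tagged `mfpt_commute`; the asymmetric MFPT
#'   matrix is attached as `meta$mfpt`.
#' @export
mfpt_commute_time <- function(ops) {
  M <- ops$transition
  n <- nrow(M)
  pi_ <- ops$degree / sum(ops$degree)
  Z <- solve(diag(n) - M + outer(rep(1, n), pi_))
  mfpt <- (outer(rep(1, n), diag(Z)) - Z) / outer(rep(1, n), pi_)
  diag(mfpt) <- 0
  C <- mfpt + t(mfpt)
  dimnames(C) <- dimnames(mfpt) <- dimnames(M)
  pairwise_metric(C, "mfpt_commute", symmetric = TRUE,
                  meta = list(mfpt = mfpt, method = "fundamental_matrix"))
}

#' Communicability
#'
#' Factorially weighted sum over walks of all lengths between two regions,
#' computed on the degree-normalized adjacency
#' `A'[i, j] = A[i, j] / sqrt(D_ii D_jj)`. The default realizes the walk
#' series as the matrix exponential `expm(A')` (spectral decomposition);
#' `method = "elementwise"` instead applies the scalar exponential to each
#' normalized entry, retained for comparison of the two readings of the
#' normalized-exponential formula.
#'
#' @inheritParams hitting_time
#' @param method `"matrix_exp"` (default) or `"elementwise"`.
#' @return `pairwise_metric` tagged `communicability`.
#' @export
communicability <- function(ops, method = c("matrix_exp", "elementwise")) {
  method <- match.arg(method)
  d <- ops$degree
  if (any(d <= 0)) stop("zero-degree node", call. = FALSE)
  An <- ops$adjacency / sqrt(outer(d, d))
  CMY <- if (method == "matrix_exp") {
    eig <- eigen(An, symmetric = TRUE)
    V <- eig$vectors
    out <- V %*% (exp(eig$values) * t(V))
    (out + t(out)) / 2
  } else {
    exp(An)
  }
  dimnames(CMY) <- dimnames(ops$adjacency)
  pairwise_metric(CMY, "communicability", symmetric = TRUE,
                  meta = list(method = method,
                              normalization = "symmetric_sqrt_degree"))
}

#' Search information
#'
#' Bits a random walker needs to follow the shortest path from `i` to `j`:
#' `SI(i, j) = -log2(prod of M transition probabilities along the path)`,
#' with the shortest path computed on the tract-length-weighted graph
#' (fallback: distances `1/A` when no lengths are available). Positive-bits
#' sign convention. Shortest-path ties are broken deterministically by
#' lexicographic predecessor index. The raw matrix is asymmetric; the
#' symmetrized mean `(SI + t(SI)) / 2` used for pair-level correlation is
#' attached as `meta$symmetrized`.
#'
#' @inheritParams hitting_time
#' @return `pairwise_metric` tagged `search_information` (raw, asymmetric).
#' @export
search_information <- function(ops) {
  conn <- ops$connectome
  M <- ops$transition
  n <- nrow(M)
  W <- if (!is.null(conn$lengths)) {
    conn$lengths
  } else {
    out <- conn$weights * 0
    sup <- conn$weights > 0
    out[sup] <- 1 / conn$weights[sup]
    out
  }
  D <- matrix(Inf, n, n)
  D[W > 0] <- W[W > 0]

  logM <- matrix(-Inf, n, n)
  logM[M > 0] <- log2(M[M > 0])

  si <- matrix(0, n, n)
  for (src in seq_len(n)) {
    dist <- rep(Inf, n); dist[src] <- 0
    pred <- rep(NA_integer_, n)
    visited <- rep(FALSE, n)
    for (it in seq_len(n)) {
      cand <- dist
      cand[visited] <- Inf
      u <- which.min(cand) # lowest index among ties
      if (is.infinite(cand[u])) break
      visited[u] <- TRUE
      nbr <- which(is.finite(D[u, ]) & !visited)
      for (v in nbr) {
        nd <- dist[u] + D[u, v]
        if (nd < dist[v] - 1e-12) {
          dist[v] <- nd
          pred[v] <- u
        } else if (abs(nd - dist[v]) <= 1e-12 && u < pred[v]) {
          pred[v] <- u
        }
      }
    }
    # accumulate -log2 path probability down the predecessor tree
    lp <- rep(NA_real_, n); lp[src] <- 0
    for (v in order(dist)) {
      if (v == src) next
      lp[v] <- lp[pred[v]] + logM[pred[v], v]
    }
    si[src, ] <- -lp
    si[src, src] <- 0
  }
  dimnames(si) <- dimnames(M)
  pairwise_metric(si, "search_information", symmetric = FALSE,
                  meta = list(sign_convention = "bits_positive",
                              distances = if (is.null(conn$lengths))
                                "inverse_weight" else "tract_length",
                              symmetrized = (si + t(si)) / 2))
}

#' Symmetrized values of a pairwise metric
#'
#' Returns the matrix used for pair-level correlation: the metric values
#' themselves when symmetric, the documented mean symmetrization for
#' hitting time and search information.
#'
#' @param m a `pairwise_metric`.
#' @return numeric matrix.
#' @export
metric_values <- function(m) {
  stopifnot(inherits(m, "pairwise_metric"))
  if (m$symmetric) m$values else (m$values + t(m$values)) / 2
}
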