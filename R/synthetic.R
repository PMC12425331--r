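#' Specification of a synthetic structural connectome
#'
#' Defines the statistical structure of dMRI-like tract-count matrices.
#' Regions are embedded in two hemispheric slabs of 3-D space; tract
#' lengths follow the region geometry (inter-hemisphere tracts are
#' necessarily longer than intra-hemisphere ones), and streamline counts
#' decay exponentially with tract length (the well-documented length bias
#' of tractography) with log-normal multiplicative scatter. The closest
#' `intra_density` fraction of within-hemisphere pairs and
#' `inter_density` fraction of between-hemisphere pairs are connected, so
#' intra-hemisphere connectivity is both denser and stronger. The
#' strongest edge (the "dominant bundle") is calibrated so that the median
#' region degree is `bundle_degree_ratio` times the maximum weight, fixing
#' the scale of the max-normalized adjacency that the Ising simulation
#' operates on. Region `i` in the left hemisphere is homotopic to region
#' `i + n/2` in the right.
#'
#' @param n_regions even region count (default 84, Desikan-Killiany
#'   scale).
#' @param intra_density fraction of within-hemisphere pairs connected, in
#'   (0, 1].
#' @param inter_density fraction of between-hemisphere pairs connected,
#'   `<= intra_density`.
#' @param weight_log_mean log of the streamline-count scale at the
#'   shortest tract (default `log(2e4)`, the order of the largest bundles
#'   seen in deterministic tractography).
#' @param weight_log_sd sdlog of the multiplicative scatter around the
#'   length rule.
#' @param length_decay e-folding length (mm) of the count-vs-length decay.
#' @param bundle_degree_ratio target ratio median(degree) / max(weight)
#'   after dominant-bundle calibration; set `NA` to skip calibration.
#' @param homotopic_weight tract count added to every homotopic pair
#'   (0 = none; dMRI under-detects homotopic tracts).
#' @param length_scale mean intra-hemisphere tract length, mm (scales the
#'   whole geometry).
#' @param seed integer seed; generation is fully reproducible.
#' @return object of class `connectome_spec`.
#' @export
connectome_spec <- function(n_regions = 84, intra_density = 0.35,
                            inter_density = 0.15,
                            weight_log_mean = log(2e4), weight_log_sd = 1,
                            length_decay = 15, bundle_degree_ratio = 0.5,
                            homotopic_weight = 0, length_scale = 60,
                            seed = 1) {
  if (n_regions %% 2 != 0 || n_regions < 4)
    stop("n_regions must be even and >= 4", call. = FALSE)
  if (intra_density <= 0 || intra_density > 1 ||
      inter_density < 0 || inter_density > 1)
    stop("densities must lie in (0, 1]", call. = FALSE)
  if (inter_density > intra_density)
    stop("inter_density must not exceed intra_density", call. = FALSE)
  if (inter_density == 0 && homotopic_weight == 0)
    stop("inter_density = 0 with no homotopic tracts disconnects the ",
         "hemispheres", call. = FALSE)
  if (length_decay <= 0 || length_scale <= 0)
    stop("length_decay and length_scale must be positive", call. = FALSE)
  structure(list(n_regions = as.integer(n_regions),
                 intra_density = intra_density,
                 inter_density = inter_density,
                 weight_log_mean = weight_log_mean,
                 weight_log_sd = weight_log_sd,
                 length_decay = length_decay,
                 bundle_degree_ratio = bundle_degree_ratio,
                 homotopic_weight = homotopic_weight,
                 length_scale = length_scale, seed = as.integer(seed)),
            class = "connectome_spec")
}

#' Generate a synthetic structural connectome
#'
#' Draws the geometric, hemispherically blocked tract-count matrix
#' described by the spec (see [connectome_spec()]), with a tract-length
#' matrix on the same support. If the sampled graph is disconnected,
#' components are bridged deterministically (continuing the seeded RNG
#' stream) with single-count tracts until connected, so every output
#' satisfies the connectome invariants without repair.
#'
#' @param spec a [connectome_spec()].
#' @return a [structural_connectome()] with hemisphere labels, lengths and
#'   the homotopic map `(i, i + n/2)`.
#' @export
generate_connectome <- function(spec) {
  stopifnot(inherits(spec, "connectome_spec"))
  set.seed(spec$seed)
  n <- spec$n_regions
  half <- n %/% 2
  hemi <- rep(c("left", "right"), each = half)
  sc <- spec$length_scale / 60  # geometry templated on an adult brain, mm

  # region centroids: two slabs separated along x (left negative)
  pos <- rbind(
    cbind(stats::runif(half, -70, -10), stats::runif(half, -80, 80),
          stats::runif(half, -50, 60)),
    cbind(stats::runif(half, 10, 70), stats::runif(half, -80, 80),
          stats::runif(half, -50, 60))) * sc
  D <- as.matrix(stats::dist(pos))

  ut <- which(upper.tri(D), arr.ind = TRUE)
  intra <- hemi[ut[, 1]] == hemi[ut[, 2]]
  di <- D[ut]
  keep <- logical(nrow(ut))
  keep[intra] <- rank(di[intra], ties.method = "first") <=
    spec$intra_density * sum(intra)
  keep[!intra] <- rank(di[!intra], ties.method = "first") <=
    spec$inter_density * sum(!intra)

  w <- pmax(1, round(exp(spec$weight_log_mean) *
                       exp(-(di - min(di)) / (spec$length_decay * sc)) *
                       stats::rlnorm(nrow(ut), 0, spec$weight_log_sd)))
  A <- matrix(0, n, n)
  Lm <- matrix(0, n, n)
  A[ut[keep, , drop = FALSE]] <- w[keep]
  Lm[ut[keep, , drop = FALSE]] <- di[keep] * 1.3  # curved tracts
  A <- A + t(A)
  Lm <- Lm + t(Lm)

  homotopic <- cbind(seq_len(half), seq_len(half) + half)
  if (spec$homotopic_weight > 0) {
    A[homotopic] <- A[homotopic] + spec$homotopic_weight
    A[homotopic[, 2:1]] <- A[homotopic]
    need <- Lm[homotopic] == 0
    Lm[homotopic][need] <- D[homotopic][need] * 1.3
    Lm[homotopic[, 2:1]] <- Lm[homotopic]
  }

  # deterministic bridging to enforce connectedness
  repeat {
    comp <- graph_components(A)
    if (max(comp) == 1) break
    a <- which(comp == 1)[1]
    b <- which(comp == 2)[1]
    A[a, b] <- A[b, a] <- 1
    Lm[a, b] <- Lm[b, a] <- D[a, b] * 1.3
  }

  # dominant-bundle calibration: pins the scale of the max-normalized
  # adjacency (median degree / max weight), the quantity the mean-field
  # Ising coupling actually sees
  if (is.finite(spec$bundle_degree_ratio)) {
    wstar <- round(stats::median(rowSums(A)) / spec$bundle_degree_ratio)
    im <- which(A == max(A), arr.ind = TRUE)[1, ]
    A[im[1], im[2]] <- A[im[2], im[1]] <- max(wstar, max(A))
  }

  labels <- c(paste0("L.", sprintf("R%02d", seq_len(half))),
              paste0("R.", sprintf("R%02d", seq_len(half))))
  structural_connectome(A, region_labels = labels, hemisphere = hemi,
                        lengths = Lm, homotopic_pairs = homotopic)
}

#' Shuffled-structure null connectome
#'
#' Randomly permutes the upper-triangle entries of the weight matrix
#' (mirrored to the lower triangle), preserving the weight multiset,
#' symmetry and zero diagonal while destroying the topology. Disconnected
#' permutations are resampled (deterministically from `seed`) until the
#' null is connected.
#'
#' @param c a [structural_connectome()].
#' @param seed integer seed.
#' @return a [structural_connectome()] (lengths are dropped: the
#'   permutation has no meaningful length assignment).
#' @export
shuffle_null <- function(c, seed = 1) {
  stopifnot(inherits(c, "structural_connectome"))
  set.seed(seed)
  n <- c$n_regions
  ut <- upper.tri(c$weights)
  vals <- c$weights[ut]
  repeat {
    A <- matrix(0, n, n)
    A[ut] <- sample(vals)
    A <- A + t(A)
    if (is_connected_adjacency(A)) break
  }
  structural_connectome(A, region_labels = c$region_labels,
                        hemisphere = c$hemisphere,
                        homotopic_pairs = c$homotopic_pairs)
}

#' Add homotopic tracts
#'
#' Adds `k` streamline counts to every homotopic pair (both triangles),
#' leaving everything else unchanged.
#'
#' @param c a [structural_connectome()] with a homotopic map.
#' @param k tract count to add, >= 0.
#' @return a new [structural_connectome()].
#' @export
add_homotopic_tracts <- function(c, k) {
  stopifnot(inherits(c, "structural_connectome"))
  if (k < 0) stop("k must be >= 0", call. = FALSE)
  if (is.null(c$homotopic_pairs))
    stop("connectome has no homotopic map", call. = FALSE)
  A <- c$weights
  A[c$homotopic_pairs] <- A[c$homotopic_pairs] + k
  A[c$homotopic_pairs[, c(2, 1), drop = FALSE]] <- A[c$homotopic_pairs]
  lengths <- adjust_lengths(c, A)
  structural_connectome(A, region_labels = c$region_labels,
                        hemisphere = c$hemisphere, lengths = lengths,
                        homotopic_pairs = c$homotopic_pairs)
}

#' Add tracts at random non-homotopic positions
#'
#' The budget-matched control for [add_homotopic_tracts()]: the same
#' number of pair entries receive `+k`, at uniformly random off-diagonal
#' non-homotopic positions.
#'
#' @inheritParams add_homotopic_tracts
#' @param seed integer seed for the position draw.
#' @return a new [structural_connectome()].
#' @export
add_random_tracts <- function(c, k, seed = 1) {
  stopifnot(inherits(c, "structural_connectome"))
  if (k < 0) stop("k must be >= 0", call. = FALSE)
  if (is.null(c$homotopic_pairs))
    stop("connectome has no homotopic map (needed to match the budget)",
         call. = FALSE)
  set.seed(seed)
  n <- c$n_regions
  ut <- which(upper.tri(c$weights), arr.ind = TRUE)
  hom_id <- c$homotopic_pairs[, 1] * (n + 1) + c$homotopic_pairs[, 2]
  cand <- which(!(pmin(ut[, 1], ut[, 2]) * (n + 1) +
                    pmax(ut[, 1], ut[, 2])) %in% hom_id)
  m <- nrow(c$homotopic_pairs)
  if (m > length(cand))
    stop("not enough non-homotopic positions", call. = FALSE)
  pick <- ut[sample(cand, m), , drop = FALSE]
  A <- c$weights
  A[pick] <- A[pick] + k
  A[pick[, c(2, 1), drop = FALSE]] <- A[pick]
  lengths <- adjust_lengths(c, A)
  structural_connectome(A, region_labels = c$region_labels,
                        hemisphere = c$hemisphere, lengths = lengths,
                        homotopic_pairs = c$homotopic_pairs)
}

# Newly created edges inherit the mean inter-hemisphere tract length so the
# lengths matrix keeps sharing the weight support.
adjust_lengths <- function(c, A_new) {
  if (is.null(c$lengths)) return(NULL)
  L <- c$lengths
  new_edges <- A_new > 0 & L == 0
  if (any(new_edges)) {
    inter <- outer(c$hemisphere, c$hemisphere, `!=`)
    fill <- mean(L[inter & L > 0])
    if (!is.finite(fill)) fill <- mean(L[L > 0])
    L[new_edges] <- fill
  }
  L
}
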