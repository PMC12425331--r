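#' Configuration of the mean-field Ising simulator
#'
#' @param lambda global coupling strength (dimensionless, >= 0). Scales the
#'   energy `E = -lambda * sum_ij A_ij s_i s_j`.
#' @param n_steps number of timesteps (frames) to record.
#' @param flip_fraction fraction of regions whose spins are proposed for a
#'   flip each timestep.
#' @param burn_in_fraction fraction of initial frames discarded before
#'   functional connectivity is computed.
#' @param adjacency_normalization `"max_one"` (divide by the maximum
#'   off-diagonal weight; default), `"mean_one"` (divide by the mean
#'   nonzero weight) or `"none"`.
#' @param seed integer seed; the full trajectory is reproducible from it.
#' @return object of class `ising_config`.
#' @export
ising_config <- function(lambda, n_steps = 5000, flip_fraction = 0.15,
                         burn_in_fraction = 0.2,
                         adjacency_normalization = c("max_one", "mean_one",
                                                     "none"),
                         seed = 1) {
  adjacency_normalization <- match.arg(adjacency_normalization)
  if (!is.numeric(lambda) || lambda < 0)
    stop("lambda must be >= 0", call. = FALSE)
  if (n_steps < 1) stop("n_steps must be >= 1", call. = FALSE)
  if (flip_fraction <= 0 || flip_fraction > 1)
    stop("flip_fraction must lie in (0, 1]", call. = FALSE)
  if (burn_in_fraction < 0 || burn_in_fraction >= 1)
    stop("burn_in_fraction must lie in [0, 1)", call. = FALSE)
  structure(list(lambda = lambda, n_steps = as.integer(n_steps),
                 flip_fraction = flip_fraction,
                 burn_in_fraction = burn_in_fraction,
                 adjacency_normalization = adjacency_normalization,
                 seed = as.integer(seed),
                 acceptance = "sequential_single_flip"),
            class = "ising_config")
}

normalize_adjacency <- function(A, normalization) {
  off <- A[upper.tri(A) | lower.tri(A)]
  switch(normalization,
         max_one = A / max(off),
         mean_one = A / mean(off[off > 0]),
         none = A)
}

#' Run the mean-field Ising simulation on a connectome
#'
#' Spins (+1/-1) sit on the regions; the (normalized) tract-count matrix
#' couples them with strength `lambda`. Spins are initialized uniformly at
#' random; each timestep a random subset of `ceil(flip_fraction * N)`
#' regions is proposed and flipped one-by-one under Metropolis-Hastings
#' (accept when the energy does not increase, else with probability
#' `exp(-dE)`). One frame is recorded per timestep.
#'
#' @param connectome a [structural_connectome()].
#' @param cfg an [ising_config()].
#' @return object of class `ising_trajectory`: list with `spins`
#'   (n_steps x N matrix of +1/-1), `energy_trace`, `config`.
#' @export
run_ising <- function(connectome, cfg) {
  stopifnot(inherits(connectome, "structural_connectome"),
            inherits(cfg, "ising_config"))
  if (!is_connected_adjacency(connectome$weights))
    stop("Ising simulation requires a connected connectome", call. = FALSE)
  A <- normalize_adjacency(connectome$weights,
                           cfg$adjacency_normalization)
  set.seed(cfg$seed)
  res <- ising_run_cpp(A, cfg$lambda, cfg$n_steps, cfg$flip_fraction)
  spins <- res$spins
  colnames(spins) <- connectome$region_labels
  structure(list(spins = spins, energy_trace = as.numeric(res$energy),
                 config = cfg),
            class = "ising_trajectory")
}

#' @export
print.ising_trajectory <- function(x, ...) {
  cat("ising_trajectory:", nrow(x$spins), "frames x", ncol(x$spins),
      "regions, lambda =", x$config$lambda, "\n")
  invisible(x)
}

#' Recompute the energy trace from stored spins
#'
#' @param traj an [run_ising()] trajectory.
#' @param connectome the connectome it was simulated on.
#' @return numeric vector of per-frame energies
#'   `-lambda * sum_ij A_ij s_i s_j` under the trajectory's normalization.
#' @export
ising_energy <- function(traj, connectome) {
  A <- normalize_adjacency(connectome$weights,
                           traj$config$adjacency_normalization)
  apply(traj$spins, 1, function(s) -traj$config$lambda * sum(s * (A %*% s)))
}

#' Canonical double-gamma hemodynamic response kernel
#'
#' `h(t) = dgamma(t, peak + 1, 1) - ratio * dgamma(t, undershoot + 1, 1)`,
#' sampled at `dt` over `len` time-units and normalized to unit sum. With
#' unit dispersions the positive lobe peaks at `peak` time-units and the
#' undershoot at `undershoot`.
#'
#' @param len kernel length in time-units.
#' @param peak peak delay (mode of the positive lobe), time-units.
#' @param undershoot undershoot delay, time-units.
#' @param ratio undershoot amplitude ratio.
#' @param dt sampling interval (seconds per frame).
#' @return numeric kernel vector with attribute `spec` recording the
#'   parameters.
#' @export
hrf_kernel <- function(len = 32, peak = 6, undershoot = 16, ratio = 1 / 6,
                       dt = 1) {
  t <- seq(0, len - dt, by = dt)
  h <- stats::dgamma(t, shape = peak + 1, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot + 1, rate = 1)
  h <- h / sum(h)
  attr(h, "spec") <- list(kernel = "double_gamma", length = len,
                          peak = peak, undershoot = undershoot,
                          ratio = ratio, dt = dt)
  h
}

#' Convolve a spin trajectory with a hemodynamic response function
#'
#' Causal same-length convolution of each region's series with the kernel
#' (zero-padded start), producing a BOLD-like continuous signal. The
#' operator is linear: superposition holds exactly.
#'
#' @param traj an [run_ising()] trajectory, or a numeric frames x regions
#'   matrix.
#' @param hrf kernel from [hrf_kernel()] (default).
#' @param sampling_interval seconds per frame (bookkeeping only).
#' @return object of class `bold_series`: list with `signal` (frames x
#'   regions), `sampling_interval`, `hrf_spec`, `config` (when available).
#' @export
hrf_convolve <- function(traj, hrf = hrf_kernel(), sampling_interval = 1) {
  x <- if (inherits(traj, "ising_trajectory")) traj$spins else traj
  if (!is.matrix(x) || nrow(x) == 0) stop("empty trajectory", call. = FALSE)
  L <- length(hrf)
  if (L > nrow(x))
    stop("kernel longer than the series (", L, " > ", nrow(x), ")",
         call. = FALSE)
  Tn <- nrow(x)
  sig <- apply(x, 2, function(col) {
    y <- stats::convolve(c(col, rep(0, L - 1)), rev(hrf), type = "open")
    y[seq_len(Tn)]
  })
  colnames(sig) <- colnames(x)
  structure(list(signal = sig, sampling_interval = sampling_interval,
                 hrf_spec = attr(hrf, "spec"),
                 config = if (inherits(traj, "ising_trajectory"))
                   traj$config),
            class = "bold_series")
}

#' Functional connectivity from a BOLD-like series
#'
#' Pearson correlation of every pair of regional series. Constant columns
#' make the correlation undefined; affected entries are set to `NA` and the
#' regions reported in the `flagged_regions` attribute.
#'
#' @param b a [hrf_convolve()] result (or frames x regions matrix).
#' @param discard_burn_in drop the initial `burn_in_fraction` of frames
#'   (read from the attached config; 0 when none) before correlating.
#' @return object of class `fc_matrix`: list with `values` (N x N, unit
#'   diagonal), `method = "pearson"`, `n_frames`, `flagged_regions`.
#' @export
fc_from_series <- function(b, discard_burn_in = TRUE) {
  sig <- if (inherits(b, "bold_series")) b$signal else b
  burn <- 0
  if (discard_burn_in && inherits(b, "bold_series") && !is.null(b$config))
    burn <- floor(nrow(sig) * b$config$burn_in_fraction)
  if (burn > 0) sig <- sig[-seq_len(burn), , drop = FALSE]
  if (nrow(sig) < 3)
    stop("need at least 3 retained frames for correlation", call. = FALSE)
  sds <- apply(sig, 2, stats::sd)
  flagged <- which(sds == 0)
  vals <- suppressWarnings(stats::cor(sig))
  diag(vals) <- 1
  structure(list(values = vals, method = "pearson", n_frames = nrow(sig),
                 flagged_regions = flagged),
            class = "fc_matrix")
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat("fc_matrix:", nrow(x$values), "regions,", x$n_frames, "frames",
      if (length(x$flagged_regions))
        paste0("(", length(x$flagged_regions), " constant regions flagged)"),
      "\n")
  invisible(x)
}

#' Simulate functional connectivity on a connectome
#'
#' Convenience pipeline: [run_ising()] -> [hrf_convolve()] ->
#' [fc_from_series()].
#'
#' @inheritParams run_ising
#' @param discard_burn_in passed to [fc_from_series()].
#' @return an `fc_matrix`.
#' @export
simulate_fc <- function(connectome, cfg, discard_burn_in = TRUE) {
  fc_from_series(hrf_convolve(run_ising(connectome, cfg)),
                 discard_burn_in = discard_burn_in)
}

#' Coupling-strength sweep of the commute-time/FC correlation
#'
#' For each coupling strength and replicate, simulates function, computes
#' FC and the Spearman correlation with commute time over all region
#' pairs.
#'
#' @param connectome a [structural_connectome()].
#' @param lambdas numeric vector of coupling strengths.
#' @param replicates replicates per lambda (distinct derived seeds).
#' @param seed master seed.
#' @param n_steps,flip_fraction,burn_in_fraction forwarded to
#'   [ising_config()].
#' @return data.frame with columns `lambda`, `replicate`, `seed`, `rho`.
#' @export
lambda_sweep <- function(connectome, lambdas, replicates = 10, seed = 1,
                         n_steps = 5000, flip_fraction = 0.15,
                         burn_in_fraction = 0.2) {
  ops <- build_operators(connectome)
  C <- commute_time(ops)$values
  mask <- pair_mask("all_pairs", connectome)
  cvec <- pair_vector(C, mask)
  rows <- list()
  for (li in seq_along(lambdas)) {
    for (r in seq_len(replicates)) {
      s <- pair_seed(seed, li, r, 1L)
      cfg <- ising_config(lambdas[li], n_steps = n_steps,
                          flip_fraction = flip_fraction,
                          burn_in_fraction = burn_in_fraction, seed = s)
      fc <- simulate_fc(connectome, cfg)
      rho <- spearman_correlation(cvec, pair_vector(fc$values, mask))$rho
      rows[[length(rows) + 1]] <- data.frame(lambda = lambdas[li],
                                             replicate = r, seed = s,
                                             rho = rho)
    }
  }
  do.call(rbind, rows)
}
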