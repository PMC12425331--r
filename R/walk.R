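#' Monte-Carlo estimate of hitting time
#'
#' Brute-force random walkers on the transition matrix `M`, kept free of
#' linear-algebra shortcuts so they remain an independent check on the
#' closed forms. `order = 1` is the plain Markov chain; `order = 2` forbids
#' immediate backtracking (transition probabilities renormalized over the
#' remaining neighbours); `order = 3` additionally excludes the node
#' visited two steps ago. When the constraint leaves no admissible
#' neighbour (a leaf), backtracking is allowed so the chain never
#' deadlocks. Walks exceeding `max_steps` are excluded and counted in
#' `n_capped`, never silently truncated.
#'
#' @param ops a [build_operators()] result.
#' @param source,target 1-based region indices, distinct.
#' @param n_walks number of independent walks.
#' @param seed master seed; the actual stream is derived per
#'   (source, target, order) so results do not depend on evaluation order.
#' @param order Markov order, 1, 2 or 3.
#' @param max_steps per-walk step cap.
#' @return object of class `walk_estimate`: list with `mean_steps`,
#'   `stderr` (NA when fewer than 2 completed walks), `n_walks`,
#'   `n_capped`, `source`, `target`, `order`, `seed`.
#' @export
simulate_hitting <- function(ops, source, target, n_walks, seed, order = 1,
                             max_steps = 1e7) {
  walk_estimate_from(ops, source, target, n_walks, seed, order, max_steps,
                     kind = "hitting")
}

#' Monte-Carlo estimate of commute time
#'
#' Each walk runs `source -> target -> source`; the mean total step count
#' estimates the commute time (exactly, for `order = 1`).
#'
#' @inheritParams simulate_hitting
#' @return a `walk_estimate` (see [simulate_hitting()]).
#' @export
simulate_commute <- function(ops, source, target, n_walks, seed, order = 1,
                             max_steps = 1e7) {
  walk_estimate_from(ops, source, target, n_walks, seed, order, max_steps,
                     kind = "commute")
}

walk_estimate_from <- function(ops, source, target, n_walks, seed, order,
                               max_steps, kind) {
  n <- nrow(ops$transition)
  if (source == target) stop("source and target must differ", call. = FALSE)
  stopifnot(source >= 1, source <= n, target >= 1, target <= n,
            n_walks >= 1, order %in% 1:3)
  set.seed(pair_seed(seed, source, target, order))
  fn <- if (kind == "hitting") walk_hitting_cpp else walk_commute_cpp
  steps <- fn(ops$transition, source - 1L, target - 1L, as.integer(n_walks),
              as.integer(order), max_steps)
  ok <- steps[!is.na(steps)]
  structure(
    list(mean_steps = if (length(ok)) mean(ok) else NA_real_,
         stderr = if (length(ok) >= 2) stats::sd(ok) / sqrt(length(ok))
                  else NA_real_,
         n_walks = n_walks, n_capped = sum(is.na(steps)),
         source = source, target = target, order = order, seed = seed,
         kind = kind),
    class = "walk_estimate")
}

#' @export
print.walk_estimate <- function(x, ...) {
  cat(sprintf("walk_estimate [%s, order %d] %d -> %d: %.4g +/- %.3g (%d walks, %d capped)\n",
              x$kind, x$order, x$source, x$target, x$mean_steps,
              x$stderr, x$n_walks, x$n_capped))
  invisible(x)
}

# Independent per-pair stream derived from one master seed.
pair_seed <- function(seed, i, j, order) {
  as.integer((as.numeric(seed) %% 2147483647 * 31 + i * 104729 +
                j * 1299709 + order * 15485863) %% 2147483647)
}

#' Agreement between analytic and simulated commute times
#'
#' For every region pair, compares the closed-form commute time against the
#' Monte-Carlo estimate and reports the z-score
#' `(analytic - simulated) / stderr` and the fraction of pairs with
#' `|z| <= 3`. Pairs with undefined standard error (`n_walks = 1`) are
#' flagged, not dropped silently.
#'
#' @param connectome a [structural_connectome()].
#' @param n_walks walks per pair.
#' @param seed master seed.
#' @param order Markov order for the walkers (analytic reference is always
#'   the first-order closed form).
#' @param max_n guard against desk-scale explosions; raise explicitly via
#'   `override` for larger systems.
#' @param override set `TRUE` to bypass the `max_n` guard.
#' @return object of class `oracle_report`: list with `pairs` (data.frame:
#'   i, j, analytic, simulated, stderr, z), `fraction_within_3`,
#'   `n_flagged`, `seed`, `order`.
#' @export
oracle_agreement <- function(connectome, n_walks = 1e4, seed = 1, order = 1,
                             max_n = 50, override = FALSE) {
  n <- connectome$n_regions
  if (n > max_n && !override)
    stop("N = ", n, " exceeds the desk-scale guard (max_n = ", max_n,
         "); pass override = TRUE to force", call. = FALSE)
  ops <- build_operators(connectome)
  C <- commute_time(ops)$values
  ij <- which(upper.tri(C), arr.ind = TRUE)
  rows <- lapply(seq_len(nrow(ij)), function(r) {
    i <- ij[r, 1]; j <- ij[r, 2]
    est <- simulate_commute(ops, i, j, n_walks, seed, order)
    data.frame(i = i, j = j, analytic = C[i, j],
               simulated = est$mean_steps, stderr = est$stderr,
               z = if (!is.na(est$stderr) && est$stderr > 0)
                 (C[i, j] - est$mean_steps) / est$stderr else NA_real_,
               n_capped = est$n_capped)
  })
  pairs <- do.call(rbind, rows)
  defined <- !is.na(pairs$z)
  structure(
    list(pairs = pairs,
         fraction_within_3 = mean(abs(pairs$z[defined]) <= 3),
         n_flagged = sum(!defined), seed = seed, order = order,
         n_walks = n_walks),
    class = "oracle_report")
}

#' @export
print.oracle_report <- function(x, ...) {
  cat(sprintf("oracle_report: %d pairs, %.1f%% within |z| <= 3 (%d flagged, order %d, %g walks/pair)\n",
              nrow(x$pairs), 100 * x$fraction_within_3, x$n_flagged,
              x$order, x$n_walks))
  invisible(x)
}

#' Write an agreement report as TSV
#'
#' @param report an [oracle_agreement()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_oracle_report <- function(report, path) {
  utils::write.table(report$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
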