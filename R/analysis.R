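#' Region-pair mask
#'
#' Selects which of the `N(N-1)/2` off-diagonal upper-triangle pairs enter
#' a pair-level comparison: all pairs, only pairs within the left (or
#' right) hemisphere, or a custom logical matrix.
#'
#' @param mode `"all_pairs"`, `"intra_left"`, `"intra_right"` or
#'   `"custom"`.
#' @param connectome a [structural_connectome()] (hemisphere labels are
#'   required for the intra-hemisphere modes).
#' @param custom for `mode = "custom"`, an N x N logical matrix; only its
#'   upper-triangle is used and the diagonal is always excluded.
#' @return object of class `pair_mask`: list with `mode`, `keep` (logical
#'   vector over row-major upper-triangle pairs), `n_pairs`, `n_regions`.
#' @export
pair_mask <- function(mode = c("all_pairs", "intra_left", "intra_right",
                               "custom"),
                      connectome, custom = NULL) {
  mode <- match.arg(mode)
  n <- connectome$n_regions
  idx <- pair_index(n)
  keep <- switch(mode,
    all_pairs = rep(TRUE, nrow(idx)),
    intra_left = ,
    intra_right = {
      if (is.null(connectome$hemisphere))
        stop("hemisphere labels required for intra-hemisphere masks",
             call. = FALSE)
      side <- if (mode == "intra_left") "left" else "right"
      connectome$hemisphere[idx[, 1]] == side &
        connectome$hemisphere[idx[, 2]] == side
    },
    custom = {
      if (is.null(custom) || !all(dim(custom) == n))
        stop("custom mask must be an N x N logical matrix", call. = FALSE)
      custom[idx]
    })
  structure(list(mode = mode, keep = keep, n_pairs = sum(keep),
                 n_regions = n),
            class = "pair_mask")
}

# Row-major upper-triangle pair indices: (1,2), (1,3), ..., (2,3), ...
pair_index <- function(n) {
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(seq_len(n - 1), function(k) (k + 1):n))
  cbind(i = i, j = j)
}

#' Extract masked pair values from a symmetric matrix
#'
#' Off-diagonal upper-triangle entries in fixed row-major order,
#' filtered by the mask. Input must be symmetric (hitting time and raw
#' search information are symmetrized first via [metric_values()]).
#'
#' @param m symmetric numeric matrix (or `pairwise_metric`/`fc_matrix`).
#' @param mask a [pair_mask()]; default: all pairs.
#' @return numeric vector of length `mask$n_pairs`.
#' @export
pair_vector <- function(m, mask = NULL) {
  if (inherits(m, "pairwise_metric")) m <- metric_values(m)
  if (inherits(m, "fc_matrix")) m <- m$values
  if (max(abs(m - t(m)), na.rm = TRUE) > 1e-8)
    stop("pair_vector requires a symmetric matrix", call. = FALSE)
  idx <- pair_index(nrow(m))
  v <- m[idx]
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "pair_mask"), mask$n_regions == nrow(m))
    v <- v[mask$keep]
  }
  v
}

#' Spearman rank correlation with large-n p-value
#'
#' Average ranks for ties; two-sided p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`. Pairs with missing values in
#' either input are dropped (and counted); constant input leaves `rho`
#' undefined (`NA`) with a flag rather than an error.
#'
#' @param x,y equal-length numeric vectors (n >= 3 after NA removal).
#' @return list with `rho`, `p_value`, `n`, `n_dropped`, `constant_input`.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y))
    stop("length mismatch: ", length(x), " vs ", length(y), call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  n_dropped <- sum(!ok)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                n_dropped = n_dropped, constant_input = TRUE))
  rho <- stats::cor(rank(x), rank(y))
  tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  list(rho = rho, p_value = p, n = n, n_dropped = n_dropped,
       constant_input = FALSE)
}

#' Rank-k principal-mode reconstruction of a symmetric matrix
#'
#' Eigendecomposition of the matrix itself (no centering), reconstruction
#' from the `k` eigenvectors with the largest algebraic eigenvalues:
#' `sum_{r<=k} lambda_r v_r v_r'`. Eigenvector signs follow a
#' deterministic convention (largest-magnitude component positive).
#'
#' @param m symmetric numeric matrix (or `pairwise_metric`/`fc_matrix`).
#' @param k number of leading modes, `1 <= k <= N`.
#' @param centered if `TRUE`, the column means are removed before the
#'   decomposition and added back (non-default PCA-style variant).
#' @return N x N rank-k reconstruction.
#' @export
top_mode <- function(m, k, centered = FALSE) {
  if (inherits(m, "pairwise_metric")) m <- metric_values(m)
  if (inherits(m, "fc_matrix")) m <- m$values
  n <- nrow(m)
  if (k < 1 || k > n) stop("k out of range [1, ", n, "]", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-8)
    stop("top_mode requires a symmetric matrix", call. = FALSE)
  mu <- if (centered) colMeans(m) else rep(0, n)
  m0 <- m - outer(rep(1, n), mu)
  eig <- eigen(m0, symmetric = TRUE)
  ord <- order(eig$values, decreasing = TRUE)
  V <- eig$vectors[, ord[seq_len(k)], drop = FALSE]
  lam <- eig$values[ord[seq_len(k)]]
  for (r in seq_len(k)) {
    mx <- which.max(abs(V[, r]))
    if (V[mx, r] < 0) V[, r] <- -V[, r]
  }
  out <- V %*% (lam * t(V)) + outer(rep(1, n), mu)
  dimnames(out) <- dimnames(m)
  (out + t(out)) / 2
}

#' Compare structural metrics against a functional connectivity matrix
#'
#' Computes, for each structural metric in
#' `{connectivity, search_information, communicability, commute_time}`,
#' the Spearman correlation with the FC matrix over the masked pairs, for
#' each requested rank setting. `"full"` uses the matrices as-is; an
#' integer `k` replaces FC (and/or the metric) by its rank-k principal-mode
#' reconstruction. Commute time and search information are distance-like
#' (large value = weak coupling), so their additive inverse is taken
#' before correlating when `orient = TRUE`, making all reported signs
#' comparable; the flip is recorded per report.
#'
#' @param connectome a [structural_connectome()].
#' @param fc an `fc_matrix` (or plain symmetric matrix).
#' @param mask a [pair_mask()]; default all pairs.
#' @param fc_rank,metric_rank `"full"` or an integer k; vectors allowed,
#'   settings are paired elementwise (recycled).
#' @param metrics character subset of the four metric tags.
#' @param orient apply the sign convention above.
#' @return data.frame with one row per metric x setting: `metric_tag`,
#'   `rho`, `p_value`, `n_pairs`, `mask`, `fc_rank`, `metric_rank`,
#'   `sign_flipped`.
#' @export
metric_comparison <- function(connectome, fc, mask = NULL,
                              fc_rank = "full", metric_rank = "full",
                              metrics = c("connectivity",
                                          "search_information",
                                          "communicability",
                                          "commute_time"),
                              orient = TRUE) {
  ops <- build_operators(connectome)
  fcm <- if (inherits(fc, "fc_matrix")) fc$values else fc
  if (is.null(mask)) mask <- pair_mask("all_pairs", connectome)

  metric_mats <- list()
  for (tag in metrics) {
    metric_mats[[tag]] <- switch(tag,
      connectivity = connectome$weights,
      search_information = metric_values(search_information(ops)),
      communicability = communicability(ops)$values,
      commute_time = commute_time(ops)$values)
  }
  flip <- c(connectivity = FALSE, search_information = TRUE,
            communicability = FALSE, commute_time = TRUE)

  nset <- max(length(fc_rank), length(metric_rank))
  fc_rank <- rep(fc_rank, length.out = nset)
  metric_rank <- rep(metric_rank, length.out = nset)

  rows <- list()
  for (s in seq_len(nset)) {
    fr <- fc_rank[[s]]; mr <- metric_rank[[s]]
    fc_s <- if (identical(fr, "full")) fcm else top_mode(fcm, as.integer(fr))
    fvec <- pair_vector(fc_s, mask)
    for (tag in metrics) {
      mm <- metric_mats[[tag]]
      if (!identical(mr, "full")) mm <- top_mode(mm, as.integer(mr))
      if (orient && flip[[tag]]) mm <- -mm
      sc <- spearman_correlation(pair_vector(mm, mask), fvec)
      rows[[length(rows) + 1]] <- data.frame(
        metric_tag = tag, rho = sc$rho, p_value = sc$p_value,
        n_pairs = sc$n, mask = mask$mode,
        fc_rank = as.character(fr), metric_rank = as.character(mr),
        sign_flipped = orient && flip[[tag]])
    }
  }
  do.call(rbind, rows)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Maximum gap between the empirical CDFs with the asymptotic p-value,
#' used to compare correlation distributions between metrics.
#'
#' @param d1,d2 numeric vectors (length >= 2).
#' @return list with `statistic` and `p_value`.
#' @export
ks_compare <- function(d1, d2) {
  if (length(d1) < 2 || length(d2) < 2)
    stop("need at least 2 values per sample", call. = FALSE)
  res <- suppressWarnings(stats::ks.test(d1, d2))
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' Run the full structure-function experiment
#'
#' End-to-end pipeline: obtain a connectome (generate from a
#' [connectome_spec()] or read from file), obtain FC per replicate
#' (simulate with the Ising model or read from file), compare the four
#' structural metrics against FC under the requested masks and rank
#' settings, and write every intermediate matrix, report and serialized
#' config to `out_dir`. Re-running with the same config reproduces every
#' file bit-identically.
#'
#' @param config list with elements:
#'   `connectome` (a `connectome_spec`, `structural_connectome`, or path),
#'   `fc` (an `ising_config` used as template, or a path to an FC TSV),
#'   `masks` (character vector of mask modes, default `"all_pairs"`),
#'   `fc_rank`, `metric_rank` (vectors as in [metric_comparison()]),
#'   `replicates` (default 1; ignored for file FC), `seed` (master seed).
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with `reports` (data.frame over replicates),
#'   `rho_quartiles` (25/50/75% per metric and setting), `out_dir`.
#' @export
run_experiment <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  conn <- config$connectome
  if (inherits(conn, "connectome_spec")) conn <- generate_connectome(conn)
  if (is.character(conn)) conn <- read_connectome(conn)
  stopifnot(inherits(conn, "structural_connectome"))
  write_connectome(conn, file.path(out_dir, "connectome"))

  ops <- build_operators(conn)
  for (tag in c("commute_time", "communicability")) {
    m <- switch(tag, commute_time = commute_time(ops),
                communicability = communicability(ops))
    write_matrix(m, file.path(out_dir, paste0(tag, ".tsv")))
  }
  write_matrix(metric_values(search_information(ops)),
               file.path(out_dir, "search_information_sym.tsv"))

  masks <- config$masks %||% "all_pairs"
  fc_rank <- config$fc_rank %||% "full"
  metric_rank <- config$metric_rank %||% "full"
  replicates <- config$replicates %||% 1L

  fc_list <- list()
  if (is.character(config$fc)) {
    fcm <- read_matrix(config$fc)
    fc_list[[1]] <- structure(list(values = fcm, method = "pearson",
                                   n_frames = NA_integer_,
                                   flagged_regions = integer()),
                              class = "fc_matrix")
    replicates <- 1L
  } else {
    stopifnot(inherits(config$fc, "ising_config"))
    for (r in seq_len(replicates)) {
      cfg <- config$fc
      cfg$seed <- pair_seed(seed, r, 0L, 1L)
      fc_list[[r]] <- simulate_fc(conn, cfg)
    }
  }

  all_reports <- list()
  for (r in seq_along(fc_list)) {
    write_matrix(fc_list[[r]]$values,
                 file.path(out_dir, sprintf("fc_replicate_%03d.tsv", r)))
    for (mk in masks) {
      rep_df <- metric_comparison(conn, fc_list[[r]],
                                  mask = pair_mask(mk, conn),
                                  fc_rank = fc_rank,
                                  metric_rank = metric_rank)
      rep_df$replicate <- r
      all_reports[[length(all_reports) + 1]] <- rep_df
    }
  }
  reports <- do.call(rbind, all_reports)
  utils::write.table(reports, file.path(out_dir, "correlation_reports.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # quartiles with linear interpolation (type 7), per metric and setting
  key <- interaction(reports$metric_tag, reports$mask, reports$fc_rank,
                     reports$metric_rank, drop = TRUE)
  qs <- do.call(rbind, lapply(split(reports, key), function(g) {
    q <- stats::quantile(g$rho, c(0.25, 0.5, 0.75), type = 7, na.rm = TRUE)
    data.frame(metric_tag = g$metric_tag[1], mask = g$mask[1],
               fc_rank = g$fc_rank[1], metric_rank = g$metric_rank[1],
               q25 = q[[1]], median = q[[2]], q75 = q[[3]],
               n = nrow(g))
  }))
  rownames(qs) <- NULL
  utils::write.table(qs, file.path(out_dir, "rho_quartiles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ser <- config
  ser$connectome <- if (inherits(config$connectome, "connectome_spec"))
    unclass(config$connectome) else "supplied"
  ser$fc <- if (inherits(config$fc, "ising_config"))
    unclass(config$fc) else config$fc
  yaml::write_yaml(ser, file.path(out_dir, "config.yaml"))

  invisible(list(reports = reports, rho_quartiles = qs, out_dir = out_dir))
}
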