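#' Structural connectome container
#'
#' Bundles a weighted, symmetric, zero-diagonal adjacency matrix of
#' streamline counts `A` with optional mean tract lengths (mm), per-region
#' hemisphere labels and homotopic (left/right counterpart) region pairs.
#' The element `A[i, j]` is the number of white-matter streamlines
#' reconstructed between regions `i` and `j`; self-loops are removed.
#'
#' @param weights N x N numeric matrix of nonnegative tract counts.
#'   Asymmetries up to `tol` are repaired by averaging; larger asymmetry is
#'   an error. Nonzero diagonal entries are stripped to zero with a warning.
#' @param region_labels character vector of N region names. Defaults to the
#'   dimnames of `weights`, else `"R1"..."RN"`.
#' @param hemisphere per-region labels in `c("left", "right")`, or `NULL`.
#' @param lengths optional N x N matrix of mean tract lengths sharing the
#'   sparsity pattern of `weights`.
#' @param homotopic_pairs optional two-column integer matrix of
#'   (left index, right index) homotopic region pairs.
#' @param tol symmetry repair tolerance (absolute).
#' @return An object of class `structural_connectome`: a list with elements
#'   `weights`, `lengths`, `region_labels`, `hemisphere`, `homotopic_pairs`,
#'   `n_regions`.
#' @export
structural_connectome <- function(weights, region_labels = NULL,
                                  hemisphere = NULL, lengths = NULL,
                                  homotopic_pairs = NULL, tol = 1e-8) {
  if (!is.matrix(weights) || !is.numeric(weights))
    stop("`weights` must be a numeric matrix", call. = FALSE)
  if (nrow(weights) != ncol(weights))
    stop("non-square connectivity matrix: ", nrow(weights), " x ",
         ncol(weights), call. = FALSE)
  n <- nrow(weights)
  if (n < 2) stop("a connectome needs at least 2 regions", call. = FALSE)
  if (anyNA(weights))
    stop("NaN/NA entries in connectivity matrix", call. = FALSE)
  if (any(weights < 0))
    stop("negative entries in connectivity matrix", call. = FALSE)
  asym <- max(abs(weights - t(weights)))
  if (asym > tol)
    stop("connectivity matrix asymmetric beyond tolerance (max |A - t(A)| = ",
         format(asym), ")", call. = FALSE)
  weights <- (weights + t(weights)) / 2
  if (any(diag(weights) != 0)) {
    warning("nonzero diagonal entries (self-loops) set to 0", call. = FALSE)
    diag(weights) <- 0
  }

  region_labels <- region_labels %||% rownames(weights) %||%
    paste0("R", seq_len(n))
  if (length(region_labels) != n)
    stop("region_labels length does not match matrix size", call. = FALSE)
  dimnames(weights) <- list(region_labels, region_labels)

  if (!is.null(hemisphere)) {
    if (length(hemisphere) != n || !all(hemisphere %in% c("left", "right")))
      stop("hemisphere must be one of 'left'/'right' per region",
           call. = FALSE)
  }

  if (!is.null(lengths)) {
    if (!is.matrix(lengths) || any(dim(lengths) != n))
      stop("lengths matrix dimensions do not match weights", call. = FALSE)
    if (anyNA(lengths) || any(lengths < 0))
      stop("lengths must be nonnegative and finite", call. = FALSE)
    lengths <- (lengths + t(lengths)) / 2
    diag(lengths) <- 0
    if (any((lengths > 0) != (weights > 0)))
      stop("lengths must share the sparsity pattern of weights",
           call. = FALSE)
    dimnames(lengths) <- dimnames(weights)
  }

  if (!is.null(homotopic_pairs)) {
    homotopic_pairs <- matrix(as.integer(homotopic_pairs), ncol = 2)
    if (any(homotopic_pairs < 1) || any(homotopic_pairs > n))
      stop("homotopic pair indices out of range", call. = FALSE)
  }

  structure(
    list(weights = weights, lengths = lengths,
         region_labels = region_labels, hemisphere = hemisphere,
         homotopic_pairs = homotopic_pairs, n_regions = n),
    class = "structural_connectome")
}

#' @export
print.structural_connectome <- function(x, ...) {
  ut <- x$weights[upper.tri(x$weights)]
  cat("structural_connectome:", x$n_regions, "regions,",
      sum(ut > 0), "edges (density",
      sprintf("%.3f", mean(ut > 0)), ")\n")
  if (!is.null(x$hemisphere))
    cat("  hemispheres:", sum(x$hemisphere == "left"), "left /",
        sum(x$hemisphere == "right"), "right\n")
  if (!is.null(x$lengths)) cat("  tract lengths present\n")
  if (!is.null(x$homotopic_pairs))
    cat("  homotopic pairs:", nrow(x$homotopic_pairs), "\n")
  invisible(x)
}

#' Write a labelled matrix as TSV
#'
#' Tab-separated, header row of region labels, first column of region
#' labels, `.` decimal. Values are printed with 17 significant digits so a
#' write/read round trip is bit-exact for doubles.
#'
#' @param m numeric matrix (rownames used as labels when `labels` is `NULL`),
#'   or a `pairwise_metric`.
#' @param path output file path.
#' @param labels optional character vector of region labels.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, labels = NULL) {
  if (inherits(m, "pairwise_metric")) {
    labels <- labels %||% rownames(m$values)
    m <- m$values
  }
  if (!is.matrix(m) || nrow(m) == 0 || ncol(m) == 0)
    stop("cannot write an empty matrix", call. = FALSE)
  labels <- labels %||% rownames(m) %||% paste0("R", seq_len(nrow(m)))
  header <- paste(c("region", labels), collapse = "\t")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(labels[i], sprintf("%.17g", m[i, ])), collapse = "\t")
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}

#' Read a labelled TSV matrix
#'
#' @param path file written by [write_matrix()] (or any TSV with a label
#'   header row and label first column).
#' @return numeric matrix with dimnames.
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("matrix file too short: ", path, call. = FALSE)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]][-1]
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  labels <- vapply(body, `[[`, character(1), 1)
  vals <- lapply(body, function(r) as.numeric(r[-1]))
  m <- do.call(rbind, vals)
  if (ncol(m) != length(header))
    stop("ragged matrix file: ", path, call. = FALSE)
  dimnames(m) <- list(labels, header)
  m
}

#' Read a structural connectome from delimited files
#'
#' Expects the TSV dialect of [write_matrix()]. An optional lengths matrix
#' and a YAML sidecar carrying hemisphere labels and homotopic pairs may
#' accompany the weights file.
#'
#' @param path weights TSV.
#' @param lengths_path optional tract-length TSV.
#' @param meta_path optional YAML sidecar with fields `hemisphere`
#'   (list/vector of "left"/"right") and `homotopic_pairs` (list of 2-int
#'   vectors).
#' @inheritParams structural_connectome
#' @return a validated [structural_connectome()].
#' @export
read_connectome <- function(path, lengths_path = NULL, meta_path = NULL,
                            tol = 1e-8) {
  w <- read_matrix(path)
  lengths <- if (!is.null(lengths_path)) read_matrix(lengths_path)
  hemisphere <- NULL
  homotopic <- NULL
  if (!is.null(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    hemisphere <- unlist(meta$hemisphere)
    if (!is.null(meta$homotopic_pairs))
      homotopic <- do.call(rbind, lapply(meta$homotopic_pairs, as.integer))
  }
  structural_connectome(w, region_labels = rownames(w),
                        hemisphere = hemisphere, lengths = lengths,
                        homotopic_pairs = homotopic, tol = tol)
}

#' Write a connectome (weights, lengths, metadata sidecar)
#'
#' @param c a [structural_connectome()].
#' @param prefix path prefix; writes `<prefix>_weights.tsv`, and when
#'   present `<prefix>_lengths.tsv` and `<prefix>_meta.yaml`.
#' @return named character vector of paths written, invisibly.
#' @export
write_connectome <- function(c, prefix) {
  stopifnot(inherits(c, "structural_connectome"))
  paths <- c(weights = paste0(prefix, "_weights.tsv"))
  write_matrix(c$weights, paths[["weights"]])
  if (!is.null(c$lengths)) {
    paths[["lengths"]] <- paste0(prefix, "_lengths.tsv")
    write_matrix(c$lengths, paths[["lengths"]])
  }
  if (!is.null(c$hemisphere) || !is.null(c$homotopic_pairs)) {
    paths[["meta"]] <- paste0(prefix, "_meta.yaml")
    meta <- list()
    if (!is.null(c$hemisphere)) meta$hemisphere <- as.list(c$hemisphere)
    if (!is.null(c$homotopic_pairs))
      meta$homotopic_pairs <- lapply(seq_len(nrow(c$homotopic_pairs)),
                                     function(i) as.integer(c$homotopic_pairs[i, ]))
    yaml::write_yaml(meta, paths[["meta"]])
  }
  invisible(paths)
}
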