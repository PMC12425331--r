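# Small canonical graphs used across the suite.

two_node <- function(w = 1) {
  A <- matrix(c(0, w, w, 0), 2, 2)
  structural_connectome(A, region_labels = c("L.A", "R.A"),
                        hemisphere = c("left", "right"))
}

path3 <- function() {
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- 1
  A[2, 3] <- A[3, 2] <- 1
  structural_connectome(A)
}

k3 <- function() {
  A <- matrix(1, 3, 3)
  diag(A) <- 0
  structural_connectome(A)
}

star4 <- function() {
  A <- matrix(0, 4, 4)
  A[1, 2:4] <- A[2:4, 1] <- 1
  structural_connectome(A)
}

# Random connected weighted graph (moderate weights, for identity checks).
random_connected <- function(n, seed, p = 0.4, wmax = 10) {
  set.seed(seed)
  repeat {
    A <- matrix(0, n, n)
    ut <- upper.tri(A)
    A[ut] <- ifelse(runif(sum(ut)) < p, sample(wmax, sum(ut), TRUE), 0)
    A <- A + t(A)
    if (commutebrain:::is_connected_adjacency(A)) break
  }
  structural_connectome(A)
}

# Small synthetic connectome with moderate weight spread, so Monte-Carlo
# commute times stay desk-scale.
small_connectome <- function(n = 12, seed = 1, sdlog = 0.5) {
  generate_connectome(connectome_spec(
    n_regions = n, intra_density = 0.6, inter_density = 0.3,
    weight_log_mean = log(50), weight_log_sd = sdlog,
    length_decay = 60, bundle_degree_ratio = NA, seed = seed))
}
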