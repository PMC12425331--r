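test_that("pair vectors follow row-major upper-triangle order and masks", {
  m <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3)
  expect_equal(pair_vector(m), c(1, 2, 3))

  cn <- generate_connectome(connectome_spec(seed = 1))
  all_m <- pair_mask("all_pairs", cn)
  expect_equal(all_m$n_pairs, 84 * 83 / 2)
  left <- pair_mask("intra_left", cn)
  expect_equal(left$n_pairs, 42 * 41 / 2)
  C <- commute_time(build_operators(cn))$values
  expect_length(pair_vector(C, all_m), 3486)
  expect_length(pair_vector(C, left), 861)

  asym <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(pair_vector(asym), "symmetric")
})

test_that("spearman correlation matches rank formulas and flags ties", {
  x <- 1:5
  expect_equal(spearman_correlation(x, exp(x))$rho, 1)
  expect_equal(spearman_correlation(x, rev(x))$rho, -1)
  s <- spearman_correlation(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4))
  expect_equal(s$rho, 0.8, tolerance = 1e-12)
  # cross-check rho against the independent stats implementation
  set.seed(1)
  a <- rnorm(50)
  b <- a + rnorm(50)
  expect_equal(spearman_correlation(a, b)$rho,
               unname(cor(a, b, method = "spearman")), tolerance = 1e-12)
  expect_error(spearman_correlation(1:4, 1:5), "mismatch")
  cs <- spearman_correlation(rep(1, 10), 1:10)
  expect_true(cs$constant_input)
  expect_true(is.na(cs$rho))
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(3)
  x <- rlnorm(100)
  y <- rlnorm(100) + x
  r0 <- spearman_correlation(x, y)$rho
  expect_equal(spearman_correlation(log(x), y)$rho, r0)
  expect_equal(spearman_correlation(x, y^3)$rho, r0)
})

test_that("top_mode reconstructs, truncates optimally, and is monotone", {
  set.seed(7)
  m <- matrix(rnorm(64), 8, 8)
  m <- m + t(m)
  expect_lt(max(abs(top_mode(m, 8) - m)), 1e-10)

  v <- rnorm(8)
  r1 <- v %*% t(v)
  expect_lt(max(abs(top_mode(r1, 1) - r1)), 1e-10)

  best <- top_mode(m, 1)
  err_best <- sum((m - best)^2)
  for (i in 1:100) {
    u <- rnorm(8)
    lam <- rnorm(1)
    err <- sum((m - lam * u %*% t(u))^2)
    expect_gte(err, err_best - 1e-8)
  }

  errs <- sapply(1:8, function(k) sum((m - top_mode(m, k))^2))
  expect_true(all(diff(errs) <= 1e-10))
  expect_error(top_mode(m, 0), "out of range")
  expect_error(top_mode(m, 9), "out of range")
})

test_that("KS statistic equals the explicit CDF gap", {
  expect_equal(ks_compare(1:10, 1:10)$statistic, 0)
  expect_equal(ks_compare(1:5, 11:15)$statistic, 1)
  expect_equal(ks_compare(c(1, 2, 3), c(1, 2, 4))$statistic, 1 / 3,
               tolerance = 1e-12)
  expect_error(ks_compare(1, 1:5), "at least 2")
})

test_that("metric comparison orients signs and enumerates settings", {
  cn <- generate_connectome(connectome_spec(n_regions = 20, seed = 5))
  C <- commute_time(build_operators(cn))$values
  fc <- exp(-C / max(C)) # monotone decreasing function of commute time
  diag(fc) <- 1
  rep1 <- metric_comparison(cn, fc, metrics = "commute_time")
  expect_equal(rep1$rho, 1, tolerance = 1e-10) # +1 after inversion
  expect_true(rep1$sign_flipped)

  reps <- metric_comparison(cn, fc, fc_rank = list("full", 2),
                            metric_rank = list("full", 2))
  expect_equal(nrow(reps), 8)
  expect_setequal(unique(reps$metric_tag),
                  c("connectivity", "search_information", "communicability",
                    "commute_time"))
})

test_that("metric comparison is invariant to consistent relabeling", {
  cn <- generate_connectome(connectome_spec(n_regions = 12,
                                            intra_density = 0.6,
                                            inter_density = 0.3, seed = 8))
  fc <- simulate_fc(cn, ising_config(2, n_steps = 600, seed = 3))$values
  base <- metric_comparison(cn, fc, metrics = c("connectivity",
                                                "commute_time"))
  set.seed(2)
  perm <- sample(12)
  cn2 <- structural_connectome(cn$weights[perm, perm],
                               region_labels = cn$region_labels[perm],
                               hemisphere = cn$hemisphere[perm],
                               lengths = cn$lengths[perm, perm])
  perm_rep <- metric_comparison(cn2, fc[perm, perm],
                                metrics = c("connectivity", "commute_time"))
  expect_equal(perm_rep$rho, base$rho, tolerance = 1e-10)
})

test_that("run_experiment writes a bit-reproducible bundle", {
  cfg <- list(
    connectome = connectome_spec(n_regions = 12, intra_density = 0.6,
                                 inter_density = 0.3, seed = 4),
    fc = ising_config(2, n_steps = 500, seed = 1),
    fc_rank = list("full", 2), metric_rank = list("full", "full"),
    replicates = 2, seed = 10)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- run_experiment(cfg, d1)
  r2 <- run_experiment(cfg, d2)
  expect_equal(nrow(r1$reports), 2 * 2 * 4)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # supplied-FC mode: reports only, no simulation
  fc_path <- file.path(d1, "fc_replicate_001.tsv")
  cfg2 <- list(connectome = cfg$connectome, fc = fc_path, seed = 1)
  r3 <- run_experiment(cfg2, withr::local_tempdir())
  expect_equal(nrow(r3$reports), 4)
})
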