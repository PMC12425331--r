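test_that("config fields are validated", {
  expect_error(ising_config(-1), "lambda")
  expect_error(ising_config(1, flip_fraction = 0), "flip_fraction")
  expect_error(ising_config(1, flip_fraction = 1.5), "flip_fraction")
  expect_error(ising_config(1, burn_in_fraction = 1), "burn_in")
  expect_error(ising_config(1, n_steps = 0), "n_steps")
})

test_that("trajectories contain only unit spins and a consistent energy", {
  cn <- small_connectome(n = 10, seed = 2)
  tr <- run_ising(cn, ising_config(1, n_steps = 400, seed = 8))
  expect_true(all(tr$spins %in% c(-1L, 1L)))
  E <- ising_energy(tr, cn)
  expect_lt(max(abs(E - tr$energy_trace)) / max(abs(E)), 1e-9)
})

test_that("identical seeds give bit-identical trajectories, BOLD and FC", {
  cn <- small_connectome(n = 10, seed = 2)
  cfg <- ising_config(2, n_steps = 300, seed = 21)
  t1 <- run_ising(cn, cfg)
  t2 <- run_ising(cn, cfg)
  expect_identical(t1$spins, t2$spins)
  b1 <- hrf_convolve(t1)
  b2 <- hrf_convolve(t2)
  expect_identical(b1$signal, b2$signal)
  expect_identical(fc_from_series(b1)$values, fc_from_series(b2)$values)
})

test_that("free spins (lambda = 0) are uncorrelated", {
  cn <- two_node(1)
  tr <- run_ising(cn, ising_config(0, n_steps = 20000,
                                   adjacency_normalization = "none",
                                   seed = 4))
  x <- tr$spins[, 1] * tr$spins[, 2]
  expect_lt(abs(mean(x)), 3 * sd(x) / sqrt(length(x)))
})

test_that("the two-spin system reaches its Boltzmann average", {
  # exact 4-state enumeration gives <s1 s2> = tanh(2 lambda)
  cn <- two_node(1)
  cfg <- ising_config(1, n_steps = 120000,
                      adjacency_normalization = "none", seed = 31)
  tr <- run_ising(cn, cfg)
  keep <- tr$spins[-seq_len(24000), ]
  expect_lt(abs(mean(keep[, 1] * keep[, 2]) - tanh(2)), 0.02)
})

test_that("energy stabilizes after burn-in", {
  cn <- small_connectome(n = 12, seed = 3)
  tr <- run_ising(cn, ising_config(1, n_steps = 4000, seed = 12))
  E <- tr$energy_trace[-seq_len(800)]
  half <- length(E) %/% 2
  e1 <- E[seq_len(half)]
  e2 <- E[(half + 1):length(E)]
  se <- sqrt(var(e1) / half + var(e2) / half)
  # generous factor: frames are autocorrelated, so the naive stderr is small
  expect_lt(abs(mean(e1) - mean(e2)), 30 * se + 1e-9)
})

test_that("the HRF kernel peaks at the stated delay and sums to one", {
  h <- hrf_kernel()
  expect_equal(sum(h), 1, tolerance = 1e-12)
  expect_equal(which.max(h) - 1, 6) # t = 0 is the first sample
})

test_that("HRF convolution is causal, linear, and null on zero input", {
  z <- matrix(0, 100, 3)
  expect_true(all(hrf_convolve(z)$signal == 0))
  imp <- matrix(0, 100, 1)
  imp[1, 1] <- 1
  h <- hrf_kernel()
  out <- hrf_convolve(imp)$signal[, 1]
  expect_equal(out[seq_along(h)], as.numeric(h), tolerance = 1e-12)
  set.seed(5)
  a <- matrix(rnorm(300), 100, 3)
  b <- matrix(rnorm(300), 100, 3)
  expect_lt(max(abs(hrf_convolve(a + b)$signal -
                      hrf_convolve(a)$signal - hrf_convolve(b)$signal)),
            1e-10)
  expect_error(hrf_convolve(matrix(0, 10, 2)), "longer")
})

test_that("FC is the Pearson matrix with flagged constant regions", {
  x <- cbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4))
  fc <- fc_from_series(cbind(x, c = x[, 1]))
  expect_equal(fc$values["a", "c"], 1)
  expect_equal(fc$values["a", "b"], 0.8, tolerance = 1e-12)
  fc2 <- fc_from_series(cbind(x, d = -x[, 1]))
  expect_equal(fc2$values["a", "d"], -1)
  fc3 <- fc_from_series(cbind(x, e = rep(2, 4)))
  expect_identical(unname(fc3$flagged_regions), 3L)
  expect_true(is.na(fc3$values["a", "e"]))
  expect_error(fc_from_series(x[1:2, ]), "3 retained frames")
})

test_that("burn-in discarding follows the attached config", {
  cn <- small_connectome(n = 10, seed = 2)
  tr <- run_ising(cn, ising_config(1, n_steps = 1000,
                                   burn_in_fraction = 0.4, seed = 3))
  b <- hrf_convolve(tr)
  expect_equal(fc_from_series(b, discard_burn_in = TRUE)$n_frames, 600)
  expect_equal(fc_from_series(b, discard_burn_in = FALSE)$n_frames, 1000)
})

test_that("lambda sweep returns one rho per lambda and replicate", {
  cn <- small_connectome(n = 10, seed = 2)
  tab <- lambda_sweep(cn, lambdas = c(0, 1), replicates = 3, seed = 1,
                      n_steps = 400)
  expect_equal(nrow(tab), 6)
  expect_equal(length(unique(tab$seed)), 6)
  expect_true(all(is.finite(tab$rho)))
})
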