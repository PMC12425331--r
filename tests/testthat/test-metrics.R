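# Expected values below are hand-derived: the path-graph hitting times solve
# the one-step recursion H_ij = 1 + sum_k M_ik H_kj, K3 values follow from
# symmetry, and resistances from series/parallel circuit reduction.

test_that("hitting time matches the recursion solutions on small graphs", {
  expect_equal(hitting_time(build_operators(two_node(3)))$values,
               matrix(c(0, 1, 1, 0), 2, 2), tolerance = 1e-10,
               ignore_attr = TRUE)
  H <- hitting_time(build_operators(path3()))$values
  expect_equal(H[1, 3], 4, tolerance = 1e-10)
  expect_equal(H[2, 1], 3, tolerance = 1e-10)
  expect_equal(H[1, 2], 1, tolerance = 1e-10)
  Hk <- hitting_time(build_operators(k3()))$values
  expect_equal(Hk[upper.tri(Hk) | lower.tri(Hk)], rep(2, 6),
               tolerance = 1e-10)
})

test_that("commute time matches closed-form values and is symmetric", {
  expect_equal(commute_time(build_operators(two_node()))$values[1, 2], 2,
               tolerance = 1e-10)
  C <- commute_time(build_operators(path3()))$values
  expect_equal(C[1, 3], 8, tolerance = 1e-10)
  expect_equal(C[1, 2], 4, tolerance = 1e-10)
  Ck <- commute_time(build_operators(k3()))$values
  expect_equal(Ck[1, 2], 4, tolerance = 1e-10)
  expect_identical(Ck, t(Ck))
  expect_true(all(Ck[upper.tri(Ck)] > 0))
})

test_that("resistance distance matches circuit values and is a metric", {
  R <- resistance_distance(build_operators(path3()))$values
  expect_equal(R[1, 3], 2, tolerance = 1e-10)
  Rk <- resistance_distance(build_operators(k3()))$values
  expect_equal(Rk[1, 2], 2 / 3, tolerance = 1e-10)
  for (seed in 1:3) {
    cn <- random_connected(12, seed)
    Rr <- resistance_distance(build_operators(cn))$values
    n <- nrow(Rr)
    for (i in 1:n) for (j in 1:n) for (k in 1:n)
      expect_lte(Rr[i, j], Rr[i, k] + Rr[k, j] + 1e-10)
  }
})

test_that("commute identities C = H + t(H) and C = R * sum(D) hold", {
  for (seed in 1:10) {
    cn <- random_connected(sample(5:30, 1), seed)
    ops <- build_operators(cn)
    C <- commute_time(ops)$values
    H <- hitting_time(ops)$values
    R <- resistance_distance(ops)$values
    expect_lt(max(abs(C - (H + t(H)))), 1e-8 * max(C))
    expect_lt(max(abs(C - R * sum(ops$degree))), 1e-8 * max(C))
  }
})

test_that("uniform weight rescaling leaves the Markov metrics unchanged", {
  cn <- random_connected(12, 11)
  ops <- build_operators(cn)
  for (k in c(0.25, 7)) {
    cn2 <- structural_connectome(cn$weights * k)
    ops2 <- build_operators(cn2)
    expect_equal(ops2$transition, ops$transition, tolerance = 1e-12)
    expect_equal(hitting_time(ops2)$values, hitting_time(ops)$values,
                 tolerance = 1e-8)
    expect_equal(commute_time(ops2)$values, commute_time(ops)$values,
                 tolerance = 1e-8)
  }
})

test_that("adding an edge never increases any resistance distance", {
  for (seed in 1:5) {
    cn <- random_connected(8, seed)
    R0 <- resistance_distance(build_operators(cn))$values
    A <- cn$weights
    off <- which(upper.tri(A), arr.ind = TRUE)
    set.seed(100 + seed)
    pick <- off[sample(nrow(off), 1), ]
    A[pick[1], pick[2]] <- A[pick[2], pick[1]] <- A[pick[1], pick[2]] + 3
    R1 <- resistance_distance(build_operators(
      structural_connectome(A)))$values
    expect_true(all(R1 <= R0 + 1e-10))
  }
})

test_that("MFPT-based commute equals the hitting-based closed form", {
  expect_equal(mfpt_commute_time(build_operators(two_node()))$values[1, 2],
               2, tolerance = 1e-8)
  expect_equal(mfpt_commute_time(build_operators(k3()))$values[1, 2], 4,
               tolerance = 1e-8)
  cn <- generate_connectome(connectome_spec(n_regions = 20,
                                            intra_density = 0.5,
                                            inter_density = 0.2, seed = 9))
  ops <- build_operators(cn)
  mf <- pair_vector(mfpt_commute_time(ops)$values)
  hc <- pair_vector(commute_time(ops)$values)
  expect_gte(spearman_correlation(mf, hc)$rho, 0.95)
  expect_lt(max(abs(mf - hc)) / max(hc), 1e-8)
})

test_that("communicability matches spectral closed forms", {
  cm <- communicability(build_operators(two_node()))$values
  expect_equal(cm[1, 2], sinh(1), tolerance = 1e-10)
  expect_equal(cm[1, 1], cosh(1), tolerance = 1e-10)
  cmk <- communicability(build_operators(k3()))$values
  expect_equal(cmk[1, 2], (exp(1) - exp(-0.5)) / 3, tolerance = 1e-10)
})

test_that("communicability equals its truncated walk series and is positive", {
  cn <- random_connected(10, 21)
  ops <- build_operators(cn)
  CMY <- communicability(ops)$values
  d <- ops$degree
  An <- ops$adjacency / sqrt(outer(d, d))
  acc <- diag(nrow(An))
  term <- diag(nrow(An))
  for (n in 1:30) {
    term <- term %*% An / n
    acc <- acc + term
  }
  expect_lt(max(abs(CMY - acc)), 1e-10)
  expect_true(all(CMY > 0))
  elem <- communicability(ops, method = "elementwise")$values
  expect_equal(elem, exp(An), ignore_attr = TRUE)
})

test_that("search information counts the bits along the shortest path", {
  expect_equal(search_information(build_operators(two_node()))$values[1, 2],
               0, tolerance = 1e-12)
  si <- search_information(build_operators(path3()))$values
  expect_equal(si[1, 3], 1, tolerance = 1e-12) # -log2(1 * 0.5)
  sis <- search_information(build_operators(star4()))$values
  expect_equal(sis[2, 3], log2(3), tolerance = 1e-12)
  expect_equal(sis[1, 2], log2(3), tolerance = 1e-12)
})

test_that("search information symmetrization averages the two directions", {
  cn <- small_connectome(n = 10, seed = 13)
  m <- search_information(build_operators(cn))
  expect_false(isTRUE(all.equal(m$values, t(m$values))))
  expect_equal(metric_values(m), (m$values + t(m$values)) / 2)
  expect_identical(m$meta$distances, "tract_length")
  no_len <- structural_connectome(cn$weights)
  m2 <- search_information(build_operators(no_len))
  expect_identical(m2$meta$distances, "inverse_weight")
})
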