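test_that("neutral SFS constants for k = 11 and small k", {
  sfs <- neutral_sfs(11)
  expect_equal(sum(sfs$prop), 1)
  expect_equal(sum(sfs$d * sfs$prop), 10 / harmonic_a(11))
  expect_equal(neutral_mean_d(11), 3.414, tolerance = 5e-4)
  expect_lt(abs(sfs$prop[1] - 0.341), 5e-4) # prints as 34.1%

  expect_equal(neutral_sfs(2)$prop, 1)
  expect_equal(neutral_mean_d(2), 1)
})

test_that("nonsingleton neutral mean excludes both singleton classes", {
  expect_equal(neutral_mean_d(11, exclude_singletons = TRUE), 4.374,
               tolerance = 5e-4)
  expect_equal(neutral_mean_d(4, exclude_singletons = TRUE), 2)
  expect_equal(neutral_mean_d(6, exclude_singletons = TRUE),
               3 / (1 / 2 + 1 / 3 + 1 / 4))
  expect_error(neutral_mean_d(3, exclude_singletons = TRUE), "k >= 4")
})

test_that("posterior odds follow the likelihood ratio times prior odds", {
  # prior odds 1 (b = 1): posterior odds equal (k - d)/d
  po <- posterior_odds(1:10, b = 1)
  expect_equal(po$odds, (11 - 1:10) / (1:10))
  # d and k-d odds are reciprocal
  expect_equal(po$odds[2] * po$odds[9], 1)

  # worked case: k = 11, d = 10, theta = 0.0222, div = 0.0763
  params <- neutral_model_params(11, theta = 0.0222, div = 0.0763)
  w <- posterior_odds(10, params)
  expect_equal(w$likelihood_ratio, 0.1)
  expect_equal(w$odds, 0.1 / (0.0763 - 10 / 11 * 0.0222), tolerance = 1e-12)
  expect_equal(w$odds, 1.782, tolerance = 5e-4)
  expect_equal(w$p_asm, 0.359, tolerance = 5e-3)

  expect_error(posterior_odds(5, neutral_model_params(11, 0.1, 0.05)),
               "must be > 0")
})

test_that("ASM forward model conserves mass and hits the worked tail values", {
  p <- neutral_sfs(11)$prop
  # b = 0 is the identity; neutral tail ratio is 10:9 i.e. 0.9
  id <- asm_forward_sfs(p, b = 0)
  expect_equal(id$presented_prop, p)
  expect_equal(p[10] / p[9], 0.9)

  params <- neutral_model_params(11, theta = 0.0222, div = 0.0763)
  fwd <- asm_forward_sfs(p, params = params)
  expect_equal(sum(fwd$presented_prop), 1)
  expect_equal(asm_tail_ratio(params), 1.12, tolerance = 5e-3)

  # tail ratio strictly increases with b
  ratios <- sapply(seq(0, 0.2, by = 0.02), function(b) {
    f <- asm_forward_sfs(p, b = b)
    f$presented_prop[10] / f$presented_prop[9]
  })
  expect_true(all(diff(ratios) > 0))

  expect_error(asm_forward_sfs(c(0.5, 0.4), b = 0.1), "summing to 1")
})

test_that("equal-tail divergence solve matches the worked value and bisection", {
  sol <- solve_equal_tail_divergence(0.0222, k = 11)
  expect_equal(sol$div, 0.0424, tolerance = 5e-4)
  expect_lt(abs(sol$tail_prop - 0.041), 5e-4) # prints as 4.1%
  # theta = 0 limit: div = b = 1/45 for k = 11
  expect_equal(solve_equal_tail_divergence(0, 11)$div, 1 / 45)

  # independent bisection on the forward model finds the same root
  p <- neutral_sfs(11)$prop
  gap <- function(div) {
    b <- div - 10 / 11 * 0.0222
    f <- asm_forward_sfs(p, b = max(b, 0))
    f$presented_prop[10] - f$presented_prop[9]
  }
  root <- uniroot(gap, c(0.021, 0.2), tol = 1e-12)$root
  expect_equal(sol$div, root, tolerance = 1e-9)
})

test_that("error mixing matrix reproduces the worked binomial figures", {
  m <- error_mixing_matrix(11, 0.001)
  expect_true(all(abs(rowSums(m) - 1) < 1e-12))
  # worked values at the precision they are printed (percent, 2-4 digits)
  expect_lt(abs(m["0", "0"] - 0.9891), 5e-5) # invariant stays invariant
  expect_lt(abs(m["0", "1"] - 0.0109), 5e-5) # apparent singleton
  expect_lt(abs(m["0", "2"] - 5.5e-5), 6e-7)
  expect_lt(abs(m["1", "1"] - 0.9900), 5e-5)
  expect_lt(abs(m["1", "2"] - 0.0099), 2e-5)
  expect_lt(abs(m["1", "3"] - 4.4e-5), 1e-6)

  # rows sum to 1 across error rates; identity at eps = 0
  for (eps in c(0, 0.01, 0.2)) {
    mm <- error_mixing_matrix(11, eps)
    expect_true(all(abs(rowSums(mm) - 1) < 1e-12))
  }
  m0 <- error_mixing_matrix(11, 0)
  expect_equal(unname(m0[, 1:11]), diag(11))
})

test_that("apparent singleton fraction is increasing in eps and invertible", {
  # eps = 0 reduces to the neutral singleton share
  expect_equal(apparent_singleton_fraction(0.0222, 11, 0),
               1 / harmonic_a(11))
  grid <- seq(0, 0.01, by = 0.001)
  vals <- sapply(grid, function(e) apparent_singleton_fraction(0.0222, 11, e))
  expect_true(all(diff(vals) > 0))

  # the worked inversion: 55.1% apparent singletons needs eps ~ 0.33%
  eps <- solve_error_rate(0.0222, 11, 0.551)
  expect_equal(100 * eps, 0.33, tolerance = 0.01)
  # round trip
  expect_lt(abs(apparent_singleton_fraction(0.0222, 11, eps) - 0.551), 1e-6)
  expect_equal(solve_error_rate(0.0222, 11, 1 / harmonic_a(11)), 0)
  expect_error(solve_error_rate(0.0222, 11, 0.1), "must lie in")
})
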