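test_that("selected SFS reduces to 1/d at gamma = 0 and shifts with gamma", {
  k <- 11
  s0 <- selected_sfs(k, 0)
  expect_equal(s0$prop, (1 / (1:10)) / harmonic_a(k))

  # quadrature across a gamma grid: mean d strictly increasing
  means <- sapply(c(-2, -1, 0, 1, 2), function(g) {
    s <- selected_sfs(k, g)
    sum(s$d * s$prop)
  })
  expect_true(all(diff(means) > 0))
  expect_equal(means[3], (k - 1) / harmonic_a(k))

  # sampler matches the neutral spectrum (chi-square goodness of fit)
  set.seed(31)
  x <- sample_selected_sfs_counts(1e5, k, 0)
  obs <- tabulate(x, nbins = 10)
  gof <- suppressWarnings(chisq.test(obs, p = s0$prop))
  expect_gt(gof$p.value, 0.001)
  expect_equal(mean(x), 3.414, tolerance = 3 * sd(x) / sqrt(1e5) / 3.414 + 0.01)
  expect_equal(mean(x == 1), 0.341, tolerance = 3 * sqrt(0.34 * 0.66 / 1e5) + 0.002)
})

test_that("singleton inflation reweights only the singleton class", {
  set.seed(32)
  x <- sample_selected_sfs_counts(5e4, 11, 0, singleton_inflation = 2.4)
  p1 <- (1 / harmonic_a(11)) * 2.4
  expected <- p1 / (p1 + (1 - 1 / harmonic_a(11)))
  expect_equal(mean(x == 1), expected, tolerance = 0.01)
})

test_that("site-table simulation honours its truth table and flip rates", {
  # no ASM, no error: observed equals truth
  p0 <- sim_params(seed = 41, n_syn = 800, n_intron = 400, asm = FALSE)
  sim0 <- simulate_sites(p0)
  expect_equal(sim0$sites$d, sim0$truth$true_d)
  expect_true(all(!sim0$truth$flipped))
  expect_true(all(sim0$sites$d >= 1 & sim0$sites$d <= 10))

  # ASM on: flip fraction approx b/(1+b) per site type
  p1 <- sim_params(seed = 42, n_syn = 6000, n_intron = 0)
  sim1 <- simulate_sites(p1)
  b <- 0.0763 - 10 / 11 * 0.0222
  f <- b / (1 + b)
  se <- sqrt(f * (1 - f) / 6000)
  expect_lt(abs(mean(sim1$truth$flipped) - f), 3 * se)
  # flipped sites have negated delta-pref relative to the drawn pair
  flip <- sim1$truth$flipped
  expect_equal(
    sim1$sites$delta_pref[flip],
    -delta_pref(sim1$sites$derived_codon[flip],
                sim1$sites$ancestral_codon[flip],
                preference_scores_dpse())
  )
})

test_that("sequencing error converts invariant sites at the binomial rate", {
  p <- sim_params(seed = 43, n_syn = 2000, n_intron = 0, eps = 0.001,
                  asm = FALSE)
  sim <- simulate_sites(p)
  err <- sim$truth[sim$truth$origin == "error_invariant", ]
  # expected count: n_invariant * P(1 <= Binom(11, eps) <= 10)
  a <- harmonic_a(11)
  l_syn <- 2000 / (a * 0.0222)
  n_inv <- round(l_syn * (1 - 0.0222 * a))
  p_conv <- sum(dbinom(1:10, 11, 0.001))
  expect_lt(abs(nrow(err) - n_inv * p_conv), 3 * sqrt(n_inv * p_conv) + 1)
  # converted invariants are overwhelmingly apparent singletons (1.09% vs 0.0055%)
  expect_gt(mean(err$d == 1), 0.98)
})

test_that("simulated recombination map is well-formed and couples theta", {
  p <- sim_params(seed = 44, map_segments = 40, rate_theta_coupling = TRUE)
  set.seed(p$seed)
  map <- simulate_recomb_map(p)
  expect_true(all(map$end > map$start))
  expect_true(all(map$start[-1] == map$end[-nrow(map)])) # contiguous tiling
  # two testcross replicates agree strongly
  expect_gt(cor(map$rate_a, map$rate_b), 0.9)
  # coupling: theta multiplier rises with rate up to saturation
  expect_gt(cor(map$theta_mult, pmin(map$rate, 2)), 0.8)
})

test_that("rate-theta coupling surfaces as a positive class-level correlation", {
  p <- sim_params(seed = 45, n_syn = 8000, n_intron = 0,
                  rate_theta_coupling = TRUE, map_segments = 50)
  sim <- simulate_sites(p)
  cls <- rate_class_summaries(sim$sites, sim$totals, k = 11, width = 0.5,
                              top = 6)
  cls <- cls[cls$site_type == "synonymous" & cls$s >= 20, ]
  ct <- correlate(cls$rate_upper, cls$theta_w, tail = "greater")
  expect_gt(ct$r, 0)
  expect_lt(ct$p_value, 0.05)
})

test_that("alignment simulator round-trips exactly through the pipeline", {
  sim <- simulate_alignments(seed = 51, n_genes = 3, n_codons = 90, k = 11)
  expect_true(all(validate_gene(sim$models, sim$aln)$included))
  aln <- apply_masks(sim$aln, sim$masks)
  calls <- call_sites(aln, sim$models)
  expect_equal(nrow(calls$sites), nrow(sim$truth))
  merged <- dplyr::inner_join(
    calls$sites, sim$truth,
    by = c("gene", "pos"), suffix = c("", ".truth")
  )
  expect_equal(nrow(merged), nrow(sim$truth))
  expect_equal(merged$d, merged$d.truth)
  expect_equal(merged$ancestral_codon, merged$ancestral_codon.truth)
  expect_equal(merged$site_type, merged$site_type.truth)
})

test_that("alignment simulator induces ASM flips the pipeline then observes", {
  sim <- simulate_alignments(seed = 52, n_genes = 6, n_codons = 120,
                             asm_b = 0.4)
  calls <- call_sites(sim$aln, sim$models)
  merged <- dplyr::inner_join(calls$sites, sim$truth, by = c("gene", "pos"),
                              suffix = c("", ".truth"))
  # pipeline-observed polarity equals the truth table's post-flip polarity
  expect_equal(merged$d, merged$d.truth)
  f <- mean(sim$truth$flipped)
  expect_gt(f, 0.1) # b = 0.4 -> flip probability ~0.286
  expect_lt(f, 0.5)
})

test_that("selection shifts U->P spectra up relative to P->U in simulation", {
  p <- sim_params(seed = 46, n_syn = 3000, n_intron = 0, gamma = 1,
                  asm = FALSE)
  sim <- simulate_sites(p)
  out <- sfs_shift_test(sim$sites[sim$sites$delta_pref != 0, ])
  expect_gt(out$mean[1], out$mean[2])
  expect_lt(out$t$p.value, 1e-6)

  # gamma = 0: no systematic shift (two-sided check at a loose level)
  p0 <- sim_params(seed = 47, n_syn = 3000, n_intron = 0, gamma = 0,
                   asm = FALSE)
  sim0 <- simulate_sites(p0)
  out0 <- sfs_shift_test(sim0$sites[sim0$sites$delta_pref != 0, ])
  expect_gt(out0$t$p.value, 0.001)
})
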