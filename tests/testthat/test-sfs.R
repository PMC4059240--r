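test_that("SFS construction counts, filters and zero-fills", {
  sites <- tibble::tibble(d = c(1L, 1L, 5L), delta_pref = c(1, -1, 1))
  sfs <- build_sfs(sites, k = 11)
  expect_equal(sfs$n[sfs$d == 1], 2L)
  expect_equal(sfs$n[sfs$d == 5], 1L)
  expect_equal(sum(sfs$n), 3L)
  expect_equal(sfs_mean_d(sfs), 7 / 3)

  up <- build_sfs(sites[sites$delta_pref > 0, ], k = 11)
  expect_equal(sum(up$n), 2L)

  nos <- build_sfs(tibble::tibble(d = c(1L, 2L, 10L, 9L)), k = 11,
                   exclude_singletons = TRUE)
  expect_equal(sum(nos$n), 2L) # d = 1 and d = 10 both removed
})

test_that("shift tests behave at symmetry and separation; U matches rank oracle", {
  set.seed(1)
  d <- sample(1:10, 60, replace = TRUE)
  sym <- tibble::tibble(d = c(d, d), delta_pref = rep(c(1, -1), each = 60))
  out <- sfs_shift_test(sym)
  expect_equal(out$t$p.value, 0.5, tolerance = 1e-9)
  expect_equal(out$u$p.value, 0.5, tolerance = 0.02)

  sep <- tibble::tibble(
    d = c(5L, 6L, 5L, 1L, 2L, 1L),
    delta_pref = rep(c(1, -1), each = 3)
  )
  out <- sfs_shift_test(sep)
  expect_lt(out$t$p.value, 0.05)

  # U statistic equals exhaustive pair counting with ties at 0.5
  x <- c(3, 5, 7, 7)
  y <- c(1, 5, 6)
  u_oracle <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  got <- sfs_shift_test(
    tibble::tibble(d = c(x, y), delta_pref = rep(c(1, -1), c(4, 3)))
  )
  expect_equal(unname(got$u$statistic), u_oracle)

  expect_error(
    sfs_shift_test(tibble::tibble(d = 1:3, delta_pref = c(1, 1, 1))),
    "nonempty"
  )
})

test_that("permutation test matches exhaustive enumeration and handles degeneracy", {
  set.seed(11)
  for (rep in 1:3) {
    d <- sample(1:10, 6, replace = TRUE)
    dp <- round(rnorm(6), 2)
    if (length(unique(d)) == 1 || length(unique(dp)) == 1) next
    p_ex <- perm_p_exhaustive(d, dp)
    mc <- sum_dpref_test(d = d, delta_pref = dp, replicates = 20000,
                         seed = rep)
    se <- sqrt(p_ex * (1 - p_ex) / 20000)
    expect_lt(abs(mc$p_value - p_ex), max(3 * se, 1e-3))
  }

  # all delta-pref equal: statistic invariant, p = 1 flagged
  inv <- sum_dpref_test(d = c(1, 5, 9), delta_pref = c(2, 2, 2),
                        replicates = 100)
  expect_equal(inv$p_value, 1)
  expect_true(inv$degenerate)

  # strong planted coupling is detected
  set.seed(3)
  coupled <- random_syn_sites(50, coupled = TRUE)
  pt <- sum_dpref_test(coupled, replicates = 5000, seed = 4)
  expect_lt(pt$p_value, 0.001)
})

test_that("polarity flips transform the statistic exactly", {
  set.seed(5)
  s <- random_syn_sites(40)
  t1 <- sum(s$d * s$delta_pref)
  # full polarity flip (d -> k - d, dp -> -dp): T' = T - k * sum(dp)
  t2 <- sum((11 - s$d) * (-s$delta_pref))
  expect_equal(t2, t1 - 11 * sum(s$delta_pref))
  # the flip leaves the k/2-centered statistic invariant
  tc1 <- sum((s$d - 11 / 2) * s$delta_pref)
  tc2 <- sum(((11 - s$d) - 11 / 2) * (-s$delta_pref))
  expect_equal(tc2, tc1)
})

test_that("neutral data give a nominal type-I error rate", {
  set.seed(21)
  alpha <- 0.05
  n_rep <- 200
  rejections <- sum(vapply(seq_len(n_rep), function(i) {
    s <- random_syn_sites(100)
    sum_dpref_test(s, replicates = 199)$p_value < alpha
  }, logical(1)))
  se <- sqrt(alpha * (1 - alpha) / n_rep)
  expect_lt(abs(rejections / n_rep - alpha), 3 * se + 1 / n_rep)
})

test_that("ASM-randomized test reduces to the plain test as b -> 0+", {
  set.seed(6)
  s <- random_syn_sites(60, coupled = TRUE)
  k <- 11
  theta <- 0.02
  div_small_b <- (k - 1) / k * theta + 1e-9 # b -> 0+, odds -> Inf, no flips
  plain <- sum_dpref_test(s, replicates = 3000, seed = 7)
  asm <- asm_sum_dpref_test(s, theta = theta, div = div_small_b,
                            replicates = 3000, draws = 3, seed = 7)
  td <- tidy(asm)
  expect_true(all(abs(td$statistic - plain$statistic) < 1e-12))

  # per-site flip probability follows the posterior odds
  po <- posterior_odds(5, b = 1)
  expect_equal(po$odds, (11 - 5) / 5)
  expect_equal(po$p_asm, 1 / (1 + 6 / 5))
})

test_that("ASM-randomized test stays significant on strongly coupled data", {
  set.seed(8)
  s <- random_syn_sites(400, coupled = TRUE)
  s$amino_acid <- sample(c("glu", "lys"), 400, replace = TRUE)
  params <- tibble::tibble(
    amino_acid = c("glu", "lys"), theta = c(0.032, 0.029),
    div = c(0.106, 0.104)
  )
  asm <- asm_sum_dpref_test(s, class_params = params, replicates = 2000,
                            draws = 5, seed = 9)
  expect_lt(asm$p_value, 0.01)
  expect_error(
    asm_sum_dpref_test(s, theta = 0.1, div = 0.05, replicates = 10, draws = 1),
    "prior odds undefined"
  )
})

test_that("regression slopes match closed form and detect planted contrasts", {
  s <- tibble::tibble(delta_pref = c(-1, 0, 1, 2), d = c(1, 3, 5, 7))
  expect_equal(suppressWarnings(fit_slope(s)$slope), 2)
  expect_error(fit_slope(tibble::tibble(delta_pref = rep(1, 5), d = 1:5)),
               "zero variance")

  set.seed(10)
  dp <- rnorm(200)
  d <- 3 + 0.7 * dp + rnorm(200, 0, 2)
  cov_ratio <- cov(d, dp) / var(dp)
  expect_equal(fit_slope(tibble::tibble(d = d, delta_pref = dp))$slope,
               cov_ratio)

  # two groups with slopes 0.2 vs 0.7, n = 500, sd 2: detected
  set.seed(12)
  mk <- function(b, n) {
    dp <- rnorm(n)
    tibble::tibble(d = 3 + b * dp + rnorm(n, 0, 2), delta_pref = dp)
  }
  g <- dplyr::bind_rows(
    dplyr::mutate(mk(0.2, 500), grp = "low"),
    dplyr::mutate(mk(0.7, 500), grp = "high")
  )
  out <- compare_slopes(g, group = "grp", one_tailed = TRUE)
  expect_lt(out$p_value, 0.05)

  # identical groups: adjusted p near 1
  same <- dplyr::bind_rows(
    dplyr::mutate(mk(0.5, 400), grp = "a"),
    dplyr::mutate(mk(0.5, 400), grp = "b")
  )
  expect_gt(compare_slopes(same, group = "grp")$p_value, 0.2)
})

test_that("two-way ANOVA matches hand-computed balanced decomposition", {
  # balanced 2x2, 2 obs per cell
  df <- tibble::tibble(
    d = c(1, 3, 5, 7, 2, 4, 8, 10),
    site_type = rep(c("intron", "codon"), each = 4),
    direction = rep(rep(c("fwd", "rev"), each = 2), 2)
  )
  out <- two_way_anova(df)
  # hand computation
  y <- df$d
  gm <- mean(y)
  m_a <- tapply(y, df$site_type, mean)
  m_b <- tapply(y, df$direction, mean)
  m_ab <- tapply(y, paste(df$site_type, df$direction), mean)
  ss_a <- 4 * sum((m_a - gm)^2)
  ss_b <- 4 * sum((m_b - gm)^2)
  ss_cells <- 2 * sum((m_ab - gm)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_tot <- sum((y - gm)^2)
  expect_equal(out$sumsq[out$term == "site_type"], ss_a)
  expect_equal(out$sumsq[out$term == "direction"], ss_b)
  expect_equal(out$sumsq[out$term == "interaction"], ss_ab)
  expect_equal(sum(out$sumsq), ss_tot)

  # equal cell means: all effect SS 0
  flat <- tibble::tibble(
    d = rep(c(1, 3), 8),
    site_type = rep(c("x", "y"), each = 8),
    direction = rep(rep(c("p", "q"), each = 4), 2)
  )
  outf <- two_way_anova(flat)
  expect_true(all(outf$sumsq[outf$term != "residual"] < 1e-10))

  # empty cell is named in the error
  bad <- df[!(df$site_type == "intron" & df$direction == "rev"), ]
  expect_error(two_way_anova(bad), "intron x rev")
})

test_that("planted site-type-by-direction interaction is recovered", {
  set.seed(13)
  n <- 400
  mk <- function(type, dir, shift) {
    tibble::tibble(
      d = pmin(pmax(round(2.5 + shift + rnorm(n, 0, 2)), 1), 10),
      site_type = type, direction = dir
    )
  }
  # codon shift (1.4) larger than intron shift (0.6), shared direction labels
  df <- dplyr::bind_rows(
    mk("codon", "toward_gc", 1.4), mk("codon", "toward_at", 0),
    mk("intron", "toward_gc", 0.6), mk("intron", "toward_at", 0)
  )
  out <- two_way_anova(df)
  expect_lt(out$p_value[out$term == "interaction"], 0.05)
  expect_lt(out$p_value[out$term == "direction"], 1e-10)
})

test_that("G-test matches an independent log-likelihood evaluation", {
  # table proportional to its margins: G = 0
  prop <- outer(c(30, 70), c(10, 40, 50)) / 100
  expect_equal(g_test(prop)$statistic, 0)

  set.seed(14)
  x <- matrix(rpois(8, 40) + 1, 2, 4)
  e <- outer(rowSums(x), colSums(x)) / sum(x)
  g_direct <- 2 * sum(x * log(x / e))
  got <- g_test(x)
  expect_equal(got$statistic, g_direct)
  expect_equal(got$df, 3)
  expect_equal(got$p_value, pchisq(g_direct, 3, lower.tail = FALSE))

  expect_error(g_test(matrix(c(0, 0, 1, 2), 2)), "zero marginal")

  # goodness-of-fit form
  gof <- g_test(c(10, 20, 30), p = c(1, 1, 1) / 3)
  e0 <- rep(20, 3)
  expect_equal(gof$statistic, 2 * sum(c(10, 20, 30) * log(c(10, 20, 30) / e0)))
})

test_that("sequential Bonferroni equals Holm's adjustment", {
  p <- c(0.001, 0.01, 0.04, 0.2)
  expect_equal(sequential_bonferroni(p), p.adjust(p, method = "holm"))
})
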