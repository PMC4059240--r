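# Unfolded SFS construction and the battery of shift tests: parametric and
# rank tests on derived counts, the sum(d x delta-pref) permutation test and
# its ASM-randomized variant, regression-slope contrasts, two-way ANOVA, and
# the log-likelihood-ratio G-test.

#' Build an unfolded site frequency spectrum
#'
#' Counts polymorphic sites by derived count `d = 1..k-1`, optionally within
#' classes.
#'
#' @param sites Site tibble with column `d` (plus any `by` columns).
#' @param k Sample size.
#' @param by Optional character vector of grouping columns.
#' @param exclude_singletons Drop sites with `d` in `{1, k-1}` (both
#'   polarities of apparent singleton).
#' @return A tibble of class `codon_sfs` with the `by` columns, `d`, and `n`
#'   (zero-filled over `d = 1..k-1`).
#' @export
build_sfs <- function(sites, k = 11, by = NULL, exclude_singletons = FALSE) {
  stopifnot(all(sites$d >= 1), all(sites$d <= k - 1))
  if (exclude_singletons) sites <- sites[!sites$d %in% c(1L, k - 1L), ]
  grid <- tibble::tibble(d = seq_len(k - 1))
  if (!is.null(by)) {
    classes <- dplyr::distinct(sites[, by, drop = FALSE])
    grid <- tidyr::crossing(classes, grid)
  }
  out <- sites |>
    dplyr::count(dplyr::across(dplyr::all_of(c(by, "d"))), name = "n") |>
    dplyr::right_join(grid, by = c(by, "d")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(by, "d"))))
  class(out) <- c("codon_sfs", class(out))
  out
}

#' Mean derived count of an SFS
#'
#' @param sfs A `codon_sfs` tibble (`d`, `n`).
#' @return `sum(d * n) / sum(n)` (NaN for an empty spectrum).
#' @export
sfs_mean_d <- function(sfs) {
  sum(sfs$d * sfs$n) / sum(sfs$n)
}

#' Parametric and rank tests for an SFS shift between two site classes
#'
#' One-tailed Student's t-test and Mann-Whitney U-test of the alternative
#' that derived counts of U->P sites (positive delta-pref) exceed those of
#' P->U sites (negative delta-pref); or of any two user-given groups.
#'
#' @param sites Site tibble with columns `d` and `delta_pref` (used when
#'   `group` is `NULL`; zero-delta-pref sites are dropped).
#' @param group Optional logical/two-level vector splitting `sites$d`; level
#'   ordering follows `levels`/`unique`, and the alternative is
#'   "first group greater".
#' @param exclude_singletons Drop `d` in `{1, k-1}` first.
#' @param k Sample size (for singleton exclusion).
#' @return An object of class `sfs_shift_test` with elements `t` and `u`
#'   (`htest` objects), group means and sizes. Use [generics::tidy()] for a
#'   tabular view.
#' @export
sfs_shift_test <- function(sites, group = NULL, exclude_singletons = FALSE,
                           k = 11) {
  if (exclude_singletons) sites <- sites[!sites$d %in% c(1L, k - 1L), ]
  if (is.null(group)) {
    up <- sites$d[sites$delta_pref > 0]
    pu <- sites$d[sites$delta_pref < 0]
    labels <- c("U->P", "P->U")
  } else {
    lev <- if (is.factor(group)) levels(group) else unique(group)
    stopifnot(length(lev) == 2)
    up <- sites$d[group == lev[1]]
    pu <- sites$d[group == lev[2]]
    labels <- as.character(lev)
  }
  if (length(up) == 0 || length(pu) == 0) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  tt <- stats::t.test(up, pu, alternative = "greater")
  ut <- suppressWarnings(
    stats::wilcox.test(up, pu, alternative = "greater", correct = TRUE)
  )
  structure(
    list(
      t = tt, u = ut, labels = labels,
      mean = c(mean(up), mean(pu)), n = c(length(up), length(pu))
    ),
    class = "sfs_shift_test"
  )
}

#' @export
print.sfs_shift_test <- function(x, ...) {
  cat("SFS shift test (one-tailed, H1:", x$labels[1], ">", x$labels[2], ")\n")
  cat(sprintf(
    "  %s: n = %d, mean d = %.3f\n  %s: n = %d, mean d = %.3f\n",
    x$labels[1], x$n[1], x$mean[1], x$labels[2], x$n[2], x$mean[2]
  ))
  cat(sprintf(
    "  t = %.3f, P = %.3g; Mann-Whitney U = %.1f, P = %.3g\n",
    x$t$statistic, x$t$p.value, x$u$statistic, x$u$p.value
  ))
  invisible(x)
}

sum_dpref_statistic <- function(d, delta_pref) sum(d * delta_pref)

#' Permutation test on the sum of d x delta-pref
#'
#' Under selection on codon usage, derived counts `d` should covary
#' positively with the preference change `delta_pref`, making
#' `T = sum(d * delta_pref)` larger than under random pairing. The one-tailed
#' p-value is the proportion of random permutations of `d` against
#' `delta_pref` with a permuted sum strictly greater than the observed sum.
#' A reported p of 0 means no permutation exceeded the observed statistic
#' (so p < 1/replicates).
#'
#' @param sites Site tibble with columns `d` and `delta_pref` (or pass bare
#'   vectors via `d`/`delta_pref`).
#' @param replicates Number of Monte Carlo permutations (default 100,000).
#' @param seed Optional integer seed for reproducibility.
#' @param d,delta_pref Bare vectors, used when `sites` is `NULL`.
#' @return An object of class `perm_test`: observed statistic, p-value,
#'   replicate count, and a `degenerate` flag (statistic invariant under
#'   permutation, p = 1 by construction).
#' @export
sum_dpref_test <- function(sites = NULL, replicates = 1e5, seed = NULL,
                           d = NULL, delta_pref = NULL) {
  if (!is.null(sites)) {
    d <- sites$d
    delta_pref <- sites$delta_pref
  }
  stopifnot(length(d) == length(delta_pref), length(d) >= 2)
  if (!is.null(seed)) set.seed(seed)
  t_obs <- sum_dpref_statistic(d, delta_pref)
  degenerate <- length(unique(d)) == 1 || length(unique(delta_pref)) == 1
  if (degenerate) {
    p <- 1
    exceed <- replicates
  } else {
    exceed <- 0L
    for (i in seq_len(replicates)) {
      if (sum(sample(d) * delta_pref) > t_obs) exceed <- exceed + 1L
    }
    p <- exceed / replicates
  }
  structure(
    list(
      statistic = t_obs, p_value = p, replicates = replicates,
      exceedances = exceed, n = length(d), seed = seed,
      degenerate = degenerate
    ),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "Permutation test: sum(d x delta-pref) = %.4f, n = %d\n", x$statistic, x$n
  ))
  p_lab <- if (x$p_value == 0) {
    sprintf("0 (none of %d permutations exceeded; p < %.2g)",
            x$replicates, 1 / x$replicates)
  } else {
    format(x$p_value)
  }
  cat("  one-tailed P =", p_lab, "\n")
  if (x$degenerate) cat("  note: statistic invariant under permutation\n")
  invisible(x)
}

#' ASM-randomized permutation test
#'
#' Repeats the [sum_dpref_test()] after randomly re-assigning each site's
#' ancestral state according to its posterior odds of correct parsimony
#' polarization ([posterior_odds()]): in each assignment draw a site keeps
#' its polarity with probability `odds / (1 + odds)` and otherwise flips
#' (`d -> k - d`, `delta_pref -> -delta_pref`). One permutation test is run
#' per draw and the p-values are averaged (individual draws are retained).
#'
#' @param sites Site tibble with columns `d`, `delta_pref`, and — when
#'   `class_params` is given — the class column it is keyed by.
#' @param theta,div Scalar per-site diversity and divergence used for every
#'   site when `class_params` is `NULL`.
#' @param class_params Optional tibble with a class column (e.g.
#'   `amino_acid`) plus `theta` and `div`, giving distinct estimates per
#'   class.
#' @param class_col Name of the class column (default `"amino_acid"`).
#' @param k Sample size.
#' @param replicates Permutations per draw.
#' @param draws Number of independent polarity-assignment draws.
#' @param seed Optional integer seed.
#' @return An object of class `asm_perm_test` with the averaged p-value and
#'   per-draw results.
#' @export
asm_sum_dpref_test <- function(sites, theta = NULL, div = NULL,
                               class_params = NULL, class_col = "amino_acid",
                               k = 11, replicates = 1e4, draws = 20,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(class_params)) {
    stopifnot(!is.null(theta), !is.null(div))
    b <- rep(div - (k - 1) / k * theta, nrow(sites))
  } else {
    stopifnot(all(c(class_col, "theta", "div") %in% names(class_params)))
    idx <- match(sites[[class_col]], class_params[[class_col]])
    if (anyNA(idx)) stop("sites with no matching class parameters", call. = FALSE)
    b <- class_params$div[idx] - (k - 1) / k * class_params$theta[idx]
  }
  if (any(b <= 0)) {
    stop("prior odds undefined: div - ((k-1)/k) * theta must be > 0",
      call. = FALSE
    )
  }
  odds <- ((k - sites$d) / sites$d) / b
  p_keep <- odds / (1 + odds)
  per_draw <- purrr::map(seq_len(draws), function(i) {
    flip <- stats::runif(nrow(sites)) > p_keep
    d_i <- ifelse(flip, k - sites$d, sites$d)
    dp_i <- ifelse(flip, -sites$delta_pref, sites$delta_pref)
    sum_dpref_test(d = d_i, delta_pref = dp_i, replicates = replicates)
  })
  structure(
    list(
      p_value = mean(purrr::map_dbl(per_draw, "p_value")),
      draws = per_draw, n = nrow(sites), k = k,
      replicates = replicates, seed = seed
    ),
    class = "asm_perm_test"
  )
}

#' @export
print.asm_perm_test <- function(x, ...) {
  cat(sprintf(
    "ASM-randomized permutation test: n = %d, %d draws x %d permutations\n",
    x$n, length(x$draws), x$replicates
  ))
  cat("  averaged one-tailed P =", format(x$p_value), "\n")
  invisible(x)
}

#' OLS slope of derived count on delta-pref
#'
#' @param sites Site tibble with columns `d` and `delta_pref`.
#' @return A tibble with `slope`, `se`, `n`, `df`, `sigma2` (residual
#'   variance).
#' @export
fit_slope <- function(sites) {
  stopifnot(nrow(sites) >= 3)
  if (stats::var(sites$delta_pref) == 0) {
    stop("delta_pref has zero variance; slope undefined", call. = FALSE)
  }
  fit <- stats::lm(d ~ delta_pref, data = sites)
  sm <- summary(fit)
  tibble::tibble(
    slope = sm$coefficients["delta_pref", "Estimate"],
    se = sm$coefficients["delta_pref", "Std. Error"],
    n = nrow(sites), df = fit$df.residual, sigma2 = sm$sigma^2
  )
}

#' Tukey-Kramer comparison of regression slopes across groups
#'
#' Fits the `d ~ delta_pref` regression separately per group and contrasts
#' every pair of slopes with a studentized-range (Tukey-Kramer) adjustment:
#' `q = |b_i - b_j| / sqrt((se_i^2 + se_j^2) / 2)` referred to the
#' studentized range with the pooled residual degrees of freedom. With
#' `one_tailed = TRUE` the adjusted p is halved when the observed ordering
#' matches `b_i < b_j` for `i` preceding `j` in group order (the alternative
#' that earlier groups — e.g. low-recombination classes — have smaller
#' slopes).
#'
#' @param sites Site tibble with `d`, `delta_pref`, and the grouping column.
#' @param group Name of the grouping column.
#' @param one_tailed Halve directionally consistent p-values.
#' @return A tibble of pairwise contrasts: groups, slopes, `q`, `p_value`;
#'   groups whose slope is undefined are omitted with a message.
#' @export
compare_slopes <- function(sites, group = "recomb_class", one_tailed = FALSE) {
  pieces <- split(sites, sites[[group]])
  fits <- purrr::imap(pieces, function(df, nm) {
    tryCatch(fit_slope(df), error = function(e) NULL)
  })
  bad <- names(fits)[purrr::map_lgl(fits, is.null)]
  if (length(bad) > 0) {
    message("groups without a valid slope omitted: ", paste(bad, collapse = ", "))
  }
  fits <- purrr::compact(fits)
  if (length(fits) < 2) stop("need at least 2 groups with valid slopes", call. = FALSE)
  g <- length(fits)
  df_pool <- sum(purrr::map_dbl(fits, "df"))
  nms <- names(fits)
  out <- list()
  for (i in seq_len(g - 1)) {
    for (j in (i + 1):g) {
      bi <- fits[[i]]$slope
      bj <- fits[[j]]$slope
      se <- sqrt((fits[[i]]$se^2 + fits[[j]]$se^2) / 2)
      q <- abs(bi - bj) / se
      p <- stats::ptukey(q, nmeans = g, df = df_pool, lower.tail = FALSE)
      if (one_tailed && bi < bj) p <- p / 2
      out[[length(out) + 1]] <- tibble::tibble(
        group_1 = nms[i], group_2 = nms[j],
        slope_1 = bi, slope_2 = bj, q = q, df = df_pool, p_value = p
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Two-way fixed-effects ANOVA on derived counts
#'
#' Sequential (Type I) sums of squares with main effects before the
#' interaction, as produced by `stats::aov`; unbalanced designs are allowed
#' but every factor-level combination must be populated.
#'
#' @param data Data frame containing the response and factors.
#' @param response,factor_a,factor_b Column names (response is typically the
#'   derived count `d`; factors e.g. site type and direction of change).
#' @return A tibble with one row per term: `term`, `df`, `sumsq`, `meansq`,
#'   `statistic`, `p_value`.
#' @export
two_way_anova <- function(data, response = "d", factor_a = "site_type",
                          factor_b = "direction") {
  data <- data.frame(
    y = data[[response]],
    a = factor(data[[factor_a]]),
    b = factor(data[[factor_b]])
  )
  stopifnot(nlevels(data$a) >= 2, nlevels(data$b) >= 2)
  cells <- table(data$a, data$b)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop("empty design cell: ", rownames(cells)[empty[1]], " x ",
      colnames(cells)[empty[2]],
      call. = FALSE
    )
  }
  fit <- stats::aov(y ~ a + b + a:b, data = data)
  tab <- summary(fit)[[1]]
  term_map <- c(a = factor_a, b = factor_b, `a:b` = "interaction")
  terms <- trimws(rownames(tab))
  tibble::tibble(
    term = ifelse(terms %in% names(term_map), term_map[terms],
      ifelse(terms == "Residuals", "residual", terms)
    ),
    df = tab$Df, sumsq = tab$`Sum Sq`, meansq = tab$`Mean Sq`,
    statistic = tab$`F value`, p_value = tab$`Pr(>F)`
  )
}

#' G-test (log-likelihood-ratio test) of independence or goodness of fit
#'
#' `G = 2 * sum(O * log(O / E))` with expected counts from the product of
#' margins (matrix input, independence) or from supplied proportions (vector
#' input, goodness of fit). No small-sample correction is applied. The
#' p-value is from the chi-square distribution with `(r-1)(c-1)` (or
#' `length(x) - 1`) degrees of freedom.
#'
#' @param x A contingency matrix of counts, or a count vector.
#' @param p Expected proportions for the goodness-of-fit form (default
#'   uniform).
#' @return An object of class `g_test` (`statistic`, `df`, `p_value`,
#'   `expected`).
#' @examples
#' g_test(matrix(c(8773, 260849, 3940, 152528), nrow = 2, byrow = TRUE))
#' @export
g_test <- function(x, p = NULL) {
  if (is.matrix(x)) {
    if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
      stop("zero marginal total", call. = FALSE)
    }
    e <- outer(rowSums(x), colSums(x)) / sum(x)
    df <- (nrow(x) - 1) * (ncol(x) - 1)
  } else {
    if (is.null(p)) p <- rep(1 / length(x), length(x))
    stopifnot(length(p) == length(x), all(p > 0))
    e <- sum(x) * p / sum(p)
    df <- length(x) - 1
  }
  if (any(e <= 0)) stop("all expected counts must be > 0", call. = FALSE)
  obs <- as.numeric(x)
  exp_ <- as.numeric(e)
  keep <- obs > 0 # lim O->0 of O*log(O/E) is 0
  g <- 2 * sum(obs[keep] * log(obs[keep] / exp_[keep]))
  structure(
    list(
      statistic = g, df = df,
      p_value = stats::pchisq(g, df, lower.tail = FALSE),
      observed = x, expected = e
    ),
    class = "g_test"
  )
}

#' @export
print.g_test <- function(x, ...) {
  cat(sprintf(
    "G-test: G = %.4f, %d d.f., P = %.4g\n", x$statistic, x$df, x$p_value
  ))
  invisible(x)
}

#' Sequential Bonferroni (Holm) correction
#'
#' Thin wrapper over `stats::p.adjust(method = "holm")`.
#'
#' @param p Vector of p-values.
#' @return Adjusted p-values.
#' @export
sequential_bonferroni <- function(p) {
  stats::p.adjust(p, method = "holm")
}
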