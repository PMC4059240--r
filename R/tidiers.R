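# broom-style tidiers for the test objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an SFS shift test
#'
#' @param x An `sfs_shift_test`.
#' @param ... Unused.
#' @return A tibble with one row per component test (t-test, Mann-Whitney U).
#' @export
tidy.sfs_shift_test <- function(x, ...) {
  tibble::tibble(
    test = c("t", "mann_whitney_u"),
    statistic = c(unname(x$t$statistic), unname(x$u$statistic)),
    p_value = c(x$t$p.value, x$u$p.value),
    alternative = paste(x$labels[1], ">", x$labels[2]),
    mean_1 = x$mean[1], mean_2 = x$mean[2],
    n_1 = x$n[1], n_2 = x$n[2]
  )
}

#' @rdname tidy.sfs_shift_test
#' @export
glance.sfs_shift_test <- function(x, ...) {
  tibble::tibble(
    mean_up = x$mean[1], mean_pu = x$mean[2],
    n_up = x$n[1], n_pu = x$n[2],
    p_t = x$t$p.value, p_u = x$u$p.value
  )
}

#' Tidy a permutation test
#'
#' @param x A `perm_test`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
tidy.perm_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, p_value = x$p_value,
    replicates = x$replicates, exceedances = x$exceedances,
    n = x$n, degenerate = x$degenerate
  )
}

#' Tidy an ASM-randomized permutation test
#'
#' @param x An `asm_perm_test`.
#' @param ... Unused.
#' @return One row per polarity-assignment draw.
#' @export
tidy.asm_perm_test <- function(x, ...) {
  dplyr::bind_rows(purrr::map(x$draws, tidy)) |>
    dplyr::mutate(draw = dplyr::row_number(), .before = 1)
}

#' @rdname tidy.asm_perm_test
#' @export
glance.asm_perm_test <- function(x, ...) {
  tibble::tibble(
    p_value = x$p_value, draws = length(x$draws),
    replicates = x$replicates, n = x$n
  )
}

#' Tidy a G-test
#'
#' @param x A `g_test`.
#' @param ... Unused.
#' @return A one-row tibble (`statistic`, `df`, `p_value`).
#' @export
tidy.g_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value)
}
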