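# Watterson's theta with fractional synonymous-site denominators, per-site
# divergence, and per-class diversity summaries.

#' Watterson's theta per site
#'
#' `theta_W = S / (a_k * L)` with `a_k = sum(1/i, i = 1..k-1)`; for k = 11,
#' `a = 2.9289683`. `L` may be fractional (degeneracy-weighted synonymous
#' site counts).
#'
#' @param s Number of segregating sites (>= 0); vectorized.
#' @param l Number of sites surveyed (> 0); fractional allowed.
#' @param k Sample size (default 11).
#' @return Per-site theta estimate(s).
#' @examples
#' watterson_theta(1500, 17437.3, k = 11)
#' @export
watterson_theta <- function(s, l, k = 11) {
  stopifnot(all(s >= 0))
  if (any(l <= 0)) stop("site total L must be > 0", call. = FALSE)
  s / (harmonic_a(k) * l)
}

#' Divergence per site
#'
#' @param d_count Number of divergent sites; vectorized.
#' @param l Number of sites surveyed (> 0).
#' @return `d_count / l`.
#' @export
divergence_per_site <- function(d_count, l) {
  if (any(l <= 0)) stop("site total L must be > 0", call. = FALSE)
  d_count / l
}

#' Diversity and divergence summaries by class
#'
#' Groups polymorphic sites and resolved-site totals by a class key and
#' returns, per class, the segregating-site count `s`, the (fractional) site
#' total `l`, Watterson's theta per site, the divergent-site count and the
#' divergence per site.
#'
#' @param sites Site tibble (one row per polymorphic site).
#' @param totals Totals tibble from [call_sites()] (`site_type`,
#'   `amino_acid`, `n_sites`, `d_count`, plus any columns named in `by`).
#' @param by Class key: a character vector of column names shared by `sites`
#'   and `totals` (e.g. `"site_type"`, `c("site_type", "amino_acid")`).
#' @param k Sample size.
#' @return A tibble with one row per class: the `by` columns plus `s`, `l`,
#'   `theta_w`, `d_count`, `div_per_bp`.
#' @export
summarize_diversity <- function(sites, totals, by = "site_type", k = 11) {
  stopifnot(all(by %in% names(sites)), all(by %in% names(totals)))
  s_tbl <- sites |>
    dplyr::count(dplyr::across(dplyr::all_of(by)), name = "s")
  l_tbl <- totals |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      l = sum(.data$n_sites), d_count = sum(.data$d_count),
      .groups = "drop"
    )
  out <- dplyr::full_join(l_tbl, s_tbl, by = by) |>
    dplyr::mutate(s = dplyr::coalesce(.data$s, 0L))
  dropped <- out[is.na(out$l) | out$l <= 0, ]
  if (nrow(dropped) > 0) {
    message(
      nrow(dropped), " class(es) without resolved sites omitted from summary"
    )
    out <- out[!(is.na(out$l) | out$l <= 0), ]
  }
  out |>
    dplyr::mutate(
      theta_w = watterson_theta(.data$s, .data$l, k),
      div_per_bp = divergence_per_site(.data$d_count, .data$l)
    ) |>
    dplyr::select(dplyr::all_of(by), "s", "l", "theta_w", "d_count", "div_per_bp")
}

#' Published per-amino-acid diversity and divergence summary
#'
#' The published Chromosome 2 per-amino-acid summary for
#' *D. pseudoobscura*: fractional synonymous site totals, polymorphic site
#' counts (all, and those segregating two codons with a recombination
#' estimate), divergent site counts, Watterson's theta per site, and
#' divergence per site.
#'
#' @return A tibble with columns `class`, `n_syn`, `s_syn`,
#'   `s_syn_two_codon`, `d_syn`, `theta_w`, `div_per_bp`.
#' @export
diversity_summary_dpse <- function() {
  readr::read_tsv(
    system.file("extdata", "dpse_diversity_summary.tsv",
      package = "codonsfs", mustWork = TRUE
    ),
    show_col_types = FALSE
  )
}

#' Published codon-pair polymorphism counts
#'
#' For each of the 16 C/T-ending and 13 A/G-ending synonymous codon pairs on
#' *D. pseudoobscura* Chromosome 2: usage of the C/G-ending codon, delta-pref
#' for the T/A -> C/G change, counts of polymorphic (`s_*`) and total (`n_*`)
#' third positions by ancestral state, and mean derived counts per direction.
#'
#' @return A tibble (one row per codon pair and base-pair class).
#' @export
codon_pair_counts_dpse <- function() {
  readr::read_tsv(
    system.file("extdata", "dpse_codon_pair_counts.tsv",
      package = "codonsfs", mustWork = TRUE
    ),
    show_col_types = FALSE
  )
}
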