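# Recombination-rate assignment, rate-class binning, and diversity / codon
# bias versus recombination summaries.

#' Read a recombination map
#'
#' Tab-separated with columns `chrom`, `start`, `end` (physical coordinates,
#' interpreted as half-open `(start, end]`), `rate_a`, `rate_b` (cM/Mb from
#' the two testcrosses; `NA` where a cross does not cover the segment).
#'
#' @param path TSV path.
#' @return A map tibble with `segment` ids and `rate` (the average of the
#'   two testcross rates where both are available).
#' @export
read_recomb_map <- function(path) {
  map <- readr::read_tsv(path, show_col_types = FALSE)
  build_recomb_map(map)
}

#' Assemble a recombination map tibble
#'
#' @param map Data frame with `chrom`, `start`, `end`, `rate_a`, `rate_b`.
#' @return The map ordered by position with `segment` ids and the averaged
#'   `rate` (`NA` unless both testcross rates are present).
#' @export
build_recomb_map <- function(map) {
  stopifnot(all(c("chrom", "start", "end", "rate_a", "rate_b") %in% names(map)))
  map <- dplyr::arrange(map, .data$chrom, .data$start)
  ov <- map |>
    dplyr::group_by(.data$chrom) |>
    dplyr::filter(dplyr::row_number() > 1 &
      .data$start < dplyr::lag(.data$end)) |>
    dplyr::ungroup()
  if (nrow(ov) > 0) stop("overlapping map segments", call. = FALSE)
  map |>
    dplyr::mutate(
      segment = paste0(.data$chrom, "_", dplyr::row_number()),
      rate = (.data$rate_a + .data$rate_b) / 2
    )
}

#' Assign recombination rates to sites
#'
#' Looks each site's physical position up in the map (half-open `(start,
#' end]` segments). Sites outside every segment, or in segments without an
#' averaged rate, get `NA` and are flagged `rate_missing`.
#'
#' @param sites Site tibble with a physical position column.
#' @param map Map tibble from [build_recomb_map()].
#' @param pos_col Name of the physical-position column (default `"phys_pos"`,
#'   falling back to `"pos"`).
#' @param chrom Chromosome of the sites (single value; default the map's
#'   first).
#' @param allow_single_map Use a single testcross rate when only one is
#'   available (default `FALSE`: the averaged rate is required).
#' @return The site tibble with `segment`, `rate`, `rate_missing` columns.
#' @export
assign_recomb_rate <- function(sites, map, pos_col = NULL, chrom = NULL,
                               allow_single_map = FALSE) {
  if (is.null(pos_col)) {
    pos_col <- if ("phys_pos" %in% names(sites)) "phys_pos" else "pos"
  }
  if (is.null(chrom)) chrom <- map$chrom[1]
  m <- map[map$chrom == chrom, ]
  m <- dplyr::arrange(m, .data$start)
  rate <- m$rate
  if (allow_single_map) {
    rate <- ifelse(is.na(rate),
      dplyr::coalesce(m$rate_a, m$rate_b), rate
    )
  }
  p <- sites[[pos_col]]
  # (start, end] lookup: index of the last start strictly below p
  idx <- findInterval(p, m$start + 1e-9) # position start itself -> previous segment
  idx[idx == 0] <- NA
  inside <- !is.na(idx) & p <= m$end[pmax(idx, 1)]
  seg <- ifelse(inside, m$segment[idx], NA_character_)
  r <- ifelse(inside, rate[idx], NA_real_)
  sites$segment <- seg
  sites$rate <- r
  sites$rate_missing <- is.na(r)
  sites
}

#' Bin recombination rates into classes
#'
#' Classes of width `width` cM/Mb up to `top`, upper-closed — `(0, 0.25]`
#' labelled `"0.00-0.25"`, `(0.25, 0.50]` labelled `">0.25-0.50"`, ... —
#' plus a final `">top"` class; rate 0 falls in the first class.
#'
#' @param rate Numeric vector of rates (cM/Mb), `NA` allowed.
#' @param width Class width (default 0.25).
#' @param top Upper bound of the last regular class (default 6).
#' @return An ordered factor of class labels (`NA` for missing rates).
#' @export
bin_rate_classes <- function(rate, width = 0.25, top = 6) {
  if (any(rate < 0, na.rm = TRUE)) stop("negative recombination rate", call. = FALSE)
  edges <- seq(0, top, by = width)
  labels <- c(
    sprintf("%.2f-%.2f", edges[1], edges[2]),
    sprintf(">%.2f-%.2f", edges[-c(1, length(edges))], edges[-(1:2)]),
    sprintf(">%.2f", top)
  )
  idx <- findInterval(rate, edges, left.open = TRUE) # (.,.] bins; 0 -> bin 0
  idx[!is.na(rate) & rate == 0] <- 1L # closed lower bound of first class
  idx[idx > length(labels)] <- length(labels)
  factor(labels[idx], levels = labels, ordered = TRUE)
}

#' Upper bound of a rate class label
#'
#' The plotting coordinate for a rate class (e.g. 0.25 for `"0.00-0.25"`;
#' the `">top"` class gets `top + width`).
#'
#' @param class Factor or character of labels from [bin_rate_classes()].
#' @param width,top As in [bin_rate_classes()].
#' @return Numeric upper bounds.
#' @export
rate_class_upper <- function(class, width = 0.25, top = 6) {
  lab <- as.character(class)
  up <- suppressWarnings(as.numeric(sub("^>?[0-9.]*-", "", lab)))
  up[lab == sprintf(">%.2f", top)] <- top + width
  up
}

#' Per-rate-class diversity and codon bias summaries
#'
#' Computes, per recombination rate class, Watterson's theta for synonymous
#' and intron sites and the frequency of preferred derived/ancestral codon
#' usage. Site totals must carry the class column too (resolved sites are
#' assigned to classes the same way as polymorphic sites).
#'
#' @param sites Site tibble with `rate` assigned ([assign_recomb_rate()]).
#' @param totals Totals tibble with a `rate` column (or prebuilt
#'   `rate_class`).
#' @param k Sample size.
#' @param width,top Binning parameters.
#' @return A tibble with one row per class and site type: `rate_class`,
#'   `rate_upper`, `site_type`, `s`, `l`, `theta_w`, `d_count`,
#'   `div_per_bp`. Empty classes are omitted (message).
#' @export
rate_class_summaries <- function(sites, totals, k = 11, width = 0.25, top = 6) {
  sites$rate_class <- bin_rate_classes(sites$rate, width, top)
  if (!"rate_class" %in% names(totals)) {
    totals$rate_class <- bin_rate_classes(totals$rate, width, top)
  }
  out <- summarize_diversity(
    sites[!is.na(sites$rate_class), ],
    totals[!is.na(totals$rate_class), ],
    by = c("rate_class", "site_type"), k = k
  )
  out$rate_upper <- rate_class_upper(out$rate_class, width, top)
  out
}

#' Pearson correlation with t-transform p-value
#'
#' Thin wrapper over `stats::cor.test` reporting `r`, `df = n - 2`, and a
#' one- or two-tailed p-value.
#'
#' @param x,y Paired numeric vectors (n >= 3).
#' @param tail `"two"` (default), `"greater"`, or `"less"`.
#' @return A tibble with `r`, `df`, `p_value`, `tail`.
#' @export
correlate <- function(x, y, tail = c("two", "greater", "less")) {
  tail <- match.arg(tail)
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance input", call. = FALSE)
  }
  alt <- switch(tail, two = "two.sided", greater = "greater", less = "less")
  ct <- stats::cor.test(x, y, alternative = alt, method = "pearson")
  tibble::tibble(
    r = unname(ct$estimate), df = unname(ct$parameter),
    p_value = ct$p.value, tail = tail
  )
}

#' Per-segment diversity and codon bias
#'
#' Summaries per recombination map segment, with an optional minimum
#' resolved-site filter to suppress sampling noise in small segments.
#'
#' @param sites Site tibble with `segment` assigned.
#' @param totals Totals tibble with a `segment` column.
#' @param map Map tibble (provides segment rates; segments without rates are
#'   retained with `NA`).
#' @param min_sites Keep only segments whose resolved synonymous site total
#'   is at least this (default 0 = keep all).
#' @param k Sample size.
#' @return A tibble per segment and site type with `s`, `l`, `theta_w`,
#'   `d_count`, `div_per_bp`, `rate`.
#' @export
segment_summaries <- function(sites, totals, map, min_sites = 0, k = 11) {
  out <- summarize_diversity(
    sites[!is.na(sites$segment), ],
    totals[!is.na(totals$segment), ],
    by = c("segment", "site_type"), k = k
  )
  out$rate <- map$rate[match(out$segment, map$segment)]
  if (min_sites > 0) {
    keep <- out |>
      dplyr::filter(.data$site_type == "synonymous", .data$l >= min_sites) |>
      dplyr::pull("segment")
    out <- out[out$segment %in% keep, ]
  }
  out
}
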