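# Per-codon preference scores from factor analysis of per-gene codon usage,
# plus the codon-bias summary statistics (ENC, scaled chi-square, Fop) used to
# polarize the factor and to describe genes.

deg_aa_count <- 18L # degenerate amino acids in the standard code
deg_codon_count <- 59L # codons encoding them

as_count_vector <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("codon", "count") %in% names(x)))
    x <- stats::setNames(x$count, x$codon)
  }
  if (is.null(names(x))) stop("codon counts must be named by codon", call. = FALSE)
  names(x) <- check_codon(names(x), allow_stop = TRUE)
  x
}

#' Count codons in coding sequences
#'
#' @param cds Named character vector of in-frame coding sequences (one per
#'   gene), or a data frame with columns `gene` and `cds`.
#' @return A tibble with columns `gene`, `codon`, `count` (all 61 sense
#'   codons per gene, zero-filled).
#' @export
count_codons <- function(cds) {
  if (is.data.frame(cds)) cds <- stats::setNames(cds$cds, cds$gene)
  if (is.null(names(cds))) names(cds) <- paste0("gene_", seq_along(cds))
  purrr::imap_dfr(cds, function(s, g) {
    s <- toupper(gsub("U", "T", s))
    if (nchar(s) %% 3 != 0) {
      stop("CDS length of ", g, " is not a multiple of 3", call. = FALSE)
    }
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    cods <- cods[cods %in% .code$sense] # skip stops / ambiguous codons
    cnt <- table(factor(cods, levels = .code$sense))
    tibble::tibble(gene = g, codon = names(cnt), count = as.integer(cnt))
  })
}

enc_classes <- function() {
  tbl <- genetic_code_table()
  tbl <- tbl[!is.na(tbl$degeneracy) & tbl$degeneracy > 1, ]
  split(tbl, tbl$degeneracy)
}

#' Effective number of codons (ENC)
#'
#' Wright-style ENC from class-averaged within-amino-acid homozygosities:
#' `2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`, where `Fm` averages, over the amino acids
#' of degeneracy `m` that the gene uses, the homozygosity `sum(p_i^2)` of its
#' within-amino-acid codon proportions. Isoleucine forms its own threefold
#' class. Perfectly even usage gives 61, single-codon usage gives 20.
#'
#' If a whole degeneracy class is unused the remaining class contributions are
#' rescaled to the full 20-61 range (`61 * (2 + sum kept) / (2 + sum kept
#' maxima)`).
#'
#' @param counts Named numeric vector of codon counts, or a data frame with
#'   columns `codon` and `count`.
#' @return ENC value in `[20, 61]`.
#' @examples
#' enc(setNames(rep(1, 59), genetic_code_table()$codon[
#'   genetic_code_table()$degeneracy > 1 & !is.na(genetic_code_table()$degeneracy)
#' ]))
#' @export
enc <- function(counts) {
  counts <- as_count_vector(counts)
  cls <- enc_classes()
  part <- 0
  part_max <- 0
  for (m in names(cls)) {
    aa_split <- split(cls[[m]]$codon, cls[[m]]$amino_acid)
    f_aa <- purrr::map_dbl(aa_split, function(cods) {
      n <- counts[cods]
      n[is.na(n)] <- 0
      tot <- sum(n)
      if (tot == 0) {
        return(NA_real_)
      }
      sum((n / tot)^2)
    })
    f_bar <- mean(f_aa, na.rm = TRUE)
    n_aa <- length(aa_split)
    if (!is.nan(f_bar)) {
      part <- part + n_aa / f_bar
      part_max <- part_max + n_aa * as.numeric(m)
    }
  }
  if (part_max == 0) stop("no degenerate amino acid is used", call. = FALSE)
  61 * (2 + part) / (2 + part_max)
}

#' Scaled chi-square (Chi/L) codon bias statistic
#'
#' Sum over degenerate codons of `(observed - expected)^2 / expected`, with
#' expected counts equal within each amino acid, divided by the number of
#' codons of degenerate amino acids, `L`. Zero for perfectly even usage;
#' larger for more biased genes.
#'
#' @inheritParams enc
#' @return Nonnegative Chi/L value.
#' @export
scaled_chi <- function(counts) {
  counts <- as_count_vector(counts)
  tbl <- genetic_code_table()
  tbl <- tbl[!is.na(tbl$degeneracy) & tbl$degeneracy > 1, ]
  chi <- 0
  l_total <- 0
  for (cods in split(tbl$codon, tbl$amino_acid)) {
    n <- counts[cods]
    n[is.na(n)] <- 0
    tot <- sum(n)
    if (tot == 0) next
    e <- tot / length(cods)
    chi <- chi + sum((n - e)^2 / e)
    l_total <- l_total + tot
  }
  if (l_total == 0) stop("no degenerate codons counted (L = 0)", call. = FALSE)
  chi / l_total
}

#' Per-gene codon bias summaries
#'
#' @param counts_df Data frame with columns `gene`, `codon`, `count`.
#' @return A tibble with one row per gene: `gene`, `n_codons` (degenerate
#'   codons counted), `enc`, `chi_l`, and `uses_all_18` (whether every
#'   degenerate amino acid is used, the inclusion rule for preference
#'   inference).
#' @export
codon_bias_stats <- function(counts_df) {
  tbl <- genetic_code_table()
  deg_cod <- tbl$codon[!is.na(tbl$degeneracy) & tbl$degeneracy > 1]
  counts_df |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_codons = sum(.data$count[.data$codon %in% deg_cod]),
      enc = enc(stats::setNames(.data$count, .data$codon)),
      chi_l = scaled_chi(stats::setNames(.data$count, .data$codon)),
      uses_all_18 = length(unique(
        translate_codon(.data$codon[.data$count > 0 & .data$codon %in% deg_cod])
      )) == deg_aa_count,
      .groups = "drop"
    )
}

#' Infer per-codon preference scores by factor analysis
#'
#' Builds the genes-by-59 matrix of within-amino-acid relative codon usage
#' (codon count divided by its amino acid's count, over the 59 codons of the
#' 18 degenerate amino acids), restricted to genes that use all 18 amino
#' acids, and extracts the primary factor as the first principal component of
#' the column-standardized matrix. The factor is polarized so that per-gene
#' factor scores correlate positively with Chi/L and negatively with ENC;
#' each codon's preference score is its loading (correlation with the
#' polarized factor), and codons with positive scores are flagged preferred.
#'
#' @param counts_df Data frame with columns `gene`, `codon`, `count`.
#' @return A tibble of class `preference_table` with columns `codon`,
#'   `amino_acid`, `score`, `preferred`; per-gene factor scores and bias
#'   statistics are attached as attribute `"gene_scores"`.
#' @seealso [preference_scores_dpse()] for the packaged published scores.
#' @export
infer_preference_table <- function(counts_df) {
  stats_df <- codon_bias_stats(counts_df)
  keep <- stats_df$gene[stats_df$uses_all_18]
  if (length(keep) < 2) {
    stop("need at least 2 genes that use all 18 degenerate amino acids",
      call. = FALSE
    )
  }
  tbl <- genetic_code_table()
  tbl <- tbl[!is.na(tbl$degeneracy) & tbl$degeneracy > 1, ]

  rel <- counts_df |>
    dplyr::filter(.data$gene %in% keep, .data$codon %in% tbl$codon) |>
    dplyr::mutate(amino_acid = translate_codon(.data$codon)) |>
    dplyr::group_by(.data$gene, .data$amino_acid) |>
    dplyr::mutate(rel_use = .data$count / sum(.data$count)) |>
    dplyr::ungroup()
  m <- rel |>
    dplyr::select("gene", "codon", "rel_use") |>
    tidyr::pivot_wider(names_from = "codon", values_from = "rel_use") |>
    tibble::column_to_rownames("gene") |>
    as.matrix()
  m <- m[keep, tbl$codon, drop = FALSE]
  m[is.na(m)] <- 0 # codon absent from a sparse counts table = unused

  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop(
      "zero-variance codon usage column(s): ",
      paste(colnames(m)[sds == 0], collapse = ", "),
      "; factor extraction is degenerate",
      call. = FALSE
    )
  }
  z <- scale(m)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  scores <- pc$x[, 1]
  loadings <- as.numeric(stats::cor(m, scores))

  r_chi <- stats::cor(scores, stats_df$chi_l[match(keep, stats_df$gene)])
  r_enc <- stats::cor(scores, stats_df$enc[match(keep, stats_df$gene)])
  if (r_chi > 0 && r_enc < 0) {
    flip <- 1
  } else if (r_chi < 0 && r_enc > 0) {
    flip <- -1
  } else {
    stop(
      "polarization anchors disagree: cor(scores, Chi/L) = ",
      signif(r_chi, 3), ", cor(scores, ENC) = ", signif(r_enc, 3),
      call. = FALSE
    )
  }
  out <- tibble::tibble(
    codon = tbl$codon,
    amino_acid = tbl$amino_acid,
    score = flip * loadings,
    preferred = flip * loadings > 0
  )
  attr(out, "gene_scores") <- tibble::tibble(
    gene = keep, factor_score = flip * scores,
    chi_l = stats_df$chi_l[match(keep, stats_df$gene)],
    enc = stats_df$enc[match(keep, stats_df$gene)]
  )
  class(out) <- c("preference_table", class(out))
  out
}

#' Published codon preference scores for D. pseudoobscura
#'
#' Per-codon preference scores (primary-factor loadings from codon-usage
#' factor analysis of Chromosome 2 genes) for *Drosophila pseudoobscura*,
#' shipped so downstream analyses can run with the published scores instead
#' of re-inferred ones. All C-ending codons and all but three G-ending codons
#' are preferred; all A- and T-ending codons are unpreferred.
#'
#' @return A `preference_table` tibble (`codon`, `amino_acid`, `score`,
#'   `preferred`).
#' @export
preference_scores_dpse <- function() {
  path <- system.file("extdata", "dpse_preference_scores.tsv",
    package = "codonsfs", mustWork = TRUE
  )
  out <- read_preference_table(path)
  out
}

#' Read / write a preference table as TSV
#'
#' @param path File path. Columns `codon`, `amino_acid`, `score` (and
#'   optionally `preferred`, otherwise derived as `score > 0`).
#' @return `read_preference_table()` returns a `preference_table` tibble;
#'   `write_preference_table()` returns `path` invisibly.
#' @export
read_preference_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("codon", "amino_acid", "score") %in% names(out)))
  if (!"preferred" %in% names(out)) out$preferred <- out$score > 0
  class(out) <- c("preference_table", class(out))
  out
}

#' @rdname read_preference_table
#' @param table A `preference_table`.
#' @export
write_preference_table <- function(table, path) {
  readr::write_tsv(as.data.frame(table), path)
  invisible(path)
}

pref_score_lookup <- function(table) {
  stats::setNames(table$score, table$codon)
}

#' Frequency of optimal (preferred) codons
#'
#' Fraction of a gene's degenerate-amino-acid codons that carry a preferred
#' codon.
#'
#' @inheritParams enc
#' @param table A `preference_table`.
#' @return Fop in `[0, 1]`.
#' @export
fop <- function(counts, table) {
  counts <- as_count_vector(counts)
  deg_cod <- table$codon
  n <- counts[deg_cod]
  n[is.na(n)] <- 0
  tot <- sum(n)
  if (tot == 0) stop("gene has no degenerate codons", call. = FALSE)
  sum(n[table$preferred]) / tot
}

#' Change in codon preference for a synonymous substitution
#'
#' `delta_pref = score(derived) - score(ancestral)`. Positive values mark
#' unpreferred-to-preferred (U->P) changes, negative values preferred-to-
#' unpreferred (P->U).
#'
#' @param ancestral,derived Character vectors of synonymous sense codons.
#' @param table A `preference_table`.
#' @return Numeric vector of delta-pref values.
#' @examples
#' delta_pref("GAA", "GAG", preference_scores_dpse())
#' @export
delta_pref <- function(ancestral, derived, table) {
  ancestral <- check_codon(ancestral)
  derived <- check_codon(derived)
  if (any(translate_codon(ancestral) != translate_codon(derived))) {
    stop("delta_pref requires synonymous codon pairs", call. = FALSE)
  }
  s <- pref_score_lookup(table)
  missing <- setdiff(unique(c(ancestral, derived)), names(s))
  if (length(missing) > 0) {
    stop("no preference score for codon(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  unname(s[derived] - s[ancestral])
}
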