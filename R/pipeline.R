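# End-to-end orchestration: filters -> preference table -> site table ->
# diversity, SFS and recombination reports, with deterministic seeding and a
# run manifest for audit.

#' Configuration for a full analysis run
#'
#' @param seed Integer seed for all Monte Carlo steps (mandatory).
#' @param k Sample size.
#' @param quality_min,coverage_min Masking thresholds.
#' @param intron_max_len,intron_head,intron_tail Short-intron filter.
#' @param min_segment_sites Segment filter for recombination summaries.
#' @param replicates Permutation-test replicates.
#' @param exclude_singletons Also report singleton-excluded analyses.
#' @param preference `"fixture"` (use [preference_scores_dpse()]) or
#'   `"infer"` (re-infer from the data's codon usage).
#' @param reference,outgroup Strain names.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed, k = 11, quality_min = 30, coverage_min = 15,
                       intron_max_len = 80, intron_head = 9, intron_tail = 8,
                       min_segment_sites = 5000, replicates = 1e5,
                       exclude_singletons = TRUE,
                       preference = c("fixture", "infer"),
                       reference = "ref", outgroup = "outgroup") {
  stopifnot(!missing(seed), quality_min > 0, coverage_min > 0)
  structure(
    list(
      seed = as.integer(seed), k = k,
      quality_min = quality_min, coverage_min = coverage_min,
      intron_max_len = intron_max_len, intron_head = intron_head,
      intron_tail = intron_tail, min_segment_sites = min_segment_sites,
      replicates = replicates, exclude_singletons = exclude_singletons,
      preference = match.arg(preference),
      reference = reference, outgroup = outgroup
    ),
    class = "run_config"
  )
}

#' Run the full analysis on alignments and gene models
#'
#' Validates genes, applies the quality/coverage masks, calls and polarizes
#' biallelic sites, attaches preference scores, and produces the standard
#' report bundle: the preference table, per-amino-acid diversity/divergence,
#' SFS shift tests (all sites and singleton-excluded), the permutation test,
#' the site-type-by-direction ANOVA, and — when a recombination map is
#' given — per-rate-class and per-segment summaries. A manifest records
#' counts at each filter stage.
#'
#' @param aln Alignment tibble ([read_strain_alignments()]).
#' @param models Gene-model tibble.
#' @param config A [run_config()].
#' @param masks Optional mask tibble.
#' @param map Optional recombination map ([build_recomb_map()]); when
#'   missing, recombination reports are skipped with a warning.
#' @param out_dir Optional directory: every report is also written as TSV.
#' @return A list of class `analysis_run`: `sites`, `totals`, `drops`,
#'   `preference`, `diversity`, `shift_test`, `shift_test_nosingle`,
#'   `perm_test`, `anova`, `rate_classes`, `segments`, `manifest`.
#' @export
run_full_analysis <- function(aln, models, config, masks = NULL, map = NULL,
                              out_dir = NULL) {
  set.seed(config$seed)
  manifest <- list(seed = config$seed, k = config$k)

  valid <- validate_gene(models, aln, reference = config$reference)
  manifest$genes_total <- nrow(valid)
  manifest$genes_included <- sum(valid$included)
  models_ok <- models[models$gene %in% valid$gene[valid$included], ]
  if (nrow(models_ok) == 0) stop("no gene passed validation", call. = FALSE)

  aln <- apply_masks(aln, masks,
    quality_min = config$quality_min, coverage_min = config$coverage_min,
    reference = config$reference
  )
  calls <- call_sites(aln, models_ok,
    reference = config$reference, outgroup = config$outgroup
  )
  manifest$sites_called <- nrow(calls$sites)
  manifest$sites_dropped <- nrow(calls$drops)

  pref <- if (config$preference == "fixture") {
    preference_scores_dpse()
  } else {
    cds <- extract_cds(aln, models_ok, reference = config$reference)
    infer_preference_table(count_codons(cds))
  }
  sites <- add_delta_pref(calls$sites, pref)

  diversity <- summarize_diversity(sites, calls$totals,
    by = c("site_type", "amino_acid"), k = config$k
  )

  syn <- sites[sites$site_type == "synonymous" & sites$delta_pref != 0, ]
  shift <- sfs_shift_test(syn, k = config$k)
  shift_ns <- sfs_shift_test(syn, exclude_singletons = TRUE, k = config$k)
  perm <- sum_dpref_test(syn,
    replicates = config$replicates, seed = config$seed
  )
  anova_tbl <- tryCatch(
    {
      dat <- sites[!is.na(sites$d), ]
      dat$change <- paste(dat$ancestral, dat$derived, sep = "->")
      pair_dat <- dat[
        paste(pmin(dat$ancestral, dat$derived),
          pmax(dat$ancestral, dat$derived),
          sep = "/"
        ) %in% c("C/T", "A/G"),
      ]
      two_way_anova(pair_dat,
        response = "d", factor_a = "site_type", factor_b = "change"
      )
    },
    error = function(e) {
      warning("ANOVA skipped: ", conditionMessage(e), call. = FALSE)
      NULL
    }
  )

  rate_classes <- segments <- NULL
  if (is.null(map)) {
    warning("no recombination map supplied; recombination reports skipped",
      call. = FALSE
    )
  } else {
    sites_r <- assign_recomb_rate(sites, map)
    totals_r <- calls$totals
    if (!"rate" %in% names(totals_r)) {
      # totals carry no positions; attach the site-weighted mean rate per gene
      gene_rate <- sites_r |>
        dplyr::group_by(.data$gene) |>
        dplyr::summarise(rate = mean(.data$rate, na.rm = TRUE),
                         segment = .data$segment[1], .groups = "drop")
      totals_r$rate <- gene_rate$rate[match(totals_r$gene, gene_rate$gene)]
      totals_r$segment <- gene_rate$segment[match(totals_r$gene, gene_rate$gene)]
    }
    rate_classes <- rate_class_summaries(sites_r, totals_r, k = config$k)
    segments <- segment_summaries(sites_r, totals_r, map,
      min_sites = 0, k = config$k
    )
  }

  out <- structure(
    list(
      sites = sites, totals = calls$totals, drops = calls$drops,
      preference = pref, diversity = diversity,
      shift_test = shift, shift_test_nosingle = shift_ns,
      perm_test = perm, anova = anova_tbl,
      rate_classes = rate_classes, segments = segments,
      manifest = manifest
    ),
    class = "analysis_run"
  )
  if (!is.null(out_dir)) write_reports(out, out_dir)
  out
}

#' Extract reference CDS sequences
#'
#' @param aln Alignment tibble.
#' @param models Gene-model tibble.
#' @param reference Reference strain name.
#' @return Named character vector of spliced coding sequences.
#' @export
extract_cds <- function(aln, models, reference = "ref") {
  genes <- unique(models$gene)
  stats::setNames(purrr::map_chr(genes, function(g) {
    ref <- aln$seq[aln$gene == g & aln$strain == reference]
    m <- gene_blocks(models, g, nchar(ref))
    strand <- unique(models$strand[models$gene == g])
    ref <- orient_gene(ref, strand)
    cds_pos <- unlist(purrr::map2(
      m$start[m$feature == "CDS"], m$end[m$feature == "CDS"], seq
    ))
    paste(strsplit(ref, "")[[1]][cds_pos], collapse = "")
  }), genes)
}

write_reports <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) {
    if (is.null(x)) {
      return(invisible(NULL))
    }
    readr::write_tsv(x, file.path(out_dir, paste0(name, ".tsv")))
  }
  w(run$sites, "site_table")
  w(run$drops, "drop_log")
  w(as.data.frame(run$preference), "preference_table")
  w(run$diversity, "diversity_by_class")
  w(tidy(run$shift_test), "sfs_shift_test")
  w(tidy(run$shift_test_nosingle), "sfs_shift_test_nosingletons")
  w(tidy(run$perm_test), "permutation_test")
  w(run$anova, "anova_site_type_direction")
  w(run$rate_classes, "rate_class_summaries")
  w(run$segments, "segment_summaries")
  manifest <- tibble::tibble(
    key = names(run$manifest),
    value = as.character(unlist(run$manifest))
  )
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(out_dir)
}

#' @export
print.analysis_run <- function(x, ...) {
  cat("codonsfs analysis run\n")
  cat("  genes:", x$manifest$genes_included, "of", x$manifest$genes_total,
      "included\n")
  cat("  polymorphic sites:", nrow(x$sites),
      sprintf("(%d dropped)\n", nrow(x$drops)))
  print(x$shift_test)
  print(x$perm_test)
  invisible(x)
}
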