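# Gene validation, quality/coverage masking, biallelic site calling, and
# outgroup-parsimony polarization. The site table produced here is the
# interchange format for every downstream analysis.

#' Read per-gene strain alignments from FASTA
#'
#' Each FASTA holds the aligned sequences of one gene: the ingroup strains
#' (including the reference) and the outgroup, equal lengths, no gaps
#' (resequenced strains are mapped onto the reference coordinate system;
#' unresolved bases are `N`).
#'
#' @param paths Character vector of FASTA paths; names are used as gene ids
#'   (default: file name without extension).
#' @return A tibble with columns `gene`, `strain`, `seq`.
#' @export
read_strain_alignments <- function(paths) {
  if (is.null(names(paths))) {
    names(paths) <- sub("\\.(fa|fasta|fna)$", "", basename(paths))
  }
  purrr::imap_dfr(paths, function(p, g) {
    ss <- Biostrings::readDNAStringSet(p)
    tibble::tibble(gene = g, strain = names(ss), seq = as.character(ss))
  })
}

#' Write per-gene strain alignments to FASTA
#'
#' @param aln Alignment tibble (`gene`, `strain`, `seq`).
#' @param dir Output directory; one `<gene>.fa` per gene.
#' @return Named vector of written paths, invisibly.
#' @export
write_strain_alignments <- function(aln, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- purrr::imap_chr(split(aln, aln$gene), function(df, g) {
    path <- file.path(dir, paste0(g, ".fa"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(stats::setNames(df$seq, df$strain)), path
    )
    path
  })
  invisible(paths)
}

#' Read simplified gene models
#'
#' Tab-separated with columns `gene`, `strand` (`+`/`-`), `feature`
#' (`CDS`/`intron`), `start`, `end` (1-based, inclusive, in alignment
#' coordinates).
#'
#' @param path TSV path.
#' @return A gene-model tibble.
#' @export
read_gene_models <- function(path) {
  readr::read_tsv(path,
    col_types = readr::cols(
      gene = readr::col_character(), strand = readr::col_character(),
      feature = readr::col_character(), start = readr::col_integer(),
      end = readr::col_integer()
    )
  )
}

#' Read per-base quality/coverage masks
#'
#' Tab-separated with columns `gene`, `strain`, `pos` (1-based alignment
#' coordinate), `quality` (phred consensus quality), `coverage` (read depth).
#' Positions absent from the table are treated as unresolved for the masked
#' strains.
#'
#' @param path TSV path.
#' @return A mask tibble.
#' @export
read_masks <- function(path) {
  readr::read_tsv(path,
    col_types = readr::cols(
      gene = readr::col_character(), strain = readr::col_character(),
      pos = readr::col_integer(), quality = readr::col_double(),
      coverage = readr::col_double()
    )
  )
}

seq_to_mat <- function(seqs) {
  # strains x positions character matrix
  do.call(rbind, strsplit(toupper(seqs), ""))
}

revcomp_chr <- function(s) {
  chartr("ACGTN", "TGCAN", vapply(
    s, function(x) paste(rev(strsplit(x, "")[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE
  ))
}

#' Apply quality and coverage masks to an alignment
#'
#' Bases of every strain except the reference (the outgroup is masked like
#' the resequenced strains) are set to `N` wherever the phred consensus
#' quality is below `quality_min` or the coverage is below `coverage_min`,
#' or where no mask record exists.
#'
#' @param aln Alignment tibble (`gene`, `strain`, `seq`).
#' @param masks Mask tibble from [read_masks()], or `NULL` to skip masking.
#' @param quality_min,coverage_min Strict lower thresholds (a base is kept
#'   only if `quality >= quality_min` and `coverage >= coverage_min`).
#' @param reference Name of the reference strain (never masked).
#' @return The alignment tibble with masked sequences.
#' @export
apply_masks <- function(aln, masks, quality_min = 30, coverage_min = 15,
                        reference = "ref") {
  if (is.null(masks)) {
    return(aln)
  }
  keep <- masks$quality >= quality_min & masks$coverage >= coverage_min
  ok <- masks[keep, c("gene", "strain", "pos")]
  aln |>
    dplyr::group_by(.data$gene) |>
    dplyr::mutate(seq = {
      g <- .data$gene[1]
      ok_g <- ok[ok$gene == g, ]
      purrr::map2_chr(.data$strain, .data$seq, function(st, s) {
        if (st == reference) {
          return(s)
        }
        n <- nchar(s)
        resolved <- logical(n)
        resolved[ok_g$pos[ok_g$strain == st & ok_g$pos <= n]] <- TRUE
        chars <- strsplit(s, "")[[1]]
        chars[!resolved] <- "N"
        paste(chars, collapse = "")
      })
    }) |>
    dplyr::ungroup()
}

gene_blocks <- function(models, g, total_len) {
  m <- models[models$gene == g, ]
  if (nrow(m) == 0) stop("no gene model for ", g, call. = FALSE)
  strand <- unique(m$strand)
  stopifnot(length(strand) == 1)
  if (any(m$start < 1) || any(m$end > total_len) || any(m$start > m$end)) {
    stop("gene model coordinates out of range for ", g, call. = FALSE)
  }
  if (strand == "-") {
    # flip to coding orientation
    new_start <- total_len - m$end + 1
    m$end <- total_len - m$start + 1
    m$start <- new_start
  }
  m[order(m$start), ]
}

orient_gene <- function(seqs, strand) {
  if (strand == "-") revcomp_chr(seqs) else seqs
}

#' Validate genes against the inclusion criteria
#'
#' A gene is excluded if, in the reference sequence: the start codon is not
#' ATG; the stop codon is not TGA/TAG/TAA; any codon is incompletely
#' resolved; there is a premature stop codon; or an intron does not have
#' canonical GT..AG boundaries.
#'
#' @param models Gene-model tibble ([read_gene_models()]).
#' @param aln Alignment tibble; the reference strain's sequence is checked.
#' @param reference Reference strain name.
#' @return A tibble with columns `gene`, `included`, `reason` (`NA` when
#'   included).
#' @export
validate_gene <- function(models, aln, reference = "ref") {
  purrr::map_dfr(unique(models$gene), function(g) {
    ref <- aln$seq[aln$gene == g & aln$strain == reference]
    if (length(ref) != 1) {
      stop("reference sequence missing for gene ", g, call. = FALSE)
    }
    m <- gene_blocks(models, g, nchar(ref))
    strand <- unique(models$strand[models$gene == g])
    ref <- orient_gene(ref, strand)
    cds_pos <- unlist(purrr::map2(
      m$start[m$feature == "CDS"], m$end[m$feature == "CDS"], seq
    ))
    cds <- paste(strsplit(ref, "")[[1]][cds_pos], collapse = "")
    reason <- NA_character_
    if (nchar(cds) %% 3 != 0) {
      reason <- "frame"
    } else {
      cods <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
      aa <- ifelse(cods %in% names(.code$aa), .code$aa[cods], NA)
      if (cods[1] != "ATG") {
        reason <- "start"
      } else if (!cods[length(cods)] %in% .code$stop) {
        reason <- "stop"
      } else if (any(is.na(aa))) {
        reason <- "unresolved codon"
      } else if (any(aa[-length(aa)] == "stop")) {
        reason <- "premature stop"
      } else {
        for (i in which(m$feature == "intron")) {
          intron <- substr(ref, m$start[i], m$end[i])
          if (substr(intron, 1, 2) != "GT" ||
            substr(intron, nchar(intron) - 1, nchar(intron)) != "AG") {
            reason <- "noncanonical intron"
            break
          }
        }
      }
    }
    tibble::tibble(gene = g, included = is.na(reason), reason = reason)
  })
}

#' Call biallelic polymorphic sites and resolved-site totals
#'
#' For every gene, codons are counted only when all three positions are
#' resolved (A/C/G/T) in every ingroup strain and the outgroup; intron
#' positions likewise. Synonymous polymorphic sites are codon columns where
#' the ingroup segregates exactly two codons that are synonymous and differ
#' at one position; intron sites segregate exactly two bases. Sites are
#' polarized by parsimony: the outgroup state is taken as ancestral and must
#' match one of the two segregating states, otherwise the site is dropped as
#' unpolarizable. Columns segregating more than two states are excluded.
#'
#' Resolved totals use degeneracy-weighted fractional counting for
#' synonymous sites ([synonymous_site_count()] of the reference codon) and
#' one full site per intron position. Fixed differences from the outgroup
#' (for divergence) are counted at codons/positions where the ingroup is
#' monomorphic and the outgroup differs — for codons, by a single-position
#' synonymous difference.
#'
#' @param aln Alignment tibble (masked; see [apply_masks()]).
#' @param models Gene-model tibble.
#' @param reference,outgroup Strain names.
#' @return A list of class `site_calls`:
#'   * `sites`: one row per polymorphic site (`gene`, `pos` in coding-strand
#'     alignment coordinates, `site_type`, `amino_acid`, `ancestral_codon`,
#'     `derived_codon`, `ancestral`, `derived`, `pair`, `subclass`, `d`);
#'   * `totals`: resolved site totals and divergence counts per gene,
#'     site type and amino acid;
#'   * `drops`: excluded polymorphic columns with reasons.
#' @export
call_sites <- function(aln, models, reference = "ref", outgroup = "outgroup") {
  res <- purrr::map(unique(models$gene), function(g) {
    df <- aln[aln$gene == g, ]
    if (!outgroup %in% df$strain) {
      stop("outgroup sequence missing for gene ", g, call. = FALSE)
    }
    strand <- unique(models$strand[models$gene == g])
    m <- gene_blocks(models, g, nchar(df$seq[1]))
    seqs <- orient_gene(df$seq, strand)
    mat <- seq_to_mat(seqs)
    rownames(mat) <- df$strain
    out_row <- which(df$strain == outgroup)
    in_rows <- setdiff(seq_len(nrow(mat)), out_row)
    k <- length(in_rows)

    sites <- list()
    drops <- list()
    totals <- list()

    cds_pos <- unlist(purrr::map2(
      m$start[m$feature == "CDS"], m$end[m$feature == "CDS"], seq
    ))
    if (length(cds_pos) %% 3 != 0) stop("frame inconsistency in ", g, call. = FALSE)
    n_codon <- length(cds_pos) %/% 3
    for (ci in seq_len(n_codon)) {
      pos3 <- cds_pos[(3 * ci - 2):(3 * ci)]
      sub <- mat[, pos3, drop = FALSE]
      if (!all(sub %in% c("A", "C", "G", "T"))) next # unresolved somewhere
      cods <- unname(apply(sub, 1, paste, collapse = ""))
      if (cods[out_row] %in% .code$stop) next
      in_cods <- cods[in_rows]
      ref_cod <- cods[match(reference, rownames(mat))]
      if (ref_cod %in% .code$stop) next
      aa_ref <- .code$aa[[ref_cod]]
      # resolved codon: contributes fractional synonymous sites
      totals[[length(totals) + 1]] <- tibble::tibble(
        gene = g, site_type = "synonymous", amino_acid = aa_ref,
        n_sites = synonymous_site_count(ref_cod),
        d_count = 0
      )
      uniq <- unique(in_cods)
      if (length(uniq) == 1) {
        # monomorphic: check fixed synonymous difference vs outgroup
        oc <- cods[out_row]
        if (oc != uniq &&
          oc %in% .code$sense && .code$aa[[oc]] == .code$aa[[uniq]] &&
          sum(strsplit(oc, "")[[1]] != strsplit(uniq, "")[[1]]) == 1) {
          totals[[length(totals)]]$d_count <- 1
        }
        next
      }
      pos_lab <- pos3[1] # report first base of the codon for drops
      if (length(uniq) > 2) {
        drops[[length(drops) + 1]] <- tibble::tibble(
          gene = g, pos = pos_lab, site_type = "synonymous",
          reason = "more than two states"
        )
        next
      }
      if (any(uniq %in% .code$stop)) next # nonsense polymorphism
      if (.code$aa[[uniq[1]]] != .code$aa[[uniq[2]]]) next # nonsynonymous site
      ndiff <- sum(strsplit(uniq[1], "")[[1]] != strsplit(uniq[2], "")[[1]])
      if (ndiff != 1) {
        drops[[length(drops) + 1]] <- tibble::tibble(
          gene = g, pos = pos_lab, site_type = "synonymous",
          reason = "two-position codon difference"
        )
        next
      }
      oc <- cods[out_row]
      if (!oc %in% uniq) {
        drops[[length(drops) + 1]] <- tibble::tibble(
          gene = g, pos = pos_lab, site_type = "synonymous",
          reason = "unpolarizable"
        )
        next
      }
      anc <- oc
      der <- setdiff(uniq, anc)
      d <- sum(in_cods == der)
      diff_pos <- which(strsplit(anc, "")[[1]] != strsplit(der, "")[[1]])
      cls <- classify_pair(anc, der)
      sites[[length(sites) + 1]] <- tibble::tibble(
        gene = g, pos = pos3[diff_pos], site_type = "synonymous",
        amino_acid = cls$amino_acid,
        ancestral_codon = anc, derived_codon = der,
        ancestral = substr(anc, diff_pos, diff_pos),
        derived = substr(der, diff_pos, diff_pos),
        pair = cls$pair, subclass = cls$subclass, d = d
      )
    }

    # intron sites
    int_idx <- which(m$feature == "intron")
    n_int <- 0
    d_int <- 0
    for (i in int_idx) {
      for (p in seq(m$start[i], m$end[i])) {
        col <- unname(mat[, p])
        if (!all(col %in% c("A", "C", "G", "T"))) next
        n_int <- n_int + 1
        in_b <- col[in_rows]
        uniq <- unique(in_b)
        if (length(uniq) == 1) {
          if (col[out_row] != uniq) d_int <- d_int + 1
          next
        }
        if (length(uniq) > 2) {
          drops[[length(drops) + 1]] <- tibble::tibble(
            gene = g, pos = p, site_type = "intron",
            reason = "more than two states"
          )
          next
        }
        ob <- col[out_row]
        if (!ob %in% uniq) {
          drops[[length(drops) + 1]] <- tibble::tibble(
            gene = g, pos = p, site_type = "intron",
            reason = "unpolarizable"
          )
          next
        }
        der <- setdiff(uniq, ob)
        sites[[length(sites) + 1]] <- tibble::tibble(
          gene = g, pos = p, site_type = "intron",
          amino_acid = NA_character_,
          ancestral_codon = NA_character_, derived_codon = NA_character_,
          ancestral = ob, derived = der,
          pair = NA_character_, subclass = NA_character_,
          d = sum(in_b == der)
        )
      }
    }
    if (n_int > 0) {
      totals[[length(totals) + 1]] <- tibble::tibble(
        gene = g, site_type = "intron", amino_acid = NA_character_,
        n_sites = n_int, d_count = d_int
      )
    }
    list(
      sites = dplyr::bind_rows(sites),
      totals = dplyr::bind_rows(totals),
      drops = dplyr::bind_rows(drops),
      k = k
    )
  })
  totals <- dplyr::bind_rows(purrr::map(res, "totals"))
  if (nrow(totals) > 0) {
    totals <- totals |>
      dplyr::group_by(.data$gene, .data$site_type, .data$amino_acid) |>
      dplyr::summarise(
        n_sites = sum(.data$n_sites), d_count = sum(.data$d_count),
        .groups = "drop"
      )
  }
  structure(
    list(
      sites = dplyr::bind_rows(purrr::map(res, "sites")),
      totals = totals,
      drops = dplyr::bind_rows(purrr::map(res, "drops")),
      k = unique(purrr::map_int(res, "k"))
    ),
    class = "site_calls"
  )
}

#' Polarize a single site by outgroup parsimony
#'
#' Exposed mainly for testing and small interactive checks;
#' [call_sites()] applies the same rule to whole alignments.
#'
#' @param ingroup Character vector of ingroup states (codons or bases).
#' @param outgroup The outgroup state.
#' @return A list with `ancestral`, `derived`, `d`, or `NULL` if the site is
#'   not biallelic or the outgroup matches neither segregating state
#'   (unpolarizable).
#' @export
polarize <- function(ingroup, outgroup) {
  uniq <- unique(ingroup)
  if (length(uniq) != 2 || !outgroup %in% uniq) {
    return(NULL)
  }
  der <- setdiff(uniq, outgroup)
  list(ancestral = outgroup, derived = der, d = sum(ingroup == der))
}

#' Restrict intron sites to short-intron interiors
#'
#' Keeps intron sites lying in introns of at most `max_len` bases, excluding
#' the first `head` and last `tail` bases adjacent to the splice junctions
#' (the weakly constrained interior of short introns). Synonymous sites pass
#' through untouched if `keep_synonymous` is `TRUE`.
#'
#' @param sites Site tibble from [call_sites()].
#' @param models Gene-model tibble (coding-strand coordinates are derived
#'   internally, matching the site table).
#' @param max_len,head,tail Filter parameters (defaults 80, 9, 8).
#' @param keep_synonymous Keep non-intron rows (default `FALSE`).
#' @return Filtered site tibble.
#' @export
short_intron_filter <- function(sites, models, max_len = 80, head = 9,
                                tail = 8, keep_synonymous = FALSE) {
  lens <- attr(models, "aln_len")
  keep_rows <- purrr::pmap_lgl(
    sites[, c("gene", "pos", "site_type")],
    function(gene, pos, site_type) {
      if (site_type != "intron") {
        return(keep_synonymous)
      }
      m <- models[models$gene == gene & models$feature == "intron", ]
      if (unique(m$strand) == "-") {
        len <- if (!is.null(lens)) lens[[gene]] else max(models$end[models$gene == gene])
        new_start <- len - m$end + 1
        m$end <- len - m$start + 1
        m$start <- new_start
      }
      hit <- which(m$start <= pos & pos <= m$end)
      if (length(hit) != 1) {
        return(FALSE)
      }
      ilen <- m$end[hit] - m$start[hit] + 1
      ilen <= max_len && pos >= m$start[hit] + head && pos <= m$end[hit] - tail
    }
  )
  sites[keep_rows, ]
}

#' Attach preference scores to a site table
#'
#' Adds `delta_pref` (derived minus ancestral preference score) and the
#' direction label (`"U->P"` for positive, `"P->U"` for negative,
#' `"neutral"` at exactly zero) to synonymous sites; intron sites get `NA`.
#'
#' @param sites Site tibble.
#' @param table A `preference_table`.
#' @return The site tibble with `delta_pref` and `direction` columns.
#' @export
add_delta_pref <- function(sites, table) {
  s <- pref_score_lookup(table)
  syn <- sites$site_type == "synonymous"
  dp <- rep(NA_real_, nrow(sites))
  dp[syn] <- unname(s[sites$derived_codon[syn]] - s[sites$ancestral_codon[syn]])
  sites$delta_pref <- dp
  sites$direction <- dplyr::case_when(
    !syn ~ NA_character_,
    dp > 0 ~ "U->P",
    dp < 0 ~ "P->U",
    TRUE ~ "neutral"
  )
  sites
}

#' Read / write the site table as TSV
#'
#' @param sites Site tibble.
#' @param path File path.
#' @return `read_site_table()` returns the tibble; `write_site_table()`
#'   returns `path` invisibly.
#' @export
write_site_table <- function(sites, path) {
  readr::write_tsv(sites, path)
  invisible(path)
}

#' @rdname write_site_table
#' @export
read_site_table <- function(path) {
  readr::read_tsv(path,
    col_types = readr::cols(
      gene = readr::col_character(), pos = readr::col_integer(),
      site_type = readr::col_character(), d = readr::col_integer(),
      .default = readr::col_guess()
    )
  )
}
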