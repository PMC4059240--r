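# Synthetic data with the statistical structure the analysis assumes:
# biallelic synonymous and intron sites whose derived counts follow a neutral
# or selected frequency spectrum, ancestral-state misassignment induced by
# outgroup-branch substitutions, independent per-sequence sequencing errors,
# and a two-testcross recombination map with an optional diversity coupling.

#' Selected site-frequency-spectrum sampling distribution
#'
#' Sampling probabilities of derived counts `d = 1..k-1` at stationarity for
#' a scaled selection coefficient `gamma` acting on the derived allele:
#' `P(d) proportional to C(k, d) * integral x^d (1-x)^(k-d) * H(x) dx` with
#' the stationary density
#' `H(x) = (1 - exp(-2 gamma (1 - x))) / ((1 - exp(-2 gamma)) x (1 - x))`.
#' At `gamma = 0` this reduces to the neutral `1/d` spectrum.
#'
#' @param k Sample size.
#' @param gamma Scaled selection coefficient (positive favours the derived
#'   allele).
#' @return A tibble with `d` and `prop` (summing to 1).
#' @export
selected_sfs <- function(k, gamma) {
  if (abs(gamma) < 1e-8) {
    return(neutral_sfs(k))
  }
  d <- seq_len(k - 1)
  w <- vapply(d, function(dd) {
    f <- function(x) {
      x^(dd - 1) * (1 - x)^(k - dd - 1) *
        (1 - exp(-2 * gamma * (1 - x))) / (1 - exp(-2 * gamma))
    }
    int <- stats::integrate(f, 0, 1, rel.tol = 1e-10, abs.tol = 0)
    if (int$message != "OK") stop("quadrature failure: ", int$message, call. = FALSE)
    choose(k, dd) * int$value
  }, numeric(1))
  tibble::tibble(d = d, prop = w / sum(w))
}

#' Sample derived counts from the selected SFS
#'
#' @param n_sites Number of draws.
#' @param k Sample size.
#' @param gamma Scaled selection coefficient.
#' @param singleton_inflation Multiplier applied to the singleton class
#'   before renormalization — a phenomenological stand-in for the singleton
#'   excess that population growth or background selection produces (no
#'   demographic model is fitted).
#' @return Integer vector of derived counts in `1..k-1`.
#' @export
sample_selected_sfs_counts <- function(n_sites, k, gamma,
                                       singleton_inflation = 1) {
  stopifnot(n_sites >= 0)
  p <- selected_sfs(k, gamma)$prop
  p[1] <- p[1] * singleton_inflation
  p <- p / sum(p)
  if (n_sites == 0) {
    return(integer(0))
  }
  sample(seq_len(k - 1), n_sites, replace = TRUE, prob = p)
}

#' Simulation parameters
#'
#' Defaults mirror the study conditions of the Chromosome 2 data the package
#' emulates: `k = 11` sequences, synonymous diversity `theta_syn = 0.0222`
#' and divergence `div_syn = 0.0763`, intron diversity `theta_intron =
#' 0.0085` and divergence `div_intron = 0.0297`, the published preference
#' table, no sequencing error, and neutrality (`gamma = 0`).
#'
#' @param seed Integer seed (mandatory; all randomness flows from it).
#' @param k Sample size.
#' @param n_syn,n_intron Numbers of polymorphic synonymous / intron sites.
#' @param theta_syn,theta_intron Per-site diversities (set the resolved site
#'   totals via `L = S / (a_k theta)`).
#' @param div_syn,div_intron Per-site divergences (drive the ASM flip
#'   probability `b/(1+b)` with `b = div - ((k-1)/k) theta`).
#' @param gamma Selection scale per unit delta-pref: a site with preference
#'   change `dp` experiences scaled selection `gamma * dp`.
#' @param eps Per-base per-sequence sequencing error rate.
#' @param asm Apply ASM polarity flips (default `TRUE` when `b > 0`).
#' @param singleton_inflation See [sample_selected_sfs_counts()].
#' @param pref Preference table (default [preference_scores_dpse()]).
#' @param map_segments,chrom_length,rate_top Recombination map shape.
#' @param rate_theta_coupling Couple per-segment diversity to recombination
#'   rate, saturating at `rate_sat` cM/Mb.
#' @param rate_sat Saturation rate of the coupling (default 2 cM/Mb).
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(seed, k = 11, n_syn = 5000, n_intron = 5000,
                       theta_syn = 0.0222, theta_intron = 0.0085,
                       div_syn = 0.0763, div_intron = 0.0297,
                       gamma = 0, eps = 0, asm = NULL,
                       singleton_inflation = 1,
                       pref = preference_scores_dpse(),
                       map_segments = 30, chrom_length = 3e7, rate_top = 8,
                       rate_theta_coupling = FALSE, rate_sat = 2) {
  stopifnot(!missing(seed), is.finite(gamma), eps >= 0, eps < 1,
            theta_syn >= 0, theta_intron >= 0)
  b_syn <- div_syn - (k - 1) / k * theta_syn
  if (is.null(asm)) asm <- b_syn > 0
  structure(
    list(
      seed = as.integer(seed), k = k, n_syn = n_syn, n_intron = n_intron,
      theta_syn = theta_syn, theta_intron = theta_intron,
      div_syn = div_syn, div_intron = div_intron,
      gamma = gamma, eps = eps, asm = asm,
      singleton_inflation = singleton_inflation, pref = pref,
      map_segments = map_segments, chrom_length = chrom_length,
      rate_top = rate_top, rate_theta_coupling = rate_theta_coupling,
      rate_sat = rate_sat
    ),
    class = "sim_params"
  )
}

#' Simulate a two-testcross recombination map
#'
#' Segments of jittered length tile the chromosome; each carries a true rate
#' drawn uniformly on `[0, rate_top]` and two noisy replicate estimates
#' (emulating independent testcrosses). With `rate_theta_coupling` a
#' per-segment diversity multiplier rises with the true rate and saturates
#' at `rate_sat` cM/Mb.
#'
#' @param params A [sim_params()] (the caller is responsible for seeding).
#' @return A list: `map` (a [build_recomb_map()] tibble with an extra
#'   `theta_mult` column) .
#' @export
simulate_recomb_map <- function(params) {
  n <- params$map_segments
  stopifnot(n >= 1)
  len <- stats::runif(n, 0.5, 1.5)
  bounds <- round(c(0, cumsum(len)) / sum(len) * params$chrom_length)
  true_rate <- stats::runif(n, 0, params$rate_top)
  noise_sd <- 0.1 * pmax(true_rate, 0.5)
  map <- tibble::tibble(
    chrom = "chr2",
    start = bounds[-length(bounds)],
    end = bounds[-1],
    rate_a = pmax(0, stats::rnorm(n, true_rate, noise_sd)),
    rate_b = pmax(0, stats::rnorm(n, true_rate, noise_sd))
  )
  map <- build_recomb_map(map)
  map$theta_mult <- if (params$rate_theta_coupling) {
    0.4 + 0.6 * pmin(true_rate, params$rate_sat) / params$rate_sat
  } else {
    rep(1, n)
  }
  map
}

# draw a random biallelic synonymous third-position codon pair, uniformly
# over the 29 C/T and G/A (and remaining A/T etc.) single-step pairs
third_position_pairs <- function() {
  prs <- synonymous_pairs()
  prs[prs$position == 3, ]
}

#' Simulate a polymorphic-site table with ground truth
#'
#' Generates synonymous sites (random third-position codon pairs from the
#' preference table, random true polarity, derived counts from the selected
#' SFS with per-site selection `gamma * delta_pref`) and neutral intron
#' sites, then layers on the two observation artifacts the analysis must
#' cope with:
#'
#' * ASM: each site's observed polarity flips (`d -> k - d`,
#'   ancestral/derived swapped) with probability `b / (1 + b)`;
#' * sequencing error: each of the `k - d` ancestral copies independently
#'   presents as derived with probability `eps`; truly invariant resolved
#'   sites enter the observed table as error-created low-frequency sites;
#'   sites whose every copy presents derived leave the polymorphic table.
#'
#' @param params A [sim_params()].
#' @return A list of class `sim_sites`: `sites` (observed site table, the
#'   pipeline interchange format, with `phys_pos`, `segment`, `rate`),
#'   `truth` (per observed site: true `d`, polarity flip and error events;
#'   plus dropped true sites), `totals` (resolved-site totals per segment
#'   and site type), `map` (the simulated recombination map), and `params`.
#' @export
simulate_sites <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  k <- params$k
  map <- simulate_recomb_map(params)
  a <- harmonic_a(k)

  # resolved-site totals (denominators), allocated along the chromosome
  l_syn <- params$n_syn / (a * params$theta_syn)
  l_int <- if (params$n_intron > 0) params$n_intron / (a * params$theta_intron) else 0
  seg_w <- (map$end - map$start) * map$theta_mult
  seg_share <- seg_w / sum(seg_w)
  # polymorphic sites land in segments in proportion to length x theta_mult;
  # resolved totals in proportion to length only
  len_share <- (map$end - map$start) / sum(map$end - map$start)
  totals <- dplyr::bind_rows(
    tibble::tibble(
      segment = map$segment, site_type = "synonymous",
      amino_acid = NA_character_, n_sites = l_syn * len_share,
      d_count = round(params$div_syn * l_syn * len_share), rate = map$rate
    ),
    if (l_int > 0) {
      tibble::tibble(
        segment = map$segment, site_type = "intron",
        amino_acid = NA_character_, n_sites = l_int * len_share,
        d_count = round(params$div_intron * l_int * len_share), rate = map$rate
      )
    }
  )

  prs <- third_position_pairs()
  prs <- prs[prs$codon_1 %in% params$pref$codon & prs$codon_2 %in% params$pref$codon, ]
  s <- pref_score_lookup(params$pref)

  draw_syn <- function(n) {
    if (n == 0) {
      return(NULL)
    }
    pick <- sample(nrow(prs), n, replace = TRUE)
    swap <- stats::runif(n) < 0.5
    anc <- ifelse(swap, prs$codon_2[pick], prs$codon_1[pick])
    der <- ifelse(swap, prs$codon_1[pick], prs$codon_2[pick])
    dp <- unname(s[der] - s[anc])
    # sites sharing a delta-pref value share a selected-SFS, so draw by group
    d <- integer(n)
    for (val in unique(dp)) {
      rows <- which(dp == val)
      d[rows] <- sample_selected_sfs_counts(
        length(rows), k, params$gamma * val,
        singleton_inflation = params$singleton_inflation
      )
    }
    tibble::tibble(
      site_type = "synonymous",
      amino_acid = prs$amino_acid[pick],
      ancestral_codon = anc, derived_codon = der,
      pair = prs$pair[pick], subclass = prs$subclass[pick],
      d = d, delta_pref = dp
    )
  }
  syn <- draw_syn(params$n_syn)

  intron <- if (params$n_intron > 0) {
    anc_b <- sample(the_bases, params$n_intron, replace = TRUE)
    der_b <- vapply(anc_b, function(b) sample(setdiff(the_bases, b), 1),
      character(1),
      USE.NAMES = FALSE
    )
    tibble::tibble(
      site_type = "intron", amino_acid = NA_character_,
      ancestral_codon = NA_character_, derived_codon = NA_character_,
      pair = NA_character_, subclass = NA_character_,
      d = sample_selected_sfs_counts(params$n_intron, k, 0,
        singleton_inflation = params$singleton_inflation
      ),
      delta_pref = NA_real_
    )
  } else {
    NULL
  }
  sites <- dplyr::bind_rows(syn, intron)
  sites$true_d <- sites$d
  sites$origin <- "polymorphic"

  # ASM polarity flips
  sites$flipped <- FALSE
  if (params$asm) {
    b_of <- function(type) {
      if (type == "synonymous") {
        params$div_syn - (k - 1) / k * params$theta_syn
      } else {
        params$div_intron - (k - 1) / k * params$theta_intron
      }
    }
    for (type in unique(sites$site_type)) {
      rows <- which(sites$site_type == type)
      b <- max(0, b_of(type))
      flip <- stats::runif(length(rows)) < b / (1 + b)
      idx <- rows[flip]
      sites$flipped[idx] <- TRUE
      sites$d[idx] <- k - sites$d[idx]
      tmp <- sites$ancestral_codon[idx]
      sites$ancestral_codon[idx] <- sites$derived_codon[idx]
      sites$derived_codon[idx] <- tmp
      sites$delta_pref[idx] <- -sites$delta_pref[idx]
    }
  }

  # sequencing errors: ancestral copies present as derived
  sites$err_copies <- 0L
  if (params$eps > 0) {
    sites$err_copies <- stats::rbinom(nrow(sites), k - sites$d, params$eps)
    sites$d <- sites$d + sites$err_copies
    # error-created sites from truly invariant positions
    n_inv_syn <- round(l_syn * (1 - params$theta_syn * a))
    n_inv_int <- round(l_int * (1 - params$theta_intron * a))
    inv_counts <- function(n_inv) {
      j <- stats::rbinom(n_inv, k, params$eps)
      j[j >= 1 & j <= k - 1]
    }
    err_syn_d <- inv_counts(n_inv_syn)
    err_syn <- draw_syn(length(err_syn_d))
    if (!is.null(err_syn)) {
      err_syn$d <- err_syn_d
      err_syn$true_d <- 0L
      err_syn$origin <- "error_invariant"
      err_syn$flipped <- FALSE
      err_syn$err_copies <- err_syn_d
    }
    err_int_d <- inv_counts(n_inv_int)
    err_int <- if (length(err_int_d) > 0) {
      anc_b <- sample(the_bases, length(err_int_d), replace = TRUE)
      tibble::tibble(
        site_type = "intron", amino_acid = NA_character_,
        ancestral_codon = NA_character_, derived_codon = NA_character_,
        pair = NA_character_, subclass = NA_character_,
        d = err_int_d, delta_pref = NA_real_,
        true_d = 0L, origin = "error_invariant", flipped = FALSE,
        err_copies = err_int_d,
        ancestral = anc_b,
        derived = vapply(anc_b, function(b) sample(setdiff(the_bases, b), 1),
          character(1),
          USE.NAMES = FALSE
        )
      )
    } else {
      NULL
    }
    sites <- dplyr::bind_rows(sites, err_syn, err_int)
    # saturated sites leave the polymorphic table
    lost <- sites$d >= k
    dropped <- sites[lost, ]
    sites <- sites[!lost, ]
  } else {
    dropped <- sites[0, ]
  }

  # varying-base states for synonymous rows
  if (!"ancestral" %in% names(sites)) sites$ancestral <- NA_character_
  if (!"derived" %in% names(sites)) sites$derived <- NA_character_
  syn_rows <- which(sites$site_type == "synonymous")
  pos3 <- function(cod) substr(cod, 3, 3)
  sites$ancestral[syn_rows] <- pos3(sites$ancestral_codon[syn_rows])
  sites$derived[syn_rows] <- pos3(sites$derived_codon[syn_rows])
  int_rows <- which(sites$site_type == "intron" & is.na(sites$ancestral))
  if (length(int_rows) > 0) {
    anc_b <- sample(the_bases, length(int_rows), replace = TRUE)
    sites$ancestral[int_rows] <- anc_b
    sites$derived[int_rows] <- vapply(
      anc_b, function(b) sample(setdiff(the_bases, b), 1),
      character(1),
      USE.NAMES = FALSE
    )
  }

  # physical placement: segment by length x theta_mult share, position uniform
  seg_idx <- sample(nrow(map), nrow(sites), replace = TRUE, prob = seg_share)
  sites$phys_pos <- map$start[seg_idx] +
    ceiling(stats::runif(nrow(sites)) * (map$end[seg_idx] - map$start[seg_idx]))
  sites$segment <- map$segment[seg_idx]
  sites$rate <- map$rate[seg_idx]
  sites$gene <- sites$segment
  sites$pos <- sites$phys_pos
  sites$direction <- dplyr::case_when(
    sites$site_type != "synonymous" ~ NA_character_,
    sites$delta_pref > 0 ~ "U->P",
    sites$delta_pref < 0 ~ "P->U",
    TRUE ~ "neutral"
  )

  truth_cols <- c("true_d", "origin", "flipped", "err_copies")
  obs_cols <- c(
    "gene", "pos", "phys_pos", "segment", "rate", "site_type", "amino_acid",
    "ancestral_codon", "derived_codon", "ancestral", "derived",
    "pair", "subclass", "d", "delta_pref", "direction"
  )
  structure(
    list(
      sites = tibble::as_tibble(sites[, obs_cols]),
      truth = tibble::as_tibble(sites[, c(obs_cols, truth_cols)]),
      dropped = tibble::as_tibble(dropped),
      totals = totals, map = map, params = params
    ),
    class = "sim_sites"
  )
}

#' Simulate strain alignments with planted polymorphisms
#'
#' Builds a small set of fully canonical genes (ATG start, TAA stop, one
#' GT..AG intron), copies them across `k` ingroup strains plus an outgroup,
#' and plants biallelic synonymous third-position and intron polymorphisms
#' with known derived counts. With `asm_b > 0` the outgroup carries the
#' derived state with probability `asm_b / (1 + asm_b)` (inducing ASM);
#' with `eps > 0` ancestral copies of non-reference strains flip to the
#' derived state independently. Pass-through quality/coverage masks are
#' produced for all non-reference strains.
#'
#' @param seed Integer seed.
#' @param n_genes,n_codons,intron_len Gene count and geometry.
#' @param k Ingroup sample size.
#' @param n_syn_per_gene,n_intron_per_gene Planted sites per gene.
#' @param gamma Selection scale per unit delta-pref for the planted derived
#'   counts.
#' @param asm_b Outgroup-branch quantity driving ASM (0 = outgroup always
#'   ancestral).
#' @param eps Per-base per-sequence error rate applied to non-reference
#'   ingroup strains at planted sites.
#' @param bias_max Genes draw a codon-bias strength uniformly on
#'   `[0, bias_max]` and sample codons with weight `exp(strength * score)`,
#'   so gene-to-gene variation in codon bias resembles real data (0 =
#'   uniform usage).
#' @param pref Preference table used for delta-pref and site selection.
#' @return A list: `aln` (alignment tibble), `models` (gene-model tibble),
#'   `masks` (mask tibble), `truth` (planted site table in [call_sites()]
#'   column layout plus `flipped`).
#' @export
simulate_alignments <- function(seed, n_genes = 4, n_codons = 120,
                                intron_len = 60, k = 11,
                                n_syn_per_gene = 12, n_intron_per_gene = 6,
                                gamma = 0, asm_b = 0, eps = 0, bias_max = 1.5,
                                pref = preference_scores_dpse()) {
  set.seed(seed)
  prs <- third_position_pairs()
  s <- pref_score_lookup(pref)
  deg_cod <- pref$codon
  strains <- c("ref", paste0("strain_", seq_len(k - 1)))

  genes <- purrr::map(seq_len(n_genes), function(gi) {
    g <- sprintf("gene_%02d", gi)
    bias <- stats::runif(1, 0, bias_max)
    body <- sample(deg_cod, n_codons - 2,
      replace = TRUE, prob = exp(bias * unname(s[deg_cod]))
    )
    cds <- c("ATG", body, "TAA")
    intron <- paste0(
      "GT", paste(sample(the_bases, intron_len - 4, replace = TRUE),
        collapse = ""
      ), "AG"
    )
    split_after <- sample(2:(n_codons - 2), 1) # intron between codons
    exon1 <- paste(cds[1:split_after], collapse = "")
    exon2 <- paste(cds[(split_after + 1):length(cds)], collapse = "")
    refseq <- paste0(exon1, intron, exon2)
    total <- nchar(refseq)
    models <- tibble::tibble(
      gene = g, strand = "+",
      feature = c("CDS", "intron", "CDS"),
      start = c(1L, nchar(exon1) + 1L, nchar(exon1) + intron_len + 1L),
      end = c(
        nchar(exon1), nchar(exon1) + intron_len,
        total
      )
    )
    # map codon index -> alignment position of its first base
    codon_start <- function(ci) {
      p <- (ci - 1) * 3 + 1
      ifelse(p > nchar(exon1), p + intron_len, p)
    }
    mat <- matrix(rep(strsplit(refseq, "")[[1]], k + 1),
      nrow = k + 1, byrow = TRUE
    )
    rownames(mat) <- c(strains, "outgroup")

    truth <- list()
    # synonymous sites: pick codons whose reference codon has a
    # third-position synonymous partner
    candidates <- which(cds %in% c(prs$codon_1, prs$codon_2))
    candidates <- setdiff(candidates, c(1, length(cds)))
    pick <- sample(candidates, min(n_syn_per_gene, length(candidates)))
    for (ci in pick) {
      anc <- cds[ci]
      partners <- c(
        prs$codon_2[prs$codon_1 == anc],
        prs$codon_1[prs$codon_2 == anc]
      )
      der <- if (length(partners) == 1) partners else sample(partners, 1)
      dp <- unname(s[der] - s[anc])
      d <- sample_selected_sfs_counts(1, k, gamma * dp)
      carriers <- sample(k, d)
      p3 <- codon_start(ci) + 2
      mat[carriers, p3] <- substr(der, 3, 3)
      flip <- asm_b > 0 && stats::runif(1) < asm_b / (1 + asm_b)
      if (flip) mat[k + 1, p3] <- substr(der, 3, 3)
      cls <- classify_pair(anc, der)
      truth[[length(truth) + 1]] <- tibble::tibble(
        gene = g, pos = p3, site_type = "synonymous",
        amino_acid = cls$amino_acid,
        ancestral_codon = if (flip) der else anc,
        derived_codon = if (flip) anc else der,
        ancestral = substr(if (flip) der else anc, 3, 3),
        derived = substr(if (flip) anc else der, 3, 3),
        pair = cls$pair, subclass = cls$subclass,
        d = if (flip) k - d else d,
        true_d = d, flipped = flip
      )
    }
    # intron sites in the interior
    ipos <- sample(
      seq(models$start[2] + 2, models$end[2] - 2),
      n_intron_per_gene
    )
    for (p in ipos) {
      anc <- mat[1, p]
      der <- sample(setdiff(the_bases, anc), 1)
      d <- sample_selected_sfs_counts(1, k, 0)
      carriers <- sample(k, d)
      mat[carriers, p] <- der
      flip <- asm_b > 0 && stats::runif(1) < asm_b / (1 + asm_b)
      if (flip) mat[k + 1, p] <- der
      truth[[length(truth) + 1]] <- tibble::tibble(
        gene = g, pos = p, site_type = "intron", amino_acid = NA_character_,
        ancestral_codon = NA_character_, derived_codon = NA_character_,
        ancestral = if (flip) der else anc,
        derived = if (flip) anc else der,
        pair = NA_character_, subclass = NA_character_,
        d = if (flip) k - d else d,
        true_d = d, flipped = flip
      )
    }
    if (eps > 0) {
      # independent errors on non-reference ingroup strains at planted sites
      for (t in seq_along(truth)) {
        tr <- truth[[t]]
        anc_rows <- which(mat[seq_len(k), tr$pos] == tr$ancestral & strains != "ref")
        hits <- anc_rows[stats::runif(length(anc_rows)) < eps]
        if (length(hits) > 0) {
          mat[hits, tr$pos] <- tr$derived
          truth[[t]]$d <- tr$d + length(hits)
        }
      }
    }
    aln <- tibble::tibble(
      gene = g, strain = rownames(mat),
      seq = apply(mat, 1, paste, collapse = "")
    )
    masks <- tidyr::crossing(
      gene = g,
      strain = setdiff(rownames(mat), "ref"),
      pos = seq_len(total)
    ) |>
      dplyr::mutate(quality = 40, coverage = 30)
    list(
      aln = aln, models = models, masks = masks,
      truth = dplyr::bind_rows(truth)
    )
  })
  list(
    aln = dplyr::bind_rows(purrr::map(genes, "aln")),
    models = dplyr::bind_rows(purrr::map(genes, "models")),
    masks = dplyr::bind_rows(purrr::map(genes, "masks")),
    truth = dplyr::bind_rows(purrr::map(genes, "truth"))
  )
}
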