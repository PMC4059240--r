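# Shared fixture builders and small independent oracles.

deg_codons <- function() {
  tbl <- genetic_code_table()
  tbl$codon[!is.na(tbl$degeneracy) & tbl$degeneracy > 1]
}

# counts table for a set of genes with usage biased toward `planted` codons
make_biased_counts <- function(n_genes = 30, n_codons = 600,
                               planted = NULL, seed = 42) {
  set.seed(seed)
  degc <- deg_codons()
  if (is.null(planted)) planted <- degc[substr(degc, 3, 3) %in% c("C", "G")]
  purrr::map_dfr(seq_len(n_genes), function(i) {
    bias <- stats::runif(1)
    w <- ifelse(degc %in% planted, 1 + 4 * bias, 1)
    cods <- sample(degc, n_codons, replace = TRUE, prob = w)
    cnt <- table(factor(cods, levels = degc))
    tibble::tibble(
      gene = paste0("g", i), codon = names(cnt), count = as.integer(cnt)
    )
  })
}

# independent ENC oracle: literal class-homozygosity formula, no rescaling
enc_oracle <- function(counts) {
  tbl <- genetic_code_table()
  tbl <- tbl[!is.na(tbl$degeneracy) & tbl$degeneracy > 1, ]
  f_bar <- sapply(split(tbl, tbl$degeneracy), function(cls) {
    mean(sapply(split(cls$codon, cls$amino_acid), function(cods) {
      n <- counts[cods]
      n[is.na(n)] <- 0
      sum((n / sum(n))^2)
    }))
  })
  2 + 9 / f_bar[["2"]] + 1 / f_bar[["3"]] + 5 / f_bar[["4"]] + 3 / f_bar[["6"]]
}

# independent Chi/L oracle: explicit per-amino-acid chi-square tables
scaled_chi_oracle <- function(counts) {
  tbl <- genetic_code_table()
  tbl <- tbl[!is.na(tbl$degeneracy) & tbl$degeneracy > 1, ]
  chi <- 0
  L <- 0
  for (cods in split(tbl$codon, tbl$amino_acid)) {
    n <- counts[cods]
    n[is.na(n)] <- 0
    if (sum(n) == 0) next
    e <- rep(sum(n) / length(n), length(n))
    chi <- chi + sum((n - e)^2 / e)
    L <- L + sum(n)
  }
  chi / L
}

# all permutations of seq_len(n) (tiny n only)
all_perms <- function(n) {
  if (n == 1) {
    return(matrix(1L, 1, 1))
  }
  sub <- all_perms(n - 1)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- (seq_len(n))[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# exhaustive permutation p-value for the sum(d x dpref) statistic
perm_p_exhaustive <- function(d, dp) {
  t_obs <- sum(d * dp)
  pm <- all_perms(length(d))
  mean(apply(pm, 1, function(ix) sum(d[ix] * dp) > t_obs))
}

# random synonymous (d, delta_pref) sites from the packaged preference table
random_syn_sites <- function(n, k = 11, coupled = FALSE) {
  prs <- synonymous_pairs()
  prs <- prs[prs$position == 3, ]
  s <- setNames(preference_scores_dpse()$score, preference_scores_dpse()$codon)
  pick <- sample(nrow(prs), n, replace = TRUE)
  swap <- stats::runif(n) < 0.5
  anc <- ifelse(swap, prs$codon_2[pick], prs$codon_1[pick])
  der <- ifelse(swap, prs$codon_1[pick], prs$codon_2[pick])
  dp <- unname(s[der] - s[anc])
  d <- if (coupled) {
    pmin(pmax(round(3 + 2 * dp + stats::rnorm(n)), 1), k - 1)
  } else {
    sample(seq_len(k - 1), n, replace = TRUE, prob = 1 / seq_len(k - 1))
  }
  tibble::tibble(d = d, delta_pref = dp)
}
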