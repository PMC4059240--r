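# A tiny hand-built two-exon gene shared by several blocks:
# CDS ATG | GAA GAA | TAA with a 12 bp GT..AG intron after codon 3.
tiny_gene <- function() {
  exon1 <- "ATGGAAGAA"
  intron <- "GTAAACCCTTAG"
  exon2 <- "GAATAA"
  ref <- paste0(exon1, intron, exon2)
  models <- tibble::tibble(
    gene = "g1", strand = "+",
    feature = c("CDS", "intron", "CDS"),
    start = c(1L, 10L, 22L), end = c(9L, 21L, 27L)
  )
  list(ref = ref, models = models)
}

tiny_alignment <- function(n_var = 3, d = 3, outgroup_base = NULL) {
  tg <- tiny_gene()
  strains <- c("ref", paste0("s", 1:10))
  seqs <- rep(tg$ref, 12)
  names(seqs) <- c(strains, "outgroup")
  # polymorphism at codon 2 third position (alignment pos 6): GAA -> GAG in d strains
  carriers <- strains[seq_len(d) + 1] # never the reference
  for (st in carriers) {
    s <- seqs[st]
    substr(s, 6, 6) <- "G"
    seqs[st] <- s
  }
  if (!is.null(outgroup_base)) {
    s <- seqs["outgroup"]
    substr(s, 6, 6) <- outgroup_base
    seqs["outgroup"] <- s
  }
  aln <- tibble::tibble(
    gene = "g1", strain = names(seqs), seq = unname(seqs)
  )
  list(aln = aln, models = tg$models)
}

test_that("gene validation applies each exclusion criterion", {
  tg <- tiny_gene()
  mk_aln <- function(ref) {
    tibble::tibble(gene = "g1", strain = "ref", seq = ref)
  }
  expect_true(validate_gene(tg$models, mk_aln(tg$ref))$included)

  gtg <- tg$ref
  substr(gtg, 1, 3) <- "GTG"
  v <- validate_gene(tg$models, mk_aln(gtg))
  expect_false(v$included)
  expect_equal(v$reason, "start")

  premat <- tg$ref
  substr(premat, 4, 6) <- "TAA" # in-frame internal stop
  expect_equal(validate_gene(tg$models, mk_aln(premat))$reason, "premature stop")

  badint <- tg$ref
  substr(badint, 10, 11) <- "CT" # intron must start GT
  expect_equal(validate_gene(tg$models, mk_aln(badint))$reason,
               "noncanonical intron")

  badstop <- tg$ref
  substr(badstop, 25, 27) <- "AAA"
  expect_equal(validate_gene(tg$models, mk_aln(badstop))$reason, "stop")

  unres <- tg$ref
  substr(unres, 5, 5) <- "N"
  expect_equal(validate_gene(tg$models, mk_aln(unres))$reason,
               "unresolved codon")
})

test_that("masks unresolve bases below strict thresholds, sparing the reference", {
  ta <- tiny_alignment()
  masks <- tidyr::crossing(
    gene = "g1", strain = setdiff(ta$aln$strain, "ref"), pos = 1:27
  )
  masks$quality <- 40
  masks$coverage <- 30
  # threshold edge cases at position 1 of strain s1
  low_q <- masks
  low_q$quality[low_q$strain == "s1" & low_q$pos == 1] <- 29
  out <- apply_masks(ta$aln, low_q)
  expect_equal(substr(out$seq[out$strain == "s1"], 1, 1), "N")

  low_c <- masks
  low_c$coverage[low_c$strain == "s1" & low_c$pos == 2] <- 14
  out <- apply_masks(ta$aln, low_c)
  expect_equal(substr(out$seq[out$strain == "s1"], 2, 2), "N")

  edge <- masks
  edge$quality[edge$strain == "s1" & edge$pos == 3] <- 30
  edge$coverage[edge$strain == "s1" & edge$pos == 3] <- 15
  out <- apply_masks(ta$aln, edge)
  expect_equal(substr(out$seq[out$strain == "s1"], 3, 3),
               substr(ta$aln$seq[ta$aln$strain == "s1"], 3, 3))

  # reference is exempt even with a failing mask row
  ref_mask <- masks
  ref_mask <- dplyr::bind_rows(
    ref_mask,
    tibble::tibble(gene = "g1", strain = "ref", pos = 1,
                   quality = 0, coverage = 0)
  )
  out <- apply_masks(ta$aln, ref_mask)
  expect_equal(out$seq[out$strain == "ref"], ta$aln$seq[ta$aln$strain == "ref"])

  # missing mask rows unresolve whole strains
  out <- apply_masks(ta$aln, masks[masks$strain != "s2", ])
  expect_true(grepl("^N+$", out$seq[out$strain == "s2"]))
})

test_that("site calling finds the planted synonymous site and totals", {
  ta <- tiny_alignment(d = 3)
  calls <- call_sites(ta$aln, ta$models)
  expect_equal(nrow(calls$sites), 1)
  s <- calls$sites
  expect_equal(s$site_type, "synonymous")
  expect_equal(s$amino_acid, "glu")
  expect_equal(s$ancestral_codon, "GAA")
  expect_equal(s$derived_codon, "GAG")
  expect_equal(s$d, 3)
  expect_equal(s$pos, 6)
  # totals: 3 Glu codons at 1/3 site each + Met 0 + 12 intron sites
  tot <- calls$totals
  expect_equal(tot$n_sites[tot$site_type == "synonymous" &
                             tot$amino_acid == "glu"], 1)
  expect_equal(tot$n_sites[tot$site_type == "intron"], 12)
})

test_that("unresolved bases remove whole codons from sites and totals", {
  ta <- tiny_alignment(d = 3)
  s <- ta$aln$seq[ta$aln$strain == "s9"]
  substr(s, 4, 4) <- "N" # first base of the polymorphic codon
  ta$aln$seq[ta$aln$strain == "s9"] <- s
  calls <- call_sites(ta$aln, ta$models)
  expect_equal(nrow(calls$sites), 0)
  tot <- calls$totals
  expect_equal(sum(tot$n_sites[tot$site_type == "synonymous" &
                                 tot$amino_acid == "glu"]), 2 / 3)
})

test_that("outgroup polarity: mismatched outgroup drops the site", {
  # outgroup carries a third state at the varying position
  ta <- tiny_alignment(d = 3, outgroup_base = "C") # GAC = Asp: not segregating
  calls <- call_sites(ta$aln, ta$models)
  expect_equal(nrow(calls$sites), 0)
  expect_true("unpolarizable" %in% calls$drops$reason)

  # outgroup matching the derived state flips the polarity
  ta2 <- tiny_alignment(d = 3, outgroup_base = "G")
  calls2 <- call_sites(ta2$aln, ta2$models)
  expect_equal(calls2$sites$ancestral_codon, "GAG")
  expect_equal(calls2$sites$d, 8) # 11 - 3
})

test_that("polarize() applies the parsimony rule directly", {
  p <- polarize(c(rep("C", 10), "T"), "C")
  expect_equal(p$derived, "T")
  expect_equal(p$d, 1)
  p <- polarize(c("C", rep("T", 10)), "C")
  expect_equal(p$d, 10)
  expect_null(polarize(c(rep("C", 10), "T"), "A"))
  expect_null(polarize(rep("C", 11), "C"))
})

test_that("three-state columns are excluded", {
  ta <- tiny_alignment(d = 3)
  s <- ta$aln$seq[ta$aln$strain == "s8"]
  substr(s, 6, 6) <- "T" # GAT = Asp, third state at the codon
  ta$aln$seq[ta$aln$strain == "s8"] <- s
  calls <- call_sites(ta$aln, ta$models)
  expect_equal(nrow(calls$sites), 0)
  expect_true("more than two states" %in% calls$drops$reason)
})

test_that("short-intron filter keeps only interior positions of <=80 bp introns", {
  models <- tibble::tibble(
    gene = c("g1", "g2"), strand = "+", feature = "intron",
    start = c(101L, 101L), end = c(180L, 181L) # 80 bp and 81 bp
  )
  sites <- tibble::tibble(
    gene = c("g1", "g1", "g1", "g1", "g2"),
    pos = c(109L, 110L, 172L, 173L, 140L), # 9th base, 10th, last-8th, last-7th
    site_type = "intron", d = 1L
  )
  out <- short_intron_filter(sites, models)
  expect_equal(out$pos, c(110L, 172L))
  # an 80 bp intron exposes 63 eligible positions
  expect_equal(sum(110:172 %in% 101:180), 63)
})

test_that("site tables round-trip through TSV", {
  sim <- simulate_alignments(seed = 5, n_genes = 2, n_codons = 60)
  calls <- call_sites(sim$aln, sim$models)
  sites <- add_delta_pref(calls$sites, preference_scores_dpse())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_site_table(sites, path)
  back <- read_site_table(path)
  expect_equal(as.data.frame(back), as.data.frame(sites))
})

test_that("every called site satisfies 1 <= d <= k-1", {
  sim <- simulate_alignments(seed = 17, n_genes = 3, n_codons = 100)
  calls <- call_sites(sim$aln, sim$models)
  expect_true(all(calls$sites$d >= 1 & calls$sites$d <= 10))
})
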