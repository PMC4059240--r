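# Genetic-code facts used throughout: the standard nuclear code, degeneracy
# classes, fractional synonymous-site counting, and codon-pair classification.

the_bases <- c("T", "C", "A", "G")

#' Standard genetic code as a tibble
#'
#' One row per codon of the standard nuclear genetic code, with the encoded
#' amino acid (three-letter lower case, `"stop"` for termination codons) and
#' the degeneracy of that amino acid (number of synonymous codons: 1, 2, 3,
#' 4 or 6).
#'
#' @return A tibble with columns `codon`, `amino_acid`, `degeneracy`.
#' @examples
#' genetic_code_table()
#' @export
genetic_code_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  aa3 <- c(
    A = "ala", R = "arg", N = "asn", D = "asp", C = "cys", Q = "gln",
    E = "glu", G = "gly", H = "his", I = "ile", L = "leu", K = "lys",
    M = "met", F = "phe", P = "pro", S = "ser", T = "thr", W = "trp",
    Y = "tyr", V = "val", `*` = "stop"
  )
  tbl <- tibble::tibble(
    codon = names(gc),
    amino_acid = unname(aa3[gc])
  )
  deg <- table(tbl$amino_acid[tbl$amino_acid != "stop"])
  tbl$degeneracy <- ifelse(tbl$amino_acid == "stop", NA_integer_,
    as.integer(deg[tbl$amino_acid])
  )
  tbl
}

# cached lookup vectors (evaluated once at install)
.code <- local({
  tbl <- genetic_code_table()
  list(
    aa = stats::setNames(tbl$amino_acid, tbl$codon),
    deg = stats::setNames(tbl$degeneracy, tbl$codon),
    sense = tbl$codon[tbl$amino_acid != "stop"],
    stop = tbl$codon[tbl$amino_acid == "stop"]
  )
})

check_codon <- function(codon, allow_stop = FALSE) {
  codon <- toupper(gsub("U", "T", codon))
  bad <- !codon %in% names(.code$aa)
  if (any(bad)) {
    stop("unknown codon(s): ", paste(unique(codon[bad]), collapse = ", "),
      call. = FALSE
    )
  }
  if (!allow_stop && any(codon %in% .code$stop)) {
    stop("stop codon(s) not allowed here: ",
      paste(unique(codon[codon %in% .code$stop]), collapse = ", "),
      call. = FALSE
    )
  }
  codon
}

#' Amino acid encoded by a codon
#'
#' @param codon Character vector of codons (T or U accepted).
#' @return Character vector of three-letter amino-acid names (`"stop"` for
#'   termination codons).
#' @examples
#' translate_codon(c("ATG", "GAA"))
#' @export
translate_codon <- function(codon) {
  codon <- check_codon(codon, allow_stop = TRUE)
  unname(.code$aa[codon])
}

#' Degeneracy of a sense codon's amino acid
#'
#' @param codon Character vector of sense codons.
#' @return Integer vector in `{1, 2, 3, 4, 6}`.
#' @examples
#' degeneracy(c("ATG", "AAA", "CTG"))
#' @export
degeneracy <- function(codon) {
  codon <- check_codon(codon)
  unname(.code$deg[codon])
}

#' Fractional synonymous site count of a codon
#'
#' Each codon position contributes the fraction of its three possible
#' single-base changes that are synonymous (changes to a stop codon count as
#' nonsynonymous). A fourfold-degenerate third position therefore contributes
#' one full synonymous site and a twofold-degenerate third position 1/3 of a
#' site.
#'
#' @param codon Character vector of sense codons.
#' @return Numeric vector of fractional synonymous site counts.
#' @examples
#' synonymous_site_count(c("GCT", "AAA", "ATG"))
#' @export
synonymous_site_count <- function(codon) {
  codon <- check_codon(codon)
  vapply(codon, function(cd) {
    aa <- .code$aa[[cd]]
    total <- 0
    for (pos in 1:3) {
      for (b in setdiff(the_bases, substr(cd, pos, pos))) {
        mut <- cd
        substr(mut, pos, pos) <- b
        if (.code$aa[[mut]] == aa) total <- total + 1 / 3
      }
    }
    total
  }, numeric(1), USE.NAMES = FALSE)
}

#' Classify a biallelic synonymous codon pair
#'
#' A biallelic synonymous polymorphism segregates two codons for the same
#' amino acid that differ at exactly one position. The pair is labelled by the
#' unordered base pair at the varying position (e.g. `"C/T"`, `"G/A"`) and by
#' an amino-acid subclass: `"fourfold"`, `"twofold"`, `"threefold"` (Ile), or
#' the fourfold/twofold subsets of the sixfold amino acids (Leu, Ser, Arg).
#'
#' @param ancestral,derived Sense codons (synonymous, one-position difference).
#' @return A tibble with columns `amino_acid`, `position` (1-3), `pair`
#'   (sorted base pair, T-or-C first to match the conventional C/T and G/A
#'   labels), and `subclass`.
#' @examples
#' classify_pair("GAA", "GAG")
#' classify_pair("TCT", "TCC")
#' @export
classify_pair <- function(ancestral, derived) {
  ancestral <- check_codon(ancestral)
  derived <- check_codon(derived)
  stopifnot(length(ancestral) == length(derived))
  purrr::map2_dfr(ancestral, derived, function(a, d) {
    if (.code$aa[[a]] != .code$aa[[d]]) {
      stop("codon pair ", a, "/", d, " is not synonymous", call. = FALSE)
    }
    diff <- which(strsplit(a, "")[[1]] != strsplit(d, "")[[1]])
    if (length(diff) != 1) {
      stop(
        "codon pair ", a, "/", d, " differs at ", length(diff),
        " positions (exactly 1 required)",
        call. = FALSE
      )
    }
    aa <- .code$aa[[a]]
    b <- c(substr(a, diff, diff), substr(d, diff, diff))
    # conventional ordering: pyrimidine pair "C/T", purine pair "G/A",
    # otherwise alphabetical
    ord <- c(C = 1, T = 2, G = 1, A = 2)
    pair <- paste(b[order(ord[b], b)], collapse = "/")
    tibble::tibble(
      amino_acid = aa,
      position = as.integer(diff),
      pair = pair,
      subclass = pair_subclass(a, d, aa, diff)
    )
  })
}

pair_subclass <- function(a, d, aa, pos) {
  deg <- .code$deg[[a]]
  if (aa == "ile") {
    return("threefold")
  }
  if (deg == 2) {
    return("twofold")
  }
  if (deg == 4) {
    return("fourfold")
  }
  # sixfold (leu, ser, arg): a third-position change within the fourfold box
  # (shared first two bases among four synonyms) is the fourfold subset; the
  # remaining pairs (e.g. TTA/TTG for Leu, AGT/AGC for Ser, AGA/AGG for Arg)
  # are the twofold subset.
  if (pos != 3) {
    return("sixfold_first_position")
  }
  fam <- .code$sense[.code$aa[.code$sense] == aa]
  box <- fam[substr(fam, 1, 2) == substr(a, 1, 2)]
  if (length(box) == 4 && d %in% box) "fourfold_of_sixfold" else "twofold_of_sixfold"
}

#' Enumerate all biallelic synonymous codon pairs
#'
#' All unordered pairs of sense codons that are synonymous and differ at
#' exactly one position, with their classification. In the standard code there
#' are 16 third-position C/T pairs and 13 third-position G/A pairs.
#'
#' @return A tibble with one row per unordered pair: `codon_1`, `codon_2`
#'   (alphabetical), plus the [classify_pair()] columns.
#' @export
synonymous_pairs <- function() {
  sense <- .code$sense
  out <- list()
  for (i in seq_along(sense)) {
    for (j in seq_along(sense)) {
      if (j <= i) next
      a <- sense[i]
      d <- sense[j]
      if (.code$aa[[a]] != .code$aa[[d]]) next
      if (sum(strsplit(a, "")[[1]] != strsplit(d, "")[[1]]) != 1) next
      out[[length(out) + 1]] <-
        dplyr::bind_cols(tibble::tibble(codon_1 = a, codon_2 = d),
                         classify_pair(a, d))
    }
  }
  dplyr::bind_rows(out)
}
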