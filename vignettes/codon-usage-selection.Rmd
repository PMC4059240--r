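---
title: "Detecting selection on codon usage from site frequency spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selection on codon usage from site frequency spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonsfs)
library(dplyr)
```

## The question and the model

Weak selection on synonymous codon usage is too small to see at a single
site, but it biases the frequencies at which derived alleles segregate. In a
Wright–Fisher population of constant size, the expected unfolded SFS of
neutral polymorphic sites is proportional to 1/d over derived counts
d = 1..k−1; with k = 11 sampled sequences the expected mean d is
(k−1)/a = 3.414 (a = Σ 1/i = 2.9289683) and 34.1% of sites are singletons.
Selection of scaled strength γ on the derived allele tilts this spectrum:
positive γ pushes mass toward high d, negative γ toward low d. If codon
preference is under selection, sites gaining a preferred codon (U→P,
Δpref > 0) should sit to the right of sites losing one (P→U, Δpref < 0),
*regardless* of demography, which shifts both classes alike.

`codonsfs` operationalizes this comparison three ways: one-tailed t and
Mann–Whitney tests on d between the two classes (`sfs_shift_test()`), and a
binning-free permutation test on T = Σ d·Δpref (`sum_dpref_test()`), whose
null is generated by permuting the observed d against the observed Δpref.
T is a proxy for the regression of d on Δpref, so it uses the size of each
preference change, not only its sign.

### Preference scores

Scores come from factor analysis of per-gene codon usage
(`infer_preference_table()`). The input is the genes × 59 matrix of
within-amino-acid relative usage (count of a codon over the count of its
amino acid), restricted to genes that use all 18 degenerate amino acids.
Two open choices were fixed as follows:

* **Extraction method.** The primary factor is the first principal
  component of the column-standardized matrix. This is deterministic, needs
  no rotation or iterative fitting, and reproduces the structure the scores
  must have — in particular, the two codons of a twofold amino acid have
  perfectly anticorrelated relative usages, so their loadings are exactly
  equal in magnitude and opposite in sign.
* **Input scale.** Within-amino-acid relative usage (not raw counts, not
  RSCU) is what makes that twofold symmetry exact.

The factor is polarized against two classical bias statistics computed per
gene: scaled chi-square (Chi/L, `scaled_chi()`) must correlate positively
and the effective number of codons (ENC, `enc()`) negatively with the
per-gene factor scores; if the two anchors disagree the function stops with
diagnostics rather than guess. Loadings (correlations of each usage column
with the polarized factor) are the preference scores; `preferred` is
`score > 0`, with a score of exactly 0 flagged unpreferred.

ENC uses the class-homozygosity form 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6, with
isoleucine as its own threefold class and F taken as the raw
within-amino-acid homozygosity Σp². This makes perfectly even usage give
exactly 61 and single-codon usage exactly 20; no small-sample correction is
applied because the statistic is only used as a polarization anchor and
descriptive summary. If a whole degeneracy class is unused, its term is
dropped and the remaining terms rescaled to the 20–61 range.

The package also ships the published *D. pseudoobscura* Chromosome 2 score
table (`preference_scores_dpse()`), so downstream stages can run with fixed,
citable scores instead of re-inferred ones; `run_config(preference =)`
switches between the two.

## From alignments to the site table

The calling pipeline follows strict resolution rules; all thresholds are
exposed in `run_config()` with these defaults:

* genes are excluded if the annotated start is not ATG, the stop is not
  TGA/TAG/TAA, any reference codon is unresolved, there is a premature
  stop, or an intron lacks GT..AG boundaries (`validate_gene()`);
* every base of a non-reference strain (the outgroup included) is masked to
  N when its phred consensus quality is below 30 or its coverage below 15×
  (`apply_masks()`; "below" is strict, so quality 30 / coverage 15 are
  kept). The reference strain is exempt, as it is not a resequencing
  consensus;
* a codon counts only if all three positions are resolved in all k ingroup
  strains *and* the outgroup; an intron site likewise (`call_sites()`);
* polymorphic sites must be biallelic: exactly two segregating codons,
  synonymous and differing at exactly one position (codons differing at two
  positions are excluded even if both changes are synonymous), or exactly
  two segregating intron bases;
* polarity is assigned by parsimony — the outgroup state is ancestral and
  must be one of the two segregating states, otherwise the site goes to the
  drop log as `unpolarizable` (nothing is discarded silently).

Coordinates are 1-based inclusive in all files, and all codon logic runs on
the coding strand (minus-strand genes are reverse-complemented internally).
Resolved-site totals use degeneracy-weighted fractional counting for
synonymous sites — each codon position contributes the fraction of its
three possible single-base changes that are synonymous, so a fourfold third
position is one site and a twofold third position 1/3 — and one full site
per intron position. The same rule extends to the threefold (isoleucine)
and sixfold cases, where published tables do not state the exact convention;
small rounding differences against published site totals are expected.

Watterson's θ = S/(a·L) and per-site divergence D/L are computed per class
by `summarize_diversity()`. Divergence counts only codons resolved in all
ingroup strains and the outgroup, with a single-position synonymous
difference; multiple-hit codons are not decomposed.

The short-intron view (`short_intron_filter()`, defaults 80/9/8) keeps
intron sites in introns of ≤ 80 bp outside the first nine and last eight
bases, the weakly constrained interior.

## Error and ASM null models

Two artifacts mimic selection-like SFS distortions, and the package carries
a closed-form model of each (`R/neutral-models.R`).

**Sequencing error** at rate ε per base per sequence converts ancestral
copies to the derived state; with all errors producing the same state, a
truly invariant site presents j derived copies with probability
C(k,j)εʲ(1−ε)^{k−j}, and a true class-d site presents d+j with probability
C(k−d,j)εʲ(1−ε)^{k−d−j} (`error_mixing_matrix()`; rows sum to one; a site
whose copies all end up derived leaves the polymorphic set). Mixing the
neutral class frequencies (invariant 1−θa, class d at θ/d) through this
matrix gives the apparent-singleton fraction as an increasing function of ε
(`apparent_singleton_fraction()`), which `solve_error_rate()` inverts by
bisection (tolerance 1e−10, bracketed in the low-error regime where the
function is monotone).

**ASM**: a substitution on the outgroup branch flips the inferred polarity
(d → k−d). The branch carries b = D̂ − ((k−1)/k)·θ̂ expected substitutions
per site, so a site flips with probability f = b/(1+b) — the odds of one
versus no substitution on that branch. Two readings of this model circulate
(flip probability from the likelihood ratio alone versus from the branch
odds); the implementation uses f = b/(1+b) because only that reading
reproduces its own downstream worked values (equal-tail divergence 0.0424
at θ = 0.0222 with 4.1% in each tail class; presented 10:9 ratio 1.12 at
D̂ = 0.0763), as the tests verify. The forward model
(`asm_forward_sfs()`) conserves mass and its tail ratio is strictly
increasing in b; `solve_equal_tail_divergence()` has a closed form because
presented(k−2) = presented(k−1) is linear in f.

For inference the same model gives per-site posterior odds of correct
parsimony polarization, ((k−d)/d)·(1/b) (`posterior_odds()`), requiring
b > 0 (divergence must exceed the within-ingroup expectation, or the prior
is undefined and the function stops). The ASM-randomized permutation test
(`asm_sum_dpref_test()`) keeps each site's polarity with probability
odds/(1+odds), otherwise flips d and negates Δpref, then runs the
permutation test; class-specific θ̂/D̂ (e.g. per amino acid) are supported.
How to aggregate over polarity draws is not standardized anywhere we know
of; the default averages the p-values of 20 independent draws (each with
its own permutation null), keeps every per-draw result accessible via
`tidy()`, and both the draw count and the permutation count are arguments.

### Monte Carlo conventions

100,000 permutations by default, seeded explicitly; exceedance is counted
with a strict inequality, and a reported p of 0 is printed together with
its guaranteed bound p < 1/replicates. If the statistic is invariant under
permutation (all d equal or all Δpref equal) the test reports p = 1 with a
`degenerate` flag instead of a meaningless small value.

## Secondary analyses

* `two_way_anova()`: fixed-effects two-way ANOVA with interaction on d
  (site type × direction of change), sequential (Type I) sums of squares
  with main effects before the interaction — the convention of `stats::aov`
  — documented here because unbalanced data make the choice visible. Empty
  design cells are an error naming the cell.
* `g_test()`: log-likelihood-ratio test G = 2ΣO·ln(O/E), independence and
  goodness-of-fit forms, no small-sample correction.
* `compare_slopes()`: per-group OLS slopes of d on Δpref contrasted
  pairwise with a Tukey–Kramer studentized-range adjustment,
  q = |b_i − b_j| / √((se_i² + se_j²)/2) on the pooled residual df; the
  one-tailed option halves directionally consistent p-values. The exact
  machinery behind published "Tukey-Kramer" slope contrasts is rarely
  stated; this construction is the standard one for unequal group sizes.
* `correlate()`: Pearson r with the t-transform, df = n−2 (so 23 rate
  classes give 21 df), one- or two-tailed.
* `sequential_bonferroni()`: Holm's step-down procedure via
  `stats::p.adjust`.
* Recombination: `assign_recomb_rate()` uses half-open (start, end]
  segments; `bin_rate_classes()` uses upper-closed 0.25 cM/Mb classes with
  the first class closed at 0 and a single class above 6 cM/Mb (the
  boundary conventions match the usual ">x–y" class labels); averaged
  two-testcross rates are required unless `allow_single_map` is set.

## The synthetic-data generator

`simulate_sites()` produces site tables with the statistical structure the
analysis assumes, plus a ground-truth table; `simulate_alignments()`
produces small FASTA-level inputs that exercise the whole calling pipeline.
The generator's defaults are the study conditions the package emulates:
k = 11, synonymous θ = 0.0222 and divergence 0.0763, intron θ = 0.0085 and
divergence 0.0297, the published preference table, no sequencing error,
neutrality (γ = 0).

Derived counts come from the stationary sampling distribution
P(d) ∝ C(k,d)∫ x^d (1−x)^{k−d} H(x) dx with
H(x) = (1−e^{−2γ(1−x)}) / ((1−e^{−2γ}) x(1−x)), evaluated by quadrature
(`selected_sfs()`). This is the minimal standard form whose γ = 0 limit is
the 1/d neutral spectrum; per-site selection is γ·Δpref, so the generator
plants exactly the coupling the permutation test looks for. ASM is applied
as polarity flips with probability b/(1+b) per site type; sequencing error
follows the binomial error model, including invariant-site conversions and
loss of saturated sites. A `singleton_inflation` multiplier is available as
a purely phenomenological stand-in for demographic singleton excess — no
growth model is fitted. Genes in `simulate_alignments()` draw codons with
gene-specific bias strength uniform on [0, 1.5] on the preference-score
scale, so gene-to-gene variation in codon bias resembles real data.

The recombination map generator tiles a 30 Mb chromosome with ~30 segments,
two noisy replicate rates (emulating independent testcrosses), and an
optional θ–rate coupling that rises to a plateau at 2 cM/Mb.

What the generator does **not** emulate: linkage between sites (sites are
independent draws, no coalescent trees), biased gene conversion as a
distinct process, inversion polymorphism, demographic history beyond the
singleton multiplier, and alignment or variant-calling error other than the
independent per-base model. Passing tests therefore validate the
statistical machinery and its null models, not robustness to those
real-data complications.

## Test problem sizes

The test-suite simulations were sized for tight Monte Carlo bounds at
interactive runtimes: 10⁵ draws for sampler goodness-of-fit, 20,000
permutations against exhaustive enumeration at n ≤ 7, 120–200 replicate
datasets of 100 sites for type-I calibration at α = 0.05, and ten replicate
datasets of 5,000 synonymous sites with γ = 1 (10⁴ permutations each) for
the power check at α = 10⁻⁴, all of which reject. The FASTA-level round
trips use 3–8 genes of 90–250 codons.

## Known limitations

* Preference scores are a qualitative target: sign structure and ordering
  are stable, but exact loading values depend on the (unknown) extraction
  and standardization choices of any published table one compares against.
* The ASM model assumes at most one substitution on the outgroup branch
  and a neutral SFS for the prior; under strong selection the posterior
  odds are mildly misspecified.
* The error model assumes all errors at a site produce the same (derived)
  state; three-state artifacts are outside the biallelic analysis.
* π and Tajima's D are deliberately out of scope; θ_W is the only
  diversity estimator used.
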