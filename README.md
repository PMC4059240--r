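# codonsfs

Detecting weak natural selection on synonymous codon usage from population
polymorphism data.

Synonymous codons are not used interchangeably: in *Drosophila* and many
other taxa, genes are biased toward a set of "preferred" codons (mostly C-
and G-ending), and one long-standing explanation is ongoing weak selection
for translational efficiency or accuracy. If that selection is real, it
leaves a fingerprint in present-day polymorphism: at sites where a mutation
moves a codon *toward* the preferred state (U→P), the derived allele should
segregate at higher frequencies than at sites where it moves *away* (P→U).
`codonsfs` implements the full analysis that turns resequenced strain
alignments into that test, together with the null models needed to keep the
two main observational artifacts — sequencing error and ancestral-state
misassignment (ASM) — from masquerading as selection.

The package is aimed at population geneticists working with small panels of
resequenced genomes (about 10–20 strains plus one outgroup) and at anyone
who wants the closed-form neutral/error/ASM machinery for unfolded site
frequency spectra (SFS).

## The statistics at the core

**Preference scores.** Per-codon preference is inferred by factor analysis
of per-gene codon usage: the first factor of the genes × 59 matrix of
within-amino-acid relative codon usage, polarized so that per-gene factor
scores correlate positively with the scaled chi-square (Chi/L) and
negatively with the effective number of codons (ENC). A codon's score is its
loading; positive scores mark preferred codons. For a polymorphic site with
ancestral and derived codons,

    Δpref = pref(derived) − pref(ancestral),

so U→P sites have Δpref > 0 and P→U sites Δpref < 0.

**SFS shift tests.** For sites polarized by outgroup parsimony, the derived
count d (out of k sequences) is compared between U→P and P→U classes by
one-tailed t and Mann–Whitney tests, and — without any binning — by a
permutation test on

    T = Σ_i d_i · Δpref_i,

whose one-tailed p-value is the fraction of random permutations of d against
Δpref with a larger sum.

**ASM correction.** Parsimony mispolarizes a site when the outgroup lineage
itself substituted. Under a constant-size neutral SFS, the posterior odds
that the parsimony assignment is correct are

    odds = ((k − d) / d) · 1/b,   b = D̂ − ((k − 1)/k)·θ̂,

where D̂ and θ̂ are per-site divergence and Watterson diversity. The
ASM-randomized permutation test re-draws each site's polarity from these
odds before permuting; the forward version of the same model predicts how
ASM inflates the high-frequency tail of an observed SFS, and a binomial
error-mixing model predicts how sequencing error inflates singletons.

**Diversity.** Watterson's θ = S/(a·L) with degeneracy-weighted fractional
synonymous site counts (a fourfold third position is one site, a twofold
third position 1/3), plus per-site outgroup divergence, summarized by amino
acid, site type, recombination-rate class, or map segment.

## Worked example

Simulate data with the package's study-like defaults (k = 11 sequences,
synonymous θ = 0.0222, divergence 0.0763, ASM on) and planted selection
γ = 1 per unit Δpref, then run the shift tests:

```r
library(codonsfs)
library(dplyr)

prm <- sim_params(seed = 7, n_syn = 3000, n_intron = 1500, gamma = 1)
sim <- simulate_sites(prm)
syn <- filter(sim$sites, site_type == "synonymous", delta_pref != 0)

sfs_shift_test(syn)
#> SFS shift test (one-tailed, H1: U->P > P->U )
#>   U->P: n = 1539, mean d = 3.943
#>   P->U: n = 1461, mean d = 3.281
#>   t = 6.492, P = 4.93e-11; Mann-Whitney U = 1267452.5, P = 3.49e-10

sum_dpref_test(syn, replicates = 10000, seed = 7)
#> Permutation test: sum(d x delta-pref) = 1178.2300, n = 3000
#>   one-tailed P = 0 (none of 10000 permutations exceeded; p < 0.0001)
```

U→P sites segregate at visibly higher derived counts (3.94 vs 3.28 on
average) and the permutation test finds no random pairing of d with Δpref
that beats the observed coupling — exactly the signature selection should
leave. The ASM machinery quantifies how much polarity error to expect:

```r
posterior_odds(10, neutral_model_params(11, theta = 0.0222, div = 0.0763))
#> # A tibble: 1 × 4
#>       d likelihood_ratio  odds p_asm
#>   <dbl>            <dbl> <dbl> <dbl>
#> 1    10              0.1  1.78 0.359
```

A site with 10 of 11 sequences derived has a 36% chance of being a
mispolarized singleton — which is why the raised SFS tail is modelled
rather than read as selection.

Real data enter through `read_strain_alignments()`, `read_gene_models()`,
`read_masks()` and `run_full_analysis()`; `vignette("codon-usage-selection")`
walks through the models, filters and design choices.

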