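---
title: "Mapping recessive mutations by pooled segregation signatures in selfing lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping recessive mutations by pooled segregation signatures in selfing lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The mapping problem

In a self-fertilizing, highly isogenic line, a recessive mutation induced by
chemical mutagenesis can be mapped without crosses or linkage analysis.
Because a hermaphroditic carrier produces both gametes, a single selfed
spawning yields homozygous mutant embryos at Mendelian ratios, and because
the line is isogenic, almost every sequence difference between the mutant
line and the parental wild-type strain is either the causal variant, one of
a small number of other induced variants, or a fixed strain difference.

Pooling embryos by phenotype turns this into a three-sample allele-frequency
problem. For a fully penetrant recessive allele $a$ at the causal locus, the
expected alternate-allele frequency of each pool is:

* **mutant pool** (homozygous $aa$ embryos): $f = 1$;
* **parental wild-type strain**: $f = 0$;
* **sibling pool** (phenotypically normal offspring of a selfed $Aa$
  carrier): the normal offspring are $\tfrac13\,AA$ and $\tfrac23\,Aa$, so
  $f = \tfrac23 \cdot \tfrac12 = \tfrac13$ — the wild-type allele is exactly
  twice as abundant as the mutant allele.

`selfseg` implements this screen end to end: a segregation filter over
pooled allele depths, an exact consistency test of the sibling ratio,
codon-level annotation of candidate substitutions, and prioritization by
substitution severity, residue conservation and domain overlap — together
with a synthetic pedigree generator that produces datasets with known
ground truth at desk scale.

## The segregation filter

`classify_segregation()` assigns each variant exactly one class, in a fixed
cascade: `low_depth` (any pool under `min_depth`), `strain_fixed` (all
three pools near-fixed for the alternate allele — a strain-vs-reference
difference), `wt_contaminated` (alternate allele present in the wild-type
strain), `non_segregating` (mutant pool not fixed), and
`sibling_ratio_inconsistent` before a variant is accepted as a
`candidate`. The idealised 100%/0% signature is unattainable at finite
depth with nonzero error, so the defaults `min_mutant_freq = 0.95`,
`max_wt_freq = 0.05` and `min_depth = 10` tolerate sequencing noise; all
are configurable through `filter_thresholds()`.

## The sibling consistency test

"Intermediate frequency in the sibling pool" is operationalised as an exact
two-sided test of the sibling alternate read count against the Mendelian
expectation of 1/3, rather than a fixed window: this is the criterion that
actually dismisses variants whose sibling pools are near-fixed for the
alternate allele. The two-sided p-value follows the standard exact-test
convention — the sum of the probabilities of all outcomes whose point
probability does not exceed that of the observed outcome (with a relative
tie tolerance of $10^{-7}$, as in `binom.test()`).

The null distribution matters more than the convention. With
`pool_size = Inf`, reads are modelled as
$k \sim \mathrm{Bin}(d, \tfrac13)$: the classical exact binomial test.
But a real sibling pool contains a *finite* number $m$ of embryos, and its
true allele frequency is the mean dosage of $m$ draws from
$\{0, \tfrac12\}$ with $P(\text{het}) = \tfrac23$ — for $m = 12$ the pool
frequency has standard deviation $\approx 0.07$ around 1/3 before a single
read is sequenced. A binomial test at depth 100 treats that biological
spread as evidence against the null and rejects the *true causal variant*
in roughly a quarter of screens. `sibling_ratio_test()` therefore supports
a pool-aware null that integrates over the embryo composition,

$$P(k \mid d) = \sum_{j=0}^{m} \binom{m}{j} \left(\tfrac23\right)^j
  \left(\tfrac13\right)^{m-j} \mathrm{Bin}\!\left(k \,\middle|\, d,
  \tfrac{j}{2m}\right),$$

which is the exact null for pooled sequencing of $m$ phenotypically normal
selfed offspring and reduces to the binomial as $m \to \infty$. The
classifier default is `sibling_pool_size = 12`, matching the default
simulated study design. An observed sibling frequency of 38/100 is
comfortably consistent with 1/3 under either null; a sibling pool at 95/100
rejects at $p < 10^{-20}$.

Because the pool-aware null is exact, the significance level `sibling_alpha`
*is* the probability of discarding the true causal variant. A screen whose
false-rejection cost is losing the gene it exists to find should keep that
probability small, and the genuinely inconsistent signatures it must remove
reject at astronomically small p-values, so the default is
`sibling_alpha = 0.01` rather than the conventional 0.05. The test itself
is exposed at any `alpha`, and the pool-aware null deliberately omits the
sequencing error rate (at Illumina-scale error rates its effect on the null
is negligible) and conditions on the observed depth.

No multiple-testing correction is applied: the filter is a screen, and the
funnel summary reports how many variants were tested so users can apply
one if desired.

## Coding-effect annotation

Coordinates are 1-based CDS positions counted from the A of the start
codon, so nucleotide position 574 is the first base of codon 192
(`cds_position_to_codon(574)`), and a C→T change in an arginine codon CGT
yields cysteine — a missense substitution. Translation uses the standard
nuclear genetic code only. Two deliberately strict contracts:

* a mismatch between the variant's reference base and the CDS is a hard
  error, never a warning — silent strand or offset bugs are the dominant
  failure mode in effect annotation, and the package tests document that
  minus-strand input must be reverse-complemented upstream;
* only single-nucleotide substitutions are accepted; indels and
  multi-nucleotide variants are rejected, as the screen concerns
  mutagen-induced point substitutions.

## Prioritization

Severity of a missense change is scored with the Grantham (1974)
physicochemical distance, embedded as the full symmetric 20×20 matrix.
The published judgments the scale must reproduce anchor the bins:
Ser→Thr (58) is the kind of substitution common in natural variation,
Arg→Cys (180) a radical one; `severity_class()` bins at
`conservative < 100 ≤ moderate ≤ 150 < radical`, configurable.

Conservation of the affected residue is the fraction of ortholog sequences
matching the reference residue at the mapped alignment column, with gaps on
either side counting as mismatches; with the small ortholog sets this
screen is designed for (a handful of species), match-to-reference is
informative where column entropy is not. Reference residue indices are
mapped through reference gap columns, and an index beyond the reference is
an error. Domain intervals are user-supplied residue ranges, inclusive at
both ends; the package computes overlap only and never infers domain
boundaries.

`rank_candidates()` orders candidates lexicographically: effect class
(nonsense > stop-loss > missense > synonymous > noncoding), then severity
class, then conservation descending, then in-domain first, then variant id
— the final key makes the order total, so repeated runs and shuffled
inputs give identical rankings. Missing evidence (no alignment, no domain
table) sorts below present evidence at the same level and never errors.

## What the simulator emulates — and what it does not

`simulate_dataset()` draws one fully penetrant recessive causal variant and
`n_background_variants` phenotype-independent variants. Each background
variant is, with probability `residual_het_fraction` (default 0.8),
heterozygous in the mutagenized founder — its parent-of-pool genotype is
then drawn from the selfing distribution after `selfing_generations - 1`
further generations, conditioned on the variant not having been lost —
and otherwise a fixed strain-vs-reference difference shared with the
parental strain (frequency 1 in all pools). Pool frequencies are the mean
genotype dosage of the pooled embryos (equal-mass pooling), per-pool depths
are Poisson around `mean_depth` (default 100, a plausible median coverage
for expressed transcripts in pooled RNA-seq), and read counts add binomial
miscalls at `error_rate` (default 0.001). Defaults of 12 embryos per pool
and 2 generations reflect a small selfed screen; all are configurable, and
one top-level seed with per-variant substreams makes datasets reproducible.

The observed sibling percentage of the causal variant scatters around 33%
(roughly 27–41% across seeds) purely through the embryo-composition
variance described above — an observed value of 38% arises naturally and
is not hard-coded.

Simplifications to keep in mind when extrapolating from passing tests to
real data: no read-level simulation (no mapping or calling artefacts), no
allele-specific or variable expression beyond Poisson depth, no linked
variants (every background locus segregates independently, whereas real
variants near the causal locus co-segregate and would survive the filter),
no genotyping error in the embryo pools, and synthetic ortholog alignments
generated by point mutation without gaps. The funnel counts from any real
screen therefore need not match the simulator's.

## Numerical choices and degenerate inputs

* Exact p-values use the point-probability ("minlike") two-sided
  convention with a $1 + 10^{-7}$ relative tie fuzz; agreement with a
  brute-force enumeration oracle is asserted for every depth up to 200.
* Depth 0 yields no p-value (`low_depth`), not a numeric sentinel.
* An empty variant table is a warning plus an all-zero funnel, not an
  error; a table whose every variant fails the filter produces an empty,
  well-formed report.
* The pool-aware null requires `expected_freq ≤ 1/2` (a carrier pool
  contains no homozygous-alternate embryos); the binomial null has no such
  restriction.
* Genotype distributions must sum to 1 within $10^{-12}$; the selfing
  transition preserves allele frequency exactly and halves heterozygosity
  per generation, with the closed form $h_0 2^{-g}$ tested against the
  iterated transition.

## Scale of the shipped checks

The test suite and the acceptance script exercise the pipeline at the scale
the screen is designed for: 500 background variants per dataset, mean depth
100, 12 embryos per pool, 100 independent seeds for the recovery rate, and
2000 null draws for the type-I calibration of the sibling test — sizes at
which the whole suite runs in about a minute on a single core. Recovery of
the planted causal variant at rank 1 exceeds 95% of seeds under these
conditions; the binding constraint is the sibling test's rejection rate,
which the pool-aware null holds at its nominal level.

## Known limitations

The screen assumes full penetrance, a single causal locus, and pools
labelled without phenotyping error; partial penetrance would shift the
sibling expectation away from 1/3 and currently has no dedicated model.
Conservation scoring presumes a trustworthy ortholog alignment and does not
model alignment uncertainty. The Grantham scale is one defensible
operationalisation of "conservative substitution"; the class boundaries are
exposed precisely because they are a design choice, not a measurement.
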