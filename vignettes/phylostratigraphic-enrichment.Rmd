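---
title: "Testing gene sets for evolutionary-age enrichment with phylodeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing gene sets for evolutionary-age enrichment with phylodeg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylodeg)
```

## The model

Phylostratigraphy assigns each protein-coding gene an ordinal evolutionary
age: the rank of the most distant clade in which homologs are detectable.
`phylodeg` works on a fixed 19-level scale from "All living organisms"
(rank 1, most ancient) through Eukaryota, Metazoa, Chordata and so on to
"Primates" (rank 19, youngest). Two questions are asked of a set of
differentially expressed genes (DEGs):

1. **Per-stratum enrichment.** Is stratum *s* over- or under-represented in
   the set? Under the null that the set is a uniform draw of *n* genes from
   the universe of *N* aged genes (of which *M* lie in *s*), the stratum
   count *k* is hypergeometric. We report both one-tailed probabilities,
   P(X ≥ k) and P(X ≤ k), each including the observed value — the two
   one-sided hypotheses are tested explicitly rather than doubling a single
   tail. Benjamini–Hochberg FDR correction is applied within one dataset
   across the 19 strata, separately for the over-tail family and the
   under-tail family: the two tails answer different questions, and mixing
   them in one family would couple their corrections.

2. **Distribution-level age shift.** The mean age shift is
   mean(set ranks) − mean(universe ranks), in age categories; negative
   values mean the set skews ancient. Significance comes from a Mann–Whitney
   rank test of the set's ranks against the universe's rank multiset.

### Assumptions

The enrichment null assumes the DEG set is an unordered subset of the
universe — no gene-length, expression-level or GC covariates enter the
null, exactly as in standard over-representation analysis. The baseline for
both statistics is the *whole* universe, not universe-minus-set: this
matches the expected fraction M/N used for the enrichment columns and keeps
the two modules consistent. For small sets the distinction is negligible;
for a set that is a third of the universe it is a deliberate, documented
convention.

Genes without an age assignment are dropped from the set and reported as
`n_unmapped`, never imputed: only the protein-coding universe with known
ages is in scope. Symbols are harmonized by uppercasing and trimming only —
no alias resolution, so mapping losses are visible rather than silently
patched. A gene appearing with both directions (common when pooling cell
types) is kept once in the combined set, labeled `both`, and contributes to
each direction view; the alternative (dropping or majority-voting
conflicts) discards information the direction-balance summary needs.

## Parameters that matter

* `alpha` (default 0.05): threshold on the *adjusted* p-values for flagging
  a stratum, and the conventional labels (\*, \*\*, \*\*\*) for the
  Mann–Whitney p-value.
* `exact_limit` (default 200 on n1·n2): below this, the Mann–Whitney null
  distribution is computed exactly by convolution over the tie pattern;
  above it, a normal approximation with midranks, tie-corrected variance
  and 0.5 continuity correction. With only 19 distinct values, ties
  dominate any realistic input, so the tie correction is essential, not
  cosmetic. The exact path conditions on the observed tie pattern
  (standard for rank tests) and defines the two-sided p as twice the
  smaller tail, capped at 1.
* Strata with M = 0 are untestable: they stay in the output table with
  p = 1 on both tails but are excluded from the BH family so they cannot
  dilute the correction for the testable strata.

## Numerical choices

Hypergeometric probabilities are computed in log space (`lchoose`) and tail
sums are always taken over the requested tail directly: every term is
positive, so a tail of 10⁻³⁰⁰ keeps full relative accuracy, whereas
complementing the other tail would lose it to cancellation. Tails are
floored at the smallest positive double — an observed count always has
positive probability, and downstream FDR correction requires p ∈ (0, 1].
The Mann–Whitney normal path computes log p directly, so extreme shifts
(|log₁₀ p| in the hundreds, routine for n in the thousands) remain
representable; `age_shift_result` carries `log10_p` alongside `p_value`.
BH adjustment is the standard step-up with a reverse cumulative minimum,
capped at 1, returned in input order.

Degenerate inputs: an empty intersected set is an error for enrichment and
age shift (there is nothing to test); a pooled rank sample with a single
distinct value yields p = 1 by convention; if both adjusted tails pass
`alpha` the smaller one determines the flag, with ties going to `over`.

## What the synthetic generator emulates

`synthetic_config()` fixes the study conditions: a universe of 19,000 genes
(the scale of the human protein-coding genome with age assignments), a DEG
set of 500 genes (typical of aging signatures) and an ancientness bias β.
The universe is a multinomial draw over a documented default composition —
heavy mass on ranks 1 and 12 with the smallest strata at 1%, mimicking the
qualitative shape of genome-wide phylostratum counts (large ancient core, a
vertebrate-era bump, thin recent strata). It is explicitly **not** an
empirical genome-wide vector; analyses of real data must supply a real
gene-age table.

DEG sets are drawn without replacement with weight exp(−β·(rank−1)).
Conceptually this is sequential sampling with renormalization of the
remaining weights; it is implemented by exponential race keys (draw
Exp(w_i) per gene, keep the n smallest), which yields the identical
distribution in one vectorized pass. At β = 0 the draw is uniform — the
exact null of the hypergeometric test — so null calibration of the whole
pipeline is meaningful, not approximate. Directions are labeled up with
probability plogis(intercept + slope·rank), allowing stratum-dependent
direction structure for the heterogeneity summaries.

`estimate_beta()` inverts the observed mean rank through the expected mean
rank of the sampling model. The expectation uses the successive-sampling
inclusion-probability approximation π_s = 1 − exp(−θ·w_s), with θ solving
Σ M_s π_s = n: unlike the infinite-population weight ratio, this accounts
for weight depletion when the set is a sizable fraction of the universe
(recovery simulations at n = 5,000 of 19,000 confirm the bias stays within
a few percent of β). The curve is evaluated numerically and inverted by
monotone root-finding on [0, 50]; sets no older than the universe mean
return 0, and sets more ancient than the bound can express return 50 with a
`boundary` attribute.

What the generator does **not** emulate: expression magnitudes, gene-gene
correlation, cell-type structure, or symbol-mapping noise. Passing the
simulation-based tests therefore demonstrates the statistics are correct
under their own null and alternative — it does not certify any biological
claim about real tissues, where DEG calling and universe choice dominate.

## Test and simulation sizes

The suite verifies the hypergeometric tails against exhaustive enumeration
of all draws for every universe up to N = 12, the tail identity
p_over + p_under − pmf = 1 on 10,000 random configurations, BH against the
literal step-up definition on 10,000 random vectors, and the Mann–Whitney
exact path against subset enumeration for all ordinal samples up to size 6
per group over three categories. Calibration uses 1,000 null replicates
(n = 500 from 19,000); because the hypergeometric p-value is discrete, each
stratum's empirical rejection rate is compared with the test's *exact
attainable size* P(p < 0.05) under binomial acceptance bounds that are
Bonferroni-adjusted across the 19 strata, plus an anti-conservatism bound
at the nominal level — for a discrete test, "calibrated" means achieving
its attainable size and never exceeding the nominal one. Parameter recovery
runs 100 replicates at β ∈ {0, 0.25, 0.5, 1} with n = 5,000. These sizes
were chosen so every property has negligible Monte-Carlo ambiguity.

## Reporting conventions

Bar charts show, per stratum, the percentage of upregulated and of
downregulated genes next to the expected percentage M/N. Percentages are
computed within each direction series (each series sums to 100% across
strata) so a direction with few genes remains readable; the denominator is
switchable to combined-n. Stars above a stratum mark its combined-scope
flag, colored by tail. Enrichment tables serialize to TSV with a three-line
metadata header and round-trip losslessly through `read_enrichment_table()`.

## Known limitations

* The ordinal scale treats adjacent strata as equidistant; the mean age
  shift is in "categories", not years.
* Direction heterogeneity across datasets is summarised by the sample SD of
  the per-stratum up-balance — a minimal, package-defined statistic for a
  qualitative notion; other operationalizations are possible.
* BH controls FDR per dataset and tail; analyses pooling many datasets
  should consider the implied number of families.
* No ortholog translation: cross-species DEG tables must arrive pre-mapped
  to the universe's symbol space.
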