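# phylodeg

Phylostratigraphic enrichment analysis of differentially expressed gene
(DEG) sets.

## The problem

Every protein-coding gene can be dated: the most distant clade in which
homologs are detectable defines its *phylostratum*, an ordinal category of
evolutionary age. On the 19-level human scale used here, rank 1 ("All living
organisms") holds genes shared with unicellular life and rank 19
("Primates") the youngest lineage-specific genes. A recurring observation in
aging and senescence transcriptomics is that expression changes concentrate
in the most ancient strata — an *atavistic* skew toward ancestral cellular
programs. `phylodeg` makes that claim testable for any gene set: it asks, per
stratum, whether a DEG set contains more (or fewer) genes of that age than a
random draw from the genome would, and whether the set's overall age
distribution is shifted relative to the genome baseline.

The package is aimed at computational biologists who already have DEG calls
(old vs. young, senescent vs. proliferating, ...) as gene-symbol tables and
want the age-composition analysis, its statistics, figures and a simulation
harness in one tested place.

## The statistics

**Per-stratum enrichment.** With a gene universe of `N` aged genes, `M` of
them in stratum `s`, and a DEG set of `n` genes of which `k` fall in `s`,
the null distribution of `k` is hypergeometric:

    P(X = k) = C(M, k) C(N − M, n − k) / C(N, n)

Over-representation is tested with the upper tail `P(X ≥ k)` and
under-representation with the lower tail `P(X ≤ k)` (both tails include the
observed value). Benjamini–Hochberg FDR correction is applied across the 19
strata, separately per tail; strata with `M = 0` are reported but excluded
from the correction family. A stratum is flagged at adjusted `p < 0.05` by
default.

**Age shift.** The *mean evolutionary age shift* is the difference between
the mean stratum rank of the set and of the universe, in age categories
(negative = older). Its significance comes from a Mann–Whitney rank test of
the set's ranks against the universe's rank multiset, with midrank tie
handling, tie-corrected variance and continuity correction — or an exact
convolution over the tie pattern for small problems.

**Heterogeneity.** Per stratum, the direction balance
`n_up / (n_up + n_down)` summarises whether changes are dominated by up- or
downregulation; its standard deviation across datasets quantifies how much
tissues disagree.

**Synthetic data.** A seeded generator draws universes with a configurable
stratum composition and DEG sets with sampling weight
`exp(−β · (rank − 1))`, so `β = 0` is the exact null of the hypergeometric
test and larger `β` injects an ancient bias. `estimate_beta()` recovers `β`
by method of moments, which closes the loop for calibration and
parameter-recovery checks.

## Worked example

```r
library(phylodeg)

cfg      <- synthetic_config(universe_size = 19000, beta = 0.5,
                             n_deg = 1200, seed = 42)
bundle   <- synthetic_bundle(cfg)
universe <- universe_distribution(bundle$universe)

tab <- stratum_enrichment(universe, bundle$deg)
tab[c(1, 2, 12, 19), c("rank", "name", "M", "k", "expected_fraction",
                       "observed_fraction", "q_over", "q_under", "flag")]
#>  rank                 name    M   k expected_fraction observed_fraction
#>     1 All living organisms 5761 857            0.3032             0.714
#>     2            Eukaryota 2435 235            0.1282             0.196
#>    12         Euteleostomi 1824   0            0.0960             0.000
#>    19             Primates  430   0            0.0226             0.000
#>     q_over  q_under  flag
#>  2.34e-201 1.00e+00  over
#>   4.93e-11 1.00e+00  over
#>   1.00e+00 7.13e-54 under
#>   1.00e+00 1.28e-12 under

age_shift_result(bundle$deg, universe)
#> Age shift for 'synthetic_deg': -4.538 categories (n = 1200)
#>   Mann-Whitney U = 5208433.0, p = 4.41e-228 [***]

estimate_beta(bundle$deg, universe)
#> [1] 0.49
```

Reading: 71% of this (deliberately biased) DEG set sits in the most ancient
stratum against an expected 30%, flagged `over`; the youngest strata are
depleted, flagged `under`; the set is on average 4.5 age categories older
than the genome, and the generating bias β = 0.5 is recovered from the set
alone.

Real datasets enter through `load_gene_ages()` (gene → stratum table),
`read_deg_table()` (gene, direction and/or log fold change), and
`run_analysis()` (a YAML config naming several datasets), which writes
enrichment TSVs per direction scope, an age-shift summary table, direction
balances and grouped bar charts with significance stars. A thin CLI over the
same functions is in `inst/scripts/phylodeg-cli.R`
(`analyze` / `simulate` / `calibrate` / `plot`).

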