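# microspec

Seasonal microhabitat specialization of soil arthropod communities:
bipartite network indices, fixed-margin null models, and environmental
occurrence niches, as a tested R package.

## What it is for

Soil-dwelling arthropods — the motivating case is adult oribatid mites in
a temperate forest — partition themselves among discrete microhabitats
(moss, dead wood, litter), and that partitioning shifts over the year with
air temperature and humidity. `microspec` takes a long-format survey table
(taxon, microhabitat, month, replicate, raw count, sample dry weight) and
a weather-logger series, and computes:

- **Community profiles**: abundance standardized to individuals per kg
  sample dry weight (Ind/kg), species richness, and effective Shannon
  diversity e^H, summarized per microhabitat and month (mean ± SE across
  replicates).
- **Network specialization**: treating the taxon × microhabitat abundance
  table as a weighted bipartite network, the complementary specialization

      H2' = (H2_max − H2) / (H2_max − H2_min) ∈ [0, 1],

  where H2 = −Σ (a_ij/m) ln(a_ij/m) is the two-dimensional Shannon entropy
  and the extrema are taken over tables with the observed margins; and the
  node-level standardized Kullback–Leibler divergence

      d'_h = d_h / ln(m / B_h),   d_h = Σ_j p'_j ln(p'_j / q_j),

  the exclusiveness of habitat h's community relative to overall taxon
  availability. Both come with fixed-margin null models (Patefield RxC
  randomization, add-one permutation p-values), pairwise H2' distances
  between habitats, and permutation-tested Pearson correlations of the
  link-temperature matrices (standardized deviations from the neutral
  expectation E_ij = A_i B_j / m) of consecutive monthly networks.
- **Environmental occurrence niches**: per taxon, the abundance-weighted
  mean μ_i = Σ_m p_{m,i} · θ_m of monthly air temperature (or relative
  humidity), its weighted SD as niche breadth, a month-permutation null
  test, and a warmer/colder/neutral/none classification.
- **Association statistics** on the monthly summaries: OLS F-tests
  (≡ Gaussian identity-link GLMs), Wilks-lambda multivariate regression
  with protected univariate follow-ups, Spearman and Pearson correlations.
- A **synthetic-data generator** (`generateCommunity()`, with `baseline`,
  `specialist_shift` and `may_june_turnover` scenario presets) that
  emulates the survey design with known ground truth, so every estimator
  is testable without external data.

A published year-long oribatid survey ships as a plain-text fixture: the
pooled taxon × {moss, dead wood, litter} abundance table
(`oribatidPooledNetwork()`) and the monthly weather/index summary
(`oribatidMonthlyConditions()`).

## Worked example

```r
library(microspec)

net <- oribatidPooledNetwork()
net
#> InteractionMatrix: 61 taxa x 3 habitats (density mode), m = 1.40071e+07
#>   column totals: moss = 1.07216e+07, dead_wood = 2.43104e+06, litter = 854440

h2Prime(net)
#> H2' = 0.1404  (H2 = 3.5194 in [2.9356, 3.6147], continuous mode)

dPrime(net, "moss")
#> d'(moss) = 0.0703  (d = 0.0188 in [0.0000, 0.2673], continuous mode)
dPrime(net, "litter")
#> d'(litter) = 0.2640  (d = 0.7384 in [0.0000, 2.7969], continuous mode)
```

The pooled network is highly generalized (H2' ≈ 0.14 on a 0–1 scale):
most taxa occur in all three microhabitats, in different frequencies.
Within that, moss hosts the least exclusive community (d' = 0.07) and
litter the most (d' = 0.26). The monthly summaries show the seasonal
driver:

```r
m <- oribatidMonthlyConditions()
olsFTest(m$temp_mean, m$h2_prime)[c("f_stat", "df", "p_value")]
#> F(1,10) = 11.35, p = 0.007   (slope < 0)

wilksManova(as.matrix(m[, c("dprime_dead_wood", "dprime_litter",
                            "dprime_moss")]), m$temp_mean)
#> Wilks lambda = 0.321, F(3,8) = 5.63, p = 0.023
```

Network specialization falls as air temperature rises — communities are
more generalized in warm months — and the multivariate regression of the
three d' series on temperature confirms the effect across habitats.

End-to-end runs (`runFullAnalysis()`) and a thin command-line wrapper
(`inst/scripts/microspec.R`, subcommands `simulate`, `diversity`,
`network`, `dynamics`, `niche`, `stats`, `run-all`) write the full report
as CSVs plus JSON run metadata; every randomized result records its seed
and reruns are byte-identical.

See the methods vignette
(`vignettes/microhabitat-specialization.Rmd`) for the model details,
null-model conventions, generator design and known limitations.

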