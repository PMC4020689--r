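# rankshift

Quantitative comparison of community structure between repeated
standardized surveys — built for the classic resurvey design in ground-beetle
(Carabidae) ecology, where a row of pitfall traps is re-installed in the same
sites decades after a historical campaign, but applicable to any paired
abundance samples.

## What it computes

Starting from long-format trap catches (site, period, trap, collection
interval, species, count), the package provides:

* **Effort standardization** — pooled catches converted to annual activity
  density, aAD = (count / n traps) / (exposure days / 10), the mean catch
  per trap per standard 10 trapping days.
* **Richness estimation** — exact individual-based rarefaction
  E[S_m] = Σᵢ (1 − C(N−Nᵢ, m)/C(N, m)); the incidence-based bootstrap
  estimator Ŝ = S_obs + Σᵢ (1−pᵢ)ⁿ with percentile confidence intervals;
  rescaling of unequal-density surveys to a common total.
* **Rank-abundance (SAD) model selection** — Poisson maximum-likelihood fits
  of broken stick, niche preemption, lognormal, Zipf and Zipf–Mandelbrot
  expected rank-abundance sequences, compared by AIC.
* **Assemblage comparison** — Renkonen minimum percentage similarity
  Σ min(p_A, p_B); chord distance with minimum-variance (Ward) clustering
  and Newick export; species-turnover accounting; trait summaries (dispersal
  power, diet guilds).
* **The Index of Rank-abundance Change (IRC)** — the mean absolute shift in
  species rank order between two samples over their species union,
  IRC = Σᵢ |R_A(spᵢ) − R_B(spᵢ)| / |A ∪ B|, with species absent from one
  sample ranked just below its last present species. IRC = 0 means the
  assemblage kept its internal structure; values grow (up to |A ∪ B| − 1) as
  dominance reorders, even when the species list barely changes.
* **A synthetic-data generator** — paired before/now surveys with a regional
  species pool, trait-dependent extinctions, within-region colonization,
  abundance boosts for warm-adapted species, rank jitter, and
  Poisson/multinomial trap noise, so every estimator is testable against
  known truth.

See `vignettes/comparing-resurveys.Rmd` for the methods in full.

## Worked example

Simulate a six-site paired survey under the default scenario and run the
whole pipeline:

```r
library(rankshift)
cfg <- scenario_config(seed = 2026)   # 6 sites x 2 periods, 6 traps, 90 days
report <- run_pipeline(cfg, n_boot = 999)
report
#> Before/now comparison: 6 sites (1980 vs 2008)
#>   1980: 23 species observed, 23.0 expected (100% coverage)
#>   2008: 22 species observed, 22.0 expected (100% coverage)
#>    site renkonen   irc shared only_before only_now sad_before    sad_now
#>  site01    0.450 2.250      4           2        2  lognormal mandelbrot
#>  site02    0.780 1.250      4           2        2  lognormal preemption
#>  site03    0.605 0.875      6           0        2  lognormal mandelbrot
#>  site04    0.768 1.143      3           2        2  lognormal mandelbrot
#>  site05    0.742 1.667      6           1        2  lognormal mandelbrot
#>  site06    0.419 2.091      8           1        2  lognormal mandelbrot
```

Each row compares one site across the ~30 simulated years: `renkonen` is the
overlap of relative-abundance profiles (1 = identical), `irc` the mean rank
shift per species of the union (0 = same order), and the remaining columns
the turnover accounting and the AIC-selected SAD model in each period. Here
every "before" assemblage was generated from a lognormal SAD; the simulated
extinctions and abundance boosts push several "now" fits toward more
dominance-skewed shapes.

Drill into a single sample or pair:

```r
sad_select(report$samples[["site03_1980"]]$raw_counts)
#> SAD model selection (Poisson ML, AIC):
#>         model k     AIC    dAIC
#> 1   lognormal 2  64.595   0.000
#> 2  mandelbrot 3 148.856  84.261
#> 3  preemption 1 204.822 140.227
#> 4 brokenstick 0 224.136 159.541
#> 5        zipf 2 350.631 286.035
#> best: lognormal

irc(report$samples[["site03_1980"]], report$samples[["site03_2008"]])
#> IRC = 0.8750 over 8 species (sum of rank shifts = 7)
#>   largest shifts: sp008 (2), sp028 (2), sp002 (1), sp025 (1), sp029 (1)
```

`run_pipeline(cfg, out_dir = "out")` additionally writes `report.json`,
`comparison.csv`, `richness.csv`, `radfit.csv` and `dendrogram.nwk`. Real
data enter through `read_long_table()` / `read_trait_table()` or a YAML
config with `catch:` and `traits:` paths; a thin command-line wrapper with
`simulate`, `richness`, `radfit`, `compare`, `traits` and `run` subcommands
lives at `inst/scripts/rankshift-cli.R`.

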