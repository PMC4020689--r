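---
title: "Quantifying three decades of assemblage change from paired pitfall surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying three decades of assemblage change from paired pitfall surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rankshift)
```

## The problem

Historical standardized surveys are rare and precious: when a row of pitfall
traps can be re-installed in the same sites decades later, with the same trap
type, attractant and season, the two catches can be compared quantitatively.
`rankshift` implements the full chain of statistics needed for such a
before/now comparison of ground-beetle (or any epigean arthropod) assemblages:
effort standardization, richness estimation, rank-abundance model selection,
similarity and clustering, and a rank-shift index that summarizes how much the
internal structure of an assemblage has reordered.

This vignette explains each method, its assumptions, and the design decisions
taken where more than one defensible convention exists.

## Activity density: the abundance currency

Pitfall catches measure *activity density*, not population density: a count is
the product of abundance and mobility over the trapping period. Catches from
the row of traps in one site-period are pooled (which also absorbs occasional
trap losses) and standardized to annual activity density,

$$\mathrm{aAD} = \frac{\text{pooled count}/n_\text{traps}}{\text{exposure days}/10},$$

the mean catch per trap per standard 10 trapping days. The standardization is
linear in the counts and invariant to how the season was cut into collection
intervals; it makes sites and periods with different effort comparable even if
the exact season lengths differed between campaigns. Exposure is the union
span from the earliest interval start to the latest interval end, with all
traps assumed simultaneously active; a per-trap active-day override is
available when traps were lost part-season. aAD values are kept as exact
reals; the raw pooled integer counts travel alongside, because the
likelihood-based and rarefaction methods below require integers.

## Richness: rarefaction and the incidence bootstrap

Observed richness depends on effort and on total catch, so two corrections
are offered.

**Individual-based rarefaction.** The expected number of species in a random
subsample of $m$ individuals has the hypergeometric closed form
$E[S_m] = \sum_i \left(1 - \binom{N-N_i}{m}/\binom{N}{m}\right)$, evaluated
through log-binomial coefficients. The exact variance (including
pairwise-absence covariances) is provided for curve plotting. When one period
caught far more individuals than the other, `rescale_to_common_density()`
compares both at the smaller total — the denser sample is rarefied at the
sparser sample's total catch, which is the fair richness comparison (a
rounded-half-to-even pseudo-sample is also returned for workflows that need
integer counts).

**Bootstrap expected richness.** From a unit × species incidence matrix the
point estimate is $\hat S = S_{obs} + \sum_i (1-p_i)^n$, where $p_i$ is the
fraction of the $n$ units occupied by species $i$: the correction term is the
expected number of species a same-sized survey would miss, so $\hat S$
estimates the richness that would be recorded if even the least catchable
species were intercepted. The confidence interval is the 2.5/97.5 percentile
interval over resamples of units with replacement (999 by default). Percentile
intervals were chosen because the estimator's distribution over unit
resamples is asymmetric near complete detection. The resampling unit defaults
to the most granular one available, the trap × collection interval, and is
configurable (`"trap"`, `"site"`); coarser units give smaller $p_i$ and
larger corrections, so the unit must be reported with the estimate. Observed
coverage is reported as `round(100 * s_obs / s_expected)` percent.

## Rank-abundance models and AIC selection

The shape of the rank-abundance distribution (RAD) summarizes community
structure: strongly dominance-skewed assemblages behave like the geometric
niche-preemption series, while more equitable ones are closer to the broken
stick, lognormal or Zipf–Mandelbrot forms. Five models are fitted, with
expected abundance at rank $r$ of $S$ species totalling $N$ individuals:

| model | $\hat a_r$ | free parameters |
|---|---|---|
| broken stick | $(N/S)\sum_{k=r}^{S} 1/k$ | 0 |
| preemption | $N\alpha(1-\alpha)^{r-1}/(1-(1-\alpha)^S)$ | 1 |
| lognormal | $\exp(\mu^* + \sigma^*\Phi^{-1}(1-(r-\tfrac12)/S))$ | 2 |
| Zipf | $N p_1 r^\gamma$ | 2 |
| Zipf–Mandelbrot | $N c (r+\beta)^\gamma$ | 3 |

Conventions worth noting: the preemption series is normalized over the $S$
*observed* species so that it sums to $N$ exactly; the lognormal uses the
$(r-\tfrac12)/S$ plotting-position quantile so $\mu^*, \sigma^*$ are
interpretable on the log-abundance scale; Zipf is retained as the
$\beta \to 0$ limit of Zipf–Mandelbrot (it stabilizes the Mandelbrot
initialization, and can be excluded from headline selection by passing a
four-model set to `sad_select()`).

Fitting maximizes the Poisson log-likelihood
$\sum_r (a_r \ln \hat a_r - \hat a_r)$ on the raw pooled counts — not on aAD,
because aAD is a site-constant rescaling that changes no ranks and no
relative fit, while the Poisson family needs integer counts. The dropped
$\ln a_r!$ constant is restored in the reported log-likelihood so AIC values
($-2\ell + 2k$) are comparable across models of the same counts. Domains are
enforced by transformation ($\alpha$ by logit, $\gamma$ as $-e^\theta$,
$\beta$ as $e^\theta - 1$, scales by log); the one-parameter preemption model
is optimized by deterministic golden-section search, and the multi-parameter
models by Nelder–Mead from three fixed moment-based starting points (relative
tolerance $10^{-10}$), keeping the best of the three. A model competes only
when $S \ge k+1$; AIC ties below $10^{-6}$ go to the smaller $k$, then to the
fixed model order. Lognormal and Mandelbrot fits are known to be
near-degenerate on many empirical shapes — both can trace almost the same
concave RAD — so disagreement between those two labels should not be
over-interpreted; the validation suite therefore demands reliable recovery
only for the structurally distinctive preemption and Zipf generators.

## Comparing assemblages

**Renkonen similarity** $PS = \sum_i \min(p_{Ai}, p_{Bi})$ uses relative aAD
within each sample, so it compares *profiles* and is robust to the large
absolute abundance differences typical between decades.

**Chord distance and minimum-variance clustering.** Abundance vectors on the
species union are normalized to unit Euclidean norm; their Euclidean distance
(0 to $\sqrt 2$) is scale-invariant. Because chord distance is Euclidean in
the normalized space, Ward's minimum-variance criterion is valid; clustering
runs `hclust(method = "ward.D")` on *squared* chord distances, so merge
heights are on the variance scale. Dendrograms export to Newick.

**The rank-shift index (IRC).** Renkonen and chord distance weight abundant
species heavily; neither notices when a formerly dominant species slides to
the tail while the set of species barely changes. The Index of
Rank-abundance Change targets exactly this: rank the species of the union
$A \cup B$ within each sample (1 = most abundant) and report the mean
absolute rank shift,

$$\mathrm{IRC} = \frac{1}{|A \cup B|} \sum_{i \in A \cup B} |R_A(sp_i) - R_B(sp_i)|,$$

a city-block distance in rank space divided by the union size so values are
comparable across sites. IRC is 0 exactly when the rank order is unchanged,
is bounded above by $|A \cup B| - 1$, is symmetric, and is invariant to
rescaling either sample (it sees only ranks).

Two conventions had to be fixed where a definition over $A \cup B$ is silent:

* *Absent species.* A species of the union missing from one sample takes rank
  $S_\text{present}+1$ in that sample — "just below the last present
  species". This keeps ranks integral, shared by all absentees, and preserves
  $\mathrm{IRC}(A,A) = 0$. The alternative (rank = union size), which
  penalizes extinctions of common species more strongly, is available via
  `absent_rank = "union_size"`.
* *Ties.* Equal abundances are broken lexicographically by species name —
  arbitrary, but deterministic, which reproducibility requires.

Species turnover (`turnover()`) is plain set arithmetic on the present
species: shared, lost, gained, union.

**Trait summaries.** Three percentages aid interpretation: aAD share of
macropterous + dimorphic species (dispersal power, an indicator of
disturbance), aAD share of zoophytophagous species (followers of xeric
vegetation), and the percent of species that are specialized predators.
Percentages are computed from the same aAD vectors the comparison operations
use and are rounded (half away from zero) only at the reporting layer.

## The synthetic-data generator

Because raw site-level abundance matrices of historical resurveys are rarely
published, every estimator here is validated against simulated surveys with
known truth. `scenario_config()` fixes the study conditions:

* **Design** — 6 sites × 2 periods, 6 traps per site, 3 collection intervals
  spanning 90 days from mid-June: the standard season of a temperate-alpine
  pitfall campaign.
* **Communities** — a regional pool of 36 species with species-level traits;
  per-site richness drawn from 5–12; expected abundances follow a configured
  SAD (lognormal, $\sigma^* = 1$, by default — an intermediate, equitable
  shape) rescaled to ~300 expected individuals per site-period, a typical
  seasonal catch for a six-trap row at these densities.
* **Turnover** — microtherm species go locally extinct with probability 0.5
  and hygrophilic species with 0.7 (cold- and moisture-demanders are the
  documented losers of alpine warming and drying), others with background
  0.1; surviving thermophilic species are multiplied by 6, reflecting the
  severalfold "sharp increases" reported for warm-adapted species, which
  together with the extinctions makes total activity roughly double while
  richness declines; 2 colonists per site arrive at low-to-mid abundance
  (uniform between the site's minimum and median prior abundance), drawn from
  species occupying *other* sites beforehand — a within-region range shift,
  so the regional species total does not inflate; a log-normal rank jitter
  (sd 0.3 on the log scale) models undirected abundance drift.
* **Noise** — the pooled total catch per species is Poisson with mean
  $\mathrm{aAD} \times n_\text{traps} \times \text{days}/10$, allocated
  multinomially over trap × interval cells with equal probabilities. This is
  the simplest noise model consistent with pooled counts (pooling discards
  trap-level structure anyway) and makes the computed aAD an unbiased
  estimator of the generating abundance, which the test suite verifies by
  simulation. No noise model for pitfall catches is established in the
  literature; Poisson/multinomial is an assumption, and real catches are
  likely overdispersed relative to it.
* **Determinism** — every draw derives from the single scenario seed through
  a fixed linear splitting scheme (one stream per site and step), with no
  hidden global state.

What the generator does *not* emulate: spatial autocorrelation between traps,
within-season phenology (catches are uniform over cells), observation-level
overdispersion, taxonomic misidentification, and any explicit
altitude/climate forcing. Tests passing on these simulations therefore
demonstrate correctness of the estimators under idealized sampling, not
robustness to every property of field data.

## Validation strategy and problem sizes

The test suite checks each closed form against an independent route:
rarefaction against 10,000-draw Monte-Carlo subsampling (50 random count
vectors, $N \le 200$) and against `vegan::rarefy`; the bootstrap estimator
against hand-computed 3-unit cases, `vegan::specpool`, and recovery of a
known 30-species pool over 100 simulated surveys; IRC against a brute-force
rank-enumeration oracle on 1,000 random pairs ($S \le 10$); preemption
fitting against an exact geometric series (the MLE must recover
$\alpha = 0.5$ to $10^{-4}$); model selection by recovery rates over 200
Poisson-sampled communities per generator ($S = 20$, $N = 1000$); clustering
by requiring each before/now pair to be its own first merge in no-turnover
scenarios (20 seeds); and the IRC/Renkonen anti-correlation by monotonicity
along a rank-jitter grid (5 levels × 50 seeds). These sizes keep the full
suite under a few minutes while leaving Monte-Carlo error well below the
asserted tolerances.

## Limitations

* IRC has no null distribution here; the package deliberately offers no
  significance test for it (a permutation null would be a methodological
  extension).
* The bootstrap richness estimator corrects for *detection within the
  realized design*; it does not extrapolate to unseen sampling intensities,
  and its value depends on the chosen resampling unit.
* Poisson ML RAD fitting treats counts as independent across ranks; the
  multinomial dependence induced by fixing $N$ is ignored, as is standard.
* aAD corrects for effort, not for activity differences driven by
  temperature itself: a warmer resurvey season inflates activity density for
  fixed abundance. This is a property of the data type, not of the
  estimators.
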