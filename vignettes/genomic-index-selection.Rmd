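---
title: "Desired-gains genomic index selection: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Desired-gains genomic index selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gisel)
```

## The model

A selection index scores each candidate genotype as a linear combination of
its phenotypes, `I = b'X`. Classically (Smith–Hazel) the weights solve
`P b = G a`, where `G` and `P` are the additive-genetic and phenotypic
variance–covariance matrices among the `n` traits and `a` is a vector of
economic values per unit of genetic change. `gisel` implements the
complementary *desired-gains* construction: instead of requiring economic
values up front, the breeder states a vector `Q` of desired genetic gains on
a subset of `m ≤ n` traits, and the weights are

```
b = P⁻¹ G* [G*' P⁻¹ G*]⁻¹ Q
```

where `G*` keeps the `m` columns of `G` for the targeted traits (the
relationship matrix of the general restricted-index result is set to the
identity, i.e. candidates are phenotyped directly). This `b` is the
minimum-variance index whose expected response matches `Q` exactly on the
targeted traits — our tests verify it against an independent
constrained-quadratic-program oracle (a direct KKT-system solve of
"minimize `b'Pb` subject to `G*'b = Q`").

From `b` the rest of the pipeline follows:

* implied economic values `a = G⁻¹ P b` — the values under which this index
  *would* have been Smith–Hazel optimal, reported as ratios to a reference
  trait (dry biomass per plant, grams);
* correlated responses `Q* = G b` for **all** `n` traits, targeted or not;
* index standard deviation `σ_I = √(b'Pb)`. When the gains are to be
  achieved in a single generation, the required selection intensity is
  `i = σ_I`. We use the square root even though a common shorthand writes
  the relation without the radical: only `σ_I = √(b'Pb)` is consistent with
  the univariate breeder's equation `i = R/(h²σ_P)`, which our tests check
  in closed form.
* the selected fraction `p` solving `i = φ(z)/p`, `z` the upper-`p` standard
  normal quantile (infinite-population truncation selection). We invert this
  by bisection on `z`; the published footnote correspondences
  (`i = 2.15 ↔` top 4 %, `2.58 ↔` 1.3 %) match this formula, which is why no
  finite-sample correction is applied by default (one is available via the
  `N` argument of `intensity_from_fraction()` for comparing against small
  simulations).

Monetization converts a trait change `Δ` into per-hectare dry-biomass
equivalents via its economic ratio `c` (grams of biomass per plant per unit
of the trait): `tonnes/ha = density · Δ · c / 10⁶`, then currency at a price
per tonne. Defaults are 4444 plants ha⁻¹ (a 1.5 × 1.5 m grid) and €70 t⁻¹.

### Units of the valued change

The per-unit basis of economic values for percentage-scale traits (cell-wall
composition, moisture) is ambiguous in practice: a "5 % change" may mean
5 percentage points or 5 % of the current mean. Worked example conventions
mix the two (flowering valued per absolute day, cell-wall traits per printed
percent figure). `run_scenario()` therefore monetizes each targeted trait at
its *absolute* resolved gain and records that mode in the report, while
`monetize_trait()` accepts any explicit `Δ` so either convention can be
reproduced; the analysis scripts use the printed-figure convention where
that is what the published arithmetic does.

## Tunable parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `reference` | trait whose economic value is 1 | `DryMatter` (g/plant) | yield is the natural numéraire for a biomass crop |
| `density` | plants per hectare | 4444 | 1.5 × 1.5 m establishment grid |
| `price` | currency per tonne dry biomass | 70 | conservative market price |
| `repair` | clip small negative eigenvalues of `G`, `E` | off | marker-estimated matrices are often slightly indefinite, but silent repair would mask genuinely bad inputs; opt in explicitly |
| `tol` | symmetry/PSD relative tolerance | 1e-8 | double-precision round-trip of published matrices |

Linear solves use Cholesky factorizations with an LU fallback; condition
numbers above 1e12 trigger a warning naming the matrix, because a
marker-estimated 16-trait `G` from ~138 genotypes is close to singular.

## The synthetic panel: what it emulates, and what it does not

The study population whose covariance matrices motivate this package is 138
*Miscanthus sinensis* genotypes scored for 16 phenology, morphometric and
cell-wall traits. The full marker-estimated `G` and `P` live in a
journal-hosted supplementary spreadsheet that this package does not ship, so
`default_panel()` provides an *emulation* with the structure the analysis
assumes:

* the 16 trait names, units, current population means and broad-sense
  heritabilities (0.48–0.89) as published;
* the stated genetic correlations: weak flowering–yield (0.19) and strong
  flowering–senescence / flowering–moisture (|r| = 0.85). Only magnitudes
  are stated for the strong pair, so signs were chosen to reproduce the
  *direction* of the published correlated responses — delaying flowering
  lowers senescence score (r = −0.85) and raises harvest moisture
  (r = +0.85);
* everywhere else, modest documented defaults (|r| ≤ 0.3): positive
  correlations among plant-size traits and with yield, a mild negative
  lignin–cellulose trade-off. The matrix is projected to the nearest
  positive semi-definite correlation matrix if needed;
* phenotypic SDs are not published in the main text, so they are set once
  to plausible coefficients of variation for each trait type (≈ 8–30 % for
  size and yield traits, tighter for bounded scores and percentages);
* environmental correlations are a damped (halved off-diagonal) version of
  the genetic ones; `G = D_g r_g D_g` with `D_g = diag(sd_p·√h²)`, `E`
  analogously with `√(1−h²)`, `P = G + E`, so heritabilities are recovered
  exactly.

Consequences to keep in mind: the emulation reproduces the *structural*
behaviour of the published scenarios (exact gain achievement, higher
intensity after refinement, sign flips in correlated responses) but **not**
their numeric table values — e.g. on the emulation, S1 requires i ≈ 2.8
rather than the published 1.41, and holding moisture fixed in S1* while
delaying flowering by 44 days against an 0.85 genetic correlation pushes the
required intensity into infeasible territory. That is itself the kind of
diagnosis the framework exists to surface: a refinement that looks mild can
be unattainable under a plausible covariance structure. Passing tests on the
emulation therefore demonstrate the algebra and the Monte-Carlo consistency
of the machinery, not the reproduction of the original breeding-population
estimates. Table 1's heritabilities are broad-sense while the index algebra
treats `G` as additive; the simulator follows the source in conflating the
two rather than "fixing" it.

## Monte-Carlo validation

`simulate_population()` draws true breeding values from `N(0, G)` and adds
per-replicate residuals with covariance `E = P − G` (one seeded generator per
population; every stochastic function takes an explicit seed).
`realized_response()` truncation-selects the top `⌈pN⌉` genotypes on their
index scores and compares the selected group's mean breeding value against
the population mean. With phenotypes observed once per genotype (reps = 1),
selecting at the `p` for which `i(p) = σ_I` recovers `Q* = Gb` within
Monte-Carlo error — the package's acceptance tests check every trait at
N = 20 000 within 2 standard errors of the selected-group mean.
`estimate_covariances()` implements the classical clonal-replicate moment
decomposition (among-genotype covariance of clone means minus `E_hat/reps`;
pooled within-genotype covariance for `E`), and 50 seeded replicates of
N = 1000 × 4 clones verify elementwise unbiasedness within 3 standard
errors. Problem sizes were chosen so the full suite runs in well under a
minute while leaving the standard errors small relative to the responses
being checked.

## Numerical choices and degenerate inputs

* **Trait order is canonical**: the panel fixes it; file readers reorder
  matrices by label, never by position, and fail loudly on missing traits.
* **PSD handling**: eigenvalues within `tol · λ_max` of zero are clipped
  silently (they are numerical zeros); anything more negative errors unless
  `repair = TRUE`, which clips with a warning.
* **Rank-deficient `G*'P⁻¹G*`** is reported as "desired gains
  unattainable/degenerate" rather than silently pseudo-inverted.
* **Intensity inversion** bisects on the truncation threshold `z` rather
  than on `p` directly, keeping full relative precision in `p` for large
  intensities; intensities below the `p → 1` limit warn and return `p ≈ 1`.
* **Ties in truncation selection** break by stable genotype order, and an
  all-equal-scores population warns of degenerate selection.
* **Zero weight vectors** give `σ_I = 0`; a zero-mean trait cannot receive a
  percent-of-mean gain (error), though an absolute gain is fine.
* **Intensity printing** uses two decimals, but all derived quantities use
  the unrounded value; published-table comparisons are made on the selected
  fraction, which is insensitive to the upstream rounding that makes a
  printed `1.41` correspond to a tabulated `1.40` at p = 0.20.

## Known limitations

Single-generation, infinite-population truncation-selection theory: no
multi-stage or optimal-contribution selection, no relationship-matrix
generalization (candidates are assumed phenotyped directly), no non-normal
index distributions, no marker-level simulation (SNP effects, LD) and no
estimation of `G`/`P` from markers or pedigrees — matrices are inputs. The
monetization is a linear equivalence through the reference trait; it ignores
downstream effects such as improved bioconversion efficiency of modified
cell-wall composition, and no discounting or multi-year economics is
attempted.
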