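---
title: "Joint segregation analysis of stay-green traits with major-gene plus polygene mixture models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint segregation analysis of stay-green traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segmix)
```

## The problem

Stay green — delayed leaf senescence that keeps photosynthetic leaf area
alive through grain filling — is a quantitative maize trait with a major
impact on yield. Without marker data, the genetic architecture of such a
trait can still be inferred from the phenotype distributions of a structured
cross: two inbred parents (P1 stay-green, P2 non-stay-green), their F1, and
a selfed F2. In the F2, any large-effect ("major") gene segregates in
Mendelian ratios and leaves a visible signature — a multimodal phenotype
distribution — while many small-effect ("polygenic") loci blur each mode
into a normal component. `segmix` implements this joint four-generation
segregation analysis: a catalog of major-gene plus polygene inheritance
models, constrained normal-mixture maximum likelihood, AIC model selection
with goodness-of-fit screening, and genetic-parameter estimation, together
with a synthetic-population generator that reproduces the statistical
structure of the maize stay-green study populations (crosses T01 × Mo17 and
T01 × Xin3, two environments, six traits: VSG, GLNM, SPADS, SPADM, GLAD,
GYP).

## The model

Each inheritance model constrains a two-locus genotypic-value
parameterization. Writing `m` for the baseline, `da`/`db` for additive
effects, `ha`/`hb` for dominance, and `i`, `jab`, `jba`, `l` for
additive×additive, additive×dominance, dominance×additive and
dominance×dominance epistasis, the nine two-locus genotypic values are

```
G(AABB) = m + da + db + i      G(AABb) = m + da + hb + jab
G(AAbb) = m + da - db - i      G(AaBB) = m + ha + db + jba
G(AaBb) = m + ha + hb + l      G(Aabb) = m + ha - db - jba
G(aaBB) = m - da + db - i      G(aaBb) = m - da + hb - jab
G(aabb) = m - da - db + i
```

The pooled polygenic background contributes fixed offsets `[d]` and `[h]`
to the generation means (P1: `+[d]`, P2: `-[d]`, F1: `+[h]`, every F2
component: `+[h]/2`, the expected dominance contribution at heterozygosity
1/2; the expected additive polygenic deviation in the F2 is zero) and a
segregation variance `sigma2_pg` that inflates the F2 components only.
Generations are then

* P1, P2, F1: single normals with environmental variance `sigma2_e`;
* F2: a Mendelian mixture — weights (1,2,1,2,4,2,1,2,1)/16 over the nine
  genotypes for two-locus models, (1,2,1)/4 for one-locus models — with
  component variance `sigma2_e + sigma2_pg`.

A model is a set of linear constraints on this basis (for example `2MG-EA`
fixes `db = da` and zeroes dominance and epistasis; `2MG-CD` fixes
`ha = da`, `hb = db`). Components whose mean expressions coincide under the
constraints are merged with summed weights, exactly — `2MG-EA` collapses to
the binomial five-component mixture. The catalog holds 24 models: four
one-gene (`1MG-AD`, `1MG-A`, `1MG-EAD`, `1MG-NCD`), six two-gene, the
no-genetics null `0MG`, two polygene-only, four one-gene-plus-polygene and
seven two-gene-plus-polygene models; the ten codes reported by the study
are all present. The catalog is data-driven (one declarative table), so the
set can be edited without touching the fitting code.

For the `*-ADI` polygene class the pooled polygenic epistasis is realized
as two further fixed offsets `[i]` (entering P1 and P2, and nothing else in
expectation) and `[l]` (entering F1 fully and each F2 component with
coefficient 1/4). These models are deliberately overparameterized in their
mean structure (more free effects than distinct mean equations); the fitter
handles them with a minimum-norm least-squares step, and the least-squares
effect read-out refuses them with an explicit "confounded effects" error.

```{r catalog}
length(model_catalog())
genotype_means("2MG-EA", genetic_effects(da = 1, db = 1))$F2
```

## Fitting: constrained-mixture ECM

All four generations share one likelihood: single-normal terms for P1, P2,
F1 plus the log mixture density for every F2 plant. Maximization is an
expectation conditional maximization (ECM):

* **E-step** — posterior component memberships for each F2 plant;
* **CM-step (a)** — the free effect vector solves a generalized
  least-squares system across all generation/component mean equations
  (means are linear in the effects via the model's design matrix; each
  equation is weighted by its effective sample mass over its variance);
* **CM-step (b)** — closed-form variance updates: `sigma2_e` from the
  pooled within-component residuals, and for mixed models `sigma2_pg` as
  the extra F2 within-component variance, floored at zero (when the floor
  binds, `sigma2_e` reverts to the all-generation pooled estimate, which is
  the constrained joint maximizer).

Both CM-steps maximize the ECM Q-function exactly, so the observed
log-likelihood never decreases; the iteration stops when the change drops
below `tol` (default 1e-8) or after `max_iter` (default 2000) iterations.
Collapsing variances are floored at `1e-6` times the overall phenotypic
variance and flagged.

Mixture likelihoods of this kind are multimodal, and the difficult discrete
unknown is which Mendelian weight belongs to which phenotype cluster. The
fitter therefore combines several start families before polishing the best
few to convergence:

* ranked-quantile assignments (ascending and descending), refined by
  classification rounds until the component ordering is self-consistent;
* component-layout starts: k-means clusterings of the F2 over a range of
  cluster counts, with Mendelian weights matched to clusters by
  randomized-greedy mass matching (a cluster holding 5/16 of the plants
  plausibly hosts a 4/16 and a 1/16 component), each candidate layout
  polished by a short fixed-weight free-means EM and converted to an
  effect start by weighted least squares;
* `restarts` further randomized component orderings (default 10).

Because the two major loci enter the likelihood exchangeably
(`da<->db, ha<->hb, jab<->jba` permutes F2 components without changing any
generation distribution), fits are reported in the canonical orientation
`|da| >= |db|` — the field convention that the "first" major gene is the
larger one. This is applied through the exact symmetry, never by sorting
mixture components; component identities stay pinned to the design matrix.

`k` for AIC counts free mean parameters plus one for `sigma2_e` plus one for
`sigma2_pg` when present (`2MG-EA`: 3, `1MG-AD`: 4, `MX2-ADI-AD`: 13).

```{r fit-demo}
sc <- scenario("demo", "1MG-AD", genetic_effects(m = 0, da = 10, ha = 5),
               sigma2_e = 4, n = c(P1 = 10, P2 = 10, F1 = 10, F2 = 200),
               seed = 1)
fit <- em_fit(simulate_population(sc), "1MG-AD",
              em_options(restarts = 4, seed = 1))
fit
```

## Goodness of fit and model selection

Model adequacy is checked per generation on the probability integral
transform (PIT) scale: under a correct model the fitted-CDF values of the
observations are uniform on (0,1). Five statistics are computed:

* `U1^2`, `U2^2`, `U3^2` — Neyman smooth components on normalized shifted
  Legendre polynomials (departures in mean, spread and skewness of the PIT
  values), each `n * mean(pi_k(e))^2`, asymptotically chi-square with 1 df;
  flagged at 3.841;
* `nW^2` — the Cramér–von Mises statistic
  `1/(12n) + sum(e_(i) - (2i-1)/(2n))^2`, flagged at its asymptotic 5%
  point 0.461;
* `Dn` — the Kolmogorov sup-distance, with exact small-sample significance
  for `n < 35` and the asymptotic `1.358/sqrt(n)` threshold otherwise.

The original analysis tool names the three uniformity statistics but
nowhere prints their formulas; the smooth-component realization used here
matches their reported scale and chi-square-1 significance behaviour and is
validated by Monte-Carlo null calibration (rejection rates at the 5%
thresholds fall in [3.5%, 6.5%] under the true model at n = 200), not
asserted by citation.

Selection is two-stage: models within `delta` AIC of the minimum (default
2 — the study itself weighs several near-tied candidates per trait) are
candidates; among candidates the fewest significant statistics across all
four generations wins, ties broken by lower AIC.

## Genetic parameters

First-order effects are re-read from the fitted means by ordinary least
squares on the design matrix (identical to the EM effects for exactly
identified models). Second-order components decompose the F2 phenotypic
variance `sigma2_p` (sample variance, n−1):

```
sigma2_mg = sigma2_p - sigma2_pg - sigma2_e   (floored at 0)
h2_mg = 100 * sigma2_mg / sigma2_p            h2_pg = 100 * sigma2_pg / sigma2_p
```

`sigma2_e` here is the ML-fitted shared within-component variance, not the
pooled parental sample variance: back-computing the study's own tables
(e.g. TMF2 VSG: 25.66² − 631.67 − 10.32 ≈ 16.5) is consistent with the
fitted-variance convention and inconsistent with the printed parental
variances. Two published rows do not reconcile under any convention we
tried (TMF2 GLNM: 5.32/2.48² gives 86.5% against a printed 89.03%; TMF2
GLAD off by an order of magnitude in the same direction) and are treated as
probable typos rather than emulated.

## The synthetic-population generator

The raw field phenotypes were never deposited, so the generator *is* the
data source, parameterized by the published tables
(`study_summary_stats()`, `study_effects()`, `study_variance_components()`):

* one scenario per published best-model row; effects as printed;
* the baseline `m` anchored so the model's P1 mean reproduces the reported
  T01 mean (`m` itself is never published);
* `sigma2_e` = reported F2 variance − reported major-gene and polygene
  variances, floored at 1% of the F2 variance where the published
  components leave no room (TMF2 GYP: 26.60² < 707.77);
* F2 sizes follow the field design — 200 plants per population in E1, 400
  in E2; parents and F1 default to triplicates, the replicate count implied
  by the reported parent SD patterns (configurable upward, since n = 3
  makes parent-generation goodness-of-fit tests fragile).

P1/P2/F1 are drawn from their single normals; each F2 plant draws a
genotype from the Mendelian weights, then a normal deviate around its
component mean with variance `sigma2_e + sigma2_pg`. Under
dominance/epistasis the component means extend beyond the parental means
and the simulated F2 shows the bidirectional transgressive segregation seen
in the field data.

The published tables are not everywhere internally consistent: the printed
effect values do not always reproduce the printed F2 moments (the GYP rows,
for instance, print additive effects far too small to span the reported
parent gap), so simulated scenarios reproduce what the printed *parameters*
imply under the model, not the printed F2 summary statistics themselves.

What the generator does **not** emulate: correlations between traits (each
trait is simulated independently, so the trait-by-trait correlation
analysis on simulated data is a machinery demonstration with r ≈ 0, unlike
the positive trait–yield correlations in the field); genotype×environment
structure; field spatial effects; non-normal measurement error. Passing
tests on simulated data therefore validate the estimation machinery under
the model's own assumptions, not the biological claims.

## Derived traits

GLAD fits the per-plant green leaf-area time course with the logistic
`y(t) = a / (1 + exp(b + c t))` (unweighted Levenberg–Marquardt least
squares; self-start from the linearization `log(a0/y - 1) = b + c t` with
`a0 = 1.05 max(y)`, plus jittered restarts) and reports the daily mean area
over the 40 days after flowering:

```
GLAD = (1/40) * integral_0^40 a / (1 + exp(b + c t)) dt
     = [a*40 - (a/c) * (softplus(b + 40c) - softplus(b))] / 40
```

The closed form uses `softplus(x) = log(1 + exp(x))` evaluated
overflow-safely and agrees with adaptive quadrature to 1e-6 relative; at
`c = 0` the analytic constant limit `a/(1 + exp(b))` applies. The study's
text calls GLAD both a cumulative and a daily-average quantity; the
daily-average reading is used because the reported GLAD magnitudes
(~3000 cm²) match the parents' leaf areas, and the raw integral is exposed
as an attribute. VSG is `100 × area at maturity / area at flowering`;
values above 100% are permitted but flagged, since the study's summary
alternately defines the denominator as the maximum leaf area.

## Descriptive statistics

Summaries report the sample SD (n−1), `CV = 100·sd/mean`, and adjusted
Fisher–Pearson (SPSS-convention) skewness and excess kurtosis, matching the
conventions behind the published descriptive table. Parent comparisons use
Welch's t-test with significance letters — with only two parent groups the
published multiple-range letter display reduces to exactly this pairwise
test. Correlations are pairwise-complete Pearson with two-sided t-test
p-values and no multiple-testing correction (individuals with partial trait
records contribute per trait, not listwise).

## Numerical choices and limitations

* EM tolerance 1e-8 (absolute lnL change), 2000 iterations, 10 restarts by
  default; the analysis scripts and test suite use restarts 4–8, tolerance
  1e-6–1e-7 and F2 sizes of 200–400, which keep the full simulation studies
  at a few minutes on one CPU while leaving estimates well inside
  Monte-Carlo error of the converged values.
* Weights are exact binary fractions (sixteenths), so mixture weights sum
  to exactly 1 in floating point.
* The `MX2-ADI-*` mean structures are nearly saturated (11–13 free effects
  against 12 mean equations with only triplicate parents). At some
  published parameter values several F2 component means coincide almost
  exactly (TXF2 SPADM places three of the nine components within 0.01 of
  each other), leaving individual epistatic effects — `jba` in that case —
  on a likelihood ridge: quite different effect vectors fit within a
  fraction of a log-likelihood unit. Simulation recovery of such effects is
  information-limited, which shows up as inflated Monte-Carlo SEs and
  occasional sign-flipped solutions rather than as fitting failures.
* No linkage between the two major loci (independent assortment), no
  three-gene models, no standard errors on effects, and no Bayesian
  fitting.
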