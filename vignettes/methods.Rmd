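---
title: "Methods: pollen stoichiometry and trophic mismatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pollen stoichiometry and trophic mismatch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Elevated atmospheric CO2 (eCO2) tends to increase plant carbohydrate
production faster than the uptake of other elements, diluting nutrients in
plant tissues and products (the nutrient dilution hypothesis). For
palynivores — bees whose larvae are built entirely from pollen — any
increase in the carbon-to-element ratios (C:X) of pollen translates
directly into a poorer diet. This package implements a complete, testable
pipeline for quantifying that effect from elemental composition data of
pollen-bearing flowers collected in a free-air CO2 enrichment (FACE)
design: two CO2 treatments (ambient and ambient + 150 ppm), three arrays
per treatment, one sampled tree per array, with analytical subsamples
nested in trees. C, N and S are measured on small per-inflorescence
subsamples (6–10 per tree); the remaining nine elements (P, K, Na, Ca, Mg,
Cu, Zn, Fe, Mn) require more material and are measured on pooled
subsamples (3–5 per tree).

```{r setup}
library(pollenstoich)
```

# The trophic stoichiometric ratio

The core statistic is the trophic stoichiometric ratio,

$$\mathrm{TSR}_x = \frac{(C{:}X)_{\mathrm{food}}}{(C{:}X)_{\mathrm{consumer}}},$$

the dietary C:X of the food divided by the C:X of the matter the consumer
must synthesise (the adult body of the honey bee; adult body plus cocoon
for the red mason bee, whose cocoon is a major elemental sink). If the
consumer assimilates only a fraction $A_C$ of ingested carbon (losing the
rest to respiration) but all of element $x$, then food with
$\mathrm{TSR}_x \ge 1/A_C$ cannot supply $x$ at the rate carbon is
actually used, and $x$ may limit growth. With the conventional
$A_C = 0.25$, the limitation threshold is exactly 4; the boundary value
counts as limiting.

Assimilation of non-carbon elements is not actually perfect. The package
models imperfect assimilation of $x$ as
$\mathrm{TSR}^{\mathrm{adj}}_x = \mathrm{TSR}_x / A_x$: if only a fraction
$A_x$ of dietary $x$ is usable, the effective dietary C:X is inflated by
$1/A_x$. This is the simplest rule consistent with the interpretation of
$A_x$ as a usable fraction, and applying it with the conventional
sensitivity value $A_x = 0.75$ to the shipped reference TSR medians
(`reference_tsr_quartiles()`) reclassifies exactly three species-element
cases (red mason bee N under ambient CO2; honey bee P under ambient CO2
and S under elevated CO2) — the pattern the acceptance suite asserts.

```{r tsr}
assim <- assimilation_config()   # A_C = 0.25, threshold 4
comp <- generate_study(synthetic_study_config(), seed = 1)
food <- aggregate_food_ratios(compute_cx_ratios(comp))
bees <- consumer_profile(rbind(
  generate_consumers(synthetic_consumer_config("O_bicornis"), seed = 2),
  generate_consumers(synthetic_consumer_config("A_mellifera"), seed = 3)))
records <- compute_tsr(food, bees, assim)
head(summarize_tsr(records))
```

Design choices worth knowing:

* **Ratio basis.** C:X ratios default to the mass basis (concentrations
  are mass fractions); a molar basis is available and differs exactly by
  the atomic-mass factor $M_x / M_C$.
* **Ratio-of-means vs mean-of-ratios.** C:X is computed per subsample and
  then averaged per array, preserving the subsample-level pairing of C
  and X. Because C is not measured on the pooled subsamples, C:X for the
  nine pooled elements pairs each subsample's X with the array-mean C
  (recorded per row in `c_source`); N and S pair within subsample.
* **Cross product.** TSRs form the full cross product of array-level food
  ratios (3 per treatment) and consumer replicates (30 for the red mason
  bee, 45 for the honey bee), giving 90 and 135 values per treatment and
  element. These are not independent observations; see the treatment
  comparison below.
* **Unit conversion** uses 1 % dry mass = 10,000 mg/kg, with the
  conversion direction chosen so percent → mg/kg → percent round-trips to
  machine precision.

# Treatment comparison of TSR distributions

`compare_treatments()` applies the Mann–Whitney test per species and
element. The statistic is the number of pairs with $x_i > y_j$ (half per
tie); for small untied samples ($\min(n) \le 8$) the null distribution is
computed exactly by the rank-sum counting recursion (equivalent to
enumerating all assignments), otherwise a normal approximation with
tie-corrected variance and continuity correction is used. Because the
cross-product values share only three food arrays per treatment, the
subsample-style test overstates the effective sample size; the package
therefore also reports an array-level variant on per-array mean TSRs
(n = 3 vs 3), without asserting that either is "the" correct test.
Significance tiers default to the conventional 0.05/0.01/0.001.

# Whole-composition comparison

Because no single subsample carries all 12 elements, the default
multivariate table (`composition_matrix(..., element_set = "merged")`)
takes the pooled subsamples as rows (matching the residual degrees of
freedom of a 23-sample analysis) and attaches each array's mean C, N and
S; `"pooled9"` (nine measured columns only) and `"cns"` are available.
Note the merged fill-in makes rows within an array share values, i.e. the
rows are not exchangeable — which matters for permutation inference (see
calibration below).

Elements are measured on wildly different scales, so profiles are
normalised per element before computing dissimilarities. The default is
min–max scaling to [0, 1]: z-scores produce negative values that break
Bray–Curtis, so that combination is rejected with an informative error
(z-score + Euclidean is offered as an alternative configuration).

* **PERMANOVA** partitions squared Bray–Curtis dissimilarities between
  and within treatments; the p-value permutes labels freely with the +1
  convention, and an exact mode enumerates all permutations for small n.
* **NMDS** minimises Kruskal stress-1 by alternating isotonic regression
  of configuration distances on dissimilarity ranks (ties broken by
  configuration distance, Kruskal's primary approach) with a
  Guttman-transform update. The first start is the metric
  principal-coordinates solution, the rest random; defaults are 20
  restarts, 300 iterations, tolerance 1e-6. Non-convergence flags the
  result instead of failing. Reported stress is the best across restarts,
  hence non-increasing in the number of restarts.
* **Environmental fitting** regresses each (centred) variable on the two
  ordination axes; arrows are unit coefficient directions scaled by
  $\sqrt{r^2}$, with permutation p-values.

Bray–Curtis is a semimetric (the triangle inequality can fail); nothing
in the pipeline assumes otherwise.

# Per-element mixed models

Each element concentration and the C:N, C:P and N:P ratios are modelled
as `response ~ CO2 treatment + (1 | array)` by REML. The observation unit
is the analytical subsample; a further subsample-level random intercept
would be confounded with the residual, so a single array-level intercept
is used — the treatment test is unchanged either way, with between-within
Wald degrees of freedom `n_arrays - 2` (4 in this design) for the CO2
effect and `n_obs - n_arrays` for the intercept.

Transforms default to the study's choices — Box–Cox for C, N and C:N
(profile-likelihood $\lambda$ on a [-2, 2] grid, step 0.01, ties broken
toward $\lambda = 1$), log for Mn, identity otherwise — and can be
re-pinned per response or selected automatically by Shapiro–Wilk W
(`transforms = "auto"`). Estimates for transformed responses are reported
on the transformed scale, with original-scale group means attached.
Shapiro–Wilk normality and a Brown–Forsythe spread comparison of
standardised residuals are reported but never used to auto-reject a fit;
singular fits (array variance estimated at zero) are retained and
flagged. Marginal and conditional $R^2$ follow the variance
decomposition $R^2_m = \sigma^2_f / (\sigma^2_f + \sigma^2_r +
\sigma^2_e)$ and $R^2_c = (\sigma^2_f + \sigma^2_r) / (\sigma^2_f +
\sigma^2_r + \sigma^2_e)$. No multiple-testing correction is applied;
p-values are reported raw.

# What the synthetic generator emulates — and what it does not

`generate_study()` draws the full hierarchical design: per array and
element an array effect $\mathcal{N}(0, \sigma_{\mathrm{array}})$ shared
by all the tree's subsamples, plus independent residual noise, truncated
at zero, with C/N/S on 6–10 per-inflorescence subsamples and the other
nine elements on 3–5 pooled subsamples per tree. Ambient means and
additive eCO2 effects default to the study conditions (e.g. S 0.21 %
with effect −0.02; K 19,254 mg/kg with effect −1,568.7; Fe 118.19 mg/kg
with effect −20.66; C and N use the reported concentration ranges'
midpoints, 49.7 % and 4.75 %, with small positive effects consistent with
the null C:N result; Mn is back-transformed from its log-scale fit).

The array and residual noise magnitudes are not published. They are set
once to 10 % and 1.5 % of the ambient mean respectively, chosen so the
array level dominates the variance and the fitted models reproduce the
qualitative pattern of the study's Table-1-style output — conditional
$R^2 > 0.9$ for every response with low-to-moderate marginal $R^2$ —
with enough margin that the REML variance estimate's sampling noise at
six arrays (which can easily halve a realised variance ratio) does not
break the pattern. With these defaults the CO2 effect on S has a
standard error near 0.012, so the design detects it only in a minority
of runs: the generator honestly reproduces the power limits of a
3-arrays-per-treatment design rather than guaranteeing the study's
significant S result.

Elements are generated independently (no cross-element covariance) and
noise is additive Gaussian; real compositions have correlated elements,
skewed trace-metal distributions and analytical error structure none of
which the generator claims to capture. Passing tests therefore validate
the pipeline's arithmetic and statistical calibration, not distributional
realism.

Consumer profiles are lognormal around per-element medians (log-scale SD
0.1, about 10 % CV, a typical replicate-to-replicate spread for body
stoichiometry). Default medians are back-calculated
(`back_calculate_consumer_medians()`) so that TSRs of the default
ambient food reproduce the shipped reference TSR medians; the reference
table is a stand-in for the published bee composition datasets, which are
external to this package.

# Statistical calibration

The acceptance suite (`tests/testthat/test-acceptance.R`) verifies, at
sizes chosen to keep a full run in a few minutes:

* PERMANOVA agrees exactly with a brute-force enumeration oracle for
  n ≤ 8, and the Mann–Whitney exact path with full enumeration of rank
  assignments.
* Under zero treatment effects, rejection rates at $\alpha = 0.05$ over
  300 seeded runs fall in [0.02, 0.09] for both PERMANOVA and the LMM.
  The two tests are calibrated against their own nulls: the LMM on the
  hierarchical design (it models the array variance), but PERMANOVA on
  data with zero array variance and the pooled-only element set, because
  free permutation of subsample labels is exact only under
  exchangeability. Running the PERMANOVA calibration on clustered null
  data instead measures the pseudoreplication inflation of
  subsample-level permutation (rejection near 0.75 under the default
  variance settings) — a caveat that applies equally to any
  subsample-level permutation analysis of this design.
* The generating S effect (−0.02 % dry mass) is covered by the LMM's 95 %
  CI in ≈95 % of 200 seeded replicates.
* The default generator yields $R^2_m \le R^2_c$ with $R^2_c > 0.9$ for
  all 15 responses.

# Degenerate inputs and numerical conventions

Zero denominators in ratio computation exclude the row with a warning
(and a record in the run log) rather than dropping it silently; missing
carbon is an error. Constant element columns cannot be min–max scaled and
raise an error naming the element. A constant response produces a
flagged degenerate LMM fit with zero variance components rather than an
error. PERMANOVA with perfect within-group separation reports an
infinite pseudo-F consistently in observed and permuted statistics.
All randomised procedures (generator, permutation tests, NMDS restarts)
take explicit seeds, which are logged; a pipeline run is reproducible
byte-for-byte from its serialised configuration and seed.

# Running the pipeline

```{r pipeline, eval = FALSE}
res <- run_pipeline(list(
  seed = 1,
  output_dir = "run1",
  extra_a_x = 0.75))   # adds a limiting_at_75 column to the summary
res$permanova
head(res$table1)
```

The run directory contains the subsample and array-level ratio tables,
the PERMANOVA JSON, ordination coordinates and fitted vectors, the
coefficient table, TSR records, quartile summaries, treatment
comparisons and boxplot statistics (with the threshold line), the
serialised configuration and a JSON-lines log recording seeds, versions,
excluded rows and degenerate-fit flags.

# Known limitations

* The TSR treats the consumer's elemental demand as fixed targets;
  physiological plasticity in assimilation is reduced to the scalar
  $A_x$.
* Subsample-level multivariate inference inherits the design's
  pseudoreplication; the package reports array-level alternatives but
  cannot manufacture replication the design lacks.
* The generator's independence and Gaussian assumptions are pragmatic
  defaults, not estimates; array/residual variance magnitudes are
  assumptions documented above.
* Only two-group (ambient vs elevated) designs are supported throughout.
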