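---
title: "Methods: models, defaults and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, defaults and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(upho)
```

This vignette is the package's own account of its methods: what each stage
assumes, which knobs matter, which numerical choices were made where the
design was genuinely open, and what the synthetic experiments do and do not
show about real data.

## The synthetic tract generator

`generate_tracts()` emulates census-tract tables of the kind distributed as
CDC 500 Cities crude-prevalence estimates joined to ACS/USDA SDoH variables:
an 11-digit tract FIPS `geoid`, a percent-scaled outcome (`obesity_prev`),
six percent-scaled SDoH/behavioural features, one count
(`low_access_supermarket`) and one rate (`crime_rate`). Default marginal
means and SDs are the summary statistics reported for the n = 178 Memphis,
TN census tracts this setting models (the geoid prefix `47157` is Shelby
County); the default crime marginal uses the full-sample summary
(mean 350.20, SD 126.26).

**Dependence structure.** The features are drawn from a latent Gaussian
copula with a single-factor correlation matrix: feature *j*'s latent loading
is `2 sin(pi * rho_j / 6)`, the latent Pearson value whose Gaussian copula
reproduces a Spearman correlation of `rho_j`. The `rho_j` defaults are the
reported feature-outcome Spearman coefficients (0.92 physical inactivity,
0.83 poverty, 0.81 education, 0.77 Black population share, 0.73
unemployment, 0.37 supermarket access, 0.37 crime). No coefficient is
reported for lack of insurance (it is dropped from the published
multicollinearity table), so its default target is set once at 0.60, a
plausible value for an SDoH strongly tied to poverty. A one-factor structure
is always positive semi-definite, so the copula needs no repair for the
defaults; arbitrary user targets are repaired via `Matrix::nearPD` and
rejected if the repair moves the matrix by more than 0.1.

**Outcome model.** The outcome is linear:
`y = intercept + sum(w_j x_j) + N(0, sigma)`, clipped to [0, 100]. When the
user does not supply weights, they are derived in closed form so that the
configured rank-correlation targets hold for the *outcome itself*: in latent
standardized space `w = R^{-1} r` and `sigma_std = sqrt(1 - r' R^{-1} r)`,
which makes `cor(x_j, y) = r_j` exactly on the latent scale. Two
consequences are documented rather than hidden:

- The derived default noise is not small (about 1.96 percentage points,
  true-model R² ≈ 0.94) — it is whatever the correlation targets imply.
- The derived |weight| ordering follows `r_j / (1 - r_j²)`: physical
  inactivity > poverty > education > Black population > unemployment >
  insurance > access = crime. This ordering was chosen over hand-picked
  weights because it makes the correlation contract testable
  (`Spearman(poverty, y) ≈ 0.83` at large n is a checked property); the
  price is that two adjacent mid-ranked features swap relative to the
  dataset-level importance ordering observed on the real extract, and the
  two weakest features tie.

**Clipping.** Margins are clipped after rescaling (percents to [0, 100],
counts/rates to ≥ 0) and the outcome after noise addition. Clipping
guarantees the record invariants but slightly biases extreme margins (the
Black-population margin loses about 6% of its SD to the cap at 100) and
makes the rank-correlation targets approximate near clipped tails; the
checked tolerance is ±0.05 at n = 10000. With zero noise and no clipping
active, OLS recovers the generating weights to 1e-6 — the generator is
exactly linear.

**What passing tests do not show.** The generator is Gaussian, single-factor
and linear. Real tract data have skewed margins, spatial autocorrelation,
multi-factor dependence, and a nonlinear outcome surface; recovery results
here certify the pipeline's statistical machinery, not its adequacy for any
particular real extract.

## The analytics pipeline

`run_analytics()` executes, in order:

1. **Spearman screening.** `rho` is the Pearson correlation of midranks; the
   p-value uses the t approximation with n − 2 degrees of freedom (checked
   against the exact permutation distribution at n = 8, where it agrees
   within 10% at moderate effect sizes). Features with p above
   `significance_alpha` (default 0.05, configurable; no standard choice is
   dictated by the problem) are dropped.
2. **VIF filter.** `VIF_j = 1 / (1 − R²_j)` from regressing feature *j* on
   the others with intercept; exact collinearity yields `Inf`. Features with
   VIF > 10 (the conventional cutoff) are removed, input order preserved.
3. **Split and standardization.** Training size is `round(n × 0.85)`
   (half-up, so 178 tracts give 151/27); features are centred and scaled by
   *training* statistics only; the outcome stays in percent units so
   predictions and attributions read as percentage points.
4. **Grid-searched ε-SVR.** Linear kernel,
   `½‖w‖² + C Σ max(0, |resid| − ε)`, solved by libsvm (via e1071) at
   tolerance 1e-6. The degenerate zero-loss case (outcome range ≤ 2ε) is
   solved directly as w = 0, b = midrange — the minimum-norm optimum. The
   default grid C ∈ {0.25, 0.5, 1, 2, 4}, ε ∈ {0.01, 0.1, 0.2, 0.5} spans
   under- to over-regularization on standardized features; no canonical grid
   exists for this problem, so it is deliberately small and symmetric around
   C = 1. Folds are contiguous blocks of a seeded shuffle, remainder rows
   one per leading fold; ties in mean CV RMSE break toward smaller C, then
   smaller ε, so the search is fully deterministic. Tests verify the fitted
   solution against an independent dual quadratic-program solve
   (kernlab::ipop), requiring a relative duality gap below 1e-6.
5. **Evaluation.** RMSE and R² = 1 − SS_res/SS_tot about the sample mean.
6. **Importance.** Raw importance is |w_j| in standardized space — for a
   linear kernel this is the model's own effect size per feature-SD, and is
   exactly reproducible (permutation or wrapper-based importances would add
   simulation noise without adding information for a linear model). Scaled
   importance is min–max rescaled with the ratio computed before the
   multiplication by 100, so the extremes are exactly 0 and 100; equal raw
   importances give all-zero scaled values with a warning.
7. **Attribution.** For a linear model with features imputed independently
   at the background mean, the Shapley value has the closed form
   `phi_j = w'_j (x_j − mean(bg_j))` with `w'_j` the weight in natural
   units. The background set is the *full* input table (the natural
   "regional average" a dashboard would compare against); tests verify
   equality with exhaustive coalition enumeration at p = 8 to 1e-9.

## The knowledge graph and reasoner

Concepts live in six namespaces (disease, SDoH/behaviour, geography, health
indicators, risk factors, observatory entities) with an acyclic `isA`
hierarchy containing exactly the concepts the pipeline uses. Typed literal
nodes carry a tract's metric values, keyed by (tract, metric concept) so
equal values never collide; `measures` axioms link metric concepts to the
risk-factor concepts they quantify.

The reasoner is negation-free, set-semantics forward chaining, so the least
fixpoint is unique and rule order cannot change the derived triple set (a
tested property). Every inferred triple records its rule and antecedent
triple ids; `replay_derivation()` walks chains down to asserted/data/ml
facts, which is what the edge explanations render. When a triple is
derivable several ways, the first derivation under (rule order, triple-id
order) iteration is kept for stable output. The three ground domain axioms
are encoded as zero-antecedent rules (their consequents assert
unconditionally), and three bridging rules derive exposure
(residence + typed metric + `measures` link), risk (exposure + `leadsTo`),
and screening (risk + `isRiskFactorOf`) — the smallest rule set under which
the demonstration scenario's derivations follow mechanically. The risk
derivation necessarily passes through an `atRiskOf` intermediate; it is kept
in the graph as documented, explainable knowledge. Exposure fires on the
mere presence of a metric by default; `default_rules(exposure_threshold =)`
adds a numeric guard for users who want exposure only above a cutoff, since
no principled universal threshold exists.

ML enrichment adds `isPredictorOf` edges for the top-5 features by scaled
importance (weight = scaled/100 ∈ [0, 1]) at the metric-concept level —
prediction is a dataset-level statement, not a per-tract one. Whether the
Black-population metric (or any other) enters is decided by the importance
ranking, never hard-coded.

## Pathways, scores and explanations

Pathways are depth-first enumerations constrained to registered metapath
templates (default maximum length 6 edges). The published template notation
elides the literal-typing hop, so the registered sequences include the
explicit `isA` step (e.g. livesIn → has → isA → isPredictorOf →
isHealthIndicatorFor). The score is the product of *ML-edge* weights with
all other edges counting 1: data-provenance `has` edges carry raw metric
values (e.g. 49) as weights, which are measurements rather than confidences,
so including them would break the score's [0, 1] interpretation. A pathway
mixing ML and semantic edges is labelled evidence `"both"`. Ties in score
break by the lexicographic node-id sequence, keeping output deterministic.

Explanations render numbers to one decimal place, always from the stored
literal (never recomputed), and record every number appearing in the text in
a `values` field. Recommendations are one per inferred screening triple plus
one per traced pathway (intervention framing on its risk factor),
deduplicated, screening first then pathways by score.

## Problem sizes and experiments

The ranking-recovery experiment (`importance_recovery_experiment()`) runs
100 replicates of the full pipeline at the default n = 178 tracts with
strictly ordered generating standardized weights
(4.5, 3.5, 2.6, 1.9, 1.1, 0.65, 0.35, 0.1 percentage points per feature-SD)
and noise SD 0.5 points. The gaps are set large relative to coefficient
sampling error at this n — including the clipping-induced shrinkage of the
Black-population margin — because the experiment certifies that the pipeline
*can* recover a recoverable ordering, not that any ordering is recoverable;
with these conditions the observed recovery is 100/100 with test R² ≈ 0.998.
Property tests on the reasoner use 50-triple random graphs; the exact
Shapley and permutation oracles run at p = 8 and n = 8, the largest sizes
where exhaustive enumeration stays instant.

## Known limitations

- Patient-level analysis is neighborhood-proxy analysis: the patient
  inherits tract-level exposures, which is the design's stated scope, not an
  approximation error the software can remove.
- Only the linear kernel is supported; importance and attribution formulas
  are exact *because* of linearity and would not transfer to nonlinear
  kernels.
- The concept scheme is a minimal stand-in: it contains the concepts the
  pipeline needs and no OWL/RDF semantics beyond the explicit `isA` DAG.
- Only the causal-pathway-analysis aim, the census-tract granularity and the
  obesity-prevalence outcome are implemented; other dashboard selections are
  rejected with explicit messages rather than silently approximated.
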