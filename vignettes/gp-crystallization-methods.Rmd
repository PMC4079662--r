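---
title: "Methods: Gaussian-process models of crystallization screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Gaussian-process models of crystallization screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xtalgp)
```

This vignette documents the statistical and numerical methods behind
`xtalgp`: the feature definitions, the Gaussian-process regression and
classification models, the mechanism and contact analyses, and the synthetic
screen generator used to validate everything end to end. It is a methods
reference; the README gives the quick tour.

## 1. Feature definitions

### 1.1 Protein features (89 dimensions)

`structure_feature_vector()` computes, from a parsed PDB structure:

- **Surface residue fractions** (20): the fraction of *surface* residues of
  each amino-acid type. A residue is "surface" when its Shrake–Rupley SASA is
  at least 2.5 Å² (inclusive threshold, adjustable).
- **Category fractions** (5, in the fixed order small, positive, negative,
  polar, hydrophobic): residues are assigned to one of five physico-chemical
  categories (`residue_categories()`), and the surface fraction of each
  category is reported.
- **Neighbouring-pair fractions** (15): for every unordered pair of
  categories, the fraction of sequence-adjacent surface residue pairs whose
  categories match. Pair names are order-normalized (`pair_S_P`, never
  `pair_P_S`).
- **Exposure-weighted variants** (40): the same 20 + 5 + 15 quantities,
  prefixed `w`, where each residue contributes proportionally to its SASA
  rather than with unit weight. This up-weights the most solvent-exposed
  residues, which dominate intermolecular contacts.
- **Global descriptors** (9, fixed order): isoelectric point `pI` (bisection
  on the Henderson–Hasselbalch net charge), total `SASA`, radius of gyration
  `Rg`, hydropathy `GRAVY`, side-chain conformational entropy `SCE`, polarity
  `POL`, and the surface-weighted variants `sGRAVY`, `sSCE`, `sPOL` (scale
  averages over surface residues only).

SASA uses the Shrake–Rupley method with a Fibonacci lattice of 960 sphere
points per atom, a 1.4 Å water probe, and Bondi van der Waals radii. The
Fibonacci quadrature is accurate to well under 1% for typical burial patterns
but is not exactly mirror-symmetric; tests tolerate ~1% asymmetry.

### 1.2 Cocktail features (61 dimensions)

A cocktail is a named molarity vector over the species registry
(`build_registry()`: 19 cations, 24 anions, 13 PEGs; 56 species total) plus a
pH. `cocktail_feature_vector()` appends five derived quantities:

- **Ionic strength** `IS` = ½ Σ cᵢ zᵢ², summed over dissociated ions.
- **Hofmeister sums** `HSpos`, `HSneg`: each ranked ion gets a coefficient
  h = 1 − 2(rank − 1)/(r_max − 1), linearly mapping the Hofmeister series onto
  [+1 (kosmotrope), −1 (chaotrope)]; the feature is Σ cᵢ hᵢ per ion sign.
  Ions without a literature rank sit at the series midpoint (h = 0) and a
  message notes the fallback.
- **Depletion coefficient** `DEP` = Σ c (1 + R_dep/Rg)³ over PEG species,
  with polymer radius R_dep = 12.1·(M/1000)^0.588 Å from the molar mass M.
  This is the excluded-volume strength a polymer of that size exerts on a
  protein of radius of gyration Rg — the one place where protein and cocktail
  information mix, so cocktail featurization takes an `Rg` argument.

## 2. Propensity regression

### 2.1 Model

Per-protein crystallization propensity π ∈ [0, 1] is the fraction of screened
cocktails yielding crystals. We regress the transformed target
f = sign(π)·√|π| (in practice √π; `prop_transform`/`prop_inverse`) on
z-scored protein features with a zero-mean GP and anisotropic squared
exponential kernel

k(x, x′) = σ_f² exp(−½ Σ_d (x_d − x′_d)²/ℓ_d²) + σ_n² δ,

one length scale ℓ_d per input dimension (automatic relevance determination).
The square-root transform stabilizes the binomial variance of the observed
fraction and keeps the inverse map simple.

### 2.2 Training

Hyperparameters maximize the log marginal likelihood by conjugate-gradient
`optim` with the analytic gradient ½ tr((ααᵀ − K⁻¹) ∂K/∂θ), α = K⁻¹y.
Because the LML surface is multimodal — a "memorization" mode with tiny
length scales and near-zero noise competes with the smooth mode — training
restarts from random draws: log-length-scales from a Beta(0.5, 0.5) stretched
over [log 0.05, log 20] (favouring the edges of the box), keeping the best
converged optimum. Cholesky factorizations get a jitter ladder (increasing
diagonal inflation on failure). Twenty restarts are enough to find the smooth
optimum reliably at n ≈ 200; five are not, and the memorization mode then
pins irrelevant length scales near the lower box edge.

### 2.3 Relevance and validation

- **Relevance**: small ℓ_d ⇒ the output varies quickly along dimension d ⇒
  relevant. `significant_variables()` flags dimensions with
  ℓ_d ≤ √(ℓ_min·ℓ_max), the geometric midpoint of the observed range —
  *after clipping all length scales to the search box*. Beyond the box a
  z-scored dimension is already indistinguishable from inert, and without
  clipping a single runaway ℓ (e.g. 10⁶) inflates the midpoint enough to
  drag inert dimensions below it.
- **Leave-one-out**: with K⁻¹ in hand, LOO means and variances are closed
  form: μᵢ = yᵢ − αᵢ/[K⁻¹]ᵢᵢ, σᵢ² = 1/[K⁻¹]ᵢᵢ — no refitting. The test
  suite verifies this against literal n-fold refits.
- **Linear baseline**: `compare_with_linear()` fits a ridge regression on the
  same inputs and reports the fraction of proteins where the GP's LOO
  absolute residual is smaller. On a genuinely linear truth this fraction
  hovers near ½; on a curved truth it rises well above.

## 3. Condition classification

Per-experiment outcomes (crystal / no crystal for one protein across all
cocktails) are modelled with a probit GP classifier on the 61 cocktail
features, made sparse in the informative-vector-machine style:

1. **Active set selection**: greedily add the training point whose
   assumed-density-filtering update most reduces posterior entropy, until
   `d_active` points are selected (default min(n, min(500, max(⌈n/10⌉, 20)))).
2. **EP refinement**: several expectation-propagation sweeps over the active
   set, recomputing the full posterior each sweep for numerical robustness.
3. **Prediction**: standard probit-GP predictive probability
   P = Φ(μ*/√(1 + σ*²)).

With the active set equal to the full training set the procedure converges to
dense EP; the test suite checks agreement with a from-scratch textbook EP
implementation to 0.02 in predicted probability, and symmetry under label
flips.

### Response curves

`additive_response_curve()` sweeps one additive's concentration over a grid
(log-spaced via `make_conc_grid`, anchored at the training distribution's 95th
percentile), rebuilding the full cocktail feature vector at each point —
including the derived IS/Hofmeister/DEP features — and records the predicted
probability. `fit_quadratic()` summarizes the curve with an OLS quadratic and
classifies it as interior-max, interior-min, or monotone; monotone-decreasing
(purely suppressive) additives are flagged excluded. Prediction outside the
training concentration range triggers a warning: the GP reverts to its prior
there and the curve is not interpretable.

## 4. Mechanism analysis

Two physical routes to crystallization motivate the analysis: an **entropic**
route (low surface side-chain entropy → cheaper to immobilize surface residues
in a lattice, favoured by PEG-driven depletion) and an **electrostatic** route
(charge-mediated contacts, favoured by salt screening).

- `assign_quadrants()` splits proteins at the medians of the surface
  hydropathy (sGRAVY) / surface side-chain entropy (sSCE) plane;
  `quadrant_orientation` controls which quadrant is labelled Q1.
- `enrichment_tables()` runs two-sample Kolmogorov–Smirnov tests of each
  feature between the easiest and hardest crystallizers within a quadrant.
  The KS statistic is the exact ECDF sup-difference (tie-aware); the p-value
  uses the asymptotic Kolmogorov distribution with the effective sample size
  n₁n₂/(n₁+n₂). Quadrants too small for the asymptotics are reported with a
  message rather than a p-value.
- `hotspot_search()` takes the fitted propensity GP, restricts to the
  significant composition features, and grid-searches perturbations around the
  top-percentile proteins, renormalizing compositions to the simplex
  (`enforce_composition`) so the search never leaves feasible space. The
  result ranks candidate composition moves by predicted propensity gain.

## 5. Crystal contacts

`expand_symmetry()` applies the structure's Cartesian symmetry operators
combined with ±1 unit-cell translations (27 lattice shells), excluding the
identity-with-zero-shift copy, and prunes copies whose bounding boxes are
further than the contact cutoff plus a margin from the reference copy.
`contact_residues()` marks a surface residue as a crystal contact when any of
its atoms lies within the cutoff (default 5 Å) of any atom of a neighbouring
copy. `contact_profile()` reports the category and category-pair composition
of the contact set, and `contact_enrichment()` compares profiles across
protein groups. A rigidity property is tested to 10⁻⁹: applying a rotation +
translation operator must preserve all intramolecular distances.

## 6. Synthetic screens with planted truth

Real screen outcomes are expensive; the generator provides unlimited
screens with known answers.

- **Proteins**: surface compositions are Dirichlet draws around realistic
  amino-acid frequencies; pair fractions follow a category-product model with
  multiplicative Gamma noise; global descriptors are recomputed from the
  composition so the feature identities (e.g. sSCE as a scale average) hold
  exactly in the synthetic data.
- **Truth**: the latent propensity depends on exactly five features (sSCE,
  sGRAVY, cat_S, cat_P, pair_pos_neg) through two Gaussian bumps — an
  entropic bump (low sSCE, high cat_S) and an electrostatic bump (high sSCE,
  high cat_P and pair_pos_neg) — mapped through a probit link. An alternative
  `latent = "linear"` truth is linear *in the regression target* √π, giving a
  correctly specified null for the GP-versus-linear comparison.
- **Cocktails**: a mixture of salt-dominated recipes (1–2 salts, 0.3–2.5 M)
  and PEG recipes (one PEG at 5–30 %w/v, usually with a low salt), pH from a
  truncated normal on [3, 11].
- **Outcomes**: per-well Bernoulli draws whose success probability tilts the
  protein's propensity toward salt-rich wells for electrostatic-mechanism
  proteins and PEG-rich wells for entropic ones. The tilt is centred over the
  realized cocktail panel and amplitude-limited so each protein's *marginal*
  propensity equals its planted value exactly; observed propensities then sit
  within binomial noise of truth.

Default problem sizes (182 proteins × 1,536 cocktails for the full analysis,
smaller for unit tests) were chosen to be large enough for ARD recovery to be
reliable and small enough that the full pipeline runs in minutes on one core.

## 7. Numerical choices, in one place

| Choice | Value | Why |
|---|---|---|
| SASA sphere points | 960 (Fibonacci) | <1% quadrature error |
| Probe radius | 1.4 Å | water |
| Surface threshold | 2.5 Å² (inclusive) | separates buried from exposed in toy and real structures |
| GP length-scale box | [0.05, 20] (log) | z-scored inputs; beyond 20 ≈ inert, below 0.05 ≈ memorization |
| Restarts | 20 (full fits), fewer in tests | multimodal LML |
| Jitter ladder | 1e-10 … 1e-4 | Cholesky robustness |
| Relevance rule | ℓ ≤ √(ℓ_min ℓ_max) on box-clipped scales | robust geometric midpoint |
| EP agreement tolerance | 0.02 | probit probabilities, dense vs sparse-with-full-active-set |
| Contact cutoff | 5 Å | typical heavy-atom contact distance |
| KS p-value | asymptotic, effective n | exact tie-aware D |

## 8. Reproducibility

Everything is seeded: the generator (`synthetic_screen_spec(seed=)`),
restart draws (`gpr_train(seed=)`), active-set tie-breaking
(`ivm_fit(seed=)`), and the pipeline (`default_run_config()$seed`). The
pipeline writes a manifest of MD5 sums and a cleaned copy of its
configuration, so a rerun can be verified byte for byte. The
`scripts/acceptance.R` script recomputes the headline validation quantities
as JSON from a single `--seed`.
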