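---
title: "Phylogenetic evolutionary allometry of turtle shell and limb size: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic evolutionary allometry of turtle shell and limb size: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carapace)
```

## The problem

Turtles carry a bony shell whose straight carapace length (SCL, mm) is the
standard body-size proxy for the group: it is measurable on live animals,
museum skins, skeletons and fossils alike. Many fossil turtles, however,
are known only from isolated limb bones. Because the humerus and femur (the
stylopodia) are identifiable at low taxonomic levels, a calibrated scaling
relationship between stylopodial length and SCL turns such fragments into
body-size estimates. `carapace` implements the statistical machinery for
this programme: phylogenetic regression of log-transformed trait pairs,
model selection among candidate models with binary ecological or clade
covariates, bootstrap uncertainty, evolutionary-rate estimation, the
specimen-level maturity filter that guards the species means against
ontogenetic allometry, and the resulting prediction equations.

## The model

For species-level mean traits on the log10 scale, the working model is a
generalised least squares regression

$$y = X\beta + \varepsilon, \qquad
  \varepsilon \sim \mathcal{N}\!\left(0,\; \sigma^2 V(\lambda)\right),
  \qquad V(\lambda) = \lambda C + (1-\lambda)\,\mathrm{diag}(C),$$

where `C` is the phylogenetic variance–covariance matrix of the dated tree
(entry *ij* = depth of the most recent common ancestor of tips *i* and
*j*; diagonal = root-to-tip path length). Pagel's λ rescales the shared
(off-diagonal) covariances: λ = 1 is evolution of the residuals by Brownian
motion along the tree, λ = 0 is phylogenetic independence, and intermediate
values interpolate. λ is estimated *jointly* with the coefficients by
maximum likelihood: the profile log-likelihood is evaluated on a grid
(default step 0.01 on [0, 1]) and refined by golden-section search between
the winning grid point's neighbours, with ties broken toward the smaller λ.
σ² is the ML residual rate `r'V⁻¹r/n`; because branch lengths are in Myr it
reads as variance accumulated per million years, the natural scale for
comparing evolutionary rates across traits and clades.

Estimation is full ML rather than REML because the package's model
comparisons (AICc) cross models with different fixed effects. Reported
coefficient standard errors apply the unbiased rescaling `n/(n-k)` and
p-values use Student's t with `n - k` degrees of freedom; the AICc
parameter count is the number of regression coefficients plus one for σ²
plus one for λ when it was estimated (for OLS fits λ is not a parameter).
This counting convention is recorded in every fit object (`k_aicc`) since
published tables rarely state theirs; comparisons within a model set are
therefore internally consistent even if not bit-identical to any particular
external software.

Numerically, writing `D = diag(C)` and `K = D^{-1/2} C D^{-1/2}`, the
covariance factorises as `V(λ) = D^{1/2}(λK + (1-λ)I)D^{1/2}`, so one
symmetric eigendecomposition of `K` (done in compiled code) makes every λ
evaluation a weighted least-squares problem costing O(nk²). This is what
makes profiling λ finely — and re-estimating it inside every bootstrap
replicate — affordable.

### OLS and the independence model

The package distinguishes the λ = 0 *transform* of `C` (a diagonal matrix
whose entries are root-to-tip path lengths, which differ once fossil tips
are present) from the ordinary least squares model with iid residuals.
`pgls(..., method = "ols")` fits the latter (identity covariance), which is
the model published OLS comparisons refer to; on an ultrametric tree the
two coincide up to a constant absorbed by σ². The OLS-vs-PGLS slope
comparison uses `t = (b_OLS - b_PGLS)/\sqrt{SE_1^2 + SE_2^2}` with
`df = n - k - 1` (so a purely allometric model on 201 species gives
df = 198).

### Model sets, selection and R²

For each relationship the candidate set is the purely allometric PGLS
model, one PGLS model per binary covariate (terrestrial specialist, clade
flags; coded 1 = yes), an intercept-only null, and an OLS copy of the
allometric model. All are fitted on the complete cases of the union of
variables so their AICc values are comparable. The selection rule is the
lowest-AICc model whose every non-intercept coefficient is significant at
p < 0.05; if none qualifies the purely allometric model is returned with a
flag. The null model is not a selection candidate — it exists as the
reference for the likelihood R²,
`R² = 1 - exp(-(2/n)(lnL_fit - lnL_null))`, clipped to [0, 1). No
Nagelkerke maximum rescaling is applied; the unrescaled form is simple,
monotone in the likelihood ratio, and adequate for comparing nested fits
on the same data.

### Bootstrap intervals

Coefficient intervals are 95% percentile intervals over B = 1000 resamples
of species rows with replacement. The resample's covariance is the
corresponding row/column selection of the full matrix, so a species drawn
twice enters as two observations with identical covariances — at exactly
λ = 1 such a matrix is singular and the profile likelihood is -Inf there,
which correctly keeps the maximiser interior. λ is re-estimated in every
replicate (grid step 0.05 plus refinement; coefficient draws are
insensitive to the coarser grid). Resamples with fewer than three unique
species are discarded, redrawn and counted. Whether the original analyses
resampled rows or residuals is not stated in the source material for this
design; row resampling is the most common reading and is what the package
documents and does.

### Prediction intervals for fossils

Predicting the SCL of a new (fossil) specimen from a fitted model
propagates two sources of uncertainty on the log10 scale: the spread of
the linear predictor across bootstrap replicates, and the model residual
variance, taken as `σ̂² × (mean root-to-tip depth)` — the variance a new
tip is expected to accrue under the fitted residual process. The default
95% interval is `10^(η̂ ± 1.96·sqrt(var_boot(η) + σ̂²·T̄))`; a
coefficient-only interval is available but not the default, because
intervals that ignore residual variance are far too narrow for a new
observation. Predictions from the shipped published equations are point
estimates only (their bootstrap draws are not available), matching how
clade-specific estimates are normally reported.

### Evolutionary rates

`univariate_bm_rate()` estimates the Brownian rate of a single trait by
maximising the multivariate-normal likelihood with covariance
`σ²C + diag((me·x)²)`, where `me` is a relative measurement error
(default use: 1% of each length measurement). With `me = 0` the closed-form
ML estimator is used. Rate distributions (e.g. bootstrap σ² samples of two
relationships) are compared with Welch's t-test.

## The maturity filter

Evolutionary allometry must not be contaminated by ontogenetic allometry,
so specimens below adult size are excluded before species means are taken.
The rule set, applied per specimen and logged per exclusion:

1. somatically immature specimens (incomplete skeletal fusion, supplied as
   a flag) are excluded regardless of size;
2. specimens flagged `include_override` are retained (the escape hatch for
   rare large species whose best available material sits a few percent
   below the threshold);
3. a sexed specimen must reach 60% of the maximum recorded SCL *for its
   sex* — sexual size dimorphism in turtles can approach two-fold;
4. an unsexed specimen is held to 60% of the *larger* sex's maximum, so a
   subadult of the large sex cannot slip through;
5. specimens without SCL cannot be assessed and are excluded.

The 60% threshold reflects that turtles mature sexually at roughly 50–65%
of maximum SCL (gravid females are observed just above 60%). When both the
override and the somatic-immaturity flag apply, immaturity wins: the
override exists to admit slightly-small but otherwise adult material, not
juveniles. Species means are arithmetic means of raw millimetre values,
log-transformed afterwards (a geometric-mean alternative sits behind a
flag). Filtering is idempotent: re-filtering retained specimens changes
nothing.

## The synthetic-data generator

`sim_config()` fixes the study conditions the test-suite runs under:
pure-birth (Yule) trees conditioned on the tip count and rescaled to a
230 Myr root depth (the age of the turtle total-group); a predictor
evolving by Brownian motion at 7 × 10⁻⁴ per Myr on the log10 scale from a
root state of 2.0 (100 mm); a response built from the allometric link
(intercept 0.64, slope 0.96 — the global shell-length ~ femur-length
values) with λ = 0.94-structured residuals at 8 × 10⁻⁵ per Myr; a
terrestrial-like covariate offset of −0.05 carried by 20% of tips; and 1%
relative measurement error at specimen level. These values mirror the
fitted global relationships, so parameter-recovery tests exercise the
estimator exactly where the method is used in practice.

The specimen-level generator adds the structure the filter must handle:
uniform ontogenetic size spread between 30% and 100% of the sex maximum,
female-biased dimorphism, a configurable unsexed fraction, gravid flags
only above 60% of the female maximum, and somatic immaturity concentrated
below 75% of maximum.

What the generator does *not* emulate: non-Brownian evolution (OU-like
attraction, early bursts), correlated missingness (fossils missing traits
non-randomly), topological uncertainty, and measurement error correlated
within collections. Passing tests therefore demonstrate correctness of the
estimators under the stated model, not robustness to violations of it.

## Numerical choices and degenerate inputs

* λ profile: grid step 0.01 (0.05 inside the bootstrap), golden-section
  refinement to 10⁻⁸, ties toward the smaller λ.
* Eigenvalues of `K` clipped at zero to absorb roundoff; a resampled
  covariance that is singular at a candidate λ simply contributes -Inf to
  the profile.
* Zero-residual (exactly collinear) data return the exact coefficients
  with σ² = 0, λ at the lower bound, infinite log-likelihood and a
  degeneracy flag plus warning, rather than an error — downstream code can
  still read the coefficients.
* Zero-length terminal branches are permitted with a warning.
* Trees need not be ultrametric; fossil tips simply have shorter
  root-to-tip paths, and tip ages are measured from the present defined as
  the deepest tip.
* Pruning a tree to a taxon set records the basal path to the retained
  clade as a root edge, so the pruned covariance equals the corresponding
  submatrix of the full covariance exactly.
* Grafting a fossil tip takes explicit attachment and tip ages and never
  guesses placements; it cannot change covariances among pre-existing
  tips.

## Problem sizes used by the test suite

Simulation-based checks run at 200 tips with 100 replicates (slope and λ
recovery, bootstrap coverage with B = 1000, covariate selection rates),
200 random instances of up to 8 taxa for the brute-force λ-grid oracle,
and 1000 synthetic specimens for the filter replay. These sizes were
chosen to match the empirical datasets the methods target (about 190–200
species) while keeping each property estimable with usefully tight Monte
Carlo error.

## Known limitations

* Only the λ correlation structure is offered (no OU, early-burst, kappa
  or delta transforms), matching the analyses the package reproduces.
* Responses are univariate; multivariate allometry is out of scope.
* The bootstrap treats the tree as fixed; phylogenetic uncertainty is not
  propagated.
* The shipped prediction equations are exactly the published global and
  clade-specific coefficient sets; refitting them from new data is
  supported, but the constants themselves are inputs, not re-derived.

## Worked example

```{r example}
cfg <- sim_config(n_tips = 60, seed = 42)
tree <- simulate_tree(cfg)
species <- simulate_allometric_dataset(tree, cfg)

specs <- build_model_set("log10_scl", "log10_fl", "terrestrial",
                         data = species)
fits <- fit_model_set(specs, species, tree)
sel <- select_best_model(fits[vapply(fits, function(f) f$k > 1, logical(1))])
sel$best

classify_allometry(sel$best$coefficients$estimate[2])

# a 100 mm femur under the shipped global equation, and body mass
predict_scl(100, "femur")
predict_bm(519)
```
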