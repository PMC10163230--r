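---
title: "Panel designs for the richness-productivity effect: models, assumptions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Panel designs for the richness-productivity effect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causalbef)
```

## The estimation problem

Annual observations of aboveground live biomass (g/m²) and plant species
richness on small plots, nested in sites, over multiple years. The target
is the average causal effect of an incremental change in richness on
productivity. In a ln-ln specification the coefficient β on ln richness is
an elasticity; the package reports it both raw and as the percent change
in productivity per +10% richness, in two conventions: the linearized
`10·β` and the exact `100·(1.1^β − 1)` (both printed, since the linear
form is the common field shorthand and the exact form is the honest
transform).

Confounding has a specific anatomy in this setting. Writing the error of
a naive regression as a sum of components: time-invariant plot and site
attributes (soil, topography, history), time-varying site attributes
(weather and herbivory shocks shared by the site's plots in a year),
time-varying plot attributes (micro-disturbances), and pure noise. Each
design below neutralizes a different subset, and the package's synthetic
generator reproduces exactly this decomposition so that every claim a
design makes can be checked by parameter recovery.

## The designs and their assumptions

**Bivariate.** `estimate_bivariate()`: ln biomass on ln richness and an
intercept. Causal only if nothing confounds — the baseline every other
design is compared against.

**Covariate conditioning.** `estimate_common_design()`: enters a supplied
covariate list directly (factors expanded; listwise deletion of missing
values; collinear columns dropped deterministically left-to-right with a
report). This mirrors the conditioning-on-observables analyses common in
observational ecology; its assumption — the list captures *every*
confounder — is the one the rest of the package is designed to avoid.

**Two-way fixed effects (the main design).**
`estimate_main_design()` absorbs a fixed effect per plot and one per
site-year cell, then regresses residualized ln biomass on the
residualized diversity variable. Plot effects remove *all* time-invariant
plot and site confounders without measuring them; site-year effects
remove *all* site-level shocks, observable or not. The remaining
assumption is that no time-varying plot-level confounder is left in the
error. Supported diversity variables: ln richness (default), ln inverse
Simpson, untransformed richness, and a quadratic richness specification;
optional extra covariates (e.g. evenness) enter alongside.

**Instrumental variables.** `estimate_iv()`: two-stage least squares with
plot and site-year effects absorbed from outcome, regressor and
instrument. The intended instrument is the mean richness of neighboring
nutrient-manipulated plots in the same block (`neighbor_mean_instrument()`
builds that group mean), assumed to shift a focal plot's richness via
dispersal but to touch its productivity only through richness. 2SLS is
robust to *all* confounding channels and to reverse causality, at the
price of that exclusion assumption and lower precision. Instrument
strength is reported as the Montiel–Pflueger-style effective F — with one
instrument, the squared first-stage coefficient over its cluster-robust
variance — alongside the classical homoskedastic F.

**Mechanism blocking.** `estimate_mechanism_block()`: if productivity
suppresses richness mainly through shading, conditioning on the shading
variable blocks that back-path; an unchanged β is evidence against
reverse-causality bias. The package's generator is recursive — richness
responds to *last season's* shading, and shading is a logistic function
of current ln biomass — so the blocking covariate defaults to the
one-year-lagged shade. Conditioning on *current* shade in such a system
would partial out a near-deterministic transform of the outcome itself
and drive every coefficient toward zero; with the lag, the design is
provably inert when the reverse channel is off (checked in the tests) and
removes the bias when it is on. `lag = FALSE` restores the
contemporaneous form for field data, where measured ground-level light is
a noisy proxy rather than a deterministic function of biomass.

**Lagged dependent variable.** `estimate_ldv()`: ln biomass on ln
richness and last year's ln biomass, with site-year effects but *no* plot
effects — mixing a lagged outcome with unit fixed effects in a short
panel induces Nickell bias, and the LDV design's identifying assumption
(plot-level confounding operates through prior productivity) *replaces*
the fixed-effects assumption rather than supplementing it. Lags are built
strictly within plots from consecutive years. Under standard conditions
the fixed-effects and LDV estimates bracket the true effect from opposite
sides; `bracket()` reports the ordered interval and whether the two
estimates agree in sign (only then is a substantive conclusion printed).

**Sensitivity bound.** `oster_adjusted_beta()` asks how strong an
unobserved confounder would need to be to overturn the conclusion, under
proportional selection: the unobservables select on richness π times as
strongly as the observables do, and a fully specified model would attain
R² = Rmax. Two methods: the first-order approximation
β* = β̃ − π(β̇ − β̃)(Rmax − R̃)/(R̃ − Ṙ), and the exact root of the cubic
in the bias ν = β̃ − β* implied by the single-index model's moment
conditions,

−τ(π−1)(σ²ₓ−τ)·ν³ − d₂σ²ₓτ(π−2)·ν² + (d₂²σ²ₓτ + d₃τ − d₄π(σ²ₓ−τ))·ν − d₂d₄πσ²ₓ = 0,

with d₂ = β̇−β̃, d₃ = (R̃−Ṙ)σ²ᵧ, d₄ = (Rmax−R̃)σ²ᵧ, and τ the residual
variance of the treatment after the controls. At π = 1 the cubic
degenerates to a quadratic, as it should. Among real roots the one
closest to β̃ (smallest implied bias) is selected. The exact method needs
three second moments beyond the two regressions' coefficients and R²
values; `oster_inputs_from_fits()` fills them from the fitted designs,
taking the controlled R² as the total R² including the absorbed fixed
effects (those *are* the observables whose explanatory power the
proportional-selection assumption scales against). Both π = −0.10 (a
confounder inducing a spurious negative association) and π = +0.10 (a
masking confounder) are default rows of the design-suite table. The two
methods agree to first order in π; both identities β*(π=0) = β̃ and
β*(Rmax=R̃) = β̃ hold exactly.

**Heterogeneity by species type.** Species are classified per site as
rare/non-rare × native/non-native (`classify_species()`): site-level
abundance is the mean relative cover over the site's plot-years (absences
count as zero), or a presence frequency with
`metric = "relative_frequency"`; a species is rare below the cutoff
(default 0.05 — the conventional 5% relative-abundance line; a sweep
utility re-runs the analysis across cutoffs since any single line is
arbitrary). `estimate_by_type()` replaces ln richness with the inverse
hyperbolic sine of the four per-type counts — IHS rather than ln because
a plot-year can contain zero species of a type, and IHS is defined at
zero while behaving like ln(2x) for large counts. The four counts
partition total richness by construction. `equality_test()` is the Wald
chi-square (3 df) test that all four effects are equal, invariant to the
choice of contrast base. Cross-type interactions are deliberately
excluded: with four types and within-plot variation only, there is no
realistic power for them.

## Inference

All designs use the CR1 cluster-robust sandwich
`(X'X)⁻¹[Σ_g X_g'u_g u_g'X_g](X'X)⁻¹ · G/(G−1) · (n−1)/(n−k)`, clustered
at the plot by default (arbitrary within-plot serial correlation,
heteroskedasticity across plots) with site-level clustering available as
a robustness option. The model degrees of freedom k include the absorbed
fixed effects, counted exactly as levels₁ + levels₂ − (connected
components of the plot × site-year bipartite graph). Confidence intervals
use t critical values with G − 1 degrees of freedom — conservative for
small cluster counts. 2SLS standard errors follow the standard
convention: second-stage residuals are recomputed with the observed (not
fitted) regressor.

## The synthetic data generator

`simulate_panel()` draws, per confounding channel, a bivariate Gaussian
*pair* of loadings — one on ln richness, one on ln biomass — with the
channel's standard deviation and a correlation ρ. This is the minimal
parameterization in which "a confounder" is literally one latent variable
pushing both outcomes: ρ controls the direction and strength of the
induced bias, and setting a channel's SD to zero switches it off. The
structural equations are, per plot p in site s and year t:

* ln richness: baseline + plot, site-year and plot-year richness loadings
  + γ·Z (standard-normal instrument) + λ·(lagged shade − ½) +
  idiosyncratic shock; observed richness is `max(1, round(exp(·)))`
  capped at the pool size — estimation then uses the log of the observed
  integer, so mild discretization noise is part of the study conditions;
* ln biomass: baseline + β·ln(observed richness) + the biomass loadings +
  θ·(lagged ln biomass − baseline) + noise; with `by_type = TRUE` the
  single β is replaced by four per-type effects on IHS per-type counts;
* shade: logistic in centered ln biomass, i.e. the fraction of light the
  canopy intercepts — which closes the reverse-causality loop with a
  one-year lag and keeps the system recursive (no simultaneous equations
  to solve).

The persistence coefficient θ exists so that the LDV design has a world
in which its assumption set holds exactly: with θ > 0 and λ > 0, last
year's productivity drives both current richness and current
productivity, which is precisely the confounding the LDV design controls
and the fixed-effects design does not. Year 1 has no reverse pressure or
persistence (lag terms centered at their neutral values).

The community model gives each site a pool of species with geometric
rank-abundance (rank k's relative abundance ∝ decay^k, renormalized) and
a fixed Bernoulli origin label. A plot-year of richness R samples R
species *without replacement with probability proportional to pool
abundance*: the first draws are dominated by common species, so the
marginal species present at higher richness is increasingly likely to be
rare — the defining compositional feature of diverse natural grasslands
that randomized experiments do not reproduce. Covers are pool abundances
perturbed by lognormal noise and renormalized to sum to one. A species'
true type (rare iff pool abundance < cutoff) is what
`classify_species()` should approximately recover from the realized
covers.

Default parameters and why:

| parameter | default | rationale |
|---|---|---|
| n_sites × plots × years | 43 × 4 × 8 | the scale of a multi-site grassland network panel (tens of sites, 3–4 plots each, 5–11 years) |
| beta_true | −0.24 | an elasticity of the magnitude reported for natural grasslands; negative so that confounding (positive ρ) and truth have opposite signs, the hard case |
| mean ln richness | ln 10 | median richness ≈ 10 species/m², range ~1–37 after log-normal spread and rounding |
| mean ln biomass | ln 300 | ~300 g/m², mid-range for mesic grasslands |
| confounder SDs (plot, site-year) | 0.3, 0.2 | between-plot spread larger than year-to-year site shocks, both comparable to the within noise |
| ρ (all channels) | 0.5 | moderate same-direction confounding |
| sd_noise, sd_richness_shock | 0.35, 0.3 | within-plot residual spread of log biomass and log richness typical of annual vegetation data |
| instrument strength γ | 0.2 | a usable but not overwhelming first stage at study scale |
| pool_size, decay | 60, 0.85 | pool safely above the maximum achievable richness; most pool species fall below a 5% abundance line, as in real rank-abundance curves |
| frac_nonnative | 0.25 | non-native species present but a minority |
| rarity_cutoff | 0.05 | conventional relative-abundance threshold; swept in the sensitivity utility |

Named scenarios (`sim_scenario()`) freeze the configurations used for
validation: `confounded` (the default recovery scenario, 10 × 4 × 6),
`signflip` (strong positive site-year confounding against a negative
truth), `iv` (plot-year confounding plus a valid instrument),
`reverse`/`ldv_world` (lagged shading channel with productivity
persistence), `null` and `ideal`. Validation problem sizes were chosen so
that the whole test suite runs in a few minutes on one CPU: recovery and
coverage use 200 replicates of the 10 × 4 × 6 scenario; the
equality-test size check uses 500 replicates of a 20 × 4 × 6 scenario
(the chi-square reference needs the larger cluster count — with 40
clusters the 3-df Wald test over-rejects).

What the generator deliberately does **not** emulate: spatially explicit
dispersal (the instrument is an abstract exogenous shifter, not a
neighbor-richness mechanism), weather reanalysis, species traits,
unbalanced panels with missing years (supported by the estimators, not
produced by the generator), and any claim about the empirical
distribution of within-plot richness *changes* in real network data —
the SD parameters are exposed rather than asserted. Passing recovery
tests therefore shows the estimators are correct under the stated DGP,
not that real grassland data satisfy any design's assumptions.

## Numerical choices

* Fixed-effect absorption: alternating demeaning, tolerance 1e−10 on the
  largest update, max 1000 sweeps; exactness is testable against the
  explicit-dummy oracle at desk scale, and a single factor converges in
  one sweep by construction.
* Collinearity: columns are screened left-to-right; a column enters only
  if it raises the rank, so the drop order is deterministic and reported.
* Degenerate inputs are errors with named causes: duplicate plot-years, a
  plot under two sites, no identifying within variation, a single
  cluster, an instrument constant after absorption, R̃ = Ṙ in the
  sensitivity approximation.
* Evenness (Pielou J) is undefined at richness 1 and stored as missing —
  never zero; rows drop only in the evenness-controlled variant.
* Simpson diversity uses the inverse form 1/Σp²; the cover shares are
  renormalized per plot-year before any index is computed.
* Biomass of exactly zero cannot enter ln models; such rows are excluded
  and counted in the panel's drop log, which reconciles exactly
  (rows in = rows used + Σ dropped by reason).
* Root selection for the sensitivity cubic: real roots only
  (|Im| < 1e−8 relative), then smallest |bias|; `polyroot()` does the
  work and a grid-search oracle double-checks it in the tests.
* Seeds: one integer seed governs a simulation; `monte_carlo()` spawns
  per-replicate sub-seeds from it, so the whole bundle is reproducible
  bit for bit.

## Known limitations

* The Common design here is covariate-adjusted least squares, not a
  random-intercept mixed model; with the same covariate list the fixed
  estimates differ little, but small-sample shrinkage behavior is not
  reproduced.
* The effective F reduces to the single-instrument form; multiple
  instruments, over-identification tests and weak-instrument-robust
  confidence sets are out of scope.
* The equality test relies on the large-cluster chi-square reference;
  with few clusters it over-rejects slightly (hence the validation at 80
  clusters).
* Bracketing is an argument about biases of opposite sign under rival
  assumption sets, not an interval estimator: when neither assumption set
  holds, the truth can fall outside the interval, and the package only
  ever reports the ordered pair plus a sign-agreement flag.
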