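---
title: "Joint LAI and soil-moisture assimilation into a water-limited wheat model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint LAI and soil-moisture assimilation into a water-limited wheat model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheatDA)
```

## The problem

Crop growth models propagate a daily state — phenology, canopy, biomass
pools, root-zone water — from weather forcing and parameters. Two of those
states can be observed remotely at field scale: leaf area index (LAI, from
optical imagery) and volumetric soil moisture (SM, from C-band radar). Both
are noisy, sparse in time, and tied to model errors that accumulate over a
season. Sequential data assimilation blends the two information sources: an
ensemble of model runs carries the forecast uncertainty, and an ensemble
Kalman filter (EnKF) update pulls the state toward each observation in
proportion to the ratio of forecast to observation error.

`wheatDA` implements this pipeline end to end for winter wheat: a reduced
water-limited growth model, a perturbed-observation EnKF over the state
subvector (LAI, SM), four experiment schemes (open-loop, LAI-only, SM-only,
joint), a synthetic weather/observation generator so the whole system can be
exercised as twin experiments without any satellite data, and the evaluation
statistics (R², mean relative error, RMSE) used to compare schemes.

## The crop model

The simulator is a deliberately reduced, WOFOST-style water-limited model.
It keeps exactly the states and parameters the assimilation touches, and
replaces process detail that the filter never sees with standard simpler
forms:

* **Phenology.** Development stage DVS runs 0 (emergence) → 1 (anthesis) →
  2 (maturity), driven by thermal time above `TBASEM` with requirements
  `TSUM1` and `TSUM2`. No vernalization or photoperiod response.
* **Canopy.** Leaves live in daily cohorts with weight, age and the specific
  leaf area (`SLATB(DVS)`) they were born with; LAI = Σ weight·SLA. Cohorts
  age by `(Tmean − TBASE)/(35 − TBASE)` physiological days, so a leaf at
  35 °C lives exactly `SPAN` days. Hard frost (`tmin` below −10 °C) kills a
  linearly increasing fraction of every cohort — the winter canopy thins and
  regrows in spring, as winter wheat does in a dry-winter temperate climate.
  While the canopy is expanding (DVS < 1 and LAI < 6), daily canopy growth is
  capped at the exponential rate `LAI·(exp(RGRLAI·ΔTeff) − 1)`; beyond that
  the canopy is source-limited only. This window matters: it is what makes
  `RGRLAI` a genuine sensitivity parameter for LAI, and it is what gives a
  parameter-perturbed ensemble its spring LAI spread.
* **Growth.** Gross assimilation uses a light-use-efficiency form:
  `LUE · radiation · (1 − exp(−k_ext·LAI)) · water-stress · TMPFTB(Tmean)`,
  replacing leaf-level photosynthesis integration. Maintenance respiration
  uses fixed per-pool coefficients (Q10 = 2). Net growth goes first to roots
  (`FRTB`), the shoot share to leaves/stems/storage organs by DVS-indexed
  fractions that sum to one at every knot. The storage pool (`wso`, the
  yield) never shrinks, and growth stops at maturity.
* **Soil water.** A one-layer free-draining bucket of rooting depth `RD`.
  Rain and irrigation infiltrate; potential ET (a Hargreaves-type
  temperature–radiation form, so humidity and wind stay optional) is split
  into soil evaporation and transpiration by canopy cover; both are reduced
  by a factor linear in SM between the wilting point and the critical point
  `SMW + 0.5·(SMFCF − SMW)`; percolation above field capacity is limited by
  `KSUB`; saturation excess runs off. Every flux is returned, and the balance
  closes to numerical precision — a property the tests enforce at 10⁻⁶ cm
  over full seasons.

Defaults describe a generic North China Plain winter wheat system: sowing in
mid-October, anthesis around the start of May, maturity in mid-June, maximum
LAI near 4.5 and yields around 8 t/ha under the default climate. `LUE = 22`
kg ha⁻¹ per MJ m⁻² of *total* global radiation intercepted corresponds to
≈2.2 g DM/MJ, in the usual range once the temperature response is applied.
All values are configuration, not fitted constants.

## The filter

The EnKF is implemented over an arbitrary labelled state vector; in this
study the assimilated subvector is x = (LAI, SM) and the observation
operator is a selection/identity matrix. One analysis is:

1. forecast statistics: ensemble mean and covariance with the 1/(Ne − 1)
   divisor;
2. gain `K = Pf Hᵀ (H Pf Hᵀ + R)⁻¹`;
3. perturbed observations: each member receives `y + v_i`, `v_i ~ N(0, R)`,
   so the analysis ensemble keeps the right spread;
4. member update `x_i ← x_i + K (y_i − H x_i)`.

Observations of both variables sharing a date are stacked into one
observation vector with diagonal R (a single analysis); otherwise events are
processed in date order. No process noise is added in the study runs — the
ensemble spread comes entirely from parameter and initial-condition
perturbations — though the forecast API accepts a full Q. No covariance
inflation or localization is used at this state dimension.

**Second-order exact sampling.** By default the perturbations are not plain
independent draws: each replicate set is centered, made orthogonal in sample
to the ensemble anomalies, and rescaled so its sample covariance equals R
(and Q in the forecast) exactly. Plain draws at a finite ensemble inject
spurious noise–state correlations and χ²-distributed variance error
(relative s.d. √(2/Ne) ≈ 20% at Ne = 50) into every analysis; with exact
sampling the analysis mean follows the Kalman update of the ensemble mean
and the posterior sample covariance follows the Joseph form
`(I − KH) Pf (I − KH)ᵀ + K R Kᵀ` identically, so the observed-variable
variance contracts at every event and the filter reproduces the closed-form
Kalman recursion on linear-Gaussian systems to machine precision. Plain
independent draws remain available via `exact = FALSE`.

**Observation error.** The relative-error rule R = (rel_error · value)²
(10% LAI, 35% SM) has a degenerate corner: a near-zero retrieval would claim
near-perfect certainty, drive the gain to one, and slam the whole ensemble
onto a single garbage value — we observed exactly this with multiplicative
noise at 35%, including LAI being catapulted far outside physical range
through the cross-covariance. `scheme_config` therefore applies per-variable
variance floors (s.d. 0.1 for LAI, 0.04 cm³ cm⁻³ for SM), both below the
absolute accuracy any optical-LUT LAI or C-band change-detection SM
retrieval achieves in validation. The floors bind only for small observed
values; at typical magnitudes R is the relative-error value.

**Reconciliation.** The filter overwrites only (LAI, SM); the rest of the
crop state follows deterministically: SM is clamped to the member's
physical range [SMW, SM0], leaf cohorts are rescaled multiplicatively so
Σ weight·SLA equals the updated LAI (one fresh cohort is created if the
canopy was empty), and the biomass bookkeeping (`wlv`, `tagp`) is updated
consistently. Analyses happen end-of-day, after the day's forecast step.

**Seed discipline.** One master seed is split into independent streams
(ensemble build, observation perturbation, weather generation), so schemes
run with the same seed share bit-identical ensembles and differ only in
which observations they assimilate. Every run is reproducible bit-for-bit.

## The synthetic data

The weather generator draws a sinusoidal annual temperature cycle with
Gaussian day-to-day noise, a first-order wet/dry rainfall occurrence process
with monthly probabilities and exponential wet-day depths, beta-distributed
sunshine fractions converted to radiation with the Angstrom formula
(`Rs = (a + b·n/N)·Ra`, standard solar geometry), and fixed irrigation
events. Defaults emulate a semi-humid dry-winter climate at 37.7° N: annual
mean 12.5 °C, ≈650 mm rainfall concentrated in summer, and three spring
irrigations (70/70/60 mm) as practised in intensively irrigated winter wheat
systems. The default observation calendar has 7 LAI dates and 8 SM dates
between late February and late May at a ~5–12 day cadence, with 10%/35%
multiplicative Gaussian noise clamped at zero.

What the generator does *not* emulate: spatially correlated retrieval error,
cloud-driven gaps, the surface-(0–10 cm)-versus-root-zone SM mismatch
(available as an optional additive `sm_bias` but off by default), or real
soil heterogeneity. Passing twin tests therefore demonstrates the filter and
model mechanics under the stated noise model, not retrieval skill on real
imagery.

## Twin-experiment design

A twin replicate draws the *truth* in two parts:

* truth parameters: one draw from the same 10% Gaussian perturbation prior
  the ensemble samples (TDWI, WAV, RGRLAI, SPAN, SMFCF, SM0);
* truth forcing: the shared weather realisation modified by season-constant
  deviations unknown to the ensemble — a multiplicative factor on water
  input (rain and irrigation, s.d. 0.25), a radiation factor (s.d. 0.03) and
  an additive temperature offset (s.d. 0.1 °C).

The forcing mismatch is the scientific core of the design. The filter
configuration deliberately ignores model-structure and input-data
uncertainty (Q = 0); reality does not cooperate: station weather interpolated
to a field — and above all farmer-scheduled irrigation — differs from what
any cell of a regional run assumes, while temperature and radiation
interpolate well across a station network. If instead the truth were drawn
from the ensemble's own prior under identical forcing, the open-loop mean
would be unbiased by construction and *no* filter could improve on it; the
twin would test nothing. With the forcing mismatch, observations carry real
signal about a truth the model cannot reach on its own, which is precisely
the situation regional crop assimilation is for.

Noisy observations are then sampled from the truth trajectory and all four
schemes run with identical master seeds. Skill is measured per replicate as
the absolute error of the ensemble-mean yield against the truth yield, and
as trajectory RMSEs of LAI and SM, summarised by medians over ≥30 replicate
seeds (default problem size: 255-day seasons, 50 members, 30 seeds — about
a quarter-hour of single-core work for a full study).

### What the twin study shows — and what it honestly cannot

Across replicates, LAI assimilation improves the LAI trajectory consistently
(median RMSE reductions of roughly 10–25%) and the yield estimate
moderately; SM assimilation improves the LAI trajectory slightly (the
water-stress coupling works in the right direction) while being close to
neutral on yield; joint assimilation inherits both and is typically the
best scheme. The median yield-error reduction itself is a noisy statistic
across studies — the per-replicate error distribution is heavy-tailed, so
30-replicate medians move by tens of percent between master seeds. The
*magnitude* of the yield improvement is also structurally limited in this
reduced model, for reasons worth stating plainly:

* most of the open-loop yield error is water-forcing-driven, and its yield
  expression runs through the transpiration-stress factor;
* the ensemble SM spread is small (members share weather and a fast
  free-draining bucket, so their SM trajectories converge within days),
  which makes 35%-noise SM observations nearly uninformative to the filter
  — gains rarely exceed 0.2 — and the bucket's short memory erodes whatever
  correction is applied;
* LAI corrections act on yield through Beer-law light interception, which is
  near-saturated at a closed canopy, leaving only ~6–10% leverage at peak
  LAI.

A deeper root zone was tried and rejected: it lengthens the memory of noise
kicks as much as of genuine corrections and made assimilation worse. These
are properties of the reduced model's structure, not of the filter; a model
with leaf-level photosynthesis and a multi-layer soil profile holds more
spread in both assimilated states and gives the same filter more purchase.

## Regional runs

`generate_region` draws a grid of cells with wheat fractions ~ U(0, 1),
optional per-cell parameter jitter, one shared weather realisation, and
per-cell truths and observations. `regional_run` simulates exactly the cells
whose wheat fraction strictly exceeds the 40% threshold, averages a cell's
observations per date and variable before assimilation, and reports per-cell
yields with a spatial summary. The regional open-loop is the deterministic
base-parameter run (the no-update baseline); assimilation runs carry their
ensembles. Because each cell assimilates its own observation stream,
assimilation introduces spatial yield variability that a cell-invariant
open-loop cannot have.

## Evaluation

`fit_metrics` computes RMSE, mean relative error (mean |pred − ref|/|ref|,
in percent, undefined and flagged when a reference value is zero), and R².
R² defaults to the squared Pearson correlation — the natural reading of a
scatter-fit — with the goodness-of-fit form 1 − SSE/SST available behind
`r2_method = "gof"`, since the two differ for biased predictions.
`compare_schemes` assembles the per-scheme table and reports RMSE deltas
against the open-loop row unrounded.

## Numerical choices and degenerate inputs

* Water-balance arithmetic is ordered so the flux identity
  infiltration − E − T − percolation − runoff = ΔW holds to machine
  precision; extraction is capped so SM never crosses the wilting point.
* The 40% regional threshold is strict (`>`), so a fraction of exactly 0.40
  is excluded.
* Observation variance is `(rel_error·value)²` exactly as stated — a zero
  value gives zero variance — with the floors above applied only where R
  enters the gain computation.
* Perturbed parameter draws are redrawn (up to 100 times) until positive and
  ordering-consistent (SMW < SMFCF < SM0 < 1 per member); WAV is clipped to
  its feasible range given the member's retention triplet.
* A `TDWI` of zero yields an empty canopy and zero yield; an observation
  demanding LAI > 0 on an empty canopy creates one fresh cohort at the
  current specific leaf area.
* All seeds are 32-bit; derived sub-seeds stay below 2³¹.

## Known limitations

The reduced model omits WOFOST's leaf-level photosynthesis, multi-layer soil
water, nutrient limitation, vernalization and CO₂ response; the filter is
the stochastic (perturbed-observation) EnKF only; observation errors are
treated as uncorrelated in time and between variables; and the surface-probe
versus root-zone SM bias is not corrected (the observation operator stays an
identity). The synthetic climate is a statistical sketch of a dry-winter
temperate system, not a reanalysis of any particular region.
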