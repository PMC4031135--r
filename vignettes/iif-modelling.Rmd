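---
title: "Modelling cell dehydration and nucleation-limited intracellular ice formation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cell dehydration and nucleation-limited intracellular ice formation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryoiif)
```

## The problem

When a cell suspension is frozen without cryoprotectants, extracellular ice
concentrates the external solution and water leaves the cell osmotically.
Each cell then faces two fates: it dehydrates, or the supercooled cytoplasm
nucleates ice (intracellular ice formation, IIF). Because ice growth through
a cell at physiological viscosity is effectively instantaneous, IIF is
nucleation-limited, and the population-level observable is the probability
of ice formation (PIF): the cumulative fraction of cells that have frozen
internally by a given temperature while cooling at rate $B$.

`cryoiif` implements the coupled model of these two processes for a
spherical cell under a linear cooling ramp, together with stochastic
single-cell event simulation and the two-stage pooled least-squares
machinery needed to estimate its parameters from cryomicroscopy-style
observation tables. Its central scientific feature is a critical-volume
modification of the classical heterogeneous nucleation-rate model: each
nucleation mechanism is switched off once the cell has dehydrated below a
mechanism-specific critical volume $V_f$, which lets predicted PIF curves
plateau below 1 — as observed in cell populations whose maximum PIF is well
under 100% — where the unmodified model is forced towards certainty at deep
subzero temperatures.

## Water transport

Cell volume $V$ follows a Mazur-type membrane-limited transport law written
with temperature as the independent variable along the ramp:

$$\frac{dV}{dT} = \frac{L_p A R T}{B\, v_w}
  \left[\ln x_w - \frac{\Delta H_f}{R}
  \left(\frac{1}{T_R} - \frac{1}{T}\right)\right],
\qquad
L_p = L_{pg} \exp\!\left[-\frac{E_{Lp}}{R}
  \left(\frac{1}{T}-\frac{1}{T_R}\right)\right],$$

where $x_w$ is the water mole fraction of the cytosol (ideal binary
solution of osmotically active water $(V - V_b)/v_w$ and dissociated salt
$\phi_s n_s$), $A$ the membrane area, $T_R = 273.15$ K, and $\Delta H_f$
the molar heat of fusion of water, taken independent of temperature. The
bracket vanishes exactly when the cytoplasm freezing point
$T_f(x_w)$ — defined by the ideal freezing-point-depression relation
$\ln x_w = (\Delta H_f/R)(1/T_R - 1/T_f)$ — equals the current temperature,
which defines the equilibrium (infinitely slow cooling) dehydration curve.

Key modelling choices:

* **Units.** Internal units are $\mu$m, $\mu$m$^3$, minutes, atm, K and
  kcal/mol, matching how the membrane parameters are conventionally
  reported ($L_{pg}$ in $\mu$m min$^{-1}$ atm$^{-1}$, $E_{Lp}$ in
  kcal/mol, $B$ in °C/min). The gas constant is carried in a pressure view
  for the osmotic term and an energy view for the Arrhenius and
  freezing-point terms. All °C↔K conversion happens at the file/config
  boundary.
* **Salt content closure.** $n_s$ is rarely reported directly; it is
  derived from the isotonic condition that the cytoplasm at volume $V_0$
  freezes at $T_0 = -0.5$ °C, by exact closed-form inversion
  (`isotonic_salt_content()`). The same closed form inverts the
  equilibrium volume; tests verify both against brute-force root solves to
  $10^{-10}$.
* **Area.** The membrane area is recomputed from the instantaneous volume
  through the sphere model at every step (`area_mode = "sphere_dynamic"`);
  a `"constant"` mode freezes it at $A_0$ for comparison with
  formulations that do so.
* **Initial state.** The simulation starts at the isotonic volume at
  $T_{start} = -0.5$ °C, i.e. at equilibrium after extracellular ice
  seeding; the brief seeding excursion itself is not simulated, and
  volumes are reported normalized to $V_0$.
* **Integration.** `deSolve::lsoda` with relative tolerance $10^{-8}$ and
  absolute tolerance $10^{-10}\ \mu$m$^3$, dense output every 0.05 K by
  default (the PIF quadrature downstream wants a uniform fine grid). The
  problem stiffens at low temperature only in the sense that $L_p$
  collapses — at $-40$ °C it is 2.4% of its $-0.5$ °C value for
  $E_{Lp} = 11.9236$ kcal/mol — which the adaptive solver handles
  directly; an explicit-Euler oracle at 1 mK steps agrees to $10^{-4}$
  relative in terminal volume.

## Viscosity

Nucleation kinetics are damped by the cytoplasm viscosity, modelled as
free-volume (Vrentas–Duda) water viscosity times a crowding correction:

$$\eta_w(T) = \eta_{w,0}
  \exp\!\left[\frac{\hat V_w}{(K_{11}/\lambda)(K_{21}+T-T_{gw})}\right],
\qquad
\eta = \eta_w\, g(\phi_{salt}),$$

with the standard water free-volume parameter set
($\hat V_w = 0.91$ cm$^3$/g, $K_{11}/\lambda = 1.945\times10^{-3}$
cm$^3$ g$^{-1}$ K$^{-1}$, $K_{21} = -19.73$ K, $T_{gw} = 136$ K) and
$\eta_{w,0}$ calibrated once so that $\eta_w(20\,°C) = 1.002$ mPa s. The
crowding factor defaults to a Krieger–Dougherty form
$g(\phi) = (1-\phi/\phi_{max})^{-2.5\,\phi_{max}}$ with
$\phi_{max}=0.64$ and is a pluggable strategy (`crowding` argument), since
composition corrections for cytoplasm appear in several variants in the
literature; at physiological salt volume fractions ($\phi \lesssim 10^{-2}$)
the correction is nearly negligible, so this choice has little leverage.
The expression diverges at $T_{gw} - K_{21} \approx 155.7$ K, which
represents the glass transition of the residual solution; its consequences
for the deep-subzero behaviour of the model are discussed under
*Limitations*.

## Nucleation and PIF

Each catalytic mechanism — surface-catalyzed nucleation (SCN) at the
membrane, scaling with area, and volume-catalyzed nucleation (VCN) in the
cytoplasm, scaling with volume — has a Toner-type heterogeneous rate

$$I(T) = \Omega_0\,\frac{\eta_0}{\eta(T)}
  \exp\!\left[-\frac{\kappa_0 (T_f/T_{f,0})^4}{(T_f - T)^2\, T^3}\right],$$

zero for $T \ge T_f$. $\kappa_0$ carries K$^5$ so the barrier exponent is
dimensionless, and the $(T_f/T_{f,0})^4$ factor refers the thermodynamic
parameter to the isotonic freezing temperature $T_{f,0}$; likewise
$\eta_0$ is the isotonic-composition viscosity at $T_{f,0}$, which makes
$\Omega_0$ the isotonic-condition rate scale and insulates the fitted
kinetics from the absolute calibration of the viscosity model. The
modified model multiplies the rate by the critical-volume gate
$\mathbf{1}[V \ge V_f]$ (boundary inclusive).

PIF per mechanism is the survival-model composition along the dehydration
trajectory,

$$PIF(T) = 1 - \exp\!\left[-\frac{1}{B}\int_T^{T_{start}}
  I(T')\,S(T')\,dT'\right],$$

with $S$ the area in m$^2$ (SCN) or the volume in m$^3$ (VCN; total cell
volume by default, `volume_basis = "water"` for $V-V_b$), and the total is
the independent-competition composition
$PIF^{tot} = 1-(1-PIF^{SCN})(1-PIF^{VCN})$. The hazard integral is
cumulative trapezoidal quadrature on the trajectory grid; against a
$10^5$-interval Riemann oracle the error is below $10^{-4}$ everywhere,
and curves are invariant to grid refinement beyond 0.05 K to better than
$10^{-3}$ relative.

Two numerical details matter:

* **Gate crossing.** Because dehydration is monotone, each gate closes at
  most once. The crossing is resolved *inside* its grid interval by linear
  interpolation and the cumulative hazard truncated there, rather than
  masking whole grid nodes. Node-masking makes PIF a step function of
  $V_f$ at grid resolution, which (besides being cruder quadrature)
  defeats finite-difference derivatives during fitting.
* **Prefactor composition.** Full formulations of the rate carry a factor
  counting the water molecules in catalytic contact. Here the dehydration
  dependence enters through $S(T')$ and $\eta(T)$; an optional
  multiplicative depletion factor ($A/A_0$ for SCN,
  $(V-V_b)/(V_0-V_b)$ for VCN) is available behind
  `prefactor_mode = "dehydration"`, default off, so the choice is explicit
  and testable. A $(T/T_f)^{1/2}$ kinetic factor that appears in some
  statements of the rate is likewise excluded by default.

## Two-stage pooled fitting

Estimation mirrors experimental practice:

1. **Membrane parameters.** One shared $(L_{pg}, E_{Lp}, V_b)$ triple is
   fitted to normalized-volume observations from all cooling rates
   simultaneously (a single pooled sum of squares; one printed $R^2$).
   $L_{pg}$ and $E_{Lp}$ are searched in $\log_{10}$ space, $V_b$ as a
   fraction of $V_0$, with the salt content re-derived from the isotonic
   condition for every candidate $V_b$. Optional $1/\mathrm{SEM}^2$
   weighting is available; the default is unweighted.
2. **Nucleation parameters.** With the stage-1 trajectories frozen (the
   stages never feed back), SCN/VCN parameters are fitted to observed
   cumulative PIF — darkening and twitching events combined — either per
   cooling rate (`fit_pif()`) or as one shared set across rates
   (`fit_pif_pooled()`). $\Omega_0$ and $\kappa_0$ are searched in
   $\log_{10}$ space over $[10^5,10^{30}]$ and $[10^8,10^{13}]$ (fitted
   magnitudes span many decades), critical volumes as fractions of $V_0$.

Further estimator choices, each of which was genuinely open:

* **Ordering constraint.** Only the combined PIF enters the objective, so
  the two mechanisms are nearly exchangeable and critical volumes can swap
  roles under sampling noise. The modified-model fit therefore constrains
  $V_f^{SCN} \ge V_f^{VCN}$ — the ordering found in every reported
  parameter set and implied by the sequential interpretation in which VCN
  becomes the dominant channel only after dehydration shuts SCN off —
  by parameterizing $V_f^{VCN}$ as a position between its lower bound and
  $V_f^{SCN}$.
* **Weighted residuals.** Cumulative PIF observations from $n$ cells have
  binomial sampling error $\sqrt{p(1-p)/n}$. When cell counts accompany
  the observations, residuals are scaled by the reciprocal of this
  standard error (with a continuity correction at $p \in \{0,1\}$); this
  measurably sharpens recovery of $V_f^{VCN}$, whose signal sits in the
  mid-probability plateau-onset region. $R^2$ and reported residuals stay
  unweighted. Set `weighting = "none"` for plain SSE.
* **Global search.** The objective is multimodal. Starting points come
  from a seeded Latin-hypercube pool (about 25 candidates per polished
  start) screened on the raw objective, with the best 20 (single-rate) or
  40 (pooled recovery; 20 proved insufficient to reach the global basin
  reliably in six dimensions) polished by bounded Levenberg–Marquardt
  (`minpack.lm`). Refits with the same seed are bit-reproducible, and the
  best-of-$k$ objective is non-increasing in $k$.
* **Ill-conditioning.** The VCN kinetic prefactor is notoriously weakly
  determined (fitted values spanning $10^{8}$–$10^{27}$ are on record).
  Results carry a warning flag when a tenfold $\Omega_0^{VCN}$
  perturbation moves the objective by less than $10^{-3}$, and when a
  critical-volume estimate pins at a bound.

## Synthetic data

`ground_truth()` fixes a generating model and study design;
`generate_volume_observations()` and `simulate_iif_events()` emulate the
two observation-table types, and `empirical_pif()` tallies cumulative
event fractions. Event temperatures are drawn by inverse-CDF sampling on
the cumulative hazard; the mechanism at an event is attributed by a
Bernoulli draw with probability $h_{SCN}/(h_{SCN}+h_{VCN})$ at the event
temperature, which is exact for competing risks with independent hazards.
The generator labels SCN events "darkening" and VCN events "twitching" as
a configurable convenience (`label_map`); the association is a
simplification hook, not a mechanistic claim, and the fitting pathway never
uses the labels.

The default design mirrors the study conditions the package is built
around: volume tables at 5–60 °C/min (30 cells/rate, 2% multiplicative
noise, sampled every 2 K from $-0.5$ to $-45$ °C) and event tables at
45–100 °C/min (200 cells/rate, to $-50$ °C), for a HeLa-like cell of
radius 7.51 $\mu$m with $L_{pg} = 0.1166\ \mu$m min$^{-1}$ atm$^{-1}$ and
$E_{Lp} = 11.9236$ kcal/mol. Two generator defaults deserve comment:

* $V_b$ is usually fitted but rarely printed; the default $0.25\,V_0$ was
  chosen once so that the predicted dehydration curves cross the
  0.30–0.55 $V_0$ critical-volume range inside the experimental window at
  the IIF cooling rates, as the coupled model requires for plateaus to
  appear there.
* Published nucleation parameter values are conditional on the particular
  $V_b$ and viscosity constants used in the source fits and do not
  transplant across those choices (under this package's defaults, a
  literature $\kappa_0^{VCN}$ of $5\times10^{11}$ K$^5$ predicts
  essentially no VCN above $-50$ °C). The generator instead uses a set
  calibrated once against the reported *observables*: total PIF plateaus
  between roughly 0.3 and 0.75 increasing with cooling rate over
  45–100 °C/min, an SCN-dominated rise at about $-10$ to $-35$ °C, VCN
  appearing at deeper supercooling and faster rates, and critical volumes
  $V_f^{SCN} = 0.45\,V_0 > V_f^{VCN} = 0.36\,V_0$ inside the reported
  0.30–0.55 range.

All randomness flows from one mandatory seed through named substreams
(volume noise, event draws, mechanism attribution), so fixtures are
bit-reproducible; tables round-trip losslessly through the CSV schemas in
`read_volume_table()` / `read_iif_table()` (°C in files, K in memory).

What the generator does *not* emulate: imaging artifacts (e.g. the
transient apparent volume increase sometimes seen at $-3$ to $-7$ °C at
fast rates), cell movement during ice seeding, membrane leakage after
IIF, inter-cell parameter heterogeneity, or any mechanistic tie between
morphological label and mechanism. Passing recovery tests therefore show
that the estimation machinery is correct and adequately powered under the
stated design — not that real cryomicroscopy data are free of systematic
effects outside the model.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run the pipeline at the study
design above: 5 rates × 30 cells of volume data and 4 rates × 200 cells of
event data for the recovery loop, 10,000 cells for the Monte-Carlo
consistency check, $10^5$ oracle sub-intervals for the quadrature check,
and 1 mK Euler steps for the ODE check. With those sizes the full recovery
loop completes in a few minutes on one core; recovery accuracy is limited
by sampling noise, not search effort (the fitted optimum typically
attains a lower objective than the generating parameters).

## Limitations

* **Deep-subzero contrast between the models.** With the free-volume
  constants used here, viscosity diverges near 156 K and quenches all
  nucleation below about $-80$ °C. One consequence is honest and
  reported: when the *original* (ungated) model is fitted to data that
  plateau at ~0.5, a parameterization exists whose hazard is quenched by
  the viscosity term plus dehydration feedback, so the fitted original
  model can itself plateau (predicting ≈0.5 at $-100$ °C in the shipped
  contrast check) instead of racing to 100% as classically reported. The
  qualitative blow-up of the ungated model is therefore conditional on
  the viscosity parameter set; the gated model's advantage here shows up
  as a ~100-fold smaller fitting SSE and a prediction that stays within
  0.007 of the plateau, rather than as a dramatic divergence of the
  ungated curve.
* **Identifiability of the critical volumes.** Under the 4 × 200-cell
  design the absolute recovery error of the critical-volume fractions
  across data seeds is typically 0.02–0.03 $V_0$, with occasional
  realizations up to about 0.06 $V_0$ (the fitted optimum then attains a
  *lower* objective than the generating parameters, i.e. the limit is
  sampling noise, not search effort). The information sits in a narrow
  plateau-onset window; larger designs or per-mechanism observables would
  sharpen it.
* **Scope.** No cryoprotective-agent chemistry, no ice growth or
  recrystallization, no vitrification kinetics beyond the phenomenological
  viscosity divergence, no population heterogeneity, and no image
  analysis: event labels are carried through the data model but never
  classified from images.
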