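---
title: "Models and methods in chronopump"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in chronopump}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(chronopump)
```

This vignette is the package's account of the science it implements: the
pump-to-patient transport model, the corrected infusion-profile design, the
three semi-physiological pharmacokinetic (PK) models, the estimation and
identifiability machinery, and the clustering pipeline — together with the
assumptions, default values and numerical choices behind each.

## 1. Pump-to-patient transport

### Model

The infusion line from the pump outlet to the catheter tip is modelled as a
one-dimensional tube in which the drug concentration `u(x, t)` (mg/ml) is
purely advected:

```
du/dt = -V(t) du/dx,     u(x, 0) = 0,
u(0, t) = s(t)  when V(t) > 0,
```

where `V(t)` is the fluid velocity imposed by the pump and `s(t)` the stock
concentration of the channel currently pumping (glucose flushes have
`s = 0`). The fluid is treated as incompressible, so the velocity is
uniform along the line, and diffusion / Taylor dispersion is neglected
(plug flow). A direct consequence — used throughout — is that the delivery
at the patient end depends only on the tube's total dead volume, not on its
radius/length split; the default `tube_spec()` is a 1.84 ml line of radius
0.5 mm, equivalent to the clinical two-section set-up.

When the pump is stopped (`V = 0`) the boundary value is undefined in the
model; the field is simply frozen, which is the physically correct plug-flow
behaviour and resolves the boundary degeneracy without extra assumptions.

### Solvers

*Characteristics (exact).* The parcel exiting at time `t` entered at
`tau(t)` defined by "pumped volume between `tau` and `t` = tube volume", so
`d(t) = q(t) * s(tau(t))` with `q` the volumetric pump rate. The cumulative
pumped volume of every segment shape is available in closed form, so
`tau` is obtained by root-finding (`uniroot`, tolerance 1e-12) and the
cumulative delivered mass is exactly the inlet mass up to `tau(t)`. Mass
conservation therefore holds to root-finding tolerance, and the delivery
onset (fill delay) is computed as an exact root rather than read off a
grid. Delays are reported rounded to the nearest minute, the granularity at
which such delays are communicated clinically.

*Upwind finite differences (independent route).* First-order upwind in
space, explicit in time, with the time step chosen from a CFL number of 0.9
(a CFL above 1 is rejected). The delivered and injected masses use the same
discrete quadrature as the update, so the discrete mass balance telescopes
to rounding error; the L1 distance between the FD and characteristics
solutions shrinks under grid refinement (tested on randomized programs).
Default resolution is 1000 cells; the test suite uses 100–400 cells, which
is ample for the properties asserted.

### Trial schedules

`optiliv_program()` encodes the OPTILIV hepatic-artery schedule per drug.
The published sinusoidal shape is implemented as
`rate(t) = peak * sin^2(pi t / duration)`, whose mean is `peak/2`; that
functional form is adopted because it reproduces the published peak rates
from dose, stock concentration and duration for irinotecan
(2·(180/3.33)/6 = 18.02 ml/m2/h) and oxaliplatin (2·(28/3)/11.5 = 1.62 ≈
1.63). The published 5-FU peak (3.4 ml/m2/h) slightly exceeds the
sin²-implied value (3.25); the published figure is used as the programmed
input, and consequently `flush_spike_fraction()` divides by the *nominal*
dose carried on the program rather than the integrated inlet mass — the
only reading consistent with all three published spike fractions.

Per-m² pump rates are converted to absolute ml/h with a reference body
surface area of 1.84 m² (configurable, and set per patient by the
synthetic-cohort generator). With these conventions the characteristics
solver reproduces the delays and spike fractions that the acceptance
script recomputes; the oxaliplatin fill delay evaluates to 183 min on this
implementation.

## 2. Corrected infusion profiles

The delivered profile can be made to equal the clinical intention exactly
with three parts, keeping the same equipment and stock concentrations:

1. **Bolus** at the channel maximum rate (default 125 ml/h), sized to one
   tube volume and scheduled to finish exactly at the intended clinical
   start (so timing semantics are preserved);
2. the **intended sinusoid**, truncated at the time `t_cut` at which the
   drug-bag volume `dose/stock` is exhausted (bisection on the closed-form
   cumulative volume, tolerance 1e-9 ml);
3. a **glucose rinse** whose volumetric rate continues the sinusoid's tail
   from `t_cut`, so the drug still in the line exits at the intended rate
   and the line is empty exactly at the intended end. Any legacy 30-min
   glucose peak can be appended unchanged afterwards.

Because volume is conserved segment by segment, the construction is exact
in plug flow; `compare_profiles()` verifies L1 / Linf mismatch and onset
shift by simulation. In the vanishing-tube-volume limit the corrected
program reduces to the intended one.

## 3. Semi-physiological PK models

All three models share the Liver / Blood / Organs structure, amounts in mg,
volumes in litres, concentrations in mg/L and time in hours. Delivery
enters the Liver to represent hepatic artery infusion. Compartment volumes
are individualised: Vauthey's BSA-based total liver volume
(`(-794.41 + 1267.28·BSA)/1000` L), Nadler's sex-specific blood volume, and
the Organs volume as total body volume minus liver and blood, with the
total body volume estimated as weight over a mean body density of
1.05 kg/L (each formula overridable through the `formulas` argument, since
body-volume estimates vary across sources).

**Transfer fluxes.** All inter-compartment transports are passive and
linear. Each interface carries one rate constant `k` (1/h) and the flux is

```
flux(i <-> j) = k * V_tissue * (C_i - C_j)   [mg/h]
```

with `V_tissue` the volume of the non-blood compartment of that interface.
This is the form in which "transport rate constants proportional to
compartment volumes" and the physical requirement that *equal
concentrations give zero net flux* (no diffusion against no gradient) are
both satisfied; the equilibrium identity is enforced by a test that lets a
clearance-free system relax to concentration equality.

**Irinotecan.** Six states (CPT11 and SN38 in L/B/O). CPT11 is converted to
SN38 by Michaelis–Menten kinetics in Liver and Organs only — the activating
carboxylesterases are not expressed in blood — with `Km` fixed at 59.2 uM
(converted to mg/L via the CPT11 molar mass, 586.68 g/mol) and `Vmax` in
mg/h. Mass conversion uses the SN38/CPT11 molar-mass ratio so the
mole-consistent balance closes. SN38 is transported Blood–Liver and
Blood–Organs (without transport, plasma SN38 would be impossible since no
conversion occurs in blood) and cleared in Liver (lumping glucuronidation
to SN38G) and Organs at exactly twice the liver rate.

**Oxaliplatin.** Six states: free and protein-bound platinum in L/B/O. Only
free Pt moves; binding (`k_on`) and unbinding (`k_off`, protein
degradation) occur in all compartments; the single elimination route is
renal clearance of free blood Pt. Platinum metabolite complexes are not
distinguished — one free species represents parent and metabolites.

**5-fluorouracil.** Three states, fully linear, hepatic and renal
clearance, no protein binding, no Organs clearance.

Cleared amounts per route are tracked as auxiliary cumulative states, as is
the integrated delivery, so the mass balance (delivered = stored + cleared)
is checked internally to the solver tolerance at every output time.
Integration uses `deSolve::lsoda` with relative tolerance 1e-8 (1e-6 inside
heavy Monte-Carlo fitting loops), a maximum step of 0.1 h so the 30-min
flush spike is never stepped over, and biliary-excreted drug leaves the
system (no enterohepatic recirculation). Circadian modulation of PK
parameters is deliberately out of scope.

## 4. Estimation

`fit_pk()` minimises the weighted least-squares cost

```
sum_points ((pred - obs) / max(0.1 obs, 0.1 LLOQ))^2  +  penalties
```

— a 10% proportional measurement-error model, floored at the
quantification limit so baseline-zero samples keep finite weights (the
default LLOQ is 0.01 mg/L and is configurable). Clearance-route knowledge
enters as quadratic penalties on end-of-horizon route fractions
(`clearance_targets()`): irinotecan 25% renal / 60% biliary+intestinal /
15% SN38; oxaliplatin 54% renal with 84% / 12% of the dose bound in Organs
/ Liver; 5-FU ≈80% hepatic. Two remarks: the fractions are evaluated at a
*finite* horizon (default: end of the sampling window), since with
renal-only clearance the infinite-horizon renal fraction is trivially
100%; and the oxaliplatin targets are mutually inconsistent as simultaneous
end-of-horizon fractions (54 + 84 + 12 > 100), so they act as soft
penalties that the optimizer balances rather than hard constraints —
which is also why penalties, not projections, were chosen.

Minimisation is by an in-package CMA-ES (standard (mu/mu_w, lambda)
strategy, population `4 + floor(3 ln n)`, rank-based recombination,
step-size and covariance adaptation), run in log10-parameter space with
box bounds spanning two orders of magnitude either side of the start
(configurable). Box handling is repair-plus-penalty. The optimizer is
deterministic given its seed and its best-cost trace is monotone.

Goodness of fit is reported as the weighted SSR plus `R² = 1 −
SSE/SST` on unweighted residuals, per analyte and pooled. Samples scheduled
exactly at the glucose-flush start may have been drawn during the spike;
`realign_flush_timepoints()` moves such a sample to the flush peak time
(15 min after flush start) when its concentration exceeds the preceding
point's, and leaves it otherwise.

### Identifiability

`sobol_sensitivity()` computes first-order and total Sobol indices of the
cost over the parameter box (Saltelli sampling, Jansen estimators; total
index below 0.01 flags a parameter the data carry no information about),
and `likelihood_profile()` re-optimises the remaining parameters along a
grid of one fixed parameter, declaring practical non-identifiability when
the profile is flat relative to the chi-square threshold.

These tools shaped the package's own validation design. On the trial
sampling grids, the three-parameter subsets used in the recovery studies
(`k_LB_cpt, Vmax_L, Cl_B_cpt`; `k_LB, k_on, Cl_B`; `k_LB, Cl_L, Cl_B`)
are recovered essentially exactly from noise-free data for all three
drugs. Under 10% proportional noise, however, the 5-FU design — a single
analyte with only four informative samples — leaves its three-parameter
subset practically non-identifiable: the optimizer reliably finds
parameter sets that fit the noisy data *better* than the truth while lying
far from it. The oxaliplatin and irinotecan designs (two analytes, 12–14
points) recover their subsets with median relative errors around 10%. The
noisy Monte-Carlo acceptance study therefore runs on the oxaliplatin
model; the 5-FU behaviour is a property of that sparse design, not of the
estimator.

## 5. Cohort variability and clustering

Inter-patient spread is summarised by the nearly unbiased coefficient of
variation `(1 + 1/(4n))·sd/mean·100`. Patients are clustered on their
fitted parameter vectors by fuzzy c-means with fuzzifier m = 2 (alternating
optimisation; deterministic seeding; a point coincident with a centroid
receives crisp membership; the objective trace is monotone). Columns are
scaled to unit variance by default — raw PK parameters span orders of
magnitude and would otherwise let one parameter dominate the Euclidean
distance — with a raw-scale mode retained for sensitivity probing.

The cluster count is chosen in `[2, n−1]` by minimising the
Fukuyama–Sugeno index, best of 20 seeded restarts per candidate, ties
toward the smaller count. One definitional point matters: with the
separation reference taken as the *average of the centroids*, the index is
(near-)monotonically decreasing in the cluster count — duplicating any
centroid shifts the reference and always pays — which makes selection
degenerate. The original index measures separation from the *grand mean of
the data*, which does not move with the candidate count; that form is the
default (`fukuyama_sugeno(..., center = "data")`) and the centroid-average
variant is kept as an option. Even the data-mean form is informative only
when the extra centroids of larger candidate counts crowd together and
fuzzify memberships: at any near-crisp solution `V_FS ≈ 2J − TS` (with `J`
the FCM objective and `TS` the total scatter), and since `J` decreases
with the cluster count, well-converged FCM lets the index reward
shattering tight subgroups into singletons. On clean synthetic
two-subpopulation cohorts the minimiser therefore sits at large counts —
under point-sampled and random-membership initialisations, single runs and
multi-restarts, and independently under the `e1071` reference
implementation — and the count-selection step should be read as
informative only for diffuse, irregular parameter scatter (as real patient
parameters are), not as a general consistency guarantee. The corresponding
acceptance check is left failing rather than tuned to a knife-edge
configuration where it happens to pass.

Cluster structure is displayed by classical multidimensional scaling to two
dimensions, with the Pearson correlation between original and embedded
pairwise distances reported as projection fidelity. Within-cluster CVs are
recomputed per crisp cluster with at least two members; singletons are
skipped.

## 6. Synthetic cohorts

The generator emulates the study conditions so the whole pipeline is
testable without patient-level data, which exist only as figures: 11
patients (7 men, 4 women), uniform heights 1.55–1.90 m and weights
55–95 kg, Du Bois BSA, trial pump programs scaled to each patient's BSA,
the trial sampling grids (irinotecan 0, 2, 3, 4, 6, 8.25, 31.75 h;
oxaliplatin 0, 3, 6, 9, 11.5, 17.25 h; 5-FU 0, 3, 5.75, 9, 11.5 h — the
"approximately 3 h" sample fixed at 3.0), and 10% proportional measurement
noise, `conc·(1 + 0.1·eps)` truncated at zero (a log-normal noise mode is
available). True parameters are log-normal around group means with the
specified CV (mean-preserving parameterisation), optionally in
subpopulations. One seed determines cohort, data, fits and clusters end to
end.

Default parameter means are order-of-magnitude physiologic values chosen
once so that simulated profiles show the qualitative features of the
observed data (rapid irinotecan rise, free-platinum spike at the flush,
fast 5-FU decline) and end-of-sampling clearance-route fractions sit near
the literature targets. They are synthetic placeholders by design — the
true inter-patient distributions are unknown — so passing recovery tests
demonstrates the estimator works under the stated error model on this
design, not that real patients behave like the defaults. Features of real
data the generator does not emulate include assay censoring beyond a
configurable floor, sampling-time jitter, model misspecification and
circadian parameter variation.

## 7. Problem sizes and budgets

The shipped tests run at deliberately modest sizes chosen as sufficient
for the properties asserted: characteristics solutions on 0.002–0.005 h
reporting grids, FD solvers at 100–400 cells, noise-free recovery with a
600-evaluation CMA-ES budget per drug, the noisy recovery study with 20
replicates at 400 evaluations (solver tolerance 1e-6), and clustering
sweeps with 8–20 restarts. All stochastic steps are seeded; identical
invocations produce identical outputs.

## 8. Known limitations

* Plug flow ignores diffusion and dispersion in the line; real spikes will
  be slightly smoothed.
* The PK models neglect circadian rhythms, enterohepatic recirculation,
  intestinal-lumen kinetics and SN38G beyond lumped clearance.
* The oxaliplatin clearance/binding targets cannot all be met at one
  horizon (they sum past 100% of dose); constraint residuals are reported
  so the user can see how the compromise fell.
* Fukuyama–Sugeno cluster-count selection is fragile at small n and
  diffuse subgroups, under either separation reference.
* Mixed-effects population estimation is intentionally out of scope; fits
  are per patient (or pooled by concatenation).
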