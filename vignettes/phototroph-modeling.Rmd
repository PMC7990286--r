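---
title: "Modeling phototroph metabolism: light, maintenance, and nitrogen starvation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling phototroph metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photofba)
```

This vignette is the package's account of its science: the models and
procedures it implements, the assumptions behind them, the parameters
that matter, what the synthetic study system does and does not emulate,
and the numerical choices made where the design was genuinely open.

## The constraint-based core

A metabolic model is a stoichiometric matrix $S$ (metabolites x
reactions) with flux bounds. Flux balance analysis assumes intracellular
steady state, $S v = 0$, and maximizes a linear objective over
$LB \le v \le UB$. Parsimonious FBA then fixes the achieved objective and
minimizes total absolute flux $\sum_i |v_i|$ — a proxy for minimizing
enzyme investment — which collapses the usually-degenerate optimal set to
a single, futile-cycle-free solution. All condition constraints are
linear flux-sum relations $lb \le \sum_i w_i v_i \le ub$ attached to the
model; nothing kinetic is modeled at the reaction level.

The LP engine is a dense bounded-variable two-phase primal simplex
written for this package. Three numerical choices matter:

* **Tolerance** is $10^{-8}$ throughout (optimality and feasibility),
  exposed as an argument on the solvers.
* **Rank deficiency** is routine in stoichiometric matrices (conserved
  moieties), so artificial variables stay in the working problem
  permanently, pinned to zero after phase 1; the basis can then never be
  structurally singular.
* **Equilibration**: rows are scaled to unit maximum and variables
  substituted so columns are too. Biomass reactions put coefficients of
  several thousand (growth-associated maintenance) next to trace pigment
  stoichiometry of $10^{-4}$; without scaling the basis condition number
  degrades until pivoting fails. Degenerate cycling is handled by
  switching from largest-reduced-cost pivoting to Bland's rule after a
  run of degenerate steps, and the ratio test prefers large pivot
  elements within a small window of the minimal ratio.

Phase-1 fixing in pFBA uses $(1 - 10^{-6})$ times the phase-1 optimum
rather than exact fixing, avoiding spurious infeasibility at the
tolerance boundary. Ties among equal-$\sum|v|$ optima are
solver-determined; tests assert set-level properties only.

## Mechanistic light harvesting

Photon supply is resolved into fifteen 20 nm wavebands spanning
photosynthetically active radiation (400--700 nm), keyed by the lower
band edge — the binning convention is ours. Per band,
$$LB_\lambda = -\,r_\lambda \, I \, a_\lambda \times 3.6, \qquad
  UB_\lambda = 0.9999\, LB_\lambda,$$
where $r_\lambda$ is the light source's photon-flux fraction in the band,
$I$ the irradiance (µmol photons m⁻² s⁻¹), and $a_\lambda$ the
biomass-specific absorption (m² gDW⁻¹) assembled from pigment mass
fractions times weight-specific pigment spectra. The factor 3.6 converts
µmol gDW⁻¹ s⁻¹ to mmol gDW⁻¹ h⁻¹. The 0.9999 factor makes absorption
*obligatory*: a cell in the light cannot decline incident photons, it can
only dissipate them — which is why explicit de-excitation (heat/
fluorescence) reactions must exist; removing them makes high light
infeasible, the stoichiometric form of photoinhibition.

Absorbed photons become pigment-specific excitation states, transferred
to reaction-center chlorophyll *a* with per-pigment efficiencies
(defaults: chl *c* 0.95, fucoxanthin 0.80, and low values, 0.15--0.20,
for the photoprotective carotenoids diadinoxanthin and β-carotene).
These efficiencies, like the built-in smooth pigment spectra and the
cool-white source spectrum, are clearly-labeled assumptions — replace
them with measured tables via `pigment_profile()` for real work.

**Unit convention for electron flow.** Charge-separation fluxes (PSIICS,
PSICS) count single electrons — one exciton per electron, 4 electrons
per O2 at PSII — while quinol-level reactions (cytochrome *b₆f*, cyclic
electron flow, the plastid terminal oxidase) count two-electron quinol
units. This is the only assignment under which the total-electron-flow
expression $PSICS + PSIIICS - 2\,CBFC2 + 2\,CEF$ actually measures
electrons; with PSII in O2 units the expression can go negative.

D1 photodamage enters as a massless by-product of PSII, at
`slope * I / phi_m` events per O2 evolved (linear in irradiance), and a
repair reaction charges ATP per event — photodamage as metabolic cost,
with charge recombination modeled as explicit loss reactions so the
stoichiometry stays auditable.

## Biomass objectives, frustule, redox descriptors

A measured composition (g per gDW, or pg per cell divided by the
composition's own total dry weight) becomes a biomass reaction with
coefficients $1000\, w_i / M_{r,i}$ mmol gDW⁻¹; mass closure to 1 g is
asserted to $10^{-6}$. When components do not sum to the measured dry
weight, the residual is assigned to the silica frustule — the component
that is typically inferred, not measured.

Frustule chemistry: condensation of Si(OH)₄ releases $2q$ H₂O per Si for
condensation fraction $q$ (from NMR Q-speciation), leaving a unit
SiO$_{4-2q}$H$_{4-4q}$; at the default $q = 0.75$ that is SiO₁.₅(OH),
Mr 69.1. Frustule weight scales with growth rate linearly under light
limitation (negative slope: slow-dividing cells silicify most) and as a
power law under N limitation.

Degree of reduction $\gamma$ — electron equivalents per gram atom C — is
computed as $(4C + H - 2O + nN + 5P + 6S)/C$ with the nitrogen reference
configurable. The default is nitrate ($n = +5$): protein-rich biomass
then exceeds $\gamma = 5$, consistent with published diatom values,
whereas the ammonia reference ($n = -3$) cannot reach them. The
photosynthetic quotient (mol O₂ per mol CO₂ for new biomass) is obtained
by balancing biomass synthesis from CO₂, H₂O and the N source; the
identity $PQ_{NO_3} - PQ_{NH_4} = 2N/C$ (8 electrons per nitrate, 4 per
O₂) holds exactly and is tested as such.

## ATP maintenance

Photosynthesis–irradiance curves are fit by multi-start
Levenberg–Marquardt least squares (starting values from the data: plateau
for $P_s$, initial slope for $\alpha$), and confidence bands propagate by
the first-order delta method — matching a "95% confidence interval"
specification without assuming a bootstrap. The compensation irradiance
$I_c = I_k\,\mathrm{atanh}(-DR/P_s)$ converts, through the chlorophyll-
specific absorption, the chl:dry-weight ratio, the quantum efficiency
$\phi_m$ and the ATP yield per O₂ $e$, into a closed-form upper bound on
non-growth maintenance. $e$ defaults to 3 mol ATP per mol O₂ — the
approximate ATP yield of linear electron flow per O₂ when its NADPH is
also counted in ATP equivalents — and is a config parameter because the
published value lives in supplementary data.

Growth-associated maintenance is calibrated per condition by bisection on
the GAM coefficient embedded in the biomass reaction until optimal growth
matches the measured rate (0.1% relative by default); monotonicity of
growth in GAM is verified during the search, and a measured rate above
the zero-GAM maximum raises an error reporting the feasible maximum. The
regression route (ATP optimum against growth rate; slope = GAM,
intercept = NGAM) is provided for comparison — with few chemostats it
yields enormous standard errors, which is precisely the motivation for
the closed-form and iterative routes.

## The dynamic-FBA loop

The batch simulation divides ten days into eighty 3 h intervals under a
12:12 light:dark cycle starting at dawn. Per interval:

1. **Objective.** The difference between target composition (pg/cell ×
   interpolated cell count, fold-change-scaled for the diel storage
   compounds in the light) and simulated composition. Positive
   differences, normalized, form the biomass objective; when the
   difference vector has mixed signs only the positive components enter,
   the negative ones feed remobilization — the normalization formula is
   ambiguous on this point and this is our reading. Pigments,
   chrysolaminarin and triacylglycerides are dropped from dark objectives
   (no light-independent protochlorophyllide oxidoreductase; storage
   compounds are consumed at night). If nothing needs production the
   objective switches to ATP maintenance.
2. **Bounds.** Uptake: $-\min(V_{max} x/(K_m + x),\ x/(bio\,\Delta t))$,
   whichever is closer to zero; water and protons bypass the pool limb
   (solvent and pH-buffered species). Remobilization: sinks may supply
   declining components up to the surplus; chlorophyll *a* additionally
   gets a *forced* degradation demand matched to its decline, with
   products routed to a demand because its catabolic pathway is
   uncharacterized — this is flagged, and logged in the mass ledger.
   Photon absorption reactions are rebuilt each interval from the
   simulated pigment composition; PSII is bounded by the FRRf-style
   confidence band converted from per-chlorophyll to per-dry-weight
   units with the simulated chl:biomass ratio.
3. **PQ coupling** (light intervals): O₂ evolution per unit dissolved
   inorganic carbon uptake confined to the ammonium--nitrate PQ window of
   the interval's new-biomass formula, scaled by 102% by default — the
   condition under which organic-sulfur secretion is most visible in the
   95--105% exploration range. Carbon-free intervals (frustule-only
   targets) have no ratio to constrain and skip it.
4. **Solve and advance.** pFBA; on infeasibility the objective falls back
   to ATP maintenance, then to a recorded zero-growth hold — never
   silent. Biomass advances as $bio\,e^{\mu\Delta t}$ and each
   environment metabolite as
   $x_j + (v_j/\mu)\,bio\,(e^{\mu\Delta t} - 1)$, with the explicit-Euler
   limit below $\mu = 10^{-9}$. O₂, CO₂ and HCO₃ reset to fixed
   atmospheric-equilibrium values (390 ppm pCO₂ carbonate system,
   bubbled, well-mixed culture).

**A known, quantified approximation.** The availability bound is linear
in biomass while the within-step update integrates exponential growth, so
consumption can overshoot a nearly-empty pool by at most
$(e^{\mu\Delta t} - 1)/(\mu\Delta t) - 1$ — about 6% at these growth
rates. The overshoot is clamped to zero and logged; on the reference
trajectory total clamped mass is under 0.1% of environmental throughput,
and the elemental conservation test closes every element (other than H
and O, which flow through the explicit water/proton reservoir) to
$10^{-6}$ relative per step using the gas, clamp and chlorophyll-
degradation ledgers.

The unit rescaling step some pipelines use before the LP (mmol to µmol,
against tiny-flux precision loss) is unnecessary here: the solver
equilibrates internally, so the scale knob exists in the config but stays
at 1.

## The synthetic study system

`make_toy_phototroph_model()` builds a ~185-reaction, six-compartment
network (cytosol, plastid, thylakoid lumen, mitochondrion, peroxisome,
extracellular) with the canonical machinery: the full thylakoid electron
chain, RuBisCO carboxylase/oxygenase with a lumped Calvin route, the
truncated photorespiratory glycolate route, Mehler/PTOX/AOX/cytochrome-
oxidase dissipation, nitrate and sulfate assimilation through to DMSP and
DHPS, silica condensation, fermentative by-products, maintenance, and a
composition-parameterized biomass. Construction closes every reaction's
O, H and charge books with water, protons and a redox couple by solving a
small exact linear system — a wrong skeleton cannot slip through, and the
balance test verifies all of it independently. Lumped species use
documented formulas (the protein unit is a glutamate residue carrying
0.5% w/w cysteine/methionine sulfur; RNA an AMP-like unit; the membrane
lipid a galactolipid). Real small molecules use their standard formulas.

The chemostat generator anchors per-cell dry weights (22.4/16.6/17.8 pg),
frustule (5.2/1.6/0.7 pg) and protein (10.5/4.3/3.3 pg) to published
values for cells acclimated to 5/60/200 µmol photons m⁻² s⁻¹ and fills
the remaining components with realistic splits (carbohydrates rising with
light, pigments falling). Its P–I curves use dark respiration at 15--25%
of $P_s$, placing compensation irradiances at ~2 (low light) to ~27
(high light) µmol photons m⁻² s⁻¹.

The batch generator emulates the structure of a ten-day N-starvation
experiment sampled at days 0/1/3/7/10: protein per cell holds its
N-replete value through late exponential then falls ~3.5-fold;
storage carbohydrate and TAG rise; DNA accumulates as division stops;
chlorophyll declines; osmolytes dilute during fast division and
accumulate in stationary phase (DMSP replacing N-rich osmolytes under
N starvation); cell counts (1.5 → 3.2 × 10⁹ L⁻¹) are chosen so the
20 µM nitrate pool is spent within the first day and the ten-day
nitrogen budget stays inside initial nitrate + biomass N. Initial
sulfate is at seawater scale (28 mM) against that low nitrate.

**What passing tests do and do not show.** The fixtures are structurally
and qualitatively faithful — compartments, pathway topology, balanced
stoichiometry, acclimation gradients, starvation phenomenology — but make
no claim of numeric fidelity to any measured dataset. A green suite shows
the algorithms are correct and the pipeline reproduces the qualitative
biology (nitrate depletion before growth cessation, the nitrogen-to-
sulfur redox handoff, diel secretion cycling); it does not validate
predictions for a real culture, which requires the deposited genome-scale
network and measured constraint sets.

## Problem sizes and runtime

The defaults are sized for interactive use: the mini-network solves FBA
in well under a second and pFBA in about one; the 80-interval batch run
(~2 pFBA solves per interval on ~185 reactions) completes in about two
minutes; the property suite (enumeration oracles up to 6 reactions, 50
seeded noisy fits, a cached full batch trajectory shared across test
files) runs end to end in a few minutes.

## Known limitations

* No flux variability analysis, gap-filling, or bilevel network repair;
  energy-generating cycle detection reports repairs, it does not apply
  them.
* No non-photochemical-quenching kinetics: photoprotective pigments act
  only through absorption and loss stoichiometry.
* Chlorophyll degradation products are unresolved (demand reaction with
  a mass ledger), as the pathway itself is uncharacterized in diatoms.
* The SBML layer covers the constraint-based subset (species, bounds,
  gene associations, objective, subsystem notes); auxiliary flux-sum
  constraints are runtime objects and are not serialized.
* The secretion identity of the toy network under strong redox forcing
  leans on its small fermentative repertoire; a genome-scale network
  distributes the same electron pressure over many more routes.
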