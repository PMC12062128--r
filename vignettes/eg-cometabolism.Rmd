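---
title: "Modeling ethylene glycol co-metabolism in Rhodotorula toruloides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling ethylene glycol co-metabolism in Rhodotorula toruloides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egflux)
```

## The biological problem

The oleaginous red yeast *Rhodotorula toruloides* oxidizes ethylene glycol
(EG, C2H6O2, the diol monomer of PET plastic) to glycolic acid (GA, C2H4O3)
through the intermediate glycolaldehyde (GAH), without assimilating any of
the carbon into biomass: EG serves purely as an energy/redox source. Each EG
oxidized to GA hands two electron pairs to NAD(P)+, so EG co-feeding can
regenerate reduced cofactor. That matters most on xylose, whose canonical
fungal assimilation route is redox-asymmetric: xylose reductase (XR)
consumes NADPH while xylitol dehydrogenase (XDH) produces NADH, leaving the
cell short of NADPH. On glucose, EG oxidation is repressed until nitrogen
runs out; in the nitrogen-limited (Nlim) phase — the same phase in which
this yeast accumulates lipid — EG is converted to GA at essentially 100%
molar yield. On xylose the measured GA yield in the Nlim phase exceeds
100%, which requires a second carbon source for GA; candidate routes are a
xylulose-1P aldolase side activity (D-xylulose -> DHAP + GAH) and reduction
of glyoxylate coming off the peroxisomal glyoxylate shunt.

This package rebuilds that analysis as three testable layers:

1. `model_core` / `fba_engine` — a reduced, elementally balanced core
   network with the curated EG pathway in two cofactor flavors, and a
   linear-programming engine (FBA, parsimonious FBA, flux variability,
   seeded flux sampling, uptake-normalized reporting);
2. `physiology` — the batch-fermentation calculus (growth rates, phase
   detection, specific rates, yields, carbon balance, RQ, media
   stoichiometry);
3. `synthetic_data` — a seeded generator of two-phase batch cultures that
   stands in for bioreactor data and defines ground truth for every
   estimator.

## The reduced core network

The genome-scale model of *R. toruloides* has thousands of reactions; this
package deliberately rebuilds only the central-carbon core needed for the
EG questions (91 reactions, 83 metabolites with every option enabled),
with compartments e/c/m/p and full elemental bookkeeping over C,H,O,N
(P and S are tracked where formulas carry them). Every internal reaction
balances C,H,O,N to 1e-9; `check_mass_balance()` asserts this and exempts
only the system boundaries (exchanges) and the biomass pseudo-reaction,
whose carbon must still match the biomass composition exactly.

Deliberate simplifications, each visible in the reaction names:

* the oxidative PPP and the non-oxidative TKT/TAL block are lumped into
  single balanced reactions (`G6PDH_GND`, `TKT_TAL`);
* succinate dehydrogenase is written NAD-linked rather than
  quinone-linked, keeping the cofactor alphabet to NAD/NADP; this slightly
  inflates the P/O yield on succinate and does not touch any EG claim;
* respiration is one lumped reaction with P/O = 2
  (`nadh_m + 3 h + 0.5 o2 + 2 adp + 2 pi -> nad + 2 atp + 3 h2o`);
* glycine produced by alanine-glyoxylate aminotransferase is drained by a
  lumped full oxidation (`GLYOXm`);
* biomass is CH1.8O0.5N0.2 per Cmol (24.63 g/Cmol, 11.4% N w/w), the
  generic yeast composition, assembled from G6P, pyruvate, acetyl-CoA,
  glutamate plus configurable ATP (2.5 mol/Cmol) and NADPH
  (0.45 mol/Cmol) demands. The NADPH demand is the lipid-synthesis sink,
  and it is what makes the cofactor question non-degenerate (below).

The curated EG pathway follows the two-step oxidation: an EG dehydrogenase
(`EGDH_NAD`, `EGDH_NADP`; both irreversible oxidative — the literature
reports the reductive GRE2-homolog activity separately, so `GRE2` is
included reductively but bounded to zero) and a glycolaldehyde
dehydrogenase in both flavors (`GAHDH_NAD`, `GAHDH_NADP`, mirroring the
wide-spectrum aldehyde dehydrogenases). Glyoxylate reductase is present
twice, cytosolic NADP (`GLYCLTDy`) and mitochondrial NAD (`GLYCLTDxm`),
reversible by default; `build_core_model(ga_reoxidation = FALSE)` closes
the GA -> glyoxylate direction to reflect the observed 100% GA yield. The
D-xylulose-1P aldolase route and a glyoxylate exchange are optional flags,
off by default, because the observations they explain (GA yield above
100%) are specific to xylose/Nlim conditions.

Two open placements were decided here: the D-arabitol pair is written as
NAD-linked 2-dehydrogenase (forming D-xylulose) and NADP-linked
4-dehydrogenase (forming D-ribulose, rekindled by a ribulokinase), the
assignment that reproduces the redox-cycle reading of the arabitol loop;
and EG dehydrogenases are irreversible oxidative since their physiological
direction in vivo is the open question the wet experiments address.

Serialization stores every coefficient as a decimal string with 17
significant digits, so a JSON round trip is bit-for-bit exact; a TSV
reaction table (id, equation, bounds, subsystem, cofactor) is written
alongside for human eyes.

## The flux engine

`solve_fba()` maximizes (or minimizes) an objective flux subject to
S v = 0 and bounds. No linear-programming backend is assumed: the package
carries a dense bounded-variable two-phase revised simplex
(tolerances: reduced-cost/feasibility 1e-9 inside the solver, 1e-6 for
assertions on returned vectors; Dantzig pricing with a Bland's-rule
fallback for anti-cycling). The test suite checks it against brute-force
vertex enumeration of the flux polytope on small random networks, the
property that makes the solver trustworthy independently of any reference
implementation.

`solve_pfba()` is the two-stage parsimonious FBA: growth is maximized,
fixed at its optimum to within 1e-9 relative, and total absolute flux
sum(|v|) is minimized after splitting every reaction into irreversible
halves. The split is internal and never serialized.

`flux_variability()` and `sample_solution_space()` read "10% variability
from the predicted specific growth rate" as a one-sided floor: growth
constrained to at least 90% of the optimum (`growth_fraction = 0.9`).
The floor keeps the region convex and matches the phrase; a two-sided
band differs only in also capping growth, which no claim here depends on.
The sampler is coordinate hit-and-run in the null space of S: bounds are
first tightened to the FVA box, the walk starts from the mean of the FVA
vertex solutions (an interior point), directions are random Gaussian
combinations of an orthonormal null-space basis, and every 10th point is
recorded (thinning 10) until `n` samples (default 2000) are taken. The
walk is re-projected onto the null space every 200 steps to curb drift.
Everything is driven by one integer seed; the same seed reproduces the
summary exactly.

Why the NADP route wins on glucose: with EG uptake and GA secretion fixed
equimolar, both dehydrogenase flavors can carry the flux, but routing
through NADP supplies the biomass NADPH demand directly and lets the cell
shave flux off the oxidative PPP (which pays one CO2 per 2 NADPH), so the
NADP route gives strictly higher growth — the preference is structural,
not a solver tie-break. Note one genuine degeneracy the reduced model
shares with its genome-scale parent: the reversible cytosolic-NADP /
mitochondrial-NAD glyoxylate-reductase pair plus glycolate transport forms
a latent transhydrogenase loop, which is why those reactions show large
flux variability under sampling; parsimonious FBA suppresses the loop
(it costs flux), which is exactly the behavior the flux tables report.

## Physiology calculus

* Growth rates are least-squares slopes of ln(OD) vs time
  (`fit_growth_rate()`), with an optional OD floor to drop lag-phase
  points.
* Specific rates regress the analyte amount (mmol/L) on the biomass-time
  integral of CDW (`specific_rate()`), the noise-robust alternative to
  point derivatives. The integral uses the logarithmic mean of consecutive
  CDW samples, which is exact under exponential growth — with the ordinary
  trapezoid, a 4-h sampling grid at mu = 0.34 1/h would bias q by ~15%.
* Phase detection (`detect_phases()`) uses the ammonium channel when
  present (Nlim starts where NH4+ falls below 0.1 mM, with linear
  interpolation of the crossing) and otherwise the %DO trace: the local
  minimum of a 3-point moving average followed by a clear rise, i.e. the
  dissolved-oxygen spike when growth decelerates at nitrogen depletion.
* Yields come in mol/mol, Cmol/Cmol and g/g variants tied together by the
  molar masses (EG 62.07, GA 76.05 g/mol) and carbon counts (2 C each);
  `regression_yield()` estimates the conversion yield as the free-intercept
  slope of cumulative GA on cumulative EG, the estimator that tolerates a
  nonzero starting offset.
* `carbon_balance()` sums Cmol/Cmol yields of biomass, CO2 and net
  products; an EG->GA pair at 100% yield nets zero carbon and drops out.
  Closures above 1.05 are flagged.
* Media stoichiometry is molar: C/N = (sum of sugar carbon)/12.011 over
  nitrogen from (NH4)2SO4 (2 N per salt, 132.14 g/mol), with EG excluded
  from the carbon count since it is not assimilated. The molar reading
  reproduces the published recipe ratios 80 and 8.8; the bioreactor "C/N
  40" recipe back-computes to 43.5 molar, and the calculator reports
  computed values rather than correcting toward printed ones.
* OD converts to dry cell weight with the calibration coefficient 0.3.

One published-number caveat is reproduced deliberately: the control-row RQ
computed directly from the mean yields (29.88/23.32) is 1.28, one
hundredth below the printed 1.29, which comes from averaging per-replicate
ratios; the EG row gives 1.36 either way.

## The synthetic fermenter

`simulate_batch()` produces the data structure the whole physiology layer
assumes: exponential growth at `mu_exp` until the ammonium pool (sized by
the 11.4% N content of exponential biomass) is exhausted, then
nitrogen-limited growth at `mu_nlim` on the remaining sugar — the Nlim
biomass is treated as nitrogen-free (lipid), which is the phenomenological
reading of lipogenic growth. Glucose is consumed strictly before xylose.
Sugar consumption is tied to growth through `y_xs`; EG is oxidized at a
constant specific rate `q_eg` whenever its gating mode permits:

* `glucose_nlim_only` — EG untouched until nitrogen depletion *or* glucose
  exhaustion (this one rule reproduces both the C/N 80 phenotype, EG
  consumption starting at the Nlim onset, and the C/N 8.8 phenotype,
  EG consumption starting only after glucose depletion);
* `xylose_coconsume` — co-consumption from inoculation;
* `none` — ungated.

GA is produced at `y_ga_eg` mol/mol plus `extra_ga_factor` while xylose is
present during Nlim (the xylulose-route signature); yield beyond 1:1 draws
sugar carbon, so without sugar the effective yield caps at 1. CO2 is the
exact carbon residual (sugar C + EG C − biomass C − GA C), O2 is CO2/RQ,
and %DO is an affine, clipped proxy of the oxygen-uptake rate
(100 − 5 × OUR): only the location of its change-point is meaningful, not
its absolute level. Noise — multiplicative log-normal on OD, additive on
concentrations — is applied only at sampling times, under a mandatory
seed, so the underlying trajectory stays closed-form.

The integrator is piecewise-exact on a fixed step grid (default 0.05 h):
biomass is propagated exponentially within each step and the times of
nitrogen, sugar or EG depletion are solved analytically, so the configured
ground truth (mu, q, yields, RQ, total carbon) is recovered by the
estimators to machine precision on noise-free output — an invariant the
test suite asserts at 1% and the generator meets at ~1e-14. A plain
first-order scheme at the same step would bias the log-OD slope by
ln(1 + mu dt)/dt − mu (~0.8% at mu = 0.34), which is why exact propagation
was chosen.

Defaults are the flask glucose condition: 10 g/L glucose, 0.275 g/L
ammonium sulfate (molar C/N 80), 150 mM (9.31 g/L) EG, mu_exp = 0.34 1/h,
mu_nlim = 0.084 1/h, Y_X/S = 0.41 g/g, Y_GA/EG = 1.01 mol/mol, RQ = 1.36.
The specific EG uptake rate is not a published quantity; the default
q_eg = 0.06 mmol/gCDW/h is a repository choice set so that a flask-scale
Nlim phase accumulates GA of the observed order (~2 g/L), and it is the
one generator parameter a user should expect to retune against real data.
`write_fixture_suite()` emits the four desk-scale regimes (glucose C/N 80,
glucose C/N 8.8, xylose C/N 80, glucose+xylose C/N 80), each with and
without 150 mM EG, as CSV plus ground-truth JSON.

What the generator does **not** emulate — and therefore what passing
recovery tests do not show about real cultures: pH drift and its growth
feedback (the flask experiments without buffer are strongly
pH-confounded), lag phases, gradual rate transitions around depletion
events (switches here are instantaneous), variable biomass yield between
phases, glycerol by-production, and any single-cell stochasticity.

## Problem sizes and numerical choices

The test suite and the acceptance script run the engine at the scale the
reduced model needs: FVA solves two LPs per reaction (~180 LPs on the
core model), sampling draws 2000 points with thinning 10, estimator
recovery uses 0.5-h grids over 40 h, and the Monte-Carlo batteries use
100 seeds of 12-point noisy series. Solver tolerances are 1e-9; steady
state and bound feasibility of returned vectors are asserted at 1e-6;
serialization is exact by construction. Ties in the LP (alternate optima)
are resolved by parsimonious FBA where they matter scientifically; plain
FBA flux vectors should be read as one representative optimum.

## Known limitations

* The reduced network cannot reproduce genome-scale flux numbers that
  depend on pathways outside the core (amino-acid, lipid-chain detail);
  it reproduces the structural claims (cofactor routing, shunt topology,
  EG energetics) and the published physiology arithmetic.
* The one-sided growth floor is a reading of an ambiguous phrase; both
  readings are implementable and the choice is documented above.
* `summarize_physiology()` on coarse noisy series inherits the usual
  window-selection sensitivity of batch yield calculus; the per-estimator
  functions with explicit windows are the precise interface.
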