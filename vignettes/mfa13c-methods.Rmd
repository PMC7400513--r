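---
title: "Methods: stationary 13C metabolic flux analysis with mfa13c"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stationary 13C metabolic flux analysis with mfa13c}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package computes

`mfa13c` implements stationary ¹³C metabolic flux analysis (¹³C-MFA) for
cultured mammalian cells: given a compartmentalized, atom-mapped model of
central carbon metabolism, measured extracellular exchange rates, and mass
isotopomer distributions (MIDs) of intracellular metabolites under parallel
tracer experiments ([1,2-¹³C]glucose and [U-¹³C]glutamine), it estimates the
intracellular net and exchange fluxes by weighted least squares, validates
the fit with a chi-squared test, derives profile-likelihood ("grid search")
confidence intervals, and converts the fitted fluxes into NADH/NADPH/FADH₂
and ATP production–consumption balances attributed to glycolysis and the
TCA cycle.

The package ships a complete synthetic emulation of a paired study of
parental cells and cells with diminished fumarate hydratase (FH) activity,
so that every stage — rate regression, isotope simulation,
natural-abundance correction, fitting, interval estimation, cofactor
accounting — can be exercised and validated offline against known ground
truth. The numbered scripts under `analysis/` run those stages in order.

# The network model

Models are plain tab-separated tables (`load_model()`,
`model_from_tables()`): a metabolite table (id, compartment, carbon count,
rotational-symmetry flag, balanced flag) and a reaction table whose
equations carry letter atom maps, e.g.

```
fum_m (abcd) --> mal_m (abcd)
hexp_c (abcdef) --> gap_c (cba) + gap_c (def)
```

Every substrate-side letter must appear exactly once on the product side;
violations are rejected at load with the reaction named. Reactions without
atom maps (the lumped biomass drain) participate only in the stoichiometric
balance.

Design choices that shape the reference model:

* **Compartments.** Pyruvate, citrate, oxaloacetate, acetyl-CoA and malate
  are split between cytosol and mitochondria. Mitochondrial pyruvate is
  represented by two pools — one feeding pyruvate dehydrogenase, one
  feeding the anaplerotic reactions (pyruvate carboxylase, alanine
  transaminase) — with the carrier flux split between them as free
  parameters.
* **Mixing pools.** GC–MS cannot distinguish compartment pools of one
  metabolite. A mixing pool (`pyr_mix`, `mal_mix`, `cit_mix`) is a virtual,
  non-balanced metabolite whose MID is the fraction-weighted average of its
  contributors; the fractions are fitted parameters that sum to one and
  carry no net flux, so they cannot distort the flux distribution.
* **Symmetric metabolites.** Fumarate and succinate are rotationally
  symmetric; each reaction touching one automatically receives equal-weight
  (0.5/0.5) alternative atom maps with that molecule's carbon string
  reversed. This keeps stoichiometry unique while producing the positional
  scrambling that, for example, lets M+3 malate made by anaplerosis or
  reductive carboxylation appear as M+3 fumarate through the reverse FH
  reaction.
* **Biomass.** A single lumped drain with coefficients in nmol per 10⁶
  cells of new biomass, scaled for a dry cell weight of 514 pg/cell from
  literature-typical precursor demands (protein-dominated amino acid
  drains, lipid acetyl-CoA, nucleotide pentose). The coefficients are
  shipped defaults in the model file and fully overridable; pinning the
  biomass reaction at the measured growth rate makes the drain flux
  `mu * coefficient`.
* **Units.** All fluxes are nmol/10⁶ cells/h; time is in hours.

`parameterize_model()` turns `S v = 0` over the balanced metabolites plus
any fixed-value constraints into a coordinate parameterization: QR column
pivoting picks actual reactions as the free coordinates, so recovering free
values from an expanded flux vector is exact, and `expand_fluxes()` solves
for the dependent reactions (steady-state residual checked against 1e-9
relative). Inconsistent constraint sets are reported with the violated
balance named.

# Simulating mass isotopomer distributions

The production algorithm is the elementary metabolite unit (EMU)
decomposition: starting from each observed fragment's backbone carbon set,
production events are traced backwards through the atom maps, and the
resulting EMUs are solved layer by layer in increasing size, each layer a
dense linear system factorized by LU. Reversible reactions contribute
production events in both directions with fluxes `fwd = net⁺ + exch`,
`bwd = net⁻ + exch`; the exchange flux therefore controls label
back-mixing (the FH reverse/forward flux ratio is `bwd/fwd`).

Singular layers are reported with the offending EMUs named, never
regularized. A singular layer is diagnostic: either a pool has zero
production flux at the candidate flux vector, or the model contains a
closed positional carbon cycle with no external inflow (as happens, for
instance, if fumarate's symmetry is omitted from a TCA loop — position
cycles like OAA-C2 → citrate-C3 → ... → OAA-C2 then have steady states
that depend on initial conditions, and the user should see that rather
than a silently regularized answer).

Tracers are described positionally: each labelled carbon is ¹³C with
probability equal to the stated isotopic purity (0.99 for
[1,2-¹³C]glucose, 0.98 for [U-¹³C]glutamine), independently per position;
unlabelled positions, unlabelled substrates, and the CO₂ pool carry the
natural ¹³C fraction (0.0107). Treating refixed CO₂ as unlabelled is a
deliberate simplification shared by the generator and the fit, noted under
limitations.

A brute-force oracle (`brute_force_mids()`) represents every metabolite by
its full 2ⁿ isotopomer distribution and iterates the steady-state balance
to a fixed point, with the same pool-independence assumption the EMU
method makes when a reaction condenses two molecules. It exists purely to
verify the cascade: the test suite demands agreement within 1e-8 on toy
networks covering condensation, splitting, reversibility, symmetry and
mixing pools. It refuses state spaces beyond 2²⁰.

# Natural isotope abundance correction

GC–MS measures the derivatized ion, so silicon, sulfur and every carbon
outside the traced backbone add natural-abundance mass shifts on top of the
tracer labelling. `build_correction_matrix()` convolves per-element
mass-shift distributions (IUPAC compositions, shipped as a data file and
overridable) over all non-backbone atoms of the fragment formula; column
*j* of the matrix is that distribution shifted by *j*. Raw MIDs retain
`n + 1 + 4` masses — four tail masses capture the Si/S isotope tails of
TBDMS/TMS derivatives while keeping the matrices small.

Correction (`correct_mid()`) solves the truncated system by nonnegative
least squares and renormalizes, rather than applying a plain inverse:
measured MIDs are noisy and can leave the probability simplex, and the
NNLS solution degrades gracefully (small negative inputs are clipped and
flagged). On noise-free data the round trip
`correct_mid(convolve_natural(x))` reproduces `x` to 1e-10 on every
shipped fragment. Note the convention: correction removes the
natural-abundance contribution of non-backbone atoms only; the backbone
carbons' own natural ¹³C is physical signal, so an unlabelled control
corrects to `M+0 = 0.9893^n`, not 1.

# Extracellular rates

Cell growth is exponential over the observation window, so the medium
amount of a consumed or secreted species obeys
`dA/dt = q X₀ e^{μt} - kA` with `A(0) = A₀`, giving

```
A(t) = A0 exp(-k t) + q X0 (exp(mu t) - exp(-k t)) / (mu + k)
```

with the limiting forms `A₀ e^{-kt} + q X₀ t e^{-kt}` at `μ + k = 0` and
`A₀ + q X₀ t` when both vanish. The `exp(mu t) - exp(-k t)` numerator is
forced by the stated model — it is the unique solution with `A(0) = A₀`
— and the implementation verifies it by numerical differentiation in the
tests. `q` is signed (secretion positive, uptake negative) and reported as
a magnitude under an uptake/secretion heading.

The growth rate comes from a semi-logarithmic regression of cell counts,
the glutamine degradation constant from a log-linear fit of a cell-free
decay series (clamped at zero if the series increases), and `(A₀, q)` by
least squares — the model is linear in both once `μ`, `X₀`, `k` are fixed.
Confidence intervals use a seeded parametric bootstrap (1000 resamples by
default); the bootstrap was chosen because nothing constrains the original
analysis to a specific CI construction, and its coverage is verified by
simulation in the test suite (within 90–99% at 200 replicates).

The synthetic time courses default to a 0–40 h window sampled every 8 h in
triplicate with 2% multiplicative concentration noise: with 2 mM glutamine
and 0.4 mM serine in a 4 mL dish, the pools stay positive over 40 h at the
anchored uptake rates, whereas by 48 h glutamine would be exhausted and
clipping would bias the regression.

# Flux fitting

`fit_fluxes()` minimizes

```
RSS = sum over tracers, fragments, masses ((sim - meas) / 0.01)^2
    + sum over soft fluxes ((v - value) / (0.05 * value))^2
```

jointly over both labelling experiments with a single parameter vector:
the free net fluxes (QR coordinates), one bounded exchange coordinate
`u = xch / (100 + xch)` per reversible reaction (the transform stabilizes
unidentifiable reversibilities; `u` is capped at 0.999, i.e. exchange up
to ~10⁵), and stick-breaking coordinates for each mixing pool's fractions.
MID standard deviations are fixed at 0.01 per mass; glucose uptake and
lactate secretion are fitted softly with 5% relative error; the other
measured exchange fluxes and the growth-pinned biomass drain are hard
constraints inside the parameterization. Dependent fluxes that leave their
bounds incur a quadratic penalty (weight 1e6) so the optimizer is steered
back to the feasible region; the reported RSS is always the pure
measurement term.

Optimization is bound-constrained quasi-Newton (`nlminb`/PORT) with
per-parameter scaling (fluxes of order hundreds sit next to transforms of
order one; without scaling the finite-difference gradients are unusable).
Multistart defaults to 20 seeded draws; the analysis scripts use 2–4
starts plus a data-informed warm start, which the noise-free recovery
tests show is sufficient on the reference network (generating fluxes
recovered within 0.1%, RSS < 1e-6). Identical seeds give bit-identical
fits.

## Degrees of freedom and chi-squared calibration

The fit is accepted at `α = 0.05` when `RSS ≤ χ²₀.₉₅(dof)` with
`dof = (number of fitted MID masses + soft flux measurements) - (number of
free parameters)` — the raw counting convention (`count_mode = "raw"`).
A second convention discounting one mass per normalized MID vector is
available (`"independent"`).

One subtlety deserves record. If Gaussian per-mass noise is renormalized
to sum to one, the per-mass errors become coupled, and the diagonal error
model the RSS assumes is wrong in a direction that depends on each MID's
shape: renormalization can either inflate or deflate the expected RSS, so
*no* mass-counting convention yields exact chi-squared calibration for
renormalized noise. The calibration study (`chi2_calibration()`) therefore
applies exact per-mass Gaussian noise without renormalizing — precisely
the error model the fit assumes — and under it the empirical pass rate at
`α = 0.05` sits near 0.95 (the acceptance suite runs 100 replicates). The
scenario generator, by contrast, renormalizes raw MIDs like any real
processing pipeline and pools replicate measurements while keeping the
conventional SD of 0.01; fits against such data are chi-squared
*conservative* (RSS well below dof), which mirrors how the fixed-SD
convention behaves on real data.

Calibration and interval-coverage studies run on a compact, fully
identifiable network (two substrates, one reversible interconversion, two
fragments, two soft fluxes — 4 parameters, 5 dof) rather than the full
reference network, so that 100 fit replicates and 20 profile-CI replicates
complete in minutes; the statistical machinery exercised is identical.

## Grid-search confidence intervals

`grid_search_ci()` profiles one quantity at a time: the target net flux is
re-expressed as a free coordinate (re-parameterizing if needed), pinned
across an outward scan starting at 5% of the best value with doubling
steps, and every other parameter is re-optimized at each pin, warm-started
from the neighbouring solution. The 95% bound is where the profiled RSS
crosses `RSS_best + χ²₀.₉₅(1) = RSS_best + 3.84`, refined by bisection to
0.1% of the best value by default. Exchange fluxes are profiled on the
bounded `u` coordinate and reported on the exchange scale.

Directions in which the profile never crosses the threshold before the
parameter bound or scan cap are reported as not determined (`NA`/ND) —
typical for structurally unidentifiable exchange fluxes. Reactions fixed by
a hard constraint collapse to point intervals. Failed re-optimizations at a
grid point are skipped with a warning, never silently kept. On a
linear-Gaussian problem, where the profile is exactly quadratic, the
machinery reproduces the analytic `±1.96·SE` interval within 1%
(verified in the acceptance suite), and on the calibration network the
95% intervals cover the generating values at near-nominal rates.

Between conditions, a flux difference is called significant exactly when
the two 95% intervals are disjoint; touching endpoints count as overlap
(not significant), and an ND bound on a deciding side makes the call
indeterminate.

## Stationarity screening

Stationary MFA requires isotopically steady MIDs. `assess_stationarity()`
regresses each mass fraction on quench time (24/29/32 h replicates) and
flags a fragment when any slope differs from zero at `α = 0.05` after
Bonferroni correction across its masses. With twenty fragment series at
this threshold, roughly one false flag per condition is expected and the
analysis script reports it as such.

# ATP and cofactor accounting

`cofactor_balance()` contracts a cofactor stoichiometry table (reaction ×
cofactor coefficients; mitochondrial and cytosolic NADH kept separate)
against the net fluxes. `atp_production()` then attributes:

* **Glycolysis** — net substrate-level phosphorylation of the glycolytic
  reactions (+1 at phosphoglycerate kinase and pyruvate kinase, −1 at
  hexokinase and phosphofructokinase): approximately 2 ATP per glucose,
  which is why this row tracks twice the glucose uptake up to the biomass
  hexose drain.
* **TCA cycle** — GTP from succinyl-CoA synthetase (counted as ATP, lumped
  into the α-ketoglutarate dehydrogenase step) plus oxidative
  phosphorylation from net mitochondrial NADH at P/O = 2.3 and FADH₂ at
  P/O = 1.38. The FADH₂ default preserves the conventional NADH:FADH₂
  efficiency ratio (2.3 × 1.5/2.5) because the original analysis states a
  single P/O without distinguishing donors; a single-ratio accounting is
  one configuration flag away (`atp_config(po_fadh2 = 2.3)`).
* **Other production** — OxPHOS ATP from net cytosolic NADH, assumed
  shuttled into mitochondria at no ATP cost. It is deliberately not added
  to the glycolysis row: the published glycolysis attribution is
  consistent with substrate-level phosphorylation alone.
* **Consumption** — ATP used outside glycolysis: carboxylation, lipid
  synthesis initiation, proline synthesis.
  `total_net = glycolysis + TCA + other − consumption`, and the
  per-reaction contributions are retained so the arithmetic is auditable.
  The shipped stoichiometry counts explicit reaction-level ATP only: the
  published-style ledger's total sits close to the sum of its two pathway
  rows, which is only reproducible if the (much larger, but flux-opaque)
  growth-associated maintenance demand stays outside the table. Users who
  want it included add a single `BIOMASS ATP` row, and because the biomass
  reaction is pinned at `μ`, that demand then scales with growth.

All ledger entries are linear in the fluxes, and the tests verify them
against a direct dot-product oracle on random steady-state flux vectors.

# The synthetic study

`make_scenario()` fixes the ground truth from the published anchors:
exchange fluxes (glucose 578.8 → 533.5, glutamine 82.7 → 52.7, lactate
1087.7 → 1009.8, pyruvate 61.7 → 57.8, alanine 17.1 → 19.4, proline
13.9 → 1.5, serine 22.0 → 16.2 nmol/10⁶ cells/h), growth rates
0.0343/0.0208 h⁻¹, glutamine degradation 0.00345 h⁻¹, glutamate-to-αKG
flux 52.9/45.9, an FH reverse/forward ratio near 1.0 in parental versus
0.18 in FH-diminished cells, and an unchanged pyruvate carboxylase flux.
With eleven anchors the reference network's flux space is pinned exactly
(zero remaining free dimensions), so the ground truth is the unique
steady-state solution; the resulting internal pattern — TCA-side fluxes
uniformly lower in the FH-diminished condition while glycolysis barely
moves — reproduces the study's qualitative conclusions without claiming
its unpublished internal values. Remaining generator constants (medium
amounts from 20 mM glucose / 2 mM glutamine in a 4 mL dish; 2%
concentration CV; modest exchange fluxes on reversible steps; mixing
fractions) are single realistic choices documented in the code and not
revisited.

What the generator does **not** emulate: chromatographic peak integration
and calibration, drift or batch structure in the MID noise (draws are
independent Gaussian per mass), ¹³CO₂ refixation, day-to-day variation in
growth, and any misspecification between the fitted and generating network.
Passing tests therefore demonstrate that the estimation machinery is
correct and calibrated under its stated assumptions — not that those
assumptions hold for any particular real dataset.

# Known limitations

* Stationary MFA only; no isotopically non-stationary fitting, no ²H/¹⁵N.
* CO₂ is an unlabelled input; reductive carboxylation labelling through
  refixed ¹³CO₂ is not represented.
* The chi-squared test treats every mass as an independent measurement
  with SD 0.01, inheriting both the convenience and the approximation of
  that convention.
* The reference model is a curated reconstruction of the described scope
  (its exact reaction list, atom maps and biomass coefficients were not
  published); all of its tables are plain text and user-replaceable.
* Profile CIs assume the re-optimization at each pin finds the global
  minimum; warm-started scans make this reliable but not guaranteed on
  heavily multimodal problems.
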