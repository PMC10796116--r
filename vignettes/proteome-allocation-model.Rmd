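---
title: "A proteome allocation model of phytoplankton thermal responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A proteome allocation model of phytoplankton thermal responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`phytoalloc` implements a coarse-grained, steady-state resource allocation
model of a generic photosynthetic cell. Eight catalytic pools are modeled
explicitly — rubisco (`ru`), nitrogen transporters (`tr`), ribosomes
(`ri`), photosystems (`p`, split into functional and damaged), repair
proteases (`re`), lipid synthesis (`lb`), glycolysis (`gl`) and lipid
degradation (`ld`) — plus the macromolecule pools they produce and consume:
internal carbon and nitrogen, membrane lipids, stress-mitigation lipid
droplets, and the glucose and lipid stores that fuel dark respiration.

At balanced exponential growth every pool concentration $c$ obeys
$\sum v_{\mathrm{synthesis}} - \sum v_{\mathrm{degradation}} - \mu c = 0$,
with Michaelis–Menten kinetics $v_i = k_i p_i S_i/(S_i + K_i)$ for
substrate-limited reactions and linear kinetics for the two respiratory
pathways (their entire store is consumed every night). All turnover rates
scale with absolute temperature by the Arrhenius factor
$\gamma = \exp[(E_a/R)(1/T_{\mathrm{ref}} - 1/T)]$, with two deliberate
exceptions: photon capture is temperature independent, and transporters
carry half the generic activation energy, so nitrogen uptake falls behind
the rest of metabolism as the water warms. Photosystems are damaged at a
rate that rises steeply above a pivot temperature $T_d$; stored lipid
droplets quench the damage in proportion to how full the store is
($v_d = k_d\,p_p\,c_{tag}^{max}/c_{tag}$), and a repair pool restores
damaged photosystems. Damage and repair are fast relative to growth, so the
damaged fraction is resolved by a quasi-steady state with a closed form.

The cell faces four budgets:

* **Proteome.** The modeled investment fractions sum to
  $1 - \phi_{\mathrm{other}} = 0.5$; half the proteome is structural and
  outside the model.
* **Energy.** Photochemistry must first pay carbon fixation
  ($e_p v_p \ge e_{ru} v_{ru}$); the remainder covers all other metabolic
  costs, and a fraction $f_{dr} = 0.25$ of those costs falls at night and
  must be met by glycolysis or lipid degradation from stores built during
  the day.
* **Surface.** Transporters and membrane lipids tile the membrane:
  $1 = (p_{tr} s_{tr} + c_{lm} s_{lm})\beta$, where $\beta = V/SA = r/3$
  for a sphere is the single geometric decision variable. A
  temperature-dependent bound caps the transporter-to-lipid ratio: warm
  membranes are built from saturated lipids that pack tightly, so more
  lipid per transporter is required as $T$ rises.
* **Space.** Photosystems and lipid droplets exclude volume; everything
  else must fit under a macromolecular density ceiling $D_{max}$ applied to
  the remaining volume.

The optimizer finds the allocation (proteome fractions $\phi_i$, lipid-flux
splits $\alpha_{lm}+\alpha_{tag}+\alpha_{ld}=1$, internal substrate levels
and $\beta$) that maximizes $\mu$ subject to all balances and budgets.

## How the problem is solved

The decision space is reduced by forward substitution. Given the
investment fractions, the membrane share of the lipid flux, the internal
substrate saturations $f_c, f_n$ and $\beta$, the growth rate follows
directly from the ribosome balance
($\mu = k_{ri}\phi_{ri} f_c f_n/\eta_{ri}$), the surface identity fixes the
absolute flux scale, every pool concentration follows algebraically, and
the damaged photosystem fraction has a closed form. Only the internal
carbon and nitrogen balances remain as nonlinear equalities, alongside the
energy, membrane, stored-lipid and space inequalities.

This reduced problem (11 variables, 2 equalities, up to 9 inequalities) is
solved by a multistart augmented-Lagrangian method over `optim`'s
L-BFGS-B, with an analytic-quality gradient assembled from a vectorized
evaluation of all finite-difference points. Each start receives a short
screening run; the most promising candidates (always including the warm
start and two fixed heuristic starts, one growth-oriented and one
stress-oriented) are driven to full convergence. Two structured polish
steps exploit model structure the smooth solver resolves poorly:

* **Balance polish.** A damped Newton step re-solves the two balances in
  $(f_c, f_n)$ exactly, leaving equality residuals at roughly $10^{-13}$
  relative.
* **Crowding line search.** Growth is weakly increasing as the cell
  shrinks (the only scale-breaking terms are dilution losses), so the
  optimum sits where a crowding constraint — density, occupied volume or
  the stored-lipid cap — becomes active. A bisection on $\log\beta$
  finishes this nearly flat direction.

Numerical defaults: growth tolerance $10^{-4}\ \mathrm{d^{-1}}$,
feasibility tolerance $10^{-8}$ (relative), 8 starts, seed 0. Restricted
modes pin the unavailable pathway to zero; the free mode takes the best of
the glycolysis-only, lipid-only and unrestricted solves, so the discrete
respiratory choice is scanned explicitly rather than asking the continuous
solver to cross a nonconvex ridge. A solve is reported `nonviable` when no
feasible state grows faster than the growth tolerance, which is how the
fatal temperature emerges.

Temperature sweeps solve each restricted configuration as its own
warm-started chain — ascending, then a descending pass that keeps the
pointwise best — and combine the chains pointwise. Single grid points
whose winning pathway differs from two agreeing neighbors are re-solved
warm-started from those neighbors before the combination is final; such
points are almost always under-converged solves rather than genuine
switches. Within a warm-started descending pass the random starts are
trimmed (they would duplicate the ascending pass).

An independent verifier (`verify_solution`) recomputes every residual and
slack through the public model functions, never through the solver's
internal algebra, and an exhaustive grid search over the reduced
three-pool configuration (`toy_params()` + `grid_search_toy()`) provides a
solver-free check of optimality.

## Parameter choices

Constants fixed by the model description are encoded directly:
$\phi_{\mathrm{other}} = 0.5$, $f_{dr} = 0.25$, a 720-minute dark period,
Boltzmann's constant $8.617\times10^{-5}$ eV K$^{-1}$, 140 chlorophylls
per photosystem at 893.5 g mol$^{-1}$, and the halved transporter
activation energy. The remaining turnover rates, molecular sizes, energy
stoichiometries and geometry are the package's own defaults, chosen once
at literature scale for a generic diatom-like cell and then held fixed.
Where a constant was only weakly constrained, the value was selected so
that the model's qualitative regime structure — the unimodal thermal
performance curve, the glycolysis/lipid-degradation/glycolysis switch
sequence, the shrink-then-rebound size curve, and the reported directions
of acclimation — emerges from the optimization rather than being imposed.
The choices that matter most:

* `k_ref` per pool (min$^{-1}$): ribosomes are slow (33 amino acids per
  ribosome-minute at 20 °C) so that cold growth is limited by how many
  ribosomes a crowded cell can hold, while photon capture is fast
  (18 000 photons min$^{-1}$ per photosystem) so that warm growth is
  limited by the temperature-independent energy supply. This pair sets a
  realized growth $Q_{10}$ of roughly 2 between 16 and 26 °C, above the
  transporter $Q_{10}$ of about 1.8 — the inequality behind the rising
  transporter investment with warming.
* Energy stoichiometry (ATP-equivalents): fixation costs 8 per C,
  protein synthesis 4.5 per amino acid, lipid synthesis 5.5 per C of
  lipid, and respiration recovers 5 per C from glucose but 7 per C from
  lipids. Lipid respiration therefore has the higher carbon yield but the
  higher daytime energy overhead: glycolysis wins when energy is scarce
  (cold, and again near-fatal when damage drains the budget), lipids win
  mid-range where space is the binding currency.
* Space: $D_{max} = 1.2\times10^{10}$ Da µm$^{-3}$, glucose stores count
  against the density ceiling at 180 Da per molecule while lipid stores
  occupy droplet volume at $1.6\times10^{-8}$ µm$^3$ per molecule
  (a triacylglycerol plus its share of droplet packing overhead). This
  asymmetry is what lets the optimizer discover the respiratory switch.
* Damage: $k_{ref,d} = 0.4$ min$^{-1}$ at $T_d = 31$ °C with
  $E_d = 2.5$ eV, yielding negligible damage below ~25 °C, a rising
  repair burden through the thirties, and collapse at 42 °C.
* Geometry: the transporter complex occupies $10^{-4}$ µm$^2$ of
  membrane, large enough that transporter thermal behavior dominates the
  surface budget; the transporter-to-lipid bound spans 0.002–0.035 across
  the 5–45 °C sweep range.

The membrane-saturation effect on cell size is small in this
parameterization (as a secondary mechanism it is easily dominated by the
transporter effect); disabling it flattens the size–temperature slope only
slightly.

## What the baseline run shows

With the default parameters and `temperature_sweep()` from 5 to 45 °C the
model produces: a unimodal growth curve peaking near 30 °C and collapsing
at 42 °C; glycolysis-fueled growth up to 24 °C, lipid-fueled growth from
25–40 °C, and a final glycolysis regime at 41 °C where the lipid budget is
reassigned to stress mitigation ($c_{tag}$ at its cap); carbon use
efficiency falling monotonically from 0.95 to below 0.3; a nitrogen-to-
carbon quota falling as the proteome shifts from N-rich ribosomes to
N-poor photosystems and carbon stores accumulate; chlorophyll per
biovolume rising with temperature; and cell volume shrinking from
~800 µm$^3$ to ~23 µm$^3$ before rebounding several-fold as storage
demands near the fatal point force a lower surface-to-volume ratio.

Directional acclimation responses are extracted with
`directional_response_report()` between 13 and 27 °C — one comparison
point on each flank of the first metabolic switch, mirroring how
two-temperature acclimation experiments are analyzed. The reported signs
(photosystems, transporters, repair, lipid degradation and stored lipids
up; rubisco, ribosomes, glycolysis and ribosome concentration down) are
asserted in the test suite.

## Adaptation scenarios

`adaptation_scenario()` applies mutation-like parameter changes: scaling
activation energies (enzyme thermostability), raising the stored-lipid
capacity (oxidative-stress tolerance), or scaling all turnover rates. The
shipped presets (`adaptation_presets()`) are synthetic stand-ins encoding
the direction of each evolved change on the package's default parameter
set — the quantitative values behind the published evolved strains are not
part of the main-text record, so the presets state directions, not
magnitudes, and the file is named accordingly.

## Reduced model and fixtures

`toy_params()` strips the model to photosystems, ribosomes and
transporters (no lipids, damage, dark respiration or carbon tracking).
The resulting three-dimensional allocation problem is small enough for an
exhaustive grid search at resolution 0.01 on the investment fractions and
a 40-point log grid on $\beta$, which the test suite compares against the
full solver at five temperatures. `build_balanced_state()` constructs
states whose equality residuals vanish to root-finding precision by
forward substitution plus bracketed root finding on the two balances, and
`random_feasible_state()` adds a deterministic repair loop that also
satisfies every inequality; these are the construction oracles used in the
tests.

## Scope and limitations

The model is steady-state only: no diel cycling, no dynamic integration of
the balance equations, and therefore a sharp (rather than smoothed)
respiratory switch. External nutrients and carbon are saturating by
default. Cell geometry is spherical. Quantitative trait values depend on
the package's own default constants and should be read as those of a
generic large phytoplankter, not of any particular strain; the qualitative
structure — regime sequence, trait directions, curve shapes — is the
tested, reproducible content. Problem sizes used in the shipped tests
(1 °C sweep with 8 starts, 2–4 °C grids for toggles and scenarios) were
chosen to keep a full run of the suite in the tens of minutes on one CPU.
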