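---
title: "Modeling interspecies metabolic exchange in a methanotroph-phototroph coculture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling interspecies metabolic exchange in a methanotroph-phototroph coculture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coflux)
```

## The system and the modeling problem

A binary synthetic microbiome of an aerobic methanotroph (M) and an
oxygenic photoautotrophic cyanobacterium (C) grows in a closed bottle on a
CH4/CO2 headspace. The two partners are obligately coupled through gas
exchange -- the phototroph's photosynthetic O2 fuels methane oxidation,
whose CO2 in turn feeds carbon fixation -- and, more interestingly,
through *emergent* exchanges of organic and nitrogen compounds that
neither partner needs in monoculture. Because a rate-limiting exchanged
metabolite (O2 in this pair) is consumed the instant it is produced, it
can be experimentally undetectable; constraint-based models of the
community are then the main tool for inferring who feeds whom, how much,
and how that changes over a batch.

`coflux` implements three complementary views of this inference problem
on genome-scale stoichiometric models (GEMs):

1. **Steady-state community FBA** (`build_community()`,
   `solve_steadycom()`): both species grow at one community rate; the
   model predicts the rate, the population composition, and a snapshot of
   cross-feeding fluxes.
2. **Dynamic FBA** (`dfba_simulate()`): each species is an independent
   FBA model embedded in bioreactor mass balances; uptake caps follow
   Michaelis-Menten kinetics. It captures batch dynamics but has no
   shared metabolite pool, so interspecies exchange must be wired in by
   hand and emergent exchanges are invisible.
3. **Kinetically constrained dynamic community FBA**
   (`simulate_kinetics()` + `run_dyncom()`): a semi-structured kinetic
   model -- the component that can be validated against growth data --
   drives the reactor state, and its per-species rates are imposed, one
   time point at a time, on the steady-state community LP. The coupling
   is strictly unidirectional, so the GEM layer can be queried at any
   frequency without perturbing the dynamics, and the recorded
   cross-feeding fluxes evolve over the batch.

## The community LP

Species models are namespaced (`M1`, `C1`, ...) and joined through a
shared community compartment `[u]`. For every whitelisted extracellular
metabolite each species gets a reversible transport
`M1met[e] <-> met[u]` with open bounds; one community exchange reaction
per `[u]` metabolite carries the medium-level bounds (uptake negative).
Blacklisting a metabolite simply omits it from `[u]`: with no transport
there is no route between species, which keeps the reduced model small.
Whether cross-feeding happens, and in which direction, is an outcome of
optimization, never an input.

With abundance fractions `X_k >= 0` (summing to 1) and community-basis
fluxes `V_jk`, the steady-state community problem at growth rate `mu` is

```
max  sum_k X_k
s.t. S_k V_k = 0                        (per-species steady state)
     lb_jk X_k <= V_jk <= ub_jk X_k     (abundance-scaled bounds)
     V_bio,k = mu X_k                   (equal growth coupling)
     community exchange bounds on [u]   (per gDCW of total biomass)
     sum_k X_k <= 1
```

`solve_steadycom()` finds the largest `mu` at which total abundance 1 is
attainable, by bisection with the bracket `[0, min_k mu_max,k]` (the
monoculture optima under wide-open exchanges), tolerance `1e-6`/hr by
default. One subtlety: the flagship constraint set fixes the *net* CO2
consumption as an equality (the measured community rate), and an equality
exchange makes `mu = 0` infeasible -- zero growth cannot consume CO2.
Feasible growth rates then form an interval rather than a half-line, so
when `mu = 0` fails the solver first locates a feasible point by a
descending geometric scan (factor 1.15) before bisecting for the upper
end. Monotonicity of feasibility in `mu`, which the bisection relies on
above the feasible window, holds exactly when exchange constraints are
inequalities; the property-based tests assert it in that regime.

### Uniqueness of reported fluxes

FBA-type LPs have alternate optima, and a cross-feeding report built from
an arbitrary vertex would not be reproducible. All reported solutions
therefore pass through a lexicographic tie-break at fixed composition:

0. re-maximise the shared growth rate as a free variable (this pins `mu`
   to the exact root implied by the equality constraints, rather than the
   bisection iterate, and is why the toy optima are reproduced to
   `~1e-11` relative);
1. minimise total community substrate uptake over `[u]` exchanges
   (photon excluded) -- the parsimonious-substrate criterion familiar
   from pFBA;
2. minimise the sum of absolute species-pool transport fluxes
   (parsimonious cross-feeding).

Stage 1 precedes stage 2 deliberately. Transport-parsimony alone prefers
the topologically cheapest nitrogen route -- direct nitrate uptake, one
transport, over cross-fed ammonium, which needs three -- even when
ammonium assimilation costs the methanotroph less substrate. Putting
substrate efficiency first makes the LP prefer partner-derived ammonium
whenever the phototroph can supply it, and fall back to nitrate only when
it cannot; this is also what produces the nitrogen-source handover in the
dynamic analysis below. Only quantities that are unique under this
tie-break are asserted in tests.

## The toy community

`make_toybin1()` freezes a deterministic two-species fixture whose optima
are exact rationals, so every method is testable without downloading
curated GEMs. The methanotroph grows by `40 CH4 + 52 O2 + 8 N -> biomass
+ 12 CO2` with two nitrogen routes (ammonium directly; nitrate at an
extra dissimilatory cost of `0.25 CH4 + 0.5 O2` per N); the phototroph by
`45 CO2 + 400 photon + 6 NH4 -> biomass + 45 O2`, with nitrate reduction
to ammonium at 2 photons per N. Each species carries an ATP maintenance
subsystem so growth- and non-growth-associated maintenance
(`set_maintenance()`) are exercised. Photon, internal nitrogen and ATP
are massless bookkeeping species; `audit_toybin1_elements()` verifies
carbon/nitrogen bookkeeping per reaction, with the nitrate route's
dissimilated CH4 the single documented carbon exemption.

Under the reference constraint set (net O2 exchange closed, net CO2
uptake fixed at 0.680 mmol/gDCW/hr, nitrate-only medium) the optimum is
solvable by hand: the O2 balance `45 mu X_C = 52 mu X_M` pins the
composition `X_M = 45/97`, and the CO2 equality
`mu (45 X_C - 12 X_M) = 0.680` pins `mu = 0.680 * 97/1800 ~ 0.036644`/hr.
Blocking the ammonium transport forces the nitrate route and lowers the
optimum to `0.680 * 101/1980` -- a parameter-free, toy-scale rendition of
the mutualistic nitrogen exchange: the community grows strictly faster
when the phototroph feeds the methanotroph ammonium.

```{r steadycom}
tb <- make_toybin1()
cm <- build_community(harmonize_ids(list(tb$M, tb$C)),
                      policy_preset("toybin"))
cm <- set_exchange_policy(cm, list(o2 = c(0, 0), co2 = c(-0.680, -0.680),
                                   nh4 = c(0, 0)))
sol <- solve_steadycom(cm)
summary(sol)
```

## The kinetic layer

The semi-structured kinetic model tracks biomass of both species,
dissolved CH4/O2/CO2, and headspace partial pressures. Its closure is
this package's concrete instantiation of a Monod-type gas-liquid
bioreactor model: product-law double Monod growth for the methanotroph
(`mu_M = mu_max,M * C_CH4/(K+C_CH4) * C_O2/(K+C_O2)`; a minimum-law
switch is available via `growth_law`), Monod-times-light-saturation for
the phototroph, Pirt-type rate laws `q_i = a_i mu + m_i` linking gas
rates to growth, two-film `kLa` transfer against Henry equilibrium, and
an ideal-gas headspace. Light is a constant saturation factor (no
self-shading). Refeeds are instantaneous headspace resets that leave the
liquid untouched; stored trajectories are right-continuous at events.
Integration uses `deSolve::lsoda` at `rtol 1e-8 / atol 1e-10`, output
interval 1 hr by default.

Parameters that matter, with the built-in `batch_default` values
(declared once as the study conditions; all rates per hour, amounts in
mmol, biomass in gDCW/L):

* `mu_max = c(M = 0.12, C = 0.08)`; Monod `K` of 0.03 (CH4), 0.01 (O2),
  0.05 (CO2) mmol/L -- realistic saturation ranges for dissolved gases;
* per-growth requirements `a_M = c(ch4 = 41, o2 = 54, co2 = 13)`
  mmol/gDCW: the midpoint of the toy GEM's ammonium-route (40/52/12) and
  nitrate-route (42/56/14 with the extra 2 CH4 counted as 2 x (1, 2, 1)
  x 0.25/0.5/0) stoichiometries, so that the GEM layer retains freedom to
  choose the nitrogen route within the constraint slack;
  `a_C = c(co2 = 45, o2 = 45)` (photosynthetic quotient 1), exactly the
  phototroph stoichiometry;
* `kLa = 5`/hr per gas (shaken serum bottle), Henry solubilities 1.3,
  1.2, 30 mmol/L/bar (CH4, O2, CO2 at ~30 C), 1 L liquid / 1 L headspace
  at 303 K;
* headspace initialised at 0.60/0.30/0.10 bar CH4/CO2/N2, the reference
  batch gas mix; inocula 0.02 gDCW/L each.

A closed-system carbon inventory (`carbon_inventory()`), with biomass
carbon contents implied by the yields, is conserved to integrator
precision; the test suite requires closure within 0.5% over a full batch.

### What the generator emulates, and what it does not

The scenarios emulate the *structure* of closed-bottle coculture batch
experiments -- gas-limited Monod growth, O2/CO2 mutualism, headspace
depletion and refeeds -- with coefficients yield-matched to the toy
stoichiometry. They do not emulate the scale of curated GEMs (hundreds of
reactions, amino-acid and organic-acid exchanges), pH or ion balancing,
light self-shading, or fitted parameter values for any real strain.
Passing tests therefore demonstrate that the algorithms are correct and
internally consistent, not that any particular real coculture behaves
like the toy.

### Identifiability of the kinetic parameters

The parameter-recovery property (simulate, add 2% multiplicative noise to
biomass, refit) is assessed at a design where the parameters are actually
identifiable: a CH4-limited methanotroph monoculture on a 30/60/10
CH4/O2/N2 headspace observed at 30 three-hourly time points, so that
dissolved CH4 sweeps down through `K_ch4` during the batch. In a
CH4-replete batch the Monod term saturates and `K_ch4` is nearly
unidentifiable -- recovery claims at such designs would be meaningless.
`fit_monod_growth()` fits on the log scale by Nelder-Mead, re-simulating
inside the objective.

## The coupled dynamic community method

`run_dyncom()` walks the kinetic trajectory and, at each output time,
fixes the community LP's composition and per-species growth rates at the
kinetic values (relaxing the equal-growth assumption -- the composition
changes over a batch) and constrains each species' CH4/O2/CO2 transport
to its kinetic specific rate within a relative slack `eps`. The slack
absorbs the structural mismatch between kinetic yield coefficients and
GEM stoichiometry; hard equalities would be infeasible whenever the two
disagree at all. The package default is `eps = 0.01`; the bundled batch
scenario uses `eps = 0.10`, wide enough (CH4 spans +/-2.4% between the
two nitrogen routes, CO2 +/-8%) that the nitrogen route remains the LP's
choice rather than the kinetic layer's. The phototroph's photon transport
is capped at a constant light-harvesting capacity per gDCW
(`photon_cap = 412 * 0.08 * 2/3` mmol/gDCW/hr -- its own requirement at
the light-saturated maximal growth rate), which makes ammonium export a
*capacity-limited* service: surplus photons, 2 per ammonium, only exist
when the phototroph grows below its maximum.

Those three ingredients -- substrate-minimal tie-break, rate slack, and
photon capacity -- produce the emergent nitrogen-source handover at toy
scale: early in the batch the phototroph grows near its maximum, has no
spare photon capacity, and the methanotroph must reduce nitrate itself;
as CO2 and CH4 deplete, spare capacity appears, cross-fed ammonium
becomes available, and nitrate uptake decays to zero while the ammonium
cross-feed rises. Refeeding the headspace re-accelerates growth and
transiently reverses the handover, visible as kinks in the exchange
series. The handover time is a property of the scenario kinetics, not a
claim about any real system.

Contracts that the tests enforce: the kinetic trajectory object is
byte-identical before and after a run (unidirectionality); LP biomass
fluxes equal `mu_k X_k` exactly at feasible times; with O2 exchange
closed, phototroph production equals methanotroph consumption exactly;
and running at different output intervals gives identical values at
shared times. Infeasible time points are recorded in-series with a
status, never interpolated over; more than 50% infeasibility aborts with
a summary error.

`normalize_series()` rescales exchange fluxes by the community CH4 uptake
at the same time (dimensionless mmol per mmol CH4) or by the total
community growth rate (mmol per gDCW formed); zero denominators yield
missing values. On the balanced-growth reference state the ammonium
cross-feed per CH4 is exactly `8/40 = 0.2`.

```{r dyncom, fig.width = 6, fig.height = 4}
sc <- make_scenario("batch_default")
kt <- simulate_kinetics(sc$params, sc$init, seq(0, 96, by = 4))
cmd <- set_exchange_policy(cm, list(o2 = c(-1000, 1000),
                                    co2 = c(-1000, 1000)))
es <- run_dyncom(kt, cmd, eps = sc$dyncom$eps,
                 photon_cap = sc$dyncom$photon_cap)
plot(es, metabolites = c("nh4", "no3", "o2"))
```

## Numerical choices

* **LP solver.** All optimisation runs on a built-in dense two-phase
  primal simplex (`solve_lp()`) with variable bounds, Dantzig pricing,
  and an automatic switch to Bland's rule on stalling, so degenerate
  community LPs cannot cycle. Pivot tolerance `1e-8`; phase-1
  feasibility threshold `1e-7`; optimal solutions satisfy `|S v| <= 1e-6`
  (asserted in tests). The solver is validated against independently
  computed optima, including frozen values from an external
  interior-point/simplex implementation, and statuses (optimal /
  infeasible / unbounded) are part of its contract.
* **Blocked-reaction removal** opens all exchanges to +/-1000
  mmol/gDCW/hr (the COBRA convention for "any conditions") and iterates
  flux-variability screening to a fixed point, since removing a reaction
  can block others. Species biomass and maintenance reactions are never
  removed.
* **Dynamic FBA stepping** is explicit Euler (static optimisation
  approach) with `dt = 0.1` hr by default; a step-halving test bounds the
  discretisation drift at 1% on the bundled scenario. Concentrations are
  event-clamped at zero, and uptake shuts off through the Monod factor.
  Within lexicographic programs each attained optimum is fixed to within
  `1e-9` absolute before the next level.
* **Degenerate inputs.** Zero biomass at a time point yields a
  `no_biomass` status; growth rates and abundances are validated
  (non-negative, summing to 1); infeasible fixed-composition solves run
  an elastic diagnosis that names the unbalanceable boundary metabolites
  (e.g. the nitrogen pool when ammonium demand exceeds supply, or the
  carbon balance when kinetic and stoichiometric yields disagree).

## Problem sizes

The bundled analyses run on the toy community: 25-reaction community LPs,
bisections of ~45 LP solves, dynamic FBA at 240 steps per run, kinetic
batches of 96 h at 1 h output, and coupled community tracking at 25 time
points -- chosen so the full test suite and the reproduction script
complete in a few minutes on a single core. The same code paths accept
genome-scale SBML models; the LP solver is dense, so communities beyond a
few thousand reactions would want a sparse external solver behind the
same interface.

## Known limitations

* Equal-growth steady state is an idealisation; the fixed-composition
  mode relaxes it, but early-batch dynamics far from balanced growth are
  still filtered through a steady-state GEM at each instant.
* The tie-break is a modeling choice. The data determine the feasible
  set; substrate-minimality picks one point of it, and alternate optima
  are only surfaced through the infeasibility diagnostics, not
  enumerated.
* The toy community cannot, by construction, exhibit organic-acid or
  amino-acid cross-feeding; ranked exchange lists for real strain pairs
  require externally curated models supplied by the user.
* The kinetic model contains no nitrogen kinetics; nitrogen appears only
  in the GEM layer.
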