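---
title: "Designing sulfate-switched plasmid DNA fed-batches with pdnaflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing sulfate-switched plasmid DNA fed-batches with pdnaflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdnaflux)
```

## The design problem

Plasmid DNA (pDNA) competes with growth for carbon: every mmol of glucose
polymerized into plasmid is a mmol not spent on biomass. A growth-decoupled
fed-batch resolves the conflict in time rather than in flux: first grow the
catalyst, then switch the population into a non-growing production state.
The switch exploited here is *nutrient withdrawal* — choose a medium
component that biomass formation requires but pDNA synthesis does not, dose
it so that it runs out mid-feed, and let its exhaustion arrest growth while
glucose keeps feeding the product. `pdnaflux` covers the three computational
stages of that design: finding candidate switching nutrients, simulating the
switched process, and optimizing its timing.

## Constraint-based machinery

All stages rest on flux balance analysis over a stoichiometric model
(`metabolic_model`): maximize or minimize a reaction flux subject to
steady-state mass balance $S v = 0$ and flux bounds. Three refinements are
used throughout:

* **Parsimonious FBA** (`pfba()`): after optimizing the objective, the total
  absolute flux $\sum_i |v_i|$ is minimized with the objective held at its
  optimum. Uptake patterns read from a pFBA solution are therefore minimal
  representatives, not arbitrary vertices of the optimal face — this is what
  makes the uptake comparison between the growth and production objectives
  meaningful (it also resolves harmless degeneracies such as iron or oxygen
  over-uptake balanced by re-excretion).
* **Lexicographic FBA** (`lexicographic_fba()`): an ordered objective list;
  level $k+1$ is solved with levels $1..k$ fixed at their optima. The
  process simulator uses the triple *max growth → min sulfate uptake → max
  pDNA synthesis*, which encodes the biological priority of a growing
  culture and makes the flux state unique enough to integrate.
* **Minimal medium** (`minimal_medium()`): the exchange reactions with
  non-zero uptake under biomass pFBA; all other exchanges except water and
  protons are closed before any screen.

Objective fixing uses a slack of $\varepsilon = 10^{-6}\max(1, |z^*|)$ on the
optimizing side; without it, fixing at the exact optimum makes the next
level numerically infeasible on some solvers. The slack is visible in
results as deviations of order $10^{-6}$ mmol g$^{-1}$ h$^{-1}$ (about
$3\times10^{-3}$ mg g$^{-1}$ h$^{-1}$ after conversion by the dummy-plasmid
molecular weight); tests and tolerances account for it.

**Linear programming.** The LP solver is built into the package: a
two-phase bounded-variable revised simplex with Dantzig pricing that falls
back to Bland's rule after a run of degenerate pivots, with a
product-form-updated basis inverse refactorized every 40 pivots. Flux
balance LPs are small here (tens of reactions) but highly degenerate, and a
pivoting rule without an anti-cycling guarantee stalls on exactly the
flux-splitting LPs that pFBA creates; Bland's rule restores finite
termination. The solver is cross-checked in the test suite against an
independent implementation (cobrapy with GLPK, via the system Python) on
the fixture network, to $10^{-6}$ relative agreement. All variable bounds
are finite (the conventional $\pm 1000$ caps), which rules out unbounded
rays by construction.

## The plasmid pathway

`plasmid_spec(length_bp, gc_fraction, atp_per_dntp)` derives the dNTP
stoichiometry of a double-stranded plasmid: GC pairs are
`round(gc * length)` (round-half-up, so the count is deterministic), dATP =
dTTP and dGTP = dCTP by strand complementarity, and the counts sum to twice
the length. The synthesis reaction consumes the dNTPs plus
`atp_per_dntp * 2 * length` ATP — 1.36 mol ATP per mol dNTP by default,
hydrolyzed to ADP and phosphate by the standard convention (the cost source
states only the stoichiometric amount) — and releases one pyrophosphate per
nucleotide. An unbounded sink makes synthesis flux feasible; the plasmid
does **not** enter the biomass reaction, i.e. changes in overall biomass
composition due to plasmid load are taken as negligible.

The default is an 8 bp, 50% GC *dummy* plasmid. Length does not change the
per-base-pair stoichiometry, so results in grams of pDNA are
length-invariant, while the small molecular weight (4943.2 g/mol versus
millions for a real plasmid) keeps the mg↔mmol conversions well
conditioned. The molecular weight is the sum of neutral average dNMP
residue masses (313.21, 304.20, 329.21, 289.18 g/mol); the charged-species
convention used in model formulas differs by one proton per residue
(~16 g/mol for the dummy), and the neutral convention is the one that
reproduces the customary printed value. The SBML species still carries the
charged formula and charge derived from dNTP − PPi, so elemental and charge
bookkeeping inside the model stays consistent.

## Decoupling screen

A medium component decouples production from growth when it is (i)
essential for biomass and (ii) unused by pDNA synthesis. The operational
test (`classify_decouplers()`) caps the component's uptake at 100, 75, 50,
25, and 5% of its biomass-optimal rate and asks whether the maximal pDNA
flux *at the capped growth optimum* increases as the cap tightens
(relative tolerance $10^{-6}$ between consecutive levels). This envelope
formulation is equivalent to the two-predicate definition — the test suite
asserts that equivalence — but it is robust to components that the product
pathway uses only indirectly. Production envelopes
(`production_envelope()`) are reported normalized: growth as a percentage
of the uncapped optimum, pDNA flux as a percentage of the zero-growth
synthesis capacity, evaluated at 20 equidistant growth levels (the
boundary is piecewise linear; 20 points over-resolve it).

## Process simulation

`simulate_fedbatch()` integrates amounts, not concentrations: biomass $XV$,
plasmid $n_{pDNA}$, sulfate $n_{SO_4}$, volume $V$ (plus residual glucose
and tracked secreted byproducts). Amounts eliminate dilution terms from the
balance equations; concentrations are derived on output. The right-hand
side re-solves the lexicographic triple at every evaluation with three
momentary constraints:

* glucose uptake **fixed as an equality** to the feed-implied rate
  $q_{glc} = r^{feed} C^{feed}_{glc} / (C_{biomass} V)$ — the fed-batch is
  designed so residual glucose stays at zero, and during starvation the
  equality forces carbon disposal through the open secretion exchanges
  (acetate overflow appears qualitatively; quantitative byproduct
  prediction is out of scope). This equality deliberately overrides the
  screening-stage uptake cap: early in the feed the implied uptake can
  exceed it, exactly as a freshly fed culture outpaces its steady-state
  maximum. If the equality is infeasible the simulator relaxes it to an
  upper limit, warns, and tracks the accumulating residual;
* sulfate exchange **open while $C_{SO_4} > 0$, blocked at depletion**. No
  sulfate uptake kinetics are modeled (none are reliably known); uptake
  follows from biomass stoichiometry and growth rate, so dissolved sulfate
  is consumed proportionally to biomass gain — the sulfur-conservation
  invariant checked in the tests;
* pDNA synthesis bounded in $[q^\mu, \kappa q^\mu]$ in *both* phases (a
  high-copy-number plasmid replicates alongside genomic DNA even while the
  culture grows, hence the global lower bound, default
  $q^\mu = 4.9$ mg g$^{-1}$ h$^{-1}$). During growth the lexicographic
  solution sits at the lower bound; during starvation it reaches the upper
  bound whenever carbon suffices. The maintenance reaction is held at its
  fixed demand throughout the simulation, so surplus carbon leaves as
  overflow rather than as fictitious extra maintenance.

Integration uses `deSolve::lsodar` (adaptive, with root finding) at
rtol/atol $10^{-8}$. Sulfate depletion is a genuine discontinuity of the
right-hand side; locating it by root finding on $n_{SO_4}(t)$ and
restarting the integration in the starved phase avoids the smearing a
fixed-step scheme would produce. Termination is by volume ($V = V_{max}$,
located by a root to $10^{-6}$ L), by the time cap, or — in batch mode,
supported as feed mode `"none"` with an initial glucose pool — by glucose
exhaustion, after which the culture is treated as dormant.

Feed laws: linear (constant $r^{feed}$, default 13.91 mL/h) and
exponential ($\mu_{set} C_X(0) V(0) Y_{feed/biomass} e^{\mu_{set} t}$, with
$Y_{feed/biomass}$ in L of feed per g biomass — the volumetric reading of
that yield). Defaults describe a 1 L-scale process: 0.5 L batch volume
containing 1.51 g biomass, 0.5 L of feed at 320 g/L glucose (48.5 g of
biomass at a 0.303 g/g yield), 36 h feed phase; the linear feed fills the
reactor in just under 36 h. Unit conversions use 180.156 g/mol (glucose),
96.06 g/mol (sulfate), and the plasmid spec's molecular weight.

## Optimization layer

`productivity_scan()` simulates a grid over $\kappa$ and the initial
sulfate dose $C_{SO_4}(0)$ and reports end-of-process productivity, yield,
and starvation length $t^*$; the reference grids are 41 κ levels in [1, 5]
and 301 sulfate steps up to the *no-limitation* dose (the dose that exactly
covers full-feed growth, computed from the biomass sulfate coefficient via
one sulfate-replete simulation). Optima are reported at grid resolution —
no continuous refinement — so "within one grid cell" is the natural
agreement criterion; `optimal_so4_dose()` offers a continuous
golden-section search where a scalar optimum is wanted.

`breakthrough_length()` answers the robustness question: if the boosted
rate $q^*$ cannot be held for the whole starvation phase, how long must it
last for the starved process to still beat a never-starved control?
Production is assumed to stop entirely after the sustained window (the
conservative choice; any residual production only shortens the required
window), the control is the same feed with sulfate in excess and $q^\mu$
throughout, and the window length is found by bisection of the
productivity difference. The scan variant with a linearly drifting
$q^\mu(t) = q_0 + \text{slope}\,t$ (clamped at zero) and a parallel
starvation offset (`time_dependent_q_scan()`) reduces exactly to the
constant-rate scan at slope 0 and offset $(\kappa-1) q_0$ — a reduction the
tests assert — and exists because measured synthesis rates in real
processes decay over time.

## Metrics for measured series

The evaluation quantities are deliberately plain: specific yield
$Y = C_{pDNA}/C_{biomass}$, average volumetric productivity
$p = (C_{pDNA}(t) - C_{pDNA}(0))/t$ with $t_0 = 0$ at feed start (the two
coincide when no product is present at feed start), and the
time-dependent synthesis rate estimated by second-order finite differences
— three-point Lagrange stencils on the possibly non-uniform sampling grid,
one-sided at the ends. The rate is computed on *amounts*, $q_{pDNA} =
\frac{d(C_{pDNA} V)/dt}{C_{biomass} V}$, because sampling during the feed
changes the volume; this amount-based convention is the package's recorded
choice. Plasmid copy number converts a specific yield through
$PCN = Y\, m_{cell} / (MW/N_A)$ (default 110 fg cell mass, 50% GC). Arm
comparisons use Student's pooled-variance one-sided t-test across
replicates (Welch optional); supercoiled-fraction columns are carried
through and all metrics can be restricted to the supercoiled conformation,
but supercoiling biology itself is out of scope.

## The MiniSulf fixture: what it does and does not show

Genome-scale models are multi-megabyte downloads; the package instead ships
a generator for **MiniSulf**, a ~22-metabolite network with the qualitative
structure the screens assume: biomass requires glucose, O2, NH4+,
phosphate, sulfate, and potassium; dNTPs derive from glucose, NH4+,
phosphate, and respiratory O2 (no sulfur); maintenance is a fixed
glucose-oxidation drain; an acetate overflow disposes of carbon when growth
halts; a sulfate-reduction route provides a sulfur-containing product for
the product screen. Energy metabolism is folded into lumped glucose
coefficients so that every LP optimum is hand-checkable: maximal growth is
$(10 - g_m)/g_X$, the zero-growth synthesis capacity is $(10 - g_m)/a_{glc}$,
and the linear-feed fed-batch has an exact closed-form solution (biomass
follows a linear ODE; sulfate tracks biomass; plasmid integrates piecewise)
against which the simulator is held to 0.1%.

Default coefficients are chosen once to mimic the validated process scale:
biomass/glucose yield 0.303 g/g ($g_X = 18.32$ mmol/g), maintenance
$g_m = 0.3$ mmol glucose g$^{-1}$ h$^{-1}$ (the glucose equivalent of the
canonical 6.86 mmol ATP NGAM at ~23 ATP/glucose), sulfate coefficient
$s_X = 0.62$ mmol/g (the effective sulfate yield of a process in which
3.8 g/L sulfate in 0.5 L is exhausted roughly two thirds into the feed),
nitrogen 8.6, phosphate 0.9, potassium 0.15, oxygen 10 mmol/g. The
synthetic measurement generator (`make_series()`) samples a trajectory and
applies mean-preserving multiplicative lognormal noise (default CV below
10%, matching routine assay precision), seeded and restoring the caller's
random state.

What passing on MiniSulf shows: the algorithms — LP layer, screens,
event-driven dFBA, optimizers, metrics — are correct against independent
closed forms. What it does not show: quantitative agreement with any real
organism's stoichiometry. MiniSulf's lumped yields are effective,
maintenance-inclusive numbers, so its absolute productivities and switching
times are illustrative; runs against a genome-scale *E. coli*
reconstruction (read with `read_sbml()`) are the intended production use,
and the decoupler list there extends to the full set of growth-only ions
(Ca, Cl, Co, Cu, Fe, K, Mg, Mn, Mo, Ni, SO4, Zn), of which sulfate is the
practical choice — taken up at bulk rates, easy to quantify, and free of
catalytic side roles.

## Problem sizes and runtime choices

The shipped tests run the simulator at 61–121 output points per trajectory,
scans at 2 κ levels × 9 sulfate steps, and the breakthrough search at a
0.02 h bisection tolerance; a full 41 × 301 reference scan is the same code
at larger grid arguments. The dFBA right-hand side costs three LP solves
per evaluation (~200 evaluations per simulated fed-batch), so scan cost
scales linearly in grid size at roughly one second per simulated process on
commodity hardware.

## Known limitations

* No sulfate (or any nutrient) uptake kinetics: the on/off switching rule
  is exact in the model but soft in a reactor.
* The glucose-equality assumption presumes cells keep consuming at the feed
  rate during starvation; if uptake collapses, the simulator's starved-phase
  productivity is optimistic (the breakthrough analysis quantifies how much
  of it is actually needed).
* Byproduct secretion during starvation is qualitative; no attempt is made
  to predict the acetate titer.
* Supercoiled-fraction dynamics are carried as data, never modeled.
* The LP layer is dense and tuned for models up to a few thousand
  reactions; it is exact but not engineered for very large reconstructions
  at dFBA call rates.
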