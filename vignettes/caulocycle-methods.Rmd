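---
title: "caulocycle: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{caulocycle: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(caulocycle)
```

## The model

`caulocycle` simulates the cell-division clock of *Caulobacter crescentus*
as a deterministic, well-mixed hybrid system: 29 continuous state
variables governed by ordinary differential equations, interrupted by five
instantaneous threshold events that represent discrete milestones of
chromosome replication and division. Concentrations are in arbitrary units
(a.u.) on the scale of the packaged initial-value table; time is in
minutes throughout.

The continuous states fall into four groups:

* **DNA progress variables.** `Ini` accumulates initiation licensing;
  `Elong` tracks replication-fork progress on \[0, 1\]; `Zring` is a linear
  clock for cytokinetic constriction. Three hemimethylation probabilities
  `hCori`, `hccrM`, `hctrA` describe the methylation state of the
  replication origin and of the *ccrM* and *ctrA* promoters: semiconservative
  replication leaves a locus hemimethylated (h = 1), and the
  methyltransferase CcrM restores full methylation (h → 0) with fourth-order
  Hill kinetics in CcrM.
* **mRNAs** for the five master regulators, plus an intermediate `IccrM`
  that delays *ccrM* transcription behind CtrA~P accumulation.
* **Master regulator proteins** DnaA, GcrA, CcrM, SciP, and CtrA split into
  unphosphorylated and phosphorylated (`CtrAP`) forms. CtrA~P is the
  active species: it blocks replication initiation, activates *sciP*,
  *ccrM*, its own P2 promoter, and the proteolysis-module genes.
* **The proteolysis / second-messenger module.** ClpXP primed by
  unphosphorylated CpdR (Complex 1) recruits RcdA (Complex 2) and then the
  c-di-GMP–loaded adaptor (Complex 3), which degrades CtrA through a
  saturable second-order Hill term. The state `cdG` represents the
  PopA:2c-di-GMP adaptor species; PleD (active when dephosphorylated by
  the PleC phosphatase) synthesizes it and PdeA hydrolyzes it. cdG also
  inhibits the CckA kinase, coupling proteolysis to the phosphorylation of
  CtrA and CpdR. CckA~P is conserved against a fixed total pool
  (`CckA_T`), and ClpXP is a constant pool that complex formation does not
  deplete.

Activation and inhibition are classical Hill functions
(`hill_activation()`, `hill_inhibition()`); Hill exponents are fixed
integers per term (4 for the initiation gate, methylation kinetics and the
CtrA/SciP repression of *ctrA*; 2 elsewhere) and are deliberately not
tunable. All rate and binding constants live in a single named vector
(`caulo_params()`, 97 entries), serialized bit-exactly to
`inst/extdata/params_wildtype.tsv`.

Two formulation details deserve emphasis:

* **Lumped adaptor stoichiometry.** Because `cdG` stands for the already
  dimerized PopA:2c-di-GMP species, Complex-3 assembly is second order in
  the lumped concentration, and the same `k3+·cdG²·Complex2` flux appears
  in the Complex-2, Complex-3 *and* cdG balances. An asymmetric (linear)
  debit on the cdG side would act as a spurious sink that collapses the
  second messenger far below the documented initial orbit and silently
  disables cyclic CtrA proteolysis; the consistent form keeps the settled
  cdG and Complex-3 levels on the same scale as the packaged initial
  values.
* **PleC forcing.** PleC is not a state variable; its cell-cycle profile
  enters as a fixed two-sinusoid fit,
  `80.09·sin(0.013 t + 1.74) + 78.77·sin(0.013 t + 4.85)` (`plec_level()`).
  The two components nearly cancel, leaving a small oscillation around
  zero, so inside the equations the profile is truncated at zero — a
  phosphatase concentration cannot be negative, and feeding the negative
  lobe into the PleD phosphotransfer reverses its direction and
  destabilizes the module. The forcing clock is re-zeroed at each division
  (see below).

## Events and conventions

Five rules fire on upward threshold crossings
(`builtin_event_table()`):

| event | trigger | assignments |
|---|---|---|
| initiation | `Ini` = `P_elong` (0.05) | `Ini := 0`, `Elong := 0.1`, `hCori := 1`, Z-ring clock on (0.011 min⁻¹), `DNA := 1.05`, `Count := 2` |
| fork passes *ccrM* | `Elong` = 0.2 | `hccrM := 1` |
| fork passes *ctrA* | `Elong` = 0.375 | `hctrA := 1` |
| termination | `Elong` = 1 | `Elong := 0` |
| Z-ring constriction | `Zring` = 1 | `Zring := 0`, clock off, `DNA := 1`, `Count := 1` |

Design choices here, all exposed as arguments:

* **`Elong` seed 0.1 (default) vs 0.05.** Replication is bidirectional, so
  at initiation two forks have each cleared `P_elong = 0.05` of the
  chromosome; seeding `Elong` at `2 × P_elong` is the convention adopted as
  default (`elong_at_initiation = 0.1`). It also reproduces the documented
  wild-type period (see below); the single-fork value 0.05 remains
  available and lengthens the settled period by about 1.4 min.
* **Per-cycle PleC clock.** The forcing has a 483-min period,
  incommensurate with the 150-min cycle. Evaluated on absolute time
  (`plec_mode = "absolute"`) no limit cycle can exist and successive
  periods wander by around a minute. Since the profile was fitted over a
  single cycle, the default (`plec_mode = "cycle"`) restarts the forcing
  clock at each division, making the system piecewise-autonomous with a
  strict limit cycle.
* **One-shot initiation.** The initiation rule cannot re-fire while a
  replication round is in progress; if the licensing variable crosses its
  threshold early, the event fires at termination. On the wild-type limit
  cycle this guard is inert (licensing completes ~4 min after
  termination).
* **Event ordering.** With the slow elongation constant
  (`k_elong = 6.53e-3` min⁻¹) a full round of elongation takes
  `(1 − 0.1)/k_elong ≈ 138` min, so termination lands *after* the Z-ring
  event (~91 min after initiation). The realized per-cycle order is
  therefore initiation → fork(*ccrM*) → fork(*ctrA*) → Z-ring →
  termination, and the test suite asserts exactly this order.
* Integration restarts with fresh solver state after every event;
  `locate_and_apply()` exposes the root-finding semantics (crossing
  located to 1e-8 min, assignments atomic, all other states continuous).

## Numerics

The right-hand side is implemented three times: a documented R reference
(`caulo_rhs()`), a fast R closure, and the compiled C version used by
default (`engine = "compiled"`); the suite checks all three against an
independently transcribed oracle at random states to 1e-12 relative
error, and compiled vs R trajectories agree to solver precision.
Integration uses `deSolve::lsodar` (stiff-capable, with root finding),
`rtol = 1e-8`, `atol = 1e-10`, maximum step 1 min so no threshold crossing
can be stepped over; all trigger variables are monotone between resets, so
crossings cannot be missed by double-crossing within a step. Sub-roundoff
negative excursions are clipped at zero; a state below −1e-6 aborts with a
diagnostic. Objective evaluations during fitting relax to
`rtol = 1e-6` — the settled period moves by less than 0.05 min, far below
any decision threshold, and the search needs thousands of simulations.

**Measurement protocols.** The cycle period is the mean inter-initiation
interval after discarding transient cycles (`cycle_period()`, default two)
with a 1% convergence flag; the acceptance script runs 24 cycles and
averages the last three intervals, where successive intervals agree to
&lt;0.1%. The approach to the limit cycle is slow (the first interval is
~145.6 min, the settled one 149.997 min), which is why period claims
should always be made on settled cycles. The phenotype classifier calls a
run *arrested* below three initiations, and *damped* when the total-CtrA
amplitude of the last cycle falls below 10% of the first post-transient
cycle — the reference is cycle 3, not cycle 1, because the relaxation of
the initial condition would otherwise read as damping. The S-phase
interval (initiation to constriction) is analytically `1/0.011 ≈ 90.9`
min and the event log reproduces it to &lt;0.01 min.

```{r wt, eval = FALSE}
sim <- simulate_caulobacter(duration = 1200)
cycle_period(sim)$period   # ~149.96
sphase_interval(sim)       # 90.909
```

## The QSSA variant

Complex 3 assembles and dissociates fast relative to the cycle, so
`simulate_qssa()` replaces it by its algebraic steady state
`k3+·cdG²·Complex2/k3−` and drops its differential equation; the exchange
fluxes then cancel identically in the Complex-2 and cdG balances. The
settled period agrees with the full model within 2.5%, and every mutant
classification is unchanged. The waveform is only qualitatively preserved:
instantaneous equilibration deepens proteolysis at the cdG peak and
shallows the swarmer-phase clearance of CtrA, leaving a phase-aligned RMS
difference of roughly a quarter of the CtrA amplitude over one cycle. A
mass-conserving reduction (tracking Complex 2 + Complex 3 as one pool)
would likely track more closely but changes the meaning of the remaining
states, so it is not offered.

## Mutants

`builtin_panel()` defines eleven strains: knockouts zero the relevant
synthesis rate (`ks_ccrM`, `ks_gcrA`, `ks_dnaA`, `ks_cdG`, `ks_PdeA`,
`ks_PleD`), the non-proteolyzable CtrA allele reduces `kd_CtrA_ClpXP` to
10%, and the proteolysis variants zero a half-saturation constant
(`Jd_CtrA_ClpXP`, `Jd_CpdR`, `Jd_RcdA`, or all three), which turns the
corresponding saturable degradation term into a constant-rate one. Mutants
reuse the wild-type initial state, so the override set is the *only*
difference (asserted by the tests). `run_mutant_panel()` reproduces: the
arrest of the *dnaA* knockout; viability of the other six strains; the
~163 min cycle without CcrM (hemimethylation never clears, weakening the
methylation boost of initiation); ~10 min lengthening without GcrA; raised
mean cdG without PdeA and collapsed cdG without PleD; the longer, damped
cycle under constant-rate CtrA proteolysis; and the near-loss of CtrA
oscillation under constant-rate CpdR or RcdA proteolysis. Under five-fold
accelerated CtrA proteolysis the wild-type network still oscillates.

## Observation sets and fitting

`generate_observations()` emulates digitized immunoblot/transcript time
courses: each observable is sampled at ~5–15 uniformly random times over
one settled cycle mapped to \[0, 150\] min, corrupted with additive
Gaussian noise proportional to its amplitude (truncated at zero — blot
densitometry cannot go negative), and min–max normalized per species. The
fifteen observables are the five mRNAs, the five regulators and CpdR,
RcdA, PleD, PdeA, cdG; protein observables are totals over phosphoforms,
as a western blot measures. For synthetic fixtures the sampled range
doubles as the species' target scaling range, so
rescale(normalize(x)) = x and a noiseless fixture is interpolated exactly
by its own generator — which pins the misfit minimum at zero for recovery
tests. What these fixtures do *not* emulate: systematic digitization bias,
between-source scale disagreements, unevenly clustered sampling designs,
or non-Gaussian blot noise; a fit that recovers parameters from fixtures
demonstrates identifiability of the machinery, not performance on real
blots. Externally digitized tables enter through
`read_observations()` + `rescale_observations()` with ranges from a
reference simulation (`species_ranges()`), since per-species absolute
scales are not identifiable from normalized data.

The misfit `f1` is the squared deviation between the simulated settled
cycle and the observations, averaged per species and then across species
(default). With per-species point counts varying, a single `1/(n·m)`
prefactor is ambiguous; the per-species mean avoids over-weighting densely
sampled species, and `weighting = "pooled"` provides the grand-mean
alternative. `f2` is `|T_c − 150|` min. Failed or arrested evaluations
receive a large finite sentinel (1e6) so the evolutionary search remains
totally ordered.

The two-objective search (`optimize_mop()`) is a compact real-coded
NSGA-II — simulated binary crossover (η = 15), polynomial mutation
(η = 20, rate 1/p), binary tournament on rank then crowding distance,
elitist μ+λ selection, and a cumulative nondominated archive whose
hypervolume (fixed reference point) is non-decreasing by construction. One
integer seed controls all randomness; identical seeds give identical
archives. On the separable toy problem min(x², (x−2)²) the archive reaches
the closed-form front's hypervolume within a fraction of a percent.
Surrogate-assisted or trust-region multiobjective methods are out of
scope. `perturbation_sensitivity()` perturbs parameter vectors by a fixed
relative magnitude — either one sign for the whole vector ("uniform",
which changes any degree-1 homogeneous objective by exactly the
magnitude, giving a closed-form check) or independent per-parameter signs
— and averages |Δf/f|, excluding points whose baseline `f2` is near zero,
where relative change is unbounded by construction.
`refit_parameters()` offers bounded Nelder–Mead (logit-box transform, with
simplex restarts, since the simplex collapses on the synthesis/degradation
compensation ridges) for few-parameter recovery; from noiseless fixtures
it returns 5 perturbed parameters to within 10% of truth.

## Known limitations

* No spatial structure: polar localization, the PopZ scaffold and the
  swarmer/stalked compartments are ignored; both daughters are not
  tracked, so the simulated cycle closes on itself rather than inheriting
  asymmetrically.
* The Z-ring is a bare linear clock; mutants whose real phenotype runs
  through division machinery (e.g. the much larger experimental slowdown
  of the *gcrA* knockout) are underestimated by construction.
* The PleC forcing is a fixed fit, truncated at zero, re-zeroed per cycle;
  it does not respond to the state of the cell.
* `DNA` and `Count` are bookkeeping outputs only — gene dosage does not
  feed back on transcription rates.
* Deterministic ODEs only: no stochastic (SSA) variant, no cell-size
  control, no growth dilution.
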