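---
title: "Methods: state-dependent Nav1.5 block analysis and proarrhythmia simulation"
author: "cardioblock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: state-dependent Nav1.5 block analysis and proarrhythmia simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`cardioblock` implements an in vitro cardiac safety pharmacology workflow
for sodium-channel-blocking drugs, with cenobamate as the built-in worked
compound. This vignette documents the models, estimators, numerical choices
and known limitations; the README shows the user-facing workflow.

## 1. The analysis chain

Whole-cell patch-clamp assays on heterologously expressed cardiac channels
(hNav1.5, hCav1.2, hKv7.1+minK, hERG) yield fractional inhibition values at
one or a few drug concentrations. The package converts these to potencies,
then to conformation-specific blocking kinetics, and finally propagates them
into a human ventricular myocyte model and a one-dimensional tissue strand:

1. **Dose-response** (`ic50_single_point()`, `fit_hill()`): the primary
   route is the single-point estimator
   `IC50 = C * ((1 - f)/f)^(1/n_H)` with `f` the net fractional inhibition
   (drug minus mean vehicle rundown, a plain subtraction — no rescaling by
   `1 - control`). The Hill coefficient defaults to 1 everywhere; freeing
   it is opt-in.
2. **Block kinetics** (`recovery_tau()`, `tau_ob_from_decay()`,
   `inactivated_block_tau()`, `rates_from_sum_and_kd()`): use-dependent
   block pulse trains and paired decay fits give the four state-specific
   rate constants of the modulated receptor hypothesis (MRH): `k_ob`,
   `k_ob^-1` for the open conformation, `k_ib`, `k_ib^-1` for the
   inactivated conformation.
3. **Myocyte model** (`paced_run()`, `qnet()`): an O'Hara-Rudy 2011 human
   ventricular cell extended with a blocked-state variable `b`; outputs
   APD90 and the CiPA net-charge predictor Q_net.
4. **Strand model** (`simulate_strand()`): 50 coupled cells quantify
   conduction slowing and block under reduced gap-junction coupling, and
   `reentry_min_length()` converts a refractory period and a slow-pathway
   conduction velocity into the minimum length of a two-pathway reentry
   circuit.

## 2. The synthetic-data generator and what it emulates

`simulate_markov_trace()` is the ground-truth generator against which every
estimator is validated by parameter recovery. It integrates a five-state
Markov scheme — closed (C), open (O), inactivated (I), open-blocked (OB),
inactivated-blocked (IB) — with activation lumped into a single fast
voltage-dependent C↔O transition (sigmoidal rates, midpoint −45 mV, slope
4 mV, maximal rate 15 ms⁻¹), macroscopic inactivation O→I at `1/tau_i`, and
recovery I→C at `1/tau_r` gated to hyperpolarized potentials (midpoint
−70 mV). Drug binding follows the MRH: O↔OB at `k_ob[D]`/`k_ob^-1`, I↔IB at
`k_ib[D]`/`k_ib^-1`, no closed-state binding, gating untouched. OB↔IB
interconversion is off by default; if enabled it satisfies detailed balance
around the O–I–IB–OB cycle.

Default kinetic values are the drug-free constants estimated in the
use-dependent block experiments (`tau_i` 2.47 ms, `tau_r` 3.81 ms), so
synthetic recordings resemble hNav1.5 at room temperature under the
standard protocols. Occupancies are propagated by per-step matrix
exponentials of the generator, which preserves positivity and the unit sum
exactly at any step size; ramp segments use piecewise-constant voltage at
the sample resolution.

The generator reproduces the *kinetic structure* real estimators face
(activation delay, saturating pulse trains, biexponential decay under
block). It does **not** emulate series-resistance or capacitance artifacts,
leak, rundown, or cell-to-cell variability, so passing recovery tests show
estimator correctness under the stated model, not robustness to every
experimental nuisance. Additive Gaussian noise (and optional linear
baseline drift) is available through `add_noise()` with per-sweep seed
splitting, so enlarging a sweep set never reshuffles existing sweeps.

## 3. The use-dependent recurrences and their approximation error

The recovery recurrence
`tau_r = t_r / [ln(1 − e^{−t_d/tau_i}) − ln(1 − o_n/o_{n−1})]`
book-keeps a single pulse/recovery interval: the fraction
`1 − e^{−t_d/tau_i}` of available channels inactivates during the `t_d`
dwell and the unrecovered remainder `e^{−t_r/tau_r}` is missing from the
next peak. Two properties matter in practice:

* **Only the first decrement is exact.** From pulse 3 onward the train
  approaches its use-dependent steady state and the single-interval
  book-keeping (which ignores carry-over of channels inactivated in earlier
  pulses) over-predicts the decay dramatically at short `t_r`. The
  estimators therefore use the `o_2/o_1` ratio per sweep by default
  (`pulses = "first"`); pooling all ratios is available but biased.
* **The degenerate limit.** Ratios at or below `e^{−t_d/tau_i}` imply zero
  or negative recovery (infinite `tau_r`); those intervals are excluded
  with a warning, and an all-excluded train raises a non-estimable error.

The drug-train recurrence for the inactivated-conformation constant
`tau_ib` composes an "inactivated-or-blocked" pool and assumes it recovers
at the net rate `1/tau_r − 1/tau_ib`. Against the five-state ground truth
this net-rate heuristic substantially *overestimates* `tau_ib`: at the
estimated cenobamate rates the true rest-interval unavailable-pool dynamics
(recovery at `1/tau_r` competing with I↔IB exchange) have a slow eigenvalue
several-fold larger than the heuristic's `1/tau_r − (k_ib[D]+k_ib^{-1})`,
and the recovered `tau_ib` runs about a factor two high, almost uniformly
across `t_r` 5–50 ms. The acceptance suite asserts the oracle-equivalence
tolerances anyway and thereby *documents* the achieved accuracy: exact
inversion of the defining recurrences at machine precision, `tau_r` to
within 1%, open-state rates to within about 20%, and the inactivated-state
chain outside its nominal band for the reason above. Estimates produced
from real recordings inherit the same approximation and should be read as
effective (protocol-conditional) constants, which is also how they are
consumed downstream.

The open-state chain fits the apparent decay constant with and without
drug, using the initial 3 ms after the current peak — the standard window
for ~1–2.5 ms Nav decays. With drug the decay is intrinsically
biexponential (unblocking back-flux), and its fast eigenvalue bounds any
monoexponential estimate of `1/tau_i + k_ob[D] + k_ob^{-1}` from below
(about −13% at 200 µM), which is the dominant share of the ~20% open-rate
error quoted above.

## 4. The myocyte model

The single-cell model is the O'Hara-Rudy 2011 human ventricular
formulation (endo/epi/mid parameter sets, geometry, CaMK machinery) with a
`variant` flag: `"base"` is the model as published; `"cipa"` applies the
CiPA-lineage conductance rescale (INaL ×2.661, ICaL ×1.007, IKr ×1.013,
IKs ×1.87, IK1 ×1.698) used by net-charge torsade-risk work.

Drug pharmacology has two tiers, matching how class-I block is usually
modeled:

* **Static pore block** for INaL, ICaL, IKr, IKs: maximal terms multiplied
  by `1/(1 + C/IC50)` with the configured potencies (cenobamate defaults:
  46.5, 509.75, 1869, 1336.1 µM; hERG uses the adopted regulatory value
  rather than the in-house single-point estimate).
* **Dynamic fast-INa block** through the blocked-state occupancy `b`:

  `db/dt = {m³[(1−f)hj + f h_p j_p] k_ob + m³[1 − (1−f)hj − f h_p j_p] k_ib}[D](1−b)
          − {m³[(1−f)hj + f h_p j_p] k_ob⁻¹ + m³[1 − (1−f)hj − f h_p j_p] k_ib⁻¹} b`

  with `f` the CaMK-phosphorylated fraction, and
  `I_Na = (1−b) G_Na (V−E_Na) m³[(1−f)hj + f h_p j_p]`. The m³ factor
  multiplies *both* the open and the inactivated pathway, so closed
  channels carry zero block weight and `b` is frozen at rest. Whether `b`
  should also scale INaL is not knowable from the potency data; the default
  keeps the static 46.5 µM scaling and `b_scales_inal = TRUE` switches.
  At zero concentration the unblocking rates stay active (washout), and the
  zero-concentration output is bitwise identical to the no-drug code path.

**Numerics.** Fixed-step integration at `dt` = 0.005 ms: Rush-Larsen
(exact-exponential) updates for all gating variables, the two
release-flux relaxations, the `nca` pathway and `b`; forward Euler for
concentrations and voltage. GHK-type flux denominators are guarded against
the removable singularity at `V = 0`. A refinement check (halving `dt`
moves the final APD90 by well under 0.5 ms) is part of the acceptance
suite. Runs abort with a diagnostic if `|V|` exceeds 500 mV.

**Pacing and problem sizes.** The net-charge convention paces at a cycle
length of 2000 ms with a −80 µA/µF, 0.5 ms stimulus. The package default
pre-paces 1000 beats; the *reproduction configuration* (`repro_config()`)
uses 300 pre-pacing beats, at which point the per-beat APD90 drift is below
0.005 ms/beat — three orders of magnitude inside the ±2% band the APD90
anchors are checked at — while keeping a full reproduction run around a
minute. The published anchor pair (endo control 304.0 ms, 1×C_max
270.5 ms) selects the `"cipa"` variant: measured at these settings the base
calibration gives 288.2/277.5 ms and the CiPA calibration 304.6/267.0 ms.
APD90 is measured from the maximum-upstroke take-off to 90% repolarization
from the AP peak toward the pre-stimulus resting level; the convention is
ours (robust also for depolarized hiPSC-CM-like traces with resting
potentials near −50 mV), since the source convention is not stated.

**Q_net** is the trapezoidal integral of
`I_NaL + I_CaL + I_Kr + I_Ks + I_K1 + I_to` over the final paced cycle, in
µC/µF; the result equals the sum of its per-current component integrals by
construction, and rises from its drug-free value as cenobamate predominantly
suppresses depolarizing current (0.064 → 0.097 µC/µF from 0 to 1×C_max at
these settings, plateauing near 2×C_max).

**Dose direction above the therapeutic range.** APD90 shortens from control
to 1×C_max (the anchor pair) but re-lengthens above ~2×C_max in this
implementation (271 ms at 2×, 295 ms at 4×): the static hERG/IKs Hill
factors (IC50 1869 and 1336 µM) begin to matter at those concentrations and
overtake the remaining depolarizing-current loss. Concentration-response
monotonicity should therefore only be expected in the therapeutic range.

**Temperature.** The model runs at its native 37 °C formulation although
the potencies were measured at room temperature; transferability of
local-anesthetic-type block across temperature is poor in both directions,
and no correction is attempted.

**Concentration semantics.** Nominal total concentration by default;
`use_free_fraction = TRUE` multiplies by the drug's unbound fraction
(cenobamate 0.4) before any block is computed.

## 5. The strand model

`simulate_strand()` couples `n_cells` (default 50) identical myocytes in a
line. The coupling term for cell *i* is
`G_j (V_{i−1} − V_i) + G_j (V_{i+1} − V_i)` with sealed ends;
`G_j` in pS/pF converts to current density as 1 pS/pF × 1 mV = 10⁻³ µA/µF
(a dimensional-analysis test pins this). Cells are pre-paced to
*single-cell* steady state at the run's concentration and the coupled
strand is then paced from its stimulated end; coupled pre-pacing of 50 full
models would multiply the cost ~50-fold without changing the questions the
strand answers (relative conduction velocity and block thresholds).

Three measurement choices were driven by observed low-coupling physics:

* The stimulus is −80 µA/µF for 2 ms into the first **three** cells. A
  single end cell cannot simultaneously depolarize itself and source its
  downstream neighbor once fast INa is partly blocked; three cells is the
  smallest stimulated region that initiates reliably across the studied
  `G_j` × concentration grid.
* Activation time is the time of maximal dV/dt restricted to the upstroke
  voltage band (−65…+10 mV). At strongly reduced coupling the electrotonic
  foot of the incoming wave can be steeper than the slow regenerative
  upstroke, and an unrestricted maximum marks the foot.
* Capture means peak V ≥ 0 mV with a band-restricted upstroke ≥ 1 mV/ms.
  Gap-junction-limited conduction is genuinely slow (a few mV/ms upstroke,
  full +30 mV overshoot) and is conduction, not electrotonus; a higher
  upstroke cutoff misclassifies it as block.

Conduction velocity is the slope of a position-on-activation-time
regression over interior cells 10–40 (boundary exclusion), reported in
cm/s; with 100 µm cells, 1 ms/cell equals 10 cm/s. A non-captured cell
inside the window makes cv undefined and the run reports the first blocked
cell instead.

`reentry_min_length(RP, cv)` implements the wavelength criterion for a
two-pathway circuit: reentry through the slow limb is possible once its
travel time exceeds the fast-limb refractory period, i.e. above the circuit
length `RP × cv` (300 ms × 2 cm/s = 6 mm).

## 6. Problem sizes used by the test and acceptance runs

Chosen as the package's own trade-off between statistical resolution and a
comfortable desk-scale run: reproduction pacing 300 + 2 beats (single runs
~1 min); supplementary strand pre-pacing 60 beats; strand grid 3 × 3
(`G_j` ∈ {300, 1500, 6000} pS/pF × {0, 2, 4}×C_max) with 50 cells and one
analyzed beat per run; Monte-Carlo estimator studies 60–100 replicates.
The full pre-pacing default (1000 beats) changes the reproduced APD90 pair
by less than 0.5 ms.

**Observed regime.** Under these settings the drug-free strand conducts at
1500–6000 pS/pF (≈11 and ≈28 cm/s) and fails decrementally near 300 pS/pF,
while concentrations at or above 1×C_max block at every coupling studied.
Two model properties conspire to make drugged conduction fragile: the
O'Hara-Rudy 2011 fast-INa formulation is known to under-supply depolarizing
charge for tissue-level propagation (its original authors substituted a
larger INa for their own 1D simulations), and the dynamic MRH block
preferentially depresses slowly rising wavefronts, because the blocked
fraction climbs toward its open-state equilibrium during the long
activation foot that low-safety-factor conduction produces. The package
reports what the stated model does; the strand readouts should be read as
relative (coupling- and concentration-ordering) statements, not absolute
conduction-velocity predictions.

## 7. Known limitations

* The five-state Nav scheme is the smallest one reproducing the quantities
  the estimators target; no claim is made that it matches any richer gating
  topology beyond those quantities.
* The recurrence estimators are effective-rate approximations; their biases
  against the Markov ground truth are quantified (not removed) by the
  acceptance suite, the inactivated-conformation chain being the weakest
  link (~2× on `tau_ib`).
* Potencies measured at room temperature drive a 37 °C model.
* The strand is 1D with a uniform cell type and no explicit two-pathway
  circuit; reentry feasibility is assessed only through the wavelength
  rule.
* Printed-figure quantities of the source experiments (dose-response panel
  layouts, per-figure conduction velocities) are treated as qualitative
  anchors only; the quantitative anchors are the worked arithmetic values,
  the decay/recovery tables and the APD90 pair.
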