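---
title: "Modeling CO2/H+-sensitive locus coeruleus neurons with lcneuro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling CO2/H+-sensitive locus coeruleus neurons with lcneuro}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`lcneuro` simulates a single-compartment, conductance-based model of a
CO2/H+-sensitive neuron of the locus coeruleus (LC), the brainstem
noradrenergic nucleus whose pacemaker neurons increase their firing rate
when CO2 or proton levels rise.  The membrane equation is the
Hodgkin-Huxley current balance

$$c\,\frac{dV}{dt} \;=\; \sum_i I_i \;+\; I_{app},$$

in the inward-positive convention $I_i = g_i\,(E_i - V)$, over twelve
currents: transient sodium (Na), delayed-rectifier, A-type and M-type
potassium (K\_dr, K\_A, K\_M), an inward rectifier (Kir), a
hyperpolarization-activated cation current (H), low- and high-threshold
calcium currents (Ca\_T, Ca\_L, Ca\_N), calcium-controlled SK and BK
potassium currents, and a three-component linear background leak
(Na/K/Cl).  Voltage-gated channels carry activation and (where present)
inactivation gates obeying

$$\frac{dx}{dt} = \frac{x_\infty(V) - x}{\tau_x(V)}, \qquad
x_\infty(V) = \frac{1}{1 + e^{-(V - V_{1/2})/k}},$$

with a Gaussian time-constant kernel for the sodium gates and T-type
inactivation and a reciprocal-cosh kernel for everything else.  Because the
gates relax toward a target inside $[0,1]$, they can never leave that
interval; the test suite asserts this numerically as well.

Units are fixed package-wide as mV, nA, uS, nF, ms and mM, which makes
$dV/dt = \Sigma I/c$ dimensionally consistent without conversion factors.

### Chemosensitivity

Each chemosensitive conductance is scaled by a unitless factor

$$\varphi_i = 1 - \sum_{s} w_{i,s}\, \varphi_s(s), \qquad
s \in \{\mathrm{pH_i}, \mathrm{pH_o}, \mathrm{CO_2}\},$$

with signed channel-specific weights (positive = inhibition).  The CO2 term
is a Hill saturation curve on the CO2 percentage.  The pH terms describe
titration of channel-protein residues; the package default evaluates them
as the base-10 titration fraction

$$\varphi_s = \frac{1}{1 + 10^{\,h\,(\mathrm{pH} - \mathrm{pK})}},$$

which has its midpoint at the pK, grows as the bath acidifies, and for
$h = 1$ is exactly the Henderson-Hasselbalch protonation fraction.  This
was a genuinely open design choice and the main fork in this
implementation: evaluating the Hill response on the raw pH numeral with
the published direction (`ph_hill_form = "printed"`) makes *alkalosis*
maximize channel inhibition, so acidosis then lowers the firing rate and
hypocapnic alkalosis cannot silence the cell — the opposite of the
behavior the model exists to reproduce.  The acid-activated direction is
therefore the default, with `"printed"` and a gentler pH-ratio variant
(`"ph_ratio"`) selectable in `options$ph_hill_form` for sensitivity
analyses.  A consequence documented under "Limitations" below: with the
tabulated Hill coefficients of 15, the intracellular-pH titrations are
nearly binary switches around their pK, so a full acidotic challenge (pH_i
7.0) turns the delayed rectifier and A-current off completely rather than
partially.

### Calcium dynamics, SK and BK

Free calcium in a thin sub-membrane shell obeys

$$\frac{d\,\mathrm{Ca}}{dt} = \mathrm{CSF}\,\frac{I_{Ca}}{2Fv}\,(1 - P_B)
 \;-\; K_s \frac{\mathrm{Ca}}{\mathrm{Ca} + K_m}, \qquad
P_B = \frac{B_{tot}}{\mathrm{Ca} + B_{tot} + K_d},$$

where $I_{Ca}$ is the summed high-threshold (L- plus N-type) calcium
current in the inward-positive convention — so calcium entry raises the
shell concentration — $P_B$ is the fraction captured by the buffer, and
the Michaelis-Menten term is the membrane pump.  The SK current activates
with calcium through the standard Hill form
$m_{SK}^\infty = \mathrm{Ca}^n/(\mathrm{Ca}^n + K_c^n)$ (the difference
form that appears in some transcriptions cannot produce a value in
$[0,1]$) and relaxes with a 5 ms time constant.  The BK current is coupled
to the instantaneous magnitude of a partner calcium current,
$I_{BK} = g_{BK}\,L\,(E_K - V)$ with
$L = |I_{Ca}^{partner}| / (\bar g\,|E_{Ca} - V_r|)$.  The partner defaults
to the N-type channel (`options$bk_couples_to`): the N-type current is not
chemosensitive, so spike repolarization survives acidotic challenges that
suppress the L-type current — with L-type coupling the model enters
depolarization block under hypercapnic acidosis.

This calcium/SK loop is the pacemaker's clock.  Each spike loads the shell
with roughly $5\times10^{-9}$ mM of free calcium; the pump clears it over
a couple of seconds; firing resumes, or accelerates, as the SK brake
decays.  It also produces spike-frequency adaptation under sustained
stimulation and the post-stimulation quiescence that follows strong
depolarization.

### Background currents and the leak decomposition

The total leak conductance is $1/R_{in}$.  Its potassium share is the
TASK-like, pH-sensitive conductance; the sodium share is fixed by
requiring the three linear leaks to balance exactly at the resting
potential; chloride absorbs the remainder.  With the tabulated cell
constants this leaves the passive membrane resting at $-60$ mV.  The
inward rectifier is implemented exactly as its closed form is defined
(numerator zero at $E_K + 36$, thermal slope $ZF/RT = 0.0394$/mV at
295 K); note that with these constants its rectification window lies below
the physiological voltage range, so the current is essentially silent —
one reason its maximal conductance (absent from the published tables) is a
benign calibrated parameter.

## Parameters: provenance and calibration

All channel kinetics, conductances, chemosensitivity weights/midpoints and
cell constants are transcribed from the published tables and shipped both
in code (`lc_default_params()`) and as a YAML configuration
(`inst/extdata/default_params.yaml`).  `effective_parameters()` prints
every value the right-hand side uses, tagged `table`, `calibrated` or
`default-decision`, together with the list of table inconsistencies the
loader resolves.  The resolutions worth knowing about:

* **Inactivation assignment.**  The published inactivation table repeats
  its first four value columns under a second set of headers, and taking
  the header assignment literally leaves the model unable to fire
  repetitively at *any* applied current: the 1.5 uS A-current, assigned a
  half-inactivation of $-45$ mV, clamps the membrane permanently.  The
  value sets are instead assigned by their kinetic lineage — $(-78, 6, 19,
  45, -80)$ is a textbook A-current inactivation and $(-81, 4, 28, 300,
  -81)$ a textbook T-type inactivation — and the delayed rectifier and
  M-current, which classically do not inactivate, carry no inactivation
  gate.  This restores pacemaking and matches the described mechanism of
  postinhibitory rebound (T- and A-current de-inactivation during
  hyperpolarization).
* **Calibrated parameters.**  Five quantities are not recoverable from the
  publication and are declared `calibrated` in the configuration: the BK
  and Kir maximal conductances ($0.2$ and $0.002$ uS), the SK
  half-activation calcium $K_c$ ($3\times10^{-8}$ mM), the pump rate $K_s$
  ($4\times10^{-8}$ mM/ms) and the baseline shell calcium
  ($2\times10^{-9}$ mM).  The printed values for the last three (25 mM,
  0.39 nM/s, 50 nM) are mutually inconsistent by four to nine orders of
  magnitude with the influx scale $1/(2Fv)$ that the printed area, shell
  thickness and Faraday constant fix; any unit reading of the printed pump
  rate gives an extrusion timescale of minutes, incompatible with an
  afterhyperpolarization that spans a ~700 ms inter-spike interval.  The
  calibration targets were the published model's spontaneous rate
  (1.43 Hz), its action-potential metrics, and its firing-rate response to
  the minimal 0.02 nA current step; they were fixed before the chemical
  condition table was evaluated.
* **Other gaps.**  Time-constant widths $k_\tau$ default to each gate's
  slope factor (overridable per channel).  The duplicated L-type
  conductance row is read as the N-type conductance.  The TASK
  extracellular Hill coefficient, absent from the tables, is 1 — the
  shallow titration characteristic of TASK-1.  The hyperpolarization-
  activated current stores a negative slope factor so that it activates
  with hyperpolarization.  Every inactivation slope is stored negative so
  the curves decrease with depolarization.

## Stimulus protocols and measurement conventions

A protocol is an ordered list of segments, each holding applied current
and chemical condition constant; condition changes are instantaneous
steps.  Canned protocols mirror the published experiments: a 0.1 nA
depolarizing pulse (`fig2`), a CO2 step from 5% to 15% (`fig3`), a
hyperpolarizing/depolarizing pulse pair (`fig4`; the depolarizing
magnitude follows the 0.2 nA of the published post-stimulation-recovery
experiment, because the 0.6 nA in the corresponding figure caption drives
this parameterization into depolarization block), constant chemical
conditions (`fig5a`-`fig5d`), a chemical inhibition/excitation sequence
(`fig6`) and the sensitivity-condition sequence (`fig8`).  Pulse durations
are not part of the published protocols; the fixtures use 5 s.

Every run starts from $V = -60$ mV with gates at steady state and is
pre-equilibrated for 2 s of simulated time before the protocol proper.
Integration uses lsoda (stiff, variable-step) through a compiled
right-hand side with `rtol = 1e-6` and `atol = 1e-9` (three orders tighter
on the calcium component, whose scale is $10^{-4}$ mM); halving or
doubling these tolerances moves the steady firing rate by well under 1%,
and repeated runs are bit-identical — the model has no stochastic
component.  Dense output is sampled at 0.05 ms by default (0.1 ms is
sufficient for rate measurements).

Measurement windows follow one convention everywhere: the *steady* rate is
the spike count over the final 2 s of a segment divided by the window
length; the *peak* rate is the reciprocal of the minimum inter-spike
interval in the first second of a stimulus segment (a windowed count
cannot resolve a brief high-frequency transient); their quotient is the
spike-frequency-adaptation ratio.  Spike threshold is the voltage where
$dV/dt$ first exceeds 10 mV/ms on the rising phase (a configurable
criterion — the publication does not define how its thresholds were
measured), amplitude is peak minus threshold, and AHP depth is threshold
minus the inter-spike voltage minimum.  The 2-s count window quantizes
steady rates to 0.5 Hz steps at pacemaker frequencies; `isi_rate`-style
reciprocal-interval estimates are used where finer resolution matters and
both are reported where they differ.

Spiking-onset scans classify a parameterization as "sustained spiking"
when the final 5 s of a 10 s run contain at least five spikes (so ~1 Hz
pacemaking counts), and bisect the scanned parameter (extracellular or
intracellular pH, or applied current) to $10^{-3}$ resolution.

## What the simulations reproduce, and what they do not

With the defaults, the model is a regular ~1.4 Hz pacemaker under
normocapnia (inter-spike-interval rate 1.41 Hz; period stable to <1%), it
doubles its rate for a 0.02 nA depolarizing step, its firing rate rises
without saturating over the depolarizing current range while the
CO2-driven response saturates, hyperpolarizing current beyond ~6 pA
silences it, and extracellular alkalization beyond pH ~7.7 silences it.
A hyperpolarizing/depolarizing pulse pair elicits postinhibitory rebound
(T- and A-current de-inactivation) followed by calcium-mediated
post-stimulation quiescence; purely chemical stimulation elicits neither.
Acidosis raises the firing rate and hypocapnic alkalosis strongly reduces
it (1.41 to ~0.8 Hz).

Known limitations, all traceable to the published parameter set and
documented in the effective-parameters report:

* The full acidotic conditions overshoot the published rates (e.g.
  hypercapnic acidosis ~6.5 Hz against a published 2.85 Hz), because the
  $h = 15$ titrations saturate completely between control and acidotic pH
  and switch the delayed rectifier and A-current fully off, where the
  published rates imply a ~50% partial release.
* Isohydric hypercapnia *raises* the rate here (published: a small
  decrease).  Raising CO2 only inhibits the L-type calcium current, which
  weakens the SK braking pathway; with the printed L-type conductance of
  0.0005 uS its direct depolarizing current cannot outweigh that
  disinhibition in any calcium-to-SK wiring.
* The printed SK conductance (0.003 uS) caps the adaptation current near
  0.1 nA, so the 0.1 nA stimulated state adapts to ~16 Hz rather than
  8 Hz and the adaptation ratio overshoots (6.3 vs 3.75).
* Action-potential morphology is compressed relative to the published
  values (amplitude ~49 vs 70 mV): with the printed sodium kinetics
  ($V_{1/2} = -34.77$, $k = 10.5$) the 10 mV/ms threshold criterion
  cannot fall near $-50$ mV.
* Alkalosis reduces but does not abolish spiking: complete silencing
  would require ~0.02 nA of standing chemical inhibition, while the
  printed TASK/Ca-channel conductances supply at most ~0.005 nA.

These are properties of the printed parameterization, not of the
integration: the structural test tier (gating bounds, reversal-potential
zeros, additivity of the chemosensitivity scaling, leak conservation,
agreement of the compiled right-hand side with an independent term-by-term
summation, tolerance robustness, determinism) passes exactly.

## Problem sizes

The shipped tests and the acceptance script integrate 10-12 s of simulated
time per protocol (a few hundred ODE steps per spike on a 16-dimensional
state), sampled at 0.05-0.25 ms; a full 12 s run takes well under a second
on one core, the whole test suite a few tens of seconds, and the complete
acceptance recomputation a few seconds.  These sizes were chosen to match
the published measurement windows (2 s steady-state windows after 2 s
equilibration), not by computational necessity.
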