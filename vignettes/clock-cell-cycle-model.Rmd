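---
title: "A coupled circadian clock / cell-cycle ODE model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coupled circadian clock / cell-cycle ODE model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circacycle)
```

## The biological question

The mammalian circadian clock and the cell-division cycle are coupled
oscillators.  The *Ink4a/Arf* (*Cdkn2a*) locus encodes two tumour
suppressors, p16^INK4a^ and ARF, that sit at the interface: *Ink4a*
transcription is clock-controlled (through the PER complex), INK4a restrains
CDK4/6-cyclin activity and thereby RB1 phosphorylation and E2F1 release,
while ARF stabilises p53 by degrading MDM2.  Oncogenic RAS perturbs
CLOCK/BMAL-dependent transcription, lengthening the circadian period in
wild-type fibroblasts but shortening it when *Ink4a/Arf* is knocked out.
`circacycle` implements a semi-quantitative ODE model of this coupled
system and the in-silico protocols used to dissect it: RAS dose-response
scans, the Ink4a/Arf double knockout, Bmal1 knockdown, and the modular
decoupling/clamping analysis of the INK4a/RB1/E2F1 ("module 1") and
ARF/MDM2/p53 ("module 2") pathways.

## Model structure

The network has 46 species and 45 rate equations built from Hill-type,
Michaelis-Menten and mass-action kinetics, with 170 kinetic parameters plus
the dimensionless RAS factor `ktt`.

**Core clock (19 species).**  Five gene entities — *Bmal*, *Per*, *Cry*,
*Rev-Erb*, *Ror* — are each resolved into mRNA, cytoplasmic protein and
nuclear protein.  Nuclear BMAL matures into the active CLOCK/BMAL
transactivator (`CB`); PER and CRY form cytoplasmic and nuclear PER/CRY
complexes, and the nuclear complex sequesters `CB` into an inactive complex
(`CBI`) — the classical negative feedback.  `CB` drives the E-box genes
(*Per*, *Cry*, *Rev-Erb*, *Ror*, and the cell-cycle genes *Wee1* and,
repressively, *Myc*); REV-ERB and ROR close the second loop by repressing
and activating *Bmal* transcription at ROREs.

**Cell-cycle arm (27 species).**  Nine regulators — INK4a, ARF, MYC, WEE1,
MDM2, p53, E2F1, RB1 and a lumped CDK/cyclin pool — with mRNA,
cytoplasmic-protein and nuclear-protein resolution for most of them.
Module 1: PER/CRY activates *Ink4a*; nuclear INK4a sequesters the active
CDK/cyclin pool; CDK/cyclin phosphorylates RB1 (blocked by p53, standing in
for the p21/CDK/CycE branch); hypophosphorylated RB1 binds E2F1 into a
repressive complex; free nuclear E2F1 activates the CDK/cyclin mRNA, its own
transcription, and — the predicted coupling link — *Bmal* transcription.
Module 2: MYC activates *Arf*; nuclear ARF accelerates MDM2 degradation;
MDM2 destabilises p53; p53 activates *Mdm2* and represses *Per*
transcription (the merged net effect of the p53/PER2 mutual regulation).
The RB1 pool is conserved (`RB1_N + RBE2F + RB1p_N = rb_tot`), which is why
46 variables need only 45 ODEs; the phosphorylated form is reported as the
conserved remainder.

Rate equations are numbered with the cell-cycle block first, so that the
intervention recipes are executable by index: the Ink4a/Arf knockout zeroes
equations 1, 2, 8, 10, 14 and 19 (the six INK4a/ARF species), module-1
decoupling zeroes equations 7, 12 and 22 (the E2F species), and module-2
decoupling zeroes equation 16 (nuclear p53).  `cc_equation_species()`
exposes the map.

## The RAS factor ktt

RAS overexpression acts on the clock by reducing the transcriptional
activity of CLOCK/BMAL.  We model this as a multiplier on the effective
transactivator concentration: every E-box transcription term (the Hill
activations of *Per*, *Cry*, *Rev-Erb*, *Ror*, *Wee1* and the Hill
repression of *Myc*) sees `ktt * CB` instead of `CB`.  `ktt = 1` is normal
RAS, `ktt < 1` RAS overexpression, `ktt > 1` RAS inhibition (e.g. MEK
inhibition).  Scaling the activity rather than the term keeps a single,
interpretable mechanism for both activating and repressing E-box terms and
naturally de-represses *Myc* under RAS overexpression, which feeds
MYC -> ARF, one of the documented RAS routes into module 2.  At `ktt = 1`
the perturbation machinery is exactly inert (bit-identical vector field).

## Parameter provenance and calibration

The kinetic parameter values shipped with the package are not literature
transcriptions; they were resolved by the package's own calibration
machinery (`cc_calibrate()`, plus the staged fits described below) against
the published dynamical constraints of the coupled system:

* wild-type limit-cycle period 23.65 h (Bmal mRNA; the luciferase-reporter
  proxy in experiments);
* circadian-time peak phases with Bmal anchored at CT 21: Rev-Erb 3.80,
  Ror 10.97, Per 11.30, Cry 12.52, PER/CRY complex pool 16.32;
* constitutive (cycle-mean) levels E2F_N = 5.7 and p53_N = 0.6, the values
  used by the clamping scenarios;
* knockout and modular-analysis periods: Ink4a/Arf knockout 23.68 h,
  module-1-decoupled 22.86 h, E2F_N-clamped 23.63 h;
* qualitative RAS phenotypes: period lengthening in wild type for
  `ktt < 1`, shortening with a non-monotonic minimum at `ktt = 0.7` in the
  knockout, lengthening for `ktt > 1` in the knockout.  These were used as
  search objectives; see the limitations section for which of them this
  parameterisation realises.

Calibration exploits one exact structural property: multiplying every
parameter with units of 1/h by a common factor `s` rescales time by `1/s`
(the system is autonomous), so the period scales exactly as `1/s` while all
circadian-time phase relations are untouched.  The phase relations are
therefore fitted first (derivative-free Nelder-Mead on log-parameters of
the clock limb), coupling gains are fitted second against the knockout and
modular-analysis period ratios (which are also invariant under rescaling),
and the final uniform rescaling pins the absolute period.  `cc_calibrate()`
packages the last two ingredients — the weighted least-squares objective
(period weight 10, phase weight 1) and the closed-form rescaling — for
re-calibration after user edits.

One structural choice deserves emphasis: E2F1 keeps turning over while
bound in the repressive RB1:E2F complex (at the nuclear E2F turnover rate,
with RB1 recycled).  Without that turnover the binding/release/
phosphorylation cycle conserves E2F exactly, and the mean free E2F level is
then provably independent of the whole INK4a/CDK/RB limb at steady state —
the knockout would be dynamically inert on the very route the modular
analysis dissects.

The E2F oscillation is deliberately low-amplitude around its mean of 5.7:
the modular analysis requires that clamping E2F_N at its mean changes the
period by only ~0.02 h while removing E2F entirely shortens it by ~0.8 h,
i.e. most of the E2F -> Bmal effect is carried by the constitutive level,
not the oscillation.  p53_N likewise oscillates weakly around 0.6 in the
wild type and loses its oscillation in the knockout.

## Perturbation semantics

* **Knockout** (`knockout_ink4a_arf()`): the six INK4a/ARF species are set
  to zero and their derivatives forced to zero for all time.
* **Decoupling** (`decouple_module1()`, `decouple_module2()`): the module's
  nuclear transcription factor (all three E2F species; nuclear p53) is
  forced to zero.  Decoupling equals clamping at level 0.
* **Clamping** (`clamp_species()`): the species' state is overwritten at
  onset and its derivative zeroed — no stiff forcing terms, so the
  integrator sees a smooth vector field within each segment.  Only the
  clamped species' own equation is frozen; its upstream mRNA/protein
  equations keep running (they feed nothing else), which is dynamically
  equivalent to freezing the whole limb.
* **Knockdown** (`knockdown_bmal1()`): the entire Bmal transcription rate
  (basal + RORE + E2F terms) is scaled by the residual fraction (default
  0.3, the experimentally observed shRNA residual).  The realised Bmal mRNA
  reduction is weaker than the input scaling (ratio ~0.6 at fraction 0.3)
  because the weakened clock relieves REV-ERB repression of *Bmal*; strong
  knockdown abolishes rhythmicity (period reported as ND).  The source
  study did not simulate the knockdown; this operation is exploratory
  plumbing.
* **RAS** (`apply_ras()`): the ktt factor, switched on at its onset.

Perturbations are time-stamped.  `cc_run_scenario()` burns the unperturbed
genotype in for 240 h (about ten periods) so the system sits on its limit
cycle, then switches perturbations on at their onsets by stopping and
restarting the integrator at the onset time — the discontinuity never sits
inside an adaptive step.  Because the post-perturbation transient depends
on the oscillation phase at onset, the onset is always an explicit, logged
setting; the dose-response protocols default to onset 24 h after burn-in,
the value used when calibrating the scan behaviour.

## Settling behaviour of the modular scenarios

With its E2F input removed (module 1 decoupled) the calibrated clock is
only weakly stable: it settles onto a slowly modulated orbit rather than a
clean limit cycle, and the four-peak period statistic then depends mildly
on where in the modulation the analysis window falls.  The modular-analysis
protocols therefore use an extended 400 h burn-in (the spread of successive
peak intervals drops from ~0.3 h after 240 h to ~0.05 h after 400 h);
the residual modulation still moves the decoupled-period statistic by a few
hundredths of an hour between protocols, which is the dominant uncertainty
on the decoupled and clamped period values.

## Numerics

Integration uses the Dormand-Prince 4(5) adaptive Runge-Kutta pairing
(deSolve's `ode45`) with relative and absolute tolerances of 1e-9 and a
fixed output grid of 0.01 h, the study's settings; the right-hand side is
compiled C.  States are accepted down to -1e-6 (integrator slack) and
clipped to zero when passed between segments.  Default initial conditions
set every species to 1.0 and rely on burn-in for convergence; the RB1 pool
is redistributed at segment start to satisfy its conservation law.  Peak
times are refined by quadratic interpolation around the discrete argmax
(plateaus resolve to their midpoint), so a 0.02 h analysis grid already
determines periods well below the 0.01 h reporting precision; the scans
use 0.02-0.05 h grids to keep memory and runtime proportionate.

## Rhythm metrics

The period statistic is the study's transient estimator: the mean of the
three successive peak-to-peak intervals among the first four peaks after
the perturbation onset.  On the limit cycle the intervals are constant and
the statistic equals the limit-cycle period, so the same estimator serves
both uses.  A condition is *rhythmic* when at least four peaks with
relative prominence >= 5 % of the series range are found; otherwise the
period is reported as not defined (ND, `NA`) — the source data report ND
for arrhythmic conditions without stating a criterion, so the 5 %/4-peak
rule is this package's documented choice.  Circadian-time phases map peak
times through the affine transformation that sends the Bmal mRNA peak to
CT 21 and one period to 24 CT-hours; phases are reported to two decimals.
Sampled time courses are fitted with a linear cosinor (`fit_harmonic()`,
optionally profiling a free period) or a degree-4 polynomial
(`fit_polynomial()`), the two descriptive fits used for qPCR-style sparse
data.

## Synthetic fixtures

`cc_trace_spec()`/`make_trace()`/`make_timecourse()` generate seeded damped
noisy cosinor traces — dense bioluminescence-style recordings and sparse
9-point/3-h qPCR-style tables.  They emulate waveform, damping and additive
Gaussian noise, but not photon-count statistics, baseline drift or
inter-replicate variance of real recordings; tests passing on them
demonstrate correctness of the estimators, not robustness to every
real-data pathology.

## Problem sizes used by tests and the acceptance script

Scenario simulations use 240 h burn-in plus 120-150 h analysis windows on
0.02-0.1 h grids; dose-response scans use 7-point ktt grids; the
sensitivity analysis re-settles each of the 340 perturbed systems for
160 h before measuring.  These sizes put every reported quantity on the
limit cycle (or the documented transient protocol) while keeping a full
test run in minutes on a single CPU.

## Known limitations and unreproduced phenotypes

The genotype-dependent *direction* of the RAS effect is only partly
realised by this parameterisation.  The knockout behaves as published for
RAS overexpression at `ktt = 0.7` (shorter transient period than at
`ktt = 1`), and across wide parameter ranges the system reproduces the
bare-clock behaviour of the decoupled scenario (shortening under RAS).
However, the wild-type lengthening under RAS overexpression and the
knockout's non-monotonic dose response with a minimum at `ktt = 0.7` are
not reproduced: in every parameter regime found, the period response to
reduced CLOCK/BMAL activity flips from shortening to lengthening as the
E2F-mediated *Bmal* drive increases, and free nuclear E2F is structurally
at least as high in the knockout as in the wild type for this RB1/E2F
motif — so the genotype with the higher drive always sits deeper in the
lengthening regime, assigning the signs the wrong way round.  The package
reports these quantities exactly as computed; the corresponding acceptance
checks are expected to fail and say so.

* The kinetic parameterisation is a calibrated realisation of the published
  constraints, not a literature transcription; quantities not pinned by
  those constraints (e.g. absolute concentrations of cell-cycle species)
  are only order-of-magnitude meaningful.
* The clock is free-running: no synchronisation cues (dexamethasone pulses,
  feeding cycles) are modelled, matching the constant-condition recordings.
* Single-cell determinism: no cell-population coupling, damping through
  desynchronisation, or stochastic gene expression.
* The Bmal1 knockdown is transcription-rate scaling, an exploratory
  operation without a published in-silico counterpart.
* SBML import/export and bifurcation analysis are out of scope.
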