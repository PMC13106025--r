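---
title: "Methods: simulating dual-chamber pacemaker timing with prolonged retrograde conduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating dual-chamber pacemaker timing with prolonged retrograde conduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pacesim)
```

## The problem

A dual-chamber pacemaker in DDD mode tracks atrial senses: an atrial event
starts the sensed AV delay (SAV) and triggers a ventricular pace (VP). In a
patient with intact retrograde (ventriculoatrial, VA) conduction, that VP can
itself conduct back to the atrium; if the retrograde P wave falls outside the
post-ventricular atrial refractory period (PVARP), the device tracks it and
paces the ventricle again — an endless-loop, pacemaker-mediated tachycardia
(PMT). With a retrograde conduction time (VAC) of 450–570 ms, well beyond
typical values, the loop runs *below* the maximum tracking rate (MTR) and can
evade the manufacturers' anti-PMT detectors, each of which encodes different
assumptions about how fast and how regular a PMT must be.

The complementary hazard arises in non-tracking (DDI) mode or behind a long
PVARP: the retrograde P is sensed but only as a refractory event (AR), the
scheduled atrial pace lands on refractory atrial tissue and fails to capture,
the ventricular pace conducts retrogradely again, and the cycle repeats —
repetitive nonreentrant ventriculoatrial synchrony (RNRVAS).

`pacesim` reproduces both phenomena with a deterministic discrete-event
engine and five vendor algorithm models, so that every published categorical
outcome and interval boundary can be recomputed from first principles.

## The model

### Heart substrate

The simulated patient has sinus arrest and complete AV block: the heart
never generates spontaneous events, so every atrial activation traces to an
atrial pace (AP) or a retrograde wavefront, and every ventricular activation
to a VP. Two parameters matter:

* `vac_time_ms` — fixed 1:1 retrograde conduction time. There is no
  decremental or Wenckebach retrograde behaviour: the bench protocols this
  package reproduces used a programmable stimulator with constant conduction.
* `atrial_myo_refractory_ms` (default 250 ms) — atrial tissue refractory
  period. A retrograde wavefront *arriving* within it blocks; a pacing
  stimulus *delivered* within it fails to capture. The bench reports never
  state this value. 250 ms is a physiologically ordinary choice that makes
  the two published coupling intervals behave as the tracings show: the
  189 ms escape-pace coupling of the Abbott DDI scenario fails to capture,
  while every vendor-deferred pace (>= 300 ms coupling) captures. It was
  chosen once on that reasoning and is configurable.

The scenarios quote *device-measured* VAC values (468 and 570 ms for nominal
450/550 ms settings; the discrepancy is attributed to sensing-filter
characteristics, which we do not model). All interval arithmetic in the
published results uses the measured values, so scenario files carry 468/570
directly and `sense_offset_ms` defaults to 0. Whether the offset is
rate-dependent is unknown; the parameter exists for sensitivity analyses
only.

### Timing engine

Time is integer milliseconds; rates convert once via `round(60000/ppm)` and
every comparison is exact integer arithmetic, which removes float-tie
ambiguity and makes logs reproducible bit for bit. Three timers drive the
event loop — the atrial escape, the pending VP, and the in-flight retrograde
wavefront. Coincident timestamps are processed heart-activation first, then
device scheduling; marker ties order A < V < DEVICE.

Key scheduling rules:

* **Atrial escape.** V-V timing bases the escape at `VP + (LRL interval −
  PAV)`; A-A timing at `last atrial paced/sensed event + LRL interval`
  (refractory senses do not count). Medtronic models default to A-A, the
  others to V-V; the published tracings pin down only Medtronic (alternating
  PAV with AP–AP at the lower rate) and the V-V stability of Boston and
  BIOTRONIK, so the Abbott/MicroPort assignment is an assumption with no
  effect on any reproduced result.
* **Sense classification.** Relative to the last VP: blanked below PVAB
  (default 150 ms — unstated in the source material and irrelevant at these
  VAC values, but required for a complete engine), refractory (AR) below the
  effective PVARP, otherwise tracked (DDD) or inhibiting (DDI).
* **Upper-rate behaviour.** A tracked VP is postponed to `last VP + MTR
  interval` when the SAV would violate it; the pending SAV is not
  re-triggered. Classical 2:1 block would emerge only if the postponed sense
  fell into PVARP, which these rates never produce.
* **Induction.** No premature beat is injected. Because the atrium is
  silent, the device's own AP→PAV→VP sequence runs at the lower rate, and
  the atrium has always recovered by `VP + VAC` (PAV 200 + VAC >= 650 ms >>
  250 ms), so PMT self-initiates the moment a retrograde sense escapes the
  PVARP — matching the onset visible in the stored episode tracings.

The steady loop obeys a closed form used throughout the tests as an
independent oracle: the PMT cycle length is

$$L = \max(\mathrm{VAC} + \mathrm{SAV},\ \mathrm{MTR\ interval}),$$

i.e. the loop locks to the MTR exactly when VAC + SAV is shorter than the
upper-rate interval, and otherwise runs below the MTR at VAC + SAV. With
VAC 570 and SAV 140 this gives the published 710 ms (84.5 bpm). (The source
text's "approximately 605 ms" at VAC 468 is 608 ms by this arithmetic; the
3 ms is unexplained device rounding and we treat the quoted value as
approximate.)

### Vendor algorithm models

Each model is a small state machine over tracked-sense events
(idle → counting → verifying → confirm → intervention):

| Model | Qualifying beat | Count | Verification | Termination |
|---|---|---|---|---|
| Abbott *PMT Response* | A–A interval faster than the programmable detection rate (floor 90 bpm, 5-bpm grid) and stable VP–AS | 8 | SAV −50 ms for one beat; VP–AS unchanged | VP suppressed; AP 330 ms after the AS |
| BIOTRONIK *PMT Protection* | VP–AS < VA criterion (max 500 ms) with small deviation | 8 | same | one-cycle PVARP extension to criterion + 50 ms |
| Boston *PMT Termination* | VP delivered at the MTR boundary after an AS; VP–AS within 32 ms of cycle 2's value | 16 | none | one-cycle PVARP extension to 500 ms |
| Medtronic *PMT Intervention* | VP–AS strictly < 400 ms | 8 | none modelled | one-cycle PVARP extension to 400 ms |
| MicroPort *Anti-PMT* | VP–AS <= 470 ms, stable | 8 | same as Abbott | 500 ms atrial refractory period after the next VP |

A `PMT_TERMINATE` marker is emitted only when the intervention actually
breaks the loop: for refractory-extension vendors, when the next retrograde
sense falls inside the extension (so a 570 ms VAC defeats a 500 ms
extension and the loop continues); for Abbott, at the termination AP, which
re-times the atrium unconditionally. Because the substrate keeps conducting
retrogradely, a terminated loop re-induces and the device terminates it
again — detection and termination flags report "at least once", which is
what the bench protocols scored.

Post-AR atrial pacing protection is modelled as a deferral window from the
refractory sense: BIOTRONIK 350 ms, Boston the atrial flutter response
window (`round(60000/170)` = 353 ms), Medtronic the 300 ms non-competitive
atrial pacing (NCAP) window; Abbott has none, and MicroPort's WARAD is
inactive in DDI where the question arises. When a deferral pushes the AP
past its escape, the paced AV delay is shortened to hold the VP at its
undeferred target, floored at the vendor's minimum PAV (75 ms BIOTRONIK,
30 ms Boston/Medtronic). The BIOTRONIK floor produces the documented
below-lower-rate prolongation exactly when
`VAC + 350 + 75 > LRL interval`. None of the three window widths is
published; they were fixed once so that the qualitative tracing features
(constant V-V with uniformly shortened PAV; alternating PAV under A-A
timing; capture of every deferred pace) reproduce, and they are all
programmable.

The stability tolerance for "stable"/"small deviation" (Abbott, BIOTRONIK,
MicroPort) is ±16 ms, mirroring the only printed stability window (Boston's
32 ms total); the SAV modulation magnitude is −50 ms. Both are assumptions,
both configurable, and neither matters under constant retrograde conduction
— the verification beat always confirms, as it did on the bench.

### MicroPort in DDI

MicroPort's WARAD substitutes for a PVARP and is inactive in DDI, so every
atrial sense there is annotated "Ar" yet functions as an ordinary inhibiting
sense: atrial pacing is withheld and the rhythm becomes VVI-like at the
lower rate. The engine implements this as a dedicated DDI rule; outcome
classification counts only genuinely refractory senses as AR detection,
which is why the MicroPort AR cells read "No" and its Study-3 cells "N/A".

## Outcome classification

* **Sustained PMT** — at least 8 consecutive tracked V-V cycles varying by
  <= 2 ms (8 matches the smallest vendor detection count; the tolerance
  guards hypothetical future noise features, the integer engine being
  exact).
* **RNRVAS episode** — >= 3 consecutive `AP_NONCAPTURE → VP → AR` cycles.
* **Table cells** — the Study-1 detection/termination cells mean
  "achievable by adjusting only the vendor's dedicated anti-PMT parameter"
  (Abbott's detection rate, BIOTRONIK's VA criterion). Boston's only lever
  is the MTR, a core bradycardia setting, so its cells reflect the protocol
  MTR of 130 ppm and the workable MTR bound is reported under "Required
  changes". This resolves the apparent conflict between the summary
  statement (four devices detect at VAC 450) and the matrix (Boston "No"
  with an MTR change listed).

## What the simulation does and does not establish

The generator *is* the stated bench world: constant 1:1 retrograde
conduction, silent atrium, ideal sensing. A green acceptance suite
establishes that the timing arithmetic, the algorithm state machines and the
outcome classification jointly reproduce the published matrix and
boundaries. It does not validate behaviour under autonomic variation,
decremental VA conduction, fusion/pseudofusion, sensing noise, premature
beats, mode switching, or rate-response sensors — all outside scope, as are
real electrogram processing (reduced to the measured-VAC convention) and any
firmware behaviour beyond what the bench reports describe. The vendor
models are behavioural reconstructions, not firmware.

## Numerical and degenerate-input choices

* Rate→interval rounding uses R's `round` (half-to-even); every protocol
  value lands off the .5 boundary so the choice is inert, and it is applied
  identically everywhere including the closed-form oracle.
* Parameter objects reject degenerate values at construction (LRL > MTR,
  SAV > PAV, PVAB > PVARP, non-positive intervals), so the engine itself
  never branches on invalid state.
* A retrograde wavefront is re-checked against tissue refractoriness at
  arrival, so an interposed captured AP blocks it; blocked wavefronts
  disappear silently (no marker exists for an event the device cannot see).
* Simulations require >= 10 lower-rate cycles; protocol runs use 60 s.
  Outcomes are duration-invariant beyond that (tested), and the large
  property grids run 20 s per point for suite speed.
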