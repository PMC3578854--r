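---
title: "Polymerase traffic: the elongation model and its implementation"
author: "RNAPtraffic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polymerase traffic: the elongation model and its implementation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

RNAPtraffic simulates transcription elongation as a sequence-dependent
stochastic process, for a single RNA polymerase (RNAP) or for many
polymerases transcribing the same DNA template simultaneously. This
vignette is the package's account of the model: the physics it encodes,
the parameters that matter, the conventions adopted where the published
record leaves choices open, and what the synthetic-data generator does
and does not emulate.

## The single-molecule elongation model

The transcription elongation complex (TEC) is described by the
transcript length $n$, the active-site template position $m$, and a
translocation register. After adding nucleotide $n$ the complex is
*pre-translocated* (the active site still holds the 3' end, the RNA-DNA
hybrid is 9 bp); a one-nucleotide forward step yields the
*post-translocated* state (8-bp hybrid, active site free for the next
NTP). Only the post state binds the next substrate, so elongation is a
Brownian ratchet: the pre/post equilibrium gates the catalytic step.

### The free-energy landscape

The standard Gibbs free energy of a TEC configuration is the sum of its
sequence-dependent parts:

$$\Delta G^\circ_{\mathrm{TEC}} = \Delta G_{\mathrm{bubble}} +
\Delta G_{\mathrm{hybrid}} + \Delta G_{\mathrm{RNAP}},$$

where $\Delta G_{\mathrm{bubble}}$ is the cost of keeping the 12-bp
transcription bubble melted (minus the DNA/DNA duplex formation energy
over the bubble window), $\Delta G_{\mathrm{hybrid}}$ is the formation
energy of the RNA/DNA hybrid (8 or 9 bp depending on register), and the
RNAP-nucleic-acid interaction term is sequence-independent and set to
zero. Both sequence-dependent terms use the nearest-neighbor model:
the unified DNA/DNA parameters and the RNA/DNA hybrid parameters are
shipped as TSV tables (`inst/extdata/`) with $\Delta H$ and $\Delta S$
per dinucleotide step, so that $\Delta G(T) = \Delta H - T\Delta S$ can
be recomputed at the simulation temperature (24&nbsp;°C by default)
rather than only at the tables' 37&nbsp;°C reference.

Two conventions required a choice:

* **Bubble placement.** How many of the 12 bubble base pairs lie
  downstream of the active site is not fixed by the published record.
  We place the hybrid in the upstream part of the bubble and the
  remaining bubble base pairs downstream (`TECGeometry`). Only energy
  *differences* between adjacent states enter the kinetics, and those
  depend on the window contents at the edges, not on the labeling, so
  this convention is innocuous away from template ends.
* **Template ends.** Bubble and hybrid windows are clamped at template
  boundaries, and a run terminates when the leading edge of the
  polymerase footprint reaches the last base. End behavior is not
  specified by the sources; clamping avoids silently wrong-length
  windows.

### Rates

With the landscape in hand, three kinds of reactions drive a molecule:

* **Nucleotide incorporation.** The pre/post occupancy ratio is the
  Boltzmann factor
  $B = \exp[(\Delta G^\circ_{\mathrm{post}} -
  \Delta G^\circ_{\mathrm{pre}} - F\delta)/k_BT]$,
  with $\delta = 0.34$ nm per step and $F$ the force assisting
  translocation ($F\delta$ converted at 1 kcal/mol = 6.9477 pN nm).
  Incorporation follows effective Michaelis-Menten kinetics,
  $$k = \frac{V_{\max}[\mathrm{NTP}]}{[\mathrm{NTP}] + K_m(1+B)},$$
  with the experimentally determined per-NTP parameters
  ($V_{\max}$ = 50, 18, 36, 33 s$^{-1}$ and $K_m$ = 38, 24, 62, 7 µM
  for ATP, UTP, GTP, CTP). A site whose pre state is strongly
  stabilized has a large $B$, an inflated apparent $K_m$, and a long
  dwell: that is a sequence-encoded pause site. Note the published
  rendering of the translocation factor is ambiguous about the sign of
  the energy difference; we use the Boltzmann form above, which makes
  pre-stabilized sites slow — the behavior pause sites must have.
* **Backtracking and recovery.** The polymerase can slide backward,
  disengaging the RNA 3' end (offset $b \ge 1$), and return. Hops are
  thermally activated: $k = k_0\exp(-\Delta G^\ddagger/k_BT)$ with
  $\Delta G^\ddagger = \max(0, \Delta G_{\mathrm{target}} -
  \Delta G_{\mathrm{current}}) + \Delta G_0 \mp F\delta/2$, which
  satisfies detailed balance against the landscape at zero force (a
  property-tested invariant). Backtracked windows are evaluated in the
  post-register geometry at the displaced active site.
* **The backtracked-state penalty.** Hops crossing between the
  elongating and backtracked pathways carry an additional equilibrium
  penalty `dGbt` on the backtracked side, reflecting the disengagement
  of the 3' end from the active site. This single parameter shapes the
  pause phenomenology: entry into backtracking is uphill by `dGbt`
  (so excursions start almost exclusively where incorporation is slow
  and the local landscape descends backward), while the first recovery
  step is downhill by `dGbt` (so shallow excursions resolve in
  seconds). Without it, a nearest-neighbor landscape contains frequent
  multi-kcal backward descents and most trajectories fall into
  effectively irreversible arrest — escape times grow as
  $e^{\Delta G_{\mathrm{well}}/k_BT}$ — which contradicts the
  minutes-scale completion seen in transcription experiments.

Defaults: $k_0 = 10$ s$^{-1}$, $\Delta G_0 = 1.2$ kcal/mol,
`dGbt` $= 4$ kcal/mol. These are order-of-magnitude choices fixed once:
together they give a flat-landscape hop time of ~0.8 s, sub-second
recovery from single-step excursions, second-scale pauses at planted
sites, and entry rates of order 0.01 s$^{-1}$ on quiet sequence. The
attempt frequency and barrier offsets of backtracking are not published
for this model family, only the detailed-balance ratio is pinned.

### Forces

Two force parameters are distinguished. `force` is an external load
applied to every molecule (optical-tweezers style; default 0).
`collisionForce` (default 25 pN, the average stalling force of RNAP) is
the force a molecule exerts on its neighbor *while the two are in
contact*. This split matches the observation that the force sweep in
multi-round simulations acts through collisions while an isolated
polymerase is unaffected.

## The multi-polymerase event loop

Each molecule carries its own reaction clock, drawn by the Gillespie
first-reaction method (one exponential per channel, earliest wins), and
moves uniformly between reactions, so its position is a
piecewise-linear function of time. The loop:

1. draw (or keep) each molecule's tentative next reaction;
2. form the linear position segments;
3. find the earliest of: a molecular reaction, an initiation attempt,
   or a pairwise collision (contact of footprints, solved in closed
   form from the linear segments);
4. advance to that time, execute it, and recompute only what changed.

Initiation attempts occur every 0.5 s (deterministic interval) and
succeed only when the promoter-proximal footprint is clear; each
molecule is removed at termination. Exponential waiting times are
memoryless, so pending reactions of uninvolved molecules stay valid
across collisions.

**Random-number discipline.** Every molecule owns an RNG stream derived
from the replicate seed, so collision resolutions never perturb other
molecules' draws and the one-molecule limit of the traffic engine is
*bit-identical* to the single-round simulator. Replicate seeds derive
from the master seed the same way.

### Collision rules

Collisions between a trailing (T) and leading (L) molecule fall into
six categories by motion: normal elongation (N), backtracking moving
backward (Bb) or forward (Bf).

* **T in normal elongation** (TN-LN, TN-LBf, TN-LBb): T presses on L,
  transmitting `collisionForce` as an assisting load on L and receiving
  the reaction as an opposing load; while in contact T cannot advance
  into L and L cannot move backward. For a backtracked leader this
  means its only available move is the pushed forward step — the
  trailing molecule acts as a roadblock that converts a backtracking
  pause into forward recovery. Contact ends as soon as either molecule
  opens a gap; forces are contact-scoped.
* **Both backtracking** (TBf-LBb, TBf-LBf, TBb-LBb): a perfectly
  elastic encounter, implemented as the exchange of the two molecules'
  intended step directions and remaining flight times (the 1-D
  equal-mass elastic exchange). If an exchanged intent is infeasible —
  it would cross the template start, violate a standing contact with a
  third molecule, or fail to separate the pair — the contact degrades
  to the roadblock resolution above, which preserves exclusion by
  construction.
* A backtracked trailer reaching a leader in normal elongation is not
  covered by the six-way enumeration; it is resolved as a roadblock,
  the conservative extension.

Hard-core exclusion (leading edge to trailing edge, footprint 17 nt on
each side of the active site, i.e. a 34-nt center-to-center distance)
is enforced throughout and asserted on every emitted trajectory in the
test suite.

**Tie-breaking and guards.** A collision coinciding with a molecular
event within $10^{-12}$ s resolves first (this preserves exclusion). A
livelock guard bounds collision resolutions between molecular events.
Fully blocked molecules (all channels suppressed by contacts) simply
wait; they are re-drawn when released. Velocity changes that occur
without a lattice step (contact formation, release, elastic exchange)
are recorded as breakpoints so the emitted piecewise-linear record is
faithful to the simulated motion.

## The analysis layer

* **Dwell times.** The dwell at position $i$ runs from the
  incorporation that brings the 3' end to $i$ until the incorporation
  advancing past it; backtracking excursions starting at $i$ are
  charged to $i$ (matching gel-band persistence semantics). The
  per-position statistic is the third quartile (TQ) across the
  ensemble; all quantiles in the package use the type-7 (linear
  interpolation) definition, in one shared helper, because the third
  quartile appears in four different analyses and must agree.
* **Pause calling.** Position $i$ is a pause site when
  $\tau_{TQ}(i) > \tau_{\min}/\alpha$ with $\tau_{\min}$ the smallest
  TQ dwell on the template. Larger $\alpha$ means a larger implied
  absolute threshold. The comparison lives in one function
  (`callPauses`) so the convention is easy to audit. $\alpha$ can be
  tuned against experimental pause lists by minimizing
  $(FP+FN)/TP$ after 3-bp clustering (`tuneAlpha`; ties resolve to the
  smallest $\alpha$).
* **Clustering and quality.** Pause positions within 3 bp chain into
  clusters; a predicted cluster detects an experimental cluster if any
  members are within 3 bp (the symmetric extension of the published
  3-bp clustering rule). $Q = TP/(TP+FP+FN)$ by default; the
  incorrect-to-correct ratio form is available because the source's
  algebra is ambiguous. Uncertainty from the finite number of
  sequences is estimated by bootstrap over the sequence set.
* **Efficiency.** For a run allowing $N$ molecules,
  $T_{avg}(N) = \frac1N\sum_{j=1}^{N}\mathrm{median}_j$ over binding
  orders, and the relative transcription efficiency is
  $\varepsilon(N) = T_{avg}(1)/T_{avg}(N)$, 1 at $N=1$ by construction;
  values above 1 quantify cooperative acceleration.
* **Gels.** `simulatedGel` counts transcripts per length at sampling
  times, the in-silico analogue of a transcription gel lane; lane mass
  equals the number of initiated transcripts (a conservation law in
  the tests).

## The synthetic-template generator

Real templates from the experimental literature are not bundled, so
`makeTemplate` builds study templates with *known* structure:

* A random background is first driven into a **quiet band**: the
  pre/post stabilization is capped at 2 kcal/mol and the backward
  landscape descent over 1-6 steps at 2.5 kcal/mol at every interior
  position outside motif windows. A raw nearest-neighbor landscape
  contains accidental arrest-depth wells; quieting makes planted
  motifs the only strong kinetic features, which is what a controlled
  fixture must guarantee.
* A **strong_pause** motif is planted by banded local search driving
  the pre-vs-post stabilization at the site into [3.3, 4.3] kcal/mol —
  strong enough for second-scale dwells, bounded so the site pauses
  rather than arrests. The search mutates single bases and *stops at
  the band*: motif strength is controlled, not maximized.
* A **backtrack_trap** combines a moderate pause (entry must compete
  with incorporation), a first backtracked state ~2.2-3.2 kcal/mol
  below the elongating state (entry is then nearly barrier-free given
  `dGbt`), and a gently descending well behind it, so excursions are
  frequent and reach several nucleotides but remain climbable.

All searches run against the package's real energetics, so fixtures
stay valid if the parameter tables are swapped, and are deterministic
given the seed.

**What the generator does not emulate.** Quieted backgrounds are
*tamer* than real sequences: real templates carry many near-threshold
pause sites, so tuned pause thresholds on synthetic templates come out
much lower than values fitted to experimental data, and the share of
elongation time in the slowest sites is higher. Passing tests on these
fixtures show that the machinery (exclusion, pushing, roadblocking,
statistics) behaves correctly; they do not certify quantitative
agreement with any particular biological template. RNA secondary
structure, factor-assisted rescue and promoter kinetics are outside
the model.

## Problem sizes

The test suite and the acceptance script scale the published study
design (thousands of replicates, up to 10 polymerases) to desk scale:
150-250 replicates per condition, templates of 160-500 nt, polymerase
counts swept over 1-10. These sizes give stable medians and quartiles
for every statistic asserted while keeping a full run in minutes.

## Known limitations

* Backtracking kinetics are parameterized phenomenologically
  (`k0`, `dG0`, `dGbt`); only the detailed-balance structure is pinned
  by thermodynamics.
* The elastic collision rule is an interpretation (exchange of step
  intentions); the original description does not fix the semantics.
* Deep arrest at pathological sequences is possible by construction
  (escape is exponential in well depth); the time cap flags such
  trajectories rather than hiding them.
* The published nearest-neighbor tables round $\Delta H$/$\Delta S$ to
  one decimal, so recomputed $\Delta G^\circ_{37}$ values can deviate
  from the printed ones by up to ~0.015 kcal/mol; the package ships
  the published values untouched and tests document the bound.
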