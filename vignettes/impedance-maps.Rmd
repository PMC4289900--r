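---
title: "Modeling impedance and resonance maps under dendritic atrophy"
author: "resonmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling impedance and resonance maps under dendritic atrophy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(resonmap)
```

## The scientific question

Hippocampal CA1 pyramidal neurons carry a steep somatodendritic gradient of
HCN (h) channels. At hyperpolarized potentials this gradient produces
coexisting functional maps along the apical trunk: input resistance falls
with distance from the soma, while the resonance frequency of the local
impedance rises through the theta band, accompanied by gradients in peak
impedance amplitude, resonance strength and inductive phase, for both local
and soma-recorded (transfer) measurements. A channel gradient is known to be
*necessary* for these maps. This package implements the computational
machinery to ask whether it is *sufficient* — specifically, whether the same
gradient still expresses the maps on a dendritic tree that has undergone
progressive atrophy.

The design is causal rather than correlative: a single base morphology is
pruned step by step, the identical biophysics are imposed on every pruned
member, and all nine measurements are taken at the *same* locations in every
member. Because each member is a strict subtree of its predecessors, any
change in a map is attributable to the structural change alone.

## Model and assumptions

**Cable model.** Each morphology is discretized by the d-lambda rule: every
unbranched section is split into the smallest odd number of equal segments
shorter than 0.1 lambda_100, where lambda_100 = 1e5 sqrt(d / (4 pi 100 Ra
Cm)) um is the 100 Hz space constant from the section's length-weighted mean
diameter and local axial resistivity. Odd counts guarantee an on-center
segment midpoint per section, which is where all spatial profiles are
evaluated and where measurement sites live. Membrane area is the lateral
frustum area of the segment's share of the reconstruction; the soma is a
single compartment (sphere for one-point somata, stacked frusta otherwise).

**Passive gradients.** Specific membrane resistivity and axial resistivity
fall sigmoidally with *radial* (straight-line) distance x from the soma
centroid:

    Rm(x) = 55 + (20 - 55) / (1 + exp((250 - x)/50))   kOhm cm2
    Ra(x) = 70 + (30 - 70) / (1 + exp((250 - x)/50))   Ohm cm

with Cm = 1 uF/cm2. Basal dendrites and the soma take the x = 0 values.
These choices make the passive somatic input resistance roughly uniform
along the trunk.

**HCN gradient.** The maximal h conductance rises 25-fold with a sigmoid
centered 350 um out:

    gh(x) = 50 (1 + 25 / (1 + exp(-(x - 350)/15)))     uS/cm2

again with basal/somatic compartments at the x = 0 value.

**HCN kinetics.** The published source models report voltage clamp data, not
closed-form equations, so the gate here is a declared parameterization: a
single first-order gate with m_inf(V) = 1/(1 + exp((V + 82)/9)) and a
bell-shaped time constant tau(V) = 2 tau_peak / (exp(u) + exp(-u)),
u = (V + 75)/20, referenced at 27 C and scaled by Q10 = 4.5 to the 34 C
simulation temperature; E_h = -30 mV. The peak time constant was calibrated
once against the map-level behavior the gradient is known to produce: with
tau_peak = 40 ms the 34 C time constant (~14 ms at rest) left the somatic
resonance so shallow (Q ~ 1.01) that the peak frequency was numerically
ill-defined; tau_peak = 60 ms (~21 ms at 34 C, inside the experimentally
reported range for CA1 dendritic h currents at physiological temperature)
yields well-formed theta-band resonance (Q ~ 1.1-1.4) and a monotone f_R
map. All kinetic parameters are exposed in `hcnKinetics()`.

**Holding at -65 mV.** All measurements are taken at -65 mV. With the
gradient's distal densities, a model initialized at -65 mV would drift
depolarized by ~10 mV in its distal compartments, deactivating the very
conductance under study. The package therefore treats -65 mV the way an
experimenter's holding current does: the leak battery of each segment is
offset so that the uniform -65 mV state is an exact DC steady state
(`hold_mV` argument; `NULL` restores the nominal leak reversal and lets the
model find its own rest). Inserted conductance clusters are *not*
re-balanced — their depolarizing influence is part of the effect being
measured, and the standard 200 ms settle window precedes every measurement.

**Integration.** The branched cable system is advanced by the trapezoid
(Crank-Nicolson) implicit rule with an exact Hines-ordered tree solve per
step and the h gate updated by the locally exact exponential rule; backward
Euler is available as a fallback (`method = "euler"`). The full-resolution
protocol uses 25 us steps; the default reduced protocol uses 100 us. The
scheme's accuracy is asserted by invariants rather than by fiat: halving dt
from 0.05 to 0.025 ms changes reference traces by < 0.2 % max-norm, and
halving d-lambda changes steady-state deflections by < 0.5 %.

## Stimulation and measurement

**V-I protocol.** R_in is the least-squares slope of steady-state voltage
deflections against -50..50 pA current pulses in 10 pA steps (300 ms
pulses; the deflection is the mean over the final 10 ms minus the
pre-pulse baseline). A reduced -25..25 pA range is used where deflections
must stay small (influence fields on high-impedance pruned trees), mirroring
usual practice.

**Chirp impedance.** The chirp is I(t) = A sin(pi (f_end/T) t^2), a
constant-amplitude sinusoid sweeping 0 to 25 Hz; the full protocol sweeps in
25 s, the reduced protocol in 10 s (0.1 Hz transform grid). For HCN models
the amplitude is scaled by the somatic R_in relative to the base member so
the somatic response amplitude stays comparable across the series
(`normalizeChirpAmplitude()`). Z(f) is the ratio of discrete Fourier
transforms of response and stimulus, restricted to 0.5-25 Hz — the band
floor avoids the ill-conditioned 0 Hz end of the sweep and matches the
definition Q = |Z(f_R)|/|Z(0.5)|.

Two numerical choices matter here. First, a 500 ms zero-stimulus *tail* is
appended after the chirp and included in the transform window; without it
the truncated response decay leaks ~1-2 % ripple into |Z(f)| (with it, the
single-compartment RC profile is reproduced to ~1e-5). Second, f_R is the
vertex of a least-squares parabola fitted over a +/-1 Hz window around the
grid argmax: a three-point refinement would follow the residual ripple of
the nonlinear h response, while the windowed fit averages it out. Band-edge
peaks resolve to the band floor with Q = 1 (the passive case). Phi_L is the
trapezoid integral of the phase profile over the region where it is
positive, with the sign threshold at exactly 0. An optional 0.25 Hz boxcar
smoothing of Z exists but defaults off; results are insensitive to it at
these sweep lengths.

## The stylized morphology generator

The generator emulates a CA1 pyramidal cell at the level of detail the
measurements actually consume — lengths, diameters, branch topology, and
radial stratum occupancy:

- soma: one node, 10 um radius;
- apical trunk: straight, 450 um, diameter tapering 4 -> 1 um, embedded
  along +y so its radial and path extents coincide (the literature leaves
  the trunk-end convention ambiguous; a straight trunk makes both readings
  identical, and both coordinates are exposed for site lookup);
- obliques: lengths ~N(120, 30) um clipped to [60, 180], attached uniformly
  along the trunk, running near-horizontally so each stays roughly within
  the radial stratum of its attachment (as real obliques do within stratum
  radiatum), branching recursively so no unbranched run exceeds ~120 um;
  diameter 0.8 um;
- basal tree: two primary dendrites descending at 20 degrees, recursively
  bifurcating binary trees; diameter 1 um; 30 % of the non-trunk length
  budget.

Piece lengths are drawn and then rescaled so the total dendritic length
equals the target *exactly*; positions are deterministic functions of the
seed. Nodes carry subtree labels ("trunk", "oblique", "basal"), so trunk
identification does not rely on the max-radial-tip heuristic used for
unlabeled SWC files.

What the generator does *not* emulate: real reconstruction tortuosity,
diameter noise, a distal tuft beyond the trunk, spines, or the specific
morphometry of any archived reconstruction. Consequences: total membrane
area and load differ from any real cell, so absolute map values (e.g. a
somatic R_in of ~87 MOhm passive / ~32 MOhm with the gradient on the
17.5 mm base) are not calibrated to experimental values, and the f_R rise
along the trunk (~2-fold to the trunk end) is flatter than the ~3-fold
reported for real reconstructions, whose distal strata carry more membrane.
Passing tests therefore demonstrate the *directional* physics — map
expression on the base tree, atrophy-induced excitability increase, map
constriction, influence-field broadening — not agreement with any specific
reconstruction.

## Pruning

Atrophy is produced by removing whole terminal sections, never rerouting:
every member is a strict subtree, surviving nodes keep their ids and
coordinates, and section boundaries of the base tree are preserved (branch
points whose children vanish become fixed break points), so the d-lambda
segments of surviving branches are bitwise identical across the series —
the property that makes same-location comparisons meaningful.

Uniformity across the tree is enforced with concentric radial strata of
50 um (configurable): the removal quota is proportional to each stratum's
removable length, and each step removes the terminal section whose
stratum-overlap best serves the current deficits (ties to the longer
section, then the smaller id). Near the target the step switches to the
best-fitting section so whole-section removal still lands within 0.1 mm.
Proximal strata dominated by branch stems cannot be pruned until their
children are gone; the test suite audits the achieved balance against an
independent greedy oracle that minimizes imbalance under the same
whole-terminal-section constraint, rather than against an unattainable
perfect-uniformity bound. The series is chained (each member pruned from
the previous one) with targets evenly spaced from the base length to the
1 mm floor — 17 members for a 17.5 mm base, ~1.03 mm steps. The apical
trunk and soma are always protected, so the canonical measurement sites
(soma, ~150 um, ~300 um) exist in every member.

## Influence fields

A localized HCN cluster is inserted by adding a total conductance to the
trunk segment nearest a path-distance location (default: the midpoint of
the trunk path, "the center of the apical trunk"); the specific density the
segment receives is total conductance divided by its area. The default
magnitude is 100 nS: the area-scaled alternative (gradient midpoint density
times the host segment's area, `defaultClusterConductance()`) amounts to
under 1 nS on d-lambda-sized segments and measurably perturbs nothing,
whereas 100 nS reshapes R_in by ~50 % locally and lifts f_R off the band
floor on a passive background, giving the fields the structure the analysis
needs. The magnitude is configurable and reported with results.

IF(x) = |M_org(x) - M_new(x)|/M_org(x) is computed per trunk segment (the
host segment is always included so the peak is resolvable), Lambda(x)
normalizes by the field maximum, and both are integrated over the trunk by
the trapezoid rule. On a passive background M_org for f_R is pinned at the
0.5 Hz band floor, which is positive, so the division is safe; sites with a
zero reference measurement would be excluded with a warning. A cluster of
zero conductance yields an all-zero field flagged `degenerate`. On small
trees the Lambda peak of the f_R field can sit distal to the cluster (the
sealed trunk end resonates more strongly); the peak-at-cluster property is
asserted for the base morphology, where it holds.

## Problem sizes and protocol scaling

The package defaults are the reduced-cost protocol: 0.1 ms integration
steps, a 10 s chirp (0.1 Hz grid), 200 ms settle, 500 ms tail;
`simProtocol(full = TRUE)` selects the full-resolution 25 us / 25 s
protocol. The convergence invariants above are the evidence that the
reduced protocol reproduces the full one. The shipped analyses use: the
17.5 mm base with ~830 segments for map and constriction measurements (five
series members for maps, all 17 for the pruning contract), 2-6 mm trees for
module-level properties, and 7-9-site trunk grids for influence fields.
These sizes were chosen so every analysis is reproducible on a single CPU
in minutes.

## Known limitations

- No other conductances (Na+, K+, M-current, Ca2+); the depolarized
  M-resonance regime is out of scope.
- The stylized generator is not fitted to any archived reconstruction;
  absolute map values carry morphology-scale uncertainty (see above).
- The h-gate parameterization is a calibrated assumption, not a fit to
  published kinetics data; all parameters are exposed.
- Chirp-based f_R extraction retains a small nonlinear-distortion ripple at
  the 50 pA default amplitude; the windowed-parabola estimator absorbs it,
  but sub-0.1 Hz differences between members are not meaningful.
- Transfer measurements always record at the soma; arbitrary
  injection/recording pairs are available through `runSimulation()` but not
  through the map layer.
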