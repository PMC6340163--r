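---
title: "A timed-automata model of the right atrium and its heart-rhythm readout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A timed-automata model of the right atrium and its heart-rhythm readout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atriasim)
```

## The model

`atriasim` represents the right atrium as an `L x L` square lattice of
three-state timed automata.  Each cell cycles through firing (`F`, the
rapid depolarization), refractory (`R`, plateau and repolarization) and
activity/rest (`A`, excitable; pacemaker cells drift toward
self-excitation), driven by a single integer clock and per-state guards
`f`, `r`, `a`.  The step semantics is *increment-then-check*: each global
step the clock advances by one, then the guard is evaluated, so a phase
with guard `theta` lasts exactly `ceiling(theta)` steps and an isolated
cell fires every `f + r + a` steps.  This makes the nominal sinoatrial
period `T_SAN = f_SAN + r_SAN + a_SAN` exact rather than approximate,
which the rhythm classifier relies on.

Two neighbor-interaction rules couple the cells.  A resting cell whose
number of firing in-neighbors strictly exceeds `N_F` is forced to fire; a
refractory cell whose count strictly exceeds `N_R` has its clock halved
(`x <- floor(x/2)`), which *prolongs* its refractory stay — the discrete
analogue of strong junctional currents delaying repolarization.  Within a
step the precedence is forced firing > clock halving > intrinsic guard
transition > time pass, and all cells commit simultaneously from a
snapshot, so a wavefront advances one lattice link per step.

The tissue geometry embeds two special regions.  The SAN is an elongated
rectangle of self-exciting cells (default 20 x 4, upper left) whose
internal links are drawn with a single common probability; it never
receives edges from the atrium, and only a random half of its bordering
cells (the *exit* subset) can transmit outward, one-way, through links
drawn with the ordinary direction-class probabilities.  The AVN is a
passive 2 x 4 block centered on the bottom border; a heartbeat is an
edge-triggered event registered when at least `avn_k` of its 8 cells fire
simultaneously (default 3; the event detector disarms until the count
falls below `avn_k`, so one wavefront cannot double-count).  The RR
series is the sequence of step distances between AVN events; one step
corresponds to about 7 ms, mapping `T_SAN = 115` steps onto an 805 ms
beat.

Atrial connectivity is stochastic by direction class: vertical neighbor
pairs are linked with `p_V` (1 by default), horizontal with `p_H`,
diagonal with `p_L`, giving the closed-form mean degree
`2 (p_V + p_H) + 4 p_L`.  Lowering `p_H = p_L` emulates transversal
uncoupling by collagen deposition; the per-cell refractory guard
`r = r0 + r_noise * xi`, `xi ~ U(0,1)`, emulates cell-to-cell variation
of the action-potential duration.

## Parameters that matter

| parameter | default | units | meaning |
|---|---|---|---|
| `L` | 100 | cells | lattice side |
| `p_V`, `p_H`, `p_L` | 1, 0.5, 0.5 | — | link probabilities by direction |
| SAN `f, r, a` | 5, 70, 40 | steps | `T_SAN = 115` (~805 ms at 7 ms/step) |
| atrial `f, r0, r_noise` | 5, 50, 10 | steps | up to 20% refractory spread |
| atrial `a` | 1150 | steps | ten SAN periods: never self-fires in practice |
| `N_F`, `N_R` | 0, 3 | neighbors | strict `>` thresholds |
| `avn_k` | 3 (2 for walk runs) | cells | simultaneity defining a beat |
| `p_refuse` | 0 | — | probability of refusing an enabled firing |
| `transient_beats` | 10 | beats | discarded before classification |

The SAN/atrial timers, the region geometry and the run lengths are this
package's own reconstruction: the defaults were chosen once so that the
nominal period sits in the human resting range, the atrial refractory
(50–60 steps) is comfortably below the pacing period, and the atrium
cannot pace itself; they are not revisited per experiment.  All of them
are exposed through `sim_config()`/`parse_config()`.

## Refusal semantics

The dysfunction parameter `p_refuse` lets a cell refuse an enabled fire
transition.  Two readings are possible, and the package implements both
(`refuse_mode`):

* **episode** (default): one Bernoulli draw per *excitation attempt*,
  taken at the onset of the enabling condition (a new supra-threshold
  stimulus while resting, or the clock crossing `a`); a refused cell
  stays silent until the next onset.  A passing wavefront therefore
  tests each cell exactly once, and the effective block rate equals
  `p_refuse`.
* **step**: the draw is re-taken every step while the transition stays
  enabled, as in the single-cell `intrinsic_step()` semantics, where the
  extra delay before self-excitation is geometric.

The episode mode is the default because the per-step reading makes
refusal almost inert at the tissue level: a neighbor stays in `F` for
`f = 5` steps, so a cell would get five independent chances per front and
the effective block rate would be `p_refuse^5` — at `p_refuse = 0.5`
about 3%, leaving the rhythm essentially normal.  Under episode
semantics the model reproduces the expected sequence of limit states as
fatigue grows at `p_H = p_L = 0.5`: normal up to about `p_refuse ~ 0.15`,
then missed-beat states mixed with re-entry arrhythmia, then dead
rhythms by about 0.5.  The bounded random walk of `p_refuse` on
`[0, 0.45]` (`walk_spec()`, move probability 0.001, step 0.05, rejected
at the boundary rather than clamped) swings the system out of and back
into the normal state, producing epochs of shortened and missed beats.

## Rhythm classification

`classify_rhythm()` works on the RR series after discarding the first 10
beats.  The cascade: (1) no beats, or mean RR above three SAN periods —
*dead* (more than two thirds of SAN excitations lost); (2) RR span below
`0.25 T_SAN` with mean within 10% of `T_SAN` — *normal* (the 0.25 comes
from the physiological rule of thumb that an increment above 200 ms on
an 800 ms beat is questionable); (3) otherwise shortened beats
(`< 0.75 T_SAN`) mark re-entry doubling, missed beats (`> 1.25 T_SAN`)
mark lost wavefronts, their combination is *lost arrhythmia* (which also
absorbs fibrillation-like states — spatial rotor detection is out of
scope), and a wide-but-bounded series without either falls back to
*normal*.  The cascade is this package's own formalization of those
rules, with every threshold exposed in
`classifier_thresholds()`; the nominal `T_SAN`
(not the empirical SAN rate) is used so that labels stay stable under
refusal jitter.  The cascade is scale invariant, so it applies equally
to step counts and millisecond series.

## Numerical choices and degenerate inputs

* Clocks are integers; fractional refractory guards act as their
  ceiling.  Clock halving at `x <= 1` is a fixed point (`floor(x/2) = 0`).
* The RNG is consumed in a fixed order (build: per-cell deviates
  row-major, edge coins per direction class, exit sample; run: walk
  deviates, then refusal draws row-major), so `(config, seed)` is
  bit-reproducible; networks can also be frozen to JSON and replayed.
* The initial condition is all cells at `(A, 0)`: the SAN fires in
  unison after `a_SAN` steps.  An option randomizes SAN clocks to
  exercise the node's self-organization; with dense internal wiring the
  node re-synchronizes within a couple of steps.
* Runs with zero AVN events return an empty RR series and classify as
  dead.  Exactly-at-threshold neighbor counts do nothing (strict `>`).
* The exit-cell count rounds `0.5 x` (bordering cells) to the nearest
  integer; "bordering" means having at least one non-SAN 8-neighbor.

## RR editing and pattern matrices

`clean_rr()` applies the Holter normal-to-normal protocol: runs of fewer
than 5 non-normal beats are replaced beat-by-beat by the median of the
last seven edited beats (always seven values, so the median is the 4th
order statistic); runs of 5 or more are deleted and the junction logged;
a patchable run with fewer than seven preceding beats is deleted
instead.  `pattern_matrix()` bins consecutive increment pairs
`(dRR_k, dRR_{k+1})` — overlapping pairs, as they are subsequent in the
signal — on half-open bins centered at multiples of the bin width
(8 ms at the recording resolution, 7 ms for model output scaled to ms,
1 step raw), and `pattern_from_rr()` refuses to form pairs across
deletion junctions.  A stationary rhythm puts all mass at the origin
bin; refusal-walk runs move mass off-origin.

## What the synthetic generator does and does not emulate

`gen_synthetic_rr()` produces annotated series with quantized jitter and
planted artifact runs of known position and length — enough to verify
the editing rules and matrix normalization by construction.  It does not
emulate respiratory modulation, circadian trends, or the heavy-tailed
artifact structure of real Holter recordings, so passing the editing
tests says nothing about R-peak detection quality upstream; the package
deliberately starts from already-annotated RR series.

## Problem sizes used by the test suite

The suite verifies the synchronous engine against an independent
per-cell reference on 12 x 12 lattices over 500 steps, the mean-degree
closed form on twenty L = 100 networks, the velocity metric against a
breadth-first arrival-time oracle at full density, the deterministic
transition statistic on fifty L = 100 realizations of 4000 steps, and
the refusal-walk experiment on a single 60 000-step L = 100 run — sizes
chosen so the whole suite completes in minutes on one core while keeping
every statistic comfortably away from its decision boundary.

## Known limitations

* With the reconstructed defaults, the deterministic (`p_refuse = 0`)
  regime is *more* robust than intended at low transversal density: all
  columns conduct every beat (`p_V = 1`) and the AVN's four columns stay
  within the 5-step firing window, so simultaneity rarely fails and
  nearly all realizations classify normal even at `p_H = p_L = 0.1`,
  where a sparser exit geometry would yield re-entry and dead states.
  The high-density side (normal beyond the 0.40 transition) is
  reproduced; the low-density side is sensitive to geometry details we
  had to reconstruct.
* The AVN is a detector, not a conduction model; ventricular propagation
  is assumed perfect.
* Autonomic regulation is absent by design: the model targets
  denervated (post-transplant) rhythms.
* Spatial arrhythmia morphology (spirals, rotors) is not detected from
  the grid; classification uses the RR series alone.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(lattice = lattice_spec(L = 100, p_H = 0.5, p_L = 0.5),
                  regions = node_regions(100, avn_k = 2),
                  total_steps = 60000, seed = 42)
res <- run_sim(cfg, walk = walk_spec(p_walk = 0.001, eps = 0.05, z = 0.45))
rr <- analysis_rr(res)
P <- pattern_matrix(rr_increments(scale_rr(rr)), bin_width = 7)
off_origin_mass(P)
```

With the walk disabled the same configuration concentrates the whole
pattern-matrix mass at the origin; with it, the matrix grows off-origin
peaks fed by the missed and doubled beats of the high-`p_refuse`
epochs.
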