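---
title: "Morphing Cα traces: model, parameters and design notes"
author: "CaMorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphing Cα traces: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CaMorph)
```

## The model

CaMorph treats a protein structure as its Cα trace: an ordered sequence of
`n` three-dimensional points, one per residue. A trace is **protein-like**
when three purely geometric window constraints hold:

* **equidistance** — every consecutive distance lies in
  [3.7, 3.9] Å (the 3.8 ± 0.1 Å virtual bond between Cα atoms; the
  shortened cis-proline bond is deliberately out of scope);
* **angle consistency** — every interior pseudo-bond angle, the vertex
  angle at residue *j* formed with residues *j−1* and *j+1*, lies in
  [70°, 120°], the range covering nearly all Cα angles in solved
  structures;
* **steric consistency** — no two non-consecutive residues (index
  separation ≥ 2) are closer than 2.0 Å.

A morph between aligned, superposed conformations `P_start` and `P_end` is
a sequence of K protein-like traces. Each is produced by linear
interpolation followed by a geometric correction ("proteinization"):
interpolation supplies a first approximation, and a dynamic program snaps
every point onto a vertex of a small local lattice so that the constraints
are restored at the minimum total squared displacement. Assumptions worth
stating explicitly: the two inputs have been reduced to shared (aligned)
positions, conformations are compared after rigid superposition, and the
whole trajectory model is geometric — no energies, forces or solvent.

## The lattice dynamic program

Around each interpolated point `v0j` an axis-aligned cubic grid of `Q`
candidate vertices is built. The optimal path — one vertex per lattice —
minimizes the sum of:

* `VScore(v) = d(v, v0j)^2`, plus, for vertices near the lattice centers of
  *earlier* chain positions (1..j−2), a soft penalty
  `100 * sum(d(v, v0m)^-2)`;
* `EScore` = 0/∞ on the [3.7, 3.9] Å distance window, and
* `AScore` = 0/∞ on the [70°, 120°] angle window.

Three recurrences trade optimality for cost:

| strategy | state | constraints | cost | guarantee |
|---|---|---|---|---|
| basic | vertex | distance | O(nQ²) | exact optimum (distance only) |
| advanced | vertex pair | distance + angle + penalty | O(nQ³) | exact optimum |
| simplified | vertex + stored predecessor | distance + angle + penalty | O(nQ²) | sound, possibly suboptimal |

The simplified recurrence — the default, and the one used for every
full-scale run — checks the angle against the predecessor recorded on the
best path into the previous vertex. It may therefore miss solutions the
advanced recurrence finds, and `runMorph()` compensates by escalating the
lattice size. Whatever it outputs does satisfy the distance and angle
windows. A pure-R exhaustive enumerator (`bruteForceOesp()`) serves as an
independent oracle in the test suite; on several hundred random instances
small enough to enumerate (n ≤ 4, Q = 27), the advanced recurrence's
optimum equals the enumerated optimum exactly, and the basic recurrence
equals the enumeration with angle and penalty terms disabled.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `targetDist`, `tol` | 3.8, 0.1 | Å | consecutive Cα distance window observed in real chains |
| `angleLow`, `angleHigh` | 70, 120 | degrees | pseudo-bond angle range in real chains |
| `clashDist` | 2.0 | Å | minimum non-consecutive Cα separation |
| `clashPenalty` | 100 | — | makes one near-clash (~25+) dominate any vertex displacement (≤ 0.75 at edge 1 Å) |
| `density` | 6 | points/Å | finer grids were not observed to improve structures; Q grows cubically |
| `edgeSchedule` | 1.0, 1.5, 2.0 | Å | per-frame escalation; beyond 2 Å the morph is declared infeasible |
| `K` | auto | frames | rounded largest Cα displacement, so consecutive frames differ by ≤ ~1 Å |
| `strategy` | simplified | — | O(nQ²); the recurrence used for the full-scale experiments |

All windows are closed intervals (boundary values pass). With density 6 the
per-axis point count is 7 at edge 1.0 Å (Q = 343) and 13 at edge 2.0 Å
(Q = 2197).

## Numerical and design choices

**Lattice construction.** Grid spacing is exactly `1/density`; the grid
extends `h = floor(edgeLength * density / 2)` steps per side, so the center
is always a grid point and the lattice is reflection-symmetric. When
`edgeLength * density` is even this is the natural `edgeLength*density + 1`
points per axis; when it is odd (the 1.5 Å rung of the default schedule at
density 6) the largest centered sub-grid is used (9 points per axis,
Q = 729) rather than an asymmetric or off-spacing grid. Vertices are
ordered lexicographically by (x, y, z) offset, which makes DP tie-breaking
("lowest vertex index wins") deterministic; morphs are therefore
byte-reproducible.

**Clash-penalty trigger.** The penalty is added when a vertex lies within
`clashDist` of some earlier lattice center. A literal reading under which
the trigger is the distance to the vertex's *own* center is also
implemented (`scoreParams(clashTrigger = "literal")`); it cannot
distinguish anything at edge ≤ 2 Å, where every vertex is within ~1.7 Å of
its own center, which is why the proximity reading is the default.

**Interpolation schedule.** At step k the target is
`C + (P_end − C) / (K − k + 2)` from the *current* (already corrected)
conformation `C` — each residue repeatedly moves an appropriate fraction of
its remaining gap, targets are evenly spaced along the approach, and the
final intermediate lands one step short of the end. The alternative
`schedule = "fixed"` interpolates the original endpoints at
`alpha = k / (K + 1)`; it ignores accumulated corrections but makes targets
independent of earlier frames.

**Rounding of K.** Half-away-from-zero by default (15.2 Å → 15);
`rounding = "truncate"` is available, since for large motions one fewer
frame is sometimes preferred (34.8 Å → 34). K is floored at 1 so
sub-Ångström motions still morph.

**Infinite scores.** IEEE infinities are used directly; they are absorbing
under addition and `min()`, so no large-constant surrogates (and none of
their overflow artifacts) enter the arithmetic. A result is feasible
exactly when its total score is finite.

**Degenerate inputs.** Proteinization needs n ≥ 2; the advanced recurrence
falls back to the basic one at n = 2 (no angle exists, and the penalty sum
over positions 1..j−2 is empty). Kabsch superposition requires n ≥ 3 and
uses SVD with reflection correction (determinant sign), so mirror images
are never produced. A vertex coinciding exactly with an earlier lattice
center is scored ∞ (division guard).

**Alignment.** Needleman–Wunsch global alignment via
`Biostrings::pairwiseAlignment` with BLOSUM62, gap open 10 / extend 1. The
intended inputs are two conformations of the same or nearly identical
sequences, so the result is insensitive to the scoring scheme; a fixed
scheme plus the library's deterministic traceback keeps runs reproducible.
Positions adjacent to alignment gaps (non-consecutive residue numbers in
the original start structure) have their distance/angle constraints waived
— there is no physical bond to constrain. Only the start structure's
numbering defines these flags; discontinuities present solely in the end
structure do not.

## What the synthetic generator does and does not emulate

`generateChain()` grows a self-avoiding chain with exact 3.8 Å spacing,
pseudo-bond angles uniform in [70°, 120°], free dihedrals, and
rejection-sampled 2.0 Å steric separation — i.e. exactly the constraint
set the validator checks, with a seeded RNG. `perturbChain()` adds
isotropic Gaussian noise (per-point displacement norms are then
Maxwell-distributed, mean σ·√(8/π)), which structurally resembles the
damage raw interpolation inflicts. `makeMorphPair()` rotates the segment
past an interior residue about a random axis, an idealized domain hinge
motion: only the hinge angle changes among the internal coordinates.

These fixtures deliberately have no secondary structure, no realistic
dihedral preferences, no sequence-dependent geometry and no excluded-volume
envelope beyond the 2 Å rule. Tests passing on them demonstrate the
*geometric contract* — constraints restored, scores optimal, trajectories
reproducible — not that morphs of real proteins are biophysically accurate
transition paths.

## Problem sizes used by the test suite

Unit and acceptance tests run entirely on generated data: oracle
comparisons on a few hundred instances with n ≤ 4 and Q = 27 (small enough
to enumerate all lattice paths), constraint and idempotence checks on
30-residue chains at the full Q = 343, and complete morphs on 10–30-residue
hinge fixtures. These sizes exercise every code path (including lattice
escalation and infeasibility) while keeping the default suite fast.

## Known limitations

* **The proximity guarantee is soft.** The penalty compares candidate
  vertices with earlier lattice *centers*, not with the finally chosen
  path vertices. Each chosen point may sit up to (edge/2)·√3 from its
  center (~0.87 Å at edge 1), so two chosen points can end up slightly
  closer than 2.0 Å without any penalty having triggered. On perturbed
  random chains a noticeable minority of corrections retain such a
  near-clash (typically at 1.6–2.0 Å); the distance and angle guarantees,
  being hard ∞-scores, never fail. A guarantee against the actual path
  would require carrying path history in the DP state, which is
  exponential; the center-based heuristic is the tractable compromise.
* **Large or complex motions.** Linear interpolation with local corrections
  cannot route around obstacles; when a target strays further from any
  protein-like chain than the largest lattice can reach, the morph honestly
  fails rather than producing a distorted frame.
* **Cα only.** No backbone or side-chain atoms are modeled; full-atom
  intermediates require external reconstruction tools downstream.
* **Simplified-strategy completeness.** The default recurrence can declare
  a frame infeasible where the advanced one would succeed; the edge
  escalation narrows but does not close this gap.
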