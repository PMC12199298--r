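---
title: "Methods: Qo-site hydrogen-bond networks, torsional landscapes and proton wires"
author: "qowire"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Qo-site analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qowire)
```

## The scientific problem

Quinol oxidation at the Q~o~ site of cytochrome *bc*~1~ releases two
protons. One is taken by the Rieske histidine (H152 in *Rhodobacter
sphaeroides* numbering); the fate of the second depends on a dynamic
hydrogen-bond network formed by the conserved Y147/E295/Y297 (YEY) side
chains, H276, D278, the heme *b*~L~ propionate-A (PRA) and site waters.
This package implements the analyses needed to characterise that network:
side-chain rotamer surveys over structure ensembles, water-bridge contact
statistics over MD trajectories, metadynamics-reweighted free-energy
profiles, and enumeration of donor-to-release proton wires on the
resulting contact graph.

## Geometry conventions

Distances are in nm, torsions in degrees wrapped to (−180, 180] with
+180 preferred over −180 so the trans rotamer has a single label. The
signed torsion follows the standard convention and is invariant under
quartet reversal. χ~1~ uses the N–Cα–Cβ–Cγ quartet; χ~2~ uses the
conventional next-bond quartets (Glu: Cα–Cβ–Cγ–Cδ; Tyr: …–Cδ1; His:
…–Nδ1; Asp: …–Oδ1). Periodic (minimum-image) treatment is opt-in per
call: trajectory analyses of solvated systems should pass the box, while
experimental models are treated non-periodically because a crystal cell
is not a meaningful solvation box for this analysis. The minimum image is
found by fractional wrapping plus a 27-image scan, which is exact for any
triclinic cell.

## Rotamer classification and torsional modes

Side chains in the Q~o~ site populate rotamers near 180° (*t*), +60°
(*g*) and −60° (−*g*). Only the centres are physically defined, so the
package partitions the circle into three 120° bins with boundaries at 0°
and ±120°; boundary angles join the bin whose closed edge they touch
(|χ| ≥ 120 → *t*; [0, 120) → *g*; (−120, 0) → −*g*). This makes
classification a total function — every angle gets exactly one label —
at the cost of assigning rare boundary angles by convention rather than
by physics.

`survey_modes` tabulates the joint tuple (Y147 χ₁, E295 χ₁, E295 χ₂,
Y297 χ₁) over an ensemble. Modes are sorted by descending count and
labelled A, B, C, …, with lexicographic tie-breaking, so labels are a
deterministic function of the ensemble and invariant under input order.
Models missing a mapped residue or atom are reported as skipped with a
reason rather than silently dropped: a silent drop would corrupt the mode
denominators. Residue mapping is an explicit curated input (a TSV of
model/role/chain/resid), not a computation — cross-organism numbering is
a curation problem. Alternate locations collapse to the highest-occupancy
altloc (ties to the alphabetically first), multi-model files expand one
model per MODEL record, and dimeric entries expand one model per protein
chain; waters are recognised by residue names HOH/WAT/H2O/SOL/TIP3 and
counted by their oxygen atoms only. These conventions are recorded in the
survey output headers.

## Contact criterion, occupancy and lifetimes

All H-bond detection is heavy-atom distance only, strictly below a
0.35 nm cutoff (configurable); no donor–H–acceptor angle term is used. A
*k*-water bridge requires an ordered chain of *k* distinct water oxygens
with every link under the cutoff. The bridged state is defined frame by
frame and is agnostic to water identity: site waters exchange on fast
timescales, and a bridge whose water is replaced within one frame is
still a formed bridge. Bridge search uses a neighbour-pruned depth-first
search; tests verify it against an exhaustive scan over all ordered water
tuples.

Occupancy θ is the fraction of formed frames. The moving average
(default window 1 ns, rectangular, centred, truncated at the edges)
preserves the series mean up to edge effects of order window/length.
Lifetimes use a continuous-with-tolerance estimator: maximal formed runs,
where interruptions no longer than `gap_tolerance` (default one frame
interval) are absorbed, and absorbed gap frames count toward the event's
duration. The estimator is provably monotone non-decreasing in the
tolerance, and `gap_tolerance = 0` gives the strict intermittent-free
alternative; both are exposed because the choice materially affects
reported lifetimes, and the default is recorded in output metadata.
Frames with missing atoms abort the run: silent gaps would corrupt θ.

## Free-energy profiles and metadynamics reweighting

Profiles are binned estimates ΔG~b~ = −kT ln p~b~, min-shifted so the
lowest unmasked bin is zero. kT is fixed from T = 310 K (2.577 kJ/mol).
Empty bins are masked and never interpolated: a gap in a profile means
undersampling, and reading a barrier across a masked gap would be
invention. Default bin widths are 5° for torsions and 0.025 nm for
distances; both are surfaced in the configuration as package choices.
Angular histograms wrap, and bias Gaussians use periodic images.

Well-tempered metadynamics bias is removed by *final-bias reweighting*:
each frame enters the unbiased ensemble with weight
w~i~ ∝ exp(+V(s~i~)/kT), where V is the final accumulated bias evaluated
at the frame's CV value. This is the simplest estimator consistent with a
converged well-tempered bias; its adequacy is not assumed but checked —
the test suite compares reweighted profiles against an unbiased twin run
and against direct Boltzmann integration of the planted potential. A
constant (or zero) bias provably reduces to the plain histogram pipeline
bit for bit. When biased and unbiased trajectories are pooled
(`combine_sample_sets`), each trajectory's weights are first normalised
to its own frame count, so replicas contribute by simulated time rather
than raw weight mass.

Replica combination reports the per-bin mean and SE = sd/√n over
replicas, masking any bin empty in any replica. With n = 2 replicas the
SE has one degree of freedom; it is reported as-is with that caveat.

## Proton-wire graph and enumeration

The wire graph's nodes carry roles: *donors* (quinol-head oxygens O1,
O4), *relays* (Y147, E295, Y297, H276), and *release* groups (H152,
PRA, D278). Edges carry mechanism sets from {direct, 1-water, 2-water};
mechanisms requiring more than two bridging waters are rejected outright
— a three-water chain is too transient to propose as a Grotthuss
pathway. When edges come from contact statistics, any mechanism with
occupancy ≥ θ_min (default 0.05) admits the edge; the curated instance
is insensitive to any θ_min ≤ 0.16, the weakest quantified bridge in it.

`enumerate_wires` returns all simple donor→release paths with two
structural rules: release nodes are terminal sinks (a proton that
reaches a release group is considered discharged, so paths never
continue through one), and donors never appear as interior relays.
Wires are deduplicated by node sequence — a direct and a water-bridged
variant of the same residue sequence is one wire, because wires are
distinguished by their relays, not their instantaneous mechanism. H152
is modelled as a release node: chemically it is an acceptor whose proton
leaves with Rieske-domain motion, but for enumeration it terminates its
wire. Output order is deterministic (donor, length, lexicographic).
Correctness is established against a brute-force all-simple-paths
oracle, and against an independent graph library, on random graphs.

## Conservation

Rows with gap fraction strictly above 0.25 are removed (a row at exactly
25 % stays, matching a strict-greater reading of the filter); the
reference row must survive. Conservation of a residue at a reference
position excludes gaps from numerator and denominator — the reported
percentage is "of sequences aligning a residue here, how many have this
one". Because reported conservation can refer either to the consensus or
to the *R. sphaeroides* residue, the residue is an explicit argument.
Column-to-position mapping comes from the reference row's gap structure.

## Synthetic generators: what they emulate, and what they do not

The generators define the package's study conditions:

* `sample_potential` / `sample_metadynamics` — discrete-time Metropolis
  sampling of analytic 1D torsional potentials (radians on (−π, π]),
  auto-tuned to 30–50 % acceptance, with well-tempered deposition
  h~k~ = h₀ exp(−V(s~k~)/((γ−1)kT)) at defaults h₀ = 0.6 kJ/mol,
  σ = 0.4 rad, γ = 15. The deposition stride is 500 sampler steps, the
  analogue of a 2 ps stride in time-stepped dynamics. The accumulated
  bias lives on a 2048-point periodic grid with linear interpolation,
  making per-step evaluation O(1); tests confirm the grid agrees with
  the explicit Gaussian sum and that the long-run bias approaches the
  well-tempered limit −(1−1/γ)(U − const).
* `telegraph_series` — a discrete two-state Markov chain with switch
  probabilities k·dt (validated against dt·max(k) ≤ 0.1), stationary
  occupancy k_on/(k_on+k_off) and exponential dwell times.
* `make_model_ensemble` — single-chain coordinate models built from
  internal coordinates so planted χ angles are exact (well under 0.1°
  even after PDB's 0.001 Å rounding), with waters at exact planted radii
  and an optional rigid-body rotation+translation that all analyses must
  be invariant to.
* `make_msa` — per-column multinomial draws with a gap-free consensus
  reference row and planted per-row gap fractions.

These emulate the *statistical* structure of the real inputs — rotamer
wells, two-state contact kinetics, planted geometry, column-wise
conservation — but none of the physics: no real force field, no
correlated multi-residue dynamics, no solvent structure, no experimental
noise model. Passing tests therefore demonstrate estimator correctness
(the analyses recover known ground truth), not that the package's
defaults are optimal for any particular real system. Real-trajectory
magnitudes (bridge occupancies of ~16 %, lifetimes of several ns, median
hydration of 5–6 waters at acidic centres) require microsecond-scale MD
of the solvated complex and are outside what synthetic desk-scale runs
can or should reproduce.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: 79-model synthetic
survey ensembles (the curated mode design 51/24/2/1/1), telegraph chains
of 10^5 frames, Metropolis runs of 10^4–10^6 steps with 5° (0.087 rad)
torsion bins, and alignments of 10^4 rows. Stochastic recovery checks
use three-standard-error bands with SEs that respect autocorrelation
(closed-form lag-covariance sum for the telegraph chain, replica spread
for metadynamics). Ties, boundaries and degenerate inputs are all
decided explicitly: strict `<` at the contact cutoff, boundary rotamer
angles to the closed bin edge, empty contact series report zero lifetime
with a warning, collinear dihedral quartets raise an error rather than
returning an arbitrary angle, and degenerate (zero-volume) boxes are
rejected.

## Known limitations

* The survey takes structures at face value: no electron-density or
  B-factor screening, no symmetry expansion, and only first-altloc
  geometry.
* Final-bias reweighting carries a transient bias from early frames
  sampled under a partly built bias; it vanishes with run length (tests
  run long enough for this) but a time-dependent estimator would
  converge faster.
* The lifetime estimator is sensitive to the gap tolerance near the
  frame interval; compare `gap_tolerance = 0` and the default before
  interpreting absolute lifetimes.
* Wire enumeration is purely topological: it proposes candidate
  Grotthuss pathways from contact statistics and says nothing about
  proton-transfer energetics or pK~a~.
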