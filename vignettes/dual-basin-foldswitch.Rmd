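---
title: "Dual-basin structure-based models of protein fold-switching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-basin structure-based models of protein fold-switching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duobasin)
```

## The problem

Metamorphic proteins such as the transcription factor RfaH switch between
two folds of the same sequence: an autoinhibited state in which the
C-terminal KOW domain is an alpha-helical hairpin packed against the
N-terminal NGN domain, and an activated state in which KOW has refolded
into a beta-barrel and the domains are dissociated. Because both
conformations are experimentally known, the transition can be studied
with *dual-basin structure-based models* (SBMs): Go-like force fields in
which both end states are explicit minima and the dynamics between them
is emergent. `duobasin` implements that workflow end to end — native
contact maps, single-basin all-atom SBM construction, the two-state
merge, Langevin dynamics in reduced units, and the
fraction-of-native-contacts analysis of the resulting refolding
landscapes — together with the rigid-body geometry descriptors used to
characterise paused transcription elongation complexes (domain swiveling
angles, DNA duplex axis angles, RNA:DNA hybrid diameters).

## Native contacts: the shadow criterion

Native interactions are all heavy-atom pairs within a cutoff (default
0.6 nm) that pass two filters:

* **sequence separation** — at least 3 residues for protein-protein
  pairs within one chain; none for pairs involving nucleic acids;
  inter-chain pairs are always eligible;
* **shadow occlusion** — a third atom, modeled as an opaque sphere of
  radius 0.1 nm (the sight line carries the same radius, so the
  effective occlusion distance is 0.2 nm), blocks a pair when its centre
  projects strictly between the endpoints and lies closer than that
  distance to the segment.

Pairs that are covalently bonded or share an angle term (bond-graph
distance two or less) are never contacts. The implementation is verified
against a brute-force ray-sampling oracle in the test suite, and is
invariant under rigid motion and monotone in both the cutoff and the
shadow radius.

## The potential

All quantities are in reduced units (length nm, energy, mass and time
all 1). Bonds and angles are harmonic,
$V_b = \tfrac{1}{2} k_b (r - r_0)^2$ with $k_b = 2\times10^4$ and
$V_\theta = \tfrac{1}{2} k_\theta (\theta - \theta_0)^2$ with
$k_\theta = 40$. Proper dihedrals use the standard two-term cosine form

$$V_d(\varphi) = k_d\left[(1 - \cos\Delta) + \tfrac{1}{2}(1 - \cos 3\Delta)\right],
  \qquad \Delta = \varphi - \varphi_0,$$

and a two-well dihedral is the mean of that form evaluated at the two
equilibrium angles. A native contact is a Gaussian well over an
excluded-volume core,

$$V_c(r) = \varepsilon\left[\left(1 + (r_{ex}/r)^{12}\right)
  \prod_b\left(1 - e^{-(r - r_{0b})^2 / 2\sigma^2}\right) - 1\right],$$

with one Gaussian factor per basin ($\sigma = 0.05$ nm,
$r_{ex} = 0.04$ nm, $\varepsilon = 1$ by default); every non-native,
non-excluded pair is purely repulsive, $(r_{nn}/r)^{12}$, truncated and
shifted at $2.5\,r_{nn}$. All constants are configurable through
`sbm_params()`. The source conformation is the built-in minimum of its
single-basin topology, and analytic forces are validated against central
finite differences at relative error $10^{-4}$.

### The dual-basin merge

Two single-basin topologies built on models with identical atom ordering
are merged as follows. Contacts present in both maps become dual-basin
when their relative distance difference $|r_A - r_B| / \bar r$ exceeds
0.10; otherwise they stay single-basin at the state-B (target/active)
distance. Contacts unique to one state keep that state's distance.
Dihedrals become two-well when their periodic angular difference exceeds
0.20 of a full turn (72 degrees). Bonds and angles always take state-B
values, mirroring the published convention of parameterising them from
the energy-minimised active-state complex. Both denominators — the mean
distance and the angular fraction of a turn — are explicit
configuration values because the published description does not define
them; the angular-fraction reading of the dihedral criterion is one of
two possible interpretations (an energy-based criterion would be the
other) and is flagged as such. The merge reports divergence counts
(dual contacts, dual dihedrals) that are bit-reproducible for fixed
inputs, and the classification is symmetric in the two states.

## Langevin dynamics

The integrator is BAOAB splitting with unit masses. At zero temperature
and friction it reduces to velocity Verlet, which the energy-conservation
test exploits; at finite temperature the sampled kinetic energy satisfies
equipartition and the time-averaged instantaneous temperature is
controlled to within 2 percent. Production parameters follow the
reduced-unit convention for all-atom SBMs: temperature 0.67 (nucleic-acid
native interactions in this model class begin to melt near 0.75), time
step 0.002 tau, one stored frame per 1000 steps, and termination when the
best-fit RMSD of a monitored selection against a target conformation
falls below 0.5 nm.

Two points deserve explicit flags:

* **Stop-criterion target.** The published protocol wording names the
  autoinhibited state as the RMSD reference although the simulated
  transition ends in the active state; the default here monitors the
  ACTIVE-state target (the consistent reading) and the reference is
  fully configurable, so either interpretation can be run.
* **Friction.** The friction coefficient is not published; the default
  is $\gamma = 1\,\tau^{-1}$. Absolute first-passage times scale with
  this choice, so the analysis asserts event *orderings* and never
  absolute passage-time values.

Randomness comes from a dedicated mt19937-64 stream with an inline
Box-Muller transform, so a single integer seed makes trajectories
bitwise reproducible on one thread, independent of R's RNG state and of
the platform's `std::normal_distribution`. Two numerical guards matter
for bead-chain (one atom per residue) systems: the torsion gradient
diverges when three consecutive atoms go transiently collinear during a
torsion flip, so the $|m|^2$, $|n|^2$ denominators are floored at
$10^{-5}$ (a force cap that leaves regular geometries untouched), and
bead chains use a smaller step (0.001 tau) than the all-atom default.

## Order parameters and events

A contact is *formed* in a frame when its distance is below
$\lambda r_0$ with $\lambda = 1.2$ (configurable; the published analysis
does not state its criterion). For dual-basin contacts each state's Q
uses that state's own native distance, which the per-state contact
subsets carry. The per-frame series comprises Q_ID (fraction of
interdomain contacts), Q of each end state of the switching segment,
their difference Q_diff, and Delta-d, the anchor-switch
centre-of-geometry distance relative to its active-state value (the
quantity plotted in place of Q_ID once all interdomain contacts are
gone). Landscapes are plain 2-D occupancy histograms whose counts
conserve the number of frames.

Events are first threshold crossings: strand-pair formation and
RNAP-association events fire when a contact subset's formed fraction
reaches 0.75 (association convention: more than 75 percent of native
contacts formed), and domain dissociation fires when Q_ID drops to 0.30
(70 percent of interdomain contacts broken). Whether the published
"70 percent" is an event-defining threshold or a measured peak is
ambiguous; it is implemented as a threshold and configurable. For
per-trajectory ordering statistics the *committed* crossing of Q_diff is
used — the last frame at which Q_diff is still non-positive — because
with a desk-scale contact count a single thermally flickering contact
can push Q_diff momentarily above zero long before the switch.

## The synthetic two-state switcher

Every stage is testable without downloads through a bead-per-residue toy
(41 beads by default): a rigid helical *anchor* (NGN stand-in, 24 beads),
a 3-bead linker, and a 14-bead *switch* (KOW stand-in) that packs
against the anchor as a helix in state A and refolds into an
antiparallel hairpin away from the anchor in state B. State B is rebuilt
from state A's measured bond lengths and bend angles with redesigned
torsions (NeRF chain extension), so the two conformations share all
covalent internal coordinates exactly — as two folds of one protein do —
and differ only in dihedrals and packing. Construction goals, verified
in the tests: at least 5 interdomain contacts in A, at most 1 in B, and
switch RMSD between states above 0.5 nm.

The toy's force-field choice (`toy_sbm_params()`) rescales three
constants to residue-bead scale: per-contact depth $\varepsilon = 2$
(one bead pair stands in for several atomic contacts), and bead-sized
excluded volumes ($r_{ex} = 0.35$ nm, $r_{nn} = 0.38$ nm, about one
virtual-bond length). The second choice is essential, not cosmetic:
with atom-sized cores the chain can collapse into compact non-native
blobs in which the distance criterion counts contacts of *both* states
as formed simultaneously, destroying the two-state character. With
bead-scale cores the toy is bistable — the docked state holds Q above
0.8 for $10^4$ tau at temperature 0.3, and at the toy's switching
temperature of 1.0 all of a 20-replica campaign completes the
transition, breaking at least 60 percent of interdomain contacts before
the committed Q_diff crossing, with dissociation preceding
barrel-completion in every replica. The switching temperature is the
toy's own (its basins are shallower than the full-size system's, which
runs at 0.67), and switching runs stop at 0.2 nm switch RMSD from state
B, scaled from the production 0.5 nm in rough proportion to system size.

What the toy does *not* emulate: the RNAP/DNA environment (no partner
contacts stabilise the post-switch state, so its two basins are tuned to
comparable depth by construction), secondary-structure specificity
beyond contact topology, and the contact statistics of an all-atom
interface (tens of thousands of atoms, hundreds of interdomain
contacts). Passing the toy-based tests therefore demonstrates that the
machinery is correct and that the qualitative physics (bistability,
dissociation-first ordering) is reproduced — not that the deposited
systems' printed numbers are.

Ideal B-form duplex generators provide ground truth for the geometry
stack: C1' and P pseudo-atoms on an exact helix (twist 36 degrees, rise
3.38 Angstrom, P radius 9.4 Angstrom), with paired C1' atoms placed
diametrically so base-pair midpoints lie exactly on the true axis, and
bent pairs whose axes meet at a requested angle.

## Elongation-complex geometry

Swiveling is quantified by two-stage superposition: align both
complexes on the core module (alpha subunits and omega whole, the
published beta and beta-prime segments), then take the best-fit rotation
mapping one swivel module onto the other; the angle is the axis-angle
magnitude $\arccos((\mathrm{tr}\,R - 1)/2)$. Superposition is
least-squares with reflections rejected, atoms matched 1:1 by chain,
residue and atom name. `rnap_selections()` encodes the published module
ranges with chain identifiers as arguments, since subunit-to-chain
mapping varies between depositions.

Duplex axes are fitted as the principal direction of per-base-pair C1'
midpoints (total least squares), oriented 5' to 3' along the first
strand; the radius is the mean P-atom distance from the axis and the
hybrid diameter twice that. This is deliberately a midpoint
principal-direction fit, not a base-pair-step algorithm as used by
dedicated nucleic-acid geometry tools; on distorted junctions the two
conventions can differ by a few degrees, which is why cross-validation
against published inter-duplex angles uses a widened (5-degree)
tolerance while swivel angles — computed by the same algorithm as the
published script — are held to 0.3 degrees.

## Problem sizes and runtime choices

The shipped tests and the acceptance script run entirely on generated
fixtures at desk scale: the 41-bead toy, 20-replica switching campaigns
of at most $1.5\times10^6$ steps each, a $10^7$-step low-temperature
stability run, and 100-atom thermostat checks. Comparisons that need the
deposited coordinate sets (the archived encounter/recruited SBM input
models and the cryoEM entries) are implemented and documented but
require the user to place those files under `inst/extdata/deposited/`;
the corresponding checks fail with an explanatory message when the files
are absent.

## Known limitations

* Dihedral enumeration is template-free: one canonical proper dihedral
  per rotatable bond (lowest-index flanking atoms) and no automatic
  improper terms. Counts of dual dihedrals on all-atom systems therefore
  depend on this convention, as they do on any generator's.
* Covalent bonds are inferred geometrically (distance thresholds plus
  standard inter-residue linkage atoms), not from residue chemical
  templates; exotic ligands fall back to class `other` with no bonds.
* Per-contact well depths are uniform; no residue- or atom-type-specific
  energies.
* The helix-axis algorithm is global, not per-step; strongly bent or
  partially melted duplexes should be split before fitting.
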