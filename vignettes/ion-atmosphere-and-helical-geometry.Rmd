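---
title: "Methods: the ion atmosphere and helical geometry of A-RNA duplexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the ion atmosphere and helical geometry of A-RNA duplexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixion)
```

# The scientific problem

Double-helical RNA is a densely charged polyanion. Mobile monovalent cations
condense into a diffuse atmosphere around it — typically organised into a
first solvation shell ~3.3–3.5 Å and a second shell ~6.0–6.5 Å from the RNA
surface — and this atmosphere co-determines how compact the A-form helix is.
Compactness is best summarised by a single helical parameter, the
**inclination** of the base pairs with respect to the global helix axis: an
A-form duplex sits near +15° to +20°, while an uncompacted helix drifts
toward 0°. `helixion` implements the complete measurement chain for both
quantities from structure ensembles, plus the box-setup arithmetic and a
synthetic generator that makes the whole chain verifiable without running any
molecular dynamics.

# Surface-distance RDFs and solvation shells

The radial coordinate everywhere is the **surface-minimal distance**: the
Euclidean distance from an ion to its nearest RNA *heavy* atom. Hydrogens are
excluded by design — MD-exported and crystallographic PDBs frequently lack
them, and the 3.3–3.5 Å first-shell scale is defined on heavy-atom contacts.
Distances are computed on the coordinates as given (no periodic re-imaging);
trajectories are expected to keep the solute whole.

`rdf_histogram()` bins these distances at a fixed 0.1 Å pitch and averages
over frames; the invariant `sum(counts) * n_frames == n_obs` is enforced by
construction and tested. `concentration_profile()` turns counts into mol/L
by dividing by the volume of each distance shell. The shell around an
irregular solute has no closed form, so volumes are estimated by classifying
probe points in the box by their own surface-minimal distance. Probes are
**quasi-random (Halton) points** rather than pseudo-random ones: per-bin
volume error at 10^6 probes stays below 2% throughout the solvation-shell
regime (verified against the analytic spherical shells of a point solute),
where pseudo-random sampling would be several-fold noisier at the same cost.
The probe count and the sequence offset ("seed") are configuration keys, so
the normalisation is exactly reproducible.

`detect_shells()` works on the concentration profile when present (the
counts histogram otherwise) — which of the two a reference analysis used is
generally not knowable, so the choice is explicit and overridable. The
profile is smoothed with a centred 3-bin moving average, local extrema are
extracted, and extrema whose peak-to-valley contrast is below 5% of the
first-peak height are pruned (persistence pruning). This guards minimum
detection against Monte-Carlo and sampling noise without moving genuine
boundaries. Conventions:

* the **first shell peak** is the first surviving maximum (physically the
  contact shell), and the first-shell boundary `r_min1` the first minimum
  after it; flat minima resolve to the smallest radius;
* the **second-shell boundary** `r_min2` is the first minimum after the
  second peak; when the profile decays into bulk without a further
  significant minimum, `r_min2` is reported absent and a fixed fallback
  radius of **6.3 Å** stands in downstream — mirroring the tabulation
  convention of reporting parenthetical counts at 6.3 Å when an RDF has no
  second minimum;
* a peak that decays into a flat tail (single-shell profiles) takes its
  boundary where the significant descent ends.

`shell_occupancy()` reports cumulative time-averaged counts within `r_min1`,
within `r_min2` (or the fallback), and within the fallback radius; a flag
exposes per-shell (non-cumulative) counts. `residue_occupancy()` counts ions
within a cutoff (default **3.5 Å**, the first-shell scale) of either the
nucleotide heavy-atom centroid or any atom of a site class. The groove atom
sets are data, not code (`groove_atlas()`), and overridable: major groove
N7/O6 or N6/C8 (purines) and O4 or N4/C5/C6 (pyrimidines); minor groove
N3 and C2 or N2, and O2; phosphate OP1/OP2.

Density maps (`density3d()`) superpose every frame onto a reference by
least-squares (Kabsch) over a fit selection, wrap ions by the orthorhombic
minimum image into the cell centred on the RNA centroid, and accumulate
counts on a cubic grid over the reference box; grids serialise to OpenDX.
`project2d()` sums a z-slab and converts to a 2D concentration map; the slab
for "the central part of the duplex" is derived from chosen base-pair
origins padded by half a rise (`pair_z_window()`) — the exact slab thickness
such maps use is a convention, and this one is ours.

# Base-pair frames and helical parameters

Base frames follow the standard-reference-frame family of conventions: the
observed base heavy atoms are fitted by a rigid superposition of an embedded
standard base geometry, and the transformed standard frame (x toward the
major groove, y along the pair long axis, z the base normal) is the base
frame. At least six base atoms must match; fewer is an error naming the
absent atoms. A pair frame averages the two base frames after negating y and
z of the complementary strand's frame; anti-aligned normals (>90°) are a
pairing-geometry error in strict mode, and degrade gracefully to the
strand-A frame in trajectory summaries so transiently frayed frames do not
abort a whole-series analysis.

Step parameters (twist, roll, tilt; shift, slide, rise) use the mid-step
frame construction: the bending rotation between consecutive z axes is split
symmetrically, twist is measured about the mid-frame normal, and roll/tilt
are the bend components along the mid-frame y and x. `apply_step()` is the
exact inverse, which the tests verify to 1e-8 on random steps — the
build→measure round trip is the backbone of the validation suite.

**Inclination** is the signed angle between a pair's long axis and the plane
perpendicular to a single straight global axis, positive for the A-form-like
tilt, averaged with **two terminal pairs excluded at each end** (terminal
pairs fray and would contaminate the mean; end-to-end distance, which is
deliberately not terminal-excluded, retains that sensitivity). Two axis
estimators are provided. `helix_axis()` is the classical smallest-RSS
straight line through the pair origins; it is exact only in the limit of
many full turns — a 10-bp duplex minus four terminal pairs spans barely half
a turn, where the line fit tilts by several degrees. `inclination()`
therefore defaults to `screw_axis()`: the mean rotation axis of consecutive
pair-frame steps, which is exact for a regular helix of any length, is still
one straight global axis (no curved-axis analysis is attempted — the
duplexes of interest are short), and coincides with the line fit for long
regular helices. With it, built inclinations of 5–25° are recovered within
0.05° on noise-free duplexes.

The generator realises a requested inclination through the
**roll–twist coupling** of regular helices: for constant (twist, roll, rise)
steps, the global screw axis — hence the inclination — follows analytically
from the step transform, and `roll_for_inclination()` inverts that relation
by root finding. This keeps the base-pair internal geometry perfectly rigid;
nothing is sheared after the fact.

Backbone torsions use the standard four-point IUPAC-signed dihedral, checked
against an independent rotation-matrix construction to 1e-6°. Sugar pucker
follows the Altona–Sundaralingam pseudorotation analysis of the five
endocyclic torsions; a planar ring reports amplitude 0 with the phase
flagged indeterminate rather than an arbitrary value.

# Base-pair classification and fraying

Hydrogen bonds default to a **distance-only heavy-atom criterion**
(donor–acceptor ≤ 3.4 Å): MD-exported PDBs are often stripped of hydrogens,
and the donor-angle criterion (≥ 120°) engages automatically when hydrogens
exist. Both cutoffs are declared conventions, configurable — they are not
reconstructions of any reference implementation's internal values.

A pair annotation needs at least one inter-base hydrogen bond, base
centroids within 12 Å, and approximate coplanarity: the centroid offset
projected on the mean base normal must stay below 2.5 Å. The coplanarity
gate is what distinguishes pairing from stacking — in an ideal stack,
polar atoms of adjacent bases sit ~3.3 Å apart *along the normal* and would
otherwise satisfy the distance criterion. Each base's interacting edge is
the majority edge of its hydrogen-bonded atoms under the edge atlas
(`edge_atlas()`, data and overridable); atoms sitting between two edges
(O6/N6, N2, O2, O4/N4) carry both memberships, and ties resolve
Watson-Crick > Hoogsteen > Sugar. Orientation is cis when the
C1′–N(glycosidic)–N(glycosidic)–C1′ pseudo-torsion is within ±90°
(a tie at exactly 90° is cis, documented). A pair is canonical when both
edges are Watson-Crick, the orientation is cis, at least two hydrogen bonds
connect the bases, and the bases are complementary (G·U wobble included).

**Fraying**: a terminal pair is open in a frame when no annotation is found
or the annotation is non-canonical — a single residual contact still counts
as open, because fraying is defined as loss of canonical pairing. The
estimator is validated as unbiased at opening probabilities 0.05–0.5.

# NOE chi-square

Effective distances are `⟨r⁻⁶⟩^(−1/6)` over frames — the standard ensemble
convention for NOE back-calculation; a flag switches to the plain linear
average (and the comparison could equally be run on the intensity scale),
because the precise averaging inside a reference calculation is often not
recoverable from a methods section. The chi-square divides each deviation by
the **larger** of the two experimental bound gaps, `max(max − exp, exp −
min)`, and averages the squared normalised deviations; values below 1 mean
agreement within experimental error. Items with non-positive error are
excluded with a warning, never silently zero-weighted. The exact identities
(zero at agreement, unit at unit deviation, quartering under error doubling)
are asserted in the tests.

# Ion-count planning

Formal-charge arithmetic assumes one negative charge per phosphodiester.
Termini default to **5′-OH** — the convention of standard duplex builders —
so a duplex of two n-nucleotide strands carries 2(n−1) charges; a flag adds
terminal phosphates. Concentration→count conversion rounds half away from
zero (the convention of common box-setup tools; it keeps 0.15 M in 200 nm³
at 18 ions). Every `salt_plan()` satisfies
`charge + cations − anions = 0` by construction.

# The synthetic generator

`build_duplex()` places rigid all-heavy-atom nucleotide templates by
accumulated step transforms; strand B is the y/z-flipped template at the
same pair frame, which yields correct Watson–Crick hydrogen-bond geometry
automatically because the standard reference frame is defined that way. The
templates (`inst/extdata/nucleotide-templates/`) are idealized nucleotide
geometries re-oriented into the standard base frame; their ribose retains
the idealized single-nucleotide conformation, so the *backbone* of built
duplexes is plausible but not a fibre-model A-form backbone — no analysis in
the package depends on backbone conformation beyond atom presence.

`sample_atmosphere()` draws ion positions whose surface-minimal distances
follow a declared mixture: Gaussian shells (defaults 3.4 ± 0.3 Å and
6.2 ± 0.4 Å, the A-RNA two-shell regime) plus a spatially uniform bulk with
a 2.5 Å exclusion. Shell draws are volume-corrected rejection samples — a
uniform proposal would otherwise bias the distance law by the shell volume
factor. Default weights (0.35/0.30/0.35) put roughly a third of a
net-neutral ion complement in the first shell and two-thirds within the
fallback radius, the regime reported for net-neutral small-box setups.
`make_trajectory()` adds i.i.d. Gaussian coordinate noise, resamples ions
independently every frame (the analyses are distributional, so i.i.d.
sampling makes expectations exact), and swings terminal pairs open with a
per-frame Bernoulli probability by rotating the strand-B residue 80° about
its glycosidic bond and displacing it 8 Å outward — enough to break every
pair contact while keeping base-frame construction well-defined. All
randomness flows from explicit seeds; regeneration is bit-identical.

What the generator deliberately does **not** emulate: water, periodic-image
effects, correlated ion dynamics, sequence-dependent groove widths, backbone
substates, or force-field physics of any kind. Closure tests therefore
demonstrate that the *measurement chain* is correct and unbiased under known
ground truth — they say nothing about force-field accuracy on real data, and
real trajectories additionally require the user to ensure whole-molecule
coordinates (for RDFs) and consistent topologies.

# Numerical choices and problem sizes

* RDF bin pitch 0.1 Å; smoothing 3-bin centred moving average; extremum
  prominence 5% of the first peak; flat-extremum ties break to the smallest
  radius.
* Shell-volume probes: Halton sequence, default 1e5 (1e6 in the
  point-solute oracle); fewer than 1e4 warns.
* Superposition: Kabsch with reflection guard; frame orthonormalisation by
  polar decomposition (SVD).
* Degenerate inputs: empty selections, overlapping ion/RNA selections,
  non-complementary strands, collinear fit selections, anti-aligned pair
  normals, monotone RDF profiles, zero-error NOE items and planar sugar
  rings all raise targeted errors (or flagged degenerate states) rather
  than returning numbers.
* Validation problem sizes: duplexes of 3–14 bp; trajectories of 10–500
  frames; ion samples of 10³–10⁴ for distribution recovery; 10⁶ probes for
  the volume oracle. These sizes give the stated statistical resolutions
  (e.g. 3σ binomial bands at 300–500 frames) while keeping the full suite
  in the minutes range on one CPU.

# Known limitations

* RDFs use non-imaged coordinates; a duplex broken across a periodic
  boundary must be made whole upstream.
* The global axis is straight; strongly bent duplexes (beyond the short
  A-form regime) would need a curved-axis analysis that is out of scope.
* Edge assignment uses majority voting over H-bonded atoms; exotic
  multi-edge pairs (bifurcated or water-mediated) and base triples are not
  classified.
* Crystal-structure validation requires the deposited PDB files; the
  package ships none, and `tests/testthat/test-acceptance.R` looks for them
  under `inst/extdata/crystal/`.
* Per-frame classification re-derives hydrogen bonds from scratch; for very
  long trajectories a future incremental path would be faster.
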