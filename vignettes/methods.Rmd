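---
title: "Methods: coarse-grained event-driven dynamics of amyloid-beta self-assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coarse-grained event-driven dynamics of amyloid-beta self-assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`abetadmd` simulates the self-assembly of amyloid-beta (A&beta;) peptides
with discrete molecular dynamics (DMD): all interactions are hard cores and
square wells, so particles move ballistically between instantaneous events
(collisions, well-edge crossings, bond-wall reflections) and the integrator
is exact between events. Four C-terminal isoforms are built in —
A&beta;1–38, A&beta;1–40, A&beta;1–42 and A&beta;1–43 — the shorter three
being N-terminal prefixes of the 43-residue sequence.

Each residue is represented by up to four beads: amide N, C&alpha;,
carbonyl C&prime;, and a single side-chain C&beta; (absent for glycine).
Local geometry is maintained by bonded square-well constraints: covalent
links (N–C&alpha; 1.46 &Aring;, C&alpha;–C&prime; 1.51 &Aring;,
C&prime;–N 1.33 &Aring;, C&alpha;–C&beta; 1.53 &Aring;) with ±2% widths and
next-neighbour pseudo-bonds at ideal-geometry distances (law of cosines on
canonical backbone angles) with ±2.5% widths. The pseudo-bonds fix bond
angles while leaving the φ/ψ-like backbone rotations free. All constants
live in one table, `ff_constants()`, so the geometry can be recalibrated in
one place.

Solvent is implicit and enters through hydropathy: C&beta; beads of the six
hydrophobic residues (Ile, Phe, Cys, Val, Ala, Met) attract, C&beta; beads
of hydrophilic residues (His, Gln, Asn uncharged; Arg, Lys, Asp, Glu
charged) repel, through a square well with a 7.5 &Aring; cutoff. The
anchor is the deepest attraction, Ile–Ile at −0.3 E~HB~; other pair depths
scale with the geometric mean of the Kyte–Doolittle values. Backbone
hydrogen bonds are multiatom square-well interactions between N and
C&prime; beads (depth 1 E~HB~, bonding window 4–5 &Aring;) whose formation
additionally requires the four flanking beads (C&alpha; and the adjacent
backbone bead of each partner) to sit within 3.5–7 &Aring; of the partner,
a distance-window surrogate for directionality. Effective electrostatics
are deliberately absent.

### Units

E~HB~ is the energy unit; simulated temperature is in E~HB~/k~B~ with
T = 0.13 corresponding to 310 K, hence E~HB~ ≈ 4.6 kcal/mol and the
hydropathic depth E~HP~ = 0.3 E~HB~ ≈ 1.4 kcal/mol. The bead mass is one
quarter of the alanine mass. One simulation time unit (tu) is the time to
travel the spatial resolution (0.1 &Aring;) at the 1D thermal rms speed of
the production temperature; `derive_time_unit()` gives ≈ 0.03 ps/tu, so a
4×10^7^ tu trajectory corresponds to 1.2 &mu;s. Internally the engine
integrates in reduced time t~0~ = &Aring;·&radic;(m/E~HB~); 1 tu =
0.277 t~0~. Coordinates are kept in &Aring;ngstr&ouml;m throughout and
converted only at file boundaries.

## Design choices in the engine

* **Steric exclusions.** Bead pairs within the same or adjacent residues
  are excluded from nonbonded interactions. With the chosen bead diameters
  (backbone 3.0 &Aring;, C&beta; 4.0 &Aring;) a hard core between, say,
  C&beta;~i~ and N~i+1~ (which can never exceed 3.71 &Aring; given the
  bonded geometry) would freeze every backbone dihedral; the local geometry
  of such pairs is already governed by the covalent and pseudo-bond
  network, so excluding them restores the intended "rigid local geometry,
  free backbone rotation" behaviour.
* **Event scheduling.** A binary min-heap keyed by (time, bead, partner)
  holds the earliest event of every interacting pair, scheduled from both
  sides; per-bead event counters invalidate stale entries lazily. A
  one-event-per-bead variant was tried and rejected: with lazy invalidation
  it can miss collisions (a bead whose stored event went stale is only
  rescheduled when the stale entry surfaces, possibly too late).
* **Neighbour search.** Cubic cells sized by the hard-core reach
  (≈4.2 &Aring;) with a 27-cell block for all pairs and a wider shell —
  chosen so that any pair outside it is beyond 7.5 &Aring; — scanned only
  for pairs that can engage a well or hydrogen bond. Cell-boundary
  crossings are themselves events; their times are computed in the cell's
  nearest periodic image, which matters immediately after a bead wraps
  across the box.
* **Thermostat.** Berendsen-style velocity rescaling,
  &lambda; = &radic;(1 + (&delta;t~c~/&tau;)(T~target~/T~kin~ − 1)),
  applied every &delta;t~c~ = 10^3^ tu with &tau; = 2×10^3^ tu and
  &lambda; clamped to [0.8, 1.25]. The coupling is deliberately stronger
  than a "gentle" Berendsen because hydrophobic collapse and hydrogen-bond
  formation release energy continuously; with &tau; = 10^4^ tu the kinetic
  temperature stalls near 0.27 instead of 0.13 during assembly.
* **Protocol.** Peptides start in a compact reference conformation
  (φ = −125°, ψ = −60°, chosen from a grid scan as a self-clearing, compact
  repeat) on a cubic lattice, oriented along the cell diagonal. A
  high-temperature stage (T = 4) with wells and hydrogen bonds switched off
  decorrelates the replicas; production then redraws Maxwell–Boltzmann
  velocities at T = 0.13 and runs under the thermostat. Replica r uses
  seed + r − 1; identical inputs replay bit-identically.
* **Conservation.** Between thermostat interventions total energy is
  conserved to ≈10^−18^ E~HB~ per event and momentum exactly; both are
  enforced by tests, as is agreement with an independent synchronous
  all-pairs oracle on small systems.

## Analysis pipeline

* **Oligomers.** Two peptides are linked when any inter-peptide bead pair
  is strictly closer than 5 &Aring; (minimum image); oligomers are
  connected components. Molar distributions count oligomers, mass-weighted
  distributions count peptides; both normalise to 1 per frame, and replica
  ensembles carry the standard error of the mean. The threshold is strict
  (<), whereas the residue contact criterion below is inclusive (≤ 0.5 nm);
  both conventions are preserved exactly as stated and tested.
* **Secondary structure.** The classifier is a documented surrogate for
  full-atom algorithms: φ/ψ pseudo-dihedrals on the bead backbone assign
  strand (extended band, runs ≥ 2) and helix (helical band, runs ≥ 4);
  turn requires both a turn-like dihedral pattern at residues i+1, i+2 and
  a C&alpha;~i~–C&alpha;~i+3~ contact below 7 &Aring;; the rest is coil.
  Thresholds live in one place (`.ss_rules()`). Amide H and carbonyl O
  positions, needed only for geometry checks, are reconstructed from the
  neighbouring beads (H at 1.0 &Aring; from N, O at 1.24 &Aring; from
  C&prime;, opposing the local bond bisector). Comparisons with published
  propensity curves are therefore qualitative; the classifier is validated
  on generated chains with known labels (strand recall ≥ 0.75 on interior
  residues, strand false positives ≤ 10% on random chains, planted turns
  recovered exactly).
* **Contact maps.** Residue centres of mass (equal bead masses) within
  0.5 nm define a contact; intramolecular maps exclude |i−j| ≤ 1 and are
  averaged per peptide conformation, intermolecular maps per ordered
  peptide pair within an oligomer. Difference maps align on the shared
  residue range and report the C-terminal overhang separately.
* **SASA.** Shrake–Rupley-style sphere sampling with a 1.4 &Aring; probe,
  960 deterministic Fibonacci-lattice points per bead, hard-core radii as
  van der Waals radii, restricted to beads of hydrophobic residues with all
  beads occluding. The point lattice is oriented in a canonical body frame
  (covariance eigenvectors with a third-moment sign convention), making the
  measurement invariant under rigid motions to floating-point precision —
  a property no space-fixed point set has. Coincident identical spheres
  are counted once (lower-index tie-break).
* **Free-energy landscapes.** W = W~0~ − ln P over 2D histograms of
  hydrophobic SASA (default 50 &Aring;² bins) and N–C distance (2 &Aring;
  bins), with W~0~ = −ln(N+1). The offset makes the absolute level depend
  on the sample count by construction; only differences of W are
  meaningful, and the package preserves the convention verbatim.
  Unoccupied bins are NA sentinels, never infinities. The
  per-oligomer-average mode pools the coordinates over the peptides of each
  oligomer before binning.
* **Shape scaling.** Principal moments of inertia I~1~ ≥ I~2~ ≥ I~3~
  (equal bead masses, normalised by the monomer mass) are fitted as
  log I~i~ vs log n on configurable order ranges (defaults 4–10 for
  I~1~, I~2~ and 1–6 for I~3~); the derived exponents are the elongation
  &alpha; = (a~1~+a~2~)/4 − 1/2, thickness &beta; = a~3~/2 − 1/2 and volume
  &gamma; = (a~1~+a~2~)/4 + a~3~ − 3/2. Rod ensembles must return
  &alpha; = 1, &beta; = 0, &gamma; = 1 and compact spheres
  &alpha; = &beta; = 1/3, &gamma; = 1; both closed forms are enforced in
  the test suite via the synthetic generators.

## What the synthetic generators emulate

`make_partition_frame()` realises an exact planted clustering under the
5 &Aring; criterion (bridge beads guarantee the linkage distance);
`make_shape_ensemble()` samples uniform solids (spheres, rods, ellipsoids,
dumbbells) whose analytic moments follow exact power laws;
`make_ss_chain()` builds ideal-dihedral chains with per-residue truth
labels; `make_mock_trajectory()` interpolates a monotone merging schedule.
They share the engine's frame format, so the analysis stack has a single
input path. They do **not** emulate realistic energetics, solvent
correlations, or the conformational heterogeneity of real trajectories:
passing these tests shows the analysis operators are correct, not that the
force field reproduces experiment.

## Problem sizes used by tests and the acceptance script

Full-scale production (32 peptides × 4×10^7^ tu × 32 replicas × 4
isoforms) is a cluster-scale computation: at this model's constraint
widths it amounts to ~10^13^ events. The packaged checks therefore run the
same physics at reduced scale, which is stated here once as the package's
own choice of problem sizes:

* the self-assembly check uses 8 A&beta;1–42 peptides in a 15.7 nm box
  (the same concentration as 32 peptides in 25 nm), 5×10^2^ tu of
  decorrelation and 6×10^3^ tu of production (~3×10^7^ events). At this
  scale the hydrophobic collapse is already visible: intrapeptide collapse
  and hydrogen-bond saturation within ~10^3^ tu, first dimers from
  ~10^3^–4×10^3^ tu, decreasing hydrophobic SASA, and a mass-weighted mean
  oligomer size above one;
* conservation checks accumulate ≥10^6^ events on dense 12-bead systems;
* the Boltzmann occupancy check samples an isolated pair over 800
  segments of 50 t~0~ with a Maxwell–Boltzmann velocity redraw before
  each (the redraws make the invariant measure canonical, which a
  deterministic two-body trajectory is not, and frequent redraws keep the
  radial energy well mixed);
* scaling-exponent checks use 10 orders × 8 replicate clouds of 120 beads
  per order unit.

## Known limitations

* The bonded geometry (bond widths, pseudo-bond set) and the hydrogen-bond
  window are surrogates for the original four-bead parameterisation, which
  is not tabulated here; all values are centralised for recalibration.
* The secondary-structure surrogate is not a reimplementation of any
  full-atom algorithm; per-residue propensities should be compared to
  published curves only qualitatively.
* Berendsen rescaling does not generate a canonical ensemble; equilibrium
  statistics in the tests are sampled with velocity redraws instead.
* At desk scale the oligomer size distributions have not converged to
  their quasi-steady-state shapes; the package validates the pipeline and
  the qualitative collapse, not the full-scale distributions.
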