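---
title: "Methods: conformational-transition analysis with confshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformational-transition analysis with confshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confshift)
```

`confshift` analyses how a multi-domain protein moves between a compact,
ring-like conformation and extended open conformations, and what that does
to the solvent exposure, flexibility and mutual distances of candidate
epitope regions. This vignette documents the models and procedures, the
parameters that matter, the synthetic-data generator that supplies ground
truth, and the numerical and design choices that were genuinely open.

## Units and conventions

All internal coordinates are nanometres; PDB I/O converts from and to
Angstrom. A single unit everywhere prevents cutoff mistakes — the contact
cutoff (0.24 nm), probe radius (0.14 nm) and restraint walls (0.15/0.4 nm)
are all natively nm quantities. Residue numbering is 1-based mature-protein
numbering and region spans are inclusive on both ends, so `"39-43"` means
the five residues 39..43. Time is carried as a frame interval in ps
(default 100 ps, a common coordinate-saving interval). Atomic radii come
from one documented table (`element_radii()`: C 0.170, N 0.155, O 0.152,
S 0.180, H 0.120 nm); hydrogens are kept explicit when the input has them,
never merged into heavy atoms. Blank chain identifiers are treated as a
single chain "A".

## Superposition and shape metrics

Rigid-body superposition uses the Kabsch SVD solution with the standard
reflection fix: when the cross-covariance determinant is negative, the sign
of the smallest singular vector is flipped, so returned rotations always
have determinant +1. Collinear point sets are rejected as degenerate
because the rotation about the line is then undetermined. The default
selection for all shape metrics is Cα atoms (`selection = "calpha"`), with
`"all"` available; on the coarse-grained bead models every bead is a Cα.
Pairwise frame-to-frame RMSD matrices superpose every frame on every other
frame; this and the SASA kernel are the two compiled (C++) code paths,
everything else is plain R.

## Path similarity

Two trajectories are compared as sets of conformations under the Hausdorff
distance, with the superposed Cα RMSD as the frame metric. The directed
form `max_p min_q d(p, q)` is exposed (`directed_hausdorff()`), but the
symmetric form `max(directed(P|Q), directed(Q|P))` is the default and is
what `psa_matrix()` tabulates: the symmetric form is a pseudometric
(symmetry, zero self-distance, triangle inequality — all property-tested),
which makes all-vs-all matrices interpretable. The method used is recorded
in the matrix's `method` attribute. When group labels are supplied, the
mean off-diagonal distance within each group is attached so that, e.g.,
wild-type and clipped repeat families can be compared on a common scale;
group means increase monotonically with the generator's noise level.

## Conformational landscape

`fit_landscape()` combines all repeats into one frame stack so that a
single set of principal components describes every trajectory. Frames are
superposed to an iteratively refined mean (align to frame 1, then twice to
the current mean) — the reference is otherwise arbitrary, and the iterative
mean is the least arbitrary choice. The 3N-coordinate covariance is
eigen-decomposed through an SVD of the centred frame matrix, which
transparently handles both the frames > 3N and frames < 3N regimes and
yields identical results to the explicit dual solution by construction.
Eigenvector signs are fixed (largest-magnitude loading positive) so results
are reproducible run to run.

Frames are clustered with average-linkage agglomerative clustering on
Euclidean distance in the first `n_pc = 4` components (unscaled — standard
for coordinate PCA, where component variances are physically meaningful),
cut to `k = 5` groups. `k` is exposed, never auto-selected; cluster labels
are renumbered in order of first appearance so that cluster 1 is always the
state containing the first frame (the starting, closed shape), which is
also the default reference state for delta tables. Population tables are
emitted in both normalisations: share of each cluster by group (rows sum to
100%) and composition of each group across clusters (columns sum to 100%).

Local point density in PC1/PC2 is a Gaussian product-kernel estimate with
Scott's-rule bandwidths, normalised to a maximum of 1; bandwidth and
normalisation are artifact choices recorded in the output metadata. The
representative ("mid-point") frame of a cluster is the member closest to
the cluster centroid in PC space, ties broken toward the lower frame index.

Convergence analysis runs K-means (10 restarts, fixed seed) on the combined
projections and slides a 10-frame window along each repeat: the convergence
frame is the start of the earliest window after which every window's
majority cluster equals the final window's majority. Frames are 1-based, so
a repeat that never changes state converges at frame 1. Earlier convergence
operationalises "reaches its final conformation faster".

## Exposure

SASA uses the Shrake–Rupley construction: `n_points = 960` test points on a
deterministic golden-spiral sphere at radius r + probe around every atom; a
point is accessible if outside every neighbour's expanded sphere, and the
neighbour search is restricted to atoms within `r_i + r_j + 2*probe`. The
closed form for an isolated atom, a Monte-Carlo point-sampling oracle for
overlapping spheres, and point-refinement stability are all tested. Two
numerical notes: doubling the sphere resolution changes totals by < 0.5%,
and rigid rotations reproduce totals to ~0.2% at 960 points (the residual
is test-point anisotropy; at 3840 points it falls under 0.1%).

`delta_table()` is the central epitope-exposure computation: for each
group, state and region it reports the mean metric, its SEM, and the
percent difference from the group's reference state,
`100 (m_state − m_ref)/m_ref`, with the SEM of the ratio propagated in
quadrature. Cross-group rows (same state, second group vs the first, first
group's mean as denominator) are appended when two groups are present. The
plain SEM treats frames as independent samples; because consecutive MD
frames are autocorrelated, a block-averaged SEM (`block` argument) is
available and more honest for real trajectories. The same machinery accepts
any per-frame per-region metric, which is how inter-region distance deltas
are produced.

The SASA computation runs over whatever atoms the input contains (e.g.
including glycans if present); the choice is recorded in the run manifest.

## Dynamics

Windowed RMSF splits a trajectory into consecutive non-overlapping windows
(default 25 frames, so a 150-frame trajectory gives six fragments), drops a
trailing partial window, and superposes each window to its own mean before
computing `RMSF_i = sqrt(mean |r_i(t) − <r_i>|²)` — per-window alignment
measures local flexibility rather than drift. The percent difference of
each later window against window 1 is the stabilisation readout: negative
values mean a region has become more rigid over time.

The DCCM uses the isotropic scalar-product convention,
`C_ij = <Δr_i·Δr_j>/sqrt(<|Δr_i|²><|Δr_j|²>)`, after superposing the whole
trajectory to its mean. Residues with zero variance are reported as NA
(masked), never as 0, since "no motion" and "uncorrelated motion" are
different findings. Contact probability counts a frame as "in contact" when
any inter-region atom pair is strictly below the cutoff (default 0.24 nm);
the frame counts once however many pairs touch, while the residue-pair map
preserves per-pair multiplicity. For inter-region distances both centroid
and minimum-atom modes exist because published figures rarely say which was
used; the mode is recorded in the output.

## Interface scanning

`generate_orientations()` builds the pose grid for a two-domain affinity
scan: `n_axial = 3` anchor points evenly spaced along the target's main
axis times `n_angles = 8` rotations evenly spaced over 360°, 24 poses by
default. The "main axis" is defined as the principal inertia axis of the
target selection (`principal_axis()`), since no sharper definition is
standard. Angle 0 reproduces the input orientation translated to the axial
point, and every pose preserves internal geometry exactly. Contact maps per
pose feed `rank_contact_specificity()`: specificity of a residue pair =
largest single-pose frequency / total frequency across poses, so a pair
seen in exactly one pose scores 1 and a pair seen equally in all n poses
scores 1/n; total frequency breaks ties. The specificity score is this
package's construction — the notion "most specific interaction" is used in
the field without a formula.

The flat-bottom ring-closure restraint is zero between the walls and
half-harmonic outside, `E = ½k(Δd)²`, with defaults k = 1000 kJ/mol/nm²
and walls at 0.15/0.4 nm. The ½k prefactor is a convention choice (biasing
packages are split between ½k and k); it is documented here and in the
function so users matching the other convention can double `k`. The
returned force `−dE/dd` is continuous and zero at both walls.

## Motif scanning

Residues are classified nonpolar (ϕ) = {A,V,L,I,M,F,W,C,G,P} or polar (ζ)
= {S,T,N,Q,Y,H,K,R,D,E}; only F and C are fixed by the motif definitions
themselves (both nonpolar), the remainder follows the common hydropathy
partition and is overridable. `scan_motif()` matches a pattern over
{ϕ, ζ, x, literal letter} at every offset, forward and in reverse (the
reversed pattern read high-to-low, since surface motifs can present in
either chain direction), counting one mismatch per failed position.

The epitope family reproduction (`scan_epitope_motifs()`) needs more care,
because the published family (ϕϕϕζζFxϕ, ϕϕϕζζFxC, simplified ϕϕϕζζϕxϕ) is
loose: an exhaustive scan of the simplified pattern alone finds more exact
matches than any published motif table lists. The recipe adopted here is:
scan the literal-anchored members (ϕϕϕζζFxϕ, ϕϕϕζζFxC in both directions,
and the C-terminally anchored relative ϕϕϕζζϕxC forward-only, its single
anchor being terminal); treat the literal F/C anchors as hard constraints;
allow up to 3 mismatches on class positions; and keep one best match per
anchor residue (fewest mismatches, doubly anchored beating singly anchored
on ties). The scan region defaults to domain I plus the DI–DII interlinker
(residues 1–72), the segment whose exposure the O→J transition controls.
On the bundled β2GPI sequence this yields five loci — 10–17 (reverse, 0
mismatches), 16–23 (forward, 1), 40–47 (forward, 0), 53–60 (forward, 0)
and 65–72 (reverse, 3) — reported with their mismatch counts. Note that
motif tables in the literature print one of these intervals as "16–24",
nine residues against an eight-symbol motif; the scanner reports the
8-mer 16–23. A flat tolerance of 2 mismatches against the simplified
pattern alone was evaluated and rejected: it cannot reach the 65–72
relative (3 class mismatches from every family member) while already
admitting loci no table lists.

```{r motif}
fa <- system.file("extdata", "b2gpi_di_dii.fasta", package = "confshift")
scan_epitope_motifs(read_fasta_sequence(fa))
```

The bundled sequence is the mature β2GPI chain, residues 1–120 (UniProt
P02749 numbering of the mature protein). The motif reproduction is confined
to residues 1–72, where every anchor residue is corroborated by
independently known landmarks (K19, K33, R39, M42, R43, T50, N56, R63,
F67).

## The synthetic-data generator

Because real opening trajectories of this protein are not redistributable,
the generator supplies trajectories whose every property is planted:

* **Anchors**: ring (closed "O"-like; consecutive-bead chord exactly equal
  to the 0.38 nm Cα–Cα bond, first and last bead one bond apart), hook
  (a straight stem flowing into a semicircular arc — "J"-like) and extended
  ("S"-stand-in) shapes, all with exact bond lengths. For exposure studies,
  `make_shielded_anchor()` lifts the last few beads out of the chain and
  parks them 0.45 nm above a target segment — a shield that buries the
  target the way a blocking domain buries an epitope, in *every* anchor
  shape, so exposure is controlled purely by the planted displacement and
  not conflated with the shape change itself.
* **Schedules**: ordered dwell/interpolation segments. Dwell frames are
  anchor + isotropic Gaussian noise; transition frames linearly blend the
  flanking anchors (the simplest transition model that still produces a
  distinct transition cluster). Default noise is σ = 0.03 nm per
  coordinate, a realistic thermal-fluctuation scale for a coarse-grained
  bead; the recovery guarantees are stated (and tested) up to σ = 0.05 nm
  with anchors ≥ 1 nm RMSD apart.
* **Planted exposure change**: from a switch frame on, the shield is
  rigidly translated away from the target centroid; target coordinates are
  untouched, so any SASA or distance change is attributable to the shield.
  The shield's influence saturates once its gap exceeds
  `r_i + r_j + 2*probe` (0.66 nm for 0.19 nm beads), so
  displacement-monotonicity of the exposure delta holds within, and only
  within, that range.
* **Planted correlated motion**: a shared zero-mean scalar drive along a
  fixed random direction added to bead i and ±drive to bead j; with drive
  amplitude well above the noise the DCCM recovers the pair at |C| > 0.9
  with the planted sign.
* **Determinism**: one RNG stream per trajectory derived from the seed; the
  caller's RNG state is always restored. Identical (spec, seed) pairs are
  bit-identical.

What the generator does **not** emulate: physics. There are no forces, no
thermostat, no solvent, no autocorrelated noise (frames are independent
draws around the anchors), no glycans, and linear interpolation is not a
transition path ensemble. Passing tests on synthetic data therefore
demonstrate that the *analysis chain* recovers planted signals at realistic
noise; they do not validate force fields or sampling of real MD data.

## The demo conditions

`run_demo()` generates two groups × 5 repeats × 300 frames of a 40-bead
chain (problem sizes chosen so the whole pipeline — including ~3000 SASA
frames and ten 300×300 superposed-RMSD grids — completes in about a
minute on one CPU): a wt-like group dwelling in the ring state for two
thirds of the run before moving through the hook to the extended state, and
a clipped-like group that leaves the ring after one third and stays in the
hook state. The shield displacement is 0.12 nm (partial lift) in wt-like
and 1.5 nm (complete departure) in clipped-like; one anticorrelated bead
pair (5, 30) is planted. The demo uses k = 4 states (ring, transition,
hook, extended) and 240 SASA points — bead-model SASA converges much faster
than atomic SASA, and the demo's conclusions are unchanged at 960 points.

## Known limitations

* The pipeline analyses whatever atoms it is given; there is no glycan
  typing, no mmCIF, and no topology-file (PSF/PRMTOP) support.
* SEM over frames understates uncertainty on autocorrelated real MD data;
  use the block-SEM option there.
* The transition-state cluster of linearly interpolated synthetic data can
  transiently *compact* the chain (the blend of two extended shapes is not
  itself a plausible conformation), which shows up as negative exposure
  deltas for that cluster; interpret transition-cluster deltas on synthetic
  data accordingly.
* The epitope-motif reproduction recipe is an interpretation (documented
  above) of a loosely specified published family; changing the alphabet or
  tolerance changes the locus list, and the function reports mismatch
  counts so users can apply their own stringency.
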