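# confshift

Trajectory analysis for proteins that change shape. `confshift` implements
the full analysis chain used to study how a compact, ring-like ("O"-shaped)
multi-domain protein such as beta-2-glycoprotein I opens into extended
hook-("J"-) and sigmoid-("S"-) shaped conformations, and how that
transition exposes a cryptic, discontinuous antibody epitope. It is aimed
at structural bioinformaticians who have repeat MD trajectories (or want
synthetic stand-ins with planted ground truth) and need the downstream
statistics, not the MD engine itself.

## What it computes

* **Path similarity** between repeat trajectories via the Hausdorff
  distance, `δ_H(P,Q) = max( max_p min_q d(p,q), max_q min_p d(p,q) )`,
  with `d` the Kabsch-superposed Cα RMSD between frames — higher values
  mean more dissimilar paths (`hausdorff()`, `psa_matrix()`).
* **Conformational landscape**: coordinate PCA on a combined trajectory,
  agglomerative ("average"-linkage) clustering of frames in the first 4
  principal components into k = 5 states, cluster populations by group,
  local point density, representative mid-point frames, and a rolling
  10-frame K-means convergence analysis (`fit_landscape()`,
  `cluster_frames()`, `convergence_analysis()`).
* **Exposure**: per-residue Shrake–Rupley SASA (probe 0.14 nm, 960
  deterministic golden-spiral test points) over every frame, aggregated to
  named regions, and per-region/per-state percent-difference tables with
  SEMs propagated in quadrature — mean_state vs the reference (closed)
  state (`shrake_rupley()`, `sasa_series()`, `delta_table()`).
* **Dynamics**: windowed RMSF (25-frame fragments by default), dynamic
  cross-correlation matrices `C_ij = <Δr_i·Δr_j> / √(<|Δr_i|²><|Δr_j|²>)`,
  inter-region distances, and contact probabilities with the 0.24 nm
  close-contact cutoff (`windowed_rmsf()`, `dccm()`,
  `contact_probability()`).
* **Interface scanning**: rigid-body pose grids (3 axial positions × 8
  angles = 24 orientations by default), contact-specificity ranking of
  residue pairs across poses, and the flat-bottom restraint
  `E = ½k(Δd)²` outside walls at 0.15/0.4 nm with k = 1000 kJ/mol/nm²
  (`generate_orientations()`, `flat_bottom_energy()`).
* **Motif scanning**: polar/nonpolar classification and bidirectional,
  mismatch-tolerant scanning for the amphipathic epitope family
  ϕϕϕζζFxϕ / ϕϕϕζζFxC / ϕϕϕζζϕxϕ (`scan_motif()`,
  `scan_epitope_motifs()`).
* **Synthetic trajectories with planted truth**: anchor conformations
  (ring / hook / extended, plus shield-capped variants), dwell/transition
  schedules, Gaussian coordinate noise, planted exposure changes and
  planted correlated motions (`make_anchor()`, `generate_trajectory()`,
  `plant_exposure_change()`, `plant_correlated_motion()`).

Structures are read from PDB (multi-model PDB natively, DCD through an
adapter), regions from YAML, sequences from FASTA. All internal coordinates
are nanometres; residue numbering is 1-based and inclusive.

## Worked example

```r
library(confshift)
man <- run_demo(seed = 1)
```

The demo generates two groups of five synthetic repeats of a 40-bead chain
(a "wt-like" group that dwells long in the ring state and ends extended,
and a "clipped-like" group that leaves the ring early and settles in the
hook state), plants a shield-displacement exposure change (0.12 nm lift in
wt-like, complete 1.5 nm departure in clipped-like) plus one
anticorrelated bead pair, and runs every stage. It prints:

```
[confshift]   mean convergence frame: wt_like 272.0, clipped_like 85.0
[confshift]   target-region exposure deltas vs reference state:
              wt_like/2 -42.5%; wt_like/3 +11.9%; wt_like/4 +13.1%;
              clipped_like/2 -31.3%; clipped_like/3 +30.3%
```

Reading: the clipped-like repeats settle into their final conformational
state at frame 85 on average versus 272 for wt-like (the planted early
transition); the planted target region gains +11.9% SASA in the open
(hook) state of the wt-like group and +30.3% in the clipped-like group
relative to each group's closed state — positive in both, larger where the
shield was displaced further. Cluster 2 is the transition state, where the
linear blend transiently compacts the chain. All stage tables (PSA matrix,
projections, populations, convergence, SASA and distance deltas, RMSF,
DCCM) are written as TSV/JSON twins under the run's output directory,
listed in `manifest.json`.

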