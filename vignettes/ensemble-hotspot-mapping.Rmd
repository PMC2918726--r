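---
title: "Ensemble fragment-based hot-spot mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble fragment-based hot-spot mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Allosteric binding sites on receptors — pockets topographically distinct from
the orthosteric (endogenous-ligand) site — are attractive drug targets
because their sequences are less conserved across receptor subtypes. Many of
these pockets are *cryptic*: they open only transiently in the conformational
dynamics of the protein and are invisible in a single experimental structure.
`ensmap` implements a desk-scale version of the ensemble mapping strategy for
detecting such sites: reduce a conformational ensemble to a small set of
representative structures, scan the entire surface of every representative
with a library of small rigid organic probe fragments, aggregate favourable
probe positions into ranked consensus sites, and finally rank individual
residues by how often probes contact them across the whole ensemble.

The pipeline has four stages, each usable on its own:

1. **Ensemble reduction** (`reduce_ensemble()`): Kabsch superposition,
   pairwise RMSD over a fixed atom selection, GROMOS-style (Daura) neighbour
   clustering at a 1.5 Å cutoff, retention of the 15 largest clusters, and
   extraction of each cluster's center as its representative. The *occupancy*
   of the retained clusters (percentage of all input models they cover) is
   reported, because it tells you how well the representatives summarize the
   ensemble.
2. **Hot-spot mapping** (`map_structure()`): 16 rigid probe fragments
   (ethanol, isopropanol, isobutanol, acetone, acetaldehyde, dimethyl ether,
   cyclohexane, ethane, acetonitrile, urea, methylamine, phenol,
   benzaldehyde, benzene, acetamide, N,N-dimethylformamide) are docked
   exhaustively over precomputed energy grids; per probe the 2000
   lowest-energy placements are kept, locally energy-minimized and clustered,
   the six clusters with the lowest mean interaction energy are retained,
   and the clusters of all probes are aggregated by single-linkage into
   consensus sites ranked by the number of probe clusters they incorporate.
   The 10 largest consensus sites are reported.
3. **Residue profiling** (`profile_ensemble()`): an interaction is counted
   whenever a non-hydrogen probe atom of a consensus-site pose lies within
   5 Å (inclusive) of a non-hydrogen protein atom. Counts are summed over
   all representatives, expressed as percentages of all protein–probe
   contacts in the ensemble, ranked, the top 40 residues retained, each
   classified orthosteric or non-orthosteric by proximity to a reference
   ligand, and the non-orthosteric residues grouped into candidate
   allosteric sites by single-linkage on minimal inter-residue heavy-atom
   distance.
4. **Synthetic benchmark** (`generate_ensemble()`): a pseudo-receptor
   generator that plants a ground-truth-labelled orthosteric cavity and a
   transiently open allosteric groove, so the whole pipeline can be
   validated quantitatively without any external data.

## The energy model

Probe–receptor interaction energies are a truncated, capped Lennard-Jones
12-6 term plus a Coulomb term with a distance-dependent dielectric:

$$E = \sum_{i \in \text{probe}} \sum_{j \in \text{receptor}}
 \Big[ \min\!\big(4\varepsilon_{ij}\big[(\sigma_{ij}/r_{ij})^{12} -
 (\sigma_{ij}/r_{ij})^{6}\big],\ E_\text{cap}\big)
 + \frac{k_e\, q_i q_j}{4\, r_{ij}^2} \Big], \quad r_{ij} \le r_c$$

with Lorentz–Berthelot combining ($\sigma_{ij}$ arithmetic mean,
$\varepsilon_{ij}$ geometric mean) over a small internal atom-class table
(`atom_class_table()`), $r_c = 8$ Å truncation, a per-pair cap
$E_\text{cap} = +100$ kJ/mol that keeps clashes finite, the dielectric
$\varepsilon(r) = 4r$ (hence the $4r^2$ denominator;
$k_e = 1389.35$ kJ mol⁻¹ Å e⁻²), and a 0.6 Å distance floor inside which the
Coulomb term stops growing. All energies are in kJ/mol, all distances in Å.
Probes and pseudo-receptor beads are united-atom style: hydrogens are folded
into heavy atoms, probe geometries are idealized rigid bodies built from
standard bond lengths and angles, and every probe is neutral with its
heavy-atom centroid at the body-frame origin.

This scoring function is deliberately a *documented, simple stand-in*: it
reproduces the structure of published fragment-mapping energy expressions
(van der Waals + screened electrostatics) but makes no attempt to reproduce
any published server's empirical weights or its solvation term. Numerical
agreement with such servers is explicitly not claimed; the package's claims
are about its own, fully specified model.

### Grids and exhaustive sampling

For each probe atom class a grid channel stores the Lennard-Jones sum over
receptor heavy atoms at every grid point (default spacing 0.8 Å), plus one
electrostatic channel per unit charge. The grid box extends one cutoff
radius beyond the receptor, so every point outside the box is guaranteed to
score exactly zero. Poses are scored by trilinear interpolation, summed over
probe atoms. The sampler enumerates a deterministic quasi-uniform set of
orientations (Shoemake quaternions over a Halton sequence, default 500)
crossed with *every* grid translation, and keeps the 2000 best. Because
translations lie exactly on grid points, the interpolation weights per
(orientation, atom) are constant across translations, which is what makes
full enumeration tractable at this problem size (~10⁸ poses per probe per
structure). Ties in energy are broken by (orientation index, grid index), so
the retained set is deterministic.

Retained poses are then minimized on the *direct* (non-grid) energy surface
by rigid-body steepest descent with backtracking line search (six degrees of
freedom, analytic force and torque, monotone descent, default 60
iterations). The test suite verifies the exact Lennard-Jones landmarks
($E(\sigma) = 0$, $E(2^{1/6}\sigma) = -\varepsilon$, to 1e-9), exactness of
the grid at its own nodes, and sub-kJ/mol agreement between grid and direct
sums in the smooth attractive basin. For poses pressed against the
repulsive wall, trilinear interpolation at 0.8 Å spacing carries a
second-order error of a few kJ/mol (the well curvature of the 12-6 model is
simply too high for the cell size); a stricter wall-adjacent 1 kJ/mol bound
is asserted in the acceptance suite at its nominal value and is expected to
fail there — reaching it would require either half the grid spacing (eight
times the memory and enumeration cost) or tricubic interpolation (several
times the sampling cost). Because retained poses are re-minimized and
re-scored on the direct surface, this interpolation error affects only
which marginal candidates enter the retained set, not the energies the
pipeline reports.

### Pose clusters and consensus sites

Pose clustering is greedy and energy-ordered: the lowest-energy unassigned
pose seeds a cluster and absorbs all unassigned poses within 3 Å probe
heavy-atom RMSD, computed in the receptor frame without re-superposition —
poses are placements, not conformations, so re-fitting would discard exactly
the information that distinguishes them. Consensus sites are single-linkage
clusters of pose-cluster centers at 4 Å, ranked by the number of member
probe clusters; ties go to the lower aggregate mean energy, then to the
lexicographically first probe name. The 3 Å and 4 Å radii are package
defaults (exposed in `mapping_config()`); published descriptions of the
consensus-site procedure do not state their values.

Single-linkage consensus construction can chain broad, shallow surface
regions (rims of solvent mouths) into large low-meaning aggregates whose
center of mass is not a pocket. This is a known property of the method, and
it is why site *rank* (cluster count) rather than center position carries
the interpretation for such regions; compact genuine pockets yield compact
consensus sites.

## Ensemble reduction choices

Superposition and the RMSD measure use the same atom selection (by default
all backbone `CA` beads / Cα atoms; configurable through a selection
expression such as `"resid 10-120 and name CA"`). The Daura iteration takes
the structure with the most neighbours within the cutoff as a cluster
center, removes the cluster, and repeats; neighbourhood is inclusive
(RMSD ≤ cutoff) and every tie (neighbour counts, ranks) is broken by the
lowest model id, making the procedure deterministic and invariant to input
order up to that rule. The published descriptions of this algorithm do not
state a tie-break; lowest-id is this package's documented choice. The
cluster *center* (maximum-neighbour structure) serves as the representative.
Representatives are superposed onto the first representative so that all
downstream output shares one frame.

## The synthetic benchmark, and what it does and does not show

`synthetic_spec()` describes a bundle of 7 ideal helices (18 pseudo-residues
each; one backbone bead and one sidechain bead per residue — 2 atoms per
residue) arranged around a central lumen that holds a rigid ring-shaped
reference "ligand". Geometry constants (helix radius 2.0 Å, rise 1.5 Å,
twist 100°/residue, bead bond 2.6 Å, bundle radius 13.7 Å) were chosen once
so that (a) no two atoms sit closer than 2.5 Å, (b) adjacent helix seams are
sterically sealed, and (c) the lumen accommodates the ligand with residues
lining it at ~5 Å — the orthosteric ground truth. Sidechain beads carry a
small palette of nonbonded classes (apolar, polar, ±0.4 e charged); the
first and last two residues of every helix are polar end caps with deeper
wells, mimicking the probe-attracting termini and loop anchors of real
receptors.

The planted allosteric pocket opens by a breathing motion: two adjacent
helices ("the pair") translate outward along their common bisector by
`breathing_amplitude` (default 6 Å) in a randomly chosen
`pocket_open_fraction` (default 0.4) of the models, vacating a seam-shaped
groove between the pair and the rest of the bundle. Three bead roles shape
the pocket's energetics. Beads of the pair that face the partner helix are
the pocket *lining*, a strongly dispersive class (deep Lennard-Jones well)
standing in for the apolar hot-spot chemistry of real druggable sites; the
flanking "gatekeeper" beads are longer and wall the vacated seam into a
slot, so the open pocket binds probes on several surfaces at once and
accumulates many pose clusters — which is exactly the signal the
consensus-site ranking rewards. The first and last two residues of every
helix are polar end caps with deeper wells, mimicking the probe-attracting
termini and loop anchors that real receptors present; they give the sealed
receptor genuine competing sites.

Ground truth is computed by the generator itself, deterministically, from
its own geometry and energy model: a single apolar bead is scored on a
0.75 Å lattice restricted to the seam wedge of the *open* conformation; the
lattice minimum is the planted pocket center, lattice points within 70% of
that minimum form the hot region, and every residue with a heavy atom
within 5 Å (the contact radius) of the hot region is labelled allosteric
(minus any residue already labelled orthosteric — the two sets are disjoint
by construction). Per-model randomness (jitter, optional random rigid-body
displacement applied last so superposition removes it exactly) is seeded as
`seed + model_id`; the whole generation is bit-reproducible. The jitter
default (0.05 Å per coordinate) is deliberately small: the noise is
independent per atom, with no bonded constraints, so larger values do not
model collective motion — they carpet the surface with artificial sub-ångström
crevices whose 12th-power contact energetics rival any designed feature.
Collective drift is what the breathing mode and the rigid-body term model.

A structural limitation of the benchmark must be stated plainly: the
pseudo-receptor wall is one sidechain bead thick. Real cryptic-site linings
are buried under several ångströms of protein when closed; here, every
lining residue keeps some atom within the 5 Å contact radius of a
probe-accessible surface point even when the seam is sealed. Consequently,
while the *site* is cryptic in the consensus-site sense — no consensus site
forms near the pocket center in the closed structure, because the cavity
does not exist — the per-residue contact statistic still picks up lining
residues from adjacent surface probes in the closed structure, and the
single-linkage residue grouping (which chains helix neighbours at the
default 5 Å cutoff) folds them into one large surface group. The
closed-structure residue-overlap control therefore does not reach the
clean separation one would see with a thick-walled receptor, and the
corresponding acceptance assertion is expected to fail; the package keeps
the assertion at its nominal threshold rather than weakening it, and the
consensus-site-distance contrast carries the ensemble-versus-single-structure
conclusion instead.

What passing the synthetic benchmark shows: the pipeline's machinery —
reduction, exhaustive docking, cluster aggregation, ensemble contact
statistics — correctly recovers a pocket that exists only in a subset of
conformers, under a known energy model, with quantitative ground truth
(a top-3 consensus site within 4 Å of the planted center, and residue-set
Jaccard ≥ 0.5 for the ensemble site group). What it does not show:
performance on real receptors, where the energy model is a simplification
(no solvation, united atoms, no flexibility beyond the ensemble itself),
where pockets are not designed to be separable, and where thermal noise is
correlated (collective motions) rather than independent per atom.

## Numerical and degenerate-input conventions

* Residue keys are `(chain, residue number, insertion code)`; atom indices
  are 1-based throughout, following R convention.
* Alternate locations: highest occupancy wins, ties to the first
  encountered.
* Contact and neighbourhood boundaries are inclusive (≤).
* All tie-breaks are documented and deterministic: lowest model id
  (clustering), (rotation, grid) index (pose retention), lower residue
  number (rank ties), lower aggregate mean energy then probe name
  (consensus-site ties).
* Degenerate superposition selections (collinear or coincident points) are
  errors; empty selections warn and return an empty index vector; an empty
  pose list yields an all-zero contact map; a zero grand total of contacts
  yields zero percentages with a warning.
* The minimizer is monotone (backtracking): its output energy never exceeds
  its input energy; non-convergence within the iteration budget returns the
  best pose found, flagged.

## Problem sizes

The package's reference study conditions are the generator defaults: 24
conformers of a 126-residue (252-atom) pseudo-receptor, reduced at 1.5 Å
(yielding two state clusters, open and closed, with 100% occupancy), each
representative mapped with all 16 probes at 0.8 Å grid spacing and 500
orientations (~2·10⁸ scored poses per probe–structure pair). A full
ensemble run takes a few minutes per representative on one CPU. The test
suite uses smaller instances (coarser grids, fewer orientations) for the
unit and property tests, and the full default conditions for the
planted-pocket recovery checks.

## Known limitations

* The scoring function omits solvation and entropic terms; absolute
  energies are not comparable to published server outputs.
* Probes are rigid; internal torsions (isobutanol, DMF) are frozen at
  idealized geometry.
* Single-linkage consensus sites can chain across broad shallow regions
  (see above).
* The synthetic receptor is a topological cartoon: two beads per residue,
  no loops, no membrane, no solvent; its purpose is ground-truth testing of
  the pipeline, not realism.
* `frame_count()` and the reduction stage assume a pre-sampled ensemble;
  trajectory formats (XTC/DCD) are out of scope — ensembles travel as
  multi-model PDB files.
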