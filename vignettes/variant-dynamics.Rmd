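---
title: "Consensus variant screening and comparative protein dynamics with vardyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus variant screening and comparative protein dynamics with vardyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vardyn)
```

## Scope and rationale

vardyn supports a common workflow in the structural characterization of
missense variants (nsSNPs): first a *consensus screen* reduces a large
candidate list to the few substitutions that many independent predictors
agree are deleterious, then a *comparative trajectory analysis*
quantifies how each surviving variant changes the conformational
dynamics of the affected protein domain relative to wild-type. The
motivating use case is a nucleotide-binding domain of an ABC
transporter, whose catalytic machinery (Walker A/B, LSGGQ, Q/D/H-loop
motifs) is exquisitely sensitive to changes in flexibility and
inter-residue communication; the machinery is generic, though, and works
on any single-chain domain.

The package deliberately stops at the analysis layer. It does not run
predictors (their scores are its input), does not run molecular
dynamics (multi-model PDB ensembles are its input), and does not render
figures (every stage writes plain tabular data).

## The consensus screen

The input is one row per variant and one score column per predictor.
Nine tools are supported, with the deleteriousness rules applied exactly
at their printed boundaries:

| tool | rule |
|---|---|
| SIFT | score <= 0.05 |
| PolyPhen-2 | HumDiv > 0.9 **and** HumVar > 0.9 (one tool, two columns) |
| PROVEAN | score <= -2.5 |
| I-Mutant | DDG < -0.5 |
| PhD-SNP | score > 0.5 |
| SNP&GO | score > 0.5 |
| PANTHER | score >= 0.5 |
| PredictSNP | "D", or score > 0.5 |
| MAPP | "D", or score > 0.5 |

Two policies matter and are worth stating explicitly:

* **A missing score is a no-call, never a neutral call.** A variant
  scored by only seven tools can still reach seven-of-nine support. This
  is what makes screens with partially covered tools (MAPP and SNP&GO
  cover few positions) behave sensibly.
* **PolyPhen-2's two models are one tool** that must pass jointly; the
  screen is a nine-tool screen even though tables carry ten score
  columns.

The consensus flag requires `min_tools` deleterious calls (default 7).
Pairwise tool agreement is reported as the phi coefficient of the binary
calls over the variants both tools scored; pairs with fewer than two
co-called variants are undefined (`NA`) rather than guessed. I-Mutant's
DDG is used purely as a thresholded score, not interpreted as a
stability prediction. How per-variant significance levels might be
attached to consensus counts is not modelled; no published method for
that step is available to reproduce.

## Trajectory model

All dynamics stages consume a `trajectory`: a topology (atoms with
author residue numbering, never renumbered, so motif positions like
"Walker A 933--940" stay addressable) plus ordered coordinate frames in
Angstrom. Only multi-model PDB is read and written; binary trajectory
formats are out of scope. When alternate locations occur, the
highest-occupancy conformer is kept so that every frame is a
single-conformer structure. The frame interval (default 25 ps) is
metadata only.

Analyses run on a configurable *equilibration window*: the leading
`cutoff_fraction` (default 0.4) of frames is discarded, mirroring the
practice of dropping the pre-equilibration part of a production run
(e.g. the first 120 ns of 300 ns). The window is a plain config value,
not an automatic detector -- equilibration judgments are left to the
analyst.

## Descriptors and their conventions

* **RMSD** per frame after least-squares (Kabsch) superposition onto
  either the first frame or the mean structure; superposition is
  mass-unweighted on the analysis selection (on C-alpha-only selections,
  weighting would be irrelevant anyway). The default RMSD selection is
  the backbone, configurable to heavy atoms.
* **RMSF** per residue about the mean structure after a two-pass fit
  (fit to frame 1, recompute the mean, refit). The mean-structure
  reference is the standard convention behind B-factor-style tube
  plots; `B = (8 pi^2 / 3) RMSF^2` converts to pseudo-B-factors.
* **Rg** is mass-weighted by default, with elements inferred from atom
  names when the element column is absent.
* **SASA** uses the Shrake--Rupley construction: `n_sphere_points`
  (default 960) quasi-uniform points per atom on the probe-expanded
  sphere (probe 1.4 Angstrom, a water), an atom's accessible area being
  the unoccluded fraction times the sphere area. Shrake--Rupley was
  chosen over analytic approximations because it is auditable against
  the closed-form sphere and its quadrature error is controllable by
  the point count.
* **Hydrogen bonds** are unique donor--acceptor pairs with heavy-atom
  distance <= 3.5 Angstrom and D-H...A angle >= 120 degrees. For the
  hydrogen-free structures this package mostly sees, the backbone amide
  H is reconstructed geometrically (N-H 1.01 Angstrom, anti to the
  preceding carbonyl) so the angle criterion still discriminates true
  helical i -> i+4 bonds (angle near 163 degrees in an ideal helix)
  from merely short i -> i+2/i+3 contacts (69/110 degrees), which a
  distance-only rule would miscount. Donors whose hydrogen cannot be
  placed fall back to the distance criterion. Absolute counts are
  therefore not comparable across programs with different geometric
  definitions; wild-vs-variant contrasts within one convention are.

## DCCM and PCA

The cross-correlation map is
`C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2> <|dr_j|^2>)` over the window,
with `dr` the deviation of a residue's (C-alpha) position from its time
average after superposition on the window mean. This is the only
normalization that gives a unit diagonal and values in [-1, 1], which
is how the map is defined here. Residues with zero positional variance
have no defined correlation and are flagged `NA` rather than silently
set to 0. Superposition can be disabled; that is essential for the
rigid-motion test cases, where fitting would remove exactly the signal
being asserted.

PCA diagonalizes the `3N x 3N` covariance of the superposed
coordinates, with denominator `T` (not `T - 1`) so that the eigenvalue
sum equals the summed squared RMSF on the same selection -- an identity
the test suite asserts to 1e-6. Eigenvector signs are arbitrary; they
are fixed by making each vector's largest-magnitude component positive
so projections are reproducible run-to-run. The PC1 residue mobility is
the per-residue magnitude of the first eigenvector scaled by
`sqrt(lambda_1)`.

## Residue interaction networks

Per frame, residues are nodes and an edge joins two residues whose
C-beta atoms (C-alpha for glycine) lie within 6.7 Angstrom (boundary
inclusive). Graphs are unweighted: the quoted definitions of
betweenness centrality (BC) and average shortest path (L) are hop-count
definitions. BC is normalized by `(N-1)(N-2)/2` so profiles are
comparable across systems and window lengths. For L, unreachable pairs
are excluded from both numerator and denominator -- an infinite or
penalty distance would make L useless on transiently disconnected
graphs -- and affected residues are flagged in the profile's metadata
so the exclusion is auditable.

Two delta conventions exist and the choice is recorded in the result:
`"vs_first_frame"` (a system's windowed mean profile minus the profile
of the window's first frame alone, the per-system convention) and
`"vs_other_system"` (direct wild-minus-variant). *Residue usage* is the
wild-minus-variant difference of per-system delta-BC profiles. Which
baseline a published delta-profile figure used is often unstated;
carrying the convention in the output metadata is the safeguard.

## Secondary structure

A simplified Kabsch--Sander assigner produces per-frame, per-residue
classes in {H, G, E, T, S, C}. Backbone hydrogen bonds use the
electrostatic model
`E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)` kcal/mol, a
bond being `E < -0.5`; the amide hydrogen is reconstructed as above.
n-turns at offsets 3/4/5 within a chain yield T; two consecutive
4-turns yield an alpha-helix (H), two consecutive 3-turns a 3-10 helix
(G); Kabsch--Sander parallel/antiparallel bridge patterns between
sequence-distant (or cross-chain) residues yield E; a bend (S) is a
C-alpha direction change above 70 degrees. Priority on conflict is
H > E > G > T > S > C, and terminal residues lacking the neighbors a
motif needs stay C. Pi-helices, chirality flags and chain-break
handling are intentionally omitted: the goal is class-level timelines,
not full DSSP fidelity, and only qualitative agreement with any
particular DSSP build should be expected.

## Free-energy landscapes

The (RMSD, Rg) pairs of the window are binned on a regular grid
(default 50 x 50 over the observed range, upper edge of the last bin
inclusive) and converted by Boltzmann inversion,
`G_i = -kB T ln(N_i / N_max)`, `kB = 0.0083145 kJ/(mol K)`, T default
300 K, so the modal bin sits at `G = 0`. Empty bins get an unnatural
barrier of `max(finite G) + 2 kB T`: high enough never to be a minimum,
finite so plots and basin searches stay well-behaved.

Basins are local minima of G over populated bins, with two guards
against histogram noise: a candidate minimum connected to a deeper one
through bins all within `merge_barrier` (default `kB T`) of its own
level is the same basin, not a new one; and a bin must hold at least
`min_occupancy` (default 1%) of the frames -- a single outlier frame
(for instance the reference frame itself, whose RMSD is exactly zero)
is not a free-energy minimum. Each basin reports its member frames and
a representative frame nearest the bin center, which can be written out
as a single-model PDB.

## What the synthetic generators emulate

* `sample_harmonic_ensemble()` draws, per frame, one Gaussian scalar
  displacement per residue with a prescribed residue--residue
  covariance, added identically to x, y, z and to all atoms of the
  residue. Ground truth is therefore *residue-level*, matching the
  residue-level observables (RMSF, DCCM, PCA) it validates: the DCCM of
  such an ensemble converges to the normalized input covariance, the
  PCA spectrum to the input eigenvalues (times a factor 3 shared by all
  modes), and the RMSF at unit per-axis variance to `sqrt(3)`.
* `sample_two_state()` mixes two conformations at a prescribed
  occupancy with isotropic jitter: the ground truth for basin counts,
  occupancy ratios (`delta G = -kB T ln(p1/p2)`) and PCA cluster
  separation.
* `build_ideal_helix()` / `build_extended_strand()` construct ideal
  poly-alanine backbones (phi/psi of -57/-47 and 180/180) with standard
  bond geometry; they pin down hydrogen-bond registers, DSSP classes
  and contact-graph structure by construction.
* `generate_score_table()` plants deleterious variants whose scores
  pass each tool's cutoff with probability 0.95 (neutral rows: 0.05),
  with optional missingness.

What they do **not** emulate: anharmonicity, solvent, correlated
side-chain motion, sequence-dependent geometry, or the actual force
field dynamics of any real domain. A passing suite demonstrates that
each estimator recovers what it is defined to estimate, not that any
biological conclusion about a particular protein is correct.

All generators are deterministic for a fixed `seed`, and the pipeline
manifest records every parameter and the seed, so a run can be
reproduced bit-identically from its manifest.

## Numerical choices and problem sizes

Statistical recovery checks in the tests and in `scripts/acceptance.R`
use ensembles of 5,000 frames (10,000 for two-state landscapes) over
domains of 4--30 residues: large enough that Monte-Carlo error sits
well inside the asserted tolerances (0.05 on correlations, 0.03 on
variance fractions, 0.3 kJ/mol on basin energies), small enough to run
in seconds. Superposition uses SVD with the usual determinant
correction for reflections; it is validated against a brute-force
Euler-angle grid search. The betweenness and shortest-path statistics
are validated against exhaustive path enumeration on random graphs of
up to 8 nodes.

## Known limitations

* PDB is the only trajectory format; convert binary formats upstream.
* The SSE assigner is a simplified Kabsch--Sander, not DSSP.
* SASA and hydrogen-bond *absolute* values depend on operational
  definitions (point counts, radii, angle criteria) and should only be
  compared within one convention.
* Networks are unweighted contact graphs; contact-frequency weighting,
  community detection and perturbation-response analyses are out of
  scope.
* The screen consumes predictor scores; it cannot detect predictors
  that are themselves biased on a protein family.
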