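---
title: "Methods: trajectory geometry, collective motion and shape statistics in trajgeom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory geometry, collective motion and shape statistics in trajgeom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajgeom)
```

trajgeom analyses protein MD trajectories the way a structural
bioinformatician studying thiol–disulphide oxidoreductases would: it
quantifies stability (RMSD/RMSF), collective motion (PCA and dynamic
cross-correlation), conformational heterogeneity (ensemble-based
clustering), the geometry of the redox-active CX₁X₂C motif (distances,
pseudo-torsions, Kendall shape statistics) and the noncovalent contacts
that stabilise folds and interfaces. This vignette documents the models,
the numerical choices, and what the synthetic validation data do and do
not establish.

## Data model

A `Topology` carries atom names, elements and residue identities (name,
author number, chain); a `Trajectory` is an F × N × 3 array of Cartesian
coordinates in Å with strictly increasing timestamps in ps. Multi-model
PDB and per-frame XYZ are supported; nothing is inferred about units.
Selections use a small conjunction grammar (`"resid 37-40 and name SG"`)
and always resolve to a sorted, duplicate-free index mask, so repeated
selection is idempotent and adding clauses can only shrink the mask.

Residues are classified once and for all as positively charged {R, K},
negatively charged {D, E}, polar {S, T, N, Q, C, H}, hydrophobic
{A, V, L, I, P, F, M, G} and amphipathic {W, Y}. Histidine is kept
neutral (the ε-protonated convention used when such systems are
prepared at physiological pH), tryptophan and tyrosine are treated as
amphipathic surface residues, and glycine sits with the hydrophobics so
that Cα-proxy hydrophobic contacts involving glycine are expressible.

## Superposition and fluctuation statistics

Rigid-body fitting uses the Kabsch SVD solution restricted to proper
rotations: the smallest singular direction is sign-flipped whenever the
unconstrained optimum would be a reflection. Chirality is physically
meaningful for protein coordinates, so reflections are never allowed,
and the fit refuses masks with fewer than three non-collinear atoms.

`rmsdSeries()` separates the *fit* mask from the *measure* mask. With
equal masks it is the standard fitted RMSD against a reference frame;
fitting on one domain while measuring another turns the series into the
rigid-body displacement of the measured domain in the fitted domain's
frame — the natural way to ask whether a luminal loop drifts as a
pseudo-rigid body relative to a transmembrane bundle.

RMSF defaults to the time-mean reference: frames are fitted to the
initial conformation, the mean structure is formed, and frames are
re-fitted to that mean in one pass. A fixed point of the fit–average
cycle is not iterated for; on the ensembles this package targets the
one-pass mean moves by far less than the fluctuation scale, and the
single pass keeps the estimator simple and deterministic. The
high-fluctuation rule retains atoms with RMSF below a threshold
(default 4 Å) and reports how many were excluded, as a single pass —
profile, exclusion, recomputation — not a fixed-point loop.

## Covariance, PCA and cross-correlation

The covariance of fitted coordinates uses the population (1/F)
normaliser, reading the definition as a time average over recorded
frames. Eigendecomposition is `eigen(symmetric = TRUE)` with
eigenvalues clamped at zero and sorted decreasingly; validity checks
enforce trace conservation (ΣΛ = tr C to 1e-8 relative) and
orthonormality of the eigenvector matrix. Projections subtract the
model's mean coordinates and truncate to the requested number of
modes, so the score variance along mode *i* estimates Λᵢ.

Dynamic cross-correlation is computed per atom from 3-vector
displacement dot products, which is what keeps the diagonal exactly 1
and bounds every entry in [−1, 1]. Zero-variance atoms make the
definition 0/0; they are reported as 0 with a warning, a documented
convention rather than a mathematical fact. The fit mask may differ
from the measured mask: anchoring the superposition on a rigid domain
(a transmembrane bundle, or a synthetic rigid anchor) avoids the
spurious anticorrelations that superposition otherwise injects into
weakly coupled atoms, because removing six rigid-body degrees of
freedom from the measured atoms themselves couples their residuals by
construction. Mode arrows are eigenvector components scaled by √Λ (an
RMS amplitude in Å) with a 2 Å display floor by default.

PCA scores are unweighted (no mass weighting): the analyses here run on
Cα masks where all masses are equal anyway, and unweighted scores keep
the covariance model exactly the second-moment matrix of the plotted
coordinates.

## Ensemble-based clustering

The algorithm is deliberately the simple two-step randomized procedure:
(i) draw a reference frame uniformly at random from the remaining
ensemble, remove every frame within fitted RMSD *r* of it, repeat until
the ensemble is empty — the harvested references are pairwise more than
*r* apart by construction; (ii) assign every frame (including those
removed in step i) to the nearest reference by fitted RMSD, ties to the
lowest reference index, with no re-thresholding — a frame farther than
*r* from every reference still joins its nearest cluster. Populations
are percentages of frames and must sum to 100.

The seed is a required argument: the reference set is a random
variable, and cut-off scans across a grid (default 1.6–3.0 Å in 0.2 Å
steps, dense-cluster floor 4 %) use seeds derived deterministically
from the supplied one. Cluster counts need not be monotone in *r* for
a randomized harvest, and the scan does not pretend otherwise. Merged
replicas are concatenated before harvesting, and each cluster is
decomposed into the percentage contributed by each source replica.
Representatives are medoids — the frame minimising mean fitted RMSD to
its cluster — with ties again to the lowest frame id.

## Motif and loop geometry

A CX₁X₂C motif is summarised by the S⋯S′ distance and the absolute
pseudo-torsion |S−Cα−Cα′−S′|, classified on standard Klyne–Prelog
bands over the absolute angle: syn-periplanar [0°, 30°), synclinal
[30°, 90°), anticlinal [90°, 150°), antiperiplanar [150°, 180°]. The
absolute value makes the landmark labelling direction irrelevant. The
directional S−H⋯S probability is the fraction of frames with
S⋯S′ under the distance cut-off and the S−H⋯S′ angle at the hydrogen
at or above the angular cut-off; the two donation directions are
separate measurements. Thiol hydrogens are never idealised — their
position is the measurement — so explicit hydrogens are required there,
while backbone amide hydrogens may be reconstructed on the bisector of
the two N bonds when a structure lacks them.

Tetrahedron analysis tracks the six pairwise Cα distances of four
anchor residues; a synchronous shift of the three edges meeting at one
vertex localises which residue moved. Anchor choice is user
configuration (typically RMSF extrema). Helix axes join the main-chain
{N, Cα, C, O} centroids of the first and last residues of the helix;
an elongation factor stretches the drawn axis symmetrically about its
midpoint for display, and drift analysis projects the fitted endpoints
on the x–z and y–z planes.

## Kendall shape space

Landmark configurations are normalised to pre-shapes (centred, unit
Frobenius norm); the geodesic distance optimises over proper rotations
only and is computed in the chordal form 2·asin(‖A − BR*‖/2), which is
numerically exact near zero where the arccosine form loses half the
machine digits. Reflections are excluded deliberately: the handedness
of an S−Cα−Cα′−S′ tetrahedron is chemistry, not nuisance. Distances
are radians on the unit pre-shape sphere; the radius-½ shape-sphere
rendering of triangles is handled in the disk map, where the colatitude
is twice the unit-sphere distance from the labelled equilateral
triangle and the disk radius is its sine — 0 at the equilateral pole, 1
on the collinear equator. The longitude convention is fixed by a
tangent basis at the pole built from labelled deformations of the
equilateral triangle (vertex 1 defines the φ = 0 meridian); any other
convention would rotate the disk rigidly.

Metric MDS minimises the raw stress Σ(d − ‖xᵢ − xⱼ‖)² by SMACOF
majorisation from a classical-scaling start; the Guttman transform
guarantees a non-increasing stress sequence, and the seed only matters
in the degenerate case where the classical start collapses. The Fréchet
mean iterates tangent-space averaging (align, log-map, average,
exp-map) with gradient tolerance 1e-8 and a 1000-iteration cap,
erroring rather than silently returning a non-converged mean. In the
flat limit it reduces to the aligned arithmetic mean, and for two
shapes it is the geodesic midpoint — both properties are asserted in
the tests.

## Contacts and interfaces

Hydrogen bonds connect N/O/S donors (heavy atoms carrying at least one
hydrogen, found by bond list or a 1.45 Å proximity rule that spans O−H
through S−H bond lengths) to N/O/S acceptors of other residues when
D⋯A < 3.6 Å and ∠DHA ≥ 120°. Salt bridges are an operational rule —
any Arg {NE, NH1, NH2} or Lys {NZ} nitrogen within 4 Å of an Asp
{OD1, OD2} or Glu {OE1, OE2} oxygen — because "ionic plus hydrogen
bonding" needs a numeric criterion to be computable; 4 Å is the common
community convention and a configurable knob. Histidine is excluded
from salt-bridge donors, consistent with its neutral protonation here.
Hydrophobic contacts require two hydrophobic residues with side-chain
heavy atoms under 4 Å; glycine's Cα is its side-chain proxy, and
sequence-adjacent residues are excluded as trivially close. A residue
pair may legitimately appear both as salt bridge and hydrogen bond, so
interface summaries also report the deduplicated residue-pair count —
the "number of noncovalent contacts" of an interface. The
exposed-residue report lists residues with zero intra-molecular
contacts at the configured cut-offs, labelled by class; it is a
contact-graph proxy for protrusion, explicitly not a
solvent-accessible-surface computation.

## Secondary structure

Backbone hydrogen bonds use the Kabsch–Sander electrostatic model,
E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN) kcal/mol with a bond
below −0.5 kcal/mol, amide hydrogens idealised when absent. Labels
follow the published patterns: H needs two consecutive i→i+4 turns, G
two consecutive i→i+3 turns, E parallel/antiparallel bridge patterns, T
isolated turns, S a Cα-trace kink beyond 70°, priority
H > G > E > T > S > C. The π-helix label is omitted (its patterns fold
into T), and the goal is faithful behaviour on well-formed backbones,
not byte equality with any particular DSSP release.

## Synthetic data: what it shows and what it cannot

Every generator plants its ground truth and is deterministic under a
seed. Gaussian ensembles draw i.i.d. frames with a prescribed
covariance; by default the planted directions are orthogonalised
against the six rigid-body modes of the reference
(`internalModeBasis()`), so the planted spectrum represents pure
internal motion and survives the superposition step — the honest way to
test covariance recovery, since rigid-body variance is removed by
fitting in any real analysis. Multi-state trajectories switch between
reference structures i.i.d. (given occupancies) or by a Markov chain
(given a transition matrix), with isotropic per-coordinate Gaussian
jitter, the simplest noise model consistent with RMSF assumptions. The
two-state validation conditions — occupancies 0.7/0.3, inter-state
RMSD 8 Å, jitter 0.3 Å, cut-off 2 Å, 2000 frames — put the state
separation far above the cut-off and the jitter far below it, the
regime in which exact cluster-count recovery is a theorem rather than
luck. Ideal helices are built by natural-extension (NeRF) placement
from canonical torsions (α: −57/−47; 3₁₀: −49/−26; extended:
−180/180) with trans peptides and bisector amide hydrogens; the α
geometry reproduces the canonical 1.5 Å rise / 100° twist and
2.0–2.2 Å O⋯H(i+4) distances. Planted interfaces place each contact
pair in its own slot 20 Å from the next, with geometry margins of at
least 0.1 Å / 5° against the detection criteria, so the planted set is
recovered exactly or something is genuinely wrong.

What passing these tests does *not* show: synthetic ensembles are
geometric, not physical — no solvent, no membrane, no force field, no
anharmonicity, no correlated side-chain dynamics. Recovery of planted
structure validates the estimators and algorithms, not any claim about
a particular protein's behaviour; quantities reported in the literature
from undeposited trajectories (specific cluster populations, S−H⋯S
percentages, per-protein fold fractions) are reproducible here only as
*mechanisms* exercised on planted analogues of matching structure. The
bundled worked example for the minimal inter-domain S⋯S distance runs
on a synthetic stand-in complex for the same reason: it validates the
measurement, on coordinates built to a known answer.

## Problem sizes and determinism

The validation suite and `scripts/acceptance.R` use 5000-frame
ensembles of 20 atoms for spectrum recovery (sampling error on an
eigenvalue ≈ √(2/F) ≈ 2 %), 2000-frame two-state systems across a
20-seed sweep for clustering (binomial error on a population ≈ 1
point), and seconds-scale closed-form anchors everywhere else. These
sizes were chosen so that statistical tolerances (10 % on eigenvalues,
3 points on populations, 0.05 on decorrelation) are comfortable
multiples of the sampling error. All randomness flows through explicit
integer seeds; the pipeline manifest records the config hash and seed,
and re-running a config reproduces deterministic outputs byte for
byte.

## Pipeline configuration

`runPipeline()` accepts a nested list or YAML file: `inputs` (or
in-memory trajectories), a global `seed`, an equilibration `trim_ps`
window (default 0 — trimming is opt-in), an optional stepped
restraint `schedule` (half-open [start, end) windows in ps, so a frame
on a boundary belongs to the later step), and an `analyses` block
whose entries switch on individual stages with their parameters. Each
stage logs a structured line with timing; a failing stage marks the
bundle `partial` in `manifest.json` and the remaining stages still
run. For this package the exported functions, the config file and this
vignette are the interface; there is no separate shell executable.

## Known limitations

* The PDB reader handles the ATOM/HETATM dialect needed for model and
  MD-derived structures: no mmCIF, no altloc beyond blank/'A', no
  insertion codes, no bond-order perception.
* Contact detection has no π-stacking, cation-π or SASA terms.
* Secondary-structure assignment folds π-helix patterns into turns and
  is validated on ideal fixtures, not on crystallographic edge cases.
* The Fréchet mean assumes the shape set lies within a geodesic ball
  where the mean is unique; widely scattered shape sets can fail to
  converge, and the error says so.
* Clustering is exactly the randomized two-step algorithm described
  above; no hierarchical, k-means or density-based alternatives are
  provided.
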