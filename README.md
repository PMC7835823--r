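# trajgeom

Geometry, collective motion and shape-space statistics of protein
molecular-dynamics (MD) trajectories, written for the analysis problems
posed by thioredoxin-fold (Trx-fold) oxidoreductases and the human
vitamin K epoxide reductase (hVKORC1): how stable is a fold over a
simulation, which parts of it move together, how many conformational
states does a flexible loop visit, what does the redox-active
CX<sub>1</sub>X<sub>2</sub>C motif look like, and which noncovalent
contacts hold a protein–protein interface together.

The package is aimed at structural bioinformaticians who have
trajectories (multi-model PDB or XYZ) and want a reproducible, tested R
implementation of the full analysis chain, plus synthetic-trajectory
generators with planted ground truth so every stage can be validated
without reference simulation data.

## What it computes

* **Fluctuations** — Kabsch least-squares superposition (proper
  rotations only), RMSD series with separate fit/measure masks (so the
  rigid-body drift of one domain relative to another is measurable),
  RMSF profiles about the initial or time-mean conformation, and the
  exclusion rule that drops residues fluctuating beyond 4 Å.
* **Collective motion** — the covariance matrix of fitted coordinates
  `C = ⟨(x − ⟨x⟩)(x − ⟨x⟩)ᵀ⟩`, its eigendecomposition `C = VΛVᵀ`
  (essential dynamics/PCA), cumulative variance, per-frame projections,
  mode "arrow" fields with an amplitude floor, and the dynamic
  cross-correlation map
  `CC_ij = ⟨Δr_iᵀΔr_j⟩ / (⟨Δr_iᵀΔr_i⟩⟨Δr_jᵀΔr_j⟩)^{1/2} ∈ [−1, 1]`.
* **Ensemble-based clustering** — random reference harvesting at
  cut-off *r* (pick a random frame, remove everything within *r*,
  repeat), nearest-reference assignment, cut-off scans
  (1.6–3.0 Å by 0.2), populations, medoid representatives, timelines,
  and merged-replica clustering with per-cluster source composition.
* **Motif and loop geometry** — the S⋯S′ distance and absolute
  pseudo-torsion |S−Cα−Cα′−S′| of a CXXC motif with Klyne–Prelog
  classification, directional S−H⋯S hydrogen-bond probabilities,
  Cα-tetrahedron edge series with synchronous-shift detection, and
  helix axes (terminal-residue main-chain centroids) with drift tracks
  projected on the x–z / y–z planes.
* **Kendall shape space** — pre-shape normalisation, the geodesic
  (Procrustes) distance with reflections excluded, distance matrices,
  metric MDS by SMACOF majorisation of the raw stress
  `Σ_{i≠j}(d_ij − ‖x_i − x_j‖)²`, Fréchet means by tangent-space
  averaging, and the triangle disk map `(φ, θ) → (r = sin θ, φ)` with
  the equilateral triangle at the centre and collinear triangles on the
  rim.
* **Contacts** — hydrogen bonds (N/O/S donors and acceptors,
  D⋯A < 3.6 Å and ∠DHA ≥ 120°), salt bridges (Arg/Lys side-chain N to
  Asp/Glu carboxylate O under 4 Å; His excluded), hydrophobic
  side-chain contacts under 4 Å (glycine's Cα stands in for its side
  chain), residue contact maps, interface tables for two-chain
  complexes, and a contact-free-residue proxy for protrusion.
* **Secondary structure** — Kabsch–Sander electrostatic hydrogen-bond
  energies (`E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)`
  kcal/mol, bond below −0.5), DSSP-style labels H/G/E/T/S/C, timelines
  and fold fractions.
* **Synthetic data** — Gaussian ensembles with a planted covariance
  spectrum, multi-state switching trajectories with known occupancies,
  ideal α/3₁₀/extended chains, CXXC motifs with prescribed geometry,
  planted two-chain interfaces, and labelled shape samples. Every
  generator returns its ground truth and is deterministic under a seed.
* **Pipeline** — `runPipeline()` drives all stages from a nested list
  or YAML config and writes CSV tables plus a JSON manifest (inputs,
  config hash, seeds, per-stage status/timings);
  `annotateSchedule()` labels frames by stepped restraint-schedule
  windows.

## Worked example

A two-state loop ensemble (70/30 occupancies, 8 Å apart, 0.3 Å
thermal jitter) is generated, clustered with the ensemble-based
algorithm at r = 2 Å, and its CXXC motif anchor is measured:

```r
library(trajgeom)

set.seed(99)
ref <- cbind(seq(0, 76, by = 4), rnorm(20, 0, 3), rnorm(20, 0, 3))
v   <- internalModeBasis(ref, 1, seed = 3)
st2 <- ref + uniroot(function(c)
  superpose(ref + c * matrix(v, 20, 3, byrow = TRUE), ref)$rmsd - 8,
  c(0, 800))$root * matrix(v, 20, 3, byrow = TRUE)

ms <- makeMultistateTrajectory(list(ref, st2), nframes = 2000, seed = 13,
                               occupancies = c(0.7, 0.3), jitter = 0.3)
cm <- clusterTrajectory(ms$trajectory, cutoff = 2, seed = 13)
cm
#> ClusterModel: r = 2.00 A, 2 cluster(s) over 2000 frames
#>   populations (%): 30.4, 69.7

g <- motifGeometry(frameCoords(makeMotif(4.0, 60)$trajectory),
                   sPair = c(1, 4), caPair = c(2, 3))
unlist(g)
#>   s_s_distance pseudo_torsion          class
#>            "4"           "60"    "synclinal"
```

The cluster populations recover the planted 70/30 occupancies within
sampling error, and a motif built at 4 Å / 60° measures back exactly
and classifies as synclinal — the geometry characteristic of a reduced
CXXC motif sitting on a well-folded helix.

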