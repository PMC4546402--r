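---
title: "Modelling a four-helix transmembrane bundle: methods and design notes"
author: "tmbundler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a four-helix transmembrane bundle: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmbundler)
```

`tmbundler` models the packing of the four predicted transmembrane (TM)
helices of bilitranslocase (BTL), a plasma-membrane organic-anion
transporter with no solved structure and no sequence homologs, and
provides the companion analyses used to characterise the two central
helices experimentally: Lipari–Szabo model-free fitting of backbone
¹⁵N relaxation, dissociation-constant fitting of FRET titrations, and
Stokes–Einstein conversion of DOSY diffusion coefficients. This
vignette explains the models, the defaults and why they were chosen,
and what the synthetic-data based tests do and do not demonstrate.

## The coarse-grained bundle model

Each TM helix is a rigid body represented by its Cα trace on an ideal
α-helix: 1.5 Å rise per residue, 100° twist per residue, 2.3 Å axial
radius (all overridable in `build_ideal_helix()`). The membrane frame
is fixed: z is the membrane normal and +z the extracellular side.
Models are emitted at Cα resolution throughout; everything the
clustering, classification and distance analyses need lives at that
level, and an atomistic reconstruction would only feed an all-atom
scoring stage this package deliberately does not implement.

The four helices are TM1 Phe24–Asp48, TM2 Phe75–Cys94, TM3
Gly220–Tyr238 and TM4 Pro254–Ser276 (UniProt numbering, 1-based,
exposed unchanged). Two sequence caveats, both visible in
`btl_helix_specs()` and the shipped `inst/extdata/btl_helices.yaml`:

* **TM3 length.** The experimentally characterised TM3 peptide has 18
  residues ending at Thr237, while the stated helix range extends to
  Tyr238 (19 residues). Both variants ship
  (`tm3_variant = "range"` / `"peptide"`); the 19-residue range variant
  is the default. The discrepancy is documented, not resolved.
* **TM1/TM4 sequences are synthetic placeholders.** No experimentally
  determined sequence for these segments is bundled; the shipped
  sequences are hydrophobic stand-ins with the functionally
  constrained residues pinned (His43 in TM1; Pro254, Pro258, Ser276 in
  TM4) and are flagged `synthetic: true`. Distance and contact
  analyses touching those pinned residues are meaningful; anything
  sequence-detail-dependent on TM1/TM4 (e.g. their contribution to the
  contact potential) is not, until real sequences are supplied via a
  helix config.

Topology is not stated per-helix anywhere authoritative; the package
defaults to the alternating (antiparallel) arrangement natural for a
four-pass membrane protein — TM1/TM3 N-termini extracellular, TM2/TM4
cytoplasmic — and exposes it as the `n_term` config field.

Helix axes are estimated from a trace as the null direction of its
second differences rather than a direct principal component of the
points: the axial coordinate of a helix is linear in residue index, so
second differences lie exactly in the plane perpendicular to the axis.
A direct PCA of the points is biased by up to ~1.2° when the trace
does not close an integer number of turns; the second-difference
estimator is exact for ideal geometry and keeps the tilt restraint
from charging spurious penalties to perfectly vertical helices.

## Restraints

`restraint_set()` collects the scoring terms; all parameters are
config-exposed, and per-term weights default to 1.0 (no weighting
scheme is prescribed anywhere, so the neutral choice is recorded in
every run's output metadata).

* **Diameter** — the largest xy distance between helix midpoints plus
  two helix radii, harmonically penalised beyond the 26 Å target.
* **Tilt and depth** — per helix, tilt is allowed up to
  `acos(thickness / L)` (only helices longer than the membrane may
  tilt, to bury their excess length); the axial z-span
  `z_mid ± (L/2) cos θ` must cover the hydrophobic slab, shortfall at
  either face penalised harmonically. This formulation leaves exactly
  `L cos θ − thickness` of free z-translation slack for a longer
  helix.
* **Excluded volume** — harmonic penalty for inter-helix Cα pairs
  closer than 4.0 Å.
* **Packing** — minus the count of inter-helix Cα pairs inside the
  4.0–6.5 Å contact window.
* **Interaction restraints** — flat-bottom harmonics holding the
  predicted interacting pairs TM2–TM3 and TM1–TM4 within 10.4 Å
  inter-axis distance, and the five predicted residue contacts
  (Thr81–Gln223, Thr81–Cys224, Pro85–Val222, Cys76–Ala225, His43–Pro258,
  certainties 1.00/0.96/0.82/0.81/0.79) within 8 Å Cα–Cα distance,
  each weighted by its certainty.
* **Residue-contact potential** — a transparent stand-in for a
  knowledge-based statistical potential: contact energies are negated,
  scaled sums of Kyte–Doolittle hydropathies
  (`default_pair_potential()`), making buried hydrophobic pairings
  favourable. The table is fully user-replaceable; ranking behaviour,
  not fidelity to any particular published potential, is what the
  package tests.

Membrane thickness 30 Å, clash distance 4.0 Å, contact window
4.0–6.5 Å and axis-distance bound 10.4 Å are literature-typical values
for α-helical membrane proteins; none is prescribed by the problem
statement, and all are config fields. Crossing-angle filtering
(`filter_crossing_angles()`, default |Ω| ≤ 40°) is applied as a hard
analysis-time filter, not a scoring term; the signed crossing angle
uses unsigned axis lines, so an exactly antiparallel untilted pair has
Ω = 0.

## Monte Carlo sampling

`run_mc()` is a Metropolis sampler over per-helix rigid transforms:
axial rotation, tilt (perturbed as a 2-D tilt vector, which keeps the
polar angle non-negative and treats directions symmetrically), and
translation restricted per helix — TM1 only z (its xy centre anchors
the frame), TM2 y and z, TM3/TM4 all axes. "Varying temperatures" is
realised as a geometric annealing ladder, default 5.0 → 0.2 in 10
rungs, repeated over restarts; no particular schedule is prescribed,
and the ladder is the simplest reproducible reading of
sampling-then-quench. Seeds are mandatory everywhere; identical
`(seed, config)` reproduces a run bit-for-bit.

Initial configurations randomise axial rotations (full circle) and
tilts (up to 10°) from the seeded stream, since the original seeding
conformations are not available. Desk-scale defaults (5 000–50 000
steps) are used in examples and tests; the sampler is linear in steps
and the full-size runs differ only in wall time.

Sampler correctness is tested physically: a single-helix double-well
toy system must reproduce Boltzmann basin occupancies within three
batch-means standard errors at 100 000 steps, and near-zero-temperature
runs must be monotonically non-increasing in score. The directional
effect of the interaction restraints (mean TM2–TM3 inter-axis distance
strictly smaller with the term on, same seed) is tested with the
packing and contact-potential terms disabled in both arms: those terms
are nonspecific attractions that collapse the bundle on their own, and
with them active the on/off comparison measures run-to-run noise
rather than the specific-interaction effect it is meant to isolate.

## Clustering and arrangement classification

Ensembles are clustered on pairwise Cα RMSD computed **without
superposition** by default. The membrane frame is physically
meaningful — arrangement differences are exactly differences of
absolute xy geometry — and superposing would erase them. Best-fit RMSD
is available behind `superpose = TRUE` for users who want the
conventional behaviour.

Complete linkage was chosen because cutting the dendrogram at h
guarantees every intra-cluster pair is within h, a property the tests
verify directly at the 2 Å default cutoff. Centroids minimise the
summed RMSD to co-members, ties to the lowest index. Above 20 000
conformations a two-stage scheme (greedy leader pre-clustering at
cutoff/2, then exact hierarchical clustering of leaders) bounds memory
and time; the intra-cluster guarantee then holds only approximately.

Arrangements are read from the extracellular side (+z, y up): project
the four helix midpoints to xy, order them clockwise around their
centroid starting at A = TM1. There are 3! = 6 cyclic orders: ABCD,
ADBC, ACDB, ABDC, ACBD, ADCB. Geometry with coincident or collinear
midpoints (no defined cyclic order) is reported `"unclassifiable"`
rather than forced into a label. `arrangement_counts()` reproduces the
ranked table and top-3 shares from any per-type counts, e.g. the
published distribution 1330/862/778/281/213/56 over 3520 centroids
gives a top-3 share of 84.4%, and 44/27/15/9/4/1 over the 100
top-scoring gives a top-3 count of 86.

## Synthetic data: what it emulates and what it does not

The generators produce every input with known ground truth:
bundle ensembles with planted arrangement labels (helices on a
9–11 Å square in the label's clockwise order, random axial spins,
Gaussian coordinate jitter), planted cluster structure (references
separated by exact-RMSD translations), relaxation datasets from the
model-free spectral density, and titrations from the exact 1:1
isotherm. Noise is multiplicative Gaussian throughout, the form in
which NMR and fluorescence uncertainties are typically reported.

The random axial spin in the bundle generator matters: with a fixed
spin, residue-level distances carry a deterministic radial-phase
offset of up to ±4.6 Å, and the Pro85–Pro231 distance no longer tracks
the axis separation. With spins randomised, the generator reproduces
by construction the qualitative finding that TM2/TM3-adjacent
arrangements (ADCB, ACBD) have shorter proline–proline distances than
the diagonal ABDC.

Passing tests on these ensembles demonstrates that the pipeline's
machinery — clustering, classification, fitting — recovers planted
truth under controlled noise. It does not demonstrate that the
restraint set or the contact potential reproduce the true BTL bundle:
synthetic bundles are ideal straight helices without proline kinks,
loops, lipids or micelle effects, and the arrangement distribution an
MC run produces depends on restraint weights no authoritative source
prescribes.

## Model-free analysis

The isotropic Lipari–Szabo spectral density
J(ω) = (2/5)[S²τ_m/(1+(ωτ_m)²) + (1−S²)τ/(1+(ωτ)²)], 1/τ = 1/τ_m+1/τ_e,
feeds the standard ¹⁵N dipolar + CSA expressions for R1, R2 and the
heteronuclear NOE. Physical constants (r_NH = 1.02 Å, Δσ = −160 ppm,
standard gyromagnetic ratios; 18.8 T field) are config-exposed.
Positive-magnitude frequency conventions are used, with the signed
γH/γN ratio only in the NOE. No exchange (R_ex) term is included — a
documented limitation; data with substantial exchange broadening will
bias S² upward.

Fitting proceeds in two stages: τ_m is initialised from the mean of
per-residue R2/R1 ratio roots (solved on 0.5–50 ns, where the ratio is
monotone), then the shared τ_m and per-residue (S², τ_e) are refined by
joint least squares on relative deviations. The refinement matters:
the ratio estimator assumes a rigid residue, and at S² ≈ 0.5–0.8 with
τ_e = 50 ps it is biased by a few percent; the joint fit removes the
bias and makes noiseless round trips exact. Multi-starting guards
against the extreme-narrowing local minimum, and τ_e is bounded at
500 ps by default (`tau_e_max`): the simple model-free form assumes
internal motions much faster than tumbling, and unbounded fits can
trade a lower S² against a spuriously slow τ_e ≈ τ_m. S² is kept in
[0, 1] and times positive by the parameterisation.

One labelling caveat: the labelled TM3 alanines appear in one
methods listing as Ala223/Ala231 but in all results and sequence
contexts as Ala225/Ala233; the package follows the results numbering
(Ala225, Ala233), which is also what the printed TM3 peptide sequence
supports.

## FRET titrations and DOSY

No binding model is prescribed for the titrations; the package fits
the simplest model consistent with reporting a single Kd per pair: a
1:1 association with the exact quadratic isotherm (no weak-binding
approximation), the complex concentration interpolating the emission
ratio linearly between `r_free` and `r_bound`. Homo-dimer titrations
(TM2:TM2, TM3:TM3) are treated with the same functional form on the
labelled/unlabelled pools. `fit_kd()` multi-starts over Kd decades
(1–1000 µM) and flags flat titrations as explicitly non-identifiable.

A design limit worth stating plainly: for a 12-point titration to
1000 µM with the partner at 50 µM, ratio endpoints 1.0 → 0.3 and 3%
multiplicative noise, the Cramér–Rao bound on Kd at 346.1 µM is a
relative standard deviation of ~21% (best-possible median relative
error ~14%), because the curve reaches only ~74% saturation. The
fitted estimator sits at that bound. Kd values of 71.85 and 190.6 µM
are recovered with median errors of ~8–9% under the same design;
recovering a 346 µM Kd to 10% would require titrating further past
saturation or fixing `r_bound` independently. The corresponding
acceptance check is left failing rather than widening its band.

`hydrodynamic_radius()` is plain Stokes–Einstein,
R_h = k_B·T/(6πηD_tr). The solvent viscosity of a deuterated detergent
solution is not bundled; the default is water at 298 K and quantitative
work must supply the real value.

## Problem sizes used in tests

The shipped tests run desk-scale problems chosen as the smallest sizes
at which each property is sharply testable: MC property runs of
3 000–10 000 steps (100 000 for the Boltzmann toy, where the
statistical test needs the samples), ensembles of tens to hundreds of
conformations for clustering and classification, 100 seeded replicates
for model-free recovery and 50 per Kd for titration recovery. The
full-scale analogues (millions of MC samples, thousands of clusters)
differ only in wall time, not in code path, with the single exception
of the two-stage clustering scheme described above.
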