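---
title: "Domain-motion analysis with hingewatch: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Domain-motion analysis with hingewatch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hingewatch)
```

## The scientific problem

Many multidomain enzymes bind their substrates at sites formed between two
domains that sit too far apart in the resting structure for chemistry to
happen. A prominent example is the dimeric triokinase/FMN cyclase fold: two
identical subunits, each with a kinase (K) and an ATP-binding (L) domain,
intertwined in an elongated L2-K1-K2-L1 arrangement with two active sites at
the L/K interfaces. In the open structure the ATP gamma-phosphorus and the
triose hydroxyl oxygen are roughly 14 Å apart, so catalysis requires a
large-scale closure motion of the domains. hingewatch implements the standard
computational toolkit for characterising such motions:

1. **Elastic-network normal-mode analysis (NMA)** — harmonic modes of a
   spring network built on the structure, whose lowest non-trivial modes are
   the collective hinge-bend, twist and wobble motions of the lobes;
2. **Essential dynamics** — principal component analysis (PCA) of the
   Cartesian covariance of a trajectory, whose top eigenvectors are the
   dominant collective motions actually sampled;
3. **Cross-system mode comparison** — absolute inner products of unit
   eigenvectors after reduction of each system to a shared atom set, so that
   systems differing in ligand content become comparable;
4. **Mobility statistics** — RMSD traces and RMSF profiles after rigid-body
   superposition, with detection of contiguous high-mobility regions;
5. **Near-attack-conformation (NAC) census** — per-frame O⋯P distances and
   O⋯P–O angles at the active site, filtered for in-line attack geometry.

Because the original study's force-field Hessians and explicit-solvent
trajectories are not deposited anywhere, the package ships a deterministic
synthetic generator that reproduces the *shape* and *statistical structure*
of those inputs, so every stage runs and is tested end to end without any
download.

## Models and conventions

### Elastic network Hessian

`buildEnmHessian()` implements the anisotropic network model: every atom
pair $(i,j)$ within a cutoff $r_c$ contributes a $3\times3$ superelement
$-k\,\hat r_{ij}\hat r_{ij}^{\mathsf T}$, and diagonal blocks are the
negative sums of each row's off-diagonal blocks, which enforces exact
translation invariance (zero row sums). Defaults are $r_c = 13$ Å on
C$\alpha$ atoms and a uniform $k = 1$ (energy Å$^{-2}$, energies in kJ/mol
throughout). An all-atom force-field Hessian computed elsewhere can be fed
into the same eigen-pipeline via `importHessian()`; consequently absolute
frequencies from the built-in network are not comparable with force-field
values — mode *shapes* and everything downstream of them are.

`massWeight()` applies $H'_{ia,jb} = H_{ia,jb}/\sqrt{m_i m_j}$ and
`eigenModes()` returns the full spectrum ascending, with eigenvector signs
fixed so the largest-magnitude component is positive (eigen solvers return
arbitrary signs; fixing them makes runs and comparisons reproducible).
Frequencies follow $\nu_i = \sqrt{\lambda_i}/2\pi$; with $\lambda$ in
kJ mol$^{-1}$ Å$^{-2}$ amu$^{-1}$, $\omega[\mathrm s^{-1}] =
\sqrt\lambda\cdot10^{13}$, so wavenumbers are
$\tilde\nu = \sqrt\lambda\cdot10^{13}/(2\pi c)$ with
$c = 2.99792458\times10^{10}$ cm/s. Eigenvalues down to
$-10^{-6}\lambda_{\max}$ are treated as nullspace noise and clamped; larger
negatives are an error (the analogue of an unconverged minimisation).

The six lowest modes of a connected structure are the rigid-body
translations and rotations. `splitTrivial()` removes them *and* reports the
projection of each removed mode onto the exact rigid-body basis built from
the reference coordinates, rather than trusting the count silently — a
linear molecule, for instance, has only five rigid degrees of freedom, and
an under-connected network has more than six near-zero modes.

### Thermal ensembles and mode recovery

`thermalEnsemble()` samples conformations $x_{\mathrm{ref}} + \sum_i c_i
M^{-1/2} d_i$ with $c_i \sim N(0, \sqrt{k_BT/\lambda_i})$: classical
equipartition in mass-weighted coordinates, under which the mass-weighted
variance along mode $i$ is exactly $k_BT/\lambda_i$
($k_B = 0.0083144621$ kJ mol$^{-1}$ K$^{-1}$). The amplitude convention of
the original ensemble generator is not documented anywhere; classical
equipartition is the defensible default and is what the tests verify.

`modeViaEnsemble()` implements the comparison protocol: generate a 5000-
conformation single-mode ensemble at 300 K, reduce every conformation to a
common atom selection (main-chain `"name CA C O N"` by default), and recover
the mode as PC1 of the reduced ensemble. $\lambda_2/\lambda_1$ is returned
as a purity diagnostic — for a faithful single-mode ensemble the rest of the
spectrum is null — and a ratio above 0.05 warns about mode leakage through
the reduction. The leading eigenpairs are found by blocked subspace
iteration on the implicit operator $v \mapsto X_c^{\mathsf T}(X_c v)/F$, so
the $3n\times3n$ covariance never has to be formed for this step.
Inner products are reported as absolute values because eigenvector signs
are arbitrary; modes are matched across systems by frequency-ordered index,
with no assignment optimisation — an off-diagonal match (a mode swap
between systems) is a finding, not something to optimise away.

### Essential dynamics

`covarianceMatrix()` fits every frame of the analysis window to the window's
first frame (removing overall translation/rotation), then accumulates
$C_{ij} = \langle(x_i - \langle x_i\rangle)(x_j - \langle x_j\rangle)\rangle$
over the analysis atoms with $1/F$ (population) normalisation —
configurable to $1/(F-1)$, since conventions differ between tools and the
choice is immaterial for directions and variance *fractions*.
`pcaModes()` returns descending eigenvalues (variances, Å$^2$) and unit
eigenvectors; `projectOnComponent()` and `extremeConformations()` reuse the
stored alignment so that projection variances reproduce the eigenvalues
exactly, and extreme conformations are actual trajectory frames, never
extrapolations. Two invariants tie the stages together and are enforced in
the tests: $\sum_i \mathrm{RMSF}_i^2 = \mathrm{tr}(C) = \sum_i \lambda_i$
under identical alignment, and PCA of a single-mode thermal ensemble
returns that mode with $|{\langle d,\mathrm{PC1}\rangle}| \ge 0.999$.

### Superposition and mobility

`kabsch()` computes the optimal proper rotation by SVD of the weighted
cross-covariance with the determinant correction, refusing reflections and
degenerate (collinear) inputs; the tests check it against an independent
quaternion-search oracle to $10^{-6}$ Å. RMSF profiles fit frames to the
evolving mean structure (two iterations by default — further iterations
change nothing measurable); a single-fit-to-first-frame mode exists so the
profile can share its alignment with the covariance, and a no-fit mode for
pre-aligned input. Mobile-region detection uses a configurable rule —
RMSF above mean + 1 SD, runs separated by fewer than 2 residues merged —
because no numeric criterion for "high-mobility region" is standard; region
counts therefore depend on the rule and are reported, not asserted.

### Near-attack geometry

The closure observable is the distance between a marker pair (the L-domain
Mg$^{2+}$ and the catalytic histidine N$\epsilon$2). The attack geometry
couples the distance from a triose hydroxyl oxygen to the ATP
gamma-phosphorus with the angle at the P vertex between P→O$_{nucleophile}$
and P→O$_{leaving}$ (180° = perfect in-line attack on the scissile bond; the
vertex convention is stated explicitly because the notation O⋯P–O leaves it
implicit). The NAC filter is strict on both sides — distance $< 3.5$ Å AND
angle $> 155°$ — so boundary values fail; passing snapshots closer than the
3.3 Å van der Waals P+O contact sum are additionally annotated. Both
hydroxyl oxygens (labelled O1 and O3) are chemically equivalent and tracked
separately. Site definitions are index-based and user-suppliable;
`sitePreset()` encodes the conventional atom names (MG, NE2 of residue 221,
PG, O3B, O1/O3) so the synthetic systems and similarly annotated real
structures both resolve.

## The synthetic generator: what it emulates and what it does not

`makeToyDimer()` builds a dimer of two identical subunits (575 residues
each by default), each split into a K domain (330 residues) and an L domain
(245), as four uniform-density spherical C$\alpha$ clouds along an axis in
L2-K1-K2-L1 order. Uniform density matters: Gaussian clouds have sparse
fringes whose atoms are poorly braced at a 13 Å cutoff and generate spurious
floppy zero modes; uniform balls of radius 17 Å (roughly protein-like
C$\alpha$ density for a 330-residue domain) keep the network rigid, so the
nullspace is exactly six-dimensional. Domain centres are 28 Å apart, which
keeps neighbouring clouds connected. Each L/K interface carries the closure
marker pair placed exactly 14 Å apart (the open state) and, optionally, a
minimal P/O triad plus the two hydroxyl oxygens — the minimum geometry the
site analyses need. A backbone variant adds N/C/O atoms per residue
(4 × 1150 = 4600 main-chain atoms for the default dimer).

`makeHingeTrajectory()` plants three orthonormalised collective
displacement fields — linearised rigid rotations of the two L domains about
perpendicular axes, the hinge-bend/twist/wobble triad of bilobate proteins —
with Gaussian amplitudes, plus isotropic Gaussian jitter
($\sigma = 0.25$ Å per coordinate) on every atom. Linearisation keeps the
planted motion exactly rank-3 and hence PCA-recoverable; a planted variance
large enough to leave the linear regime triggers a warning. The planted
variances are solved, given the noise level, so that the three planted modes
explain a target fraction (default 68%) of the total C$\alpha$ variance,
noise contribution along the planted directions included:
$(V + 3\sigma^2)/(V + 3n\sigma^2) = t$. The default trajectory is 6001
frames at 20 ps — the closed 0–120 ns window, matching the convention of
simulation engines that write both endpoints (which is also why a 100-ns
window at 1 ps holds 100,001 conformations, and a 2-ns thinning of the
120-ns trajectory without the origin holds 60 snapshots).

`plantNacEpisode()` drives a chosen oxygen towards the phosphorus, in plane
with the scissile bond, along smooth half-sine profiles that reach the
episode's minimum distance and maximum angle exactly at the episode
midpoint; the default episode spans 105–112 ns and reaches 3.16 Å and
178.45°. Outside episodes the geometry stays open (> 10 Å). Because the
profiles are deterministic given the spec, the NAC census over a planted
trajectory is exactly predictable, which is how the filter is validated.

What the generator does **not** emulate: real protein geometry (no chain
connectivity, secondary structure or side chains), anharmonicity, solvent
damping, or coupling between the planted collective modes and the site
geometry (closure markers ride only the noise; the triad is driven
explicitly). Passing tests therefore demonstrate that the *analysis
machinery* is correct on data with the assumed statistical structure — they
say nothing about force fields or sampling of real trajectories.

## Numerical choices

* Internal units: Å, ps, amu, kJ/mol; all readers convert on ingest.
* Time windows are half-open $[a, b)$ by default with a `closed` flag,
  because both conventions occur in practice (see the frame-count arithmetic
  above); episode windows may end on the half-open boundary of a sampled
  window.
* Symmetry is enforced, not assumed: Hessians beyond $10^{-8}$ relative
  asymmetry are rejected, imported matrices beyond $10^{-6}$ are rejected
  rather than silently averaged, and covariance inputs are symmetrised
  only within tolerance.
* Degenerate inputs fail loudly: empty selections, fewer than 3 or collinear
  superposition points, zero-length angle vectors, ensembles over trivial
  modes, double mass-weighting.
* Subspace iteration in `modeViaEnsemble()` starts from the first frames of
  the centred ensemble (deterministic, inside the row space) and finishes
  with a Rayleigh–Ritz step; tolerance $10^{-12}$ relative on the
  eigenvalues.
* All randomness flows through explicit seeds; a fixed seed gives
  bit-identical structures, trajectories and ensembles (the RNG state of the
  caller is restored afterwards).

## Problem sizes used in the shipped analyses

The test suite exercises small dimers (10–60 residues per subunit, a few
hundred frames, dense clouds paired with a generous 20 Å cutoff so the toy
networks stay rigid); the full property suite runs in well under a minute.
The acceptance script (`scripts/acceptance.R`) runs the full-size recipe —
1150 C$\alpha$ atoms, 3450-dimensional covariance from 5001 frames,
5000-conformation ensembles per mode, a 7000-snapshot 1-ps window for the
NAC census — as a deliberate match to the shapes of the study it emulates.

## Known limitations

* The elastic-network backend reproduces mode shapes, not absolute
  frequencies; comparing wavenumbers against force-field normal modes
  requires `importHessian()` with a real Hessian.
* Mobile-region counts depend on the (configurable) threshold rule.
* The mode-comparison protocol matches modes by index; genuinely swapped or
  mixed modes across systems show up as off-diagonal structure for the user
  to interpret, exactly as the underlying method intends.
* On very small toy systems the ligand triad is a proportionally large
  perturbation of the network, so holo/apo mode similarity is lower there
  than for realistic sizes — an expected finite-size effect, visible in the
  cross-system overlap reported by the acceptance script (near 1 at full
  size).
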