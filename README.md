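# hingewatch

Domain-motion analysis for multidomain proteins: elastic-network normal
modes, essential dynamics, cross-system mode comparison, mobility profiling
and near-attack-conformation geometry — with a deterministic synthetic
generator so the whole pipeline runs and is tested without external data.

## The problem and who this is for

Enzymes like the dimeric triokinase/FMN cyclase fold bind their substrates
between two domains that sit ~14 Å apart in the open structure — far too
far for phosphoryl transfer — so catalysis hinges on a large-scale closure
motion. Structural bioinformaticians characterise such motions with a
standard toolkit that this package implements as composable, tested R
functions:

- **Normal-mode analysis.** From a Hessian **H** (here an anisotropic
  elastic network with pair superelements −k·r̂r̂ᵀ, or an imported
  force-field matrix), the mass-weighted eigenproblem

  Λ = diag(λ₁…λ₃N) = R M^(−1/2) H M^(−1/2) Rᵀ,  νᵢ = √λᵢ / 2π

  yields collective modes; the six lowest (rigid-body) modes are removed
  with an explicit rigid-body-projection diagnostic, and the next modes
  (NM7, NM8, NM9, …) are the hinge-bend/twist/wobble motions of the lobes.
- **Thermal ensembles.** Conformations x_ref + Σ cᵢ M^(−1/2) dᵢ with
  cᵢ ~ N(0, √(k_B T/λᵢ)) — classical equipartition — used both for
  visualisation and for the **cross-system comparison protocol**: reduce a
  single-mode ensemble to a common atom set, recover the mode as PC1 of the
  reduced ensemble, and compare systems by |dᵢ·dⱼ| ∈ [0, 1].
- **Essential dynamics.** C = ⟨(x −⟨x⟩)(x −⟨x⟩)ᵀ⟩ over rigid-body-fitted
  frames; Λ = R C Rᵀ with descending eigenvalues (variances, Å²),
  cumulative variance spectra, projections, extreme frames and porcupine
  (NMD) export.
- **Mobility.** Kabsch superposition (SVD with reflection exclusion), RMSD
  traces, RMSF about the iterated mean structure, mobile-region detection.
- **Near-attack census.** Per-frame O···P distances and O···P–O angles at
  the P vertex; a snapshot is a near-attack conformation when distance
  < 3.5 Å **and** angle > 155° (strict), with the 3.3 Å van-der-Waals P+O
  contact annotated.

## Worked example

A toy dimer (60 residues per subunit, two chains, one active site per L/K
interface), its elastic-network modes, the ensemble-recovery protocol, the
essential dynamics of a planted-hinge trajectory, and a NAC census over a
planted closure episode:

```r
library(hingewatch)

spec <- syntheticSpec(nResPerSubunit = 60, kDomainSize = 36, cloudRadius = 6,
                      domainSpacing = 22, nFrames = 2001, frameDt = 20,
                      nacEpisodes = data.frame(start = 20000, end = 30000,
                                               minDistance = 3.16,
                                               maxAngle = 178.45,
                                               oxygen = "O3"),
                      seed = 1)
dimer <- makeToyDimer(spec)
dimer
#> Structure: 132 atoms, 128 residues, chains: A B

modes <- eigenModes(massWeight(buildEnmHessian(dimer, cutoff = 20)))
split <- splitTrivial(modes)
round(split$rigidOverlap, 4)      # the 6 removed modes are exactly rigid-body
#> [1] 1 1 1 1 1 1
signif(eigenvalues(split$nontrivial)[1:3], 3)   # NM7-NM9
#> [1] 0.00401 0.00537 0.00580

rec <- modeViaEnsemble(dimer, modes, mode = 7, commonSelector = "name CA",
                       nConf = 5000, seed = 2)
rec$purity                        # lambda2/lambda1 of the reduced ensemble
#> [1] 3.670812e-34

traj <- makeHingeTrajectory(dimer, spec)
site <- sitePreset(dimer, kChain = "A", lChain = "B", label = "L2-K1")
traj <- plantNacEpisode(traj, site, spec@nacEpisodes)

pc <- pcaModes(covarianceMatrix(traj, selectAtoms(dimer, "name CA")))
head(varianceSpectrum(pc, 5))
#>   component eigenvalue cumulative
#> 1         1 28.6941473   41.42218
#> 2         2 12.0102945   58.75995
#> 3         3  6.6632570   68.37887
#> 4         4  0.1251489   68.55953
#> 5         5  0.1239668   68.73849

recs <- nacFilter(opDistanceSeries(traj, site, "O3"),
                  opoAngleSeries(traj, site, "O3"))
unlist(nacSummary(recs))
#>        nPass     fraction         dCut         aCut
#>  81.00000000   0.04047976   3.50000000 155.00000000
```

Reading the output: the three non-trivial modes carry the lowest
frequencies; the ensemble-recovery purity ~10⁻³⁴ confirms a clean
single-mode ensemble; the first three principal components explain 68% of
the C-alpha variance (the generator's planted spectrum); and 81 snapshots
(4.0% of the trajectory) satisfy the joint in-line-attack criterion, all
inside the planted 20–30 ns episode with extremes 3.16 Å and 178.45°.

`runPipeline(pipelineConfig(...))` chains all stages and writes CSV/NMD/PDB
outputs plus a `manifest.json` (parameters, seeds, file hashes, headline
numbers) under one run directory. A thin command-line wrapper lives at
`inst/scripts/hingewatch.R`.

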