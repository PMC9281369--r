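# quadval

Validation of quadruplex–duplex MD conformational ensembles against
solution-NMR observables.

## The problem

G-quadruplexes (G4s) are four-stranded nucleic-acid motifs: stacked planar
quartets of guanines, each quartet held together by a cyclic pattern of eight
Hoogsteen hydrogen bonds (N1–O6 and N2–N7) and stabilized by cations seated in
the central channel between the tetrad O6 planes. Complex G4s such as the
28-nt HIV LTR-III motif — `d[GGGAGGCGTGGCCTGGGCGGGACTGGGG]`, a three-tetrad
core whose 12-nt diagonal loop carries a GC duplex stem joined through an A4/T14
junction — are studied by molecular dynamics, and the simulations must be
judged against the NMR evidence: the deposited multi-model bundle and its NOE
distance restraints.

`quadval` is for computational structural biologists who need that comparison
as auditable, testable code rather than one-off scripts. It computes:

* **NOE back-calculation** — per-restraint effective distances as r⁻⁶ ensemble
  averages, d = ⟨r⁻⁶⟩^(−1/6), pooled over equilibrated frames and equivalent
  protons, with violation accounting beyond a 1 Å tolerance and per-residue
  attribution;
* **Hydrogen-bond analysis** — tetrad Hoogsteen (24 distances for a
  three-tetrad core), duplex Watson–Crick (9 for three GC pairs) and
  bifurcated N1–N7 classes, with a 3.0 Å / 135° formation criterion and
  per-bond persistence;
* **Torsion occupancy matrices** — the six backbone dihedrals per residue in
  normalized 15° bins with NMR-bundle overlay points;
* **RMSD splits and RMSF** — Kabsch superposition, align/measure mask
  separation (align on the quadruplex, measure on tetrad bases, backbone or
  duplex backbone), running averages, fluctuations about the mean structure;
* **Ion-atmosphere analyses** — centre-of-mass RDFs normalized against a bulk
  shell at 30 Å, SDF voxel grids (0.125 Å³) in OpenDX format, channel-state
  classification (bulk/approach/in-plane/cavity) and the occupancy-based
  binding free energy ΔG = −RT ln K;
* **Duplex clustering** — pairwise RMSD after quadruplex alignment,
  hierarchical agglomerative clustering, medoid representatives reported to
  80% cumulative population.

A first-class synthetic-data module (`buildIdealG4`, `buildDuplexStem`,
`generateFluctuatingTrajectory`, `injectIonEntry`, `deriveNOETable`,
`addBulkIons`) generates structures, trajectories, ion-entry schedules and
restraint tables with known ground truth, so the whole pipeline is exercised
end to end without downloading anything.

File formats: multi-model PDB bundles; DCD and a documented plain-text
trajectory dialect; NOE restraints as Amber DISANG, NMR-STAR
distance-constraint loops, or a documented 8-column TSV; reports as TSV/JSON;
configs and annotations as YAML.

## Worked example

```r
library(quadval)

## a synthetic quadruplex-duplex system with ground-truth annotation
sys <- buildSyntheticSystem(nTetrads = 3, nPairs = 3, channelIons = 2)
sys$model
#> StructureModel: 407 atoms, 20 residues
detectTetrads(sys$model)
#> [[1]]
#> [1] 1 2 3 4
#> [[2]]
#> [1] 5 6 7 8
#> [[3]]
#> [1]  9 10 11 12

## the full validation stage on a fluctuating trajectory with self-derived
## restraints (rigid G4: sigma 0.15 A; flexible duplex: sigma 0.45 A)
cfg <- defaultRunConfig(seed = 1)
cfg$synthetic$nFrames <- 200L
cfg$outputDir <- "quadval-demo"
val <- runValidation(cfg)
#> [inputs] 200 frames, 447 atoms, 667 restraints
#> [validation] 0/667 restraints violated
str(val$hbondPersistence)
#> List of 3
#>  $ tetrad    : num 0.683
#>  $ duplex    : num 0.116
#>  $ bifurcated: num 0
print(val$rmsdMean)
#>       mask      rmsd
#> 1 backbone 0.4984699
#> 2 duplexBB 0.7815164
#> 3  g4bases 0.2595521
```

Reading the output: the self-derived restraint table back-calculates with
**zero violations** (the self-consistency the r⁻⁶ convention guarantees); the
rigid tetrad core keeps ~68% Hoogsteen H-bond persistence under 0.15 Å noise
while the deliberately floppy duplex loses most Watson–Crick persistence at
0.45 Å; no bifurcated N1–N7 artifact geometry appears; and the RMSD split
ranks the elements exactly as their generator sigmas dictate (tetrad bases <
backbone < duplex backbone).

```r
ions <- runIonAnalysis(cfg)
ions$freeEnergy$boundFraction   # 2 seated ions vs a 40-ion bulk cloud
#> [1] 0.0476
cl <- runClustering(cfg)
cl$representatives
#>   cluster population cumulative representative
#> 1       1       0.97       0.97            180
```

With Gaussian fluctuation around one reference there is a single
conformational family, so one medoid already covers 97% of frames. Two-family
trajectories (see the clustering tests) are recovered perfectly.

Real-data use is identical, with file inputs instead of the synthetic block:
point `cfg$inputs` at a deposited multi-model PDB (for the LTR-III system,
accession 6H1K: 10 models), its 433-restraint NOE list in any supported
dialect, a trajectory, and the packaged annotation `ltr3Annotation()` —
tetrad membership is filled by `detectTetrads()` on the structure.

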