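---
title: "Validating quadruplex-duplex MD ensembles against NMR observables"
author: "quadval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating quadruplex-duplex MD ensembles against NMR observables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadval)
```

## The problem

Molecular-dynamics simulations of G-quadruplex (G4) nucleic acids are only as
trustworthy as their agreement with solution NMR. For a quadruplex-duplex
system such as the 28-nt HIV LTR-III motif — a three-tetrad G4 whose
12-nt diagonal loop carries a short GC duplex stem, joined through an A/T
junction — that agreement is judged on several fronts at once: NOE distance
restraints, hydrogen-bond geometry, backbone torsion distributions, RMSD/RMSF
of the structural elements against the deposited NMR bundle, the ion
atmosphere around the molecule, and the conformational families of the
flexible duplex. `quadval` implements that whole validation battery as
reusable, testable components, together with a synthetic-data generator that
provides ground-truth inputs for every stage.

## The observables and their models

**NOE back-calculation.** An NOE restraint relates two protons (or two groups
of equivalent protons) with lower/upper distance bounds. Because NOE
intensities average as $r^{-6}$, an ensemble is compared to a restraint
through the effective distance

$$d \;=\; \Big\langle r^{-6} \Big\rangle^{-1/6},$$

where the average pools all equilibrated frames and all inter-group proton
pairs. Averaging (rather than summing) over equivalent protons keeps the
identity $d(\text{constant } r) = r$, so a static structure back-calculates
its own distances exactly; users comparing against sum-over-pairs conventions
should expect systematically shorter effective distances from those. A
restraint is *violated* when $d$ exceeds a bound by more than a tolerance,
1.0 Å by default — the customary slack for the uncertainties in deriving NOE
bounds. Violations are attributed to both participating residues in the
per-residue table. Equilibration defaults to discarding the first 10% of
frames; a plateau criterion (first frame after which the running average of
the all-atom RMSD stays within 0.5 Å of its final value) is available where
a qualitative "equilibrated part" cut is wanted.

**Hydrogen bonds.** Tetrads are monitored through the eight cyclic Hoogsteen
bonds per quartet (four N1–O6, four N2–N7 — 24 distances for a three-tetrad
core), the duplex through the three Watson–Crick GC bonds per pair (O6–N4,
N1–N3, N2–O2 — nine for a three-pair stem), and, optionally, the bifurcated
N1–N7 geometry that flags a known force-field artifact. A bond is formed when
the donor–acceptor distance is ≤ 3.0 Å and the donor–H–acceptor angle is
≥ 135°; persistence is the formed fraction of frames. The angle is taken at
the hydrogen because that is the geometry the criterion is meant to gate;
the cutoffs are arguments, not constants.

**Torsions.** The six backbone dihedrals (α, β, γ, δ, ε, ζ) are histogrammed
per residue into left-closed 15° bins over [−180°, 180°) and normalized to
unit mass; each NMR-bundle model contributes one overlay point per angle, the
compact matrix representation used to compare simulated occupancies with
experimental bundles. The 5′ residue lacks α and β (no 5′ phosphate in
standard depositions) and the 3′ residue lacks ε and ζ; undefined entries are
marked as such, never zero-filled.

**RMSD/RMSF.** All superpositions are Kabsch-optimal proper rotations.
RMSD series align on one mask and measure on another (align on the
quadruplex, measure on tetrad bases, backbone, or duplex backbone — the
element-wise splits that separate the rigid G4 core from the mobile duplex),
against every model of the reference bundle; long traces get an edge-shrunk
centred running average (window 1000 frames by default) for plotting. RMSF is
computed about the average structure after one re-alignment iteration, and
defaults to heavy atoms since the reference bundles carry no reliable proton
dynamics; masks are configurable.

**Ion atmosphere.** The RDF is counted from the per-frame centre of mass of a
solute selection under the minimum-image convention and normalized by
$\rho \, 4\pi r^2 \mathrm{d}r$. The reference bulk density $\rho$ is measured
in a spherical shell at 30 Å from the centre of mass ([30, 31) Å — the shell
thickness is a package choice, as only the 30 Å radius is conventionally
fixed). No excluded-volume correction is applied for the irregular solute
shape: peak heights near the surface are therefore qualitative
(underestimated), a limitation recorded in the output metadata. The unnormalized
cumulative count $n(<r)$ is returned alongside; for a channel holding two
cations it must integrate to exactly 2 at the first minimum. SDFs accumulate
particles on cubic voxels (0.125 Å³ by default) after aligning all frames on
the solute, normalized by a reference density so that 1 means bulk-water-like.
The default reference density is 0.033456 Å⁻³, the number density of water at
1.0 g/mL; a different (e.g. historical or tool-specific) normalization can be
supplied via the config, since published values for this constant are not
always self-consistent.

**Channel occupancy and binding.** Each cation is classified per frame from
the tetrad O6-plane geometry: `cavity` within 2.0 Å of an inter-plane
midpoint, `in-plane` within 1.0 Å of a tetrad O6 plane (inside the ring
radius), `approach` within 4.5 Å above an outer plane on the solvent side,
else `bulk`. With the canonical 3.4 Å rise the cavity sphere and the in-plane
slab overlap geometrically; the tighter in-plane test takes precedence, which
is the physically meaningful resolution (an ion seated *in* a plane is not
octa-coordinated between two planes). All thresholds are configuration, since
no standard fixes them. Counting bound (default: `cavity`) versus unbound
ion-frames gives $K$ and $\Delta G = -RT\ln K$ in kJ/mol at the configured
temperature (300 K default, R = 8.314 J mol⁻¹ K⁻¹). One-sided occupancies
(all bound or none) are flagged rather than reported as infinite numbers.

**Duplex clustering.** Frames are aligned on the quadruplex and distances
measured on the duplex, giving a pairwise RMSD matrix (symmetrized by
averaging the two fit directions) that feeds hierarchical agglomerative
clustering. Average linkage is the default — only the agglomerative family is
conventionally fixed, and average linkage resists chaining; the cut is either
a cluster count (6 by default, matching the usual number of collected
representative conformations) or a height. Representatives are medoids with
ties broken by the lowest frame index, and the representativeness report
returns the shortest population-sorted prefix reaching 80% cumulative
coverage. Trajectories longer than 10⁴ frames are strided (default 10)
before the O(n²) matrix; the stride is recorded in the solution.

## The synthetic-data generator

Every analysis is testable without downloads because the generator builds
inputs with known ground truth:

* `buildIdealG4()` places planar guanines (standard base-frame geometry) in
  quartets whose cyclic Hoogsteen donor–acceptor distances are solved to
  exactly 2.87 Å, stacked at a 3.4 Å rise and 30° twist (canonical stacking,
  configurable), with channel cations exactly at inter-plane midpoints.
* `buildDuplexStem()` builds GC pairs whose three Watson–Crick distances are
  solved into the 2.8–3.0 Å window, with H-bonding protons aimed along the
  donor–acceptor lines (idealized 180° geometry).
* `generateFluctuatingTrajectory()` adds isotropic per-coordinate Gaussian
  noise with per-group σ — so per-atom RMSF has the closed form σ√3 and
  every estimator can be checked against the generating parameter.
* `injectIonEntry()` scripts an ion through bulk → approach → in-plane →
  cavity anchors computed from the per-frame tetrad geometry, so the state
  classifier can be round-tripped exactly.
* `deriveNOETable()` emits restraints for every proton pair within a cutoff,
  with target equal to the reference distance (bundles: the r⁻⁶ model
  average) and bounds target ± padding — self-consistent by construction, so
  the violation count on the generating structure is 0 at tolerance 0.
* `addBulkIons()` appends a uniform ion cloud, the ideal-gas null for the
  RDF/SDF estimators.

Residues carry the minimal atom set the analyses touch (H-bond donors and
acceptors, C1′, a six-atom backbone chain with plausible but not chemically
exact internal geometry, and named base/sugar protons). What the generator
does **not** emulate: force-field energetics, correlated motions, solvent
structure, sequence-dependent helical parameters, or realistic proton
positions beyond the H-bonding geometry. Tests passing on synthetic data
therefore certify the *estimators* — their arithmetic, conventions, units and
invariances — not the physical realism of any simulation; conclusions about a
real system still require real trajectories and the deposited bundle and
restraint list.

## Numerical choices

* Coordinates are Å, times ps, 1-based residue ids, 0-based half-open frame
  ranges at the user surface.
* Restraint-file dialects are never sniffed; the dialect flag is mandatory
  because a silently misparsed bound is the worst failure mode of a
  validation tool. Pseudoatom/wildcard proton names are expanded to explicit
  proton groups at parse time from a packaged nomenclature map, and
  ambiguous groups are kept as groups.
* Back-calculated excesses below 10⁻⁹ Å are reported as exactly 0, so
  padding-0 self-consistency is not broken by float rounding.
* Tetrad detection requires a closed 4-cycle of N1→O6 / N2→N7 contacts
  (defaults 3.5 Å, loose enough for NMR-quality geometry) with base atoms
  within 1.0 Å of their common plane; quartets are ordered along the channel
  axis with the direction tied to residue numbering, making the order
  invariant under rigid moves.
* Cluster labels are renumbered by first appearance and medoid ties break to
  the lowest frame index, so solutions are deterministic.
* Trajectory I/O: binary DCD (written by the package, readable by standard
  tools) and a documented plain-text TSV dialect; XTC/NetCDF are out of scope
  as no reader dependency is available. DCD stores float32, so round-trips
  are exact to ~10⁻⁶ Å.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the generator at desk scale:
200–400-frame validation trajectories, a 5000-frame single-tetrad trajectory
for the RMSF σ√3 recovery (5% tolerance), a 100-frame scripted ion-entry
trajectory, a 200-frame / 100-ion ideal-gas box for the g(r) = 1 null, and a
10-frame two-family trajectory for cluster recovery. These sizes were chosen
so the closed-form expectations dominate sampling noise by a comfortable
margin. Headline numbers that in the original study derive from 12 μs of
all-atom MD (per-condition violation counts, ΔG magnitudes, RMSD plateaus)
are *not* reproducible from synthetic Gaussian dynamics and are not claimed;
the pipeline computes them, but their values on synthetic input characterize
the generator, not any force field.

## A worked run

```{r run, eval = FALSE}
cfg <- defaultRunConfig(seed = 1)
cfg$outputDir <- "quadval-demo"
res <- runAll(cfg)
res$validation$nViolations     # 0 on the self-consistent synthetic system
res$manifest$total_us          # 12
```

See the README for the complete worked example with printed output, and
`scripts/acceptance.R` for the script that recomputes every headline quantity
from scratch.

## Known limitations

* The RDF spherical-shell normalization is qualitative near an irregular
  solute surface (no excluded-volume correction; see above).
* The DISANG reader resolves plain atom indices against the supplied
  topology; restraint files using Amber's extended grouping syntax beyond
  `iat`/`igr1`/`igr2`/`r1..r4` are out of scope.
* Channel-state thresholds are geometry heuristics; for systems far from a
  canonical three-tetrad stack they should be re-examined rather than
  trusted.
* The NMR-STAR reader handles distance-constraint loops with one tag set per
  loop; full STAR grammar (multi-datablock, quoted multiline values) is not
  implemented.
```
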