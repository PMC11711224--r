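# slabtraj

Trajectory analysis of proteins at water/organic slab interfaces.

When protein solutions are emulsified against an organic solvent (as in
double-emulsion particle manufacturing, where an aqueous cytokine phase
meets dichloromethane), proteins adsorb to the liquid–liquid interface,
reorient, spread and partially unfold. Molecular-dynamics slab simulations
probe this at atomic resolution, but they are only as useful as the
analysis chain that reads them. `slabtraj` implements that chain for
biphasic slab trajectories, for researchers in structural bioinformatics
and molecular modelling:

* **Interface localization**, per frame, by cross-solvent proximity
  histograms — organic particles within a cutoff (default 0.5 nm) of any
  water particle and vice versa are histogrammed along the normal, and
  each interface is the midpoint between the two histogram modes — with
  the **Gibbs dividing surface** construction (the equal-excess balance
  ∫ deviations of both species on the water side of x_b = ∫ deviations on
  the organic side) as the protein-free reference oracle.
* **Signed protein–COM interfacial distance** (positive on the water
  side), **close/near/far regime classification**, per-residue distance
  profiles, frame-count histograms and spreading widths.
* **Orientation classification** against a six-pose reference library
  (base pose rotated by 90° about two axes), by smallest per-atom
  deviation after COM alignment.
* **RMSD** (with or without Kabsch superposition) and per-residue
  **RMSF** over an equilibrated window, resolved by orientation and
  regime.
* **Mechanical surface tension** from diagonal pressure-tensor series,
  γ(t) = (L_N/n)·(P_NN − (P_T1T1 + P_T2T2)/2), with block-averaged
  errors, and the **Girifalco–Good parameter**
  φ = (γ_A + γ_B − γ_AB)/(2√(γ_A γ_B)).
* **Per-residue contact-frequency maps** over docked-complex ensembles
  (any atom within 5 Å of the partner protein), docking-campaign
  bookkeeping, and geometric hydrogen-bond counting.
* A **synthetic-data layer** that generates slab trajectories, pressure
  series and complex ensembles with known ground truth (planted
  interfaces, COM programs, orientation schedules, tensions, contact
  rates), so every estimator is validated by parameter recovery.

Formats: PDB (via bio3d), GRO, multi-frame XYZ, TSV/CSV tables, JSON
sidecars. Internal units: nm, ps, bar, u, bar·nm.

## Worked example

Generate a slab with a pseudo-protein drifting from the water bulk toward
the interface under a cycling orientation schedule, then run the analysis
chain:

```r
library(slabtraj)

ref  <- makeTestProtein(60, size = 0.9)
lib  <- makeOrientationLibrary(ref)
prot <- pseudoProteinSpec(ref, library = lib, comProgram = "drift",
                          comStart = c(1.5, 2, 2), comEnd = c(4.1, 2, 2),
                          orientations = rep(orientationLabels(lib),
                                             length.out = 12))
sim <- makeSlabTrajectory(slabSpec(box = c(10, 4, 4), interfaces = 5.5,
                                   mixingWidth = 0.3, nFrames = 12,
                                   seed = 7), prot)

iface <- locateInterfaceHistogram(sim$trajectory, sim$topology, pbc = FALSE)
iface
#> InterfaceModel (histogram): 12 frames, 1 interface(s) along x
#>   mean position(s): 5.521 nm

series <- conformationSeries(sim$trajectory, sim$topology, iface, lib)
series$regime <- as.character(classifyRegime(series$distance))
head(series[, c("frame", "rmsd", "orientation", "distance", "regime")], 4)
#>   frame  rmsd orientation distance regime
#> 1     0 0.000         red     4.05    far
#> 2     1 0.726      orange     3.76    far
#> 3     2 1.080      yellow     3.53    far
#> 4     3 0.987       green     3.29    far
```

The locator recovers the planted interface (5.5 nm) to within a fraction
of the 0.1 nm histogram bin; the distance column tracks the planted drift
(4 nm down toward 1.4 nm, positive = water side); the orientation column
reproduces the planted schedule; and the RMSD column reports raw
(non-superposed) deviation from the first frame, so the planted
reorientations register as structural change — pass `superpose = TRUE`
to measure pure deformation instead.

Surface tension from a pressure series with a planted 300 bar·nm tension
under 50 bar component noise, and the Girifalco–Good parameter at the
water/dichloromethane literature tensions:

```r
est <- surfaceTension(makePressureSeries(300, boxLength = 10,
                                         nInterfaces = 2, nFrames = 5000,
                                         noiseSd = 50, seed = 1))
est
#> TensionEstimate: 303.2 +/- 1.48 bar nm (5000 frames, 2 interface(s), 5-block SE)

girifalcoGoodPhi(720, 280, 551)
#> [1] 0.5000012
```

End-to-end runs with TSV outputs and a reproducible manifest:

```r
runInterfaceAnalysis(list(
  seed = 5,
  synthetic = list(box = c(8, 4, 4), interfaces = 5, nFrames = 6),
  regime = list(close_nm = 1.2, near_nm = 3.0),
  output = list(dir = "out")))
```

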