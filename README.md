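# trajprofiler

Trajectory-ensemble analysis of protein–ligand binding sites, built for
the question that arises when a membrane lipid such as phosphatidylinositol
(PI) competes with another ligand at a site on a C4-symmetric channel like
TRPV1: **which residues define the site, how selective are they between
two ligand species, and which species binds more stably?**

It is aimed at structural bioinformaticians and MD practitioners who have
a multi-frame ensemble (multi-model PDB, or a plain per-frame coordinate
table) of a protein–ligand complex and want reproducible, testable numbers
rather than one-off analysis scripts.

## What it computes

For an ensemble of `T` frames over a fixed topology with subunits
`s = 1..S`:

- **Contact frequency** of residue `r` against a ligand headgroup `H`:
  `f_s(r) = (1/T) Σ_t 1[ min_{i∈side(r), j∈H} ‖x_i(t) − x_j(t)‖ ≤ c ]`,
  with cutoff `c = 5 Å` over sidechain/headgroup *heavy* atoms, combined
  over subunits by the arithmetic mean `f(r) = (1/S) Σ_s f_s(r)`.
- **Selectivity** between species A and B at threshold `t = 0.5`:
  residue classes `selective_A` (`f_A ≥ t > f_B`), `selective_B`,
  `shared`, `neither`, plus the cumulative frequency `f_A + f_B ∈ [0, 2]`.
- **Minimum-distance time series** per residue, subunit-averaged, with a
  mean-separation screen (flagging residues, e.g., > 4 Å farther than the
  contact shell).
- **Ligand RMSD vs the initial configuration**, per subunit, after Kabsch
  superposition on binding-site Cα atoms (SVD with proper-rotation
  correction).
- **Atomic density maps**: each heavy atom deposited as a Gaussian of
  σ = 1.0 Å (truncated at 4σ, mass-normalized) on a 0.5 Å grid, frames
  averaged; OpenDX in/out; map–map **cross-correlation about zero** after
  trilinear resampling (for two unit Gaussians offset by δ this equals
  `exp(−δ²/4σ²)`).
- **Water bridges**: fraction of frames in which a water oxygen is within
  3.5 Å of both a polar (N/O) sidechain atom and a polar ligand atom, and
  the corresponding 6 Å water occupancy map.

A seeded generator of C4-symmetric tetramer ensembles with designed
contact probabilities, ligand pose noise and bridge occupancy provides
ground truth for every stage, and `run_pipeline()` executes the whole
sequence from one YAML config (also available as the `profiler` script in
`exec/`).

## Worked example

Two 500-frame synthetic tetramer ensembles with a designed contrast —
species A stable (σ = 0.5 Å) and selective residues 401–408, species B
unstable (σ = 2.0 Å) — analyzed end to end:

```r
library(trajprofiler)
spec <- synthetic_spec(n_frames = 500, seed = 42)
genA <- generate_ensemble(spec, "A")
genB <- generate_ensemble(spec, "B")

profA <- contact_frequencies(genA$ensemble, genA$ligand, cutoff = 5)
profB <- contact_frequencies(genB$ensemble, genB$ligand, cutoff = 5)
classify_selectivity(profA, profB, threshold = 0.5)
#> Selectivity of A vs B at threshold 0.50:
#>   selective_A ( 8): ASP401 SER402 LYS403 LEU404 ILE405 VAL406 THR407 PHE408
#>   selective_B ( 2): ARG415 HIS416
#>   shared      ( 6): GLN409 MET410 ALA411 TYR412 ASN413 TRP414
#>   neither     ( 4): CYS417 PRO418 ASP419 SER420

rmsd_series(genA$ensemble, genA$ligand)
#> RMSD series: 500 frames x 4 subunit(s) [site_ca (15 A), subunit alignment], ref frame 1
#>   time-averaged RMSD per subunit (A):  A=0.85 B=0.86 C=0.86 D=0.86
rmsd_series(genB$ensemble, genB$ligand)
#> RMSD series: 500 frames x 4 subunit(s) [site_ca (15 A), subunit alignment], ref frame 1
#>   time-averaged RMSD per subunit (A):  A=3.42 B=3.40 C=3.41 D=3.44

water_bridge_frequency(genA$ensemble, 409, genA$ligand)
#> Water bridge GLN409 -- A (d <= 3.50 A): frequency 0.692 over 500 frames x 4 subunit(s)
```

The selectivity classes recover the design exactly; the time-averaged
RMSDs estimate σ√3 (0.87 Å and 3.46 Å) for the two noise levels, so the
stable species is identified immediately; and the bridge frequency
estimates the designed 0.7 occupancy. On real data, replace the generated
ensembles with `read_structure_ensemble("traj.pdb")` and a
`ligand_spec()` naming your headgroup atoms.

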