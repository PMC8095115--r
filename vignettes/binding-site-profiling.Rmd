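---
title: "Profiling phosphoinositide binding sites from trajectory ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling phosphoinositide binding sites from trajectory ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajprofiler)
```

## The problem

Membrane phosphoinositides such as phosphatidylinositol (PtdIns, PI) and
PtdIns(4,5)P~2~ (PIP~2~) regulate TRP-family ion channels by binding at
specific sites on the transmembrane domain. Locating such a lipid site from
a molecular-dynamics ensemble, deciding which residues define it, and
judging whether one lipid species binds more stably than another are
recurring analysis tasks: the raw material is always the same — a
multi-frame coordinate ensemble of a (often C4-symmetric, homotetrameric)
protein–ligand complex — and the questions are always geometric.

`trajprofiler` packages that workflow as a set of composable, tested
operations:

1. **Contact fingerprinting** — per-residue contact frequencies against a
   ligand headgroup, per subunit and subunit-combined.
2. **Differential selectivity** — classifying residues as selective for one
   of two ligand species, shared, or neither, at a frequency threshold.
3. **Minimum-distance series** — per-frame residue–headgroup minimum
   distances, with subunit averaging and mean-separation screening.
4. **Superposition and RMSD** — Kabsch least-squares fitting and
   per-subunit ligand RMSD relative to the initial configuration.
5. **Density maps** — frame-averaged, mass- or occupancy-weighted atomic
   density on a regular grid, with OpenDX input/output and map–map
   correlation against a reference density.
6. **Water bridges** — occupancy of water molecules simultaneously
   hydrogen-bond close to a residue sidechain and a ligand polar atom.

Because production MD trajectories are rarely redistributable, the package
also ships a **synthetic ensemble generator** whose ground truth is known
by construction; every analysis stage is validated against it.

## Contact fingerprinting

A protein residue is *in contact* with the ligand in a frame iff the
minimum distance between any of its **sidechain heavy atoms** and any
**heavy headgroup atom** of that subunit's ligand is at most the cutoff.
Defaults and conventions:

| parameter | default | meaning |
|---|---|---|
| `cutoff` | 5.0 Å | contact distance threshold (closed boundary: a pair at exactly the cutoff counts) |
| `combine_mode` | `subunit_mean` | arithmetic mean of per-subunit frequencies |
| `threshold` | 0.5 | selectivity threshold: contact in at least half of the frames |

Hydrogens are retained in the data model but excluded from every distance
and density analysis; headgroups are defined on heavy atoms. Backbone
atoms (`N`, `CA`, `C`, `O`) never participate in contacts, so glycine —
having no sidechain heavy atom — can never register contact; this is a
deliberate convention, and users who want backbone contacts can inspect
minimum-distance series instead. Where the threshold could be applied
per-subunit or to the combined value, we apply it to the **combined**
frequency; `frame_pooled` combination is available because per-subunit
counts pooled over frames are an equally defensible reading (the two agree
exactly for residues present on all subunits).

The headgroup atom set must be named explicitly in the `ligand_spec()`:
which atoms constitute the polar headgroup is a chemical definition that
coordinate files do not carry.

Neighbor detection uses a uniform cell grid with edge equal to the cutoff,
querying the 27 surrounding cells; for small atom counts a vectorized
brute-force path is used instead, and the two are verified to return
identical contact sets on seeded random frames.

Ligand-to-subunit pairing defaults to same-chain. Inter-subunit sites (a
ligand bound between two protomers, as at vanilloid-type pockets) are
handled with an explicit pairing map.

## Selectivity between two ligand species

Given two contact profiles computed with the same cutoff and combine mode,
`classify_selectivity()` partitions the union of contacted residues at the
threshold *t*:

- selective for A: freq~A~ ≥ *t* and freq~B~ < *t*;
- selective for B: the converse;
- shared: both ≥ *t*; neither: both < *t*;

and reports the cumulative frequency freq~A~ + freq~B~ ∈ [0, 2] per
residue, the quantity plotted as stacked bars when comparing a lipid and a
competing agonist. `dual_ligand_shared_contacts()` is a convenience view of
the shared class for the two-lipid comparison.

## Superposition and RMSD

`superpose()` implements the Kabsch algorithm via singular value
decomposition of the weighted covariance matrix; a reflection in the
least-squares optimum is corrected by a sign flip along the smallest
singular axis so the rotation is always proper (determinant +1).
Degenerate inputs — fewer than three points, or collinear points, detected
by the ratio of the second singular value of the centered coordinates —
are rejected with an error. Superposition is unweighted by default;
mass-weighting is available.

`rmsd_series()` reports, per frame and subunit, the heavy-atom RMSD of a
target (typically the ligand) after superposing the frame onto the
reference frame on an alignment selection, with **no further fitting of
the target**. The reference is frame 1, the initial configuration; frames
are 1-based throughout the package, following R convention. The alignment
selection defaults to the subunit's Cα atoms within 15 Å of the target's
reference-frame centroid (falling back to all Cα of the subunit if fewer
than three qualify) — the choice of alignment region is genuinely open in
this kind of analysis, so it is configurable, and a `scope = "global"`
variant aligns the whole tetramer with a single fit instead; results
should state which was used. Per-subunit alignment is the default because
it isolates the ligand's motion relative to its own binding site from
slow inter-subunit drift.

## Density maps

`atomic_density_map()` interprets *resolution* as the grid spacing and
*atom size* as the standard deviation of the isotropic Gaussian deposited
per atom (the upstream grid tools leave kernel semantics undefined, so
both are explicit, configurable parameters; defaults 0.5 Å and 1.0 Å,
mass-weighted). Numerical choices:

- the kernel is spherically truncated at 4σ and renormalized so each
  deposit integrates to exactly the atom's weight (hence single-frame maps
  conserve the selection's total mass to machine precision, and clipping
  at map edges cannot lose mass);
- the grid covers the selection's bounding box over all frames, padded by
  4·atom_size, with the origin snapped to a multiple of the spacing so
  that maps of the same region are commensurable;
- per-frame maps are combined by arithmetic averaging, which makes the
  frame average exactly linear.

Maps are written and read as OpenDX scalar grids (z-fastest data order);
only uniform, axis-aligned grids are supported, and anything else is
rejected as an unsupported dialect. BRIX or MRC ingestion is out of scope;
convert externally.

`map_correlation()` resamples the second map onto the first map's grid by
trilinear interpolation and correlates over voxels where either map
exceeds a mask threshold. The default score is the **cross-correlation
about zero** (no mean subtraction), the convention used when judging how
well a computed ligand density fits an experimental blob: for two unit
Gaussians of width σ offset by δ it equals exp(−δ²/(4σ²)) up to
discretization, which makes it directly interpretable as fractional
overlap. The mean-centered Pearson coefficient is available with
`center = TRUE`; over a compact masked region the two differ
substantially, so reports should state which was used. The paper-style
visual "better fit / worse fit" judgement has no standard numeric
equivalent — this correlation is our quantification of it.

## Water bridges

`water_bridge_frequency()` counts a frame (per subunit) as bridged iff
some water oxygen lies within `d_bridge` (default 3.5 Å) of a polar (N/O)
sidechain heavy atom of the residue **and** within `d_bridge` of a polar
(N/O) heavy atom of the ligand. This is a pure heavy-atom donor–acceptor
criterion with no angular term — deliberately minimal, since distance
criteria dominate bridge detection and the angular refinement would add a
parameter with little discriminating power at this resolution.
`water_occupancy_map()` is the volumetric counterpart: water oxygens
within a 6 Å shell of both the residue and the ligand are deposited with
weight 1 and frame-averaged, so the map integral equals the mean number
of qualifying waters per frame (summed over subunits).

## The synthetic generator

`synthetic_spec()` / `generate_ensemble()` build a **deliberately
schematic** C4-symmetric tetramer: four subunits related by 90° rotations
about z, each with 20 proxy residues (4-atom backbone, 3-atom sidechain on
a fixed radial ray) around a bound ligand whose 3-atom headgroup triad
anchors all distance definitions. It is not a protein model — the analyses
under test are purely geometric, so chemical realism would add cost
without adding test power. What it emulates, with exact ground truth:

- **designed contact probabilities**: per frame and subunit, each residue
  is placed inside the 5 Å shell (at 3.0 ± 0.3 Å) with probability *p* or
  beyond it (8.0 ± 0.3 Å) otherwise. The designed distance is realized
  against the *actual, jittered* headgroup positions of that frame, so
  realized contact states equal the designed Bernoulli draws exactly when
  the protein scaffold is noise-free, at any ligand noise level;
- **ligand pose stability**: per-coordinate Gaussian jitter of all ligand
  atoms, σ = 0.5 Å for the stable species A versus 2.0 Å for the unstable
  species B by default, mirroring a stable-lipid versus unstable-lipid
  contrast; time-averaged RMSD then estimates σ√3;
- **a water bridge**: one water per subunit toggling, with designed
  occupancy 0.7, between the midpoint of the bridge residue's polar tip
  and the nearest ligand oxygen (bridging) and a parked position 18 Å
  away. The bridge residue is glutamine-like and held in permanent
  contact so the bridge geometry is well defined; the midpoint
  construction guarantees the designed occupancy whenever the tip-to-
  oxygen separation is below twice the bridge cutoff, which holds
  essentially always at the stable-species noise level and degrades only
  at extreme ligand noise.

The default design — 8 residues selective for A (0.9/0.1), 6 shared
(0.9/0.9), 2 selective for B, 4 background (0.1), over 1000 frames —
matches the scale of the site this package was built to characterize.
Frame 1 is the noise-free base configuration and serves as the RMSD
reference. All random draws are made as whole arrays in one documented
order from a single seeded stream, so fixtures are byte-identical across
runs; per-species sub-seeds are derived from the spec seed.

What the generator does **not** emulate: correlated protein dynamics,
rotamer chemistry, solvent structure beyond the designed bridge,
periodic-boundary artifacts, or force-field physics. Passing the recovery
tests therefore demonstrates the *analysis* code is correct, not that any
particular biological conclusion is — on real trajectories the usual
caveats (sampling, imaging, alignment choice) apply.

## Problem sizes and verification

The test suite and the acceptance script regenerate everything they
measure. Representative sizes, chosen to make the statistics decisive at
desk scale: contact and bridge recovery on the full T = 1000 tetramer
(3σ binomial envelopes); the noise-RMSD closed form on a 100-heavy-atom
ligand over 500 sampled frames; the stability contrast over 100 replicate
ensemble pairs of 60 frames; neighbor-search equivalence on 100 random
frames of up to 200 atoms; density checks on single- and two-atom maps
where closed forms exist. The pipeline runner thins frames for the
density stage (`density_stride`, default 10) since frame-averaged maps
converge quickly relative to contact statistics.

## Known limitations

- Inputs must be pre-imaged; no periodic wrapping is applied (a bounding-
  box sanity check flags suspect frames).
- Binary trajectory formats (DCD/XTC) are out of scope; convert to
  multi-model PDB or the frame-table dialect first.
- Contact definitions are per-residue, not per-atom, and make no
  interaction-type distinction beyond the water-bridge analysis.
- The `summary.txt` pipeline log records wall times and is therefore the
  one output file excluded from byte-identity checks; all TSV/DX outputs
  are exactly reproducible given the same configuration and seed.
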