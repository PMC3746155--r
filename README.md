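# lipidprint

Protein–lipid contact fingerprints and annular-lipid analysis for
membrane proteins, in R.

Membrane proteins are ringed by an *annulus* of lipids that exchange with
the bulk bilayer. A handful of 2D electron-crystallography structures
resolve some of these lipids directly; molecular-dynamics trajectories
resolve all of them, at the price of needing validation against the
structural data. `lipidprint` implements the analysis layer connecting
the two for coordinate data in PDB/GRO form:

- **Contact fingerprints** — per-residue lipid contact frequencies from
  trajectories (4 Å heavy-atom cutoff for atomistic data, 6 Å for
  coarse-grained beads), decomposed by lipid segment (terminal head
  group, phosphate, glycerol, acyl tail), plus 0/1 profiles from
  lipid-containing crystal structures. A residue's head-group fraction is

  `f_hg(r) = (1/N) * #{ frames : min dist(r, head-group particles of any lipid) <= cutoff }`

  over the N frames of the analysis window (default: the final 80% of
  the run).
- **Profile correlations** — Pearson r between fingerprints from
  different sources (simulation vs crystal, lipid A vs lipid B), with
  head-group/tail channels split across the triangles of the
  correlation matrix.
- **Annulus geometry** — leaflet assignment, in-plane phosphate density
  maps, local bilayer-thickness (P–P distance) maps with bulk and
  annular summaries (hydrophobic-mismatch relief), axial distributions
  of residue types.
- **Residence statistics** — per-lipid fractional contact times, binding
  events, and the in-plane trace of the most-bound lipid.
- **Residue-type × segment tables** — interaction percentages normalised
  by residue-type occurrence across many structures.
- **Alignment projection** — contact conservation mapped onto a family
  multiple sequence alignment with per-column family means.
- **A synthetic trajectory generator** — seeded toy membrane systems
  (protein cylinder, two-state Markov annulus sites, bulk lipids on a
  radial thickness profile) with closed-form ground truth, standing in
  for microsecond MD in every test.

## Worked example

Generate a coarse-grained toy system under the default study conditions —
a DSPE-like bilayer (bulk P–P distance 50 Å thinning to 35 Å at the
protein), 24 annulus sites at 15% occupancy, 100 bulk lipids per leaflet,
200 frames — and run the main analyses:

```r
library(lipidprint)

params <- syntheticParams(nFrames = 200L, seed = 7L)
sim    <- generateMembraneTrajectory(params)
traj   <- classifyParticles(sim$trajectory, bundledScheme("martini"))
traj
#> Trajectory: 200 frames x 1016 particles, coarse_grained

prof <- contactProfile(traj, sourceTag = "CG toy")
prof
#> ContactProfile [CG toy]: 120 residues, 160 frame(s), scale=fraction
r <- profileTable(prof)
head(r[order(-r$headgroup_fraction),
       c("chain", "resseq", "resname", "headgroup_fraction",
         "tail_fraction")], 3)
#>    chain resseq resname headgroup_fraction tail_fraction
#> 42     B     12     TRP             0.3375        0.3375
#> 43     B     13     LYS             0.3375        0.0500
#> 44     B     14     ARG             0.3375        0.0000

thicknessMap(traj)
#> ThicknessMap: bulk 49.86 A (2400 bins), annular 34.99 A (18 bins)

lipidContactFractions(traj)
#> ResidenceTable: 224 lipids over 160 frames; mean contact fraction 0.016

interactingLipidCount(traj)$mean
#> 3.62
```

Reading the output: the highest-frequency contacts sit on the basic and
aromatic residues at the phosphate/glycerol levels (here, a
Trp/Lys/Arg patch in contact in ~34% of analysed frames — two annulus
sites at 15% occupancy each feed the same residues); the thickness map
recovers the designed 50 Å bulk and 35 Å annular P–P distances; the mean
number of lipids with a phosphate within 6 Å of the protein is the
annulus occupancy (24 sites × 0.15 ≈ 3.6).

Per-residue values can be coloured onto a structure via the B-factor
column (`writeBfactorPdb()`), profiles written as TSV (`writeProfile()`),
and contact conservation projected onto a family alignment
(`mapProfileToAlignment()`, `aggregateFamily()`).

## Scope notes

Text PDB/GRO coordinates only (no XTC/DCD), orthorhombic boxes only, no
hydrogen-bond detection or kinetic rate fitting. The vignette
(`vignettes/lipidprint-methods.Rmd`) documents the models, parameter
choices, generator design and known limitations.
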