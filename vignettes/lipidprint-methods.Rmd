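---
title: "Lipid contact fingerprinting: models, parameters and validation"
author: "lipidprint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lipid contact fingerprinting: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidprint)
```

## The scientific problem

Membrane proteins sit in a shell of *annular* lipids that exchange with
the bulk bilayer. Crystal structures occasionally resolve a few of these
lipids; simulations resolve all of them but need validation. This package
implements the analysis layer that connects the two: per-residue lipid
contact fingerprints, their correlation across data sources, the geometry
of the annulus (in-plane phosphate density, local bilayer thickness,
residence statistics), residue-type preferences for the four chemical
segments of a phospholipid, and the projection of contact conservation
onto a family sequence alignment.

## Contact model

A *contact* is residue-level presence/absence per frame: protein residue
`r` contacts lipid molecule `l` in a frame when any heavy particle of `r`
lies within the cutoff of any particle of `l`. The cutoff follows the
field's two conventions, selected by the data's resolution tag:

* **4 Å** between heavy atoms for atomistic coordinates (hydrogens are
  excluded: crystal structures rarely resolve them, and the 4 Å
  convention is heavy-atom based);
* **6 Å** between beads for coarse-grained coordinates, the accepted
  equivalent of the atomistic 4 Å criterion.

Presence/absence (rather than atom-pair counts) keeps single-structure
0/1 profiles commensurable with trajectory frequency profiles. Contacts
are decomposed by the lipid segment involved -- terminal head group
(choline or ethanolamine), phosphate, glycerol backbone, acyl tail --
with the head-group *class* defined as terminal + phosphate + glycerol.
The `ContactProfile` of a trajectory records, per residue, the fraction
of analysed frames with at least one contact in each segment and class.

Contacts are found with a cell-list spatial index whose result is
bit-identical to the all-pairs computation (both paths share one distance
kernel); the brute-force path is retained and compared in the tests.
Minimum-image distances are used when a periodic box is present;
orthorhombic boxes only -- triclinic inputs are rejected at read time so
the minimum-image arithmetic stays exact.

### Analysis window

Production analyses conventionally discard the equilibration phase. The
window is fractional: the default `c(0.2, 1)` analyses frames after the
first fifth of the trajectory (for a 1 microsecond run, 200 ns onward),
and applies to any trajectory length. A frame `i` of `n` is analysed when
`start < i/n <= end`.

### Correlations between profiles

`correlateProfiles()` computes the standard Pearson product-moment
correlation over the per-residue fraction vectors of one channel
(head-group or tail). Design choices where conventions diverge:

* residues missing from one profile (unresolved termini) are **dropped**,
  not zero-filled, and the dropped count is reported -- zero-filling
  would manufacture agreement;
* zero-variance vectors yield `NA` with an explicit `undefined`
  attribute instead of `NaN`;
* correlating a trajectory profile against a crystal 0/1 profile mixes
  scales; it is permitted (it is the standard use) and flagged via a
  `mixed_scale` attribute;
* homo-oligomer profiles are computed per chain; `averageSubunits()`
  pools chains by residue number, and family-level comparisons use the
  averaged profile. Whether published correlation tables averaged or
  concatenated subunits is generally unstated; both remain available.
* `correlationMatrix()` places head-group correlations in the upper
  triangle and tail correlations in the lower, the layout used in
  published contact-correlation tables.

## Membrane geometry

**Leaflets.** The bilayer midplane is the median phosphate z, recomputed
per frame (robust to slow drift); a lipid's leaflet is the sign of its
mean phosphate z against it.

**Alignment.** Before any in-plane gridding, frames are aligned by
removing the protein's xy centre-of-geometry drift. No rotational fit is
applied by default: for a roughly four-fold-symmetric tetramer a
rotation fit is poorly conditioned and translation-only is least
destructive.

**Density.** The phosphate density of a leaflet is a 2D histogram over
analysed frames, normalised to mean count per Å² per frame. Default
spacing 1 Å resolves single-lipid peaks. By construction the integral
(sum × spacing²) equals the leaflet's mean per-frame phosphate count --
an exact conservation law the tests assert to 1e-12.

**Thickness.** Each leaflet's z surface is the time-averaged mean
phosphate z per 2 Å bin (nearest-phosphate binning, no smoothing);
local thickness is the difference of the two surfaces, NA where either
leaflet lacks samples. The *annular* summary averages bins whose centre
lies within the contact cutoff of the protein's xy footprint, reusing
the contact convention for consistency; the *bulk* summary averages bins
farther than a 20 Å margin. The summaries quantify hydrophobic-mismatch
relief: a lipid much thicker than the protein's hydrophobic span (e.g. a
di-C18:0 PE at ~50 Å P-P distance) thins locally to the protein-imposed
~35 Å, while a matched lipid (di-C14:0 PC at ~35 Å) shows bulk =
annular.

**Axial distributions.** Histograms of side-chain reference z (centroid
of non-backbone heavy particles; the bead itself for single-bead
residues) relative to the midplane, for chosen residue types -- typically
Trp/Tyr/Arg/Lys, the types that lock proteins into the head-group
region. The head-group band (mean phosphate z ± 1 sd per leaflet) is
reported alongside.

## Residence statistics

Per-lipid *fractional contact time* is the fraction of analysed frames
with at least one protein contact, histogrammed at bin width 0.05 (fine
enough to separate the typical ~15% majority population from the 30-40%
annular population). This is occupancy, not a dwell-time survival
analysis -- it matches how such distributions are usually reported.
Binding events are counted with a one-frame tolerance (a single off-frame
inside a run does not split an event), exposed as a parameter because
frame strides vary; `longest_run` counts raw unbroken in-contact frames.
The most-bound lipid's phosphate trace (`maxContactLipidTrace()`, ties
broken by lowest molecule id) uses the same frame alignment as the grids.

## Residue-type × segment statistics

For a set of systems, the raw score of (type, segment) sums that
segment's contact fraction over all residues of the type; dividing by the
type's occurrence (its residue count across the inputs, not a background
proteome) removes abundance bias, and each segment column is rescaled to
percentages summing to 100. The contribution is time-weighted by default
(`weighting = "binary"` gives the ever-contacted alternative; which
weighting published figures used is usually not determinable). On the
generator's default residue layout, basic pseudo-residues flank the
phosphate levels and aromatics the glycerol level, so the qualitative
enrichment expected of membrane proteins (basics at phosphate, aromatics
at glycerol/tail) emerges -- a documentation example, deliberately not a
test assertion, because binary presence contacts at a 6 Å cutoff make
the exact ranking geometry-sensitive.

## Alignment projection

Contact frequencies are projected onto a user-supplied multiple sequence
alignment (FASTA or Clustal; the package never computes alignments): the
k-th non-gap column of a row receives the k-th residue's fraction, gaps
are NA, and the family view is the per-column mean over non-gap entries
(all-gap columns carry no mean). Unresolved residues should be
gap-marked, not zero-filled, to avoid diluting conservation. Projection
followed by gap-stripping is exactly invertible, which the tests assert
on a 40-member synthetic family. Output is TSV; the alignment row's
sequence must match the profile's (an explicit offset handles trimmed
constructs), and mismatches report the first offending position.

## The synthetic-data generator

Real microsecond trajectories cannot be regenerated at desk scale, so
validation uses a seeded toy generator with closed-form ground truth
(`generateMembraneTrajectory()`, expectations from
`groundTruthExpectations()`):

* a cylindrical four-chain protein (radius 20 Å, span 50 Å, 30
  pseudo-residues per chain on a surface lattice with ~4 Å z-spacing)
  fixed at the centre of a 120 × 120 × 80 Å box;
* `nSites = 24` annular sites in trans-bilayer pairs anchored to protein
  surface columns, 3 Å outside the protein radius, phosphates pinned at
  ± (annular thickness)/2. Site occupancy is a two-state Markov chain
  (`pOn`, `pOff`) or independent Bernoulli draws (`pOcc = 0.15` by
  default, the majority contact-time population); an occupied site's
  lipid sits on the site, an unoccupied one swaps into the bulk;
* 100 bulk lipids per leaflet, re-placed uniformly each frame at least
  10 Å outside the protein radius (so bulk lipids never contact), with
  leaflet z following the radial thickness profile;
* the thickness profile is pinned at the annular value (35 Å) out to
  6 Å beyond the protein radius -- the annular zone, matching the
  contact cutoff -- then relaxes exponentially to the bulk value (50 Å,
  the di-C18:0 PE case) with a 5 Å length scale. The 50 → 35 Å defaults
  are the membrane-thinning conditions the analyses must recover; the
  uniform 35 Å configuration reproduces the matched-lipid (di-C14:0 PC)
  case;
* Gaussian jitter (σ = 0.5 Å) on every particle; 500 frames by default.
* residue types are laid out in z bands (basics at phosphate level,
  aromatics below, hydrophobics in the core, polars at the termini), so
  axial distributions and residue-type statistics have structure.

There are **no inertial dynamics**: frames are independent except through
site occupancy. That is sufficient -- and honest -- because every
analysis here measures occupancy-based statistics, geometry, or
bookkeeping. What passing tests on generated data therefore show is that
the analyses recover known occupancies, thicknesses, densities, leaflets
and projections under realistic noise; what they cannot show is behaviour
under correlated lipid diffusion, undulations, curvature, or
protein conformational change, none of which the analyses model.

Synthetic stand-ins for lipid-bridged 2D-crystal layers
(`makeSyntheticCrystal()`) place a designed number of annular lipids
around the tetramer at a designed P-P distance;
`buildDoubleLayerAssembly()` stacks the flipped second layer of the
octameric crystal packing, doubling the lipid complement. These objects
are synthetic by construction and are used to validate the census and
P-P machinery against known design values (72/56/40 lipids, ~35 Å).

## Numerical choices and degenerate inputs

* Cell lists fall back to brute force when the box is under two cells
  per dimension (minimum image needs ≥ 2).
* Grid origins snap to spacing multiples, so nested spacings (1 and 2 Å)
  produce block-consistent bins.
* Ties in minimum distance are irrelevant (presence/absence semantics);
  ties in maximum contact fraction break to the lowest molecule id.
* Empty analysis windows, missing boxes under PBC, lipids without
  phosphate particles (where the phosphate is the reference), coplanar
  phosphates, and all-gap alignment inconsistencies are hard errors, not
  silent results. Classification accepts partial lipids only with
  `requirePhosphate = FALSE`.
* Bulk placement uses rejection sampling with bounded retries; a lipid
  count exceeding the leaflet's area capacity errors as infeasible
  packing.

## Problem sizes used in the shipped checks

The test suite and the acceptance script size their simulations at
100 annular lipids × 500 frames for occupancy recovery, 300 frames for
thickness recovery, 100 random systems of up to 500 particles for the
spatial-index oracle, and a 40-member family for the projection
round-trip -- sizes at which the statistical tolerances
(3·sqrt(p(1−p)/n) for occupancy, ±1 Å for thickness) are meaningful and
the whole validation completes in well under a minute each.

## Known limitations

* No XTC/DCD binary trajectories (text PDB/GRO only) and no triclinic
  boxes.
* No hydrogen-bond detection, per-atom contact maps, curvature, order
  parameters or area-per-lipid.
* No kinetic rate fitting: fractional contact time is occupancy, and the
  generator's Markov chain is memoryless per frame.
* The bundled atomistic segment schemes use CHARMM-style atom naming;
  structures with other dialects need alias lines or a user scheme.
* The optional HTML heat-coloured alignment rendering is not included;
  projections are written as TSV.
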