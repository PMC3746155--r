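#' @import methods
NULL

PARTICLE_COLS <- c("name", "resname", "resseq", "inscode", "chain",
                   "molecule_id", "element", "x", "y", "z")

SEGMENT_LEVELS <- c("head_terminal", "phosphate", "glycerol", "tail")
HEADGROUP_SEGMENTS <- c("head_terminal", "phosphate", "glycerol")
ROLE_LEVELS <- c("protein", "lipid", "solvent", "other")

#' MolecularSystem: one frame of a structure or trajectory
#'
#' Container for a set of particles (atoms or coarse-grained beads) with
#' coordinates in Angstrom, residue/chain identity and a molecule
#' partition, plus an optional orthorhombic periodic box.
#'
#' @slot particles data.frame with columns \code{name}, \code{resname},
#'   \code{resseq}, \code{inscode}, \code{chain}, \code{molecule_id},
#'   \code{element}, \code{x}, \code{y}, \code{z}. Each particle belongs to
#'   exactly one \code{molecule_id}: protein chains are one molecule each,
#'   every non-protein residue (lipid, water, ...) its own molecule.
#' @slot box numeric(3) orthorhombic box lengths in Angstrom, or
#'   numeric(0) when no box is defined. Triclinic boxes are rejected at
#'   read time.
#' @slot resolution \code{"atomistic"} or \code{"coarse_grained"};
#'   controls default contact cutoffs (4 vs 6 Angstrom) and whether
#'   hydrogens are excluded from contact searches.
#' @export
setClass("MolecularSystem",
  representation(particles = "data.frame", box = "numeric",
                 resolution = "character"),
  prototype(box = numeric(0), resolution = "atomistic"))

setValidity("MolecularSystem", function(object) {
  p <- object@particles
  msg <- character(0)
  missing_cols <- setdiff(PARTICLE_COLS, names(p))
  if (length(missing_cols))
    msg <- c(msg, paste("particles lacks columns:",
                        paste(missing_cols, collapse = ", ")))
  else {
    if (!all(is.finite(p$x) & is.finite(p$y) & is.finite(p$z)))
      msg <- c(msg, "particle coordinates must be finite")
    if (anyNA(p$molecule_id))
      msg <- c(msg, "every particle needs a molecule_id")
  }
  if (length(object@box) && (length(object@box) != 3L ||
                             !all(is.finite(object@box) & object@box > 0)))
    msg <- c(msg, "box must be three strictly positive lengths")
  if (length(object@resolution) != 1L ||
      !object@resolution %in% c("atomistic", "coarse_grained"))
    msg <- c(msg, "resolution must be 'atomistic' or 'coarse_grained'")
  if (length(msg)) msg else TRUE
})

#' AnnotatedSystem: a MolecularSystem with role and segment labels
#'
#' Produced by [classifyParticles()]. The particle table gains a
#' \code{role} column (protein / lipid / solvent / other) and a
#' \code{segment} column (head_terminal / phosphate / glycerol / tail for
#' lipid particles, NA otherwise).
#'
#' @export
setClass("AnnotatedSystem", contains = "MolecularSystem")

setValidity("AnnotatedSystem", function(object) {
  p <- object@particles
  msg <- character(0)
  if (!all(c("role", "segment") %in% names(p)))
    return("annotated particles need 'role' and 'segment' columns")
  if (!all(p$role %in% ROLE_LEVELS))
    msg <- c(msg, "unknown role label")
  lip <- p$role == "lipid"
  if (any(lip) && !all(p$segment[lip] %in% SEGMENT_LEVELS))
    msg <- c(msg, "every lipid particle needs one of the four segment labels")
  if (length(msg)) msg else TRUE
})

#' Trajectory: an ordered series of frames over one topology
#'
#' @slot topology data.frame of per-particle identity (same columns as a
#'   \linkS4class{MolecularSystem} particle table minus coordinates;
#'   gains \code{role}/\code{segment} after classification).
#' @slot coords numeric array [n_particles, 3, n_frames], Angstrom.
#' @slot box numeric(3) or numeric(0); one box shared by all frames.
#' @slot times numeric(n_frames) in ns, or numeric(0); strictly increasing.
#' @slot resolution "atomistic" or "coarse_grained".
#' @export
setClass("Trajectory",
  representation(topology = "data.frame", coords = "array", box = "numeric",
                 times = "numeric", resolution = "character"),
  prototype(box = numeric(0), times = numeric(0), resolution = "atomistic"))

setValidity("Trajectory", function(object) {
  msg <- character(0)
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L)
    msg <- c(msg, "coords must be an [n_particles, 3, n_frames] array")
  else if (d[1] != nrow(object@topology))
    msg <- c(msg, "coords row count must match topology")
  if (length(object@times)) {
    if (length(object@times) != d[3])
      msg <- c(msg, "times length must equal frame count")
    else if (any(diff(object@times) <= 0))
      msg <- c(msg, "frame times must be strictly increasing")
  }
  if (length(object@box) && (length(object@box) != 3L ||
                             !all(object@box > 0)))
    msg <- c(msg, "box must be three strictly positive lengths")
  if (length(msg)) msg else TRUE
})

#' SegmentScheme: lipid segment classification rules
#'
#' Maps (residue name, particle name) pairs to one of the four lipid
#' segments -- terminal head group (choline/ethanolamine), phosphate,
#' glycerol backbone, acyl tail -- plus residue-name roles and aliases for
#' lipid naming dialects (e.g. the PDB component code vs the force-field
#' name). Every lipid residue type must map at least one particle to the
#' phosphate segment: the phosphate is the reference particle for leaflet
#' assignment, density and thickness.
#'
#' @slot segments data.frame(resname, particle, segment)
#' @slot roles named character: residue name -> role
#' @slot aliases named character: alias -> canonical residue name
#' @export
setClass("SegmentScheme",
  representation(segments = "data.frame", roles = "character",
                 aliases = "character"),
  prototype(roles = character(0), aliases = character(0)))

setValidity("SegmentScheme", function(object) {
  s <- object@segments
  msg <- character(0)
  if (!all(c("resname", "particle", "segment") %in% names(s)))
    return("segments needs resname, particle, segment columns")
  if (nrow(s)) {
    if (!all(s$segment %in% SEGMENT_LEVELS))
      msg <- c(msg, paste("segments must be one of:",
                          paste(SEGMENT_LEVELS, collapse = ", ")))
    has_p <- tapply(s$segment == "phosphate", s$resname, any)
    if (!all(has_p))
      msg <- c(msg, paste("lipid residue(s) with no phosphate particle:",
                          paste(names(has_p)[!has_p], collapse = ", ")))
  }
  if (length(object@roles) && !all(object@roles %in% ROLE_LEVELS))
    msg <- c(msg, "roles must be protein/lipid/solvent/other")
  if (length(msg)) msg else TRUE
})

#' ContactProfile: per-residue lipid contact frequencies
#'
#' For each protein residue, the fraction of analysed frames in which it
#' contacts a lipid, decomposed by lipid segment and by head-group
#' (terminal + phosphate + glycerol) vs tail class. Crystal-structure
#' profiles are single-frame 0/1 indicators (\code{scale = "binary"}).
#'
#' @slot residues data.frame(chain, resseq, inscode, resname,
#'   head_terminal, phosphate, glycerol, tail, headgroup_fraction,
#'   tail_fraction); all fractions in [0, 1].
#' @slot nFrames number of frames analysed.
#' @slot sourceTag free-text label for the data source.
#' @slot scale "fraction" (trajectory) or "binary" (single structure).
#' @export
setClass("ContactProfile",
  representation(residues = "data.frame", nFrames = "integer",
                 sourceTag = "character", scale = "character"),
  prototype(nFrames = 1L, sourceTag = "", scale = "fraction"))

setValidity("ContactProfile", function(object) {
  r <- object@residues
  need <- c("chain", "resseq", "inscode", "resname", SEGMENT_LEVELS,
            "headgroup_fraction", "tail_fraction")
  if (!all(need %in% names(r)))
    return(paste("residues lacks columns:",
                 paste(setdiff(need, names(r)), collapse = ", ")))
  frac <- as.matrix(r[, c(SEGMENT_LEVELS, "headgroup_fraction",
                          "tail_fraction")])
  msg <- character(0)
  if (nrow(r) && (min(frac) < 0 || max(frac) > 1 + 1e-12))
    msg <- c(msg, "fractions must lie in [0, 1]")
  if (nrow(r) && any(r$headgroup_fraction + 1e-12 <
                     pmax(r$head_terminal, r$phosphate, r$glycerol)))
    msg <- c(msg, "headgroup_fraction must dominate its constituent segments")
  if (object@nFrames < 1L)
    msg <- c(msg, "nFrames must be >= 1")
  if (length(msg)) msg else TRUE
})

#' PlanarGrid: a 2D field over the membrane plane
#'
#' @slot origin numeric(2): xy of the lower-left corner of bin (1,1), Angstrom.
#' @slot spacing bin edge length in Angstrom.
#' @slot values matrix (x index by y index); NA marks unsampled bins.
#' @slot kind "density" (per Angstrom^2), "thickness" (Angstrom) or "occupancy".
#' @export
setClass("PlanarGrid",
  representation(origin = "numeric", spacing = "numeric", values = "matrix",
                 kind = "character"))

setValidity("PlanarGrid", function(object) {
  msg <- character(0)
  if (length(object@origin) != 2L) msg <- c(msg, "origin must be length 2")
  if (length(object@spacing) != 1L || object@spacing <= 0)
    msg <- c(msg, "spacing must be a single positive number")
  if (any(dim(object@values) < 1L)) msg <- c(msg, "grid must be >= 1x1")
  if (!object@kind %in% c("density", "thickness", "occupancy"))
    msg <- c(msg, "kind must be density/thickness/occupancy")
  if (object@kind == "density" &&
      any(object@values < 0, na.rm = TRUE))
    msg <- c(msg, "density grids must be non-negative")
  if (length(msg)) msg else TRUE
})

#' ThicknessMap: local bilayer thickness with bulk/annular summaries
#'
#' @slot grid \linkS4class{PlanarGrid} of local leaflet-to-leaflet
#'   phosphate distance (P-P distance), Angstrom.
#' @slot bulkThickness mean thickness over bins farther than the bulk
#'   margin from the protein footprint (NA if no bin qualifies).
#' @slot annularThickness mean thickness over bins within the contact
#'   cutoff of the protein footprint (NA if no bin qualifies).
#' @slot nBulkBins,nAnnularBins number of bins entering each summary.
#' @export
setClass("ThicknessMap",
  representation(grid = "PlanarGrid", bulkThickness = "numeric",
                 annularThickness = "numeric", nBulkBins = "integer",
                 nAnnularBins = "integer"))

#' AxialHistogram: residue-type distributions along the bilayer normal
#'
#' @slot breaks bin edges in z (Angstrom, relative to the bilayer midplane).
#' @slot counts matrix bins x residue types.
#' @slot headgroupBand 2x2 matrix; rows lower/upper leaflet, columns the
#'   z-interval (mean phosphate z +/- one sd) marking the head-group region.
#' @export
setClass("AxialHistogram",
  representation(breaks = "numeric", counts = "matrix",
                 headgroupBand = "matrix"))

setValidity("AxialHistogram", function(object) {
  msg <- character(0)
  if (any(diff(object@breaks) <= 0))
    msg <- c(msg, "breaks must be strictly increasing")
  if (nrow(object@counts) != length(object@breaks) - 1L)
    msg <- c(msg, "counts rows must match bins")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' ResidenceTable: per-lipid fractional contact times
#'
#' @slot lipids data.frame(molecule_id, contact_fraction, longest_run,
#'   n_binding_events): fraction of analysed frames in contact with the
#'   protein, the longest unbroken run of in-contact frames, and the
#'   number of binding events (brief single-frame losses do not split an
#'   event by default).
#' @slot histogram data.frame(bin_lo, bin_hi, count) over [0, 1].
#' @slot nFrames number of frames analysed.
#' @export
setClass("ResidenceTable",
  representation(lipids = "data.frame", histogram = "data.frame",
                 nFrames = "integer"))

setValidity("ResidenceTable", function(object) {
  l <- object@lipids
  msg <- character(0)
  if (!all(c("molecule_id", "contact_fraction", "longest_run",
             "n_binding_events") %in% names(l)))
    return("lipids table lacks required columns")
  if (nrow(l)) {
    if (any(l$contact_fraction < 0 | l$contact_fraction > 1))
      msg <- c(msg, "contact_fraction must lie in [0, 1]")
    if (any((l$n_binding_events >= 1L) != (l$contact_fraction > 0)))
      msg <- c(msg, "n_binding_events >= 1 iff contact_fraction > 0")
  }
  if (nrow(object@histogram) &&
      sum(object@histogram$count) != nrow(l))
    msg <- c(msg, "histogram counts must sum to the number of lipids")
  if (length(msg)) msg else TRUE
})

#' SegmentInteractionTable: residue-type x lipid-segment percentages
#'
#' Interaction scores summed over residues of each amino-acid type,
#' normalised by the type's occurrence in the input structures, then
#' rescaled so each segment column sums to 100.
#'
#' @slot percentages matrix residue types x four segments.
#' @slot occurrence named integer: residues of each type in the input set.
#' @slot weighting "fraction" (time-weighted) or "binary".
#' @export
setClass("SegmentInteractionTable",
  representation(percentages = "matrix", occurrence = "integer",
                 weighting = "character"))

setValidity("SegmentInteractionTable", function(object) {
  msg <- character(0)
  if (!identical(colnames(object@percentages), SEGMENT_LEVELS))
    msg <- c(msg, "columns must be the four lipid segments")
  cs <- colSums(object@percentages)
  bad <- abs(cs - 100) > 0.01 & cs != 0
  if (any(bad))
    msg <- c(msg, "each non-empty segment column must sum to 100")
  nz <- rowSums(object@percentages) > 0
  occ <- object@occurrence[rownames(object@percentages)]
  if (any(nz & (is.na(occ) | occ <= 0)))
    msg <- c(msg, "types with nonzero percentages need positive occurrence")
  if (length(msg)) msg else TRUE
})

#' AlignmentProjection: contact frequencies on a family alignment
#'
#' @slot ids sequence identifiers (alignment rows).
#' @slot alignment gapped sequences, one string per id, equal widths.
#' @slot values matrix rows x alignment columns; NA marks gaps.
#' @slot columnMeans per-column mean over non-gap entries (NA if all gap).
#' @slot annotations optional per-column labels (e.g. helix H1-H6), "" if none.
#' @export
setClass("AlignmentProjection",
  representation(ids = "character", alignment = "character",
                 values = "matrix", columnMeans = "numeric",
                 annotations = "character"),
  prototype(annotations = character(0)))

setValidity("AlignmentProjection", function(object) {
  msg <- character(0)
  w <- unique(nchar(object@alignment))
  if (length(w) > 1L) msg <- c(msg, "alignment rows must share one width")
  if (length(object@ids) != length(object@alignment))
    msg <- c(msg, "one id per alignment row")
  if (nrow(object@values) != length(object@ids) ||
      (length(w) == 1L && ncol(object@values) != w))
    msg <- c(msg, "values must be rows x alignment-width")
  if (length(object@columnMeans) != ncol(object@values))
    msg <- c(msg, "columnMeans must have one entry per column")
  ok <- is.na(object@columnMeans) |
    (object@columnMeans >= -1e-12 & object@columnMeans <= 1 + 1e-12)
  if (!all(ok)) msg <- c(msg, "column means must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' SyntheticParams: full specification of a generated membrane system
#'
#' Describes a roughly cylindrical multi-chain protein spanning a
#' two-leaflet bilayer in a periodic box, with an annulus of lipid sites
#' on the protein rim whose occupancy follows a two-state Markov chain
#' (or independent Bernoulli draws), and bulk lipids whose leaflet z
#' follows a radial thickness profile thinning from a bulk value to an
#' annular value at the protein. Same seed + params give a bit-identical
#' trajectory.
#'
#' @export
setClass("SyntheticParams",
  representation(
    nChains = "integer", residuesPerChain = "integer",
    proteinRadius = "numeric", proteinSpan = "numeric",
    particlesPerResidue = "integer", residueLayout = "character",
    nLipidsPerLeaflet = "integer", boxLengths = "numeric",
    bulkThickness = "numeric", annularThickness = "numeric",
    thinningLength = "numeric",
    nSites = "integer", siteOffset = "numeric", bulkStandoff = "numeric",
    occupancyModel = "character", pOcc = "numeric", pOn = "numeric",
    pOff = "numeric",
    nFrames = "integer", jitter = "numeric", seed = "integer",
    resolution = "character"))

setValidity("SyntheticParams", function(object) {
  msg <- character(0)
  probs <- c(object@pOcc, object@pOn, object@pOff)
  if (any(probs < 0 | probs > 1)) msg <- c(msg, "probabilities must be in [0, 1]")
  if (object@annularThickness <= 0 || object@bulkThickness <= 0)
    msg <- c(msg, "thicknesses must be positive")
  if (object@annularThickness > object@bulkThickness)
    msg <- c(msg, "annular thickness cannot exceed bulk thickness")
  if (!object@occupancyModel %in% c("independent", "markov"))
    msg <- c(msg, "occupancyModel must be 'independent' or 'markov'")
  if (length(object@boxLengths) != 3L || any(object@boxLengths <= 0))
    msg <- c(msg, "boxLengths must be three positive lengths")
  if (object@nFrames < 1L) msg <- c(msg, "need at least one frame")
  if (object@proteinSpan < object@annularThickness)
    msg <- c(msg, "protein span must cover the annular thickness")
  if (length(msg)) msg else TRUE
})
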