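#' @include AllClasses.R
NULL

#' Number of particles
#' @param x a MolecularSystem or Trajectory
#' @export
setGeneric("nParticles", function(x) standardGeneric("nParticles"))

#' Number of frames
#' @param x a Trajectory
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Particle table
#' @param x a MolecularSystem
#' @export
setGeneric("particles", function(x) standardGeneric("particles"))

#' Topology (per-particle identity) of a trajectory
#' @param x a Trajectory
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' Coordinates
#'
#' For a MolecularSystem an n x 3 matrix; for a Trajectory either the full
#' [n, 3, frames] array or, with \code{frame=}, one frame's n x 3 matrix.
#' @param x object
#' @param ... \code{frame}: frame index for trajectories
#' @export
setGeneric("coords", function(x, ...) standardGeneric("coords"))

#' Periodic box lengths (Angstrom), numeric(0) if absent
#' @param x object
#' @export
setGeneric("boxLengths", function(x) standardGeneric("boxLengths"))

#' Resolution tag ("atomistic" or "coarse_grained")
#' @param x object
#' @export
setGeneric("resolutionTag", function(x) standardGeneric("resolutionTag"))

#' Extract one frame of a trajectory as a system
#' @param x a Trajectory
#' @param i frame index
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))

#' Classify particles into roles and lipid segments
#'
#' @param x a MolecularSystem or Trajectory
#' @param scheme a \linkS4class{SegmentScheme}
#' @param ... method arguments (e.g. \code{requirePhosphate})
#' @return the same object with \code{role} and \code{segment} particle
#'   annotations (an \linkS4class{AnnotatedSystem} for systems)
#' @export
setGeneric("classifyParticles",
           function(x, scheme, ...) standardGeneric("classifyParticles"))

#' Per-residue table of a contact profile
#' @param x a ContactProfile
#' @export
setGeneric("profileTable", function(x) standardGeneric("profileTable"))

#' Grid values matrix
#' @param x a PlanarGrid or ThicknessMap
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' Bulk bilayer thickness summary (Angstrom)
#' @param x a ThicknessMap
#' @export
setGeneric("bulkThickness", function(x) standardGeneric("bulkThickness"))

#' Annular bilayer thickness summary (Angstrom)
#' @param x a ThicknessMap
#' @export
setGeneric("annularThickness",
           function(x) standardGeneric("annularThickness"))

#' Per-lipid residence statistics table
#' @param x a ResidenceTable
#' @export
setGeneric("lipidTable", function(x) standardGeneric("lipidTable"))
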