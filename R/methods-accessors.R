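#' @include AllGenerics.R
NULL

#' @describeIn nParticles particle count of a system
#' @export
setMethod("nParticles", "MolecularSystem",
          function(x) nrow(x@particles))

#' @describeIn nParticles particle count shared by all frames
#' @export
setMethod("nParticles", "Trajectory", function(x) nrow(x@topology))

#' @describeIn nFrames frame count
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[3])

#' @describeIn particles the particle table (identity + coordinates)
#' @export
setMethod("particles", "MolecularSystem", function(x) x@particles)

#' @describeIn topology per-particle identity table
#' @export
setMethod("topology", "Trajectory", function(x) x@topology)

#' @describeIn coords n x 3 coordinate matrix
#' @export
setMethod("coords", "MolecularSystem", function(x, ...) {
  as.matrix(x@particles[, c("x", "y", "z")])
})

#' @describeIn coords full array, or one frame's n x 3 matrix via
#'   \code{frame=}
#' @export
setMethod("coords", "Trajectory", function(x, ..., frame = NULL) {
  if (is.null(frame)) return(x@coords)
  m <- x@coords[, , frame, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  colnames(m) <- c("x", "y", "z")
  m
})

#' @describeIn boxLengths box of a system
#' @export
setMethod("boxLengths", "MolecularSystem", function(x) x@box)

#' @describeIn boxLengths box shared by all frames
#' @export
setMethod("boxLengths", "Trajectory", function(x) x@box)

#' @describeIn resolutionTag of a system
#' @export
setMethod("resolutionTag", "MolecularSystem", function(x) x@resolution)

#' @describeIn resolutionTag of a trajectory
#' @export
setMethod("resolutionTag", "Trajectory", function(x) x@resolution)

#' @describeIn getFrame frame \code{i} as a MolecularSystem (annotated if
#'   the trajectory topology carries role/segment labels)
#' @export
setMethod("getFrame", "Trajectory", function(x, i) {
  stopifnot(length(i) == 1L, i >= 1L, i <= nFrames(x))
  p <- x@topology
  xyz <- coords(x, frame = i)
  p$x <- xyz[, 1]; p$y <- xyz[, 2]; p$z <- xyz[, 3]
  cls <- if (all(c("role", "segment") %in% names(p)))
    "AnnotatedSystem" else "MolecularSystem"
  new(cls, particles = p, box = x@box, resolution = x@resolution)
})

#' @describeIn profileTable per-residue fractions
#' @export
setMethod("profileTable", "ContactProfile", function(x) x@residues)

#' @describeIn gridValues values of a planar grid
#' @export
setMethod("gridValues", "PlanarGrid", function(x) x@values)

#' @describeIn gridValues values of the thickness grid
#' @export
setMethod("gridValues", "ThicknessMap", function(x) x@grid@values)

#' @describeIn bulkThickness bulk summary
#' @export
setMethod("bulkThickness", "ThicknessMap", function(x) x@bulkThickness)

#' @describeIn annularThickness annular summary
#' @export
setMethod("annularThickness", "ThicknessMap",
          function(x) x@annularThickness)

#' @describeIn lipidTable per-lipid statistics
#' @export
setMethod("lipidTable", "ResidenceTable", function(x) x@lipids)

setMethod("show", "MolecularSystem", function(object) {
  p <- object@particles
  cat(sprintf("%s: %d particles, %d molecules, %s%s\n",
              class(object), nrow(p), length(unique(p$molecule_id)),
              object@resolution,
              if (length(object@box))
                sprintf(", box %.1f x %.1f x %.1f A",
                        object@box[1], object@box[2], object@box[3])
              else ", no box"))
  if (is(object, "AnnotatedSystem"))
    cat("  roles:", paste(sprintf("%s=%d", names(table(p$role)),
                                  table(p$role)), collapse = " "), "\n")
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d frames x %d particles, %s\n",
              nFrames(object), nParticles(object), object@resolution))
})

setMethod("show", "SegmentScheme", function(object) {
  cat(sprintf("SegmentScheme: %d lipid type(s), %d particle rules, %d alias(es)\n",
              length(unique(object@segments$resname)),
              nrow(object@segments), length(object@aliases)))
})

setMethod("show", "ContactProfile", function(object) {
  cat(sprintf("ContactProfile [%s]: %d residues, %d frame(s), scale=%s\n",
              object@sourceTag, nrow(object@residues), object@nFrames,
              object@scale))
})

setMethod("show", "PlanarGrid", function(object) {
  cat(sprintf("PlanarGrid (%s): %d x %d bins, spacing %.2f A, origin (%.1f, %.1f)\n",
              object@kind, nrow(object@values), ncol(object@values),
              object@spacing, object@origin[1], object@origin[2]))
})

setMethod("show", "ThicknessMap", function(object) {
  cat(sprintf("ThicknessMap: bulk %.2f A (%d bins), annular %.2f A (%d bins)\n",
              object@bulkThickness, object@nBulkBins,
              object@annularThickness, object@nAnnularBins))
})

setMethod("show", "ResidenceTable", function(object) {
  cat(sprintf("ResidenceTable: %d lipids over %d frames; mean contact fraction %.3f\n",
              nrow(object@lipids), object@nFrames,
              mean(object@lipids$contact_fraction)))
})

setMethod("show", "SegmentInteractionTable", function(object) {
  cat(sprintf("SegmentInteractionTable (%s-weighted): %d residue types\n",
              object@weighting, nrow(object@percentages)))
})

setMethod("show", "AlignmentProjection", function(object) {
  cat(sprintf("AlignmentProjection: %d sequences x %d columns\n",
              length(object@ids), ncol(object@values)))
})

setMethod("show", "SyntheticParams", function(object) {
  cat(sprintf(paste0(
    "SyntheticParams: %d chains x %d residues (R=%.1f A, span %.1f A), ",
    "%d sites + %d bulk lipids/leaflet\n  bilayer %.1f -> %.1f A ",
    "(lambda %.1f A), %s occupancy, %d frames, seed %d\n"),
    object@nChains, object@residuesPerChain, object@proteinRadius,
    object@proteinSpan, object@nSites, object@nLipidsPerLeaflet,
    object@bulkThickness, object@annularThickness, object@thinningLength,
    object@occupancyModel, object@nFrames, object@seed))
})
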