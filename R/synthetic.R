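#' @include geometry.R
NULL

#' Parameters for the synthetic membrane-trajectory generator
#'
#' Defaults describe the reference study conditions: a roughly cylindrical
#' four-chain protein (radius 20 Angstrom, span 50) across a DSPE-like
#' bilayer whose leaflet-to-leaflet phosphate distance thins from a bulk
#' 50 Angstrom to 35 Angstrom at the protein, 24 annular sites on the
#' protein rim whose occupancy follows the given model (independent
#' Bernoulli draws at p = 0.15, the major contact-time population, by
#' default), 100 bulk lipids per leaflet re-placed independently per
#' frame, 500 frames, 0.5 Angstrom Gaussian jitter.
#'
#' @param nChains,residuesPerChain protein size
#' @param proteinRadius,proteinSpan cylinder radius and z extent, Angstrom
#' @param particlesPerResidue pseudo-particles per residue (first is the
#'   backbone bead "BB"; extras "SC1", ... offset radially outward)
#' @param residueLayout "banded" places basic residues at the phosphate
#'   levels, aromatics at the glycerol level, hydrophobics in the core and
#'   polars at the termini; "uniform" cycles all twenty types
#' @param nLipidsPerLeaflet bulk lipids per leaflet
#' @param boxLengths periodic box, Angstrom
#' @param bulkThickness,annularThickness,thinningLength bilayer P-P
#'   distance far from the protein, at the protein, and the exponential
#'   length scale of the thinning
#' @param nSites annular lipid sites (alternating leaflets)
#' @param siteOffset radial distance of sites beyond the protein surface
#' @param bulkStandoff minimum radial distance of bulk lipids beyond the
#'   protein surface (keeps bulk lipids out of contact range)
#' @param occupancyModel "independent" (per-frame Bernoulli at
#'   \code{pOcc}) or "markov" (two-state chain with per-frame transition
#'   probabilities \code{pOn} off->on and \code{pOff} on->off)
#' @param pOcc,pOn,pOff occupancy probabilities
#' @param nFrames number of frames
#' @param jitter Gaussian positional noise sigma, Angstrom
#' @param seed RNG seed; same seed + params give a bit-identical trajectory
#' @param resolution resolution tag attached to the trajectory
#' @return a \linkS4class{SyntheticParams}
#' @export
syntheticParams <- function(nChains = 4L, residuesPerChain = 30L,
                            proteinRadius = 20, proteinSpan = 50,
                            particlesPerResidue = 1L,
                            residueLayout = "banded",
                            nLipidsPerLeaflet = 100L,
                            boxLengths = c(120, 120, 80),
                            bulkThickness = 50, annularThickness = 35,
                            thinningLength = 5,
                            nSites = 24L, siteOffset = 3, bulkStandoff = 10,
                            occupancyModel = "independent",
                            pOcc = 0.15, pOn = 0.1, pOff = 0.1,
                            nFrames = 500L, jitter = 0.5, seed = 1L,
                            resolution = "coarse_grained") {
  new("SyntheticParams",
      nChains = as.integer(nChains),
      residuesPerChain = as.integer(residuesPerChain),
      proteinRadius = proteinRadius, proteinSpan = proteinSpan,
      particlesPerResidue = as.integer(particlesPerResidue),
      residueLayout = residueLayout,
      nLipidsPerLeaflet = as.integer(nLipidsPerLeaflet),
      boxLengths = boxLengths, bulkThickness = bulkThickness,
      annularThickness = annularThickness, thinningLength = thinningLength,
      nSites = as.integer(nSites), siteOffset = siteOffset,
      bulkStandoff = bulkStandoff, occupancyModel = occupancyModel,
      pOcc = pOcc, pOn = pOn, pOff = pOff, nFrames = as.integer(nFrames),
      jitter = jitter, seed = as.integer(seed), resolution = resolution)
}

## analytic bilayer thickness profile: pinned at the annular value out to
## the edge of the annular zone (protein radius + annularZone), then
## relaxing exponentially to the bulk value
thicknessProfileFun <- function(params, annularZone = 6) {
  R <- params@proteinRadius
  bulk <- params@bulkThickness
  ann <- params@annularThickness
  lam <- params@thinningLength
  edge <- R + annularZone
  function(r) {
    ifelse(r <= edge, ann, bulk - (bulk - ann) * exp(-(r - edge) / lam))
  }
}

bandedResidueType <- function(zAbs, pz, i) {
  basics <- c("ARG", "LYS")
  aromatics <- c("TRP", "TYR")
  core <- c("LEU", "ILE", "VAL", "PHE", "ALA")
  polar <- c("SER", "ASN", "GLN", "ASP", "GLU", "GLY")
  if (abs(zAbs - pz) <= 2.5) basics[(i %% 2L) + 1L]
  else if (zAbs < pz - 2.5 && zAbs >= pz - 6.5) aromatics[(i %% 2L) + 1L]
  else if (zAbs < pz - 6.5) core[(i %% 5L) + 1L]
  else polar[(i %% 6L) + 1L]
}

## lattice shape of the cylinder surface: residues fill z-rows within
## angular columns (~4 Angstrom row spacing), so the surface is sampled
## densely enough in z that every annular site faces a particle
proteinLattice <- function(params) {
  ncols <- max(1L, as.integer(round(params@residuesPerChain * 4 /
                                    params@proteinSpan)))
  nrows <- as.integer(ceiling(params@residuesPerChain / ncols))
  list(nrows = nrows, ncols = ncols)
}

## angles of protein columns that carry a particle at both phosphate
## levels; sites anchor to these so an occupied site always sits within
## contact range of the protein surface
annulusAnchorAngles <- function(prot, ctr, zLevel, tolZ) {
  ang <- round(atan2(prot$y - ctr[2], prot$x - ctr[1]) %% (2 * pi), 6)
  zrel <- prot$z - ctr[3]
  up <- unique(ang[abs(zrel - zLevel) <= tolZ])
  lo <- unique(ang[abs(zrel + zLevel) <= tolZ])
  good <- sort(intersect(up, lo))
  if (!length(good))
    stop("no protein column reaches both phosphate levels; ",
         "increase residuesPerChain or proteinSpan")
  good
}

## protein particle table of the synthetic cylinder (coordinates are the
## noiseless reference; jitter is added per frame)
syntheticProteinTable <- function(params) {
  ctr <- params@boxLengths / 2
  R <- params@proteinRadius
  n <- params@residuesPerChain
  pz <- params@annularThickness / 2
  sector <- 2 * pi / params@nChains
  lat <- proteinLattice(params)
  rows <- list()
  for (c in seq_len(params@nChains)) {
    for (i in seq_len(n)) {
      zrow <- (i - 1L) %% lat$nrows
      col <- (i - 1L) %/% lat$nrows
      z <- -params@proteinSpan / 2 +
        (zrow + 0.5) * params@proteinSpan / lat$nrows
      theta <- (c - 1) * sector + (col + 0.5) * sector / lat$ncols
      ty <- if (params@residueLayout == "banded")
        bandedResidueType(abs(z), pz, i) else AMINO3[((i - 1L) %% 20L) + 1L]
      for (k in seq_len(params@particlesPerResidue)) {
        rows[[length(rows) + 1L]] <- data.frame(
          name = if (k == 1L) "BB" else paste0("SC", k - 1L),
          resname = ty, resseq = i, inscode = "",
          chain = LETTERS[c], molecule_id = NA_integer_, element = "",
          x = ctr[1] + (R + (k - 1L)) * cos(theta),
          y = ctr[2] + (R + (k - 1L)) * sin(theta),
          z = ctr[3] + z, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

## z offsets of the four beads relative to the phosphate, toward the
## midplane for positive leaflet sign
lipidZOffsets <- function(sgn) sgn * c(2, 0, -2.5, -7)

## four-bead lipid: terminal head bead (NH3 for the PE lipids, NC3
## otherwise), phosphate, glycerol, first tail bead
lipidParticleNames <- function(resname) {
  head <- if (resname %in% c("DSP", "DSPE")) "NH3" else "NC3"
  c(head, "PO4", "GL1", "C1A")
}

syntheticLipidTable <- function(nLipids, resname = "DMP") {
  data.frame(
    name = rep(lipidParticleNames(resname), nLipids),
    resname = resname,
    resseq = rep(seq_len(nLipids), each = 4L),
    inscode = "", chain = "L", molecule_id = NA_integer_, element = "",
    x = 0, y = 0, z = 0, stringsAsFactors = FALSE)
}

## uniform xy in the box at radial distance >= rmin from the box centre
sampleBulkXY <- function(n, box, rmin, maxTries = 1000L) {
  ctr <- box[1:2] / 2
  out <- matrix(NA_real_, n, 2)
  got <- 0L
  for (t in seq_len(maxTries)) {
    m <- n - got
    cand <- cbind(stats::runif(m, 0, box[1]), stats::runif(m, 0, box[2]))
    r <- sqrt((cand[, 1] - ctr[1])^2 + (cand[, 2] - ctr[2])^2)
    ok <- r >= rmin
    k <- sum(ok)
    if (k) {
      out[got + seq_len(k), ] <- cand[ok, , drop = FALSE]
      got <- got + k
    }
    if (got == n) return(out)
  }
  stop("infeasible packing: could not place ", n, " bulk lipids outside ",
       "radius ", rmin, " in the box")
}

#' Generate a synthetic membrane-protein trajectory with ground truth
#'
#' Builds a seeded toy trajectory: the protein cylinder is fixed at the
#' box centre; each annular site holds a dedicated lipid that sits on the
#' site (phosphate pinned at the annular P-P distance) when the site is
#' occupied and swaps into the bulk otherwise; bulk lipids are re-placed
#' uniformly (outside the standoff radius) every frame, with leaflet z
#' following the radial thickness profile; Gaussian jitter is added to all
#' particles. There are no inertial dynamics: frames are independent
#' except through the site-occupancy Markov chain, which is all the
#' occupancy-based analyses measure.
#'
#' @param params a \linkS4class{SyntheticParams}
#' @return list(trajectory, groundTruth) where groundTruth records the
#'   per-site occupancy series, per-lipid leaflet and contact series, site
#'   coordinates, site lipid molecule ids and the analytic thickness
#'   profile function
#' @export
generateMembraneTrajectory <- function(params) {
  validObject(params)
  box <- params@boxLengths
  ctr <- box / 2
  R <- params@proteinRadius
  ## feasibility: exclusion disc must leave room for the bulk lipids
  freeArea <- box[1] * box[2] - pi * (R + params@bulkStandoff)^2
  if (freeArea < 55 * params@nLipidsPerLeaflet)
    stop("infeasible packing: lipid count exceeds the leaflet's area capacity")
  prot <- syntheticProteinTable(params)
  nSites <- params@nSites
  ## sites come in trans-bilayer pairs (odd = upper, even = lower) at the
  ## same angle, anchored to protein columns that reach both phosphate
  ## levels, so each site faces a protein particle across the siteOffset gap
  lat <- proteinLattice(params)
  tolZ <- params@proteinSpan / lat$nrows / 2 + 0.01
  colAngles <- annulusAnchorAngles(prot, ctr,
                                   params@annularThickness / 2, tolZ)
  nPairs <- as.integer(ceiling(nSites / 2))
  nCols <- length(colAngles)
  pairAngle <- colAngles[(floor((seq_len(nPairs) - 1) * nCols / nPairs)
                          %% nCols) + 1L]
  siteLeaflet <- rep(c("upper", "lower"), length.out = nSites)
  theta <- pairAngle[ceiling(seq_len(nSites) / 2)]
  sgn <- ifelse(siteLeaflet == "upper", 1, -1)
  siteXY <- cbind(ctr[1] + (R + params@siteOffset) * cos(theta),
                  ctr[2] + (R + params@siteOffset) * sin(theta))
  siteZ <- ctr[3] + sgn * params@annularThickness / 2
  nBulk <- 2L * params@nLipidsPerLeaflet
  bulkLeaflet <- rep(c("upper", "lower"), each = params@nLipidsPerLeaflet)
  lip <- rbind(syntheticLipidTable(nSites),
               syntheticLipidTable(nBulk))
  lip$resseq <- rep(seq_len(nSites + nBulk), each = 4L)
  top <- rbind(prot, lip)
  top$molecule_id <- assignMoleculeIds(top)
  lipMolIds <- unique(top$molecule_id[top$chain == "L"])
  siteMol <- lipMolIds[seq_len(nSites)]
  bulkMol <- lipMolIds[nSites + seq_len(nBulk)]
  thickFun <- thicknessProfileFun(params)
  np <- nrow(top)
  nf <- params@nFrames
  arr <- array(NA_real_, c(np, 3L, nf))
  protXYZ <- as.matrix(prot[, c("x", "y", "z")])
  nprot <- nrow(prot)
  lipStart <- nprot  # particle row offset of the first lipid particle
  occ <- matrix(FALSE, nf, nSites)
  p <- params
  withSeed(p@seed, {
    if (p@occupancyModel == "independent") {
      occ[] <- stats::runif(nf * nSites) < p@pOcc
    } else {
      stat <- if (p@pOn + p@pOff > 0) p@pOn / (p@pOn + p@pOff) else 0
      state <- stats::runif(nSites) < stat
      for (f in seq_len(nf)) {
        occ[f, ] <- state
        u <- stats::runif(nSites)
        state <- ifelse(state, u >= p@pOff, u < p@pOn)
      }
    }
    allLeaflet <- c(siteLeaflet, bulkLeaflet)
    allSgn <- ifelse(allLeaflet == "upper", 1, -1)
    nLip <- nSites + nBulk
    for (f in seq_len(nf)) {
      xyz <- matrix(NA_real_, np, 3L)
      xyz[seq_len(nprot), ] <- protXYZ
      ## phosphate anchor of every lipid this frame
      anchor <- matrix(NA_real_, nLip, 3L)
      off <- which(!occ[f, ])
      on <- which(occ[f, ])
      if (length(on)) {
        anchor[on, 1:2] <- siteXY[on, , drop = FALSE]
        anchor[on, 3] <- siteZ[on]
      }
      loose <- c(off, nSites + seq_len(nBulk))
      if (length(loose)) {
        xy <- sampleBulkXY(length(loose), box, R + p@bulkStandoff)
        r <- sqrt((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2)
        anchor[loose, 1:2] <- xy
        anchor[loose, 3] <- ctr[3] + allSgn[loose] * thickFun(r) / 2
      }
      ## expand anchors into the four-bead lipids
      zoff <- ifelse(rep(allSgn, each = 4L) > 0,
                     rep(lipidZOffsets(1), nLip),
                     rep(lipidZOffsets(-1), nLip))
      rows <- lipStart + seq_len(4L * nLip)
      xyz[rows, 1] <- rep(anchor[, 1], each = 4L)
      xyz[rows, 2] <- rep(anchor[, 2], each = 4L)
      xyz[rows, 3] <- rep(anchor[, 3], each = 4L) + zoff
      if (p@jitter > 0)
        xyz <- xyz + stats::rnorm(length(xyz), 0, p@jitter)
      arr[, , f] <- xyz
    }
  })
  traj <- new("Trajectory", topology = top[, setdiff(names(top),
                                                     c("x", "y", "z"))],
              coords = arr, box = box, times = numeric(0),
              resolution = p@resolution)
  contactSeries <- matrix(FALSE, nSites + nBulk, nf,
                          dimnames = list(c(siteMol, bulkMol), NULL))
  contactSeries[seq_len(nSites), ] <- t(occ)
  gt <- list(params = params,
             occupancy = occ,
             siteXY = siteXY, siteZ = siteZ,
             siteLeaflet = siteLeaflet,
             siteMoleculeIds = siteMol,
             bulkMoleculeIds = bulkMol,
             lipidLeaflet = stats::setNames(c(siteLeaflet, bulkLeaflet),
                                            c(siteMol, bulkMol)),
             contactSeries = contactSeries,
             thicknessProfile = thickFun)
  list(trajectory = traj, groundTruth = gt)
}

#' Closed-form expectations for a synthetic parameter set
#'
#' The quantities the analyses should recover: the stationary site
#' occupancy (\code{pOn / (pOn + pOff)} for the Markov model, \code{pOcc}
#' for independent frames), the per-lipid contact-fraction variance for
#' independent frames over \code{n} analysed frames, the analytic
#' thickness profile, and the bulk/annular thickness values.
#'
#' @param params a \linkS4class{SyntheticParams}
#' @return list(stationaryOccupancy, contactFractionVar(n), thicknessAt,
#'   bulkThickness, annularThickness)
#' @export
groundTruthExpectations <- function(params) {
  validObject(params)
  p <- if (params@occupancyModel == "independent") params@pOcc
  else if (params@pOn + params@pOff > 0)
    params@pOn / (params@pOn + params@pOff) else 0
  list(stationaryOccupancy = p,
       contactFractionVar = function(n) p * (1 - p) / n,
       thicknessAt = thicknessProfileFun(params),
       bulkThickness = params@bulkThickness,
       annularThickness = params@annularThickness)
}

#' Synthetic stand-in for a lipid-bridged 2D-crystal structure
#'
#' Builds a tetramer-plus-annulus system mimicking the lipid-containing
#' 2D electron-crystallography structures: a protein cylinder with
#' \code{nLipids} annular lipids ringing it, phosphates at the two leaflet
#' levels of the given P-P distance. This is a synthetic object with known
#' ground truth (the deposited structures themselves are not bundled);
#' lipid count and thickness are design parameters, so the census and
#' P-P distance machinery can be validated against them.
#'
#' @param nLipids lipids in the single-layer (tetramer) unit
#' @param ppDistance leaflet-to-leaflet phosphate distance, Angstrom
#' @param lipidResname residue name for the lipids (e.g. "DSP", "DMP")
#' @param jitter Gaussian noise sigma, Angstrom
#' @param seed RNG seed for the jitter
#' @return a \linkS4class{MolecularSystem} (coarse-grained naming; classify
#'   with the bundled "martini" scheme)
#' @export
makeSyntheticCrystal <- function(nLipids, ppDistance = 35,
                                 lipidResname = "DSP", jitter = 0.3,
                                 seed = 1L) {
  params <- syntheticParams(annularThickness = ppDistance,
                            bulkThickness = max(50, ppDistance),
                            boxLengths = c(120, 120, 80))
  prot <- syntheticProteinTable(params)
  ctr <- params@boxLengths / 2
  R <- params@proteinRadius + params@siteOffset
  leaflet <- rep(c("upper", "lower"), length.out = nLipids)
  sgn <- ifelse(leaflet == "upper", 1, -1)
  ## trans-bilayer pairs anchored to protein columns, as in the
  ## trajectory generator, so the ring lipids genuinely touch the protein
  lat <- proteinLattice(params)
  tolZ <- params@proteinSpan / lat$nrows / 2 + 0.01
  colAngles <- annulusAnchorAngles(prot, ctr, ppDistance / 2, tolZ)
  nPairs <- as.integer(ceiling(nLipids / 2))
  nCols <- length(colAngles)
  pairAngle <- colAngles[(floor((seq_len(nPairs) - 1) * nCols / nPairs)
                          %% nCols) + 1L] +
    2 * pi * ((seq_len(nPairs) - 1) %/% nCols) / (nCols * 40)
  theta <- pairAngle[ceiling(seq_len(nLipids) / 2)]
  lip <- syntheticLipidTable(nLipids, resname = lipidResname)
  anchor <- cbind(ctr[1] + R * cos(theta), ctr[2] + R * sin(theta),
                  ctr[3] + sgn * ppDistance / 2)
  zoff <- ifelse(rep(sgn, each = 4L) > 0, rep(lipidZOffsets(1), nLipids),
                 rep(lipidZOffsets(-1), nLipids))
  lip$x <- rep(anchor[, 1], each = 4L)
  lip$y <- rep(anchor[, 2], each = 4L)
  lip$z <- rep(anchor[, 3], each = 4L) + zoff
  top <- rbind(prot, lip)
  withSeed(seed, {
    if (jitter > 0) {
      top$x <- top$x + stats::rnorm(nrow(top), 0, jitter)
      top$y <- top$y + stats::rnorm(nrow(top), 0, jitter)
      top$z <- top$z + stats::rnorm(nrow(top), 0, jitter)
    }
  })
  top$molecule_id <- assignMoleculeIds(top)
  new("MolecularSystem", particles = top, box = params@boxLengths,
      resolution = "coarse_grained")
}

#' Stack a second, flipped copy of a crystal layer (octameric assembly)
#'
#' The lipid-bridged 2D crystals pack as double layers: two tetramers
#' related by a two-fold axis, doubling the lipid complement. The copy is
#' rotated 180 degrees about the x axis through the original's top and
#' appended with fresh chain ids and molecule ids.
#'
#' @param system a \linkS4class{MolecularSystem} (one layer)
#' @param gap z distance between the layers' facing surfaces, Angstrom
#' @return a \linkS4class{MolecularSystem} with both layers
#' @export
buildDoubleLayerAssembly <- function(system, gap = 10) {
  p1 <- system@particles
  p2 <- p1
  zTop <- max(p1$z)
  ## 180-degree rotation about x: (y, z) -> (-y, -z), then shift on top
  cy <- mean(range(p1$y))
  p2$y <- 2 * cy - p1$y
  p2$z <- (2 * zTop + gap) - p1$z
  used <- unique(p1$chain)
  pool <- setdiff(c(LETTERS, letters, as.character(0:9)), used)
  if (length(unique(p2$chain)) > length(pool))
    stop("not enough chain identifiers for the assembly copy")
  p2$chain <- pool[match(p2$chain, used)]
  both <- rbind(p1, p2)
  both$molecule_id <- assignMoleculeIds(both)
  box <- system@box
  if (length(box)) box[3] <- box[3] + zTop + gap
  new("MolecularSystem", particles = both, box = box,
      resolution = system@resolution)
}

#' Count lipid molecules in a structure
#'
#' The annular lipid census of a lipid-bridged crystal: the number of
#' distinct lipid molecules (all resolved lipids in such structures form
#' the annulus).
#'
#' @param system a \linkS4class{MolecularSystem}
#' @param scheme a \linkS4class{SegmentScheme} identifying lipid residues
#' @return integer count
#' @export
annularLipidCensus <- function(system, scheme) {
  ann <- classifyParticles(system, scheme)
  p <- ann@particles
  length(unique(p$molecule_id[p$role == "lipid"]))
}

#' Leaflet-to-leaflet phosphate (P-P) distance of one bilayer
#'
#' Mean phosphate z of the upper leaflet minus that of the lower leaflet,
#' the local bilayer thickness measure used for crystal lipid positions.
#'
#' @param frame an \linkS4class{AnnotatedSystem} containing one bilayer
#' @return P-P distance in Angstrom
#' @export
bilayerPPDistance <- function(frame) {
  lf <- assignLeaflets(frame)
  p <- frame@particles
  phos <- p$role == "lipid" & p$segment == "phosphate"
  z <- tapply(p$z[phos], p$molecule_id[phos], mean)
  leaf <- lf$leaflet[match(as.integer(names(z)), lf$molecule_id)]
  mean(z[leaf == "upper"]) - mean(z[leaf == "lower"])
}
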