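#' @include contacts.R
NULL

## backbone particle names (atomistic + coarse-grained) used to pick a
## side-chain reference for axial distributions
BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT", "BB")

## per-lipid mean phosphate z and the frame's midplane
phosphateZTable <- function(top, xyz, phosIdx) {
  z <- xyz[phosIdx, 3]
  mol <- top$molecule_id[phosIdx]
  zbar <- tapply(z, mol, mean)
  mid <- stats::median(z)
  list(mol = as.integer(names(zbar)), z = as.numeric(zbar), mid = mid)
}

#' Assign lipids to bilayer leaflets
#'
#' The midplane is the median z of all phosphate particles; each lipid is
#' assigned by the sign of its (mean) phosphate z relative to the
#' midplane.
#'
#' @param frame an \linkS4class{AnnotatedSystem}
#' @return data.frame(molecule_id, leaflet) with leaflet "upper"/"lower"
#' @export
assignLeaflets <- function(frame) {
  stopifnot(is(frame, "AnnotatedSystem"))
  p <- frame@particles
  phosIdx <- which(p$role == "lipid" & p$segment == "phosphate")
  if (length(unique(p$molecule_id[phosIdx])) < 2L)
    stop("need at least two lipids with phosphate particles")
  pt <- phosphateZTable(p, as.matrix(p[, c("x", "y", "z")]), phosIdx)
  if (all(pt$z == pt$mid))
    stop("all phosphates coplanar at the midplane; cannot assign leaflets")
  data.frame(molecule_id = pt$mol,
             leaflet = ifelse(pt$z >= pt$mid, "upper", "lower"),
             stringsAsFactors = FALSE)
}

## grid covering a point cloud; origin snapped to spacing multiples
gridFrame <- function(xy, spacing) {
  lo <- floor(apply(xy, 2, min) / spacing) * spacing
  hi <- apply(xy, 2, max)
  n <- pmax(1L, as.integer(floor((hi - lo) / spacing)) + 1L)
  list(origin = lo, nx = n[1], ny = n[2])
}

binIndex2d <- function(xy, origin, spacing, nx, ny) {
  ix <- pmin(nx, pmax(1L, as.integer(floor((xy[, 1] - origin[1]) /
                                           spacing)) + 1L))
  iy <- pmin(ny, pmax(1L, as.integer(floor((xy[, 2] - origin[2]) /
                                           spacing)) + 1L))
  cbind(ix, iy)
}

## gather aligned phosphate positions per analysed frame, split by leaflet
collectPhosphates <- function(traj, params) {
  top <- traj@topology
  if (!all(c("role", "segment") %in% names(top)))
    stop("trajectory must be classified first (see classifyParticles)")
  phosIdx <- which(top$role == "lipid" & top$segment == "phosphate")
  if (!length(phosIdx)) stop("no phosphate-labelled particles")
  frames <- windowFrames(nFrames(traj), params$window)
  off <- proteinXYOffsets(traj)
  out <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    f <- frames[k]
    xyz <- coords(traj, frame = f)
    pt <- phosphateZTable(top, xyz, phosIdx)
    up <- pt$mol[pt$z >= pt$mid]
    mol <- top$molecule_id[phosIdx]
    out[[k]] <- data.frame(
      frame = f,
      x = xyz[phosIdx, 1] - off[f, 1],
      y = xyz[phosIdx, 2] - off[f, 2],
      z = xyz[phosIdx, 3],
      zrel = xyz[phosIdx, 3] - pt$mid,
      leaflet = ifelse(mol %in% up, "upper", "lower"),
      stringsAsFactors = FALSE)
  }
  list(points = do.call(rbind, out), frames = frames, offsets = off)
}

#' In-plane phosphate density map of one leaflet
#'
#' 2D histogram of phosphate xy positions over the analysed frames, after
#' removing the protein's in-plane centre-of-geometry drift, normalised to
#' mean count per Angstrom^2 per frame. By construction the integral
#' (sum of values x spacing^2) equals the leaflet's mean per-frame
#' phosphate count.
#'
#' @param traj a classified \linkS4class{Trajectory}
#' @param leaflet "upper" or "lower"
#' @param spacing bin size in Angstrom (default 1, resolving single-lipid
#'   peaks)
#' @param params a [contactParams()] list (analysis window)
#' @return a \linkS4class{PlanarGrid} of kind "density"
#' @export
phosphateDensity <- function(traj, leaflet = c("upper", "lower"),
                             spacing = 1, params = contactParams()) {
  leaflet <- match.arg(leaflet)
  cp <- collectPhosphates(traj, params)
  pts <- cp$points[cp$points$leaflet == leaflet, , drop = FALSE]
  if (!nrow(pts)) stop("no phosphates in the ", leaflet, " leaflet")
  g <- gridFrame(cbind(pts$x, pts$y), spacing)
  idx <- binIndex2d(cbind(pts$x, pts$y), g$origin, spacing, g$nx, g$ny)
  counts <- matrix(0, g$nx, g$ny)
  tab <- table(factor(idx[, 1], levels = seq_len(g$nx)),
               factor(idx[, 2], levels = seq_len(g$ny)))
  counts[] <- as.numeric(tab)
  values <- counts / (length(cp$frames) * spacing^2)
  new("PlanarGrid", origin = as.numeric(g$origin), spacing = spacing,
      values = values, kind = "density")
}

#' Local bilayer thickness map with bulk and annular summaries
#'
#' Per xy-bin leaflet-to-leaflet phosphate distance (P-P distance): each
#' leaflet's z surface is the time-averaged mean phosphate z per bin, and
#' thickness is their difference; bins lacking samples in either leaflet
#' are NA. The annular summary averages bins whose centre lies within the
#' contact cutoff (6 Angstrom coarse-grained, 4 atomistic) of the protein
#' xy footprint; the bulk summary averages bins farther than
#' \code{bulkMargin} from it.
#'
#' @param traj a classified \linkS4class{Trajectory}
#' @param spacing bin size in Angstrom (default 2)
#' @param params a [contactParams()] list (window, cutoff override)
#' @param bulkMargin distance (Angstrom) beyond which bins count as bulk
#' @return a \linkS4class{ThicknessMap}
#' @export
thicknessMap <- function(traj, spacing = 2, params = contactParams(),
                         bulkMargin = 20) {
  cp <- collectPhosphates(traj, params)
  pts <- cp$points
  if (!any(pts$leaflet == "upper") || !any(pts$leaflet == "lower"))
    stop("both leaflets must be populated")
  g <- gridFrame(cbind(pts$x, pts$y), spacing)
  acc <- function(which) {
    p <- pts[pts$leaflet == which, , drop = FALSE]
    idx <- binIndex2d(cbind(p$x, p$y), g$origin, spacing, g$nx, g$ny)
    lin <- idx[, 1] + g$nx * (idx[, 2] - 1L)
    s <- matrix(0, g$nx, g$ny); n <- matrix(0, g$nx, g$ny)
    sz <- tapply(p$z, lin, sum)
    nz <- tapply(rep(1, nrow(p)), lin, sum)
    s[as.integer(names(sz))] <- sz
    n[as.integer(names(nz))] <- nz
    list(s = s, n = n)
  }
  up <- acc("upper"); lo <- acc("lower")
  thick <- matrix(NA_real_, g$nx, g$ny)
  ok <- up$n > 0 & lo$n > 0
  thick[ok] <- up$s[ok] / up$n[ok] - lo$s[ok] / lo$n[ok]
  thick[ok] <- abs(thick[ok])
  grid <- new("PlanarGrid", origin = as.numeric(g$origin),
              spacing = spacing, values = thick, kind = "thickness")
  ## protein footprint from the first analysed frame, same alignment
  top <- traj@topology
  pidx <- which(top$role == "protein")
  f1 <- cp$frames[1]
  pxy <- cbind(traj@coords[pidx, 1, f1] - cp$offsets[f1, 1],
               traj@coords[pidx, 2, f1] - cp$offsets[f1, 2])
  cx <- g$origin[1] + (seq_len(g$nx) - 0.5) * spacing
  cy <- g$origin[2] + (seq_len(g$ny) - 0.5) * spacing
  centers <- cbind(rep(cx, times = g$ny), rep(cy, each = g$nx))
  d2 <- outer(centers[, 1], pxy[, 1], "-")^2 +
    outer(centers[, 2], pxy[, 2], "-")^2
  dmin <- sqrt(apply(d2, 1, min))
  cutoff <- resolveCutoff(params, traj@resolution)
  annSel <- dmin <= cutoff & !is.na(as.vector(thick))
  bulkSel <- dmin > bulkMargin & !is.na(as.vector(thick))
  annular <- if (any(annSel)) mean(thick[annSel]) else {
    message("no bins qualify for the annular summary"); NA_real_
  }
  bulk <- if (any(bulkSel)) mean(thick[bulkSel]) else {
    message("no bins qualify for the bulk summary"); NA_real_
  }
  new("ThicknessMap", grid = grid, bulkThickness = bulk,
      annularThickness = annular, nBulkBins = sum(bulkSel),
      nAnnularBins = sum(annSel))
}

#' Axial (bilayer-normal) distribution of residue types
#'
#' Histogram of side-chain reference z positions (relative to the
#' per-frame bilayer midplane) for the requested residue types over the
#' analysed frames, with the head-group band (mean phosphate z +/- one sd
#' per leaflet) reported alongside. The side-chain reference is the
#' centroid of the residue's non-backbone heavy particles (the particle
#' itself for single-bead residues).
#'
#' @param traj a classified \linkS4class{Trajectory}
#' @param residueTypes three-letter codes, e.g. c("TRP","TYR","ARG","LYS")
#' @param binWidth histogram bin width in Angstrom
#' @param params a [contactParams()] list
#' @return an \linkS4class{AxialHistogram}
#' @export
axialDistribution <- function(traj,
                              residueTypes = c("TRP", "TYR", "ARG", "LYS"),
                              binWidth = 1, params = contactParams()) {
  stopifnot(all(residueTypes %in% AMINO3))
  top <- traj@topology
  if (!all(c("role", "segment") %in% names(top)))
    stop("trajectory must be classified first")
  phosIdx <- which(top$role == "lipid" & top$segment == "phosphate")
  frames <- windowFrames(nFrames(traj), params$window)
  prot <- which(top$role == "protein")
  rkey <- residueKey(top$chain[prot], top$resseq[prot], top$inscode[prot])
  rname <- top$resname[prot]
  heavy <- !isHydrogen(top$element[prot], top$name[prot])
  sidechain <- heavy & !top$name[prot] %in% BACKBONE_NAMES
  samples <- stats::setNames(vector("list", length(residueTypes)),
                             residueTypes)
  phosSamples <- list(upper = numeric(0), lower = numeric(0))
  for (ty in residueTypes) {
    sel <- rname == ty
    if (!any(sel)) {
      warning("residue type ", ty, " absent from the protein")
      samples[[ty]] <- numeric(0)
      next
    }
    ref <- prot[sel & sidechain]
    refKey <- rkey[sel & sidechain]
    if (!length(ref)) { ref <- prot[sel & heavy]; refKey <- rkey[sel & heavy] }
    zs <- numeric(0)
    for (f in frames) {
      xyz <- coords(traj, frame = f)
      mid <- stats::median(xyz[phosIdx, 3])
      zs <- c(zs, as.numeric(tapply(xyz[ref, 3], refKey, mean)) - mid)
    }
    samples[[ty]] <- zs
  }
  for (f in frames) {
    xyz <- coords(traj, frame = f)
    z <- xyz[phosIdx, 3]
    mid <- stats::median(z)
    phosSamples$upper <- c(phosSamples$upper, z[z >= mid] - mid)
    phosSamples$lower <- c(phosSamples$lower, z[z < mid] - mid)
  }
  all_z <- c(unlist(samples), unlist(phosSamples))
  lo <- floor(min(all_z) / binWidth) * binWidth
  hi <- ceiling(max(all_z) / binWidth + 1e-9) * binWidth
  breaks <- seq(lo, hi, by = binWidth)
  counts <- vapply(residueTypes, function(ty) {
    if (!length(samples[[ty]])) return(numeric(length(breaks) - 1L))
    graphics::hist(samples[[ty]], breaks = breaks, plot = FALSE)$counts
  }, numeric(length(breaks) - 1L))
  counts <- matrix(counts, ncol = length(residueTypes),
                   dimnames = list(NULL, residueTypes))
  band <- rbind(
    lower = mean(phosSamples$lower) + c(-1, 1) * stats::sd(phosSamples$lower),
    upper = mean(phosSamples$upper) + c(-1, 1) * stats::sd(phosSamples$upper))
  colnames(band) <- c("lo", "hi")
  new("AxialHistogram", breaks = breaks, counts = counts,
      headgroupBand = band)
}

#' Write / read a planar grid as plain text
#'
#' Three-line header (origin, spacing, kind) followed by the values matrix
#' (rows = x bins, tab-separated).
#'
#' @param grid a \linkS4class{PlanarGrid}
#' @param path output path
#' @export
writeGrid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# origin\t%.6g\t%.6g", grid@origin[1],
                       grid@origin[2]),
               sprintf("# spacing\t%.6g", grid@spacing),
               paste0("# kind\t", grid@kind)), con)
  utils::write.table(grid@values, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeGrid
#' @export
readGrid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- strsplit(lines[1:3], "\t")
  vals <- as.matrix(utils::read.table(text = lines[-(1:3)], sep = "\t"))
  dimnames(vals) <- NULL
  new("PlanarGrid",
      origin = as.numeric(c(hdr[[1]][2], hdr[[1]][3])),
      spacing = as.numeric(hdr[[2]][2]),
      values = vals, kind = hdr[[3]][2])
}
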