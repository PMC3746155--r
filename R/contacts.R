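#' @include neighbors.R scheme.R
NULL

#' Contact-analysis parameters
#'
#' @param cutoff contact distance in Angstrom; \code{NA} (default) selects
#'   the convention for the data's resolution: 4 for atomistic (heavy
#'   atoms), 6 for coarse-grained particles.
#' @param usePbc use minimum-image distances (requires a box).
#' @param window fractional analysis window \code{c(start, end)} of the
#'   trajectory; the default \code{c(0.2, 1)} discards the first fifth
#'   (e.g. the 0-200 ns equilibration of a 1 us run).
#' @param method neighbour search: "cell" (spatial index) or "brute".
#' @return a list of validated parameters
#' @export
contactParams <- function(cutoff = NA_real_, usePbc = FALSE,
                          window = c(0.2, 1), method = c("cell", "brute")) {
  method <- match.arg(method)
  stopifnot(is.na(cutoff) || cutoff > 0,
            length(window) == 2L, window[1] >= 0, window[2] <= 1,
            window[1] < window[2])
  structure(list(cutoff = cutoff, usePbc = usePbc, window = window,
                 method = method), class = "ContactParams")
}

resolveCutoff <- function(params, resolution) {
  if (is.na(params$cutoff)) defaultCutoff(resolution) else params$cutoff
}

## index bundle reused across frames of one classified topology
contactIndex <- function(top, resolution) {
  heavy <- if (resolution == "atomistic")
    !isHydrogen(top$element, top$name) else rep(TRUE, nrow(top))
  pidx <- which(top$role == "protein" & heavy)
  lidx <- which(top$role == "lipid" & heavy)
  if (!length(pidx)) stop("no protein particles after heavy-atom selection")
  keys <- residueKey(top$chain[pidx], top$resseq[pidx], top$inscode[pidx])
  resFac <- factor(keys, levels = unique(keys))
  first <- pidx[!duplicated(keys)]
  residues <- data.frame(chain = top$chain[first],
                         resseq = top$resseq[first],
                         inscode = top$inscode[first],
                         resname = top$resname[first],
                         key = unique(keys), stringsAsFactors = FALSE)
  list(pidx = pidx, lidx = lidx, resIdx = as.integer(resFac),
       residues = residues,
       lipidMol = top$molecule_id[lidx],
       segIdx = match(top$segment[lidx], SEGMENT_LEVELS),
       phosIdx = lidx[top$segment[lidx] == "phosphate"],
       phosMol = top$molecule_id[lidx][top$segment[lidx] == "phosphate"])
}

annotatedTopology <- function(x, scheme) {
  if (is(x, "Trajectory")) {
    if (!all(c("role", "segment") %in% names(x@topology))) {
      if (is.null(scheme))
        stop("trajectory is not classified; supply a SegmentScheme")
      x <- classifyParticles(x, scheme)
    }
    x
  } else {
    if (!is(x, "AnnotatedSystem")) {
      if (is.null(scheme))
        stop("system is not classified; supply a SegmentScheme")
      x <- classifyParticles(x, scheme)
    }
    x
  }
}

#' Protein-lipid contacts in one frame
#'
#' All (protein residue, lipid molecule, lipid segment) triples whose
#' minimum heavy-particle pair distance is within the cutoff. Atomistic
#' systems use heavy atoms only; coarse-grained systems use all particles.
#'
#' @param frame an \linkS4class{AnnotatedSystem} (see [classifyParticles()])
#' @param params a [contactParams()] list
#' @return data.frame(chain, resseq, inscode, residue_key, resname,
#'   lipid_id, segment, distance), one row per triple (minimum distance
#'   kept)
#' @export
frameContacts <- function(frame, params = contactParams()) {
  stopifnot(is(frame, "AnnotatedSystem"))
  p <- frame@particles
  cutoff <- resolveCutoff(params, frame@resolution)
  box <- if (params$usePbc) {
    if (!length(frame@box)) stop("usePbc requires a periodic box")
    frame@box
  } else NULL
  ci <- contactIndex(p, frame@resolution)
  xyz <- as.matrix(p[, c("x", "y", "z")])
  pairs <- neighborPairs(xyz[ci$pidx, , drop = FALSE],
                         xyz[ci$lidx, , drop = FALSE],
                         cutoff, box, params$method)
  reducePairs(pairs, ci)
}

## particle pairs -> unique (residue, lipid molecule, segment) triples
## with minimum distance
reducePairs <- function(pairs, ci) {
  res <- ci$resIdx[pairs$i]
  lip <- ci$lipidMol[pairs$j]
  seg <- ci$segIdx[pairs$j]
  key <- paste(res, lip, seg)
  ord <- order(key, pairs$dist)
  keep <- ord[!duplicated(key[ord])]
  r <- ci$residues[res[keep], , drop = FALSE]
  out <- data.frame(chain = r$chain, resseq = r$resseq,
                    inscode = r$inscode, residue_key = r$key,
                    resname = r$resname, lipid_id = lip[keep],
                    segment = SEGMENT_LEVELS[seg[keep]],
                    distance = pairs$dist[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$residue_key, out$lipid_id, out$segment), ]
  rownames(out) <- NULL
  out
}

profileFromCounts <- function(residues, segCount, headCount, tailCount,
                              nAnalyzed, sourceTag, scale) {
  res <- residues
  f <- segCount / nAnalyzed
  res$head_terminal <- f[, 1]; res$phosphate <- f[, 2]
  res$glycerol <- f[, 3]; res$tail <- f[, 4]
  res$headgroup_fraction <- headCount / nAnalyzed
  res$tail_fraction <- tailCount / nAnalyzed
  res$key <- NULL
  new("ContactProfile", residues = res, nFrames = as.integer(nAnalyzed),
      sourceTag = sourceTag, scale = scale)
}

#' Per-residue lipid contact frequency profile of a trajectory
#'
#' For every protein residue, the fraction of analysed frames in which the
#' residue has at least one lipid contact, decomposed by lipid segment and
#' by head-group class (terminal + phosphate + glycerol) vs tail class.
#' Frames outside the fractional analysis window are excluded.
#'
#' @param traj a classified \linkS4class{Trajectory} (or any trajectory
#'   plus a \code{scheme})
#' @param scheme a \linkS4class{SegmentScheme}, if \code{traj} is not yet
#'   classified
#' @param params a [contactParams()] list
#' @param sourceTag label recorded in the profile
#' @return a \linkS4class{ContactProfile}
#' @export
contactProfile <- function(traj, scheme = NULL, params = contactParams(),
                           sourceTag = "trajectory") {
  traj <- annotatedTopology(traj, scheme)
  top <- traj@topology
  cutoff <- resolveCutoff(params, traj@resolution)
  box <- if (params$usePbc) {
    if (!length(traj@box)) stop("usePbc requires a periodic box")
    traj@box
  } else NULL
  ci <- contactIndex(top, traj@resolution)
  frames <- windowFrames(nFrames(traj), params$window)
  nres <- nrow(ci$residues)
  segCount <- matrix(0L, nres, 4L)
  headCount <- integer(nres)
  tailCount <- integer(nres)
  for (f in frames) {
    P <- traj@coords[ci$pidx, , f, drop = FALSE]; dim(P) <- c(length(ci$pidx), 3L)
    L <- traj@coords[ci$lidx, , f, drop = FALSE]; dim(L) <- c(length(ci$lidx), 3L)
    pairs <- neighborPairs(P, L, cutoff, box, params$method)
    if (!nrow(pairs)) next
    res <- ci$resIdx[pairs$i]
    seg <- ci$segIdx[pairs$j]
    u <- !duplicated(paste(res, seg))
    segCount[cbind(res[u], seg[u])] <- segCount[cbind(res[u], seg[u])] + 1L
    headCount[unique(res[seg <= 3L])] <-
      headCount[unique(res[seg <= 3L])] + 1L
    tailCount[unique(res[seg == 4L])] <-
      tailCount[unique(res[seg == 4L])] + 1L
  }
  profileFromCounts(ci$residues, segCount, headCount, tailCount,
                    length(frames), sourceTag, "fraction")
}

#' 0/1 contact profile of a single (crystal) structure
#'
#' Single-frame profile whose fractions are presence/absence indicators of
#' a lipid contact in the structure, at the atomistic 4 Angstrom (or
#' coarse-grained 6 Angstrom) convention. Comparable to trajectory
#' profiles via [correlateProfiles()] (the mixed fraction/binary scale is
#' flagged there).
#'
#' @param structure an \linkS4class{AnnotatedSystem} containing lipids
#' @param params a [contactParams()] list
#' @param sourceTag label recorded in the profile
#' @return a \linkS4class{ContactProfile} with \code{scale = "binary"}
#' @export
crystalContactProfile <- function(structure, params = contactParams(),
                                  sourceTag = "crystal") {
  stopifnot(is(structure, "AnnotatedSystem"))
  if (!any(structure@particles$role == "lipid"))
    stop("structure contains no lipid molecules")
  ct <- frameContacts(structure, params)
  ci <- contactIndex(structure@particles, structure@resolution)
  nres <- nrow(ci$residues)
  segCount <- matrix(0L, nres, 4L)
  headCount <- integer(nres); tailCount <- integer(nres)
  if (nrow(ct)) {
    res <- match(ct$residue_key, ci$residues$key)
    seg <- match(ct$segment, SEGMENT_LEVELS)
    u <- !duplicated(paste(res, seg))
    segCount[cbind(res[u], seg[u])] <- 1L
    headCount[unique(res[seg <= 3L])] <- 1L
    tailCount[unique(res[seg == 4L])] <- 1L
  }
  profileFromCounts(ci$residues, segCount, headCount, tailCount, 1L,
                    sourceTag, "binary")
}

#' Average a contact profile over subunits
#'
#' Homo-oligomer profiles are computed per chain; for family-level
#' comparisons the per-chain fractions are averaged over chains at each
#' aligned residue number. Only residue numbers present in all chains are
#' kept.
#'
#' @param profile a \linkS4class{ContactProfile}
#' @return a \linkS4class{ContactProfile} with a single pseudo-chain "*"
#' @export
averageSubunits <- function(profile) {
  r <- profile@residues
  chains <- unique(r$chain)
  if (length(chains) == 1L) return(profile)
  key <- paste(r$resseq, r$inscode)
  keep <- names(which(table(unique(data.frame(key, r$chain))$key) ==
                      length(chains)))
  r <- r[key %in% keep, , drop = FALSE]
  key <- paste(r$resseq, r$inscode)
  num <- c(SEGMENT_LEVELS, "headgroup_fraction", "tail_fraction")
  agg <- aggregate(r[num], by = list(key = key), FUN = mean)
  first <- r[!duplicated(key), c("resseq", "inscode", "resname")]
  first <- first[match(agg$key, paste(first$resseq, first$inscode)), ]
  out <- data.frame(chain = "*", resseq = first$resseq,
                    inscode = first$inscode, resname = first$resname,
                    agg[num], stringsAsFactors = FALSE)
  out <- out[order(out$resseq, out$inscode), ]
  rownames(out) <- NULL
  new("ContactProfile", residues = out, nFrames = profile@nFrames,
      sourceTag = paste0(profile@sourceTag, "|subunit-mean"),
      scale = profile@scale)
}

#' Number of interacting lipids per frame
#'
#' A lipid counts in a frame iff at least one of its phosphate-labelled
#' particles lies within the cutoff of any protein particle (the
#' "phosphate within 6 Angstrom of the protein" convention for
#' coarse-grained data). Returns per-frame counts over the analysis window
#' and their mean.
#'
#' @param traj a classified \linkS4class{Trajectory} (or pass a scheme)
#' @param scheme optional \linkS4class{SegmentScheme}
#' @param params a [contactParams()] list
#' @return list(frames, counts, mean)
#' @export
interactingLipidCount <- function(traj, scheme = NULL,
                                  params = contactParams()) {
  traj <- annotatedTopology(traj, scheme)
  top <- traj@topology
  cutoff <- resolveCutoff(params, traj@resolution)
  box <- if (params$usePbc) traj@box else NULL
  ci <- contactIndex(top, traj@resolution)
  if (!length(ci$phosIdx)) stop("no phosphate-labelled particles")
  frames <- windowFrames(nFrames(traj), params$window)
  counts <- integer(length(frames))
  for (k in seq_along(frames)) {
    f <- frames[k]
    P <- traj@coords[ci$pidx, , f, drop = FALSE]; dim(P) <- c(length(ci$pidx), 3L)
    Q <- traj@coords[ci$phosIdx, , f, drop = FALSE]
    dim(Q) <- c(length(ci$phosIdx), 3L)
    pairs <- neighborPairs(P, Q, cutoff, box, params$method)
    counts[k] <- length(unique(ci$phosMol[pairs$j]))
  }
  list(frames = frames, counts = counts, mean = mean(counts))
}

#' Pearson correlation between two contact profiles
#'
#' Standard product-moment correlation over the per-residue fraction
#' vectors of the chosen channel. Residues not shared by both profiles
#' (e.g. unresolved termini) are dropped, not zero-filled; the number
#' dropped is reported as an attribute. Zero variance in either vector
#' yields NA with \code{attr(., "undefined") = TRUE} rather than NaN.
#' Correlating a trajectory profile against a crystal 0/1 profile is
#' permitted and flagged via \code{attr(., "mixed_scale")}.
#'
#' @param p1,p2 \linkS4class{ContactProfile}s
#' @param channel "headgroup" or "tail"
#' @return Pearson r (possibly NA), with attributes \code{n_shared},
#'   \code{n_dropped}, \code{mixed_scale}, and \code{undefined} when
#'   variance vanished
#' @export
correlateProfiles <- function(p1, p2, channel = c("headgroup", "tail")) {
  channel <- match.arg(channel)
  col <- paste0(channel, "_fraction")
  k1 <- residueKey(p1@residues$chain, p1@residues$resseq,
                   p1@residues$inscode)
  k2 <- residueKey(p2@residues$chain, p2@residues$resseq,
                   p2@residues$inscode)
  shared <- intersect(k1, k2)
  if (length(shared) < 3L)
    stop("need >= 3 shared residues to correlate (got ",
         length(shared), ")")
  x <- p1@residues[[col]][match(shared, k1)]
  y <- p2@residues[[col]][match(shared, k2)]
  dropped <- (length(k1) - length(shared)) + (length(k2) - length(shared))
  mixed <- !identical(p1@scale, p2@scale)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(NA_real_, undefined = TRUE, n_shared = length(shared),
                     n_dropped = dropped, mixed_scale = mixed))
  structure(stats::cor(x, y), undefined = FALSE,
            n_shared = length(shared), n_dropped = dropped,
            mixed_scale = mixed)
}

#' Correlation matrix across contact profiles
#'
#' Pairwise Pearson r between profiles: head-group channel in the upper
#' triangle, tail channel in the lower triangle (the split used in
#' published contact-correlation tables), diagonal 1.
#'
#' @param profiles list of \linkS4class{ContactProfile}s (names taken from
#'   sourceTags if unnamed)
#' @return square numeric matrix
#' @export
correlationMatrix <- function(profiles) {
  stopifnot(length(profiles) >= 2L)
  tags <- names(profiles)
  if (is.null(tags))
    tags <- vapply(profiles, function(p) p@sourceTag, "")
  n <- length(profiles)
  m <- diag(1, n)
  dimnames(m) <- list(tags, tags)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    m[i, j] <- as.numeric(correlateProfiles(profiles[[i]], profiles[[j]],
                                            "headgroup"))
    m[j, i] <- as.numeric(correlateProfiles(profiles[[j]], profiles[[i]],
                                            "tail"))
  }
  m
}

#' Write / read a contact profile as a tab-separated table
#'
#' @param profile a \linkS4class{ContactProfile}
#' @param path TSV path
#' @export
writeProfile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# source_tag\t", profile@sourceTag),
               paste0("# n_frames\t", profile@nFrames),
               paste0("# scale\t", profile@scale)), con)
  utils::write.table(profile@residues, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeProfile
#' @param path TSV path written by [writeProfile()]
#' @export
readProfile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- strsplit(sub("^# ", "", hdr), "\t")
  meta <- stats::setNames(vapply(meta, `[`, "", 2),
                          vapply(meta, `[`, "", 1))
  body <- utils::read.table(text = lines[!grepl("^#", lines)],
                            header = TRUE, sep = "\t",
                            colClasses = c(chain = "character",
                                           inscode = "character",
                                           resname = "character"))
  body$inscode[is.na(body$inscode)] <- ""
  new("ContactProfile", residues = body,
      nFrames = as.integer(meta[["n_frames"]]),
      sourceTag = meta[["source_tag"]], scale = meta[["scale"]])
}
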