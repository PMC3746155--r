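#' @include AllClasses.R utils.R
NULL

#' Read a lipid segment-classification scheme
#'
#' Plain-text format, one rule per line ('#' starts a comment):
#' \preformatted{
#'   <residue> <particle> <segment>   # segment in head_terminal/phosphate/
#'                                    #   glycerol/tail
#'   alias <old> <new>                # residue-name dialect, e.g. DMP -> DMPC
#'   role <residue> <role>            # protein/lipid/solvent/other override
#' }
#'
#' @param path scheme file
#' @return a \linkS4class{SegmentScheme}
#' @export
readSegmentScheme <- function(path) {
  if (!file.exists(path)) stop("scheme file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  seg <- list(); roles <- character(0); aliases <- character(0)
  for (i in seq_along(lines)) {
    tok <- strsplit(lines[i], "\\s+")[[1]]
    if (tok[1] == "alias") {
      if (length(tok) != 3L) stop("bad alias line in scheme: ", lines[i])
      aliases[tok[2]] <- tok[3]
    } else if (tok[1] == "role") {
      if (length(tok) != 3L || !tok[3] %in% ROLE_LEVELS)
        stop("bad role line in scheme: ", lines[i])
      roles[tok[2]] <- tok[3]
    } else {
      if (length(tok) != 3L || !tok[3] %in% SEGMENT_LEVELS)
        stop("bad segment line in scheme (expect 'residue particle ",
             "segment'): ", lines[i])
      seg[[length(seg) + 1L]] <- tok
    }
  }
  segments <- if (length(seg))
    data.frame(resname = vapply(seg, `[`, "", 1),
               particle = vapply(seg, `[`, "", 2),
               segment = vapply(seg, `[`, "", 3),
               stringsAsFactors = FALSE)
  else data.frame(resname = character(0), particle = character(0),
                  segment = character(0))
  new("SegmentScheme", segments = segments, roles = roles,
      aliases = aliases)
}

#' Construct a SegmentScheme in code
#'
#' @param resname,particle,segment parallel vectors of classification rules
#' @param roles named character (residue -> role), optional
#' @param aliases named character (old -> new residue name), optional
#' @export
segmentScheme <- function(resname, particle, segment,
                          roles = character(0), aliases = character(0)) {
  new("SegmentScheme",
      segments = data.frame(resname = resname, particle = particle,
                            segment = segment, stringsAsFactors = FALSE),
      roles = roles, aliases = aliases)
}

#' Load a bundled segment scheme
#'
#' Schemes shipped with the package: \code{"martini"} (coarse-grained
#' DMPC/DPPC/DSPE with MARTINI-style particle names, also covering the
#' synthetic generator's lipids) and \code{"atomistic"} (heavy-atom
#' DMPC/DPPC/DSPE naming as found in crystal structures).
#'
#' @param name "martini" or "atomistic"
#' @export
bundledScheme <- function(name = c("martini", "atomistic")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".scheme"),
                      package = "lipidprint", mustWork = TRUE)
  readSegmentScheme(path)
}

resolveAliases <- function(resname, scheme) {
  if (!length(scheme@aliases)) return(resname)
  hit <- match(resname, names(scheme@aliases))
  ifelse(is.na(hit), resname, unname(scheme@aliases[hit]))
}

annotateParticleTable <- function(p, scheme, requirePhosphate = TRUE) {
  canon <- resolveAliases(p$resname, scheme)
  role <- rep(NA_character_, nrow(p))
  lipid_names <- unique(scheme@segments$resname)
  role[canon %in% lipid_names] <- "lipid"
  role[canon %in% AMINO3] <- "protein"
  role[canon %in% WATER_NAMES] <- "solvent"
  if (length(scheme@roles)) {
    hit <- match(canon, names(scheme@roles))
    role[!is.na(hit)] <- unname(scheme@roles[hit[!is.na(hit)]])
  }
  if (anyNA(role))
    stop("residue name(s) not covered by the scheme: ",
         paste(sort(unique(canon[is.na(role)])), collapse = ", "),
         " (add segment rules, an alias, or a role line)")
  segment <- rep(NA_character_, nrow(p))
  lip <- which(role == "lipid")
  if (length(lip)) {
    skey <- paste(scheme@segments$resname, scheme@segments$particle)
    hit <- match(paste(canon[lip], p$name[lip]), skey)
    if (anyNA(hit)) {
      miss <- unique(paste0(canon[lip], ":", p$name[lip])[is.na(hit)])
      stop("lipid particle(s) not in scheme: ",
           paste(sort(miss), collapse = ", "))
    }
    segment[lip] <- scheme@segments$segment[hit]
    ## the phosphate is the reference particle everywhere downstream
    if (requirePhosphate) {
      has_p <- tapply(segment[lip] == "phosphate", p$molecule_id[lip], any)
      if (!all(has_p))
        stop("lipid molecule(s) with no phosphate-labelled particle: ",
             "molecule_id ", paste(names(has_p)[!has_p], collapse = ", "))
    }
  }
  p$role <- role
  p$segment <- segment
  p
}

#' @describeIn classifyParticles annotate one frame. Set
#'   \code{requirePhosphate = FALSE} to accept lipid molecules whose
#'   phosphate particle is unresolved (phosphate-based analyses will then
#'   refuse them later).
#' @param requirePhosphate error when a lipid molecule lacks a
#'   phosphate-labelled particle (default TRUE; the phosphate is the
#'   reference particle for leaflets, density, thickness and counts)
#' @export
setMethod("classifyParticles", signature("MolecularSystem", "SegmentScheme"),
  function(x, scheme, requirePhosphate = TRUE) {
    new("AnnotatedSystem",
        particles = annotateParticleTable(x@particles, scheme,
                                          requirePhosphate),
        box = x@box, resolution = x@resolution)
  })

#' @describeIn classifyParticles annotate a trajectory's shared topology
#' @export
setMethod("classifyParticles", signature("Trajectory", "SegmentScheme"),
  function(x, scheme, requirePhosphate = TRUE) {
    x@topology <- annotateParticleTable(x@topology, scheme,
                                        requirePhosphate)
    x
  })
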