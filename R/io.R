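#' @include utils.R
NULL

## molecule partition: each protein chain is one molecule, every other
## residue (lipid, water, ligand) its own molecule
assignMoleculeIds <- function(df) {
  is_prot <- df$resname %in% AMINO3
  key <- ifelse(is_prot,
                paste0("P|", df$chain),
                paste0("M|", df$chain, "|", df$resname, "|", df$resseq, "|",
                       ifelse(is.na(df$inscode), "", df$inscode)))
  as.integer(factor(key, levels = unique(key)))
}

parseCryst1 <- function(lines) {
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cl)) return(numeric(0))
  cl <- cl[1]
  abc <- as.numeric(c(substr(cl, 7, 15), substr(cl, 16, 24),
                      substr(cl, 25, 33)))
  ang <- suppressWarnings(as.numeric(c(substr(cl, 34, 40),
                                       substr(cl, 41, 47),
                                       substr(cl, 48, 54))))
  if (anyNA(abc)) stop("malformed CRYST1 record in PDB file")
  ## the conventional placeholder cell (1 A cube) means "no box"
  if (all(abc == 1)) return(numeric(0))
  if (any(!is.na(ang) & abs(ang - 90) > 1e-6))
    stop("triclinic box (angles != 90 degrees) not supported; ",
         "orthorhombic boxes only")
  abc
}

cryst1Line <- function(box) {
  sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
          box[1], box[2], box[3], 90, 90, 90)
}

pdbAtomTable <- function(pdb) {
  a <- pdb$atom
  data.frame(name = trimws(a$elety),
             resname = trimws(a$resid),
             resseq = as.integer(a$resno),
             inscode = ifelse(is.na(a$insert), "", a$insert),
             chain = ifelse(is.na(a$chain), "A", a$chain),
             molecule_id = NA_integer_,
             element = ifelse(is.na(a$elesy), "", trimws(a$elesy)),
             x = a$x, y = a$y, z = a$z,
             stringsAsFactors = FALSE)
}

## drop all but the first-seen alternate location of each atom
dropAltlocs <- function(df) {
  key <- paste(df$chain, df$resseq, df$inscode, df$name, sep = "|")
  df[!duplicated(key), , drop = FALSE]
}

guessFormat <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("pdb", "ent")) "pdb"
  else if (ext == "gro") "gro"
  else stop("cannot guess format from extension '", ext,
            "'; pass format = \"pdb\" or \"gro\"")
}

#' Read a molecular structure (PDB or GRO)
#'
#' Reads one structure into a \linkS4class{MolecularSystem}. Alternate
#' locations are resolved deterministically (the first-seen altloc of each
#' atom is kept); molecule ids are assigned so that each protein chain and
#' each lipid/heteromolecule residue is a distinct molecule. Orthorhombic
#' boxes are read from CRYST1 (PDB) or the box vector line (GRO);
#' triclinic cells are rejected.
#'
#' @param path file path
#' @param format "pdb", "gro" or "auto" (by extension)
#' @param resolution resolution tag to attach ("atomistic" default;
#'   "coarse_grained" selects the 6 Angstrom contact convention downstream)
#' @return a \linkS4class{MolecularSystem}
#' @export
readStructure <- function(path, format = c("auto", "pdb", "gro"),
                          resolution = "atomistic") {
  format <- match.arg(format)
  if (format == "auto") format <- guessFormat(path)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("empty file: ", path)
  if (format == "pdb") {
    lines <- readLines(path, warn = FALSE)
    box <- parseCryst1(lines)
    pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                    verbose = FALSE),
                    error = function(e)
                      stop("failed to parse PDB file '", path, "': ",
                           conditionMessage(e)))
    df <- dropAltlocs(pdbAtomTable(pdb))
  } else {
    g <- readGroFile(path)
    df <- g$atoms
    box <- g$box
  }
  if (!nrow(df)) stop("no atom records in ", path)
  df$molecule_id <- assignMoleculeIds(df)
  rownames(df) <- NULL
  new("MolecularSystem", particles = df, box = box, resolution = resolution)
}

## GRO fixed-format reader (coordinates stored in nm, returned in Angstrom)
readGroFile <- function(path, skip = 0L) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) stop("GRO file too short: ", path)
  nat <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(nat) || nat < 1L)
    stop("GRO line 2 must be the atom count (file ", path, ")")
  if (length(lines) < 2L + nat + 1L)
    stop("GRO file truncated: expected ", nat, " atom lines (file ",
         path, ")")
  al <- lines[3:(2 + nat)]
  num <- function(from, to, what, ln) {
    v <- suppressWarnings(as.numeric(substr(al, from, to)))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop("malformed GRO record at line ", 2L + bad[1],
           " (field ", what, ") in ", path)
    v
  }
  resseq <- as.integer(num(1, 5, "resseq"))
  resname <- trimws(substr(al, 6, 10))
  name <- trimws(substr(al, 11, 15))
  x <- num(21, 28, "x") * 10
  y <- num(29, 36, "y") * 10
  z <- num(37, 44, "z") * 10
  bl <- strsplit(trimws(lines[2L + nat + 1L]), "\\s+")[[1]]
  bv <- suppressWarnings(as.numeric(bl))
  if (anyNA(bv)) stop("malformed box line in GRO file ", path)
  if (length(bv) >= 9 && any(abs(bv[4:9]) > 1e-9))
    stop("triclinic box not supported; orthorhombic boxes only (", path, ")")
  box <- if (all(bv[1:3] == 0)) numeric(0) else bv[1:3] * 10
  atoms <- data.frame(name = name, resname = resname, resseq = resseq,
                      inscode = "", chain = "A",
                      molecule_id = NA_integer_, element = "",
                      x = x, y = y, z = z, stringsAsFactors = FALSE)
  list(atoms = atoms, box = box)
}

writeGroFile <- function(system, path, title = "written by lipidprint") {
  p <- system@particles
  lines <- c(title, sprintf("%5d", nrow(p)))
  atomno <- seq_len(nrow(p)) %% 100000L
  lines <- c(lines, sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                            p$resseq %% 100000L, substr(p$resname, 1, 5),
                            substr(p$name, 1, 5), atomno,
                            p$x / 10, p$y / 10, p$z / 10))
  box <- if (length(system@box)) system@box / 10 else c(0, 0, 0)
  lines <- c(lines, sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]))
  writeLines(lines, path)
  invisible(path)
}

writePdbFile <- function(system, path, xyzMulti = NULL, b = NULL) {
  p <- system@particles
  if (is.null(b)) b <- rep(0, nrow(p))
  xyz <- if (is.null(xyzMulti))
    matrix(as.numeric(t(as.matrix(p[, c("x", "y", "z")]))), nrow = 1)
  else xyzMulti
  if (length(system@box)) {
    writeLines(cryst1Line(system@box), path)
    append <- TRUE
  } else append <- FALSE
  bio3d::write.pdb(file = path, xyz = xyz, resno = p$resseq,
                   resid = p$resname, eleno = seq_len(nrow(p)),
                   elety = p$name, chain = p$chain,
                   insert = ifelse(p$inscode == "", NA, p$inscode),
                   b = b, elesy = ifelse(p$element == "", NA, p$element),
                   o = rep(1, nrow(p)), append = append)
  invisible(path)
}

#' Write a structure (PDB or GRO)
#'
#' @param system a \linkS4class{MolecularSystem}
#' @param path output path
#' @param format "pdb", "gro" or "auto" (by extension)
#' @export
writeStructure <- function(system, path, format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  if (format == "auto") format <- guessFormat(path)
  if (format == "pdb") writePdbFile(system, path)
  else writeGroFile(system, path)
}

#' Read a trajectory (multi-model PDB or a sequence of GRO files)
#'
#' All frames must share one topology (same particle count and identity).
#'
#' @param paths one multi-model PDB path, or a character vector of GRO
#'   (or single-model PDB) paths taken in the given order
#' @param format "pdb", "gro" or "auto"
#' @param resolution resolution tag ("atomistic" or "coarse_grained")
#' @param times optional frame times in ns (strictly increasing)
#' @return a \linkS4class{Trajectory}
#' @export
readTrajectory <- function(paths, format = c("auto", "pdb", "gro"),
                           resolution = "atomistic", times = numeric(0)) {
  format <- match.arg(format)
  if (format == "auto") format <- guessFormat(paths[1])
  if (length(paths) == 1L && format == "pdb") {
    lines <- readLines(paths, warn = FALSE)
    box <- parseCryst1(lines)
    pdb <- tryCatch(bio3d::read.pdb(paths, multi = TRUE, rm.alt = FALSE,
                                    verbose = FALSE),
                    error = function(e)
                      stop("failed to parse PDB file '", paths, "': ",
                           conditionMessage(e)))
    full <- pdbAtomTable(pdb)
    keep <- !duplicated(paste(full$chain, full$resseq, full$inscode,
                              full$name, sep = "|"))
    df <- full[keep, , drop = FALSE]
    xyz <- pdb$xyz
    nf <- nrow(xyz)
    np <- ncol(xyz) / 3L
    arr <- array(NA_real_, c(sum(keep), 3L, nf))
    for (f in seq_len(nf)) {
      m <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
      arr[, , f] <- m[keep, , drop = FALSE]
    }
    df$molecule_id <- assignMoleculeIds(df)
    top <- df[, setdiff(names(df), c("x", "y", "z"))]
    rownames(top) <- NULL
  } else {
    systems <- lapply(paths, readStructure, format = format,
                      resolution = resolution)
    np <- nParticles(systems[[1]])
    for (f in seq_along(systems))
      if (nParticles(systems[[f]]) != np)
        stop("frame ", f, " has ", nParticles(systems[[f]]),
             " particles; expected ", np, " (topology mismatch)")
    id1 <- systems[[1]]@particles[, c("name", "resname", "resseq", "chain")]
    for (f in seq_along(systems))
      if (!identical(systems[[f]]@particles[, c("name", "resname",
                                                "resseq", "chain")], id1))
        stop("frame ", f, " differs in particle identity (topology mismatch)")
    arr <- array(NA_real_, c(np, 3L, length(systems)))
    for (f in seq_along(systems)) arr[, , f] <- coords(systems[[f]])
    top <- systems[[1]]@particles[, setdiff(PARTICLE_COLS, c("x", "y", "z"))]
    box <- systems[[1]]@box
  }
  new("Trajectory", topology = top, coords = arr, box = box,
      times = as.numeric(times), resolution = resolution)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj a \linkS4class{Trajectory}
#' @param path output path
#' @export
writeTrajectory <- function(traj, path) {
  np <- nParticles(traj)
  nf <- nFrames(traj)
  xyz <- matrix(NA_real_, nf, 3L * np)
  for (f in seq_len(nf))
    xyz[f, ] <- as.numeric(t(coords(traj, frame = f)))
  sys <- getFrame(traj, 1L)
  writePdbFile(sys, path, xyzMulti = xyz)
  invisible(path)
}

#' Write per-residue values into the B-factor column of a PDB
#'
#' Every atom's B-factor is set to its residue's value (clipped to
#' [0, 999.99], fixed two-decimal formatting), the convention used to
#' colour contact frequencies onto a structure with a white-to-red
#' gradient in molecular viewers. Residues absent from \code{values}
#' default to 0.
#'
#' @param system a \linkS4class{MolecularSystem}
#' @param values named numeric vector keyed by residue key
#'   ("chain:resseq", see [residueKeys()]), or a data.frame with columns
#'   chain, resseq and value
#' @param path output PDB path
#' @export
writeBfactorPdb <- function(system, values, path) {
  p <- system@particles
  if (is.data.frame(values)) {
    v <- values$value
    names(v) <- residueKey(values$chain, values$resseq,
                           if ("inscode" %in% names(values))
                             values$inscode else "")
    values <- v
  }
  if (!all(is.finite(values))) stop("B-factor values must be finite")
  keys <- residueKey(p$chain, p$resseq, p$inscode)
  b <- unname(values[keys])
  b[is.na(b)] <- 0
  b <- pmin(pmax(b, 0), 999.99)
  writePdbFile(system, path, b = b)
}

#' Residue keys of a system
#'
#' The "chain:resseq[inscode]" strings keying per-residue values, in
#' particle-table order (one per residue).
#' @param system a \linkS4class{MolecularSystem}
#' @export
residueKeys <- function(system) {
  p <- system@particles
  unique(residueKey(p$chain, p$resseq, p$inscode))
}
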