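#' @include AllClasses.R
NULL

AMINO3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
            "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
            "TYR", "VAL")
AMINO1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
            "I", "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
names(AMINO1) <- AMINO3

WATER_NAMES <- c("HOH", "WAT", "SOL", "W", "TIP3", "TIP4", "SPC")

aa3to1 <- function(resname) {
  out <- AMINO1[toupper(resname)]
  out[is.na(out)] <- "X"
  unname(out)
}

## residue key: chain + resseq (+ insertion code when present), the
## convention used throughout for matching residues across profiles
residueKey <- function(chain, resseq, inscode = "") {
  ins <- ifelse(is.na(inscode) | inscode == "", "", inscode)
  paste0(chain, ":", resseq, ins)
}

## hydrogen test from the element column (falling back to the name with
## leading digits stripped, per PDB conventions)
isHydrogen <- function(element, name) {
  el <- toupper(ifelse(is.na(element) | element == "",
                       substr(sub("^[0-9]+", "", name), 1, 1), element))
  el == "H"
}

## frames inside the fractional analysis window (start_frac, end_frac]:
## frame i is analysed iff start_frac < i/n <= end_frac
windowFrames <- function(n, window = c(0.2, 1)) {
  stopifnot(length(window) == 2L, window[1] >= 0, window[2] <= 1,
            window[1] < window[2])
  i <- seq_len(n)
  keep <- i[(i / n) > window[1] & (i / n) <= window[2] + 1e-12]
  if (!length(keep))
    stop("analysis window [", window[1], ", ", window[2],
         "] contains no frames (n = ", n, ")")
  keep
}

## minimum-image displacement components for an orthorhombic box
minImage <- function(d, box) d - box * round(d / box)

## run a block with a private, restored RNG stream
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## per-frame xy offsets of the protein centre of geometry; used to align
## frames before any in-plane gridding or tracing
proteinXYOffsets <- function(traj) {
  top <- traj@topology
  if (!"role" %in% names(top))
    stop("trajectory must be classified before alignment (see classifyParticles)")
  idx <- which(top$role == "protein")
  if (!length(idx)) stop("no protein particles in trajectory")
  nf <- nFrames(traj)
  off <- matrix(0, nf, 2)
  for (f in seq_len(nf)) {
    off[f, 1] <- mean(traj@coords[idx, 1, f])
    off[f, 2] <- mean(traj@coords[idx, 2, f])
  }
  off
}

## default contact cutoff by resolution: 4 A atomistic, 6 A coarse-grained
defaultCutoff <- function(resolution) {
  switch(resolution, atomistic = 4.0, coarse_grained = 6.0,
         stop("unknown resolution tag: ", resolution))
}

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " must be finite")
  invisible(x)
}
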