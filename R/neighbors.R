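#' @include utils.R
NULL

## squared distances between two coordinate sets, optionally under
## minimum-image convention; the single arithmetic path shared by the
## brute-force and cell-list searches so their results are bit-identical
pairDist2 <- function(A, B, box = NULL) {
  d2 <- 0
  for (k in 1:3) {
    d <- outer(A[, k], B[, k], "-")
    if (!is.null(box)) d <- d - box[k] * round(d / box[k])
    d2 <- d2 + d * d
  }
  d2
}

bruteNeighbors <- function(A, B, cutoff, box = NULL) {
  if (!nrow(A) || !nrow(B))
    return(data.frame(i = integer(0), j = integer(0), dist = numeric(0)))
  d2 <- pairDist2(A, B, box)
  hit <- which(d2 <= cutoff * cutoff, arr.ind = TRUE)
  data.frame(i = hit[, 1], j = hit[, 2],
             dist = sqrt(d2[hit]))
}

## cell-list neighbour search: bin particles into cells of edge >= cutoff,
## examine only the 27 neighbouring cells of each occupied query cell
cellNeighbors <- function(A, B, cutoff, box = NULL) {
  if (!nrow(A) || !nrow(B))
    return(data.frame(i = integer(0), j = integer(0), dist = numeric(0)))
  if (is.null(box)) {
    lo <- pmin(apply(A, 2, min), apply(B, 2, min))
    hi <- pmax(apply(A, 2, max), apply(B, 2, max))
    nc <- pmax(1L, as.integer(ceiling((hi - lo + 1e-9) / cutoff)))
    cellOf <- function(M) {
      ci <- matrix(0L, nrow(M), 3)
      for (k in 1:3)
        ci[, k] <- pmin(nc[k] - 1L,
                        as.integer(floor((M[, k] - lo[k]) / cutoff)))
      ci
    }
  } else {
    nc <- pmax(1L, as.integer(floor(box / cutoff)))
    cs <- box / nc
    cellOf <- function(M) {
      ci <- matrix(0L, nrow(M), 3)
      for (k in 1:3) {
        w <- M[, k] - box[k] * floor(M[, k] / box[k])  # wrap into [0, box)
        ci[, k] <- pmin(nc[k] - 1L, as.integer(floor(w / cs[k])))
      }
      ci
    }
  }
  keyOf <- function(ci) ci[, 1] + nc[1] * (ci[, 2] + nc[2] * ci[, 3])
  ca <- cellOf(A); cb <- cellOf(B)
  kb <- keyOf(cb)
  bByCell <- split(seq_len(nrow(B)), kb)
  ka <- keyOf(ca)
  offs <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  out_i <- list(); out_j <- list(); out_d <- list(); nout <- 0L
  for (cell in split(seq_len(nrow(A)), ka)) {
    cc <- ca[cell[1], ]
    nbx <- cc[1] + offs[, 1]; nby <- cc[2] + offs[, 2]
    nbz <- cc[3] + offs[, 3]
    if (!is.null(box)) {
      nbx <- nbx %% nc[1]; nby <- nby %% nc[2]; nbz <- nbz %% nc[3]
    } else {
      ok <- nbx >= 0 & nbx < nc[1] & nby >= 0 & nby < nc[2] &
        nbz >= 0 & nbz < nc[3]
      nbx <- nbx[ok]; nby <- nby[ok]; nbz <- nbz[ok]
    }
    keys <- unique(nbx + nc[1] * (nby + nc[2] * nbz))
    cand <- unlist(bByCell[as.character(keys)], use.names = FALSE)
    if (!length(cand)) next
    d2 <- pairDist2(A[cell, , drop = FALSE], B[cand, , drop = FALSE], box)
    hit <- which(d2 <= cutoff * cutoff, arr.ind = TRUE)
    if (!nrow(hit)) next
    nout <- nout + 1L
    out_i[[nout]] <- cell[hit[, 1]]
    out_j[[nout]] <- cand[hit[, 2]]
    out_d[[nout]] <- sqrt(d2[hit])
  }
  if (!nout)
    return(data.frame(i = integer(0), j = integer(0), dist = numeric(0)))
  data.frame(i = unlist(out_i), j = unlist(out_j), dist = unlist(out_d))
}

#' Neighbour pairs between two particle sets
#'
#' All pairs (one from \code{A}, one from \code{B}) within \code{cutoff},
#' using minimum-image distances when a box is given. The default cell
#' list and the all-pairs reference give bit-identical results; the brute
#' path is kept as the oracle for property tests.
#'
#' @param A,B n x 3 coordinate matrices (Angstrom)
#' @param cutoff distance cutoff (Angstrom)
#' @param box orthorhombic box lengths, or NULL for no periodicity
#' @param method "cell" (spatial index) or "brute" (all pairs)
#' @return data.frame(i, j, dist) of row indices into A and B
#' @export
neighborPairs <- function(A, B, cutoff, box = NULL,
                          method = c("cell", "brute")) {
  method <- match.arg(method)
  stopifnot(cutoff > 0)
  if (!is.null(box) && length(box) == 0L) box <- NULL
  if (!is.null(box) && any(box < 2 * cutoff) && method == "cell")
    method <- "brute"  # minimum image needs >= 2 cells per dimension
  if (method == "brute") bruteNeighbors(A, B, cutoff, box)
  else cellNeighbors(A, B, cutoff, box)
}
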