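#' @include contacts.R
NULL

#' Residue-type x lipid-segment interaction table
#'
#' Aggregates per-segment contact fractions over many systems: the raw
#' score of (type, segment) is the sum of that segment's contact fraction
#' over all residues of the type; it is normalised by the type's
#' occurrence (its residue count across the input structures, so abundant
#' types are not over-weighted), then each segment column is rescaled to
#' percentages summing to 100.
#'
#' @param profiles list of \linkS4class{ContactProfile}s
#' @param systems matching list of \linkS4class{MolecularSystem}s (or
#'   \linkS4class{Trajectory}s) from which the profiles were computed;
#'   used to count residue-type occurrence
#' @param weighting "fraction" (time-weighted contribution, default) or
#'   "binary" (a residue contributes 1 if it ever contacts the segment)
#' @return a \linkS4class{SegmentInteractionTable}
#' @export
segmentInteractionFrequencies <- function(profiles, systems,
                                          weighting = c("fraction",
                                                        "binary")) {
  weighting <- match.arg(weighting)
  stopifnot(length(profiles) >= 1L, length(profiles) == length(systems))
  residueTypesOf <- function(s) {
    p <- if (is(s, "Trajectory")) s@topology else s@particles
    prot <- p$resname %in% AMINO3
    keys <- residueKey(p$chain[prot], p$resseq[prot], p$inscode[prot])
    p$resname[prot][!duplicated(keys)]
  }
  occ_list <- lapply(systems, residueTypesOf)
  occurrence <- table(unlist(occ_list))
  prof_types <- unique(unlist(lapply(profiles,
                                     function(p) p@residues$resname)))
  prof_types <- intersect(prof_types, AMINO3)
  missing <- setdiff(prof_types, names(occurrence))
  if (length(missing))
    stop("residue type(s) in profiles but absent from systems: ",
         paste(missing, collapse = ", "))
  types <- sort(unique(names(occurrence)))
  raw <- matrix(0, length(types), 4L,
                dimnames = list(types, SEGMENT_LEVELS))
  for (p in profiles) {
    r <- p@residues
    r <- r[r$resname %in% types, , drop = FALSE]
    for (seg in SEGMENT_LEVELS) {
      v <- r[[seg]]
      if (weighting == "binary") v <- as.numeric(v > 0)
      s <- tapply(v, factor(r$resname, levels = types), sum, default = 0)
      raw[, seg] <- raw[, seg] + as.numeric(s)
    }
  }
  norm <- raw / as.numeric(occurrence[types])
  pct <- apply(norm, 2, function(col) {
    tot <- sum(col)
    if (tot == 0) col else 100 * col / tot
  })
  occ <- as.integer(occurrence[types])
  names(occ) <- types
  new("SegmentInteractionTable", percentages = pct, occurrence = occ,
      weighting = weighting)
}

#' Write a segment-interaction table as TSV
#' @param table a \linkS4class{SegmentInteractionTable}
#' @param path output path
#' @export
writeSegmentTable <- function(table, path) {
  df <- data.frame(type = rownames(table@percentages),
                   table@percentages,
                   occurrence = table@occurrence[rownames(table@percentages)])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
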